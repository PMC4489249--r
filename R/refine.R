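# Refinement stage: filtering of redundant and overlapping interactions.
# Refinement never adds records and never edits measurements; applying it
# twice equals applying it once.

#' Reduce hydrophobic contacts to the most relevant ones
#'
#' Keeps, for each ligand atom, only its nearest protein partner among the
#' contacts sharing that ligand atom; then, for each surviving protein
#' atom, only its nearest ligand partner. Distance ties are broken by the
#' lower protein atom serial in the first pass and the lower ligand atom
#' serial in the second, so the result is deterministic. Afterwards no
#' ligand atom and no protein atom takes part in more than one contact.
#'
#' @param contacts List of hydrophobic `ligprof_interaction` records.
#' @return Filtered subset of `contacts`.
#' @export
reduce_hydrophobic <- function(contacts) {
  if (length(contacts) == 0) return(contacts)
  types <- vapply(contacts, function(x) x$type, character(1))
  if (any(types != "hydrophobic")) {
    stop("reduce_hydrophobic expects only hydrophobic contacts")
  }
  df <- data.frame(
    idx = seq_along(contacts),
    lig = vapply(contacts, function(x) x$lig_serials[1], integer(1)),
    prot = vapply(contacts, function(x) x$prot_serials[1], integer(1)),
    dist = vapply(contacts, function(x) x$measurements$dist, numeric(1))
  )
  pass1 <- do.call(rbind, lapply(split(df, df$lig), function(g) {
    g[order(g$dist, g$prot), ][1, ]
  }))
  pass2 <- do.call(rbind, lapply(split(pass1, pass1$prot), function(g) {
    g[order(g$dist, g$lig), ][1, ]
  }))
  contacts[sort(pass2$idx)]
}

.hbond_pair_key <- function(x) {
  paste(sort(c(x$donor_serial, x$acceptor_serial)), collapse = "-")
}

#' Remove hydrogen bonds subsumed by salt bridges (and pi-cation contacts)
#'
#' A hydrogen bond whose donor and acceptor heavy atoms both belong to the
#' atom sets of one reported salt bridge duplicates the electrostatic
#' contact and is removed; the salt bridge is retained. Analogously, a
#' hydrogen bond whose donor is the cation nitrogen of a reported pi-cation
#' interaction and whose acceptor belongs to that ring is dropped (rare;
#' counted in the `"dedup_log"` attribute).
#'
#' @param interactions Named list of per-type interaction lists, as
#'   returned by [run_all_detectors()].
#' @return The mapping with overlapping hydrogen bonds removed.
#' @export
dedup_saltbridge_hbond <- function(interactions) {
  hb <- interactions$hbond
  if (length(hb) == 0) return(interactions)
  sb_sets <- lapply(interactions$saltbridge, function(x) {
    c(x$prot_serials, x$lig_serials)
  })
  pc_pairs <- lapply(interactions$pication, function(x) {
    list(atoms = c(x$prot_serials, x$lig_serials))
  })
  log <- character(0)
  keep <- vapply(hb, function(x) {
    for (set in sb_sets) {
      if (x$donor_serial %in% set && x$acceptor_serial %in% set) {
        return(FALSE)
      }
    }
    for (pc in pc_pairs) {
      if (x$donor_serial %in% pc$atoms && x$acceptor_serial %in% pc$atoms) {
        log <<- c(log, paste0(
          "hbond ", x$donor_serial, "->", x$acceptor_serial,
          " overlaps pi-cation interaction; removed"
        ))
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  interactions$hbond <- hb[keep]
  attr(interactions, "dedup_log") <-
    c(attr(interactions, "dedup_log"), log)
  interactions
}

#' Remove water bridges duplicating a direct hydrogen bond
#'
#' A water bridge whose ligand-polar/protein-polar atom pairing is already
#' reported as a direct hydrogen bond is pruned (the direct hydrogen bond
#' wins as the more parsimonious explanation). One water may still support
#' several distinct bridges.
#'
#' @inheritParams dedup_saltbridge_hbond
#' @return The mapping with duplicated water bridges removed.
#' @export
dedup_waterbridge_hbond <- function(interactions) {
  wb <- interactions$waterbridge
  if (length(wb) == 0) return(interactions)
  hb_keys <- vapply(interactions$hbond, function(x) {
    paste(sort(c(x$prot_serials[1], x$lig_serials[1])), collapse = "-")
  }, character(1))
  keep <- vapply(wb, function(x) {
    key <- paste(sort(c(x$prot_serials[1], x$lig_serials[1])), collapse = "-")
    !key %in% hb_keys
  }, logical(1))
  interactions$waterbridge <- wb[keep]
  interactions
}

#' Refine a full interaction mapping
#'
#' Applies hydrophobic neighborhood reduction, salt-bridge-over-hydrogen-bond
#' precedence and water-bridge deduplication. Idempotent; the output is a
#' per-type subset of the input.
#'
#' @inheritParams dedup_saltbridge_hbond
#' @return The refined mapping (same seven keys).
#' @export
refine_interactions <- function(interactions) {
  interactions$hydrophobic <- reduce_hydrophobic(interactions$hydrophobic)
  interactions <- dedup_saltbridge_hbond(interactions)
  interactions <- dedup_waterbridge_hbond(interactions)
  interactions
}

#' Count interactions per type
#'
#' @param interactions Named per-type mapping of interaction lists.
#' @return Named integer vector over the seven types.
#' @export
interaction_counts <- function(interactions) {
  vapply(
    .interaction_types,
    function(t) length(interactions[[t]]),
    integer(1)
  )
}
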