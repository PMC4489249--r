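# Structure preparation stage, part 3: ligand selection (blacklist +
# covalent-link exclusion) and binding-site extraction.

#' Read a ligand blacklist file
#'
#' One residue code per line; `#` starts a comment.
#'
#' @param path Path to the blacklist file.
#' @return Character vector of residue codes.
#' @export
read_blacklist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  codes <- toupper(trimws(lines))
  codes[nzchar(codes)]
}

#' Default ligand blacklist
#'
#' Water codes, monoatomic ions and common cryo/buffer artifacts shipped
#' with the package as an editable text file
#' (`system.file("extdata", "ligand_blacklist.txt", package = "ligprof")`).
#'
#' @return Character vector of residue codes.
#' @export
default_blacklist <- function() {
  read_blacklist(
    system.file("extdata", "ligand_blacklist.txt", package = "ligprof")
  )
}

#' Select relevant ligands from a parsed structure
#'
#' Keeps ligand-candidate (HETATM) residues that are not water, not on the
#' blacklist, and not covalently linked into the polymer (a HET group bonded
#' to any protein-residue atom is treated as a modified residue and
#' excluded). Enlarging the blacklist can only shrink the result.
#'
#' @param s A `ligprof_structure`.
#' @param blacklist Character vector of excluded residue codes.
#' @return Data frame of retained ligand residues (rows of `s$residues`).
#'   Excluded candidates are attached as the `"excluded"` attribute together
#'   with the reason.
#' @export
filter_ligands <- function(s, blacklist = default_blacklist()) {
  cand <- s$residues[s$residues$kind == "ligand-candidate", , drop = FALSE]
  if (nrow(cand) == 0) {
    out <- cand
    attr(out, "excluded") <- data.frame(
      reskey = character(0), reason = character(0)
    )
    return(out)
  }
  prot_keys <- s$residues$reskey[s$residues$kind == "protein"]
  prot_serials <- s$atoms$serial[s$atoms$reskey %in% prot_keys]
  keep <- logical(nrow(cand))
  reason <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (toupper(cand$resid[i]) %in% toupper(blacklist)) {
      reason[i] <- "blacklisted"
      next
    }
    serials <- s$atoms$serial[s$atoms$reskey == cand$reskey[i]]
    linked <- any(vapply(serials, function(serial) {
      any(s$bonds[[as.character(serial)]] %in% prot_serials)
    }, logical(1)))
    if (linked) {
      reason[i] <- "covalently linked to polymer"
      next
    }
    keep[i] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- data.frame(
    reskey = cand$reskey[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  out
}

.min_dist2 <- function(A, B) {
  # minimum squared distance between two coordinate matrices
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  min(d2)
}

#' Extract one binding site per ligand
#'
#' Protein residues and waters with any atom within `cutoff` of any ligand
#' heavy atom are included. Ligand residues connected by covalent bonds
#' (e.g. oligosaccharides built from several HET residues) are merged into
#' one composite site. A ligand with no protein residue in range still
#' yields a site, flagged `isolated`.
#'
#' @param s A `ligprof_structure` (hydrogenated).
#' @param ligands Data frame of ligand residues from [filter_ligands()].
#' @param cutoff Site envelope distance in Angstrom (default 7.5, chosen to
#'   exceed the largest interaction cutoff).
#' @return List of `binding_site` objects with fields `site_id`,
#'   `ligand_reskeys`, `protein_reskeys`, `water_reskeys`, `isolated`,
#'   `atoms` (site atoms with a `side` column), and the parent structure's
#'   atom table and bond list for neighborhood lookups.
#' @export
extract_binding_sites <- function(s, ligands, cutoff = 7.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (nrow(ligands) == 0) return(list())

  # group covalently connected ligand residues into composite ligands
  n <- nrow(ligands)
  groups <- seq_len(n)
  serials_of <- lapply(ligands$reskey, function(rk) {
    s$atoms$serial[s$atoms$reskey == rk]
  })
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      linked <- any(vapply(serials_of[[i]], function(serial) {
        any(s$bonds[[as.character(serial)]] %in% serials_of[[j]])
      }, logical(1)))
      if (linked) groups[groups == groups[j]] <- groups[i]
    }
  }

  sites <- list()
  for (g in unique(groups)) {
    members <- which(groups == g)
    lig_keys <- ligands$reskey[members]
    lig_atoms <- s$atoms[s$atoms$reskey %in% lig_keys & !s$atoms$is_h, , drop = FALSE]
    L <- cbind(lig_atoms$x, lig_atoms$y, lig_atoms$z)
    first <- ligands[members[1], ]
    site_id <- sprintf("%s:%s:%d", first$resid, first$chain, first$resno)

    prot_keys <- character(0)
    water_keys <- character(0)
    others <- s$residues[s$residues$kind %in% c("protein", "water"), , drop = FALSE]
    for (r in seq_len(nrow(others))) {
      ra <- s$atoms[s$atoms$reskey == others$reskey[r], , drop = FALSE]
      B <- cbind(ra$x, ra$y, ra$z)
      if (.min_dist2(B, L) <= cutoff^2) {
        if (others$kind[r] == "protein") {
          prot_keys <- c(prot_keys, others$reskey[r])
        } else {
          water_keys <- c(water_keys, others$reskey[r])
        }
      }
    }

    site_keys <- c(lig_keys, prot_keys, water_keys)
    atoms <- s$atoms[s$atoms$reskey %in% site_keys, , drop = FALSE]
    atoms$side <- ifelse(
      atoms$reskey %in% lig_keys, "ligand",
      ifelse(atoms$reskey %in% water_keys, "water", "protein")
    )
    rownames(atoms) <- NULL
    sites[[length(sites) + 1]] <- structure(
      list(
        site_id = site_id,
        ligand_reskeys = lig_keys,
        protein_reskeys = prot_keys,
        water_reskeys = water_keys,
        isolated = length(prot_keys) == 0,
        atoms = atoms,
        parent_atoms = s$atoms,
        bonds = s$bonds
      ),
      class = "binding_site"
    )
  }
  sites
}

#' @export
print.binding_site <- function(x, ...) {
  cat(
    "<binding_site>", x$site_id, "|",
    length(x$ligand_reskeys), "ligand residue(s),",
    length(x$protein_reskeys), "protein residue(s),",
    length(x$water_reskeys), "water(s)",
    if (x$isolated) "[isolated]" else "", "\n"
  )
  invisible(x)
}
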