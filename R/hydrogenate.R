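# Structure preparation stage, part 2: rule-based polar hydrogen placement
# at the pH-7 policy. Heavy-atom coordinates are never changed and
# pre-existing hydrogens are preserved.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

.perp_of <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(ref - sum(ref * u) * u)
}

.cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Unit directions for n hydrogens on a heavy atom with the given bonded
# heavy-neighbor coordinates. `ref` (a neighbor-of-neighbor position) fixes
# the azimuth for planar groups; the fallback is an arbitrary but
# deterministic perpendicular.
.place_h_dirs <- function(D, nb_xyz, n, ref = NULL) {
  k <- if (is.null(nb_xyz)) 0 else nrow(nb_xyz)
  if (k == 0 || n == 0) return(NULL)
  units <- t(apply(nb_xyz, 1, function(p) .unit(p - D)))
  if (n == 1) {
    v <- -colSums(units)
    if (sqrt(sum(v^2)) < 1e-6) v <- .perp_of(units[1, ])
    return(matrix(.unit(v), nrow = 1))
  }
  if (k == 1) {
    u <- .unit(D - nb_xyz[1, ])
    e1 <- NULL
    if (!is.null(ref)) {
      rv <- ref - nb_xyz[1, ]
      rv_perp <- rv - sum(rv * u) * u
      if (sqrt(sum(rv_perp^2)) > 1e-6) e1 <- .unit(rv_perp)
    }
    if (is.null(e1)) e1 <- .perp_of(u)
    if (n == 2) {
      # trigonal-planar NH2: H-X-C angles of 120 degrees
      c60 <- cos(pi / 3)
      s60 <- sin(pi / 3)
      return(rbind(c60 * u + s60 * e1, c60 * u - s60 * e1))
    }
    # tetrahedral NH3+: cone of half-angle 70.53 degrees about the bond axis
    e2 <- .cross3(u, e1)
    ct <- cos(70.53 * pi / 180)
    st <- sin(70.53 * pi / 180)
    phis <- c(0, 2 * pi / 3, 4 * pi / 3)[seq_len(n)]
    return(t(vapply(
      phis,
      function(phi) ct * u + st * (cos(phi) * e1 + sin(phi) * e2),
      numeric(3)
    )))
  }
  if (k == 2 && n == 2) {
    b <- -(units[1, ] + units[2, ])
    b <- if (sqrt(sum(b^2)) > 1e-6) .unit(b) else .perp_of(units[1, ])
    w <- .cross3(units[1, ], units[2, ])
    w <- if (sqrt(sum(w^2)) > 1e-6) .unit(w) else .perp_of(b)
    ch <- cos(54.75 * pi / 180)
    sh <- sin(54.75 * pi / 180)
    return(rbind(ch * b + sh * w, ch * b - sh * w))
  }
  # generic: all hydrogens along the vacancy direction (n > perceivable)
  v <- -colSums(units)
  if (sqrt(sum(v^2)) < 1e-6) v <- .perp_of(units[1, ])
  matrix(rep(.unit(v), n), nrow = n, byrow = TRUE)
}

.h_bond_length <- function(element) {
  switch(element, O = 0.96, S = 1.34, 1.01)
}

# 5- and 6-membered cycles among the given atom serials.
.cycles_56 <- function(bonds, serials) {
  if (length(serials) < 5) return(list())
  edges <- list()
  sset <- as.character(serials)
  for (a in sset) {
    nb <- bonds[[a]]
    nb <- nb[as.character(nb) %in% sset & nb > as.integer(a)]
    for (b in nb) edges[[length(edges) + 1]] <- c(a, as.character(b))
  }
  if (length(edges) < 5) return(list())
  g <- igraph::graph_from_data_frame(
    do.call(rbind, edges),
    directed = FALSE,
    vertices = sset
  )
  rings <- list()
  seen <- character(0)
  for (k in 5:6) {
    if (igraph::vcount(g) < k) next
    maps <- igraph::subgraph_isomorphisms(igraph::make_ring(k), g, method = "vf2")
    for (m in maps) {
      ring <- sort(as.integer(names(m)))
      key <- paste(ring, collapse = "-")
      if (!key %in% seen) {
        seen <- c(seen, key)
        rings[[length(rings) + 1]] <- ring
      }
    }
  }
  rings
}

.bond_length <- function(s, a, b) {
  point_distance(.atom_xyz(s, a), .atom_xyz(s, b))
}

# Classification helpers on the perceived bond graph (HET chemistry).
.is_carboxylate_c <- function(s, cserial) {
  if (s$atoms$element[match(cserial, s$atoms$serial)] != "C") return(FALSE)
  nb <- .heavy_neighbors(s, cserial)
  onb <- nb[s$atoms$element[match(nb, s$atoms$serial)] == "O"]
  term <- onb[vapply(onb, function(o) length(.heavy_neighbors(s, o)) == 1, logical(1))]
  length(term) == 2 && length(nb) <= 3
}

.is_guanidine_c <- function(s, cserial) {
  if (s$atoms$element[match(cserial, s$atoms$serial)] != "C") return(FALSE)
  nb <- .heavy_neighbors(s, cserial)
  sum(s$atoms$element[match(nb, s$atoms$serial)] == "N") >= 3
}

.has_carbonyl_o <- function(s, cserial) {
  nb <- .heavy_neighbors(s, cserial)
  onb <- nb[s$atoms$element[match(nb, s$atoms$serial)] == "O"]
  any(vapply(onb, function(o) {
    length(.heavy_neighbors(s, o)) == 1 && .bond_length(s, cserial, o) < 1.32
  }, logical(1)))
}

# Number of polar hydrogens a HET oxygen/nitrogen should carry under the
# pH-7 policy (carboxylates, phosphates and sulfonates deprotonated; amines
# protonated; ring and amide nitrogens neutral).
.het_n_target <- function(s, serial, ring_members) {
  i <- match(serial, s$atoms$serial)
  el <- s$atoms$element[i]
  nb <- .heavy_neighbors(s, serial)
  deg <- length(nb)
  if (el == "O") {
    if (deg != 1) return(0L)
    nbi <- match(nb, s$atoms$serial)
    nbel <- s$atoms$element[nbi]
    if (nbel %in% c("P", "S")) return(0L)
    if (nbel == "C") {
      if (.is_carboxylate_c(s, nb)) return(0L)
      if (.bond_length(s, serial, nb) < 1.32) return(0L) # carbonyl
      return(1L) # hydroxyl / phenol
    }
    return(0L)
  }
  if (el == "N") {
    if (deg == 0) return(0L)
    if (serial %in% ring_members) return(0L)
    if (deg == 1 && .bond_length(s, serial, nb) < 1.25) return(0L) # nitrile
    nbel <- s$atoms$element[match(nb, s$atoms$serial)]
    cnb <- nb[nbel == "C"]
    if (any(vapply(cnb, function(c) .is_guanidine_c(s, c), logical(1)))) {
      return(max(0L, 3L - deg))
    }
    if (any(vapply(cnb, function(c) .has_carbonyl_o(s, c), logical(1)))) {
      return(max(0L, 3L - deg)) # amide
    }
    if (deg <= 3 && all(nbel == "C")) {
      return(4L - deg) # protonated amine
    }
    return(0L)
  }
  0L
}

#' Add polar hydrogens at physiological protonation
#'
#' Rule-based polar hydrogen placement with idealized bond geometry. Standard
#' residues follow a pH-7 template (Arg/Lys protonated, Asp/Glu deprotonated,
#' His as the neutral tau tautomer with H on NE2, backbone N-H except
#' proline). HET groups are perceived from connectivity and bond lengths:
#' hydroxyls gain one H, amines are protonated, carboxylates/phosphates/
#' sulfonates stay deprotonated, ring and amide nitrogens stay neutral.
#' Rotatable hydroxyl/thiol hydrogens added here are oriented toward the
#' nearest nitrogen or oxygen of another residue within 4.5 Angstrom. Waters
#' are left without hydrogens (their orientation is unknowable from a single
#' oxygen position); water-mediated geometry is handled by the water-bridge
#' detector without explicit water hydrogens.
#'
#' Pre-existing hydrogens are preserved and counted toward the targets;
#' heavy-atom coordinates are unchanged. Groups whose geometry cannot be
#' perceived (e.g. isolated atoms) are skipped and noted in the
#' `"h_log"` attribute.
#'
#' @param s A `ligprof_structure` from [parse_pdb()].
#' @return The structure with added hydrogen atoms and bonds.
#' @export
hydrogenate <- function(s) {
  a <- s$atoms
  res <- s$residues
  next_serial <- max(a$serial) + 1L
  new_rows <- list()
  new_bonds <- list()
  rotatable <- list() # parent serial -> H serial for the orientation pass
  log <- character(0)

  add_hs <- function(parent_serial, n_add, ref_serial = NULL) {
    i <- match(parent_serial, a$serial)
    D <- c(a$x[i], a$y[i], a$z[i])
    nb <- .heavy_neighbors(s, parent_serial)
    if (length(nb) == 0) {
      log <<- c(log, paste0("atom ", parent_serial, ": no neighbors, H skipped"))
      return(integer(0))
    }
    nb_xyz <- .atom_xyz(s, nb)
    if (is.null(dim(nb_xyz))) nb_xyz <- matrix(nb_xyz, nrow = 1)
    ref <- NULL
    if (is.null(ref_serial)) {
      nn <- setdiff(.heavy_neighbors(s, nb[1]), parent_serial)
      if (length(nn) > 0) ref_serial <- nn[1]
    }
    if (!is.null(ref_serial)) ref <- .atom_xyz(s, ref_serial)
    dirs <- .place_h_dirs(D, nb_xyz, n_add, ref)
    if (is.null(dirs)) return(integer(0))
    blen <- .h_bond_length(a$element[i])
    out <- integer(0)
    for (r in seq_len(nrow(dirs))) {
      serial <- next_serial
      next_serial <<- next_serial + 1L
      pos <- D + blen * dirs[r, ]
      new_rows[[length(new_rows) + 1]] <<- data.frame(
        serial = serial, name = paste0("H", length(new_rows) + 1),
        altloc = "", resid = a$resid[i], chain = a$chain[i],
        resno = a$resno[i], icode = a$icode[i],
        x = pos[1], y = pos[2], z = pos[3], occupancy = 1,
        element = "H", record = a$record[i], is_h = TRUE,
        reskey = a$reskey[i], stringsAsFactors = FALSE
      )
      new_bonds[[length(new_bonds) + 1]] <<- c(parent_serial, serial)
      out <- c(out, serial)
    }
    out
  }

  for (r in seq_len(nrow(res))) {
    kind <- res$kind[r]
    if (kind == "water") next
    rk <- res$reskey[r]
    ridx <- which(a$reskey == rk & !a$is_h)
    if (kind == "protein") {
      resid <- res$resid[r]
      targets <- list()
      if (resid != "PRO") {
        bbn <- ridx[a$name[ridx] == "N"]
        if (length(bbn) == 1) targets[[as.character(a$serial[bbn])]] <- 1L
      }
      tmpl <- .sidechain_h_template[[resid]]
      if (!is.null(tmpl)) {
        for (an in names(tmpl)) {
          j <- ridx[a$name[ridx] == an]
          if (length(j) == 1) targets[[as.character(a$serial[j])]] <- tmpl[[an]]
        }
      }
      for (ps in names(targets)) {
        parent <- as.integer(ps)
        have <- length(.h_neighbors(s, parent))
        need <- max(0L, targets[[ps]] - have)
        if (need > 0) {
          hs <- add_hs(parent, need)
          el <- a$element[match(parent, a$serial)]
          if (length(hs) == 1 && el %in% c("O", "S") &&
              length(.heavy_neighbors(s, parent)) == 1 && have == 0) {
            rotatable[[ps]] <- hs
          }
        }
      }
    } else {
      serials <- a$serial[ridx]
      ring_members <- unlist(.cycles_56(s$bonds, serials))
      for (parent in serials) {
        el <- a$element[match(parent, a$serial)]
        if (!el %in% c("N", "O")) next
        target <- .het_n_target(s, parent, ring_members)
        have <- length(.h_neighbors(s, parent))
        need <- max(0L, target - have)
        if (need > 0) {
          hs <- add_hs(parent, need)
          if (length(hs) == 1 && el == "O" &&
              length(.heavy_neighbors(s, parent)) == 1 && have == 0) {
            rotatable[[as.character(parent)]] <- hs
          }
        }
      }
    }
  }

  if (length(new_rows) > 0) {
    s$atoms <- rbind(a, do.call(rbind, new_rows))
    rownames(s$atoms) <- NULL
    for (p in new_bonds) {
      ka <- as.character(p[1])
      kb <- as.character(p[2])
      s$bonds[[ka]] <- sort(union(s$bonds[[ka]], p[2]))
      s$bonds[[kb]] <- sort(union(s$bonds[[kb]], p[1]))
    }
  }

  # Orient rotatable O-H/S-H toward the nearest N/O of another residue.
  if (length(rotatable) > 0) {
    acc_idx <- which(s$atoms$element %in% c("N", "O"))
    for (ps in names(rotatable)) {
      parent <- as.integer(ps)
      i <- match(parent, s$atoms$serial)
      D <- c(s$atoms$x[i], s$atoms$y[i], s$atoms$z[i])
      cand <- acc_idx[s$atoms$reskey[acc_idx] != s$atoms$reskey[i]]
      if (length(cand) == 0) next
      d <- sqrt((s$atoms$x[cand] - D[1])^2 +
                  (s$atoms$y[cand] - D[2])^2 +
                  (s$atoms$z[cand] - D[3])^2)
      if (min(d) > 4.5) next
      A <- c(
        s$atoms$x[cand[which.min(d)]],
        s$atoms$y[cand[which.min(d)]],
        s$atoms$z[cand[which.min(d)]]
      )
      nb <- .heavy_neighbors(s, parent)
      u <- .unit(D - .atom_xyz(s, nb[1]))
      av <- .unit(A - D)
      w <- av - sum(av * u) * u
      if (sqrt(sum(w^2)) < 1e-6) next
      ct <- cos(70.53 * pi / 180)
      st <- sin(70.53 * pi / 180)
      dir <- ct * u + st * .unit(w)
      blen <- .h_bond_length(s$atoms$element[i])
      hi <- match(rotatable[[ps]], s$atoms$serial)
      s$atoms$x[hi] <- D[1] + blen * dir[1]
      s$atoms$y[hi] <- D[2] + blen * dir[2]
      s$atoms$z[hi] <- D[3] + blen * dir[3]
    }
  }

  attr(s, "h_log") <- log
  s
}
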