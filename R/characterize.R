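# Functional characterization of binding partners: hydrophobic atoms,
# hydrogen/halogen-bond donors and acceptors, aromatic rings and formal
# charge centers. Perception is a function of topology (bond graph +
# templates) only, so results are invariant under rigid motion.

.res_label <- function(atoms, i) {
  sprintf("%s-%s-%d", atoms$resid[i], atoms$chain[i], atoms$resno[i])
}

.site_lookup <- function(site, serials) {
  match(serials, site$parent_atoms$serial)
}

#' Find hydrophobic atoms in a binding site
#'
#' Carbon atoms (both sides) whose bonded heavy neighbors are all carbon.
#'
#' @param site A `binding_site`.
#' @return Data frame with serial, coordinates, side and residue label.
#' @export
find_hydrophobic_atoms <- function(site) {
  a <- site$atoms
  pa <- site$parent_atoms
  rows <- which(!a$is_h & a$element == "C" & a$side != "water")
  keep <- vapply(rows, function(i) {
    nb <- site$bonds[[as.character(a$serial[i])]]
    if (is.null(nb) || length(nb) == 0) return(TRUE)
    j <- match(nb, pa$serial)
    heavy <- j[!pa$is_h[j]]
    all(pa$element[heavy] == "C")
  }, logical(1))
  rows <- rows[keep]
  data.frame(
    serial = a$serial[rows],
    x = a$x[rows], y = a$y[rows], z = a$z[rows],
    side = a$side[rows],
    residue = vapply(rows, function(i) .res_label(a, i), character(1)),
    stringsAsFactors = FALSE
  )
}

.bonded_h <- function(site, serial) {
  pa <- site$parent_atoms
  nb <- site$bonds[[as.character(serial)]]
  if (is.null(nb)) return(integer(0))
  nb[pa$is_h[match(nb, pa$serial)]]
}

.bonded_heavy <- function(site, serial) {
  pa <- site$parent_atoms
  nb <- site$bonds[[as.character(serial)]]
  if (is.null(nb)) return(integer(0))
  nb[!pa$is_h[match(nb, pa$serial)]]
}

#' Find hydrogen-bond donors and acceptors in a binding site
#'
#' Donors: N/O/S heavy atoms carrying at least one hydrogen. Acceptors:
#' any oxygen; nitrogens without hydrogens and with at most two heavy
#' neighbors (excluding protein backbone amide N); sulfur with at most two
#' heavy neighbors (Met thioether, Cys thiol). Waters are excluded here;
#' they are handled by the water-bridge detector.
#'
#' @param site A `binding_site`.
#' @return List with `donors` (list of records with heavy atom, hydrogens,
#'   side, residue) and `acceptors` (data frame).
#' @export
find_hbond_partners <- function(site) {
  a <- site$atoms
  rows <- which(!a$is_h & a$element %in% c("N", "O", "S") & a$side != "water")
  donors <- list()
  acc_rows <- integer(0)
  for (i in rows) {
    serial <- a$serial[i]
    hs <- .bonded_h(site, serial)
    heavy <- .bonded_heavy(site, serial)
    if (length(hs) > 0) {
      h_xyz <- .atom_xyz(list(atoms = site$parent_atoms), hs)
      if (is.null(dim(h_xyz))) h_xyz <- matrix(h_xyz, nrow = 1)
      donors[[length(donors) + 1]] <- list(
        serial = serial,
        xyz = c(a$x[i], a$y[i], a$z[i]),
        h_serials = hs,
        h_xyz = h_xyz,
        side = a$side[i],
        residue = .res_label(a, i),
        element = a$element[i]
      )
    }
    is_acc <- switch(
      a$element[i],
      O = TRUE,
      N = length(hs) == 0 && length(heavy) <= 2 &&
        !(a$record[i] == "ATOM" && a$name[i] == "N"),
      S = length(heavy) <= 2,
      FALSE
    )
    if (is_acc) acc_rows <- c(acc_rows, i)
  }
  acceptors <- data.frame(
    serial = a$serial[acc_rows],
    x = a$x[acc_rows], y = a$y[acc_rows], z = a$z[acc_rows],
    element = a$element[acc_rows],
    side = a$side[acc_rows],
    residue = vapply(acc_rows, function(i) .res_label(a, i), character(1)),
    stringsAsFactors = FALSE
  )
  list(donors = donors, acceptors = acceptors)
}

#' Find halogen-bond donors and acceptors in a binding site
#'
#' Donors are carbon-bound halogens (F/Cl/Br/I, each singly bonded to one
#' carbon) on the ligand side; protein-side halogen donors would require
#' halogenated modified residues and are not perceived. Acceptors are O/N/S
#' atoms with at least one bonded heavy neighbor (which defines the Y-A
#' acceptor axis); the first neighbor by serial is used when several exist.
#' Fluorine donors are retained but flagged `weak`.
#'
#' @param site A `binding_site`.
#' @return List with `donors` and `acceptors` (lists of records).
#' @export
find_halogen_partners <- function(site) {
  a <- site$atoms
  pa <- site$parent_atoms
  donors <- list()
  for (i in which(a$element %in% .halogen_elements & a$side == "ligand")) {
    heavy <- .bonded_heavy(site, a$serial[i])
    if (length(heavy) != 1) next
    j <- match(heavy, pa$serial)
    if (pa$element[j] != "C") next
    donors[[length(donors) + 1]] <- list(
      x_serial = a$serial[i],
      x_xyz = c(a$x[i], a$y[i], a$z[i]),
      c_serial = heavy,
      c_xyz = c(pa$x[j], pa$y[j], pa$z[j]),
      side = "ligand",
      residue = .res_label(a, i),
      element = a$element[i],
      weak = a$element[i] == "F"
    )
  }
  acceptors <- list()
  for (i in which(!a$is_h & a$element %in% c("O", "N", "S") & a$side != "water")) {
    heavy <- .bonded_heavy(site, a$serial[i])
    if (length(heavy) == 0) next
    y <- sort(heavy)[1]
    j <- match(y, pa$serial)
    acceptors[[length(acceptors) + 1]] <- list(
      serial = a$serial[i],
      xyz = c(a$x[i], a$y[i], a$z[i]),
      y_serial = y,
      y_xyz = c(pa$x[j], pa$y[j], pa$z[j]),
      side = a$side[i],
      residue = .res_label(a, i)
    )
  }
  list(donors = donors, acceptors = acceptors)
}

#' Find aromatic rings in a binding site
#'
#' Protein rings come from Phe/Tyr/Trp/His side-chain templates; ligand
#' rings are 5/6-membered cycles of sp2-capable atoms (C/N/O/S with at most
#' three heavy neighbors). Every ring must pass a planarity check: the
#' root-mean-square deviation from its least-squares plane must not exceed
#' `planarity_tol` (saturated rings such as chair cyclohexane fail).
#'
#' @param site A `binding_site`.
#' @param planarity_tol Maximum allowed planarity RMSD in Angstrom.
#' @return List of ring records with atom serials, fitted plane, size,
#'   side and residue label.
#' @export
find_aromatic_rings <- function(site, planarity_tol = 0.25) {
  a <- site$atoms
  rings <- list()
  add_ring <- function(serials, side, residue) {
    xyz <- .atom_xyz(list(atoms = site$parent_atoms), serials)
    pl <- tryCatch(fit_plane(xyz), error = function(e) NULL)
    if (is.null(pl) || pl$planarity_rmsd > planarity_tol) return(invisible())
    rings[[length(rings) + 1]] <<- list(
      serials = serials,
      centroid = pl$centroid,
      normal = pl$normal,
      planarity_rmsd = pl$planarity_rmsd,
      plane = pl,
      size = length(serials),
      side = side,
      residue = residue
    )
  }
  # protein side: residue templates
  prot_keys <- unique(a$reskey[a$side == "protein"])
  for (rk in prot_keys) {
    ridx <- which(a$reskey == rk)
    resid <- a$resid[ridx[1]]
    tmpl <- .ring_templates[[resid]]
    if (is.null(tmpl)) next
    for (names_set in tmpl) {
      j <- ridx[match(names_set, a$name[ridx])]
      if (anyNA(j)) next
      add_ring(a$serial[j], "protein", .res_label(a, ridx[1]))
    }
  }
  # ligand side: perceived cycles
  lig_serials <- a$serial[a$side == "ligand" & !a$is_h]
  if (length(lig_serials) >= 5) {
    pa <- site$parent_atoms
    sp2_ok <- function(serial) {
      i <- match(serial, pa$serial)
      pa$element[i] %in% c("C", "N", "O", "S") &&
        length(.bonded_heavy(site, serial)) <= 3
    }
    for (cyc in .cycles_56(site$bonds, lig_serials)) {
      if (!all(vapply(cyc, sp2_ok, logical(1)))) next
      i <- match(cyc[1], a$serial)
      add_ring(cyc, "ligand", .res_label(a, i))
    }
  }
  rings
}

#' Find formal charge centers in a binding site
#'
#' Protein side at pH 7: Arg guanidinium (+, centroid over CZ/NH1/NH2),
#' Lys NZ (+), His imidazolium (+ only when both ring nitrogens carry H),
#' Asp/Glu carboxylate (-, centroid over both oxygens). Ligand side by
#' connectivity patterns: carboxylate, phosphate, sulfonate (-);
#' guanidinium, quaternary and protonated primary/secondary/tertiary
#' amines (+). Centroids are unweighted means of the contributing atoms.
#' No atom contributes to two centers of opposite sign.
#'
#' @param site A `binding_site`.
#' @return List of charge-center records with sign, atom serials, centroid,
#'   group label, side and residue label.
#' @export
find_charge_centers <- function(site) {
  a <- site$atoms
  pa <- site$parent_atoms
  s_like <- list(atoms = pa)
  centers <- list()
  add_center <- function(sign, serials, group, side, residue) {
    xyz <- .atom_xyz(s_like, serials)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    centers[[length(centers) + 1]] <<- list(
      sign = sign,
      serials = serials,
      centroid = colMeans(xyz),
      group = group,
      side = side,
      residue = residue
    )
  }

  prot_keys <- unique(a$reskey[a$side == "protein"])
  for (rk in prot_keys) {
    ridx <- which(a$reskey == rk)
    resid <- a$resid[ridx[1]]
    lab <- .res_label(a, ridx[1])
    tmpl <- .protein_charge_templates[[resid]]
    if (!is.null(tmpl)) {
      j <- ridx[match(tmpl$atoms, a$name[ridx])]
      if (!anyNA(j)) add_center(tmpl$sign, a$serial[j], tmpl$group, "protein", lab)
    }
    if (resid == "HIS") {
      nd1 <- ridx[a$name[ridx] == "ND1"]
      ne2 <- ridx[a$name[ridx] == "NE2"]
      if (length(nd1) == 1 && length(ne2) == 1 &&
          length(.bonded_h(site, a$serial[nd1])) > 0 &&
          length(.bonded_h(site, a$serial[ne2])) > 0) {
        ce1 <- ridx[a$name[ridx] == "CE1"]
        add_center(
          +1L, a$serial[c(nd1, ce1, ne2)], "imidazolium", "protein", lab
        )
      }
    }
  }

  # ligand side: connectivity patterns, each atom used at most once
  used <- integer(0)
  lig_rows <- which(a$side == "ligand" & !a$is_h)
  lig_serials <- a$serial[lig_rows]
  s_struct <- list(atoms = pa, bonds = site$bonds)
  class(s_struct) <- "ligprof_structure"
  ring_members <- unlist(.cycles_56(site$bonds, lig_serials))
  lab_of <- function(serial) .res_label(a, match(serial, a$serial))

  terminal_o <- function(cserial) {
    nb <- .bonded_heavy(site, cserial)
    onb <- nb[pa$element[match(nb, pa$serial)] == "O"]
    onb[vapply(onb, function(o) length(.bonded_heavy(site, o)) == 1, logical(1))]
  }

  for (serial in lig_serials) {
    el <- pa$element[match(serial, pa$serial)]
    if (serial %in% used) next
    nb <- .bonded_heavy(site, serial)
    nbel <- pa$element[match(nb, pa$serial)]
    if (el == "C") {
      to <- terminal_o(serial)
      if (length(to) == 2 && length(nb) <= 3 && !any(to %in% used)) {
        add_center(-1L, to, "carboxylate", "ligand", lab_of(serial))
        used <- c(used, serial, to)
        next
      }
      nnb <- nb[nbel == "N"]
      if (length(nnb) >= 3 && !any(nnb %in% used)) {
        term_n <- nnb[vapply(nnb, function(x) {
          length(.bonded_heavy(site, x)) == 1
        }, logical(1))]
        add_center(
          +1L, c(serial, term_n), "guanidinium", "ligand", lab_of(serial)
        )
        used <- c(used, serial, nnb)
        next
      }
    }
    if (el == "P") {
      to <- terminal_o(serial)
      if (length(to) >= 2 && !any(to %in% used)) {
        add_center(-1L, to, "phosphate", "ligand", lab_of(serial))
        used <- c(used, serial, to)
        next
      }
    }
    if (el == "S") {
      to <- terminal_o(serial)
      if (length(to) >= 3 && !any(to %in% used)) {
        add_center(-1L, to, "sulfonate", "ligand", lab_of(serial))
        used <- c(used, serial, to)
        next
      }
    }
    if (el == "N") {
      deg <- length(nb)
      if (deg >= 4) {
        add_center(+1L, serial, "quaternary-amine", "ligand", lab_of(serial))
        used <- c(used, serial)
        next
      }
      if (deg >= 1 && deg <= 3 && all(nbel == "C") &&
          !serial %in% ring_members &&
          !any(vapply(nb, function(c) .is_guanidine_c(s_struct, c), logical(1))) &&
          !any(vapply(nb, function(c) .has_carbonyl_o(s_struct, c), logical(1)))) {
        add_center(+1L, serial, "ammonium", "ligand", lab_of(serial))
        used <- c(used, serial)
      }
    }
  }
  centers
}

#' Functionally characterize a binding site
#'
#' Runs all perception steps and bundles the results for the detectors.
#'
#' @param site A `binding_site` (hydrogenated structure).
#' @param planarity_tol Ring planarity tolerance in Angstrom.
#' @return Object of class `site_features`.
#' @export
characterize_site <- function(site, planarity_tol = 0.25) {
  hb <- find_hbond_partners(site)
  xb <- find_halogen_partners(site)
  a <- site$atoms
  wrows <- which(a$side == "water" & a$element == "O")
  waters <- data.frame(
    serial = a$serial[wrows],
    x = a$x[wrows], y = a$y[wrows], z = a$z[wrows],
    residue = vapply(wrows, function(i) .res_label(a, i), character(1)),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      site_id = site$site_id,
      hydrophobic = find_hydrophobic_atoms(site),
      donors = hb$donors,
      acceptors = hb$acceptors,
      halogen_donors = xb$donors,
      halogen_acceptors = xb$acceptors,
      rings = find_aromatic_rings(site, planarity_tol),
      charges = find_charge_centers(site),
      waters = waters
    ),
    class = "site_features"
  )
}
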