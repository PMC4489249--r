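# Rule-based geometric matching: one detector per interaction type. Each
# detector pairs protein-side with ligand-side features under the distance
# and angle constraints of a threshold configuration. Intra-molecular
# (protein-protein or ligand-ligand) pairs are never reported.

.interaction_types <- c(
  "hydrophobic", "hbond", "waterbridge", "saltbridge",
  "pistack", "pication", "halogen"
)

new_interaction <- function(type, residue, prot_serials, lig_serials,
                            measurements, donor_side = NA_character_,
                            subtype = NA_character_,
                            water_serial = NA_integer_,
                            donor_serial = NA_integer_,
                            acceptor_serial = NA_integer_) {
  structure(
    list(
      type = type,
      residue = residue,
      prot_serials = as.integer(prot_serials),
      lig_serials = as.integer(lig_serials),
      water_serial = as.integer(water_serial),
      donor_side = donor_side,
      subtype = subtype,
      donor_serial = as.integer(donor_serial),
      acceptor_serial = as.integer(acceptor_serial),
      measurements = measurements
    ),
    class = "ligprof_interaction"
  )
}

#' @export
print.ligprof_interaction <- function(x, ...) {
  cat(
    sprintf(
      "<%s> %s | prot %s | lig %s | %s\n",
      x$type, x$residue,
      paste(x$prot_serials, collapse = ","),
      paste(x$lig_serials, collapse = ","),
      paste(names(x$measurements), sprintf("%.2f", unlist(x$measurements)),
            sep = "=", collapse = " ")
    )
  )
  invisible(x)
}

.cross_pairs <- function(side1, side2) {
  (side1 == "protein" & side2 == "ligand") |
    (side1 == "ligand" & side2 == "protein")
}

#' Detect hydrophobic contacts
#'
#' One candidate per (protein carbon, ligand carbon) pair whose distance
#' does not exceed `hydrophobic_dist_max`. The neighborhood reduction to
#' the most relevant contacts happens later in [reduce_hydrophobic()].
#'
#' @param features A `site_features` object.
#' @param cfg A `threshold_config`.
#' @return List of `ligprof_interaction` records.
#' @export
detect_hydrophobic <- function(features, cfg) {
  h <- features$hydrophobic
  prot <- h[h$side == "protein", , drop = FALSE]
  lig <- h[h$side == "ligand", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(prot))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((prot$x[i] - lig$x[j])^2 + (prot$y[i] - lig$y[j])^2 +
                  (prot$z[i] - lig$z[j])^2)
      if (d <= cfg$hydrophobic_dist_max) {
        out[[length(out) + 1]] <- new_interaction(
          "hydrophobic", prot$residue[i],
          prot$serial[i], lig$serial[j],
          list(dist = d)
        )
      }
    }
  }
  out
}

.best_donor_angle <- function(donor, acceptor_xyz) {
  angles <- vapply(seq_len(nrow(donor$h_xyz)), function(r) {
    point_angle(donor$xyz, donor$h_xyz[r, ], acceptor_xyz)
  }, numeric(1))
  max(angles)
}

#' Detect hydrogen bonds
#'
#' Donor-acceptor pairs (one on each side, waters excluded) with heavy-atom
#' distance at most `hbond_dist_max` and donor angle D-H...A of at least
#' `hbond_don_angle_min`, using the best hydrogen of the donor.
#'
#' @inheritParams detect_hydrophobic
#' @return List of `ligprof_interaction` records.
#' @export
detect_hbonds <- function(features, cfg) {
  out <- list()
  acc <- features$acceptors
  for (don in features$donors) {
    for (j in seq_len(nrow(acc))) {
      if (!.cross_pairs(don$side, acc$side[j])) next
      if (don$serial == acc$serial[j]) next
      axyz <- c(acc$x[j], acc$y[j], acc$z[j])
      d <- point_distance(don$xyz, axyz)
      if (d > cfg$hbond_dist_max) next
      ang <- .best_donor_angle(don, axyz)
      if (ang < cfg$hbond_don_angle_min) next
      prot_serial <- if (don$side == "protein") don$serial else acc$serial[j]
      lig_serial <- if (don$side == "ligand") don$serial else acc$serial[j]
      residue <- if (don$side == "protein") don$residue else acc$residue[j]
      out[[length(out) + 1]] <- new_interaction(
        "hbond", residue, prot_serial, lig_serial,
        list(dist_da = d, don_angle = ang),
        donor_side = don$side,
        donor_serial = don$serial,
        acceptor_serial = acc$serial[j]
      )
    }
  }
  out
}

# Unique polar (donor and/or acceptor) atoms of one side, for water bridges.
.polar_atoms_of_side <- function(features, side) {
  recs <- list()
  for (don in features$donors) {
    if (don$side != side) next
    recs[[as.character(don$serial)]] <- list(
      serial = don$serial, xyz = don$xyz, residue = don$residue,
      donor = don, is_acceptor = FALSE
    )
  }
  acc <- features$acceptors
  for (j in which(acc$side == side)) {
    key <- as.character(acc$serial[j])
    if (is.null(recs[[key]])) {
      recs[[key]] <- list(
        serial = acc$serial[j],
        xyz = c(acc$x[j], acc$y[j], acc$z[j]),
        residue = acc$residue[j],
        donor = NULL, is_acceptor = TRUE
      )
    } else {
      recs[[key]]$is_acceptor <- TRUE
    }
  }
  recs
}

#' Detect water bridges
#'
#' Ligand-polar ... water ... protein-polar triples in which both legs have
#' a heavy-atom distance within `[waterbridge_mindist, waterbridge_maxdist]`,
#' the water-centered angle omega between the legs lies within
#' `[waterbridge_omega_min, waterbridge_omega_max]`, and every donating leg
#' (a polar atom carrying hydrogens) satisfies a donor angle of at least
#' `waterbridge_theta_min` toward the water oxygen. Waters carry no
#' hydrogens after preparation, so a leg in which the water donates imposes
#' no theta constraint.
#'
#' @inheritParams detect_hydrophobic
#' @return List of `ligprof_interaction` records.
#' @export
detect_waterbridges <- function(features, cfg) {
  out <- list()
  w <- features$waters
  if (nrow(w) == 0) return(out)
  lig <- .polar_atoms_of_side(features, "ligand")
  prot <- .polar_atoms_of_side(features, "protein")
  leg_ok <- function(rec, wxyz) {
    d <- point_distance(rec$xyz, wxyz)
    if (d < cfg$waterbridge_mindist || d > cfg$waterbridge_maxdist) {
      return(NA_real_)
    }
    if (!is.null(rec$donor)) {
      theta <- .best_donor_angle(rec$donor, wxyz)
      if (theta < cfg$waterbridge_theta_min) {
        if (!rec$is_acceptor) return(NA_real_)
        # falls back to the water-donates reading; no theta constraint
      }
    }
    d
  }
  for (k in seq_len(nrow(w))) {
    wxyz <- c(w$x[k], w$y[k], w$z[k])
    for (L in lig) {
      dl <- leg_ok(L, wxyz)
      if (is.na(dl)) next
      for (P in prot) {
        dp <- leg_ok(P, wxyz)
        if (is.na(dp)) next
        omega <- point_angle(L$xyz, wxyz, P$xyz)
        if (omega < cfg$waterbridge_omega_min ||
            omega > cfg$waterbridge_omega_max) next
        out[[length(out) + 1]] <- new_interaction(
          "waterbridge", P$residue, P$serial, L$serial,
          list(dist_lw = dl, dist_pw = dp, omega = omega),
          water_serial = w$serial[k]
        )
      }
    }
  }
  out
}

#' Detect salt bridges
#'
#' Pairs of opposite-sign charge centers on opposite sides whose centroid
#' distance does not exceed `saltbridge_dist_max`.
#'
#' @inheritParams detect_hydrophobic
#' @return List of `ligprof_interaction` records.
#' @export
detect_saltbridges <- function(features, cfg) {
  out <- list()
  ch <- features$charges
  n <- length(ch)
  if (n < 2) return(out)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      a <- ch[[i]]
      b <- ch[[j]]
      if (!.cross_pairs(a$side, b$side)) next
      if (a$sign * b$sign >= 0) next
      d <- point_distance(a$centroid, b$centroid)
      if (d > cfg$saltbridge_dist_max) next
      prot <- if (a$side == "protein") a else b
      lig <- if (a$side == "ligand") a else b
      out[[length(out) + 1]] <- new_interaction(
        "saltbridge", prot$residue, prot$serials, lig$serials,
        list(dist = d)
      )
    }
  }
  out
}

#' Detect pi-stacking
#'
#' Cross-side ring pairs with centroid distance at most `pistack_dist_max`,
#' plane angle within `pistack_ang_dev` of 0 (subtype `"P"`, parallel) or
#' of 90 degrees (subtype `"T"`, perpendicular), and a lateral offset of at
#' most `pistack_offset_max` in at least one of the two projections.
#'
#' @inheritParams detect_hydrophobic
#' @return List of `ligprof_interaction` records.
#' @export
detect_pistacking <- function(features, cfg) {
  out <- list()
  rings <- features$rings
  n <- length(rings)
  if (n < 2) return(out)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      r1 <- rings[[i]]
      r2 <- rings[[j]]
      if (!.cross_pairs(r1$side, r2$side)) next
      d <- point_distance(r1$centroid, r2$centroid)
      if (d > cfg$pistack_dist_max) next
      ang <- plane_angle(r1$plane, r2$plane)
      subtype <- if (ang <= cfg$pistack_ang_dev) {
        "P"
      } else if (abs(ang - 90) <= cfg$pistack_ang_dev) {
        "T"
      } else {
        next
      }
      offset <- min(
        projected_offset(r1$plane, r2$centroid),
        projected_offset(r2$plane, r1$centroid)
      )
      if (offset > cfg$pistack_offset_max) next
      prot <- if (r1$side == "protein") r1 else r2
      lig <- if (r1$side == "ligand") r1 else r2
      out[[length(out) + 1]] <- new_interaction(
        "pistack", prot$residue, prot$serials, lig$serials,
        list(centdist = d, angle = ang, offset = offset),
        subtype = subtype
      )
    }
  }
  out
}

#' Detect pi-cation interactions
#'
#' Cross-side (ring, positive charge center) pairs with centroid distance
#' at most `pication_dist_max` and lateral offset of the charge from the
#' ring axis at most `pistack_offset_max`.
#'
#' @inheritParams detect_hydrophobic
#' @return List of `ligprof_interaction` records.
#' @export
detect_pication <- function(features, cfg) {
  out <- list()
  for (ring in features$rings) {
    for (ch in features$charges) {
      if (ch$sign <= 0) next
      if (!.cross_pairs(ring$side, ch$side)) next
      d <- point_distance(ring$centroid, ch$centroid)
      if (d > cfg$pication_dist_max) next
      offset <- projected_offset(ring$plane, ch$centroid)
      if (offset > cfg$pistack_offset_max) next
      prot_serials <- if (ring$side == "protein") ring$serials else ch$serials
      lig_serials <- if (ring$side == "ligand") ring$serials else ch$serials
      residue <- if (ring$side == "protein") ring$residue else ch$residue
      out[[length(out) + 1]] <- new_interaction(
        "pication", residue, prot_serials, lig_serials,
        list(dist = d, offset = offset)
      )
    }
  }
  out
}

#' Detect halogen bonds
#'
#' (C-X donor, acceptor) pairs with X...A distance at most
#' `halogen_dist_max`, donor angle C-X...A within
#' `halogen_don_angle +/- halogen_angle_dev` (the sigma-hole direction) and
#' acceptor angle Y-A...X within `halogen_acc_angle +/- halogen_angle_dev`.
#' Donors are ligand-side carbon-bound halogens; acceptors protein-side
#' O/N/S.
#'
#' @inheritParams detect_hydrophobic
#' @return List of `ligprof_interaction` records.
#' @export
detect_halogenbonds <- function(features, cfg) {
  out <- list()
  for (don in features$halogen_donors) {
    for (acc in features$halogen_acceptors) {
      if (acc$side != "protein") next
      d <- point_distance(don$x_xyz, acc$xyz)
      if (d > cfg$halogen_dist_max) next
      don_ang <- point_angle(don$c_xyz, don$x_xyz, acc$xyz)
      if (abs(don_ang - cfg$halogen_don_angle) > cfg$halogen_angle_dev) next
      acc_ang <- point_angle(acc$y_xyz, acc$xyz, don$x_xyz)
      if (abs(acc_ang - cfg$halogen_acc_angle) > cfg$halogen_angle_dev) next
      out[[length(out) + 1]] <- new_interaction(
        "halogen", acc$residue, acc$serial, don$x_serial,
        list(dist = d, don_angle = don_ang, acc_angle = acc_ang),
        donor_side = "ligand"
      )
    }
  }
  out
}

#' Run all seven detectors on a characterized binding site
#'
#' @inheritParams detect_hydrophobic
#' @return Named list with exactly the seven interaction types as keys
#'   (`hydrophobic`, `hbond`, `waterbridge`, `saltbridge`, `pistack`,
#'   `pication`, `halogen`), each a (possibly empty) list of raw
#'   pre-refinement `ligprof_interaction` records.
#' @export
run_all_detectors <- function(features, cfg = default_thresholds()) {
  validate_thresholds(cfg)
  list(
    hydrophobic = detect_hydrophobic(features, cfg),
    hbond = detect_hbonds(features, cfg),
    waterbridge = detect_waterbridges(features, cfg),
    saltbridge = detect_saltbridges(features, cfg),
    pistack = detect_pistacking(features, cfg),
    pication = detect_pication(features, cfg),
    halogen = detect_halogenbonds(features, cfg)
  )
}
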