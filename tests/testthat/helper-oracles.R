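# Independent brute-force helpers used as oracles: plain formulas written
# directly from the geometric definitions, kept separate from the package
# implementation paths they check.

bf_dist <- function(a, b) sqrt(sum((a - b)^2))

bf_angle <- function(a, v, c) {
  u <- a - v
  w <- c - v
  cosang <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

bf_plane_offset <- function(centroid, normal, pt) {
  v <- pt - centroid
  v_in <- v - sum(v * normal) * normal
  sqrt(sum(v_in^2))
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# --- feature-scene construction for detector tests -------------------------

empty_features <- function() {
  structure(
    list(
      site_id = "LG1:L:1",
      hydrophobic = data.frame(
        serial = integer(0), x = numeric(0), y = numeric(0), z = numeric(0),
        side = character(0), residue = character(0),
        stringsAsFactors = FALSE
      ),
      donors = list(),
      acceptors = data.frame(
        serial = integer(0), x = numeric(0), y = numeric(0), z = numeric(0),
        element = character(0), side = character(0), residue = character(0),
        stringsAsFactors = FALSE
      ),
      halogen_donors = list(),
      halogen_acceptors = list(),
      rings = list(),
      charges = list(),
      waters = data.frame(
        serial = integer(0), x = numeric(0), y = numeric(0), z = numeric(0),
        residue = character(0), stringsAsFactors = FALSE
      )
    ),
    class = "site_features"
  )
}

make_ring_feature <- function(center, normal, serials, side, residue) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    n[2] * e1[3] - n[3] * e1[2],
    n[3] * e1[1] - n[1] * e1[3],
    n[1] * e1[2] - n[2] * e1[1]
  )
  pts <- t(vapply(seq(0, 300, by = 60), function(deg) {
    th <- deg * pi / 180
    center + 1.39 * (cos(th) * e1 + sin(th) * e2)
  }, numeric(3)))
  pl <- fit_plane(pts)
  list(
    serials = serials, centroid = pl$centroid, normal = pl$normal,
    planarity_rmsd = pl$planarity_rmsd, plane = pl, size = 6L,
    side = side, residue = residue
  )
}

make_donor <- function(serial, xyz, h_serials, h_xyz, side,
                       residue = if (side == "protein") "SER-A-1" else "LG1-L-1") {
  if (is.null(dim(h_xyz))) h_xyz <- matrix(h_xyz, nrow = 1)
  list(
    serial = serial, xyz = xyz, h_serials = h_serials, h_xyz = h_xyz,
    side = side, residue = residue, element = "O"
  )
}

# Random scene of features on both sides inside a 12 A box.
make_scene <- function(seed) {
  set.seed(seed)
  serial <- 0L
  nxt <- function(n = 1) {
    out <- serial + seq_len(n)
    serial <<- serial + n
    out
  }
  f <- empty_features()
  for (side in c("protein", "ligand")) {
    res <- if (side == "protein") "ALA-A-1" else "LG1-L-1"
    ids <- nxt(8)
    pts <- matrix(runif(24, 0, 12), ncol = 3)
    f$hydrophobic <- rbind(f$hydrophobic, data.frame(
      serial = ids, x = pts[, 1], y = pts[, 2], z = pts[, 3],
      side = side, residue = res, stringsAsFactors = FALSE
    ))
    for (k in 1:4) {
      p <- runif(3, 0, 12)
      nh <- sample(1:3, 1)
      hx <- t(vapply(seq_len(nh), function(i) p + rand_unit(), numeric(3)))
      f$donors[[length(f$donors) + 1]] <-
        make_donor(nxt(1), p, nxt(nh), hx, side, res)
    }
    apts <- matrix(runif(12, 0, 12), ncol = 3)
    aid <- nxt(4)
    f$acceptors <- rbind(f$acceptors, data.frame(
      serial = aid, x = apts[, 1], y = apts[, 2], z = apts[, 3],
      element = "O", side = side, residue = res, stringsAsFactors = FALSE
    ))
    for (k in 1:2) {
      f$rings[[length(f$rings) + 1]] <- make_ring_feature(
        runif(3, 2, 10), rand_unit(), nxt(6), side, res
      )
    }
    for (k in 1:2) {
      f$charges[[length(f$charges) + 1]] <- list(
        sign = sample(c(-1L, 1L), 1), serials = nxt(1),
        centroid = runif(3, 0, 12), group = "carboxylate",
        side = side, residue = res
      )
    }
  }
  for (k in 1:2) {
    p <- runif(3, 0, 12)
    f$halogen_donors[[length(f$halogen_donors) + 1]] <- list(
      x_serial = nxt(1), x_xyz = p, c_serial = nxt(1),
      c_xyz = p + 1.75 * rand_unit(), side = "ligand",
      residue = "LG1-L-1", element = "CL", weak = FALSE
    )
  }
  for (k in 1:3) {
    p <- runif(3, 0, 12)
    f$halogen_acceptors[[length(f$halogen_acceptors) + 1]] <- list(
      serial = nxt(1), xyz = p, y_serial = nxt(1),
      y_xyz = p + 1.23 * rand_unit(), side = "protein", residue = "ALA-A-1"
    )
  }
  wp <- matrix(runif(9, 0, 12), ncol = 3)
  f$waters <- data.frame(
    serial = nxt(3), x = wp[, 1], y = wp[, 2], z = wp[, 3],
    residue = "HOH-W-201", stringsAsFactors = FALSE
  )
  f
}

# Brute-force reference scans sharing only the inequality definitions.
bf_scan <- function(f, cfg) {
  out <- list(
    hydrophobic = character(0), hbond = character(0),
    waterbridge = character(0), saltbridge = character(0),
    pistack = character(0), pication = character(0), halogen = character(0)
  )
  h <- f$hydrophobic
  for (i in seq_len(nrow(h))) for (j in seq_len(nrow(h))) {
    if (!(h$side[i] == "protein" && h$side[j] == "ligand")) next
    d <- bf_dist(c(h$x[i], h$y[i], h$z[i]), c(h$x[j], h$y[j], h$z[j]))
    if (d <= cfg$hydrophobic_dist_max) {
      out$hydrophobic <- c(out$hydrophobic, paste(h$serial[i], h$serial[j]))
    }
  }
  best_angle <- function(don, target) {
    max(vapply(seq_len(nrow(don$h_xyz)), function(r) {
      bf_angle(don$xyz, don$h_xyz[r, ], target)
    }, numeric(1)))
  }
  a <- f$acceptors
  for (don in f$donors) for (j in seq_len(nrow(a))) {
    s2 <- a$side[j]
    if (!((don$side == "protein" && s2 == "ligand") ||
            (don$side == "ligand" && s2 == "protein"))) next
    ax <- c(a$x[j], a$y[j], a$z[j])
    if (bf_dist(don$xyz, ax) > cfg$hbond_dist_max) next
    if (best_angle(don, ax) < cfg$hbond_don_angle_min) next
    out$hbond <- c(out$hbond, paste(don$serial, a$serial[j]))
  }
  polar <- function(side) {
    recs <- list()
    for (don in f$donors) {
      if (don$side == side) {
        recs[[as.character(don$serial)]] <-
          list(serial = don$serial, xyz = don$xyz, donor = don, acc = FALSE)
      }
    }
    for (j in which(a$side == side)) {
      key <- as.character(a$serial[j])
      if (is.null(recs[[key]])) {
        recs[[key]] <- list(
          serial = a$serial[j], xyz = c(a$x[j], a$y[j], a$z[j]),
          donor = NULL, acc = TRUE
        )
      } else {
        recs[[key]]$acc <- TRUE
      }
    }
    recs
  }
  lp <- polar("ligand")
  pp <- polar("protein")
  w <- f$waters
  leg <- function(rec, wx) {
    d <- bf_dist(rec$xyz, wx)
    if (d < cfg$waterbridge_mindist || d > cfg$waterbridge_maxdist) return(FALSE)
    if (!is.null(rec$donor) &&
        best_angle(rec$donor, wx) < cfg$waterbridge_theta_min && !rec$acc) {
      return(FALSE)
    }
    TRUE
  }
  for (k in seq_len(nrow(w))) {
    wx <- c(w$x[k], w$y[k], w$z[k])
    for (L in lp) for (P in pp) {
      if (!leg(L, wx) || !leg(P, wx)) next
      om <- bf_angle(L$xyz, wx, P$xyz)
      if (om < cfg$waterbridge_omega_min || om > cfg$waterbridge_omega_max) next
      out$waterbridge <- c(
        out$waterbridge, paste(P$serial, L$serial, w$serial[k])
      )
    }
  }
  for (ci in f$charges) for (cj in f$charges) {
    if (!(ci$side == "protein" && cj$side == "ligand")) next
    if (ci$sign * cj$sign >= 0) next
    if (bf_dist(ci$centroid, cj$centroid) > cfg$saltbridge_dist_max) next
    out$saltbridge <- c(out$saltbridge, paste(ci$serials[1], cj$serials[1]))
  }
  for (ri in f$rings) for (rj in f$rings) {
    if (!(ri$side == "protein" && rj$side == "ligand")) next
    d <- bf_dist(ri$centroid, rj$centroid)
    if (d > cfg$pistack_dist_max) next
    cosang <- abs(sum(ri$normal * rj$normal))
    ang <- acos(min(1, cosang)) * 180 / pi
    if (!(ang <= cfg$pistack_ang_dev || abs(ang - 90) <= cfg$pistack_ang_dev)) next
    off <- min(
      bf_plane_offset(ri$centroid, ri$normal, rj$centroid),
      bf_plane_offset(rj$centroid, rj$normal, ri$centroid)
    )
    if (off > cfg$pistack_offset_max) next
    out$pistack <- c(out$pistack, paste(ri$serials[1], rj$serials[1]))
  }
  for (ri in f$rings) for (ch in f$charges) {
    if (ch$sign <= 0) next
    if (!((ri$side == "protein" && ch$side == "ligand") ||
            (ri$side == "ligand" && ch$side == "protein"))) next
    if (bf_dist(ri$centroid, ch$centroid) > cfg$pication_dist_max) next
    if (bf_plane_offset(ri$centroid, ri$normal, ch$centroid) >
          cfg$pistack_offset_max) next
    out$pication <- c(
      out$pication,
      paste(sort(c(ri$serials[1], ch$serials[1])), collapse = " ")
    )
  }
  for (don in f$halogen_donors) for (acc in f$halogen_acceptors) {
    if (acc$side != "protein") next
    if (bf_dist(don$x_xyz, acc$xyz) > cfg$halogen_dist_max) next
    da <- bf_angle(don$c_xyz, don$x_xyz, acc$xyz)
    if (abs(da - cfg$halogen_don_angle) > cfg$halogen_angle_dev) next
    aa <- bf_angle(acc$y_xyz, acc$xyz, don$x_xyz)
    if (abs(aa - cfg$halogen_acc_angle) > cfg$halogen_angle_dev) next
    out$halogen <- c(out$halogen, paste(don$x_serial, acc$serial))
  }
  lapply(out, sort)
}

# Keys of the detector output in the same encoding as bf_scan.
detector_keys <- function(raw) {
  list(
    hydrophobic = sort(vapply(raw$hydrophobic, function(x) {
      paste(x$prot_serials[1], x$lig_serials[1])
    }, character(1))),
    hbond = sort(vapply(raw$hbond, function(x) {
      paste(x$donor_serial, x$acceptor_serial)
    }, character(1))),
    waterbridge = sort(vapply(raw$waterbridge, function(x) {
      paste(x$prot_serials[1], x$lig_serials[1], x$water_serial)
    }, character(1))),
    saltbridge = sort(vapply(raw$saltbridge, function(x) {
      paste(x$prot_serials[1], x$lig_serials[1])
    }, character(1))),
    pistack = sort(vapply(raw$pistack, function(x) {
      paste(x$prot_serials[1], x$lig_serials[1])
    }, character(1))),
    pication = sort(vapply(raw$pication, function(x) {
      paste(sort(c(x$prot_serials[1], x$lig_serials[1])), collapse = " ")
    }, character(1))),
    halogen = sort(vapply(raw$halogen, function(x) {
      paste(x$lig_serials[1], x$prot_serials[1])
    }, character(1)))
  )
}
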