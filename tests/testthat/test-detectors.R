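cfg <- default_thresholds()

test_that("hydrophobic detector applies the exact distance boundary", {
  f <- empty_features()
  add_pair <- function(f, d, id) {
    f$hydrophobic <- rbind(f$hydrophobic, data.frame(
      serial = c(id, id + 1), x = c(0, d), y = 0, z = 0,
      side = c("protein", "ligand"),
      residue = c("ALA-A-1", "LG1-L-1"), stringsAsFactors = FALSE
    ))
    f
  }
  near <- detect_hydrophobic(add_pair(f, cfg$hydrophobic_dist_max - 0.05, 1), cfg)
  expect_length(near, 1)
  expect_equal(near[[1]]$measurements$dist, cfg$hydrophobic_dist_max - 0.05)
  far <- detect_hydrophobic(add_pair(f, cfg$hydrophobic_dist_max + 0.05, 1), cfg)
  expect_length(far, 0)
})

test_that("hydrogen-bond detector enforces distance and donor-angle rules", {
  make_f <- function(d, h_dir) {
    f <- empty_features()
    f$donors <- list(make_donor(
      1L, c(0, 0, 0), 2L, 1.0 * h_dir, "ligand", "LG1-L-1"
    ))
    f$acceptors <- data.frame(
      serial = 3L, x = d, y = 0, z = 0, element = "O", side = "protein",
      residue = "SER-A-1", stringsAsFactors = FALSE
    )
    f
  }
  ideal <- detect_hbonds(make_f(2.9, c(1, 0, 0)), cfg) # linear O-H...O
  expect_length(ideal, 1)
  expect_equal(ideal[[1]]$measurements$dist_da, 2.9)
  expect_equal(ideal[[1]]$measurements$don_angle, 180)
  expect_equal(ideal[[1]]$donor_side, "ligand")

  # H pointing 100 degrees away from the acceptor: donor angle ~ 80 < 100
  bent_dir <- c(cos(100 * pi / 180), sin(100 * pi / 180), 0)
  bent <- detect_hbonds(make_f(2.9, bent_dir), cfg)
  expect_length(bent, 0)

  too_far <- detect_hbonds(make_f(cfg$hbond_dist_max + 0.1, c(1, 0, 0)), cfg)
  expect_length(too_far, 0)

  # the best hydrogen is chosen per donor
  f2 <- make_f(2.9, bent_dir)
  f2$donors[[1]]$h_serials <- c(2L, 4L)
  f2$donors[[1]]$h_xyz <- rbind(bent_dir, c(1, 0, 0))
  both <- detect_hbonds(f2, cfg)
  expect_length(both, 1)
  expect_equal(both[[1]]$measurements$don_angle, 180)
})

test_that("hydrogen-bond acceptance region over a (dist, angle) grid equals the rule inequalities", {
  for (d in seq(2.5, 4.7, by = 0.4)) {
    for (ang in seq(60, 180, by = 20)) {
      h_dir <- c(cos((180 - ang) * pi / 180), sin((180 - ang) * pi / 180), 0)
      f <- empty_features()
      f$donors <- list(make_donor(1L, c(0, 0, 0), 2L, h_dir, "ligand", "LG1-L-1"))
      f$acceptors <- data.frame(
        serial = 3L, x = d, y = 0, z = 0, element = "O", side = "protein",
        residue = "SER-A-1", stringsAsFactors = FALSE
      )
      got <- length(detect_hbonds(f, cfg))
      # independent check: distance rule + angle at H computed from scratch
      ang_at_h <- bf_angle(c(0, 0, 0), h_dir, c(d, 0, 0))
      want <- as.integer(d <= cfg$hbond_dist_max &&
                           ang_at_h >= cfg$hbond_don_angle_min)
      expect_equal(got, want, info = sprintf("d=%.1f ang=%d", d, ang))
    }
  }
})

test_that("water-bridge detector accepts textbook geometry and rejects long legs", {
  make_f <- function(leg1, leg2, omega) {
    f <- empty_features()
    w <- c(0, 0, 0)
    l <- c(leg1, 0, 0)
    th <- omega * pi / 180
    p <- leg2 * c(cos(th), sin(th), 0)
    f$waters <- data.frame(
      serial = 9L, x = 0, y = 0, z = 0, residue = "HOH-W-201",
      stringsAsFactors = FALSE
    )
    f$donors <- list(make_donor(1L, l, 2L, l - c(1, 0, 0), "ligand", "LG1-L-1"))
    f$acceptors <- data.frame(
      serial = c(1L, 3L), x = c(l[1], p[1]), y = c(l[2], p[2]),
      z = c(l[3], p[3]), element = "O", side = c("ligand", "protein"),
      residue = c("LG1-L-1", "SER-A-1"), stringsAsFactors = FALSE
    )
    f
  }
  ok <- detect_waterbridges(make_f(2.8, 2.8, 110), cfg)
  expect_length(ok, 1)
  expect_equal(ok[[1]]$water_serial, 9L)
  expect_equal(ok[[1]]$measurements$omega, 110)

  expect_length(
    detect_waterbridges(make_f(cfg$waterbridge_maxdist + 0.2, 2.8, 110), cfg), 0
  )
  expect_length(detect_waterbridges(make_f(2.8, 2.8, 60), cfg), 0)
  expect_length(detect_waterbridges(make_f(2.8, 2.8, 150), cfg), 0)
})

test_that("water-bridge triples on a 3-water scene equal the exhaustive scan", {
  for (seed in c(5, 6)) {
    f <- make_scene(seed)
    got <- detector_keys(run_all_detectors(f, cfg))$waterbridge
    want <- bf_scan(f, cfg)$waterbridge
    expect_equal(got, want)
  }
})

test_that("salt-bridge detector uses centroid distance and the sign rule", {
  make_f <- function(d, s1 = +1L, s2 = -1L) {
    f <- empty_features()
    f$charges <- list(
      list(sign = s1, serials = 1:3, centroid = c(0, 0, 0),
           group = "guanidinium", side = "protein", residue = "ARG-A-1"),
      list(sign = s2, serials = 4:5, centroid = c(d, 0, 0),
           group = "carboxylate", side = "ligand", residue = "LG1-L-1")
    )
    f
  }
  ok <- detect_saltbridges(make_f(4.0), cfg)
  expect_length(ok, 1)
  expect_equal(ok[[1]]$measurements$dist, 4.0)
  expect_equal(ok[[1]]$prot_serials, 1:3)
  expect_length(detect_saltbridges(make_f(cfg$saltbridge_dist_max + 0.1), cfg), 0)
  expect_length(detect_saltbridges(make_f(3.0, +1L, +1L), cfg), 0)
  expect_length(detect_saltbridges(make_f(3.0, -1L, -1L), cfg), 0)
})

test_that("pi-stacking detector distinguishes P and T subtypes and applies the offset rule", {
  make_f <- function(center, normal) {
    f <- empty_features()
    f$rings <- list(
      make_ring_feature(c(0, 0, 0), c(0, 0, 1), 1:6, "protein", "PHE-A-1"),
      make_ring_feature(center, normal, 7:12, "ligand", "LG1-L-1")
    )
    f
  }
  p <- detect_pistacking(make_f(c(0, 0, 3.5), c(0, 0, 1)), cfg)
  expect_length(p, 1)
  expect_equal(p[[1]]$subtype, "P")
  expect_equal(p[[1]]$measurements$centdist, 3.5)
  expect_equal(p[[1]]$measurements$offset, 0, tolerance = 1e-9)

  t_stack <- detect_pistacking(make_f(c(0, 0, 5.0), c(1, 0, 0)), cfg)
  expect_length(t_stack, 1)
  expect_equal(t_stack[[1]]$subtype, "T")

  off <- detect_pistacking(make_f(c(3.0, 0, 3.5), c(0, 0, 1)), cfg)
  expect_length(off, 0) # lateral offset 3.0 > 2.0

  tilted <- detect_pistacking(
    make_f(c(0, 0, 3.5), c(sin(50 * pi / 180), 0, cos(50 * pi / 180))), cfg
  )
  expect_length(tilted, 0) # 50 degrees: neither parallel nor perpendicular
})

test_that("pi-cation detector applies distance and offset rules", {
  make_f <- function(pos) {
    f <- empty_features()
    f$rings <- list(
      make_ring_feature(c(0, 0, 0), c(0, 0, 1), 1:6, "ligand", "LG1-L-1")
    )
    f$charges <- list(list(
      sign = +1L, serials = 7L, centroid = pos, group = "ammonium",
      side = "protein", residue = "LYS-A-1"
    ))
    f
  }
  ok <- detect_pication(make_f(c(0, 0, 4.0)), cfg)
  expect_length(ok, 1)
  expect_equal(ok[[1]]$measurements$dist, 4.0)
  expect_length(detect_pication(make_f(c(0, 0, 7.5)), cfg), 0)
  expect_length(detect_pication(make_f(c(3.0, 0, 4.0)), cfg), 0)
})

test_that("halogen-bond detector enforces sigma-hole and acceptor-axis angles", {
  make_f <- function(d, don_ang, acc_ang) {
    f <- empty_features()
    x <- c(0, 0, 0)
    a <- c(d, 0, 0)
    th <- don_ang * pi / 180
    cpos <- 1.75 * c(cos(th), sin(th), 0) # angle(C, X, A) = don_ang
    ya <- acc_ang * pi / 180
    ypos <- a + 1.23 * c(-cos(ya), sin(ya), 0) # angle(Y, A, X) = acc_ang
    f$halogen_donors <- list(list(
      x_serial = 1L, x_xyz = x, c_serial = 2L, c_xyz = cpos,
      side = "ligand", residue = "LG1-L-1", element = "CL", weak = FALSE
    ))
    f$halogen_acceptors <- list(list(
      serial = 3L, xyz = a, y_serial = 4L, y_xyz = ypos,
      side = "protein", residue = "GLY-A-1"
    ))
    f
  }
  ok <- detect_halogenbonds(make_f(3.3, 175, 120), cfg)
  expect_length(ok, 1)
  expect_equal(ok[[1]]$measurements$dist, 3.3)
  expect_equal(ok[[1]]$measurements$don_angle, 175, tolerance = 1e-6)
  expect_equal(ok[[1]]$measurements$acc_angle, 120, tolerance = 1e-6)
  expect_length(detect_halogenbonds(make_f(3.3, 120, 120), cfg), 0)
  expect_length(detect_halogenbonds(make_f(4.3, 175, 120), cfg), 0)
  expect_length(detect_halogenbonds(make_f(3.3, 175, 75), cfg), 0)
})

test_that("run_all_detectors always returns exactly the seven type keys", {
  res <- run_all_detectors(empty_features(), cfg)
  expect_named(
    res,
    c("hydrophobic", "hbond", "waterbridge", "saltbridge",
      "pistack", "pication", "halogen")
  )
  expect_true(all(vapply(res, length, integer(1)) == 0))
})

test_that("each detector equals the brute-force inequality scan on random scenes", {
  for (seed in 1:25) {
    f <- make_scene(seed)
    got <- detector_keys(run_all_detectors(f, cfg))
    want <- bf_scan(f, cfg)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("tightening any threshold yields a subset of the interactions", {
  tighten <- list(
    hydrophobic_dist_max = 3.0, hbond_dist_max = 3.0,
    saltbridge_dist_max = 4.0, pistack_dist_max = 4.0,
    pication_dist_max = 4.0, halogen_dist_max = 3.0,
    waterbridge_maxdist = 3.2, pistack_offset_max = 1.0
  )
  for (seed in c(3, 14)) {
    f <- make_scene(seed)
    base <- detector_keys(run_all_detectors(f, cfg))
    for (key in names(tighten)) {
      cfg2 <- cfg
      cfg2[[key]] <- tighten[[key]]
      sub <- detector_keys(run_all_detectors(f, cfg2))
      for (t in names(sub)) {
        expect_true(all(sub[[t]] %in% base[[t]]),
                    info = paste(key, t, "seed", seed))
      }
    }
  }
})

test_that("reported measurements re-checked against the config always pass", {
  for (seed in c(2, 9)) {
    f <- make_scene(seed)
    res <- run_all_detectors(f, cfg)
    for (x in res$hydrophobic) {
      expect_lte(x$measurements$dist, cfg$hydrophobic_dist_max)
    }
    for (x in res$hbond) {
      expect_lte(x$measurements$dist_da, cfg$hbond_dist_max)
      expect_gte(x$measurements$don_angle, cfg$hbond_don_angle_min)
    }
    for (x in res$waterbridge) {
      expect_true(x$measurements$dist_lw >= cfg$waterbridge_mindist &&
                    x$measurements$dist_lw <= cfg$waterbridge_maxdist)
      expect_true(x$measurements$omega >= cfg$waterbridge_omega_min &&
                    x$measurements$omega <= cfg$waterbridge_omega_max)
    }
    for (x in res$pistack) {
      expect_lte(x$measurements$centdist, cfg$pistack_dist_max)
      expect_lte(x$measurements$offset, cfg$pistack_offset_max)
    }
    for (x in res$halogen) {
      expect_lte(x$measurements$dist, cfg$halogen_dist_max)
      expect_lte(abs(x$measurements$don_angle - cfg$halogen_don_angle),
                 cfg$halogen_angle_dev)
    }
  }
})
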