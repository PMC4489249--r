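# Synthetic-complex generator: minimal PDB files containing one protein
# fragment with correct atom nomenclature plus a fictitious HET ligand
# ("LG1", kept off the blacklist) placed so a requested interaction
# geometry holds exactly. Decoy variants fail the corresponding threshold
# by at least 0.2 Angstrom / 5 degrees. Every detector and filter is
# therefore testable without downloading any structure.

.deg2rad <- function(x) x * pi / 180

# Glycine backbone fragment in the fixture frame. The carbonyl points along
# `a` = (0.858, 0.514, 0); ligands are grown from O along that direction.
.fx_gly <- function() {
  data.frame(
    name = c("N", "CA", "C", "O"),
    element = c("N", "C", "C", "O"),
    x = c(-0.730, 0.000, 1.330, 2.385),
    y = c(-1.270, 0.000, -0.740, -0.108),
    z = c(0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

.fx_carbonyl_dir <- c(0.858, 0.514, 0)

.fx_ala <- function() {
  g <- .fx_gly()
  rbind(g, data.frame(
    name = "CB", element = "C", x = 0, y = 1.53, z = 0,
    stringsAsFactors = FALSE
  ))
}

.fx_arg <- function() {
  g <- .fx_gly()
  side <- data.frame(
    name = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
    element = c("C", "C", "C", "N", "C", "N", "N"),
    x = c(0.0, 0.5, 0.0, 0.5, 0.0, 1.152, -1.152),
    y = c(1.53, 2.97, 4.41, 5.75, 6.99, 7.655, 7.655),
    z = c(0, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
  rbind(g, side)
}

.fx_lys_above <- function(nz) {
  # side chain climbing away from the ring plane below NZ
  step <- c(0, 0.437, 1.456)
  ce <- nz + 1.47 * .unit(c(0, 0.45, 1))
  cd <- ce + step
  cg <- cd + step
  cb <- cg + step
  ca <- cb + c(0, 0.5, 1.45)
  n <- ca + c(-1.0, 0.9, 0.5)
  cc <- ca + c(1.2, 0.8, 0.4)
  o <- cc + c(0.99, 0.69, 0.20)
  xyz <- rbind(n, ca, cc, o, cb, cg, cd, ce, nz)
  data.frame(
    name = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
    element = c("N", "C", "C", "O", "C", "C", "C", "C", "N"),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
}

.fx_hexagon <- function(center, normal, phase = 90, radius = 1.39) {
  n <- .unit(normal)
  e1 <- .perp_of(n)
  e2 <- .cross3(n, e1)
  t(vapply(seq(0, 300, by = 60) + phase, function(deg) {
    center + radius * (cos(.deg2rad(deg)) * e1 + sin(.deg2rad(deg)) * e2)
  }, numeric(3)))
}

.fx_phe <- function() {
  ring <- .fx_hexagon(c(0, 0, 0), c(0, 0, 1), phase = 90)
  # ring order CG(90) CD1(150) CE1(210) CZ(270) CE2(330) CD2(30)
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  cb <- c(0, 2.90, 0.20)
  ca <- c(0, 4.20, 1.00)
  n <- ca + c(-1.0, 1.0, 0.3)
  cc <- ca + c(1.2, 0.9, 0.2)
  o <- cc + c(0.99, 0.69, 0.20)
  xyz <- rbind(n, ca, cc, o, cb, ring)
  data.frame(
    name = c("N", "CA", "C", "O", "CB", ring_names),
    element = c("N", "C", "C", "O", rep("C", 7)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
}

.fx_benzene_lig <- function(center, normal, phase = 15) {
  ring <- .fx_hexagon(center, normal, phase = phase)
  list(
    atoms = data.frame(
      name = paste0("C", 1:6),
      element = rep("C", 6),
      x = ring[, 1], y = ring[, 2], z = ring[, 3],
      stringsAsFactors = FALSE
    ),
    bonds = lapply(1:6, function(i) {
      c(paste0("C", i), paste0("C", if (i == 6) 1 else i + 1))
    })
  )
}

# --- per-type builders -----------------------------------------------------
# Each returns list(protein, resid, ligand, lig_bonds, waters, inventory).

.fx_build_hydrophobic <- function(dist) {
  list(
    protein = .fx_ala(), resid = "ALA",
    ligand = data.frame(
      name = "C1", element = "C", x = 0, y = 1.53 + dist, z = 0,
      stringsAsFactors = FALSE
    ),
    lig_bonds = list(), waters = NULL,
    inventory = c(hydrophobic = if (dist <= 4.0) 1L else 0L)
  )
}

.fx_build_hbond <- function(dist, don_angle) {
  a <- .fx_carbonyl_dir
  p <- c(0.514, -0.858, 0)
  o_prot <- c(2.385, -0.108, 0)
  o1 <- o_prot + dist * a
  beta <- .deg2rad(70.53 + (180 - don_angle))
  u <- cos(beta) * (-a) + sin(beta) * p # axis C1 -> O1
  c1 <- o1 - 1.43 * u
  list(
    protein = .fx_gly(), resid = "GLY",
    ligand = data.frame(
      name = c("C1", "O1"), element = c("C", "O"),
      x = c(c1[1], o1[1]), y = c(c1[2], o1[2]), z = c(c1[3], o1[3]),
      stringsAsFactors = FALSE
    ),
    lig_bonds = list(c("C1", "O1")), waters = NULL,
    inventory = c(hbond = if (dist <= 4.1 && don_angle >= 100) 1L else 0L)
  )
}

.fx_build_waterbridge <- function(dist_lw, dist_pw, omega) {
  a <- .fx_carbonyl_dir
  p <- c(0.514, -0.858, 0)
  o_prot <- c(2.385, -0.108, 0)
  ow <- o_prot + dist_pw * a
  m <- -cos(.deg2rad(omega)) * a + sin(.deg2rad(omega)) * p
  o1 <- ow + dist_lw * m
  q <- .unit(.cross3(.cross3(m, c(0, 0, 1)), m)) # in-plane perpendicular of m
  u <- -cos(.deg2rad(70.53)) * m + sin(.deg2rad(70.53)) * q # axis C1 -> O1
  c1 <- o1 - 1.43 * u
  ok <- dist_lw >= 2.5 && dist_lw <= 4.1 && dist_pw >= 2.5 &&
    dist_pw <= 4.1 && omega >= 75 && omega <= 140
  list(
    protein = .fx_gly(), resid = "GLY",
    ligand = data.frame(
      name = c("C1", "O1"), element = c("C", "O"),
      x = c(c1[1], o1[1]), y = c(c1[2], o1[2]), z = c(c1[3], o1[3]),
      stringsAsFactors = FALSE
    ),
    lig_bonds = list(c("C1", "O1")),
    waters = data.frame(
      name = "O", element = "O", x = ow[1], y = ow[2], z = ow[3],
      stringsAsFactors = FALSE
    ),
    inventory = c(waterbridge = if (ok) 1L else 0L)
  )
}

.fx_build_saltbridge <- function(dist) {
  centroid_arg <- c(0, (6.99 + 7.655 + 7.655) / 3, 0)
  cent <- centroid_arg + c(0, dist, 0)
  o1 <- cent + c(1.1, 0, 0)
  o2 <- cent + c(-1.1, 0, 0)
  c1 <- cent + c(0, 0.61, 0)
  c2 <- c1 + c(0, 1.50, 0)
  xyz <- rbind(c1, c2, o1, o2)
  list(
    protein = .fx_arg(), resid = "ARG",
    ligand = data.frame(
      name = c("C1", "C2", "O1", "O2"),
      element = c("C", "C", "O", "O"),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE
    ),
    lig_bonds = list(c("C1", "C2"), c("C1", "O1"), c("C1", "O2")),
    waters = NULL,
    inventory = c(saltbridge = if (dist <= 5.5) 1L else 0L)
  )
}

.fx_build_pistack <- function(dist, angle, offset) {
  normal <- if (angle == 0) c(0, 0, 1) else c(sin(.deg2rad(angle)), 0, cos(.deg2rad(angle)))
  benz <- .fx_benzene_lig(c(offset, 0, dist), normal)
  subtype_ok <- angle <= 30 || abs(angle - 90) <= 30
  ok <- dist <= 5.5 && subtype_ok && offset <= 2.0 &&
    sqrt(dist^2 + offset^2) <= 5.5
  list(
    protein = .fx_phe(), resid = "PHE",
    ligand = benz$atoms, lig_bonds = benz$bonds, waters = NULL,
    inventory = c(pistack = if (ok) 1L else 0L)
  )
}

.fx_build_pication <- function(dist, offset) {
  benz <- .fx_benzene_lig(c(0, 0, 0), c(0, 0, 1))
  prot <- .fx_lys_above(c(offset, 0, dist))
  list(
    protein = prot, resid = "LYS",
    ligand = benz$atoms, lig_bonds = benz$bonds, waters = NULL,
    inventory = c(
      pication = if (sqrt(dist^2 + offset^2) <= 6.0 && offset <= 2.0) 1L else 0L
    )
  )
}

.fx_build_halogen <- function(dist, don_angle, acc_angle) {
  a <- .fx_carbonyl_dir
  v1 <- -a # O -> C direction
  p <- c(0.514, -0.858, 0)
  o_prot <- c(2.385, -0.108, 0)
  dx <- cos(.deg2rad(acc_angle)) * v1 + sin(.deg2rad(acc_angle)) * p
  x <- o_prot + dist * dx
  u0 <- .unit(o_prot - x)
  w <- .unit(.cross3(.cross3(u0, c(0, 0, 1)), u0))
  if (sum(w * p) > 0) w <- -w # keep the ligand on the far side
  e <- cos(.deg2rad(don_angle)) * u0 + sin(.deg2rad(don_angle)) * w
  c1 <- x + 1.75 * e
  c2 <- c1 + 1.50 * e
  xyz <- rbind(c1, c2, x)
  ok <- dist <= 4.0 && abs(don_angle - 165) <= 30 && abs(acc_angle - 120) <= 30
  list(
    protein = .fx_gly(), resid = "GLY",
    ligand = data.frame(
      name = c("C1", "C2", "CL1"),
      element = c("C", "C", "CL"),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE
    ),
    lig_bonds = list(c("C1", "C2"), c("C1", "CL1")),
    waters = NULL,
    inventory = c(halogen = if (ok) 1L else 0L)
  )
}

.fx_defaults <- list(
  hydrophobic = list(pos = list(dist = 3.6), decoy = list(dist = 4.5)),
  hbond = list(
    pos = list(dist = 2.9, don_angle = 180),
    decoy = list(dist = 2.9, don_angle = 90)
  ),
  waterbridge = list(
    pos = list(dist_lw = 2.8, dist_pw = 2.8, omega = 110),
    decoy = list(dist_lw = 4.3, dist_pw = 2.8, omega = 110)
  ),
  saltbridge = list(pos = list(dist = 4.0), decoy = list(dist = 6.5)),
  pistack = list(
    pos = list(dist = 4.8, angle = 0, offset = 0),
    decoy = list(dist = 4.8, angle = 0, offset = 3.0)
  ),
  pication = list(
    pos = list(dist = 4.0, offset = 0),
    decoy = list(dist = 7.5, offset = 0)
  ),
  halogen = list(
    pos = list(dist = 3.3, don_angle = 175, acc_angle = 120),
    decoy = list(dist = 3.3, don_angle = 120, acc_angle = 120)
  )
)

#' Specify a synthetic interaction fixture
#'
#' @param interaction_type One of the seven interaction types.
#' @param overrides Named list of geometry overrides (distances in Angstrom
#'   within 0.5-20, angles in degrees within 0-180); unset parameters use
#'   the type's idealized defaults.
#' @param decoy If `TRUE`, geometry is placed outside the default detection
#'   thresholds by at least 0.2 Angstrom / 5 degrees.
#' @param seed Integer seed for coordinate jitter (reproducible).
#' @param jitter Uniform jitter amplitude in Angstrom (default 0, exact
#'   geometry).
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(interaction_type, overrides = list(), decoy = FALSE,
                         seed = NULL, jitter = 0) {
  if (!interaction_type %in% .interaction_types) {
    stop(
      "unknown interaction type '", interaction_type, "'; expected one of: ",
      paste(.interaction_types, collapse = ", ")
    )
  }
  defaults <- .fx_defaults[[interaction_type]][[if (decoy) "decoy" else "pos"]]
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop(
      "unknown geometry override(s) for ", interaction_type, ": ",
      paste(unknown, collapse = ", ")
    )
  }
  params <- modifyList(defaults, overrides)
  for (key in names(params)) {
    v <- params[[key]]
    lim <- if (grepl("angle|omega", key)) {
      c(0, 180)
    } else if (grepl("offset", key)) {
      c(0, 20)
    } else {
      c(0.5, 20)
    }
    if (!is.finite(v) || v < lim[1] || v > lim[2]) {
      stop("override ", key, "=", v, " outside the physically sensible range")
    }
  }
  spec <- structure(
    list(
      interaction_type = interaction_type,
      params = params,
      decoy = decoy,
      seed = seed,
      jitter = jitter
    ),
    class = "fixture_spec"
  )
  frame <- .fx_frame(spec)
  n_expected <- sum(frame$inventory)
  if (decoy && n_expected > 0) {
    stop("contradictory overrides: decoy geometry lies inside the detection thresholds")
  }
  if (!decoy && n_expected == 0) {
    stop("contradictory overrides: positive geometry lies outside the detection thresholds")
  }
  spec
}

.fx_frame <- function(spec) {
  p <- spec$params
  switch(
    spec$interaction_type,
    hydrophobic = .fx_build_hydrophobic(p$dist),
    hbond = .fx_build_hbond(p$dist, p$don_angle),
    waterbridge = .fx_build_waterbridge(p$dist_lw, p$dist_pw, p$omega),
    saltbridge = .fx_build_saltbridge(p$dist),
    pistack = .fx_build_pistack(p$dist, p$angle, p$offset),
    pication = .fx_build_pication(p$dist, p$offset),
    halogen = .fx_build_halogen(p$dist, p$don_angle, p$acc_angle)
  )
}

# Assemble one or more fixture frames into PDB text. Each frame gets its
# own protein residue number, ligand residue (code LG1, chain L) and
# optional water; serials run consecutively.
.fx_to_pdb <- function(frames, shift_step = 50, jitter = 0, seed = NULL) {
  lines <- character(0)
  conect <- character(0)
  serial <- 0L
  if (jitter > 0 && !is.null(seed)) set.seed(seed)
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    shift <- c(shift_step * (i - 1), 0, 0)
    jit <- function(n) {
      if (jitter > 0) stats::runif(n, -jitter, jitter) else rep(0, n)
    }
    emit <- function(df, record, resid, chain, resno) {
      n <- nrow(df)
      jx <- jit(n); jy <- jit(n); jz <- jit(n)
      serials <- serial + seq_len(n)
      serial <<- serial + n
      for (r in seq_len(n)) {
        lines <<- c(lines, .format_pdb_line(
          record, serials[r], df$name[r], resid, chain, resno, "",
          df$x[r] + shift[1] + jx[r],
          df$y[r] + shift[2] + jy[r],
          df$z[r] + shift[3] + jz[r],
          1.00, df$element[r]
        ))
      }
      setNames(serials, df$name)
    }
    emit(fr$protein, "ATOM", fr$resid, "A", i)
    lig_serials <- emit(fr$ligand, "HETATM", "LG1", "L", i)
    for (b in fr$lig_bonds) {
      conect <- c(conect, sprintf(
        "CONECT%5d%5d", lig_serials[[b[1]]], lig_serials[[b[2]]]
      ))
    }
    if (!is.null(fr$waters)) {
      emit(fr$waters, "HETATM", "HOH", "W", 200 + i)
    }
  }
  c(lines, conect, "END")
}

#' Build a synthetic fixture PDB
#'
#' @param spec A `fixture_spec`.
#' @return Character vector of PDB lines with attributes `inventory`
#'   (named expected per-type interaction counts after refinement),
#'   `type` and `decoy`.
#' @export
build_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  frame <- .fx_frame(spec)
  pdb <- .fx_to_pdb(list(frame), jitter = spec$jitter, seed = spec$seed)
  inv <- setNames(integer(length(.interaction_types)), .interaction_types)
  inv[names(frame$inventory)] <- frame$inventory
  attr(pdb, "inventory") <- inv
  attr(pdb, "type") <- spec$interaction_type
  attr(pdb, "decoy") <- spec$decoy
  pdb
}

#' Build the fixture gallery
#'
#' One positive and one decoy case per interaction type, plus an extra
#' T-shaped stacking case: 15 cases, each with its ground-truth inventory.
#' Running the full pipeline on each case must reproduce the inventory
#' exactly (decoys yield empty inventories).
#'
#' @return List of cases: each has `name`, `type`, `decoy`, `pdb` (PDB
#'   lines) and `inventory` (named integer vector over the seven types).
#' @export
build_gallery <- function() {
  cases <- list()
  add <- function(name, spec) {
    pdb <- build_fixture(spec)
    cases[[length(cases) + 1]] <<- list(
      name = name,
      type = spec$interaction_type,
      decoy = spec$decoy,
      pdb = pdb,
      inventory = attr(pdb, "inventory")
    )
  }
  for (t in .interaction_types) {
    add(paste0(t, "_positive"), fixture_spec(t))
    add(paste0(t, "_decoy"), fixture_spec(t, decoy = TRUE))
  }
  add(
    "pistack_t_positive",
    fixture_spec("pistack", overrides = list(dist = 5.4, angle = 90))
  )
  cases
}

#' Build a combined fixture containing all seven positive cases
#'
#' The seven positive sub-complexes are placed 50 Angstrom apart so each
#' ligand forms its own binding site; the union of the per-site
#' inventories covers all seven interaction types exactly once.
#'
#' @return PDB lines with the summed `inventory` attribute.
#' @export
build_combined_fixture <- function() {
  frames <- lapply(.interaction_types, function(t) {
    .fx_frame(fixture_spec(t))
  })
  pdb <- .fx_to_pdb(frames)
  inv <- setNames(integer(length(.interaction_types)), .interaction_types)
  for (fr in frames) inv[names(fr$inventory)] <- inv[names(fr$inventory)] + fr$inventory
  attr(pdb, "inventory") <- inv
  pdb
}
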