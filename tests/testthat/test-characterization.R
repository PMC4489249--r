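test_that("hydrophobic perception follows the all-carbon-neighbor rule", {
  site <- site_of(pdb_from_atoms(rbind(leu_frag(), lig_probe(x = 6))))
  h <- find_hydrophobic_atoms(site)
  prot_names <- site$atoms$name[match(
    h$serial[h$side == "protein"], site$atoms$serial
  )]
  # CD1/CD2 see only CG; CB sees CA+CG; CG sees CB,CD1,CD2 - all carbon
  expect_setequal(prot_names, c("CB", "CG", "CD1", "CD2"))
  expect_true("C1" %in% site$atoms$name[match(
    h$serial[h$side == "ligand"], site$atoms$serial
  )])

  # serine CB is bonded to OG -> not hydrophobic
  site2 <- site_of(pdb_from_atoms(rbind(ser_frag(), lig_probe(x = 6))))
  h2 <- find_hydrophobic_atoms(site2)
  names2 <- site2$atoms$name[match(h2$serial, site2$atoms$serial)]
  expect_false("CB" %in% names2)
})

test_that("a fatty-acid-like chain is hydrophobic everywhere except the carboxyl carbon", {
  chain <- data.frame(
    record = "HETATM",
    name = c("C1", "O1", "O2", "C2", "C3", "C4", "C5"),
    resid = "LG1", chain = "L", resno = 1,
    x = c(6.0, 6.6, 6.6, 6.0, 6.7, 6.0, 6.7),
    y = c(0, 1.05, -1.05, 0, 0, 0, 0),
    z = c(0, -0.4, -0.4, 1.5, 2.8, 4.1, 5.4),
    element = c("C", "O", "O", "C", "C", "C", "C"),
    stringsAsFactors = FALSE
  )
  conect <- list(c(5, 6), c(5, 7), c(5, 8), c(8, 9), c(9, 10), c(10, 11))
  site <- site_of(pdb_from_atoms(rbind(gly_frag(), chain), conect))
  h <- find_hydrophobic_atoms(site)
  lig_names <- site$atoms$name[match(
    h$serial[h$side == "ligand"], site$atoms$serial
  )]
  expect_setequal(lig_names, c("C2", "C3", "C4", "C5"))
  # and the carboxylate head carries one negative charge center
  cc <- find_charge_centers(site)
  lig_cc <- Filter(function(x) x$side == "ligand", cc)
  expect_length(lig_cc, 1)
  expect_equal(lig_cc[[1]]$sign, -1L)
  expect_equal(lig_cc[[1]]$group, "carboxylate")
})

test_that("tyrosine OH is both donor and acceptor; carboxylate O acceptor-only; proline N is no donor", {
  site <- site_of(pdb_from_atoms(rbind(tyr_frag(), lig_probe(x = 5, y = -4))))
  hb <- find_hbond_partners(site)
  oh_serial <- site$atoms$serial[site$atoms$name == "OH"]
  expect_true(oh_serial %in% vapply(hb$donors, `[[`, integer(1), "serial"))
  expect_true(oh_serial %in% hb$acceptors$serial)

  # deprotonated ligand carboxylate oxygens: acceptors, never donors
  pdb <- paste(build_fixture(fixture_spec("saltbridge")), collapse = "\n")
  site2 <- site_of(pdb)
  hb2 <- find_hbond_partners(site2)
  o_serials <- site2$atoms$serial[site2$atoms$name %in% c("O1", "O2") &
                                    site2$atoms$resid == "LG1"]
  expect_true(all(o_serials %in% hb2$acceptors$serial))
  expect_false(any(o_serials %in%
                     vapply(hb2$donors, `[[`, integer(1), "serial")))

  site3 <- site_of(pdb_from_atoms(rbind(pro_frag(), lig_probe(x = 6))))
  hb3 <- find_hbond_partners(site3)
  n_serial <- site3$atoms$serial[site3$atoms$name == "N"]
  expect_false(n_serial %in% vapply(hb3$donors, `[[`, integer(1), "serial"))
})

test_that("halogen partner perception requires a carbon-bound halogen", {
  pdb <- paste(build_fixture(fixture_spec("halogen")), collapse = "\n")
  site <- site_of(pdb)
  xb <- find_halogen_partners(site)
  expect_length(xb$donors, 1)
  expect_equal(xb$donors[[1]]$element, "CL")
  # backbone carbonyl O is an acceptor with the carbonyl C as Y axis
  acc_serials <- vapply(xb$acceptors, `[[`, integer(1), "serial")
  o_serial <- site$atoms$serial[site$atoms$name == "O" &
                                  site$atoms$record == "ATOM"]
  expect_true(o_serial %in% acc_serials)

  # a bare chloride (no bonded carbon) is not a donor
  free_cl <- data.frame(
    record = "HETATM", name = "CL1", resid = "LG1", chain = "L", resno = 1,
    x = 5, y = 0, z = 0, element = "CL", stringsAsFactors = FALSE
  )
  site2 <- site_of(pdb_from_atoms(rbind(gly_frag(), free_cl)))
  expect_length(find_halogen_partners(site2)$donors, 0)
})

test_that("ring perception: one ring for Phe-like, two for Trp, none for chair cyclohexane", {
  pdb <- paste(build_fixture(fixture_spec("pistack")), collapse = "\n")
  site <- site_of(pdb)
  rings <- find_aromatic_rings(site)
  expect_length(Filter(function(r) r$side == "protein", rings), 1)
  expect_length(Filter(function(r) r$side == "ligand", rings), 1)
  expect_equal(rings[[1]]$size, 6)

  site2 <- site_of(pdb_from_atoms(rbind(trp_frag(), lig_probe(x = 6, y = -2))))
  rings2 <- find_aromatic_rings(site2)
  prot2 <- Filter(function(r) r$side == "protein", rings2)
  expect_length(prot2, 2)
  expect_setequal(vapply(prot2, `[[`, integer(1), "size"), c(5L, 6L))

  # chair cyclohexane: 0.3 A ring pucker fails the planarity tolerance
  chair <- t(vapply(0:5, function(k) {
    th <- k * pi / 3
    c(7 + 1.46 * cos(th), 1.46 * sin(th), 0.3 * (-1)^k)
  }, numeric(3)))
  hex <- data.frame(
    record = "HETATM", name = paste0("C", 1:6), resid = "LG1", chain = "L",
    resno = 1, x = chair[, 1], y = chair[, 2], z = chair[, 3],
    element = "C", stringsAsFactors = FALSE
  )
  conect <- lapply(1:6, function(i) c(4 + i, 4 + if (i == 6) 1 else i + 1))
  site3 <- site_of(pdb_from_atoms(rbind(gly_frag(), hex), conect))
  rings3 <- find_aromatic_rings(site3)
  expect_length(Filter(function(r) r$side == "ligand", rings3), 0)
})

test_that("charge centers: guanidinium centroid, no centers on alanine, opposite signs never share atoms", {
  pdb <- paste(build_fixture(fixture_spec("saltbridge")), collapse = "\n")
  site <- site_of(pdb)
  cc <- find_charge_centers(site)
  prot <- Filter(function(x) x$side == "protein", cc)
  expect_length(prot, 1)
  expect_equal(prot[[1]]$sign, +1L)
  expect_equal(prot[[1]]$group, "guanidinium")
  # centroid over CZ/NH1/NH2 computed by hand from the fixture coordinates
  expect_equal(prot[[1]]$centroid, c(0, (6.99 + 7.655 + 7.655) / 3, 0),
               tolerance = 1e-3)
  lig <- Filter(function(x) x$side == "ligand", cc)
  expect_length(lig, 1)
  expect_equal(lig[[1]]$sign, -1L)

  # no atom in two centers of opposite sign
  pos <- unlist(lapply(Filter(function(x) x$sign > 0, cc), `[[`, "serials"))
  neg <- unlist(lapply(Filter(function(x) x$sign < 0, cc), `[[`, "serials"))
  expect_length(intersect(pos, neg), 0)

  ala <- rbind(
    res_atoms(
      c("N", "CA", "C", "O", "CB"), c("N", "C", "C", "O", "C"),
      rbind(c(-0.73, -1.27, 0), c(0, 0, 0), c(1.33, -0.74, 0),
            c(2.385, -0.108, 0), c(0, 1.53, 0)), "ALA"
    ),
    lig_probe(x = 5)
  )
  cc2 <- find_charge_centers(site_of(pdb_from_atoms(ala)))
  expect_length(Filter(function(x) x$side == "protein", cc2), 0)
})

test_that("perception depends on topology only: rigid motion changes no feature counts", {
  set.seed(31)
  pdb <- paste(build_fixture(fixture_spec("saltbridge")), collapse = "\n")
  count_features <- function(f) {
    c(
      nrow(f$hydrophobic), length(f$donors), nrow(f$acceptors),
      length(f$halogen_donors), length(f$halogen_acceptors),
      length(f$rings), length(f$charges), nrow(f$waters)
    )
  }
  ref <- count_features(characterize_site(site_of(pdb)))
  for (i in 1:5) {
    moved <- transformed_pdb_text(pdb, random_rotation(), runif(3, -20, 20))
    expect_equal(count_features(characterize_site(site_of(moved))), ref)
  }
})

test_that("aromatic rings re-validate their own planarity invariant", {
  pdb <- paste(build_fixture(fixture_spec("pistack")), collapse = "\n")
  site <- site_of(pdb)
  for (r in find_aromatic_rings(site)) {
    xyz <- site$parent_atoms[match(r$serials, site$parent_atoms$serial),
                             c("x", "y", "z")]
    pl <- fit_plane(as.matrix(xyz))
    expect_lte(pl$planarity_rmsd, 0.25)
    expect_equal(pl$planarity_rmsd, r$planarity_rmsd, tolerance = 1e-9)
  }
})
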