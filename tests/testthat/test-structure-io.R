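test_that("a minimal one-residue glycine file parses into one protein residue", {
  s <- parse_pdb(pdb_from_atoms(gly_frag()))
  expect_s3_class(s, "ligprof_structure")
  expect_equal(nrow(s$residues), 1)
  expect_equal(s$residues$kind, "protein")
  expect_equal(nrow(s$atoms), 4)
  # peptide-unit bonds are inferred from covalent radii
  expect_true(2 %in% s$bonds[["1"]]) # N-CA
  expect_true(4 %in% s$bonds[["3"]]) # C=O
})

test_that("water codes are classified as water and HET codes as ligand candidates", {
  df <- rbind(
    gly_frag(),
    data.frame(
      record = "HETATM", name = "O", resid = "HOH", chain = "W", resno = 201,
      x = 8, y = 0, z = 0, element = "O", stringsAsFactors = FALSE
    ),
    lig_probe(x = 12)
  )
  s <- parse_pdb(pdb_from_atoms(df))
  kinds <- setNames(s$residues$kind, s$residues$resid)
  expect_equal(unname(kinds["HOH"]), "water")
  expect_equal(unname(kinds["LG1"]), "ligand-candidate")
})

test_that("altloc conflicts keep the highest-occupancy conformer", {
  df <- gly_frag()
  dup <- df[2, ]
  df$occ <- 1
  df$altloc <- " "
  df$occ[2] <- 0.6
  df$altloc[2] <- "A"
  dup$x <- 0.5
  dup$occ <- 0.4
  dup$altloc <- "B"
  s <- parse_pdb(pdb_from_atoms(rbind(df, dup)))
  ca <- s$atoms[s$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 0) # conformer A
  expect_equal(ca$altloc, "A")
})

test_that("model selection works and absent models raise a listing error", {
  body <- pdb_from_atoms(gly_frag())
  two_models <- paste(
    c("MODEL     1", strsplit(body, "\n")[[1]][1:4], "ENDMDL",
      "MODEL     2", strsplit(body, "\n")[[1]][1:4], "ENDMDL", "END"),
    collapse = "\n"
  )
  s2 <- parse_pdb(two_models, model = 2)
  expect_equal(s2$model_index, 2)
  expect_equal(s2$n_models, 2)
  expect_error(parse_pdb(two_models, model = 3), "available models: 1, 2")
  expect_error(parse_pdb("REMARK nothing here"), "no ATOM or HETATM")
})

test_that("hydrogenation adds exactly one polar H to serine OG and is idempotent", {
  s <- parse_pdb(pdb_from_atoms(ser_frag()))
  h <- hydrogenate(s)
  og <- h$atoms$serial[h$atoms$name == "OG"]
  og_h <- h$bonds[[as.character(og)]]
  og_h <- og_h[h$atoms$is_h[match(og_h, h$atoms$serial)]]
  expect_length(og_h, 1)
  # backbone N gains its amide H as well
  n <- h$atoms$serial[h$atoms$name == "N"]
  n_h <- h$bonds[[as.character(n)]]
  n_h <- n_h[h$atoms$is_h[match(n_h, h$atoms$serial)]]
  expect_length(n_h, 1)
  # heavy-atom coordinates unchanged
  expect_equal(
    h$atoms[!h$atoms$is_h, c("x", "y", "z")],
    s$atoms[, c("x", "y", "z")]
  )
  # idempotence
  h2 <- hydrogenate(h)
  expect_equal(nrow(h2$atoms), nrow(h$atoms))
})

test_that("free carboxylates stay deprotonated at the pH-7 policy", {
  pdb <- build_fixture(fixture_spec("saltbridge"))
  s <- hydrogenate(parse_pdb(paste(pdb, collapse = "\n")))
  for (an in c("O1", "O2")) {
    o <- s$atoms$serial[s$atoms$name == an & s$atoms$resid == "LG1"]
    nb <- s$bonds[[as.character(o)]]
    expect_false(any(s$atoms$is_h[match(nb, s$atoms$serial)]))
  }
  # Asp/Glu-equivalent: ligand oxygens are still acceptors via perception,
  # checked in the characterization tests.
})

test_that("ligand filtering honors the blacklist and keeps fatty-acid-like HET groups", {
  # palmitic-acid-like chain (PLM), glycerol and sulfate in one structure
  plm <- data.frame(
    record = "HETATM",
    name = c("C1", "O1", "O2", "C2", "C3"),
    resid = "PLM", chain = "L", resno = 1,
    x = c(10, 10.8, 8.9, 10.6, 10.0),
    y = c(0, 0.9, 0.4, -1.4, -2.6),
    z = 0,
    element = c("C", "O", "O", "C", "C"),
    stringsAsFactors = FALSE
  )
  gol <- data.frame(
    record = "HETATM", name = c("C1", "O1"), resid = "GOL", chain = "L",
    resno = 2, x = c(20, 21), y = 0, z = 0, element = c("C", "O"),
    stringsAsFactors = FALSE
  )
  so4 <- data.frame(
    record = "HETATM", name = c("S", "O1"), resid = "SO4", chain = "L",
    resno = 3, x = c(30, 31.4), y = 0, z = 0, element = c("S", "O"),
    stringsAsFactors = FALSE
  )
  s <- parse_pdb(pdb_from_atoms(rbind(gly_frag(), plm, gol, so4)))
  kept <- filter_ligands(s)
  expect_equal(kept$resid, "PLM")
  excluded <- attr(kept, "excluded")
  expect_setequal(excluded$reason, "blacklisted")

  # only water + ion: nothing retained
  ion <- data.frame(
    record = "HETATM", name = "NA", resid = "NA", chain = "L", resno = 5,
    x = 5, y = 5, z = 5, element = "NA", stringsAsFactors = FALSE
  )
  hoh <- data.frame(
    record = "HETATM", name = "O", resid = "HOH", chain = "W", resno = 201,
    x = 3, y = 3, z = 3, element = "O", stringsAsFactors = FALSE
  )
  s2 <- parse_pdb(pdb_from_atoms(rbind(gly_frag(), ion, hoh)))
  expect_equal(nrow(filter_ligands(s2)), 0)
})

test_that("HET groups covalently linked into the polymer are excluded", {
  # HET carbon 1.5 A from the backbone carbonyl carbon -> covalent bond
  linked <- data.frame(
    record = "HETATM", name = "C1", resid = "XYZ", chain = "A", resno = 2,
    x = 1.33 + 1.5, y = -0.74, z = 0, element = "C", stringsAsFactors = FALSE
  )
  s <- parse_pdb(pdb_from_atoms(rbind(gly_frag(), linked)))
  kept <- filter_ligands(s)
  expect_equal(nrow(kept), 0)
  expect_match(attr(kept, "excluded")$reason, "covalent")
})

test_that("ligand filtering is monotone in the blacklist", {
  pdb <- pdb_from_atoms(rbind(gly_frag(), lig_probe(), within(lig_probe(), {
    resid <- "LG2"
    resno <- 2
    x <- 9
  })))
  s <- parse_pdb(pdb)
  small <- filter_ligands(s, blacklist = character(0))
  bigger <- filter_ligands(s, blacklist = "LG2")
  biggest <- filter_ligands(s, blacklist = c("LG2", "LG1"))
  expect_true(all(bigger$reskey %in% small$reskey))
  expect_true(all(biggest$reskey %in% bigger$reskey))
  expect_equal(nrow(small), 2)
  expect_equal(nrow(bigger), 1)
  expect_equal(nrow(biggest), 0)
})

test_that("binding-site membership respects the cutoff boundary", {
  cutoff <- 7.5
  # ligand at the origin; one residue whose nearest atom sits just inside
  # the envelope, one entirely outside it
  near <- gly_frag(resno = 1, shift = c(cutoff - 0.1 + 1.27, 0, 0))
  # nearest atom of `near` is N at x = cutoff - 0.1 - 0.73 ... well inside
  far <- gly_frag(resno = 2, shift = c(cutoff + 1 + 2.0, 0, 0))
  df <- rbind(near, far, lig_probe(x = 0, y = 0, z = 0))
  s <- hydrogenate(parse_pdb(pdb_from_atoms(df)))
  s_far_min <- min(sqrt(s$atoms$x^2 + s$atoms$y^2 + s$atoms$z^2)[
    s$atoms$resno == 2 & s$atoms$record == "ATOM"
  ])
  expect_gt(s_far_min, cutoff) # construction check
  sites <- extract_binding_sites(s, filter_ligands(s), cutoff = cutoff)
  expect_length(sites, 1)
  expect_true("GLY:A:1" %in% sites[[1]]$protein_reskeys)
  expect_false("GLY:A:2" %in% sites[[1]]$protein_reskeys)
})

test_that("two ligand copies yield two sites with distinct identifiers", {
  lig2 <- lig_probe(x = 5, y = -2)
  lig2$chain <- "M"
  lig2$resno <- 2
  df <- rbind(gly_frag(), lig_probe(x = 5, y = 2), lig2)
  s <- hydrogenate(parse_pdb(pdb_from_atoms(df)))
  sites <- extract_binding_sites(s, filter_ligands(s))
  expect_length(sites, 2)
  ids <- vapply(sites, function(x) x$site_id, character(1))
  expect_equal(length(unique(ids)), 2)
})

test_that("an isolated ligand still yields a flagged site", {
  df <- rbind(gly_frag(), lig_probe(x = 40))
  s <- hydrogenate(parse_pdb(pdb_from_atoms(df)))
  sites <- extract_binding_sites(s, filter_ligands(s))
  expect_length(sites, 1)
  expect_true(sites[[1]]$isolated)
})

test_that("parse -> serialize -> re-parse preserves coordinates at PDB precision", {
  for (t in c("saltbridge", "halogen", "waterbridge")) {
    pdb <- build_fixture(fixture_spec(t))
    s1 <- parse_pdb(paste(pdb, collapse = "\n"))
    s2 <- parse_pdb(paste(write_structure_pdb(s1), collapse = "\n"))
    expect_equal(nrow(s1$atoms), nrow(s2$atoms))
    expect_equal(s1$atoms$x, s2$atoms$x, tolerance = 1e-3)
    expect_equal(s1$atoms$y, s2$atoms$y, tolerance = 1e-3)
    expect_equal(s1$atoms$z, s2$atoms$z, tolerance = 1e-3)
    expect_equal(s1$atoms$name, s2$atoms$name)
  }
})

test_that("binding-site membership is invariant under rigid motion", {
  set.seed(7)
  pdb <- paste(build_fixture(fixture_spec("saltbridge")), collapse = "\n")
  s <- hydrogenate(parse_pdb(pdb))
  ref <- extract_binding_sites(s, filter_ligands(s))[[1]]
  for (i in 1:5) {
    s2 <- transform_structure(
      hydrogenate(parse_pdb(pdb)), random_rotation(), runif(3, -30, 30)
    )
    st2 <- extract_binding_sites(s2, filter_ligands(s2))[[1]]
    expect_setequal(st2$protein_reskeys, ref$protein_reskeys)
    expect_setequal(st2$ligand_reskeys, ref$ligand_reskeys)
  }
})
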