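# Helpers to build small PDB fixtures directly from atom tables, plus
# hand-built residue fragments used in the characterization tests.

pdb_line <- function(record, serial, name, resid, chain, resno,
                     x, y, z, element, occ = 1, altloc = " ") {
  fname <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf("%-3s", name)
  if (nchar(fname) == 3) fname <- paste0(" ", fname)
  sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    record, serial, fname, altloc, resid, chain, resno, " ",
    x, y, z, occ, 0, element
  )
}

# df columns: record, name, resid, chain, resno, x, y, z, element and
# optionally occ, altloc. Serial numbers are the row numbers; `conect`
# holds integer row-index pairs.
pdb_from_atoms <- function(df, conect = list()) {
  if (is.null(df$occ)) df$occ <- 1
  if (is.null(df$altloc)) df$altloc <- " "
  lines <- vapply(seq_len(nrow(df)), function(i) {
    pdb_line(
      df$record[i], i, df$name[i], df$resid[i], df$chain[i], df$resno[i],
      df$x[i], df$y[i], df$z[i], df$element[i], df$occ[i], df$altloc[i]
    )
  }, character(1))
  cl <- vapply(conect, function(p) {
    sprintf("CONECT%5d%5d", p[1], p[2])
  }, character(1))
  paste(c(lines, cl, "END"), collapse = "\n")
}

res_atoms <- function(names, elements, xyz, resid, chain = "A", resno = 1,
                      record = "ATOM") {
  data.frame(
    record = record, name = names, resid = resid, chain = chain,
    resno = resno, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = elements, stringsAsFactors = FALSE
  )
}

gly_frag <- function(chain = "A", resno = 1, shift = c(0, 0, 0)) {
  xyz <- rbind(
    c(-0.73, -1.27, 0), c(0, 0, 0), c(1.33, -0.74, 0), c(2.385, -0.108, 0)
  )
  xyz <- sweep(xyz, 2, -shift)
  res_atoms(c("N", "CA", "C", "O"), c("N", "C", "C", "O"), xyz,
            "GLY", chain, resno)
}

ser_frag <- function() {
  xyz <- rbind(
    c(-0.73, -1.27, 0), c(0, 0, 0), c(1.33, -0.74, 0), c(2.385, -0.108, 0),
    c(0, 1.53, 0), c(0.70, 2.43, 0.80)
  )
  res_atoms(
    c("N", "CA", "C", "O", "CB", "OG"),
    c("N", "C", "C", "O", "C", "O"), xyz, "SER"
  )
}

leu_frag <- function() {
  xyz <- rbind(
    c(-0.73, -1.27, 0), c(0, 0, 0), c(1.33, -0.74, 0), c(2.385, -0.108, 0),
    c(0, 1.53, 0), c(0.50, 2.97, 0), c(1.90, 3.57, 0), c(-0.10, 4.07, 0.80)
  )
  res_atoms(
    c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
    c("N", "C", "C", "O", "C", "C", "C", "C"), xyz, "LEU"
  )
}

pro_frag <- function() {
  xyz <- rbind(
    c(-0.73, -1.27, 0), c(0, 0, 0), c(1.33, -0.74, 0), c(2.385, -0.108, 0),
    c(0, 1.53, 0), c(-1.20, 1.00, 0.50), c(-1.93, -0.47, 0.40)
  )
  res_atoms(
    c("N", "CA", "C", "O", "CB", "CG", "CD"),
    c("N", "C", "C", "O", "C", "C", "C"), xyz, "PRO"
  )
}

tyr_frag <- function() {
  hexagon <- t(vapply(seq(90, 390, by = 60)[1:6], function(deg) {
    th <- deg * pi / 180
    c(1.39 * cos(th), 1.39 * sin(th), 0)
  }, numeric(3)))
  # order CG(90) CD1(150) CE1(210) CZ(270) CE2(330) CD2(30)
  xyz <- rbind(
    c(-1.0, 5.2, 1.3), c(0, 4.2, 1.0), c(1.2, 5.1, 1.2), c(2.19, 5.79, 1.4),
    c(0, 2.9, 0.2), hexagon, c(0, -2.77, 0)
  )
  res_atoms(
    c("N", "CA", "C", "O", "CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2", "OH"),
    c("N", "C", "C", "O", "C", rep("C", 6), "O"), xyz, "TYR"
  )
}

trp_frag <- function() {
  pent <- t(vapply(c(90, 162, 234, 306, 18), function(deg) {
    th <- deg * pi / 180
    c(1.19 * cos(th), 1.19 * sin(th), 0)
  }, numeric(3))) # CG CD1 NE1 CE2 CD2
  hexc <- c(2.07, -0.667, 0)
  hexpart <- t(vapply(c(72, 12, -48, 252), function(deg) {
    th <- deg * pi / 180
    hexc + 1.40 * c(cos(th), sin(th), 0)
  }, numeric(3))) # CE3 CZ3 CH2 CZ2
  xyz <- rbind(
    c(-1.2, 4.3, 1.8), c(0, 3.6, 1.8), c(1.3, 4.2, 2.0), c(2.3, 4.9, 2.2),
    c(0, 2.4, 0.9), pent, hexpart
  )
  res_atoms(
    c("N", "CA", "C", "O", "CB",
      "CG", "CD1", "NE1", "CE2", "CD2", "CE3", "CZ3", "CH2", "CZ2"),
    c("N", "C", "C", "O", "C", "C", "C", "N", rep("C", 6)), xyz, "TRP"
  )
}

lig_probe <- function(x = 5, y = 0, z = 0) {
  data.frame(
    record = "HETATM", name = "C1", resid = "LG1", chain = "L", resno = 1,
    x = x, y = y, z = z, element = "C", stringsAsFactors = FALSE
  )
}

# Parse, hydrogenate and extract the first binding site of a PDB text.
site_of <- function(pdbtext, cutoff = 7.5) {
  s <- hydrogenate(parse_pdb(pdbtext))
  ligs <- filter_ligands(s)
  sites <- extract_binding_sites(s, ligs, cutoff = cutoff)
  stopifnot(length(sites) >= 1)
  sites[[1]]
}

gallery_pdb_text <- function(case) paste(case$pdb, collapse = "\n")

# Translate / rotate raw PDB fixture text via the structure transform.
transformed_pdb_text <- function(pdbtext, rotation, translation) {
  s <- parse_pdb(pdbtext)
  s <- transform_structure(s, rotation, translation)
  paste(write_structure_pdb(s), collapse = "\n")
}
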