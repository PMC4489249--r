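# Chemistry lookup tables: element covalent radii, residue classification,
# donor/acceptor templates for the 20 standard amino acids.

# Single-bond covalent radii (Angstrom), Cordero-style values for the
# elements that occur in PDB entries relevant here. Used for bond inference:
# two atoms are bonded if d <= r1 + r2 + 0.45 (capped at 3.4 A).
.covalent_radii <- c(
  H = 0.31, D = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  P = 1.07, S = 1.05, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20,
  B = 0.84, "NA" = 1.54, K = 1.96, MG = 1.41, CA = 1.76, ZN = 1.22,
  MN = 1.39, FE = 1.32, CU = 1.32, NI = 1.24, CO = 1.26, CD = 1.44,
  HG = 1.32
)

.water_codes <- c("HOH", "DOD", "WAT", "H2O")

.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

.halogen_elements <- c("F", "CL", "BR", "I")

# Polar hydrogen counts added to standard side chains at the pH-7 policy:
# Arg/Lys protonated, Asp/Glu deprotonated, His neutral tau tautomer
# (single H on NE2, ND1 is an acceptor).
.sidechain_h_template <- list(
  SER = c(OG = 1),
  THR = c(OG1 = 1),
  TYR = c(OH = 1),
  CYS = c(SG = 1),
  TRP = c(NE1 = 1),
  ASN = c(ND2 = 2),
  GLN = c(NE2 = 2),
  LYS = c(NZ = 3),
  ARG = c(NE = 1, NH1 = 2, NH2 = 2),
  HIS = c(NE2 = 1)
)

# Aromatic ring atom names for the four aromatic standard residues.
.ring_templates <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(
    c("CG", "CD1", "NE1", "CE2", "CD2"),
    c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
  ),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2"))
)

# Formal charge centers on standard side chains at pH 7. Histidine is
# handled separately (charged only when both ring nitrogens carry H).
.protein_charge_templates <- list(
  ARG = list(sign = +1L, atoms = c("CZ", "NH1", "NH2"), group = "guanidinium"),
  LYS = list(sign = +1L, atoms = c("NZ"), group = "ammonium"),
  ASP = list(sign = -1L, atoms = c("OD1", "OD2"), group = "carboxylate"),
  GLU = list(sign = -1L, atoms = c("OE1", "OE2"), group = "carboxylate")
)

.covalent_radius <- function(element) {
  r <- .covalent_radii[element]
  r[is.na(r)] <- 1.5
  unname(r)
}

# Derive an element symbol from a PDB atom name when the element column is
# blank. Two-letter symbols are recognized only when the full alphabetic
# token matches a known element (CL, BR, FE, ...).
.guess_element <- function(name) {
  token <- toupper(gsub("[^A-Za-z]", "", name))
  if (nchar(token) == 0) return("X")
  two <- substr(token, 1, 2)
  if (nchar(token) >= 2 && two %in% names(.covalent_radii) &&
      !two %in% c("CA", "CD", "CO", "NA")) {
    # CA/CD/CO/NA as atom names are almost always carbons/nitrogens within
    # residues; metals come through the element column instead.
    return(two)
  }
  substr(token, 1, 1)
}
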