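# Heavy-atom bond templates for the 20 standard residues, heme b (HEM) and
# water, plus covalent radii for the distance fallback rule.

pair_mat <- function(...) {
  v <- c(...)
  matrix(v, ncol = 2, byrow = TRUE)
}

BACKBONE_BONDS <- pair_mat("N", "CA", "CA", "C", "C", "O", "C", "OXT")

SIDECHAIN_BONDS <- list(
  ALA = pair_mat("CA", "CB"),
  ARG = pair_mat("CA", "CB", "CB", "CG", "CG", "CD", "CD", "NE", "NE", "CZ",
                 "CZ", "NH1", "CZ", "NH2"),
  ASN = pair_mat("CA", "CB", "CB", "CG", "CG", "OD1", "CG", "ND2"),
  ASP = pair_mat("CA", "CB", "CB", "CG", "CG", "OD1", "CG", "OD2"),
  CYS = pair_mat("CA", "CB", "CB", "SG"),
  GLN = pair_mat("CA", "CB", "CB", "CG", "CG", "CD", "CD", "OE1", "CD", "NE2"),
  GLU = pair_mat("CA", "CB", "CB", "CG", "CG", "CD", "CD", "OE1", "CD", "OE2"),
  GLY = matrix(character(0), ncol = 2),
  HIS = pair_mat("CA", "CB", "CB", "CG", "CG", "ND1", "ND1", "CE1",
                 "CE1", "NE2", "NE2", "CD2", "CD2", "CG"),
  ILE = pair_mat("CA", "CB", "CB", "CG1", "CB", "CG2", "CG1", "CD1"),
  LEU = pair_mat("CA", "CB", "CB", "CG", "CG", "CD1", "CG", "CD2"),
  LYS = pair_mat("CA", "CB", "CB", "CG", "CG", "CD", "CD", "CE", "CE", "NZ"),
  MET = pair_mat("CA", "CB", "CB", "CG", "CG", "SD", "SD", "CE"),
  PHE = pair_mat("CA", "CB", "CB", "CG", "CG", "CD1", "CD1", "CE1",
                 "CE1", "CZ", "CZ", "CE2", "CE2", "CD2", "CD2", "CG"),
  PRO = pair_mat("CA", "CB", "CB", "CG", "CG", "CD", "CD", "N"),
  SER = pair_mat("CA", "CB", "CB", "OG"),
  THR = pair_mat("CA", "CB", "CB", "OG1", "CB", "CG2"),
  TRP = pair_mat("CA", "CB", "CB", "CG", "CG", "CD1", "CD1", "NE1",
                 "NE1", "CE2", "CE2", "CD2", "CD2", "CG", "CE2", "CZ2",
                 "CZ2", "CH2", "CH2", "CZ3", "CZ3", "CE3", "CE3", "CD2"),
  TYR = pair_mat("CA", "CB", "CB", "CG", "CG", "CD1", "CD1", "CE1",
                 "CE1", "CZ", "CZ", "CE2", "CE2", "CD2", "CD2", "CG",
                 "CZ", "OH"),
  VAL = pair_mat("CA", "CB", "CB", "CG1", "CB", "CG2")
)

# Heme b (protoporphyrin IX + Fe), wwPDB chemical component HEM connectivity.
HEM_BONDS <- pair_mat(
  "FE", "NA", "FE", "NB", "FE", "NC", "FE", "ND",
  "NA", "C1A", "NA", "C4A", "C1A", "C2A", "C2A", "C3A", "C3A", "C4A",
  "C1A", "CHA", "C4A", "CHB", "C2A", "CAA", "C3A", "CMA",
  "CAA", "CBA", "CBA", "CGA", "CGA", "O1A", "CGA", "O2A",
  "NB", "C1B", "NB", "C4B", "C1B", "C2B", "C2B", "C3B", "C3B", "C4B",
  "C1B", "CHB", "C4B", "CHC", "C2B", "CMB", "C3B", "CAB", "CAB", "CBB",
  "NC", "C1C", "NC", "C4C", "C1C", "C2C", "C2C", "C3C", "C3C", "C4C",
  "C1C", "CHC", "C4C", "CHD", "C2C", "CMC", "C3C", "CAC", "CAC", "CBC",
  "ND", "C1D", "ND", "C4D", "C1D", "C2D", "C2D", "C3D", "C3D", "C4D",
  "C1D", "CHD", "C4D", "CHA", "C2D", "CMD", "C3D", "CAD",
  "CAD", "CBD", "CBD", "CGD", "CGD", "O1D", "CGD", "O2D")

WATER_BONDS <- pair_mat("O", "H1", "O", "H2", "OW", "HW1", "OW", "HW2")

residue_template <- function(resname) {
  if (resname %in% names(SIDECHAIN_BONDS))
    return(rbind(BACKBONE_BONDS, SIDECHAIN_BONDS[[resname]]))
  if (resname == "HEM") return(HEM_BONDS)
  if (resname %in% WATER_RESNAMES) return(WATER_BONDS)
  NULL
}

# Covalent radii (Angstrom, Cordero et al. consensus values) used in the
# distance fallback rule: bonded iff r <= r_i + r_j + 0.45.
COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                    P = 1.07, Se = 1.20, F = 0.57, Cl = 1.02, Br = 1.20,
                    I = 1.39, Fe = 1.32, Zn = 1.22, Mg = 1.41, Mn = 1.39,
                    Cu = 1.32, Ni = 1.24, Co = 1.26, Ca = 1.76, Na = 1.66,
                    K = 2.03)

covalent_radius <- function(element) {
  r <- COVALENT_RADII[element]
  r[is.na(r)] <- 0.77  # generic heavy-atom radius for unlisted elements
  unname(r)
}
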