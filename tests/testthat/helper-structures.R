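# Structures built in code for the tests.  mini_peroxidase() is a reduced
# heme/His/Tyr/Trp arrangement whose optimal paths have hand-computable
# scores; the PDB text helpers exercise the real reader.

atom_row <- function(serial, name, element, resname, resno, chain,
                     het = FALSE, water = FALSE) {
  data.frame(serial = serial, name = name, element = element,
             resname = resname, resno = resno, chain = chain,
             het = het, water = water, stringsAsFactors = FALSE)
}

# Heme iron at the origin with its four pyrrole nitrogens, a proximal His
# NE2 2.1 A below, and three aromatic acceptors attached by through-space
# jumps longer than the heavy-atom H-bond fallback cutoff (3.5 A), so every
# non-covalent step is a space edge:
#   TYR 10 OH:  Fe-NA (2.0, covalent) then NA..OH 3.6 space
#   TRP 20 NE1: Fe-NB (2.0, covalent) then NB..NE1 3.7 space
#   TYR 30 OH:  Fe-NE2 (2.1, Fe-His link) then NE2..OH 3.8 space
mini_peroxidase <- function() {
  atoms <- rbind(
    atom_row(1L, "FE", "Fe", "HEM", 501L, "A", het = TRUE),
    atom_row(2L, "NA", "N", "HEM", 501L, "A", het = TRUE),
    atom_row(3L, "NB", "N", "HEM", 501L, "A", het = TRUE),
    atom_row(4L, "NC", "N", "HEM", 501L, "A", het = TRUE),
    atom_row(5L, "ND", "N", "HEM", 501L, "A", het = TRUE),
    atom_row(6L, "NE2", "N", "HIS", 215L, "A"),
    atom_row(7L, "OH", "O", "TYR", 10L, "A"),
    atom_row(8L, "CZ", "C", "TYR", 10L, "A"),
    atom_row(9L, "NE1", "N", "TRP", 20L, "A"),
    atom_row(10L, "OH", "O", "TYR", 30L, "A"))
  xyz <- rbind(
    c(0, 0, 0),         # FE
    c(2, 0, 0),         # NA
    c(0, 2, 0),         # NB
    c(-2, 0, 0),        # NC
    c(0, -2, 0),        # ND
    c(0, 0, -2.1),      # HIS NE2
    c(5.6, 0, 0),       # TYR10 OH (3.6 from NA)
    c(7.0, 0, 0),       # TYR10 CZ
    c(0, 5.7, 0),       # TRP20 NE1 (3.7 from NB)
    c(0, 0, -5.9))      # TYR30 OH (3.8 from NE2)
  et_structure(atoms, xyz)
}

# hand-computed optimal scores for mini_peroxidase with default parameters
mini_expected <- function() {
  covalent <- log(0.6)
  space <- function(r) log(0.6) - 1.7 * (r - 1.4)
  list(
    tyr10 = covalent + space(3.6),
    trp20 = covalent + space(3.7),
    tyr30 = covalent + space(3.8))   # via the Fe-His link
}

pdb_line <- function(type, serial, name, resname, chain, resno, x, y, z,
                     element = "") {
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          type, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          resname, chain, resno, x, y, z, element)
}

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# ideal water dimer for H-bond detection tests: donor O-H pointing at an
# acceptor O at the given H..A distance and D-H..A angle (degrees)
water_dimer <- function(ha_dist = 1.9, dha_angle = 170) {
  theta <- (180 - dha_angle) * pi / 180
  h <- c(0.96, 0, 0)
  acc <- h + ha_dist * c(cos(theta), sin(theta), 0)
  atoms <- rbind(
    atom_row(1L, "O", "O", "HOH", 1L, "W", het = TRUE, water = TRUE),
    atom_row(2L, "H1", "H", "HOH", 1L, "W", het = TRUE, water = TRUE),
    atom_row(3L, "O", "O", "HOH", 2L, "W", het = TRUE, water = TRUE))
  et_structure(atoms, rbind(c(0, 0, 0), h, acc))
}

constant_trajectory <- function(structure, n_frames = 3L) {
  xyz <- model_xyz(structure, 1L)
  et_trajectory(structure,
                array(rep(xyz, n_frames),
                      dim = c(nrow(xyz), 3L, n_frames)))
}
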