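# Synthetic structures, graphs and trajectories with known ground truth.
# Generators reuse legal PDB vocabulary (glycine chains, HOH waters) so the
# fixtures pass through the real reader and the real bond-perception rules
# rather than bypassing them.  Each generator attaches its analytic ground
# truth (closed-form ln_k, occupancy mask, expected count) as the
# `ground_truth` attribute, to be asserted -- never recomputed -- by
# consumers.

with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is mandatory for stochastic generators")
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# atom names walking away from a chain's bridge-adjacent terminus so that
# every consecutive pair is a template or peptide bond
chain_names_from_terminal <- function(n_atoms, terminal = c("C", "O")) {
  terminal <- match.arg(terminal)
  names_from_end <- character(n_atoms)
  cycle <- c("C", "CA", "N")
  for (k in seq_len(n_atoms)) {
    names_from_end[k] <- if (terminal == "O") {
      if (k == 1) "O" else cycle[(k - 2) %% 3 + 1]
    } else cycle[(k - 1) %% 3 + 1]
  }
  # residue numbers grouped so that template bonds (N-CA, CA-C, C-O) are
  # intra-residue and C-N junctions fall between residues
  resno <- integer(n_atoms)
  r <- 1L
  for (k in seq_len(n_atoms)) {
    resno[k] <- r
    nxt <- if (k < n_atoms) names_from_end[k + 1] else ""
    if (names_from_end[k] == "N" && nxt == "C") r <- r + 1L
  }
  list(name = names_from_end, resno = resno)
}

gly_atoms <- function(names, resno, chain, serial_offset = 0L) {
  data.frame(serial = serial_offset + seq_along(names), name = names,
             element = ifelse(substr(names, 1, 1) == "N", "N",
                       ifelse(substr(names, 1, 1) == "O", "O", "C")),
             resname = "GLY", resno = resno, chain = chain,
             het = FALSE, water = FALSE, stringsAsFactors = FALSE)
}

#' Linear covalent chain with a closed-form path score
#'
#' A straight glycine-backbone pseudo-molecule of `n_bonds` consecutive
#' covalent bonds.  The unique optimal path from the first to the last atom
#' scores `ln_k = n_bonds * log(A_covalent)`.
#'
#' @param n_bonds number of bonds (>= 1)
#' @param bond_length Angstrom between consecutive atoms
#' @param params [decay_parameters()] used for the emitted ground truth
#' @return an [et_structure()] with attribute `ground_truth`
#'   (`ln_k`, `donor`, `acceptor` atom indices, `n_edges`)
#' @export
make_covalent_chain <- function(n_bonds, bond_length = 1.5,
                                params = decay_parameters()) {
  if (n_bonds < 1) stop("n_bonds must be >= 1")
  n <- n_bonds + 1L
  nm <- chain_names_from_terminal(n, "C")
  atoms <- gly_atoms(rev(nm$name), rev(max(nm$resno) + 1L - nm$resno), "A")
  xyz <- cbind((seq_len(n) - 1) * bond_length, 0, 0)
  s <- et_structure(atoms, xyz)
  attr(s, "ground_truth") <- list(
    ln_k = n_bonds * log(params$covalent$A),
    donor = 1L, acceptor = n, n_edges = n_bonds)
  s
}

#' Two covalent chains joined by a single H-bond or space bridge
#'
#' Mirrors the topology of an inter-residue electron-transfer relay (two
#' bonded segments connected by one non-covalent jump).  The optimal path
#' score is `(chain_a + chain_b) * log(A_covalent) + log(q_bridge)`.
#'
#' @param chain_a,chain_b bonds in each chain (>= 1)
#' @param bridge_kind "hbond" or "space"
#' @param bridge_r bridge length, Angstrom; for an H-bond bridge it must lie
#'   inside the heavy-atom detection cutoff
#' @param criteria [hbond_criteria()] used to validate `bridge_r`
#' @param params [decay_parameters()] for the emitted ground truth
#' @return an [et_structure()] with attribute `ground_truth`
#' @export
make_bridged_pair <- function(chain_a, chain_b,
                              bridge_kind = c("space", "hbond"),
                              bridge_r = 3.4,
                              criteria = hbond_criteria(),
                              params = decay_parameters()) {
  bridge_kind <- match.arg(bridge_kind)
  if (chain_a < 1 || chain_b < 1) stop("both chains need at least one bond")
  if (bridge_kind == "hbond" &&
      bridge_r >= criteria$heavy_atom_fallback_distance)
    stop("bridge_r = ", bridge_r, " Angstrom is outside the H-bond ",
         "detection cutoff (", criteria$heavy_atom_fallback_distance, ")")
  terminal <- if (bridge_kind == "hbond") "O" else "C"
  na <- chain_a + 1L; nb <- chain_b + 1L
  L <- 1.5
  a_nm <- chain_names_from_terminal(na, terminal)   # index 1 = bridge end
  b_nm <- chain_names_from_terminal(nb, terminal)
  atoms_a <- gly_atoms(rev(a_nm$name), rev(max(a_nm$resno) + 1L - a_nm$resno),
                       "A")
  atoms_b <- gly_atoms(b_nm$name, b_nm$resno + 100L, "B", serial_offset = na)
  xyz_a <- cbind((seq_len(na) - na) * L, 0, 0)          # bridge end at x = 0
  xyz_b <- cbind(bridge_r + (seq_len(nb) - 1) * L, 0, 0)
  s <- et_structure(rbind(atoms_a, atoms_b), rbind(xyz_a, xyz_b))
  q_bridge <- edge_decay(bridge_r, bridge_kind, params)
  attr(s, "ground_truth") <- list(
    ln_k = (chain_a + chain_b) * log(params$covalent$A) + log(q_bridge),
    donor = 1L, acceptor = na + nb, n_edges = chain_a + chain_b + 1L,
    bridge_kind = bridge_kind, q_bridge = q_bridge)
  s
}

#' Trajectory with prescribed Bernoulli hydrogen-bond occupancy
#'
#' A donor water (O with one H) and an acceptor water oxygen toggle between
#' a hydrogen-bonded geometry (H...A 1.8 Angstrom, angle 165 degrees) and a
#' broken one (H...A 3.2 Angstrom) by seeded Bernoulli draws, emulating an
#' intermittent hydrogen bond.  The realized bonded-frame mask is returned
#' as ground truth.
#'
#' @param p_on probability a frame is bonded
#' @param n_frames number of frames (>= 1)
#' @param seed RNG seed (mandatory)
#' @return list: `trajectory` ([et_trajectory()], donor O = atom 1, donor H
#'   = atom 2, acceptor O = atom 3), `mask` (logical, per frame), `p_on`
#' @export
make_occupancy_trajectory <- function(p_on, n_frames, seed) {
  stopifnot(p_on >= 0, p_on <= 1, n_frames >= 1)
  mask <- with_seed(seed, stats::runif(n_frames) < p_on)
  atoms <- data.frame(
    serial = 1:3, name = c("O", "H1", "O"), element = c("O", "H", "O"),
    resname = "HOH", resno = c(1L, 1L, 2L), chain = "W",
    het = TRUE, water = TRUE, stringsAsFactors = FALSE)
  h <- c(0.96, 0, 0)
  dir15 <- c(cos(15 * pi / 180), sin(15 * pi / 180), 0)  # 165 deg at H
  acc_on <- h + 1.8 * dir15
  acc_off <- h + 3.2 * dir15
  coords <- array(0, dim = c(3L, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    coords[1, , f] <- c(0, 0, 0)
    coords[2, , f] <- h
    coords[3, , f] <- if (mask[f]) acc_on else acc_off
  }
  topo <- et_structure(atoms, coords[, , 1])
  list(trajectory = et_trajectory(topo, coords), mask = mask, p_on = p_on)
}

#' Uniform-density water box around a central probe atom
#'
#' Water oxygens are placed uniformly at the stated number density (count
#' drawn from the matching Poisson distribution), giving the ideal-gas
#' normalization limit g(r) = 1.
#'
#' @param density water oxygens per cubic Angstrom (bulk water is about
#'   0.0334)
#' @param box 3-vector of box edge lengths, Angstrom
#' @param seed RNG seed (mandatory)
#' @param n_frames number of models; frames beyond the first redraw all
#'   water positions independently (an ideal-gas "trajectory" for averaging
#'   normalization checks)
#' @return an [et_structure()] (probe = atom 1, a glycine CA at the box
#'   center) with attributes `box` and `ground_truth` (`expected_count`,
#'   `n_waters`, `density`)
#' @export
make_water_box <- function(density, box, seed, n_frames = 1L) {
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(density > 0, length(box) == 3, all(box > 0), n_frames >= 1)
  vol <- prod(box)
  gen <- with_seed(seed, {
    n <- stats::rpois(1, density * vol)
    pos <- lapply(seq_len(n_frames), function(f)
      matrix(stats::runif(3 * n) * rep(box, each = n), ncol = 3))
    list(n = n, pos = pos)
  })
  n <- gen$n
  probe <- data.frame(serial = 1L, name = "CA", element = "C",
                      resname = "GLY", resno = 1L, chain = "A",
                      het = FALSE, water = FALSE, stringsAsFactors = FALSE)
  waters <- data.frame(serial = 1L + seq_len(n), name = "O", element = "O",
                       resname = "HOH", resno = 1L + seq_len(n), chain = "W",
                       het = TRUE, water = TRUE, stringsAsFactors = FALSE)
  xyz <- array(NA_real_, dim = c(n + 1L, 3L, n_frames))
  for (f in seq_len(n_frames))
    xyz[, , f] <- rbind(matrix(box / 2, 1, 3), gen$pos[[f]])
  s <- et_structure(rbind(probe, waters), xyz)
  attr(s, "box") <- box
  attr(s, "ground_truth") <- list(expected_count = density * vol,
                                  n_waters = n, density = density)
  s
}

#' Random typed graph for oracle testing
#'
#' Random geometric node positions with independently sampled edges of
#' random kind.  Connectivity is not guaranteed, so the no-path sentinel is
#' exercised too.  Node count is capped at the exhaustive-enumeration guard.
#'
#' @param n_nodes 2..14 nodes
#' @param edge_prob probability each pair gets an edge
#' @param seed RNG seed (mandatory)
#' @return an `et_graph`
#' @export
make_random_graph <- function(n_nodes, edge_prob, seed) {
  if (n_nodes < 2 || n_nodes > 14)
    stop("n_nodes must be between 2 and 14")
  stopifnot(edge_prob >= 0, edge_prob <= 1)
  gen <- with_seed(seed, {
    pos <- matrix(stats::runif(3 * n_nodes, 0, 10), ncol = 3)
    pairs <- t(utils::combn(n_nodes, 2))
    on <- stats::runif(nrow(pairs)) < edge_prob
    kind <- sample(c("covalent", "hbond", "space"), nrow(pairs),
                   replace = TRUE)
    list(pos = pos, pairs = pairs, on = on, kind = kind)
  })
  atoms <- data.frame(serial = seq_len(n_nodes), name = "CA", element = "C",
                      resname = "GLY", resno = seq_len(n_nodes), chain = "A",
                      het = FALSE, water = FALSE, stringsAsFactors = FALSE)
  s <- et_structure(atoms, gen$pos)
  keep <- which(gen$on)
  edges <- if (length(keep) > 0) {
    i <- gen$pairs[keep, 1]; j <- gen$pairs[keep, 2]
    edge_frame(i, j, gen$kind[keep], dist_ij(gen$pos, i, j))
  } else data.frame(i = integer(0), j = integer(0), kind = character(0),
                    r = numeric(0), fe_his = logical(0))
  structure(list(structure = s, edges = edges, space_cutoff = NA_real_,
                 n_atoms = n_nodes), class = "et_graph")
}
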