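#' @keywords internal
"_PACKAGE"

# Residue names recognized as water when flagging solvent atoms.
WATER_RESNAMES <- c("HOH", "WAT", "SOL", "TIP3", "TIP4", "SPC", "DOD")

# Two-letter element symbols that occur in protein/cofactor PDB files and
# must not be truncated to their first letter.
TWO_LETTER_ELEMENTS <- c("FE", "ZN", "MG", "MN", "CU", "NI", "CO", "CA",
                         "NA", "CL", "BR", "SE", "MO", "CD", "HG", "AS")

#' Construct a molecular structure object
#'
#' The central container of the package: an atom table plus one or more
#' coordinate models.  Coordinates are always in Angstrom.
#'
#' @param atoms data.frame with columns `serial` (integer), `name` (PDB atom
#'   name), `element` (symbol, e.g. "C", "Fe"), `resname` (3-letter residue
#'   code), `resno` (author residue number), `chain` (single character),
#'   `het` (logical, HETATM record), `water` (logical).
#' @param xyz numeric array of dimension `c(n_atoms, 3, n_models)` (a plain
#'   `n x 3` matrix is promoted to one model), Angstrom.
#' @return object of class `et_structure` with elements `atoms` and `xyz`.
#' @export
et_structure <- function(atoms, xyz) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  needed <- c("serial", "name", "element", "resname", "resno", "chain",
              "het", "water")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0)
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), 3L, 1L))
  if (length(dim(xyz)) != 3L || dim(xyz)[2] != 3L)
    stop("xyz must be an n_atoms x 3 x n_models array")
  if (dim(xyz)[1] != nrow(atoms))
    stop("xyz has ", dim(xyz)[1], " atoms but the atom table has ",
         nrow(atoms))
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (any(!nzchar(atoms$element)))
    stop("empty element symbol in atom table")
  if (anyDuplicated(atoms$serial))
    stop("duplicated atom serials within a model")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, xyz = xyz), class = "et_structure")
}

#' @export
print.et_structure <- function(x, ...) {
  cat("et_structure:", nrow(x$atoms), "atoms,", n_models(x), "model(s)\n")
  cat("  residues:", length(unique(paste(x$atoms$chain, x$atoms$resno))),
      " waters:", sum(x$atoms$water), "\n")
  invisible(x)
}

#' Number of coordinate models in a structure
#' @param structure an `et_structure`
#' @return integer model count
#' @export
n_models <- function(structure) dim(structure$xyz)[3]

#' Coordinates of one model
#' @param structure an `et_structure`
#' @param model model index (default 1)
#' @return numeric `n x 3` matrix, Angstrom
#' @export
model_xyz <- function(structure, model = 1L) {
  m <- structure$xyz[, , model, drop = FALSE]
  dim(m) <- dim(structure$xyz)[1:2]
  m
}

#' Extract a single-model structure
#' @param structure an `et_structure`
#' @param model model index to keep
#' @return `et_structure` with one model
#' @export
single_model <- function(structure, model = 1L) {
  et_structure(structure$atoms, model_xyz(structure, model))
}

#' Resolve an atom selector to atom indices
#'
#' Selectors are lists with any of `chain`, `resno`, `resname`, `name`,
#' `serial`, `element`; all supplied fields must match.
#'
#' @param structure an `et_structure`
#' @param selector named list (or a bare integer vector of atom indices,
#'   returned unchanged)
#' @return integer vector of row indices into `structure$atoms`
#' @export
select_atoms <- function(structure, selector) {
  if (is.numeric(selector)) return(as.integer(selector))
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  for (field in c("chain", "resno", "resname", "name", "serial", "element"))
    if (!is.null(selector[[field]]))
      keep <- keep & a[[field]] %in% selector[[field]]
  which(keep)
}

#' Resolve a selector that must match exactly one atom
#' @inheritParams select_atoms
#' @return single integer atom index
#' @export
select_one_atom <- function(structure, selector) {
  idx <- select_atoms(structure, selector)
  if (length(idx) != 1L)
    stop("selector matched ", length(idx), " atoms (need exactly 1): ",
         paste(names(selector), unlist(selector), sep = "=", collapse = " "))
  idx
}

#' Human-readable atom labels ("A/TYR247/OH")
#' @param structure an `et_structure`
#' @param idx atom indices (default all)
#' @return character vector
#' @export
atom_labels <- function(structure, idx = seq_len(nrow(structure$atoms))) {
  a <- structure$atoms[idx, , drop = FALSE]
  paste0(a$chain, "/", a$resname, a$resno, "/", a$name)
}

#' Construct a trajectory object
#'
#' @param topology single-model `et_structure` giving the atom identities
#' @param coords array `n_atoms x 3 x n_frames` of coordinates, Angstrom
#' @return object of class `et_trajectory` with `topology` and `coords`
#' @export
et_trajectory <- function(topology, coords) {
  stopifnot(inherits(topology, "et_structure"))
  if (is.matrix(coords)) coords <- array(coords, dim = c(nrow(coords), 3L, 1L))
  if (dim(coords)[1] != nrow(topology$atoms))
    stop("frame atom count (", dim(coords)[1],
         ") does not match topology (", nrow(topology$atoms), ")")
  if (dim(coords)[3] < 1L) stop("trajectory needs at least one frame")
  structure(list(topology = single_model(topology),
                 coords = coords), class = "et_trajectory")
}

#' @export
print.et_trajectory <- function(x, ...) {
  cat("et_trajectory:", nrow(x$topology$atoms), "atoms,",
      n_frames(x), "frame(s)\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `et_trajectory`
#' @return integer frame count
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame
#' @param traj an `et_trajectory`
#' @param frame frame index
#' @return numeric `n x 3` matrix
#' @export
frame_xyz <- function(traj, frame) {
  m <- traj$coords[, , frame, drop = FALSE]
  dim(m) <- dim(traj$coords)[1:2]
  m
}

#' View a multi-model structure as a trajectory
#' @param structure an `et_structure`; its models become frames
#' @return `et_trajectory`
#' @export
as_trajectory <- function(structure) {
  et_trajectory(single_model(structure), structure$xyz)
}
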