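# Structure and trajectory I/O.  PDB parsing/writing is delegated to bio3d;
# this layer normalizes atoms into the et_structure data model (element
# inference, altloc resolution, water flagging).

infer_element <- function(name, elesy = NA_character_, het = FALSE) {
  ele <- toupper(trimws(elesy))
  nm <- toupper(gsub("[^A-Za-z]", "", trimws(name)))
  out <- character(length(name))
  ok <- !is.na(ele) & nzchar(ele)
  out[ok] <- ele[ok]
  # fall back to atom-name convention: two-letter metals/halogens for
  # HETATM records ("FE" of heme), else the first alphabetic character
  # (handles "OH", "NE1", "1HB"; an alanine "CA" stays carbon)
  miss <- !ok
  two <- substr(nm[miss], 1L, 2L)
  first <- substr(nm[miss], 1L, 1L)
  het <- rep_len(het, length(name))
  out[miss] <- ifelse(two %in% TWO_LETTER_ELEMENTS & nchar(nm[miss]) == 2L &
                        het[miss], two, first)
  # normalize case: "FE" -> "Fe"
  long <- nchar(out) > 1L
  out[long] <- paste0(substr(out[long], 1, 1),
                      tolower(substr(out[long], 2, nchar(out[long]))))
  out
}

# Keep one altloc conformer per atom: highest occupancy, ties broken toward
# the alphabetically first altloc code ('A' before 'B').
resolve_altloc <- function(atom) {
  alt <- atom$alt
  if (all(is.na(alt) | alt == "")) return(seq_len(nrow(atom)))
  key <- paste(atom$chain, atom$resno, atom$resid, atom$elety,
               ifelse(is.na(atom$insert), "", atom$insert))
  occ <- atom$o
  occ[is.na(occ)] <- 1
  altc <- ifelse(is.na(alt) | alt == "", "A", alt)
  ord <- order(key, -occ, altc)
  keep_first <- !duplicated(key[ord])
  sort(ord[keep_first])
}

#' Read a PDB file into an `et_structure`
#'
#' All MODEL/ENDMDL blocks are read; they must contain the same atoms in the
#' same order.  The element is taken from PDB columns 77-78 when present and
#' inferred from the atom name otherwise.  For atoms with alternate
#' locations the highest-occupancy conformer is kept (ties: altloc 'A').
#'
#' @param path path to a PDB file with at least one ATOM/HETATM record
#' @param water_resnames residue names flagged as water
#' @return an [et_structure()]
#' @export
read_pdb <- function(path, water_resnames = WATER_RESNAMES) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e)))
  if (nrow(pdb$atom) == 0) stop("no ATOM/HETATM records in ", path)
  keep <- resolve_altloc(pdb$atom)
  at <- pdb$atom[keep, , drop = FALSE]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_mod <- nrow(xyz)
  arr <- array(NA_real_, dim = c(length(keep), 3L, n_mod))
  for (m in seq_len(n_mod)) {
    mm <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    arr[, , m] <- mm[keep, , drop = FALSE]
  }
  atoms <- data.frame(
    serial  = as.integer(at$eleno),
    name    = trimws(at$elety),
    element = infer_element(at$elety, at$elesy, at$type == "HETATM"),
    resname = trimws(at$resid),
    resno   = as.integer(at$resno),
    chain   = ifelse(is.na(at$chain), " ", at$chain),
    het     = at$type == "HETATM",
    water   = trimws(at$resid) %in% water_resnames,
    stringsAsFactors = FALSE)
  et_structure(atoms, arr)
}

#' Write an `et_structure` to a PDB file
#'
#' Multi-model structures are written as MODEL/ENDMDL blocks.
#'
#' @param structure an [et_structure()]
#' @param path destination file
#' @return `path`, invisibly
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  n <- nrow(a)
  m <- n_models(structure)
  # bio3d expects xyz rows as models with columns x1,y1,z1,x2,...
  xyz <- t(vapply(seq_len(m), function(k) as.numeric(t(model_xyz(structure, k))),
                  numeric(3 * n)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   eleno = a$serial, elety = a$name, resid = a$resname,
                   chain = a$chain, resno = a$resno,
                   elesy = toupper(a$element))
  invisible(path)
}

parse_xyz_stack <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop("malformed XYZ frame header at line ", i, " of ", path)
    if (i + 1L + n > length(lines))
      stop("truncated XYZ frame in ", path)
    block <- lines[(i + 2L):(i + 1L + n)]
    fields <- strsplit(trimws(block), "[[:space:]]+")
    coords <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (any(!is.finite(coords))) stop("non-numeric coordinates in ", path)
    frames[[length(frames) + 1L]] <- coords
    i <- i + 2L + n
  }
  frames
}

#' Read a coordinate ensemble as a trajectory
#'
#' Accepts a multi-model PDB (models become frames; no separate topology
#' needed) or an XYZ frame stack together with a topology structure that
#' supplies atom identities.
#'
#' @param path trajectory file (`.pdb` multi-model, or `.xyz` frame stack)
#' @param topology single-model [et_structure()]; required for XYZ input
#' @return an [et_trajectory()]
#' @export
read_trajectory <- function(path, topology = NULL) {
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    if (is.null(topology))
      stop("an XYZ frame stack needs a topology structure")
    frames <- parse_xyz_stack(path)
    n <- nrow(topology$atoms)
    bad <- which(vapply(frames, nrow, 1L) != n)
    if (length(bad) > 0)
      stop("XYZ frame ", bad[1], " has ", nrow(frames[[bad[1]]]),
           " atoms; topology has ", n)
    coords <- array(NA_real_, dim = c(n, 3L, length(frames)))
    for (k in seq_along(frames)) coords[, , k] <- frames[[k]]
    return(et_trajectory(topology, coords))
  }
  s <- read_pdb(path)
  if (!is.null(topology) && nrow(topology$atoms) != nrow(s$atoms))
    stop("trajectory atom count (", nrow(s$atoms),
         ") does not match topology (", nrow(topology$atoms), ")")
  as_trajectory(s)
}

#' Write a residue ranking to TSV or JSON
#'
#' One row per ranked residue: chain, residue number/name, acceptor atom,
#' `ln_k`, atom count and per-edge-kind counts.  The JSON form round-trips
#' bit-exactly through [read_ranking()].
#'
#' @param ranking an `et_ranking` from [rank_residues()]
#' @param path destination file
#' @param format "tsv" or "json"
#' @return `path`, invisibly
#' @export
write_ranking <- function(ranking, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(ranking)
  if (nrow(df) == 0) stop("refusing to write an empty ranking")
  cols <- c("chain", "resno", "resname", "acceptor", "ln_k", "atom_count",
            "n_covalent", "n_hbond", "n_space", "uses_fe_his")
  df <- df[, cols]
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    # I(17) significant digits: doubles survive the round trip bit-exactly
    jsonlite::write_json(df, path, digits = I(17), auto_unbox = FALSE,
                         dataframe = "columns")
  }
  invisible(path)
}

#' Re-read a ranking written by [write_ranking()]
#' @param path file written by `write_ranking`
#' @param format "tsv" or "json"
#' @return data.frame of ranking rows
#' @export
read_ranking <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(jsonlite::fromJSON(path))
  }
  df$ln_k <- as.numeric(df$ln_k)
  df
}
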