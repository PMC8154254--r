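# Per-residue ranking: one optimal pathway from the heme iron to the
# phenolic oxygen (OH) of every tyrosine and the central indole nitrogen
# (NE1) of every tryptophan, sorted by descending ln(k).

#' Find the heme iron atom
#' @param structure an [et_structure()]
#' @return atom index of the (first) HEM Fe
#' @export
find_heme_fe <- function(structure) {
  fe <- which(structure$atoms$resname == "HEM" &
                toupper(structure$atoms$name) == "FE")
  if (length(fe) == 0) stop("no heme iron (HEM/FE) found in structure")
  fe[1]
}

acceptor_table <- function(structure) {
  a <- structure$atoms
  targets <- a[a$resname %in% c("TYR", "TRP") & !a$water, , drop = FALSE]
  if (nrow(targets) == 0) return(NULL)
  res <- unique(targets[, c("chain", "resno", "resname")])
  res$acceptor <- ifelse(res$resname == "TYR", "OH", "NE1")
  res
}

#' Rank tyrosine/tryptophan residues by optimal pathway decay
#'
#' Scores the electron-transfer route from the heme iron to every tyrosine
#' OH and tryptophan NE1 in the structure and sorts residues by descending
#' `ln_k` (least attenuated first).  Rows whose optimal path traverses the
#' heme-iron/proximal-histidine link are flagged `uses_fe_his`; set
#' `forbid_fe_his = TRUE` to exclude that link from the search instead.
#'
#' @param structure an [et_structure()] containing a heme and at least one
#'   Tyr or Trp
#' @param graph optional prebuilt `et_graph` (built from `structure`,
#'   `criteria` and `space_cutoff` when omitted)
#' @param params [decay_parameters()]
#' @param criteria [hbond_criteria()]
#' @param space_cutoff Angstrom, through-space edge cutoff
#' @param forbid_fe_his exclude the Fe-His link from all searches
#' @param donor optional donor override (atom index or selector); defaults
#'   to the heme iron
#' @return an `et_ranking`: data.frame-like rows (chain, resno, resname,
#'   acceptor, ln_k, atom_count, edge-kind counts, uses_fe_his) with the
#'   full `et_path` objects in `attr(, "paths")`
#' @export
rank_residues <- function(structure, graph = NULL,
                          params = decay_parameters(),
                          criteria = hbond_criteria(), space_cutoff = 6.0,
                          forbid_fe_his = FALSE, donor = NULL) {
  if (is.null(graph)) graph <- transfer_graph(structure, criteria,
                                              space_cutoff)
  donor_idx <- if (is.null(donor)) find_heme_fe(structure)
               else resolve_node(graph, donor)
  res <- acceptor_table(structure)
  if (is.null(res)) stop("no tyrosine or tryptophan residues in structure")
  rows <- list(); paths <- list()
  for (k in seq_len(nrow(res))) {
    sel <- list(chain = res$chain[k], resno = res$resno[k],
                name = res$acceptor[k])
    idx <- select_atoms(structure, sel)
    if (length(idx) != 1L) {
      warning(res$resname[k], res$resno[k], " (chain ", res$chain[k],
              ") lacks acceptor atom ", res$acceptor[k], "; skipped",
              call. = FALSE)
      next
    }
    p <- best_path(graph, donor_idx, idx, params, forbid_fe_his)
    rows[[length(rows) + 1L]] <- data.frame(
      chain = res$chain[k], resno = res$resno[k], resname = res$resname[k],
      acceptor = res$acceptor[k], ln_k = p$ln_k,
      atom_count = p$atom_count,
      n_covalent = p$kind_counts[["covalent"]],
      n_hbond = p$kind_counts[["hbond"]],
      n_space = p$kind_counts[["space"]],
      uses_fe_his = p$uses_fe_his, stringsAsFactors = FALSE)
    paths[[length(paths) + 1L]] <- p
  }
  if (length(rows) == 0) stop("no scorable Tyr/Trp residues")
  df <- do.call(rbind, rows)
  ord <- order(-df$ln_k, df$atom_count, df$chain, df$resno)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, paths = paths[ord], class = c("et_ranking", "data.frame"))
}

#' @export
print.et_ranking <- function(x, ...) {
  cat("et_ranking:", nrow(x), "residue(s), best ln(k) =",
      format(x$ln_k[1], digits = 6), "\n")
  print.data.frame(x, digits = 6)
  invisible(x)
}

#' Select candidate radical sites above a decay cutoff
#'
#' Keeps ranking rows with `ln_k >= cutoff_ln_k`, preserving order.  In the
#' peroxidase application the cutoff is taken from the scores of
#' experimentally established radical sites in related enzymes.
#'
#' @param ranking an `et_ranking` from [rank_residues()]
#' @param cutoff_ln_k minimum `ln_k`
#' @return subset of the ranking (possibly zero rows)
#' @export
select_candidates <- function(ranking, cutoff_ln_k) {
  if (nrow(ranking) == 0) stop("empty ranking")
  keep <- ranking$ln_k >= cutoff_ln_k
  out <- ranking[keep, , drop = FALSE]
  attr(out, "paths") <- attr(ranking, "paths")[keep]
  out
}
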