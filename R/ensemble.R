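# Ensemble path analysis: repeat the optimal-path search over trajectory
# frames (hydrogen-bond and space edges rebuilt per frame, covalent topology
# held fixed) and summarize per-atom participation and decay statistics.
# Thermal fluctuations in interatomic distances can reroute the optimal
# pathway frame to frame, so the static single-structure score is only one
# member of the ensemble.

#' Optimal pathway in every trajectory frame
#'
#' Covalent connectivity is perceived once from the topology and kept fixed;
#' hydrogen-bond and through-space edges (and all edge lengths) are rebuilt
#' from each frame's coordinates before the search.
#'
#' @param traj an [et_trajectory()]
#' @param donor,acceptor atom index or selector (resolved on the topology)
#' @param params [decay_parameters()]
#' @param criteria [hbond_criteria()]
#' @param space_cutoff Angstrom
#' @param forbid_fe_his exclude the Fe-His link in every frame
#' @param subsample analyze every `subsample`-th frame (default 1 = all)
#' @return list of `et_path`, one per analyzed frame (unreachable frames
#'   yield the `ln_k = -Inf` sentinel and stay in the list)
#' @export
per_frame_paths <- function(traj, donor, acceptor,
                            params = decay_parameters(),
                            criteria = hbond_criteria(), space_cutoff = 6.0,
                            forbid_fe_his = FALSE, subsample = 1L) {
  topo <- traj$topology
  cov0 <- perceive_covalent_bonds(topo)
  donor <- if (is.list(donor)) select_one_atom(topo, donor) else as.integer(donor)
  acceptor <- if (is.list(acceptor)) select_one_atom(topo, acceptor)
              else as.integer(acceptor)
  frames <- seq(1L, n_frames(traj), by = as.integer(subsample))
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    xyz <- frame_xyz(traj, frames[k])
    cov <- cov0
    cov$r <- dist_ij(xyz, cov$i, cov$j)
    hb <- detect_hbond_edges(topo, criteria, cov, xyz = xyz)
    g <- build_transfer_graph(topo, cov, hb, space_cutoff, criteria,
                              xyz = xyz)
    out[[k]] <- best_path(g, donor, acceptor, params, forbid_fe_his)
    attr(out[[k]], "frame") <- frames[k]
  }
  out
}

PARTICIPATION_BINS <- data.frame(
  label = c("<10%", "10-30%", "30-40%", "40-50%", "50-65%", "65-80%",
            "80-90%", ">90%"),
  lo = c(-Inf, 0.10, 0.30, 0.40, 0.50, 0.65, 0.80, 0.90),
  hi = c(0.10, 0.30, 0.40, 0.50, 0.65, 0.80, 0.90, Inf),
  stringsAsFactors = FALSE)

participation_bin <- function(fraction) {
  # left-open/right-closed: a fraction of exactly 0.90 is "80-90%"
  idx <- findInterval(fraction, PARTICIPATION_BINS$lo, left.open = TRUE)
  PARTICIPATION_BINS$label[idx]
}

#' Per-atom path-participation frequencies
#'
#' For each topology atom, the fraction of analyzed frames (those with a
#' reachable acceptor) whose optimal path contains the atom, with the
#' fraction assigned to one of eight occupancy bins
#' (<10%, 10-30%, 30-40%, 40-50%, 50-65%, 65-80%, 80-90%, >90%).
#'
#' @param results list of `et_path` from [per_frame_paths()]
#' @param n_atoms number of topology atoms; inferred from the largest path
#'   index when omitted
#' @return data.frame with columns `atom`, `fraction`, `bin`
#' @export
participation_frequencies <- function(results, n_atoms = NULL) {
  if (length(results) == 0) stop("no path results")
  valid <- Filter(function(p) p$reachable, results)
  if (length(valid) == 0) stop("no frame has a reachable acceptor")
  if (is.null(n_atoms))
    n_atoms <- max(vapply(valid, function(p) max(p$atoms), 1L))
  counts <- integer(n_atoms)
  for (p in valid) counts[p$atoms] <- counts[p$atoms] + 1L
  fraction <- counts / length(valid)
  data.frame(atom = seq_len(n_atoms), fraction = fraction,
             bin = participation_bin(fraction), stringsAsFactors = FALSE)
}

#' Ensemble decay-factor summary
#'
#' Mean and standard deviation of per-frame `ln_k` over frames with a
#' reachable acceptor, plus the best and worst frames.  The mean of `ln_k`
#' corresponds to the geometric mean of the decay product `k`.
#'
#' @param results list of `et_path` from [per_frame_paths()]
#' @return list: `mean_ln_k`, `sd_ln_k`, `best_frame` (list index, ln_k),
#'   `worst_frame`, `frames_analyzed` (valid), `frames_total`
#' @export
ensemble_decay <- function(results) {
  ok <- vapply(results, function(p) p$reachable, logical(1))
  if (!any(ok)) stop("no frame has a reachable acceptor")
  lnk <- vapply(results[ok], function(p) p$ln_k, numeric(1))
  idx <- which(ok)
  list(mean_ln_k = mean(lnk),
       sd_ln_k = if (length(lnk) > 1) stats::sd(lnk) else 0,
       best_frame = list(index = idx[which.max(lnk)], ln_k = max(lnk)),
       worst_frame = list(index = idx[which.min(lnk)], ln_k = min(lnk)),
       frames_analyzed = sum(ok),
       frames_total = length(results))
}

#' Write a participation table as TSV
#' @param participation data.frame from [participation_frequencies()]
#' @param topology optional [et_structure()] supplying atom labels
#' @param path destination file
#' @return `path`, invisibly
#' @export
write_participation <- function(participation, path, topology = NULL) {
  out <- participation
  if (!is.null(topology))
    out <- cbind(label = atom_labels(topology, participation$atom), out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
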