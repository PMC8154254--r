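# Hydrogen-bond occupancy over a trajectory: for a chosen donor hydroxyl
# (or other polar group) and a set of candidate acceptors, the fraction of
# frames in which the geometric criteria hold, with mean geometry over the
# bonded frames.  Distances are reported in nm, matching common MD-analysis
# convention.

#' Hydrogen-bond occupancy statistics
#'
#' For every candidate acceptor, counts trajectory frames in which any polar
#' hydrogen of the donor satisfies the criteria (H...acceptor distance below
#' the cutoff and donor-H...acceptor angle above the threshold; a frame
#' counts once per donor-acceptor pair).  Mean distance (nm) and angle
#' (degrees) are computed over the satisfying frames only, using the
#' best-scoring hydrogen per frame.
#'
#' @param traj an [et_trajectory()] whose topology carries the donor's polar
#'   hydrogen(s)
#' @param donor_selector atom index or selector resolving to one N/O donor
#' @param acceptor_selectors list of selectors (or vector of atom indices)
#'   for candidate acceptor atoms
#' @param criteria [hbond_criteria()]
#' @return data.frame sorted by descending occupancy: `donor`, `acceptor`
#'   (labels), `mean_distance_nm`, `mean_angle_deg`, `occurrence_count`,
#'   `occupancy_percent`, plus the atom indices
#' @export
hbond_occupancy <- function(traj, donor_selector, acceptor_selectors,
                            criteria = hbond_criteria()) {
  topo <- traj$topology
  donor <- if (is.list(donor_selector) && !is.null(names(donor_selector)))
    select_one_atom(topo, donor_selector) else as.integer(donor_selector)
  cov <- perceive_covalent_bonds(topo)
  adj <- adjacency_list(cov, nrow(topo$atoms))
  hyd <- adj[[donor]][topo$atoms$element[adj[[donor]]] == "H"]
  if (length(hyd) == 0)
    stop("donor atom ", atom_labels(topo, donor),
         " has no attached hydrogen in the topology")
  if (is.numeric(acceptor_selectors)) {
    acceptors <- as.integer(acceptor_selectors)
  } else {
    if (!is.null(names(acceptor_selectors)))
      acceptor_selectors <- list(acceptor_selectors)
    acceptors <- vapply(acceptor_selectors,
                        function(s) select_one_atom(topo, s), integer(1))
  }
  if (length(acceptors) == 0)
    return(data.frame(donor = character(0), acceptor = character(0),
                      mean_distance_nm = numeric(0),
                      mean_angle_deg = numeric(0),
                      occurrence_count = integer(0),
                      occupancy_percent = numeric(0)))
  nf <- n_frames(traj)
  count <- integer(length(acceptors))
  dsum <- numeric(length(acceptors))
  asum <- numeric(length(acceptors))
  for (f in seq_len(nf)) {
    xyz <- frame_xyz(traj, f)
    for (k in seq_along(acceptors)) {
      acc <- acceptors[k]
      best_d <- Inf; best_a <- NA_real_
      for (h in hyd) {
        dha <- sqrt(sum((xyz[h, ] - xyz[acc, ])^2))
        if (dha >= criteria$max_ha_distance) next
        ang <- angle_at(xyz, donor, h, acc)
        if (ang <= criteria$min_dha_angle) next
        if (dha < best_d) { best_d <- dha; best_a <- ang }
      }
      if (is.finite(best_d)) {
        count[k] <- count[k] + 1L
        dsum[k] <- dsum[k] + best_d
        asum[k] <- asum[k] + best_a
      }
    }
  }
  out <- data.frame(
    donor = atom_labels(topo, rep(donor, length(acceptors))),
    acceptor = atom_labels(topo, acceptors),
    mean_distance_nm = ifelse(count > 0, dsum / count / 10, NA_real_),
    mean_angle_deg = ifelse(count > 0, asum / count, NA_real_),
    occurrence_count = count,
    occupancy_percent = 100 * count / nf,
    donor_atom = donor, acceptor_atom = acceptors,
    stringsAsFactors = FALSE)
  out <- out[order(-out$occupancy_percent, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an H-bond occupancy table as TSV
#' @param records data.frame from [hbond_occupancy()]
#' @param path destination file
#' @return `path`, invisibly
#' @export
write_hbond_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
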