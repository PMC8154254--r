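# Water-structure analytics around a target atom: radial distribution
# function g(r) of water oxygens and the per-frame minimum water distance.

water_oxygens <- function(topology, water_selector = NULL) {
  if (!is.null(water_selector)) return(select_atoms(topology, water_selector))
  which(topology$atoms$water & topology$atoms$element == "O")
}

# minimum-image displacement for an orthorhombic box
min_image <- function(d, box) {
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

center_water_dists <- function(xyz, center, waters, box = NULL) {
  d <- xyz[waters, , drop = FALSE] -
    matrix(xyz[center, ], length(waters), 3, byrow = TRUE)
  if (!is.null(box)) d <- min_image(d, box)
  sqrt(rowSums(d^2))
}

#' Radial distribution function of water around a target atom
#'
#' Histograms center-to-water-oxygen distances over all frames, normalizes
#' each shell by its volume `4*pi*r^2*dr` and by the mean water number
#' density, and averages over frames.  With a periodic box the density is
#' `N / V` and distances use the minimum-image convention; without a box the
#' density is estimated from the mean count inside `r_max`.  Raw per-shell
#' counts are returned alongside g(r) so an unnormalized distance
#' distribution is available too.
#'
#' @param traj an [et_trajectory()]
#' @param center_selector atom index or selector resolving to one atom
#' @param water_selector optional selector for water oxygens (default: all
#'   topology atoms flagged as water with element O)
#' @param bin_width histogram bin width, Angstrom
#' @param r_max maximum radius, Angstrom
#' @param box optional 3-vector of orthorhombic box lengths, Angstrom
#' @return list of class `et_rdf`: `bin_centers`, `g_of_r`, `counts` (mean
#'   per frame), `bin_width`, `r_max`, `frames_averaged`, `density`
#' @export
radial_distribution <- function(traj, center_selector, water_selector = NULL,
                                bin_width = 0.1, r_max = 10, box = NULL) {
  stopifnot(bin_width > 0, r_max > bin_width)
  topo <- traj$topology
  center <- if (is.list(center_selector)) select_one_atom(topo, center_selector)
            else as.integer(center_selector)
  waters <- water_oxygens(topo, water_selector)
  if (length(waters) == 0) stop("no water oxygens in topology")
  if (!is.null(box)) {
    if (r_max > min(box) / 2)
      stop("r_max (", r_max, ") exceeds half the shortest box edge (",
           min(box) / 2, ")")
  }
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  n_inside <- 0
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    r <- center_water_dists(frame_xyz(traj, f), center, waters, box)
    r <- r[r <= r_max]
    n_inside <- n_inside + length(r)
    if (length(r) > 0)
      counts <- counts + tabulate(findInterval(r, edges, left.open = TRUE,
                                               rightmost.closed = TRUE),
                                  nbins = nb)
  }
  mean_counts <- counts / nf
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  density <- if (!is.null(box)) length(waters) / prod(box)
             else (n_inside / nf) / (4 / 3 * pi * r_max^3)
  g <- if (density > 0) mean_counts / (shell_vol * density)
       else rep(0, nb)
  structure(list(bin_centers = centers, g_of_r = g, counts = mean_counts,
                 bin_width = bin_width, r_max = r_max,
                 frames_averaged = nf, density = density),
            class = "et_rdf")
}

#' @export
print.et_rdf <- function(x, ...) {
  cat("et_rdf:", length(x$bin_centers), "bins to", x$r_max, "A over",
      x$frames_averaged, "frame(s); density", format(x$density, digits = 4),
      "waters/A^3\n")
  invisible(x)
}

#' Per-frame minimum water distance to a target atom
#'
#' @inheritParams radial_distribution
#' @return numeric vector, one minimum center-to-water-oxygen distance
#'   (Angstrom) per frame
#' @export
min_distance_series <- function(traj, center_selector, water_selector = NULL,
                                box = NULL) {
  topo <- traj$topology
  center <- if (is.list(center_selector)) select_one_atom(topo, center_selector)
            else as.integer(center_selector)
  waters <- water_oxygens(topo, water_selector)
  if (length(waters) == 0) stop("no water oxygens in topology")
  vapply(seq_len(n_frames(traj)), function(f)
    min(center_water_dists(frame_xyz(traj, f), center, waters, box)),
    numeric(1))
}

#' Write an RDF (or any x/y profile) as two-column TSV
#' @param rdf an `et_rdf`
#' @param path destination file
#' @return `path`, invisibly
#' @export
write_rdf <- function(rdf, path) {
  utils::write.table(data.frame(r = rdf$bin_centers, g = rdf$g_of_r),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
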