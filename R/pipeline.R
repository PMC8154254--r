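# Pipeline commands tying the stages together:
#   score     structure -> graph -> per-residue ranking -> candidates
#   ensemble  trajectory -> per-frame paths -> participation + decay summary
#   hbonds    trajectory -> H-bond occupancy table
#   solvation trajectory -> water rdf + minimum-distance series
# A JSON (or YAML) config is the single source of truth; the effective
# configuration is echoed into the output directory so a run can be
# reproduced from its outputs alone.

default_config <- function() {
  list(
    structure = NULL, trajectory = NULL, topology = NULL,
    out_dir = ".",
    space_cutoff = 6.0,
    forbid_fe_his = FALSE,
    cutoff_ln_k = NULL,
    subsample = 1L,
    seed = 1L,
    decay = list(covalent = list(A = 0.6, B = 0.0, R = 0.0),
                 hbond = list(A = 0.36, B = 1.7, R = 2.8),
                 space = list(A = 0.6, B = 1.7, R = 1.4)),
    hbond_criteria = list(max_ha_distance = 2.5, min_dha_angle = 135,
                          heavy_atom_fallback_distance = 3.5),
    donor = NULL, acceptor = NULL,
    hbond_donor = NULL, hbond_acceptors = NULL,
    rdf = list(bin_width = 0.1, r_max = 10, box = NULL, center = NULL))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration file
#'
#' JSON (always) or YAML (when the yaml package is installed); unset fields
#' take package defaults.
#'
#' @param path config file, or `NULL` for pure defaults
#' @param overrides named list applied on top of the file
#' @return config list
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML config needs the yaml package; use JSON instead")
      yaml::read_yaml(path)
    } else jsonlite::fromJSON(path, simplifyVector = TRUE)
    cfg <- merge_config(cfg, user)
  }
  merge_config(cfg, overrides)
}

config_params <- function(cfg) {
  do.call(decay_parameters, cfg$decay)
}

config_criteria <- function(cfg) {
  do.call(hbond_criteria, cfg$hbond_criteria)
}

echo_config <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(cfg, file.path(out_dir, "config_used.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

as_selector <- function(x) {
  if (is.null(x) || is.numeric(x)) return(x)
  x <- as.list(x)
  if (!is.null(x$resno)) x$resno <- as.integer(x$resno)
  x
}

#' Score a structure and select candidate radical sites
#'
#' Runs read -> bond perception -> graph -> per-residue ranking ->
#' candidate selection and writes `ranking.tsv`, `ranking.json` and (when a
#' cutoff is configured) `candidates.tsv` into the output directory.
#'
#' @param cfg config list from [read_config()]; needs `structure`
#' @return the `et_ranking`, invisibly
#' @export
cmd_score <- function(cfg) {
  if (is.null(cfg$structure)) stop("score: no structure input configured")
  s <- read_pdb(cfg$structure)
  ranking <- rank_residues(single_model(s),
                           params = config_params(cfg),
                           criteria = config_criteria(cfg),
                           space_cutoff = cfg$space_cutoff,
                           forbid_fe_his = isTRUE(cfg$forbid_fe_his),
                           donor = as_selector(cfg$donor))
  echo_config(cfg, cfg$out_dir)
  write_ranking(ranking, file.path(cfg$out_dir, "ranking.tsv"), "tsv")
  write_ranking(ranking, file.path(cfg$out_dir, "ranking.json"), "json")
  if (!is.null(cfg$cutoff_ln_k)) {
    cand <- select_candidates(ranking, cfg$cutoff_ln_k)
    if (nrow(cand) > 0)
      write_ranking(cand, file.path(cfg$out_dir, "candidates.tsv"), "tsv")
  }
  message("score: ", nrow(ranking), " residues ranked; best ln(k) = ",
          format(ranking$ln_k[1], digits = 6))
  invisible(ranking)
}

load_trajectory <- function(cfg) {
  if (is.null(cfg$trajectory)) stop("no trajectory input configured")
  topo <- if (!is.null(cfg$topology)) single_model(read_pdb(cfg$topology))
          else NULL
  read_trajectory(cfg$trajectory, topo)
}

#' Ensemble pathway analysis over a trajectory
#'
#' Writes `participation.tsv` and `ensemble_summary.json`.
#'
#' @param cfg config list; needs `trajectory`, `acceptor` (selector) and
#'   optionally `donor` (defaults to the heme iron)
#' @return list(results, participation, summary), invisibly
#' @export
cmd_ensemble <- function(cfg) {
  traj <- load_trajectory(cfg)
  donor <- as_selector(cfg$donor)
  if (is.null(donor)) donor <- find_heme_fe(traj$topology)
  acceptor <- as_selector(cfg$acceptor)
  if (is.null(acceptor)) stop("ensemble: no acceptor configured")
  results <- per_frame_paths(traj, donor, acceptor,
                             params = config_params(cfg),
                             criteria = config_criteria(cfg),
                             space_cutoff = cfg$space_cutoff,
                             forbid_fe_his = isTRUE(cfg$forbid_fe_his),
                             subsample = cfg$subsample)
  part <- participation_frequencies(results,
                                    n_atoms = nrow(traj$topology$atoms))
  summ <- ensemble_decay(results)
  echo_config(cfg, cfg$out_dir)
  write_participation(part, file.path(cfg$out_dir, "participation.tsv"),
                      traj$topology)
  jsonlite::write_json(summ, file.path(cfg$out_dir, "ensemble_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  message("ensemble: ", summ$frames_analyzed, "/", summ$frames_total,
          " frames; mean ln(k) = ", format(summ$mean_ln_k, digits = 6))
  invisible(list(results = results, participation = part, summary = summ))
}

#' Hydrogen-bond occupancy analysis over a trajectory
#'
#' Writes `hbonds.tsv` (Table-style occupancy report).
#'
#' @param cfg config list; needs `trajectory`, `hbond_donor` and
#'   `hbond_acceptors` selectors
#' @return the occupancy data.frame, invisibly
#' @export
cmd_hbonds <- function(cfg) {
  traj <- load_trajectory(cfg)
  if (is.null(cfg$hbond_donor)) stop("hbonds: no donor configured")
  acceptors <- cfg$hbond_acceptors
  if (is.null(acceptors)) stop("hbonds: no acceptors configured")
  if (is.data.frame(acceptors))
    acceptors <- lapply(seq_len(nrow(acceptors)),
                        function(k) as_selector(acceptors[k, , drop = FALSE]))
  else if (is.list(acceptors) && !is.null(names(acceptors)))
    acceptors <- list(as_selector(acceptors))
  else if (is.list(acceptors))
    acceptors <- lapply(acceptors, as_selector)
  tab <- hbond_occupancy(traj, as_selector(cfg$hbond_donor), acceptors,
                         config_criteria(cfg))
  echo_config(cfg, cfg$out_dir)
  write_hbond_table(tab, file.path(cfg$out_dir, "hbonds.tsv"))
  invisible(tab)
}

#' Water-structure analysis over a trajectory
#'
#' Writes `rdf.tsv` (g(r) profile) and `min_distance.tsv` (per-frame
#' minimum water distance).
#'
#' @param cfg config list; needs `trajectory` and `rdf$center`
#' @return list(rdf, min_distance), invisibly
#' @export
cmd_solvation <- function(cfg) {
  traj <- load_trajectory(cfg)
  center <- as_selector(cfg$rdf$center)
  if (is.null(center)) stop("solvation: no rdf center configured")
  box <- cfg$rdf$box
  if (!is.null(box)) box <- as.numeric(box)
  rdf <- radial_distribution(traj, center, bin_width = cfg$rdf$bin_width,
                             r_max = cfg$rdf$r_max, box = box)
  mds <- min_distance_series(traj, center, box = box)
  echo_config(cfg, cfg$out_dir)
  write_rdf(rdf, file.path(cfg$out_dir, "rdf.tsv"))
  utils::write.table(data.frame(frame = seq_along(mds), min_distance = mds),
                     file.path(cfg$out_dir, "min_distance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(rdf = rdf, min_distance = mds))
}
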