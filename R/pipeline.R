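#' Run the analysis pipeline end to end
#'
#' Orchestrates featurize -> landscape -> MSM (and optionally SCA and
#' NEB) from a single YAML configuration, writing every artifact as
#' plain text (CSV/JSON) into the output directory together with a
#' manifest carrying a content hash per file. Reruns with the same
#' configuration and seed are byte-identical for the deterministic
#' stages.
#'
#' The configuration has top-level keys `seed`, `out_dir`, and one block
#' per stage:
#' \describe{
#'   \item{features}{either `csv:` (path to a feature table with columns
#'     `traj`, `frame`, `distance_sum`, `dihedral`) or `simulate: true`
#'     to draw Brownian trajectories on the default three-well surface
#'     (`n_traj`, `steps` optional).}
#'   \item{landscape}{`bins` (length 2), `temperature` (K).}
#'   \item{msm}{`k`, `lags`, `n_macro`, `lag` (frames; default chosen by
#'     the implied-timescale flatness rule).}
#'   \item{sca}{optional: `fasta` (alignment path) or `simulate: true`;
#'     `epsilon`.}
#'   \item{neb}{optional: `surface` (`"muller_brown"` or
#'     `"double_well_1d"`), `n_interior`, `start`, `end`.}
#' }
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return Invisibly, the manifest tibble (`file`, `md5`), also written
#'   to `manifest.csv`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- validate_pipeline_config(cfg)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  artifacts <- character(0)
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    if (is.matrix(obj)) {
      utils::write.csv(obj, path, row.names = TRUE)
    } else if (is.data.frame(obj)) {
      utils::write.csv(obj, path, row.names = FALSE)
    } else {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    artifacts <<- c(artifacts, path)
    path
  }

  # --- features ---------------------------------------------------------
  feats <- if (!is.null(cfg$features$csv)) {
    utils::read.csv(cfg$features$csv)
  } else {
    srf <- make_cv_surface()
    simulate_brownian(srf, brownian_config(
      n_traj = cfg$features$n_traj %||% 10,
      steps = cfg$features$steps %||% 50000,
      seed = seed))
  }
  feats <- feature_frames(feats)
  emit(feats, "features.csv")

  # --- landscape --------------------------------------------------------
  grid <- estimate_landscape(feats,
                             n_bins = unlist(cfg$landscape$bins) %||% c(100, 100),
                             temperature = cfg$landscape$temperature %||% 300)
  emit(tidy(grid), "landscape.csv")

  # --- msm --------------------------------------------------------------
  micro <- cluster_microstates(feats, k = cfg$msm$k %||% 500, seed = seed)
  lags <- unlist(cfg$msm$lags) %||% 1:10
  scan <- implied_timescales(micro, lags = lags)
  emit(as.data.frame(scan), "implied_timescales.csv")
  lag <- cfg$msm$lag %||% choose_lag(scan)$lag_frames
  model <- estimate_tpm(micro, lag = lag)
  emit(model$T, "tpm.csv")
  emit(tidy(model), "stationary.csv")
  macro <- pcca_macrostates(model, n_macro = cfg$msm$n_macro %||% 3)
  reps <- representative_frames(micro, macro)
  emit(list(lag_frames = lag,
            macrostate_of_microstate = macro$macrostate,
            proportions = macro$proportions,
            representatives = reps),
       "macrostates.json")

  # --- sca (optional) ---------------------------------------------------
  if (!is.null(cfg$sca)) {
    msa <- if (!is.null(cfg$sca$fasta)) {
      load_msa(cfg$sca$fasta)
    } else {
      generate_msa(msa_spec(seed = seed))
    }
    sca <- sca_matrix(msa)
    sectors <- define_sectors(sca, eps = cfg$sca$epsilon %||% 0.05)
    emit(sca$profile, "conservation.csv")
    emit(sca$C, "sca_matrix.csv")
    emit(tidy(sectors), "sectors.csv")
  }

  # --- neb (optional) ---------------------------------------------------
  if (!is.null(cfg$neb)) {
    srf <- switch(cfg$neb$surface %||% "muller_brown",
                  muller_brown = muller_brown(),
                  double_well_1d = double_well_1d(),
                  abort(paste0("unknown surface: ", cfg$neb$surface)))
    band <- init_band(unlist(cfg$neb$start), unlist(cfg$neb$end),
                      n_interior = cfg$neb$n_interior %||% 52)
    band <- relax_band(band, srf, seed = seed,
                       schedule = anneal_schedule(
                         step_size = cfg$neb$step_size %||% 1e-4))
    emit(tidy(band), "neb_band.csv")
  }

  manifest <- tibble::tibble(
    file = basename(artifacts),
    md5 = unname(tools::md5sum(artifacts))
  )
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$out_dir)) abort("config needs an out_dir",
                                  class = "conformscape_config_error")
  cfg$seed <- as.integer(cfg$seed %||% 1)
  for (key in c("features", "sca")) {
    p <- cfg[[key]]$csv %||% cfg[[key]]$fasta
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("input path does not exist: ", p),
            class = "conformscape_config_error")
    }
  }
  if (is.null(cfg$features)) cfg$features <- list(simulate = TRUE)
  cfg
}
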