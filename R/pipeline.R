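# End-to-end orchestration: sweep -> simulate -> binarize -> features ->
# WTA filter -> train restarts -> winner -> posteriors for target rasters
# -> best-fit lookup, with per-stage seeds, timings and artifact manifests.

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, checks parameter ranges against the prior box
#' (`G_I` in `[0.002, 0.02]`, `G_E` in `[0, 2e-5]`) and basic sanity
#' (positive duration, holdout smaller than the number of simulations), and
#' injects a deterministic default seed when none is given.
#'
#' Two named profiles are provided: `"full"` (400 cells, 600 s, 200
#' simulations -- cluster-scale, not for routine use) and `"desk"`
#' (100 cells, 120 s, 40 simulations).
#'
#' @param config a (possibly partial) named list; see Details for fields.
#' @return The normalized config (class `msnet_config`).
#' @details Fields: `profile` ("desk"/"full"), `n_sims`, `n_cells`,
#'   `duration` (s), `gi_range`, `ge_range`, `simulator` ("biophysical" or
#'   "surrogate"), `n_restarts`, `holdout`, `min_records`,
#'   `posterior_samples`, `grid_n`, `seed`, `outdir`, `quiet`,
#'   `transient_bins`, `wta_threshold`.
#' @export
validate_config <- function(config = list()) {
  prof <- config$profile %||% "desk"
  base <- switch(prof,
    desk = list(n_sims = 40, n_cells = 100, duration = 120, p = 0.8),
    full = list(n_sims = 200, n_cells = 400, duration = 600, p = 0.4),
    stop("unknown profile: ", prof))
  cfg <- modifyList(list(
    profile = prof, n_sims = base$n_sims, n_cells = base$n_cells,
    duration = base$duration, p = base$p,
    gi_range = c(0.002, 0.02), ge_range = c(0, 2e-5),
    simulator = "biophysical", n_restarts = 30, holdout = 20,
    min_records = 50, posterior_samples = 1e5, grid_n = 200,
    seed = NULL, outdir = NULL, quiet = FALSE,
    transient_bins = 120, wta_threshold = 0.09
  ), config)
  if (cfg$gi_range[1] < 0.002 - 1e-12 || cfg$gi_range[2] > 0.02 + 1e-12)
    stop("G_I range must lie within the stated prior box [0.002, 0.02]")
  if (cfg$ge_range[1] < 0 || cfg$ge_range[2] > 2e-5 + 1e-18)
    stop("G_E range must lie within the stated prior box [0, 2e-5]")
  if (cfg$duration <= 0) stop("duration must be positive")
  if (cfg$holdout >= cfg$n_sims)
    stop("holdout must be smaller than the number of simulations")
  if (is.null(cfg$seed)) {
    cfg$seed <- 20240606L
    if (!cfg$quiet) message("no seed given; using deterministic default ",
                            cfg$seed)
  }
  if (!(cfg$simulator %in% c("biophysical", "surrogate")))
    stop("simulator must be 'biophysical' or 'surrogate'")
  class(cfg) <- "msnet_config"
  cfg
}

#' Read / write a pipeline config as YAML
#'
#' @param path YAML file path.
#' @param config config list to write.
#' @return `read_config` returns the validated config.
#' @export
read_config <- function(path) validate_config(yaml::read_yaml(path))

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.log_stage <- function(quiet, stage, t0) {
  if (!quiet)
    message(sprintf("[msnet] %-12s %.1f s", stage,
                    as.numeric(Sys.time() - t0, units = "secs")))
}

#' Run the full inference pipeline
#'
#' Executes the end-to-end procedure on simulated data: sample a parameter
#' sweep, simulate each network (biophysical integrator or the analytic
#' surrogate), extract the three summary features and the total-fluctuation
#' QC metric, reject winners-take-all runs, train the density estimator
#' with restarts, select the winner by held-out weighted MSE, compute
#' posteriors for the supplied target rasters (or, if none, for the first
#' holdout records), and look up the best-fit simulation for each target.
#'
#' All artifacts (sweep manifest, feature table, posterior summaries) are
#' written under `config$outdir` when set; a manifest with config snapshot,
#' per-stage seeds and timings is returned.
#'
#' @param config a config list; passed through [validate_config()].
#' @param targets optional named list of `ca_raster` objects to infer on.
#' @return A list of class `pipeline_result`: `manifest`, `records`
#'   (feature table), `filter` (kept/removed), `winner`, `posteriors`,
#'   `best_fits`.
#' @export
run_pipeline <- function(config = list(), targets = NULL) {
  cfg <- validate_config(config)
  t0 <- Sys.time()
  manifest <- list(config = unclass(cfg), started = format(t0),
                   seeds = list(), timings = list(), files = list())
  outdir <- cfg$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  # --- sweep ----------------------------------------------------------
  sw_seed <- derive_seed(cfg$seed, "pipeline-sweep")
  manifest$seeds$sweep <- sw_seed
  sweep <- sample_sweep(cfg$n_sims, cfg$gi_range, cfg$ge_range, sw_seed)
  .log_stage(cfg$quiet, "sweep", t0)

  # --- simulate + features -------------------------------------------
  if (cfg$simulator == "surrogate") {
    fx <- surrogate_features(sweep$g_i, sweep$g_e, surrogate_spec(),
                             seed = derive_seed(cfg$seed, "surrogate"))
    records <- cbind(sweep, fx,
                     fluct = rep(1, nrow(sweep)),    # surrogate has no WTA runs
                     n_active = NA_integer_)
  } else {
    rows <- lapply(seq_len(nrow(sweep)), function(i) {
      np <- network_params(n_cells = cfg$n_cells, p = cfg$p,
                           g_i = sweep$g_i[i], g_e = sweep$g_e[i],
                           duration = cfg$duration)
      net <- build_network(np, seed = sweep$seed[i])
      summarize_raster(run_network(net),
                       transient_bins = cfg$transient_bins)
    })
    records <- cbind(sweep, do.call(rbind, rows))
  }
  .log_stage(cfg$quiet, "features", t0)
  if (!is.null(outdir)) {
    write_features(records, file.path(outdir, "features.csv"))
    manifest$files$features <- "features.csv"
  }

  # --- WTA filter -----------------------------------------------------
  flt <- wta_filter(records, cfg$wta_threshold)
  if (!nrow(flt$kept))
    stop("pipeline halted at stage 'wta_filter': no simulations survive")
  .log_stage(cfg$quiet, "wta_filter", t0)

  # --- train restarts + winner ---------------------------------------
  icfg <- inference_config(gi_range = cfg$gi_range, ge_range = cfg$ge_range,
                           n_restarts = cfg$n_restarts,
                           holdout = min(cfg$holdout, nrow(flt$kept) - 1),
                           posterior_samples = cfg$posterior_samples,
                           grid_n = cfg$grid_n,
                           min_records = min(cfg$min_records,
                                             nrow(flt$kept) - cfg$holdout),
                           seed = derive_seed(cfg$seed, "train"))
  manifest$seeds$train <- icfg$seed
  restarts <- train_restarts(flt$kept, icfg)
  winner <- select_winner(restarts)
  .log_stage(cfg$quiet, "train", t0)

  # --- posteriors for targets ----------------------------------------
  if (is.null(targets)) {
    ho <- restarts[[winner$index]]$holdout
    take <- head(ho, 3)
    targets <- lapply(take, function(i)
      unlist(flt$kept[i, c("activity", "interval", "cv")]))
    names(targets) <- paste0("holdout_", flt$kept$sim_id[take])
  }
  posteriors <- lapply(targets, function(tg) {
    fv <- if (inherits(tg, "ca_raster")) feature_vector(tg) else tg
    posterior_map(winner$estimator, fv, icfg)
  })
  best_fits <- lapply(posteriors, function(ps)
    best_fit_lookup(ps$map, flt$kept, icfg$mse_weight))
  .log_stage(cfg$quiet, "infer", t0)

  if (!is.null(outdir)) {
    maps <- data.frame(target = names(posteriors),
                       g_i = vapply(posteriors, function(p) p$map[["g_i"]], 1),
                       g_e = vapply(posteriors, function(p) p$map[["g_e"]], 1))
    write_features(maps, file.path(outdir, "posterior_maps.csv"))
    manifest$files$posterior_maps <- "posterior_maps.csv"
  }
  manifest$timings$total_s <- as.numeric(Sys.time() - t0, units = "secs")
  structure(list(manifest = manifest, records = records, filter = flt,
                 winner = winner, posteriors = posteriors,
                 best_fits = best_fits), class = "pipeline_result")
}
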