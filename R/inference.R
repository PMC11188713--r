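# Neural posterior estimation over (G_I, G_E): training with restarts,
# winner selection by held-out weighted MSE, posterior evaluation on a
# grid, and best-fit simulation lookup.

#' Inference configuration
#'
#' @param gi_range,ge_range the prior box over `(G_I, G_E)`.
#' @param n_restarts number of independent trainings (the published
#'   procedure uses 30).
#' @param holdout simulations left out per restart (20).
#' @param mse_weight excitation weighting in the mean-squared error, fixed
#'   at 900 to balance the disparate parameter ranges.
#' @param posterior_samples samples drawn per posterior (1e6).
#' @param components mixture components of the density estimator.
#' @param hidden hidden-layer width (two layers).
#' @param epochs maximum training epochs.
#' @param grid_n posterior evaluation grid resolution per axis.
#' @param min_records minimum records required for training.
#' @param seed master seed.
#' @return A list of class `inference_config`.
#' @export
inference_config <- function(gi_range = c(0.002, 0.02),
                             ge_range = c(0, 2e-5), n_restarts = 30,
                             holdout = 20, mse_weight = 900,
                             posterior_samples = 1e6, components = 8,
                             hidden = 64, epochs = 500, grid_n = 200,
                             min_records = 50, seed = 1) {
  structure(list(gi_range = gi_range, ge_range = ge_range,
                 n_restarts = n_restarts, holdout = holdout,
                 mse_weight = mse_weight,
                 posterior_samples = posterior_samples,
                 components = components, hidden = hidden, epochs = epochs,
                 grid_n = grid_n, min_records = min_records, seed = seed),
            class = "inference_config")
}

#' Weighted mean-squared parameter error
#'
#' `(G_I* - G_I)^2 + 900^2 (G_E* - G_E)^2`: the excitation factor rescales
#' `G_E` (range 2e-5) onto the `G_I` range (0.018) so both axes contribute
#' comparably.
#'
#' @param true,est length-2 vectors `(g_i, g_e)`.
#' @param weight the excitation weighting factor.
#' @return Non-negative scalar; zero iff `true == est`; symmetric.
#' @export
weighted_mse <- function(true, est, weight = 900) {
  (est[[1]] - true[[1]])^2 + weight^2 * (est[[2]] - true[[2]])^2
}

# feature/parameter transforms stored with every estimator
.make_transforms <- function(records, cfg) {
  X <- as.matrix(records[, c("activity", "interval", "cv")])
  mu <- colMeans(X); sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  list(f_mu = mu, f_sd = sdv,
       p_lo = c(cfg$gi_range[1], cfg$ge_range[1]),
       p_w = c(diff(cfg$gi_range), diff(cfg$ge_range)))
}

.tx_features <- function(tr, records) {
  X <- as.matrix(records[, c("activity", "interval", "cv")])
  sweep(sweep(X, 2, tr$f_mu), 2, tr$f_sd, `/`)
}

.tx_params <- function(tr, records) {
  Y <- as.matrix(records[, c("g_i", "g_e")])
  sweep(sweep(Y, 2, tr$p_lo), 2, tr$p_w, `/`)
}

#' Train the conditional density estimator
#'
#' Fits a conditional Gaussian-mixture (mixture-density network: two tanh
#' hidden layers; mixture weights, means and diagonal covariances as
#' functions of the three features) by minimizing the negative
#' log-likelihood of the parameters given the features.  Features are
#' z-scored with training-set moments and parameters min-max scaled to the
#' prior box; both transforms are stored with the estimator.
#'
#' @param records data.frame with columns `activity`, `interval`, `cv`,
#'   `g_i`, `g_e` (after [wta_filter()]).
#' @param cfg an [inference_config()].
#' @param seed training seed (initial conditions and validation split).
#' @return A list of class `npe_estimator`.
#' @export
train_estimator <- function(records, cfg = inference_config(), seed = cfg$seed) {
  if (nrow(records) < cfg$min_records)
    stop("need at least ", cfg$min_records, " training records")
  tr <- .make_transforms(records, cfg)
  X <- .tx_features(tr, records)
  Y <- .tx_params(tr, records)
  net <- .mdn_train(X, Y, k = cfg$components, hidden = cfg$hidden,
                    epochs = cfg$epochs, seed = seed)
  structure(list(net = net, transforms = tr, cfg = cfg, seed = seed,
                 n_train = nrow(records)), class = "npe_estimator")
}

# joint posterior density of (g_i, g_e) evaluated on a grid, conditioned on
# a feature vector; returned truncated to the prior box and renormalized
.posterior_grid <- function(est, features, grid_n) {
  tr <- est$transforms
  x <- drop(.tx_features(tr, as.data.frame(as.list(features))))
  cond <- .mdn_cond(est$net, x)
  gx <- (seq_len(grid_n) - 0.5) / grid_n          # scaled cell centers
  gy <- gx
  dens_x <- sapply(seq_along(cond$pi), function(kk)
    stats::dnorm(gx, cond$mu[kk, 1], cond$sig[kk, 1]))
  dens_y <- sapply(seq_along(cond$pi), function(kk)
    stats::dnorm(gy, cond$mu[kk, 2], cond$sig[kk, 2]))
  joint <- matrix(0, grid_n, grid_n)
  for (kk in seq_along(cond$pi))
    joint <- joint + cond$pi[kk] * outer(dens_x[, kk], dens_y[, kk])
  cell <- (1 / grid_n)^2
  joint <- joint / (sum(joint) * cell)            # renormalize over the box
  gi <- tr$p_lo[1] + gx * tr$p_w[1]
  ge <- tr$p_lo[2] + gy * tr$p_w[2]
  list(gi = gi, ge = ge, joint_scaled = joint, cond = cond,
       cell_scaled = cell)
}

#' Posterior summary for an observed feature vector
#'
#' Evaluates the trained estimator at the observed features: the joint
#' density on a `grid_n x grid_n` grid over the prior box (truncated and
#' renormalized there), marginal densities by grid summation, the joint
#' maximum a-posteriori point (grid argmax), marginal peaks, and a sample
#' set drawn from the mixture (rejection-sampled into the box).
#'
#' @param est an [train_estimator()] result.
#' @param features named vector/list with `activity`, `interval`, `cv`.
#' @param cfg an [inference_config()] (defaults to the estimator's).
#' @param n_samples posterior samples (defaults to `cfg$posterior_samples`).
#' @return A list of class `posterior_summary`: `map` (named `g_i`, `g_e`),
#'   `marginal_gi`, `marginal_ge` (data.frames value/density), `joint`
#'   (matrix over `gi`/`ge` grids, density per unit parameter area),
#'   `samples`, `outside_support` flag.
#' @export
posterior_map <- function(est, features, cfg = est$cfg,
                          n_samples = cfg$posterior_samples) {
  pg <- .posterior_grid(est, features, cfg$grid_n)
  tr <- est$transforms
  jac <- prod(tr$p_w)
  joint_param <- pg$joint_scaled / jac
  imax <- arrayInd(which.max(pg$joint_scaled), dim(pg$joint_scaled))
  map <- c(g_i = pg$gi[imax[1]], g_e = pg$ge[imax[2]])
  h <- 1 / cfg$grid_n
  marg_gi <- rowSums(pg$joint_scaled) * h / tr$p_w[1]
  marg_ge <- colSums(pg$joint_scaled) * h / tr$p_w[2]
  x <- drop(.tx_features(tr, as.data.frame(as.list(features))))
  outside <- any(abs(x) > 4)
  if (outside)
    warning("features lie outside the training support (|z| > 4)")
  samples <- NULL
  if (n_samples > 0) {
    cond <- pg$cond
    set.seed(derive_seed(est$seed, "posterior-samples"))
    comp <- sample.int(length(cond$pi), n_samples, replace = TRUE,
                       prob = cond$pi)
    s1 <- rnorm(n_samples, cond$mu[comp, 1], cond$sig[comp, 1])
    s2 <- rnorm(n_samples, cond$mu[comp, 2], cond$sig[comp, 2])
    for (i in 1:100) {      # redraw points falling outside the box
      bad <- which(s1 < 0 | s1 > 1 | s2 < 0 | s2 > 1)
      if (!length(bad)) break
      comp_b <- sample.int(length(cond$pi), length(bad), replace = TRUE,
                           prob = cond$pi)
      s1[bad] <- rnorm(length(bad), cond$mu[comp_b, 1], cond$sig[comp_b, 1])
      s2[bad] <- rnorm(length(bad), cond$mu[comp_b, 2], cond$sig[comp_b, 2])
    }
    s1 <- pmin(pmax(s1, 0), 1); s2 <- pmin(pmax(s2, 0), 1)
    samples <- data.frame(g_i = tr$p_lo[1] + s1 * tr$p_w[1],
                          g_e = tr$p_lo[2] + s2 * tr$p_w[2])
  }
  structure(list(
    map = map,
    marginal_gi = data.frame(g_i = pg$gi, density = marg_gi),
    marginal_ge = data.frame(g_e = pg$ge, density = marg_ge),
    marginal_peaks = c(g_i = pg$gi[which.max(marg_gi)],
                       g_e = pg$ge[which.max(marg_ge)]),
    joint = joint_param, gi = pg$gi, ge = pg$ge,
    samples = samples, outside_support = outside
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary> MAP: G_I*=%.4g, G_E*=%.4g%s\n",
              x$map[["g_i"]], x$map[["g_e"]],
              if (x$outside_support) " (features outside training support)" else ""))
  invisible(x)
}

#' Train the estimator repeatedly with random holdouts
#'
#' Runs `cfg$n_restarts` independent trainings; each leaves out its own
#' random selection of `cfg$holdout` records as a test set and scores the
#' restart by the mean weighted MSE between true parameters and joint-MAP
#' estimates over that holdout.
#'
#' @param records training records (post-filter).
#' @param cfg an [inference_config()].
#' @param map_grid_n grid resolution used for the holdout MAPs (coarser
#'   than the reporting grid for speed).
#' @return A list of class `npe_restarts`: per-restart `estimator`,
#'   `holdout` indices and `mse`.
#' @export
train_restarts <- function(records, cfg = inference_config(),
                           map_grid_n = 100) {
  n <- nrow(records)
  if (cfg$holdout >= n)
    stop("holdout must be smaller than the number of records")
  res <- vector("list", cfg$n_restarts)
  for (r in seq_len(cfg$n_restarts)) {
    rs <- derive_seed(cfg$seed, paste0("restart", r))
    set.seed(rs)
    ho <- sort(sample.int(n, cfg$holdout))
    est <- train_estimator(records[-ho, , drop = FALSE], cfg, seed = rs)
    mses <- vapply(ho, function(i) {
      pg <- .posterior_grid(est, unlist(records[i, c("activity", "interval", "cv")]),
                            map_grid_n)
      im <- arrayInd(which.max(pg$joint_scaled), dim(pg$joint_scaled))
      weighted_mse(c(records$g_i[i], records$g_e[i]),
                   c(pg$gi[im[1]], pg$ge[im[2]]), cfg$mse_weight)
    }, numeric(1))
    res[[r]] <- list(estimator = est, holdout = ho, mse = mean(mses))
  }
  structure(res, class = "npe_restarts")
}

#' Select the winning restart
#'
#' Returns the restart with the minimum held-out weighted MSE; ties are
#' broken by restart index.
#'
#' @param restarts an [train_restarts()] result (at least one restart).
#' @return A list with `estimator`, `index`, `mse`, and the full `mse`
#'   vector as `all_mse`.
#' @export
select_winner <- function(restarts) {
  if (!length(restarts)) stop("no restarts given")
  mses <- vapply(restarts, `[[`, numeric(1), "mse")
  i <- which.min(mses)
  list(estimator = restarts[[i]]$estimator, index = i, mse = mses[i],
       all_mse = mses)
}

#' Best-fit simulation lookup
#'
#' Finds the simulation record whose parameters minimize the weighted MSE
#' to a target `(G_I*, G_E*)`; ties are broken by lowest `sim_id`.
#'
#' @param target length-2 vector `(g_i, g_e)`.
#' @param records data.frame with `sim_id`, `g_i`, `g_e` columns.
#' @param weight the excitation weighting factor.
#' @return The winning record (one-row data.frame) with its `mse` attached.
#' @export
best_fit_lookup <- function(target, records, weight = 900) {
  if (!nrow(records)) stop("empty record list")
  mse <- (records$g_i - target[[1]])^2 + weight^2 * (records$g_e - target[[2]])^2
  o <- order(mse, records$sim_id)
  out <- records[o[1], , drop = FALSE]
  out$mse <- mse[o[1]]
  out
}
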