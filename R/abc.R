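# Approximate Bayesian computation: rejection, GLM-smoothed model choice,
# PLS-based parameter posteriors and model averaging.
#
# Model choice follows the ABC-GLM idea: over the simulations retained for a
# model, the summary statistics are regressed on the parameters with a
# multivariate Gaussian linear model; the marginal density of the observed
# statistics under the model is then estimated as the average, over all of
# the model's simulations, of the fitted Gaussian density at the observed
# point (simulations outside the retained set contribute negligibly and are
# dropped from the sum but kept in the denominator).  Posterior model
# probabilities are proportional to prior x estimated density.
#
# Parameter posteriors invert the same Gaussian linear model: with
# likelihood s | theta ~ N(a + B theta, Sigma) fitted on the retained set
# (in PLS space), the posterior is prior(theta) x that Gaussian, evaluated
# by importance sampling from the prior and summarized on per-parameter
# density grids.

PARAM_NAMES <- c("lN_ASIA", "lN_JP", "lN_HI", "lN_WUS", "lN_EUS", "lN_SP",
                 "lf_HI", "lf_WUS", "lf_EUS", "lf_SP",
                 "tau_HI", "tau_WUS", "tau_EUS", "tau_SP", "lNm", "mu")

#' Prior specification for the colonization models
#'
#' Defaults: log10 sizes U\[4,8\] (ASIA) and U\[2,6\] (sampled regions),
#' log10 founder numbers U\[0.6,3\], colonization times U\[100,750\]
#' generations for HI and U\[10,100\] for the recent invasions constrained to
#' `tau_HI > tau_WUS > tau_SP > tau_EUS`, log10 migrant number U\[-2,2\], and
#' a mutation-rate prior Normal(3.46e-9, sd 0.28e-9) truncated at zero (the
#' experimental estimate for *D. melanogaster* with widened uncertainty).
#'
#' @param mu_mean,mu_sd mutation-rate prior mean and standard deviation.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(mu_mean = 3.46e-9, mu_sd = 0.28e-9) {
  bounds <- rbind(
    lN_ASIA = c(4, 8),
    lN_JP = c(2, 6), lN_HI = c(2, 6), lN_WUS = c(2, 6),
    lN_EUS = c(2, 6), lN_SP = c(2, 6),
    lf_HI = c(0.6, 3), lf_WUS = c(0.6, 3), lf_EUS = c(0.6, 3),
    lf_SP = c(0.6, 3),
    tau_HI = c(100, 750),
    tau_WUS = c(10, 100), tau_EUS = c(10, 100), tau_SP = c(10, 100),
    lNm = c(-2, 2),
    mu = c(0, Inf))
  colnames(bounds) <- c("lo", "hi")
  structure(list(bounds = bounds, mu_mean = mu_mean, mu_sd = mu_sd),
            class = "prior_spec")
}

#' Draw parameter vectors from the prior
#'
#' Colonization-time triples are drawn by rejection until the ordering
#' constraint holds; the mutation rate is redrawn while non-positive.
#'
#' @param n number of draws.
#' @param prior a [prior_spec()].
#' @return `n` x 16 matrix on the prior (log10 / generations) scale.
#' @export
sample_prior <- function(n, prior = prior_spec()) {
  b <- prior$bounds
  out <- matrix(NA_real_, n, length(PARAM_NAMES),
                dimnames = list(NULL, PARAM_NAMES))
  for (p in setdiff(PARAM_NAMES, c("tau_WUS", "tau_EUS", "tau_SP", "mu")))
    out[, p] <- runif(n, b[p, "lo"], b[p, "hi"])
  tri <- matrix(NA_real_, n, 3)
  todo <- seq_len(n)
  while (length(todo)) {
    cand <- matrix(runif(3 * length(todo), b["tau_WUS", "lo"],
                         b["tau_WUS", "hi"]), ncol = 3)
    ok <- cand[, 1] > cand[, 3] & cand[, 3] > cand[, 2]
    tri[todo[ok], ] <- cand[ok, , drop = FALSE]
    todo <- todo[!ok]
  }
  out[, c("tau_WUS", "tau_EUS", "tau_SP")] <- tri
  mu <- rnorm(n, prior$mu_mean, prior$mu_sd)
  while (any(bad <- mu <= 0))
    mu[bad] <- rnorm(sum(bad), prior$mu_mean, prior$mu_sd)
  out[, "mu"] <- mu
  out
}

#' Convert a prior-scale parameter vector to natural-scale simulator input
#'
#' @param theta named vector (or one-row matrix) on the prior scale.
#' @return named list with `N_*`, `f_*`, `tau_*`, `Nm`, `mu`.
#' @export
prior_to_natural <- function(theta) {
  theta <- drop(theta)
  list(N_ASIA = 10^theta[["lN_ASIA"]], N_JP = 10^theta[["lN_JP"]],
       N_HI = 10^theta[["lN_HI"]], N_WUS = 10^theta[["lN_WUS"]],
       N_EUS = 10^theta[["lN_EUS"]], N_SP = 10^theta[["lN_SP"]],
       f_HI = 10^theta[["lf_HI"]], f_WUS = 10^theta[["lf_WUS"]],
       f_EUS = 10^theta[["lf_EUS"]], f_SP = 10^theta[["lf_SP"]],
       tau_HI = theta[["tau_HI"]], tau_WUS = theta[["tau_WUS"]],
       tau_EUS = theta[["tau_EUS"]], tau_SP = theta[["tau_SP"]],
       Nm = 10^theta[["lNm"]], mu = theta[["mu"]])
}

#' Simulate an ABC reference table
#'
#' Draws parameters from the prior and simulates the 67-statistic summary
#' vector for each draw under each model.
#'
#' @param n_sims simulations per model.
#' @param models subset of `M1`, `M2`, `M3`.
#' @param prior a [prior_spec()].
#' @param config a [sample_config()] naming the five sampled regions.
#' @param verbose print progress.
#' @return object of class `ref_table` with fields `model` (factor),
#'   `params` (matrix), `stats` (matrix), `prior`, `config`.
#' @export
reference_table <- function(n_sims, models = c("M1", "M2", "M3"),
                            prior = prior_spec(),
                            config = sample_config(default_sample_sizes()),
                            verbose = FALSE) {
  sv <- sample_vectors_for_models(config)
  all_params <- all_stats <- list()
  model_col <- character(0)
  for (m in models) {
    theta <- sample_prior(n_sims, prior)
    stats <- matrix(NA_real_, n_sims, 67,
                    dimnames = list(NULL, stat_names(names(config$n))))
    for (i in seq_len(n_sims)) {
      demog <- build_demography(m, prior_to_natural(theta[i, ]))
      stats[i, ] <- cpp_sim_statvec(unclass(demog), sv$deme, sv$region,
                                    length(sv$regions),
                                    as.integer(config$loci$length),
                                    theta[i, "mu"])
      if (verbose && i %% 1000 == 0)
        message(m, ": ", i, "/", n_sims)
    }
    all_params[[m]] <- theta
    all_stats[[m]] <- stats
    model_col <- c(model_col, rep(m, n_sims))
  }
  structure(list(model = factor(model_col, levels = models),
                 params = do.call(rbind, all_params),
                 stats = do.call(rbind, all_stats),
                 prior = prior, config = config),
            class = "ref_table")
}

# precompute sampling vectors once (reference_table hot path)
sample_vectors_for_models <- function(config) {
  demog <- build_demography("M1", list(
    N_ASIA = 1e6, N_JP = 1e4, N_HI = 1e4, N_WUS = 1e4, N_EUS = 1e4,
    N_SP = 1e4, f_HI = 10, f_WUS = 10, f_EUS = 10, f_SP = 10,
    tau_HI = 400, tau_WUS = 90, tau_SP = 50, tau_EUS = 20, Nm = 1,
    mu = 3.46e-9))
  sample_vectors(demog, config)
}

#' Default per-region haploid sample sizes
#'
#' The worldwide design emulated by the generator: 20 (JP), 15 (HI),
#' 40 (WUS), 120 (EUS) and 15 (SP) haploid X-linked sequences.
#' @return named integer vector.
#' @export
default_sample_sizes <- function() {
  c(JP = 20L, HI = 15L, WUS = 40L, EUS = 120L, SP = 15L)
}

#' @export
print.ref_table <- function(x, ...) {
  cat(sprintf("ABC reference table: %d simulations (%s), %d statistics\n",
              nrow(x$stats),
              paste(sprintf("%s: %d", levels(x$model), table(x$model)),
                    collapse = ", "),
              ncol(x$stats)))
  invisible(x)
}

# --- rejection ------------------------------------------------------------

standardize_stats <- function(stats, center = NULL, scale = NULL) {
  if (is.null(center)) center <- apply(stats, 2, stats::median)
  if (is.null(scale)) scale <- robust_scale(stats)
  list(z = sweep(sweep(stats, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' Retain the simulations nearest to the observed statistics
#'
#' Statistics are standardized by their median and median absolute deviation
#' over the table; distance is Euclidean on the chosen subset; ties are
#' broken by row index.
#'
#' @param table_stats matrix of simulated statistics.
#' @param observed named vector of observed statistics.
#' @param k number retained.
#' @param stat_subset statistic names to use (default: all columns).
#' @return list with `idx` (row indices, distance-ordered), `dist`,
#'   `center`, `scale`.
#' @export
retain_nearest <- function(table_stats, observed, k,
                           stat_subset = colnames(table_stats)) {
  if (k > nrow(table_stats)) stop("k exceeds the table size")
  sub <- table_stats[, stat_subset, drop = FALSE]
  std <- standardize_stats(sub)
  z0 <- (observed[stat_subset] - std$center) / std$scale
  if (any(!is.finite(z0))) stop("observed statistics not finite after scaling")
  d2 <- colSums((t(std$z) - z0)^2)
  o <- order(d2, seq_along(d2))[seq_len(k)]
  list(idx = o, dist = sqrt(d2[o]), center = std$center, scale = std$scale)
}

# --- GLM model choice -----------------------------------------------------

# Gaussian linear model of (standardized) stats on params over retained rows
fit_glm_block <- function(z, params) {
  X <- cbind(1, params)
  fit <- lm.fit(X, z)
  res <- as.matrix(fit$residuals)
  p <- qr(X)$rank
  sigma <- crossprod(res) / max(1, nrow(z) - p)
  list(coef = fit$coefficients, fitted = as.matrix(fit$fitted.values),
       sigma = sigma)
}

glm_log_marginal <- function(z0, fitted, sigma, n_total) {
  logsumexp(dmvnorm_log_rows(z0, fitted, sigma)) - log(n_total)
}

#' GLM-smoothed posterior model probabilities
#'
#' @param ref a [reference_table()].
#' @param observed named statistic vector of the observed data.
#' @param k simulations retained per model.
#' @param stats statistic names used for model choice (the PLS transform is
#'   model-specific, so model choice uses raw statistics).
#' @param prior_model prior model probabilities (default equal).
#' @return object of class `model_choice` with posterior probabilities and
#'   the per-model GLM components.
#' @export
model_posterior <- function(ref, observed, k = 1000,
                            stats = selected_stats(), prior_model = NULL) {
  models <- levels(ref$model)
  if (is.null(prior_model))
    prior_model <- setNames(rep(1 / length(models), length(models)), models)
  std <- standardize_stats(ref$stats[, stats, drop = FALSE])
  z0 <- (observed[stats] - std$center) / std$scale
  per_model <- list()
  logdens <- setNames(numeric(length(models)), models)
  for (m in models) {
    rows <- which(ref$model == m)
    zm <- std$z[rows, , drop = FALSE]
    d2 <- colSums((t(zm) - z0)^2)
    o <- order(d2, seq_along(d2))[seq_len(min(k, length(rows)))]
    g <- fit_glm_block(zm[o, , drop = FALSE],
                       ref$params[rows[o], , drop = FALSE])
    logdens[m] <- glm_log_marginal(z0, g$fitted, g$sigma, length(rows))
    per_model[[m]] <- list(retained = rows[o], z_retained = zm[o, ,
                                                               drop = FALSE],
                           fitted = g$fitted, sigma = g$sigma,
                           n_sims = length(rows))
  }
  lp <- log(prior_model[models]) + logdens
  post <- exp(lp - logsumexp(lp))
  structure(list(posterior = post / sum(post), log_marginal = logdens,
                 models = models, k = k, stats = stats, z_observed = z0,
                 center = std$center, scale = std$scale,
                 per_model = per_model),
            class = "model_choice")
}

#' @export
print.model_choice <- function(x, ...) {
  cat("ABC-GLM model choice (", length(x$stats), " statistics, k = ",
      x$k, ")\n", sep = "")
  print(round(x$posterior, 4))
  invisible(x)
}

# fast batch version for power / calibration experiments: returns a matrix
# of posterior probabilities (pods x models)
model_choice_batch <- function(ref, pod_stats, k = 1000,
                               stats = selected_stats(),
                               prior_model = NULL) {
  models <- levels(ref$model)
  if (is.null(prior_model))
    prior_model <- setNames(rep(1 / length(models), length(models)), models)
  std <- standardize_stats(ref$stats[, stats, drop = FALSE])
  z_pods <- sweep(sweep(pod_stats[, stats, drop = FALSE], 2, std$center),
                  2, std$scale, "/")
  rows_by_model <- lapply(models, function(m) which(ref$model == m))
  z_by_model <- lapply(rows_by_model, function(r) std$z[r, , drop = FALSE])
  zt_by_model <- lapply(z_by_model, t)
  n_pods <- nrow(z_pods)
  post <- matrix(NA_real_, n_pods, length(models),
                 dimnames = list(NULL, models))
  for (i in seq_len(n_pods)) {
    z0 <- z_pods[i, ]
    ld <- numeric(length(models))
    for (j in seq_along(models)) {
      d2 <- colSums((zt_by_model[[j]] - z0)^2)
      o <- order(d2, seq_along(d2))[seq_len(min(k, length(d2)))]
      rows <- rows_by_model[[j]][o]
      g <- fit_glm_block(z_by_model[[j]][o, , drop = FALSE],
                         ref$params[rows, , drop = FALSE])
      ld[j] <- glm_log_marginal(z0, g$fitted, g$sigma, length(d2))
    }
    lp <- log(prior_model[models]) + ld
    post[i, ] <- exp(lp - logsumexp(lp))
  }
  post
}

# --- PLS ------------------------------------------------------------------

#' Partial-least-squares projection of statistics
#'
#' Finds linear combinations of the summary statistics maximizing covariance
#' with the parameters (regression-mode PLS), used to reduce the statistic
#' space before retention for parameter estimation.
#'
#' @param stats matrix of simulated statistics.
#' @param params matrix of the corresponding parameters.
#' @param n_components number of PLS components.
#' @return object of class `pls_projection`; use [project_stats()] to apply
#'   the projection to new statistic vectors.
#' @export
pls_project <- function(stats, params, n_components = 7) {
  keep <- which(apply(stats, 2, sd) > 0)
  if (length(keep) < n_components)
    stop("fewer informative statistics than PLS components")
  if (length(keep) < 2) {
    # a single informative statistic: the projection is the (scaled)
    # statistic itself
    ctr <- mean(stats[, keep])
    scl <- sd(stats[, keep])
    return(structure(list(fit = NULL, keep = keep, center = ctr,
                          scale = scl, n_components = 1),
                     class = "pls_projection"))
  }
  fit <- mixOmics::pls(stats[, keep, drop = FALSE], params,
                       ncomp = n_components, mode = "regression",
                       scale = TRUE)
  structure(list(fit = fit, keep = keep, n_components = n_components),
            class = "pls_projection")
}

#' Apply a PLS projection to new statistic vectors
#'
#' @param proj a [pls_project()] object.
#' @param stats matrix (or single named vector) of statistics.
#' @return matrix of PLS component scores.
#' @export
project_stats <- function(proj, stats) {
  if (is.null(dim(stats))) stats <- matrix(stats, nrow = 1,
                                           dimnames = list(NULL,
                                                           names(stats)))
  if (is.null(proj$fit)) {
    v <- (stats[, proj$keep, drop = FALSE] - proj$center) / proj$scale
    colnames(v) <- "comp1"
    return(v)
  }
  pr <- predict(proj$fit, stats[, proj$keep, drop = FALSE])
  pr$variates
}

# --- parameter posteriors -------------------------------------------------

prior_log_density <- function(theta, prior) {
  # uniform box contributes a constant; only mu is non-uniform
  dnorm(theta[, "mu"], prior$mu_mean, prior$mu_sd, log = TRUE)
}

param_grid_range <- function(prior, param) {
  b <- prior$bounds[param, ]
  if (param == "mu")
    c(max(0, prior$mu_mean - 5 * prior$mu_sd), prior$mu_mean +
        5 * prior$mu_sd)
  else unname(b)
}

#' Wrap an arbitrary prior for the posterior machinery
#'
#' Allows reference tables built outside the colonization models (e.g. toy
#' conjugate pipelines used for calibration checks) to flow through
#' [parameter_posterior()].
#'
#' @param sample function(n) returning an n x p parameter matrix with named
#'   columns.
#' @param log_density function(theta) returning the log prior density per row
#'   (up to a constant).
#' @param ranges p x 2 matrix of grid ranges with parameter rownames.
#' @return object of class `generic_prior`.
#' @export
generic_prior <- function(sample, log_density, ranges) {
  structure(list(sample = sample, log_density = log_density,
                 ranges = ranges), class = "generic_prior")
}

prior_sample_n <- function(prior, n) {
  if (inherits(prior, "prior_spec")) sample_prior(n, prior)
  else prior$sample(n)
}

prior_logdens <- function(prior, theta) {
  if (inherits(prior, "prior_spec")) prior_log_density(theta, prior)
  else prior$log_density(theta)
}

prior_range <- function(prior, param) {
  if (inherits(prior, "prior_spec")) param_grid_range(prior, param)
  else unname(prior$ranges[param, ])
}

# bounded logit transform used so regression-adjusted draws stay inside the
# prior support (the convention of regression-adjustment implementations)
logit_bounded <- function(x, lo, hi) {
  eps <- 1e-9 * (hi - lo)
  x <- pmin(pmax(x, lo + eps), hi - eps)
  log((x - lo) / (hi - x))
}

expit_bounded <- function(y, lo, hi) lo + (hi - lo) / (1 + exp(-y))

# local-linear (Epanechnikov-weighted) regression adjustment of the retained
# parameters in PLS-component space; returns a weighted posterior sample
regression_adjust <- function(V, params, v0, k, prior) {
  ret <- retain_nearest(V, setNames(v0, colnames(V)), min(k, nrow(V)))
  d <- ret$dist
  dmax <- max(d) * (1 + 1e-9)
  w <- if (dmax > 0) 1 - (d / dmax)^2 else rep(1, length(d))
  Vd <- sweep(V[ret$idx, , drop = FALSE], 2, v0)
  pn <- colnames(params)
  rngs <- lapply(pn, function(p) prior_range(prior, p))
  names(rngs) <- pn
  Y <- vapply(pn, function(p)
    logit_bounded(params[ret$idx, p], rngs[[p]][1], rngs[[p]][2]),
    numeric(length(ret$idx)))
  fit <- stats::lm.wfit(cbind(1, Vd), Y, w)
  beta <- as.matrix(fit$coefficients)[-1, , drop = FALSE]
  beta[is.na(beta)] <- 0
  Yadj <- Y - Vd %*% beta
  theta <- vapply(pn, function(p)
    expit_bounded(Yadj[, p], rngs[[p]][1], rngs[[p]][2]),
    numeric(nrow(Yadj)))
  colnames(theta) <- pn
  list(theta = theta, w = w, ess = sum(w)^2 / sum(w^2), idx = ret$idx)
}

#' Regression-adjusted parameter posterior for one model
#'
#' Retains the simulations nearest the observed data in PLS-component space
#' with Epanechnikov distance weights, applies the local-linear regression
#' adjustment (parameters regressed on the component deviations, on a
#' bounded-logit scale so the adjusted draws respect the prior support), and
#' summarizes the weighted adjusted sample.  Marginal densities are
#' reported on 512-point grids over the prior support, truncated and
#' renormalized.
#'
#' @param ref a [reference_table()].
#' @param observed named statistic vector.
#' @param model model id within the table.
#' @param k retained simulations.
#' @param n_components PLS components.
#' @param grid_n grid points per parameter.
#' @return object of class `parameter_posterior` with per-parameter density
#'   grids and summaries (mode, mean, median, Q5, Q95).
#' @export
parameter_posterior <- function(ref, observed, model, k = 1000,
                                n_components = 7, grid_n = 512) {
  eng <- prep_posterior_engine(ref, model, n_components)
  v0 <- drop(project_stats(eng$proj, observed))
  adj <- regression_adjust(eng$V, eng$params, v0, k, eng$prior)
  wn <- adj$w / sum(adj$w)

  grids <- list()
  summ <- list()
  for (p in colnames(ref$params)) {
    rng <- prior_range(ref$prior, p)
    den <- suppressWarnings(
      density(adj$theta[, p], weights = wn, from = rng[1], to = rng[2],
              n = grid_n))
    y <- den$y
    area <- sum(y) * diff(rng) / (grid_n - 1)
    if (area > 0) y <- y / area
    grids[[p]] <- list(x = den$x, y = y)
    q <- weighted_quantile(adj$theta[, p], adj$w, c(0.05, 0.5, 0.95))
    summ[[p]] <- c(mode = den$x[which.max(y)],
                   mean = weighted_mean(adj$theta[, p], adj$w),
                   median = q[2], q5 = q[1], q95 = q[3])
  }
  summary <- do.call(rbind, summ)
  colnames(summary) <- c("mode", "mean", "median", "q5", "q95")
  structure(list(model = model, grids = grids, summary = summary,
                 ess = adj$ess, k = k, n_components = n_components),
            class = "parameter_posterior")
}

#' Model-averaged parameter posterior
#'
#' Mixes per-model marginal posteriors with the posterior model
#' probabilities; summaries are recomputed from the mixture densities.
#'
#' @param posteriors named list of [parameter_posterior()] objects.
#' @param weights named numeric weights (posterior model probabilities).
#' @return a `parameter_posterior` with `model = "weighted"`.
#' @export
weight_posteriors <- function(posteriors, weights) {
  stopifnot(length(posteriors) == length(weights))
  weights <- weights / sum(weights)
  base <- posteriors[[1]]
  grids <- list()
  summ <- list()
  for (p in rownames(base$summary)) {
    x <- base$grids[[p]]$x
    y <- rep(0, length(x))
    for (i in seq_along(posteriors)) {
      gi <- posteriors[[i]]$grids[[p]]
      if (!isTRUE(all.equal(gi$x, x)))
        stop("posteriors must share parameter grids")
      y <- y + weights[i] * gi$y
    }
    grids[[p]] <- list(x = x, y = y)
    dx <- x[2] - x[1]
    cdf <- cumsum(y) * dx
    cdf <- cdf / cdf[length(cdf)]
    qs <- vapply(c(0.05, 0.5, 0.95), function(q) x[which(cdf >= q)[1]],
                 numeric(1))
    mean_mix <- sum(vapply(seq_along(posteriors), function(i)
      weights[i] * posteriors[[i]]$summary[p, "mean"], numeric(1)))
    summ[[p]] <- c(mode = x[which.max(y)], mean = mean_mix,
                   median = qs[2], q5 = qs[1], q95 = qs[3])
  }
  summary <- do.call(rbind, summ)
  colnames(summary) <- c("mode", "mean", "median", "q5", "q95")
  structure(list(model = "weighted", grids = grids, summary = summary,
                 ess = NA, weights_models = weights),
            class = "parameter_posterior")
}

#' @export
print.parameter_posterior <- function(x, ...) {
  cat(sprintf("parameter posterior (%s)\n", x$model))
  print(round(x$summary, 4))
  invisible(x)
}

# --- the fitted object ----------------------------------------------------

#' Fit the ABC model-choice and parameter-estimation pipeline
#'
#' The central fitting function: given the observed summary statistics and a
#' simulated reference table, performs GLM-smoothed model choice on the
#' selected statistics, estimates PLS/GLM parameter posteriors under each
#' model, averages them by the posterior model probabilities, and attaches
#' goodness-of-fit diagnostics (observed P value, Tukey depth and Tukey P
#' value per model).
#'
#' @param observed named 67-statistic vector (from [compute_stat_vector()] or
#'   [simulate_stat_vector()]).
#' @param ref a [reference_table()].
#' @param k simulations retained (both for model choice and posteriors).
#' @param model_stats statistics used for model choice.
#' @param pls_components PLS components for parameter estimation.
#' @param n_directions random directions for the Tukey-depth approximation.
#' @param diagnostics compute goodness-of-fit diagnostics.
#' @return object of class `abc_fit`.
#' @export
abc_fit <- function(observed, ref, k = 1000, model_stats = selected_stats(),
                    pls_components = 7, n_directions = 2000,
                    diagnostics = TRUE) {
  mc <- model_posterior(ref, observed, k = k, stats = model_stats)
  post_params <- lapply(mc$models, function(m)
    parameter_posterior(ref, observed, m, k = k,
                        n_components = pls_components))
  names(post_params) <- mc$models
  weighted <- weight_posteriors(post_params, mc$posterior)

  diag_tbl <- NULL
  if (diagnostics) {
    diag_tbl <- do.call(rbind, lapply(mc$models, function(m) {
      pm <- mc$per_model[[m]]
      op <- observed_p_value(pm, mc$z_observed)
      td <- tukey_depth(mc$z_observed, pm$z_retained,
                        n_directions = n_directions)
      tp <- tukey_p_value(mc$z_observed, pm$z_retained,
                          n_directions = min(n_directions, 500))
      data.frame(model = m, posterior = unname(mc$posterior[m]),
                 observed_p = op, tukey_depth = td, tukey_p = tp)
    }))
  }
  structure(list(model_choice = mc, parameters = post_params,
                 weighted = weighted, diagnostics = diag_tbl,
                 k = k, model_stats = model_stats,
                 pls_components = pls_components),
            class = "abc_fit")
}

#' @export
print.abc_fit <- function(x, ...) {
  cat("ABC fit: model choice over",
      paste(x$model_choice$models, collapse = ", "), "\n\n")
  if (!is.null(x$diagnostics)) {
    tbl <- x$diagnostics
    tbl[-1] <- lapply(tbl[-1], round, 4)
    print(tbl, row.names = FALSE)
  } else print(round(x$model_choice$posterior, 4))
  cat("\nModel-averaged parameter estimates (posterior medians):\n")
  print(signif(coef(x), 4))
  invisible(x)
}

#' @export
summary.abc_fit <- function(object, ...) {
  structure(list(posterior = object$model_choice$posterior,
                 diagnostics = object$diagnostics,
                 parameters = object$weighted$summary),
            class = "summary.abc_fit")
}

#' @export
print.summary.abc_fit <- function(x, ...) {
  cat("Posterior model probabilities:\n")
  print(round(x$posterior, 4))
  if (!is.null(x$diagnostics)) {
    cat("\nGoodness of fit:\n")
    tbl <- x$diagnostics
    tbl[-1] <- lapply(tbl[-1], round, 4)
    print(tbl, row.names = FALSE)
  }
  cat("\nModel-averaged posteriors (mode / mean / median / Q5% / Q95%):\n")
  print(signif(x$parameters, 4))
  invisible(x)
}

#' @export
coef.abc_fit <- function(object, ...) {
  setNames(object$weighted$summary[, "median"],
           rownames(object$weighted$summary))
}

#' @export
plot.abc_fit <- function(x, params = PARAM_NAMES, ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(params)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in params) {
    g <- x$weighted$grids[[p]]
    plot(g$x, g$y, type = "l", xlab = p, ylab = "density",
         main = p, ...)
  }
  invisible(x)
}
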