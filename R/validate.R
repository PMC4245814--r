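# Goodness-of-fit and calibration machinery: observed P value, randomized
# Tukey half-space depth, pseudo-observed calibration of model choice and
# posteriors, and greedy summary-statistic selection.

#' Observed P value of a model fit
#'
#' The fraction of retained simulations whose GLM marginal likelihood is
#' smaller than or equal to that of the observed data; values near zero
#' signal that the model cannot reproduce the observation.
#'
#' @param per_model one element of the `per_model` list of a
#'   [model_posterior()] fit (fitted means, residual covariance, retained
#'   standardized statistics).
#' @param z_observed observed statistics on the same standardized scale.
#' @return a fraction in \[0,1\].
#' @export
observed_p_value <- function(per_model, z_observed) {
  f <- per_model$fitted
  s <- per_model$sigma
  n <- per_model$n_sims
  lik_obs <- logsumexp(dmvnorm_log_rows(z_observed, f, s)) - log(n)
  zr <- per_model$z_retained
  lik_ret <- vapply(seq_len(nrow(zr)), function(i)
    logsumexp(dmvnorm_log_rows(zr[i, ], f, s)) - log(n), numeric(1))
  mean(lik_ret <= lik_obs)
}

# random unit directions (columns), deterministic given the RNG state
random_directions <- function(d, n_directions) {
  u <- matrix(rnorm(d * n_directions), nrow = d)
  sweep(u, 2, sqrt(colSums(u^2)), "/")
}

#' Randomized Tukey half-space depth
#'
#' Approximates the half-space depth of `point` in `cloud` by minimizing,
#' over random projection directions, the smaller tail fraction of the cloud
#' on either side of the point.  The approximation upper-bounds the exact
#' depth and decreases (weakly) as directions are added.
#'
#' @param point numeric vector.
#' @param cloud matrix (points x dimensions).
#' @param n_directions number of random directions.
#' @return depth as a fraction of the cloud.
#' @export
tukey_depth <- function(point, cloud, n_directions = 10000) {
  if (nrow(cloud) < 2) stop("cloud must contain at least 2 points")
  if (all(apply(cloud, 2, sd) == 0)) stop("zero-variance cloud")
  u <- random_directions(ncol(cloud), n_directions)
  pc <- cloud %*% u
  p0 <- drop(point %*% u)
  le <- colMeans(sweep(pc, 2, p0) <= 0)
  ge <- colMeans(sweep(pc, 2, p0) >= 0)
  min(pmin(le, ge))
}

#' Exact Tukey depth in two dimensions
#'
#' Brute-force oracle over all directions normal to point-pair differences
#' (sufficient in the plane); intended for validating the randomized
#' approximation on small clouds.
#'
#' @inheritParams tukey_depth
#' @return exact half-space depth.
#' @export
tukey_depth_exact2d <- function(point, cloud) {
  stopifnot(ncol(cloud) == 2)
  pts <- rbind(cloud, point)
  n <- nrow(pts)
  dirs <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      v <- pts[j, ] - pts[i, ]
      if (all(v == 0)) next
      dirs[[length(dirs) + 1]] <- c(-v[2], v[1]) / sqrt(sum(v^2))
    }
  }
  # perturb each candidate normal slightly on both sides to handle ties
  eps <- 1e-9
  best <- 0.5
  for (u0 in dirs) {
    for (ang in c(-eps, 0, eps)) {
      rot <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2)
      u <- rot %*% u0
      pc <- drop(cloud %*% u)
      p0 <- drop(point %*% u)
      best <- min(best, mean(pc <= p0), mean(pc >= p0))
    }
  }
  best
}

# depths of every cloud point (leave-one-in) plus an external point,
# sharing one direction set
tukey_depth_all <- function(point, cloud, n_directions = 500) {
  u <- random_directions(ncol(cloud), n_directions)
  pc <- cloud %*% u # k x nd
  p0 <- drop(point %*% u)
  k <- nrow(pc)
  depth_cloud <- rep(1, k)
  depth_obs <- 1
  for (j in seq_len(n_directions)) {
    x <- pc[, j]
    r_le <- rank(x, ties.method = "max") / k
    r_ge <- (k - rank(x, ties.method = "min") + 1) / k
    depth_cloud <- pmin(depth_cloud, pmin(r_le, r_ge))
    depth_obs <- min(depth_obs, mean(x <= p0[j]), mean(x >= p0[j]))
  }
  list(obs = depth_obs, cloud = depth_cloud)
}

#' Tukey-depth P value
#'
#' The fraction of retained simulations whose (randomized) Tukey depth in
#' the retained cloud is smaller than or equal to the depth of the observed
#' point; small values indicate the observation lies outside the bulk of the
#' simulations.
#'
#' @inheritParams tukey_depth
#' @param cloud matrix of retained simulated statistics (standardized).
#' @export
tukey_p_value <- function(point, cloud, n_directions = 500) {
  d <- tukey_depth_all(point, cloud, n_directions)
  mean(d$cloud <= d$obs)
}

# --- pseudo-observed experiments -----------------------------------------

#' Simulate pseudo-observed datasets (statistics and truth records)
#'
#' @param n_per_model pods per model.
#' @param models model ids.
#' @param prior a [prior_spec()].
#' @param config a [sample_config()].
#' @return list with `stats` (matrix), `model` (factor), `params` (matrix).
#' @export
simulate_pods <- function(n_per_model, models = c("M1", "M2", "M3"),
                          prior = prior_spec(),
                          config = sample_config(default_sample_sizes())) {
  ref <- reference_table(n_per_model, models, prior, config)
  list(stats = ref$stats, model = ref$model, params = ref$params)
}

#' Calibration of posterior model probabilities
#'
#' Runs ABC model choice on pseudo-observed datasets with known generating
#' model, bins the posterior probability of the chosen model (p_ABC), and
#' compares it with the empirical fraction of correct choices in each bin
#' (p_empirical).  A well-calibrated pipeline has p_empirical close to
#' p_ABC; bins holding fewer than `min_bin` pods are flagged.
#'
#' @param ref a [reference_table()].
#' @param pod_stats matrix of pseudo-observed statistic vectors.
#' @param pod_model factor of true generating models.
#' @param k retained simulations.
#' @param stats statistics used for model choice.
#' @param n_bins number of equal bins on \[0,1\].
#' @param min_bin minimum pods per bin before flagging.
#' @return object of class `calibration_report`: per-bin table, the overall
#'   accuracy, and the weighted least-squares calibration slope.
#' @export
calibrate_model_choice <- function(ref, pod_stats, pod_model, k = 1000,
                                   stats = selected_stats(), n_bins = 10,
                                   min_bin = 20) {
  post <- model_choice_batch(ref, pod_stats, k = k, stats = stats)
  chosen <- colnames(post)[max.col(post, ties.method = "first")]
  p_abc <- post[cbind(seq_len(nrow(post)),
                      max.col(post, ties.method = "first"))]
  correct <- chosen == as.character(pod_model)
  br <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(p_abc, br, include.lowest = TRUE)
  tbl <- do.call(rbind, lapply(levels(bin), function(b) {
    i <- which(bin == b)
    data.frame(bin = b, n = length(i),
               p_abc = if (length(i)) mean(p_abc[i]) else NA_real_,
               p_empirical = if (length(i)) mean(correct[i]) else NA_real_)
  }))
  tbl$flagged <- tbl$n < min_bin
  use <- !tbl$flagged & tbl$n > 0
  slope <- if (sum(use) >= 2)
    unname(coef(lm(p_empirical ~ p_abc, data = tbl[use, ],
                   weights = tbl$n[use]))[2]) else NA_real_
  structure(list(table = tbl, accuracy = mean(correct), slope = slope,
                 posteriors = post, correct = correct),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("model-choice calibration: accuracy %.3f, slope %.2f\n",
              x$accuracy, x$slope))
  tbl <- x$table
  tbl$p_abc <- round(tbl$p_abc, 3)
  tbl$p_empirical <- round(tbl$p_empirical, 3)
  print(tbl, row.names = FALSE)
  invisible(x)
}

# --- posterior calibration -------------------------------------------------

# reusable engine: fit PLS + retention-independent pieces once per model
prep_posterior_engine <- function(ref, model, n_components = 7) {
  rows <- which(ref$model == model)
  stats <- ref$stats[rows, , drop = FALSE]
  params <- ref$params[rows, , drop = FALSE]
  proj <- pls_project(stats, params, n_components)
  V <- project_stats(proj, stats)
  list(proj = proj, V = V, params = params, prior = ref$prior,
       param_names = colnames(ref$params))
}

# weighted posterior sample for one observation given an engine
posterior_sample_for <- function(eng, observed, k = 1000) {
  v0 <- drop(project_stats(eng$proj, observed))
  adj <- regression_adjust(eng$V, eng$params, v0, k, eng$prior)
  list(theta = adj$theta, w = adj$w / sum(adj$w))
}

# posterior mass of the smallest HPD region containing `truth` (per param)
hpd_mass_at_truth <- function(x, w, truth, range, grid_n = 256) {
  den <- suppressWarnings(density(x, weights = w, from = range[1],
                                  to = range[2], n = grid_n))
  d_t <- approx(den$x, den$y, truth, rule = 2)$y
  sum(den$y[den$y >= d_t]) / sum(den$y)
}

#' Posterior-quantile and HPD-coverage check
#'
#' Draws pseudo-observed datasets with parameters from the prior, estimates
#' the marginal posteriors, and records for every parameter the posterior
#' quantile of the true value (uniform for unbiased posteriors) and the
#' mass of the smallest HPD region containing the truth (also uniform).
#'
#' @param ref a [reference_table()].
#' @param model model id used for the pods and the posterior.
#' @param pod_stats matrix of pod statistic vectors generated under `model`.
#' @param pod_params matrix of the generating parameters.
#' @param k retained simulations.
#' @param n_components PLS components.
#' @return object of class `quantile_check`: matrices `quantiles` and
#'   `hpd_mass` (pods x parameters), per-parameter KS statistics against the
#'   uniform, and HPD coverage at 50/90/95%.
#' @export
posterior_quantile_check <- function(ref, model, pod_stats, pod_params,
                                     k = 1000, n_components = 7) {
  eng <- prep_posterior_engine(ref, model, n_components)
  n_pods <- nrow(pod_stats)
  pn <- eng$param_names
  qs <- hp <- matrix(NA_real_, n_pods, length(pn),
                     dimnames = list(NULL, pn))
  for (i in seq_len(n_pods)) {
    ps <- posterior_sample_for(eng, pod_stats[i, ], k = k)
    for (p in pn) {
      truth <- pod_params[i, p]
      qs[i, p] <- sum(ps$w[ps$theta[, p] <= truth])
      hp[i, p] <- hpd_mass_at_truth(ps$theta[, p], ps$w, truth,
                                    prior_range(eng$prior, p))
    }
  }
  ks <- vapply(pn, function(p)
    suppressWarnings(ks.test(qs[, p], "punif"))$statistic, numeric(1))
  ks_p <- vapply(pn, function(p)
    suppressWarnings(ks.test(qs[, p], "punif"))$p.value, numeric(1))
  cover <- matrix(vapply(c(0.5, 0.9, 0.95), function(l) colMeans(hp <= l),
                         numeric(length(pn))),
                  nrow = length(pn),
                  dimnames = list(pn, c("50%", "90%", "95%")))
  structure(list(quantiles = qs, hpd_mass = hp,
                 ks = setNames(ks, pn), ks_p = setNames(ks_p, pn),
                 hpd_coverage = cover, n_pods = n_pods),
            class = "quantile_check")
}

#' @export
print.quantile_check <- function(x, ...) {
  cat(sprintf("posterior-quantile check over %d pods\n", x$n_pods))
  cat("KS statistics vs uniform:\n")
  print(round(x$ks, 3))
  cat("HPD coverage:\n")
  print(round(x$hpd_coverage, 3))
  invisible(x)
}

# --- summary-statistic selection ------------------------------------------

#' Greedy selection of summary statistics by model-choice power
#'
#' Evaluates, with a shared reference table and shared pseudo-observed
#' datasets (common random numbers), the power of every statistic pair to
#' select the true model, then greedily adds the statistic with the largest
#' power gain until no improvement is observed.
#'
#' @param ref a [reference_table()].
#' @param pod_stats,pod_model pods with known truth.
#' @param candidates candidate statistic names.
#' @param k retained simulations.
#' @param max_stats hard cap on the subset size.
#' @return list with `subset`, `power`, and the greedy `trace`.
#' @export
select_statistics_greedy <- function(ref, pod_stats, pod_model,
                                     candidates = colnames(ref$stats),
                                     k = 1000, max_stats = 8) {
  truth <- as.character(pod_model)
  power_of <- function(subset) {
    post <- model_choice_batch(ref, pod_stats, k = k, stats = subset)
    mean(colnames(post)[max.col(post, ties.method = "first")] == truth)
  }
  best_pair <- NULL
  best_pow <- -Inf
  for (i in seq_len(length(candidates) - 1)) {
    for (j in seq.int(i + 1, length(candidates))) {
      pw <- power_of(candidates[c(i, j)])
      if (pw > best_pow) {
        best_pow <- pw
        best_pair <- candidates[c(i, j)]
      }
    }
  }
  subset <- best_pair
  trace <- data.frame(step = 1, added = paste(best_pair, collapse = "+"),
                      power = best_pow)
  repeat {
    if (length(subset) >= max_stats) break
    rest <- setdiff(candidates, subset)
    if (!length(rest)) break
    pows <- vapply(rest, function(s) power_of(c(subset, s)), numeric(1))
    if (max(pows) <= best_pow) break
    add <- rest[which.max(pows)]
    subset <- c(subset, add)
    best_pow <- max(pows)
    trace <- rbind(trace, data.frame(step = nrow(trace) + 1, added = add,
                                     power = best_pow))
  }
  list(subset = subset, power = best_pow, trace = trace)
}
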