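test_that("prior draws respect the support and the ordering constraint", {
  set.seed(41)
  th <- sample_prior(10000)
  expect_true(all(th[, "tau_HI"] > th[, "tau_WUS"]))
  expect_true(all(th[, "tau_WUS"] > th[, "tau_SP"]))
  expect_true(all(th[, "tau_SP"] > th[, "tau_EUS"]))
  expect_true(all(th[, "mu"] > 0))
  expect_true(all(th[, "lN_ASIA"] >= 4 & th[, "lN_ASIA"] <= 8))
  expect_gt(suppressWarnings(
    ks.test(th[, "lNm"], "punif", -2, 2))$p.value, 0.01)
  # acceptance rate of the ordering rejection is 1/3! = 1/6 by symmetry
  raw <- matrix(runif(3 * 20000, 10, 100), ncol = 3)
  ok <- raw[, 1] > raw[, 3] & raw[, 3] > raw[, 2]
  expect_lt(abs(mean(ok) - 1 / 6), 3 * sqrt(1 / 6 * 5 / 6 / 20000))
  # natural-scale conversion inverts the log10 transform
  nat <- prior_to_natural(th[1, ])
  expect_equal(log10(nat$N_ASIA), unname(th[1, "lN_ASIA"]))
  expect_equal(nat$tau_WUS, unname(th[1, "tau_WUS"]))
})

test_that("retention returns the exact nearest rows, ties by index", {
  stats <- matrix(c(0, 1, 2, 3, 10,
                    0, 1, 2, 3, 10), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  obs <- c(a = 2.1, b = 2.1)
  r <- retain_nearest(stats, obs, 3)
  # brute force: standardized distances preserve the order of |x - 2.1|
  expect_equal(sort(r$idx), c(2, 3, 4))
  expect_equal(r$idx[1], 3)
  # observed equal to a table row -> distance zero, retained first
  r2 <- retain_nearest(stats, c(a = 3, b = 3), 2)
  expect_equal(r2$idx[1], 4)
  expect_equal(r2$dist[1], 0)
  # k = table size retains everything
  expect_equal(sort(retain_nearest(stats, obs, 5)$idx), 1:5)
  expect_error(retain_nearest(stats, obs, 6), "exceeds")
})

test_that("GLM model choice matches the analytic Bayes factor on a toy", {
  set.seed(42)
  ref <- toy_gaussian_ref(c(A = 0, B = 1.5, C = -1.5), n = 6000)
  obs <- c(s = 0.4)
  mp <- model_posterior(ref, obs, k = 2000, stats = "s")
  pa <- vapply(c(0, 1.5, -1.5), toy_gaussian_marginal, numeric(1), s = 0.4)
  pa <- pa / sum(pa)
  expect_lt(max(abs(mp$posterior - pa)), 0.02)
  expect_equal(sum(mp$posterior), 1)

  # posterior probabilities are invariant to rescaling a statistic
  ref2 <- ref
  ref2$stats[, "s"] <- ref2$stats[, "s"] * 1000
  mp2 <- model_posterior(ref2, c(s = 400), k = 2000, stats = "s")
  expect_equal(unname(mp2$posterior), unname(mp$posterior),
               tolerance = 1e-8)
})

test_that("separated and exchangeable model clouds give the expected calls", {
  set.seed(43)
  # far-separated clouds: the generating model gets essentially all mass
  ref <- toy_gaussian_ref(c(A = 0, B = 30, C = -30), n = 3000)
  mp <- model_posterior(ref, c(s = 0.2), k = 500, stats = "s")
  expect_gt(mp$posterior["A"], 0.99)
  # identically distributed statistics: posterior ~ 1/3 each
  ref0 <- toy_gaussian_ref(c(A = 0, B = 0, C = 0), n = 3000)
  mp0 <- model_posterior(ref0, c(s = 0.2), k = 500, stats = "s")
  expect_lt(max(abs(mp0$posterior - 1 / 3)), 0.05)
  # with k equal to the full per-model table the same symmetry holds
  mp_full <- model_posterior(ref0, c(s = 0.2), k = 3000, stats = "s")
  expect_lt(max(abs(mp_full$posterior - 1 / 3)), 0.05)
})

test_that("PLS components recover a planted signal subspace", {
  set.seed(44)
  n <- 2000
  th <- matrix(rnorm(2 * n), ncol = 2,
               dimnames = list(NULL, c("t1", "t2")))
  stats <- cbind(s1 = th[, 1] + rnorm(n, 0, 0.1),
                 s2 = th[, 2] + rnorm(n, 0, 0.1),
                 n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  proj <- pls_project(stats, th, n_components = 2)
  # loadings of the first two components live in the (s1, s2) plane:
  # principal angle between spans below 5 degrees
  W <- proj$fit$loadings$X[, 1:2]
  signal <- matrix(0, 5, 2, dimnames = list(colnames(stats), NULL))
  signal[1, 1] <- signal[2, 2] <- 1
  qs <- qr.Q(qr(signal))
  qw <- qr.Q(qr(W))
  angle <- acos(min(svd(t(qs) %*% qw)$d)) * 180 / pi
  expect_lt(angle, 5)
  # projection applies identically to new data
  v <- project_stats(proj, stats[3, ])
  V <- project_stats(proj, stats)
  expect_equal(as.numeric(v), as.numeric(V[3, ]), tolerance = 1e-10)

  # permuted parameters: components capture no covariance with the
  # (permuted) response they were fit against
  th_perm <- th[sample(n), ]
  proj0 <- pls_project(stats, th_perm, n_components = 2)
  V0 <- project_stats(proj0, stats)
  expect_lt(max(abs(cor(V0, th_perm))), 0.1)

  # full-dimensional projection is injective (rank preserved)
  projf <- pls_project(stats, th, n_components = 5)
  Vf <- project_stats(projf, stats)
  expect_equal(qr(Vf)$rank, 5)
})

test_that("regression-adjusted posterior matches the conjugate solution", {
  set.seed(45)
  ref <- toy_conjugate(6000)
  obs <- c(s1 = 1.2, s2 = 0.3)
  pp <- parameter_posterior(ref, obs, "A", k = 1500, n_components = 2)
  an <- toy_conjugate_posterior(1.2)
  expect_lt(abs(pp$summary["th", "median"] - an$mean), 0.12)
  expect_lt(abs(pp$summary["th", "q5"] - (an$mean - 1.645 * an$sd)), 0.2)
  expect_lt(abs(pp$summary["th", "q95"] - (an$mean + 1.645 * an$sd)), 0.2)
  # density grid integrates to one over the support
  g <- pp$grids$th
  expect_equal(sum(g$y) * diff(range(g$x)) / (length(g$x) - 1), 1,
               tolerance = 1e-6)
})

test_that("posterior falls back to the prior for uninformative statistics", {
  set.seed(46)
  ref <- toy_conjugate(6000)
  ref$stats <- cbind(s1 = rnorm(6000), s2 = rnorm(6000)) # cut the link
  pp <- parameter_posterior(ref, c(s1 = 0, s2 = 0), "A", k = 1500,
                            n_components = 2)
  # total-variation distance to the prior below 0.1
  g <- pp$grids$th
  prior_y <- dnorm(g$x) / (pnorm(6) - pnorm(-6))
  dx <- g$x[2] - g$x[1]
  tv <- 0.5 * sum(abs(g$y - prior_y)) * dx
  expect_lt(tv, 0.1)
})

test_that("a noiseless linear statistic concentrates the posterior", {
  set.seed(47)
  n <- 5000
  th <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "th"))
  ref <- toy_conjugate(n)
  ref$params <- th
  ref$stats <- cbind(s1 = th[, 1], s2 = rnorm(n))
  pp <- parameter_posterior(ref, c(s1 = 0.8, s2 = 0), "A", k = 800,
                            n_components = 2)
  expect_lt(abs(pp$summary["th", "median"] - 0.8), 0.02)
  expect_lt(pp$summary["th", "q95"] - pp$summary["th", "q5"], 0.1)
})

test_that("model averaging mixes densities and summaries correctly", {
  set.seed(48)
  ref <- toy_conjugate(4000)
  p1 <- parameter_posterior(ref, c(s1 = -1.5, s2 = 0), "A", k = 800,
                            n_components = 2)
  p2 <- parameter_posterior(ref, c(s1 = 1.5, s2 = 0), "A", k = 800,
                            n_components = 2)
  # degenerate weights return the first posterior
  w10 <- weight_posteriors(list(p1, p2), c(1, 0))
  expect_equal(w10$grids$th$y, p1$grids$th$y)
  # identical posteriors are unchanged
  wsame <- weight_posteriors(list(p1, p1), c(0.5, 0.5))
  expect_equal(wsame$grids$th$y, p1$grids$th$y)
  # mixture mean is the weighted mean of the component means
  w <- 0.3
  wm <- weight_posteriors(list(p1, p2), c(w, 1 - w))
  expect_equal(wm$summary["th", "mean"],
               w * p1$summary["th", "mean"] +
                 (1 - w) * p2$summary["th", "mean"],
               tolerance = 1e-8)
  # mixture of two separated posteriors is bimodal with mass ~ w on the left
  g <- wm$grids$th
  dx <- g$x[2] - g$x[1]
  left <- sum(g$y[g$x < 0]) * dx
  expect_lt(abs(left - w), 0.1)
})

test_that("the fitted object exposes methods and coherent diagnostics", {
  set.seed(49)
  ref <- toy_gaussian_ref(c(M1 = 0, M2 = 1, M3 = -1), n = 2000)
  ref$prior <- generic_prior(
    sample = function(m) matrix(runif(m, -1, 1), ncol = 1,
                                dimnames = list(NULL, "th")),
    log_density = function(theta) rep(0, nrow(theta)),
    ranges = matrix(c(-1, 1), 1, 2, dimnames = list("th", NULL)))
  fit <- abc_fit(c(s = 0.3), ref, k = 500, model_stats = "s",
                 pls_components = 1, n_directions = 300)
  expect_s3_class(fit, "abc_fit")
  expect_equal(sum(fit$model_choice$posterior), 1)
  expect_true(all(fit$diagnostics$observed_p >= 0 &
                    fit$diagnostics$observed_p <= 1))
  expect_true(all(fit$diagnostics$tukey_depth <= 0.5))
  expect_named(coef(fit), "th")
  out <- capture.output(print(fit))
  expect_true(any(grepl("model choice", out)))
  s <- summary(fit)
  expect_s3_class(s, "summary.abc_fit")
})
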