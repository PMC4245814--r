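# shared builders for toy reference tables and pipelines

# Gaussian location toy: model m has stats s ~ N(theta + shift_m, 1),
# theta ~ U(-1, 1); analytic marginal available for model-choice checks
toy_gaussian_ref <- function(shifts, n, sd = 1) {
  blocks <- lapply(shifts, function(sh) {
    th <- matrix(runif(n, -1, 1), ncol = 1, dimnames = list(NULL, "th"))
    list(params = th,
         stats = matrix(rnorm(n, th + sh, sd), ncol = 1,
                        dimnames = list(NULL, "s")))
  })
  structure(list(
    model = factor(rep(names(shifts), each = n), levels = names(shifts)),
    params = do.call(rbind, lapply(blocks, `[[`, "params")),
    stats = do.call(rbind, lapply(blocks, `[[`, "stats"))),
    class = "ref_table")
}

toy_gaussian_marginal <- function(s, shift, sd = 1) {
  # integral of N(s; th + shift, sd) over th ~ U(-1, 1)
  (pnorm((s - shift + 1) / sd) - pnorm((s - shift - 1) / sd)) / 2
}

# conjugate pipeline: theta ~ N(0,1), s1 = theta + N(0, 0.5), s2 pure noise
toy_conjugate <- function(n) {
  th <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "th"))
  st <- cbind(s1 = th[, 1] + rnorm(n, 0, 0.5), s2 = rnorm(n))
  prior <- generic_prior(
    sample = function(m) matrix(rnorm(m), ncol = 1,
                                dimnames = list(NULL, "th")),
    log_density = function(theta) dnorm(theta[, "th"], log = TRUE),
    ranges = matrix(c(-6, 6), 1, 2, dimnames = list("th", NULL)))
  structure(list(model = factor(rep("A", n)), params = th, stats = st,
                 prior = prior), class = "ref_table")
}

toy_conjugate_posterior <- function(s1) {
  # theta | s1 ~ N(s1 / (1 + 0.25), sqrt(0.25 / 1.25))
  list(mean = s1 / 1.25, sd = sqrt(0.25 / 1.25))
}

# small complete dataset for brute-force diversity oracles
random_small_dataset <- function(n_seq = 8, n_sites = 30) {
  m <- matrix(sample(c("A", "C", "G", "T"), n_seq * n_sites, replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1)),
              nrow = n_seq,
              dimnames = list(sprintf("s%02d", seq_len(n_seq)), NULL))
  multilocus_dataset(list(L1 = m),
                     setNames(rep("P1", n_seq), rownames(m)),
                     c(P1 = "JP"))
}

# a five-region demography with mid-range parameters, for structural tests
mid_params <- function() {
  list(N_ASIA = 1e6, N_JP = 1e4, N_HI = 1e4, N_WUS = 3e4, N_EUS = 5e4,
       N_SP = 1e4, f_HI = 100, f_WUS = 150, f_EUS = 60, f_SP = 10,
       tau_HI = 430, tau_WUS = 88, tau_SP = 58, tau_EUS = 21, Nm = 0.6,
       mu = 3.46e-9)
}
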