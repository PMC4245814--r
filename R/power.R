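# Power and information analyses: model-choice power against the number of
# loci, ancestral-lineage and genealogy-length grids for founder scenarios,
# new-mutation count distributions and their overlap, and sample-size
# arithmetic.

#' Model-choice power for a given number of loci
#'
#' Simulates a reference table and pseudo-observed datasets (drawn equally
#' from the three colonization models under the priors), runs ABC model
#' choice, and reports the fraction of pods whose true model attains the
#' highest posterior, with its binomial standard error.
#'
#' @param n_loci number of independent 450-bp loci.
#' @param n_sims simulations per model for the reference table.
#' @param n_pods total pseudo-observed datasets (split equally).
#' @param k retained simulations.
#' @param stats statistic names used for model choice.
#' @param prior a [prior_spec()].
#' @param sample_sizes named per-region haploid sample sizes.
#' @param locus_bp locus length in bp.
#' @param models model ids.
#' @param ref optional precomputed [reference_table()] to reuse.
#' @return list with `power`, `se`, `n_pods`, `n_loci`.
#' @export
model_choice_power <- function(n_loci, n_sims = 10000, n_pods = 600,
                               k = 1000, stats = selected_stats(),
                               prior = prior_spec(),
                               sample_sizes = default_sample_sizes(),
                               locus_bp = 450,
                               models = c("M1", "M2", "M3"), ref = NULL) {
  stopifnot(n_loci >= 1)
  config <- sample_config(sample_sizes,
                          data.frame(locus_id = paste0("L",
                                                       seq_len(n_loci)),
                                     length = rep(locus_bp, n_loci)))
  if (is.null(ref)) ref <- reference_table(n_sims, models, prior, config)
  per <- floor(n_pods / length(models))
  pods <- simulate_pods(per, models, prior, config)
  post <- model_choice_batch(ref, pods$stats, k = k, stats = stats)
  correct <- colnames(post)[max.col(post, ties.method = "first")] ==
    as.character(pods$model)
  p <- mean(correct)
  list(power = p, se = sqrt(p * (1 - p) / length(correct)),
       n_pods = length(correct), n_loci = n_loci)
}

#' Fit the power-versus-loci curve
#'
#' Least-squares fit of `power = a + b * log10(loci)`, the empirical form
#' describing how model-choice power grows with sequencing effort.
#'
#' @param loci_counts numbers of loci (>= 3 points).
#' @param power power estimates at those counts.
#' @return object of class `power_curve` with coefficients `a`, `b`.
#' @export
fit_power_curve <- function(loci_counts, power) {
  stopifnot(length(loci_counts) >= 3, length(power) == length(loci_counts),
            all(loci_counts > 0), !is.unsorted(loci_counts))
  fit <- lm(power ~ log10(loci_counts))
  a <- unname(coef(fit)[1])
  b <- unname(coef(fit)[2])
  if (!all(is.finite(c(a, b)))) stop("power-curve fit is not finite")
  structure(list(a = a, b = b, loci = loci_counts, power = power,
                 fit = fit), class = "power_curve")
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("power = %.4f + %.4f * log10(loci) over %d points\n",
              x$a, x$b, length(x$loci)))
  invisible(x)
}

#' Number of loci required for a target power
#'
#' Inverts a fitted [fit_power_curve()]; warns when the answer lies beyond
#' the largest number of loci actually measured, and returns `Inf` when the
#' curve is flat or decreasing.
#'
#' @param curve a `power_curve`.
#' @param target target power (e.g. 0.9).
#' @return required number of loci.
#' @export
loci_for_power <- function(curve, target) {
  if (curve$b <= 0) {
    warning("flat or decreasing power curve; target unreachable")
    return(Inf)
  }
  loci <- 10^((target - curve$a) / curve$b)
  if (loci > max(curve$loci))
    warning(sprintf(
      "extrapolating beyond the largest measured loci count (%d)",
      max(curve$loci)))
  loci
}

#' Sequence requirement in megabases for a target power
#'
#' @inheritParams loci_for_power
#' @param locus_bp locus length in bp.
#' @export
sequence_requirement_mb <- function(curve, target = 0.9, locus_bp = 450) {
  loci_for_power(curve, target) * locus_bp / 1e6
}

# single founded population (exponential growth from f at tau to N);
# the source deme only matters above tau
founder_demography <- function(f, tau, N_present, N_source = N_present) {
  structure(list(model_id = "founder", params = list(f = f, tau = tau,
                                                     N = N_present),
                 demes = c("COL", "SRC"),
                 N = c(N_present, N_source),
                 g = c(log(N_present / f) / tau, 0),
                 t_end = c(tau, Inf), merge_to = c(1L, -1L),
                 mig = matrix(0, 2, 2)), class = "demography")
}

#' Monte-Carlo grid of ancestral lineages and genealogy length
#'
#' For each (founders f, colonization time tau) pair, simulates genealogies
#' of `n` samples from a population growing exponentially from `f` at `tau`
#' to `N_present` now, and reports the expected number of lineages not yet
#' coalesced at `tau` (`L_A`) and the expected total branch length more
#' recent than `tau` (`G_L`).
#'
#' @param f_values,tau_values grid coordinates.
#' @param N_present present population size.
#' @param n haploid sample size.
#' @param reps Monte-Carlo replicates per cell.
#' @return data.frame with columns `f`, `tau`, `E_LA`, `se_LA`, `E_GL`,
#'   `se_GL`.
#' @export
lineage_grid <- function(f_values, tau_values, N_present = 10000, n = 25,
                         reps = 1000) {
  out <- expand.grid(f = f_values, tau = tau_values)
  out$E_LA <- out$se_LA <- out$E_GL <- out$se_GL <- NA_real_
  cfg <- sample_config(c(COL = n), 1)
  for (i in seq_len(nrow(out))) {
    demog <- founder_demography(out$f[i], out$tau[i], N_present)
    cfg_rep <- cfg
    cfg_rep$loci <- cfg$loci[rep(1, reps), , drop = FALSE]
    sims <- simulate_genealogy(demog, cfg_rep, tau = out$tau[i])
    la <- vapply(sims, `[[`, numeric(1), "L_A")
    gl <- vapply(sims, `[[`, numeric(1), "G_L")
    out$E_LA[i] <- mean(la)
    out$se_LA[i] <- sd(la) / sqrt(reps)
    out$E_GL[i] <- mean(gl)
    out$se_GL[i] <- sd(gl) / sqrt(reps)
  }
  out
}

#' Distribution of new mutations since colonization
#'
#' Simulates the total post-colonization genealogy length of `l_loci`
#' independent loci and mixes Poisson counts with rate `mu * L * G` over the
#' replicates, giving the probability distribution of the number of new
#' (post-founding) mutations.
#'
#' @param f,tau,N_present founder scenario.
#' @param n haploid sample size.
#' @param l_loci number of loci.
#' @param mu per-site per-generation mutation rate.
#' @param L locus length (bp).
#' @param reps Monte-Carlo replicates.
#' @return object of class `mutation_pmf` with fields `counts`, `prob`.
#' @export
new_mutation_pmf <- function(f, tau, N_present = 10000, n = 25, l_loci = 96,
                             mu = 3.46e-9, L = 450, reps = 1000) {
  stopifnot(reps >= 100)
  demog <- founder_demography(f, tau, N_present)
  cfg <- sample_config(c(COL = n), 1)
  g_tot <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg_rep <- cfg
    cfg_rep$loci <- cfg$loci[rep(1, l_loci), , drop = FALSE]
    sims <- simulate_genealogy(demog, cfg_rep, tau = tau)
    g_tot[r] <- sum(vapply(sims, `[[`, numeric(1), "G_L"))
  }
  lam <- mu * L * g_tot
  kmax <- max(1, stats::qpois(0.99999, max(lam)))
  counts <- 0:kmax
  prob <- vapply(counts, function(kk) mean(dpois(kk, lam)), numeric(1))
  prob <- prob / sum(prob)
  structure(list(counts = counts, prob = prob, mean = mean(lam),
                 params = list(f = f, tau = tau, N = N_present, n = n,
                               l = l_loci, mu = mu, L = L)),
            class = "mutation_pmf")
}

#' Example founder scenarios with matched ancestral-lineage expectations
#'
#' Three pairs of (founders f, colonization time tau) scenarios at a present
#' size of 10,000 and sample size 25, found by grid search to share the same
#' expected number of ancestral lineages within Monte-Carlo error (low,
#' intermediate and high E(L_A)).  Within a pair, the ancestral diversity is
#' indistinguishable and only new (post-colonization) mutations separate the
#' scenarios.
#'
#' @return named list of pairs, each a list of two `c(f, tau)` vectors.
#' @export
example_scenarios <- function() {
  list(A = list(c(f = 2, tau = 45), c(f = 5, tau = 90)),
       B = list(c(f = 10, tau = 37), c(f = 30, tau = 90)),
       C = list(c(f = 30, tau = 25), c(f = 150, tau = 90)))
}

#' Overlap between two discrete distributions
#'
#' `sum_k min(p_k, q_k)` over a common support; 1 for identical
#' distributions, 0 for disjoint ones.
#'
#' @param p,q probability vectors or `mutation_pmf` objects.
#' @export
pmf_overlap <- function(p, q) {
  if (inherits(p, "mutation_pmf")) p <- p$prob
  if (inherits(q, "mutation_pmf")) q <- q$prob
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("inputs must be normalized probability vectors")
  n <- max(length(p), length(q))
  p <- c(p, rep(0, n - length(p)))
  q <- c(q, rep(0, n - length(q)))
  sum(pmin(p, q))
}

#' Expected-mutation gain from a larger sample
#'
#' Percent increase in the expected number of mutations when enlarging the
#' sample from `n1` to `n2`.  Under a constant-size population (no `f`/`tau`
#' given) the expectation is proportional to the total genealogy length;
#' under a founder-growth scenario the post-colonization genealogy length
#' (the new-mutation reservoir) is used.
#'
#' @param n1,n2 haploid sample sizes, `n2 > n1`.
#' @param N_present population size now.
#' @param f,tau optional founder scenario.
#' @param reps Monte-Carlo replicates.
#' @return percent increase.
#' @export
sample_size_gain <- function(n1, n2, N_present = 10000, f = NULL,
                             tau = NULL, reps = 2000) {
  stopifnot(n2 > n1, n1 >= 2)
  expected_length <- function(n) {
    if (is.null(f)) {
      demog <- structure(list(model_id = "constant", params = list(),
                              demes = "POP", N = N_present, g = 0,
                              t_end = Inf, merge_to = -1L,
                              mig = matrix(0, 1, 1)),
                         class = "demography")
      cfg <- sample_config(c(POP = n), 1)
      cfg$loci <- cfg$loci[rep(1, reps), , drop = FALSE]
      sims <- simulate_genealogy(demog, cfg)
      mean(vapply(sims, `[[`, numeric(1), "total_length"))
    } else {
      demog <- founder_demography(f, tau, N_present)
      cfg <- sample_config(c(COL = n), 1)
      cfg$loci <- cfg$loci[rep(1, reps), , drop = FALSE]
      sims <- simulate_genealogy(demog, cfg, tau = tau)
      mean(vapply(sims, `[[`, numeric(1), "G_L"))
    }
  }
  100 * (expected_length(n2) / expected_length(n1) - 1)
}

#' Exact sample-size gain in a constant population
#'
#' In a constant-size population the expected number of mutations among `n`
#' samples is proportional to the harmonic sum `H_{n-1} = sum_{j<n} 1/j`;
#' the exact percent gain from `n1` to `n2` is `100 (H_{n2-1}/H_{n1-1} - 1)`.
#'
#' @param n1,n2 haploid sample sizes with `n2 > n1 >= 2`.
#' @return percent increase.
#' @export
harmonic_gain <- function(n1, n2) {
  if (!(n2 > n1 && n1 >= 2)) stop("need n2 > n1 >= 2")
  h <- function(n) sum(1 / seq_len(n - 1))
  100 * (h(n2) / h(n1) - 1)
}
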