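test_that("demography construction wires colonization sources per model", {
  p <- mid_params()
  for (m in c("M1", "M2", "M3")) {
    d <- build_demography(m, p)
    src <- function(deme) d$demes[d$merge_to[match(deme, d$demes)] + 1]
    expect_equal(src("HI"), "ASIA")
    expect_equal(src("WUS"), "ASIA")
    expect_equal(src("EUS"), if (m == "M1") "ASIA" else "WUS")
    expect_equal(src("SP"), if (m == "M3") "WUS" else "ASIA")
  }
  d_jp <- build_demography("M1", p, native_source = "JP")
  expect_equal(d_jp$demes[d_jp$merge_to[match("HI", d_jp$demes)] + 1], "JP")

  # ordering constraint
  bad <- p
  bad$tau_EUS <- 70 # > tau_SP = 58
  expect_error(build_demography("M1", bad), "tau_HI > tau_WUS")
  expect_error(build_demography("M9", p), "unknown model")
  # sizes decline backward to the founder count
  d1 <- build_demography("M1", p)
  i <- match("SP", d1$demes)
  expect_equal(d1$N[i] * exp(-d1$g[i] * p$tau_SP), p$f_SP)
})

test_that("coalescence times match constant-size closed forms", {
  demog <- build_demography("native-constant", list(N_JP = 1000))
  cfg <- sample_config(c(JP = 10), 1)
  cfg$loci <- cfg$loci[rep(1, 10000), , drop = FALSE]
  set.seed(31)
  sims <- simulate_genealogy(demog, cfg)
  tm <- vapply(sims, `[[`, numeric(1), "tmrca")
  # E(T_MRCA) = 2N(1 - 1/n), haploid
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2 * 1000 * (1 - 1 / 10)), 3 * se)
  # total length E = 2N * H_{n-1}
  tl <- vapply(sims, `[[`, numeric(1), "total_length")
  se_l <- sd(tl) / sqrt(length(tl))
  expect_lt(abs(mean(tl) - 2 * 1000 * sum(1 / (1:9))), 3 * se_l)

  # n = 2: exponential with mean N
  cfg2 <- sample_config(c(JP = 2), 1)
  cfg2$loci <- cfg2$loci[rep(1, 4000), , drop = FALSE]
  t2 <- vapply(simulate_genealogy(demog, cfg2), `[[`, numeric(1), "tmrca")
  expect_gt(ks.test(t2, "pexp", 1 / 1000)$p.value, 0.001)
})

test_that("mutation counts follow the Watterson expectation", {
  # theta_locus = mu * L * 2N = 0.2 -> E(S) = 0.2/2 * 2 * H_9
  demog <- build_demography("native-constant", list(N_JP = 1000))
  cfg <- sample_config(c(JP = 10),
                       data.frame(locus_id = paste0("L", 1:8000),
                                  length = 450))
  sv <- invasionABC:::sample_vectors(demog, cfg)
  mu <- 0.1 / (1000 * 450)
  set.seed(32)
  sim <- invasionABC:::cpp_sim_haplotypes(unclass(demog), sv$deme,
                                          as.integer(cfg$loci$length), mu)
  S <- vapply(sim, function(x) length(x$positions), numeric(1))
  expected <- 0.1 * 2 * sum(1 / (1:9))
  expect_lt(abs(mean(S) - expected), 3 * sd(S) / sqrt(length(S)))
  # mu = 0 -> monomorphic
  ds0 <- simulate_dataset(demog, sample_config(c(JP = 5), 2), mu = 0)
  expect_equal(site_summaries(ds0, "JP", level = "region")$S, 0)
})

test_that("site-frequency spectrum matches the neutral expectation", {
  # E(xi_i) = theta / i for a constant-size population (independent oracle)
  n <- 8
  demog <- build_demography("native-constant", list(N_JP = 2000))
  cfg <- sample_config(c(JP = n),
                       data.frame(locus_id = paste0("L", 1:6000),
                                  length = 400))
  sv <- invasionABC:::sample_vectors(demog, cfg)
  mu <- 2.5e-6
  theta_locus <- 2 * 2000 * mu * 400
  set.seed(33)
  sim <- invasionABC:::cpp_sim_haplotypes(unclass(demog), sv$deme,
                                          as.integer(cfg$loci$length), mu)
  # per-locus class counts; genealogical variance exceeds the Poisson, so
  # use the empirical standard error across the independent loci
  per_locus <- vapply(sim, function(x)
    tabulate(colSums(x$derived), nbins = n - 1), numeric(n - 1))
  expected <- theta_locus / (1:(n - 1))
  for (i in 1:(n - 1)) {
    m <- mean(per_locus[i, ])
    se <- sd(per_locus[i, ]) / sqrt(ncol(per_locus))
    expect_lt(abs(m - expected[i]), 4 * se)
  }
})

test_that("ancestral lineages and genealogy length behave at the limits", {
  demog <- build_demography("native-constant", list(N_JP = 500))
  cfg <- sample_config(c(JP = 12), 1)
  set.seed(34)
  g <- simulate_genealogy(demog, cfg, tau = 0)[[1]]
  expect_equal(g$L_A, 12)
  expect_equal(g$G_L, 0)
  # with tau beyond the root, G_L equals the total length (additivity)
  g2 <- simulate_genealogy(demog, cfg, tau = 1e9)[[1]]
  expect_equal(g2$G_L, g2$total_length)
  expect_equal(g2$L_A, 1)
})

test_that("E(L_A) decreases with tau and increases with founders", {
  set.seed(35)
  grid <- lineage_grid(c(10, 100), c(20, 80), N_present = 1e4, n = 25,
                       reps = 600)
  gm <- function(f, tau) grid[grid$f == f & grid$tau == tau, ]
  # monotone in tau at fixed f (within 2 SE)
  for (f in c(10, 100)) {
    a <- gm(f, 20); b <- gm(f, 80)
    expect_gt(a$E_LA - b$E_LA, -2 * sqrt(a$se_LA^2 + b$se_LA^2))
  }
  # monotone in f at fixed tau
  for (tau in c(20, 80)) {
    a <- gm(100, tau); b <- gm(10, tau)
    expect_gt(a$E_LA - b$E_LA, -2 * sqrt(a$se_LA^2 + b$se_LA^2))
  }
  expect_true(all(grid$E_LA >= 1 & grid$E_LA <= 25))
  expect_true(all(grid$E_GL >= 0))
})

test_that("island-model differentiation tracks 1/(1 + 2Nm) and declines", {
  set.seed(36)
  fst_hat <- vapply(c(0.25, 1, 4), function(Nm) {
    demog <- build_demography("native-structured",
                              list(N_JP = 5000, N_ASIA = 5e5, Nm = Nm))
    cfg <- sample_config(c(JP = 20, ASIA = 20), 20)
    sv <- invasionABC:::sample_vectors(demog, cfg)
    pw <- pb <- numeric(30)
    for (r in 1:30) {
      M <- invasionABC:::cpp_sim_counts(unclass(demog), sv$deme, sv$region,
                                        2, as.integer(cfg$loci$length),
                                        2e-6)$counts
      dx <- M[, 1]; dy <- M[, 2]
      pw[r] <- sum(2 * dx * (20 - dx) / (20 * 19))
      pb[r] <- sum((dx * (20 - dy) + (20 - dx) * dy) / 400)
    }
    1 - mean(pw) / mean(pb)
  }, numeric(1))
  expect_lt(max(abs(fst_hat - 1 / (1 + 2 * c(0.25, 1, 4)))), 0.06)
  expect_true(all(diff(fst_hat) < 0))
})

test_that("dataset simulation is deterministic under a fixed seed", {
  demog <- build_demography("M1", mid_params())
  cfg <- sample_config(c(JP = 5, HI = 4, WUS = 4, EUS = 5, SP = 4), 3)
  set.seed(37); ds1 <- simulate_dataset(demog, cfg, missing_rate = 0.2)
  set.seed(37); ds2 <- simulate_dataset(demog, cfg, missing_rate = 0.2)
  expect_identical(ds1$loci, ds2$loci)
  set.seed(38); sv1 <- simulate_stat_vector(demog,
                                            sample_config(
                                              default_sample_sizes(), 6))
  set.seed(38); sv2 <- simulate_stat_vector(demog,
                                            sample_config(
                                              default_sample_sizes(), 6))
  expect_identical(sv1, sv2)
})

test_that("strong migration drives the sampled deme toward panmixia", {
  # native-structured with large Nm: Tajima's D of the JP sample ~ 0 on
  # average (panmixia limit of the island model)
  demog <- build_demography("native-structured",
                            list(N_JP = 5000, N_ASIA = 5000, Nm = 100))
  cfg <- sample_config(c(JP = 15), 40)
  set.seed(39)
  d_vals <- replicate(25, {
    ds <- simulate_dataset(demog, cfg, mu = 5e-6)
    site_summaries(ds, "JP", level = "region")$tajima_D
  })
  se <- sd(d_vals) / sqrt(length(d_vals))
  expect_lt(abs(mean(d_vals)), max(3 * se, 0.15))
})
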