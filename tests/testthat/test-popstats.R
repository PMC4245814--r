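test_that("nucleotide diversity matches per-site pair enumeration", {
  # ACGT/ACGA/TCGA: site diversities 2/3, 0, 0, 2/3 -> pi = 1/3
  ds <- make_toy_fixture("pi_onethird")
  expect_equal(nucleotide_diversity(ds, "P1")$pi, 1 / 3)
  # a missing call at an invariant site changes nothing
  dsm <- make_toy_fixture("pi_missing")
  expect_equal(nucleotide_diversity(dsm, "P1")$pi, 1 / 3)
  # monomorphic data
  expect_equal(nucleotide_diversity(make_toy_fixture("monomorphic"),
                                    "P1")$pi, 0)
})

test_that("pi on complete data equals mean pairwise Hamming distance", {
  for (seed in 1:4) {
    set.seed(seed)
    ds <- random_small_dataset(n_seq = 7 + seed %% 3, n_sites = 40)
    m <- ds$loci$L1
    n <- nrow(m)
    dists <- c()
    for (i in seq_len(n - 1))
      for (j in seq.int(i + 1, n))
        dists <- c(dists, sum(m[i, ] != m[j, ]))
    expect_equal(nucleotide_diversity(ds, "P1")$pi,
                 mean(dists) / ncol(m))
  }
})

test_that("pi is invariant to row order and to duplicating every individual", {
  set.seed(9)
  ds <- random_small_dataset()
  pi0 <- nucleotide_diversity(ds, "P1")$pi
  perm <- sample(nrow(ds$loci$L1))
  ds2 <- ds
  ds2$loci$L1 <- ds$loci$L1[perm, ]
  ds2$pop <- ds$pop[perm]
  expect_equal(nucleotide_diversity(ds2, "P1")$pi, pi0)
  # duplication: the allele-frequency (plug-in) component is exactly
  # invariant; only the small-sample pair correction n/(n-1) changes.
  # Undo the corrections and compare exactly.
  m3 <- rbind(ds$loci$L1, ds$loci$L1)
  rownames(m3) <- sprintf("d%02d", seq_len(nrow(m3)))
  ds3 <- multilocus_dataset(list(L1 = m3),
                            setNames(rep("P1", nrow(m3)), rownames(m3)),
                            c(P1 = "JP"))
  n <- nrow(ds$loci$L1)
  pi_dup <- nucleotide_diversity(ds3, "P1")$pi
  expect_equal(pi_dup * (2 * n - 1) / (2 * n), pi0 * (n - 1) / n)
})

test_that("paired site bootstrap matches exhaustive enumeration on 2 sites", {
  # two populations, two sites; site heterozygosities computed per group
  m <- rbind(a1 = c("A", "A"), a2 = c("T", "A"),
             b1 = c("A", "C"), b2 = c("A", "G"))
  ds <- multilocus_dataset(list(L1 = m),
                           c(a1 = "PA", a2 = "PA", b1 = "PB", b2 = "PB"),
                           c(PA = "JP", PB = "SP"))
  hA <- c(1, 0) # site het for PA
  hB <- c(0, 1)
  # resampling 2 sites with replacement: (1,1) w.p. 1/4 -> delta = 1 - 0
  # (1,2)/(2,1) w.p. 1/2 -> delta = 0.5 - 0.5 ; (2,2) w.p. 1/4 -> delta = -1
  # two-tailed p = 2 * min(P(delta <= 0), P(delta >= 0)) = 2 * min(.75, .75)
  exact_p <- 2 * min(1 / 4 + 1 / 2, 1 / 2 + 1 / 4)
  res <- pi_change_test(ds, "PA", ref_pop = "PB", B = 4000, seed = 5)
  expect_equal(res$pct_change, 0)
  expect_lt(abs(res$p - min(1, exact_p)), 0.05)
  # identity comparison: pct change 0 and p near 1
  res2 <- pi_change_test(ds, "PA", ref_pop = "PA", B = 400, seed = 6)
  expect_equal(res2$pct_change, 0)
  expect_gt(res2$p, 0.9)
})

test_that("haplotype diversity uses the unbiased estimator, complete cases", {
  # 4 haplotypes, 2 distinct with counts 3/1: Hd = (4/3)(1 - (9+1)/16) = 0.5
  ds <- make_toy_fixture("hd_half")
  expect_equal(haplotype_diversity(ds, "L1", "P1"), 0.5)
  # relative change formula
  m <- rbind(j1 = c("A", "A"), j2 = c("A", "T"), j3 = c("T", "A"),
             j4 = c("T", "T"),
             s1 = c("A", "A"), s2 = c("A", "A"), s3 = c("A", "A"),
             s4 = c("A", "T"))
  ds2 <- multilocus_dataset(list(L1 = m),
                            setNames(c(rep("JPp", 4), rep("SPp", 4)),
                                     rownames(m)),
                            c(JPp = "JP", SPp = "SP"))
  hd_jp <- haplotype_diversity(ds2, "L1", "JPp")
  hd_sp <- haplotype_diversity(ds2, "L1", "SPp")
  expect_equal(haplotype_diversity_change(ds2, "L1", "SPp", "JPp"),
               (hd_sp - hd_jp) / hd_jp)
  expect_equal(haplotype_diversity_change(ds2, "L1", "JPp", "JPp"), 0)
  # individuals with missing calls are excluded before counting haplotypes
  m2 <- m
  m2["s4", 1] <- "N"
  ds3 <- multilocus_dataset(list(L1 = m2), ds2$pop, ds2$region)
  expect_equal(haplotype_diversity(ds3, "L1", "SPp"), 0) # 3 identical left
})

test_that("site summaries match the textbook Tajima's D at n = 4, S = 1", {
  m <- rbind(t1 = c("A", "C", "G", "T", "A"),
             t2 = c("A", "C", "G", "T", "A"),
             t3 = c("T", "C", "G", "T", "A"),
             t4 = c("T", "C", "G", "T", "A"))
  ds <- multilocus_dataset(list(L1 = m),
                           setNames(rep("P1", 4), rownames(m)),
                           c(P1 = "JP"))
  ss <- site_summaries(ds, "P1")
  expect_equal(ss$S, 1)
  # independent recomputation of the constants at n = 4
  n <- 4
  a1 <- sum(1 / (1:3)); a2 <- sum(1 / (1:3)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  k_hat <- 2 * 2 * 2 / (4 * 3) # one 2/2 site
  D <- (k_hat - 1 / a1) / sqrt(e1 * 1 + e2 * 0)
  expect_equal(ss$tajima_D, D)
  # monomorphic sample: S = 0, K_sd = 0, D undefined
  ss0 <- site_summaries(make_toy_fixture("monomorphic"), "P1")
  expect_equal(ss0$S, 0)
  expect_equal(ss0$K_sd, 0)
  expect_true(is.na(ss0$tajima_D))
})

test_that("private segregating sites require an allele unique to the group", {
  m <- rbind(j1 = c("A", "A", "C"), j2 = c("T", "A", "C"),
             s1 = c("A", "A", "C"), s2 = c("A", "G", "C"))
  ds <- multilocus_dataset(list(L1 = m),
                           c(j1 = "PJ", j2 = "PJ", s1 = "PS", s2 = "PS"),
                           c(PJ = "JP", PS = "SP"))
  # site 1 segregates in PJ with T unique to PJ; site 2 in PS with G unique
  expect_equal(site_summaries(ds, "PJ")$prS, 1)
  expect_equal(site_summaries(ds, "PS")$prS, 1)
})

test_that("pairwise Fst reproduces hand AMOVA arithmetic and extremes", {
  # fixed difference, no within-pop variation
  res <- pairwise_fst(make_toy_fixture("fst_one"), "P1", "P2",
                      n_perm = 200, seed = 1)
  expect_equal(res$fst, 1)
  # hand AMOVA on a crafted 2+2 alignment.  Pairwise differences:
  # d(a1,a2) = d(b1,b2) = 1; cross pairs 2, 3, 3, 2 (sum 10)
  m <- rbind(a1 = c("A", "A", "C"), a2 = c("A", "T", "C"),
             b1 = c("G", "A", "T"), b2 = c("G", "T", "T"))
  ds <- multilocus_dataset(list(L1 = m),
                           c(a1 = "PA", a2 = "PA", b1 = "PB", b2 = "PB"),
                           c(PA = "JP", PB = "SP"))
  # SSD_T = (1 + 1 + 10)/4 = 3 ; SSD_WP = 1/2 + 1/2 = 1 ; SSD_AP = 2
  # MSD_AP = 2, sigma_w = 1/2, n_c = (4 - 8/4)/1 = 2
  # sigma_a = (2 - 0.5)/2 = 0.75 ; Fst = 0.75/1.25
  hand <- 0.75 / (0.75 + 0.5)
  expect_equal(pairwise_fst(ds, "PA", "PB", n_perm = 100, seed = 2)$fst,
               hand)
  # a random split of one population gives Fst near 0 and retains sign
  set.seed(3)
  big <- random_small_dataset(n_seq = 10, n_sites = 60)
  pop <- setNames(rep(c("X", "Y"), 5), rownames(big$loci$L1))
  ds2 <- multilocus_dataset(big$loci, pop, c(X = "JP", Y = "SP"))
  null <- pairwise_fst(ds2, "X", "Y", n_perm = 200, seed = 4)
  expect_lt(abs(null$fst), 0.3)
  expect_gt(null$p, 0.05)
})

test_that("Fst permutation p-values are uniform under the null", {
  set.seed(11)
  ps <- replicate(120, {
    ds <- random_small_dataset(n_seq = 8, n_sites = 25)
    pop <- setNames(rep(c("X", "Y"), 4), rownames(ds$loci$L1))
    ds2 <- multilocus_dataset(ds$loci, pop, c(X = "JP", Y = "SP"))
    pairwise_fst(ds2, "X", "Y", n_perm = 60)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("multi-population AMOVA returns components and a valid p", {
  set.seed(12)
  ds <- random_small_dataset(n_seq = 12, n_sites = 50)
  pop <- setNames(rep(c("X", "Y", "Z"), 4), rownames(ds$loci$L1))
  ds2 <- multilocus_dataset(ds$loci, pop,
                            c(X = "EUS", Y = "EUS", Z = "EUS"))
  res <- amova_test(ds2, n_perm = 200, seed = 13)
  expect_true(res$p >= 0 && res$p <= 1)
  expect_equal(res$df_among, 2)
  expect_gt(res$sigma_within, 0)
})

test_that("Mantel test agrees with direct correlation and with vegan", {
  pops <- c("A", "B", "C", "D")
  geo <- data.frame(pop = pops, lat = c(0, 0, 10, 20),
                    lon = c(0, 10, 10, 25))
  set.seed(14)
  fst <- matrix(0, 4, 4, dimnames = list(pops, pops))
  v <- runif(6, 0.05, 0.5)
  fst[upper.tri(fst)] <- v
  fst <- fst + t(fst)
  res <- mantel_test(fst, geo, n_perm = 500, seed = 15)
  # direct Pearson on the vectorized off-diagonals
  gd <- matrix(0, 4, 4)
  for (i in 1:3) for (j in (i + 1):4)
    gd[i, j] <- geosphere::distHaversine(c(geo$lon[i], geo$lat[i]),
                                         c(geo$lon[j], geo$lat[j])) / 1000
  gd <- gd + t(gd)
  expect_equal(res$r, cor(fst[upper.tri(fst)], gd[upper.tri(gd)]))
  vg <- vegan::mantel(as.dist(fst), as.dist(gd), permutations = 500)
  expect_equal(res$r, unname(vg$statistic))

  # perfect correlation: r = 1 and a small p (with only 4 populations the
  # sampled permutations revisit the identity, so p stays above 1/(B+1))
  dimnames(gd) <- list(pops, pops)
  res2 <- mantel_test(gd, geo, n_perm = 200, seed = 16)
  expect_equal(res2$r, 1)
  expect_lt(res2$p, 0.05)
  # constant genetic matrix has no defined correlation
  cst <- matrix(0.2, 4, 4, dimnames = list(pops, pops)); diag(cst) <- 0
  expect_error(mantel_test(cst, geo), "zero variance")
  # undefined transforms flag pairs
  fst2 <- fst; fst2[1, 2] <- fst2[2, 1] <- 0
  expect_warning(mantel_test(fst2, geo, transform = "neglog",
                             n_perm = 100, seed = 17), "excluded")
})
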