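# Missing-data-aware diversity and differentiation statistics.
#
# All per-site computations use only the alleles actually observed at a site:
# a site enters a within-group statistic when at least two non-missing
# alleles are present, and per-site heterozygosity uses the unbiased
# estimator 1 - sum c_a (c_a - 1) / (n (n - 1)).

# 4 x S matrix of A/C/G/T counts for a set of rows of the alignment
allele_counts <- function(mat) {
  out <- matrix(0L, nrow = 4, ncol = ncol(mat),
                dimnames = list(DNA_BASES, NULL))
  for (b in DNA_BASES) out[b, ] <- colSums(mat == b)
  out
}

site_heterozygosity <- function(counts) {
  n <- colSums(counts)
  het <- rep(NA_real_, ncol(counts))
  ok <- n >= 2
  if (any(ok)) {
    num <- colSums(counts[, ok, drop = FALSE] *
                     (counts[, ok, drop = FALSE] - 1L))
    het[ok] <- 1 - num / (n[ok] * (n[ok] - 1))
  }
  het
}

filter_sites <- function(ds, sites = c("all", "noncoding")) {
  sites <- match.arg(sites)
  cc <- concat_alignment(ds)
  keep <- if (sites == "all") rep(TRUE, ncol(cc$mat)) else
    cc$site_class == "noncoding"
  cc$mat <- cc$mat[, keep, drop = FALSE]
  cc$locus <- cc$locus[keep]
  cc
}

group_rows <- function(ds, group, level = c("population", "region")) {
  level <- match.arg(level)
  memb <- if (level == "population") ds$pop else ds$region[ds$pop]
  which(memb == group)
}

#' Nucleotide diversity with missing data
#'
#' Per-site diversity is the proportion of mismatching pairs among the
#' non-missing alleles at that site; sites with fewer than two observed
#' alleles are excluded from both numerator and denominator.
#'
#' @param ds a `multilocus` dataset.
#' @param pop population (or region, with `level = "region"`) id.
#' @param sites `"all"` or `"noncoding"`.
#' @param level grouping level of `pop`.
#' @return list with `pi` (per-site proportion), `n_usable_sites`.
#' @export
nucleotide_diversity <- function(ds, pop, sites = "all",
                                 level = "population") {
  cc <- filter_sites(ds, sites)
  rows <- group_rows(ds, pop, level)
  het <- site_heterozygosity(allele_counts(cc$mat[rows, , drop = FALSE]))
  usable <- !is.na(het)
  if (!any(usable)) stop("no usable sites for ", pop)
  list(pi = mean(het[usable]), n_usable_sites = sum(usable))
}

#' Paired bootstrap comparison of nucleotide diversity
#'
#' Bootstraps sites (with replacement, jointly for the two groups so the
#' resamples are paired by site) to attach standard errors to each pi and a
#' two-tailed p-value to the difference.  The percent change is
#' `100 * (pi_pop - pi_ref) / pi_ref`.
#'
#' @inheritParams nucleotide_diversity
#' @param ref_pop reference population (the presumed ancestral-range sample).
#' @param B number of bootstrap replicates (>= 100).
#' @param seed optional RNG seed.
#' @return list with `pi`, `pi_ref`, `se`, `se_ref`, `pct_change`, `p`, `B`.
#' @export
pi_change_test <- function(ds, pop, ref_pop = "JP", sites = "all",
                           level = "population", B = 1000, seed = NULL) {
  stopifnot(B >= 100)
  if (!is.null(seed)) set.seed(seed)
  cc <- filter_sites(ds, sites)
  hA <- site_heterozygosity(allele_counts(
    cc$mat[group_rows(ds, pop, level), , drop = FALSE]))
  hR <- site_heterozygosity(allele_counts(
    cc$mat[group_rows(ds, ref_pop, level), , drop = FALSE]))
  piA <- mean(hA, na.rm = TRUE)
  piR <- mean(hR, na.rm = TRUE)
  if (is.nan(piA) || is.nan(piR)) stop("no usable sites")
  if (piA == 0 && piR == 0) stop("both groups are monomorphic")
  S <- length(hA)
  bA <- bR <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(S, S, replace = TRUE)
    bA[b] <- mean(hA[idx], na.rm = TRUE)
    bR[b] <- mean(hR[idx], na.rm = TRUE)
  }
  delta <- bA - bR
  p <- min(1, 2 * min(mean(delta <= 0), mean(delta >= 0)))
  list(pi = piA, pi_ref = piR, se = sd(bA), se_ref = sd(bR),
       pct_change = 100 * (piA - piR) / piR, p = p, B = B)
}

#' Unbiased haplotype diversity at one locus
#'
#' Individuals with any missing call at the locus are excluded
#' (complete-case per locus).  `Hd = n/(n-1) * (1 - sum (n_i/n)^2)` over the
#' distinct haplotypes.
#'
#' @inheritParams nucleotide_diversity
#' @param locus locus id.
#' @export
haplotype_diversity <- function(ds, locus, pop, level = "population") {
  m <- ds$loci[[locus]]
  if (is.null(m)) stop("unknown locus: ", locus)
  rows <- group_rows(ds, pop, level)
  m <- m[rows, , drop = FALSE]
  complete <- rowSums(m == MISSING | m == GAP) == 0
  m <- m[complete, , drop = FALSE]
  n <- nrow(m)
  if (n < 2) stop("fewer than 2 complete haplotypes for ", pop, " at ", locus)
  haps <- apply(m, 1, paste0, collapse = "")
  cnt <- table(haps)
  n / (n - 1) * (1 - sum((cnt / n)^2))
}

#' Relative change in haplotype diversity against a reference population
#'
#' Returns `(Hd_pop - Hd_ref) / Hd_ref` for one locus, or, with
#' `locus = NULL`, the average of the per-locus changes weighted by locus
#' length.
#'
#' @inheritParams haplotype_diversity
#' @param ref_pop reference population.
#' @export
haplotype_diversity_change <- function(ds, locus = NULL, pop, ref_pop = "JP",
                                       level = "population") {
  if (is.null(locus)) {
    lens <- vapply(ds$loci, ncol, 0L)
    ch <- vapply(names(ds$loci), function(l)
      haplotype_diversity_change(ds, l, pop, ref_pop, level), numeric(1))
    return(sum(ch * lens) / sum(lens))
  }
  hd_ref <- haplotype_diversity(ds, locus, ref_pop, level)
  if (hd_ref == 0) stop("reference haplotype diversity is zero at ", locus)
  (haplotype_diversity(ds, locus, pop, level) - hd_ref) / hd_ref
}

# Tajima's D from S segregating sites, total mean pairwise differences k_hat
# and sample size n (NA when undefined)
tajima_d_stat <- function(S, k_hat, n) {
  if (is.na(n) || n < 3 || S < 1) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  den <- sqrt(e1 * S + e2 * S * (S - 1))
  if (den <= 0) return(NA_real_)
  (k_hat - S / a1) / den
}

#' Per-group site summaries: S, prS, K_sd, H_sd and Tajima's D
#'
#' `S` counts sites with at least two observed alleles in the group; `prS`
#' counts segregating sites carrying an allele absent from all individuals
#' outside the group; `K_sd` and `H_sd` are standard deviations across sites
#' of the observed allele count and of per-site heterozygosity (monomorphic
#' usable sites included).  Tajima's D uses the rounded mean per-site
#' non-missing sample size, a stable convention under moderate missingness.
#'
#' @inheritParams nucleotide_diversity
#' @param group population or region id.
#' @return list with `S`, `prS`, `K_sd`, `H_sd`, `tajima_D` (NA when `S` is
#'   too small), `n_bar`, `n_usable_sites`.
#' @export
site_summaries <- function(ds, group, level = "population", sites = "all") {
  cc <- filter_sites(ds, sites)
  rows <- group_rows(ds, group, level)
  if (!length(rows)) stop("unknown group: ", group)
  cnt <- allele_counts(cc$mat[rows, , drop = FALSE])
  cnt_out <- allele_counts(cc$mat[-rows, , drop = FALSE])
  n <- colSums(cnt)
  usable <- n >= 2
  if (!any(usable)) stop("no usable sites for ", group)
  K <- colSums(cnt > 0L)
  het <- site_heterozygosity(cnt)
  seg <- usable & K >= 2
  private <- seg & colSums(cnt > 0L & cnt_out == 0L) > 0L
  k_hat <- sum(het[usable])
  n_bar <- round(mean(n[usable]))
  S <- sum(seg)
  list(S = S, prS = sum(private),
       K_sd = sd(K[usable]), H_sd = sd(het[usable]),
       tajima_D = tajima_d_stat(S, k_hat, n_bar),
       n_bar = n_bar, n_usable_sites = sum(usable))
}

# one-level AMOVA on a pairwise-difference distance matrix (haploid)
amova_components <- function(d, groups) {
  groups <- as.factor(groups)
  n <- nrow(d)
  P <- nlevels(groups)
  stopifnot(P >= 2, n >= P + 1)
  ssd_t <- sum(d[upper.tri(d)]) / n
  ssd_wp <- 0
  n_g <- tabulate(groups)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) >= 2)
      ssd_wp <- ssd_wp + sum(d[idx, idx][upper.tri(d[idx, idx])]) /
        length(idx)
  }
  ssd_ap <- ssd_t - ssd_wp
  sigma_w <- ssd_wp / (n - P)
  n_c <- (n - sum(n_g^2) / n) / (P - 1)
  sigma_a <- (ssd_ap / (P - 1) - sigma_w) / n_c
  tot <- sigma_a + sigma_w
  list(sigma_among = sigma_a, sigma_within = sigma_w,
       phi_st = if (tot == 0) 0 else sigma_a / tot,
       ssd_among = ssd_ap, ssd_within = ssd_wp, df_among = P - 1,
       df_within = n - P)
}

# pairwise-difference distances over a chosen site set, pairwise-complete;
# mismatches = shared non-missing sites minus base matches (BLAS-friendly)
hamming_dist <- function(mat) {
  obs <- (mat != MISSING) * 1
  shared <- tcrossprod(obs)
  matches <- matrix(0, nrow(mat), nrow(mat))
  for (b in DNA_BASES) matches <- matches + tcrossprod((mat == b) * 1)
  d <- shared - matches
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

#' AMOVA-based Fst between two groups with a permutation test
#'
#' Computes the haploid pairwise-difference AMOVA Phi-ST restricted to sites
#' at which both groups have at least two sampled alleles, and assesses
#' significance by permuting individuals between the groups.  Negative
#' estimates are retained.
#'
#' @inheritParams nucleotide_diversity
#' @param popA,popB group ids.
#' @param n_perm number of label permutations.
#' @param seed optional RNG seed.
#' @return list with `fst`, `p`, `n_sites`, `n_perm`.
#' @export
pairwise_fst <- function(ds, popA, popB, n_perm = 1000, seed = NULL,
                         level = "population", sites = "all") {
  if (!is.null(seed)) set.seed(seed)
  cc <- filter_sites(ds, sites)
  ra <- group_rows(ds, popA, level)
  rb <- group_rows(ds, popB, level)
  na <- colSums(cc$mat[ra, , drop = FALSE] != MISSING)
  nb <- colSums(cc$mat[rb, , drop = FALSE] != MISSING)
  qual <- na >= 2 & nb >= 2
  if (!any(qual)) stop("no qualifying sites")
  mat <- cc$mat[c(ra, rb), qual, drop = FALSE]
  keep <- rowSums(mat != MISSING) > 0
  mat <- mat[keep, , drop = FALSE]
  groups <- rep(c("A", "B"), c(length(ra), length(rb)))[keep]
  d <- hamming_dist(mat)
  obs <- amova_components(d, groups)$phi_st
  if (n_perm == 0)
    return(list(fst = obs, p = NA_real_, n_sites = sum(qual), n_perm = 0L))
  null <- numeric(n_perm)
  for (b in seq_len(n_perm))
    null[b] <- amova_components(d, sample(groups))$phi_st
  list(fst = obs, p = perm_pvalue(null, obs), n_sites = sum(qual),
       n_perm = n_perm)
}

#' Pairwise Fst matrix over populations
#'
#' @inheritParams pairwise_fst
#' @param level grouping level.
#' @return list with symmetric matrix `fst` and matrix `p` of permutation
#'   p-values.
#' @export
fst_matrix <- function(ds, level = "population", n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- if (level == "population") unique(unname(ds$pop)) else
    unique(unname(ds$region[ds$pop]))
  k <- length(groups)
  fst <- p <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  diag(fst) <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      r <- pairwise_fst(ds, groups[i], groups[j], n_perm = n_perm,
                        level = level)
      fst[i, j] <- fst[j, i] <- r$fst
      p[i, j] <- p[j, i] <- r$p
    }
  }
  list(fst = fst, p = p)
}

#' One-level AMOVA across several populations
#'
#' @inheritParams pairwise_fst
#' @param pops populations to include (default: all).
#' @return variance components, Phi-ST and the permutation p-value.
#' @export
amova_test <- function(ds, pops = NULL, n_perm = 1000, seed = NULL,
                       sites = "all") {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pops)) pops <- unique(unname(ds$pop))
  cc <- filter_sites(ds, sites)
  rows <- which(ds$pop %in% pops)
  counts_ok <- vapply(pops, function(p)
    colSums(cc$mat[group_rows(ds, p), , drop = FALSE] != MISSING),
    numeric(ncol(cc$mat)))
  qual <- rowSums(counts_ok >= 2) == length(pops)
  if (!any(qual)) stop("no qualifying sites")
  mat <- cc$mat[rows, qual, drop = FALSE]
  keep <- rowSums(mat != MISSING) > 0
  mat <- mat[keep, , drop = FALSE]
  groups <- unname(ds$pop[rows])[keep]
  d <- hamming_dist(mat)
  obs <- amova_components(d, groups)
  null <- numeric(n_perm)
  for (b in seq_len(n_perm))
    null[b] <- amova_components(d, sample(groups))$phi_st
  c(obs, list(p = perm_pvalue(null, obs$phi_st), n_perm = n_perm))
}

#' Mantel test of genetic against geographic distance
#'
#' Geographic distances are great-circle (haversine) distances from the
#' collection-site coordinates.  The genetic matrix may be used as is,
#' minus-log-transformed, or linearized as `fst / (1 - fst)`; pairs for
#' which the transform is undefined are excluded with a warning.
#'
#' @param fst symmetric genetic-distance matrix with population dimnames.
#' @param geo data.frame with columns `pop`, `lat`, `lon`.
#' @param transform `"identity"`, `"neglog"` or `"fst_ratio"`.
#' @param n_perm permutations for the one-tailed (positive association) test.
#' @param seed optional RNG seed.
#' @return list with Mantel `r`, permutation `p`, and `n_pairs` used.
#' @export
mantel_test <- function(fst, geo, transform = c("identity", "neglog",
                                                "fst_ratio"),
                        n_perm = 1000, seed = NULL) {
  transform <- match.arg(transform)
  if (!is.null(seed)) set.seed(seed)
  pops <- rownames(fst)
  stopifnot(!is.null(pops), all(pops %in% geo$pop))
  geo <- geo[match(pops, geo$pop), ]
  n <- length(pops)
  gd <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      gd[i, j] <- gd[j, i] <- geosphere::distHaversine(
        c(geo$lon[i], geo$lat[i]), c(geo$lon[j], geo$lat[j])) / 1000
    }
  }
  g <- fst
  if (transform == "neglog") {
    bad <- g <= 0
    g <- -log(g)
  } else if (transform == "fst_ratio") {
    bad <- g >= 1
    g <- g / (1 - g)
  } else bad <- matrix(FALSE, n, n)
  diag(bad) <- FALSE
  if (any(bad[upper.tri(bad)]))
    warning(sum(bad[upper.tri(bad)]), " pairs undefined under transform '",
            transform, "'; excluded")
  ut <- upper.tri(g) & !bad
  x <- g[ut]
  y <- gd[ut]
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in a distance matrix")
  r_obs <- cor(x, y)
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    o <- sample.int(n)
    gp <- g[o, o]
    null[b] <- cor(gp[ut], y)
  }
  list(r = r_obs, p = perm_pvalue(null, r_obs), n_pairs = sum(ut))
}
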