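# The candidate summary-statistic vector used by the ABC machinery.
#
# 67 statistics over the five sampling regions (JP, HI, WUS, EUS, SP):
#  - per region: S, pi, prS, K_sd, H_sd, Tajima's D             (30)
#  - pooled worldwide sample: S, pi, K_sd, H_sd, Tajima's D      (5)
#  - log(S_i / S_JP) for the four colonized regions              (4)
#  - prS_i / S_i for the four colonized regions                  (4)
#  - mean and SD of S and of pi over regions                     (4)
#  - between-region pairwise pi, all 10 region pairs            (10)
#  - between-region pairwise Fst, all 10 region pairs           (10)
# Undefined entries (Tajima's D with S = 0, log ratios with S = 0) are
# imputed with 0 and recorded in the "imputed" attribute; the imputation
# only enters ABC through the distance standardization.

region_pairs <- function(regions = REGIONS) {
  k <- length(regions)
  out <- character(0)
  for (a in seq_len(k - 1))
    for (b in seq.int(a + 1, k))
      out <- c(out, paste0(regions[a], "_", regions[b]))
  out
}

#' Names of the full candidate statistic set
#'
#' @param regions region labels (five, in fixed order).
#' @return character vector of 67 names.
#' @export
stat_names <- function(regions = REGIONS) {
  per <- c("S", "pi", "prS", "Ksd", "Hsd", "TajD")
  col <- regions[-1]
  c(as.vector(t(outer(regions, per, function(r, s) paste0(s, "_", r)))),
    paste0(per[-3], "_all"),
    paste0("logS_", col, "_JP"),
    paste0("prSr_", col),
    c("mean_S", "sd_S", "mean_pi", "sd_pi"),
    paste0("piB_", region_pairs(regions)),
    paste0("Fst_", region_pairs(regions)))
}

#' The six statistics selected for model choice
#'
#' The subset found (by greedy empirical power search) to best discriminate
#' the three colonization models: four between-region Fst values and the
#' private-to-total segregating-site ratios of WUS and EUS.
#'
#' @return character vector of six statistic names.
#' @export
selected_stats <- function() {
  c("Fst_EUS_SP", "Fst_WUS_EUS", "Fst_HI_EUS", "Fst_HI_SP",
    "prSr_WUS", "prSr_EUS")
}

# per-group block of six statistics from allele-count matrices
sitestats_from_counts <- function(cnt, cnt_out, with_prs = TRUE) {
  n <- colSums(cnt)
  usable <- n >= 2
  K <- colSums(cnt > 0L)
  het <- site_heterozygosity(cnt)
  seg <- usable & K >= 2
  S <- sum(seg)
  if (with_prs) {
    private <- seg & colSums(cnt > 0L & cnt_out == 0L) > 0L
    prS <- sum(private)
  } else prS <- NA_real_
  k_hat <- sum(het[usable])
  n_bar <- round(mean(n[usable]))
  c(S = S, pi = mean(het[usable]), prS = prS,
    Ksd = sd(K[usable]), Hsd = sd(het[usable]),
    TajD = tajima_d_stat(S, k_hat, n_bar))
}

#' Compute the full summary-statistic vector of a dataset
#'
#' The missing-data-aware reference implementation: every statistic is
#' computed from the observed alleles only (see [site_summaries()] for
#' conventions).  On complete data it agrees exactly with the fast
#' count-based path used when building simulated reference tables.
#'
#' @param ds a `multilocus` dataset whose populations cover the five regions.
#' @param sites `"all"` or `"noncoding"`.
#' @return named numeric vector of 67 statistics with an `imputed` attribute
#'   naming entries that were undefined and set to 0.
#' @export
compute_stat_vector <- function(ds, sites = "all") {
  regions <- REGIONS
  have <- unique(unname(ds$region[ds$pop]))
  if (!all(regions %in% have))
    stop("dataset must cover all regions; missing: ",
         paste(setdiff(regions, have), collapse = ", "))
  cc <- filter_sites(ds, sites)
  reg_of <- region_of_individual(ds)
  cnts <- lapply(regions, function(r)
    allele_counts(cc$mat[reg_of == r, , drop = FALSE]))
  names(cnts) <- regions
  cnt_all <- Reduce(`+`, cnts)

  out <- setNames(numeric(67), stat_names(regions))
  imputed <- character(0)

  per <- matrix(NA_real_, nrow = length(regions), ncol = 6,
                dimnames = list(regions,
                                c("S", "pi", "prS", "Ksd", "Hsd", "TajD")))
  for (r in regions) {
    blk <- sitestats_from_counts(cnts[[r]], cnt_all - cnts[[r]])
    if (is.na(blk["TajD"])) {
      blk["TajD"] <- 0
      imputed <- c(imputed, paste0("TajD_", r))
    }
    per[r, ] <- blk
    out[paste0(colnames(per), "_", r)] <- blk
  }
  blk <- sitestats_from_counts(cnt_all, cnt_all * 0L, with_prs = FALSE)
  if (is.na(blk["TajD"])) {
    blk["TajD"] <- 0
    imputed <- c(imputed, "TajD_all")
  }
  out[paste0(c("S", "pi", "Ksd", "Hsd", "TajD"), "_all")] <-
    blk[c("S", "pi", "Ksd", "Hsd", "TajD")]

  for (r in regions[-1]) {
    if (per[r, "S"] > 0 && per["JP", "S"] > 0) {
      out[paste0("logS_", r, "_JP")] <- log(per[r, "S"] / per["JP", "S"])
    } else {
      out[paste0("logS_", r, "_JP")] <- 0
      imputed <- c(imputed, paste0("logS_", r, "_JP"))
    }
    if (per[r, "S"] > 0) {
      out[paste0("prSr_", r)] <- per[r, "prS"] / per[r, "S"]
    } else {
      out[paste0("prSr_", r)] <- 0
      imputed <- c(imputed, paste0("prSr_", r))
    }
  }

  out["mean_S"] <- mean(per[, "S"])
  out["sd_S"] <- sd(per[, "S"])
  out["mean_pi"] <- mean(per[, "pi"])
  out["sd_pi"] <- sd(per[, "pi"])

  for (pr in region_pairs(regions)) {
    ab <- strsplit(pr, "_")[[1]]
    ca <- cnts[[ab[1]]]
    cb <- cnts[[ab[2]]]
    na <- colSums(ca)
    nb <- colSums(cb)
    ok <- na >= 1 & nb >= 1
    pib <- 1 - colSums(ca[, ok, drop = FALSE] * cb[, ok, drop = FALSE]) /
      (na[ok] * nb[ok])
    out[paste0("piB_", pr)] <- mean(pib)
    out[paste0("Fst_", pr)] <- pairwise_fst(ds, ab[1], ab[2], n_perm = 0,
                                            level = "region",
                                            sites = sites)$fst
  }
  attr(out, "imputed") <- imputed
  out
}
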