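# Pseudo-observed data generation emulating the statistical shape of the
# worldwide sequencing study: 6 independent non-recombining X-linked loci of
# 450 bp, 12 populations in 5 regions, region sample sizes 15-120 haploid
# sequences, and ~21.4% missing genotypes.

default_pop_split <- function() {
  list(JP = "JP", HI = "HI", WUS = c("ST", "SD"),
       EUS = c("FL", "GA", "MA", "MI", "NC", "SC", "WV"), SP = "SP")
}

#' Shape specification for pseudo-observed datasets
#'
#' @param n_loci number of loci.
#' @param locus_bp locus length (bp).
#' @param sizes named per-region haploid sample sizes.
#' @param missing_rate proportion of masked genotypes.
#' @param missing_mode `"iid"` cell masking or `"block"` per
#'   individual-locus masking (mimics failed PCR).
#' @param pop_split named list splitting each region's individuals across
#'   population labels.
#' @return object of class `shape_spec`.
#' @export
shape_spec <- function(n_loci = 6, locus_bp = 450,
                       sizes = default_sample_sizes(),
                       missing_rate = 0.214,
                       missing_mode = "iid",
                       pop_split = default_pop_split()) {
  stopifnot(all(sizes >= 2), n_loci >= 1, locus_bp >= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_loci = n_loci, locus_bp = locus_bp, sizes = sizes,
                 missing_rate = missing_rate, missing_mode = missing_mode,
                 pop_split = pop_split), class = "shape_spec")
}

#' Generate a pseudo-observed dataset with known truth
#'
#' Draws parameters from the prior (unless given), simulates haplotypes
#' under the chosen colonization model, applies the missing-data mask, and
#' returns the dataset together with its generating truth record.
#'
#' @param model_id `M1`, `M2` or `M3`.
#' @param params optional named prior-scale parameter vector (a row of
#'   [sample_prior()]); drawn from `prior` when `NULL`.
#' @param shape a [shape_spec()].
#' @param prior a [prior_spec()].
#' @return list with `dataset` (a `multilocus`) and `truth`
#'   (`model_id`, prior-scale `params`, natural-scale `natural`).
#' @export
make_pseudo_observed <- function(model_id, params = NULL,
                                 shape = shape_spec(),
                                 prior = prior_spec()) {
  if (is.null(params)) params <- sample_prior(1, prior)[1, ]
  natural <- prior_to_natural(params)
  demog <- build_demography(model_id, natural)
  config <- sample_config(shape$sizes,
                          data.frame(locus_id = paste0("L",
                                                       seq_len(shape$n_loci)),
                                     length = rep(shape$locus_bp,
                                                  shape$n_loci)))
  ds <- simulate_dataset(demog, config, mu = natural$mu,
                         missing_rate = shape$missing_rate,
                         missing_mode = shape$missing_mode,
                         pop_split = shape$pop_split)
  list(dataset = ds,
       truth = list(model_id = model_id, params = params,
                    natural = natural))
}

#' Hand-crafted miniature datasets with known statistic values
#'
#' Registry of tiny fixtures used throughout the unit tests:
#' \describe{
#'   \item{pi_onethird}{3 sequences ACGT/ACGA/TCGA, nucleotide diversity
#'     exactly 1/3.}
#'   \item{pi_missing}{same alignment with one missing call at an invariant
#'     site (diversity unchanged).}
#'   \item{fst_one}{two populations fixed for different alleles, Fst = 1.}
#'   \item{monomorphic}{four identical sequences, S = 0.}
#'   \item{hd_half}{four haplotypes, two distinct in counts 3:1, unbiased
#'     haplotype diversity 0.5.}
#' }
#'
#' @param name fixture name.
#' @return a `multilocus` dataset.
#' @export
make_toy_fixture <- function(name) {
  mk <- function(seqs, pops, regions) {
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- sprintf("t%02d", seq_along(seqs))
    multilocus_dataset(list(L1 = m),
                       setNames(pops, rownames(m)), regions)
  }
  switch(name,
    pi_onethird = mk(c("ACGT", "ACGA", "TCGA"), rep("P1", 3),
                     c(P1 = "JP")),
    pi_missing = mk(c("ACGT", "ANGA", "TCGA"), rep("P1", 3),
                    c(P1 = "JP")),
    fst_one = mk(c("AAAA", "AAAA", "TTTT", "TTTT"),
                 c("P1", "P1", "P2", "P2"), c(P1 = "JP", P2 = "SP")),
    monomorphic = mk(rep("ACGT", 4), rep("P1", 4), c(P1 = "JP")),
    hd_half = mk(c("AA", "AA", "AA", "AT"), rep("P1", 4), c(P1 = "JP")),
    stop("unknown fixture: ", name))
}
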