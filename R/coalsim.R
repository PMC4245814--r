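# Demography construction and structured-coalescent simulation.
#
# Time is in generations before present; sizes are haploid effective sizes.
# A colonized region with present size N, founded by f individuals tau
# generations ago, grows deterministically and exponentially from f to N, so
# backwards in time its size declines at rate g = log(N/f)/tau until it
# merges into its source deme at tau.  The native range is an island model
# collapsed to two populations: the sampled JP deme and an unsampled ASIA
# pool, exchanging Nm migrants per generation in both directions.

COLONIZATION_MODELS <- c("M1", "M2", "M3")
NATIVE_MODELS <- c("native-constant", "native-expgrowth",
                   "native-instgrowth", "native-colonized",
                   "native-structured")

#' Build a parameterized demography
#'
#' Supported models: the three colonization histories (`M1`: HI, WUS, EUS and
#' SP founded independently from the unsampled ASIA pool; `M2`: as M1 but EUS
#' founded from WUS; `M3`: EUS and SP founded from WUS) and five single-region
#' native-range models for the ancestral population.
#'
#' @param model_id one of `M1`, `M2`, `M3`, `native-constant`,
#'   `native-expgrowth`, `native-instgrowth`, `native-colonized`,
#'   `native-structured`.
#' @param params named list/vector on the natural scale.  Colonization models
#'   need `N_ASIA`, `N_JP`, `N_HI`, `N_WUS`, `N_EUS`, `N_SP`, `f_HI`, `f_WUS`,
#'   `f_EUS`, `f_SP`, `tau_HI`, `tau_WUS`, `tau_EUS`, `tau_SP`, `Nm` and `mu`;
#'   colonization times must satisfy `tau_HI > tau_WUS > tau_SP > tau_EUS`.
#' @param native_source which native-range deme the independent colonizations
#'   emanate from: the unsampled `"ASIA"` pool (default) or the sampled
#'   `"JP"` deme.  The native range is a two-deme collapse of an island
#'   model, so either deme can be read as "the source"; the default treats
#'   the unsampled pool as the reservoir.
#' @return an object of class `demography` holding the backward event list.
#' @export
build_demography <- function(model_id, params,
                             native_source = c("ASIA", "JP")) {
  native_source <- match.arg(native_source)
  params <- as.list(params)
  p <- function(x) {
    v <- params[[x]]
    if (is.null(v)) stop("missing parameter: ", x)
    as.numeric(v)
  }
  grow <- function(N, f, tau) log(N / f) / tau
  if (model_id %in% COLONIZATION_MODELS) {
    taus <- c(HI = p("tau_HI"), WUS = p("tau_WUS"), SP = p("tau_SP"),
              EUS = p("tau_EUS"))
    if (!(taus["HI"] > taus["WUS"] && taus["WUS"] > taus["SP"] &&
            taus["SP"] > taus["EUS"]))
      stop("colonization times must satisfy tau_HI > tau_WUS > tau_SP > tau_EUS")
    demes <- c("ASIA", "JP", "HI", "WUS", "EUS", "SP")
    N <- c(p("N_ASIA"), p("N_JP"), p("N_HI"), p("N_WUS"), p("N_EUS"),
           p("N_SP"))
    g <- c(0, 0,
           grow(p("N_HI"), p("f_HI"), taus["HI"]),
           grow(p("N_WUS"), p("f_WUS"), taus["WUS"]),
           grow(p("N_EUS"), p("f_EUS"), taus["EUS"]),
           grow(p("N_SP"), p("f_SP"), taus["SP"]))
    t_end <- c(Inf, Inf, taus["HI"], taus["WUS"], taus["EUS"], taus["SP"])
    ns <- native_source
    src <- switch(model_id,
      M1 = c(EUS = ns, SP = ns),
      M2 = c(EUS = "WUS", SP = ns),
      M3 = c(EUS = "WUS", SP = "WUS"))
    sources <- c(ASIA = NA, JP = NA, HI = ns, WUS = ns,
                 EUS = unname(src["EUS"]), SP = unname(src["SP"]))
    merge_to <- match(sources, demes) - 1L
    merge_to[is.na(merge_to)] <- -1L
    mig <- matrix(0, 6, 6)
    Nm <- p("Nm")
    mig[2, 1] <- Nm / p("N_JP")   # backward JP -> ASIA
    mig[1, 2] <- Nm / p("N_ASIA") # backward ASIA -> JP
  } else if (model_id %in% NATIVE_MODELS) {
    switch(model_id,
      "native-constant" = {
        demes <- "JP"; N <- p("N_JP"); g <- 0; t_end <- Inf
        merge_to <- -1L; mig <- matrix(0, 1, 1)
      },
      "native-expgrowth" = {
        demes <- "JP"; N <- p("N_JP"); g <- p("growth_rate"); t_end <- Inf
        merge_to <- -1L; mig <- matrix(0, 1, 1)
      },
      "native-instgrowth" = {
        demes <- c("JP", "ANC")
        N <- c(p("N_JP"), p("N_ANC")); g <- c(0, 0)
        t_end <- c(p("t_change"), Inf)
        merge_to <- c(1L, -1L); mig <- matrix(0, 2, 2)
      },
      "native-colonized" = {
        demes <- c("JP", "ASIA")
        N <- c(p("N_JP"), p("N_ASIA"))
        g <- c(grow(p("N_JP"), p("f_JP"), p("tau_JP")), 0)
        t_end <- c(p("tau_JP"), Inf)
        merge_to <- c(1L, -1L); mig <- matrix(0, 2, 2)
      },
      "native-structured" = {
        demes <- c("JP", "ASIA")
        N <- c(p("N_JP"), p("N_ASIA")); g <- c(0, 0); t_end <- c(Inf, Inf)
        merge_to <- c(-1L, -1L)
        mig <- matrix(0, 2, 2)
        mig[1, 2] <- p("Nm") / p("N_JP")
        mig[2, 1] <- p("Nm") / p("N_ASIA")
      })
  } else stop("unknown model id: ", model_id)
  structure(list(model_id = model_id, params = params, demes = demes,
                 N = unname(N), g = unname(g), t_end = unname(t_end),
                 merge_to = unname(merge_to), mig = mig),
            class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat(sprintf("demography '%s' with %d demes\n", x$model_id,
              length(x$demes)))
  src <- ifelse(x$merge_to >= 0, x$demes[x$merge_to + 1], "-")
  df <- data.frame(deme = x$demes, N = signif(x$N, 4),
                   g = signif(x$g, 4), t_end = x$t_end, source = src)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Sampling configuration
#'
#' @param n named vector: haploid sample size per sampled deme (names must be
#'   deme names of the demography).
#' @param loci data.frame with columns `locus_id` and `length`, or an integer
#'   count of 450-bp loci.
#' @return object of class `sample_config`.
#' @export
sample_config <- function(n, loci = 6) {
  if (is.numeric(loci) && length(loci) == 1)
    loci <- data.frame(locus_id = paste0("L", seq_len(loci)),
                       length = rep(450L, loci))
  stopifnot(all(c("locus_id", "length") %in% names(loci)),
            all(loci$length > 0), all(n > 0), !is.null(names(n)))
  structure(list(n = n, loci = loci), class = "sample_config")
}

sample_vectors <- function(demog, config) {
  demes <- names(config$n)
  bad <- setdiff(demes, demog$demes)
  if (length(bad)) stop("sampled demes not in demography: ",
                        paste(bad, collapse = ", "))
  deme_idx <- rep(match(demes, demog$demes) - 1L, config$n)
  region_idx <- rep(seq_along(demes) - 1L, config$n)
  list(deme = as.integer(deme_idx), region = as.integer(region_idx),
       regions = demes)
}

#' Simulate genealogies and extract ancestral-lineage summaries
#'
#' Runs the structured coalescent for each locus and reports, per locus, the
#' coalescence tree (parent pointers and node times), the time to the most
#' recent common ancestor, and - when a reference time `tau` is given - the
#' number of ancestral lineages `L_A` (sample lineages not yet coalesced at
#' `tau`) and the genealogy length since colonization `G_L` (total branch
#' length more recent than `tau`).
#'
#' @param demog a [build_demography()] object.
#' @param config a [sample_config()].
#' @param tau optional reference time in generations for `L_A`/`G_L`.
#' @return list of per-locus lists with elements `parent`, `time`, `tmrca`,
#'   `total_length`, and optionally `L_A`, `G_L`.
#' @export
simulate_genealogy <- function(demog, config, tau = NULL) {
  sv <- sample_vectors(demog, config)
  trees <- cpp_sim_trees(unclass(demog), sv$deme, nrow(config$loci))
  lapply(trees, function(tr) {
    parent <- tr$parent
    tm <- tr$time
    nonroot <- which(parent >= 0)
    blen <- tm[parent[nonroot] + 1] - tm[nonroot]
    out <- list(parent = parent, time = tm, n_leaves = tr$n_leaves,
                tmrca = max(tm), total_length = sum(blen))
    if (!is.null(tau)) {
      tp <- tm[parent[nonroot] + 1]
      tc <- tm[nonroot]
      if (max(tm) <= tau) out$L_A <- 1L
      else out$L_A <- sum(tc <= tau & tp > tau)
      out$G_L <- sum(pmax(0, pmin(tp, tau) - pmin(tc, tau)))
    }
    out
  })
}

#' Simulate a multi-locus haplotype dataset under a demography
#'
#' Generates genealogies per locus, sprinkles infinite-sites mutations at
#' rate `mu * L * branch length` (Poisson), builds sequences over a random
#' ancestral background, and optionally masks genotypes as missing.
#'
#' @inheritParams simulate_genealogy
#' @param mu per-site per-generation mutation rate (defaults to the
#'   `mu` entry of the demography's parameters).
#' @param missing_rate proportion of cells masked as missing; with
#'   `missing_mode = "block"` whole individual-locus records are masked
#'   instead, mimicking failed amplification.
#' @param missing_mode `"iid"` or `"block"`.
#' @param pop_split optional named list mapping each sampled deme to the
#'   population labels its individuals are split across.
#' @return a `multilocus` dataset; the generating parameters are attached as
#'   attribute `truth`.
#' @export
simulate_dataset <- function(demog, config, mu = NULL, missing_rate = 0,
                             missing_mode = c("iid", "block"),
                             pop_split = NULL) {
  missing_mode <- match.arg(missing_mode)
  if (is.null(mu)) mu <- demog$params$mu
  if (is.null(mu)) stop("mutation rate 'mu' not given")
  sv <- sample_vectors(demog, config)
  n <- length(sv$deme)
  sim <- cpp_sim_haplotypes(unclass(demog), sv$deme,
                            as.integer(config$loci$length), mu)
  if (attr(sim, "n_capped") > 0)
    warning("infinite-sites mutation count exceeded locus length at ",
            attr(sim, "n_capped"), " loci; site count capped")
  ids <- sprintf("ind%03d", seq_len(n))
  region_of <- sv$regions[sv$region + 1]
  if (is.null(pop_split))
    pop_split <- setNames(as.list(sv$regions), sv$regions)
  pop_split <- pop_split[sv$regions]
  pop <- character(n)
  for (r in sv$regions) {
    idx <- which(region_of == r)
    pop[idx] <- rep(pop_split[[r]], length.out = length(idx))
  }
  names(pop) <- ids
  region <- setNames(rep(sv$regions, vapply(pop_split, length, 0L)),
                     unlist(pop_split))

  loci <- list()
  for (l in seq_len(nrow(config$loci))) {
    L <- config$loci$length[l]
    anc <- sample(DNA_BASES, L, replace = TRUE)
    m <- matrix(rep(anc, each = n), nrow = n, dimnames = list(ids, NULL))
    pos <- sim[[l]]$positions
    der <- sim[[l]]$derived
    for (k in seq_along(pos)) {
      alt <- sample(setdiff(DNA_BASES, anc[pos[k] + 1]), 1)
      m[der[, k], pos[k] + 1] <- alt
    }
    loci[[config$loci$locus_id[l]]] <- m
  }

  if (missing_rate > 0) {
    if (missing_mode == "iid") {
      for (l in names(loci)) {
        mask <- matrix(runif(length(loci[[l]])) < missing_rate,
                       nrow = nrow(loci[[l]]))
        loci[[l]][mask] <- MISSING
      }
    } else {
      for (l in names(loci)) {
        drop <- runif(n) < missing_rate
        loci[[l]][drop, ] <- MISSING
      }
    }
  }
  ds <- multilocus_dataset(loci, pop, region)
  attr(ds, "truth") <- list(model_id = demog$model_id,
                            params = demog$params)
  ds
}

#' Simulate the summary-statistic vector directly
#'
#' Fast path used to build reference tables: the simulator accumulates
#' per-site regional derived-allele counts and computes the 67 statistics in
#' compiled code, without materializing sequences.  On complete data this
#' agrees exactly with [compute_stat_vector()].
#'
#' @inheritParams simulate_dataset
#' @return named numeric vector of 67 statistics.
#' @export
simulate_stat_vector <- function(demog, config, mu = NULL) {
  if (is.null(mu)) mu <- demog$params$mu
  if (is.null(mu)) stop("mutation rate 'mu' not given")
  sv <- sample_vectors(demog, config)
  if (length(sv$regions) != 5)
    stop("the statistic vector is defined for five sampled regions")
  stats <- cpp_sim_statvec(unclass(demog), sv$deme, sv$region,
                           length(sv$regions),
                           as.integer(config$loci$length), mu)
  setNames(stats, stat_names(sv$regions))
}
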