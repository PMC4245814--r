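# Orchestration: validated run configurations, staged execution with
# deterministic seeding, and provenance metadata alongside every artifact.

stage_names <- c("synth", "stats", "simulate", "abc", "validate", "power")

#' Validate a pipeline run configuration
#'
#' @param config named list.  Common fields: `out_dir`, `seed` (integer).
#'   Stage-specific fields: `model_id` (synth), `dataset` (stats),
#'   `n_sims`/`models` (simulate), `observed`/`ref`/`k` (abc),
#'   `n_pods` (validate), `loci_counts` (power).
#' @param stage stage the configuration is for.
#' @return the config, invisibly, or an error describing the problem.
#' @export
validate_config <- function(config, stage) {
  if (!stage %in% stage_names)
    stop("unknown stage: ", stage)
  if (!is.list(config)) stop("config must be a list")
  need <- function(field, check = function(x) TRUE, what = "") {
    if (is.null(config[[field]]))
      stop(sprintf("config field '%s' is required for stage '%s'", field,
                   stage))
    if (!isTRUE(check(config[[field]])))
      stop(sprintf("config field '%s' is invalid%s", field,
                   if (nzchar(what)) paste0(" (", what, ")") else ""))
  }
  need("out_dir", is.character)
  need("seed", function(x) is.numeric(x) && x == round(x), "integer")
  switch(stage,
    synth = need("model_id", function(x) x %in% COLONIZATION_MODELS),
    stats = need("dataset", is.character),
    simulate = {
      need("n_sims", function(x) x >= 1)
    },
    abc = {
      need("observed", is.character)
      need("ref", is.character)
      if (!is.null(config$k) && !is.null(config$n_sims) &&
            config$k > config$n_sims)
        stop("config field 'k' exceeds 'n_sims'")
    },
    validate = need("n_pods", function(x) x >= 1),
    power = need("loci_counts", function(x) all(x >= 1)))
  invisible(config)
}

write_provenance <- function(dir, stage, config) {
  meta <- list(stage = stage, seed = config$seed,
               config_hash = config_hash(config),
               package_version = as.character(
                 utils::packageVersion("invasionABC")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, file.path(dir, paste0(stage,
                                                   "_provenance.json")),
                       auto_unbox = TRUE)
}

#' Write / read a reference table as tabular text
#'
#' One row per simulation: model id, the 16 parameter columns (prior scale)
#' and the 67 statistic columns.
#'
#' @param ref a [reference_table()].
#' @param path TSV file.
#' @export
write_ref_table <- function(ref, path) {
  df <- data.frame(model = as.character(ref$model), ref$params, ref$stats,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ref_table
#' @param prior,config the prior and sampling configuration to re-attach.
#' @export
read_ref_table <- function(path, prior = prior_spec(),
                           config = sample_config(default_sample_sizes())) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  pn <- intersect(PARAM_NAMES, names(df))
  sn <- setdiff(names(df), c("model", pn))
  structure(list(model = factor(df$model),
                 params = as.matrix(df[pn]),
                 stats = as.matrix(df[sn]),
                 prior = prior, config = config),
            class = "ref_table")
}

#' Run one pipeline stage
#'
#' Thin orchestration over the package's functions: validates the
#' configuration, seeds the RNG, executes the stage, writes its artifacts
#' (TSV/JSON) under `config$out_dir` together with a provenance record
#' (seed, configuration hash, package version).  Reruns with the same
#' configuration and seed reproduce the artifacts exactly.
#'
#' @param stage one of `synth`, `stats`, `simulate`, `abc`, `validate`,
#'   `power`.
#' @param config validated configuration list (see [validate_config()]).
#' @return named list of artifact paths, invisibly.
#' @export
run_stage <- function(stage, config) {
  validate_config(config, stage)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  out <- list()
  if (stage == "synth") {
    shape <- do.call(shape_spec, config$shape %||% list())
    sim <- make_pseudo_observed(config$model_id, shape = shape)
    out$dataset <- file.path(config$out_dir, "dataset.json")
    write_dataset(sim$dataset, out$dataset)
    out$truth <- file.path(config$out_dir, "truth.json")
    jsonlite::write_json(sim$truth, out$truth, auto_unbox = TRUE,
                         digits = 12)
  } else if (stage == "stats") {
    ds <- read_dataset(config$dataset)
    sv <- compute_stat_vector(ds, sites = config$sites %||% "all")
    out$stats <- file.path(config$out_dir, "statvec.tsv")
    write.table(as.data.frame(t(sv)), out$stats, sep = "\t",
                row.names = FALSE, quote = FALSE)
  } else if (stage == "simulate") {
    cfg <- sample_config(config$sample_sizes %||% default_sample_sizes(),
                         config$n_loci %||% 6)
    ref <- reference_table(config$n_sims,
                           config$models %||% c("M1", "M2", "M3"),
                           prior_spec(), cfg)
    out$ref <- file.path(config$out_dir, "reference_table.tsv")
    write_ref_table(ref, out$ref)
  } else if (stage == "abc") {
    obs <- read.table(config$observed, header = TRUE, sep = "\t",
                      check.names = FALSE)
    obs <- setNames(as.numeric(obs[1, ]), names(obs))
    ref <- read_ref_table(config$ref)
    if (!is.null(config$k) && config$k > nrow(ref$stats))
      stop("config field 'k' exceeds the reference-table size")
    fit <- abc_fit(obs, ref, k = config$k %||% 1000)
    out$models <- file.path(config$out_dir, "model_posterior.tsv")
    write.table(fit$diagnostics, out$models, sep = "\t",
                row.names = FALSE, quote = FALSE)
    out$params <- file.path(config$out_dir, "parameter_posterior.tsv")
    write.table(data.frame(param = rownames(fit$weighted$summary),
                           fit$weighted$summary), out$params, sep = "\t",
                row.names = FALSE, quote = FALSE)
  } else if (stage == "validate") {
    cfg <- sample_config(config$sample_sizes %||% default_sample_sizes(),
                         config$n_loci %||% 6)
    ref <- read_ref_table(config$ref, config = cfg)
    pods <- simulate_pods(max(1L, config$n_pods %/% 3L),
                          levels(ref$model), prior_spec(), cfg)
    rep_ <- calibrate_model_choice(ref, pods$stats, pods$model,
                                   k = config$k %||% 1000)
    out$calibration <- file.path(config$out_dir, "calibration.tsv")
    write.table(rep_$table, out$calibration, sep = "\t",
                row.names = FALSE, quote = FALSE)
  } else if (stage == "power") {
    rows <- lapply(config$loci_counts, function(nl)
      model_choice_power(nl, n_sims = config$n_sims %||% 2000,
                         n_pods = config$n_pods %||% 300,
                         k = config$k %||% 500))
    tbl <- data.frame(loci = config$loci_counts,
                      power = vapply(rows, `[[`, numeric(1), "power"),
                      se = vapply(rows, `[[`, numeric(1), "se"))
    out$power <- file.path(config$out_dir, "power.tsv")
    write.table(tbl, out$power, sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  write_provenance(config$out_dir, stage, config)
  out$provenance <- file.path(config$out_dir,
                              paste0(stage, "_provenance.json"))
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
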