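# Data model and I/O for multi-population, multi-locus haplotype alignments
# with missing data.  Haplotypes are stored as character matrices over
# {A,C,G,T, N (missing), - (gap)}; every locus matrix carries the full set of
# individuals as rows (an individual not sequenced at a locus is an all-N row).

#' Construct a multi-locus haplotype dataset
#'
#' Bundles per-locus haplotype alignments with the population and region
#' membership of each individual, per-site coding/noncoding classes, and
#' optional collection-site coordinates.
#'
#' @param loci named list of character matrices (individuals x sites) over
#'   the alphabet A, C, G, T, `N` (missing) and `-` (gap).  All matrices must
#'   share identical rownames (the individual ids).
#' @param pop named character vector mapping individual id to population id.
#' @param region named character vector mapping population id to region
#'   (one of `JP`, `HI`, `WUS`, `EUS`, `SP` for the worldwide sampling design,
#'   but arbitrary labels are allowed).
#' @param site_class optional named list of character vectors (`"coding"` /
#'   `"noncoding"`) per locus; defaults to all-noncoding.
#' @param geo optional data.frame with columns `pop`, `lat`, `lon`.
#' @return an object of class `multilocus`.
#' @export
multilocus_dataset <- function(loci, pop, region, site_class = NULL,
                               geo = NULL) {
  stopifnot(is.list(loci), length(loci) >= 1)
  if (is.null(names(loci))) names(loci) <- paste0("L", seq_along(loci))
  ids <- rownames(loci[[1]])
  if (is.null(ids)) stop("locus matrices must have individual ids as rownames")
  for (l in names(loci)) {
    m <- loci[[l]]
    if (!is.matrix(m) || !identical(rownames(m), ids))
      stop("all loci must be matrices with identical rownames")
    bad <- !(m %in% c(DNA_BASES, MISSING, GAP))
    if (any(bad)) {
      warning(sprintf(
        "locus %s: %d ambiguity/unknown symbols recoded as missing", l,
        sum(bad)))
      m[bad] <- MISSING
      loci[[l]] <- m
    }
  }
  missing_pop <- setdiff(ids, names(pop))
  if (length(missing_pop))
    stop("individuals absent from the population map: ",
         paste(head(missing_pop, 5), collapse = ", "))
  pop <- pop[ids]
  missing_reg <- setdiff(unique(pop), names(region))
  if (length(missing_reg))
    stop("populations without region assignment: ",
         paste(missing_reg, collapse = ", "))
  if (is.null(site_class))
    site_class <- lapply(loci, function(m) rep("noncoding", ncol(m)))
  stopifnot(identical(lengths(site_class), vapply(loci, ncol, 0L)))
  if (!is.null(geo)) {
    stopifnot(all(c("pop", "lat", "lon") %in% names(geo)))
    if (any(abs(geo$lat) > 90) || any(abs(geo$lon) > 180))
      stop("geographic coordinates out of range")
  }
  structure(list(loci = loci, site_class = site_class, pop = pop,
                 region = region, geo = geo),
            class = "multilocus")
}

#' @export
print.multilocus <- function(x, ...) {
  n <- length(x$pop)
  lens <- vapply(x$loci, ncol, 0L)
  cat(sprintf("multilocus dataset: %d individuals, %d loci (%d bp total)\n",
              n, length(x$loci), sum(lens)))
  cat(sprintf("  populations: %s\n",
              paste(names(table(x$pop)), collapse = " ")))
  cat(sprintf("  regions: %s\n",
              paste(unique(unname(x$region)), collapse = " ")))
  cat(sprintf("  missing data: %.1f%%\n", 100 * missing_fraction(x)))
  invisible(x)
}

#' Load a dataset from per-locus FASTA files and a population map
#'
#' Sequence ids in the FASTA files must appear in the population map; an
#' individual listed in the population map but absent from a locus FASTA is
#' retained as an all-missing row for that locus (sample sizes varied by
#' locus in the original sampling design).  IUPAC ambiguity codes are recoded
#' as missing with a warning.
#'
#' @param fasta_paths named character vector of FASTA files, one per locus
#'   (names become locus ids).
#' @param popmap path to a TSV with columns individual, population, region.
#' @param annotation optional TSV with columns locus, start, end, class
#'   giving 0-based half-open coding/noncoding intervals.
#' @param geo optional TSV with columns pop, lat, lon.
#' @return a [multilocus_dataset()] object.
#' @examples
#' # a small synthetic two-locus example bundled with the package
#' dir <- system.file("extdata", "synthetic_example",
#'                    package = "invasionABC")
#' fa <- c(L1 = file.path(dir, "L1.fasta"), L2 = file.path(dir, "L2.fasta"))
#' ds <- load_dataset(fa, file.path(dir, "popmap.tsv"),
#'                    geo = file.path(dir, "geo.tsv"))
#' ds
#' @export
load_dataset <- function(fasta_paths, popmap, annotation = NULL, geo = NULL) {
  pm <- read.table(popmap, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  stopifnot(all(c("individual", "population", "region") %in% names(pm)))
  pop <- setNames(pm$population, pm$individual)
  region <- setNames(pm$region, pm$population)
  region <- region[!duplicated(names(region))]
  ids <- pm$individual

  if (is.null(names(fasta_paths)))
    names(fasta_paths) <- sub("\\.[^.]*$", "", basename(fasta_paths))
  loci <- list()
  for (l in names(fasta_paths)) {
    seqs <- ape::read.FASTA(fasta_paths[l])
    chs <- toupper(vapply(as.character(seqs), paste0, "", collapse = ""))
    lens <- unique(nchar(chs))
    if (length(lens) != 1)
      stop(sprintf("locus %s: sequences differ in length", l))
    unknown <- setdiff(names(chs), ids)
    if (length(unknown))
      stop(sprintf("locus %s: ids not in population map: %s", l,
                   paste(head(unknown, 5), collapse = ", ")))
    m <- matrix(MISSING, nrow = length(ids), ncol = lens,
                dimnames = list(ids, NULL))
    for (id in names(chs))
      m[id, ] <- strsplit(chs[id], "")[[1]]
    loci[[l]] <- m
  }

  has_data <- Reduce(`|`, lapply(loci, function(m)
    rowSums(m != MISSING) > 0))
  if (any(!has_data))
    stop("individuals in the population map with no sequence data at any ",
         "locus: ", paste(head(ids[!has_data], 5), collapse = ", "))

  site_class <- NULL
  if (!is.null(annotation)) {
    an <- read.table(annotation, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    stopifnot(all(c("locus", "start", "end", "class") %in% names(an)))
    site_class <- lapply(names(loci), function(l) {
      cls <- rep("noncoding", ncol(loci[[l]]))
      for (i in which(an$locus == l)) {
        idx <- seq.int(an$start[i] + 1L, an$end[i]) # 0-based half-open
        cls[idx] <- an$class[i]
      }
      cls
    })
    names(site_class) <- names(loci)
  }

  geo_df <- NULL
  if (!is.null(geo)) {
    geo_df <- read.table(geo, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
    stopifnot(all(c("pop", "lat", "lon") %in% names(geo_df)))
  }
  multilocus_dataset(loci, pop, region, site_class, geo_df)
}

#' Remove alignment columns containing gaps
#'
#' Drops every site at which at least one individual has a gap, across all
#' loci, re-indexing the site classes.
#'
#' @param ds a `multilocus` dataset.
#' @return list with elements `dataset` (gap-free) and `removed_bp`
#'   (total columns dropped).
#' @export
strip_gap_columns <- function(ds) {
  removed <- 0L
  for (l in names(ds$loci)) {
    m <- ds$loci[[l]]
    keep <- colSums(m == GAP) == 0
    removed <- removed + sum(!keep)
    ds$loci[[l]] <- m[, keep, drop = FALSE]
    ds$site_class[[l]] <- ds$site_class[[l]][keep]
  }
  list(dataset = ds, removed_bp = removed)
}

#' Proportion of missing genotype cells
#'
#' @param ds a gap-free `multilocus` dataset.
#' @return the fraction of cells equal to the missing symbol.
#' @export
missing_fraction <- function(ds) {
  tot <- 0
  mis <- 0
  for (m in ds$loci) {
    if (any(m == GAP)) stop("dataset contains gaps; strip them first")
    tot <- tot + length(m)
    mis <- mis + sum(m == MISSING)
  }
  if (tot == 0) stop("empty dataset")
  mis / tot
}

# concatenated matrix + per-site locus id and class (internal)
concat_alignment <- function(ds) {
  m <- do.call(cbind, unname(ds$loci))
  cls <- unlist(unname(ds$site_class), use.names = FALSE)
  loc <- rep(names(ds$loci), vapply(ds$loci, ncol, 0L))
  list(mat = m, site_class = cls, locus = loc)
}

region_of_individual <- function(ds) unname(ds$region[ds$pop])

#' Write a dataset to a single JSON bundle
#'
#' @param ds a `multilocus` dataset.
#' @param path output file.
#' @export
write_dataset <- function(ds, path) {
  obj <- list(
    ids = rownames(ds$loci[[1]]),
    loci = lapply(ds$loci, function(m)
      unname(apply(m, 1, paste0, collapse = ""))),
    site_class = ds$site_class,
    pop = as.list(ds$pop),
    region = as.list(ds$region),
    geo = ds$geo
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 12, null = "null")
  invisible(path)
}

#' Read a dataset bundle written by [write_dataset()]
#'
#' @param path JSON bundle file.
#' @return a `multilocus` dataset.
#' @export
read_dataset <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  loci <- lapply(obj$loci, function(ss) {
    m <- do.call(rbind, strsplit(unlist(ss), ""))
    rownames(m) <- obj$ids
    m
  })
  geo <- obj$geo
  if (!is.null(geo)) geo <- as.data.frame(geo)
  multilocus_dataset(loci, unlist(obj$pop), unlist(obj$region),
                     lapply(obj$site_class, unlist), geo)
}

#' Export a dataset as per-locus FASTA files plus a population map
#'
#' Writes `"<locus>.fasta"` per locus (omitting all-missing individuals, as a
#' failed sequencing reaction would) and `popmap.tsv`, closing the loop with
#' [load_dataset()].
#'
#' @param ds a `multilocus` dataset.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of FASTA paths.
#' @export
export_fasta <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (l in names(ds$loci)) {
    m <- ds$loci[[l]]
    present <- rowSums(m != MISSING) > 0
    f <- file.path(dir, paste0(l, ".fasta"))
    con <- file(f, "w")
    for (id in rownames(m)[present]) {
      writeLines(paste0(">", id), con)
      writeLines(paste0(m[id, ], collapse = ""), con)
    }
    close(con)
    paths[l] <- f
  }
  pm <- data.frame(individual = names(ds$pop), population = unname(ds$pop),
                   region = unname(ds$region[ds$pop]))
  write.table(pm, file.path(dir, "popmap.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(paths)
}
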