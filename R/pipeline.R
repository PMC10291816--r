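# End-to-end orchestration: demux -> fit -> scale -> normalize -> metrics,
# with a JSON manifest tying every output to its inputs, parameters and
# seed.  Reruns with identical inputs and seed reproduce outputs
# byte-identically.

checksum <- function(paths) {
  x <- tools::md5sum(paths)
  data.frame(path = names(x), md5 = unname(x))
}

write_manifest <- function(path, command, parameters, inputs, outputs, seed) {
  manifest <- list(
    command = command,
    parameters = parameters,
    seed = seed,
    inputs = checksum(inputs[file.exists(inputs)]),
    outputs = checksum(outputs[file.exists(outputs)]),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    version = as.character(utils::packageVersion("otsp"))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes demultiplexing (if FASTQ inputs are given), NB fitting,
#' scaling-factor estimation, clonotype normalization and repertoire
#' metrics in order, writing each stage's TSV output plus a JSON manifest
#' to `out_dir`.
#'
#' @param config a named list (or path to a JSON file) with fields:
#'   \describe{
#'     \item{fastq}{optional character vector of merged-read FASTQ files,
#'       one per sample (requires `barcode_library`).}
#'     \item{barcode_library}{path to a barcode-library TSV.}
#'     \item{st_counts}{path to an ST count-matrix TSV (alternative to
#'       `fastq`).}
#'     \item{clonotypes}{optional character vector of clonotype TSVs to
#'       normalize (clonotype calling itself happens upstream).}
#'     \item{primer_map}{path to a primer-map TSV (required with
#'       `clonotypes`).}
#'     \item{method}{`"nb"` (default) or `"batch"` scaling factors.}
#'     \item{hyper_threshold}{hyperexpanded cutoff (default 0.01).}
#'     \item{max_edits}{barcode matching tolerance (default 1).}
#'     \item{out_dir}{output directory (created if missing).}
#'     \item{seed}{integer seed recorded in the manifest.}
#'   }
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must set out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  method <- if (is.null(config$method)) "nb" else config$method
  max_edits <- if (is.null(config$max_edits)) 1L else as.integer(config$max_edits)
  hyper <- if (is.null(config$hyper_threshold)) 0.01 else config$hyper_threshold
  inputs <- character(0)
  outputs <- character(0)

  # stage 1: ST counts (demux FASTQ, or load a matrix)
  if (!is.null(config$fastq)) {
    if (is.null(config$barcode_library))
      stop("demux stage: config must set barcode_library with fastq")
    lib <- read_barcode_library(config$barcode_library)
    inputs <- c(inputs, config$fastq, config$barcode_library)
    cols <- lapply(config$fastq, function(fq) {
      message("demux: ", fq)
      reads <- Biostrings::readDNAStringSet(fq, format = "fastq")
      demux_sample(as.character(reads), lib, max_edits)$counts
    })
    st <- st_count_matrix(do.call(cbind, cols),
                          sample_ids = sub("\\.(fastq|fq)(\\.gz)?$", "",
                                           basename(config$fastq)))
  } else if (!is.null(config$st_counts)) {
    inputs <- c(inputs, config$st_counts)
    st <- read_st_counts(config$st_counts)
  } else stop("config must provide either fastq or st_counts")
  st_path <- file.path(out_dir, "st_counts.tsv")
  write_st_counts(st, st_path)
  outputs <- c(outputs, st_path)

  # stage 2: NB fits and common dispersion
  fits <- NULL
  if (ncol(st) >= 2) {
    fits <- fit_nb_matrix(st)
    fit_path <- file.path(out_dir, "nb_fits.tsv")
    write.table(cbind(template = rownames(fits), fits), fit_path,
                sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, fit_path)
  }

  # stage 3: scaling factors
  factors <- if (method == "nb" && !is.null(fits))
    nb_mean_scaling_factors(fits) else batch_mean_scaling_factors(st)
  sf_path <- file.path(out_dir, "scaling_factors.tsv")
  write_scaling_factors(factors, sf_path)
  outputs <- c(outputs, sf_path)

  # stages 4-5: normalization and metrics per clonotype table
  metrics <- NULL
  if (!is.null(config$clonotypes)) {
    if (is.null(config$primer_map))
      stop("normalize stage: config must set primer_map with clonotypes")
    map <- read_primer_map(config$primer_map)
    inputs <- c(inputs, config$clonotypes, config$primer_map)
    rows <- lapply(config$clonotypes, function(ct) {
      tab <- normalize_clonotypes(read_clonotypes(ct), factors, map)
      np <- file.path(out_dir, paste0(sub("\\.tsv$", "", basename(ct)),
                                      ".normalized.tsv"))
      write_clonotypes(tab, np)
      outputs <<- c(outputs, np)
      cbind(sample = basename(ct), repertoire_metrics(tab, hyper))
    })
    metrics <- do.call(rbind, rows)
    mp <- file.path(out_dir, "metrics.tsv")
    write.table(metrics, mp, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, mp)
  }

  write_manifest(file.path(out_dir, "manifest.json"), "run",
                 config[setdiff(names(config), c("fastq", "clonotypes"))],
                 inputs, outputs, config$seed)
  invisible(list(st_counts = st, fits = fits, factors = factors,
                 metrics = metrics))
}
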