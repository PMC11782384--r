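#' Scan all introns of a set of gene records for border direct repeats
#'
#' For every intron of every record: extracts the two border windows, runs
#' [find_best_dr()], and classifies the result. The per-intron rows follow
#' the results-table dialect of [write_results()].
#'
#' @param records list of [gene_record()] objects.
#' @param params a [search_params()] object.
#' @param flank window flank in bp (default 40).
#' @return an object of class `dr_scan`: list with `results` (data.frame,
#'   one row per intron), `alignments` (list of `dr_alignment` or `NULL`),
#'   `params`, `flank`, `n_records`.
#' @export
scan_introns <- function(records, params = search_params(), flank = 40L) {
  if (inherits(records, "gene_record")) records <- list(records)
  rows <- list()
  alns <- list()
  for (g in records) {
    stopifnot(inherits(g, "gene_record"))
    for (i in seq_len(nrow(g$introns))) {
      wins <- extract_border_windows(g, i, flank = flank)
      aln <- find_best_dr(wins$five_prime, wins$three_prime, params)
      rows[[length(rows) + 1L]] <- assemble_result(g, i, aln, wins)
      alns[[length(alns) + 1L]] <- aln
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else empty_results()
  rownames(results) <- NULL
  structure(
    list(results = results, alignments = alns, params = params,
         flank = as.integer(flank), n_records = length(records)),
    class = "dr_scan"
  )
}

#' @export
print.dr_scan <- function(x, ...) {
  n <- nrow(x$results)
  found <- sum(x$results$dr_found)
  cat(sprintf(
    "<dr_scan> %d record(s), %d intron(s), repeat pair found in %d (%.1f%%)\n",
    x$n_records, n, found, if (n) 100 * found / n else 0))
  cat(sprintf(
    "  criteria: length >= %d, similarity >= %.0f%%, linker <= %d, flank %d\n",
    x$params$min_length, 100 * x$params$min_similarity,
    x$params$max_linker, x$flank))
  invisible(x)
}

#' @export
summary.dr_scan <- function(object, ...) {
  out <- list(
    scan = object,
    lengths = length_distribution(object),
    distances = distance_distribution(object),
    categories = category_frequencies(object),
    groups = group_summary(object)
  )
  class(out) <- "summary.dr_scan"
  out
}

#' @export
print.summary.dr_scan <- function(x, ...) {
  print(x$scan)
  ld <- x$lengths; dd <- x$distances
  if (ld$n) {
    cat(sprintf("  repeat length: mean %.1f +/- %.1f bp (n = %d)\n",
                ld$mean, ld$sd, ld$n))
    cat(sprintf(
      "  border distance: mean %.1f +/- %.1f bp; %.1f%% at 0, %.1f%% <= 10 bp\n",
      dd$mean, dd$sd, 100 * dd$fraction_zero, 100 * dd$fraction_within_10))
    rel <- attr(x$categories, "relations")
    for (k in seq_len(nrow(rel))) {
      cat(sprintf("  %s: %.1f%%\n", rel$relation[k], rel$pct[k]))
    }
  }
  invisible(x)
}

#' @export
plot.dr_scan <- function(x, ...) {
  ld <- length_distribution(x)
  dd <- distance_distribution(x)
  if (!ld$n) {
    warning("nothing to plot: no repeat pairs found")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::barplot(ld$bins$count, names.arg = ld$bins$value,
                    xlab = "repeat length (bp)", ylab = "introns",
                    main = "Repeat lengths")
  graphics::barplot(dd$bins$count, names.arg = dd$bins$value,
                    xlab = "distance to border (bp)", ylab = "repeat copies",
                    main = "Border distances")
  invisible(x)
}

#' Build a run configuration for [run_scan()]
#'
#' @param fasta,annotations,annotation_format FASTA + annotation input (see
#'   [read_fasta_with_annotations()]); alternatively `genbank`.
#' @param genbank GenBank flat-file input (see [read_genbank()]).
#' @param out_dir output directory (created if missing).
#' @param flank window flank in bp.
#' @param params a [search_params()] object.
#' @param seed RNG seed recorded in the manifest (the scan itself is
#'   deterministic).
#' @param verbose log progress to stderr.
#' @return an object of class `dr_run_config`.
#' @export
run_config <- function(fasta = NULL, annotations = NULL,
                       annotation_format = "tsv", genbank = NULL,
                       out_dir = ".", flank = 40L, params = search_params(),
                       seed = NULL, verbose = TRUE) {
  if (is.null(genbank) && (is.null(fasta) || is.null(annotations))) {
    stop("provide either `genbank` or both `fasta` and `annotations`")
  }
  structure(
    list(fasta = fasta, annotations = annotations,
         annotation_format = annotation_format, genbank = genbank,
         out_dir = out_dir, flank = as.integer(flank), params = params,
         seed = seed, verbose = isTRUE(verbose)),
    class = "dr_run_config"
  )
}

#' Load a run configuration from a YAML file
#'
#' Recognised keys: `fasta`, `annotations`, `annotation_format`, `genbank`,
#' `out_dir`, `flank`, `seed`, `verbose`, and the [search_params()] fields
#' (`min_length`, `min_similarity`, `max_linker`, `min_flank_block`,
#' `max_length`).
#'
#' @param path YAML file.
#' @return a `dr_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sp_keys <- intersect(names(y), names(formals(search_params)))
  params <- do.call(search_params, y[sp_keys])
  run_config(
    fasta = y$fasta, annotations = y$annotations,
    annotation_format = y$annotation_format %||% "tsv",
    genbank = y$genbank, out_dir = y$out_dir %||% ".",
    flank = y$flank %||% 40L, params = params, seed = y$seed,
    verbose = y$verbose %||% TRUE
  )
}

#' Run the end-to-end scan and write all output tables
#'
#' Reads the configured inputs, scans every intron, and writes to the output
#' directory: `results.tsv` (per intron), `group_summary.tsv`,
#' `length_distribution.tsv`, `distance_distribution.tsv`,
#' `category_frequencies.tsv`, and `manifest.json` (parameters, package
#' version, input paths, row counts). Logging goes to stderr; data only to
#' files. Deterministic: re-running the same configuration reproduces the
#' outputs byte for byte.
#'
#' @param config a `dr_run_config` (or path to a YAML file accepted by
#'   [read_run_config()]).
#' @return (invisibly) the `dr_scan` object, with the output paths attached
#'   as attribute `"paths"`.
#' @export
run_scan <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "dr_run_config"))
  log_msg <- function(...) {
    if (config$verbose) message(sprintf(...))
  }
  records <- if (!is.null(config$genbank)) {
    log_msg("reading GenBank flat file %s", config$genbank)
    read_genbank(config$genbank)
  } else {
    log_msg("reading %s + %s (%s)", config$fasta, config$annotations,
            config$annotation_format)
    read_fasta_with_annotations(config$fasta, config$annotations,
                                config$annotation_format)
  }
  log_msg("scanning %d record(s)", length(records))
  scan <- scan_introns(records, params = config$params, flank = config$flank)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c(results = "results.tsv",
                       groups = "group_summary.tsv",
                       lengths = "length_distribution.tsv",
                       distances = "distance_distribution.tsv",
                       categories = "category_frequencies.tsv",
                       manifest = "manifest.json"))
  names(paths) <- c("results", "groups", "lengths", "distances",
                    "categories", "manifest")
  n_rows <- write_results(scan, paths[["results"]])
  write.table(format_group_summary(group_summary(scan)), paths[["groups"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(length_distribution(scan)$bins, paths[["lengths"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(distance_distribution(scan)$bins, paths[["distances"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  cf <- category_frequencies(scan)
  write.table(cf, paths[["categories"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- list(
    package = "intronDR",
    version = as.character(utils::packageVersion("intronDR")),
    inputs = list(fasta = config$fasta, annotations = config$annotations,
                  genbank = config$genbank,
                  annotation_format = config$annotation_format),
    parameters = unclass(config$params),
    flank = config$flank,
    seed = config$seed,
    n_records = length(records),
    n_introns = n_rows,
    n_found = sum(scan$results$dr_found)
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  log_msg("wrote %d result row(s) to %s", n_rows, paths[["results"]])
  attr(scan, "paths") <- paths
  invisible(scan)
}
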