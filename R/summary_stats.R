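# population sd (n denominator): the descriptive spread reported alongside
# group means
pop_sd <- function(x) {
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

found_results <- function(results) {
  if (inherits(results, "dr_scan")) results <- results$results
  results <- as.data.frame(results)
  if (!nrow(results)) return(results)
  results[results$dr_found %in% TRUE, , drop = FALSE]
}

new_distribution <- function(values, type) {
  values <- values[!is.na(values)]
  bins <- if (length(values)) {
    tab <- table(values)
    data.frame(value = as.integer(names(tab)), count = as.integer(tab))
  } else data.frame(value = integer(), count = integer())
  structure(
    list(type = type, bins = bins, n = length(values),
         mean = if (length(values)) mean(values) else NA_real_,
         sd = pop_sd(values)),
    class = "dr_distribution"
  )
}

#' @export
print.dr_distribution <- function(x, ...) {
  cat(sprintf("<dr_distribution> %s: n=%d, mean=%.2f, sd=%.2f\n",
              x$type, x$n,
              if (is.na(x$mean)) NA else x$mean,
              if (is.na(x$sd)) NA else x$sd))
  if (nrow(x$bins)) print(x$bins, row.names = FALSE)
  if (!is.null(x$fraction_zero)) {
    cat(sprintf("  fraction at 0: %.3f; fraction <= 10 bp: %.3f\n",
                x$fraction_zero, x$fraction_within_10))
  }
  invisible(x)
}

#' Distribution of repeat lengths
#'
#' One length per intron (the single retained repeat pair), over results with
#' a repeat found. Mean and population sd are reported alongside the binned
#' counts.
#'
#' @param results results data.frame or `dr_scan` object.
#' @return a `dr_distribution` with `bins`, `n`, `mean`, `sd`.
#' @export
length_distribution <- function(results) {
  f <- found_results(results)
  new_distribution(if (nrow(f)) f$length else integer(), "length")
}

#' Distribution of copy-to-border distances
#'
#' Pools both copies of every found pair (two observations per intron) and
#' additionally reports the fraction of copies at distance 0 (spanning or
#' abutting a border) and within 10 bp.
#'
#' @param results results data.frame or `dr_scan` object.
#' @return a `dr_distribution` with additional fields `fraction_zero` and
#'   `fraction_within_10`.
#' @export
distance_distribution <- function(results) {
  f <- found_results(results)
  d <- if (nrow(f)) c(rbind(f$d5, f$d3)) else integer()
  out <- new_distribution(d, "distance")
  out$fraction_zero <- if (length(d)) mean(d == 0) else NA_real_
  out$fraction_within_10 <- if (length(d)) mean(d <= 10) else NA_real_
  out
}

#' Frequencies of the nine placement-pair categories
#'
#' Per-category counts and percentages over results with a repeat found,
#' together with the three length-relation percentages (each the sum of its
#' three categories). Percentages are rounded to one decimal for display but
#' kept exact in the `pct` column.
#'
#' @param results results data.frame or `dr_scan` object.
#' @return data.frame with one row per category (`loc5`, `loc3`, `category`,
#'   `relation`, `count`, `pct`); the relation totals are attached as
#'   attribute `"relations"` (data.frame `relation`, `count`, `pct`).
#' @export
category_frequencies <- function(results) {
  f <- found_results(results)
  lev <- category_levels()
  counts <- vapply(lev$category, function(cat) sum(f$category == cat),
                   integer(1L), USE.NAMES = FALSE)
  total <- sum(counts)
  out <- cbind(lev, count = counts,
               pct = if (total) 100 * counts / total else rep(NA_real_, 9L))
  rel <- vapply(split(out$count, out$relation), sum, integer(1L))
  rel_df <- data.frame(
    relation = names(rel), count = as.integer(rel),
    pct = if (total) 100 * as.integer(rel) / total else NA_real_,
    stringsAsFactors = FALSE
  )
  attr(out, "relations") <- rel_df
  out
}

#' Grouped summary of repeat placements, lengths and distances
#'
#' One row per observed `intron_type` x `location` group, plus a total row
#' per intron type and a grand total. Each row carries the group size, the
#' taxa observed, counts of the six single-copy placements (5' exon / border
#' / intron side and 3' intron side / border / exon), the mean +/- population
#' sd of repeat length, and the mean +/- sd and range of the copy-to-border
#' distance (both copies pooled). Unknown metadata group under `"unknown"`.
#'
#' @param results results data.frame or `dr_scan` object.
#' @return data.frame; see [format_group_summary()] for a display rendering.
#' @export
group_summary <- function(results) {
  f <- found_results(results)
  if (nrow(f)) {
    f$intron_type[is.na(f$intron_type) | !nzchar(f$intron_type)] <- "unknown"
    f$location[is.na(f$location) | !nzchar(f$location)] <- "unknown"
  }
  summarize <- function(rows, type_label, loc_label) {
    d <- c(rbind(rows$d5, rows$d3))
    data.frame(
      intron_type = type_label, location = loc_label,
      taxa = paste(sort(unique(rows$taxon_code)), collapse = ","),
      n = nrow(rows),
      n5_exon = sum(rows$loc5 == "e"),
      n5_border = sum(rows$loc5 == "e/i"),
      n5_intron = sum(rows$loc5 == "i"),
      n3_intron = sum(rows$loc3 == "i"),
      n3_border = sum(rows$loc3 == "e/i"),
      n3_exon = sum(rows$loc3 == "e"),
      mean_length = mean(rows$length), sd_length = pop_sd(rows$length),
      mean_distance = mean(d), sd_distance = pop_sd(d),
      min_distance = min(d), max_distance = max(d),
      stringsAsFactors = FALSE
    )
  }
  if (!nrow(f)) {
    empty <- data.frame(
      intron_type = character(), location = character(), taxa = character(),
      n = integer(), n5_exon = integer(), n5_border = integer(),
      n5_intron = integer(), n3_intron = integer(), n3_border = integer(),
      n3_exon = integer(), mean_length = double(), sd_length = double(),
      mean_distance = double(), sd_distance = double(),
      min_distance = integer(), max_distance = integer(),
      stringsAsFactors = FALSE
    )
    return(empty)
  }
  out <- NULL
  for (ty in unique(f$intron_type)) {
    rows_ty <- f[f$intron_type == ty, , drop = FALSE]
    locs <- unique(rows_ty$location)
    for (lo in locs) {
      out <- rbind(out, summarize(rows_ty[rows_ty$location == lo, ,
                                          drop = FALSE], ty, lo))
    }
    if (length(locs) > 1L) out <- rbind(out, summarize(rows_ty, ty, "total"))
  }
  out <- rbind(out, summarize(f, "grand_total", ""))
  rownames(out) <- NULL
  out
}

#' Render a group summary in the traditional table layout
#'
#' Frequencies as `"k/N"`, means as `"m +/- sd"`, distance with its
#' `(min-max)` range.
#'
#' @param gs output of [group_summary()].
#' @return data.frame of character columns.
#' @export
format_group_summary <- function(gs) {
  if (!nrow(gs)) return(gs)
  frac <- function(k, n) sprintf("%d/%d", k, n)
  data.frame(
    intron_type = gs$intron_type, location = gs$location, taxa = gs$taxa,
    f5_exon = frac(gs$n5_exon, gs$n), f5_border = frac(gs$n5_border, gs$n),
    f5_intron = frac(gs$n5_intron, gs$n),
    f3_intron = frac(gs$n3_intron, gs$n),
    f3_border = frac(gs$n3_border, gs$n), f3_exon = frac(gs$n3_exon, gs$n),
    mean_length = sprintf("%.1f +/- %.1f", gs$mean_length, gs$sd_length),
    mean_distance = sprintf("%.1f +/- %.1f (%d-%d)", gs$mean_distance,
                            gs$sd_distance, gs$min_distance, gs$max_distance),
    stringsAsFactors = FALSE
  )
}
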