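.column_kinds <- c("match", "mismatch", "gap5", "gap3")

#' Search parameters for the direct-repeat criterion
#'
#' Encodes the retention rules for a direct repeat: repeats of at least
#' `min_length` aligned columns (gaps excluded) and at least `min_similarity`
#' identity are retained; runs of up to `max_linker` non-identical columns
#' (mismatches and/or gaps) are allowed when they link identical blocks of at
#' least `min_flank_block` matched columns.
#'
#' @param min_length smallest reportable repeat length (default 4; shorter
#'   repeats are statistically uninformative in an 80-bp search space).
#' @param min_similarity minimum fraction of matching columns (default 0.70).
#' @param max_linker longest allowed run of non-match columns (default 2).
#' @param min_flank_block minimum matched-block length adjacent to a linker
#'   (default 2 -- a linker must link two identical regions).
#' @param max_length largest repeat length considered (default 40, half the
#'   default search span).
#' @return an object of class `dr_search_params`.
#' @export
search_params <- function(min_length = 4L, min_similarity = 0.70,
                          max_linker = 2L, min_flank_block = 2L,
                          max_length = 40L) {
  if (!is_count(min_length)) stop("`min_length` must be an integer >= 1")
  if (!is.numeric(min_similarity) || length(min_similarity) != 1L ||
      min_similarity <= 0 || min_similarity > 1) {
    stop("`min_similarity` must lie in (0, 1]")
  }
  if (!is_count(max_linker, min = 0)) stop("`max_linker` must be >= 0")
  if (!is_count(min_flank_block)) stop("`min_flank_block` must be >= 1")
  if (!is_count(max_length) || max_length < min_length) {
    stop("`max_length` must be an integer >= min_length")
  }
  structure(
    list(min_length = as.integer(min_length),
         min_similarity = as.numeric(min_similarity),
         max_linker = as.integer(max_linker),
         min_flank_block = as.integer(min_flank_block),
         max_length = as.integer(max_length)),
    class = "dr_search_params"
  )
}

#' Score an alignment column sequence
#'
#' Repeat length `L` counts match and mismatch columns only; gap columns are
#' excluded from both numerator and denominator. `percent` is the half-up
#' integer rounding of `100 * similarity`.
#'
#' @param columns character vector over
#'   `"match"`, `"mismatch"`, `"gap5"`, `"gap3"`.
#' @return list with `length`, `matches`, `similarity`, `percent`.
#' @export
score_alignment <- function(columns) {
  if (!length(columns)) stop("`columns` must be non-empty")
  bad <- setdiff(unique(columns), .column_kinds)
  if (length(bad)) {
    stop(sprintf("unknown column kind(s): %s", paste(bad, collapse = ", ")))
  }
  n_match <- sum(columns == "match")
  n_mismatch <- sum(columns == "mismatch")
  L <- n_match + n_mismatch
  if (L == 0L) stop("all-gap alignment cannot be scored")
  sim <- n_match / L
  list(length = L, matches = n_match, similarity = sim,
       percent = as.integer(round_half_up(100 * sim)))
}

# build a classed alignment object from spans (0-based half-open, window
# coordinates) and a column sequence
new_dr_alignment <- function(copy5_span, copy3_span, columns) {
  sc <- score_alignment(columns)
  structure(
    list(copy5_span = as.integer(copy5_span),
         copy3_span = as.integer(copy3_span),
         columns = columns,
         length = sc$length, matches = sc$matches,
         similarity = sc$similarity, percent = sc$percent),
    class = "dr_alignment"
  )
}

#' @export
print.dr_alignment <- function(x, ...) {
  cat(sprintf(
    "<dr_alignment> L=%d, matches=%d, similarity=%.3f (%d%%)\n",
    x$length, x$matches, x$similarity, x$percent))
  cat(sprintf("  copy5 [%d,%d)  copy3 [%d,%d)  columns: %s\n",
              x$copy5_span[1L], x$copy5_span[2L],
              x$copy3_span[1L], x$copy3_span[2L],
              paste(abbreviate(x$columns, 2), collapse = " ")))
  invisible(x)
}

#' Find the best direct repeat between two border windows
#'
#' Searches for the optimal pair of repeat copies, one in each window, under
#' the constraints in [search_params()]. The optimum is defined by a total
#' order: greatest repeat length, then greatest similarity, then smallest
#' summed distance of the two copies to their borders, then smallest copy5
#' start, copy3 start, copy5 end, copy3 end, then lexicographically smallest
#' column sequence. `N` bases never form match columns. Deterministic for
#' fixed inputs; returns `NULL` when no candidate satisfies the constraints.
#'
#' @param w5,w3 [border_window()] objects for the 5' and 3' borders.
#' @param params a [search_params()] object.
#' @return a `dr_alignment` (spans in window coordinates, 0-based half-open)
#'   or `NULL`.
#' @export
find_best_dr <- function(w5, w3, params = search_params()) {
  stopifnot(inherits(w5, "border_window"), inherits(w3, "border_window"),
            inherits(params, "dr_search_params"))
  if (!nzchar(w5$seq) || !nzchar(w3$seq)) return(NULL)
  res <- cpp_find_best_dr(
    dna_codes(w5$seq), dna_codes(w3$seq),
    w5$border_pos, w3$border_pos,
    params$min_length, params$max_length, params$max_linker,
    params$min_flank_block, params$min_similarity
  )
  if (is.null(res)) return(NULL)
  new_dr_alignment(copy5_span = c(res$s5, res$e5),
                   copy3_span = c(res$s3, res$e3),
                   columns = .column_kinds[res$cols + 1L])
}

#' Check that an alignment is internally consistent and satisfies the rules
#'
#' Replays the column sequence against the window sequences from the claimed
#' spans and verifies: the claimed match/mismatch pattern, span consistency,
#' terminal match columns, the linker and flanking-block constraints, the
#' length bounds and the similarity threshold. Used as a universal
#' postcondition check on search output.
#'
#' @param a a `dr_alignment`.
#' @param w5,w3 the [border_window()] objects it was computed from.
#' @param params a [search_params()] object.
#' @return `TRUE` iff every check passes (`FALSE` on any violation, never an
#'   error).
#' @export
validate_alignment <- function(a, w5, w3, params = search_params()) {
  ok <- tryCatch({
    stopifnot(inherits(a, "dr_alignment"),
              inherits(w5, "border_window"), inherits(w3, "border_window"))
    x5 <- dna_codes(w5$seq); x3 <- dna_codes(w3$seq)
    cols <- a$columns
    if (!length(cols)) return(FALSE)
    if (cols[1L] != "match" || cols[length(cols)] != "match") return(FALSE)

    i <- a$copy5_span[1L]; j <- a$copy3_span[1L]
    if (i < 0L || j < 0L) return(FALSE)
    for (k in seq_along(cols)) {
      kind <- cols[k]
      if (kind == "match") {
        if (i >= length(x5) || j >= length(x3)) return(FALSE)
        if (!(x5[i + 1L] < 4L && x5[i + 1L] == x3[j + 1L])) return(FALSE)
        i <- i + 1L; j <- j + 1L
      } else if (kind == "mismatch") {
        if (i >= length(x5) || j >= length(x3)) return(FALSE)
        if (x5[i + 1L] < 4L && x5[i + 1L] == x3[j + 1L]) return(FALSE)
        i <- i + 1L; j <- j + 1L
      } else if (kind == "gap5") {
        if (j >= length(x3)) return(FALSE)
        j <- j + 1L
      } else if (kind == "gap3") {
        if (i >= length(x5)) return(FALSE)
        i <- i + 1L
      } else return(FALSE)
    }
    if (i != a$copy5_span[2L] || j != a$copy3_span[2L]) return(FALSE)

    # run-length constraints
    is_m <- cols == "match"
    r <- rle(is_m)
    nonmatch_runs <- r$lengths[!r$values]
    if (any(nonmatch_runs > params$max_linker)) return(FALSE)
    match_runs <- r$lengths[r$values]
    if (length(match_runs) > 1L &&
        any(match_runs < params$min_flank_block)) return(FALSE)

    sc <- score_alignment(cols)
    if (sc$length != a$length || sc$matches != a$matches) return(FALSE)
    if (abs(sc$similarity - a$similarity) > 1e-12) return(FALSE)
    if (sc$length < params$min_length || sc$length > params$max_length) {
      return(FALSE)
    }
    if (sc$matches + 1e-9 < params$min_similarity * sc$length) return(FALSE)
    TRUE
  }, error = function(e) FALSE)
  isTRUE(ok)
}
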