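# Exhaustive enumeration oracle for the direct-repeat search. Written
# independently of the compiled search: plain-R depth-first enumeration of
# every valid column sequence from every start pair, keeping the optimum
# under the documented total order. Guarded to small instances.

# compare two candidates under the total order used by find_best_dr;
# candidates are lists with L, matches, dsum, s5, s3, e5, e3, cols (integer
# codes 0..3). Returns TRUE when `a` is strictly better than `b`.
cand_better <- function(a, b) {
  if (a$L != b$L) return(a$L > b$L)
  if (a$matches != b$matches) return(a$matches > b$matches)
  if (a$dsum != b$dsum) return(a$dsum < b$dsum)
  if (a$s5 != b$s5) return(a$s5 < b$s5)
  if (a$s3 != b$s3) return(a$s3 < b$s3)
  if (a$e5 != b$e5) return(a$e5 < b$e5)
  if (a$e3 != b$e3) return(a$e3 < b$e3)
  # lexicographic on column codes; a proper prefix sorts first
  n <- min(length(a$cols), length(b$cols))
  if (n > 0L) {
    diff <- which(a$cols[seq_len(n)] != b$cols[seq_len(n)])
    if (length(diff)) {
      k <- diff[1L]
      return(a$cols[k] < b$cols[k])
    }
  }
  length(a$cols) < length(b$cols)
}

oracle_dist <- function(s, e, b) {
  if (s < b && e > b) return(0L)
  if (e <= b) return(b - e)
  s - b
}

#' Exhaustive reference search for the best direct repeat
#'
#' Enumerates every start-position pair and every monotone column sequence
#' obeying the linker/flank constraints, scores each complete candidate, and
#' returns the optimum under the same total order as [find_best_dr()]. Used
#' as the independent correctness oracle; a tractability guard restricts it
#' to windows of at most 25 bases and `max_length` at most 16.
#'
#' @inheritParams find_best_dr
#' @return a `dr_alignment` or `NULL`.
#' @export
brute_force_oracle <- function(w5, w3, params = search_params()) {
  stopifnot(inherits(w5, "border_window"), inherits(w3, "border_window"),
            inherits(params, "dr_search_params"))
  n5 <- nchar(w5$seq); n3 <- nchar(w3$seq)
  if (n5 > 25L || n3 > 25L) {
    stop("oracle guard: windows must be at most 25 bases long")
  }
  if (params$max_length > 16L) {
    stop("oracle guard: params$max_length must be at most 16")
  }
  if (n5 == 0L || n3 == 0L) return(NULL)
  x5 <- dna_codes(w5$seq); x3 <- dna_codes(w3$seq)
  b5 <- w5$border_pos; b3 <- w3$border_pos
  min_len <- params$min_length; max_len <- params$max_length
  max_linker <- params$max_linker; mfb <- params$min_flank_block
  min_sim <- params$min_similarity

  env <- new.env(parent = emptyenv())
  env$best <- NULL
  env$cols <- integer(64L)
  env$depth <- 0L
  s5 <- 0L; s3 <- 0L

  is_match <- function(i, j) {
    i < n5 && j < n3 && x5[i + 1L] < 4L && x5[i + 1L] == x3[j + 1L]
  }

  consider <- function(i, j, L, matches) {
    if (L < min_len) return(invisible())
    if (matches + 1e-9 < min_sim * L) return(invisible())
    cand <- list(L = L, matches = matches,
                 dsum = oracle_dist(s5, i, b5) + oracle_dist(s3, j, b3),
                 s5 = s5, s3 = s3, e5 = i, e3 = j,
                 cols = env$cols[seq_len(env$depth)])
    if (is.null(env$best) || cand_better(cand, env$best)) env$best <- cand
    invisible()
  }

  push <- function(code) {
    env$depth <- env$depth + 1L
    if (env$depth > length(env$cols)) env$cols <- c(env$cols, integer(64L))
    env$cols[env$depth] <- code
  }
  pop <- function() env$depth <- env$depth - 1L

  # mutually recursive enumeration; sound structural pruning only
  block <- function(i, j, r, had, L, matches) {
    if (!had || r >= mfb) consider(i, j, L, matches)
    if (L + min(n5 - i, n3 - j) < min_len) return(invisible())
    if (L < max_len && is_match(i, j)) {
      push(0L)
      block(i + 1L, j + 1L, min(r + 1L, mfb), had, L + 1L, matches + 1L)
      pop()
    }
    if (r >= mfb && max_linker > 0L) linker(i, j, 0L, L, matches)
    invisible()
  }
  linker <- function(i, j, c, L, matches) {
    if (c > 0L && L < max_len && is_match(i, j)) {
      push(0L)
      block(i + 1L, j + 1L, 1L, TRUE, L + 1L, matches + 1L)
      pop()
    }
    if (c >= max_linker) return(invisible())
    if (i < n5 && j < n3 && !is_match(i, j) && L < max_len) {
      push(1L)
      linker(i + 1L, j + 1L, c + 1L, L + 1L, matches)
      pop()
    }
    if (j < n3) {
      push(2L)
      linker(i, j + 1L, c + 1L, L, matches)
      pop()
    }
    if (i < n5) {
      push(3L)
      linker(i + 1L, j, c + 1L, L, matches)
      pop()
    }
    invisible()
  }

  for (i0 in 0:(n5 - 1L)) {
    for (j0 in 0:(n3 - 1L)) {
      if (!is_match(i0, j0)) next
      s5 <- i0; s3 <- j0
      env$depth <- 0L
      push(0L)
      block(i0 + 1L, j0 + 1L, 1L, FALSE, 1L, 1L)
      pop()
    }
  }

  if (is.null(env$best)) return(NULL)
  b <- env$best
  new_dr_alignment(copy5_span = c(b$s5, b$e5), copy3_span = c(b$s3, b$e3),
                   columns = .column_kinds[b$cols + 1L])
}
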