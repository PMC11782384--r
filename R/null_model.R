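#' Number of nucleotide strings of a given length
#'
#' `4^n`, exact. Powers of four are powers of two and therefore exactly
#' representable as doubles for every length used here.
#'
#' @param n repeat length (>= 0).
#' @return `4^n` as an exact numeric.
#' @export
dr_combinations <- function(n) {
  if (!is.numeric(n) || any(is.na(n)) || any(n < 0) || any(n != floor(n))) {
    stop("`n` must be a non-negative integer")
  }
  4^n
}

#' Analytic null probability of a random repeat match
#'
#' Expected number of start positions at which a fixed length-`n` word occurs
#' in a uniform-random window of `w` bases: `(w - n + 1) / 4^n`. A single
#' string of length `n` occurs at one given position with probability
#' `1 / 4^n`; multiplying by the number of start positions gives an expected
#' count, which upper-bounds (union bound) the exact occurrence probability
#' `1 - (1 - 4^-n)^(w - n + 1)` and is within 5% of it for `n >= 7`.
#'
#' @param n repeat length, `1 <= n <= w`.
#' @param w window width in bases (default 80).
#' @return the probability, exact up to double rounding; use
#'   [format_null_probability()] for the 9-decimal display form.
#' @export
match_probability <- function(n, w = 80) {
  if (!is.numeric(n) || any(n < 1)) stop("`n` must be >= 1")
  if (any(n > w)) stop("`n` must not exceed the window width `w`")
  (w - n + 1) / 4^n
}

#' Display-format a null probability to nine decimals
#'
#' Half-up rounding at 9 decimal places; values below 5e-10 print as
#' `"< 0.000000001"`.
#'
#' @param p probability vector.
#' @return character vector.
#' @export
format_null_probability <- function(p) {
  ifelse(p < 5e-10, "< 0.000000001",
         sprintf("%.9f", round_half_up(p, 9)))
}

#' Analytic null-probability table
#'
#' One row per repeat length in `n_min..n_max`: the number of possible
#' nucleotide combinations (`4^n`) and the probability of finding a random
#' repeat match in a `w`-base window, with its 9-decimal display form.
#'
#' @param n_min,n_max repeat length range (defaults 4..30).
#' @param w window width (default 80).
#' @return data.frame with columns `n`, `combinations`, `probability`,
#'   `display`.
#' @export
probability_table <- function(n_min = 4, n_max = 30, w = 80) {
  if (!is_count(n_min) || !is_count(n_max) || n_min > n_max || n_max > w) {
    stop("need 1 <= n_min <= n_max <= w")
  }
  n <- n_min:n_max
  p <- match_probability(n, w)
  data.frame(n = n, combinations = dr_combinations(n), probability = p,
             display = format_null_probability(p),
             stringsAsFactors = FALSE)
}

#' Monte-Carlo probability that a fixed random word occurs in a random window
#'
#' Draws `trials` independent pairs (uniform-random `n`-mer, uniform-random
#' `w`-base window) and estimates the probability that the word occurs in the
#' window. The standard error is the binomial `sqrt(p(1-p)/trials)`.
#'
#' @param n word length.
#' @param w window width.
#' @param trials number of Monte-Carlo trials (>= 1).
#' @param seed RNG seed (optional; reproducible when given).
#' @param gc GC fraction of both word and window (default 0.5, the uniform
#'   null).
#' @return list with `estimate` and `standard_error`.
#' @export
empirical_fixed_word_probability <- function(n, w, trials, seed = NULL,
                                             gc = 0.5) {
  if (!is_count(trials)) stop("`trials` must be >= 1")
  if (!is_count(n) || !is_count(w)) stop("`n` and `w` must be positive integers")
  if (gc < 0 || gc > 1) stop("`gc` must lie in [0, 1]")
  if (n > w) return(list(estimate = 0, standard_error = 0))
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_seed(seed, {
    word <- matrix(sample.int(4L, trials * n, replace = TRUE, prob = prob),
                   nrow = trials)
    win <- matrix(sample.int(4L, trials * w, replace = TRUE, prob = prob),
                  nrow = trials)
    hit <- rep(FALSE, trials)
    for (s in 0:(w - n)) {
      m <- !hit   # only unresolved trials need checking
      for (k in seq_len(n)) {
        if (!any(m)) break
        m <- m & (win[, s + k] == word[, k])
      }
      hit <- hit | m
    }
    p_hat <- mean(hit)
    list(estimate = p_hat,
         standard_error = sqrt(p_hat * (1 - p_hat) / trials))
  })
}

#' Monte-Carlo false-positive rate of the repeat-retention criterion
#'
#' Fraction of independent uniform-random window pairs (each `w` bases) for
#' which [find_best_dr()] reports a repeat under `params` -- the chance level
#' of the detection criterion itself.
#'
#' @param params a [search_params()] object.
#' @param w window width.
#' @param trials number of window pairs.
#' @param seed RNG seed (optional).
#' @param gc GC fraction of the random windows (default 0.5).
#' @return list with `estimate` and `standard_error`.
#' @export
criterion_false_positive_rate <- function(params = search_params(), w = 80,
                                          trials = 1000, seed = NULL,
                                          gc = 0.5) {
  if (!is_count(trials)) stop("`trials` must be >= 1")
  if (params$min_length > w) return(list(estimate = 0, standard_error = 0))
  b <- w %/% 2L
  with_seed(seed, {
    hits <- 0L
    for (t in seq_len(trials)) {
      w5 <- border_window(random_sequence(w, gc = gc), "five_prime", b)
      w3 <- border_window(random_sequence(w, gc = gc), "three_prime", b)
      if (!is.null(find_best_dr(w5, w3, params))) hits <- hits + 1L
    }
    p_hat <- hits / trials
    list(estimate = p_hat,
         standard_error = sqrt(p_hat * (1 - p_hat) / trials))
  })
}
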