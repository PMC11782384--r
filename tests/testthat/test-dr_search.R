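test_that("alignment scoring excludes gaps from length and similarity", {
  s <- score_alignment(rep("match", 10))
  expect_identical(s[c("length", "matches")], list(length = 10L, matches = 10L))
  expect_identical(s$similarity, 1)
  expect_identical(s$percent, 100L)

  # 8 matches + 3 mismatches: the 73% entries reported for 11-bp repeats
  s2 <- score_alignment(c(rep("match", 4), "mismatch", rep("match", 2),
                          "mismatch", rep("match", 2), "mismatch"))
  expect_identical(s2$length, 11L)
  expect_identical(s2$matches, 8L)
  expect_equal(s2$similarity, 8 / 11)
  expect_identical(s2$percent, 73L)

  s3 <- score_alignment(c(rep("match", 6), "gap5"))
  expect_identical(s3$length, 6L)
  expect_identical(s3$similarity, 1)
  expect_identical(s3$percent, 100L)

  expect_error(score_alignment(character()), "non-empty")
  expect_error(score_alignment(c("gap5", "gap3")), "all-gap")
  expect_error(score_alignment(c("match", "weird")), "unknown column kind")
})

test_that("find_best_dr recovers a planted unique repeat and rejects noise", {
  w5 <- border_window(paste0(strrep("A", 34), "CGTACGTACGTA", strrep("A", 34)),
                      "five_prime", 40)
  w3 <- border_window(paste0(strrep("C", 34), "CGTACGTACGTA", strrep("C", 34)),
                      "three_prime", 40)
  a <- find_best_dr(w5, w3)
  expect_identical(a$length, 12L)
  expect_identical(a$similarity, 1)
  expect_identical(a$copy5_span, c(34L, 46L))
  expect_identical(a$copy3_span, c(34L, 46L))
  expect_true(validate_alignment(a, w5, w3))

  expect_null(find_best_dr(border_window(strrep("A", 80), "five_prime", 40),
                           border_window(strrep("C", 80), "three_prime", 40)))
})

test_that("N bases never form match columns", {
  wN5 <- border_window(strrep("N", 40), "five_prime", 20)
  wN3 <- border_window(strrep("N", 40), "three_prime", 20)
  expect_null(find_best_dr(wN5, wN3))

  # an N inside the repeat must be treated as non-identity
  w5 <- border_window(paste0(strrep("A", 10), "CGTNCGTACGT", strrep("A", 10)),
                      "five_prime", 15)
  w3 <- border_window(paste0(strrep("G", 10), "CGTACGTACGT", strrep("G", 10)),
                      "three_prime", 15)
  a <- find_best_dr(w5, w3)
  expect_false(is.null(a))
  # the N column can only be a mismatch or sit outside the alignment
  cols5 <- strsplit(w5$seq, "")[[1]][(a$copy5_span[1] + 1):a$copy5_span[2]]
  n_pos <- which(cols5 == "N")
  if (length(n_pos)) {
    expect_true(all(a$columns[a$columns != "gap5"][n_pos] != "match"))
  }
  expect_true(validate_alignment(a, w5, w3))
})

test_that("relaxing constraints never shortens the best repeat", {
  set.seed(42)
  for (k in 1:20) {
    w5 <- rand_window(30, "five_prime")
    w3 <- rand_window(30, "three_prime")
    len_of <- function(p) {
      a <- find_best_dr(w5, w3, p)
      if (is.null(a)) 0L else a$length
    }
    base <- len_of(search_params())
    expect_gte(len_of(search_params(min_similarity = 0.5)), base)
    expect_gte(len_of(search_params(min_length = 2)), base)
    expect_lte(len_of(search_params(max_linker = 0)), base)
    expect_lte(len_of(search_params(max_linker = 1)), base)
  }
})

test_that("swapping the windows swaps spans and gap kinds but not the score", {
  set.seed(43)
  for (k in 1:25) {
    w5 <- rand_window(24, "five_prime")
    w3 <- rand_window(24, "three_prime")
    a <- find_best_dr(w5, w3)
    b <- find_best_dr(border_window(w3$seq, "five_prime", w3$border_pos),
                      border_window(w5$seq, "three_prime", w5$border_pos))
    if (is.null(a)) {
      expect_null(b)
    } else {
      expect_identical(b$length, a$length)
      expect_identical(b$matches, a$matches)
      expect_identical(b$similarity, a$similarity)
      # the optima may differ in tie-broken position, but the score is stable
    }
  }
})

test_that("validate_alignment rejects corrupted alignments", {
  w5 <- border_window("GATTACAG", "five_prime", 4)
  w3 <- border_window("GATTGCAG", "three_prime", 4)
  p <- search_params(max_length = 16)
  a <- find_best_dr(w5, w3, p)
  expect_true(validate_alignment(a, w5, w3, p))

  first_mm <- a
  first_mm$columns[1] <- "mismatch"
  expect_false(validate_alignment(first_mm, w5, w3, p))

  long_linker <- intronDR:::new_dr_alignment(
    c(0L, 8L), c(0L, 8L),
    c("match", "match", "mismatch", "mismatch", "mismatch", "match",
      "match", "match"))
  expect_false(validate_alignment(long_linker, w5, w3, p))

  wrong_span <- a
  wrong_span$copy3_span <- wrong_span$copy3_span + 1L
  expect_false(validate_alignment(wrong_span, w5, w3, p))
})

test_that("search equals the exhaustive oracle on random window pairs", {
  set.seed(44)
  p <- search_params(max_length = 16)
  for (k in 1:80) {
    n <- sample(12:22, 1)
    w5 <- rand_window(n, "five_prime")
    w3 <- rand_window(n, "three_prime")
    a <- find_best_dr(w5, w3, p)
    b <- brute_force_oracle(w5, w3, p)
    expect_same_alignment(a, b)
    if (!is.null(a)) expect_true(validate_alignment(a, w5, w3, p))
  }
  # also under stricter / looser parameter settings
  for (p2 in list(search_params(min_similarity = 1, max_linker = 0,
                                max_length = 16),
                  search_params(min_length = 6, max_linker = 1,
                                max_length = 12),
                  search_params(min_length = 2, min_similarity = 0.6,
                                min_flank_block = 3, max_length = 16))) {
    for (k in 1:25) {
      w5 <- rand_window(18, "five_prime")
      w3 <- rand_window(18, "three_prime")
      expect_same_alignment(find_best_dr(w5, w3, p2),
                            brute_force_oracle(w5, w3, p2))
    }
  }
})
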