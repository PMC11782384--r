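test_that("random sequences honour length, composition and seeding", {
  expect_identical(random_sequence(0), "")
  expect_true(grepl("^[GC]+$", random_sequence(200, gc = 1, seed = 1)))
  expect_true(grepl("^[AT]+$", random_sequence(200, gc = 0, seed = 1)))
  expect_error(random_sequence(10, gc = 1.5), "gc")

  s <- random_sequence(100000, gc = 0.5, seed = 8)
  gc_frac <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  se <- sqrt(0.25 / 100000)
  expect_lte(abs(gc_frac - 0.5), 3 * se)

  expect_identical(random_sequence(50, seed = 3), random_sequence(50, seed = 3))
})

test_that("zero-noise planted repeats are recovered with similarity 1", {
  for (seed in 1:10) {
    sim <- plant_intron(sim_params(dr_len = 12, sub_rate = 0, indel_rate = 0,
                                   seed = seed))
    tr <- sim$truth
    # planted copies are identical in the gene sequence
    get_span <- function(span) substr(sim$record$sequence, span[1] + 1, span[2])
    expect_identical(get_span(tr$copy5_span), tr$repeat_seq)
    expect_identical(get_span(tr$copy3_span), tr$repeat_seq)
    expect_identical(tr$realized_similarity, 1)

    wins <- extract_border_windows(sim$record, 1)
    # under the exact-match criterion the planted pair is the unique optimum:
    # the spurious-repeat screen guarantees no other shared 12-mer
    exact <- find_best_dr(wins$five_prime, wins$three_prime,
                          search_params(min_similarity = 1, max_linker = 0))
    expect_identical(exact$copy5_span + wins$five_prime$gene_offset,
                     unname(tr$copy5_span))
    expect_identical(exact$copy3_span + wins$three_prime$gene_offset,
                     unname(tr$copy3_span))
    expect_identical(exact$similarity, 1)
    # the default permissive criterion always reports at least as long a
    # repeat (chance linker-chains may extend or outcompete the planted one)
    a <- find_best_dr(wins$five_prime, wins$three_prime)
    expect_false(is.null(a))
    expect_gte(a$length, tr$dr_len)
    expect_gte(a$similarity, 0.7)
  }
})

test_that("placement offsets realize the intended geometry", {
  sim <- plant_intron(sim_params(dr_len = 12, offset5 = -12, offset3 = 0,
                                 sub_rate = 0, indel_rate = 0, seed = 13))
  expect_identical(sim$truth$category, "e|e")
  expect_identical(sim$truth$delta, 12L)
  expect_identical(c(sim$truth$d5, sim$truth$d3), c(0L, 0L))
  expect_error(plant_intron(sim_params(dr_len = 12, offset5 = -60)),
               "infeasible")
})

test_that("substitution counts follow the configured rate", {
  set.seed(60)
  subs <- replicate(400, {
    plant_intron(sim_params(dr_len = 20, sub_rate = 0.2, indel_rate = 0,
                            exon5_len = 60, intron_len = 100,
                            exon3_len = 60))$truth$n_sub
  })
  se <- sqrt(20 * 0.2 * 0.8 / 400)
  expect_lte(abs(mean(subs) - 4), 3 * se)
})

test_that("recovered similarity degrades monotonically with substitution rate", {
  set.seed(61)
  mean_sim <- vapply(c(0, 0.1, 0.25), function(rate) {
    mean(replicate(40, {
      s <- plant_intron(sim_params(dr_len = 14, sub_rate = rate,
                                   indel_rate = 0))
      sc <- scan_introns(list(s$record))
      sc$results$similarity
    }), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_sim) < 0))
})

test_that("identical simulation parameters give byte-identical output", {
  a <- plant_intron(sim_params(dr_len = 9, seed = 99))
  b <- plant_intron(sim_params(dr_len = 9, seed = 99))
  expect_identical(a$record$sequence, b$record$sequence)
  expect_identical(a$truth, b$truth)
})

test_that("cohorts honour composition and carry a complete truth table", {
  nine <- data.frame(placement = paste(
    rep(c("EXON", "BORDER", "INTRON"), each = 3),
    rep(c("EXON", "BORDER", "INTRON"), times = 3), sep = "/"),
    fraction = rep(1 / 9, 9))
  ch <- generate_cohort(9, composition = nine, seed = 71)
  expect_length(ch$records, 9L)
  expect_identical(sort(ch$truth$placement), sort(nine$placement))

  uni <- generate_cohort(6, composition = data.frame(
    intron_type = "spliceosomal", location = "nuclear", taxon_code = "An",
    fraction = 1), seed = 72)
  expect_true(all(uni$truth$intron_type == "spliceosomal"))
  expect_true(all(uni$truth$location == "nuclear"))

  expect_error(generate_cohort(5, composition = data.frame(
    intron_type = "x", fraction = 0.5)), "sum to 1")

  # intron annotations all start GT and end AG at zero noise
  ch0 <- generate_cohort(5, param_ranges = list(sub_rate = 0, indel_rate = 0,
                                                placement = "cycle"),
                         seed = 73)
  for (g in ch0$records) {
    s <- g$introns$start; e <- g$introns$end
    intron_seq <- substr(g$sequence, s + 1, e)
    # planted copies may overwrite the consensus only when they straddle
    tr <- ch0$truth[ch0$truth$record_id == g$id, ]
    if (tr$offset5 >= 2 || tr$offset5 <= -tr$dr_len) {
      expect_identical(substr(intron_seq, 1, 2), "GT")
    }
    if (tr$offset3 + tr$dr_len <= -2 || tr$offset3 >= 0) {
      expect_identical(substr(intron_seq, e - s - 1, e - s), "AG")
    }
  }
})
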