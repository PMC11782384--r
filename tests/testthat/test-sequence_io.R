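test_that("TSV annotations convert 1-based inclusive to internal half-open", {
  set.seed(1)
  fa <- tempfile(fileext = ".fa")
  write_fasta_text("rec1", rand_dna(100), fa)
  tsv <- write_tsv_annotation(data.frame(
    record_id = "rec1", start_1based = 41, end_1based_inclusive = 60,
    intron_type = "group_I", location = "plastid", taxon_code = "Pt",
    accession = "ACC1"
  ), tempfile(fileext = ".tsv"))

  recs <- read_fasta_with_annotations(fa, tsv, "tsv")
  expect_length(recs, 1L)
  g <- recs[[1L]]
  expect_identical(g$introns$start, 40L)
  expect_identical(g$introns$end, 60L)
  expect_identical(g$introns$end - g$introns$start, 20L)
  expect_identical(g$intron_type, "group_I")
  expect_identical(g$accession, "ACC1")
})

test_that("empty annotation table yields an empty record list", {
  fa <- tempfile(fileext = ".fa")
  write_fasta_text("rec1", "ACGTACGT", fa)
  tsv <- write_tsv_annotation(
    data.frame(record_id = character(), start_1based = integer(),
               end_1based_inclusive = integer(), intron_type = character(),
               location = character(), taxon_code = character(),
               accession = character()),
    tempfile(fileext = ".tsv"))
  expect_identical(read_fasta_with_annotations(fa, tsv, "tsv"), list())
})

test_that("lowercase sequence is uppercased and round-trips through write/read", {
  fa <- tempfile(fileext = ".fa")
  write_fasta_text("rec1", "acgtacgtacgtacgtacgt", fa)
  tsv <- write_tsv_annotation(data.frame(
    record_id = "rec1", start_1based = 5, end_1based_inclusive = 12,
    intron_type = "spliceosomal", location = "nuclear", taxon_code = "An",
    accession = "X1"
  ), tempfile(fileext = ".tsv"))
  recs <- read_fasta_with_annotations(fa, tsv, "tsv")
  expect_identical(recs[[1L]]$sequence, "ACGTACGTACGTACGTACGT")

  fa2 <- tempfile(fileext = ".fa"); tsv2 <- tempfile(fileext = ".tsv")
  write_fasta(recs, fa2)
  write_annotations(recs, tsv2, "tsv")
  again <- read_fasta_with_annotations(fa2, tsv2, "tsv")
  expect_identical(again[[1L]]$sequence, recs[[1L]]$sequence)
  expect_identical(again[[1L]]$introns, recs[[1L]]$introns)
})

test_that("annotation errors are caught and name the offender", {
  fa <- tempfile(fileext = ".fa")
  write_fasta_text("rec1", strrep("ACGT", 25), fa)
  bad_id <- write_tsv_annotation(data.frame(
    record_id = "nope", start_1based = 1, end_1based_inclusive = 10,
    intron_type = "x", location = "x", taxon_code = "x", accession = "x"
  ), tempfile())
  expect_error(read_fasta_with_annotations(fa, bad_id, "tsv"), "nope")

  oob <- write_tsv_annotation(data.frame(
    record_id = "rec1", start_1based = 90, end_1based_inclusive = 120,
    intron_type = "x", location = "x", taxon_code = "x", accession = "x"
  ), tempfile())
  expect_error(read_fasta_with_annotations(fa, oob, "tsv"), "bounds")

  overlap <- write_tsv_annotation(data.frame(
    record_id = "rec1", start_1based = c(10, 15),
    end_1based_inclusive = c(20, 30),
    intron_type = "x", location = "x", taxon_code = "x", accession = "x"
  ), tempfile())
  expect_error(read_fasta_with_annotations(fa, overlap, "tsv"), "overlap")
})

test_that("GFF3 coordinates round-trip and minus-strand records are flipped", {
  set.seed(2)
  seq <- rand_dna(120)
  fa <- tempfile(fileext = ".fa")
  write_fasta_text("recA", seq, fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(gff3_text(data.frame(
    record_id = "recA", start = 31, end = 60, strand = "+",
    intron_type = "group_II", location = "plastid", taxon_code = "Pt",
    accession = "Z1", stringsAsFactors = FALSE
  )), gff)
  recs <- read_fasta_with_annotations(fa, gff, "gff3")
  g <- recs[[1L]]
  expect_identical(g$introns$start, 30L)
  expect_identical(g$introns$end, 60L)
  expect_false(g$strand_flipped)
  # internal -> 1-based inclusive reproduces the original coordinates
  out <- tempfile(); write_annotations(recs, out, "tsv")
  back <- read.delim(out)
  expect_identical(as.integer(back$start_1based), 31L)
  expect_identical(as.integer(back$end_1based_inclusive), 60L)

  gffm <- tempfile(fileext = ".gff3")
  writeLines(gff3_text(data.frame(
    record_id = "recA", start = 31, end = 60, strand = "-",
    intron_type = "group_II", location = "plastid", taxon_code = "Pt",
    accession = "Z1", stringsAsFactors = FALSE
  )), gffm)
  recs_m <- read_fasta_with_annotations(fa, gffm, "gff3")
  gm <- recs_m[[1L]]
  expect_true(gm$strand_flipped)
  expect_identical(gm$introns$start, 120L - 60L)
  expect_identical(gm$introns$end, 120L - 30L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  expect_identical(gm$sequence, rc)
  # the flipped intron sequence is the reverse complement of the original
  expect_identical(
    substr(gm$sequence, gm$introns$start + 1L, gm$introns$end),
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(seq, 31, 60)))))
})

test_that("border windows equal the implied gene slice, with clipping", {
  set.seed(3)
  seq <- rand_dna(200)
  g <- gene_record("g", seq, data.frame(start = 80, end = 120))
  w <- extract_border_windows(g, 1, flank = 40)
  expect_identical(w$five_prime$seq, substr(seq, 41, 120))
  expect_identical(w$five_prime$border_pos, 40L)
  expect_identical(w$three_prime$seq, substr(seq, 81, 160))
  expect_identical(w$three_prime$border_pos, 40L)

  # truncated upstream flank: direct-slicing oracle
  g2 <- gene_record("g", seq, data.frame(start = 10, end = 120))
  w2 <- extract_border_windows(g2, 1, flank = 40)
  expect_identical(w2$five_prime$seq, substr(seq, 1, 50))
  expect_identical(w2$five_prime$border_pos, 10L)
  expect_identical(w2$five_prime$gene_offset, 0L)

  w3 <- extract_border_windows(g, 1, flank = 1)
  expect_lte(nchar(w3$five_prime$seq), 2L)
  expect_error(extract_border_windows(g, 1, flank = 0), "flank")

  # property: window slice identity over random genes/introns/flanks
  for (k in 1:40) {
    n <- sample(30:200, 1)
    s <- sample(0:(n - 2), 1); e <- sample((s + 1):n, 1)
    fl <- sample(1:60, 1)
    gk <- gene_record("gk", rand_dna(n), data.frame(start = s, end = e))
    wk <- extract_border_windows(gk, 1, flank = fl)
    for (side in c("five_prime", "three_prime")) {
      bw <- wk[[side]]
      expect_identical(
        bw$seq,
        substr(gk$sequence, bw$gene_offset + 1L,
               bw$gene_offset + nchar(bw$seq)))
      expect_gte(bw$border_pos, 0L)
      expect_lte(bw$border_pos, nchar(bw$seq))
    }
  }
})

test_that("results tables round-trip through write/read, including NA rows", {
  out <- tempfile(fileext = ".tsv")
  expect_identical(write_results(empty_scan <- scan_introns(list()), out), 0L)
  expect_identical(nrow(read_results(out)), 0L)
  expect_identical(readLines(out)[1],
                   paste(names(read_results(out)), collapse = "\t"))

  set.seed(4)
  ch <- generate_cohort(3, seed = 9)
  sc <- scan_introns(ch$records)
  # force one not-found row to exercise the NA dialect: the two windows share
  # no common 4-mer and no linkable blocks
  g_none <- make_gene(strrep("A", 50),
                      paste0("GT", strrep("C", 57), strrep("G", 59), "AG"),
                      strrep("T", 50),
                      intron_type = "group_I", location = "plastid",
                      taxon_code = "Pt", accession = "NONE1")
  sc_none <- scan_introns(list(g_none))
  all_rows <- rbind(sc$results, sc_none$results)
  expect_identical(write_results(all_rows, out), 4L)
  back <- read_results(out)
  expect_equal(back, all_rows, tolerance = 0)
  expect_false(back$dr_found[4])
  expect_true(is.na(back$length[4]))
})

test_that("GenBank flat files parse simple intron spans and reject compound ones", {
  set.seed(5)
  seq <- rand_dna(200)
  gb <- tempfile(fileext = ".gb")
  writeLines(genbank_text("LOC1", seq, "61..90", organelle = "mitochondrion"),
             gb)
  recs <- read_genbank(gb)
  expect_length(recs, 1L)
  expect_identical(recs[[1L]]$introns$start, 60L)
  expect_identical(recs[[1L]]$introns$end, 90L)
  expect_identical(recs[[1L]]$location, "mitochondrial")
  expect_identical(recs[[1L]]$sequence, seq)

  writeLines(genbank_text("LOC2", seq, c("120..150", "30..50")), gb)
  recs2 <- read_genbank(gb)
  expect_identical(recs2[[1L]]$introns$start, c(29L, 119L))

  writeLines(genbank_text("LOC3", seq, "join(10..20,30..40)"), gb)
  expect_error(read_genbank(gb), "compound")

  writeLines(genbank_text("LOC4", seq, character(0)), gb)
  expect_warning(expect_length(read_genbank(gb), 0L), "no intron")
})
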