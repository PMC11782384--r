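#' Random DNA sequence
#'
#' I.i.d. bases with `P(G) + P(C) = gc` (the default 0.5 is the uniform
#' null: equal occurrence of A, C, G and T).
#'
#' @param length number of bases (>= 0).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed RNG seed (optional).
#' @return a DNA string.
#' @export
random_sequence <- function(length, gc = 0.5, seed = NULL) {
  if (!is.numeric(length) || length < 0) stop("`length` must be >= 0")
  if (!is.numeric(gc) || gc < 0 || gc > 1) stop("`gc` must lie in [0, 1]")
  if (length == 0) return("")
  with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
}

#' Parameters for one synthetic exon-intron-exon record
#'
#' The generator emulates an annotated gene whose intron was acquired by an
#' insertion that left a direct-repeat pair: a repeat of `dr_len` bases is
#' planted with copy starts at `offset5` / `offset3` relative to the 5' and
#' 3' borders (negative offsets reach into the exon / intron upstream of the
#' border), the intron is given consensus `GT...AG` ends, and the 3' copy is
#' then degraded by per-base substitutions and single-base indels to emulate
#' post-insertion drift. Defaults: a mid-sized intron flanked by 100-bp
#' exons, an 11-bp repeat straddling both borders (the most common observed
#' placement), and drift rates giving ~80% expected copy similarity.
#'
#' @param exon5_len,intron_len,exon3_len segment lengths in bp.
#' @param dr_len planted repeat length in bp.
#' @param offset5,offset3 signed copy start positions relative to the
#'   respective border (copy start = border + offset). `NULL` defaults to a
#'   border-straddling placement `-floor(dr_len/2)`.
#' @param sub_rate per-base substitution probability applied to the 3' copy.
#' @param indel_rate per-base probability of a single-base indel in the 3'
#'   copy (deletion or insertion with equal probability).
#' @param gc background GC fraction.
#' @param seed RNG seed (optional).
#' @param intron_type,location,taxon_code,accession record metadata.
#' @return an object of class `dr_sim_params`.
#' @export
sim_params <- function(exon5_len = 100L, intron_len = 300L, exon3_len = 100L,
                       dr_len = 11L, offset5 = NULL, offset3 = NULL,
                       sub_rate = 0.2, indel_rate = 0.01, gc = 0.5,
                       seed = NULL, intron_type = "group_II",
                       location = "plastid", taxon_code = "Pt",
                       accession = "synthetic") {
  stopifnot(is_count(exon5_len), is_count(intron_len), is_count(exon3_len),
            is_count(dr_len))
  if (sub_rate < 0 || sub_rate >= 1 || indel_rate < 0 || indel_rate >= 1) {
    stop("mutation rates must lie in [0, 1)")
  }
  if (gc < 0 || gc > 1) stop("`gc` must lie in [0, 1]")
  offset5 <- as.integer(offset5 %||% -(dr_len %/% 2L))
  offset3 <- as.integer(offset3 %||% -(dr_len %/% 2L))
  structure(
    list(exon5_len = as.integer(exon5_len), intron_len = as.integer(intron_len),
         exon3_len = as.integer(exon3_len), dr_len = as.integer(dr_len),
         offset5 = offset5, offset3 = offset3,
         sub_rate = sub_rate, indel_rate = indel_rate, gc = gc, seed = seed,
         intron_type = intron_type, location = location,
         taxon_code = taxon_code, accession = accession),
    class = "dr_sim_params"
  )
}

# degrade a repeat copy: substitutions first (always to a different base),
# then per-base single indels. Returns the mutated string plus bookkeeping
# needed for the realized similarity (deleted originals and inserted bases
# are gap columns, excluded from length; substituted retained bases are
# mismatch columns).
mutate_copy <- function(repeat_seq, sub_rate, indel_rate) {
  bases <- strsplit(repeat_seq, "", fixed = TRUE)[[1L]]
  k <- length(bases)
  sub_at <- which(stats::runif(k) < sub_rate)
  for (p in sub_at) {
    bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1L)
  }
  status <- rep("kept", k)
  status[sub_at] <- "sub"
  out <- character(0L)
  n_ins <- 0L; n_del <- 0L
  ins_before_end <- 0L; del_positions <- integer(0L); ins_points <- integer(0L)
  for (p in seq_len(k)) {
    if (stats::runif(1L) < indel_rate) {
      if (stats::runif(1L) < 0.5) {           # delete this base
        status[p] <- "del"
        n_del <- n_del + 1L
        del_positions <- c(del_positions, p)
        next
      } else {                                # insert a random base before it
        out <- c(out, sample(c("A", "C", "G", "T"), 1L))
        n_ins <- n_ins + 1L
        ins_points <- c(ins_points, p)
      }
    }
    out <- c(out, bases[p])
  }
  retained <- sum(status != "del")
  matches <- sum(status == "kept")
  list(seq = paste(out, collapse = ""),
       n_sub = sum(status == "sub"), n_del = n_del, n_ins = n_ins,
       sub_positions = which(status == "sub"),
       del_positions = del_positions, ins_points = ins_points,
       aligned_length = retained,
       similarity = if (retained > 0L) matches / retained else NA_real_)
}

#' Generate one synthetic gene with a planted direct-repeat pair
#'
#' Builds `exon5 + intron + exon3` on a random background, imposes `GT`/`AG`
#' intron ends, plants the two repeat copies at the configured offsets
#' (overwriting the background; the copies may overwrite the splice
#' consensus, which the analysis never requires), degrades the 3' copy, and
#' re-rolls the background (bounded retries) until no spurious exact common
#' `dr_len`-mer links the two 40-bp border windows outside the planted pair.
#' Indels in the 3' copy shift downstream coordinates; the annotated intron
#' span and the recorded truth spans account for this.
#'
#' @param params a [sim_params()] object.
#' @return list with `record` (a [gene_record()]) and `truth` (class
#'   `dr_sim_truth`): planted copy spans in gene coordinates, the original
#'   repeat sequence, realized mutation counts and positions, realized copy
#'   similarity, and the expected placement classification (`loc5`, `loc3`,
#'   `d5`, `d3`, `category`, `relation`, `delta`).
#' @export
plant_intron <- function(params) {
  stopifnot(inherits(params, "dr_sim_params"))
  p <- params
  with_seed(p$seed, {
    b5 <- p$exon5_len
    b3 <- p$exon5_len + p$intron_len
    gene_len <- p$exon5_len + p$intron_len + p$exon3_len
    s5 <- b5 + p$offset5
    s3 <- b3 + p$offset3
    flank <- 40L
    if (p$offset5 < -flank || p$offset5 + p$dr_len > flank ||
        p$offset3 < -flank || p$offset3 + p$dr_len > flank) {
      stop("infeasible geometry: a copy does not fit its border window")
    }
    if (s5 < 0L || s3 + p$dr_len > gene_len) {
      stop("infeasible geometry: a copy falls outside the gene")
    }
    if (s5 + p$dr_len > s3) {
      stop("infeasible geometry: the two copies overlap")
    }
    if (p$intron_len < 2L) stop("intron too short for GT..AG ends")

    repeat_seq <- random_sequence(p$dr_len, gc = p$gc)
    mut <- mutate_copy(repeat_seq, p$sub_rate, p$indel_rate)
    lm <- nchar(mut$seq)

    for (attempt in seq_len(50L)) {
      bg <- strsplit(random_sequence(gene_len, gc = p$gc), "", TRUE)[[1L]]
      bg[b5 + 1L] <- "G"; bg[b5 + 2L] <- "T"
      bg[b3 - 1L] <- "A"; bg[b3] <- "G"
      bg[(s5 + 1L):(s5 + p$dr_len)] <- strsplit(repeat_seq, "", TRUE)[[1L]]
      # splice the (possibly length-changed) mutated copy in at s3
      gene_chr <- c(bg[seq_len(s3)],
                    strsplit(mut$seq, "", TRUE)[[1L]],
                    if (s3 + p$dr_len < gene_len) {
                      bg[(s3 + p$dr_len + 1L):gene_len]
                    })
      gene_seq <- paste(gene_chr, collapse = "")

      # indels before the 3' border shift it
      shift <- sum(s3 + mut$ins_points - 1L < b3) -
               sum(s3 + mut$del_positions - 1L < b3)
      b3_adj <- b3 + as.integer(shift)
      total_len <- length(gene_chr)
      span5 <- c(s5, s5 + p$dr_len)
      span3 <- c(s3, s3 + lm)

      ok <- !has_spurious_kmer(gene_seq, b5, b3_adj, span5, span3,
                               p$dr_len, flank)
      if (ok) break
      if (attempt == 50L) {
        stop(paste("retry budget exhausted while screening spurious repeats;",
                   "use a longer repeat or different placements"))
      }
    }

    record <- gene_record(
      id = sprintf("syn_%s", substr(repeat_seq, 1L, min(6L, p$dr_len))),
      sequence = gene_seq,
      introns = data.frame(start = b5, end = b3_adj),
      intron_type = p$intron_type, location = p$location,
      taxon_code = p$taxon_code, accession = p$accession
    )

    # locate_copy only uses relative positions, so gene coordinates work here
    l5 <- locate_copy(span5, b5, "five_prime")
    l3 <- locate_copy(span3, b3_adj, "three_prime")
    cat3 <- categorize_pair(l5$location, l3$location)
    truth <- structure(
      list(copy5_span = span5, copy3_span = span3,
           repeat_seq = repeat_seq, dr_len = p$dr_len,
           offset5 = p$offset5, offset3 = p$offset3,
           n_sub = mut$n_sub, n_del = mut$n_del, n_ins = mut$n_ins,
           sub_positions = mut$sub_positions,
           realized_similarity = mut$similarity,
           aligned_length = mut$aligned_length,
           loc5 = l5$location, loc3 = l3$location,
           d5 = l5$distance, d3 = l3$distance,
           category = cat3$category, relation = cat3$relation,
           delta = (span3[1L] - b3_adj) - (span5[1L] - b5)),
      class = "dr_sim_truth"
    )
    list(record = record, truth = truth)
  })
}

# TRUE when the two border windows share an exact k-mer not attributable to
# the planted copies
has_spurious_kmer <- function(gene_seq, b5, b3, span5, span3, k, flank) {
  n <- nchar(gene_seq)
  w5_from <- max(0L, b5 - flank); w5_to <- min(n, b5 + flank)
  w3_from <- max(0L, b3 - flank); w3_to <- min(n, b3 + flank)
  kmers <- function(from, to) {
    len <- to - from
    if (len < k) return(data.frame(start = integer(), mer = character()))
    starts <- from + 0:(len - k)
    data.frame(start = starts,
               mer = substring(gene_seq, starts + 1L, starts + k),
               stringsAsFactors = FALSE)
  }
  k5 <- kmers(w5_from, w5_to)
  k3 <- kmers(w3_from, w3_to)
  if (!nrow(k5) || !nrow(k3)) return(FALSE)
  shared <- intersect(k5$mer, k3$mer)
  for (mer in shared) {
    for (a in k5$start[k5$mer == mer]) {
      for (b in k3$start[k3$mer == mer]) {
        inside5 <- a >= span5[1L] && a + k <= span5[2L]
        inside3 <- b >= span3[1L] && b + k <= span3[2L]
        if (!(inside5 && inside3)) return(TRUE)
      }
    }
  }
  FALSE
}

#' The nine canonical placement modes
#'
#' Offsets realizing each placement-pair category with both copies at
#' distance 0 from their borders: exon-side copies abut the border from the
#' exon, border copies straddle it, intron-side copies abut it from inside
#' the intron.
#'
#' @param loc5,loc3 `"EXON"`, `"BORDER"` or `"INTRON"`.
#' @param dr_len repeat length.
#' @param d5,d3 extra distance from the border (default 0).
#' @return list with `offset5` and `offset3`.
#' @export
placement_offsets <- function(loc5, loc3, dr_len, d5 = 0L, d3 = 0L) {
  loc5 <- match.arg(loc5, c("EXON", "BORDER", "INTRON"))
  loc3 <- match.arg(loc3, c("EXON", "BORDER", "INTRON"))
  if (dr_len < 2L && (loc5 == "BORDER" || loc3 == "BORDER")) {
    stop("a straddling copy needs dr_len >= 2")
  }
  off5 <- switch(loc5,
    EXON = -dr_len - d5,
    BORDER = -(dr_len %/% 2L),
    INTRON = d5)
  off3 <- switch(loc3,
    EXON = d3,
    BORDER = -(dr_len %/% 2L),
    INTRON = -dr_len - d3)
  list(offset5 = as.integer(off5), offset3 = as.integer(off3))
}

# study-like default cohort composition: intron types x genomic location
default_composition <- function() {
  data.frame(
    intron_type = c("group_I", "group_I", "group_I", "group_I",
                    "group_II", "group_II", "group_II", "group_II",
                    "group_III", "spliceosomal", "archaeal", "archaeal"),
    location = c("nuclear", "mitochondrial", "plastid", "prokaryote",
                 "nuclear", "mitochondrial", "plastid", "prokaryote",
                 "plastid", "nuclear", "nuclear", "prokaryote"),
    taxon_code = c("An", "Fu", "Pt", "Ba",
                   "Fu", "Pt", "Pt", "Ba",
                   "Ex", "An", "Fu", "Ar"),
    fraction = c(15, 2, 20, 2, 1, 33, 66, 2, 24, 43, 1, 4) / 213,
    stringsAsFactors = FALSE
  )
}

#' Generate a cohort of synthetic gene records with ground truth
#'
#' Metadata groups are allocated deterministically by largest remainder from
#' `composition` (so exact fractions are honoured where possible); placement
#' modes and geometry are drawn per `param_ranges`.
#'
#' @param n number of records.
#' @param composition data.frame with a `fraction` column plus any of
#'   `intron_type`, `location`, `taxon_code`, `placement` (a
#'   `"LOC5/LOC3"` pair such as `"BORDER/BORDER"`). Fractions must sum to 1.
#'   Default: a broad mix of intron types and locations weighted like a
#'   typical survey cohort.
#' @param param_ranges list overriding any of `dr_len` (length-2 range),
#'   `exon5_len`, `intron_len` (range), `exon3_len`, `sub_rate`,
#'   `indel_rate`, `gc`, `placement` (`"random"` to draw uniformly from the
#'   nine modes, `"cycle"` to cycle them, or a vector of `"LOC5/LOC3"`
#'   labels recycled over records), `jitter` (max extra border distance for
#'   non-straddling copies).
#' @param seed RNG seed (optional).
#' @return list with `records` (list of [gene_record()]) and `truth`
#'   (data.frame, one row per record).
#' @export
generate_cohort <- function(n, composition = NULL, param_ranges = list(),
                            seed = NULL) {
  if (!is_count(n)) stop("`n` must be a positive integer")
  composition <- composition %||% default_composition()
  composition <- as.data.frame(composition)
  if (!"fraction" %in% names(composition)) {
    stop("`composition` needs a `fraction` column")
  }
  if (abs(sum(composition$fraction) - 1) > 1e-8 ||
      any(composition$fraction < 0)) {
    stop("composition fractions must be non-negative and sum to 1")
  }
  pr <- utils::modifyList(
    list(dr_len = c(6L, 16L), exon5_len = 100L, intron_len = c(80L, 400L),
         exon3_len = 100L, sub_rate = 0.2, indel_rate = 0.01, gc = 0.5,
         placement = "random", jitter = 0L),
    param_ranges
  )
  locs <- c("EXON", "BORDER", "INTRON")
  modes <- expand.grid(loc5 = locs, loc3 = locs, stringsAsFactors = FALSE)
  mode_labels <- paste(modes$loc5, modes$loc3, sep = "/")

  # largest-remainder allocation of group counts
  raw <- n * composition$fraction
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0L) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }

  draw_range <- function(r) {
    if (length(r) == 2L) sample(r[1L]:r[2L], 1L) else as.integer(r)
  }

  with_seed(seed, {
    records <- list()
    truth_rows <- NULL
    idx <- 0L
    for (g in seq_len(nrow(composition))) {
      for (rep_i in seq_len(counts[g])) {
        idx <- idx + 1L
        placement <- composition$placement[g] %||% NULL
        if (is.null(placement) || is.na(placement)) {
          placement <- if (identical(pr$placement, "random")) {
            sample(mode_labels, 1L)
          } else if (identical(pr$placement, "cycle")) {
            mode_labels[(idx - 1L) %% 9L + 1L]
          } else {
            pr$placement[(idx - 1L) %% length(pr$placement) + 1L]
          }
        }
        parts <- strsplit(placement, "/", fixed = TRUE)[[1L]]
        dr_len <- draw_range(pr$dr_len)
        jit <- if (pr$jitter > 0L) function() sample(0:pr$jitter, 1L)
               else function() 0L
        off <- placement_offsets(parts[1L], parts[2L], dr_len,
                                 d5 = jit(), d3 = jit())
        sp <- sim_params(
          exon5_len = draw_range(pr$exon5_len),
          intron_len = draw_range(pr$intron_len),
          exon3_len = draw_range(pr$exon3_len),
          dr_len = dr_len, offset5 = off$offset5, offset3 = off$offset3,
          sub_rate = pr$sub_rate, indel_rate = pr$indel_rate, gc = pr$gc,
          intron_type = composition$intron_type[g] %||% "unknown",
          location = composition$location[g] %||% "unknown",
          taxon_code = composition$taxon_code[g] %||% "unknown",
          accession = sprintf("SYN%04d", idx)
        )
        sim <- plant_intron(sp)
        sim$record$id <- sprintf("syn%04d", idx)
        records[[idx]] <- sim$record
        tr <- sim$truth
        truth_rows <- rbind(truth_rows, data.frame(
          record_id = sim$record$id, accession = sp$accession,
          intron_type = sp$intron_type, location = sp$location,
          taxon_code = sp$taxon_code, placement = placement,
          dr_len = tr$dr_len, offset5 = tr$offset5, offset3 = tr$offset3,
          copy5_start = tr$copy5_span[1L], copy5_end = tr$copy5_span[2L],
          copy3_start = tr$copy3_span[1L], copy3_end = tr$copy3_span[2L],
          repeat_seq = tr$repeat_seq,
          n_sub = tr$n_sub, n_del = tr$n_del, n_ins = tr$n_ins,
          realized_similarity = tr$realized_similarity,
          aligned_length = tr$aligned_length,
          loc5 = tr$loc5, loc3 = tr$loc3, d5 = tr$d5, d3 = tr$d3,
          category = tr$category, relation = tr$relation, delta = tr$delta,
          stringsAsFactors = FALSE
        ))
      }
    }
    list(records = records, truth = truth_rows %||% data.frame())
  })
}
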