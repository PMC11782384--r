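#' Construct a gene record
#'
#' A gene record holds one annotated DNA sequence (transcribed orientation),
#' its intron coordinates, and study metadata. Coordinates are 0-based
#' half-open internally: an intron `[start, end)` covers bases
#' `start .. end - 1` of the gene. File interfaces (annotation TSV, GFF3,
#' GenBank) use the conventional 1-based inclusive coordinates and are
#' converted at the boundary.
#'
#' @param id record identifier (must match the FASTA id when read from files).
#' @param sequence DNA string over `A,C,G,T,N`; stored uppercased. `N` (or any
#'   other symbol) is retained but never counts as a match downstream.
#' @param introns data.frame with integer columns `start`, `end` (0-based
#'   half-open); must be sorted, non-overlapping and within the sequence.
#' @param intron_type one of `"group_I"`, `"group_II"`, `"group_III"`,
#'   `"twintron"`, `"spliceosomal"`, `"archaeal"`, or `"unknown"`.
#' @param location one of `"nuclear"`, `"mitochondrial"`, `"plastid"`,
#'   `"prokaryote"`, or `"unknown"`.
#' @param taxon_code short taxon label (e.g. `"Pt"` for plants).
#' @param accession source database accession, or `"unknown"`.
#' @param strand_flipped logical; `TRUE` when the record was
#'   reverse-complemented at read time because its features were annotated on
#'   the minus strand.
#' @return an object of class `gene_record`.
#' @export
gene_record <- function(id, sequence, introns,
                        intron_type = "unknown", location = "unknown",
                        taxon_code = "unknown", accession = "unknown",
                        strand_flipped = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 1L) stop("gene sequence must have length >= 1")
  introns <- as.data.frame(introns)
  if (!all(c("start", "end") %in% names(introns))) {
    stop("`introns` needs columns `start` and `end`")
  }
  introns$start <- as.integer(introns$start)
  introns$end <- as.integer(introns$end)
  introns <- introns[order(introns$start), c("start", "end"), drop = FALSE]
  rownames(introns) <- NULL
  if (nrow(introns)) {
    if (any(introns$start < 0L) || any(introns$end > n)) {
      stop(sprintf("intron span outside sequence bounds in record '%s'", id))
    }
    if (any(introns$end <= introns$start)) {
      stop(sprintf("intron with non-positive length in record '%s'", id))
    }
    if (nrow(introns) > 1L &&
        any(introns$start[-1L] < introns$end[-nrow(introns)])) {
      stop(sprintf("overlapping introns in record '%s'", id))
    }
  }
  structure(
    list(id = id, sequence = sequence, introns = introns,
         intron_type = as.character(intron_type),
         location = as.character(location),
         taxon_code = as.character(taxon_code),
         accession = as.character(accession),
         strand_flipped = isTRUE(strand_flipped)),
    class = "gene_record"
  )
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record> %s (%s, %s, %s): %d bp, %d intron(s)\n",
              x$id, x$intron_type, x$location, x$accession,
              nchar(x$sequence), nrow(x$introns)))
  invisible(x)
}

#' Construct a border window
#'
#' The sequence context around one intron/exon border: up to `flank` bases on
#' each side of the border (fewer when clipped by the gene ends). The border
#' itself is a between-base position: `border_pos` counts the window bases on
#' the upstream side, so the border sits between window offsets
#' `border_pos - 1` and `border_pos`.
#'
#' @param seq window sequence (verbatim slice of the gene).
#' @param border `"five_prime"` (exon | intron junction) or `"three_prime"`
#'   (intron | exon junction).
#' @param border_pos between-base coordinate of the border within the window,
#'   in `0..nchar(seq)`.
#' @param gene_offset gene coordinate (0-based) of the window's first base.
#' @param flank the flank that was requested (default 40).
#' @return an object of class `border_window`.
#' @export
border_window <- function(seq, border = c("five_prime", "three_prime"),
                          border_pos, gene_offset = 0L, flank = 40L) {
  border <- match.arg(border)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  border_pos <- as.integer(border_pos)
  if (border_pos < 0L || border_pos > n) {
    stop("`border_pos` must lie in [0, nchar(seq)]")
  }
  structure(
    list(seq = seq, border = border, border_pos = border_pos,
         gene_offset = as.integer(gene_offset), flank = as.integer(flank)),
    class = "border_window"
  )
}

#' @export
print.border_window <- function(x, ...) {
  cat(sprintf("<border_window> %s, %d bp, border at %d (gene offset %d)\n",
              x$border, nchar(x$seq), x$border_pos, x$gene_offset))
  cat(sprintf("  %s | %s\n",
              substr(x$seq, 1L, x$border_pos),
              substr(x$seq, x$border_pos + 1L, nchar(x$seq))))
  invisible(x)
}

#' Extract the two border windows of an intron
#'
#' The 5' window covers `gene[start - flank, start + flank)` and the 3' window
#' `gene[end - flank, end + flank)`, both clipped to the gene bounds (0-based
#' half-open gene coordinates). No masking of neighbouring features is
#' applied: window content is taken verbatim from the gene.
#'
#' @param gene a [gene_record()].
#' @param intron index of the intron in `gene$introns`, or a length-2 vector
#'   `c(start, end)` in 0-based half-open gene coordinates.
#' @param flank bases requested on each side of the border (default 40).
#' @return list with elements `five_prime` and `three_prime`, each a
#'   [border_window()].
#' @export
extract_border_windows <- function(gene, intron, flank = 40L) {
  stopifnot(inherits(gene, "gene_record"))
  if (!is_count(flank, min = 1)) stop("`flank` must be a positive integer")
  flank <- as.integer(flank)
  if (length(intron) == 1L) {
    if (!is_count(intron) || intron > nrow(gene$introns)) {
      stop("intron index out of range")
    }
    s <- gene$introns$start[intron]
    e <- gene$introns$end[intron]
  } else if (length(intron) == 2L) {
    s <- as.integer(intron[1L]); e <- as.integer(intron[2L])
  } else {
    stop("`intron` must be an index or a c(start, end) span")
  }
  n <- nchar(gene$sequence)
  if (s < 0L || e > n || e <= s) stop("intron span outside gene bounds")
  win <- function(center, border) {
    from <- max(0L, center - flank)
    to <- min(n, center + flank)
    border_window(
      seq = substr(gene$sequence, from + 1L, to),
      border = border, border_pos = center - from,
      gene_offset = from, flank = flank
    )
  }
  list(five_prime = win(s, "five_prime"), three_prime = win(e, "three_prime"))
}

# metadata columns of the annotation TSV interface
.annotation_cols <- c("record_id", "start_1based", "end_1based_inclusive",
                      "intron_type", "location", "taxon_code", "accession")

#' Read gene records from FASTA plus an intron annotation table
#'
#' @param fasta path to a (multi-record) FASTA file; ids are taken up to the
#'   first whitespace.
#' @param annotations path to the annotation file.
#' @param format `"tsv"` (columns `record_id`, `start_1based`,
#'   `end_1based_inclusive`, `intron_type`, `location`, `taxon_code`,
#'   `accession`) or `"gff3"` (features of type `intron`; the attributes
#'   `intron_type`, `location`, `taxon_code` and `accession` are honoured when
#'   present). Both formats use 1-based inclusive coordinates, converted to
#'   the internal 0-based half-open convention. Minus-strand GFF3 intron
#'   features cause the whole record to be reverse-complemented (coordinates
#'   flipped accordingly) and `strand_flipped` set.
#' @return list of [gene_record()] objects, one per FASTA record with at
#'   least one intron annotation.
#' @export
read_fasta_with_annotations <- function(fasta, annotations,
                                        format = c("tsv", "gff3")) {
  format <- match.arg(format)
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  seq_chr <- toupper(as.character(seqs))
  names(seq_chr) <- ids

  ann <- if (format == "tsv") read_annotation_tsv(annotations)
         else read_annotation_gff3(annotations)
  if (!nrow(ann)) return(list())

  unknown <- setdiff(unique(ann$record_id), ids)
  if (length(unknown)) {
    stop(sprintf("annotation refers to unknown record id(s): %s",
                 paste(unknown, collapse = ", ")))
  }

  records <- list()
  for (rid in unique(ann$record_id)) {
    rows <- ann[ann$record_id == rid, , drop = FALSE]
    seq <- seq_chr[[rid]]
    flip <- FALSE
    if (!is.null(rows$strand) && any(rows$strand == "-")) {
      if (!all(rows$strand == "-")) {
        stop(sprintf("record '%s' mixes intron strands", rid))
      }
      n <- nchar(seq)
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
      new_start <- n - rows$end_1based_inclusive + 1L
      new_end <- n - rows$start_1based + 1L
      rows$start_1based <- new_start
      rows$end_1based_inclusive <- new_end
      flip <- TRUE
    }
    records[[rid]] <- gene_record(
      id = rid, sequence = seq,
      introns = data.frame(start = rows$start_1based - 1L,
                           end = rows$end_1based_inclusive),
      intron_type = rows$intron_type[1L], location = rows$location[1L],
      taxon_code = rows$taxon_code[1L], accession = rows$accession[1L],
      strand_flipped = flip
    )
  }
  unname(records)
}

read_annotation_tsv <- function(path) {
  ann <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  missing <- setdiff(.annotation_cols, names(ann))
  if (length(missing)) {
    stop(sprintf("annotation TSV lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  ann$start_1based <- as.integer(ann$start_1based)
  ann$end_1based_inclusive <- as.integer(ann$end_1based_inclusive)
  ann$strand <- rep("+", nrow(ann))
  ann
}

read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "intron"]
  if (!length(gr)) {
    return(data.frame(record_id = character(), start_1based = integer(),
                      end_1based_inclusive = integer(),
                      intron_type = character(), location = character(),
                      taxon_code = character(), accession = character(),
                      strand = character()))
  }
  mc <- as.data.frame(S4Vectors::mcols(gr))
  pick <- function(col) {
    if (col %in% names(mc)) {
      v <- as.character(mc[[col]])
      ifelse(is.na(v) | !nzchar(v), "unknown", v)
    } else rep("unknown", length(gr))
  }
  data.frame(
    record_id = as.character(GenomicRanges::seqnames(gr)),
    start_1based = GenomicRanges::start(gr),
    end_1based_inclusive = GenomicRanges::end(gr),
    intron_type = pick("intron_type"), location = pick("location"),
    taxon_code = pick("taxon_code"), accession = pick("accession"),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write intron annotations for a set of gene records
#'
#' Inverse of the annotation-reading side of [read_fasta_with_annotations()]:
#' emits 1-based inclusive coordinates.
#'
#' @param records list of [gene_record()] objects.
#' @param path output file.
#' @param format `"tsv"` or `"gff3"`.
#' @return (invisibly) the number of annotation rows written.
#' @export
write_annotations <- function(records, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  rows <- do.call(rbind, lapply(records, function(g) {
    if (!nrow(g$introns)) return(NULL)
    data.frame(record_id = g$id,
               start_1based = g$introns$start + 1L,
               end_1based_inclusive = g$introns$end,
               intron_type = g$intron_type, location = g$location,
               taxon_code = g$taxon_code, accession = g$accession,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(record_id = character(), start_1based = integer(),
                       end_1based_inclusive = integer(),
                       intron_type = character(), location = character(),
                       taxon_code = character(), accession = character())
  }
  if (format == "tsv") {
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- c("##gff-version 3",
               sprintf(paste0("%s\tintronDR\tintron\t%d\t%d\t.\t+\t.\t",
                              "ID=%s.i%d;intron_type=%s;location=%s;",
                              "taxon_code=%s;accession=%s"),
                       rows$record_id, rows$start_1based,
                       rows$end_1based_inclusive, rows$record_id,
                       seq_len(nrow(rows)), rows$intron_type, rows$location,
                       rows$taxon_code, rows$accession))
    writeLines(lines, path)
  }
  invisible(nrow(rows))
}

#' Write gene record sequences as FASTA
#'
#' @param records list of [gene_record()] objects.
#' @param path output FASTA file.
#' @return (invisibly) the number of sequences written.
#' @export
write_fasta <- function(records, path) {
  if (!length(records)) {
    file.create(path)
    return(invisible(0L))
  }
  x <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(x) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(x, path)
  invisible(length(x))
}

#' Read gene records from a GenBank flat file
#'
#' A minimal offline parser for GenBank flat files: one record per
#' `LOCUS`..`//` block, with `intron` features taken from the FEATURES table
#' and the sequence from ORIGIN. Only simple spans (optionally
#' `complement(..)`) are supported; `join()`/`order()` compound locations are
#' rejected. Records without any intron feature are skipped with a warning.
#' Metadata are populated from qualifiers where recognisable
#' (`/organelle`, `/note` mentioning the intron class), otherwise `"unknown"`.
#'
#' @param file path to the flat file.
#' @return list of [gene_record()] objects.
#' @export
read_genbank <- function(file) {
  lines <- readLines(file, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (!length(starts)) stop("no LOCUS line found: not a GenBank flat file")
  ends <- c(starts[-1L] - 1L, length(lines))
  records <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    rec <- parse_genbank_record(block)
    if (is.null(rec)) next
    records[[length(records) + 1L]] <- rec
  }
  records
}

parse_genbank_record <- function(block) {
  locus_tokens <- strsplit(trimws(block[1L]), "\\s+")[[1L]]
  id <- locus_tokens[2L]
  acc_line <- grep("^ACCESSION", block, value = TRUE)
  accession <- if (length(acc_line)) {
    strsplit(trimws(acc_line[1L]), "\\s+")[[1L]][2L] %||% id
  } else id
  if (is.na(accession)) accession <- id

  origin_at <- grep("^ORIGIN", block)
  seq <- ""
  if (length(origin_at)) {
    tail_lines <- block[(origin_at[1L] + 1L):length(block)]
    tail_lines <- tail_lines[!grepl("^//", tail_lines)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(tail_lines, collapse = "")))
  }
  if (!nzchar(seq)) stop(sprintf("record '%s' has no ORIGIN sequence", id))

  feat_at <- grep("^FEATURES", block)
  feat_end <- if (length(origin_at)) origin_at[1L] - 1L else length(block)
  introns <- data.frame(start = integer(), end = integer(),
                        minus = logical())
  intron_type <- "unknown"; location <- "unknown"; taxon_code <- "unknown"
  if (length(feat_at) && feat_end > feat_at[1L]) {
    feats <- block[(feat_at[1L] + 1L):feat_end]
    key_idx <- grep("^ {5}\\S", feats)
    for (fi in seq_along(key_idx)) {
      line <- feats[key_idx[fi]]
      key <- sub("^ {5}(\\S+).*$", "\\1", line)
      loc <- trimws(sub("^ {5}\\S+\\s*", "", line))
      qual_to <- if (fi < length(key_idx)) key_idx[fi + 1L] - 1L
                 else length(feats)
      quals <- if (qual_to > key_idx[fi]) {
        trimws(feats[(key_idx[fi] + 1L):qual_to])
      } else character()
      if (key == "source") {
        org <- grep("^/organelle=", quals, value = TRUE)
        if (length(org)) {
          ov <- tolower(org[1L])
          location <- if (grepl("mitochond", ov)) "mitochondrial"
                      else if (grepl("plastid|chloroplast", ov)) "plastid"
                      else "unknown"
        }
        next
      }
      if (key != "intron") next
      if (grepl("join\\(|order\\(", loc)) {
        stop(sprintf("record '%s': compound intron location not supported: %s",
                     id, loc))
      }
      m <- regmatches(loc, regexec("^(complement\\()?<?(\\d+)\\.\\.>?(\\d+)\\)?$",
                                   loc))[[1L]]
      if (!length(m)) {
        stop(sprintf("record '%s': cannot parse intron location '%s'", id, loc))
      }
      note <- tolower(paste(grep("^/note=", quals, value = TRUE),
                            collapse = " "))
      if (grepl("group ?iii|group ?3", note)) intron_type <- "group_III"
      else if (grepl("group ?ii|group ?2", note)) intron_type <- "group_II"
      else if (grepl("group ?i|group ?1", note)) intron_type <- "group_I"
      else if (grepl("spliceosom", note)) intron_type <- "spliceosomal"
      else if (grepl("archaeal", note)) intron_type <- "archaeal"
      introns <- rbind(introns, data.frame(
        start = as.integer(m[3L]) - 1L, end = as.integer(m[4L]),
        minus = nzchar(m[2L])
      ))
    }
  }
  if (!nrow(introns)) {
    warning(sprintf("record '%s' has no intron feature; skipped", id))
    return(NULL)
  }
  flip <- FALSE
  if (any(introns$minus)) {
    if (!all(introns$minus)) stop(sprintf("record '%s' mixes strands", id))
    n <- nchar(seq)
    seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    new_start <- n - introns$end
    introns$end <- n - introns$start
    introns$start <- new_start
    flip <- TRUE
  }
  gene_record(id = id, sequence = seq,
              introns = introns[, c("start", "end")],
              intron_type = intron_type, location = location,
              taxon_code = taxon_code, accession = accession,
              strand_flipped = flip)
}

# results table dialect -------------------------------------------------------

.result_cols <- c("record_id", "accession", "intron_type", "location",
                  "taxon_code", "intron_start", "intron_end", "dr_found",
                  "dr5_start", "dr5_end", "dr3_start", "dr3_end", "length",
                  "matches", "similarity", "loc5", "loc3", "d5", "d3",
                  "category", "relation", "delta")
.result_int_cols <- c("intron_start", "intron_end", "dr5_start", "dr5_end",
                      "dr3_start", "dr3_end", "length", "matches", "d5", "d3",
                      "delta")

empty_results <- function() {
  df <- data.frame(record_id = character(), accession = character(),
                   intron_type = character(), location = character(),
                   taxon_code = character(), intron_start = integer(),
                   intron_end = integer(), dr_found = logical(),
                   dr5_start = integer(), dr5_end = integer(),
                   dr3_start = integer(), dr3_end = integer(),
                   length = integer(), matches = integer(),
                   similarity = double(), loc5 = character(),
                   loc3 = character(), d5 = integer(), d3 = integer(),
                   category = character(), relation = character(),
                   delta = integer(), stringsAsFactors = FALSE)
  df[, .result_cols]
}

#' Write a per-intron results table
#'
#' Tab-separated, one row per intron, columns as documented for
#' [read_results()]. Gene coordinates are the internal 0-based half-open
#' convention; `similarity` is written with 17 significant digits so the
#' table round-trips exactly. Introns without a repeat pair carry `NA` in the
#' repeat fields.
#'
#' @param results results data.frame (from [scan_introns()] /
#'   [assemble_result()]) or a `dr_scan` object.
#' @param path destination file.
#' @return number of data rows written.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "dr_scan")) results <- results$results
  results <- as.data.frame(results)
  if (nrow(results) && !all(.result_cols %in% names(results))) {
    stop("`results` lacks required columns")
  }
  out <- if (nrow(results)) results[, .result_cols, drop = FALSE]
         else empty_results()
  out$similarity <- ifelse(is.na(out$similarity), NA,
                           sprintf("%.17g", out$similarity))
  tryCatch(
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA"),
    error = function(e) stop(sprintf("cannot write results to '%s': %s",
                                     path, conditionMessage(e)))
  )
  nrow(out)
}

#' Read back a results table written by [write_results()]
#'
#' @param path file written by [write_results()].
#' @return results data.frame (see [write_results()] for the column dialect).
#' @export
read_results <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", na.strings = "NA",
                   colClasses = "character", check.names = FALSE)
  if (!nrow(df)) {
    out <- empty_results()
    return(out)
  }
  for (col in .result_int_cols) df[[col]] <- as.integer(df[[col]])
  df$similarity <- as.double(df$similarity)
  df$dr_found <- df$dr_found == "TRUE"
  df[, .result_cols]
}
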