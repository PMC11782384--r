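#' Locate one repeat copy relative to its border
#'
#' A copy is `BORDER` when it straddles the border (at least one base on each
#' side); a copy ending exactly at the border lies wholly on one side and is
#' classed by that side. The distance is the number of bases strictly between
#' the nearest copy end and the border: 0 for straddling or abutting copies.
#' Which side is exon and which intron depends on the border: at the 5'
#' border the upstream side is exon, at the 3' border the upstream side is
#' intron.
#'
#' @param copy_span half-open `c(start, end)` span in window coordinates.
#' @param border_pos between-base border coordinate within the window.
#' @param border `"five_prime"` or `"three_prime"`.
#' @return list with `location` (`"EXON"`, `"BORDER"` or `"INTRON"`) and
#'   `distance` (bases, >= 0).
#' @export
locate_copy <- function(copy_span, border_pos,
                        border = c("five_prime", "three_prime")) {
  border <- match.arg(border)
  s <- as.integer(copy_span[1L]); e <- as.integer(copy_span[2L])
  if (is.na(s) || is.na(e) || e <= s) stop("empty copy span")
  b <- as.integer(border_pos)
  if (s < b && e > b) {
    return(list(location = "BORDER", distance = 0L))
  }
  if (e <= b) {   # upstream side
    loc <- if (border == "five_prime") "EXON" else "INTRON"
    return(list(location = loc, distance = b - e))
  }
  loc <- if (border == "five_prime") "INTRON" else "EXON"
  list(location = loc, distance = s - b)
}

# the categorical length relation is a pure function of the placement pair
.relation_map <- c(
  "BORDER|BORDER" = "INTRON_LENGTH",
  "INTRON|EXON"   = "INTRON_LENGTH",
  "EXON|INTRON"   = "INTRON_LENGTH",
  "BORDER|INTRON" = "SHORTER_THAN_INTRON",
  "INTRON|BORDER" = "SHORTER_THAN_INTRON",
  "INTRON|INTRON" = "SHORTER_THAN_INTRON",
  "EXON|BORDER"   = "LONGER_THAN_INTRON",
  "BORDER|EXON"   = "LONGER_THAN_INTRON",
  "EXON|EXON"     = "LONGER_THAN_INTRON"
)

.loc_labels <- c(EXON = "e", BORDER = "e/i", INTRON = "i")

#' All nine placement-pair categories
#'
#' @return data.frame with `loc5`, `loc3`, `category` (the serialized
#'   `"e|e/i"`-style label) and `relation`, in a fixed order.
#' @export
category_levels <- function() {
  pairs <- strsplit(names(.relation_map), "|", fixed = TRUE)
  data.frame(
    loc5 = vapply(pairs, `[`, "", 1L),
    loc3 = vapply(pairs, `[`, "", 2L),
    category = vapply(names(.relation_map), function(k) {
      p <- strsplit(k, "|", fixed = TRUE)[[1L]]
      paste(.loc_labels[p[1L]], .loc_labels[p[2L]], sep = "|")
    }, "", USE.NAMES = FALSE),
    relation = unname(.relation_map),
    stringsAsFactors = FALSE
  )
}

#' Categorize a repeat-copy placement pair
#'
#' Maps the two copy locations to one of nine categories and the implied
#' intron-length relation: repeat separations that approximate the intron
#' length (`INTRON_LENGTH`: border/border, intron/exon, exon/intron), fall
#' short of it (`SHORTER_THAN_INTRON`: border/intron, intron/border,
#' intron/intron), or exceed it (`LONGER_THAN_INTRON`: exon/border,
#' border/exon, exon/exon -- the classic flanking target-site-duplication
#' geometry).
#'
#' @param loc5,loc3 copy locations, `"EXON"`, `"BORDER"` or `"INTRON"`.
#' @return list with `category` (serialized label, e.g. `"e/i|i"`) and
#'   `relation`.
#' @export
categorize_pair <- function(loc5, loc3) {
  loc5 <- match.arg(loc5, c("EXON", "BORDER", "INTRON"))
  loc3 <- match.arg(loc3, c("EXON", "BORDER", "INTRON"))
  key <- paste(loc5, loc3, sep = "|")
  list(
    category = paste(.loc_labels[[loc5]], .loc_labels[[loc3]], sep = "|"),
    relation = unname(.relation_map[[key]])
  )
}

#' Assemble the per-intron result row
#'
#' Translates a window-coordinate alignment to gene coordinates, classifies
#' both copies, and computes the signed offset
#' `delta = (copy3_start - border3) - (copy5_start - border5)`: 0 when the
#' repeat separation equals the intron length exactly, negative when
#' shorter, positive when longer.
#'
#' @param gene a [gene_record()].
#' @param intron index of the intron in `gene$introns`.
#' @param alignment a `dr_alignment` from [find_best_dr()], or `NULL` when no
#'   repeat was found.
#' @param windows the window pair from [extract_border_windows()] that the
#'   alignment was computed from.
#' @return one-row data.frame in the results-table dialect (see
#'   [write_results()]).
#' @export
assemble_result <- function(gene, intron, alignment, windows) {
  stopifnot(inherits(gene, "gene_record"))
  s <- gene$introns$start[intron]; e <- gene$introns$end[intron]
  base <- data.frame(
    record_id = gene$id, accession = gene$accession,
    intron_type = gene$intron_type, location = gene$location,
    taxon_code = gene$taxon_code,
    intron_start = s, intron_end = e,
    dr_found = FALSE,
    dr5_start = NA_integer_, dr5_end = NA_integer_,
    dr3_start = NA_integer_, dr3_end = NA_integer_,
    length = NA_integer_, matches = NA_integer_, similarity = NA_real_,
    loc5 = NA_character_, loc3 = NA_character_,
    d5 = NA_integer_, d3 = NA_integer_,
    category = NA_character_, relation = NA_character_,
    delta = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (is.null(alignment)) return(base)
  stopifnot(inherits(alignment, "dr_alignment"))
  w5 <- windows$five_prime; w3 <- windows$three_prime

  g5 <- alignment$copy5_span + w5$gene_offset
  g3 <- alignment$copy3_span + w3$gene_offset
  n <- nchar(gene$sequence)
  if (g5[1L] < 0L || g5[2L] > n || g3[1L] < 0L || g3[2L] > n) {
    stop("alignment span translates outside gene bounds (coordinate bug)")
  }
  l5 <- locate_copy(alignment$copy5_span, w5$border_pos, "five_prime")
  l3 <- locate_copy(alignment$copy3_span, w3$border_pos, "three_prime")
  cat3 <- categorize_pair(l5$location, l3$location)

  base$dr_found <- TRUE
  base$dr5_start <- g5[1L]; base$dr5_end <- g5[2L]
  base$dr3_start <- g3[1L]; base$dr3_end <- g3[2L]
  base$length <- alignment$length
  base$matches <- alignment$matches
  base$similarity <- alignment$similarity
  base$loc5 <- .loc_labels[[l5$location]]
  base$loc3 <- .loc_labels[[l3$location]]
  base$d5 <- l5$distance; base$d3 <- l3$distance
  base$category <- cat3$category
  base$relation <- cat3$relation
  base$delta <- (g3[1L] - e) - (g5[1L] - s)
  base
}
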