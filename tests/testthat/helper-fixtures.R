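# fixtures are built in code at test time; nothing binary is shipped

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_window <- function(n, border = "five_prime", border_pos = n %/% 2) {
  border_window(rand_dna(n), border, border_pos)
}

# a gene with one intron and fully controlled content
make_gene <- function(exon5, intron, exon3, ...) {
  gene_record(
    id = "g1", sequence = paste0(exon5, intron, exon3),
    introns = data.frame(start = nchar(exon5),
                         end = nchar(exon5) + nchar(intron)),
    ...
  )
}

write_fasta_text <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

write_tsv_annotation <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

gff3_text <- function(rows) {
  c("##gff-version 3",
    sprintf("%s\t.\tintron\t%d\t%d\t.\t%s\t.\tID=i%d;intron_type=%s;location=%s;taxon_code=%s;accession=%s",
            rows$record_id, rows$start, rows$end, rows$strand,
            seq_len(nrow(rows)), rows$intron_type, rows$location,
            rows$taxon_code, rows$accession))
}

genbank_text <- function(id, seq, intron_locs, organelle = NULL) {
  n <- nchar(seq)
  feats <- c("FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", n))
  if (!is.null(organelle)) {
    feats <- c(feats, sprintf("                     /organelle=\"%s\"", organelle))
  }
  for (loc in intron_locs) {
    feats <- c(feats, sprintf("     intron          %s", loc))
  }
  chunks <- substring(seq, seq(1, n, 60), pmin(seq(1, n, 60) + 59, n))
  origin <- c("ORIGIN",
              sprintf("%9d %s", seq(1, n, 60), tolower(chunks)))
  c(sprintf("LOCUS       %s           %d bp    DNA", id, n),
    sprintf("ACCESSION   %s", id),
    feats, origin, "//")
}

expect_same_alignment <- function(a, b) {
  if (is.null(a) || is.null(b)) {
    expect_true(is.null(a) && is.null(b))
  } else {
    expect_identical(unclass(a), unclass(b))
  }
}
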