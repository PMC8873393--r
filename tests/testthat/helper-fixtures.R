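# small in-code fixtures shared across test files

# a minimal hand-built gene-model tibble (absolute coordinates, valid
# structure) for I/O and feature tests
tiny_models <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    biotype = c("mRNA", "annotated_lncRNA", "novel_lncRNA"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "*"),
    tx_start = c(101L, 5001L, 11L),
    tx_end = c(1100L, 5800L, 310L),
    exons = list(
      tibble::tibble(start = c(101L, 601L), end = c(400L, 1100L)),
      tibble::tibble(start = 5001L, end = 5800L),
      tibble::tibble(start = 11L, end = 310L)
    ),
    template_span = c(1000L, 800L, 300L),
    tx_length = c(800L, 800L, 300L),
    exon_count = c(2L, 1L, 1L),
    intron_count = c(1L, 0L, 0L),
    cds_length = c(600L, 0L, 0L)
  )
}

# brute-force BH over all ranks (independent of stats::p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) min(1, p[ord[j]] * m / j), numeric(1))
    adj[ord[i]] <- min(vals)
  }
  adj
}

# quadratic ORF oracle: every ATG, scan codon by codon to the first stop
orf_oracle <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  best <- 0L
  if (n < 6) {
    return(best)
  }
  for (f in 0:2) {
    ncod <- (n - f) %/% 3
    if (ncod < 2) next
    codons <- substring(s, f + 1 + 3 * (seq_len(ncod) - 1), f + 3 * seq_len(ncod))
    for (a in which(codons == "ATG")) {
      j <- a + 1L
      while (j <= ncod) {
        if (codons[j] %in% c("TAA", "TAG", "TGA")) {
          best <- max(best, 3L * (j - a))
          break
        }
        j <- j + 1L
      }
    }
  }
  best
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# map classifier output labels onto simulator truth labels
truth_label_map <- c(
  recovered = "repressed_recovered",
  not_recovered = "repressed_not_recovered",
  induced = "induced",
  unchanged = "unchanged",
  other = "other"
)

balanced_accuracy <- function(calls, truth_labels) {
  classes <- c(
    "induced", "repressed_not_recovered", "repressed_recovered", "unchanged"
  )
  mapped <- truth_label_map[calls]
  mean(vapply(classes, function(k) {
    sum(mapped == k & truth_labels == k) / sum(truth_labels == k)
  }, numeric(1)))
}

# a single-exon candidate transcript row for cascade tests
make_candidate <- function(id, chrom = "chr9", strand = "+", start = 1000L,
                           len = 500L, sequence = NULL) {
  if (is.null(sequence)) sequence <- strrep("C", len)
  tibble::tibble(
    transcript_id = id, chrom = chrom, strand = strand,
    tx_start = start, tx_end = start + len - 1L,
    exons = list(tibble::tibble(start = start, end = start + len - 1L)),
    tx_length = len, sequence = sequence
  )
}

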