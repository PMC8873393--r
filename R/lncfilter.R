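#' Stage 1: length and strand filter
#'
#' A candidate transcript passes when its exonic length is at least 200 nt
#' (the lncRNA size definition; the boundary is inclusive) and its strand
#' is determined (`"+"` or `"-"`; `"*"` marks uncertain direction and
#' fails).
#'
#' @param candidates Tibble with `transcript_id`, `tx_length`, `strand`.
#' @return Tibble `transcript_id`, `pass_length_strand`.
#' @export
filter_length_strand <- function(candidates) {
  tibble(
    transcript_id = candidates$transcript_id,
    pass_length_strand = candidates$tx_length >= 200 &
      candidates$strand %in% c("+", "-")
  )
}

# exon list-columns -> GRanges, one range per exon
exons_to_granges <- function(tbl, id_col = "transcript_id") {
  ex <- tidyr::unnest(tbl[, c(id_col, "chrom", "strand", "exons")], "exons")
  GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(ex$start, ex$end),
    strand = ex$strand,
    id = ex[[id_col]]
  )
}

#' Stage 2: annotated-exon overlap filter
#'
#' A candidate fails when any of its exons overlaps any reference exon by
#' at least one base (1-based closed intervals). By default only
#' same-strand overlap counts (candidates with strand `"*"` overlap either
#' strand); set `same_strand = FALSE` for strand-blind filtering.
#'
#' @param candidates Tibble with `transcript_id`, `chrom`, `strand`,
#'   `exons` (list column of `start`/`end` tibbles).
#' @param reference Gene-model tibble of annotated transcripts (same exon
#'   representation).
#' @param same_strand Restrict overlap to matching strands (default TRUE).
#' @return Tibble `transcript_id`, `pass_overlap`.
#' @export
filter_annotation_overlap <- function(candidates, reference,
                                      same_strand = TRUE) {
  cand <- exons_to_granges(candidates)
  ref <- exons_to_granges(reference, id_col = "gene_id")
  hits <- GenomicRanges::findOverlaps(
    cand, ref,
    minoverlap = 1L, ignore.strand = !same_strand
  )
  hit_ids <- unique(cand$id[S4Vectors::queryHits(hits)])
  tibble(
    transcript_id = candidates$transcript_id,
    pass_overlap = !candidates$transcript_id %in% hit_ids
  )
}

#' Stage 3: expression filter
#'
#' A candidate passes when its maximum FPKM across all samples reaches
#' `threshold` (default 0.5, inclusive).
#'
#' @param candidates Tibble with `transcript_id`.
#' @param fpkm FPKM tibble keyed by `gene_id` or `transcript_id` matching
#'   the candidates' `transcript_id`.
#' @param threshold Minimum maximum FPKM (>= 0).
#' @return Tibble `transcript_id`, `max_fpkm`, `pass_expression`.
#' @export
filter_expression <- function(candidates, fpkm, threshold = 0.5) {
  assert_scalar_number(threshold, "threshold", min = 0)
  id_col <- if ("transcript_id" %in% names(fpkm)) "transcript_id" else "gene_id"
  missing <- setdiff(candidates$transcript_id, fpkm[[id_col]])
  if (length(missing) > 0) {
    abort(paste0(
      "candidate(s) absent from the FPKM table: ",
      paste(head(missing, 10), collapse = ", ")
    ), class = "uvtx_input_error")
  }
  m <- as_count_matrix(fpkm, id_col = id_col)
  max_fpkm <- apply(m[candidates$transcript_id, , drop = FALSE], 1, max)
  tibble(
    transcript_id = candidates$transcript_id,
    max_fpkm = unname(max_fpkm),
    pass_expression = unname(max_fpkm) >= threshold
  )
}

# longest ATG..stop ORF (nt, stop codon excluded) over the three sense
# frames; linear scan per frame
longest_orf_nt <- function(seq) {
  n <- nchar(seq)
  if (n < 6) {
    return(0L)
  }
  s <- toupper(seq)
  best <- 0L
  for (f in 0:2) {
    ncod <- (n - f) %/% 3
    if (ncod < 2) next
    codons <- substring(s, f + 1 + 3 * (seq_len(ncod) - 1), f + 3 * seq_len(ncod))
    starts <- which(codons == "ATG")
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (length(starts) == 0 || length(stops) == 0) next
    prev_stop <- 0L
    si <- 1L
    for (st in stops) {
      while (si <= length(starts) && starts[si] <= prev_stop) si <- si + 1L
      if (si <= length(starts) && starts[si] < st) {
        best <- max(best, 3L * (st - starts[si]))
      }
      prev_stop <- st
    }
  }
  best
}

#' Stage 4: ORF-based coding potential
#'
#' A self-contained heuristic replacing external coding-potential
#' predictors: the longest ATG-to-stop open reading frame across the three
#' sense frames (stop codon excluded from the length) and its coverage of
#' the transcript. Verdicts: `noncoding` when the longest ORF is under
#' 300 nt; `coding` when it reaches 900 nt and covers at least 80% of the
#' transcript; `uncertain` otherwise (the TUCP class).
#'
#' @param sequence Character vector of sense-strand nucleotide sequences
#'   over `A`, `C`, `G`, `T`, `N` (case-insensitive). Empty sequences are
#'   scored noncoding with ORF 0.
#' @return Tibble with `longest_orf_nt`, `orf_coverage`, `verdict`, one
#'   row per input sequence.
#' @export
#' @examples
#' coding_potential(paste0("ATG", strrep("GCA", 400), "TAA"))
coding_potential <- function(sequence) {
  bad <- grepl("[^ACGTNacgtn]", sequence)
  if (any(bad)) {
    abort("sequences may only contain A, C, G, T, N",
      class = "uvtx_input_error"
    )
  }
  orf <- vapply(sequence, longest_orf_nt, integer(1), USE.NAMES = FALSE)
  len <- nchar(sequence)
  coverage <- ifelse(len > 0, orf / len, 0)
  verdict <- dplyr::case_when(
    orf < 300 ~ "noncoding",
    orf >= 900 & coverage >= 0.8 ~ "coding",
    TRUE ~ "uncertain"
  )
  tibble(longest_orf_nt = orf, orf_coverage = coverage, verdict = verdict)
}

#' Run the full lncRNA / TUCP identification cascade
#'
#' Applies the four stages in fixed order -- (1) length >= 200 nt and
#' determined strand, (2) no same-strand overlap with annotated exons,
#' (3) maximum FPKM >= 0.5, (4) ORF-based coding potential -- and assigns
#' the final class: `noncoding` verdicts become `novel_lncRNA`,
#' `uncertain` become `TUCP`, `coding` become `coding_discard`; candidates
#' failing stages 1-3 are `filtered_out` with later stage flags left `NA`.
#' Candidates are emitted in stable `transcript_id` order, so the output
#' is independent of input order.
#'
#' @param candidates Tibble with `transcript_id`, `chrom`, `strand`,
#'   `tx_length`, `exons` (list column) and `sequence`.
#' @param reference Annotated gene-model tibble (stage 2).
#' @param fpkm FPKM tibble covering the candidates (stage 3).
#' @param expression_threshold,same_strand Stage parameters.
#' @return Tibble with per-stage flags (`pass_length_strand`,
#'   `pass_overlap`, `pass_expression`), `max_fpkm`, `longest_orf_nt`,
#'   `orf_coverage`, `verdict` and `final_class`; the per-stage audit
#'   (tibble `stage`, `n_in`, `n_pass`) is attached as attribute
#'   `"audit"`, retrievable with [filter_audit()].
#' @export
classify_candidates <- function(candidates, reference, fpkm,
                                expression_threshold = 0.5,
                                same_strand = TRUE) {
  out <- candidates[order(candidates$transcript_id), , drop = FALSE]
  n0 <- nrow(out)
  if (n0 == 0) {
    res <- tibble(
      transcript_id = character(),
      pass_length_strand = logical(), pass_overlap = logical(),
      max_fpkm = numeric(), pass_expression = logical(),
      longest_orf_nt = integer(), orf_coverage = numeric(),
      verdict = character(), final_class = character()
    )
    attr(res, "audit") <- tibble(
      stage = c("length_strand", "annotation_overlap", "expression", "coding_potential"),
      n_in = rep(0L, 4), n_pass = rep(0L, 4)
    )
    return(res)
  }

  s1 <- filter_length_strand(out)
  out$pass_length_strand <- s1$pass_length_strand

  alive <- out$pass_length_strand
  out$pass_overlap <- NA
  if (any(alive)) {
    s2 <- filter_annotation_overlap(out[alive, ], reference,
      same_strand = same_strand
    )
    out$pass_overlap[alive] <- s2$pass_overlap
  }

  alive2 <- alive & !is.na(out$pass_overlap) & out$pass_overlap
  out$max_fpkm <- NA_real_
  out$pass_expression <- NA
  if (any(alive2)) {
    s3 <- filter_expression(out[alive2, ], fpkm,
      threshold = expression_threshold
    )
    out$max_fpkm[alive2] <- s3$max_fpkm
    out$pass_expression[alive2] <- s3$pass_expression
  }

  alive3 <- alive2 & !is.na(out$pass_expression) & out$pass_expression
  out$longest_orf_nt <- NA_integer_
  out$orf_coverage <- NA_real_
  out$verdict <- NA_character_
  if (any(alive3)) {
    s4 <- coding_potential(out$sequence[alive3])
    out$longest_orf_nt[alive3] <- s4$longest_orf_nt
    out$orf_coverage[alive3] <- s4$orf_coverage
    out$verdict[alive3] <- s4$verdict
  }

  out$final_class <- dplyr::case_when(
    !alive3 ~ "filtered_out",
    out$verdict == "noncoding" ~ "novel_lncRNA",
    out$verdict == "uncertain" ~ "TUCP",
    TRUE ~ "coding_discard"
  )

  audit <- tibble(
    stage = c(
      "length_strand", "annotation_overlap", "expression", "coding_potential"
    ),
    n_in = c(n0, sum(alive), sum(alive2), sum(alive3)),
    n_pass = c(sum(alive), sum(alive2), sum(alive3), sum(alive3))
  )
  attr(out, "audit") <- audit
  out
}

#' @rdname classify_candidates
#' @param classified Output of [classify_candidates()].
#' @export
filter_audit <- function(classified) {
  attr(classified, "audit")
}

#' Simulate transcript candidates for the filter cascade
#'
#' Random candidate transcripts with the failure modes the cascade
#' screens for: short transcripts, uncertain strands, exons overlapping a
#' reference annotation, low expression, and sequences with or without
#' substantial ORFs. Used to exercise [classify_candidates()] end to end.
#'
#' @param n Number of candidates.
#' @param reference Gene-model tibble the candidates may overlap.
#' @param seed Integer seed.
#' @param p_short,p_unknown_strand,p_overlap,p_low_expr,p_orf Failure-mode
#'   probabilities (independent).
#' @return List with `candidates` (tibble: `transcript_id`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, `exons`, `tx_length`, `sequence`) and
#'   `fpkm` (tibble `transcript_id` + two sample columns).
#' @export
simulate_candidates <- function(n, reference, seed = 1L,
                                p_short = 0.15, p_unknown_strand = 0.15,
                                p_overlap = 0.2, p_low_expr = 0.2,
                                p_orf = 0.3) {
  rows <- vector("list", n)
  fpkm1 <- numeric(n)
  fpkm2 <- numeric(n)
  ref_ex <- tidyr::unnest(
    reference[, c("gene_id", "chrom", "strand", "exons")], "exons"
  )
  max_end <- max(ref_ex$end)
  for (i in seq_len(n)) {
    rows[[i]] <- with_stream(stream_seed(seed, 606L, i), {
      len <- if (runif(1) < p_short) {
        sample(50:199, 1)
      } else {
        sample(200:3000, 1)
      }
      strand <- if (runif(1) < p_unknown_strand) {
        "*"
      } else if (runif(1) < 0.5) "+" else "-"
      overlaps <- runif(1) < p_overlap && nrow(ref_ex) > 0
      if (overlaps) {
        j <- sample.int(nrow(ref_ex), 1)
        chrom <- ref_ex$chrom[j]
        start <- max(1L, ref_ex$start[j] - sample(0:50, 1))
        if (strand != "*") strand <- ref_ex$strand[j]
      } else {
        chrom <- "chrU" # a chromosome absent from the reference
        start <- sample.int(max_end, 1)
      }
      end <- start + len - 1L
      low <- runif(1) < p_low_expr
      f1 <- if (low) runif(1, 0, 0.49) else runif(1, 0.5, 50)
      f2 <- runif(1, 0, 1) * f1
      seq_chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      sequence <- paste(seq_chars, collapse = "")
      if (runif(1) < p_orf && len >= 312) {
        ncodon <- sample(100:min(400, (len - 6) %/% 3), 1)
        aa <- sample(setdiff(
          apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
            c("A", "C", "G", "T")
          ), 1, paste, collapse = ""),
          c("TAA", "TAG", "TGA", "ATG")
        ), ncodon - 1, replace = TRUE)
        orf <- paste0("ATG", paste(aa, collapse = ""), "TAA")
        pos <- sample.int(len - nchar(orf) + 1, 1)
        sequence <- paste0(
          substr(sequence, 1, pos - 1), orf,
          substr(sequence, pos + nchar(orf), len)
        )
      }
      list(
        row = tibble(
          chrom = chrom, strand = strand,
          tx_start = as.integer(start), tx_end = as.integer(end),
          exons = list(tibble(start = as.integer(start), end = as.integer(end))),
          tx_length = as.integer(len),
          sequence = sequence
        ),
        f = c(f1, f2)
      )
    })
    fpkm1[i] <- rows[[i]]$f[1]
    fpkm2[i] <- rows[[i]]$f[2]
    rows[[i]] <- rows[[i]]$row
  }
  candidates <- dplyr::bind_rows(rows)
  candidates <- dplyr::bind_cols(
    tibble(transcript_id = sprintf("cand_%05d", seq_len(n))), candidates
  )
  list(
    candidates = candidates,
    fpkm = tibble(
      transcript_id = candidates$transcript_id,
      s1 = fpkm1, s2 = fpkm2
    )
  )
}
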