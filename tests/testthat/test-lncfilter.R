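test_that("length/strand filter enforces the 200 nt and known-strand rules", {
  cands <- dplyr::bind_rows(
    make_candidate("short", len = 199L),
    make_candidate("unknown", len = 200L, strand = "*"),
    make_candidate("ok", len = 200L, strand = "-")
  )
  out <- filter_length_strand(cands)
  expect_equal(out$pass_length_strand, c(FALSE, FALSE, TRUE))
})

test_that("annotation overlap is exonic, same-strand and 1-base sensitive", {
  # reference gene: exons [101,200] and [401,500] on chr1 '+'
  ref <- tibble::tibble(
    gene_id = "ref1", biotype = "mRNA", chrom = "chr1", strand = "+",
    tx_start = 101L, tx_end = 500L,
    exons = list(tibble::tibble(start = c(101L, 401L), end = c(200L, 500L))),
    template_span = 400L, tx_length = 200L,
    exon_count = 2L, intron_count = 1L, cds_length = 150L
  )
  cands <- dplyr::bind_rows(
    make_candidate("intronic", chrom = "chr1", start = 201L, len = 200L), # inside the intron
    make_candidate("onebase", chrom = "chr1", start = 500L, len = 250L), # exactly 1 bp on exon 2
    make_candidate("antisense", chrom = "chr1", strand = "-", start = 101L, len = 300L),
    make_candidate("elsewhere", chrom = "chr2", start = 101L, len = 300L)
  )
  out <- filter_annotation_overlap(cands, ref)
  expect_equal(out$pass_overlap, c(TRUE, FALSE, TRUE, TRUE))
  # strand-blind mode also removes the antisense overlap
  out2 <- filter_annotation_overlap(cands, ref, same_strand = FALSE)
  expect_equal(out2$pass_overlap, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("overlap filtering agrees with a brute-force interval scan", {
  ref <- generate_gene_models(
    sim_config(n_genes = c(mRNA = 60), seed = 44)
  )
  sim <- simulate_candidates(500, ref, seed = 44)
  cands <- sim$candidates
  out <- filter_annotation_overlap(cands, ref)

  ref_ex <- tidyr::unnest(ref[, c("chrom", "strand", "exons")], "exons")
  brute <- vapply(seq_len(nrow(cands)), function(i) {
    ce <- cands$exons[[i]]
    hit <- FALSE
    for (j in seq_len(nrow(ce))) {
      same_chrom <- ref_ex$chrom == cands$chrom[i]
      same_strand <- cands$strand[i] == "*" | ref_ex$strand == cands$strand[i]
      ov <- same_chrom & same_strand &
        ce$start[j] <= ref_ex$end & ref_ex$start <= ce$end[j]
      if (any(ov)) {
        hit <- TRUE
        break
      }
    }
    !hit
  }, logical(1))
  expect_equal(out$pass_overlap, brute)
})

test_that("expression filter is inclusive at the threshold", {
  cands <- dplyr::bind_rows(
    make_candidate("at", len = 300L),
    make_candidate("below", len = 300L),
    make_candidate("zero", len = 300L)
  )
  fpkm <- tibble::tibble(
    transcript_id = c("at", "below", "zero"),
    s1 = c(0.5, 0.49, 0), s2 = c(0.2, 0.1, 0)
  )
  out <- filter_expression(cands, fpkm)
  expect_equal(out$pass_expression, c(TRUE, FALSE, FALSE))
  expect_error(
    filter_expression(make_candidate("ghost"), fpkm),
    "ghost"
  )
})

test_that("ORF scoring matches constructed cases and the verdict bands", {
  # no start codon anywhere
  expect_equal(coding_potential("CCCCCCGGGTTT")$longest_orf_nt, 0)
  expect_equal(coding_potential("CCCCCCGGGTTT")$verdict, "noncoding")
  expect_equal(coding_potential("")$verdict, "noncoding")
  expect_error(coding_potential("ACGTX"), class = "uvtx_input_error")

  # ATG + 149 non-stop codons + TAA inside a 1000 nt transcript: ORF 450
  orf450 <- paste0("ATG", strrep("GCA", 149), "TAA")
  seq1 <- paste0(strrep("C", 300), orf450, strrep("C", 1000 - 300 - nchar(orf450)))
  got <- coding_potential(seq1)
  expect_equal(got$longest_orf_nt, 450)
  expect_equal(got$verdict, "uncertain")

  # 400-codon ORF (1200 nt) in a 1300 nt transcript: coverage 0.92 -> coding
  orf1200 <- paste0("ATG", strrep("GCA", 399))
  seq2 <- paste0(strrep("C", 50), orf1200, "TAA", strrep("C", 47))
  got2 <- coding_potential(seq2)
  expect_equal(got2$longest_orf_nt, 1200)
  expect_equal(got2$verdict, "coding")

  # long ORF with poor coverage stays uncertain
  seq3 <- paste0(strrep("C", 2000), orf1200, "TAA", strrep("C", 2000))
  expect_equal(coding_potential(seq3)$verdict, "uncertain")

  # an ORF without a stop codon does not count
  open_ended <- paste0(strrep("C", 9), "ATG", strrep("GCA", 200))
  expect_equal(coding_potential(open_ended)$longest_orf_nt, 0)
})

test_that("the ORF scanner agrees with the quadratic oracle", {
  set.seed(55)
  for (i in 1:300) {
    s <- random_dna(sample(30:400, 1))
    expect_equal(
      coding_potential(s)$longest_orf_nt, orf_oracle(s),
      info = paste0("seq ", i)
    )
  }
})

test_that("the cascade matches the set-intersection oracle with audit counts", {
  ref <- generate_gene_models(sim_config(n_genes = c(mRNA = 60), seed = 46))
  sim <- simulate_candidates(400, ref, seed = 46)
  out <- classify_candidates(sim$candidates, ref, sim$fpkm)
  audit <- filter_audit(out)

  p1 <- filter_length_strand(sim$candidates)$pass_length_strand
  p2 <- filter_annotation_overlap(sim$candidates, ref)$pass_overlap
  p3 <- filter_expression(sim$candidates, sim$fpkm)$pass_expression
  expect_equal(audit$n_in[1], 400L)
  expect_equal(audit$n_pass[1], sum(p1))
  expect_equal(audit$n_pass[2], sum(p1 & p2))
  expect_equal(audit$n_pass[3], sum(p1 & p2 & p3))
  expect_true(all(diff(audit$n_pass) <= 0))

  survivors <- sort(sim$candidates$transcript_id[p1 & p2 & p3])
  expect_equal(
    sort(out$transcript_id[out$final_class != "filtered_out"]),
    survivors
  )

  # verdict mapping on the survivors
  cp <- coding_potential(
    sim$candidates$sequence[match(survivors, sim$candidates$transcript_id)]
  )
  expected_class <- dplyr::case_when(
    cp$verdict == "noncoding" ~ "novel_lncRNA",
    cp$verdict == "uncertain" ~ "TUCP",
    TRUE ~ "coding_discard"
  )
  expect_equal(
    out$final_class[match(survivors, out$transcript_id)],
    expected_class
  )

  # stage flags after the first failure stay NA
  failed1 <- out$transcript_id[!out$pass_length_strand]
  expect_true(all(is.na(out$pass_overlap[match(failed1, out$transcript_id)])))
})

test_that("the cascade output is independent of candidate order", {
  ref <- generate_gene_models(sim_config(n_genes = c(mRNA = 30), seed = 47))
  sim <- simulate_candidates(120, ref, seed = 47)
  out1 <- classify_candidates(sim$candidates, ref, sim$fpkm)
  set.seed(1)
  shuffled <- sim$candidates[sample.int(nrow(sim$candidates)), ]
  out2 <- classify_candidates(shuffled, ref, sim$fpkm)
  expect_equal(as.data.frame(out1), as.data.frame(out2))
  expect_equal(filter_audit(out1), filter_audit(out2))
})

test_that("an empty candidate set yields an all-zero audit", {
  ref <- tiny_models()[1, ]
  empty <- make_candidate("x")[0, ]
  out <- classify_candidates(empty, ref, tibble::tibble(
    transcript_id = character(), s1 = numeric()
  ))
  expect_equal(nrow(out), 0)
  expect_true(all(filter_audit(out)$n_in == 0))
})
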