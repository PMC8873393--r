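#' Generate synthetic gene models
#'
#' Draws a gene annotation emulating the structure of a human RefSeq-style
#' catalogue: per-biotype log-normal genomic spans, shifted-geometric exon
#' counts (mRNAs average ~9-10 introns, lncRNAs are exon-poor with a large
#' single-exon class), log-normal exon sizes, and CDS lengths for mRNAs only.
#' Genes are laid out end to end (1 kb spacers) on a small set of synthetic
#' chromosomes so exon coordinates are genomically consistent.
#'
#' Every gene draws from its own counter-based RNG sub-stream derived from
#' `seed`, so increasing `n_genes` appends genes without perturbing the ones
#' already generated.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A tibble with one row per gene: `gene_id`, `biotype`, `chrom`,
#'   `strand` (`"+"`/`"-"`; `"*"` denotes unknown), `tx_start`, `tx_end`
#'   (1-based closed), `exons` (list column of tibbles with `start`, `end`),
#'   `template_span`, `tx_length`, `exon_count`, `intron_count`,
#'   `cds_length` (0 for noncoding biotypes).
#' @export
#' @examples
#' models <- generate_gene_models(sim_config(n_genes = c(mRNA = 5)), seed = 1)
#' models$template_span
generate_gene_models <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "uv_sim_config"))
  total <- sum(config$n_genes)
  if (total == 0) {
    return(tibble(
      gene_id = character(), biotype = character(), chrom = character(),
      strand = character(), tx_start = integer(), tx_end = integer(),
      exons = list(), template_span = integer(), tx_length = integer(),
      exon_count = integer(), intron_count = integer(), cds_length = integer()
    ))
  }

  biotype <- rep(names(config$n_genes), times = config$n_genes)
  abbrev <- c(
    mRNA = "mrna", annotated_lncRNA = "alnc",
    novel_lncRNA = "nlnc", TUCP = "tucp"
  )
  within <- unlist(lapply(config$n_genes, seq_len), use.names = FALSE)
  gene_id <- sprintf("%s_%05d", abbrev[biotype], within)

  rows <- vector("list", total)
  for (i in seq_len(total)) {
    bt <- biotype[i]
    rows[[i]] <- with_stream(stream_seed(seed, 101L, i), {
      span <- max(200L, as.integer(round(rlnorm(
        1, config$length_meanlog[bt], config$length_sdlog[bt]
      ))))
      k <- 1L + rgeom(1, config$exon_geom_prob[bt])
      # a span of S nt fits at most floor((S + 1) / 2) exons (1 nt each,
      # 1 nt introns); clamp k accordingly
      k <- min(k, (span + 1L) %/% 2L)
      structure_gene(span, k, bt, config)
    })
  }
  out <- dplyr::bind_rows(rows)
  out$gene_id <- gene_id
  out$biotype <- biotype

  out <- layout_genes(out)
  out[, c(
    "gene_id", "biotype", "chrom", "strand", "tx_start", "tx_end", "exons",
    "template_span", "tx_length", "exon_count", "intron_count", "cds_length"
  )]
}

# draw exon/intron structure for one gene inside an active RNG stream;
# offsets are relative (1-based within the gene) until layout_genes()
structure_gene <- function(span, k, bt, config) {
  strand <- if (runif(1) < 0.5) "+" else "-"
  if (k == 1L) {
    exon_len <- span
    starts <- 1L
    ends <- span
  } else {
    e <- pmax(1L, as.integer(round(rlnorm(k, log(150), 0.6))))
    budget <- span - (k - 1L) # room left after 1 nt minimum introns
    if (sum(e) > budget) {
      e <- pmax(1L, as.integer(floor(e * (budget / sum(e)))))
      while (sum(e) > budget) e[which.max(e)] <- e[which.max(e)] - 1L
    }
    slack <- span - sum(e) - (k - 1L) # extra intron nt to distribute
    introns <- rep(1L, k - 1L)
    if (slack > 0) {
      add <- as.vector(stats::rmultinom(1, slack, rep(1 / (k - 1L), k - 1L)))
      introns <- introns + add
    }
    starts <- integer(k)
    ends <- integer(k)
    pos <- 1L
    for (j in seq_len(k)) {
      starts[j] <- pos
      ends[j] <- pos + e[j] - 1L
      pos <- ends[j] + if (j < k) introns[j] + 1L else 1L
    }
    exon_len <- sum(e)
  }
  tx_length <- as.integer(exon_len)
  cds <- if (bt == "mRNA") {
    as.integer(min(tx_length, round(tx_length * runif(1, 0.4, 0.9))))
  } else {
    0L
  }
  tibble(
    strand = strand,
    exons = list(tibble(start = as.integer(starts), end = as.integer(ends))),
    template_span = as.integer(span),
    tx_length = tx_length,
    exon_count = as.integer(k),
    intron_count = as.integer(k - 1L),
    cds_length = cds
  )
}

# assign chromosomes round-robin and absolute coordinates end to end
layout_genes <- function(models, n_chrom = 5L, spacer = 1000L) {
  chrom <- paste0("chr", ((seq_len(nrow(models)) - 1L) %% n_chrom) + 1L)
  cursor <- setNames(rep(1L, n_chrom), paste0("chr", seq_len(n_chrom)))
  tx_start <- integer(nrow(models))
  tx_end <- integer(nrow(models))
  exons <- vector("list", nrow(models))
  for (i in seq_len(nrow(models))) {
    ch <- chrom[i]
    off <- cursor[ch]
    tx_start[i] <- off
    tx_end[i] <- off + models$template_span[i] - 1L
    ex <- models$exons[[i]]
    exons[[i]] <- tibble(
      start = ex$start + off - 1L,
      end = ex$end + off - 1L
    )
    cursor[ch] <- tx_end[i] + spacer + 1L
  }
  models$chrom <- chrom
  models$tx_start <- tx_start
  models$tx_end <- tx_end
  models$exons <- exons
  models
}

# validate the structural invariants of a gene-model tibble (used in tests
# and before serialisation)
check_gene_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    ex <- models$exons[[i]]
    stopifnot(
      nrow(ex) == models$exon_count[i],
      all(diff(ex$start) > 0),
      all(ex$end >= ex$start),
      all(head(ex$end, -1) < tail(ex$start, -1)),
      ex$start[1] == models$tx_start[i],
      ex$end[nrow(ex)] == models$tx_end[i],
      models$tx_length[i] == sum(ex$end - ex$start + 1),
      models$tx_length[i] <= models$template_span[i],
      models$cds_length[i] <= models$tx_length[i],
      models$biotype[i] == "mRNA" || models$cds_length[i] == 0,
      models$intron_count[i] == models$exon_count[i] - 1L
    )
  }
  invisible(TRUE)
}
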