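#' FPKM from a count table
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `FPKM(g, s) = counts(g, s) * 1e9 / (length_g * total_s)` with `total_s`
#' the column sum. The effective gene length is the exonic transcript
#' length (`tx_length`).
#'
#' @param counts Tibble `gene_id` + one numeric column per sample.
#' @param gene_lengths Either a gene-model tibble (its `tx_length` is
#'   used) or a named numeric vector of lengths in nt.
#' @return Tibble of the same shape with FPKM values.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", s1 = 10L)
#' compute_fpkm(counts, c(g1 = 1000)) # total = 10 reads -> FPKM = 1e6
compute_fpkm <- function(counts, gene_lengths) {
  if (is.data.frame(gene_lengths)) {
    gene_lengths <- setNames(gene_lengths$tx_length, gene_lengths$gene_id)
  }
  missing <- setdiff(counts$gene_id, names(gene_lengths))
  if (length(missing) > 0) {
    abort(paste0(
      "no length for gene(s): ",
      paste(head(missing, 5), collapse = ", ")
    ), class = "uvtx_input_error")
  }
  len <- gene_lengths[counts$gene_id]
  if (any(len <= 0)) {
    abort("gene lengths must be > 0", class = "uvtx_input_error")
  }
  m <- as_count_matrix(counts)
  if (any(m < 0)) abort("counts must be nonnegative", class = "uvtx_input_error")
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(paste0(
      "zero column sum for sample(s): ",
      paste(colnames(m)[totals == 0], collapse = ", ")
    ), class = "uvtx_input_error")
  }
  fpkm <- sweep(m * 1e9 / len, 2, totals, "/")
  matrix_to_tibble(fpkm)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed as the median, over genes
#' with nonzero counts in every sample, of the ratio of the gene's count
#' to its geometric mean across samples; factors are rescaled to geometric
#' mean 1.
#'
#' @param counts Tibble `gene_id` + numeric sample columns.
#' @param pseudocount Added to every count before taking ratios (default 0;
#'   set to a small positive value when no gene is nonzero in all samples).
#' @return Tibble with `sample_id` and `size_factor`.
#' @export
size_factors <- function(counts, pseudocount = 0) {
  m <- as_count_matrix(counts) + pseudocount
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep)) {
    abort(paste0(
      "no gene has nonzero counts in every sample; ",
      "consider `pseudocount = 0.5`"
    ), class = "uvtx_input_error")
  }
  lm <- log(m[keep, , drop = FALSE])
  logratio <- lm - rowMeans(lm)
  f <- exp(apply(logratio, 2, median))
  f <- f / exp(mean(log(f)))
  tibble(sample_id = colnames(m), size_factor = unname(f))
}

#' Expressed-gene filter
#'
#' A gene is retained when its maximum FPKM over the samples of at least
#' one fraction reaches `threshold` (default FPKM >= 1, the expressed-gene
#' criterion of the study design; the boundary is inclusive).
#'
#' @param fpkm FPKM tibble from [compute_fpkm()].
#' @param design Design tibble (`sample_id`, `fraction`).
#' @param threshold Minimum per-fraction maximum FPKM (>= 0).
#' @return Tibble of retained genes: `gene_id` plus one `max_fpkm_<fraction>`
#'   column per fraction.
#' @export
filter_expressed <- function(fpkm, design, threshold = 1) {
  assert_scalar_number(threshold, "threshold", min = 0)
  m <- as_count_matrix(fpkm)
  out <- tibble(gene_id = rownames(m))
  for (fr in unique(design$fraction)) {
    ids <- design$sample_id[design$fraction == fr]
    ids <- intersect(ids, colnames(m))
    out[[paste0("max_fpkm_", fr)]] <- if (length(ids)) {
      unname(apply(m[, ids, drop = FALSE], 1, max))
    } else {
      -Inf
    }
  }
  keep <- apply(as.matrix(out[, -1, drop = FALSE]), 1, max) >= threshold
  out[keep, , drop = FALSE]
}

#' Chromatin enrichment per gene
#'
#' The fractionation statistic: per gene, the ratio of mean chromatin FPKM
#' to mean cytoplasmic FPKM, each guarded by a pseudocount, optionally
#' restricted to a subset of timepoints (e.g. untreated only) or pooled
#' over all (the default).
#'
#' @param fpkm FPKM tibble.
#' @param design Design tibble.
#' @param genes Optional gene-model tibble; adds a `biotype` column.
#' @param pseudocount Added to both means (default 0.1 FPKM). Set
#'   `drop_zero = TRUE` to instead drop genes with zero cytoplasmic mean.
#' @param timepoints Optional numeric vector restricting the samples used.
#' @param drop_zero Drop zero-cytoplasm genes instead of guarding with the
#'   pseudocount.
#' @return Tibble with `gene_id`, `mean_chromatin`, `mean_cytoplasm`,
#'   `fold`, `log2_fold` and (if `genes` given) `biotype`.
#' @export
chromatin_enrichment <- function(fpkm, design, genes = NULL,
                                 pseudocount = 0.1, timepoints = NULL,
                                 drop_zero = FALSE) {
  assert_scalar_number(pseudocount, "pseudocount", min = 0, strict = !drop_zero)
  if (!is.null(timepoints)) design <- design[design$timepoint %in% timepoints, ]
  m <- as_count_matrix(fpkm)
  ids_chr <- intersect(design$sample_id[design$fraction == "chromatin"], colnames(m))
  ids_cyt <- intersect(design$sample_id[design$fraction == "cytoplasm"], colnames(m))
  if (length(ids_chr) == 0 || length(ids_cyt) == 0) {
    abort("need samples from both fractions", class = "uvtx_input_error")
  }
  out <- tibble(
    gene_id = rownames(m),
    mean_chromatin = unname(rowMeans(m[, ids_chr, drop = FALSE])),
    mean_cytoplasm = unname(rowMeans(m[, ids_cyt, drop = FALSE]))
  )
  if (drop_zero) out <- out[out$mean_cytoplasm > 0, ]
  out$fold <- (out$mean_chromatin + pseudocount) /
    (out$mean_cytoplasm + pseudocount)
  out$log2_fold <- log2(out$fold)
  if (!is.null(genes)) {
    out <- dplyr::left_join(out, genes[, c("gene_id", "biotype")], by = "gene_id")
  }
  out
}

#' Per-biotype enrichment summary
#'
#' Quartiles of the chromatin/cytoplasm fold per biotype plus a two-sample
#' t test (Welch by default) on log2 folds of each biotype against a
#' reference biotype.
#'
#' @param enrichment Output of [chromatin_enrichment()] with a `biotype`
#'   column.
#' @param reference Reference biotype for the t tests (default `"mRNA"`).
#' @param var.equal Use the pooled-variance t test instead of Welch.
#' @return Tibble with one row per biotype: `n`, `q1`, `median`, `q3` of
#'   `fold`, `median_log2_fold`, and `t_statistic` / `p_value` against the
#'   reference (`NA` for the reference row).
#' @export
summarize_enrichment <- function(enrichment, reference = "mRNA",
                                 var.equal = FALSE) {
  if (!"biotype" %in% names(enrichment)) {
    abort("`enrichment` needs a biotype column (pass `genes` to chromatin_enrichment)",
      class = "uvtx_input_error"
    )
  }
  ref <- enrichment$log2_fold[enrichment$biotype == reference]
  enrichment |>
    dplyr::group_by(.data$biotype) |>
    dplyr::summarise(
      n = dplyr::n(),
      q1 = stats::quantile(.data$fold, 0.25),
      median = stats::median(.data$fold),
      q3 = stats::quantile(.data$fold, 0.75),
      median_log2_fold = stats::median(.data$log2_fold),
      t_statistic = if (dplyr::first(.data$biotype) == reference ||
        length(ref) < 2 || dplyr::n() < 2) {
        NA_real_
      } else {
        unname(t.test(.data$log2_fold, ref, var.equal = var.equal)$statistic)
      },
      p_value = if (dplyr::first(.data$biotype) == reference ||
        length(ref) < 2 || dplyr::n() < 2) {
        NA_real_
      } else {
        t.test(.data$log2_fold, ref, var.equal = var.equal)$p.value
      },
      .groups = "drop"
    )
}
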