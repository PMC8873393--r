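#' Method-of-moments negative-binomial dispersion
#'
#' Per gene, on normalized counts: `alpha_raw = max(0, (v - m) / m^2)` with
#' `m` the pooled mean and `v` the pooled within-group variance over groups
#' with at least two replicates; the estimate is then shrunk 50/50 toward
#' the trimmed mean (10% each tail) of `alpha_raw` across genes.
#'
#' @param norm_counts Tibble `gene_id` + normalized sample columns, or a
#'   numeric matrix with gene rownames.
#' @param groups Character/factor vector of group labels, one per sample
#'   column.
#' @return Tibble with `gene_id`, `dispersion_raw`, `dispersion`.
#' @export
estimate_dispersion <- function(norm_counts, groups) {
  m <- if (is.data.frame(norm_counts)) as_count_matrix(norm_counts) else norm_counts
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(m))
  tab <- table(groups)
  usable <- names(tab)[tab >= 2]
  if (length(usable) == 0) {
    abort("all groups are singletons; dispersion needs replicates",
      class = "uvtx_input_error"
    )
  }
  cols <- groups %in% usable
  mm <- m[, cols, drop = FALSE]
  g <- groups[cols]
  group_means <- vapply(
    unique(g),
    function(k) rowMeans(mm[, g == k, drop = FALSE]), numeric(nrow(mm))
  )
  group_vars <- vapply(
    unique(g),
    function(k) apply(mm[, g == k, drop = FALSE], 1, stats::var),
    numeric(nrow(mm))
  )
  dfs <- vapply(unique(g), function(k) sum(g == k) - 1, numeric(1))
  pooled_var <- as.vector(group_vars %*% dfs / sum(dfs))
  pooled_mean <- rowMeans(mm)
  raw <- unname(ifelse(pooled_mean > 0,
    pmax(0, (pooled_var - pooled_mean) / pooled_mean^2), 0
  ))
  target <- mean(raw, trim = 0.1)
  tibble(
    gene_id = rownames(m),
    dispersion_raw = raw,
    dispersion = 0.5 * raw + 0.5 * target
  )
}

#' Negative-binomial Wald test of two groups
#'
#' Self-contained stand-in for a GLM-based NB test: the statistic is the
#' log2 ratio of pseudocount-guarded normalized group means,
#' `log2fc = log2((muB + eps) / (muA + eps))`, with delta-method standard
#' error `SE^2 = (1/ln 2)^2 * [(1/(muA + eps) + alpha)/nA +
#' (1/(muB + eps) + alpha)/nB]` and a two-sided normal p value. No fold
#' change shrinkage is applied. Genes with both means zero get
#' `log2fc = 0`, `p = 1`.
#'
#' @param group_a,group_b Normalized counts: numeric vectors (one gene) or
#'   genes x replicates matrices with aligned rows.
#' @param dispersion Per-gene NB dispersion alpha (recycled if scalar).
#' @param epsilon Pseudocount on normalized means (default 0.5).
#' @return Tibble with `gene_id` (if rownames present), `base_mean_a`,
#'   `base_mean_b`, `log2fc`, `p_value`.
#' @export
#' @examples
#' nb_wald_test(c(100, 110, 90), c(210, 190, 200), dispersion = 0.05)
nb_wald_test <- function(group_a, group_b, dispersion, epsilon = 0.5) {
  if (is.vector(group_a)) group_a <- matrix(group_a, nrow = 1)
  if (is.vector(group_b)) group_b <- matrix(group_b, nrow = 1)
  stopifnot(nrow(group_a) == nrow(group_b))
  if (ncol(group_a) == 0 || ncol(group_b) == 0) {
    abort("both groups must be nonempty", class = "uvtx_input_error")
  }
  if (any(dispersion < 0)) {
    abort("`dispersion` must be >= 0", class = "uvtx_input_error")
  }
  alpha <- rep_len(dispersion, nrow(group_a))
  mu_a <- unname(rowMeans(group_a))
  mu_b <- unname(rowMeans(group_b))
  n_a <- ncol(group_a)
  n_b <- ncol(group_b)
  log2fc <- log2((mu_b + epsilon) / (mu_a + epsilon))
  se2 <- (1 / log(2))^2 *
    ((1 / (mu_a + epsilon) + alpha) / n_a + (1 / (mu_b + epsilon) + alpha) / n_b)
  z <- log2fc / sqrt(se2)
  p <- 2 * pnorm(-abs(z))
  both_zero <- mu_a == 0 & mu_b == 0
  log2fc[both_zero] <- 0
  p[both_zero] <- 1
  out <- tibble(
    base_mean_a = mu_a, base_mean_b = mu_b,
    log2fc = log2fc, p_value = p
  )
  if (!is.null(rownames(group_a))) {
    out <- dplyr::bind_cols(tibble(gene_id = rownames(group_a)), out)
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `padj_(i) = min over j >= i of
#' min(1, p_(j) * m / j)` in sort order, returned in the original order.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(p) {
  if (length(p) == 0) {
    return(numeric(0))
  }
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p values must lie in [0, 1]", class = "uvtx_input_error")
  }
  p.adjust(p, method = "BH")
}

#' Differential-expression calls
#'
#' Applies the study's call thresholds: `up` when `log2fc >= lfc_threshold`
#' and `padj < padj_threshold`; `down` when `log2fc <= -lfc_threshold` and
#' `padj < padj_threshold`; otherwise `ns`. The fold-change bound is
#' inclusive, the adjusted-p bound strict.
#'
#' @param results Tibble with `log2fc` and `padj` columns.
#' @param lfc_threshold Absolute log2 fold-change threshold (> 0).
#' @param padj_threshold Adjusted-p threshold (> 0).
#' @return `results` with a `status` column (`"up"`, `"down"`, `"ns"`).
#' @export
call_de <- function(results, lfc_threshold = 1, padj_threshold = 0.05) {
  assert_scalar_number(lfc_threshold, "lfc_threshold", min = 0, strict = TRUE)
  assert_scalar_number(padj_threshold, "padj_threshold", min = 0, strict = TRUE)
  results$status <- dplyr::case_when(
    results$log2fc >= lfc_threshold & results$padj < padj_threshold ~ "up",
    results$log2fc <= -lfc_threshold & results$padj < padj_threshold ~ "down",
    TRUE ~ "ns"
  )
  results
}

#' Per-fraction, per-timepoint differential expression versus baseline
#'
#' The full DE pipeline: within each fraction, counts are normalized by
#' median-of-ratios size factors, a per-gene NB dispersion is estimated
#' across the timepoint groups, each post-baseline timepoint is tested
#' against the untreated baseline with the NB Wald test, p values are
#' BH-adjusted within each (fraction, contrast) family, and the call
#' thresholds applied.
#'
#' @param counts Counts tibble (`gene_id` + sample columns).
#' @param design Design tibble (`sample_id`, `fraction`, `timepoint`,
#'   `replicate`).
#' @param baseline Baseline timepoint (default 0).
#' @param lfc_threshold,padj_threshold Call thresholds (see [call_de()]).
#' @param epsilon Pseudocount for the Wald statistic.
#' @param size_factor_pseudocount Passed to [size_factors()].
#' @return Tibble with `gene_id`, `fraction`, `timepoint`, `base_mean_a`,
#'   `base_mean_b`, `log2fc`, `p_value`, `padj`, `status`; one row per
#'   gene x fraction x post-baseline timepoint.
#' @export
de_table <- function(counts, design, baseline = 0,
                     lfc_threshold = 1, padj_threshold = 0.05,
                     epsilon = 0.5, size_factor_pseudocount = 0) {
  stopifnot(all(sample_columns(counts) %in% design$sample_id))
  out <- list()
  for (fr in unique(design$fraction)) {
    des <- design[design$fraction == fr & design$sample_id %in% names(counts), ]
    if (!baseline %in% des$timepoint) {
      abort(sprintf("fraction %s has no baseline (t = %g) samples", fr, baseline),
        class = "uvtx_input_error"
      )
    }
    sub <- counts[, c("gene_id", des$sample_id)]
    sf <- size_factors(sub, pseudocount = size_factor_pseudocount)
    m <- as_count_matrix(sub)
    norm <- sweep(m, 2, sf$size_factor[match(colnames(m), sf$sample_id)], "/")
    disp <- estimate_dispersion(norm, groups = as.character(des$timepoint))
    base_cols <- des$sample_id[des$timepoint == baseline]
    for (tp in sort(setdiff(unique(des$timepoint), baseline))) {
      tp_cols <- des$sample_id[des$timepoint == tp]
      res <- nb_wald_test(
        norm[, base_cols, drop = FALSE],
        norm[, tp_cols, drop = FALSE],
        dispersion = disp$dispersion,
        epsilon = epsilon
      )
      res$fraction <- fr
      res$timepoint <- tp
      res$padj <- bh_adjust(res$p_value)
      out[[length(out) + 1]] <- res
    }
  }
  res <- dplyr::bind_rows(out)
  res <- call_de(res,
    lfc_threshold = lfc_threshold,
    padj_threshold = padj_threshold
  )
  res[, c(
    "gene_id", "fraction", "timepoint", "base_mean_a", "base_mean_b",
    "log2fc", "p_value", "padj", "status"
  )]
}
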