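#' Binned feature histogram
#'
#' Counts values into fixed-width bins `[b*w, (b+1)*w)`; empty bins inside
#' the occupied range are emitted with count 0 so distributions plot as
#' continuous size-class curves (e.g. CDS sizes in 100 bp increments, or
#' intron counts with binwidth 1).
#'
#' @param values Nonnegative numeric vector.
#' @param binwidth Bin width (> 0).
#' @return Tibble with `bin_start`, `bin_end` (half-open), `count`.
#' @export
#' @examples
#' feature_histogram(c(50, 150, 150), binwidth = 100)
feature_histogram <- function(values, binwidth) {
  assert_scalar_number(binwidth, "binwidth", min = 0, strict = TRUE)
  if (length(values) == 0) {
    return(tibble(bin_start = numeric(0), bin_end = numeric(0), count = integer(0)))
  }
  if (any(values < 0)) {
    abort("`values` must be nonnegative", class = "uvtx_input_error")
  }
  b <- floor(values / binwidth)
  bins <- seq(min(b), max(b))
  counts <- vapply(bins, function(k) sum(b == k), integer(1))
  tibble(
    bin_start = bins * binwidth,
    bin_end = (bins + 1) * binwidth,
    count = counts
  )
}

FEATURES <- c("cds_length", "tx_length", "mean_exon_length", "intron_count")

# per-row feature table used by summarize_groups
feature_values <- function(models) {
  tibble(
    gene_id = models$gene_id,
    cds_length = as.numeric(models$cds_length),
    tx_length = as.numeric(models$tx_length),
    mean_exon_length = models$tx_length / models$exon_count,
    intron_count = as.numeric(models$intron_count),
    exon_count = as.numeric(models$exon_count)
  )
}

#' Compare gene-structure features between groups
#'
#' For each group of genes: mean and median CDS length, transcript length,
#' mean exon length and intron count, the single-exon fraction, and a
#' two-sided t test (Welch by default) of every feature against a
#' reference group -- the comparison behind recovered-versus-not-recovered
#' feature analyses.
#'
#' @param groups Tibble with `gene_id` and `group` columns; groups may
#'   overlap.
#' @param models Gene-model tibble. Multiple rows per `gene_id` are
#'   treated as isoforms.
#' @param reference Reference group for the t tests (default: first group
#'   in order of appearance).
#' @param isoform_mode `"per_gene"` (one row per gene: the longest-CDS
#'   isoform) or `"per_isoform"` (every annotated isoform counted).
#' @param var.equal Pooled-variance t test instead of Welch.
#' @return Tibble, one row per group: `group`, `n`, `mean_` / `median_`
#'   columns per feature, `single_exon_fraction`, and `p_<feature>`
#'   against the reference (`NA` on the reference row).
#' @export
summarize_groups <- function(groups, models, reference = NULL,
                             isoform_mode = c("per_gene", "per_isoform"),
                             var.equal = FALSE) {
  isoform_mode <- match.arg(isoform_mode)
  unknown <- setdiff(groups$gene_id, models$gene_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "unknown gene id(s): ",
      paste(head(unknown, 10), collapse = ", ")
    ), class = "uvtx_input_error")
  }
  feats <- feature_values(models)
  if (isoform_mode == "per_gene") {
    feats <- feats |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::arrange(dplyr::desc(.data$cds_length), .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  }
  joined <- dplyr::inner_join(groups, feats,
    by = "gene_id", relationship = "many-to-many"
  )
  grps <- unique(groups$group)
  if (is.null(reference)) reference <- grps[1]
  if (!reference %in% grps) {
    abort(paste0("reference group not present: ", reference),
      class = "uvtx_input_error"
    )
  }
  ref_rows <- joined[joined$group == reference, ]
  out <- vector("list", length(grps))
  for (i in seq_along(grps)) {
    g <- joined[joined$group == grps[i], ]
    row <- tibble(group = grps[i], n = nrow(g))
    for (f in FEATURES) {
      row[[paste0("mean_", f)]] <- mean(g[[f]])
      row[[paste0("median_", f)]] <- median(g[[f]])
    }
    row$single_exon_fraction <- mean(g$exon_count == 1)
    for (f in FEATURES) {
      row[[paste0("p_", f)]] <- if (grps[i] == reference ||
        nrow(g) < 2 || nrow(ref_rows) < 2 ||
        (sd(g[[f]]) == 0 && sd(ref_rows[[f]]) == 0)) {
        NA_real_
      } else {
        t.test(g[[f]], ref_rows[[f]], var.equal = var.equal)$p.value
      }
    }
    out[[i]] <- row
  }
  dplyr::bind_rows(out)
}
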