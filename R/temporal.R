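#' Mean temporal expression profiles
#'
#' Per gene and fraction, the mean `log2(FPKM + 1)` across replicates at
#' each timepoint, in wide form ready for [cluster_profiles()].
#'
#' @param fpkm FPKM tibble.
#' @param design Design tibble.
#' @param fraction Which fraction to profile.
#' @return Tibble `gene_id` + one `t<timepoint>` column per timepoint.
#' @export
temporal_profiles <- function(fpkm, design, fraction = "chromatin") {
  des <- design[design$fraction == fraction & design$sample_id %in% names(fpkm), ]
  if (nrow(des) == 0) {
    abort(paste0("no samples for fraction ", fraction), class = "uvtx_input_error")
  }
  m <- as_count_matrix(fpkm[, c("gene_id", des$sample_id)])
  out <- tibble(gene_id = rownames(m))
  for (tp in sort(unique(des$timepoint))) {
    cols <- des$sample_id[des$timepoint == tp]
    out[[sprintf("t%g", tp)]] <- unname(log2(rowMeans(m[, cols, drop = FALSE]) + 1))
  }
  out
}

#' Classify post-UV recovery from DE statuses
#'
#' Applies the temporal definitions to the per-timepoint DE statuses of
#' each gene (three post-exposure timepoints: immediate ~0.5 h, early
#' ~3 h, late ~24 h):
#' \itemize{
#'   \item `not_recovered`: down at the late timepoint, and already down
#'     at the immediate or early one ("never restored").
#'   \item `recovered`: down at the immediate timepoint but no longer down
#'     at the late one; `recovery_time` is the early timepoint when the
#'     gene is already restored there, otherwise the late one.
#'   \item `induced`: up at one or more timepoints and never down.
#'   \item `unchanged`: not significant throughout.
#'   \item `other`: any remaining pattern (e.g. repression appearing only
#'     at the late timepoint, or restored then repressed again).
#' }
#'
#' @param de DE tibble from [de_table()] (`gene_id`, `fraction`,
#'   `timepoint`, `status`).
#' @param timepoints The three post-exposure timepoints in increasing
#'   order (immediate, early, late).
#' @return Tibble with `gene_id`, `fraction`, `label`, `recovery_time`
#'   (`NA` unless recovered).
#' @export
#' @examples
#' de <- tibble::tibble(
#'   gene_id = "g1", fraction = "chromatin",
#'   timepoint = c(0.5, 3, 24), status = c("down", "ns", "ns")
#' )
#' classify_recovery(de)
classify_recovery <- function(de, timepoints = c(0.5, 3, 24)) {
  stopifnot(length(timepoints) == 3, all(diff(timepoints) > 0))
  de <- de[de$timepoint %in% timepoints, ]
  wide <- tidyr::pivot_wider(
    de[, c("gene_id", "fraction", "timepoint", "status")],
    names_from = "timepoint", values_from = "status"
  )
  tp_cols <- as.character(timepoints)
  if (!all(tp_cols %in% names(wide)) || anyNA(wide[tp_cols])) {
    abort(paste0(
      "statuses required at all of t = ",
      paste(timepoints, collapse = ", ")
    ), class = "uvtx_input_error")
  }
  s_imm <- wide[[tp_cols[1]]]
  s_early <- wide[[tp_cols[2]]]
  s_late <- wide[[tp_cols[3]]]
  any_down <- s_imm == "down" | s_early == "down" | s_late == "down"
  any_up <- s_imm == "up" | s_early == "up" | s_late == "up"
  label <- dplyr::case_when(
    s_late == "down" & (s_imm == "down" | s_early == "down") ~ "not_recovered",
    s_imm == "down" & s_late != "down" ~ "recovered",
    any_up & !any_down ~ "induced",
    s_imm == "ns" & s_early == "ns" & s_late == "ns" ~ "unchanged",
    TRUE ~ "other"
  )
  recovery_time <- dplyr::if_else(
    label == "recovered",
    dplyr::if_else(s_early != "down", timepoints[2], timepoints[3]),
    NA_real_
  )
  tibble(
    gene_id = wide$gene_id,
    fraction = wide$fraction,
    label = label,
    recovery_time = recovery_time
  )
}

# k-means++ seeding (Arthur & Vassilvitskii) inside the caller's RNG state
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1, prob = prob)
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
    }
  }
  centers
}

#' Cluster temporal profiles
#'
#' k-means (Lloyd iterations via [stats::kmeans()]) on row-z-scored
#' profiles with k-means++ initialisation, best of `restarts` runs by
#' within-cluster sum of squares. Rows with zero variance z-score to
#' all-zero profiles. Deterministic given `seed`.
#'
#' @param profiles Tibble `gene_id` + numeric profile columns (e.g. from
#'   [temporal_profiles()]).
#' @param k Number of clusters (>= 1, <= number of profiles).
#' @param seed Integer seed.
#' @param restarts Number of independent initialisations (>= 1).
#' @return Object of class `uv_clusters`: list with `k`, `assignments`
#'   (tibble `gene_id`, `cluster`), `centroids` (k x timepoints matrix, on
#'   the z-score scale), `inertia`, `sizes`, `profile_cols`.
#' @export
cluster_profiles <- function(profiles, k, seed = 1L, restarts = 50L) {
  x <- as_count_matrix(profiles)
  if (k < 1 || k != round(k)) {
    abort("`k` must be a positive integer", class = "uvtx_config_error")
  }
  if (k > nrow(x)) {
    abort("`k` exceeds the number of profiles", class = "uvtx_config_error")
  }
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  z <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0

  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_stream(stream_seed(seed, 505L, r), {
      centers <- kmeanspp_centers(z, k)
      centers <- centers[!duplicated(round(centers, 12)), , drop = FALSE]
      suppressWarnings(
        kmeans(z, centers = centers, iter.max = 100, algorithm = "Lloyd")
      )
    })
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  structure(
    list(
      k = as.integer(nrow(best$centers)),
      assignments = tibble(
        gene_id = rownames(z),
        cluster = as.integer(best$cluster)
      ),
      centroids = best$centers,
      inertia = best$tot.withinss,
      sizes = as.integer(best$size),
      profile_cols = colnames(x)
    ),
    class = "uv_clusters"
  )
}

#' @export
print.uv_clusters <- function(x, ...) {
  cat(sprintf(
    "<uv_clusters> k = %d, n = %d, inertia = %.3f\n",
    x$k, nrow(x$assignments), x$inertia
  ))
  invisible(x)
}

#' @method tidy uv_clusters
#' @export
tidy.uv_clusters <- function(x, ...) {
  out <- as_tibble(x$centroids)
  names(out) <- x$profile_cols
  out <- dplyr::bind_cols(
    tibble(cluster = seq_len(x$k), size = x$sizes), out
  )
  tidyr::pivot_longer(out, -c("cluster", "size"),
    names_to = "timepoint", values_to = "centroid"
  )
}

#' @method glance uv_clusters
#' @export
glance.uv_clusters <- function(x, ...) {
  tibble(k = x$k, n = nrow(x$assignments), inertia = x$inertia)
}

#' @method augment uv_clusters
#' @export
augment.uv_clusters <- function(x, data, ...) {
  dplyr::left_join(data, x$assignments, by = "gene_id")
}

#' Sample-level PCA
#'
#' Principal components of the samples: genes are variables, samples are
#' observations; the gene dimensions are mean-centred (no scaling) and
#' decomposed by SVD ([stats::prcomp()]).
#'
#' @param expr Expression tibble `gene_id` + sample columns (typically
#'   `log2(FPKM + 1)`).
#' @param design Optional design tibble joined onto the scores.
#' @return Object of class `uv_pca`: list with `scores` (tibble
#'   `sample_id`, `PC1`, ..., plus design columns), `var_explained`
#'   (named numeric, non-increasing), `sdev`.
#' @export
pca_samples <- function(expr, design = NULL) {
  m <- as_count_matrix(expr)
  if (ncol(m) < 2) {
    abort("PCA needs at least 2 samples", class = "uvtx_input_error")
  }
  fit <- prcomp(t(m), center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  keep <- seq_len(min(ncol(fit$x), ncol(m) - 1))
  scores <- as_tibble(fit$x[, keep, drop = FALSE])
  scores <- dplyr::bind_cols(tibble(sample_id = colnames(m)), scores)
  if (!is.null(design)) scores <- dplyr::left_join(scores, design, by = "sample_id")
  structure(
    list(
      scores = scores,
      var_explained = setNames(ve[keep], paste0("PC", keep)),
      sdev = fit$sdev[keep]
    ),
    class = "uv_pca"
  )
}

#' @export
print.uv_pca <- function(x, ...) {
  cat(sprintf(
    "<uv_pca> %d samples; PC1 %.1f%%, PC2 %.1f%%\n",
    nrow(x$scores), 100 * x$var_explained[1],
    if (length(x$var_explained) > 1) 100 * x$var_explained[2] else NA
  ))
  invisible(x)
}

#' @method tidy uv_pca
#' @export
tidy.uv_pca <- function(x, ...) x$scores

#' @method glance uv_pca
#' @export
glance.uv_pca <- function(x, ...) {
  tibble(
    component = names(x$var_explained),
    var_explained = unname(x$var_explained)
  )
}
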