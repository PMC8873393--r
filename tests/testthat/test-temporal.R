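status_de <- function(...) {
  pats <- list(...)
  dplyr::bind_rows(lapply(seq_along(pats), function(i) {
    tibble::tibble(
      gene_id = sprintf("g%02d", i), fraction = "chromatin",
      timepoint = c(0.5, 3, 24), status = pats[[i]]
    )
  }))
}

test_that("recovery classification implements the temporal definitions", {
  de <- status_de(
    c("down", "ns", "ns"), # recovered at the early timepoint
    c("down", "down", "ns"), # recovered only at the late timepoint
    c("down", "down", "down"), # never restored
    c("ns", "down", "down"), # repressed later, never restored
    c("ns", "up", "up"), # induced
    c("up", "ns", "ns"), # induced (transient)
    c("ns", "ns", "ns"), # unchanged
    c("ns", "ns", "down"), # late-only repression -> other
    c("down", "ns", "down"), # restored then repressed again -> not_recovered
    c("up", "down", "ns") # mixed -> other
  )
  calls <- classify_recovery(de)
  calls <- calls[order(calls$gene_id), ]
  expect_equal(calls$label, c(
    "recovered", "recovered", "not_recovered", "not_recovered",
    "induced", "induced", "unchanged", "other", "not_recovered", "other"
  ))
  expect_equal(calls$recovery_time, c(3, 24, NA, NA, NA, NA, NA, NA, NA, NA))
})

test_that("recovery classification requires all three post-UV timepoints", {
  de <- status_de(c("down", "ns", "ns"))
  expect_error(
    classify_recovery(de[de$timepoint != 3, ]),
    class = "uvtx_input_error"
  )
})

test_that("profile clustering recovers separable groups and is deterministic", {
  set.seed(20)
  up <- t(replicate(30, c(0, 1, 2, 3) + rnorm(4, 0, 0.1)))
  down <- t(replicate(30, c(3, 2, 1, 0) + rnorm(4, 0, 0.1)))
  profiles <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%02d", 1:60)),
    as.data.frame(rbind(up, down)) |>
      stats::setNames(c("t0", "t0.5", "t3", "t24"))
  )
  cl <- cluster_profiles(profiles, k = 2, seed = 4, restarts = 10)
  grp <- cl$assignments$cluster
  expect_equal(length(unique(grp[1:30])), 1)
  expect_equal(length(unique(grp[31:60])), 1)
  expect_false(grp[1] == grp[31])

  again <- cluster_profiles(profiles, k = 2, seed = 4, restarts = 10)
  expect_identical(cl$assignments, again$assignments)
  expect_identical(cl$inertia, again$inertia)

  # k = 1: one cluster holding everything; centroid is the mean profile
  one <- cluster_profiles(profiles, k = 1, seed = 1, restarts = 2)
  expect_true(all(one$assignments$cluster == 1))
  z <- uvtx:::as_count_matrix(profiles)
  z <- (z - rowMeans(z)) / apply(z, 1, sd)
  expect_equal(as.vector(one$centroids), unname(colMeans(z)), tolerance = 1e-12)

  expect_error(cluster_profiles(profiles, k = 61, seed = 1),
    class = "uvtx_config_error"
  )
})

test_that("clustering objective never worsens with more restarts", {
  set.seed(30)
  profiles <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%02d", 1:40)),
    as.data.frame(matrix(rnorm(160), 40, 4)) |>
      stats::setNames(paste0("t", 1:4))
  )
  i1 <- cluster_profiles(profiles, k = 4, seed = 2, restarts = 1)$inertia
  i10 <- cluster_profiles(profiles, k = 4, seed = 2, restarts = 10)$inertia
  i30 <- cluster_profiles(profiles, k = 4, seed = 2, restarts = 30)$inertia
  expect_lte(i10, i1)
  expect_lte(i30, i10)
})

test_that("zero-variance profiles z-score to zero and cluster together", {
  profiles <- tibble::tibble(
    gene_id = c("flat1", "flat2", "var1"),
    t0 = c(2, 5, 0), t3 = c(2, 5, 1), t24 = c(2, 5, 2)
  )
  cl <- cluster_profiles(profiles, k = 2, seed = 3, restarts = 5)
  a <- cl$assignments$cluster
  expect_equal(a[1], a[2])
  expect_false(a[1] == a[3])
})

test_that("sample PCA is centred, ordered and degenerate-safe", {
  set.seed(40)
  expr <- dplyr::bind_cols(
    tibble::tibble(gene_id = paste0("g", 1:100)),
    as.data.frame(matrix(rnorm(600), 100, 6)) |>
      stats::setNames(paste0("s", 1:6))
  )
  # duplicated samples land on identical coordinates
  expr$s6 <- expr$s5
  p <- pca_samples(expr)
  s5 <- unlist(p$scores[p$scores$sample_id == "s5", -1])
  s6 <- unlist(p$scores[p$scores$sample_id == "s6", -1])
  expect_equal(s5, s6, ignore_attr = TRUE)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-8)

  # exactly two samples: the single PC carries all the variance
  two <- expr[, c("gene_id", "s1", "s2")]
  p2 <- pca_samples(two)
  expect_equal(unname(p2$var_explained[1]), 1)

  expect_error(pca_samples(expr[, c("gene_id", "s1")]),
    class = "uvtx_input_error"
  )
})

test_that("PCA separates the two fractions on simulated data", {
  # no UV effect, so the fractionation is the only systematic axis
  cfg <- sim_config(
    n_genes = c(mRNA = 200, novel_lncRNA = 80),
    lesion_rate = 0, induced_fraction = 0,
    seed = 23
  )
  sim <- simulate_experiment(cfg, seed = 23)
  fpkm <- compute_fpkm(sim$counts, sim$models)
  logf <- dplyr::mutate(fpkm, dplyr::across(-gene_id, ~ log2(.x + 1)))
  p <- pca_samples(logf, sim$design)
  pc1 <- split(p$scores$PC1, p$scores$fraction)
  # fractions separate along PC1 (sign of the axis is arbitrary)
  expect_true(max(pc1$chromatin) < min(pc1$cytoplasm) ||
    max(pc1$cytoplasm) < min(pc1$chromatin))
})

test_that("tidy and glance methods return well-formed tibbles", {
  set.seed(50)
  profiles <- dplyr::bind_cols(
    tibble::tibble(gene_id = paste0("g", 1:30)),
    as.data.frame(matrix(rnorm(120), 30, 4)) |>
      stats::setNames(paste0("t", c(0, 0.5, 3, 24)))
  )
  cl <- cluster_profiles(profiles, k = 3, seed = 1, restarts = 5)
  td <- generics::tidy(cl)
  expect_equal(nrow(td), 3 * 4)
  expect_named(td, c("cluster", "size", "timepoint", "centroid"))
  gl <- generics::glance(cl)
  expect_equal(gl$k, 3)
  aug <- generics::augment(cl, profiles)
  expect_true("cluster" %in% names(aug))

  p <- pca_samples(profiles[, -1] |>
    dplyr::mutate(gene_id = profiles$gene_id, .before = 1))
  expect_true(all(c("component", "var_explained") %in% names(generics::glance(p))))
})
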