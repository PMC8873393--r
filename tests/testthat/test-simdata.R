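test_that("gene model generation honours counts, invariants and determinism", {
  cfg <- sim_config(n_genes = c(mRNA = 40, annotated_lncRNA = 15), seed = 5)
  models <- generate_gene_models(cfg)
  expect_equal(nrow(models), 55)
  expect_equal(sum(models$biotype == "mRNA"), 40)
  expect_true(uvtx:::check_gene_models(models))
  expect_true(all(models$cds_length[models$biotype != "mRNA"] == 0))

  again <- generate_gene_models(cfg)
  expect_identical(models, again)

  empty <- generate_gene_models(sim_config(n_genes = c(mRNA = 0)))
  expect_equal(nrow(empty), 0)

  expect_error(
    sim_config(n_genes = c(mRNA = 10), length_sdlog = c(mRNA = -1)),
    class = "uvtx_config_error"
  )
})

test_that("adding genes does not perturb earlier genes' draws", {
  small <- generate_gene_models(sim_config(n_genes = c(mRNA = 20), seed = 3))
  large <- generate_gene_models(sim_config(n_genes = c(mRNA = 35), seed = 3))
  cols <- c("gene_id", "strand", "template_span", "tx_length", "exon_count", "cds_length")
  expect_identical(small[cols], large[seq_len(20), cols])
})

test_that("template spans follow the configured log-normal law", {
  mu <- log(25000)
  sigma <- 1.2
  models <- generate_gene_models(
    sim_config(n_genes = c(mRNA = 4000), seed = 9)
  )
  theor_mean <- exp(mu + sigma^2 / 2)
  theor_sd <- theor_mean * sqrt(exp(sigma^2) - 1)
  se <- theor_sd / sqrt(nrow(models))
  expect_lt(abs(mean(models$template_span) - theor_mean), 3 * se)
})

test_that("lesion placement is Poisson at the configured rate", {
  expect_error(place_lesions(1000, -1), class = "uvtx_config_error")

  set.seed(1)
  expect_length(place_lesions(1e6, 0), 0)

  # span 2000 at 5e-4 per base: mean lesion count 1.0
  set.seed(2)
  counts <- replicate(20000, length(place_lesions(2000, 5e-4)))
  expect_lt(abs(mean(counts) - 1), 3 * sqrt(1 / 20000))

  set.seed(3)
  offs <- place_lesions(1e6, 5e-4)
  expect_true(all(diff(offs) >= 0))
  expect_true(all(offs >= 0 & offs < 1e6))
})

test_that("transcription activity follows the truncation formula", {
  # lesion-free gene is fully active at any time
  expect_equal(transcription_activity(numeric(0), 5e4, 0, 4, 25000), 1)
  expect_equal(transcription_activity(numeric(0), 5e4, 24, 4, 25000), 1)

  # unrepairable lesion midway in a 100 kb gene, 25 kb window
  expect_equal(
    transcription_activity(5e4, 1e5, 10, Inf, 25000, repair_times = Inf),
    0.5
  )
  # window floor: lesion inside the proximal window does not repress below it
  expect_equal(
    transcription_activity(1e3, 1e5, 1, Inf, 25000, repair_times = Inf),
    0.25
  )
  # finite half-life: activity returns to 1 as t grows
  expect_equal(
    transcription_activity(c(1e3, 5e4), 1e5, 1e6, 4, 25000,
      repair_times = c(2, 7)
    ),
    1
  )
  # bounded below by min(window, span)/span
  set.seed(4)
  for (t in c(0, 0.5, 3, 24)) {
    a <- transcription_activity(runif(20, 0, 8e4), 8e4, t, 4, 25000)
    expect_gte(a, 25000 / 8e4)
    expect_lte(a, 1)
  }
})

test_that("activity trajectories are monotone and lesion burden scales with span", {
  cfg <- sim_config(n_genes = c(mRNA = 300), seed = 21)
  models <- generate_gene_models(cfg)
  truth <- simulate_truth(models, cfg)
  for (i in seq_len(nrow(truth))) {
    kin <- truth$kinetics[[i]]
    expect_true(all(diff(kin$unrepaired) <= 0))
    expect_true(all(diff(kin$activity[-1]) >= 0)) # monotone after exposure
    expect_true(all(kin$activity[kin$unrepaired == 0] == 1))
  }
  # P(>= 1 lesion) = 1 - exp(-rate * span), strictly increasing in span;
  # check the empirical incidence curve at a sub-saturating rate
  rate <- 2e-5
  cfg2 <- sim_config(n_genes = c(mRNA = 1500), lesion_rate = rate, seed = 22)
  models2 <- generate_gene_models(cfg2)
  truth2 <- simulate_truth(models2, cfg2)
  terciles <- cut(
    models2$template_span,
    quantile(models2$template_span, c(0, 1 / 3, 2 / 3, 1)),
    include.lowest = TRUE
  )
  p_theor <- tapply(1 - exp(-rate * models2$template_span), terciles, mean)
  p_hat <- tapply(truth2$n_lesions > 0, terciles, mean)
  n_per <- tabulate(terciles)
  expect_true(all(diff(p_theor) > 0))
  expect_true(all(
    abs(p_hat - p_theor) < 3 * sqrt(p_theor * (1 - p_theor) / n_per) + 1e-9
  ))
  expect_true(all(diff(p_hat) > 0))
})

test_that("zero lesion rate leaves every gene fully active", {
  cfg <- sim_config(
    n_genes = c(mRNA = 60), lesion_rate = 0,
    induced_fraction = c(mRNA = 0), seed = 2
  )
  models <- generate_gene_models(cfg)
  truth <- simulate_truth(models, cfg)
  acts <- unlist(lapply(truth$kinetics, `[[`, "activity"))
  expect_true(all(acts == 1))
  expect_true(all(truth$label_chromatin == "unchanged"))
})

test_that("count simulation is deterministic and mean-faithful", {
  cfg <- sim_config(
    n_genes = c(mRNA = 80), nb_dispersion = 0,
    lesion_rate = 0, induced_fraction = c(mRNA = 0),
    n_replicates = 2, seed = 6
  )
  sim1 <- simulate_experiment(cfg, seed = 6)
  sim2 <- simulate_experiment(cfg, seed = 6)
  expect_identical(sim1$counts, sim2$counts)
  expect_true(all(vapply(
    uvtx:::sample_columns(sim1$counts),
    function(cn) is.integer(sim1$counts[[cn]]), logical(1)
  )))
  # expected column sum equals the library size (Poisson, all activity 1)
  totals <- colSums(as.matrix(sim1$counts[, -1]))
  expect_true(all(abs(totals - cfg$library_size) < 5 * sqrt(cfg$library_size)))
})

test_that("negative-binomial counts satisfy the mean-variance law", {
  alpha <- 0.05
  cfg <- sim_config(
    n_genes = c(mRNA = 3000), nb_dispersion = alpha,
    lesion_rate = 0, induced_fraction = c(mRNA = 0),
    n_replicates = 8, timepoints = c(0, 1), seed = 13
  )
  sim <- simulate_experiment(cfg, seed = 13)
  des <- sim$design
  cols <- des$sample_id[des$fraction == "chromatin" & des$timepoint == 0]
  m <- as.matrix(sim$counts[, cols])
  mu_hat <- rowMeans(m)
  var_hat <- apply(m, 1, var)
  hi <- mu_hat > 100
  slope <- coef(lm(I(var_hat[hi] - mu_hat[hi]) ~ 0 + I(mu_hat[hi]^2)))[[1]]
  expect_lt(abs(slope - alpha) / alpha, 0.10)
})

test_that("cytoplasmic pool decays exponentially when synthesis stops", {
  delta <- 0.3
  cfg <- sim_config(
    n_genes = c(mRNA = 1), mrna_decay_rate = delta,
    timepoints = c(0, 0.5, 3, 24), seed = 1
  )
  truth <- tibble::tibble(
    gene_id = "g1", biotype = "mRNA", baseline = 10,
    lesion_positions = list(numeric(0)), n_lesions = 0L, induced = FALSE,
    kinetics = list(tibble::tibble(
      timepoint = cfg$timepoints,
      unrepaired = c(1L, 1L, 1L, 1L),
      activity = c(1, 0, 0, 0),
      induction = 1
    )),
    label_chromatin = "repressed_not_recovered",
    recovery_time = NA_real_,
    label_cytoplasm = "repressed_not_recovered"
  )
  m <- uvtx:::cytoplasm_means(truth, cfg)
  m0 <- m[1, 1]
  expect_equal(m[1, "t3"], m0 * exp(-delta * 3), tolerance = 1e-12)
  expect_equal(m[1, "t24"], m0 * exp(-delta * 24), tolerance = 1e-12)
})

test_that("fixtures survive a disk round trip", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = c(mRNA = 7, novel_lncRNA = 3), seed = 8)
  sim <- simulate_experiment(cfg, seed = 8)
  paths <- write_fixtures(sim$models, sim$counts, sim$design, sim$truth, dir)
  expect_true(all(file.exists(paths)))

  models2 <- read_annotation(paths[["annotation"]])
  models2 <- models2[match(sim$models$gene_id, models2$gene_id), ]
  for (col in c(
    "gene_id", "biotype", "chrom", "strand", "tx_start", "tx_end",
    "template_span", "tx_length", "exon_count", "intron_count", "cds_length"
  )) {
    expect_equal(models2[[col]], sim$models[[col]], ignore_attr = TRUE)
  }
  for (i in seq_len(nrow(sim$models))) {
    expect_equal(as.data.frame(models2$exons[[i]]), as.data.frame(sim$models$exons[[i]]))
  }

  counts2 <- read_counts(paths[["counts"]])
  expect_equal(as.data.frame(counts2), as.data.frame(sim$counts))
  design2 <- read_design(paths[["design"]])
  expect_equal(as.data.frame(design2), as.data.frame(sim$design))

  truth2 <- read_truth(paths[["truth"]])
  expect_equal(truth2$baseline, sim$truth$baseline)
  expect_equal(truth2$lesion_positions, sim$truth$lesion_positions,
    ignore_attr = TRUE
  )
  expect_equal(truth2$label_chromatin, sim$truth$label_chromatin)
  expect_equal(truth2$recovery_time, sim$truth$recovery_time)
  for (i in seq_len(nrow(sim$truth))) {
    expect_equal(
      as.data.frame(truth2$kinetics[[i]]),
      as.data.frame(sim$truth$kinetics[[i]])
    )
  }

  # GTF holds one transcript line per gene plus one line per exon
  gtf_lines <- grep("^[^#]", readLines(paths[["annotation"]]), value = TRUE)
  expect_length(gtf_lines, nrow(sim$models) + sum(sim$models$exon_count))
})

test_that("an unknown-strand single-exon transcript round-trips via '.'", {
  dir <- withr::local_tempdir()
  models <- tiny_models()
  uvtx:::write_gtf(models, file.path(dir, "m.gtf"))
  raw <- readLines(file.path(dir, "m.gtf"))
  gc_lines <- grep("gC", raw, value = TRUE)
  expect_true(all(vapply(
    strsplit(gc_lines, "\t"),
    function(f) f[7] == ".", logical(1)
  )))
  back <- read_annotation(file.path(dir, "m.gtf"))
  expect_equal(back$strand[back$gene_id == "gC"], "*")
})
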