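# expected chromatin-fraction expression (genes x timepoints):
# baseline * activity * induction * per-biotype chromatin retention
chromatin_means <- function(truth, config) {
  tps <- config$timepoints
  out <- matrix(0, nrow(truth), length(tps))
  for (i in seq_len(nrow(truth))) {
    kin <- truth$kinetics[[i]]
    out[i, ] <- truth$baseline[i] * kin$activity * kin$induction *
      config$chromatin_retention[truth$biotype[i]]
  }
  rownames(out) <- truth$gene_id
  colnames(out) <- paste0("t", tps)
  out
}

# expected cytoplasmic abundance (genes x timepoints) under first-order
# accumulation/decay: M(t+dt) = M e^(-delta dt) + (sbar/delta)(1 - e^(-delta dt)).
# The damage state switches at the start of an interval, so synthesis is
# piecewise constant at the level of the interval's end: sbar = s(t+dt)
# (exact shutdown: synthesis 0 after exposure decays M purely
# exponentially). delta = 0 falls back to the analytic limit M + sbar * dt.
# M(0) is the pre-exposure steady state s(0)/delta (or s(0) when delta = 0).
cytoplasm_means <- function(truth, config) {
  tps <- config$timepoints
  delta <- config$mrna_decay_rate
  out <- matrix(0, nrow(truth), length(tps))
  for (i in seq_len(nrow(truth))) {
    kin <- truth$kinetics[[i]]
    s <- truth$baseline[i] * kin$activity * kin$induction *
      config$export_fraction
    m <- numeric(length(tps))
    m[1] <- if (delta > 0) s[1] / delta else s[1]
    for (j in seq_along(tps)[-1]) {
      dt <- tps[j] - tps[j - 1]
      sbar <- s[j]
      m[j] <- if (delta > 0) {
        m[j - 1] * exp(-delta * dt) + (sbar / delta) * (1 - exp(-delta * dt))
      } else {
        m[j - 1] + sbar * dt
      }
    }
    out[i, ] <- m
  }
  rownames(out) <- truth$gene_id
  colnames(out) <- paste0("t", tps)
  out
}

#' Sample design for a fractionated time course
#'
#' @param config A [sim_config()].
#' @return A tibble with `sample_id`, `fraction` (`"chromatin"` /
#'   `"cytoplasm"`), `timepoint` (hours) and `replicate`.
#' @export
#' @examples
#' sim_design(sim_config(n_replicates = 2))
sim_design <- function(config) {
  stopifnot(inherits(config, "uv_sim_config"))
  design <- tidyr::expand_grid(
    fraction = c("chromatin", "cytoplasm"),
    timepoint = config$timepoints,
    replicate = seq_len(config$n_replicates)
  )
  design$sample_id <- sprintf(
    "%s_t%g_r%d",
    ifelse(design$fraction == "chromatin", "chr", "cyt"),
    design$timepoint, design$replicate
  )
  design[, c("sample_id", "fraction", "timepoint", "replicate")]
}

#' Simulate a two-fraction count matrix
#'
#' Converts the ground-truth kinetics into expected fragment counts and
#' samples negative-binomial noise. Within each sample, a gene's expected
#' fragments are proportional to expression times transcript length
#' (`tx_length / 1000`), rescaled so the expected column sum equals
#' `config$library_size`; counts are drawn with variance
#' `mu + alpha * mu^2` (`alpha = config$nb_dispersion`; Poisson when 0).
#' Replicates are i.i.d. Each gene consumes its own RNG sub-stream, so the
#' draws of a given gene do not depend on how many other genes are
#' simulated.
#'
#' @param models Gene models from [generate_gene_models()].
#' @param truth Ground truth from [simulate_truth()] or [assign_truth()];
#'   rows must align one-to-one with `models`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `uv_sim` with elements `counts` (tibble:
#'   `gene_id` + one integer column per sample), `design` (see
#'   [sim_design()]), `models`, `truth` and `config`.
#' @export
simulate_counts <- function(models, truth, config, seed = config$seed) {
  stopifnot(inherits(config, "uv_sim_config"))
  if (!identical(models$gene_id, truth$gene_id)) {
    abort("`truth` rows must align one-to-one with `models`",
      class = "uvtx_config_error"
    )
  }
  assert_scalar_number(config$library_size, "library_size", min = 0, strict = TRUE)
  design <- sim_design(config)
  tps <- config$timepoints

  expr <- list(
    chromatin = chromatin_means(truth, config),
    cytoplasm = cytoplasm_means(truth, config)
  )
  # expected fragments before library scaling: expression * kb of transcript
  weight <- models$tx_length / 1000
  mu <- matrix(0, nrow(models), nrow(design))
  for (s in seq_len(nrow(design))) {
    e <- expr[[design$fraction[s]]][, match(design$timepoint[s], tps)]
    w <- e * weight
    tot <- sum(w)
    mu[, s] <- if (tot > 0) config$library_size * w / tot else 0
  }

  alpha <- config$nb_dispersion
  counts <- matrix(0L, nrow(models), nrow(design))
  for (i in seq_len(nrow(models))) {
    counts[i, ] <- with_stream(stream_seed(seed, 404L, i), {
      if (alpha > 0) {
        rnbinom(ncol(counts), mu = mu[i, ], size = 1 / alpha)
      } else {
        rpois(ncol(counts), lambda = mu[i, ])
      }
    })
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- models$gene_id
  colnames(counts) <- design$sample_id

  structure(
    list(
      counts = matrix_to_tibble(counts),
      design = design,
      models = models,
      truth = truth,
      config = config
    ),
    class = "uv_sim"
  )
}

#' One-call synthetic experiment
#'
#' Convenience wrapper: gene models, mechanistic (or assigned) ground
#' truth, and the count matrix, all from one seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param truth_mode `"mechanistic"` (lesion/repair model) or `"assigned"`
#'   (strong programmed effects, see [assign_truth()]).
#' @param ... Passed on to [assign_truth()] when `truth_mode = "assigned"`.
#' @return A `uv_sim` list (see [simulate_counts()]).
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = c(mRNA = 50)), seed = 7)
#' dim(sim$counts)
simulate_experiment <- function(config, seed = config$seed,
                                truth_mode = c("mechanistic", "assigned"),
                                ...) {
  truth_mode <- match.arg(truth_mode)
  models <- generate_gene_models(config, seed = seed)
  truth <- if (truth_mode == "mechanistic") {
    simulate_truth(models, config, seed = seed)
  } else {
    assign_truth(models, config, seed = seed, ...)
  }
  simulate_counts(models, truth, config, seed = seed)
}

#' @export
print.uv_sim <- function(x, ...) {
  cat(sprintf(
    "<uv_sim> %d genes x %d samples (%d timepoints, %d replicates/fraction)\n",
    nrow(x$counts), nrow(x$design), length(x$config$timepoints),
    x$config$n_replicates
  ))
  invisible(x)
}
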