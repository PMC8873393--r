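#' Place UV lesions on a gene's genomic template
#'
#' Transcription-blocking lesions (cyclobutane pyrimidine dimers) are laid
#' down by a homogeneous Poisson process along the genomic template of the
#' gene (introns included, since elongating RNA polymerase II stalls on the
#' template strand regardless of exon structure). The default rate in
#' [sim_config()], 5e-4 per base, corresponds to 500 T-T lesions per 10^6
#' bases at the modelled UV-C dose.
#'
#' Draws from the current RNG state; seed via [set.seed()] or let the
#' higher-level generators manage per-gene sub-streams.
#'
#' @param template_span Template length in nt (> 0).
#' @param lesion_rate Lesions per base (>= 0).
#' @return Sorted numeric vector of lesion offsets in `[0, template_span)`,
#'   measured in nt from the transcription start site.
#' @export
#' @examples
#' set.seed(1)
#' place_lesions(1e5, 5e-4)
place_lesions <- function(template_span, lesion_rate) {
  assert_scalar_number(template_span, "template_span", min = 0, strict = TRUE)
  assert_scalar_number(lesion_rate, "lesion_rate", min = 0)
  n <- rpois(1, lesion_rate * template_span)
  sort(runif(n, min = 0, max = template_span))
}

#' Transcriptional activity of a lesion-bearing gene
#'
#' Under the elongation-truncation model, RNA polymerase II transcribes from
#' the promoter up to the first unrepaired lesion; a promoter-proximal
#' window stays active regardless of downstream damage. Activity is the
#' transcribable fraction of the template:
#' `min(D, span) / span` with `D = max(proximal_window, first unrepaired
#' lesion offset)`, and `D = span` when no lesion remains.
#'
#' Each lesion is repaired independently with exponential kinetics: by time
#' `t` it is repaired with probability `1 - exp(-log(2) * t /
#' repair_halflife)`. Supply `repair_times` (one per lesion) to make the
#' trajectory deterministic and monotone across timepoints; otherwise
#' repair states are drawn afresh from the current RNG state.
#'
#' @param lesion_offsets Numeric vector of lesion offsets (nt from TSS).
#' @param template_span Template length in nt.
#' @param t Time after exposure in hours (>= 0).
#' @param repair_halflife Per-lesion repair half-life in hours (`Inf` =
#'   no repair).
#' @param proximal_window Promoter-proximal active window in nt.
#' @param repair_times Optional per-lesion repair times (hours); a lesion is
#'   unrepaired at `t` iff its repair time exceeds `t`.
#' @return Activity fraction in `[0, 1]`.
#' @export
#' @examples
#' transcription_activity(5e4, 1e5, t = 1, repair_halflife = Inf,
#'                        proximal_window = 25000)
transcription_activity <- function(lesion_offsets, template_span, t,
                                   repair_halflife, proximal_window,
                                   repair_times = NULL) {
  assert_scalar_number(t, "t", min = 0)
  assert_scalar_number(template_span, "template_span", min = 0, strict = TRUE)
  if (length(lesion_offsets) == 0) {
    return(1)
  }
  if (is.null(repair_times)) {
    p_repaired <- if (is.infinite(repair_halflife)) 0 else {
      1 - exp(-log(2) * t / repair_halflife)
    }
    unrepaired <- runif(length(lesion_offsets)) >= p_repaired
  } else {
    stopifnot(length(repair_times) == length(lesion_offsets))
    unrepaired <- repair_times > t
  }
  if (!any(unrepaired)) {
    return(1)
  }
  d <- max(proximal_window, min(lesion_offsets[unrepaired]))
  min(d, template_span) / template_span
}

#' Simulate lesion/repair ground truth for a gene set
#'
#' Runs the mechanistic model for every gene: Poisson lesion placement on
#' the template, one exponential repair time per lesion, and the resulting
#' activity trajectory over `config$timepoints`. A configured fraction of
#' genes per biotype additionally receives a programmed UV-induction
#' profile (fold `config$induced_fold` at the immediate and early
#' timepoints), emulating damage-response genes.
#'
#' For biotypes configured `"long_first"` the per-gene lesion intensity is
#' `lesion_rate * median_span^2 / span` instead of `lesion_rate * span`, so
#' expected lesion burden decreases with length and longer genes recover
#' first -- a phenomenological encoding of the opposite length preference
#' observed for noncoding RNAs.
#'
#' Ground-truth labels per fraction use the same two-fold rule as the
#' downstream caller: a gene is repressed at `t` when activity(t) <= 0.5.
#'
#' @param models Gene models from [generate_gene_models()].
#' @param config A [sim_config()].
#' @param seed Integer seed (per-gene sub-streams derive from it).
#' @return A tibble with one row per gene: `gene_id`, `biotype`, `baseline`
#'   (expression scale), `lesion_positions` (list), `n_lesions`, `induced`
#'   (logical), `kinetics` (list column of tibbles with `timepoint`,
#'   `unrepaired`, `activity`, `induction`), `label_chromatin`,
#'   `label_cytoplasm`, `recovery_time` (hours, `NA` unless recovered).
#' @export
simulate_truth <- function(models, config, seed = config$seed) {
  stopifnot(inherits(config, "uv_sim_config"))
  tps <- config$timepoints
  med_span <- stats::median(models$template_span)
  rows <- vector("list", nrow(models))
  for (i in seq_len(nrow(models))) {
    bt <- models$biotype[i]
    span <- models$template_span[i]
    rows[[i]] <- with_stream(stream_seed(seed, 202L, i), {
      long_first <- config$fraction_effect_direction[bt] == "long_first"
      # long-first biotypes: per-gene lesion burden decreases with span
      # (rate * med^2 / span lesions expected) and repression acts without
      # the promoter-proximal floor, so short genes are hit harder and
      # longer genes recover first
      rate_g <- if (long_first) {
        config$lesion_rate * med_span^2 / span^2
      } else {
        config$lesion_rate
      }
      window_g <- if (long_first) 0 else config$proximal_window
      lesions <- place_lesions(span, rate_g)
      repair_times <- if (is.infinite(config$repair_halflife)) {
        rep(Inf, length(lesions))
      } else {
        rexp(length(lesions), rate = log(2) / config$repair_halflife)
      }
      activity <- vapply(tps, function(t) {
        transcription_activity(lesions, span, t, config$repair_halflife,
          window_g,
          repair_times = repair_times
        )
      }, numeric(1))
      # t = 0 is the untreated control, sampled before the instantaneous
      # exposure: full activity, with the fresh lesions counted as unrepaired
      activity[tps == 0] <- 1
      unrepaired <- vapply(tps, function(t) sum(repair_times > t), numeric(1))
      induced <- runif(1) < config$induced_fraction[bt]
      induction <- rep(1, length(tps))
      if (induced) {
        # up at the immediate and early timepoints, back to baseline late
        mid <- tps > 0 & tps < max(tps)
        induction[mid] <- config$induced_fold
      }
      baseline <- rlnorm(1, config$baseline_meanlog, config$baseline_sdlog)
      tibble(
        baseline = baseline,
        lesion_positions = list(lesions),
        n_lesions = length(lesions),
        induced = induced,
        kinetics = list(tibble(
          timepoint = tps,
          unrepaired = as.integer(unrepaired),
          activity = activity,
          induction = induction
        ))
      )
    })
  }
  truth <- dplyr::bind_rows(rows)
  truth <- dplyr::bind_cols(models[, c("gene_id", "biotype")], truth)
  label_truth(truth, config)
}

#' Assign strong programmed effects as ground truth
#'
#' Alternative to the mechanistic [simulate_truth()]: every gene is
#' assigned one of the four truth classes with the given proportions and a
#' clean, strong effect trajectory (|log2 effect| >= 2 by default), useful
#' for validating the recovery classifier under unambiguous conditions.
#'
#' @param models Gene models.
#' @param config A [sim_config()]; `timepoints` must contain exactly one
#'   baseline (0) plus at least three post-exposure timepoints.
#' @param seed Integer seed.
#' @param proportions Named numeric vector over
#'   `c("unchanged", "repressed_recovered", "repressed_not_recovered",
#'   "induced")`, normalised internally.
#' @param repressed_activity Activity during repression (default 0.2, a
#'   -2.32 log2 effect).
#' @param induced_fold Fold induction for induced genes (default 5).
#' @return A truth tibble with the same shape as [simulate_truth()].
#' @export
assign_truth <- function(models, config, seed = config$seed,
                         proportions = c(
                           unchanged = 0.4, repressed_recovered = 0.25,
                           repressed_not_recovered = 0.2, induced = 0.15
                         ),
                         repressed_activity = 0.2,
                         induced_fold = 5) {
  stopifnot(inherits(config, "uv_sim_config"))
  cls <- c(
    "unchanged", "repressed_recovered", "repressed_not_recovered", "induced"
  )
  stopifnot(all(names(proportions) %in% cls), repressed_activity <= 0.25)
  proportions <- proportions[cls]
  proportions[is.na(proportions)] <- 0
  proportions <- proportions / sum(proportions)
  tps <- config$timepoints
  post <- tps[tps > 0]
  stopifnot(length(post) >= 3)
  last <- max(post)
  rows <- vector("list", nrow(models))
  for (i in seq_len(nrow(models))) {
    rows[[i]] <- with_stream(stream_seed(seed, 303L, i), {
      lab <- sample(cls, 1, prob = proportions)
      activity <- rep(1, length(tps))
      induction <- rep(1, length(tps))
      recovery <- NA_real_
      if (lab == "repressed_recovered") {
        # half recover by the early timepoint, half only at the last one
        recovery <- sample(c(post[2], last), 1)
        activity[tps > 0 & tps < recovery] <- repressed_activity
      } else if (lab == "repressed_not_recovered") {
        activity[tps > 0] <- repressed_activity
      } else if (lab == "induced") {
        induction[tps > 0 & tps < last] <- induced_fold
      }
      baseline <- rlnorm(1, config$baseline_meanlog, config$baseline_sdlog)
      tibble(
        baseline = baseline,
        lesion_positions = list(numeric(0)),
        n_lesions = 0L,
        induced = lab == "induced",
        kinetics = list(tibble(
          timepoint = tps,
          # a notional blocking lesion persists until the last repressed
          # timepoint, so unrepaired is non-increasing and 0 implies
          # activity 1
          unrepaired = rev(cummax(rev(as.integer(activity < 1)))),
          activity = activity,
          induction = induction
        ))
      )
    })
  }
  truth <- dplyr::bind_rows(rows)
  truth <- dplyr::bind_cols(models[, c("gene_id", "biotype")], truth)
  label_truth(truth, config)
}

# derive per-fraction truth labels from the kinetic trajectories using the
# same two-fold rule as the DE caller (repressed iff activity <= 0.5;
# induced iff induction >= 2 and never repressed)
label_truth <- function(truth, config) {
  tps <- config$timepoints
  post <- which(tps > 0)
  immediate <- post[1]
  last <- post[length(post)]
  lab <- character(nrow(truth))
  rec_time <- rep(NA_real_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    kin <- truth$kinetics[[i]]
    repressed <- kin$activity <= 0.5
    induced_tp <- kin$induction >= 2
    if (repressed[last] && any(repressed[setdiff(post, last)])) {
      lab[i] <- "repressed_not_recovered"
    } else if (any(repressed[post])) {
      lab[i] <- "repressed_recovered"
      restored <- post[!repressed[post] & seq_along(tps)[post] > min(post[repressed[post]])]
      rec_time[i] <- if (length(restored)) tps[min(restored)] else tps[last]
    } else if (any(induced_tp[post])) {
      lab[i] <- "induced"
    } else {
      lab[i] <- "unchanged"
    }
  }
  truth$label_chromatin <- lab
  truth$recovery_time <- rec_time
  # cytoplasmic truth from the deterministic compartment dynamics
  cyt <- cytoplasm_means(truth, config)
  m0 <- cyt[, 1]
  ratio <- cyt / ifelse(m0 > 0, m0, 1)
  lab_c <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    r <- ratio[i, post]
    if (any(r <= 0.5)) {
      lab_c[i] <- if (r[length(r)] <= 0.5) {
        "repressed_not_recovered"
      } else {
        "repressed_recovered"
      }
    } else if (any(r >= 2)) {
      lab_c[i] <- "induced"
    } else {
      lab_c[i] <- "unchanged"
    }
  }
  truth$label_cytoplasm <- lab_c
  truth
}
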