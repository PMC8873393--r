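BIOTYPES <- c("mRNA", "annotated_lncRNA", "novel_lncRNA", "TUCP")

#' Simulation configuration
#'
#' Bundles every parameter of the mechanistic UV-response simulator: the
#' annotation model (gene numbers, genomic-span and exon-count distributions
#' per biotype), the lesion/repair model (per-base lesion rate, per-lesion
#' exponential repair half-life, promoter-proximal active window), the RNA
#' dynamics (cytoplasmic decay and export), and the count-sampling model
#' (negative-binomial dispersion, library size, replicates).
#'
#' Defaults encode the study conditions: a 10 J/m2 UV-C exposure laying down
#' 500 T-T lesions per 10^6 template bases (`lesion_rate = 5e-4`), a 25 kb
#' promoter-proximal window that keeps transcribing while distal elongation
#' is blocked, and sampling at 0, 0.5, 3 and 24 h.
#'
#' @param n_genes Named integer vector: genes per biotype. Names must be a
#'   subset of `c("mRNA", "annotated_lncRNA", "novel_lncRNA", "TUCP")`.
#' @param length_meanlog,length_sdlog Named numeric vectors: log-normal
#'   parameters of the genomic template span per biotype.
#' @param exon_geom_prob Named numeric vector in (0, 1]: success probability
#'   of the shifted-geometric exon-count model (exons = 1 + Geom(p); mean
#'   exons = 1/p).
#' @param lesion_rate Lesions per template base per exposure. The default
#'   `5e-4` equals 500 lesions per 10^6 bases.
#' @param proximal_window Promoter-proximal window (nt) that remains
#'   transcriptionally active regardless of downstream lesions.
#' @param repair_halflife Per-lesion exponential repair half-life in hours;
#'   `Inf` disables repair (the no-repair mode emulating repair deficiency).
#' @param timepoints Sampling times in hours; must start at 0 and increase.
#' @param mrna_decay_rate First-order cytoplasmic decay rate (per hour).
#' @param export_fraction Fraction of nascent synthesis exported to the
#'   cytoplasm, in (0, 1].
#' @param chromatin_retention Named numeric vector (>= 0): per-biotype
#'   multiplier on chromatin-fraction signal; values > 1 model chromatin
#'   retention of noncoding RNAs.
#' @param nb_dispersion Negative-binomial dispersion alpha >= 0
#'   (variance = mu + alpha * mu^2); 0 gives Poisson counts.
#' @param library_size Expected fragments per sample (column sum target).
#' @param n_replicates Replicates per fraction x timepoint.
#' @param fraction_effect_direction Named character vector per biotype,
#'   values `"short_first"` or `"long_first"`: whether shorter or longer
#'   genes recover transcription first. mRNAs default to the mechanistic
#'   short-first coupling; noncoding biotypes default to long-first,
#'   matching the opposite length preference observed for lncRNAs.
#' @param induced_fraction Fraction of genes per biotype given a programmed
#'   UV-induction profile (the damage-response genes).
#' @param induced_fold Fold induction (>= 1) applied at 0.5 h and 3 h for
#'   induced genes.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-gene
#'   baseline expression.
#' @param seed Default master seed used when generator functions are called
#'   without one.
#'
#' @return An object of class `uv_sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = c(mRNA = 100))
#' cfg$lesion_rate * 1e6 # lesions per megabase
sim_config <- function(n_genes = c(
                         mRNA = 8000, annotated_lncRNA = 1000,
                         novel_lncRNA = 700, TUCP = 300
                       ),
                       length_meanlog = c(
                         mRNA = log(25000), annotated_lncRNA = log(9000),
                         novel_lncRNA = log(7000), TUCP = log(12000)
                       ),
                       length_sdlog = c(
                         mRNA = 1.2, annotated_lncRNA = 1.1,
                         novel_lncRNA = 1.1, TUCP = 1.1
                       ),
                       exon_geom_prob = c(
                         mRNA = 0.105, annotated_lncRNA = 0.45,
                         novel_lncRNA = 0.5, TUCP = 0.4
                       ),
                       lesion_rate = 5e-4,
                       proximal_window = 25000,
                       repair_halflife = 4,
                       timepoints = c(0, 0.5, 3, 24),
                       mrna_decay_rate = 0.15,
                       export_fraction = 0.8,
                       chromatin_retention = c(
                         mRNA = 1, annotated_lncRNA = 4,
                         novel_lncRNA = 8, TUCP = 6
                       ),
                       nb_dispersion = 0.05,
                       library_size = 5e6,
                       n_replicates = 3,
                       fraction_effect_direction = c(
                         mRNA = "short_first",
                         annotated_lncRNA = "long_first",
                         novel_lncRNA = "long_first",
                         TUCP = "long_first"
                       ),
                       induced_fraction = c(
                         mRNA = 0.05, annotated_lncRNA = 0.05,
                         novel_lncRNA = 0.05, TUCP = 0.05
                       ),
                       induced_fold = 4,
                       baseline_meanlog = log(50),
                       baseline_sdlog = 1,
                       seed = 1L) {
  fill <- function(x, default = NULL) {
    if (is.null(names(x)) && length(x) == 1L) {
      x <- setNames(rep(x, length(BIOTYPES)), BIOTYPES)
    }
    bad <- setdiff(names(x), BIOTYPES)
    if (length(bad) > 0) {
      abort(paste0("unknown biotype(s): ", paste(bad, collapse = ", ")),
        class = "uvtx_config_error"
      )
    }
    out <- setNames(rep(if (is.null(default)) 0 else default, length(BIOTYPES)), BIOTYPES)
    out[names(x)] <- x
    out
  }
  n_genes <- fill(n_genes)
  if (any(n_genes < 0) || any(n_genes != round(n_genes))) {
    abort("`n_genes` must be nonnegative integers", class = "uvtx_config_error")
  }
  length_meanlog <- fill(length_meanlog, default = log(10000))
  length_sdlog <- fill(length_sdlog, default = 1)
  if (any(length_sdlog[n_genes > 0] <= 0)) {
    abort("`length_sdlog` must be > 0 for simulated biotypes",
      class = "uvtx_config_error"
    )
  }
  exon_geom_prob <- fill(exon_geom_prob, default = 0.5)
  if (any(exon_geom_prob <= 0 | exon_geom_prob > 1)) {
    abort("`exon_geom_prob` must lie in (0, 1]", class = "uvtx_config_error")
  }
  assert_scalar_number(lesion_rate, "lesion_rate", min = 0)
  assert_scalar_number(proximal_window, "proximal_window", min = 0)
  if (!(is.numeric(repair_halflife) && length(repair_halflife) == 1L &&
    (is.infinite(repair_halflife) || repair_halflife > 0))) {
    abort("`repair_halflife` must be > 0 (Inf allowed)", class = "uvtx_config_error")
  }
  if (length(timepoints) < 2 || timepoints[1] != 0 ||
    any(diff(timepoints) <= 0)) {
    abort("`timepoints` must start at 0 and be strictly increasing",
      class = "uvtx_config_error"
    )
  }
  assert_scalar_number(mrna_decay_rate, "mrna_decay_rate", min = 0)
  assert_scalar_number(export_fraction, "export_fraction", min = 0, strict = TRUE)
  if (export_fraction > 1) {
    abort("`export_fraction` must lie in (0, 1]", class = "uvtx_config_error")
  }
  chromatin_retention <- fill(chromatin_retention, default = 1)
  if (any(chromatin_retention < 0)) {
    abort("`chromatin_retention` must be >= 0", class = "uvtx_config_error")
  }
  assert_scalar_number(nb_dispersion, "nb_dispersion", min = 0)
  assert_scalar_number(library_size, "library_size", min = 0, strict = TRUE)
  if (n_replicates < 1 || n_replicates != round(n_replicates)) {
    abort("`n_replicates` must be an integer >= 1", class = "uvtx_config_error")
  }
  fraction_effect_direction <- fill(fraction_effect_direction, default = "short_first")
  if (!all(fraction_effect_direction %in% c("short_first", "long_first"))) {
    abort('`fraction_effect_direction` values must be "short_first" or "long_first"',
      class = "uvtx_config_error"
    )
  }
  induced_fraction <- fill(induced_fraction, default = 0)
  if (any(induced_fraction < 0 | induced_fraction > 1)) {
    abort("`induced_fraction` must lie in [0, 1]", class = "uvtx_config_error")
  }
  assert_scalar_number(induced_fold, "induced_fold", min = 1)

  structure(
    list(
      n_genes = n_genes,
      length_meanlog = length_meanlog,
      length_sdlog = length_sdlog,
      exon_geom_prob = exon_geom_prob,
      lesion_rate = lesion_rate,
      proximal_window = proximal_window,
      repair_halflife = repair_halflife,
      timepoints = as.numeric(timepoints),
      mrna_decay_rate = mrna_decay_rate,
      export_fraction = export_fraction,
      chromatin_retention = chromatin_retention,
      nb_dispersion = nb_dispersion,
      library_size = library_size,
      n_replicates = as.integer(n_replicates),
      fraction_effect_direction = fraction_effect_direction,
      induced_fraction = induced_fraction,
      induced_fold = induced_fold,
      baseline_meanlog = baseline_meanlog,
      baseline_sdlog = baseline_sdlog,
      seed = as.integer(seed)
    ),
    class = "uv_sim_config"
  )
}

#' @export
print.uv_sim_config <- function(x, ...) {
  cat("<uv_sim_config>\n")
  cat("  genes:", paste(sprintf("%s=%d", names(x$n_genes), x$n_genes), collapse = " "), "\n")
  cat(sprintf(
    "  lesion_rate: %.3g /base (%.0f per Mb)   proximal_window: %g nt\n",
    x$lesion_rate, x$lesion_rate * 1e6, x$proximal_window
  ))
  cat(sprintf(
    "  repair_halflife: %s h   timepoints: %s h\n",
    format(x$repair_halflife), paste(x$timepoints, collapse = ", ")
  ))
  cat(sprintf(
    "  decay: %.3g /h   export: %.2f   dispersion: %.3g   library: %.3g   reps: %d\n",
    x$mrna_decay_rate, x$export_fraction, x$nb_dispersion,
    x$library_size, x$n_replicates
  ))
  invisible(x)
}
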