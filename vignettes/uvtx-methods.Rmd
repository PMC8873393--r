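---
title: "Models and methods behind uvtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind uvtx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvtx)
library(dplyr)
```

uvtx analyses fractionated RNA-seq time courses after UV-C irradiation:
chromatin-associated (nascent) and cytoplasmic (mature) transcripts sampled
before exposure and at an immediate (0.5 h), early (3 h) and recovery
(24 h) timepoint. Because real data of this kind require a sequencing
study, the package pairs every analysis stage with a mechanistic simulator
whose ground truth lets each stage be validated end to end. This vignette
explains the models, the defaults and the design decisions.

## The lesion / repair / elongation model

UV-C deposits transcription-blocking pyrimidine dimers on DNA. The
simulator places lesions by a homogeneous Poisson process along each
gene's *genomic template* (introns included — elongating RNA polymerase II
stalls on the template regardless of exon structure). The default rate is
`5e-4` lesions per base, i.e. 500 lesions per 10^6 bases, the measured
T-T dimer burden at the ~10 J/m2 dose this design models. If you model a
different dose, scale the rate linearly.

Each lesion is repaired independently with exponential kinetics,
half-life `repair_halflife` (default 4 h, which leaves ~92% of lesions in
place at 0.5 h, ~59% at 3 h and ~2% at 24 h — qualitatively matching
near-complete dimer removal by 24 h). `repair_halflife = Inf` is the
no-repair mode, the hook for repair-deficient genotypes; no
genotype-specific biology beyond that is claimed.

Transcriptional activity of a gene at time `t` is the transcribable
fraction of its template under elongation truncation:

    activity = min(D, span) / span,
    D = max(proximal_window, offset of first unrepaired lesion)

with `D = span` when no lesion remains. The promoter-proximal window
(default 25,000 nt, the upper end of the reported 20–25 kb active region)
keeps initiating polymerases productive even when distal elongation is
blocked. Two consequences follow directly: activity is monotone
non-decreasing after exposure (repair only removes blocks), and long genes
are both more likely to be hit and slower to clear their last blocking
lesion — which is why transcription restores short-first for mRNAs.

### The noncoding regime ("long_first")

For noncoding RNAs the observed direction is opposite: longer transcripts
recover first. No mechanism is established for this, so the simulator
encodes it phenomenologically with `fraction_effect_direction =
"long_first"` (the default for the three noncoding biotypes): the
per-gene lesion intensity becomes `rate * median_span^2 / span` (expected
burden decreasing with length) and the proximal-window floor is not
applied, i.e. repression of these genes is treated as trans-acting rather
than elongation-limited. This reproduces the sign of the effect — nothing
more — and can be switched per biotype.

## From activity to counts

Per-gene baselines are log-normal (`meanlog = log(50)`, `sdlog = 1`).
Chromatin-fraction expression is `baseline * activity * induction *
chromatin_retention(biotype)`; the retention multipliers (1 for mRNA, 4–8
for noncoding biotypes) create the chromatin enrichment of lncRNAs that
the enrichment statistic should detect. A configurable fraction of genes
(default 5%) carries a programmed induction profile (fold 4 at 0.5 h and
3 h), emulating damage-response genes; this is the only way the simulator
produces the "induced" truth class, since the lesion model can only
repress.

Cytoplasmic abundance follows first-order accumulation/decay between
timepoints:

    M(t + dt) = M(t) e^(-delta dt) + (s/delta) (1 - e^(-delta dt))

with decay `delta = 0.15`/h (a ~4.6 h mRNA half-life) and synthesis
`s = baseline * activity * induction * export_fraction`. The damage state
switches at the start of an interval, so `s` over an interval is taken at
the interval's end; with that convention an instantaneous shutdown decays
the pool purely exponentially, which is also the closed form the tests
check. `delta = 0` falls back to `M + s * dt`. The pre-exposure sample is
the steady state `s(0)/delta`. Timepoint 0 is always the untreated
control: activity 1 by definition, with freshly placed lesions counted as
unrepaired from then on.

Counts are negative binomial with variance `mu + alpha mu^2`
(`alpha = 0.05`; 0 gives Poisson), expected fragments proportional to
expression times transcript kilobases and rescaled so each sample's
expected depth equals `library_size` (default 5e6 — desk scale rather
than the hundreds of millions of reads of a real study; every statistical
property checked here is depth-calibrated through FPKM and size factors,
not raw counts). Replicates are i.i.d. The study design pooled three
biological replicates per sequenced library; a DE test needs within-group
variance, so the simulator emits true replicates (default 3) instead, and
no attempt is made to mimic pooled-library inference.

All randomness derives from one seed through counter-based per-gene
sub-streams (`stream_seed()`), so enlarging a simulation never perturbs
the genes already drawn, and every stage reproduces byte-identically
under a fixed seed.

## What the simulator does not emulate

No read-level effects (mappability, GC, positional bias), no splicing
isoforms, no inter-replicate library-preparation batch effects, no
genotype biology beyond the no-repair switch. Passing tests therefore
demonstrate that the analysis stages are correct under a faithful
generative model of the design — not that any particular biological
magnitude from a real experiment will be reproduced. The headline numbers
of the motivating study (mean CDS 1287 vs 1549 nt, 8.5 vs 10.1 introns,
44.8% single-exon recovered lncRNAs) depend on its external sequencing
data and are explicitly out of scope; the package reproduces the
*directions* of those effects on simulated data.

## Analysis stages and their defaults

**FPKM** uses the exonic transcript length (`tx_length`) as the effective
length — the standard convention; the source methods do not state theirs.
**Size factors** are median-of-ratios over genes expressed in every
sample, rescaled to geometric mean 1. **Expressed genes** are those with
FPKM >= 1 in at least one fraction (inclusive boundary).

**Chromatin enrichment** is `(mean chromatin FPKM + eps) / (mean
cytoplasm FPKM + eps)` with `eps = 0.1` by default; a drop-zero mode is
available instead, since the original figure states no zero-handling
rule. Whether to pool timepoints or use untreated samples only is exposed
via `timepoints =`; neither mode claims to replicate the published
figure. Per-biotype comparisons use Welch's t test on log2 folds —
"Student's t test" in the source is interpreted as Welch wherever group
sizes and variances differ, with the pooled-variance form behind
`var.equal = TRUE`.

**Differential expression** is a self-contained negative-binomial Wald
test standing in for a GLM-based tool: method-of-moments per-gene
dispersion (shrunk 50/50 toward the 10%-trimmed mean across genes), log2
ratio of pseudocount-guarded normalized means (`eps = 0.5`), delta-method
standard error, normal p values, BH adjustment within each (fraction,
contrast) family, and the call thresholds |log2FC| >= 1 (inclusive) and
padj < 0.05 (strict). The textbook delta-method SE uses `1/mu`; this
implementation uses `1/(mu + eps)` so that on/off genes get finite
standard errors — without the guard, a gene falling from any level to
zero would never reach significance. No
fold-change shrinkage is applied because the decision boundary operates
on the raw log2 fold change. Under a 3-vs-3 null at `mu = 100`,
`alpha = 0.05` the observed type-I rate is ~0.05 (checked by simulation
in the test suite).

**Recovery classification** operationalises the temporal definitions:
"restored to normal levels" means the DE status is no longer `down` at
that timepoint. A gene down at 0.5 h and not down at 24 h is `recovered`
(recovery time 3 h if already restored there, else 24 h); down at the
late timepoint after earlier repression is `not_recovered`; `up` somewhere
and never down is `induced`; all-`ns` is `unchanged`. A gene restored at
3 h but down again at 24 h is deliberately *not* recovered (it falls in
`not_recovered`), and repression appearing only at 24 h is `other` — the
source defines no rule for these patterns, so the conservative choice is
made explicit here.

**Clustering** is k-means on row-z-scored log2 profiles with k-means++
initialisation, Lloyd iterations via `stats::kmeans()`, best of 50
restarts by within-cluster sum of squares; zero-variance rows z-score to
zero. The published cluster counts (7 cytoplasmic mRNA, 6 chromatin mRNA,
12 chromatin lncRNA classes) are sensible defaults for `k` but carry no
claim of matching published memberships — the original clustering
algorithm is unstated. **PCA** is mean-centred SVD with samples as
observations.

**Feature comparisons** report mean/median CDS length, transcript
length, mean exon length, intron count and the single-exon fraction per
gene group, with Welch t tests against a reference group; multi-isoform
annotations can be counted per gene (longest CDS) or per isoform, since
the published CDS-size analysis counted all isoforms but its intron
analysis may not have.

**The lncRNA/TUCP cascade** applies, in fixed order: (1) length >= 200 nt
and determined strand; (2) no same-strand exonic overlap with the
reference annotation (1-base closed-interval sensitivity; an any-strand
mode exists because the source sentence does not specify strandedness);
(3) maximum FPKM >= 0.5; (4) coding potential. Stage 4 replaces four
external predictors (which cannot be reproduced offline) with a clearly
labelled ORF proxy: the longest sense-strand ATG-to-stop ORF (stop
excluded; ORFs without a stop codon do not count; antisense frames are
not scanned since inputs are sense-strand by contract). Verdicts:
< 300 nt ORF = noncoding (novel lncRNA); >= 900 nt ORF covering >= 80% of
the transcript = coding (discarded); anything between = uncertain, the
TUCP class. The 300 nt floor is the classical 100-codon lncRNA criterion;
900 nt/80% marks transcripts that are essentially a single long ORF.
Known-lncRNA database matching is out of scope (it needs the external
database).

## Numerical choices and degenerate inputs

Zero column sums abort FPKM with the offending sample named; size
factors abort when no gene is expressed everywhere unless a pseudocount
is supplied; both-zero groups in the Wald test return log2FC 0, p 1 by
definition; empty candidate sets yield an all-zero audit; empty
sequences score ORF 0/noncoding; `N` bases are accepted and never form a
start or stop codon. Duplicate k-means++ centres are deduplicated before
Lloyd iteration, so `k` can effectively shrink on degenerate data rather
than error. Fixture doubles are serialised at 17 significant digits so
disk round trips are exact.

## Problem sizes used in the checks

The test suite and acceptance script run at desk scale, chosen so every
law being checked has adequate power: 10,000 Poisson draws for the
lesion-rate check (3-standard-error band), 2,000 genes for the null-FDR
and length-direction checks, 1,500 genes under strong assigned effects
for classifier accuracy (balanced accuracy >= 0.9), 500 synthetic
candidates for the cascade oracle, and 1,000 random sequences against
the quadratic ORF oracle.
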