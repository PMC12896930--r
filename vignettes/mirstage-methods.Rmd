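---
title: "Stage-wise nCounter miRNA analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-wise nCounter miRNA analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mirstage implements a complete analysis path for NanoString nCounter miRNA
panel data in a stage-stratified case-control design: non-tumor gallstone
disease (GSD) controls versus early-stage (I/II) and advanced-stage (III/IV)
gallbladder cancer. This vignette explains the statistical machinery, the
tunable parameters and the choices made where the design was genuinely open.
Because raw nCounter count data for this disease setting are not publicly
deposited, the package ships a calibrated synthetic-data generator; every
statistical claim made by the test suite is a claim about data from that
generator, and the last section is explicit about what that does and does
not show.

```{r setup}
library(mirstage)
```

## The count model behind the generator

nCounter counts are digital molecule counts without amplification, but they
still carry biological and technical over-dispersion, so endogenous probes
are drawn negative-binomially:

$$ y_{ps} \sim \mathrm{NB}\!\left(\mu_{ps},\ \phi\right),
\qquad \mathrm{Var}(y_{ps}) = \mu_{ps} + \phi\,\mu_{ps}^2 $$

with a per-probe baseline \(\mu_p\) drawn log-normally (meanlog
\(\log 200\), sdlog 1.3, giving the several-decade dynamic range typical of
miRNA panels) and

$$ \mu_{ps} = \mu_p \cdot 2^{\beta_{p,g(s)}} \cdot 2^{\delta_{p,b(s)}}
   \cdot L_s \cdot E_s . $$

* \(\beta_{p,g}\) is the planted stage effect (log2 fold change vs GSD);
* \(\delta_{p,b}\) is a per-probe batch shift, planted on a random 20% of
  probes with SD 0.6 on the log2 scale — the technical structure the batch
  correction stage exists to remove;
* \(L_s\) is the RNA-input (library size) factor, log-normal with sdlog
  0.12. It multiplies endogenous and housekeeping probes but **not** the
  positive spike-ins, which are added at hybridization and only see the
  lane efficiency;
* \(E_s\) is the lane-efficiency factor (sdlog 0.08), which multiplies
  every hybridized probe.

Housekeeping probes use the same model with a high baseline
(log-normal around 4,000 counts) and a very small dispersion (0.005),
reflecting that these transcripts are chosen for stability. Positive
spike-ins follow their nominal four-fold titration (128 to 0.125 fM) with
expected count \(156.25 \times c\) fM\(^{-1}\), placing the top probe near
20,000 counts; negatives are Poisson with mean 15. The library-size sdlog
of 0.12 was fixed once so that the simulated housekeeping probes can
actually satisfy the pipeline's own selection rule (raw counts > 50 and
CV < 20% — a CV that a much larger input spread would violate for every
candidate, aborting every run by construction); the remaining spread is
still large enough that the two normalization pipelines are distinguishable
in RLE diagnostics.

All randomness flows from one integer seed through labelled substreams
(`with_substream`), so adding a downstream draw never perturbs an upstream
one, and a `sim_truth` object round-trips through JSON to reproduce a
cohort exactly.

Planted clinical effects shift a probe's expected counts monotonically
across the coded tumor grade (1-3) or lymph-node status (1-2) by
\(2^{s\,m\,(c - \bar c)}\) per sample, which is the structure the Spearman
stage is designed to detect.

## Quality control

Per sample, `qc_samples()` reports the background level (mean of negative
controls plus two sample standard deviations, n-1 denominator), the
positive-control scaling factor (geometric mean of positive counts over the
cohort geometric mean of those geometric means, so the factors always have
geometric mean 1), and the linearity of the titration series (R² of
log2(count+1) on log2 concentration). Factors outside [0.3, 3] are
flagged; these limits are the customary nCounter defaults, recorded here as
assumptions because no instrument-specific thresholds are available.

## Two normalization pipelines

Both pipelines share: background subtraction (threshold per sample =
negative mean + 2 SD, corrected counts floored at zero and rounded half-up
to keep count semantics; control probes are passed through unmodified for
audit), positive-control scaling, housekeeping scaling (each factor is the
cohort mean of per-sample geometric means over the sample's geometric mean,
with a +1 guard against zeros), and low-expression filtering (a probe
stays if its CPM reaches the count-10 equivalent against the median library
size in at least as many samples as the smallest group — a concrete
restatement of the usual expression filter, kept deliberately explicit and
oracle-tested rather than delegated, because its exact internals matter for
reproducibility).

Pipeline **P1** then computes log2-CPM (pseudocount 0.5, effective library
size +1) and removes batch effects. Pipeline **P2** inserts trimmed mean of
M-values (TMM) normalization before the log-CPM: the reference sample is
the one whose upper-quartile CPM is closest to the cohort mean; each
sample's log2 factor is the precision-weighted mean of its M-values against
the reference after discarding zeros, the top/bottom 30% of M-values and
the top/bottom 5% of A-values (mid-ranks under ties); factors are rescaled
so their log2 values sum to zero. P1 is exactly P2 with all TMM factors
forced to 1.

Batch correction fits, per probe, least squares with the biological groups
retained and batch in sum-to-zero coding, then subtracts only the fitted
batch term. This preserves fitted group contrasts exactly, is idempotent,
and refuses designs where batch is confounded with group. The RLE
diagnostic (log2 expression minus the probe's cross-sample median)
summarizes each pipeline by the IQR of per-sample medians; on generator
data with library-size variation and asymmetric fold changes, P2's spread
is consistently at or below P1's, which is the criterion for preferring it.

One deliberate deviation from a literal pipeline readout: differential
expression is fitted on the *uncorrected* log-CPM with batch as a model
covariate, while the batch-subtracted matrix feeds PCA, RLE and clinical
correlation. Subtracting the batch term first and then testing would
understate residual variance; modelling it keeps the degrees of freedom
honest. `fit_moderated(use_corrected = TRUE)` restores the literal
feed-forward flow for comparison.

## Moderated differential expression

Per probe, log2 expression is regressed on group (GSD reference, so the
coefficients are the Early-vs-GSD and Advanced-vs-GSD log2 fold changes)
plus batch. Residual variances \(s_g^2\) with \(d\) df are shrunk toward a
prior fitted by method of moments on \(\log s_g^2\): the prior df \(d_0\)
solves a trigamma equation (inverted by Newton iteration, tolerance 1e-8)
and the posterior variance is
\(\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)\). The moderated t uses
\(\tilde s_g\) with \(d_0 + d\) df (capped at the pooled residual df).
When the observed spread of log variances is no wider than chi-square
sampling noise the prior df is infinite and shrinkage is complete; at the
other limit, `d0_override = 0` reproduces the ordinary equal-variance
t-test to machine precision, and both limits are tested numerically. The
implementation is the package's own; the test suite cross-checks it against
an established empirical-Bayes implementation as an independent oracle.

A probe is a DEM in a contrast when its Benjamini-Hochberg adjusted p is
**strictly** below 0.05 and |log2FC| ≥ 1 (fold change ≥ 2). The two printed
conventions ("> 1" and "≥ 2-fold") are reconciled to the inclusive
fold-change form; probes sitting exactly on a threshold are flagged
`at_boundary` in the output so the choice is auditable. Contrasts are each
tumor stage against GSD only — no Early-vs-Advanced test. The Venn
partition (early-only / advanced-only / shared) is computed on the DEM
sets, and `read_dem_table()` lets a published DEM table be fed through the
same partition code.

## Target scoring and networks

Validated miRNA-target interactions are read from a miRTarBase-style TSV.
High confidence defaults to requiring all three assay families — Western
blot, qPCR and a reporter assay (synonyms like "luciferase reporter assay"
and "qRT-PCR" are normalized) — on a human-human record; because that
literal conjunction may be stricter than intended, `any_strong` is provided
as an option. Composite panel probes ("A + B") donate their fold change to
both mature miRNAs before mapping.

Each target gene's cumulative regulatory score is the sum of the log2 fold
changes of its **distinct** significant regulating miRNAs (evidence rows
collapse, so a multi-assay entry never double-counts). |score| > 4 — a
strict inequality, so exactly ±4 does not qualify — marks a gene strongly
regulated. The inferred direction is "down" when net miRNA pressure is up,
an explicit repression assumption exposed as a node attribute, never
asserted as measured expression. Networks keep the top ten genes by
|score| (ties broken by gene symbol ascending, a documented deterministic
rule), with node sizes |log2FC| for miRNAs and the sum of incident
|log2FC| for genes, and export to GraphML/SIF/TSV for rendering elsewhere.

## Over-representation and clinical correlation

Enrichment is a generic exact hypergeometric upper-tail test of the
strongly regulated genes of a contrast against user-supplied GMT sets, BH
adjusted across sets. The universe defaults to all target genes of the
interaction file — the natural sampling frame for a query derived from that
same file — rather than the genome; pathway-database retrieval is out of
scope by design.

Clinical correlation codes tumor grade WDAC/MDAC/PDAC as 1/2/3 and
lymph-node status as 1/2, excludes controls, and computes mid-rank Spearman
correlations of normalized (batch-corrected) expression per probe. The
p-value uses the t approximation \(t = r\sqrt{(n-2)/(1-r^2)}\) with n-2 df,
adequate at the cohort sizes this design targets (~30 tumors); an exact
permutation p is available for n ≤ 8 (full enumeration; beyond that the
factorial blows up and the approximation is preferable anyway).
Significance is raw p < 0.05 **and** |r| ≥ 0.4 with no multiplicity
correction — mirroring the convention of the workflow this package
systematizes, and documented here as a statistical caveat rather than a
recommendation. Published correlation values from the original cohort
(e.g. r around −0.6 for specific miRNAs) depend on the undeposited raw
data and are deliberately not asserted anywhere in the tests.

## Numerical choices and degenerate inputs

* Geometric means in scaling factors use counts + 1; log-CPM uses
  pseudocount 0.5 and library size + 1, so zeros always map to finite
  values.
* Background-corrected counts are rounded half-up (`floor(x + 0.5)`).
* Zero residual variance in a probe yields t = 0 and p = 1 when the
  coefficient is also zero (and ±Inf otherwise) instead of NaN.
* A zero-variance expression or code vector makes Spearman r undefined;
  the result row is NA and never significant.
* Empty selections fail loudly with typed conditions
  (`mirstage_norm_impossible`, `mirstage_confounded`, ...) naming the
  failing criterion; `run_pipeline()` wraps every stage so an abort names
  the stage and cause.

## Problem sizes used by the test suite

The suite exercises the full pipeline at the cohort design it emulates
(10/14/17 samples) with 800 endogenous probes for the null-calibration
(20 seeds) and sensitivity (3 seeds, planted |log2FC| in {2, 2.5, 3} on
well-expressed probes) checks, and smaller panels (60-300 probes) for
component tests. These sizes were chosen as the smallest that exercise the
statistics faithfully; a desk machine runs the whole suite in well under a
minute.

## What passing tests do and do not show

The generator reproduces the features the pipeline stages are built to
handle — over-dispersed digital counts, library-size and lane variation,
spike-in behaviour, batch structure, stage effects, monotone clinical
shifts. It deliberately does not model FFPE degradation chemistry, ligation
artifacts, probe cross-hybridization, or tissue-composition heterogeneity.
Consequently, green tests certify that the implementation does what its
definitions say (oracle equivalence), that the DEM call is calibrated under
the generator's null, and that planted effects of the stated size are
recovered — they do not certify biological conclusions about any real
cohort, and the package makes no such claims.
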