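---
title: "Detecting longitudinal methylome variability: group-level VMPs and private epimutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting longitudinal methylome variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methvar)
```

## The problem

Most differential-methylation analyses compare group *means*. Two
complementary phenomena escape that lens entirely:

* **regional variability** — a CpG whose methylation moves a lot over time
  in one clinical group but not the other, even if the group means barely
  shift, and
* **private epimutations** — individual-specific methylation changes:
  a single subject drifting far away from everyone else at one CpG, which
  averages out of any group-level contrast.

Both are natural signatures of epigenetic stochasticity ("epigenetic
drift"), and both are interesting in longitudinal clinical cohorts where
each subject is measured at a baseline (M0) and a follow-up (MF) — here,
an ultra-high-risk-for-psychosis design contrasting subjects who later
converted to psychosis (converters) with those who did not
(non-converters). The longitudinal design matters: comparing each subject
to themselves removes the between-individual variability driven by DNA
sequence.

`methvar` implements the two detectors over plain beta-value matrices
(methylation fractions in $[0,1]$, probes $\times$ samples), the array QC
rules they presuppose, and a synthetic-cohort generator with planted,
recoverable truth. Everything upstream of a normalized beta matrix
(IDAT parsing, normalization, cell-composition adjustment, batch
screening) is out of scope: the package consumes already-normalized
betas.

## Variably methylated probes (VMPs)

For each paired subject $i$ and probe $j$ the longitudinal difference is

$$\Delta\beta_{ij} = \beta_{ij}(\mathrm{MF}) - \beta_{ij}(\mathrm{M0}),$$

and each group is summarised per probe by a median statistic. Two
summaries are implemented because the field's verbal and symbolic
descriptions of "the median absolute difference" genuinely differ:

* `abs_of_median`: $\left|\operatorname{median}_i \Delta\beta_{ij}\right|$
  (the default, matching the symbolic form $|median(\Delta\beta)|$) — a
  *consistent directional* group change;
* `median_of_abs`: $\operatorname{median}_i |\Delta\beta_{ij}|$ — large
  changes of *any* direction.

The two agree when a group's changes share a sign and diverge otherwise
(a group with $\Delta\beta = \{-0.2, 0, 0.2\}$ scores 0 under the first
and 0.2 under the second). Both are exposed; the mode is recorded in the
output so downstream consumers never have to guess. A probe is called a
VMP when the statistic reaches **0.1** — the conventional
10-percentage-point bound below which array differences have substantial
probability of being technical — and the rule is *inclusive*
($\geq 0.1$), so a statistic of exactly 0.10 is a VMP.

Numerical conventions: even-sized groups use the mean-of-middle-two
median; a probe missing in more than 20% of a group's subjects (or with
fewer than two observed values) gets a missing statistic rather than a
quietly biased one; results sort by statistic descending with ties broken
lexicographically by probe id, so output order is total and reproducible.

## Private epimutations

The second detector looks for CpGs whose *variance* differs between
groups, then pinpoints the individuals responsible.

1. **Variance scan.** At each timepoint and probe, a two-sided F-test
   compares converter and non-converter beta variances:
   $F = s^2_{\mathrm{conv}} / s^2_{\mathrm{nonc}}$ with unbiased
   $(n-1)$-denominator variances on $(n_c - 1, n_{nc} - 1)$ degrees of
   freedom, $p = 2\min\{P(F_{df} \le F),\, P(F_{df} \ge F)\}$ capped at 1.
   Benjamini–Hochberg FDR is applied across all non-degenerate probes of
   a timepoint scan (one FDR family per scan). Probes with zero variance
   in a group, or any missing value among contributing samples, are
   flagged degenerate and kept out of the family rather than polluting it.
2. **Candidate filters.** A probe is a candidate private-epimutation
   locus when (i) it is FDR-significant at MF with the *converter* group
   showing the higher variance, (ii) its converter variance strictly
   increased from M0 to MF (variance grows with time; a raw comparison,
   not a second test), and (iii) it is not flagged in non-converters.
3. **Outlier calling.** At candidate probes, each converter's deviation
   from the converter-group median beta,
   $d_{ij} = \beta_{ij} - \operatorname{median}_{i'} \beta_{i'j}$, is
   thresholded at **0.10, strictly**: a call is emitted iff
   $|d_{ij}| > 0.10$, hypermethylation for positive deviations,
   hypomethylation for negative. The strict inequality is deliberate and
   is pinned by the packaged worked example, where two deviations printed
   at exactly 0.10 are not treated as calls.

### Design choices that were genuinely open

* **"Identified only in converters"** (filter iii) admits more than one
  reading. The default excludes probes that are FDR-significant *with
  higher non-converter variance* at either timepoint. An alternative
  reading — probes significant in a within-non-converter longitudinal
  (MF-vs-M0) variance test — is available via `scan_longitudinal()` and
  the `nonconverter_exclude` argument of `select_candidates()`. Both are
  labelled interpretations; neither is claimed to be uniquely correct.
* **Whether the variance increase (filter ii) should itself be
  significance-tested** is unstated in the method's sources; the raw
  strict comparison is the default.
* **The deviation reference** is the converter-group median at each
  timepoint (the group actually tabulated); a pooled-cohort median would
  be a one-line change in `compute_deviations()` via the `group`
  argument.
* **Unbiased variances** ($n-1$) are used throughout.

### The packaged worked example

`load_table3_fixture()` ships the published worked example of the caller:
25 candidate CpGs $\times$ 14 converters, before- and after-transition
deviations from the converter-group median, printed at 2 decimal places,
plus the probe-to-gene map with the FDR-adjusted follow-up F-test
p-values. Comparisons against it use 2-decimal tolerance — whether the
original 10% rule was applied to rounded or unrounded deviations is not
recoverable from printed tables, so fixture-based tests assert on the
printed values only.

```{r}
res <- run_table3_analysis()
res$summary$n_probes     # distinct called CpGs
res$summary$n_calls      # total cell-level calls
res$summary$histogram    # subjects with 0, 1, 2, 3 calls
res$summary$multi_carrier
```

The strict rule yields 12 called CpGs and 16 calls; four subjects carry
none and one carries three; four CpGs recur in two subjects each with a
shared direction (three hyper, one hypo). The before-transition block is
quiet (largest absolute deviation 0.06), which is what makes the
after-transition outliers interpretable as longitudinal events.

## Quality control

The QC filters reproduce standard array hygiene for ~450k-probe designs,
with the boundaries handled exactly:

* **samples**: excluded when *strictly more than* 4500 CpGs (about 1% of
  an array) fail detection at $p \ge 0.05$; exactly 4500 is retained.
  Detection p-values are mandatory for this filter — omitting them is a
  configuration error, never a silent skip.
* **probes**, with one primary reason each, precedence
  detection > beadcount > flags > unannotated:
  detection $p \ge 0.05$ in *at least one* sample (inclusive);
  beadcount < 3 in $\ge 5\%$ of samples, with the fraction compared in
  exact rational arithmetic (`count * 20 >= n`) so that 2/40 = 5.0%
  excludes regardless of floating-point representation; any of the
  chrX/chrY, SNP-probe, SNP-at-CpG, cross-reactive annotation flags.
* Beadcount fractions are computed over the samples retained by the
  sample filter, mirroring the sequential behaviour of the usual QC
  toolchains.
* Raw-array identity checks (sex concordance, genotype concordance)
  need array internals that sit upstream of a beta matrix; the package
  exposes them as a no-op hook (`check_sample_identity()`) that a
  pipeline with access to raw data can override.

Filtering is idempotent and monotone in the detection threshold; both
properties are tested.

## The synthetic cohort generator

Real cohorts of this design are small and rarely shareable, so every
stage is validated against simulated cohorts with *known planted truth*
(`sim_config()` / `simulate_cohort()` / `evaluate_recovery()`). The
generator's defaults are the study conditions the detectors target:
14 converters vs 25 non-converters, two timepoints.

* **Baselines**: per-probe means from a two-component logit-normal
  mixture with modes near 0.1 and 0.85 (equal weights, logit-scale spread
  0.5) — the classic bimodal shape of array beta distributions.
* **Noise and drift**: subject scatter and M0→MF drift are Gaussian *on
  the logit scale* (defaults 0.02 each), which keeps betas bounded
  without ad-hoc truncation and makes within-group variance roughly
  proportional to $\beta(1-\beta)$, as arrays show. A logit-sd of 0.02
  corresponds to a beta-scale sd of at most ~0.005 at $\beta = 0.5$ —
  small against both detection thresholds, as within-group blood
  methylation noise is. Follow-up values build on each subject's *own*
  baseline, so the simulated design is genuinely longitudinal.
* **Planted signal**, on the beta scale, at MF only (matching the
  variance-increases-with-time premise): VMP shifts (default 0.15) added
  to every member of the target group, with the sign chosen toward the
  side with headroom so the planted effect is realisable; epimutation
  offsets (default 0.25) added to a single (probe, subject), sign flipped
  if it would clip at the boundary. All betas are clipped to
  $[10^{-6}, 1-10^{-6}]$ and clipped plants are recorded in the truth
  table.
* **QC corruption** (failing detection p-values, low beadcounts) is
  optional and orthogonal, so statistical tests never entangle with QC
  tests.
* With zero noise, zero drift and no plants, M0 = MF = baseline exactly,
  and the whole cohort is a deterministic function of the seed.

What the generator does *not* emulate — probe-type (Infinium I/II)
chemistry, cell-composition mixtures, batch structure, spatially
correlated probes — bounds what passing tests show: they validate the
statistical machinery under idealised noise, not robustness to array
artefacts, which upstream normalization is assumed to have handled.

## Validation and problem sizes

The test suite validates each stage against independent oracles and the
pipeline end to end; the main checks, with the problem sizes the package
uses for them:

* Monte-Carlo calibration of the two-sided F-test: $10^5$ null
  replicates at the cohort's group sizes (14 vs 25); the type-I error at
  nominal 0.05 must land in $0.05 \pm 0.005$.
* BH-FDR against a hand-written step-up oracle; median statistics and
  deviations against sort/loop oracles on 1000-probe random matrices.
* Exact invariances: translation (adding a constant to both timepoints),
  sign flips of $\Delta\beta$, per-probe shifts (deviations, F-tests and
  calls unchanged), scale covariance of variances ($c^2$).
* Planted recovery at genome scale ($10^4$ probes, 14+25 subjects):
  planted VMPs (shift 0.15, noise 0.02) recovered with precision =
  recall = 1; planted epimutations (offset 0.25) with recall $\ge 0.95$
  and zero false calls; fully null cohorts silent after FDR — no VMPs,
  no candidates, no calls.
* The packaged worked example reproduced exactly: 12 CpGs, 16 calls, the
  {0:4, 1:5, 2:4, 3:1} histogram, and no call at the two printed 0.10
  boundary deviations.

## Known limitations

* Genome-wide findings of the original cohort (counts of significant
  probes, the specific VMP loci) are not reproducible here: the raw
  cohort data were never deposited. The fixture covers the *worked
  example* of the caller, not the scan that produced its candidate list.
* The F-test is exact under normality and is known to be sensitive to
  non-normality; on bounded beta values it is an approximation. The
  Monte-Carlo calibration covers the Gaussian case; heavy-tailed probes
  will inflate the scan's type-I error, which the FDR step only partly
  absorbs.
* Group sizes of 14 vs 25 give the variance test limited power; the
  candidate filters trade recall for specificity by design.
* With two timepoints, a "private epimutation" cannot be distinguished
  from a single aberrant measurement at MF; the design accepts this.
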