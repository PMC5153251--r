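---
title: "Methods: hydrocarbon elucidation, profile comparison and NSAF counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrocarbon elucidation, profile comparison and NSAF counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophochem)
```

This vignette is the package's own account of the models and procedures it
implements, of the parameters that matter, and of the design choices that
were genuinely open. The setting is the chemistry of social-insect
trophallactic fluid (TF): the orally exchanged crop fluid of ants carries
long-chain cuticular hydrocarbons (CHCs), and the package provides the
computations needed to (i) identify linear and methyl-branched alkanes from
their electron-impact spectra, (ii) compare TF and cuticular chromatographic
profiles across colonies, and (iii) quantify TF proteomes by spectral
counting.

## 1. Branched-alkane elucidation from EI spectra

### The model

At 70 eV, saturated alkanes fragment predominantly into the alkyl series
CnH2n+1 (m/z 43, 57, 71, ..., 14n + 1), whose intensities decay smoothly
with mass. The package models this envelope as

  I(m) = A exp(−λ m),

with amplitude A (intensity units) and rate λ (per Da). Cleavage next to a
methyl-branch carbon is favored, so a branch at locant b on a backbone of
length L produces an **enhanced pair** of even-electron ions

  m_low = 14 b + 15,  m_high = 14 (L − b + 2) + 1,

which coincide when the branch sits at the chain midpoint. For a monomethyl
alkane of nominal parent mass M = 14(L + 1) + 2 the pair sums to M + 28;
for k branches the analogous complement sum is M + 42 − 14k. Everything is
nominal-mass arithmetic (C = 12, H = 1, O = 16): the workflow targets
unit-resolution quadrupole spectra.

`identify_compound()` chains the stages: `alkyl_series()` →
`fit_decay()` → `enhanced_ions()` → `estimate_branch_count()` →
`infer_branch_positions()` → `check_consistency()`.

### Numerical choices

* **Fit loss and functional form.** The envelope has no offset term and is
  fitted by ordinary least squares on the intensity scale
  (Levenberg–Marquardt via `minpack.lm`, started from the log-linear
  regression). On noiseless series both parameters are recovered to
  numerical precision; the suite asserts six significant digits.
* **Fit domain.** The two lowest-mass present series members (typically
  m/z 43 and 57) are excluded: in real spectra they are dominated by
  non-specific fragmentation and sit far off the envelope.
* **Outlier-aware fitting.** Enhanced ions must not bias the envelope. The
  scheme is: fit a robust M-estimator regression (`MASS::rlm`) on
  log-intensities, flag members whose intensity exceeds that envelope by a
  factor τ, re-fit the robust envelope without them, and iterate to
  stability (at most `max_fit_iterations = 5` rounds); the reported (A, λ)
  are then the OLS fit over the clean members. Detection uses the robust
  log-scale envelope rather than the OLS fit itself for two reasons
  observed during development of the method: a strongly enhanced low-mass
  ion inflates the OLS amplitude enough to hide itself below the threshold,
  and threshold-flagging against an already-contaminated fit can cascade
  into excluding the whole high-mass tail. The robust envelope is accurate
  across the full mass range because it works on the log scale, where the
  model is linear and enhanced ions are simple positive outliers.
* **Enhancement threshold τ = 3** (dimensionless intensity ratio). The
  generator's enhancement factor of 5 reflects the clearly visible
  enhancements in branched-alkane spectra; τ = 3 sits between that and the
  multiplicative noise level (lognormal σ ≈ 0.1–0.15, so a spurious 3x
  excursion is a ≥ 7σ event). Exposed as `tau`.
* **Pairing tolerance ± 1 Da** on the complement sum, integer-locant
  check on inversion (a pair whose low ion does not satisfy
  b = (m_low − 15)/14 ∈ {2, ..., L−1} is rejected).
* **Single-sided pairs.** The low diagnostic ion of a 2- or 3-methyl
  branch falls at m/z 43 or 57 — inside the excluded low-mass region — so
  only its high-mass partner is observable. An unpaired enhanced ion whose
  complement lies below the fit domain is therefore accepted as a pair with
  that unobservable complement. This mirrors how 2-/3-methyl alkanes are
  assigned in practice (from the strong M−29/M−43-type fragment alone) and
  is required for exact round trips at those locants.
* **Branch counts beyond one.** The monomethyl sum M + 28 is tried first;
  if enhanced ions remain unpaired, the k-specific sums M + 42 − 14k
  (k = 2..5) are tried and the self-consistent k (pair count equal to k) is
  kept. Multi-branch locant sets are enumerated over both chain-end
  numberings, canonicalized to lowest locants, and flagged ambiguous when
  more than one distinct set survives — positional isomers of dimethyl
  alkanes genuinely cannot be separated by this information alone.
* **Degenerate inputs.** Fewer than four positive series members is an
  error; a fitted rate indistinguishable from zero (λ ≤ 1e−8 per Da, far
  below the 0.01–0.03 of real alkyl envelopes) flags the spectrum flat and
  the elucidation inconclusive rather than failing.

## 2. Kovats retention indices and consistency curves

Retention indices are computed by the van den Dool–Kratz linear
interpolation, the standard for temperature-programmed GC (the study design
this package models uses a ramped oven program); the logarithmic
(isothermal) form is deliberately not offered. The n-alkane with n carbons
maps to exactly 100n, the index is invariant to a common shift of all
retention times, and integer reporting uses half-up rounding, matching the
integer RI column of the packaged compound table. Ladder gaps (a missing
n-alkane) interpolate across the gap with a warning; retention times
outside the ladder span are refused — which is why the packaged table's
rows above C31 cannot be re-indexed from the table's own alkane rows.

Reference curves of RI vs. total carbon number are built per branching
class k = 0..5 by averaging all available literature values per
(carbons, k) and connecting the means piecewise-linearly;
non-monotone means abort curve construction with the offending points
listed. `check_consistency()` compares an observed RI against the
hypothesis's class curve with tolerance `ri_tol = 15` RI units — wide
enough for stationary-phase and program differences between the reference
collection and a given run, narrow enough to separate adjacent branching
classes, which sit ~35–60 units apart per branch. Hypotheses outside a
curve's carbon span return "inconclusive", a distinct verdict from "fail".

## 3. Chromatographic profile comparison

Per sample: restrict to the long-chain CHC retention window (default
36–51 min, covering C28–C37 under the modelled GC program; configurable),
min–max normalize the trace to [0, 1], detect local maxima at or above 7%
of the normalized range (`rel_threshold = 0.07` — the threshold is applied
after normalization, since detection follows normalization in the
procedure's stated order), and sum peak abundances into 0.03-min bins whose
edges are anchored at 0.0 min so every sample shares the binning.

Similarity between two binned profiles is the coefficient-normalized
cross-correlation Σ p1[i] p2[i+ℓ] / (‖p1‖‖p2‖), maximized over lags
|ℓ| ≤ `max_lag`. The default `max_lag = 0` compares aligned bins: binning
already absorbs sub-bin retention drift, and allowing lags on peak-sparse
vectors mostly rewards accidental alignments. Both the normalization mode
and the lag range were open choices; they are exposed as arguments.

Group comparison takes the cross-colony within-TF and within-body pairwise
similarities and applies Welch's t-test (default; pooled-variance and
permutation variants available, and the permutation route is the documented
fallback when both groups are degenerate). A caveat the calibration suite
makes explicit: pairwise similarities that share a sample are positively
correlated, so the t-test's independence assumption does not hold and it
rejects a true null more often than its nominal level — a structural
property of testing pairwise similarity values, inherited from the study
design this reproduces. The direction and strength of the TF-vs-body
contrast at realistic effect sizes are unaffected; p-values near the
threshold should be read with this in mind.

Hierarchical clustering uses correlation distance (1 − r) with average
linkage. Edge support is the percentage of bootstrap replicates (resampling
bins, or proteins for proteomic samples, with replacement; default
`n_boot = 10000`) in which an edge's leaf set recurs as a cluster. An
approximately-unbiased (AU) correction by multiscale bootstrap — replicates
at relative sizes 0.5–1.4 with the signed-distance/curvature extrapolation
— is available behind `multiscale = TRUE`; plain bootstrap proportions are
the default because they are fully specified by the resampling scheme
alone. Dendrograms export to Newick with support as node labels.

## 4. NSAF spectral counting

NSAF_ps = (SpC_ps / L_p) / Σ_q (SpC_qs / L_q): spectral counts are divided
by protein length (longer proteins yield more peptides) and renormalized so
each sample column sums to one. No pseudocounts are added; zero counts give
NSAF 0. When only a displayed subset of proteins is reported,
`relative_nsaf()` renormalizes within the subset. Because NSAF is
compositional, a genuine increase of a few proteins necessarily depresses
all other relative shares — directions of flagged changes should be read
jointly, and the worked example in the README shows the effect.

Condition testing is a per-protein two-sample t-test on NSAF values with
Bonferroni control at `alpha / family_size`; the family size defaults to
the number of proteins actually tested (the displayed top set, default top
40 by mean NSAF). Pairing by colony is applied automatically when every
colony contributes exactly one sample per condition — the repeated-measures
design of sampling the same groups before and after social isolation — and
both modes are available explicitly since the original design leaves the
choice open. Proteins with zero variance in both groups are skipped with a
warning rather than producing NaN statistics.

## 5. What the synthetic generators emulate — and what they do not

* `gen_alkane_ladder()`: a C8–C40 standard mixture with affine (optionally
  mildly curved, jittered but monotone) retention times.
* `gen_ei_spectrum()`: the alkyl ladder under the exponential envelope
  (A = 1000, λ = 0.02 per Da — the mid-range slope of long-chain alkane
  spectra), multiplicative lognormal noise, a 5x enhancement of every
  diagnostic ion, and a weak parent ion. It does **not** simulate isotope
  envelopes, the CnH2n−1 companion series, column bleed, or co-eluting
  contamination.
* `gen_cohort()`: five colonies × (TF, body), one sample each, as Gaussian
  peaks (SD 0.02 min) drawn from a species-wide 25-peak pool — sized to the
  ~20 labelled dominant peaks of real long-chain CHC profiles — with
  per-sample lognormal height variation (σ = 0.3) and additive baseline
  noise. TF samples carry 90% of the pool, body samples a colony-specific
  50% subset; that sharing contrast is the effect under study and is
  configurable (equal shares give the null). Retention drift, peak-shape
  asymmetry and within-colony replication are not simulated.
* `gen_count_matrix()`: negative-binomial counts (dispersion 5 — chosen
  over Poisson to stress the t-test with realistic overdispersion) with
  mean proportional to protein length × lognormal abundance, 40 proteins,
  6 samples per condition, and a multiplicative effect on a configured
  protein fraction; truth flags are returned alongside.

Every generator requires a seed for any stochastic output and is
bit-reproducible under it. Passing tests on these generators demonstrates
the correctness of the computations under the stated models; they do not
demonstrate robustness to instrument artifacts the generators do not
produce (drift, co-elution, missing identifications).

## 6. Problem sizes used by the test suite

The suites run the noiseless monomethyl round trip exhaustively
(L = 23..37, every canonical locant), 200 seeded noisy elucidation
replicates, 200 decay-fit recovery replicates, 400 null-calibration
cohorts, 400 null count-matrix replicates, and bootstrap clustering at
reduced replicate counts (tens) — sizes chosen so the whole suite completes
in well under a minute while keeping the binomial uncertainty of the
estimated rates a few percentage points. The `n_boot = 10000` default of
the clustering functions matches the support resolution used in published
dendrograms and is meant for analysis runs, not tests.

## 7. Known limitations

* Double-bond positions in alkenes are not localized (they remain
  asterisked, as in the packaged compound table); esters, acids and
  sterol-like molecules are carried as annotated records without
  fragmentation prediction.
* The printed molecular weight of one packaged-table row (C21H44) differs
  by 1 Da from its formula's nominal mass; the table stores both values
  with a flag rather than guessing which was intended.
* Dimethyl and higher positional isomers are enumerated, not
  disambiguated; candidates are flagged ambiguous.
* The group-comparison t-test on pairwise similarities is anti-conservative
  under dependence (Section 3); the permutation variant shares the
  limitation, as label permutation also assumes exchangeable pairs.
* Nominal-mass arithmetic throughout: high-resolution data gain nothing
  from the extra digits here.
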