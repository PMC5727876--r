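---
title: "Methods: evaluating pre-endoscopy risk scores for UGIB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating pre-endoscopy risk scores for UGIB}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ugibrisk)
```

## The problem and the scores

A patient presenting to the emergency department with upper gastrointestinal
bleeding (UGIB) must be triaged before endoscopy: does this patient need an
intervention (transfusion or endoscopic/radiologic/surgical hemostasis), and
is this patient at high risk of dying within 30 days? Three additive point
scores are computable from presentation data alone and are evaluated here:

- **mGBS** (0–16): banded points for pulse (≥ 100 → 1), systolic blood
  pressure (100–109 → 1, 90–99 → 2, < 90 → 3), blood urea nitrogen in mg/dL
  (19–22.3 → 2, 22.4–27.9 → 3, 28–69.9 → 4, ≥ 70 → 6) and hemoglobin in g/dL
  (men: 12–12.9 → 1, 10–11.9 → 3, < 10 → 6; women: 10–11.9 → 1, < 10 → 6).
- **GBS** (0–23): the mGBS bands plus hepatic disease (2), cardiac failure
  (2), melena (1) and syncope (2).
- **Pre-E RS** (0–7): age (< 60 → 0, 60–79 → 1, ≥ 80 → 2), shock, and
  comorbidity (none → 0; major, e.g. ischemic heart disease or congestive
  heart failure → 2; severe, i.e. renal failure, hepatic failure or
  malignancy → 3).

Three band conventions deserve explicit statement because the printed tables
leave them ambiguous:

1. **Half-open intervals on the printed decimals.** A printed band
   "22.4–27.9" is implemented as [22.4, 28): the underlying bands are
   contiguous and the one-decimal prints are a rounding artifact, so a value
   in a printed gap (BUN 22.35) belongs to the band whose half-open interval
   contains it — here [19, 22.4), scoring 2. A boundary-grid test asserts
   every such value maps into exactly one band.
2. **Pulse thresholds differ between scores and are preserved exactly.**
   The mGBS tachycardia band is ≥ 100; the Rockall shock item is > 100. A
   pulse of exactly 100 scores 1 on the mGBS and 0 on the Pre-E RS.
3. **Shock is a single ordinal item.** Hypotension (SBP < 100, 2 points)
   takes precedence over tachycardia (1 point); they are never summed, since
   the original Rockall shock item is one category, not two flags.

Flags (melena, syncope, hepatic disease, cardiac failure) default to absent
when their columns are missing: the scores award points only for a
documented "present". Vitals and labs are mandatory and strictly positive;
age is at least 18 (the study population is adults). BUN is taken in mg/dL
exactly as the score tables define it; no urea/SI conversion is offered.

## ROC, tie-corrected AUC and the DeLong machinery

Scores are small integers, so ties are everywhere and the tie correction is
not optional. The AUC is the tie-corrected Mann–Whitney estimator

$$\widehat{\mathrm{AUC}} = \frac{1}{n_+ n_-} \sum_{i,j}
  \Big[ \mathbb{1}(s^+_i > s^-_j) + \tfrac12 \mathbb{1}(s^+_i = s^-_j) \Big],$$

computed from grouped per-score counts in integer arithmetic (half-credits
are doubled, so the numerator is an exact integer and the estimate is the
exact rational value). The empirical ROC uses the strictly-greater rule
("positive when score > c", the convention of the published threshold
tables; the ≥ alternative is deliberately not offered), with one point per
distinct observed score; the trapezoidal area under this curve equals the
tie-corrected AUC identically, and a property test asserts agreement to
1e-12.

Variances come from DeLong placement values: for each positive patient the
fraction of negatives they outscore (ties half), and symmetrically for
negatives. The AUC variance is the sum of the two placement sample variances
scaled by their class sizes; the paired test for two scores on the same
patients standardises the AUC difference by
$\mathrm{var}(A) + \mathrm{var}(B) - 2\,\mathrm{cov}(A,B)$ with covariances
taken across paired placements, and refers $z$ to a standard normal
(two-sided). Placements are computed from mid-ranks in O(n log n). Numerical
edge cases: a class with a single member has no placement spread and
contributes 0 variance (so a single discordant pair reports AUC 1, SE 0);
identical score vectors short-circuit to z = 0, p = 1 rather than 0/0; the
95% CI is the normal approximation truncated to [0, 1]. The CI method is
DeLong's normal interval throughout (not Hanley–McNeil), matching the
machinery used for everything else. Cluster-adjusted or unpaired DeLong
variants, smoothed/binormal ROC and partial AUC are out of scope.

The paired test requires per-patient data by construction: marginal
per-score tables destroy the pairing between two scores on the same patient.
The fixture-reproduction path therefore reports paired tests as not
computable from the packaged tables, and runs them only on per-patient
(synthetic) cohorts.

## Threshold diagnostics and 2×2 analyses

`metrics_at_cutoff()` reports sensitivity, specificity, PPV and NPV
(percentages) under the strictly-greater rule; an empty denominator yields
`NA`, never 0 or 100. Published tables round sens/spec to 2 decimals and
PPV/NPV to 1; the package computes unrounded values and rounds only in
reports. The optimal cutoff maximises Youden's J = sens + spec − 100, ties
broken toward the smaller cutoff.

`reconstruct_confusion()` inverts a printed (sens, spec) row to the integer
2×2 table via nearest-integer TP and TN; the round trip reproduces the
printed values at printed precision, and Bayes consistency
$\mathrm{PPV} = \mathrm{sens}\,\pi / (\mathrm{sens}\,\pi +
(1-\mathrm{spec})(1-\pi))$ holds exactly for every reconstructed table.

Odds ratios carry Woolf (log-normal) 95% CIs,
$\exp(\ln \mathrm{OR} \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d})$, which require
all four cells positive; zero-cell corrections are explicitly refused rather
than silently applied. The chi-square is the uncorrected Pearson statistic:
the continuity-corrected statistic does not reproduce the published timing
chi-squares, the uncorrected one reproduces both — this pairing validates
the no-Yates decision, and no Yates correction exists anywhere in the
package. Fisher/mid-p exact tests and CIs on proportions are non-goals (the
study prints none to verify against).

`derive_survivor_split()` recovers unprinted survivor cells: given a
subgroup total, the death counts in two exposure arms and one printed
statistic (OR or chi-square), it enumerates every integer split of the
survivors, keeps those matching the statistic at 3-decimal rounding, and
*requires uniqueness* — with zero or multiple matches it fails loudly
instead of picking. Equal death counts make the chi-square symmetric in the
split, so such inputs are provably ambiguous; a test exercises exactly that
failure.

## The packaged fixtures and their derivations

The grouped fixtures transcribe the study's printed tables; every loader
re-checks the printed margins (590 patients = 280 intervention-positive +
310 negative per system; 25 deaths / 565 survivors). Three derivations go
beyond transcription, each with its oracle named in the fixture header:

- **One corrected cell.** The printed GBS score-9 row (Y = 4 / N = 55)
  contradicts both its own printed row total (70) and the printed column
  total (310); both constraints force N = 66. This is the only cell
  deviating from print and it is flagged in the fixture.
- **Mortality by score.** Deaths per Pre-E RS score are not printed, but the
  published cumulative mortality sensitivities pin them down: 25 deaths with
  23 above cutoff 2, 22 above 3, 22 above 4, 8 above 5 and 8 above 6 give
  deaths {3: 1, 4: 0, 5: 14, 6: 0, 7: 8} by differencing against the
  per-score totals, leaving 2 deaths at scores ≤ 2. All six feasible
  placements of those two deaths were enumerated (their AUCs ship as fixture
  metadata, spanning 0.908–0.949); exactly one placement — one death at
  score 0, one at score 2 — yields a mortality AUC rounding to the published
  0.929, and that placement is the packaged derived fixture. Recomputing all
  five published mortality rows from the reconstruction reproduces them at
  printed precision.
- **Timing 2×2 tables.** The endoscopy-timing analyses print subgroup sizes
  (397 with GBS > 9; 372 with mGBS > 9), the death split (12 late vs 9 early
  endoscopy) and one statistic each; the survivor cells come from the
  unique-match search and are cross-validated against the remaining printed
  statistics. (The narrative's 397/372 differ by 2 from the corrected
  grouped counts' 399/374; the printed subgroup sizes are used, and both
  values are preserved in the fixture header.)

Two published quantities are *not* reproducible and are reported as such
rather than approximated: the GBS and mGBS intervention AUCs (the grouped
counts yield 0.653 and 0.632, not the published 0.727/0.733 — the grouped
table and the published ROC analysis are mutually inconsistent for these two
scores, and no transcription choice reconciles them) and all paired DeLong
p-values (pairing lost, as above). Only the Pre-E RS intervention AUC, which
the grouped counts do reproduce exactly (0.564), is treated as an anchor.
Relatedly, the published CI attached to that AUC (0.696–0.769) excludes its
own point estimate and is plainly a copy error; no CI from that sentence is
used for validation. Table 2 also reports 449 transfused patients against
280 intervention-positive in the grouped table — the two tables evidently
operationalise "intervention" differently; both are preserved, no
reconciliation is attempted.

## The synthetic cohort generator

The generator exists so the per-patient machinery (DeLong pairing, cohort
evaluation, schema IO) is testable end-to-end without patient data. Two
independent standard-normal latent axes are the minimal structure that
reproduces the study's crossed discrimination pattern:

- **bleeding severity** drives the vitals and labs (monotone linear links
  with Gaussian noise; log-linear for BUN), the bleeding flags (melena,
  syncope, hepatic disease) and the intervention outcome (logistic, slope
  1.6);
- **frailty** drives age (loading 0.8 on a sd-25 age distribution centred so
  49.3% are ≥ 80), cardiac disease, the proportional-odds comorbidity level
  and the death outcome (logistic, slope 2.2, plus a weak 0.3 on severity).

So the hemodynamic/laboratory scores discriminate intervention while the
age/comorbidity score discriminates mortality, by design and not by
accident; a 100-seed property test at n = 20,000 asserts the ordering holds
in ≥ 95% of seeds. Logistic intercepts are solved numerically (Gaussian
quadrature of the marginal prevalence) against the study cohort's marginals
— female 36.4%, age ≥ 80 49.3%, melena 48.8%, syncope 3.4%, hepatic disease
6.9%, cardiac disease 57.1%, intervention 280/590, 30-day mortality 4.2% —
so large-n cohorts hit the targets by construction; a 50,000-patient check
verifies each marginal within the 3-binomial-sd band the generator promises
at n = 590. Remaining free choices (vital-map slopes and noise, the
endoscopy-delay lognormal with sicker patients scoped sooner) were fixed
once at values giving mean scores near the study's (GBS ≈ 10, mGBS ≈ 9,
Pre-E RS ≈ 2–3) and physiologic truncation ranges (pulse 40–180, SBP 60–220,
BUN 5–150, Hb 4–18) keep every record schema-valid.

A single integer seed governs all draws and the caller's RNG state is
restored afterwards; identical (spec, seed) pairs yield identical cohorts.
The latent axes are attached to the output so calibration is checkable: a
logistic refit of the outcomes on the true latents recovers the generator
slopes within 10% at n = 50,000 (tested).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: correlations among vitals beyond the single
severity axis, measurement rounding habits, missing data, time-varying
presentation, any dependence structure between the two axes, per-patient
fitting to the real cohort (no per-patient data exists to fit), or survival
time beyond the 30-day binary. Synthetic AUC magnitudes are therefore not
calibrated to the published ones (e.g. the synthetic Pre-E RS mortality AUC
runs near 0.8, not 0.929); only the orderings and the marginals are design
targets.

## Problem sizes and determinism

The fixture-reproduction path is deterministic and bit-stable (no randomness
anywhere on it). Stochastic property tests use fixed seeds and these sizes,
chosen to make the asserted properties sharp: bootstrap cross-check of the
DeLong SE at n = 20 with 10,000 resamples (agreement within 15%);
paired-test power against a permuted-score null at n = 500 over 200 seeds
(≥ 95% rejection); discrimination-ordering check at n = 20,000 over 100
seeds; calibration checks at n = 50,000.

## Known limitations

Only the three pre-endoscopy scores are implemented — the full
(post-endoscopy) Rockall score, AIMS65 and other instruments are out of
scope, as is imputation of missing clinical values. The threshold machinery
assumes integer scores (cutoffs are score values). The grouped-data AUC path
cannot produce DeLong CIs (per-patient data required), and the published
GBS/mGBS intervention AUCs remain irreproducible from the available tables,
as documented above.
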