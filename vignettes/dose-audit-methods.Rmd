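---
title: "Methods: effective-dose auditing for conventional and LAFOV PET/CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: effective-dose auditing for conventional and LAFOV PET/CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petctdose)
```

## The problem

When a nuclear-medicine department replaces a conventional PET/CT scanner
with a long axial field-of-view (LAFOV) system, the order-of-magnitude gain
in PET sensitivity allows the injected FDG activity to be roughly halved
without loss of image quality. An effective-dose audit quantifies what that
transition did to patient radiation burden: how much the PET component
fell, whether the CT component changed, and how the balance between the two
shifted. `petctdose` implements that audit as a reusable pipeline —
per-patient dosimetry, weight-stratified cohort comparison, and a seeded
synthetic-cohort generator that stands in for hospital records, which are
not publicly shareable.

## Dosimetry model

**PET component.** The effective dose from the injected activity is

$$ED_{PET} = A \,(\mathrm{MBq}) \times c \,(\mathrm{mSv/MBq}),$$

where the coefficient $c$ comes from the ICRP publication 128 reference
models. Each patient is assigned the model closest to their weight:
patients above 65 kg use the 70 kg adult (0.019 mSv/MBq), patients of
45–65 kg the 57 kg adult (0.024 mSv/MBq), and patients below 45 kg the
33 kg child (0.036 mSv/MBq). We read "45–65 kg" as the closed interval
$[45, 65]$, so both boundary weights map to the 57 kg adult; the
neighbouring rules are then strict inequalities, which makes the assignment
a partition of all positive weights. The 0.019 mSv/MBq adult value is used
rather than the more recent 0.017 mSv/MBq proposal, since the latter is not
yet in an ICRP publication.

Two rescalings refine the reference-model dose. Weight scaling multiplies
by the ratio of model weight to actual weight,

$$ED_{PET\text{-}WS} = ED_{PET} \times \frac{m_{model}}{m_{patient}},$$

and blood-volume scaling replaces the mass ratio with a blood-volume ratio,

$$ED_{PET\text{-}BV} = ED_{PET} \times \frac{IBV}{70\ \mathrm{ml/kg}},
\qquad
IBV = \frac{70\ \mathrm{ml/kg}}{\sqrt{BMI / 22}},$$

which is better suited to large patients, where much of the absorbed dose
goes to adipose tissue. The indexed blood volume (IBV) construction
satisfies $IBV \times \sqrt{BMI/22} = 70$ identically; the test suite
checks this closure to $10^{-9}$ across BMI 5–100. Heights are stored in
cm (the clinical-records convention) and converted inside the BMI
computation. When height is missing, the blood-volume quantities are
*absent* — not zero, not imputed — and the patient is excluded from
blood-volume summaries, with the exclusion count reported in the audit
metadata. This mirrors real audits, where height is the most frequently
unrecorded field.

**CT component.** The scanner-reported dose-length product is converted
with the whole-body factor

$$ED_{CT} = DLP\,(\mathrm{mGy\,cm}) \times 0.018\ \mathrm{mSv/(mGy\,cm)},$$

and totals are sums, $ED_{Total} = ED_{CT} + ED_{PET}$, computed once per
PET variant. Internally everything is kept at full precision; one decimal
place (or three significant figures for small worked examples) is applied
only at the reporting layer.

**CT exposure helpers.** Organ-dose modelling tools require acquisition
inputs the dose report does not state directly. For a multi-slice scanner,
total collimation = slice collimation × simultaneously acquired channels,
and table feed = total collimation × pitch. Scanners under automatic
exposure control do not record the delivered average mAs, so it is
recovered from the reported CTDIvol via
$\mathrm{mAs} = 100 \times CTDI_{vol} \times pitch / {}_{n}CTDI_w$, where
$_{n}CTDI_w$ (mGy per 100 mAs) is a scanner constant supplied through
configuration — the shipped values are synthetic placeholders, and the
tests of this inversion are purely algebraic. When a cohort's gender is
unknown and a male phantom is assumed throughout, the potential error of
that assumption is reported as
$100 \times (ED_{female} - ED_{male}) / ED_{female}$; the female-model
denominator is a deliberate convention, chosen because it reproduces the
reference values this helper is checked against (16.9% and 16.1%), and it
is documented here because the defining formula is rarely written out.

## Cohort comparison

Cohorts are stratified into seven weight categories — `<50`, `50–59`, …,
`90–99`, `>100` kg — implemented as contiguous half-open bins
$[\ell, \ell+10)$ with `>100` $= [100, \infty)$. A patient of exactly
100 kg falls in `>100`: the category names alone leave 100 kg unassigned,
and assigning it upward keeps the bins a partition.

Summaries are medians with interquartile ranges, which resist the outliers
expected in the extreme weight bins; quartiles use linear interpolation
between order statistics (type-7 quantiles), fixed explicitly because IQRs
differ slightly across quantile conventions. Cohorts are compared per
quantity and stratum by the percentage difference of medians (reference =
the earlier, conventional-scanner cohort) and a two-sided Mann–Whitney U
test, appropriate because the between-cohort variances are generally
unequal. The p-value is exact — full enumeration of the permutation null —
when the combined sample is at most 12 and tie-free (a threshold at which
enumeration is instant and deterministic), and otherwise uses the normal
approximation with midranks, tie-corrected variance and continuity
correction. Degenerate samples with zero rank variance return p = 1. The
significance flag is $\alpha = 0.05$ with no multiple-testing correction,
matching standard practice in descriptive dose audits. The exact branch is
verified in the tests against an independent brute-force enumeration
oracle over all labelings.

The audit also reports the CT share of the weight-scaled total dose,
$100 \times ED_{CT} / ED_{Total\text{-}WS}$, computed per patient and
summarised by stratum medians — the quantity that shows CT becoming the
dominant dose source after a LAFOV transition.

## The synthetic cohort generator

The generator's defaults encode the study conditions of the audited
transition and are not meant to be tuned:

* **Strata.** Per-stratum sample sizes and target median weights follow
  the audited cohorts (484 conventional-scanner and 553 LAFOV studies).
  Within a stratum, weights are drawn from a normal centred on the target
  median, truncated to the stratum bounds; only medians and counts are
  known, so any distribution matching them is admissible and the truncated
  normal is the simplest documented choice. Spreads of 3 kg (3.5 kg for
  `<50`, 8 kg for `>100`) give realistic within-bin dispersion; the
  open-ended bins are truncated at 35 and 160 kg to avoid implausible
  tails.
* **Injected activity.** The conventional protocol is 250 MBq, switching
  to 300 MBq above 90 kg; the LAFOV protocol is a flat 150 MBq.
  Multiplicative lognormal jitter models dispensing variation. Its median
  multiplier for the conventional cohort (1.17) was solved from the
  closed-form median of the 250/300 base mixture so the cohort median
  lands near the audited 303 MBq — the excess over protocol reflecting
  concurrent clinical-trial injections, reproduced here through jitter
  rather than an explicit trial subgroup. The LAFOV multiplier
  (149.5/150, sd 0.05) puts that cohort's median near 149.5 MBq.
* **DLP.** $DLP = \exp(a + b\,w + \varepsilon)$,
  $\varepsilon \sim N(0, 0.22^2)$. The coefficients are a least-squares
  fit of log median DLP against median weight over the seven strata of
  each audited cohort ($a = 4.797$, $b = 0.0165$ conventional;
  $a = 4.683$, $b = 0.0187$ LAFOV), so noise-free stratum-median CT doses
  reproduce the audited per-stratum medians within a few percent (the
  tests enforce ±15%). The log-scale noise sd of 0.22 gives IQR ratios
  comparable to the audited CT-dose IQRs once the weight spread is added.
* **Height and missingness.** BMI is drawn from a normal(26, 4) truncated
  to 15–45 kg/m² — a realistic adult oncology-referral distribution, since
  the audit publishes no height summaries — and height is back-computed as
  $h = 100\sqrt{w/BMI}$ cm. Exactly `round(n(1 - rate))` patients keep
  their height; the default rates reproduce the audited 387/484 and
  134/553 recorded heights.
* **Gender.** Sampled at the audited cohort ratios (273 male / 210 female /
  1 unknown, and 319/234), carried through for gender-aware CT reporting
  even though the in-scope dosimetry is gender-independent.

Generation is byte-reproducible for a fixed spec and seed and leaves the
caller's RNG stream untouched. What the generator deliberately does *not*
emulate: scan-length and bed-position variation, acquisition-time
distributions, correlated activity–weight protocols beyond the 90 kg tier,
or any within-patient correlation between PET and CT dose beyond their
shared weight dependence. Tests that pass on synthetic cohorts therefore
validate the pipeline's arithmetic, stratification and statistics — not
distributional claims about any particular hospital's patients.

## Numerical and degenerate-input choices

Zero activity or zero DLP are valid inputs (zero dose); non-positive
weights, BMIs or reference medians are errors with classed conditions so
callers and the CLI can distinguish validation from configuration
failures. Empty strata yield empty statistics and blank rendered cells
rather than NaNs; stratum/quantity cells with n < 5 trigger a warning
because their medians are unstable. Totals are checked to equal their
addends to $10^{-12}$.

## Problem sizes

The packaged tests and the acceptance script run the full pipeline at the
audited cohort sizes (484 + 553 patients), which completes in seconds; the
Mann–Whitney oracle suite enumerates all labelings for combined samples up
to 10, the largest size at which full enumeration stays instant.

## Worked audit

```{r audit}
mct <- generate_cohort(mct_cohort_spec(seed = 1))
quadra <- generate_cohort(quadra_cohort_spec(seed = 2))
report <- run_audit(mct, quadra)
report
```

## Limitations

Organ-level dosimetry is out of scope: the CT conversion uses a single
whole-body DLP factor, and the phantom-based organ-dose computation behind
the male/female comparison is treated as an external reference whose input
arithmetic (collimation, feed, mAs) this package reproduces. The ICRP
reference models under-represent very large patients, which is precisely
why the weight- and blood-volume-scaled variants are carried alongside the
unscaled dose. Cohort medians of per-patient doses are not recoverable
from published summary tables alone, so synthetic-cohort checks are
tolerance bands around the audited findings, not exact reproductions.
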