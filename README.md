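# petctdose

Effective-dose auditing for whole-body FDG PET/CT, built for the question a
physics team faces after replacing a conventional scanner with a long axial
field-of-view (LAFOV) system: the ~10× PET sensitivity gain lets the
injected activity be roughly halved — so how did patient radiation burden
actually change, component by component and weight class by weight class?

The package is aimed at medical physicists and nuclear-medicine researchers
running retrospective dose audits from routine records (weight, injected
activity, CT dose-length product, and — when recorded — height and gender).

## The model

Per patient, the PET effective dose is

    ED_PET = A (MBq) × c (mSv/MBq)

with the ICRP publication 128 coefficient `c` of the reference model
nearest the patient's weight: 0.019 mSv/MBq (70 kg adult, weight > 65 kg),
0.024 mSv/MBq (57 kg adult, 45–65 kg), 0.036 mSv/MBq (33 kg child,
< 45 kg). Two refinements are carried alongside:

    ED_PET-WS = ED_PET × m_model / m_patient
    ED_PET-BV = ED_PET × IBV / 70,   IBV = 70 / sqrt(BMI / 22)  (ml/kg)

The CT effective dose comes from the dose-length product,
`ED_CT = DLP × 0.018 mSv/(mGy·cm)`, and totals are
`ED_Total = ED_CT + ED_PET` per PET variant. Cohorts are stratified into
the standard weight categories (< 50, 50–59, …, 90–99, > 100 kg) and
compared by medians/IQRs, percentage differences and two-sided
Mann–Whitney U tests, plus the per-patient CT share of the weight-scaled
total dose. Patients without a recorded height have no blood-volume dose
(absent, not imputed) and are excluded from those summaries with the
exclusion count reported.

A seeded synthetic-cohort generator reproduces the statistical structure
of an audited scanner transition (cohort sizes, weight strata, 250/300 vs
150 MBq activity protocols with calibrated jitter, weight-dependent DLP,
height missingness), so the whole pipeline runs and is tested without any
patient data. CT exposure helpers (total collimation, table feed, mAs from
CTDIvol, male/female phantom "potential error") cover the input arithmetic
of organ-dose modelling tools. See `vignettes/dose-audit-methods.Rmd` for
the full methods account.

## Worked example

A single patient — 70 kg, 178.4 cm, 150 MBq injected, DLP 420 mGy·cm:

```r
library(petctdose)
dose_result_for_patient(
  list(weight = 70, height = 178.4, injected_activity = 150, dlp = 420))
#> <dose_result> 70 kg adult model
#>   ed_pet           2.850 mSv
#>   ed_pet_ws        2.850 mSv
#>   ed_pet_bv        2.850 mSv
#>   ed_ct            7.560 mSv
#>   ed_total_icrp   10.410 mSv
#>   ed_total_ws     10.410 mSv
#>   ed_total_bv     10.410 mSv
```

At 70 kg the weight scaling is the identity (patient at model weight) and
a BMI of 22.0 leaves the blood-volume dose essentially unchanged; the CT
component (7.56 mSv) dominates this low-activity examination.

A full audit of two synthetic cohorts:

```r
mct    <- generate_cohort(mct_cohort_spec(seed = 1))     # 484 patients
quadra <- generate_cohort(quadra_cohort_spec(seed = 2))  # 553 patients
run_audit(mct, quadra)
#> <audit_report> mCT (n = 484) vs Quadra (n = 553)
#>
#> | Quantity          | Stratum | n A | Median A (IQR)      | n B | Median B (IQR)      | % diff | p          |
#> | ----------------- | ------- | --- | ------------------- | --- | ------------------- | ------ | ---------- |
#> | weight            | ALL     | 484 | 73.0 (63.8–85.4)    | 553 | 71.1 (60.3–83.3)    | -2.6   | 0.00813*   |
#> | injected_activity | ALL     | 484 | 299.8 (273.1–336.1) | 553 | 148.9 (143.8–154.4) | -50.3  | 3.03e-170* |
#> | ed_ct             | ALL     | 484 | 7.4 (6.0–9.2)       | 553 | 7.3 (5.7–9.7)       | -1.8   | 0.838      |
#> | ed_pet            | ALL     | 484 | 6.2 (5.4–7.0)       | 553 | 3.0 (2.8–3.5)       | -51.6  | 3.72e-165* |
#> | ed_pet_ws         | ALL     | 484 | 5.4 (4.6–6.5)       | 553 | 2.9 (2.4–3.4)       | -47.3  | 3.61e-157* |
#> | ed_pet_bv         | ALL     | 387 | 5.6 (4.9–6.6)       | 134 | 2.9 (2.6–3.2)       | -49.3  | 5.01e-65*  |
#> | ed_total_icrp     | ALL     | 484 | 13.7 (12.2–15.5)    | 553 | 10.4 (9.1–12.5)     | -24.2  | 4.52e-56*  |
#> | ed_total_ws       | ALL     | 484 | 13.4 (11.9–14.8)    | 553 | 10.2 (9.0–12.2)     | -23.5  | 3.83e-56*  |
#> | ed_total_bv       | ALL     | 387 | 13.2 (11.6–15.1)    | 134 | 10.3 (8.8–12.8)     | -21.9  | 9.08e-17*  |
#>
#> CT share of weight-scaled total dose (medians):
#> | Stratum | n A | CT share A (%) | n B | CT share B (%) |
#> | ------- | --- | -------------- | --- | -------------- |
#> | ALL     | 484 | 57.5           | 553 | 71.4           |
#> | <50     | 16  | 34.6           | 39  | 51.2           |
#> | 50–59   | 75  | 43.0           | 99  | 59.8           |
#> | 60–69   | 110 | 51.2           | 122 | 66.9           |
#> | 70–79   | 107 | 58.2           | 126 | 73.4           |
#> | 80–89   | 78  | 66.1           | 84  | 81.0           |
#> | 90–99   | 63  | 66.8           | 43  | 85.2           |
#> | >100    | 35  | 75.8           | 40  | 90.0           |
```

Reading the report: injected activity falls by ~50%, the PET dose variants
fall with it (all starred, i.e. Mann–Whitney p < 0.05), the CT dose is
statistically unchanged (p = 0.84), and consequently CT's share of the
total dose climbs from ~57% to ~71% overall — and past 90% in the heaviest
patients. `write_audit_report()` saves the full stratified tables as CSV
and Markdown; `ed_pet_bv` rows use only the 387 and 134 patients with a
recorded height.

A thin command-line front end with `simulate`, `audit`, `dose` and
`ct-helpers` subcommands lives at `inst/cli/petctdose.R`:

```sh
Rscript inst/cli/petctdose.R simulate --out-dir data --seed 9
Rscript inst/cli/petctdose.R audit data/mct_cohort.csv data/quadra_cohort.csv --out-dir report
```

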