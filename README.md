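# fieldqsar

3D-QSAR by lattice molecular fields in R: CoMFA (Lennard-Jones steric +
Coulomb electrostatic probe energies) and CoMSIA (Gaussian-attenuated
steric, electrostatic, hydrophobic, H-bond donor and acceptor similarity
indices) descriptors around aligned small molecules, partial least squares
(PLS/NIPALS) regression with leave-one-out cross-validation, exhaustive
model selection over field combinations, the Golbraikh–Tropsha
external-validation battery with Roy's rm² metrics, Y-randomization,
the standardization-approach applicability domain, and StDev\*Coeff
contour-field export (OpenDX / Gaussian cube).

The package is aimed at computational medicinal chemists who want the
complete, testable arithmetic of a field-based QSAR study — the kind used
to model, e.g., agonist potency (pEC50) of aryloxypropanolamine series at
the β3-adrenergic receptor — without a commercial modelling suite.

## The core model

Activities are regressed on probe interaction values sampled on a cubic
lattice (2 Å spacing, 4 Å padding). For molecule *m* and lattice point *q*:

- CoMFA steric: Σᵢ εᵢⱼ[(r_m/r)¹² − 2(r_m/r)⁶], clipped to ±30 kcal/mol;
- CoMFA electrostatic: Σᵢ 332.0636 qᵢ q_probe / r² (dielectric ε(r)=r),
  masked inside the steric envelope;
- CoMSIA property k: −Σᵢ w_probe,k · w_ik · exp(−0.3 r²).

PLS with LOO cross-validation yields q², SEP and the component count N
(max q², N ≤ ⌊n/3⌋); the fitted model reports SEE, r²_ncv, F and per-field
contribution percentages. Test sets are judged by r², through-origin
slopes/determination coefficients in both orientations (k, k′, r0², r0′²),
the Golbraikh–Tropsha conditions, and rm² = r²(1 − √(r²−r0²)).

## Worked example

Generate a synthetic aligned series with a planted structure–activity
relationship, fit a five-field CoMSIA model, and validate it:

```r
library(fieldqsar)
gen   <- generate_dataset(generator_spec(seed = 1))
model <- qsar_model(gen$dataset, method = "comsia")
model
#> <qsar_model> COMSIA - SEHDA
#>   q2 = 0.974  N = 9  SEP = 0.152  SEE = 0.073  r2_ncv = 0.994  F = 356
#>   r2_test = 0.986
validate_model(model)$all
#> <external_validation> n = 12
#>   r2 = 0.986  r0^2 = 0.983  r0'^2 = 0.980  k = 0.992  k' = 1.008
#>   rm2(sqrt) = 0.929  rm2(abs) = 0.983
#>   conditions passed: 7 / 7
```

q² is the leave-one-out cross-validated determination coefficient of the
29-compound training set (0.974: the planted linear signal is recovered
almost completely at noise sd 0.1); r2_test is the squared correlation
between observed and predicted activity for the 12 held-out compounds, and
the external-validation block shows all seven Golbraikh–Tropsha/rm²
conditions passing, as they should on data that satisfy the model's
assumptions.

The shipped reference tables reproduce the published validation numbers of
a 41-compound β3-agonist study from its per-compound predictions (test
set, CoMSIA outliers 40/41 excluded):

```r
pred <- load_reference_tables()$predictions
rows <- pred$test_set & !pred$comsia_outlier
external_metrics(setNames(pred$experimental[rows],     pred$compound[rows]),
                 setNames(pred$comsia_predicted[rows], pred$compound[rows]))
#> <external_validation> n = 10
#>   r2 = 0.918  r0^2 = 0.911  r0'^2 = 0.885  k = 0.995  k' = 1.004
#>   rm2(sqrt) = 0.843  rm2(abs) = 0.912
#>   conditions passed: 6 / 7
```

(The one "failing" condition is q² > 0.5, which is not computable from the
prediction table alone and is reported as NA unless supplied.)

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end on the
synthetic series and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generate the 41-molecule aligned dataset (MOL2 + manifest) |
| `02_fields.R` | build the lattice, compute CoMFA/CoMSIA blocks, export a field |
| `03_fit_and_select.R` | fit all 3 + 31 field combinations, rank models |
| `04_external_validation.R` | validation battery, synthetic + reference tables |
| `05_y_randomization.R` | 10 response permutations per method |
| `06_applicability_domain.R` | standardization-approach domain verdicts |
| `07_contour_maps.R` | StDev\*Coeff volumes with 80/20 percentile levels |

```sh
Rscript analysis/01_simulate.R   # FIELDQSAR_SEED overrides the default seed 1
```

## Scope notes

Inputs are assumed pre-minimized and pre-aligned (an optional Kabsch
superposition on matched atom indices is provided); conformer generation,
geometry optimization and protonation-state enumeration are out of scope.
See the methods vignette (`vignettes/field-qsar-methods.Rmd`) for the
model assumptions, parameter defaults and their rationale, and known
limitations.
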