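---
title: "Lattice-field QSAR with PLS: models, validation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice-field QSAR with PLS: models, validation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldqsar)
```

## The modelling problem

Comparative molecular field analysis (CoMFA) and comparative molecular
similarity index analysis (CoMSIA) relate the 3D structure of a series of
aligned small molecules to a potency measure — here pEC50, the negative
decadic logarithm of the molar EC50 — by probing the space around the
molecules on a regular lattice and regressing potency on the resulting
probe interaction values with partial least squares (PLS). The package
implements the full workflow: descriptor generation, PLS with leave-one-out
(LOO) cross-validation, model selection across field combinations, the
Golbraikh–Tropsha external-validation battery with rm² metrics,
Y-randomization, the standardization-approach applicability domain, and
StDev*Coeff contour fields for visualization. It also ships, as plain CSV,
the printed tables of a published CoMFA/CoMSIA study of 41
aryloxypropanolamine β3-adrenergic receptor agonists
(`load_reference_tables()`), which anchor the validation arithmetic to
published numbers.

## Fields

Molecules are placed in a cubic lattice (`build_grid()`) with 2 Å spacing
and 4 Å padding beyond the union bounding box; the origin is snapped down
to integer multiples of the spacing so that a rigidly translated copy of a
dataset produces identical descriptor columns.

**CoMFA.** At each lattice point an sp³ carbon probe (van der Waals radius
1.52 Å, charge +1 e, well depth 0.107 kcal/mol) accumulates

* a steric Lennard-Jones 6-12 energy,
  $E_s = \sum_i \varepsilon_{ij}\left[(r_m/r)^{12} - 2(r_m/r)^6\right]$
  with $r_m = R_i + R_{probe}$ and $\varepsilon_{ij} =
  \sqrt{\varepsilon_i\,\varepsilon_{probe}}$ (Lorentz–Berthelot), and
* a Coulomb electrostatic energy with distance-dependent dielectric
  $\epsilon(r) = r$, i.e. $E_e = 332.0636\, q_i q_{probe} / r^2$
  kcal/mol.

Both are truncated at ±30 kcal/mol. Where the unclipped steric energy
reaches the cutoff (the probe sits inside the molecular envelope) the
electrostatic entry is masked and later imputed with the column's
training-set mean — the convention of the original implementations.
Distances below 10⁻⁶ Å are clamped to 10⁻⁶ Å in the Coulomb kernel; the
steric clip dominates there anyway.

**CoMSIA.** Similarity indices with Gaussian distance dependence,
$A_k(q) = -\sum_i w_{probe,k}\, w_{ik}\, e^{-\alpha r_{iq}^2}$, with
attenuation factor α = 0.3 and a unit-weight probe of radius 1 Å. Atomic
weights: steric $R_i^3$, electrostatic the partial charge, hydrophobic an
atomic logP contribution, donor/acceptor binary flags carried on heavy
atoms. No cutoff is needed; the Gaussian is smooth everywhere.

The dielectric model, the padding, and the Lennard-Jones parameter table
are not fully pinned down by the published descriptions of the commercial
implementations; the package documents its choices (Sybyl-style 1/r
dielectric, 4 Å padding, a Tripos-style ε table with Bondi radii) and pins
the kernels with closed-form oracle tests instead of attempting to match
another program's absolute field values.

## Atom properties

`assign_atom_properties()` populates radii (Bondi), hydrophobicity, H-bond
flags, and charges. Charges either come from the input file (MOL2) or from
Gasteiger–Marsili partial equalization computed through OpenBabel.
Hydrophobicity uses an element-level table of atomic logP contributions
rather than a full Ghose–Crippen atom-typing scheme: the synthetic
pseudo-molecules the package generates have no realistic valence chemistry
to type against, and for the field engine only the relative per-atom
weights matter. Donor flags follow the rule "H bonded to N/O/S donates",
with the flag carried on the heavy atom; acceptors are N or O with a lone
pair, excluding quaternary and nitro nitrogen.

## PLS, cross-validation and internal statistics

PLS1 is the classical NIPALS deflation algorithm, fully deterministic,
applied to column-centred descriptors. Two preprocessing steps precede it:

* **Column filtering** removes columns whose training-set standard
  deviation falls below a threshold. The conventional value is 2.0 in
  field-energy units (kcal/mol) and that is the CoMFA default. CoMSIA
  similarity indices are dimensionless and, on the small synthetic
  pseudo-molecules, orders of magnitude smaller than field energies, so
  the same numeric cutoff would discard every column; the CoMSIA default
  is therefore 0.05 similarity units, which prunes effectively constant
  lattice points. Both defaults are overridable everywhere.
* **Block scaling** (CoMFA-STD) divides each field block by the standard
  deviation of its training entries, equalizing the a-priori influence of
  the blocks.

LOO cross-validation refits the model with each training compound left out
once, recomputing the column filter and block scaling inside each fold,
and reports $q^2 = 1 - \mathrm{PRESS}/\sum_i (y_i - \bar y)^2$ with
$\bar y$ the full training-set mean — the literal reading of the usual
definition — and $\mathrm{SEP} = \sqrt{\mathrm{PRESS}/(n-N-1)}$. The
component count N maximizes q², with ties resolved toward the smaller N
and a cap at ⌊n/3⌋ so that models never use more components than a third
of the compounds. The sample-distance shortcut some programs use for LOO
is not implemented as an algorithm; the package simply refits, and a test
verifies the LOO path against a literal from-scratch loop to 10⁻¹⁰.

The non-cross-validated statistics are
$\mathrm{SEE} = \sqrt{\mathrm{RSS}/(n-N-1)}$, $r^2_{ncv} = 1 -
\mathrm{RSS}/\mathrm{TSS}$, and the r²-based F statistic with
$(N,\, n-N-1)$ degrees of freedom. Field contributions are
$\sum_j |\beta_j|\, s_j$ per block, normalized across blocks — the
standard display convention; the published tables print contributions
without a formula, so this choice is documented rather than inferred.

## Model selection

`enumerate_models()` spans all non-empty field subsets (3 for CoMFA, 31
for CoMSIA) and `rank_models()` applies the published selection logic:
models must clear q² > 0.5 to be eligible, eligible models are ordered by
test-set r², ties by q². Exhaustive enumeration is cheap at this scale, so
no stepwise search is needed.

## External validation

For a test set, `external_metrics()` computes the squared Pearson
correlation r², the through-origin regressions in both orientations
(slopes k and k′ with determination coefficients r0² and r0′²), the
condition verdicts (q² > 0.5; r² > 0.6; (r²−r0²)/r² < 0.1 in either
orientation; 0.85 ≤ k ≤ 1.15 in either orientation; |r0²−r0′²| < 0.3), and
both rm² variants:

* `abs`: $r^2(1-|r^2-r_0^2|)$, the form usually printed;
* `sqrt`: $r^2(1-\sqrt{r^2-r_0^2})$, Roy's published metric and the
  package default — it is the variant that reproduces the published CoMSIA
  rm² = 0.843 from the shipped prediction table, while the `abs` form does
  not. Both are always reported.

r² here is the squared Pearson correlation (this reproduces the published
0.865/0.918); the PRESS-based predictive r² is additionally reported under
the separate name `r2_pred`. Outliers are flagged at |residual| > 0.4 log
units — the smallest round threshold that reproduces exactly the published
outlier sets ({18, 23} for CoMFA at residuals 0.45/−0.44; {40, 41} for
CoMSIA at −0.42/−0.53, next largest 0.37) — and `validate_model()` reports
metrics both with and without them, since the published condition table is
reproducible from the published per-compound predictions only after
removing each model's flagged outliers.

Two published CoMFA entries (k′ = 0.937 and rm² = 0.793) are not
reproducible from the published per-compound values under any convention
tested (through-origin slope gives ≈0.997, consistent with the
reproducible r0′²; the rm² variants give ≈0.864/≈0.841); they are treated
as suspected typographical errors and excluded from the package's
reproduction tests.

## Y-randomization

`y_randomize()` permutes the training activities (seeded, one derived seed
per iteration), refits including the full LOO, and records q² and r²_ncv
per iteration; the conventional verdict requires every iteration to stay
below q² < 0.5 and r²_ncv < 0.6. The component count of the unrandomized
model is reused by default (re-selection per iteration is available); the
published description does not say which was done, and reusing N is the
stricter test of chance correlation at fixed model complexity. Note that
r²_ncv of a permuted fit can stay high when N is generous relative to n —
that is an honest feature of the statistic, visible in the synthetic runs.

## Applicability domain

The standardization approach: each retained descriptor is standardized
against the training set, $S_{ik} = |x_{ik} - \bar x_i| / s_i$. A
compound with $\max_k S \le 3$ is inside; if additionally
$\min_k S \ge 3$ it is outside; in the mixed case
$S_{new} = \bar S_k + 1.28\, \sigma_{S_k}$ decides, inside iff
$S_{new} \le 3$. The source description of the mixed-case rule is garbled
in the published text; the implemented rule follows the cited
standardization-approach method, which supplies the decision. The sample
(n−1) standard deviation is used throughout, switchable to the population
form.

## Contour fields

`stdev_coeff_field()` maps the fitted coefficients back onto the lattice
as coefficient × column standard deviation (StDev*Coeff), with filtered
columns at zero; this product is invariant to the block scaling, so the
display does not depend on preprocessing units. Display levels default to
the 80th (favored) and 20th (disfavored) percentiles of the non-zero
values, computed by linear interpolation between order statistics
(`quantile` type 7) so that exported golden files are stable. Volumes
export to OpenDX (Å) and Gaussian cube (bohr, conversion factor
1/0.529177210903) formats.

## The synthetic generator

No structure files accompany the published study (the compounds exist only
as figures), so the package generates its own ground-truth data:
pseudo-molecules sharing a rigid 6-atom scaffold, each drawing one
substituent atom per site from a 7-element library at 3 fixed sites, with
activities

$$y = 4.7 - 2.5\,q_{site1} + 2.0\,h_{site2} + 0.30\,R^3_{site3} +
\varepsilon,\qquad \varepsilon \sim N(0, 0.1^2)$$

where q is the substituent charge (e), h its hydrophobicity and R its van
der Waals radius (Å). Defaults mirror the study conditions: 41 compounds,
a 29/12 stratified train/test split drawn from [4,6) and [6,8) pEC50
activity bins, and a realized activity span of ≈3.5 log units. Effects are
planted on atomic properties, not on descriptors, so end-to-end recovery
exercises the field engines and the alignment-to-lattice plumbing, not
just the regression.

What the generator does *not* emulate: real valence chemistry (bonds,
rings, tautomers), conformational flexibility, correlated substituent
effects, or experimental activity error structure beyond i.i.d. Gaussian
noise. Passing recovery tests therefore demonstrates that the machinery is
correct under the model's own assumptions; it does not certify predictive
performance on real chemistry.

```{r, eval = FALSE}
gen <- generate_dataset(generator_spec(seed = 1))
model <- qsar_model(gen$dataset, method = "comsia")
model
validate_model(model)$all
```

## Numerical and scale choices

* Problem sizes: the default lattice over the synthetic set has ~360
  points per field and 41 molecules; a full 31-combination CoMSIA search
  with LOO takes seconds. These sizes were chosen so the whole analysis
  runs comfortably at a desk.
* Hotspot recovery is asserted site-centrically: every planted site must
  lie within 2 Å (one lattice spacing) of a top-decile |StDev*Coeff|
  voxel of the field fed by that site's planted property. With a 2 Å
  lattice and off-lattice sites, the voxel-centric direction can place a
  diagonal-neighbour voxel at 2.06 Å from its site, which says nothing
  about recovery failure.
* The EC50 unit is fixed to micromolar; pEC50 is always on the mol/L
  scale, so pEC50 = 6 − log10(EC50/µM).
* Degenerate inputs: grids enforce ≥2 points per axis; the column filter
  refuses to empty the matrix; through-origin regression refuses zero
  denominators; PLS stops cleanly when the residual covariance vanishes.

## Known limitations

* Absolute CoMFA field values cannot match any particular commercial
  implementation (dielectric model, ε table and padding are not published
  with it); all quantitative reproduction therefore rests on modules
  downstream of the descriptors or on closed-form kernels.
* H-bond donor/acceptor fields use atom-centred flags, not extension
  points along the bond axes.
* The applicability-domain verdicts for the published compounds cannot be
  checked without the original descriptor matrix; only the decision rules
  are verified, on constructed cases.
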