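---
title: "Composite biodegradability scoring and field-QSAR methods"
author: "paedeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite biodegradability scoring and field-QSAR methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paedeg)
```

## The composite biodegradability index

A phthalate ester's biodegradability is measured here against three
different plasticizer-degrading enzymes at once, so the first task is a
principled way to collapse three docking-score endpoints into one number
per compound. The package uses the classical range-normalization +
entropy-weight construction.

**Range normalization.** Each endpoint column is rescaled to $[1-a,\,1]$,

$$Y_{ij} = (1-a) + a\,\frac{X_{ij}-X_{\min,j}}{X_{\max,j}-X_{\min,j}}$$

for benefit endpoints (higher score = better binding = better predicted
degradation); cost endpoints mirror the numerator. The floor $a \in (0,1)$,
default $0.9$, keeps every normalized value strictly positive — necessary
because the next step evaluates $Y\ln Y$. Constant columns are an error,
not silently skipped: a zero range leaves both the normalization and the
weight undefined.

**Entropy weighting.** Endpoints whose normalized values are more
informative (dispersed away from the low-information extremes) should
matter more. With $k = 1/\ln m$ for $m$ compounds:

$$E_j = -k\sum_i Y_{ij}\ln Y_{ij}, \qquad
  H_j = |1 - E_j|, \qquad W_j = H_j / \textstyle\sum_j H_j,$$

and the composite is $Z_i = \sum_j W_j Y_{ij}$, again bounded in
$[1-a,\,1]$.

Two conventions deserve comment because the textbook entropy-weight
method differs:

* **Entropy on $Y$ directly.** The textbook variant first rescales each
  column to proportions $p_{ij} = Y_{ij}/\sum_i Y_{ij}$, which bounds
  $E_j \le 1$. Applied to the raw normalized values — the convention this
  package defaults to — $E_j$ routinely exceeds 1 (the 17-compound
  reference table gives $E \approx (1.799, 1.792, 1.498)$). Only this
  direct convention reproduces the published derived columns, so it is
  the default; `entropy_per_endpoint(..., proportions = TRUE)` provides
  the textbook variant.
* **$H_j = |1-E_j|$.** With $E_j > 1$ a literal $1 - E_j$ would be
  negative; the absolute value reproduces the published difference
  coefficients and degrades gracefully to the textbook $1-E_j$ when the
  proportion variant is used.

All computation is at full floating precision; printed-precision rounding
(3 decimals for values, 2 for percent) happens only in reports, with R's
round-half-even. When the reference table is recomputed from its printed
3-decimal docking scores, a handful of derived cells land one unit off
the published last digit and the weights land within 0.07 percentage
points — the published pipeline evidently carried more internal digits
than it printed. The package reports what the printed inputs support.

```{r}
res <- comprehensive_table(pae_docking_scores(), floor_a = 0.9)
round(100 * res$W, 2)
round(res$Z[c("DMP", "DEP", "DTDP", "DUP")], 3)
```

## Superposition and similarity fields

A congeneric series is brought into one frame by rigid-body least-squares
fitting of a mapped common skeleton (`superpose()`, the Kabsch/SVD
construction with an explicit determinant correction so the returned
rotation is always proper). The mapping is user-supplied: which mobile
atom corresponds to which template atom is chemistry, not geometry, and
the package does not guess it.

Fields are CoMSIA-style similarity indices on a rectangular grid
(`build_grid()`: bounding box + 4 Å margin, 2 Å spacing by default):

$$A_{q} = -\sum_{\text{atoms}} w_{\text{probe}}\, w_{\text{atom}}\,
  e^{-\alpha r_{aq}^2},$$

with Gaussian attenuation $\alpha = 0.3\ \text{Å}^{-2}$ and a unit probe.
Per-atom weights are $r_{vdW}^3$ (steric, a volume proxy), the partial
charge (electrostatic), a supplied hydrophobicity parameter, and supplied
donor/acceptor flags. Charges and flags travel in a sidecar table next to
the SDF file: the package deliberately contains no charge model or
pharmacophore perception — those belong to upstream tools, and supplying
them as data keeps the field stage transparent and testable. The Gaussian
form has no singularities at atom positions, so no inner cutoff is
needed.

Descriptor assembly applies CoMSIA block scaling (each probe block
divided by the standard deviation of all its entries, so no field type
dominates by magnitude) and then drops columns with standard deviation
below 0.01 — the analogue of a minimum-sigma filter, removing grid points
far from every molecule.

The grid settings, $\alpha$, and probe properties of the commercial
implementation behind the published statistics are not documented
anywhere recoverable, so exact reproduction of the published model
statistics is out of reach by construction; the field stage is instead
validated against brute-force summation oracles, symmetry, and
rigid-motion invariance of the assembled descriptors.

## PLS and the validation battery

`pls_fit()` is mean-centered NIPALS PLS1; at full component count it
coincides with ordinary least squares (the test suite checks both this
and agreement with an independent PLS implementation to machine
precision). The validation battery follows the standard definitions:

* `loo_q2()`: leave-one-out $q^2 = 1 - \mathrm{PRESS}/SS_{tot}$ per
  component count, optimum by maximum $q^2$. LOO (not $k$-fold) matches
  the extraction-method convention of the original workflow.
* `fit_statistics()`: $R^2$, $SEE = \sqrt{SS_{res}/(n-c-1)}$ with $c$
  components, and the corresponding $F$; a perfect fit reports `Inf`.
* `external_r2pred()`: $(SD - \mathrm{PRESS})/SD$ about the *training*
  mean.
* `y_scramble()`: the original publication names its scrambling
  statistics but not its protocol, so the package fixes one and
  documents it: pairwise-swap perturbation at fractions
  $\{0.2, 0.4, 0.6, 0.8, 1\}$ of the sample, 20 permutations per level,
  seed 1729 by default, the unperturbed model included as anchor;
  scrambled $q^2$ is regressed on $r^2_{yy'}$, reporting the slope
  ($dq^2/dr^2_{yy'}$), the extrapolation to full perturbation
  ($Q^2$ at $r^2_{yy'}=0$), and the mean scrambled
  $\sqrt{\mathrm{PRESS}/n}$ (cSDEP).
* `field_contributions()`: block share of $\sum_k |b_k s_k|$ — the
  established coefficient-times-spread accounting of how much each field
  type drives the model.

Numerical conventions: components are capped at $n-2$ for LOO (each fold
must keep $c \le n_{fold}-1$); NIPALS stops early when the residual
covariance vanishes, and a response with no covariance at all yields the
zero-coefficient mean model rather than an error. Predictions are
invariant to duplicated (perfectly collinear) columns at full rank.

The published training geometry — 16 of 17 compounds selected, a 13/4
split with the template molecule in both sets — is preserved as data
(`pae_model_roles()`) and honored when replaying, duplication included;
the package does not "fix" it.

## Derivative bookkeeping, screening, pathways

The 30-derivative catalogue is a declarative substitution scheme
(`dep_substitution_scheme()`): volume-limited and electropositive groups
at the C1/H1 position, hydrophilic groups singly and doubly at C2, and
the H1 × C2 combinations with the two amide/ketone hydrophiles. Change
rates are $100(\text{new}-\text{parent})/\text{parent}$ against the
published low-precision parent baselines (0.27 / 5.57 / 4.71 / 3.55) —
using higher-precision baselines does *not* reproduce the published
rates, so the baselines are part of the data. The per-enzyme "ratio"
triple is each endpoint's share of the summed change rates; this rule is
not stated in the source but reproduces every published triple, computed
at full precision and rounded last.

Screening applies four configurable rules: lowest vibrational frequency
> 0 (a true energy minimum), BCF < 100 (the bioaccumulation rule is
stated on the log column in the source but plainly meant on the linear
scale, where the values 18–131 live), |bio-toxicity change| < 10% (the
threshold that separates the published "no significant change" group
from the rest; the source gives no number), and composite gain > 15%.
Persistence and migration changes are reported but carry no verdict
weight. Property-table change rates follow the published per-column sign
conventions: the energy rate uses an absolute-value denominator (signed
Hartree values), and the toxicity/persistence columns print the negated
log-scale change.

Pathway totals are step-barrier sums along each validated
reactant→product chain; the per-derivative aggregate is the **sum** of
the two per-path percent change rates. Summing percentages of different
baselines is not physically meaningful, but it is the published
convention and is reproduced as such (a mean aggregate is available via
`total_change_rate(..., method = "mean")`). One published aggregate cell
(−30.26 for the third derivative) is inconsistent with its own printed
per-path rates (−21.65 and −18.61, summing to −40.26, a dropped digit);
the package computes the consistent value.

## Synthetic data: what it emulates and what it does not

`gen_score_matrix()` reproduces the *shape* that makes entropy weighting
interesting: a normal bulk of scores plus two asymmetric range anchors
(the analogues of the far-out template molecule and the worst binder),
with a per-endpoint dispersion multiplier that simultaneously widens the
anchors and tightens the bulk. Larger multipliers reliably attract larger
entropy weights — a property the test suite checks over 100 seeded
replicates. Since range normalization absorbs any per-column affine
transform, a generator that only scaled columns could not move the
weights at all.

`gen_molecule_set()` emulates a congeneric series: an identical rigid
scaffold (alignment is consistent by construction) plus a few substituent
pseudo-atoms jittered in position and probe properties, with the response
planted as a known linear function of the *true* computed field
descriptors plus Gaussian noise. With many more field columns than
molecules only the component of a coefficient vector inside the
descriptor row space is identifiable, so recovery experiments use
`beta_in_span = TRUE` to plant what is recoverable in principle.

What passing these tests shows: the field/PLS machinery recovers planted
linear structure, rejects noise, and is numerically faithful to its
oracles. What it does not show: anything about real conformational
flexibility, charge models, alignment ambiguity, or the accuracy of
docking scores — none of which the synthetic generator attempts to
emulate.

Problem sizes used throughout the suite (17–30 compounds, 3 endpoints,
scaffolds of ~6–9 atoms, grids of a few hundred points, 10–20
permutations per scrambling level) mirror the reference study's scale;
they keep every check a desk-scale computation while exercising the same
code paths as larger inputs.

## Known limitations

* Exact reproduction of the published model statistics (q², SEE, field
  contributions of the commercial CoMSIA fit) is not attempted: the
  upstream field dialect and settings are proprietary and undocumented.
* Docking scores, DFT energies, barriers, and POP property predictions
  are inputs; the package neither docks nor computes quantum chemistry.
* Derivative records are bookkeeping entities (labels + predicted
  values); 3D structure generation for substituted molecules is out of
  scope.
* The entropy-weight composite inherits the usual caveat of objective
  weighting: weights reflect dispersion in the assembled panel, not
  biological importance, and change when compounds are added or removed.
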