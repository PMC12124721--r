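---
title: "Methods: from NMR integrals to descriptor regression models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from NMR integrals to descriptor regression models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thiofluor)
```

## The scientific problem

Fluorination is a standard lever in medicinal chemistry for tuning two
coupled physicochemical properties: lipophilicity, measured as the
octanol/water distribution coefficient at pH 7.4 (logD⁷·⁴), and basicity,
measured as the pKa of the conjugate acid. For 2-(thiofluoroalkyl)- and
2-(sulfonylfluoroalkyl)pyridines the effect of fluorination is
context-dependent — terminal CF₃ groups raise logD while fluorination
adjacent to sulfur can lower it — so simple additivity fails and a
quantitative structure–property model is needed.

`thiofluor` implements the full computational chain for this system:

1. **Measurement reduction** (`logd_from_nmr`, `logd_from_hplc`,
   `fit_titration`, `second_derivative_pka`): raw ¹⁹F NMR integral ratios
   and (pH, chemical shift) titration series → logD⁷·⁴ and pKa.
2. **Descriptor assembly** (`load_compounds`, `library_descriptors`,
   `ingest_dft_descriptors`): constitutional descriptors computed from
   SMILES, merged with externally computed DFT descriptors (Mulliken
   charges q_S/q_N/q_O, E_HOMO, ΔG_wat, QPSA, volume, dipole). Quantum
   chemistry itself is out of scope: DFT values are ingested, never
   computed.
3. **Transform expansion and scaling** (`expand_transforms`,
   `scale_minmax`): each descriptor x spawns 1/x, x², 1/x² and log(x)
   where valid; all columns are then min–max scaled to [0, 1].
4. **Exhaustive model search** (`enumerate_models`, `select_best`,
   `predict`, `correlate`): every 1- and 2-descriptor ordinary
   least-squares regression against the response, ranked by R², MAE and
   RMSE.
5. **Synthetic ground truth** (`gen_descriptor_table`, `gen_partition`,
   `gen_titration`): generators for every input the pipeline consumes,
   with known answers, so each stage is testable without external data.

## Measurement models

### logD⁷·⁴ from ¹⁹F NMR partition experiments

A compound and a fluorinated internal standard of known lipophilicity are
partitioned together between 1-octanol and pH 7.4 buffer; each phase is
measured by quantitative ¹⁹F NMR. With integrals \(I\) the estimate is the
double ratio

\[
\log D^{7.4} \;=\; \log D_{\mathrm{std}} \;+\;
\log_{10}\!\frac{I^{\mathrm{oct}}_{\mathrm{analyte}}/I^{\mathrm{oct}}_{\mathrm{std}}}
     {I^{\mathrm{aq}}_{\mathrm{analyte}}/I^{\mathrm{aq}}_{\mathrm{std}}}.
\]

Ratioing against the standard inside each phase cancels instrument
scaling (gauge invariance: multiplying all four integrals by a constant
changes nothing), and the cross-phase ratio transfers the standard's known
logD to the analyte. Swapping the phases negates \(\log D -
\log D_{\mathrm{std}}\); both properties are asserted as tests. The
standard's logD is always a required input — it is an experimental
calibration constant, not something the package may assume. Replicates
(the protocol uses three) aggregate as mean ± sample SD with no outlier
rejection, matching how triplicate shake-flask data are reported.

The HPLC-UV route for compounds without fluorine uses the aqueous-phase
mass balance: \(D = \frac{A_{\mathrm{before}} -
A_{\mathrm{after}}}{A_{\mathrm{after}}}\cdot\frac{V_{\mathrm{aq}}}{V_{\mathrm{oct}}}\),
with `area_after >= area_before` rejected as "no partitioning".

### pKa from NMR pH titrations

The chemical shift of a reporter signal (¹⁹F referenced to KF at
−125.00 ppm, or ¹H referenced to trifluoroethanol at 3.14 ppm) is tracked
across a battery of samples spanning pH ≈ −1 to 12. A single protonation
equilibrium gives the Henderson–Hasselbalch sigmoid

\[
\delta(\mathrm{pH}) = \delta_{\mathrm{acid}} +
\frac{\delta_{\mathrm{base}} - \delta_{\mathrm{acid}}}{1 + 10^{\,pK_a - \mathrm{pH}}},
\]

whose inflection point is the pKa. The default fit fixes the Hill slope at
1 (one proton on the pyridine nitrogen); `free_slope = TRUE` adds the
slope as a fourth parameter for diagnostic use. Least squares is
minimised with BFGS followed by a Nelder–Mead polish; `nls` was rejected
because its relative-offset convergence test fails on the exactly
zero-residual synthetic data used for round-trip tests.

Two estimators are provided because the underlying experimental protocol
is ambiguous about whether the "second derivative" is taken on the fitted
curve or the raw data:

* `fit_titration()` — parametric; pKa is the fitted inflection.
* `second_derivative_pka()` — model-free; the series is smoothed by a
  local cubic fit over a 5-point window (bare finite differences amplify
  NMR noise), the numeric second derivative is formed, and the pKa is its
  zero crossing. Curvature below \(10^{-6}\,\Delta\delta/\Delta
  \mathrm{pH}^2\) counts as zero so a linear series raises "no inflection"
  instead of returning floating-point noise; with several crossings the
  one nearest the steepest slope wins, with a warning.

On noiseless dense grids the two agree within 0.15 pH units (asserted);
under 0.02 ppm Gaussian shift noise the parametric route recovers pKa
with |bias| < 0.02 over 100 simulations spanning pKa 0.5–4.

## The compound library and constitutional descriptors

The 22-compound library (methyl and ethyl thioethers **1–9**, **21–22**;
their sulfones **10–20**) ships as a plain CSV fixture with SMILES,
series and sulfur oxidation state, plus the printed experimental values
to exactly two decimals. Missing values are `NA`, never 0: logD of the
two water-unstable compounds (**21**, **22**, which decomposed during the
measurement) and of **10**, **11**, **19**, **20** (printed only in a
figure panel not available as text), and pKa where not determined. Load
validation enforces that the fluorine count implied by each substituent
name matches the parsed structure and that sulfones carry exactly two
oxygens on sulfur.

SMILES parsing is deliberately minimal and dependency-free: the organic
subset, brackets, branches and ring closures — enough for exact atom/bond
multisets on small neutral molecules, checked against an independent
cheminformatics implementation in the tests. TPSA is an explicit Ertl
fragment-contribution lookup restricted to the ~15 polar atom
environments relevant here (aromatic N 12.89, thioether S 25.30, sulfonyl
S 8.38, =O 17.07, …). An N/O/S environment outside the table is an error,
never a silent zero; full Ertl coverage is a non-goal.

## Transform expansion and scaling

Transforms are applied to **raw** descriptors first and the result is
min–max scaled afterwards; scaling first would change the meaning of 1/x
and log x. The family {identity, 1/x, x², 1/x², log x} generalises the
three transformed descriptors that matter for this system (1/q_S,
1/E_HOMO², log q_S) and is applied column-wise only where finite on every
compound: columns containing 0 get no inverse, columns with mixed signs
get no log, and a skipped transform is logged, never partially applied.
Log base is 10; after min–max scaling the base is irrelevant to the
regression (affine equivalence).

`scale_minmax` drops constant columns (range < 1e-12) with a warning,
maps every remaining column onto [0, 1] with the min at 0 and max at 1,
and records (min, max) per column. Scaling is idempotent and
rank-preserving. The stored training ranges are reused at prediction
time; an input outside the training range is allowed but flagged as
extrapolation.

## The exhaustive regression search

With d descriptors the search fits every singleton and every unordered
pair — \(d + \binom{d}{2}\) models; at the study's scale of 220 columns
that is 24,310 regressions, consistent with "more than 24,000" models
over ">200" descriptors. Each candidate is the closed-form
normal-equation solution with an intercept always included; per-candidate
work is one 2×2/3×3 solve against precomputed cross-products, so the full
d = 220 search takes about a second. Metrics are **in-sample** R², MAE
and RMSE — the study reports training metrics, and with n ≈ 20 compounds
a held-out split would be noise; cross-validation is deliberately not the
selection criterion.

Ranking uses max R² as primary key; ties within 1e-6 are broken by min
MAE, then min RMSE, then fewer terms, then lexical term order. The
cascade beyond R² is this package's own convention (the three metrics are
named in the source study without an ordering); parsimony-before-lexical
makes the selection deterministic and reproducible. Collinear pairs
(|r| > 0.999) are fitted and flagged but stay in the model count;
rank-deficient designs are flagged degenerate and sort last. Pair labels
are canonicalised lexically so results are invariant to descriptor column
order and compound row order (asserted by permutation tests).

Two invariants anchor correctness: the ranking agrees exactly with an
independent `lm()`-based brute-force oracle for d ≤ 6, n ≤ 12, and
RMSE ≥ MAE holds for every fitted model (the power-mean inequality — which
is also why a printed RMSE smaller than its MAE cannot describe the same
residual vector and is asserted only as the inequality here).

For the pyridine system the confirmatory fits reuse this machinery with
the term set fixed to {#F, 1/q_S} via `fit_terms()`: the lipophilicity
model has a positive #F coefficient (fluorine enlarges the hydrophobic
surface) and a negative 1/q_S contribution (positive charge buildup on
sulfur raises molecular polarity and depresses logD), while for pKa both
descriptors act in the same direction — more fluorine and more polarised
sulfur both acidify the pyridinium.

## The synthetic world

The generators state one fixed world and the tests measure it; none of
the defaults were tuned against test outcomes.

* **Descriptor tables**: columns cycle through four archetypes — partial
  charges uniform on [−0.7, 0.3] (straddling zero so the inverse/log
  validity paths are exercised), integer counts 0–5 (the #F range of the
  library), energies uniform on [−10, −1] (negative, like E_HOMO or
  ΔG_wat in the relevant units), areas uniform on [20, 120] (TPSA/QPSA
  magnitudes). The response is a planted linear law on named raw columns
  plus Gaussian noise. The paper-scale preset (`gen_paperlike_dataset`)
  uses 20 compounds × 220 descriptors with a 2-term law and noise chosen
  to land near R² ≈ 0.95 in-sample.
* **Partitions**: the four integrals are constructed to satisfy the
  double-ratio identity exactly, then multiplied by log-normal noise with
  the requested coefficient of variation (mean-1, so noise is unbiased
  multiplicatively); 1% CV mirrors careful manual integration.
* **Titrations**: Henderson–Hasselbalch shifts plus Gaussian noise;
  0.02 ppm noise and ~2 ppm plateau separation mirror ¹⁹F titrations. A
  grid not spanning pKa ± 2 warns.

Every generator is a pure function of (parameters, seed), restores the
caller's RNG state, and is exactly inverted by its pipeline stage at zero
noise. What a green test therefore establishes is that the *statistical
machinery* is correct under the stated noise model; synthetic tables do
not emulate inter-descriptor correlation structure of real DFT
descriptors (e.g. ΔG_wat tracking #F), so recovery rates on them do not
certify variable-selection behaviour under strong multicollinearity
beyond the explicitly flagged |r| > 0.999 case.

## Numerical choices and degenerate inputs

* Constant-column threshold 1e-12 (scaler degeneracy); inverse transforms
  require |x| > 1e-12.
* Titration fits reject amplitude < 0.01 ppm as degenerate (no transition
  in window) and warn when the fitted pKa leaves the observed pH range.
* Metric computation refuses zero response variance (R² undefined).
* Normal equations are solved directly; for 1–2 regressors on scaled
  [0, 1] columns conditioning is benign, and rank deficiency is caught
  and flagged rather than regularised.
* `write_descriptors` emits `%.17g`, so write → read → write is
  bit-stable for IEEE doubles.

## Known limitations

* The printed experimental values for four sulfones' logD and three
  thioethers' pKa exist only in figure panels and are `NA` in the
  fixture; the study's own DFT descriptor tables are not redistributable,
  so the printed model metrics (R² = 0.95, MAE = 0.17; pKa R² = 0.89;
  sulfone q_O r² = 0.86) cannot be recomputed from in-repo data. The
  corresponding acceptance test states this and fails red by design; the
  refit code path runs unchanged once a descriptor CSV is supplied.
* SMILES coverage is the organic subset without stereochemistry or
  charged species beyond bracket notation — sufficient for this library,
  not a general parser.
* Search size is capped at two descriptors by contract; with n ≈ 20
  training compounds anything larger invites overfitting that in-sample
  metrics cannot detect.
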