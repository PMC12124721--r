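# thiofluor

Lipophilicity and basicity modeling of fluorinated thioalkyl pyridines.

Fluorination shifts the two properties that medicinal chemists tune most —
lipophilicity (logD⁷·⁴, the octanol/water distribution coefficient at
pH 7.4) and basicity (pKa of the conjugate acid) — in ways that depend on
*where* the fluorines sit: terminal CF₃ groups raise logD, fluorination
next to sulfur can lower it. `thiofluor` implements, end to end, the
computational chain used to quantify this for
2-(thiofluoroalkyl)- and 2-(sulfonylfluoroalkyl)pyridines:

* **Measurement reduction** — shake-flask ¹⁹F NMR partition experiments to
  logD⁷·⁴ via the internal-standard double ratio
  `logD = logD_std + log10[(I_oct,analyte/I_oct,std) / (I_aq,analyte/I_aq,std)]`,
  the HPLC-UV mass-balance route, and pH/chemical-shift titrations fitted
  to the Henderson–Hasselbalch sigmoid
  `δ(pH) = δ_acid + (δ_base − δ_acid)/(1 + 10^(pKa − pH))`
  (plus a model-free second-derivative pKa estimator).
* **Descriptor assembly** — a packaged 22-compound pyridine library with
  printed experimental values; constitutional descriptors (atom counts,
  #F, MW, fragment-contribution TPSA) computed from SMILES by a built-in
  parser; ingestion of externally computed DFT descriptors (Mulliken
  charges q_S/q_N/q_O, E_HOMO, ΔG_wat, QPSA, …) from CSV.
* **Transform expansion and scaling** — per-column 1/x, x², 1/x², log x
  where mathematically valid, then min–max scaling to [0, 1] with stored
  training ranges.
* **Exhaustive model search** — every 1- and 2-descriptor ordinary
  least-squares regression (d + d(d−1)/2 models; 24,310 at d = 220),
  ranked by in-sample R², then MAE, RMSE, parsimony. The physically
  interpretable model for this system is
  `logD⁷·⁴ = a + b·#F + c·(1/q_S)` on scaled descriptors: fluorine count
  raises logD (larger hydrophobic surface), positive charge buildup on
  sulfur lowers it (larger molecular polarity); the same two descriptors
  refit against pKa with a sign flip on #F.
* **Synthetic generators** — descriptor tables with planted linear laws,
  partition replicates and titration series with known ground truth, so
  every stage is testable offline.

## Worked example

Search all 1-/2-descriptor models for logD⁷·⁴ over the packaged library
using constitutional descriptors only:

```r
library(thiofluor)
lib  <- load_compounds()                       # 22 pyridines, printed values
tab  <- expand_transforms(library_descriptors(lib))
sc   <- scale_minmax(tab)
logd <- setNames(lib$logd_exp, as.character(lib$id))
rep  <- enumerate_models(sc, logd, response_name = "logD7.4")
print(rep, n = 2)
#> <search_report> 253 models fitted for logD7.4
#>         terms n_terms        r2       mae      rmse degenerate rank
#> 1   #F + TPSA       2 0.8863541 0.2508416 0.3177219      FALSE    1
#> 2 #F + TPSA^2       2 0.8863541 0.2508416 0.3177219      FALSE    2
select_best(rep)
#> <candidate_model> logD7.4 = 1.7003 +1.0828*#F -1.5867*TPSA
#>   n=16  R2=0.8864  MAE=0.2508  RMSE=0.3177
```

Reading: on the 16 compounds with measured logD⁷·⁴, the best
constitutional model combines fluorine count (positive: each fluorine adds
lipophilic surface) with TPSA (negative: the sulfone's polar oxygens
depress logD); R² = 0.89 with mean absolute error 0.25 log units.
(TPSA takes only two distinct values here, so all its transforms tie —
ranks 1–5 are the same model in different clothes.) Reaching the study's
R² = 0.95 requires the DFT charge descriptor 1/q_S, supplied via
`ingest_dft_descriptors()` and refit with
`fit_terms(sc, logd, c("#F", "1/q_S"))`.

Predict the water-unstable compounds that have no experimental logD:

```r
predict(select_best(rep), sc, ids = c("21", "22"))
#>   id prediction extrapolated
#> 1 21   1.916821        FALSE
#> 2 22   1.916821        FALSE
```

Reduce raw measurements (here: synthetic, with known truth):

```r
logd_from_nmr(gen_partition(true_logd = 2.26, standard_logd = 1.0,
                            noise_cv = 0.01, seed = 1))
#> $logd
#> [1] 2.267039 2.266084 2.258954
#> $mean
#> [1] 2.264026
#> $sd
#> [1] 0.004417769
fit_titration(gen_titration(true_pka = 3.69, shift_acid = -63.2,
                            shift_base = -61.4, noise_sd = 0.02, seed = 1))
#> <sigmoid_fit> pKa = 3.6767  (acid -63.202 ppm -> base -61.402 ppm,
#>                              slope 1.000, residual RMS 0.0191 ppm)
```

A command-line front end covers the same pipeline
(`describe`, `descriptors`, `logd-nmr`, `pka-fit`, `model-search`,
`predict`, `simulate`); see `thiofluor_cli_help()` and
`inst/scripts/thiofluor`.

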