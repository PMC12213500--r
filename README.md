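# qealike

Quantitative estimate of algicide-likeness (QEA) scoring for chemical
compound collections.

Chemical algicides are a frontline tool against harmful algal blooms, but
prioritising candidate molecules from large libraries requires a cheap,
interpretable ranking signal. `qealike` implements a likeness score in the
QED family for that purpose: it learns, from any reference set of known
algicidal compounds, how six physicochemical descriptors distribute —
molecular weight (MW), Wildman–Crippen logP, hydrogen-bond acceptors (HBA)
and donors (HBD), rotatable bonds (nRotB) and aromatic rings (nArR) — and
scores arbitrary molecules by how typical their profile is of the actives.

Per descriptor, a four-parameter desirability curve is fitted to the
reference frequency distribution,

    df(x) = o + a · exp(−e^(−t) − t + 1),   t = (x − b) / c,

whose maximum `o + a` sits at `x = b` and whose tails decay to the baseline
`o`. Continuous descriptors are binned with the risk-minimising optimal bin
width (cost `C(Δ) = (2k̄ − v)/Δ²` over the per-bin counts); integer
descriptors are tallied exactly. The six desirabilities combine by an
unweighted geometric mean,

    QEA = exp( (1/n) Σ ln df_i ),   QEA = 0 if any df_i ≤ 0,

giving a score in [0, 1]. The package also ships ROC/AUC decoy evaluation
(Mann–Whitney ties-at-half-credit), EPA five-level aquatic acute-toxicity
categorisation of EC50/LC50 concentrations, a seed-stable synthetic
descriptor simulator for end-to-end validation, and a command-line front
end.

## Worked example

```r
library(qealike)

ref  <- simulate_descriptors(500, seed = 101)          # reference "actives"
prof <- fit_qea_profile(ref, provenance = "synthetic reference set")
glance(prof)
#> # A tibble: 6 × 6
#>   descriptor kind        peak    mode fit_rmse n_total
#> 1 mw         continuous 0.940 279.      0.0461     500
#> 2 logp       continuous 1.04    2.54    0.0426     500
#> 3 hba        discrete   1.00    2.26    0.0483     500
#> 4 hbd        discrete   1.01    0.413   0.0219     500
#> 5 nrotb      discrete   1.06    2.18    0.0331     500
#> 6 narr       discrete   1.11    1.30    0.0165     500

pos <- qea_score(simulate_descriptors(500, seed = 202), prof)
head(pos[, c("id", "mw", "logp", "qea")], 3)
#>   id          mw  logp   qea
#> 1 sim00001  215.  2.33 0.913
#> 2 sim00002  274.  2.40 0.868
#> 3 sim00003  284.  1.28 0.691

neg <- qea_score(simulate_descriptors(500, seed = 303, mode = "decoy"), prof)
roc_auc(pos$qea, neg$qea)
#> <qea_roc> AUC = 0.9836 (500 positives vs 500 negatives)
```

The `glance()` table shows each fitted desirability model: `mode` is the
fitted peak location `b` (here MW peaks near 280 g/mol and logP near 2.5,
matching the generating laws), `peak` is the fitted maximum `o + a`
(clamped to 1 during scoring), and `fit_rmse` the residual of the curve
fit. Scores near 1 mark compounds whose whole descriptor profile sits near
the reference peaks; a single atypical descriptor pulls the geometric mean
down sharply. The AUC of 0.98 says a random synthetic positive outranks a
random diffuse decoy 98% of the time.

Real compound files work the same way: `read_compounds("actives.smi")`
(also `.csv` with a `smiles` column, or V2000 `.sdf`) replaces the
simulator, `write_qea_profile()`/`read_qea_profile()` persist the fitted
model as versioned JSON, and `annotate_toxicity()` adds EPA categories to a
table of EC50/LC50 concentrations.

A command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "qea.R", package = "qealike"))')" \
    fit --input actives.smi --output profile.json
```

with `score`, `evaluate`, `classify-tox` and `simulate` subcommands.

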