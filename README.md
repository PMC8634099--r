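# resilnet

Network analysis of quality of life (QoL) and the resilience factors thought
to sustain it in later life: behavioral coping (BC), positive appraisal style
(PAS), self-management ability (SMA), physical activity (PHY), and — as a
pandemic-era control — the governmental policy stringency index (SI).

The package is for researchers who have item-level questionnaire data
(WHOQOL-OLD, SMAS-18, the shortened COPE/CERQ coping scales) plus activity
self-reports, and who want to go from raw responses to a stability-checked
pair of networks:

1. an **undirected Gaussian graphical model (GGM)** whose edges are partial
   correlations — the association between two variables conditioning on all
   others — selected without regularization by stepwise search over edge
   structures minimizing the extended Bayesian information criterion,

   EBIC = −2 ℓ(K̂) + k·log n + 4·k·γ·log p,

   where ℓ(K̂) is the Gaussian log-likelihood of the constrained
   maximum-likelihood precision matrix K̂ with k free off-diagonal entries
   (γ = 0, the default, gives BIC selection); and

2. a **directed relative-importance network** on the selected structure:
   each node is regressed on exactly its GGM neighbors and its explained
   variance R² is split among them with the LMG metric (incremental R²
   averaged over all predictor orderings — the Shapley decomposition), so
   the directed weight i→j is the share of j's variance attributable to i.
   Summing directed weights gives each node's *outstrength* (variance it
   explains elsewhere) and *instrength* (its variance explained by others).

Around this core the package provides instrument scoring, robust
median-absolute-deviation (MAD) outlier filtering of the skewed activity
score, nonparametric bootstrap quantile intervals and paired difference
tests for edges and strengths, case-dropping correlation-stability (CS)
coefficients, and a calibrated synthetic-data generator — raw cohort data of
this kind are typically not publicly shareable, so the generator encodes the
published six-node network (seven partial correlations, SI isolated) as a
reference model for simulation, testing and power exploration.

## Worked example

Simulate a cohort of n = 1392 from the reference six-node model, select the
GGM, and build the relative-importance network:

```r
library(resilnet)

spec <- reference_network_spec()      # generating model, n = 1392
x <- generate_dataset(spec, seed = 1)
net <- ggm_model_select(x)            # stepwise EBIC search, gamma = 0
net
#> Gaussian graphical model: 6 nodes, 7 edges (n = 1392, gamma = 0)
#> EBIC = 22602.70, log-likelihood = -11276.01
#> edges:
#>   QoL -- PAS   0.124
#>   QoL -- SMA   0.414
#>   BC -- PAS   0.123
#>   BC -- SMA   0.344
#>   BC -- PHY  -0.129
#>   PAS -- SMA   0.272
#>   SMA -- PHY   0.163
```

The search recovers the generating structure: QoL is directly connected
only to SMA and PAS, SI is isolated, and the estimated partial correlations
sit near the generating weights (0.39, 0.15, 0.31, 0.29, 0.14, 0.18,
−0.09). Relative importance on that structure:

```r
rin <- relative_importance_network(x, net)
strength_summaries(rin, focus = "QoL")
#>   node outstrength instrength difference focus_outstrength focus_instrength
#> 1  QoL       0.245      0.283     -0.038             0.000            0.000
#> 2   BC       0.186      0.222     -0.036             0.000            0.000
#> 3  PAS       0.219      0.223     -0.003             0.059            0.055
#> 4  SMA       0.540      0.451      0.089             0.224            0.190
#> 5  PHY       0.028      0.039     -0.011             0.000            0.000
#> 6   SI       0.000      0.000      0.000             0.000            0.000
```

Read the `instrength` of QoL (0.283) as: its GGM neighbors SMA and PAS
jointly explain 28.3% of QoL's variance in this sample; SMA's
`outstrength` of 0.540 says SMA explains 54.0 percentage points of variance
summed over its four neighbors, making it the network's hub. The
`focus_*` columns keep only edges touching QoL — the direct predictive
relationships between each resilience factor and QoL itself.

`run_pipeline(run_config(...))` chains the whole analysis — scoring input,
MAD filtering of PHY, descriptives, GGM selection, relative importance,
strength summaries, optional edge bootstrap and case-dropping stability —
and exports edge-list CSVs, GraphML, layout coordinates and a JSON run
report.

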