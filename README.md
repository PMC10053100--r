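# soilrisk

Pollution indices, PMF source apportionment and probabilistic human health
risk assessment for heavy metals in surface soils.

## What it is for

Urban-soil surveys measure a handful of heavy metals (here by default Cd,
Cr, Cu, Zn, Ni, Pb plus the crustal reference element Mn) at a few dozen
sites and then answer three questions: *how polluted is the soil*
(summary statistics, exceedance against background and regulatory guide
values, enrichment factors), *where does the metal come from* (Pearson
correlation screening and a positive matrix factorization receptor model),
and *does it hurt anyone* (EPA-style three-route exposure doses, hazard
index, total carcinogenic risk — deterministically and by Monte Carlo
simulation). `soilrisk` implements that whole chain as tested, reusable R
functions, plus inverse-distance-weighted concentration surfaces and a
synthetic-data generator with known structure so every stage can be
validated without field data.

The core statistics, in the field's standard notation:

* **Enrichment factor**: EF = (Cᵢ/C_Mn)_sample / (Cᵢ/C_Mn)_background,
  classified on the Sutherland scale (cut points 2/5/20/40).
* **PMF**: x_ij = Σ_k g_ik f_kj + e_ij with G, F ≥ 0, minimising
  Q = Σ(e_ij/u_ij)², where u_ij = √((ε·c)² + MDL²) above the detection
  limit and 5/6·MDL at or below it; multi-start multiplicative updates,
  robust downweighting of |e/u| > 4, Q_robust/Q_true diagnostics.
* **Risk**: ADD_ing = C·IngR·EFreq·ED/(BW·AT)·10⁻⁶ (and the dermal and
  inhalation analogues), HI = Σ ADD/RfD against 1, TCR = Σ ADD·SF against
  10⁻⁶–10⁻⁴; Monte Carlo propagation with 10,000 iterations over
  lognormal concentrations (moment-matched to the observed mean/SD) and
  distributional exposure parameters.

## Worked example

The shipped demo configuration carries published provincial background
values, GB15618-2018 screening values, ICP-MS detection limits, and
clearly-labelled EPA-conventional stand-in toxicity/exposure defaults.

```r
library(soilrisk)
cfg <- load_config()                                   # shipped defaults
samples <- generate_matched_samples(demo_summary(), n_sites = 40, seed = 1)

head(summarize_metals(samples, cfg$reference), 3)
#>   metal        min        max      mean        sd cv_percent
#> 1    Cd  0.0954417   8.215454  2.164068  1.928893   89.13273
#> 2    Cr 33.2530579 100.246655 56.411339 15.582730   27.62340
#> 3    Cu 12.8309840  56.526586 31.233459 10.713946   34.30278
#>   er_background_percent er_guide_percent
#> 1                    95               85
#> 2                    10                0
#> 3                    45                0

mc <- run_mc_hra(demo_summary(), cfg, n_iter = 10000, seed = 1)
mc$dist
#> <risk_distribution> 10000 iterations, seed 1
#>   adult: mean HI = 0.0543  P(HI>1) = 0.000 | mean TCR = 2.13e-05  P(TCR>1e-6) = 1.000
#>   child: mean HI = 0.424  P(HI>1) = 0.006 | mean TCR = 4.25e-05  P(TCR>1e-6) = 1.000

round(mc$contributions$child$tcr_shares, 1)
#>   Cr   Cd   Pb   Ni   Cu   Zn
#> 65.2 34.2  0.7  0.0  0.0  0.0
```

Reading the output: 95% of the synthetic sites exceed the Cd background
and 85% the Cd screening value, mirroring the survey the demo summary was
matched to. Mean hazard indices stay below the HI = 1 guideline for both
populations (children ~8× higher than adults, driven by the ingestion
dose per kg body weight), so noncancer effects are not expected; mean
total cancer risks sit in the 10⁻⁵ range — inside the conventionally
acceptable 10⁻⁶–10⁻⁴ band but above the 10⁻⁶ negligibility threshold in
100% of iterations — with Cr and Cd jointly carrying ~99% of the risk.

The full chain (indices → EF → correlations → PMF scan/fit →
deterministic HRA → Monte Carlo HRA → IDW surfaces, with a reproducible
run manifest) is one call:

```r
run_pipeline(samples, default_config_path(), "results/", seed = 42)
```

or from the shell, `Rscript inst/cli/soilrisk.R run --samples s.csv
--config config.json --out results/`.

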