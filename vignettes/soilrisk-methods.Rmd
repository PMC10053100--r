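---
title: "Methods: pollution indices, PMF source apportionment and probabilistic health risk for soil heavy metals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollution indices, PMF source apportionment and probabilistic health risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilrisk)
```

# Scope and data model

`soilrisk` implements the computational chain that urban-soil heavy-metal
surveys typically apply to a sites-by-metals concentration table: descriptive
statistics and exceedance screening, enrichment factors, Pearson correlation
screening, positive matrix factorization (PMF) source apportionment,
deterministic and Monte Carlo human health risk assessment (HRA), and inverse
distance weighted (IDW) concentration surfaces.

The central container is the `sample_table`: one row per sampling site with a
unique `site_id`, planar coordinates `x`/`y`, and concentrations in
mg kg^-1^ for each analyte (the shipped defaults cover Cd, Cr, Cu, Zn, Ni,
Pb) plus a crustal reference element (Mn). Values below the method detection
limit (MDL) are stored exactly as reported: no substitution is applied
anywhere; the PMF stage instead widens their uncertainty (see below), and
indices and HRA use them unchanged.

Configuration is a single JSON document with three blocks — `reference`
(per-metal geochemical background, regulatory guide value and MDL, plus the
reference-element background), `toxicity` (per-metal, per-route reference
doses RfD and slope factors SF) and `exposure` (per-population exposure
factors, each either a point value or a distribution). The shipped defaults
combine published provincial background values, GB15618-2018 agricultural
screening values and ICP-MS detection limits with *EPA-conventional stand-in*
toxicity and exposure values of the kind used throughout the Chinese
urban-soil literature. They are defaults to be edited, not authoritative
site-specific values; in particular the Mn background (583 mg kg^-1^, the
Chinese national-scale soil value) is a synthetic stand-in and is a required
key with no in-code default, because enrichment factors are meaningless
without a deliberate choice of reference background.

# Pollution indices

For each metal the summary reports min, max, arithmetic mean, sample SD
(n−1 denominator), the coefficient of variation CV = 100·sd/mean (%), and
exceedance rates: the share of sites *strictly* above the background and
guide values. Strict inequality matters only on ties and follows the usual
reading of "exceeding".

A consistency note on the shipped demo summary: the published table it
reproduces prints CV = 153% for Cd, while the printed mean (2.52) and SD
(4.31) imply 171%. The package computes CV from mean and SD; the test suite
documents the 171% value and the mismatch rather than matching the printed
153%.

The enrichment factor for metal *i* at a site is the double ratio

$$EF_i = \frac{(C_i / C_{Mn})_{sample}}{(C_i / C_{Mn})_{background}},$$

using the site's own Mn concentration, so EF is invariant to proportional
dilution of the whole sample. Classification follows the Sutherland scheme
with left-closed intervals at the conventional cut points 2/5/20/40
(deficient-to-minimal, moderate, significant, very high, extreme). The cut
points live in the configuration because published variants differ; the
bounds used by any given study should be copied into `ef_class_bounds`.

# PMF receptor model

The receptor model decomposes the concentration matrix as
$x_{ij} = \sum_k g_{ik} f_{kj} + e_{ij}$ with both factors nonnegative, by
minimising the uncertainty-weighted objective

$$Q = \sum_{i}\sum_{j} \left(\frac{e_{ij}}{u_{ij}}\right)^2 .$$

Per-cell uncertainties follow the standard two-branch rule: for
concentrations above the MDL, $u = \sqrt{(\epsilon\, c)^2 + MDL^2}$ with
error fraction $\epsilon$ (default 0.1 — the source study does not state its
value, so it is configurable); at or below the MDL, $u = \tfrac{5}{6}\,MDL$.

## Solver

The optimiser is multiplicative updates for the weighted Frobenius norm
(weights $1/u^2$), the natural generalisation of Lee–Seung NMF updates.
They preserve nonnegativity by construction and never increase Q; a
property test asserts the monotone descent of the stored Q trace. The
contract is the objective, not the algorithm: the test suite checks the
attained Q against an independent nonnegative-factorization oracle rather
than comparing iterates.

Each fit runs `n_runs` random restarts (default 20, the conventional
operation count for this model class), each initialised from the absolute
values of seeded Gaussian draws scaled to the data magnitude, and returns
the lowest-Q converged run. Convergence is declared when the relative Q
change stays below `tol` (default 1e-8) for 20 consecutive iterations. One
numerical subtlety: on exactly factorizable (noise-free) data the updates
approach a zero-residual solution along a geometric tail on which the
*relative* change never stabilises; a run that ends with Q below 1e-6 of the
data's weighted sum of squares is therefore also counted as converged.

Scale ambiguity between G and F is fixed only at reporting time: rows of F
are normalised to sum to one and G absorbs the mass (mg kg^-1^). This is a
pure rescaling of the factor pair, so the reconstruction G·F, Q, and all
percentage reports are invariant to it.

## Robust mode and diagnostics

Following the EPA PMF convention, cells whose scaled residual $|e/u|$
exceeds a threshold (default 4) have their uncertainty inflated by
$\sqrt{|e/u|/\text{threshold}}$; Q recomputed with the inflated
uncertainties is reported as `Q_robust` alongside `Q_true`. The
factor-number scan tabulates both and their ratio over a candidate range of
k; the working diagnostic is the k past which Q stops dropping sharply,
with Q_robust/Q_true near one indicating the absence of dominating
outliers. Reports follow the field's two standard displays: per-metal
factor shares (each metal's reconstructed mass split across factors, summing
to 100%) and each factor's share of total reconstructed mass.

Factor labels are arbitrary; recovery tests match estimated to true
profiles by cosine similarity maximised over factor permutations
(enumerated exhaustively — k ≤ 4 in all tests, so 24 permutations).

# Health risk assessment

Average daily doses (mg kg^-1^ d^-1^) for the three standard soil exposure
routes are

$$ADD_{ing} = \frac{C \cdot IngR \cdot EFreq \cdot ED}{BW \cdot AT}\times10^{-6},\qquad
ADD_{derm} = \frac{C \cdot SA \cdot AF \cdot ABS \cdot EFreq \cdot ED}{BW \cdot AT}\times10^{-6},$$
$$ADD_{inh} = \frac{C \cdot InhR \cdot EFreq \cdot ED}{PEF \cdot BW \cdot AT}\times10^{-6},$$

with AT the noncancer (ED·365 d) or cancer (70·365 d) averaging time. Note
the $10^{-6}$ factor is applied to the inhalation route exactly as in the
source formulation, although the particle emission factor PEF
(m^3^ kg^-1^) already performs the soil-to-air conversion; the practical
consequence, documented here deliberately, is that inhalation contributes
negligibly to every total. The symbol `EFreq` (exposure frequency, d a^-1^)
is used throughout to avoid the collision with EF, the enrichment factor.

Noncancer risk: HQ = ADD/RfD per metal and route that has a reference dose,
HI = ΣHQ, with HI > 1 flagging potential effects. Cancer risk:
CR = ADD·SF per metal and route that has a slope factor, TCR = ΣCR, read
against the conventional 10^-6^ (negligible below) and 10^-4^ (unacceptable
above) bounds. Which metals are carcinogens through which routes is decided
entirely by which SF entries exist in the configuration, never in code; the
shipped table carries SFs for Cd, Cr, Ni and Pb (the Pb oral slope factor
8.5×10^-3^ follows common Chinese practice, since EPA IRIS provides none).

# Monte Carlo propagation

The probabilistic assessment redraws, independently per iteration, every
metal concentration and every exposure parameter that is specified as a
distribution, applies the dose/risk equations per iteration (the same
vectorised code path as the deterministic assessment), and summarises the
HI and TCR draws by mean, SD, percentiles (5/10/25/50/75/90/95, linear
interpolation between order statistics — R type 7; a "95% interval" of
these draws is read as the 2.5–97.5 percentile band) and exceedance
probabilities P(HI>1), P(TCR>10^-6^), P(TCR>10^-4^). The default is 10,000
iterations. All quantities are sampled independently: no correlation
structure is imposed because none is stated for this model class.

Concentrations enter as lognormals moment-matched to the arithmetic mean
and SD of the sample table (or of a published summary), the standard
geochemical assumption for right-skewed concentrations, rather than by
resampling the finite site set. These distributions are *not* truncated at
the observed min/max: truncating a heavy-tailed lognormal biases the
matched moments noticeably (see next section), and the matched mean/SD are
the quantities the assessment is meant to honour.

Per-metal contribution shares are ratios of means,
share_j = mean(HQ_j)/mean(HI)·100, which sum to 100 exactly.

With all distributions degenerate (point values) the Monte Carlo engine
reproduces the deterministic assessment to 1e-12 relative — a cross-module
identity asserted in the acceptance tests.

# Synthetic data: what it emulates and what it does not

Two generators make the chain testable without field data.

`generate_factor_samples()` draws ground-truth nonnegative G (lognormal
contributions, right-skewed across sites) and F (sparse compositions —
each factor loads strongly on a small metal subset, which is what
chemically distinguishable sources look like and what makes the
factorization identifiable), forms X = G·F + E with elementwise noise SD
equal to `noise_cv` times the clean value (default 0.1, a realistic
relative measurement/model error), and clips negatives to zero. Recovery
tests on this generator establish that the solver finds a known planted
structure (profile cosine similarity, per-metal fit r², Q elbow at the true
k); they do not establish that any particular real-world factorization is
chemically correct, which is an interpretation step outside the package.

`generate_matched_samples()` draws each metal independently from a
lognormal moment-matched to a published arithmetic mean/SD, truncated to
the published [min, max] by rejection (an error is raised if acceptance
falls below 1%). One quantified caveat: for heavy-tailed targets,
truncation biases the moments even when it removes little probability
mass. For the shipped demo summary's Cd row (CV 171%), truncation to the
published range removes only ~2% of probability but lowers the mean by
~12% (truncated mean 2.205 vs target 2.52, by numerical integration). The
tests therefore validate the generator against the *truncated*
distribution's moments, computed by an independent integration oracle, and
the Monte Carlo concentration model deliberately omits truncation. The
generator draws metals independently — inter-metal correlation exists only
in the factor-structured generator, and spatial autocorrelation in neither,
so IDW output on synthetic tables is smooth noise, exercised for numerical
correctness, not realism.

# Spatial interpolation

IDW with Euclidean distance on the supplied planar coordinates (no CRS
logic: coordinates are taken as already projected), default power 2 and all
sites as neighbours; both are configurable and neither is prescribed by the
model class. Cell values are convex combinations of site values, so
surfaces are bounded by the data range and honour exact site coincidence
(distance < 1e-9). Output is an ESRI-style ASCII grid, a plain-text format
chosen so that no GIS dependency is needed.

# Pipeline and reproducibility

`run_pipeline()` executes indices → EF → correlation → PMF (scan, then
fit) → deterministic HRA → Monte Carlo HRA → IDW and writes a JSON
manifest listing every output with the package version, the root seed and
the per-stage derived seeds. All randomness flows from the single root
seed through a deterministic integer split, so reruns are bit-identical; a
stage failure aborts with the stage's name while preserving completed
outputs.

# Known limitations

* Toxicity and exposure defaults are stand-ins, not a reviewed toxicological
  database; dermal RfDs are supplied directly in the shipped table (the
  common oral-RfD × gastrointestinal-absorption derivation is a data
  decision for the user, not code).
* No bioavailability/bioaccessibility adjustment; total concentrations are
  used throughout.
* PMF provides no rotational (Fpeak) exploration and no bootstrap or
  displacement error estimates; uncertainty on the factorization is
  addressed only through multi-start dispersion of Q.
* The Monte Carlo engine assumes independence of all inputs; correlated
  sampling (e.g. Iman–Conover) is out of scope.
* IDW is the only interpolator; no kriging or variography.
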