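---
title: "Quantifying low-abundance proteins in single cells by FCS: models, filters and synthetic data"
author: "fcsquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying low-abundance proteins in single cells by FCS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcsquant)
```

## The measurement and the model

Fluorescence correlation spectroscopy (FCS) infers the number and mobility
of fluorescent molecules from intensity fluctuations in a femtolitre-scale
confocal observation volume. As labelled molecules diffuse through the
approximately 3D-Gaussian detection profile (lateral waist $w_0$, axial
extent $z_0 = S\,w_0$ with structural parameter $S$), the photon count rate
fluctuates; the normalised autocorrelation of those fluctuations,

$$
g(\tau) \;=\; \mathrm{offset} + \frac{1}{N}
\left[1 + \frac{T}{1-T}\,e^{-\tau/\tau_T}\right]
\sum_{i=1}^{2} f_i
\left(1 + \frac{\tau}{\tau_i}\right)^{-1}
\left(1 + \frac{\tau}{S^2 \tau_i}\right)^{-1/2},
$$

carries the molecule number $N$ in its amplitude ($g(0^+) = 1/N$ for a
triplet-free system), the characteristic diffusion times $\tau_i$ in its
decay, and reversible fluorophore dark-state (triplet) blinking in a fast
exponential with dark fraction $T$ and relaxation time $\tau_T$. Diffusion
coefficients follow from the calibrated beam waist as
$D_i = w_0^2 / (4\tau_i)$ (`diffusion_constant()`), and molecular
brightness (counts per molecule, CPM) is the mean count rate divided by
$N$. The two diffusing components are interpreted as freely diffusing
("fast", unbound) versus membrane-associated ("slow", bound) protein; the
slow fraction $f_2$ is the bound mobile fraction. Scaling $N$ by the ratio
of cell volume (82 fl) to calibrated confocal volume (0.57 fl) converts
molecules per confocal volume into approximate copies per cell
(`per_cell_copies()`), assuming spatial homogeneity.

The package targets the regime of the yeast mitochondrial-fission adaptor
proteins it was built around: 10–30 molecules in the confocal volume,
per-molecule brightness 5–20 kHz, fast diffusion ~9–13 µm²/s, slow
diffusion ~0.1–0.2 µm²/s, $w_0 = 0.22$ µm, $S$ fixed at 4 in reported
fits.

## The fit-and-filter procedure

`two_stage_fit()` mirrors the published analysis protocol:

1. **Stage 1 (prescreen):** the curve is fitted with $S$ free. Estimates
   outside $[0.1, 15]$ mark an ill-formed observation volume (flag
   `structural_parameter_out_of_range`) and the measurement is excluded
   downstream.
2. **Stage 2 (report):** the curve is refitted with $S = 4$ fixed; these
   parameters are the ones averaged and reported.

Fits are box-constrained nonlinear least squares (`nlminb`), with scale
parameters on a log scale. Initialisation is deterministic and data
driven: $N_0$ from the leading-lag amplitude, $\tau$ starts from where the
running-median-smoothed curve falls to 75% and 25% of that amplitude,
$f_{1,0} = 0.5$, $T_0 = 0.1$, $\tau_{T,0} = 20$ µs. The smoothing step
matters: on noisy curves the raw 75%/25% crossings trigger at spuriously
early lags and drive the optimiser into a $\tau_1 \to 0$ local minimum.
After fitting, components are relabelled so $\tau_1 < \tau_2$ (fast
first). Bounds: $N \in (10^{-3}, 10^4]$, $T \in [0, 0.8]$,
$\tau_T \in [1, 100]$ µs, $\tau_i \in [1\,\mu s, 1\,s]$, $f_1 \in [0, 1]$.

**Quality control** (`apply_filters()`): besides the $S$ prescreen, the
source protocol discards fits with $\chi^2 < 10^{-4}$, as printed — a
direction that is physically surprising (conventional practice discards
*large* residuals) and that presupposes the vendor software's undocumented
$\chi^2$ scaling. The package implements the printed rule verbatim as the
default of `apply_filters()` (threshold $10^{-4}$, direction switchable via
`chi2_rule = "exclude_large"`), with $\chi^2$ defined as the reduced
statistic: weighted residual sum of squares over residual degrees of
freedom, unit weights when no per-lag scatter is available. On this scale a
genuine fit of a 1%-of-signal-noise curve has $\chi^2 \sim 10^{-7}$, so
synthetic pipeline runs (`run_experiment()`) default the cutoff to
$10^{-12}$: the printed *direction* is retained — abnormally small
residuals, i.e. degenerate/overfitted curves, are discarded — on the scale
the artifact's $\chi^2$ actually occupies.

**Per-cell averaging** (`summarize_cell()`): repetition fits are averaged
parameter-wise (the literal reading of the protocol; curve-level averaging
is available via `average_curves()`), and a cell is excluded unless at
least 5 of 10 (10 s × 10 scheme) or 3 of 5 (5 s × 5 scheme) repetitions
survived filtering. Each trace's first 0.5 s of uncorrelated background is
dropped (`trim_trace()`) before correlation.

## What the synthetic generator emulates — and what it does not

Two synthesis paths exist, because they answer different questions:

* **Trace level** (`simulate_trace()`, Rcpp): Brownian dynamics of point
  emitters in a periodic box (at least $6 w_0$ laterally, $6 S w_0$
  axially), 3D Gaussian detection, two-state triplet blinking with
  $k_\mathrm{dark} = T/\tau_T$ and $k_\mathrm{bright} = (1-T)/\tau_T$,
  Poisson photon statistics. The molecule count is set so the expected
  occupancy of the effective volume $V_\mathrm{eff} = \pi^{3/2} S w_0^3$
  equals the requested $N$. Default binning is 2 µs rather than the
  instrument's 200 ns: the smallest physical timescale of interest is the
  triplet time ($\geq 10$ µs), and 200 ns × 10 s is not desk-scale. This
  path validates the correlator and the physics (amplitude $1/N$, mean
  rate = brightness × occupancy × $2^{-3/2}$, $D$ recovery).
* **Curve level** (`generate_curve()`, `generate_population()`): the
  closed-form model plus Gaussian noise, per cell and repetition. This is
  the default pipeline path (seconds, not minutes) and the basis of all
  population-level statements.

Per-cell heterogeneity is log-normal for positive quantities (molecule
number, brightness, diffusion coefficients) parameterised by median and
CV, and logit-normal for fractions — a package choice; the source reports
only medians/means with confidence intervals. The default cell-to-cell CV
is 20%, the calibration stated for the molecule-number recovery setup. The
triplet convention is $T = 0.15$, $\tau_T = 20$ µs (the source does not
print its triplet values). "Bound" molecules are represented as a
slow-diffusing species, not by explicit membrane geometry, matching the
interpretation of the slow component as membrane-associated. Not modelled:
photobleaching, detector afterpulsing and dead time, optical aberrations,
cross-correlation, autofluorescence background structure, and any image
formation (segmentation inputs are consumed as tables, never computed from
images). A green recovery test therefore establishes the *procedure's*
correctness on data satisfying the model's assumptions — it cannot
certify instrument- or cell-specific artefacts.

### Curve noise: two models, one important caveat

`generate_curve()` offers `noise_model = "scaled_baseline"`
(sd $= s\,(1+g)$, the default: an absolute noise floor of about $s$,
as if noise were proportional to the instrument-displayed amplitude
$1+g$) and `"proportional"` (sd $= s\,g$: noise at a constant fraction of
the correlation signal). The distinction is not cosmetic. At $N \approx
20$ the correlation amplitude is $\sim 0.05$, so a "1%" scaled-baseline
noise (0.01 absolute) is ~20% of the usable signal; we verified — by
restarting the optimiser from the true parameters, confirming the global
minimum — that maximum-likelihood scatter of $\tau_1$, $\tau_2$ and the
fractions is then several times larger than any useful tolerance. That is
a property of the data, not the fitter. All population generation and the
acceptance harness therefore use proportional 1% noise, the only reading
under which the documented recovery tolerances (median errors: $N \leq
5\%$, $\tau_i \leq 15\%$, $f_\mathrm{slow} \leq 0.05$) are attainable;
the scaled-baseline model remains available and contract-tested.

## Statistics layer

Group medians are reported with percentile-bootstrap 95% confidence
intervals (`median_ci()`, seeded; the source's GraphPad method is
unspecified). Two-sample comparisons of non-normal per-cell quantities use
the two-tailed Mann–Whitney U test (`mann_whitney()`): exact by complete
enumeration when both groups have $\leq 8$ observations without ties,
otherwise the normal approximation with mid-rank tie correction and
continuity correction. Normality screening uses the D'Agostino–Pearson
omnibus $K^2$ (`dagostino_k2()`, valid for $n \geq 20$). Normally
distributed mean measurements (diffusion coefficients) are compared with
the unpaired Welch $t$-test (`unpaired_t()`; the source does not state
pooled vs unequal-variance, and Welch is the safer default). The
CPM-versus-amplitude relation is monitored by OLS $R^2$ (`linreg_r2()`):
similar $R^2$ across strains indicates molecule-number differences are
not brightness artefacts. No multiple-testing correction is applied,
matching the source.

Whole-cell integrated intensities are coupled to FCS molecule numbers by
rank normalisation (`rank_normalize()`): each intensity maps to the FCS
reference quantile at its own mid-rank, with plotting positions
$(k-0.5)/n$ and linear interpolation (quantile type 5). The mapping is
monotone, so group ordering and Spearman correlations survive exactly;
`qq_pairs()` provides the quantile–quantile diagnostic. Both
molecules-per-confocal-volume and per-cell copies are legitimate
references; the package exposes the choice to the caller.

## Numerical and convention choices

* Correlator normalisation is symmetric (per-lag segment means), which
  removes drift bias; curves store the fluctuation correlation with
  baseline 0, and $1+g$ is only a display convention. The published
  "amplitude starting points" of 1.37/1.32 are inconsistent with
  $1 + 1/N$ at $N \approx 21$–25 and depend on an undocumented vendor
  normalisation; the package reports $g(0^+)$ and does not attempt to
  reproduce them.
* Multi-tau uses $m = 16$ channels per stage with pairwise coarsening;
  its stage-0 lags agree with the brute-force correlator exactly
  (tested to $10^{-6}$), later stages differ only by deliberate
  coarse-lag averaging.
* A curve is declared `no_correlation` when its leading-lag mean
  amplitude is below 10 times that mean's own standard error (per-point
  noise estimated from first differences). Using raw per-point noise as
  the floor would reject every legitimate noisy curve whose amplitude is
  below 10 sd — at $N = 20$ and 1% noise, all of them.
* The mobility targets not printed by the source are filled once from the
  package regime: the slow component of the FIS1 heterozygote in glucose
  at 0.15 µm²/s, the fast component of the MDV1 heterozygote in glycerol
  at the printed MDV1 glucose rate 9.56 µm²/s.

## A worked run

```{r example, eval = FALSE}
# two-group study at the published FIS1 hemizygote/heterozygote medians
design <- study_design(list(
  study_group("FIS1_GFP/-", n_cells = 60, median_n = 23.85, repetitions = 5),
  study_group("FIS1_GFP/+", n_cells = 60, median_n = 20.85, repetitions = 5)
))
res <- run_experiment(design, seed = 1)
res$summaries          # median N per group with bootstrap CI
res$recovery           # recovered vs ground-truth medians
res$tests[[1]]$report  # Mann-Whitney comparison
```

## Known limitations

* Curve-level noise is independent across lags; real correlator noise is
  lag-correlated and heteroscedastic (Koppel statistics), so absolute
  error bars on single-curve fits are optimistic.
* The trace-level simulator conserves molecule number (no bleaching) and
  uses a hard periodic box; very slow species revisit the volume more
  regularly than in an open cytoplasm.
* Exact Mann–Whitney enumeration is limited to $n \leq 8$ per group; the
  tie-corrected normal approximation is used beyond that, as in standard
  practice.
* No vendor raw formats are read; inputs are CSV with JSON sidecars.
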