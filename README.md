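# fcsquant

Single-cell quantification of low-abundance proteins by fluorescence
correlation spectroscopy (FCS), as a reusable, tested R pipeline.

FCS reads molecule numbers and mobility out of the intensity fluctuations
a fluorescently tagged protein produces while diffusing through a
femtolitre confocal volume. The autocorrelation of the photon-count trace,

    g(tau) = offset + (1/N) * [1 + T/(1-T) * exp(-tau/tau_T)] *
             sum_i f_i * (1 + tau/tau_i)^-1 * (1 + tau/(S^2 tau_i))^-1/2

has amplitude `1/N` (N = molecules in the effective volume), decays on the
diffusion times `tau_i` (diffusion coefficients `D_i = w0^2 / (4 tau_i)`
for a calibrated beam waist `w0`), and carries triplet blinking (dark
fraction `T`, relaxation `tau_T`) and a fixed aspect ratio `S = z0/w0`.
Derived per cell: molecule number, molecular brightness (CPM = count rate
/ N), fast/slow (unbound/bound) fractions, and approximate copies per cell
(N x 82 fl / 0.57 fl). It was built for — and is calibrated to — the
regime of GFP-tagged mitochondrial fission proteins in diploid budding
yeast: ~10–30 molecules in the volume, brightness 5–20 kHz, fast diffusion
~9–13 µm²/s, slow ~0.1–0.2 µm²/s, `w0 = 0.22` µm, `S = 4`.

The package covers the whole chain, each stage usable on its own:

| stage | functions |
|---|---|
| synthetic data (microscope stand-in) | `simulate_trace()` (Brownian dynamics, Rcpp), `generate_curve()`, `generate_population()`, `generate_intensity_table()`, `fcs_strain_presets()` |
| correlation | `trim_trace()`, `autocorrelate_direct()`, `autocorrelate_multitau()`, `average_curves()` |
| model fitting | `fcs_model_g()`, `fit_curve()`, `two_stage_fit()` (free-S prescreen in [0.1, 15], then S = 4 refit) |
| QC + quantification | `apply_filters()` (as-printed chi² rule, S prescreen), `summarize_cell()` (min 5/10 or 3/5 repetitions), `diffusion_constant()`, `per_cell_copies()`, `median_ci()` |
| population statistics | `mann_whitney()`, `dagostino_k2()`, `linreg_r2()`, `unpaired_t()` |
| imaging coupling | `rank_normalize()`, `qq_pairs()` |
| orchestration | `run_experiment()`, `fcsquant_cli()` (CLI: `simulate`, `correlate`, `fit`, `quantify`, `compare`, `couple`, `run`) |

## Worked example

Simulate the allele-count comparison — a hemizygote (one tagged allele,
second allele deleted) versus a heterozygote (one tagged, one untagged
allele) at the published molecule-number medians — then push the synthetic
curves through fit, QC and per-cell averaging:

```r
library(fcsquant)
design <- study_design(list(
  study_group("FIS1_GFP/-", n_cells = 60, median_n = 23.85, repetitions = 5),
  study_group("FIS1_GFP/+", n_cells = 60, median_n = 20.85, repetitions = 5)
))
res <- run_experiment(design, seed = 1)
res$summaries
#>                group  n median ci_lower ci_upper
#> 1 FIS1_GFP/-|glucose 60  24.51    23.32    25.91
#> 2 FIS1_GFP/+|glucose 60  20.61    20.26    22.85
res$tests[[1]]$report
#> Mann-Whitney U: statistic = 2565, two-tailed p = 6.006e-05 (n = 60, 60)
#>   direction: a > b
```

The recovered group medians (24.51 and 20.61 molecules per confocal
volume) track this population's ground-truth sample medians (24.47,
20.60) to ~0.2%, and the Mann–Whitney test flags the hemizygote's higher
abundance (p < 0.001) — the compensation pattern the design encodes. The
hemizygote's median per-cell copy number here is 3526 (= 24.51 x
82/0.57).

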