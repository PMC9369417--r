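# Study-level synthetic data: per-cell parameter draws and noisy curves for
# a strains x conditions design, with ground truth retained throughout.

#' One group of a synthetic study design
#'
#' Per-cell parameters are drawn from log-normal distributions for positive
#' quantities (molecule number, brightness, diffusion coefficients) and a
#' logit-normal distribution for the slow fraction; dispersion 0 gives the
#' degenerate distribution at the median.
#'
#' @param strain,condition Group labels (e.g. "FIS1_GFP/+", "glucose").
#' @param n_cells Number of cells (>= 1).
#' @param median_n Group median molecule number in the confocal volume.
#' @param cv_n Coefficient of variation of N across cells (default 0.2).
#' @param median_cpm Median per-molecule brightness in kHz.
#' @param cv_cpm CV of brightness across cells.
#' @param d_fast,d_slow Median fast/slow diffusion coefficients in um^2/s.
#' @param cv_d CV of the diffusion coefficients across cells.
#' @param fraction_slow Median slow (membrane-associated) fraction in (0, 1).
#' @param sd_logit_fraction Dispersion of the slow fraction on the logit
#'   scale (0 = degenerate).
#' @param repetitions Correlation curves per cell.
#' @param median_intensity Median whole-cell integrated intensity (a.u.).
#' @param cv_intensity CV of the integrated intensity.
#' @param prob_localised Probability that a cell shows a detected
#'   subcellular object (localisation class "positive").
#' @return A `study_group` list.
#' @export
study_group <- function(strain, condition = "glucose", n_cells,
                        median_n, cv_n = 0.2,
                        median_cpm = 10, cv_cpm = 0.1,
                        d_fast = 11, d_slow = 0.15, cv_d = 0.1,
                        fraction_slow = 0.45, sd_logit_fraction = 0.25,
                        repetitions = 5,
                        median_intensity = 5e5, cv_intensity = 0.25,
                        prob_localised = 0.8) {
  stopifnot(n_cells >= 1, median_n > 0, cv_n >= 0, median_cpm > 0,
            cv_cpm >= 0, d_fast > 0, d_slow > 0, d_fast > d_slow,
            cv_d >= 0, fraction_slow > 0, fraction_slow < 1,
            sd_logit_fraction >= 0, repetitions >= 1,
            median_intensity > 0, cv_intensity >= 0,
            prob_localised >= 0, prob_localised <= 1)
  structure(as.list(environment()), class = "study_group")
}

#' Synthetic study design
#'
#' @param groups List of [study_group] objects.
#' @param optics An [optics_spec] shared by all groups.
#' @param triplet A [triplet_spec]; simulation convention `T = 0.15`,
#'   `tau_T = 20 us` (the source protocol does not print its triplet
#'   values).
#' @param noise_scale Relative curve noise (default 0.01, i.e. 1%
#'   multiplicative noise).
#' @param noise_model Curve noise model, see [generate_curve]; the study
#'   default is `"proportional"` (1% of the correlation signal), the regime
#'   in which the fit-and-filter procedure is specified to recover its
#'   parameters (see the methods vignette).
#' @param lag_grid Lag grid for the synthetic curves.
#' @return A `study_design` list.
#' @export
study_design <- function(groups, optics = optics_spec(),
                         triplet = triplet_spec(),
                         noise_scale = 0.01,
                         noise_model = "proportional",
                         lag_grid = make_lag_grid()) {
  if (inherits(groups, "study_group")) groups <- list(groups)
  stopifnot(length(groups) >= 1L,
            all(vapply(groups, inherits, logical(1), "study_group")))
  stopifnot(inherits(optics, "optics_spec"), inherits(triplet, "triplet_spec"))
  stopifnot(noise_scale >= 0)
  noise_model <- match.arg(noise_model, c("scaled_baseline", "proportional"))
  structure(list(groups = groups, optics = optics, triplet = triplet,
                 noise_scale = noise_scale, noise_model = noise_model,
                 lag_grid = lag_grid),
            class = "study_design")
}

# log-normal parameterised by median and CV; cv = 0 degenerates
.rlnorm_med <- function(n, median, cv) {
  if (cv == 0) return(rep(median, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

.rlogitnorm_med <- function(n, median, sd_logit) {
  if (sd_logit == 0) return(rep(median, n))
  stats::plogis(stats::rnorm(n, stats::qlogis(median), sd_logit))
}

#' Generate a synthetic cell population with curves and ground truth
#'
#' Draws per-cell ground-truth parameters for every group of the design and
#' synthesises `repetitions` noisy correlation curves per cell via
#' [generate_curve]. Each curve's mean count rate is the cell's brightness
#' times its molecule number (in kHz), so CPM can be recovered downstream.
#'
#' @param design A [study_design].
#' @param seed Integer seed; output is identical for identical seeds.
#' @return A list with `ground_truth` (data.frame, one row per cell) and
#'   `curves` (named list: per group, per cell, list of [fcs_curve]).
#' @export
generate_population <- function(design, seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  set.seed(as.integer(seed))
  w0 <- design$optics$w0
  gt_list <- list(); curves <- list()
  for (gi in seq_along(design$groups)) {
    grp <- design$groups[[gi]]
    label <- paste(grp$strain, grp$condition, sep = "|")
    nc <- grp$n_cells
    n_true <- .rlnorm_med(nc, grp$median_n, grp$cv_n)
    cpm_true <- .rlnorm_med(nc, grp$median_cpm, grp$cv_cpm)
    d_fast <- .rlnorm_med(nc, grp$d_fast, grp$cv_d)
    d_slow <- .rlnorm_med(nc, grp$d_slow, grp$cv_d)
    f_slow <- .rlogitnorm_med(nc, grp$fraction_slow, grp$sd_logit_fraction)
    # group index keeps ids unique even when labels sanitise identically
    cell_ids <- sprintf("g%02d_%s_c%03d", gi,
                        gsub("[^A-Za-z0-9]+", "_", label), seq_len(nc))
    gt <- data.frame(
      cell_id = cell_ids, strain = grp$strain, condition = grp$condition,
      group = label, n = n_true, cpm = cpm_true,
      d_fast = d_fast, d_slow = d_slow, fraction_slow = f_slow,
      tau_fast = w0^2 / (4 * d_fast), tau_slow = w0^2 / (4 * d_slow),
      stringsAsFactors = FALSE
    )
    gt_list[[label]] <- gt
    grp_curves <- lapply(seq_len(nc), function(i) {
      pars <- fcs_params(
        n = n_true[i],
        triplet_fraction = design$triplet$dark_fraction,
        triplet_time = design$triplet$relaxation_time,
        f1 = 1 - f_slow[i],
        tau1 = gt$tau_fast[i], tau2 = gt$tau_slow[i],
        s = design$optics$structural_parameter, offset = 0
      )
      lapply(seq_len(grp$repetitions), function(r) {
        cv <- generate_curve(pars, lag_grid = design$lag_grid,
                             noise_scale = design$noise_scale,
                             mean_rate = cpm_true[i] * n_true[i],
                             noise_model = design$noise_model)
        cv$meta$cell_id <- cell_ids[i]
        cv$meta$group <- label
        cv$meta$repetition_id <- r
        cv
      })
    })
    names(grp_curves) <- cell_ids
    curves[[label]] <- grp_curves
  }
  list(ground_truth = do.call(rbind, c(gt_list, make.row.names = FALSE)),
       curves = curves)
}

#' Generate a synthetic whole-cell integrated-intensity table
#'
#' Log-normal integrated intensities per cell, with a Bernoulli
#' localisation class (positive = subcellular object detected), emulating
#' the segmented-image intensity tables consumed by the rank-normalisation
#' coupling.
#'
#' @param design A [study_design].
#' @param seed Integer seed.
#' @return data.frame with cell_id, strain, condition, group,
#'   integrated_intensity, localisation_class.
#' @export
generate_intensity_table <- function(design, seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  set.seed(as.integer(seed))
  out <- lapply(seq_along(design$groups), function(gi) {
    grp <- design$groups[[gi]]
    label <- paste(grp$strain, grp$condition, sep = "|")
    nc <- grp$n_cells
    ii <- .rlnorm_med(nc, grp$median_intensity, grp$cv_intensity)
    loc <- ifelse(stats::runif(nc) < grp$prob_localised,
                  "positive", "negative")
    data.frame(
      cell_id = sprintf("g%02d_%s_i%03d", gi,
                        gsub("[^A-Za-z0-9]+", "_", label), seq_len(nc)),
      strain = grp$strain, condition = grp$condition, group = label,
      integrated_intensity = ii, localisation_class = loc,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Study design pre-filled from the published strain values
#'
#' Builds a [study_design] whose group medians come from
#' [fcs_strain_presets]; quantities a preset does not report fall back to
#' the package's regime defaults (brightness 10 kHz, fast diffusion
#' 11 um^2/s, slow diffusion 0.15 um^2/s, slow fraction 0.45). Cell-to-cell
#' dispersions default to a 20% CV on positive quantities.
#'
#' @param rows Row indices of [fcs_strain_presets] to include (default all
#'   glucose groups).
#' @param n_cells Optional override of cells per group (e.g. to scale a
#'   simulation down); `NULL` keeps the published counts.
#' @param repetitions Curves per cell (default 5).
#' @param cv_n CV of the per-cell molecule number (default 0.2).
#' @param noise_scale Relative curve noise (default 0.01).
#' @param ... Passed to [study_design].
#' @return A [study_design].
#' @export
default_study <- function(rows = 1:6, n_cells = NULL, repetitions = 5,
                          cv_n = 0.2, noise_scale = 0.01, ...) {
  pre <- fcs_strain_presets()[rows, , drop = FALSE]
  groups <- lapply(seq_len(nrow(pre)), function(i) {
    p <- pre[i, ]
    ff <- if (is.na(p$frac_fast)) 0.55 else p$frac_fast
    study_group(
      strain = paste0(p$gene, "_", p$alleles),
      condition = p$condition,
      n_cells = if (is.null(n_cells)) p$n_cells else n_cells,
      median_n = p$median_n,
      cv_n = cv_n,
      median_cpm = if (is.na(p$cpm)) 10 else p$cpm,
      cv_cpm = 0.1,
      d_fast = if (is.na(p$d_fast)) 11 else p$d_fast,
      d_slow = if (is.na(p$d_slow)) 0.15 else p$d_slow,
      fraction_slow = 1 - ff,
      repetitions = repetitions
    )
  })
  study_design(groups, noise_scale = noise_scale, ...)
}

#' Published single-cell FCS reference values for the yeast fission strains
#'
#' Central values reported for GFP-tagged Fis1p and Mdv1p in diploid
#' *S. cerevisiae*: median molecule numbers per confocal volume, mean
#' molecular brightness (CPM), mean fast/slow diffusion coefficients and
#' fast-fraction percentages, with the published per-group cell counts.
#' `NA` marks quantities not reported for a group. Diffusion values for the
#' protein-abundance groups and slow-component values not printed are
#' filled with the package's regime defaults only where a simulation needs
#' them (see [default_study]).
#'
#' @return data.frame, one row per strain x condition group.
#' @export
fcs_strain_presets <- function() {
  data.frame(
    gene = c("FIS1", "FIS1", "FIS1", "MDV1", "MDV1", "MDV1",
             "FIS1", "FIS1", "MDV1", "MDV1"),
    alleles = c("GFP/GFP", "GFP/+", "GFP/-", "GFP/GFP", "GFP/+", "GFP/-",
                "GFP/+", "GFP/-", "GFP/+", "GFP/-"),
    condition = c(rep("glucose", 6), rep("glycerol", 4)),
    n_cells = c(63, 107, 145, 124, 108, 81, 103, 158, 131, 135),
    median_n = c(25.19, 20.85, 23.85, 22.29, 19.93, 20.19,
                 20.02, 22.98, NA, NA),
    cpm = c(20, 5, NA, NA, NA, NA, NA, NA, NA, NA),
    d_fast = c(NA, 12.25, 9.48, NA, 9.56, 10.46, 11.11, 11.09, NA, NA),
    d_slow = c(NA, NA, NA, NA, NA, NA, NA, NA, 0.15, 0.18),
    frac_fast = c(NA, 0.596, 0.612, NA, 0.511, 0.516,
                  0.585, 0.620, 0.445, 0.416),
    stringsAsFactors = FALSE
  )
}
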