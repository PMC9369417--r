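# Plain-text I/O: every table is CSV with a JSON sidecar named
# <table>.json carrying units, acquisition metadata and ground truth.

.sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write / read a photon trace as CSV plus JSON sidecar
#'
#' CSV columns: `bin_index`, `counts`. The sidecar carries `bin_width_s`,
#' `duration_s`, repetition and cell labels and any ground-truth block.
#'
#' @param trace An [fcs_trace].
#' @param path CSV file path (sidecar written next to it).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "fcs_trace"))
  utils::write.csv(
    data.frame(bin_index = seq_along(trace$counts) - 1L,
               counts = as.integer(trace$counts)),
    path, row.names = FALSE)
  meta <- list(bin_width_s = trace$bin_width, duration_s = trace$duration,
               repetition = trace$repetition_id, cell_id = trace$cell_id,
               group = trace$group)
  if (!is.null(trace$ground_truth))
    meta$ground_truth <- .serialize_gt(trace$ground_truth)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

.serialize_gt <- function(gt) {
  rapply(gt, unclass, how = "replace")
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  fcs_trace(df$counts, bin_width = meta$bin_width_s,
            repetition_id = meta$repetition %||% 1L,
            cell_id = meta$cell_id %||% NA_character_,
            group = meta$group %||% NA_character_)
}

#' Write / read a correlation curve as CSV plus JSON sidecar
#'
#' CSV columns: `lag_s`, `g`. Sidecar: `mean_rate_khz` and provenance.
#'
#' @param curve An [fcs_curve].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "fcs_curve"))
  utils::write.csv(data.frame(lag_s = curve$lags, g = curve$g),
                   path, row.names = FALSE)
  meta <- curve$meta
  if (!is.null(meta$ground_truth)) meta$ground_truth <- unclass(meta$ground_truth)
  meta$mean_rate_khz <- curve$mean_rate
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  side <- .sidecar_path(path)
  meta <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE) else list()
  mr <- meta$mean_rate_khz %||% NA_real_
  if (is.null(mr) || length(mr) == 0) mr <- NA_real_
  meta$mean_rate_khz <- NULL
  fcs_curve(df$lag_s, df$g, mean_rate = mr, meta = as.list(meta))
}

# flat one-row summary of a fit for CSV export
.fit_row <- function(fit, cell_id = NA_character_, group = NA_character_,
                     repetition = NA_integer_) {
  p <- fit$params
  data.frame(
    cell_id = cell_id, group = group, repetition = repetition,
    n = if (is.null(p)) NA_real_ else p$n,
    triplet_fraction = if (is.null(p)) NA_real_ else p$triplet_fraction,
    triplet_time_s = if (is.null(p)) NA_real_ else p$triplet_time,
    f1 = if (is.null(p)) NA_real_ else p$f1,
    tau1_s = if (is.null(p)) NA_real_ else p$tau1,
    tau2_s = if (is.null(p)) NA_real_ else p$tau2,
    s = if (is.null(p)) NA_real_ else p$s,
    offset = if (is.null(p)) NA_real_ else p$offset,
    chi2 = fit$chi2, cpm = fit$cpm,
    free_s_estimate = fit$free_s_estimate,
    mean_rate_khz = fit$mean_rate,
    qc_flags = paste(fit$qc_flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Flatten a list of fits into a data.frame
#'
#' @param fits List of `fcs_fit` objects; elements may carry `cell_id`,
#'   `group` and `repetition_id` fields.
#' @return data.frame with one row per fit.
#' @export
fits_to_table <- function(fits) {
  rows <- lapply(fits, function(f)
    .fit_row(f, f$cell_id %||% NA_character_, f$group %||% NA_character_,
             f$repetition_id %||% NA_integer_))
  do.call(rbind, c(rows, make.row.names = FALSE))
}
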