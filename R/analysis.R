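#' Relative impedance (extracted cell signal)
#'
#' The cell signal of one electrode is the baseline-normalised change of
#' the impedance magnitude, `(|Z| with cells - |Z| without cells) /
#' |Z| without cells x 100`, in percent per frequency. It is zero wherever
#' the with-cells spectrum equals the baseline, may be negative, and is
#' invariant to rescaling both spectra by a common positive factor.
#'
#' @param z_with,z_without Impedance magnitudes (Ohm) on a common frequency
#'   grid; `z_without` must be strictly positive.
#' @param frequencies_hz Optional frequency grid; carried along for
#'   [spectrum_maximum()].
#' @return An object of class `relative_spectrum`: a data frame with
#'   columns `frequency_hz` and `rel_imp_pct`.
#' @examples
#' rs <- relative_impedance(c(150, 100), c(100, 100), c(1e4, 1e5))
#' rs$rel_imp_pct   # 50 0
#' @export
relative_impedance <- function(z_with, z_without, frequencies_hz = NULL) {
  if (length(z_with) != length(z_without))
    stop("'z_with' and 'z_without' must have equal length", call. = FALSE)
  if (length(z_with) == 0)
    stop("empty spectra", call. = FALSE)
  if (any(!is.finite(z_without)) || any(z_without <= 0))
    stop("baseline |Z| must be positive everywhere", call. = FALSE)
  if (is.null(frequencies_hz)) frequencies_hz <- seq_along(z_with)
  if (length(frequencies_hz) != length(z_with))
    stop("'frequencies_hz' length mismatch", call. = FALSE)
  structure(
    data.frame(frequency_hz = as.numeric(frequencies_hz),
               rel_imp_pct = 100 * (z_with - z_without) / z_without),
    class = c("relative_spectrum", "data.frame")
  )
}

#' Maximum of a relative-impedance spectrum
#'
#' Returns the maximum relative impedance over the sampled frequency grid
#' and the frequency at which it is attained; ties are broken toward the
#' lower frequency. No smoothing or interpolation is applied.
#'
#' @param rs A [relative_impedance()] result (or a data frame with columns
#'   `frequency_hz`, `rel_imp_pct`).
#' @return An object of class `spectrum_max`: a list with
#'   `max_rel_imp_pct`, `f_at_max_hz` and the grid `index`.
#' @export
spectrum_maximum <- function(rs) {
  if (!is.data.frame(rs) || !all(c("frequency_hz", "rel_imp_pct") %in% names(rs)))
    stop("'rs' must be a relative_spectrum", call. = FALSE)
  if (nrow(rs) == 0) stop("empty spectrum", call. = FALSE)
  i <- which.max(rs$rel_imp_pct)   # first index wins ties -> lower frequency
  structure(list(max_rel_imp_pct = rs$rel_imp_pct[i],
                 f_at_max_hz = rs$frequency_hz[i], index = i),
            class = "spectrum_max")
}

#' @export
print.spectrum_max <- function(x, ...) {
  cat(sprintf("maximum relative impedance %.1f%% at %.3g kHz\n",
              x$max_rel_imp_pct, x$f_at_max_hz / 1e3))
  invisible(x)
}

#' Covered-electrode call
#'
#' An electrode is called covered when its maximum relative impedance
#' reaches the detection threshold (inclusive boundary). The default
#' threshold of 10 percent sits well above the 1 percent measurement-noise
#' floor and below the smallest single-cell signal the default forward
#' model produces (about 15 percent).
#'
#' @param sm A [spectrum_maximum()] result, or a numeric maximum (%).
#' @param threshold_pct Detection threshold in percent (> 0).
#' @return An object of class `coverage_call`: list with `covered`,
#'   `max_rel_imp_pct`, `threshold_pct`.
#' @export
call_covered <- function(sm, threshold_pct = 10) {
  if (!is.finite(threshold_pct) || threshold_pct <= 0)
    stop("'threshold_pct' must be positive", call. = FALSE)
  m <- if (inherits(sm, "spectrum_max")) sm$max_rel_imp_pct else as.numeric(sm)
  stopifnot(length(m) == 1, is.finite(m))
  structure(list(covered = m >= threshold_pct, max_rel_imp_pct = m,
                 threshold_pct = threshold_pct),
            class = "coverage_call")
}

# electrode x time matrix of spectral maxima (and argmax frequencies)
electrode_maxima <- function(rec) {
  stopifnot(inherits(rec, "mea_recording"))
  n_el <- dim(rec$zmag)[1]; n_t <- dim(rec$zmag)[3]
  mx <- matrix(NA_real_, n_el, n_t,
               dimnames = list(rownames(rec$baseline), rec$time_h))
  fmx <- mx
  for (j in seq_len(n_t)) {
    ri <- 100 * (rec$zmag[, , j] - rec$baseline) / rec$baseline
    i <- max.col(ri, ties.method = "first")
    mx[, j] <- ri[cbind(seq_len(n_el), i)]
    fmx[, j] <- rec$frequencies_hz[i]
  }
  list(max_pct = mx, f_at_max_hz = fmx)
}

#' Per-well coverage and impedance summary over time
#'
#' For every recorded time point, counts the electrodes called covered and
#' takes the median of the maximum relative impedance over the covered
#' electrodes only. When no eligible electrode is covered the median is
#' undefined and reported as `NA` (never as 0).
#'
#' By default (`exclude_spheroid = TRUE`) electrodes that are already
#' covered at the first time point — when a time-0 measurement exists —
#' are excluded from the median (but not from the count): those
#' electrodes sit under the spheroid body and report the 3D culture
#' itself rather than migrated cells, and would otherwise dominate the
#' cell-amount read-out of slowly spreading wells. Recordings without a
#' time-0 measurement are summarised without exclusion.
#'
#' @param rec An `mea_recording`.
#' @param threshold_pct Covered-electrode threshold in percent.
#' @param exclude_spheroid Exclude electrodes covered at time 0 from the
#'   median (default `TRUE`).
#' @return An object of class `well_summary`: a data frame with columns
#'   `well_id`, `group`, `time_h`, `covered_count`,
#'   `median_max_rel_imp_pct`; the electrode count per well is stored in
#'   attribute `"n_electrodes"`.
#' @examples
#' rec <- simulate_recording("slow", seed = 1)
#' summarize_well(rec)
#' @export
summarize_well <- function(rec, threshold_pct = 10, exclude_spheroid = TRUE) {
  stopifnot(inherits(rec, "mea_recording"))
  if (length(rec$time_h) < 1) stop("recording has no time points", call. = FALSE)
  em <- electrode_maxima(rec)
  covered <- em$max_pct >= threshold_pct
  body <- rep(FALSE, nrow(covered))
  if (exclude_spheroid && any(rec$time_h == 0))
    body <- covered[, which(rec$time_h == 0)[1]]
  med <- vapply(seq_along(rec$time_h), function(j) {
    v <- em$max_pct[covered[, j] & !body, j]
    if (length(v) == 0) NA_real_ else stats::median(v)
  }, numeric(1))
  structure(
    data.frame(well_id = rec$well_id, group = rec$group,
               time_h = rec$time_h, covered_count = colSums(covered),
               median_max_rel_imp_pct = med),
    class = c("well_summary", "data.frame"),
    n_electrodes = dim(rec$zmag)[1],
    threshold_pct = threshold_pct
  )
}

#' Spatial map of maximum relative impedance
#'
#' Arranges the per-electrode maximum relative impedance at one time point
#' on the electrode grid, mirroring the colour-coded coverage maps used to
#' visualise cell spreading. Electrodes not called covered are `NA`.
#'
#' @param rec An `mea_recording`.
#' @param t_h A recorded time point (hours).
#' @param threshold_pct Covered-electrode threshold in percent.
#' @return An `n_rows x n_cols` matrix aligned with the layout (row-major
#'   0-based electrode indexing; entry `[r+1, c+1]` is electrode `(r, c)`).
#' @export
coverage_map <- function(rec, t_h, threshold_pct = 10) {
  stopifnot(inherits(rec, "mea_recording"))
  j <- match(t_h, rec$time_h)
  if (is.na(j))
    stop(sprintf("time %g h is not a recorded time point", t_h), call. = FALSE)
  em <- electrode_maxima(rec)
  v <- em$max_pct[, j]
  v[v < threshold_pct] <- NA_real_
  lay <- rec$layout
  m <- matrix(NA_real_, lay$n_rows, lay$n_cols)
  el <- lay$electrodes
  m[cbind(el$row + 1L, el$col + 1L)] <- v
  dimnames(m) <- list(paste0("r", seq_len(lay$n_rows) - 1L),
                      paste0("c", seq_len(lay$n_cols) - 1L))
  m
}

#' Plot a coverage map
#'
#' Heat-map rendering of [coverage_map()]; uncovered electrodes are drawn
#' grey, covered ones coloured by their maximum relative impedance.
#'
#' @inheritParams coverage_map
#' @param ... Passed to [graphics::image()].
#' @return The map matrix, invisibly.
#' @export
plot_coverage_map <- function(rec, t_h, threshold_pct = 10, ...) {
  m <- coverage_map(rec, t_h, threshold_pct)
  z <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), z,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "column", ylab = "row", axes = FALSE,
                  main = sprintf("%s, %g h", rec$well_id, t_h), ...)
  graphics::box()
  invisible(m)
}

#' Coverage fraction equivalent to a relative-impedance threshold
#'
#' Numerically inverts the forward model on the acquisition grid: the
#' smallest coverage theta whose maximum relative impedance equals the
#' detection threshold. Useful as geometric ground truth when validating
#' covered-electrode calls on noise-free synthetic recordings.
#'
#' @param threshold_pct Detection threshold in percent.
#' @param acq,circuit Acquisition sweep and circuit parameters.
#' @return The equivalent theta in `[0, 1]` (or `NA` if the threshold is
#'   not reachable at full coverage).
#' @export
theta_equivalent <- function(threshold_pct = 10, acq = acquisition_config(),
                             circuit = circuit_params()) {
  f <- acq$frequencies_hz
  z0 <- electrode_impedance(f, 0, circuit)
  g <- function(theta)
    max(100 * (electrode_impedance(f, theta, circuit) - z0) / z0) - threshold_pct
  if (g(1) < 0) return(NA_real_)
  stats::uniroot(g, c(0, 1), tol = 1e-10)$root
}
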