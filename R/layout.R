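#' Electrode array layout
#'
#' Builds the geometry of one multiwell high-density microelectrode array:
#' a rectangular grid of circular working electrodes per well, replicated
#' over the wells of the chip. The default reproduces the 6 x 7 grid at
#' 300 um pitch (100 um electrode diameter, 42 electrodes per well, 9 wells,
#' 378 electrodes in total) with a monitoring area of 1.5 mm x 1.8 mm.
#'
#' Coordinates are in micrometres with the origin at the well centre; x runs
#' along the `n_cols` (6-electrode) axis and y along the `n_rows`
#' (7-electrode) axis. Electrodes are indexed by 0-based `(row, col)` in
#' row-major order.
#'
#' @param n_cols Number of electrode columns per well.
#' @param n_rows Number of electrode rows per well.
#' @param pitch_um Centre-to-centre electrode spacing in micrometres.
#' @param diameter_um Electrode diameter in micrometres; must be smaller
#'   than the pitch.
#' @param n_wells Number of culture wells on the chip (arranged as close to
#'   a square grid as possible, 9 mm well pitch).
#' @return An object of class `electrode_layout`: a list with the grid
#'   parameters, an `electrodes` data frame (`row`, `col` 0-based,
#'   `x_um`, `y_um`, row-major order) and a `well_centers` data frame.
#' @examples
#' lay <- electrode_layout()
#' nrow(lay$electrodes)            # 42
#' lay$n_wells * nrow(lay$electrodes)  # 378
#' @export
electrode_layout <- function(n_cols = 6, n_rows = 7, pitch_um = 300,
                             diameter_um = 100, n_wells = 9) {
  stopifnot(is.numeric(n_cols), is.numeric(n_rows), is.numeric(n_wells))
  if (n_cols < 1 || n_rows < 1 || n_wells < 1)
    stop("electrode and well counts must be >= 1", call. = FALSE)
  if (!is.finite(pitch_um) || pitch_um <= 0)
    stop("'pitch_um' must be positive", call. = FALSE)
  if (!is.finite(diameter_um) || diameter_um <= 0)
    stop("'diameter_um' must be positive", call. = FALSE)
  if (diameter_um >= pitch_um)
    stop("'diameter_um' must be smaller than 'pitch_um'", call. = FALSE)
  n_cols <- as.integer(n_cols); n_rows <- as.integer(n_rows)
  n_wells <- as.integer(n_wells)

  # grid centred on the well centre, row-major (row varies slowest)
  xs <- (seq_len(n_cols) - 1 - (n_cols - 1) / 2) * pitch_um
  ys <- (seq_len(n_rows) - 1 - (n_rows - 1) / 2) * pitch_um
  electrodes <- data.frame(
    row = rep(seq_len(n_rows) - 1L, each = n_cols),
    col = rep(seq_len(n_cols) - 1L, times = n_rows),
    x_um = rep(xs, times = n_rows),
    y_um = rep(ys, each = n_cols)
  )

  # wells on a square-ish grid at 9 mm pitch (96-well ANSI spacing)
  wc <- ceiling(sqrt(n_wells))
  wr <- ceiling(n_wells / wc)
  wi <- seq_len(n_wells) - 1L
  well_centers <- data.frame(
    well = wi,
    x_um = ((wi %% wc) - (wc - 1) / 2) * 9000,
    y_um = ((wi %/% wc) - (wr - 1) / 2) * 9000
  )

  structure(
    list(n_cols = n_cols, n_rows = n_rows, pitch_um = pitch_um,
         diameter_um = diameter_um, n_wells = n_wells,
         electrodes = electrodes, well_centers = well_centers),
    class = "electrode_layout"
  )
}

#' @export
print.electrode_layout <- function(x, ...) {
  ext <- layout_extent(x)
  cat(sprintf(
    "Microelectrode array layout: %d x %d electrodes/well (%d total over %d wells)\n",
    x$n_cols, x$n_rows, x$n_cols * x$n_rows * x$n_wells, x$n_wells))
  cat(sprintf("  pitch %g um, diameter %g um, centre extent %g x %g um\n",
              x$pitch_um, x$diameter_um, ext[1], ext[2]))
  invisible(x)
}

#' Bounding box of electrode centres
#'
#' @param layout An [electrode_layout()].
#' @return Numeric length-2 vector `(x extent, y extent)` in micrometres.
#' @export
layout_extent <- function(layout) {
  stopifnot(inherits(layout, "electrode_layout"))
  c((layout$n_cols - 1) * layout$pitch_um,
    (layout$n_rows - 1) * layout$pitch_um)
}

#' Acquisition configuration for impedance sweeps
#'
#' Frequency sweep and measurement schedule of the impedance analyzer.
#' Defaults correspond to migration monitoring: 41 log-spaced points from
#' 5 kHz to 5 MHz at 10 mV, recorded over 144 h. The microcavity
#' (spheroid-characterisation) mode uses 51 points at 100 mV instead.
#'
#' @param f_min_hz,f_max_hz Sweep limits in Hz.
#' @param n_points Number of log-spaced frequency points (>= 2).
#' @param amplitude_mv Excitation amplitude in mV (metadata only).
#' @param time_points_h Measurement times in hours.
#' @return An object of class `acquisition_config` with a `frequencies_hz`
#'   vector (strictly increasing, log-spaced).
#' @export
acquisition_config <- function(f_min_hz = 5e3, f_max_hz = 5e6, n_points = 41,
                               amplitude_mv = 10,
                               time_points_h = seq(0, 144, by = 24)) {
  if (!is.finite(f_min_hz) || !is.finite(f_max_hz) || f_min_hz <= 0 ||
      f_min_hz >= f_max_hz)
    stop("need 0 < f_min_hz < f_max_hz", call. = FALSE)
  if (n_points < 2) stop("'n_points' must be >= 2", call. = FALSE)
  if (length(time_points_h) < 1 || any(!is.finite(time_points_h)))
    stop("'time_points_h' must be finite", call. = FALSE)
  structure(
    list(f_min_hz = f_min_hz, f_max_hz = f_max_hz,
         n_points = as.integer(n_points), amplitude_mv = amplitude_mv,
         time_points_h = sort(unique(as.numeric(time_points_h))),
         frequencies_hz = exp(seq(log(f_min_hz), log(f_max_hz),
                                  length.out = as.integer(n_points)))),
    class = "acquisition_config"
  )
}

#' Equivalent-circuit parameters of one microelectrode
#'
#' Lumped-element forward model of the electrode-electrolyte interface used
#' to render synthetic recordings: a series solution resistance `R_sol`, a
#' constant-phase element `1 / (Q_cpe * (i w)^n_cpe)` for the double layer,
#' and a cell branch `R_cell || C_cell` whose contribution scales linearly
#' with the covered area fraction. Defaults are tuned so that a fully
#' covered electrode shows a single relative-impedance maximum of roughly
#' 290 percent near 200 kHz, in the mid-frequency band where adherent-cell
#' signals peak, and a single adherent cell (coverage about 0.05) produces
#' a maximum near 15 percent.
#'
#' @param R_sol Solution (spreading) resistance, Ohm.
#' @param Q_cpe CPE magnitude, S s^n.
#' @param n_cpe CPE exponent in (0, 1].
#' @param R_cell Cell-layer resistance at full coverage, Ohm.
#' @param C_cell Cell-layer capacitance at full coverage, F.
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(R_sol = 1500, Q_cpe = 2.5e-9, n_cpe = 0.9,
                           R_cell = 8000, C_cell = 80e-12) {
  vals <- c(R_sol = R_sol, Q_cpe = Q_cpe, n_cpe = n_cpe,
            R_cell = R_cell, C_cell = C_cell)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all circuit parameters must be positive and finite", call. = FALSE)
  if (n_cpe > 1) stop("'n_cpe' must be in (0, 1]", call. = FALSE)
  structure(as.list(vals), class = "circuit_params")
}

#' Impedance magnitude of a partially covered electrode
#'
#' Closed-form forward model: `|Z|(f) = | R_sol + 1/(Q (i 2 pi f)^n) +
#' theta * R_cell / (1 + i 2 pi f R_cell C_cell) |`. `coverage = 0` yields
#' the cell-free baseline. Because both the baseline branch and the cell
#' branch have non-negative real part and non-positive imaginary part,
#' `|Z|` is non-decreasing in `coverage` at every frequency.
#'
#' @param freqs_hz Frequencies in Hz.
#' @param coverage Covered area fraction theta in `[0, 1]` (scalar).
#' @param params A [circuit_params()].
#' @return Numeric vector of impedance magnitudes (Ohm), one per frequency.
#' @examples
#' acq <- acquisition_config()
#' z0 <- electrode_impedance(acq$frequencies_hz, 0, circuit_params())
#' z1 <- electrode_impedance(acq$frequencies_hz, 1, circuit_params())
#' all(z1 >= z0)
#' @export
electrode_impedance <- function(freqs_hz, coverage, params = circuit_params()) {
  stopifnot(inherits(params, "circuit_params"))
  if (length(coverage) != 1 || !is.finite(coverage) ||
      coverage < 0 || coverage > 1)
    stop("'coverage' must be a single value in [0, 1]", call. = FALSE)
  if (any(!is.finite(freqs_hz)) || any(freqs_hz <= 0))
    stop("'freqs_hz' must be positive", call. = FALSE)
  w <- 2i * pi * freqs_hz
  z <- params$R_sol + 1 / (params$Q_cpe * w^params$n_cpe) +
    coverage * params$R_cell / (1 + w * params$R_cell * params$C_cell)
  Mod(z)
}

#' Read and write array configuration files
#'
#' Layout, acquisition and circuit parameters round-trip through a flat
#' YAML file with keys `n_cols`, `n_rows`, `pitch_um`, `diameter_um`,
#' `n_wells`, `f_min_hz`, `f_max_hz`, `n_points`, `amplitude_mv`,
#' `time_points_h` and a `circuit` block `{R_sol, Q_cpe, n_cpe, R_cell,
#' C_cell}`. Missing keys fall back to the package defaults.
#'
#' @param path File path.
#' @param layout,acq,circuit Components to write.
#' @return `read_mea_config()` returns a list with elements `layout`,
#'   `acq` and `circuit`; `write_mea_config()` returns `path` invisibly.
#' @export
read_mea_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pick <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  cir <- cfg$circuit
  cpick <- function(key, default) if (is.null(cir[[key]])) default else cir[[key]]
  list(
    layout = electrode_layout(
      n_cols = pick("n_cols", 6), n_rows = pick("n_rows", 7),
      pitch_um = pick("pitch_um", 300), diameter_um = pick("diameter_um", 100),
      n_wells = pick("n_wells", 9)),
    acq = acquisition_config(
      f_min_hz = pick("f_min_hz", 5e3), f_max_hz = pick("f_max_hz", 5e6),
      n_points = pick("n_points", 41),
      amplitude_mv = pick("amplitude_mv", 10),
      time_points_h = unlist(pick("time_points_h", seq(0, 144, by = 24)))),
    circuit = circuit_params(
      R_sol = cpick("R_sol", 1500), Q_cpe = cpick("Q_cpe", 2.5e-9),
      n_cpe = cpick("n_cpe", 0.9), R_cell = cpick("R_cell", 8000),
      C_cell = cpick("C_cell", 80e-12))
  )
}

#' @rdname read_mea_config
#' @export
write_mea_config <- function(path, layout = electrode_layout(),
                             acq = acquisition_config(),
                             circuit = circuit_params()) {
  stopifnot(inherits(layout, "electrode_layout"),
            inherits(acq, "acquisition_config"),
            inherits(circuit, "circuit_params"))
  cfg <- list(
    n_cols = layout$n_cols, n_rows = layout$n_rows,
    pitch_um = layout$pitch_um, diameter_um = layout$diameter_um,
    n_wells = layout$n_wells,
    f_min_hz = acq$f_min_hz, f_max_hz = acq$f_max_hz,
    n_points = acq$n_points, amplitude_mv = acq$amplitude_mv,
    time_points_h = acq$time_points_h,
    circuit = unclass(circuit)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
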