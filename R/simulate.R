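#' Migration/proliferation phenotype parameters
#'
#' Parameter set of the agent-based spheroid-egress simulator. Cells leave
#' the spheroid rim at `egress_rate_per_h`, perform a persistent random
#' walk with truncated-normal step speeds, and divide as a Poisson process
#' at `proliferation_rate_per_h` (daughters placed one cell diameter from
#' the mother). `mitomycin = TRUE` models proliferation suppression and
#' forces the effective division rate to zero. A finite
#' `disassembly_time_h` models full disassembly of the spheroid body: the
#' central disc stops contributing coverage and emission stops.
#'
#' @param spheroid_radius_um Radius of the spheroid body footprint, um.
#' @param egress_rate_per_h Mean number of cells leaving the rim per hour.
#' @param speed_mean_um_h,speed_sd_um_h Mean and sd of the per-step
#'   migration speed (um/h), truncated at zero.
#' @param persistence Directional correlation of the walk over one hour,
#'   in `[0, 1)`; 0 is an uncorrelated walk.
#' @param proliferation_rate_per_h Division rate per cell per hour.
#' @param mitomycin Logical; if `TRUE` the effective division rate is 0.
#' @param disassembly_time_h Hour after which the spheroid body is gone and
#'   emission stops; `Inf` keeps it for the whole run.
#' @param cell_footprint_um2 Electrode area one adherent cell occupies.
#' @param label Optional phenotype label carried into recordings.
#' @return An object of class `phenotype_params`.
#' @seealso [phenotype_preset()] for the documented presets.
#' @export
phenotype_params <- function(spheroid_radius_um = 300,
                             egress_rate_per_h = 2,
                             speed_mean_um_h = 10,
                             speed_sd_um_h = 3,
                             persistence = 0.8,
                             proliferation_rate_per_h = 0.01,
                             mitomycin = FALSE,
                             disassembly_time_h = Inf,
                             cell_footprint_um2 = 400,
                             label = NA_character_) {
  num <- c(spheroid_radius_um = spheroid_radius_um,
           egress_rate_per_h = egress_rate_per_h,
           speed_mean_um_h = speed_mean_um_h,
           speed_sd_um_h = speed_sd_um_h,
           persistence = persistence,
           proliferation_rate_per_h = proliferation_rate_per_h,
           cell_footprint_um2 = cell_footprint_um2)
  if (any(is.na(num)) || any(!is.finite(num)))
    stop("phenotype parameters must be finite", call. = FALSE)
  if (any(num < 0))
    stop("phenotype parameters must be non-negative", call. = FALSE)
  if (persistence >= 1)
    stop("'persistence' must be in [0, 1)", call. = FALSE)
  if (is.na(disassembly_time_h) || disassembly_time_h <= 0)
    stop("'disassembly_time_h' must be positive (possibly Inf)", call. = FALSE)
  if (cell_footprint_um2 <= 0)
    stop("'cell_footprint_um2' must be positive", call. = FALSE)
  structure(
    list(spheroid_radius_um = spheroid_radius_um,
         egress_rate_per_h = egress_rate_per_h,
         speed_mean_um_h = speed_mean_um_h,
         speed_sd_um_h = speed_sd_um_h,
         persistence = persistence,
         proliferation_rate_per_h =
           if (isTRUE(mitomycin)) 0 else proliferation_rate_per_h,
         mitomycin = isTRUE(mitomycin),
         disassembly_time_h = disassembly_time_h,
         cell_footprint_um2 = cell_footprint_um2,
         label = label),
    class = "phenotype_params"
  )
}

# version-pinned preset table; calibrated so the full pipeline reproduces
# the endpoint coverage of the three phenotypes (fast: almost all
# electrodes by 96 h; intermediate: > 60 % at 144 h; slow: ~35 % at 144 h)
.preset_table <- list(
  fast = list(spheroid_radius_um = 300, egress_rate_per_h = 16,
              speed_mean_um_h = 25, speed_sd_um_h = 8, persistence = 0.85,
              proliferation_rate_per_h = 0.025, disassembly_time_h = 48),
  intermediate = list(spheroid_radius_um = 300, egress_rate_per_h = 3.5,
                      speed_mean_um_h = 9.5, speed_sd_um_h = 3.4,
                      persistence = 0.8, proliferation_rate_per_h = 0.032,
                      disassembly_time_h = Inf),
  slow = list(spheroid_radius_um = 300, egress_rate_per_h = 3,
              speed_mean_um_h = 5.5, speed_sd_um_h = 2, persistence = 0.7,
              proliferation_rate_per_h = 0.04, disassembly_time_h = Inf)
)

#' Documented phenotype presets
#'
#' Version-pinned parameter sets for the three migration phenotypes
#' observed on the array: `"fast"` (highly migrating, breast-cancer-like;
#' spheroid fully disassembles at 48 h, almost all electrodes covered by
#' 96 h), `"intermediate"` (melanoma-like, more than 60 percent of
#' electrodes covered at 144 h) and `"slow"` (melanoma-like, about 35
#' percent covered at 144 h). The `mitomycin` variant of each preset is
#' identical except that the proliferation rate is forced to zero,
#' mirroring mitomycin C treated reference spheroids.
#'
#' @param name One of `"fast"`, `"intermediate"`, `"slow"`; the suffix
#'   `"_mitomycin"` (e.g. `"slow_mitomycin"`) selects the treated variant.
#' @param mitomycin Logical; alternative way to select the treated variant.
#' @return A [phenotype_params()] object with a descriptive `label`.
#' @examples
#' phenotype_preset("slow")
#' phenotype_preset("fast", mitomycin = TRUE)
#' @export
phenotype_preset <- function(name, mitomycin = FALSE) {
  stopifnot(is.character(name), length(name) == 1)
  if (grepl("_mitomycin$", name)) {
    mitomycin <- TRUE
    name <- sub("_mitomycin$", "", name)
  }
  if (!name %in% names(.preset_table))
    stop(sprintf("unknown preset '%s' (known: %s)", name,
                 paste(names(.preset_table), collapse = ", ")), call. = FALSE)
  p <- .preset_table[[name]]
  phenotype_params(
    spheroid_radius_um = p$spheroid_radius_um,
    egress_rate_per_h = p$egress_rate_per_h,
    speed_mean_um_h = p$speed_mean_um_h,
    speed_sd_um_h = p$speed_sd_um_h,
    persistence = p$persistence,
    proliferation_rate_per_h = p$proliferation_rate_per_h,
    mitomycin = mitomycin,
    disassembly_time_h = p$disassembly_time_h,
    label = paste0(name, if (mitomycin) "_mitomycin" else "")
  )
}

# run body with RNG state isolated and restored
with_seed <- function(seed, expr) {
  if (!is.finite(seed)) stop("'seed' must be a finite integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate cell egress from a centrally placed spheroid
#'
#' Agent-based simulation of cells leaving a spheroid at the well centre.
#' Per time step of `dt_h` hours, `Poisson(egress_rate * dt)` new agents
#' appear on the spheroid rim heading radially outward; every agent then
#' divides with probability `proliferation_rate * dt` (daughter placed
#' 10 um away, random heading), turns by a wrapped-normal angle whose
#' variance is set so the one-hour directional correlation equals
#' `persistence`, and advances by an independently drawn truncated-normal
#' speed. Agents are confined to the well (radius 3.2 mm, 96-well scale)
#' by clamping. Identical `(params, seed)` give identical trajectories.
#'
#' @param params A [phenotype_params()].
#' @param duration_h Simulated time in hours.
#' @param dt_h Time step in hours (default 0.5).
#' @param seed Integer RNG seed (required; the global RNG state is
#'   restored afterwards).
#' @param record_at_h Times (hours) at which agent positions are stored;
#'   defaults to every step. Times are snapped to the simulation grid.
#' @param well_radius_um Confinement radius in um.
#' @return An object of class `egress_sim`: recorded `times_h`, a list
#'   `positions` of n x 2 matrices, and per-time counts `n_agents`,
#'   `n_emitted` (cumulative emissions) and `n_divisions`.
#' @export
simulate_agents <- function(params, duration_h = 144, dt_h = 0.5, seed,
                            record_at_h = NULL, well_radius_um = 3200) {
  stopifnot(inherits(params, "phenotype_params"))
  if (!is.finite(duration_h) || duration_h <= 0)
    stop("'duration_h' must be positive", call. = FALSE)
  if (!is.finite(dt_h) || dt_h <= 0)
    stop("'dt_h' must be positive", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)

  n_steps <- ceiling(duration_h / dt_h)
  times <- seq_len(n_steps) * dt_h
  if (is.null(record_at_h)) record_at_h <- c(0, times)
  rec_idx <- vapply(record_at_h, function(t)
    if (t <= 0) 0L else which.min(abs(times - t)), integer(1))

  sigma_turn <- if (params$persistence > 0)
    sqrt(-2 * dt_h * log(params$persistence)) else NA_real_

  with_seed(seed, {
    x <- numeric(0); y <- numeric(0); heading <- numeric(0)
    emitted <- 0L; divisions <- 0L
    out_pos <- vector("list", length(rec_idx))
    out_n <- integer(length(rec_idx))
    out_emit <- integer(length(rec_idx))
    out_div <- integer(length(rec_idx))
    snap <- function(k) {
      out_pos[[k]] <<- cbind(x = x, y = y)
      out_n[k] <<- length(x)
      out_emit[k] <<- emitted
      out_div[k] <<- divisions
    }
    for (k in which(rec_idx == 0L)) snap(k)

    for (s in seq_len(n_steps)) {
      t_now <- times[s]
      # emission from the rim while the spheroid body persists
      if (t_now <= params$disassembly_time_h && params$egress_rate_per_h > 0) {
        n_new <- stats::rpois(1, params$egress_rate_per_h * dt_h)
        if (n_new > 0) {
          ang <- stats::runif(n_new, 0, 2 * pi)
          x <- c(x, params$spheroid_radius_um * cos(ang))
          y <- c(y, params$spheroid_radius_um * sin(ang))
          heading <- c(heading, ang)   # radially outward
          emitted <- emitted + n_new
        }
      }
      n <- length(x)
      if (n > 0) {
        # divisions: daughter one cell diameter from the mother
        if (params$proliferation_rate_per_h > 0) {
          div <- stats::runif(n) < params$proliferation_rate_per_h * dt_h
          nd <- sum(div)
          if (nd > 0) {
            ang <- stats::runif(nd, 0, 2 * pi)
            x <- c(x, x[div] + 10 * cos(ang))
            y <- c(y, y[div] + 10 * sin(ang))
            heading <- c(heading, stats::runif(nd, 0, 2 * pi))
            divisions <- divisions + nd
            n <- length(x)
          }
        }
        # persistent random walk step
        heading <- if (is.na(sigma_turn))
          stats::runif(n, 0, 2 * pi)
        else heading + stats::rnorm(n, 0, sigma_turn)
        speed <- pmax(0, stats::rnorm(n, params$speed_mean_um_h,
                                      params$speed_sd_um_h))
        x <- x + speed * dt_h * cos(heading)
        y <- y + speed * dt_h * sin(heading)
        # clamp to the well wall
        r <- sqrt(x^2 + y^2)
        over <- r > well_radius_um
        if (any(over)) {
          f <- well_radius_um / r[over]
          x[over] <- x[over] * f
          y[over] <- y[over] * f
        }
      }
      for (k in which(rec_idx == s)) snap(k)
    }

    structure(
      list(params = params, duration_h = duration_h, dt_h = dt_h,
           seed = as.integer(seed), well_radius_um = well_radius_um,
           times_h = record_at_h, positions = out_pos, n_agents = out_n,
           n_emitted = out_emit, n_divisions = out_div),
      class = "egress_sim"
    )
  })
}

#' @export
print.egress_sim <- function(x, ...) {
  cat(sprintf(
    "Spheroid egress simulation: %s, %g h (dt = %g h), seed %d\n",
    if (is.na(x$params$label)) "custom phenotype" else x$params$label,
    x$duration_h, x$dt_h, x$seed))
  cat(sprintf("  final agents %d (emitted %d, divisions %d)\n",
              utils::tail(x$n_agents, 1), utils::tail(x$n_emitted, 1),
              utils::tail(x$n_divisions, 1)))
  invisible(x)
}

#' Per-electrode coverage over time
#'
#' Converts agent positions into a covered-area fraction theta per
#' electrode and recorded time: `theta = min(1, cell_footprint * n_inside /
#' electrode_area)` where `n_inside` counts agents whose centre lies within
#' the electrode disc. Electrodes whose centre lies within
#' `spheroid_radius + electrode_radius` of the well centre sit under the
#' spheroid body and receive `theta = 1` for `t < disassembly_time_h`.
#'
#' @param run An [simulate_agents()] result.
#' @param layout An [electrode_layout()] sharing the coordinate convention
#'   (origin at the well centre, um).
#' @return Matrix of theta values, electrodes (row-major layout order) by
#'   recorded times; `dimnames` carry electrode `row.col` labels and times.
#' @export
coverage_series <- function(run, layout = electrode_layout()) {
  stopifnot(inherits(run, "egress_sim"), inherits(layout, "electrode_layout"))
  el <- layout$electrodes
  r_el <- layout$diameter_um / 2
  area <- pi * r_el^2
  p <- run$params
  under_spheroid <- sqrt(el$x_um^2 + el$y_um^2) <= p$spheroid_radius_um + r_el

  theta <- matrix(0, nrow = nrow(el), ncol = length(run$times_h),
                  dimnames = list(paste(el$row, el$col, sep = "."),
                                  run$times_h))
  for (j in seq_along(run$times_h)) {
    pos <- run$positions[[j]]
    if (!is.null(pos) && nrow(pos) > 0) {
      d2 <- outer(el$x_um, pos[, 1], "-")^2 + outer(el$y_um, pos[, 2], "-")^2
      counts <- rowSums(d2 <= r_el^2)
      theta[, j] <- pmin(1, p$cell_footprint_um2 * counts / area)
    }
    if (run$times_h[j] < p$disassembly_time_h)
      theta[under_spheroid, j] <- 1
  }
  theta
}

# |Z| for many coverages at once: rows = coverages, cols = frequencies
impedance_matrix <- function(freqs_hz, thetas, params) {
  w <- 2i * pi * freqs_hz
  base <- params$R_sol + 1 / (params$Q_cpe * w^params$n_cpe)
  cell <- params$R_cell / (1 + w * params$R_cell * params$C_cell)
  Mod(matrix(base, nrow = length(thetas), ncol = length(freqs_hz),
             byrow = TRUE) + outer(thetas, cell))
}

#' Render a coverage series into an impedance recording
#'
#' Applies the equivalent-circuit forward model to per-electrode coverage
#' and adds multiplicative lognormal measurement noise with relative
#' standard deviation `noise_sd` (mean exactly 1). The cell-free baseline
#' spectrum is rendered at zero coverage, noise-free by default so that
#' the no-cell relative impedance is exactly zero.
#'
#' @param coverage Electrodes x times theta matrix from [coverage_series()].
#' @param layout,acq,circuit Array geometry, acquisition sweep and circuit
#'   parameters used for rendering.
#' @param noise_sd Relative standard deviation of the measurement noise
#'   (default 0.01); 0 renders noise-free spectra.
#' @param seed Integer RNG seed for the noise.
#' @param well_id Well identifier string.
#' @param group Optional phenotype/group label.
#' @param noisy_baseline If `TRUE`, the baseline spectra also receive noise.
#' @return An object of class `mea_recording`: `zmag` array (electrode x
#'   frequency x time), `baseline` matrix (electrode x frequency),
#'   `time_h`, layout/acquisition metadata and the true coverage matrix
#'   in attribute `"coverage_truth"`.
#' @export
render_recording <- function(coverage, layout = electrode_layout(),
                             acq = acquisition_config(),
                             circuit = circuit_params(),
                             noise_sd = 0.01, seed = 1, well_id = "W0",
                             group = NA_character_,
                             noisy_baseline = FALSE) {
  stopifnot(is.matrix(coverage), inherits(layout, "electrode_layout"),
            inherits(acq, "acquisition_config"),
            inherits(circuit, "circuit_params"))
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  n_el <- nrow(coverage)
  if (n_el != nrow(layout$electrodes))
    stop("coverage rows must match the layout electrode count", call. = FALSE)
  freqs <- acq$frequencies_hz
  time_h <- as.numeric(colnames(coverage))
  if (any(is.na(time_h))) time_h <- seq_len(ncol(coverage))

  sdlog <- sqrt(log1p(noise_sd^2))
  noise <- function(n) {
    if (noise_sd == 0) rep(1, n)
    else stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }

  with_seed(seed, {
    zmag <- array(NA_real_, dim = c(n_el, length(freqs), ncol(coverage)),
                  dimnames = list(rownames(coverage), NULL, time_h))
    for (j in seq_len(ncol(coverage))) {
      z <- impedance_matrix(freqs, coverage[, j], circuit)
      zmag[, , j] <- z * noise(length(z))
    }
    baseline <- impedance_matrix(freqs, rep(0, n_el), circuit)
    if (noisy_baseline) baseline <- baseline * noise(length(baseline))
    rownames(baseline) <- rownames(coverage)

    structure(
      list(well_id = well_id, group = group, seed = as.integer(seed),
           layout = layout, acq = acq, time_h = time_h,
           frequencies_hz = freqs, zmag = zmag, baseline = baseline),
      class = "mea_recording",
      coverage_truth = coverage
    )
  })
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf(
    "MEA impedance recording: well %s%s, %d electrodes, %d time points, %d frequencies\n",
    x$well_id, if (is.na(x$group)) "" else paste0(" (", x$group, ")"),
    dim(x$zmag)[1], dim(x$zmag)[3], dim(x$zmag)[2]))
  invisible(x)
}

#' Simulate one well end-to-end
#'
#' Convenience wrapper: simulate agents for one phenotype, compute electrode
#' coverage at the acquisition time points and render the impedance
#' recording. The simulation and noise seeds are derived from `seed`.
#'
#' @inheritParams simulate_agents
#' @inheritParams render_recording
#' @param params A [phenotype_params()] or preset name string.
#' @return An `mea_recording`.
#' @examples
#' rec <- simulate_recording("slow", seed = 1)
#' summarize_well(rec)
#' @export
simulate_recording <- function(params, seed, layout = electrode_layout(),
                               acq = acquisition_config(),
                               circuit = circuit_params(),
                               noise_sd = 0.01, dt_h = 0.5,
                               well_id = NULL) {
  if (is.character(params)) params <- phenotype_preset(params)
  stopifnot(inherits(params, "phenotype_params"))
  run <- simulate_agents(params, duration_h = max(acq$time_points_h),
                         dt_h = dt_h, seed = seed,
                         record_at_h = acq$time_points_h)
  theta <- coverage_series(run, layout)
  if (is.null(well_id)) well_id <- sprintf("W%d", as.integer(seed))
  render_recording(theta, layout = layout, acq = acq, circuit = circuit,
                   noise_sd = noise_sd, seed = as.integer(seed) + 500000L,
                   well_id = well_id, group = params$label)
}
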