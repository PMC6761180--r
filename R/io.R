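#' Write and read impedance recordings as long-format CSV
#'
#' The interchange format is a plain-text table with one row per measured
#' frequency point: `well_id`, `electrode_row`, `electrode_col` (0-based),
#' `time_h` (with `-1` reserved for the cell-free baseline block),
#' `frequency_hz`, `zmag_ohm`. Layout and acquisition metadata travel in
#' `#`-prefixed header lines, so a write/read round trip is lossless.
#' `read_recording()` validates the table — every electrode needs exactly
#' one baseline block, one common frequency grid, and positive `|Z|` —
#' and reports the first offending row on failure.
#'
#' @param rec An `mea_recording` or a list of them (one per well).
#' @param path CSV file path.
#' @return `write_recording()` returns `path` invisibly;
#'   `read_recording()` returns a named list of `mea_recording` objects
#'   keyed by `well_id`.
#' @export
write_recording <- function(rec, path) {
  recs <- if (inherits(rec, "mea_recording")) list(rec) else rec
  stopifnot(all(vapply(recs, inherits, logical(1), "mea_recording")))
  r1 <- recs[[1]]
  lay <- r1$layout; acq <- r1$acq
  hdr <- c(
    "# migrEIS-recording v1",
    sprintf("# n_cols %d", lay$n_cols), sprintf("# n_rows %d", lay$n_rows),
    sprintf("# pitch_um %g", lay$pitch_um),
    sprintf("# diameter_um %g", lay$diameter_um),
    sprintf("# n_wells %d", lay$n_wells),
    sprintf("# f_min_hz %.10g", acq$f_min_hz),
    sprintf("# f_max_hz %.10g", acq$f_max_hz),
    sprintf("# n_points %d", acq$n_points),
    sprintf("# amplitude_mv %g", acq$amplitude_mv),
    vapply(recs, function(r) sprintf("# well %s %s %d", r$well_id,
                                     if (is.na(r$group)) "." else r$group,
                                     r$seed), character(1))
  )
  tabs <- lapply(recs, function(r) {
    el <- r$layout$electrodes
    n_el <- nrow(el); n_f <- length(r$frequencies_hz); n_t <- length(r$time_h)
    data.frame(
      well_id = r$well_id,
      electrode_row = rep(el$row, times = n_f * (n_t + 1)),
      electrode_col = rep(el$col, times = n_f * (n_t + 1)),
      time_h = rep(c(-1, r$time_h), each = n_el * n_f),
      frequency_hz = rep(rep(r$frequencies_hz, each = n_el), times = n_t + 1),
      zmag_ohm = c(as.vector(r$baseline), as.vector(r$zmag))
    )
  })
  tab <- do.call(rbind, tabs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  wells_meta <- list()
  for (h in hdr) {
    parts <- strsplit(sub("^#\\s*", "", h), "\\s+")[[1]]
    if (length(parts) < 2 || parts[1] == "migrEIS-recording") next
    if (parts[1] == "well") {
      wells_meta[[parts[2]]] <- list(
        group = if (length(parts) >= 3 && parts[3] != ".") parts[3]
                else NA_character_,
        seed = if (length(parts) >= 4) as.integer(parts[4]) else NA_integer_)
    } else meta[[parts[1]]] <- as.numeric(parts[2])
  }
  tab <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  need <- c("well_id", "electrode_row", "electrode_col", "time_h",
            "frequency_hz", "zmag_ohm")
  if (!all(need %in% names(tab)))
    stop(sprintf("missing column(s): %s",
                 paste(setdiff(need, names(tab)), collapse = ", ")),
         call. = FALSE)
  bad <- which(!is.finite(tab$zmag_ohm) | tab$zmag_ohm <= 0)
  if (length(bad))
    stop(sprintf("non-positive |Z| at row %d", bad[1]), call. = FALSE)

  pick <- function(key, default) if (is.null(meta[[key]])) default else meta[[key]]
  layout <- electrode_layout(
    n_cols = pick("n_cols", max(tab$electrode_col) + 1),
    n_rows = pick("n_rows", max(tab$electrode_row) + 1),
    pitch_um = pick("pitch_um", 300), diameter_um = pick("diameter_um", 100),
    n_wells = pick("n_wells", 9))
  n_el <- layout$n_cols * layout$n_rows

  out <- list()
  for (w in unique(tab$well_id)) {
    wt <- tab[tab$well_id == w, ]
    freqs <- sort(unique(wt$frequency_hz))
    times <- sort(unique(wt$time_h[wt$time_h >= 0]))
    eidx <- wt$electrode_row * layout$n_cols + wt$electrode_col + 1L
    if (any(eidx < 1 | eidx > n_el))
      stop(sprintf("electrode index out of range in well %s at row %d",
                   w, which(tab$well_id == w)[which(eidx < 1 | eidx > n_el)[1]]),
           call. = FALSE)
    # baseline: exactly one block per electrode on the full grid
    bl <- wt[wt$time_h == -1, ]
    if (nrow(bl) != n_el * length(freqs)) {
      have <- table(factor(bl$electrode_row * layout$n_cols + bl$electrode_col,
                           levels = 0:(n_el - 1)))
      miss <- which(have != length(freqs))[1]
      stop(sprintf("well %s: electrode (%d,%d) lacks a complete baseline block",
                   w, (miss - 1) %/% layout$n_cols, (miss - 1) %% layout$n_cols),
           call. = FALSE)
    }
    # consistent frequency grid in every (electrode, time) block
    cnt <- table(wt$time_h, wt$frequency_hz)
    if (any(cnt != n_el))
      stop(sprintf("well %s: inconsistent frequency grid", w), call. = FALSE)

    fidx <- match(wt$frequency_hz, freqs)
    baseline <- matrix(NA_real_, n_el, length(freqs))
    zmag <- array(NA_real_, c(n_el, length(freqs), length(times)))
    isb <- wt$time_h == -1
    baseline[cbind(eidx[isb], fidx[isb])] <- wt$zmag_ohm[isb]
    tidx <- match(wt$time_h, times)
    zmag[cbind(eidx[!isb], fidx[!isb], tidx[!isb])] <- wt$zmag_ohm[!isb]
    el <- layout$electrodes
    rn <- paste(el$row, el$col, sep = ".")
    rownames(baseline) <- rn
    dimnames(zmag) <- list(rn, NULL, times)

    wm <- wells_meta[[as.character(w)]]
    acq <- acquisition_config(
      f_min_hz = pick("f_min_hz", min(freqs)),
      f_max_hz = pick("f_max_hz", max(freqs)),
      n_points = pick("n_points", length(freqs)),
      amplitude_mv = pick("amplitude_mv", 10),
      time_points_h = times)
    out[[as.character(w)]] <- structure(
      list(well_id = as.character(w),
           group = if (is.null(wm)) NA_character_ else wm$group,
           seed = if (is.null(wm)) NA_integer_ else wm$seed,
           layout = layout, acq = acq, time_h = times,
           frequencies_hz = freqs, zmag = zmag, baseline = baseline),
      class = "mea_recording")
  }
  out
}

#' Simulate a panel of wells for several phenotype groups
#'
#' Generates `n_per_group` single-well recordings for each requested
#' preset, with per-well seeds derived deterministically from `seed`.
#'
#' @param groups Character vector of preset names (see
#'   [phenotype_preset()]), e.g. `c("fast", "fast_mitomycin", "slow",
#'   "slow_mitomycin")`.
#' @param n_per_group Wells per group.
#' @param seed Base integer seed.
#' @param ... Passed to [simulate_recording()].
#' @return Named list of `mea_recording` objects.
#' @export
simulate_panel <- function(groups, n_per_group = 6, seed = 1, ...) {
  recs <- list()
  for (gi in seq_along(groups)) {
    for (i in seq_len(n_per_group)) {
      s <- as.integer(seed) + 1000L * gi + i
      id <- sprintf("%s_%02d", groups[gi], i)
      recs[[id]] <- simulate_recording(phenotype_preset(groups[gi]),
                                       seed = s, well_id = id, ...)
    }
  }
  recs
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis of a set of well recordings: per-well
#' summaries (covered electrodes and median maximum relative impedance
#' over time), quadrant thresholds (calibrated from reference wells when
#' reference truth is supplied, otherwise the documented defaults),
#' endpoint quadrant assignment, and — when at least `k` reference wells
#' are available — the automatic classifier (12 features, PCA to `dims`,
#' fuzzy c-means with `k` clusters) applied to every well. Deterministic
#' given the recordings and `seed`.
#'
#' @param recordings A list of `mea_recording` objects (or a path readable
#'   by [read_recording()]).
#' @param threshold_pct Covered-electrode threshold (%).
#' @param time_points_h The six feature time points.
#' @param references Optional data frame with columns `group`,
#'   `migration` (`"low"`/`"high"`), `proliferation`
#'   (`"suppressed"`/`"proliferating"`); wells whose `group` matches are
#'   used for threshold calibration and model fitting.
#' @param k,dims,m Classifier shape parameters.
#' @param seed Integer seed for the clustering restarts.
#' @param out_dir Optional directory; when given, the summary and
#'   classification tables are written as CSV and a run log as YAML.
#' @return A list with `summary` (long table over wells and times),
#'   `thresholds`, `quadrants` (per-well endpoint table), `model` (or
#'   `NULL`) and `classification` (per-well report with memberships).
#' @export
run_pipeline <- function(recordings, threshold_pct = 10,
                         time_points_h = seq(24, 144, by = 24),
                         references = NULL, k = 4, dims = 3, m = 2,
                         seed = 1, out_dir = NULL) {
  if (is.character(recordings)) recordings <- read_recording(recordings)
  if (inherits(recordings, "mea_recording")) recordings <- list(recordings)
  stopifnot(length(recordings) >= 1)

  summaries <- lapply(recordings, summarize_well, threshold_pct = threshold_pct)
  summary_tab <- do.call(rbind, summaries)
  rownames(summary_tab) <- NULL

  groups <- vapply(summaries, function(s) s$group[1], character(1))
  is_ref <- if (is.null(references)) rep(FALSE, length(summaries))
            else groups %in% references$group

  thr <- if (any(is_ref)) {
    ref_groups <- groups[is_ref]
    calibrate_thresholds(
      summaries[is_ref],
      migration = references$migration[match(ref_groups, references$group)],
      proliferation = references$proliferation[match(ref_groups,
                                                     references$group)])
  } else quadrant_thresholds()

  endpoint <- function(s) s[which.max(s$time_h), ]
  quad <- do.call(rbind, lapply(summaries, function(s) {
    e <- endpoint(s)
    data.frame(well_id = e$well_id, group = e$group,
               covered_count = e$covered_count,
               median_max_rel_imp_pct = e$median_max_rel_imp_pct,
               quadrant = assign_quadrant(e$covered_count,
                                          e$median_max_rel_imp_pct, thr))
  }))
  rownames(quad) <- NULL

  feats <- lapply(summaries, build_features, time_points_h = time_points_h)
  model <- NULL
  classification <- NULL
  if (sum(is_ref) >= k) {
    model <- fit_reference_model(feats[is_ref], groups = groups[is_ref],
                                 k = k, dims = dims, m = m, seed = seed)
    cls <- lapply(feats, classify_well, model = model)
    memb <- do.call(rbind, lapply(cls, `[[`, "memberships"))
    colnames(memb) <- paste0("membership_", seq_len(k))
    classification <- data.frame(
      well_id = vapply(summaries, function(s) s$well_id[1], character(1)),
      group = groups, is_reference = is_ref, memb,
      hard_cluster = vapply(cls, `[[`, numeric(1), "hard_cluster"),
      quadrant_at_endpoint = quad$quadrant)
    rownames(classification) <- NULL
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary_tab, file.path(out_dir, "well_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(quad, file.path(out_dir, "quadrants.csv"),
                     row.names = FALSE)
    if (!is.null(classification))
      utils::write.csv(classification,
                       file.path(out_dir, "classification.csv"),
                       row.names = FALSE)
    yaml::write_yaml(
      list(package = "migrEIS",
           version = as.character(utils::packageVersion("migrEIS")),
           seed = seed, threshold_pct = threshold_pct,
           coverage_cut = thr$coverage_cut, impedance_cut = thr$impedance_cut,
           time_points_h = time_points_h, n_wells = length(recordings),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      file.path(out_dir, "run_log.yaml"))
  }

  list(summary = summary_tab, thresholds = thr, quadrants = quad,
       model = model, classification = classification)
}
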