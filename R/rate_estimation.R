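#' Incubation time series of delta13C-DIC
#'
#' Container for one tracer-incubation time series: water from one depth and
#' treatment, amended with 13CH4, destructively sampled at fixed times, with
#' delta13C of the DIC pool measured at each time. Methane oxidation shows up
#' as 13C-DIC production.
#'
#' @param time_h sampling times in hours; strictly increasing, starting at 0.
#' @param delta_dic per-mil delta13C-DIC at each time.
#' @param depth_m sampling depth (m).
#' @param treatment treatment label, conventionally one of `"dark"`,
#'   `"light"`, `"oxygen"`, `"nitrate"`, `"nitrite"`, `"iron"`, `"manganese"`.
#' @param ambient_dic_mM ambient DIC concentration (mM); default 7.4.
#' @param added_ch4_uM added 13CH4 (uM); default 50.
#' @param replicate replicate identifier.
#' @return An object of class `incubation_series`.
#' @examples
#' incubation_series(c(0, 6, 12, 24, 48), c(-10, -9.5, -9, -8.9, -8.9),
#'                   depth_m = 16, treatment = "dark")
#' @export
incubation_series <- function(time_h, delta_dic, depth_m = NA_real_,
                              treatment = "dark", ambient_dic_mM = 7.4,
                              added_ch4_uM = 50, replicate = 1L) {
  stopifnot(length(time_h) == length(delta_dic))
  if (length(time_h) < 2L || any(diff(time_h) <= 0))
    stop("time_h must be strictly increasing with at least 2 points", call. = FALSE)
  if (time_h[1] != 0)
    stop("missing baseline: the series must start at t = 0 h", call. = FALSE)
  if (ambient_dic_mM <= 0) stop("ambient_dic_mM must be positive", call. = FALSE)
  check_delta(delta_dic)
  structure(list(time_h = as.numeric(time_h), delta_dic = as.numeric(delta_dic),
                 depth_m = depth_m, treatment = treatment,
                 ambient_dic_mM = ambient_dic_mM, added_ch4_uM = added_ch4_uM,
                 replicate = replicate),
            class = "incubation_series")
}

#' @export
print.incubation_series <- function(x, ...) {
  cat(sprintf("<incubation_series> %s @ %.1f m (rep %s), DIC %.1f mM, +%.0f uM 13CH4\n",
              x$treatment, x$depth_m, x$replicate, x$ambient_dic_mM, x$added_ch4_uM))
  print(data.frame(time_h = x$time_h, delta13c_dic_permil = x$delta_dic))
  invisible(x)
}

#' 13C-DIC concentration from delta13C-DIC
#'
#' Converts a per-mil delta13C of the DIC pool into the absolute concentration
#' of 13C-bearing DIC, `ambient_dic * F(delta)` with `F` the 13C atom
#' fraction, in micromolar.
#'
#' @param delta_dic per-mil delta13C-DIC (vectorised).
#' @param ambient_dic_mM total DIC concentration (mM).
#' @param standard an [isotope_standard()].
#' @return 13C-DIC concentration in micromolar.
#' @examples
#' dic13_concentration(0, 7.4)   # ~81.8 uM at the VPDB ratio
#' @export
dic13_concentration <- function(delta_dic, ambient_dic_mM = 7.4,
                                standard = vpdb()) {
  if (ambient_dic_mM < 0) stop("ambient_dic_mM must be non-negative", call. = FALSE)
  ambient_dic_mM * 1000 * delta_to_atom_fraction(delta_dic, standard)
}

#' Excess 13C-DIC relative to the t = 0 baseline
#'
#' Per-timepoint excess 13C-DIC (uM) over the series' own baseline; the
#' quantity whose initial slope is the methane oxidation rate.
#'
#' @param series an [incubation_series()].
#' @param standard an [isotope_standard()].
#' @return A data.frame with `time_h` and `excess_13c_uM` (zero at t = 0).
#' @export
excess_timeseries <- function(series, standard = vpdb()) {
  stopifnot(inherits(series, "incubation_series"))
  conc <- dic13_concentration(series$delta_dic, series$ambient_dic_mM, standard)
  data.frame(time_h = series$time_h, excess_13c_uM = conc - conc[1])
}

#' Estimate a potential methane oxidation rate from a tracer incubation
#'
#' Ordinary least-squares regression of excess 13C-DIC against time over the
#' initial linear window (default 0-12 h), converted to uM per day. Maximum
#' potential rates are conventionally taken from this initial segment because
#' oxidation commonly slows or ceases after 12-24 h as substrate is depleted;
#' a plateau is flagged when the post-window slope falls below
#' `plateau_fraction` of the in-window slope.
#'
#' @param series an [incubation_series()].
#' @param window numeric length-2 fit window in hours; default `c(0, 12)`.
#' @param plateau_fraction post-window slope fraction below which a plateau is
#'   declared; default 0.25.
#' @param standard an [isotope_standard()].
#' @return An object of class `rate_estimate`: a list with `rate_uM_d`,
#'   `stderr_uM_d`, `fit_window`, `n_points`, `r_squared`,
#'   `total_turnover_uM` (excess at the last timepoint), `plateau_detected`,
#'   plus the series metadata (`depth_m`, `treatment`, `replicate`).
#' @examples
#' s <- generate_incubation(incubation_scenario(true_rate_uM_d = 2.6,
#'                                              noise_sd_permil = 0))[[1]]
#' fit_rate(s)
#' @export
fit_rate <- function(series, window = c(0, 12), plateau_fraction = 0.25,
                     standard = vpdb()) {
  stopifnot(inherits(series, "incubation_series"), length(window) == 2L)
  ex <- excess_timeseries(series, standard)
  inw <- ex$time_h >= window[1] & ex$time_h <= window[2]
  if (sum(inw) < 2L)
    stop("insufficient data: need at least 2 timepoints inside the fit window",
         call. = FALSE)
  fit <- stats::lm(excess_13c_uM ~ time_h, data = ex[inw, ])
  sm <- suppressWarnings(summary(fit))   # noise-free series fit "perfectly"
  slope_h <- unname(stats::coef(fit)[2L])           # uM per hour
  se_h <- sm$coefficients[2L, 2L]
  # post-window slope for plateau detection (needs >= 2 points from window end on)
  post <- ex$time_h >= window[2]
  plateau <- NA
  if (sum(post) >= 2L) {
    post_slope <- unname(stats::coef(stats::lm(excess_13c_uM ~ time_h,
                                               data = ex[post, ]))[2L])
    plateau <- isTRUE(post_slope < plateau_fraction * slope_h)
  }
  structure(list(
    rate_uM_d = slope_h * 24,
    stderr_uM_d = se_h * 24,
    fit_window = window,
    n_points = sum(inw),
    r_squared = sm$r.squared,
    total_turnover_uM = ex$excess_13c_uM[nrow(ex)],
    plateau_detected = plateau,
    depth_m = series$depth_m,
    treatment = series$treatment,
    replicate = series$replicate
  ), class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %s @ %.1f m: %.2f +/- %.2f uM d-1 (%g-%g h, n=%d, R2=%.3f)\n",
              x$treatment, x$depth_m, x$rate_uM_d, x$stderr_uM_d,
              x$fit_window[1], x$fit_window[2], x$n_points, x$r_squared))
  cat(sprintf("  total turnover %.2f uM; plateau detected: %s\n",
              x$total_turnover_uM, format(x$plateau_detected)))
  invisible(x)
}

#' Tabulate rate estimates across treatments and depths
#'
#' Collects a list of [fit_rate()] results into a treatment-effect table keyed
#' by depth and treatment, the machine-readable analogue of a rate-comparison
#' figure panel.
#'
#' @param estimates a list of `rate_estimate` objects (length >= 1).
#' @return A data.frame with one row per estimate: `depth_m`, `treatment`,
#'   `replicate`, `rate_uM_d`, `stderr_uM_d`, `total_turnover_uM`,
#'   `r_squared`, `plateau_detected`, ordered by depth then treatment.
#' @export
compare_treatments <- function(estimates) {
  if (length(estimates) < 1L)
    stop("need at least one rate estimate", call. = FALSE)
  stopifnot(all(vapply(estimates, inherits, logical(1), "rate_estimate")))
  out <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(depth_m = e$depth_m, treatment = e$treatment,
               replicate = e$replicate, rate_uM_d = e$rate_uM_d,
               stderr_uM_d = e$stderr_uM_d,
               total_turnover_uM = e$total_turnover_uM,
               r_squared = e$r_squared,
               plateau_detected = e$plateau_detected)
  }))
  out[order(out$depth_m, out$treatment, out$replicate), , drop = FALSE]
}

#' Read and write incubation tables
#'
#' Incubation time series travel as comma-separated UTF-8 text with a header
#' and columns `depth_m`, `treatment`, `time_h`, `delta13c_dic_permil`,
#' `ambient_dic_mM`, `replicate`. `read_incubations()` returns a list of
#' [incubation_series()], one per (depth, treatment, replicate) group;
#' `write_incubations()` writes such a list back.
#'
#' @param path file path.
#' @param series_list a list of `incubation_series`.
#' @return `read_incubations()` a named list of `incubation_series`;
#'   `write_incubations()` the path, invisibly.
#' @export
read_incubations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("depth_m", "treatment", "time_h", "delta13c_dic_permil",
              "ambient_dic_mM", "replicate")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("incubation table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  key <- interaction(df$depth_m, df$treatment, df$replicate, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$time_h), ]
    incubation_series(g$time_h, g$delta13c_dic_permil,
                      depth_m = g$depth_m[1], treatment = g$treatment[1],
                      ambient_dic_mM = g$ambient_dic_mM[1],
                      replicate = g$replicate[1])
  })
  out
}

#' @rdname read_incubations
#' @export
write_incubations <- function(series_list, path) {
  df <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(depth_m = s$depth_m, treatment = s$treatment,
               time_h = s$time_h, delta13c_dic_permil = s$delta_dic,
               ambient_dic_mM = s$ambient_dic_mM, replicate = s$replicate)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
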