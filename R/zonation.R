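#' Locate the oxycline of an oxygen profile
#'
#' The oxycline is taken as the midpoint of the depth window in which the O2
#' profile is steepest (via [steepest_gradient()]). If O2 increases with depth
#' over that window the profile orientation is suspicious and a warning is
#' issued.
#'
#' @param profile data.frame with `depth_m` and the oxygen column.
#' @param o2_col name of the oxygen concentration column (uM); default
#'   `"o2_uM"`.
#' @param window_points window width for the gradient search; default 3.
#' @return Oxycline depth (m), with the gradient attached as attribute
#'   `"gradient"`.
#' @export
find_oxycline <- function(profile, o2_col = "o2_uM", window_points = 3) {
  if (!o2_col %in% names(profile))
    stop("missing analyte: profile has no '", o2_col, "' column", call. = FALSE)
  g <- steepest_gradient(profile, o2_col, window_points)
  if (g$slope_uM_m > 0)
    warning("O2 increases with depth in the steepest window; check profile orientation",
            call. = FALSE)
  structure(mean(g$depth_window), gradient = g)
}

#' Depth of anoxia onset
#'
#' Shallowest depth at which oxygen drops below `threshold_nM` and stays below
#' it at all deeper sampled depths, with linear interpolation between the
#' bracketing points of the threshold crossing. Returns `NA` (a no-anoxia
#' result, not an error) when the profile never remains below the threshold.
#'
#' @inheritParams find_oxycline
#' @param threshold_nM oxygen threshold in nanomolar; default 20, a typical
#'   trace-optode detection limit.
#' @return Onset depth in m, or `NA_real_` when the column never goes anoxic.
#' @export
find_anoxia_onset <- function(profile, threshold_nM = 20, o2_col = "o2_uM") {
  if (!o2_col %in% names(profile))
    stop("missing analyte: profile has no '", o2_col, "' column", call. = FALSE)
  df <- profile[is.finite(profile$depth_m) & is.finite(profile[[o2_col]]),
                c("depth_m", o2_col)]
  df <- df[order(df$depth_m), ]
  o2_nM <- df[[o2_col]] * 1000
  below <- o2_nM < threshold_nM
  # last index from which all deeper values stay below threshold
  n <- length(below)
  if (!below[n]) return(NA_real_)
  i <- n
  while (i > 1L && below[i - 1L]) i <- i - 1L
  if (i == 1L) return(df$depth_m[1L])          # anoxic from the top
  # linear interpolation of the threshold crossing between i-1 and i
  z1 <- df$depth_m[i - 1L]; z2 <- df$depth_m[i]
  c1 <- o2_nM[i - 1L]; c2 <- o2_nM[i]
  if (c1 == c2) return(z2)
  z1 + (threshold_nM - c1) * (z2 - z1) / (c2 - c1)
}

#' Classify methane zones from concentration and delta13C profiles
#'
#' Splits the column into the four canonical methane zones of a stratified
#' lake, from deep to shallow: a methanogenic source zone, a non-reactive
#' diffusion zone (concentration decreasing upward, delta13C-CH4 invariant —
#' methanotrophs would leave the residual pool 13C-enriched, so constant
#' delta13C rules out active oxidation), an oxidation zone (concentration
#' decreasing upward and delta13C increasing upward by more than
#' `delta_threshold` per assessment window), and an oxic zone above.
#'
#' The enrichment/invariance criteria are assessed over a depth window of
#' `window_m` metres (default 1 m): both series are first smoothed with a
#' centred running mean of that width (shrinking at the profile ends) and the
#' criteria compare each depth with the profile `window_m` deeper, so the
#' classification does not depend on the sampling resolution and tolerates
#' point noise at the isotope method reproducibility.
#'
#' @param profile data.frame with `depth_m`, the methane column and the
#'   delta13C column.
#' @param ch4_col,delta_col column names; defaults `"ch4_uM"`,
#'   `"d13c_ch4_permil"`.
#' @param delta_threshold per-mil enrichment threshold per assessment window;
#'   default 2 (above typical delta13C-CH4 method reproducibility of ~1.4).
#' @param window_m assessment window in metres; default 1.
#' @return A data.frame with columns `zone` (one of `oxic`, `oxidation`,
#'   `diffusion`, `methanogenic-source`), `top_m`, `bottom_m`, ordered from
#'   the surface down. When no structure is detectable a single row
#'   `indeterminate` spanning the profile is returned, with attribute
#'   `"flag" = "indeterminate"`.
#' @export
classify_ch4_zones <- function(profile, ch4_col = "ch4_uM",
                               delta_col = "d13c_ch4_permil",
                               delta_threshold = 2, window_m = 1) {
  for (col in c(ch4_col, delta_col))
    if (!col %in% names(profile))
      stop("missing analyte: profile has no '", col, "' column", call. = FALSE)
  df <- profile[is.finite(profile$depth_m) & is.finite(profile[[ch4_col]]) &
                  is.finite(profile[[delta_col]]), ]
  df <- df[order(df$depth_m), ]
  z <- df$depth_m
  n <- length(z)
  if (n < 3L) stop("insufficient data: need at least 3 depths", call. = FALSE)

  # running-mean smoothing over the assessment window, shrinking at edges
  run_mean <- function(x) {
    half <- window_m / 2
    vapply(seq_along(z), function(i)
      mean(x[z >= z[i] - half & z <= z[i] + half]), numeric(1))
  }
  ch4_s <- run_mean(df[[ch4_col]])
  d13_s <- run_mean(df[[delta_col]])

  # per-point assessment against the profile window_m deeper (interpolated)
  deeper_c <- stats::approx(z, ch4_s, xout = z + window_m, rule = 2)$y
  deeper_d <- stats::approx(z, d13_s, xout = z + window_m, rule = 2)$y
  conc_dec_up <- ch4_s < deeper_c
  enrich_up <- (d13_s - deeper_d) > delta_threshold
  invariant <- abs(d13_s - deeper_d) <= delta_threshold

  is_ox <- conc_dec_up & enrich_up
  is_diff <- conc_dec_up & invariant

  if (!any(is_ox) && !any(conc_dec_up)) {
    out <- data.frame(zone = "indeterminate", top_m = z[1], bottom_m = z[n])
    attr(out, "flag") <- "indeterminate"
    return(out)
  }

  longest_run <- function(mask, prefer_deep = TRUE) {
    r <- rle(mask)
    if (!any(r$values)) return(NULL)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    lens <- r$lengths[runs]
    best <- runs[lens == max(lens)]
    best <- if (prefer_deep) best[length(best)] else best[1L]
    c(starts[best], ends[best])
  }

  zones <- list()
  ox <- longest_run(is_ox)
  if (!is.null(ox)) {
    ox_top <- z[ox[1]]
    ox_bot <- z[ox[2]]
    if (ox_top > z[1])
      zones[[length(zones) + 1L]] <- c("oxic", z[1], ox_top)
    zones[[length(zones) + 1L]] <- c("oxidation", ox_top, ox_bot)
    # diffusion run below the oxidation zone
    below <- seq_len(n) > ox[2]
    dif <- longest_run(is_diff & below, prefer_deep = FALSE)
    if (!is.null(dif)) {
      dif_bot <- z[dif[2]]
      zones[[length(zones) + 1L]] <- c("diffusion", ox_bot, dif_bot)
      if (dif_bot < z[n])
        zones[[length(zones) + 1L]] <- c("methanogenic-source", dif_bot, z[n])
    } else if (ox_bot < z[n]) {
      zones[[length(zones) + 1L]] <- c("methanogenic-source", ox_bot, z[n])
    }
  } else {
    # concentration attenuates but no enrichment anywhere: pure diffusion
    dif <- longest_run(is_diff, prefer_deep = FALSE)
    top <- if (!is.null(dif)) z[dif[1]] else z[1]
    bot <- if (!is.null(dif)) z[dif[2]] else z[n]
    if (top > z[1]) zones[[length(zones) + 1L]] <- c("oxic", z[1], top)
    zones[[length(zones) + 1L]] <- c("diffusion", top, bot)
    if (bot < z[n]) zones[[length(zones) + 1L]] <- c("methanogenic-source", bot, z[n])
  }
  out <- do.call(rbind, lapply(zones, function(v)
    data.frame(zone = v[1], top_m = as.numeric(v[2]), bottom_m = as.numeric(v[3]))))
  out
}

#' Full redox and methane zonation of a water-column profile
#'
#' Combines [find_oxycline()], [find_anoxia_onset()] and
#' [classify_ch4_zones()] into a single zone map: redox zones (`oxic` above
#' the oxycline window, `oxycline`, `suboxic` down to the anoxia onset,
#' `anoxic` below) and methane zones.
#'
#' @inheritParams classify_ch4_zones
#' @inheritParams find_anoxia_onset
#' @param o2_col oxygen column name.
#' @return An object of class `zone_map`: list with `oxycline_depth`,
#'   `anoxia_onset`, `zones` (redox zones data.frame) and `ch4_zones`.
#' @export
zone_map <- function(profile, o2_col = "o2_uM", ch4_col = "ch4_uM",
                     delta_col = "d13c_ch4_permil", threshold_nM = 20,
                     delta_threshold = 2, window_m = 1) {
  oxy <- find_oxycline(profile, o2_col)
  g <- attr(oxy, "gradient")
  onset <- find_anoxia_onset(profile, threshold_nM, o2_col)
  zmin <- min(profile$depth_m, na.rm = TRUE)
  zmax <- max(profile$depth_m, na.rm = TRUE)
  bottom_suboxic <- if (is.na(onset)) zmax else onset
  zones <- data.frame(
    zone = c("oxic", "oxycline", "suboxic", if (!is.na(onset)) "anoxic"),
    top_m = c(zmin, g$depth_window[1], g$depth_window[2],
              if (!is.na(onset)) onset),
    bottom_m = c(g$depth_window[1], g$depth_window[2], bottom_suboxic,
                 if (!is.na(onset)) zmax))
  structure(list(oxycline_depth = as.numeric(oxy), anoxia_onset = onset,
                 zones = zones,
                 ch4_zones = classify_ch4_zones(profile, ch4_col, delta_col,
                                                delta_threshold, window_m)),
            class = "zone_map")
}

#' @export
print.zone_map <- function(x, ...) {
  cat(sprintf("<zone_map> oxycline %.2f m, anoxia onset %s m\n",
              x$oxycline_depth,
              if (is.na(x$anoxia_onset)) "none" else sprintf("%.2f", x$anoxia_onset)))
  cat("redox zones:\n"); print(x$zones, row.names = FALSE)
  cat("methane zones:\n"); print(x$ch4_zones, row.names = FALSE)
  invisible(x)
}
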