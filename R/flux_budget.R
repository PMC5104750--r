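# 1 cm2 s-1 = 8.64 m2 d-1
.KZ_CM2S_TO_M2D <- 8.64

#' Steepest-gradient window of a profile analyte
#'
#' Scans all contiguous depth windows of `window_points` points, fits an
#' ordinary least-squares line of concentration against depth in each, and
#' returns the window with the largest absolute slope (ties broken toward the
#' shallower window). This is the conventional way of picking the depth
#' interval over which a diffusive flux is computed.
#'
#' @param profile a data.frame with a `depth_m` column (m, positive downward)
#'   and the analyte column.
#' @param analyte name of the concentration column (uM).
#' @param window_points number of consecutive points per candidate window
#'   (default 3).
#' @return An object of class `profile_gradient`: list with `analyte`,
#'   `slope_uM_m`, `stderr_uM_m`, `depth_window` (top, bottom in m),
#'   `n_points`, `r_squared`.
#' @export
steepest_gradient <- function(profile, analyte, window_points = 3) {
  stopifnot(is.data.frame(profile), "depth_m" %in% names(profile))
  if (!analyte %in% names(profile))
    stop("missing analyte column: ", analyte, call. = FALSE)
  ok <- is.finite(profile$depth_m) & is.finite(profile[[analyte]])
  df <- profile[ok, c("depth_m", analyte)]
  df <- df[order(df$depth_m), ]
  n <- nrow(df)
  if (n < window_points)
    stop("insufficient data: need at least ", window_points,
         " finite values for ", analyte, call. = FALSE)
  best <- NULL
  for (i in seq_len(n - window_points + 1L)) {
    idx <- i:(i + window_points - 1L)
    z <- df$depth_m[idx]
    c_ <- df[[analyte]][idx]
    fit <- stats::lm(c_ ~ z)
    slope <- unname(stats::coef(fit)[2L])
    if (is.null(best) || abs(slope) > abs(best$slope) + 1e-15) {
      sm <- suppressWarnings(summary(fit))   # flat windows fit "perfectly"
      best <- list(slope = slope,
                   stderr = sm$coefficients[2L, 2L],
                   window = range(z), n = window_points,
                   r2 = sm$r.squared)
    }
  }
  structure(list(analyte = analyte, slope_uM_m = best$slope,
                 stderr_uM_m = best$stderr,
                 depth_window = best$window, n_points = best$n,
                 r_squared = best$r2),
            class = "profile_gradient")
}

#' @export
print.profile_gradient <- function(x, ...) {
  cat(sprintf("<profile_gradient> %s: %.3f +/- %.3f uM m-1 over %.1f-%.1f m (n=%d, R2=%.3f)\n",
              x$analyte, x$slope_uM_m, x$stderr_uM_m,
              x$depth_window[1], x$depth_window[2], x$n_points, x$r_squared))
  invisible(x)
}

#' Turbulent diffusive flux from a concentration gradient
#'
#' Fick's first law with a turbulent vertical dispersion coefficient,
#' \eqn{J = -K_z\, \partial C/\partial z}. Depth is positive downward and so
#' are fluxes, so a concentration increasing with depth yields a negative
#' (upward) flux. `Kz` is given in cm2 s-1 (1 cm2 s-1 = 8.64 m2 d-1) and the
#' gradient in uM m-1 (= mmol m-4); the flux comes out in mmol m-2 d-1.
#'
#' @param gradient a [steepest_gradient()] result, or a plain list with
#'   `slope_uM_m` and `stderr_uM_m`.
#' @param kz_cm2_s vertical turbulent dispersion coefficient (cm2 s-1);
#'   default 4e-3, a low-mixing value appropriate for a small wind-sheltered
#'   stratified lake.
#' @return A list with `flux_mmol_m2_d`, `stderr_mmol_m2_d`, `analyte`,
#'   `kz_cm2_s`, `depth_window`.
#' @export
diffusive_flux <- function(gradient, kz_cm2_s = 4e-3) {
  stopifnot(kz_cm2_s > 0)
  kz_m2_d <- kz_cm2_s * .KZ_CM2S_TO_M2D
  list(flux_mmol_m2_d = -kz_m2_d * gradient$slope_uM_m,
       stderr_mmol_m2_d = kz_m2_d * gradient$stderr_uM_m,
       analyte = gradient$analyte %||% NA_character_,
       kz_cm2_s = kz_cm2_s,
       depth_window = gradient$depth_window %||% c(NA_real_, NA_real_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Electron accepting/donating capacities of redox species
#'
#' The default half-reaction table used to convert molar fluxes into electron
#' equivalents. Capacities are moles of electrons transferred per mole of
#' species under the stated half-reaction; every report names the
#' half-reaction used, and the table can be overridden row-wise. Nitrate
#' carries two entries: reduction to N2 (5 e-) is the budget default, while
#' reduction to nitrite (2 e-) is the conventional choice when quoting
#' oxidant:CH4 stoichiometric ratios.
#'
#' @param overrides optional data.frame with columns `species`,
#'   `half_reaction`, `electrons`, `role` (`"acceptor"` or `"donor"`) and
#'   optionally `default`; rows replace (by species + half_reaction) or extend
#'   the built-in table.
#' @return A data.frame with columns `species`, `half_reaction`, `electrons`,
#'   `role`, `default`.
#' @examples
#' electron_capacity_table()
#' @export
electron_capacity_table <- function(overrides = NULL) {
  tab <- data.frame(
    species = c("O2", "NO3", "NO3", "NO2", "SO4", "CH4", "NH4", "Fe2", "Mn2", "H2S"),
    half_reaction = c("O2 -> H2O", "NO3 -> N2", "NO3 -> NO2", "NO2 -> N2",
                      "SO4 -> H2S", "CH4 -> CO2", "NH4 -> NO3",
                      "Fe2+ -> Fe(III)", "Mn2+ -> Mn(IV)", "H2S -> SO4"),
    electrons = c(4L, 5L, 2L, 3L, 8L, 8L, 8L, 1L, 2L, 8L),
    role = c("acceptor", "acceptor", "acceptor", "acceptor", "acceptor",
             "donor", "donor", "donor", "donor", "donor"),
    default = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    stopifnot(all(c("species", "half_reaction", "electrons", "role") %in% names(overrides)))
    if (any(overrides$electrons < 1))
      stop("electron capacities must be >= 1", call. = FALSE)
    if (!all(overrides$role %in% c("acceptor", "donor")))
      stop("role must be 'acceptor' or 'donor'", call. = FALSE)
    if (is.null(overrides$default)) overrides$default <- TRUE
    key <- paste(tab$species, tab$half_reaction)
    okey <- paste(overrides$species, overrides$half_reaction)
    tab <- tab[!key %in% okey, ]
    # an override made default displaces the species' previous default
    for (sp in unique(overrides$species[overrides$default]))
      tab$default[tab$species == sp] <- FALSE
    tab <- rbind(tab, overrides[, names(tab)])
  }
  dup <- tab$species[tab$default][duplicated(tab$species[tab$default])]
  if (length(dup))
    stop("species with more than one default half-reaction: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  tab
}

capacity_entry <- function(table, species, half_reaction = NULL) {
  rows <- table[table$species == species, , drop = FALSE]
  if (!nrow(rows))
    stop("missing electron capacity for species: ", species, call. = FALSE)
  if (!is.null(half_reaction)) {
    rows <- rows[rows$half_reaction == half_reaction, , drop = FALSE]
    if (!nrow(rows))
      stop("no entry for ", species, " with half-reaction '", half_reaction, "'",
           call. = FALSE)
  } else {
    rows <- rows[rows$default, , drop = FALSE]
  }
  rows[1L, ]
}

#' Convert a molar flux to an electron-equivalent flux
#'
#' Multiplies a species flux (mmol m-2 d-1) by its electron accepting or
#' donating capacity to yield mmol e- m-2 d-1, recording the half-reaction
#' used.
#'
#' @param flux a [diffusive_flux()] result or a number (mmol m-2 d-1).
#' @param species species label present in `table`.
#' @param table an [electron_capacity_table()].
#' @param half_reaction optional half-reaction selector; the species' default
#'   entry is used when omitted.
#' @param stderr flux uncertainty (mmol m-2 d-1) when `flux` is a bare number.
#' @return A list with `species`, `half_reaction`, `role`, `electrons`,
#'   `e_flux_mmol_m2_d`, `stderr_mmol_m2_d`.
#' @export
electron_flux <- function(flux, species, table = electron_capacity_table(),
                          half_reaction = NULL, stderr = 0) {
  if (is.list(flux)) {
    stderr <- flux$stderr_mmol_m2_d %||% 0
    flux <- flux$flux_mmol_m2_d
  }
  entry <- capacity_entry(table, species, half_reaction)
  list(species = species, half_reaction = entry$half_reaction,
       role = entry$role, electrons = entry$electrons,
       e_flux_mmol_m2_d = flux * entry$electrons,
       stderr_mmol_m2_d = stderr * entry$electrons)
}

#' Assemble an electron budget across a redox transition zone
#'
#' Sums electron-equivalent fluxes by role and computes the electron-acceptor
#' deficit, \eqn{|\sum donors| - \sum acceptors}: the portion of the upward
#' reductant flux (methane, ammonium, reduced metals) not balanced by the
#' downward flux of measured oxidants. Uncertainties are propagated in
#' quadrature. Full precision is kept in the returned object; use
#' [budget_report()] for the conventionally rounded table, in which the
#' deficit is derived from the rounded sums.
#'
#' @param e_fluxes either a list of [electron_flux()] results or a data.frame
#'   with columns `species`, `role`, `e_flux_mmol_m2_d` and optionally
#'   `stderr_mmol_m2_d`, `half_reaction`.
#' @return An object of class `electron_budget`: list with `table` (the
#'   per-species data.frame), `acceptor_sum`, `acceptor_sd`, `donor_sum`,
#'   `donor_sd`, `deficit`, `deficit_sd`.
#' @examples
#' eb <- budget(data.frame(
#'   species = c("O2", "NO3", "SO4", "CH4", "Fe2", "NH4"),
#'   role = c("acceptor", "acceptor", "acceptor", "donor", "donor", "donor"),
#'   e_flux_mmol_m2_d = c(7.3, 0.15, 0.01, -11.1, -0.03, -1.7),
#'   stderr_mmol_m2_d = c(0.03, 0.02, 0.09, 2.0, 0.01, 0.45)))
#' budget_report(eb)
#' @export
budget <- function(e_fluxes) {
  if (is.data.frame(e_fluxes)) {
    df <- e_fluxes
  } else {
    df <- do.call(rbind, lapply(e_fluxes, function(e)
      data.frame(species = e$species,
                 half_reaction = e$half_reaction %||% NA_character_,
                 role = e$role,
                 e_flux_mmol_m2_d = e$e_flux_mmol_m2_d,
                 stderr_mmol_m2_d = e$stderr_mmol_m2_d %||% 0)))
  }
  if (is.null(df$stderr_mmol_m2_d)) df$stderr_mmol_m2_d <- 0
  if (is.null(df$half_reaction)) df$half_reaction <- NA_character_
  stopifnot(all(c("species", "role", "e_flux_mmol_m2_d") %in% names(df)))
  if (!all(df$role %in% c("acceptor", "donor")))
    stop("role must be 'acceptor' or 'donor'", call. = FALSE)
  acc <- df[df$role == "acceptor", ]
  don <- df[df$role == "donor", ]
  if (!nrow(acc) || !nrow(don))
    stop("incomplete budget: need at least one acceptor and one donor",
         call. = FALSE)
  acceptor_sum <- sum(acc$e_flux_mmol_m2_d)
  donor_sum <- sum(don$e_flux_mmol_m2_d)
  acceptor_sd <- sqrt(sum(acc$stderr_mmol_m2_d^2))
  donor_sd <- sqrt(sum(don$stderr_mmol_m2_d^2))
  structure(list(
    table = df,
    acceptor_sum = acceptor_sum, acceptor_sd = acceptor_sd,
    donor_sum = donor_sum, donor_sd = donor_sd,
    deficit = abs(donor_sum) - acceptor_sum,
    deficit_sd = sqrt(acceptor_sd^2 + donor_sd^2)
  ), class = "electron_budget")
}

round_eflux <- function(x) ifelse(abs(x) >= 1, round(x, 1), round(x, 2))

#' @rdname budget
#' @param x an `electron_budget`.
#' @return `budget_report()`: a data.frame mirroring the conventional printed
#'   table — per-species rows, `Sum` rows per role, and a `Deficit` row
#'   computed from the rounded sums — with mixed one/two-decimal rounding
#'   (one decimal at or above 1, two below).
#' @export
budget_report <- function(x) {
  stopifnot(inherits(x, "electron_budget"))
  rows <- data.frame(species = x$table$species, role = x$table$role,
                     e_flux_mmol_m2_d = round_eflux(x$table$e_flux_mmol_m2_d),
                     stderr_mmol_m2_d = round_eflux(x$table$stderr_mmol_m2_d))
  acc_sum <- round_eflux(x$acceptor_sum)
  don_sum <- round_eflux(x$donor_sum)
  sums <- data.frame(
    species = c("Sum", "Sum", "Deficit"),
    role = c("acceptor", "donor", "balance"),
    e_flux_mmol_m2_d = c(acc_sum, don_sum, abs(don_sum) - acc_sum),
    stderr_mmol_m2_d = round_eflux(c(x$acceptor_sd, x$donor_sd, x$deficit_sd)))
  rbind(rows, sums)
}

#' @export
print.electron_budget <- function(x, ...) {
  cat("<electron_budget> (mmol e- m-2 d-1)\n")
  print(budget_report(x), row.names = FALSE)
  invisible(x)
}

#' Oxidant:methane stoichiometric mole ratio
#'
#' Moles of oxidant required per mole of electron donor under the given
#' half-reactions: the donor's electron yield divided by the oxidant's
#' electron capacity. With methane oxidized fully to CO2 (8 e-) this
#' reproduces the familiar ratios 2 O2 : 1 CH4, 4 NO3- : 1 CH4 (nitrate to
#' nitrite) and 8/3 NO2- : 1 CH4 (nitrite to N2).
#'
#' @param oxidant oxidant species label.
#' @param donor donor species label (default `"CH4"`).
#' @param table an [electron_capacity_table()].
#' @param oxidant_half_reaction,donor_half_reaction optional half-reaction
#'   selectors; species defaults used when omitted.
#' @return Dimensionless mole ratio (mol oxidant per mol donor).
#' @examples
#' oxidant_ratio("NO3", oxidant_half_reaction = "NO3 -> NO2")  # 4
#' oxidant_ratio("NO2")                                        # 8/3
#' @export
oxidant_ratio <- function(oxidant, donor = "CH4",
                          table = electron_capacity_table(),
                          oxidant_half_reaction = NULL,
                          donor_half_reaction = NULL) {
  ox <- capacity_entry(table, oxidant, oxidant_half_reaction)
  dn <- capacity_entry(table, donor, donor_half_reaction)
  if (ox$electrons == 0 || dn$electrons == 0)
    stop("zero-electron capacity entry", call. = FALSE)
  dn$electrons / ox$electrons
}
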