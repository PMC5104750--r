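#' Isotope reference standards
#'
#' Constructor for a carbon isotope reference standard, holding the absolute
#' \eqn{^{13}C/^{12}C} abundance ratio against which per-mil delta values are
#' expressed. The default standard is Vienna Pee Dee Belemnite (VPDB) with
#' \eqn{R = 0.0111796}.
#'
#' @param name label of the standard.
#' @param r13 absolute \eqn{^{13}C/^{12}C} abundance ratio (> 0).
#' @return An object of class `isotope_standard` (a list with `name`, `r13`).
#' @examples
#' vpdb()
#' @export
isotope_standard <- function(name, r13) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(r13) || length(r13) != 1L || !is.finite(r13) || r13 <= 0)
    stop("`r13` must be a single finite positive number", call. = FALSE)
  structure(list(name = name, r13 = r13), class = "isotope_standard")
}

#' @rdname isotope_standard
#' @export
vpdb <- function() isotope_standard("VPDB", 0.0111796)

#' @export
print.isotope_standard <- function(x, ...) {
  cat(sprintf("<isotope_standard> %s: 13C/12C = %.7f\n", x$name, x$r13))
  invisible(x)
}

same_standard <- function(a, b) {
  identical(a$name, b$name) && isTRUE(all.equal(a$r13, b$r13, tolerance = 1e-12))
}

check_delta <- function(delta) {
  if (!is.numeric(delta) || any(!is.finite(delta)))
    stop("delta values must be finite numbers (permil)", call. = FALSE)
  if (any(delta <= -1000))
    stop("invalid delta: values must exceed -1000 permil (isotope ratio must stay positive)",
         call. = FALSE)
  invisible(delta)
}

#' Convert between delta notation, isotope ratios and atom fractions
#'
#' `delta_to_ratio()` maps a per-mil \eqn{\delta^{13}C} value to the absolute
#' isotope ratio \eqn{R = (\delta/1000 + 1) R_{std}}. `ratio_to_delta()` is its
#' inverse. `ratio_to_atom_fraction()` maps a ratio to the \eqn{^{13}C} atom
#' fraction \eqn{F = R/(1+R)}; `atom_fraction_to_ratio()` inverts it.
#' `delta_to_atom_fraction()` and `atom_fraction_to_delta()` compose the two.
#'
#' @param delta numeric vector of per-mil delta values (> -1000).
#' @param ratio numeric vector of isotope ratios (>= 0).
#' @param frac numeric vector of atom fractions in \[0, 1).
#' @param standard an [isotope_standard()]; defaults to [vpdb()].
#' @return Numeric vector.
#' @examples
#' delta_to_ratio(0)                      # the VPDB ratio itself
#' ratio_to_atom_fraction(delta_to_ratio(-50))
#' @export
delta_to_ratio <- function(delta, standard = vpdb()) {
  check_delta(delta)
  (delta / 1000 + 1) * standard$r13
}

#' @rdname delta_to_ratio
#' @export
ratio_to_delta <- function(ratio, standard = vpdb()) {
  if (any(!is.finite(ratio)) || any(ratio < 0))
    stop("invalid ratio: must be finite and non-negative", call. = FALSE)
  (ratio / standard$r13 - 1) * 1000
}

#' @rdname delta_to_ratio
#' @export
ratio_to_atom_fraction <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio < 0))
    stop("invalid ratio: must be finite and non-negative", call. = FALSE)
  ratio / (1 + ratio)
}

#' @rdname delta_to_ratio
#' @export
atom_fraction_to_ratio <- function(frac) {
  if (any(!is.finite(frac)) || any(frac < 0) || any(frac >= 1))
    stop("atom fraction must lie in [0, 1)", call. = FALSE)
  frac / (1 - frac)
}

#' @rdname delta_to_ratio
#' @export
delta_to_atom_fraction <- function(delta, standard = vpdb()) {
  ratio_to_atom_fraction(delta_to_ratio(delta, standard))
}

#' @rdname delta_to_ratio
#' @export
atom_fraction_to_delta <- function(frac, standard = vpdb()) {
  ratio_to_delta(atom_fraction_to_ratio(frac), standard)
}

#' Closed-system Rayleigh fractionation: forward model
#'
#' Evaluates the closed-system Rayleigh distillation model for the residual
#' substrate pool,
#' \deqn{\delta = (\delta_0 + 1000)\, f^{(1/\alpha - 1)} - 1000,}
#' where \eqn{f} is the fraction of substrate remaining and \eqn{\alpha} the
#' kinetic fractionation factor in the positive convention (\eqn{\alpha > 1}
#' means the residual pool becomes enriched in the heavy isotope as \eqn{f}
#' decreases).
#'
#' @param delta0 per-mil delta of the untouched source pool (> -1000).
#' @param alpha fractionation factor (> 0), positive convention.
#' @param f residual fraction(s) in (0, 1].
#' @return Per-mil delta value(s) of the residual pool.
#' @examples
#' rayleigh_forward(-50, 1.005, c(1, 0.5, 0.1, 0.01))
#' @export
rayleigh_forward <- function(delta0, alpha, f) {
  check_delta(delta0)
  stopifnot(length(delta0) == 1L, length(alpha) == 1L)
  if (!is.finite(alpha) || alpha <= 0)
    stop("alpha must be a finite positive number", call. = FALSE)
  if (any(!is.finite(f)) || any(f <= 0) || any(f > 1))
    stop("residual fraction f must lie in (0, 1]", call. = FALSE)
  (delta0 + 1000) * f^(1 / alpha - 1) - 1000
}

#' Fit a Rayleigh fractionation factor to (f, delta) observations
#'
#' Linearizes the closed-system Rayleigh model:
#' \eqn{\ln\frac{\delta + 1000}{\delta_0 + 1000} = (1/\alpha - 1)\,\ln f}
#' and estimates the slope \eqn{m = 1/\alpha - 1} by least squares through the
#' origin, which is exact on noise-free forward-generated data. The source
#' composition \eqn{\delta_0} (near-bottom methane in a lake application) is
#' supplied, not co-estimated, unless `estimate_delta0 = TRUE`, in which case
#' an intercept is admitted and \eqn{\delta_0} is refit from it.
#'
#' @param f residual fractions in (0, 1]; at least two distinct values.
#' @param delta per-mil delta of the residual pool at each `f`.
#' @param delta0 per-mil delta of the source pool.
#' @param standard an [isotope_standard()].
#' @param sign_convention how `alpha_paper_convention` is filled: `"negative"`
#'   reports \eqn{-\alpha} (the signed form some field studies print for
#'   apparent community fractionation factors), `"positive"` reports
#'   \eqn{\alpha} unchanged.
#' @param estimate_delta0 if `TRUE`, co-estimate the source delta via a free
#'   intercept (off by default).
#' @return An object of class `rayleigh_fit`: a list with `alpha`, `epsilon`
#'   (\eqn{(1/\alpha - 1) \cdot 1000} permil), `alpha_paper_convention`,
#'   `delta0`, `n_obs`, `rmse` (permil, in delta space), and `data`.
#' @examples
#' f <- c(1, 0.5, 0.1, 0.05, 0.01)
#' d <- rayleigh_forward(-50, 1.005, f)
#' rayleigh_fit_alpha(f, d, delta0 = -50)
#' @export
rayleigh_fit_alpha <- function(f, delta, delta0,
                               standard = vpdb(),
                               sign_convention = c("negative", "positive"),
                               estimate_delta0 = FALSE) {
  sign_convention <- match.arg(sign_convention)
  if (any(!is.finite(f)) || any(f <= 0) || any(f > 1))
    stop("residual fraction f must lie in (0, 1]", call. = FALSE)
  check_delta(delta)
  check_delta(delta0)
  if (length(f) != length(delta))
    stop("`f` and `delta` must have the same length", call. = FALSE)
  if (length(unique(f)) < 2L)
    stop("insufficient data: need at least 2 observations with distinct f",
         call. = FALSE)

  x <- log(f)
  y <- log((delta + 1000) / (delta0 + 1000))
  if (estimate_delta0) {
    fit <- stats::lm(y ~ x)
    m <- unname(stats::coef(fit)[2L])
    delta0_hat <- (delta0 + 1000) * exp(unname(stats::coef(fit)[1L])) - 1000
  } else {
    fit <- stats::lm(y ~ x - 1)
    m <- unname(stats::coef(fit)[1L])
    delta0_hat <- delta0
  }
  alpha <- 1 / (m + 1)
  if (!is.finite(alpha) || alpha <= 0)
    stop("fit produced a non-positive fractionation factor; check inputs",
         call. = FALSE)
  pred <- rayleigh_forward(delta0_hat, alpha, f)
  structure(list(
    alpha = alpha,
    epsilon = (1 / alpha - 1) * 1000,
    alpha_paper_convention = if (sign_convention == "negative") -alpha else alpha,
    sign_convention = sign_convention,
    delta0 = delta0_hat,
    n_obs = length(f),
    rmse = sqrt(mean((delta - pred)^2)),
    standard = standard,
    data = data.frame(f = f, delta = delta)
  ), class = "rayleigh_fit")
}

#' @export
print.rayleigh_fit <- function(x, ...) {
  cat("<rayleigh_fit> closed-system Rayleigh model\n")
  cat(sprintf("  alpha  = %.6f  (epsilon = %.3f permil)\n", x$alpha, x$epsilon))
  cat(sprintf("  alpha (%s sign convention) = %.6f\n",
              x$sign_convention, x$alpha_paper_convention))
  cat(sprintf("  delta0 = %.2f permil,  n = %d,  rmse = %.3f permil\n",
              x$delta0, x$n_obs, x$rmse))
  invisible(x)
}

#' Isotopic discrimination between two pools
#'
#' Signed per-mil difference \eqn{\Delta\delta = \delta_A - \delta_B}, e.g.
#' \eqn{\Delta\delta^{13}C_{CH_4-DIC}} used to distinguish biogenic from
#' thermogenic methane sources.
#'
#' @param delta_a,delta_b per-mil delta values.
#' @param standard_a,standard_b the reference standards the two values are
#'   expressed against; must match.
#' @return Signed per-mil difference.
#' @examples
#' discrimination(-50, 1)   # CH4 vs DIC
#' @export
discrimination <- function(delta_a, delta_b,
                           standard_a = vpdb(), standard_b = vpdb()) {
  if (!same_standard(standard_a, standard_b))
    stop("incompatible reference standards: deltas must share one standard",
         call. = FALSE)
  check_delta(delta_a)
  check_delta(delta_b)
  delta_a - delta_b
}

#' Two-end-member isotope mixing
#'
#' Concentration-weighted mixture of two pools of the same analyte. The default
#' (`mode = "atom_fraction"`) mixes in atom-fraction space, which conserves
#' \eqn{^{13}C} and \eqn{^{12}C} mass exactly; `mode = "delta_linear"` performs
#' the common delta-linear approximation and flags the result.
#'
#' @param delta1,delta2 per-mil delta of the two end members.
#' @param fraction1 fraction of the mixture volume drawn from end member 1,
#'   in \[0, 1\].
#' @param c1,c2 concentrations of the analyte in the two end members (same
#'   units, >= 0, not both zero).
#' @param mode mixing space, `"atom_fraction"` (mass-conserving, default) or
#'   `"delta_linear"`.
#' @param standard an [isotope_standard()].
#' @return A list with `delta` (per-mil), `concentration` (mixture
#'   concentration, same units as `c1`), and `mode`.
#' @examples
#' two_endmember_mix(-47, -19, 0.5, 1, 1, mode = "delta_linear")
#' @export
two_endmember_mix <- function(delta1, delta2, fraction1, c1, c2,
                              mode = c("atom_fraction", "delta_linear"),
                              standard = vpdb()) {
  mode <- match.arg(mode)
  check_delta(delta1); check_delta(delta2)
  stopifnot(is.numeric(fraction1), fraction1 >= 0, fraction1 <= 1)
  if (c1 < 0 || c2 < 0) stop("concentrations must be non-negative", call. = FALSE)
  w1 <- fraction1 * c1
  w2 <- (1 - fraction1) * c2
  if (w1 + w2 <= 0)
    stop("undefined mixture: both contributions are zero", call. = FALSE)
  conc <- fraction1 * c1 + (1 - fraction1) * c2
  if (mode == "delta_linear") {
    d <- (w1 * delta1 + w2 * delta2) / (w1 + w2)
  } else {
    f1 <- delta_to_atom_fraction(delta1, standard)
    f2 <- delta_to_atom_fraction(delta2, standard)
    c13 <- w1 * f1 + w2 * f2           # heavy-isotope moles per unit volume
    d <- atom_fraction_to_delta(c13 / (w1 + w2), standard)
  }
  list(delta = d, concentration = conc, mode = mode)
}
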