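# Flask headspace CO uptake kinetics: apparent first-order rate constants
# from the logarithmic decrease of the headspace mixing ratio, conversion
# to soil-mass-normalized potential uptake rates (pmol g-1(dw) h-1) and to
# cell-specific rates for cultures (zmol cfu-1 h-1).

#' Flask headspace decay curve
#'
#' Container for one flask's CO mixing-ratio time series plus the metadata
#' needed for rate conversion. Points below the gas-chromatographic
#' detection floor (default 25 ppbv) are flagged censored and excluded from
#' fitting.
#'
#' @param flask_id flask label.
#' @param times_h strictly increasing sampling times (h).
#' @param co_ppmv headspace CO mixing ratios (ppmv), positive where
#'   uncensored.
#' @param censored optional logical flags; computed from `floor_ppbv` when
#'   omitted.
#' @param floor_ppbv detection floor (ppbv).
#' @param headspace_l headspace volume (L); when `NA` it is derived as
#'   `bottle_l` minus the soil bulk volume `soil_dw_g / bulk_density_g_cm3`.
#' @param soil_dw_g soil dry weight (g), for soil flasks.
#' @param culture_cfu total colony-forming units, for culture flasks.
#' @param temperature_k,pressure_kpa headspace conditions.
#' @param bottle_l nominal bottle volume (L).
#' @param bulk_density_g_cm3 soil bulk density used for headspace
#'   correction.
#' @return object of class `decay_curve`.
#' @export
decay_curve <- function(flask_id, times_h, co_ppmv, censored = NULL,
                        floor_ppbv = 25, headspace_l = NA_real_,
                        soil_dw_g = NA_real_, culture_cfu = NA_real_,
                        temperature_k = 298.15, pressure_kpa = 101.325,
                        bottle_l = 0.5, bulk_density_g_cm3 = 1.2) {
  if (length(times_h) != length(co_ppmv))
    .stopf("times_h and co_ppmv lengths differ")
  if (any(diff(times_h) <= 0))
    .stopf("times_h must be strictly increasing")
  if (is.null(censored)) censored <- co_ppmv < floor_ppbv / 1000
  if (any(co_ppmv[!censored] <= 0))
    .stopf("non-positive uncensored mixing ratios in flask %s", flask_id)
  structure(list(flask_id = flask_id, times_h = as.numeric(times_h),
                 co_ppmv = as.numeric(co_ppmv),
                 censored = as.logical(censored),
                 floor_ppbv = floor_ppbv, headspace_l = headspace_l,
                 soil_dw_g = soil_dw_g, culture_cfu = culture_cfu,
                 temperature_k = temperature_k, pressure_kpa = pressure_kpa,
                 bottle_l = bottle_l,
                 bulk_density_g_cm3 = bulk_density_g_cm3),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("Decay curve %s: %d points (%d censored), %.3g -> %.3g ppmv\n",
              x$flask_id, length(x$times_h), sum(x$censored),
              x$co_ppmv[1L], x$co_ppmv[length(x$co_ppmv)]))
  invisible(x)
}

#' Fit the apparent first-order CO uptake rate constant
#'
#' Integrates the logarithmic decrease of the headspace mixing ratio:
#' `k` is minus the OLS slope of `ln(CO)` on time over the uncensored
#' points. At least five usable concentration points are required.
#'
#' @param curve a [decay_curve()].
#' @param min_points minimum uncensored points (default 5).
#' @return object of class `decay_fit`: `k_per_h`, `r2`, `n_points`,
#'   `flask_id`, `reference_ppmv` (first uncensored observation).
#' @examples
#' cc <- decay_curve("f1", seq(0, 1, 0.25), exp(-0.5 * seq(0, 1, 0.25)))
#' fit_decay(cc)$k_per_h
#' @export
fit_decay <- function(curve, min_points = 5L) {
  stopifnot(inherits(curve, "decay_curve"))
  use <- !curve$censored
  if (sum(use) < min_points)
    .stopf("insufficient data in flask %s: %d uncensored points (< %d)",
           curve$flask_id, sum(use), min_points)
  t <- curve$times_h[use]
  y <- log(curve$co_ppmv[use])
  fit <- lm(y ~ t)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(k_per_h = -unname(coef(fit)[2L]), r2 = r2,
                 n_points = sum(use), flask_id = curve$flask_id,
                 reference_ppmv = curve$co_ppmv[use][1L]),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("First-order CO uptake, flask %s: k = %.4g 1/h (R2 = %.3f, n = %d)\n",
              x$flask_id, x$k_per_h, x$r2, x$n_points))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) c(k_per_h = object$k_per_h)

# Moles of air in the flask headspace by the ideal gas law.
.headspace_moles <- function(curve) {
  v_l <- curve$headspace_l
  if (is.na(v_l)) {
    if (is.na(curve$soil_dw_g))
      .stopf("flask %s: headspace_l missing and no soil mass to derive it",
             curve$flask_id)
    v_l <- curve$bottle_l - curve$soil_dw_g / curve$bulk_density_g_cm3 / 1000
  }
  if (is.na(curve$temperature_k) || is.na(curve$pressure_kpa))
    .stopf("flask %s: missing metadata: %s", curve$flask_id,
           paste(c("temperature_k", "pressure_kpa")[
             c(is.na(curve$temperature_k), is.na(curve$pressure_kpa))],
             collapse = ", "))
  curve$pressure_kpa * 1000 * v_l * 1e-3 / (GAS_CONSTANT * curve$temperature_k)
}

.resolve_xref <- function(curve, reference, x_ref_ppmv) {
  if (!is.null(x_ref_ppmv)) return(x_ref_ppmv)
  switch(reference,
         initial = curve$co_ppmv[!curve$censored][1L],
         mean = mean(curve$co_ppmv[!curve$censored]),
         atmospheric = 0.1)
}

#' Soil-mass-normalized potential CO uptake rate
#'
#' Converts a first-order rate constant into a potential uptake rate
#' `k * x_ref * n_air / m_soil` in pmol g-1(dw) h-1, where `x_ref` is the
#' reference mixing ratio and `n_air = P V / (R T)` the moles of headspace
#' air. The reference defaults to the initial observed mixing ratio (~1 ppmv
#' in flask assays); `"atmospheric"` (0.1 ppmv) and `"mean"` are available
#' since the convention is not universal.
#'
#' @param fit a [fit_decay()] result or a bare rate constant (1/h).
#' @param curve the flask's [decay_curve()] (mass and headspace metadata).
#' @param reference `"initial"`, `"atmospheric"` or `"mean"`.
#' @param x_ref_ppmv explicit reference mixing ratio, overriding
#'   `reference`.
#' @return uptake rate in pmol g-1(dw) h-1, with the reference mixing ratio
#'   attached as attribute `x_ref_ppmv`.
#' @examples
#' cc <- decay_curve("f1", seq(0, 1, 0.25), exp(-0.5 * seq(0, 1, 0.25)),
#'                   headspace_l = 0.48, soil_dw_g = 50)
#' uptake_rate(fit_decay(cc), cc)
#' @export
uptake_rate <- function(fit, curve,
                        reference = c("initial", "atmospheric", "mean"),
                        x_ref_ppmv = NULL) {
  stopifnot(inherits(curve, "decay_curve"))
  k <- if (inherits(fit, "decay_fit")) fit$k_per_h else as.numeric(fit)
  reference <- match.arg(reference)
  if (is.na(curve$soil_dw_g) || curve$soil_dw_g <= 0)
    .stopf("flask %s: missing metadata: soil_dw_g", curve$flask_id)
  x_ref <- .resolve_xref(curve, reference, x_ref_ppmv)
  n_air <- .headspace_moles(curve)
  rate_mol <- k * x_ref * 1e-6 * n_air / curve$soil_dw_g
  structure(convert_mol(rate_mol, "mol", "pmol"), x_ref_ppmv = x_ref)
}

#' Cell-specific CO oxidation rate
#'
#' Normalizes a culture flask's molar CO uptake rate to biomass (agar-plate
#' cfu counts), in zmol cfu-1 h-1 (1 zmol = 1e-21 mol). Carboxydovore
#' isolates span roughly 29 to 2171 zmol cfu-1 h-1.
#'
#' @inheritParams uptake_rate
#' @return data frame `strain`, `rate_zmol_cfu_h`, `cfu_count`.
#' @export
cell_specific_rate <- function(fit, curve,
                               reference = c("initial", "atmospheric",
                                             "mean"),
                               x_ref_ppmv = NULL) {
  stopifnot(inherits(curve, "decay_curve"))
  k <- if (inherits(fit, "decay_fit")) fit$k_per_h else as.numeric(fit)
  reference <- match.arg(reference)
  if (is.na(curve$culture_cfu) || curve$culture_cfu <= 0)
    .stopf("flask %s: culture_cfu must be a positive count", curve$flask_id)
  x_ref <- .resolve_xref(curve, reference, x_ref_ppmv)
  n_air <- .headspace_moles(curve)
  rate_mol_cfu <- k * x_ref * 1e-6 * n_air / curve$culture_cfu
  data.frame(strain = curve$flask_id,
             rate_zmol_cfu_h = convert_mol(rate_mol_cfu, "mol", "zmol"),
             cfu_count = curve$culture_cfu, stringsAsFactors = FALSE)
}
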