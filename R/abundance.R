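# qPCR absolute quantification of coxL genes and the theoretical
# carboxydovore population bands that bracket them.

#' Fit a qPCR standard curve
#'
#' OLS of Cq on log10(copies) over the standards. Amplification efficiency
#' uses the convention `E = 10^(-1/slope) - 1`, so a slope of -3.32
#' cycles/log gives `E = 1` (perfect doubling); degenerate-primer soil
#' assays typically run near `E = 0.7`.
#'
#' @param standards data frame with columns `copies` and `cq` (only rows
#'   with `role == "standard"` are used if a `role` column is present).
#' @return object of class `standard_curve`: `slope`, `intercept_cq`,
#'   `efficiency`, `r2`, `n_standards`, `copy_range`.
#' @examples
#' run <- simulate_qpcr_run(0.7, 40, sd_cq = 0, seed = 1)
#' fit_standard_curve(run$records)
#' @export
fit_standard_curve <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("copies", "cq") %in% names(standards)))
  if ("role" %in% names(standards))
    standards <- standards[standards$role == "standard", , drop = FALSE]
  standards <- standards[is.finite(standards$copies) &
                           standards$copies > 0, , drop = FALSE]
  lg <- log10(standards$copies)
  if (length(unique(lg)) < 3L || diff(range(lg)) < 2)
    .stopf("need >= 3 distinct copy levels spanning >= 2 logs")
  fit <- lm(standards$cq ~ lg)
  slope <- unname(coef(fit)[2L])
  if (slope >= 0)
    .stopf("assay failure: standard-curve slope %.3f is not negative", slope)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((standards$cq - mean(standards$cq))^2)
  structure(list(slope = slope, intercept_cq = unname(coef(fit)[1L]),
                 efficiency = 10^(-1 / slope) - 1,
                 r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 n_standards = nrow(standards),
                 copy_range = range(standards$copies)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: Cq = %.3f %+.4f log10(copies)  [E = %.2f, R2 = %.3f, n = %d]\n",
    x$intercept_cq, x$slope, x$efficiency, x$r2, x$n_standards))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept_cq = object$intercept_cq, slope = object$slope)
}

#' Expected Cq at given copy numbers
#'
#' @param object a `standard_curve`.
#' @param copies copy numbers per reaction.
#' @param ... unused.
#' @return expected Cq values.
#' @export
predict.standard_curve <- function(object, copies, ...) {
  object$intercept_cq + object$slope * log10(copies)
}

#' Absolute quantification of gene copies per gram of soil
#'
#' Inverts the standard curve at an observed Cq and scales copies per
#' reaction to copies per gram dry soil through the extraction volumes:
#' `copies_g = copies_rxn * dilution * elution_ul / (template_ul *
#' soil_dw_g)`. A Cq outside the standard range is flagged as an
#' extrapolation (warning).
#'
#' @param cq observed quantification cycle(s).
#' @param curve a [fit_standard_curve()] result.
#' @param dilution template dilution factor (e.g. 500 for 1:500).
#' @param soil_dw_g soil dry mass extracted (g).
#' @param elution_ul DNA elution volume (ul).
#' @param template_ul template volume per reaction (ul).
#' @param sample_id,assay labels carried into the output.
#' @return data frame `sample_id`, `assay`, `cq`, `copies_per_reaction`,
#'   `copies_per_g_dw`, `dilution_factor`, `extrapolated`.
#' @export
quantify_copies <- function(cq, curve, dilution = 500, soil_dw_g = 0.5,
                            elution_ul = 50, template_ul = 5,
                            sample_id = NA_character_,
                            assay = NA_character_) {
  stopifnot(inherits(curve, "standard_curve"))
  copies_rxn <- 10^((cq - curve$intercept_cq) / curve$slope)
  cq_range <- sort(predict(curve, curve$copy_range))
  extrapolated <- cq < cq_range[1L] | cq > cq_range[2L]
  if (any(extrapolated))
    .warnf("%d Cq value(s) outside the standard range [%.2f, %.2f]",
           sum(extrapolated), cq_range[1L], cq_range[2L])
  scale_g <- dilution * elution_ul / (template_ul * soil_dw_g)
  data.frame(sample_id = sample_id, assay = assay, cq = cq,
             copies_per_reaction = copies_rxn,
             copies_per_g_dw = copies_rxn * scale_g,
             dilution_factor = dilution, extrapolated = extrapolated,
             stringsAsFactors = FALSE)
}

#' Theoretical carboxydovore population band
#'
#' Brackets the density of metabolically active carboxydovores needed to
#' explain a measured soil CO uptake rate: `N = CO_soil / CO_bacteria`,
#' evaluated at the lowest and highest cell-specific oxidation rates
#' observed in reference isolates. The lowest specific activity gives the
#' upper population limit and vice versa. One coxL copy per cell and one
#' viable cell per cfu are assumed.
#'
#' @param co_soil soil CO uptake rate, pmol g-1(dw) h-1 (>= 0).
#' @param act_low,act_high lowest/highest cell-specific rates,
#'   pmol cfu-1 h-1 (> 0, `act_low <= act_high`).
#' @param sample_id label carried into the output.
#' @return object of class `population_band`: `n_lower`, `n_upper`
#'   (cells g-1(dw)) plus the inputs.
#' @examples
#' # 11 nmol g-1 h-1 forest uptake, isolates 29-2171 zmol cfu-1 h-1
#' theoretical_band(co_soil = 11e3,
#'                  act_low = convert_mol(29, "zmol", "pmol"),
#'                  act_high = convert_mol(2171, "zmol", "pmol"))
#' @export
theoretical_band <- function(co_soil, act_low, act_high,
                             sample_id = NA_character_) {
  co_soil <- .check_number(co_soil, "co_soil", lower = 0)
  act_low <- .check_number(act_low, "act_low", lower = 0,
                           strict_lower = TRUE)
  act_high <- .check_number(act_high, "act_high", lower = 0,
                            strict_lower = TRUE)
  if (act_low > act_high)
    .stopf("act_low (%g) > act_high (%g): arguments swapped?",
           act_low, act_high)
  structure(list(sample_id = sample_id, co_soil = co_soil,
                 act_low = act_low, act_high = act_high,
                 n_lower = co_soil / act_high,
                 n_upper = co_soil / act_low),
            class = "population_band")
}

#' @export
print.population_band <- function(x, ...) {
  cat(sprintf(
    "Theoretical carboxydovore population: %.3g to %.3g cells g-1(dw)\n",
    x$n_lower, x$n_upper))
  cat(sprintf("  (CO uptake %.3g pmol g-1 h-1; specific activity %.3g-%.3g pmol cfu-1 h-1)\n",
              x$co_soil, x$act_low, x$act_high))
  invisible(x)
}

#' Classify a qPCR abundance against a theoretical population band
#'
#' Compares gene copies per gram (one coxL copy per cell assumed) with the
#' closed interval `[n_lower, n_upper]` of the theoretical band.
#'
#' @param band a [theoretical_band()].
#' @param abundance copies per gram dry soil, or a [quantify_copies()] row.
#' @return `"below"`, `"within"` or `"above"`.
#' @export
band_consistency <- function(band, abundance) {
  stopifnot(inherits(band, "population_band"))
  if (is.data.frame(abundance)) abundance <- abundance$copies_per_g_dw
  vapply(abundance, function(a) {
    if (a < band$n_lower) "below"
    else if (a > band$n_upper) "above"
    else "within"
  }, character(1))
}

#' Registry of coxL detection and quantification assays
#'
#' The three degenerate-primer assays used for soil carboxydovore surveys:
#' a universal coxL PCR assay and qPCR assays for the functional type I
#' group and its delta-proteobacterial subgroup. Primer names carry the
#' priming coordinate on the gene; `printed_bp` is the amplicon size as
#' originally reported, which for the delta-proteobacteria assay differs
#' from the coordinate difference and is carried as metadata.
#'
#' @return data frame with one row per assay: `assay`, `fwd_name`,
#'   `fwd_seq`, `rev_name`, `rev_seq`, `printed_bp`.
#' @export
coxl_assays <- function() {
  data.frame(
    assay = c("universal", "type_I", "delta_proteo"),
    fwd_name = c("uni820-forward", "type I-1288-forward", "D967-forward"),
    fwd_seq = c("GGBGGBGGYTTYGGCWMSAA", "TSKKYACSGGCWSSTA",
                "TTCTWCKCYGAYGCVCARCC"),
    rev_name = c("uni1611-reverse", "type I-1540-reverse", "D1285-reverse"),
    rev_seq = c("GTBKCRTGNCCCTGNCC", "TAYGAYWSSGGYRAYTA",
                "CBGAGTCGGDSASGAADCC"),
    printed_bp = c(800L, 252L, 291L),
    stringsAsFactors = FALSE)
}

.primer_coord <- function(name) {
  m <- regmatches(name, regexpr("[0-9]+", name))
  if (length(m) == 0L)
    .stopf("cannot parse a priming coordinate from primer name '%s'", name)
  as.integer(m)
}

#' Amplicon length from primer coordinates
#'
#' Computes the amplified fragment length as the difference between the
#' coordinates parsed from the reverse and forward primer names (e.g.
#' `type I-1288-forward` / `type I-1540-reverse` give 252 bp). A
#' non-positive length is flagged invalid; a mismatch with the recorded
#' `printed_bp` is flagged with a message.
#'
#' @param assay one row of [coxl_assays()] (or any list with `fwd_name`,
#'   `rev_name`, optionally `printed_bp`).
#' @return integer length in bp, with attributes `valid` and (when
#'   `printed_bp` is present) `matches_printed`.
#' @examples
#' amplicon_length(coxl_assays()[2, ])  # 252
#' @export
amplicon_length <- function(assay) {
  fwd <- .primer_coord(assay$fwd_name)
  rev <- .primer_coord(assay$rev_name)
  if (rev < fwd)
    .stopf("reverse coordinate %d precedes forward coordinate %d", rev, fwd)
  len <- rev - fwd
  out <- structure(len, valid = len > 0L)
  if (len <= 0L) .warnf("amplicon length %d bp flagged invalid", len)
  if (!is.null(assay$printed_bp) && !is.na(assay$printed_bp)) {
    attr(out, "matches_printed") <- len == assay$printed_bp
    if (len != assay$printed_bp)
      message(sprintf(
        "coordinate rule gives %d bp, printed size is %d bp (kept as metadata)",
        len, assay$printed_bp))
  }
  out
}
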