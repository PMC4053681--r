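# Similarity-threshold calibration: pairwise similarity scores S = 1 - D
# for paired 16S rRNA / coxL panels, OLS of coxL similarity on 16S
# similarity, and the species-level coxL OTU threshold obtained by reading
# the regression (with its 95% prediction interval) at a 16S species cutoff.

.GAP_CHARS <- c("-", ".", "N", "n")

.seq_char_matrix <- function(aligned_set) {
  if (inherits(aligned_set, "XStringSet"))
    aligned_set <- setNames(as.character(aligned_set), names(aligned_set))
  if (is.matrix(aligned_set)) return(aligned_set)
  stopifnot(is.character(aligned_set), length(aligned_set) >= 2L)
  lens <- nchar(aligned_set)
  if (length(unique(lens)) != 1L)
    .stopf("aligned sequences must share one length (got %s)",
           paste(unique(lens), collapse = ", "))
  m <- do.call(rbind, strsplit(toupper(aligned_set), ""))
  rownames(m) <- names(aligned_set)
  m
}

#' Pairwise similarity scores from an alignment
#'
#' Computes the symmetric matrix of similarity scores `S = 1 - D`, where
#' `D` is the proportion of differing sites over alignment columns in which
#' neither sequence of the pair carries a gap or `N` (pairwise deletion).
#'
#' @param aligned_set named character vector, `XStringSet`, or character
#'   matrix of equal-length aligned sequences (>= 2).
#' @return symmetric numeric matrix with unit diagonal.
#' @examples
#' pairwise_similarity(c(a = "ACGT", b = "ACGA"))["a", "b"]  # 0.75
#' @export
pairwise_similarity <- function(aligned_set) {
  m <- .seq_char_matrix(aligned_set)
  n <- nrow(m)
  if (n < 2L) .stopf("need at least 2 sequences")
  valid <- !(m %in% .GAP_CHARS)
  dim(valid) <- dim(m)
  S <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- valid[i, ] & valid[j, ]
      nok <- sum(ok)
      if (nok == 0L)
        .stopf("no comparable columns between sequences %d and %d", i, j)
      S[i, j] <- S[j, i] <- 1 - sum(m[i, ok] != m[j, ok]) / nok
    }
  }
  dimnames(S) <- list(rownames(m), rownames(m))
  S
}

#' Build the table of paired 16S/coxL similarity scores
#'
#' Lists every unordered taxon pair once with its 16S and coxL similarity
#' scores; a panel of `n` taxa yields `choose(n, 2)` pairs (e.g. 820 for a
#' 41-taxon panel, 1830 for 61).
#'
#' @param s16_matrix,scoxl_matrix symmetric similarity matrices over the
#'   same taxa in the same order (dimnames are checked when present).
#' @param taxa optional taxon names overriding the dimnames.
#' @return data frame `taxon_a`, `taxon_b` (with `taxon_a < taxon_b`),
#'   `s_16s`, `s_coxl`.
#' @export
build_similarity_pairs <- function(s16_matrix, scoxl_matrix, taxa = NULL) {
  if (is.null(taxa)) taxa <- rownames(s16_matrix)
  n <- nrow(s16_matrix)
  if (is.null(taxa)) taxa <- sprintf("t%03d", seq_len(n))
  if (!all(dim(s16_matrix) == c(n, n)) || !all(dim(scoxl_matrix) == c(n, n)))
    .stopf("similarity matrices must be square and of equal size")
  cox_taxa <- rownames(scoxl_matrix)
  if (!is.null(cox_taxa) && !identical(cox_taxa, taxa)) {
    missing <- setdiff(taxa, cox_taxa)
    .stopf("taxon sets differ between matrices; missing from coxL: %s",
           if (length(missing)) paste(missing, collapse = ", ")
           else "(order mismatch)")
  }
  idx <- which(upper.tri(s16_matrix), arr.ind = TRUE)
  a <- taxa[idx[, 1]]; b <- taxa[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(taxon_a = a, taxon_b = b,
                    s_16s = s16_matrix[idx], s_coxl = scoxl_matrix[idx],
                    stringsAsFactors = FALSE)
  out[order(out$taxon_a, out$taxon_b), , drop = FALSE]
}

#' Fit the 16S/coxL similarity calibration regression
#'
#' Ordinary least squares of coxL similarity on 16S similarity over all
#' panel pairs, keeping the ingredients (`mean_x`, `sxx`, residual SD)
#' needed for prediction-interval algebra at an arbitrary 16S cutoff.
#'
#' @param pairs data frame from [build_similarity_pairs()] (columns
#'   `s_16s`, `s_coxl`), >= 3 rows with non-degenerate `s_16s` variance.
#' @param level confidence level stored for interval computation.
#' @return object of class `coxl_calibration` with components `slope`,
#'   `intercept`, `n_pairs`, `r2`, `residual_sd`, `mean_x`, `sxx`,
#'   `p_value`, `level`.
#' @seealso [derive_threshold()]
#' @export
fit_calibration <- function(pairs, level = 0.95) {
  stopifnot(is.data.frame(pairs), all(c("s_16s", "s_coxl") %in% names(pairs)))
  x <- pairs$s_16s; y <- pairs$s_coxl
  n <- length(x)
  if (n < 3L) .stopf("need at least 3 pairs (got %d)", n)
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) .stopf("degenerate regression: zero variance in s_16s")
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2L])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  fstat <- if (ss_res > 0) (ss_tot - ss_res) / (ss_res / (n - 2)) else Inf
  structure(list(slope = slope, intercept = unname(coef(fit)[1L]),
                 n_pairs = n, r2 = r2,
                 residual_sd = sqrt(ss_res / (n - 2)),
                 mean_x = mean(x), sxx = sxx,
                 p_value = pf(fstat, 1, n - 2, lower.tail = FALSE),
                 level = level),
            class = "coxl_calibration")
}

#' @export
print.coxl_calibration <- function(x, ...) {
  cat("coxL ~ 16S similarity calibration (n =", x$n_pairs, "pairs)\n")
  cat(sprintf("  s_coxl = %.4f + %.4f * s_16s   (R2 = %.3f, P = %.3g)\n",
              x$intercept, x$slope, x$r2, x$p_value))
  cat(sprintf("  residual SD %.4f\n", x$residual_sd))
  invisible(x)
}

#' @export
coef.coxl_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.coxl_calibration <- function(object, ...) object

#' Predict coxL similarity at new 16S similarities
#'
#' @param object a `coxl_calibration` fit.
#' @param x_16s numeric vector of 16S similarity scores.
#' @param interval `"none"` or `"prediction"`.
#' @param level confidence level (defaults to the fit's).
#' @param ... unused.
#' @return fitted values, or a data frame `fit`, `lwr`, `upr`.
#' @export
predict.coxl_calibration <- function(object, x_16s, interval = "none",
                                     level = object$level, ...) {
  interval <- match.arg(interval, c("none", "prediction"))
  fit <- object$intercept + object$slope * x_16s
  if (interval == "none") return(fit)
  hw <- .pred_halfwidth(object, x_16s, level)
  data.frame(fit = fit, lwr = fit - hw, upr = fit + hw)
}

.pred_halfwidth <- function(model, x, level) {
  df <- model$n_pairs - 2L
  tq <- qt(1 - (1 - level) / 2, df)
  tq * model$residual_sd *
    sqrt(1 + 1 / model$n_pairs + (x - model$mean_x)^2 / model$sxx)
}

#' Derive the species-level coxL OTU similarity threshold
#'
#' Reads the calibration regression at a 16S species-level similarity cutoff
#' (0.97 by default, the classical species boundary) and attaches the OLS
#' prediction-interval half-width at that point, the `+/-` of the threshold.
#' Thresholds outside `[0, 1]` are clamped and flagged; a near-zero slope
#' with a threshold near 1 indicates no sub-species resolution for the gene,
#' the behaviour seen for hypothetical type II panels.
#'
#' @param model a [fit_calibration()] result.
#' @param x_species 16S similarity cutoff in (0, 1].
#' @param level confidence level for the prediction interval.
#' @return object of class `threshold_estimate`: list with `threshold`,
#'   `halfwidth`, `x_species`, `level`, `clamped`.
#' @examples
#' sim <- simulate_gene_pairs(15, 0.8, 0.15, 0.02, seed = 2)
#' derive_threshold(fit_calibration(sim$pairs), 0.97)
#' @export
derive_threshold <- function(model, x_species = 0.97,
                             level = model$level) {
  stopifnot(inherits(model, "coxl_calibration"))
  if (model$n_pairs < 3L) .stopf("model has fewer than 3 pairs")
  x_species <- .check_number(x_species, "x_species", 0, 1,
                             strict_lower = TRUE)
  raw <- model$intercept + model$slope * x_species
  thr <- min(max(raw, 0), 1)
  structure(list(threshold = thr,
                 halfwidth = .pred_halfwidth(model, x_species, level),
                 x_species = x_species, level = level,
                 clamped = !identical(raw, thr)),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf(
    "Species-level similarity threshold: %.3f +/- %.3f (at 16S = %.2f, %d%% PI)%s\n",
    x$threshold, x$halfwidth, x$x_species, round(100 * x$level),
    if (x$clamped) " [clamped]" else ""))
  invisible(x)
}
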