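# Constrained ordination of Hellinger-transformed OTU tables on
# standardized soil variables: redundancy analysis written out from its
# algebra (multivariate OLS projection + eigen-decomposition), permutation
# testing, Blanchet-style forward selection and VIF screening.

#' Hellinger transformation
#'
#' `y'_ij = sqrt(y_ij / row_sum_i)`: square root of the relative abundance
#' per station, which makes Euclidean distances between stations
#' ecologically meaningful for count data and damps the weight of rare
#' OTUs.
#'
#' @param counts non-negative matrix with stations in rows, or a
#'   `coxl_otu_table` (transposed internally so stations are rows).
#' @return transformed matrix; each row has unit sum of squares.
#' @examples
#' hellinger(matrix(c(1, 1, 2), 1))
#' @export
hellinger <- function(counts) {
  if (inherits(counts, "coxl_otu_table")) counts <- t(counts$counts)
  counts <- as.matrix(counts)
  if (any(counts < 0)) .stopf("counts must be non-negative")
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    bad <- rownames(counts)[rs == 0]
    .stopf("zero row sum for station(s): %s",
           paste(if (is.null(bad)) which(rs == 0) else bad, collapse = ", "))
  }
  sqrt(sweep(counts, 1L, rs, "/"))
}

#' Standardize environmental variables to z-scores
#'
#' @param env data frame or matrix of station variables; non-numeric
#'   columns (e.g. station ids) are dropped.
#' @return numeric matrix with each column centered to mean 0, SD 1.
#' @export
standardize_env <- function(env) {
  if (is.data.frame(env))
    env <- env[vapply(env, is.numeric, logical(1))]
  X <- as.matrix(env)
  sds <- apply(X, 2L, sd)
  if (any(sds == 0))
    .stopf("constant environmental column(s): %s",
           paste(colnames(X)[sds == 0], collapse = ", "))
  scale(X)
}

#' Collapse exactly duplicated OTU profiles
#'
#' Collinear OTU columns (identical profiles across stations) carry no
#' independent information in an ordination; one representative per
#' duplicate group is kept, with a mapping report.
#'
#' @param Y matrix, stations x OTUs.
#' @return list with `Y` (deduplicated) and `mapping` (data frame `otu`,
#'   `kept_as`).
#' @export
collapse_duplicate_otus <- function(Y) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("OTU%03d", seq_len(ncol(Y)))
  key <- apply(Y, 2L, paste, collapse = "\r")
  kept <- !duplicated(key)
  mapping <- data.frame(otu = colnames(Y),
                        kept_as = colnames(Y)[kept][match(key, key[kept])],
                        stringsAsFactors = FALSE)
  list(Y = Y[, kept, drop = FALSE], mapping = mapping)
}

# Common preparation: centered response, standardized explanatory matrix,
# QR of X with a rank check naming offending columns.
.prep_rda <- function(Y, X, standardize = TRUE) {
  Y <- as.matrix(Y)
  X <- if (standardize) standardize_env(X) else
    as.matrix(if (is.data.frame(X))
      X[vapply(X, is.numeric, logical(1))] else X)
  if (nrow(Y) != nrow(X))
    .stopf("Y (%d rows) and X (%d rows) are not aligned", nrow(Y), nrow(X))
  n <- nrow(Y)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrx <- qr(Xc)
  if (qrx$rank < ncol(Xc)) {
    bad <- colnames(Xc)[qrx$pivot[seq.int(qrx$rank + 1L, ncol(Xc))]]
    .stopf("rank-deficient explanatory matrix; offending column(s): %s",
           paste(bad, collapse = ", "))
  }
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  list(Yc = Yc, X = X, Xc = Xc, qrx = qrx, n = n, m = qrx$rank)
}

.rda_ssq <- function(Yc, qrx) {
  fit <- qr.fitted(qrx, Yc)
  c(ss_fit = sum(fit^2), ss_res = sum((Yc - fit)^2))
}

.pseudo_f <- function(Yc, qrx, n, m) {
  ss <- .rda_ssq(Yc, qrx)
  f <- (ss[["ss_fit"]] / m) / (ss[["ss_res"]] / (n - m - 1))
  if (is.nan(f)) 0 else f   # constant response: no variance either way
}

#' Redundancy analysis of an OTU matrix on environmental variables
#'
#' RDA from its algebra: the (column-centered) response matrix is projected
#' onto the standardized explanatory variables by multivariate OLS; the
#' eigen-decomposition of the fitted values' covariance gives the
#' constrained axes, that of the residuals the unconstrained axes. The
#' constrained proportion is constrained inertia over total inertia.
#' Significance is assessed by free permutation of response rows.
#'
#' @param Y response matrix, stations x OTUs (typically [hellinger()]
#'   output).
#' @param X explanatory variables, stations x variables (standardized to
#'   z-scores internally unless `standardize = FALSE`).
#' @param n_perm permutations for the significance test (0 to skip).
#' @param seed integer seed for the permutations.
#' @param collapse_duplicates collapse exactly duplicated OTU columns
#'   before the analysis (mapping kept in the result).
#' @param standardize standardize `X` to z-scores.
#' @param scaling triplot scaling for scores: 2 (correlation, default)
#'   or 1 (distance).
#' @return object of class `coxl_rda`: eigenvalues (constrained and
#'   unconstrained), `constrained_proportion`, per-axis proportions,
#'   `pseudo_f`, `permutation_p`, score matrices (`site_scores`,
#'   `fitted_site_scores`, `species_scores`, `biplot_scores`), `vif`, and
#'   the duplicate-OTU `mapping`.
#' @examples
#' sim <- simulate_community_env(10, 9, noise_sd = 0, seed = 1)
#' fit <- rda_fit(sim$abundance, sim$env[c("water", "co_uptake")],
#'                n_perm = 99, seed = 1)
#' fit$constrained_proportion  # 1 at zero noise
#' @export
rda_fit <- function(Y, X, n_perm = 999L, seed = 1L,
                    collapse_duplicates = TRUE, standardize = TRUE,
                    scaling = 2) {
  mapping <- NULL
  if (collapse_duplicates) {
    dd <- collapse_duplicate_otus(Y)
    Y <- dd$Y
    mapping <- dd$mapping
  }
  pr <- .prep_rda(Y, X, standardize)
  if (pr$n <= pr$m + 1L)
    .stopf("need more stations (%d) than variables + 1 (%d)",
           pr$n, pr$m + 1L)
  Yfit <- qr.fitted(pr$qrx, pr$Yc)
  Yres <- pr$Yc - Yfit
  n1 <- pr$n - 1
  eig_c <- eigen(crossprod(Yfit) / n1, symmetric = TRUE)
  eig_u <- eigen(crossprod(Yres) / n1, symmetric = TRUE)
  tol <- max(eig_c$values[1L], eig_u$values[1L], 0) * 1e-10
  kc <- sum(eig_c$values > tol)
  ku <- sum(eig_u$values > tol)
  lam_c <- eig_c$values[seq_len(kc)]
  lam_u <- eig_u$values[seq_len(ku)]
  total <- sum(diag(crossprod(pr$Yc))) / n1

  V <- eig_c$vectors[, seq_len(kc), drop = FALSE]
  rownames(V) <- colnames(Y)
  colnames(V) <- sprintf("RDA%d", seq_len(kc))
  site_raw <- pr$Yc %*% V
  lc_raw <- Yfit %*% V
  if (scaling == 2) {
    sc <- sqrt(lam_c / total)
    species <- V %*% diag(sc * sqrt(total), kc)
    sites <- sweep(site_raw, 2L, sqrt(lam_c * n1), "/") * sqrt(total)
    lc <- sweep(lc_raw, 2L, sqrt(lam_c * n1), "/") * sqrt(total)
  } else {
    species <- V
    sites <- site_raw
    lc <- lc_raw
  }
  biplot <- cor(pr$X, lc_raw)
  colnames(biplot) <- colnames(V)

  perm <- if (n_perm > 0)
    rda_permutation_test(Y, X, n_perm = n_perm, seed = seed,
                         standardize = standardize)
  else list(p_value = NA_real_, f_obs = .pseudo_f(pr$Yc, pr$qrx, pr$n, pr$m))

  structure(list(
    eigenvalues = lam_c, unconstrained_eigenvalues = lam_u,
    total_inertia = total,
    constrained_proportion = sum(lam_c) / total,
    axis_proportions = c(lam_c, lam_u) / total,
    axis_proportions_constrained = lam_c / sum(lam_c),
    pseudo_f = perm$f_obs, permutation_p = perm$p_value,
    n_permutations = if (n_perm > 0) n_perm else 0L,
    site_scores = sites, fitted_site_scores = lc,
    species_scores = species, biplot_scores = biplot,
    vif = vif_scores(pr$X), mapping = mapping,
    n = pr$n, m = pr$m, scaling = scaling),
    class = "coxl_rda")
}

#' @export
print.coxl_rda <- function(x, ...) {
  cat("Redundancy analysis:", x$n, "stations,", x$m, "constrained df\n")
  cat(sprintf("  constrained proportion: %.3f (pseudo-F = %.3f%s)\n",
              x$constrained_proportion, x$pseudo_f,
              if (!is.na(x$permutation_p))
                sprintf(", P = %.4g [%d perms]", x$permutation_p,
                        x$n_permutations) else ""))
  k <- min(2L, length(x$eigenvalues))
  cat(sprintf("  first %d axes: %.1f%% of total variance\n", k,
              100 * sum(x$axis_proportions[seq_len(k)])))
  invisible(x)
}

#' @export
summary.coxl_rda <- function(object, ...) {
  print(object)
  cat("  eigenvalues (constrained):",
      paste(signif(object$eigenvalues, 4), collapse = " "), "\n")
  cat("  VIF:", paste(sprintf("%s=%.2f", names(object$vif), object$vif),
                      collapse = " "), "\n")
  invisible(object)
}

#' Permutation test for the RDA constrained fraction
#'
#' Pseudo-F of the constrained model under free permutation of response
#' rows, with `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @inheritParams rda_fit
#' @param n_perm number of permutations (>= 99).
#' @return list with `p_value`, `f_obs`, `f_perm` (vector).
#' @export
rda_permutation_test <- function(Y, X, n_perm = 999L, seed = 1L,
                                 standardize = TRUE) {
  n_perm <- .check_count(n_perm, "n_perm", min = 99L)
  pr <- .prep_rda(Y, X, standardize)
  f_obs <- .pseudo_f(pr$Yc, pr$qrx, pr$n, pr$m)
  f_perm <- .with_scenario_seed(seed, "rda_perm", {
    vapply(seq_len(n_perm), function(i) {
      .pseudo_f(pr$Yc[sample.int(pr$n), , drop = FALSE],
                pr$qrx, pr$n, pr$m)
    }, numeric(1))
  })
  list(p_value = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
       f_obs = f_obs, f_perm = f_perm)
}

#' Variance inflation factors
#'
#' @param X numeric matrix or data frame of explanatory variables.
#' @param warn_above threshold above which a collinearity warning is
#'   emitted (10 by convention).
#' @return named vector of VIFs (`Inf` for perfectly collinear sets).
#' @export
vif_scores <- function(X, warn_above = 10) {
  X <- as.matrix(if (is.data.frame(X))
    X[vapply(X, is.numeric, logical(1))] else X)
  if (ncol(X) < 2L) return(setNames(rep(1, ncol(X)), colnames(X)))
  R <- cor(X)
  v <- tryCatch(diag(solve(R)), error = function(e)
    rep(Inf, ncol(X)))
  v <- setNames(as.numeric(v), colnames(X))
  if (any(v > warn_above))
    .warnf("high variance inflation (> %g) for: %s", warn_above,
           paste(names(v)[v > warn_above], collapse = ", "))
  v
}

#' Forward selection of environmental variables (double stopping rule)
#'
#' Blanchet-style forward selection: at each step the candidate giving the
#' largest gain in explained variance is tested by permutation (partial
#' pseudo-F given the variables already selected); selection stops when the
#' best candidate is non-significant at `alpha` or when the adjusted R2 of
#' the selected model would exceed that of the full candidate model
#' (the double stopping rule that guards against overfitting drift).
#'
#' The ceiling comparison carries a small tolerance `ceiling_slack`: when
#' the remaining candidates are uninformative, the adjusted R2 of the
#' selected model and of the full model are unbiased estimates of the same
#' quantity, so an exact comparison reduces to a coin flip on sampling
#' noise; the tolerance keeps genuinely explanatory variables from being
#' dropped on that noise while still vetoing models that clearly
#' out-explain the full set.
#'
#' @param Y response matrix, stations x OTUs.
#' @param X_candidates data frame/matrix of candidate variables (>= 1).
#' @param alpha significance level for entry.
#' @param n_perm permutations per entry test.
#' @param seed integer seed.
#' @param ceiling_slack tolerance on the adjusted-R2 ceiling.
#' @return list with `selected` (character vector, possibly empty), `vif`
#'   (of the selected set), `adj_r2` (selected model), `adj_r2_full`, and
#'   `trace` (data frame of tested steps).
#' @export
forward_select_rda <- function(Y, X_candidates, alpha = 0.05,
                               n_perm = 199L, seed = 1L,
                               ceiling_slack = 0.01) {
  Xall <- standardize_env(X_candidates)
  if (ncol(Xall) < 1L) .stopf("need at least one candidate variable")
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  ss_tot <- sum(Yc^2)
  adj_r2 <- function(cols) {
    if (length(cols) == 0L) return(0)
    qrx <- qr(Xall[, cols, drop = FALSE])
    r2 <- .rda_ssq(Yc, qrx)[["ss_fit"]] / ss_tot
    1 - (1 - r2) * (n - 1) / (n - length(cols) - 1)
  }
  full_cols <- colnames(Xall)
  adj_full <- adj_r2(full_cols)

  selected <- character()
  trace <- data.frame(step = integer(), candidate = character(),
                      p_value = numeric(), adj_r2 = numeric(),
                      accepted = logical(), stringsAsFactors = FALSE)
  .with_scenario_seed(seed, "forward_select", {
    step <- 0L
    repeat {
      remaining <- setdiff(full_cols, selected)
      if (length(remaining) == 0L) break
      ss_sel <- if (length(selected))
        .rda_ssq(Yc, qr(Xall[, selected, drop = FALSE]))[["ss_fit"]] else 0
      gains <- vapply(remaining, function(v) {
        .rda_ssq(Yc, qr(Xall[, c(selected, v), drop = FALSE]))[["ss_fit"]] -
          ss_sel
      }, numeric(1))
      best <- remaining[which.max(gains)]
      cols <- c(selected, best)
      m <- length(cols)
      qr_new <- qr(Xall[, cols, drop = FALSE])
      qr_old <- if (length(selected))
        qr(Xall[, selected, drop = FALSE]) else NULL
      f_part <- function(Yp) {
        ss_new <- .rda_ssq(Yp, qr_new)
        ss_old <- if (is.null(qr_old)) 0 else
          .rda_ssq(Yp, qr_old)[["ss_fit"]]
        (ss_new[["ss_fit"]] - ss_old) / (ss_new[["ss_res"]] / (n - m - 1))
      }
      f_obs <- f_part(Yc)
      f_perm <- vapply(seq_len(n_perm), function(i)
        f_part(Yc[sample.int(n), , drop = FALSE]), numeric(1))
      p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
      a2 <- adj_r2(cols)
      step <- step + 1L
      accept <- p <= alpha && a2 <= adj_full + ceiling_slack
      trace <- rbind(trace, data.frame(
        step = step, candidate = best, p_value = p, adj_r2 = a2,
        accepted = accept, stringsAsFactors = FALSE))
      if (!accept) break
      selected <- cols
    }
  })
  vif <- if (length(selected))
    vif_scores(Xall[, selected, drop = FALSE]) else numeric()
  list(selected = selected, vif = vif, adj_r2 = adj_r2(selected),
       adj_r2_full = adj_full, trace = trace)
}
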