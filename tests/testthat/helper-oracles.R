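# Independent brute-force oracles, deliberately written along different
# routes than the package implementation.

# Complete-linkage agglomeration by direct O(n^3) search over cluster
# pairs: merge the pair of clusters with the smallest furthest-neighbour
# distance while it does not exceed 1 - cutoff (ties: lowest index pair).
oracle_complete_linkage <- function(S, cutoff) {
  D <- 1 - S
  clusters <- as.list(seq_len(nrow(S)))
  repeat {
    if (length(clusters) == 1L) break
    best <- NULL
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq.int(i + 1L, length(clusters))) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best_d - 1e-15) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    if (best_d > 1 - cutoff + 1e-15) break
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  clusters
}

# Canonical representation of a partition of 1..n for comparison.
partition_key <- function(groups) {
  sets <- lapply(groups, function(g) sort(g))
  paste(sort(vapply(sets, paste, character(1), collapse = ",")),
        collapse = ";")
}

membership_to_partition <- function(membership) {
  unname(split(seq_along(membership), membership))
}

# OLS slope/intercept by explicit normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# RDA eigenvalues through an explicit hat matrix and full decomposition.
oracle_rda_eigen <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- scale(as.matrix(X))
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  H <- Xc %*% solve(crossprod(Xc)) %*% t(Xc)
  Yfit <- H %*% Yc
  ev <- eigen(crossprod(Yfit) / (nrow(Y) - 1), symmetric = TRUE)$values
  ev[ev > max(ev) * 1e-9]
}

# Proportion of differing sites with pairwise deletion, recounted
# column-by-column over string splits.
oracle_pairwise_d <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  miss <- c("-", ".", "N", "n")
  used <- 0L
  diff <- 0L
  for (k in seq_along(va)) {
    if (va[k] %in% miss || vb[k] %in% miss) next
    used <- used + 1L
    if (va[k] != vb[k]) diff <- diff + 1L
  }
  diff / used
}

# A fixed random similarity matrix (symmetric, unit diagonal) for cluster
# oracle tests.
random_similarity <- function(n, seed) {
  set.seed(seed)
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0, 0.4)
  D <- D + t(D)
  S <- 1 - D
  dimnames(S) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  S
}
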