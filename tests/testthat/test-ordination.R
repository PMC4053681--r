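# Hellinger transformation, RDA algebra, permutation tests, forward
# selection and VIF screening.

test_that("Hellinger transformation matches its defining formula", {
  expect_equal(as.numeric(hellinger(matrix(c(1, 1, 2), 1))),
               c(0.5, 0.5, sqrt(0.5)), tolerance = 1e-12)
  expect_equal(as.numeric(hellinger(matrix(rep(3, 4), 1))), rep(0.5, 4))

  set.seed(1)
  Y <- matrix(rpois(60, 5) + 1L, 6, 10)
  H <- hellinger(Y)
  expect_equal(unname(rowSums(H^2)), rep(1, 6), tolerance = 1e-12)
  # idempotent only once rows are unit vectors under this normalization
  expect_equal(hellinger(H^2), H, tolerance = 1e-12)

  Yz <- Y
  Yz[2, ] <- 0
  rownames(Yz) <- paste0("st", 1:6)
  expect_error(hellinger(Yz), "st2")
})

test_that("environmental standardization yields exact z-scores", {
  sim <- simulate_community_env(8, 9, seed = 3)
  X <- standardize_env(sim$env)
  expect_equal(unname(colMeans(X)), rep(0, ncol(X)), tolerance = 1e-12)
  expect_equal(unname(apply(X, 2, sd)), rep(1, ncol(X)), tolerance = 1e-12)
  expect_false("station" %in% colnames(X))
})

test_that("RDA equals the explicit hat-matrix oracle and vegan", {
  sim <- simulate_community_env(15, 9, env_effect = 2, noise_sd = 0.5,
                                seed = 4)
  X <- sim$env[c("water", "co_uptake")]
  fit <- rda_fit(sim$abundance, X, n_perm = 0)
  ref <- oracle_rda_eigen(sim$abundance, X)
  expect_equal(fit$eigenvalues, ref, tolerance = 1e-8)
  expect_equal(sum(fit$axis_proportions), 1, tolerance = 1e-9)

  skip_if_not_installed("vegan")
  v <- vegan::rda(sim$abundance ~ ., data = as.data.frame(scale(X)))
  expect_equal(unname(fit$eigenvalues), unname(v$CCA$eig),
               tolerance = 1e-8)
  expect_equal(fit$constrained_proportion,
               sum(v$CCA$eig) / v$tot.chi, tolerance = 1e-10)
})

test_that("constrained proportion hits its analytic limits", {
  noiseless <- simulate_community_env(10, 9, env_effect = 2, noise_sd = 0,
                                      seed = 5)
  f1 <- rda_fit(noiseless$abundance,
                noiseless$env[c("water", "co_uptake")], n_perm = 0)
  expect_equal(f1$constrained_proportion, 1, tolerance = 1e-10)

  # pure noise: E[proportion] ~ p/(n-1); check it stays small
  set.seed(9)
  props <- replicate(30, {
    Y <- matrix(rnorm(9 * 12), 9, 12)
    X <- data.frame(a = rnorm(9), b = rnorm(9))
    rda_fit(Y, X, n_perm = 0)$constrained_proportion
  })
  expect_equal(mean(props), 2 / 8, tolerance = 0.1)
})

test_that("RDA results are invariant to OTU and station ordering", {
  sim <- simulate_community_env(12, 9, env_effect = 2, noise_sd = 0.4,
                                seed = 7)
  X <- sim$env[c("water", "co_uptake")]
  base <- rda_fit(sim$abundance, X, n_perm = 0)
  set.seed(1)
  oc <- sample(ncol(sim$abundance))
  rc <- sample(nrow(sim$abundance))
  perm <- rda_fit(sim$abundance[rc, oc], X[rc, ], n_perm = 0)
  expect_equal(perm$constrained_proportion, base$constrained_proportion,
               tolerance = 1e-10)
  expect_equal(perm$eigenvalues, base$eigenvalues, tolerance = 1e-10)
})

test_that("rank-deficient explanatory matrices are rejected by name", {
  sim <- simulate_community_env(8, 9, seed = 2)
  X <- sim$env[c("water", "co_uptake")]
  X$dup <- X$water
  expect_error(suppressWarnings(rda_fit(sim$abundance, X, n_perm = 0)),
               "dup|water")
})

test_that("permutation test flags planted structure and degenerate ties", {
  strong <- simulate_community_env(12, 9, env_effect = 3, noise_sd = 0.2,
                                   seed = 11)
  pt <- rda_permutation_test(strong$abundance,
                             strong$env[c("water", "co_uptake")],
                             n_perm = 999, seed = 1)
  expect_lte(pt$p_value, 0.01)

  # constant response: every permutation ties, p = 1
  Yc <- matrix(5, 9, 4)
  X <- data.frame(a = rnorm(9), b = rnorm(9))
  ptc <- rda_permutation_test(Yc, X, n_perm = 99, seed = 1)
  expect_identical(ptc$p_value, 1)

  expect_error(rda_permutation_test(Yc, X, n_perm = 50), "n_perm")
})

test_that("forward selection recovers the planted causal pair", {
  # enough stations that the full-model adjusted-R2 ceiling of the double
  # stopping rule does not bind before the second causal variable enters
  sim <- simulate_community_env(15, 30, env_effect = 3, noise_sd = 0.3,
                                seed = 17)
  set.seed(17)
  cand <- data.frame(water = sim$env$water, co_uptake = sim$env$co_uptake,
                     n1 = rnorm(30), n2 = rnorm(30), n3 = rnorm(30))
  sel <- forward_select_rda(sim$abundance, cand, alpha = 0.05,
                            n_perm = 199, seed = 1)
  expect_setequal(sel$selected, c("water", "co_uptake"))
  expect_true(all(sel$vif < 10))
})

test_that("causal-pair recovery holds across many simulated panels", {
  hits <- 0L
  n_rep <- 100L
  for (s in seq_len(n_rep)) {
    sim <- simulate_community_env(12, 30, env_effect = 3, noise_sd = 0.3,
                                  seed = 1000 + s)
    set.seed(s)
    cand <- data.frame(water = sim$env$water,
                       co_uptake = sim$env$co_uptake,
                       n1 = rnorm(30), n2 = rnorm(30), n3 = rnorm(30))
    sel <- forward_select_rda(sim$abundance, cand, alpha = 0.01,
                              n_perm = 199, seed = s)
    if (setequal(sel$selected, c("water", "co_uptake"))) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("collinear candidates: one of a duplicated pair enters, VIF warns", {
  sim <- simulate_community_env(10, 9, env_effect = 3, noise_sd = 0.3,
                                seed = 23)
  X <- data.frame(water = sim$env$water,
                  water_copy = sim$env$water + rnorm(9, 0, 1e-8),
                  co_uptake = sim$env$co_uptake)
  sel <- forward_select_rda(sim$abundance, X, alpha = 0.05, n_perm = 199,
                            seed = 2)
  expect_lte(sum(c("water", "water_copy") %in% sel$selected), 1L)
  expect_warning(vif_scores(scale(X[c("water", "water_copy")])),
                 "variance inflation")
})

test_that("the survey-like configuration retains water and CO uptake", {
  # full soil variable set with its built-in collinearity structure; the
  # station count is raised so the 7-candidate full model keeps enough
  # residual df for the adjusted-R2 ceiling to be meaningful
  sim <- simulate_community_env(15, 24, env_effect = 3, noise_sd = 0.3,
                                seed = 29)
  cand <- sim$env[c("water", "co_uptake", "pH", "C", "N", "P", "K")]
  sel <- forward_select_rda(sim$abundance, cand, alpha = 0.05,
                            n_perm = 199, seed = 3)
  expect_true(all(c("water", "co_uptake") %in% sel$selected))
  expect_true(all(sel$vif < 10))
})

test_that("duplicate OTU profiles are collapsed with a mapping report", {
  sim <- simulate_community_env(8, 9, env_effect = 2, noise_sd = 0.3,
                                seed = 31)
  Y <- cbind(sim$abundance, dupA = sim$abundance[, 1])
  fit <- rda_fit(Y, sim$env[c("water", "co_uptake")], n_perm = 0)
  expect_identical(nrow(fit$species_scores), 8L)
  expect_identical(
    fit$mapping$kept_as[fit$mapping$otu == "dupA"],
    colnames(sim$abundance)[1])
})
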