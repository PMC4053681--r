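# Synthetic-data generators. Every generator returns its inputs together
# with a `sim_truth` record of the planted parameters, so downstream stages
# have a parameter-recovery test surface. Each call runs on its own RNG
# stream derived from (seed, scenario_id) and restores the caller's RNG
# state, so adding scenarios never perturbs existing fixtures.

new_sim_truth <- function(scenario_id, parameters, seed) {
  stopifnot(all(vapply(parameters, function(p)
    all(is.finite(unlist(p))), logical(1))))
  structure(list(scenario_id = scenario_id, parameters = parameters,
                 seed = as.integer(seed)),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulation truth [", x$scenario_id, "], seed ", x$seed, "\n", sep = "")
  for (nm in names(x$parameters)) {
    v <- x$parameters[[nm]]
    if (length(v) <= 6)
      cat("  ", nm, ": ", paste(signif(unlist(v), 5), collapse = " "),
          "\n", sep = "")
    else
      cat("  ", nm, ": <", length(v), " values>\n", sep = "")
  }
  invisible(x)
}

.BASES <- c("A", "C", "G", "T")

# Mutate exactly `m` distinct random positions of an integer-coded sequence
# (1..4), each to a uniformly chosen different base.
.mutate_sites <- function(seq_int, m) {
  if (m == 0L) return(seq_int)
  pos <- sample.int(length(seq_int), m)
  seq_int[pos] <- ((seq_int[pos] - 1L + sample.int(3L, m, replace = TRUE)) %% 4L) + 1L
  seq_int
}

.int_to_seq <- function(x) paste(.BASES[x], collapse = "")

#' Simulate a paired 16S/coxL genome panel with a planted similarity relation
#'
#' Generates `n_taxa` 16S rRNA-like and `n_taxa` coxL-like sequences mutated
#' from common ancestors so that across all `choose(n_taxa, 2)` pairs the
#' coxL similarity tracks `intercept + slope * s_16S` plus noise. Each taxon
#' carries a per-gene substitution load; the loads for coxL are solved by
#' least squares on the additive `log(1 - 4/3 p)` scale so that the planted
#' linear relation holds in expectation for the raw similarity scores
#' `S = 1 - D`. No indels are introduced, so alignment-free identity holds.
#'
#' @param n_taxa number of taxa (>= 3).
#' @param slope,intercept planted linear relation between coxL and 16S
#'   pairwise similarity scores.
#' @param noise_sd standard deviation of per-pair Gaussian noise on the
#'   target coxL similarity, in `[0, 0.2)`. Pair-level noise is realized
#'   through the per-taxon loads plus site sampling, so the refit residual
#'   spread is of this order but not identical.
#' @param seed integer seed for the scenario's private RNG stream.
#' @param seq_length alignment length for both genes (no gaps).
#' @param s16_range range of target pairwise 16S similarities.
#' @param scenario_id label stored in the truth record.
#' @return list with `s16_seqs`, `coxl_seqs` (named character vectors of
#'   aligned sequences), `pairs` (data frame of realized
#'   [similarity pairs][build_similarity_pairs]), the two realized similarity
#'   matrices, and `truth`.
#' @examples
#' sim <- simulate_gene_pairs(10, slope = 0.8, intercept = 0.15,
#'                            noise_sd = 0.02, seed = 1)
#' nrow(sim$pairs)  # choose(10, 2) = 45
#' @export
simulate_gene_pairs <- function(n_taxa, slope, intercept, noise_sd, seed,
                                seq_length = 1200,
                                s16_range = c(0.78, 0.98),
                                scenario_id = "gene_pairs") {
  n_taxa <- .check_count(n_taxa, "n_taxa", min = 3L)
  noise_sd <- .check_number(noise_sd, "noise_sd", 0, 0.2, strict_upper = TRUE)
  slope <- .check_number(slope, "slope")
  intercept <- .check_number(intercept, "intercept")
  seq_length <- .check_count(seq_length, "seq_length", min = 100L)
  stopifnot(length(s16_range) == 2L, s16_range[1] < s16_range[2],
            s16_range[1] > 0, s16_range[2] <= 1)
  # Reject planted relations that push coxL similarity outside [0, 1]
  # before any noise is added.
  y_ends <- intercept + slope * s16_range
  if (any(y_ends < 0 | y_ends > 1))
    .stopf(paste("degenerate slope/intercept: planted coxL similarity",
                 "spans [%0.3f, %0.3f], outside [0, 1]"),
           min(y_ends), max(y_ends))

  .with_scenario_seed(seed, scenario_id, {
    taxa <- sprintf("t%03d", seq_len(n_taxa))
    # Per-taxon 16S substitution loads: pairwise divergence is ~ additive.
    q <- runif(n_taxa, (1 - s16_range[2]) / 2, (1 - s16_range[1]) / 2)
    anc16 <- sample.int(4L, seq_length, replace = TRUE)
    s16_int <- lapply(q, function(qi)
      .mutate_sites(anc16, round(qi * seq_length)))
    s16_seqs <- setNames(vapply(s16_int, .int_to_seq, character(1)), taxa)
    s16_mat <- pairwise_similarity(s16_seqs)

    # Per-pair coxL similarity targets from the realized 16S similarities.
    idx <- which(upper.tri(s16_mat), arr.ind = TRUE)
    x <- s16_mat[idx]
    y <- intercept + slope * x + rnorm(length(x), 0, noise_sd)
    y <- pmin(pmax(y, 0), 1)
    p <- 1 - y                      # target raw difference proportion
    if (any(p >= 0.745))
      .stopf("target coxL divergence %.3f too large for the site model",
             max(p))
    # Solve per-taxon loads on the additive log(1 - 4/3 p) scale:
    # P(differ | loads a_i, a_j) = a_i + a_j - 4/3 a_i a_j, hence
    # log(1 - 4/3 P) = log(1 - 4/3 a_i) + log(1 - 4/3 a_j).
    z <- log(1 - (4 / 3) * p)
    A <- matrix(0, nrow(idx), n_taxa)
    A[cbind(seq_len(nrow(idx)), idx[, 1])] <- 1
    A[cbind(seq_len(nrow(idx)), idx[, 2])] <- 1
    l <- lm.fit(A, z)$coefficients
    a <- pmin(pmax((3 / 4) * (1 - exp(l)), 0), 0.7)

    anccox <- sample.int(4L, seq_length, replace = TRUE)
    cox_int <- lapply(a, function(ai)
      .mutate_sites(anccox, round(ai * seq_length)))
    coxl_seqs <- setNames(vapply(cox_int, .int_to_seq, character(1)), taxa)
    cox_mat <- pairwise_similarity(coxl_seqs)

    pairs <- build_similarity_pairs(s16_mat, cox_mat)
    truth <- new_sim_truth(scenario_id, list(
      true_slope = slope, true_intercept = intercept, noise_sd = noise_sd,
      n_taxa = n_taxa, seq_length = seq_length, n_pairs = nrow(pairs)),
      seed)
    list(s16_seqs = s16_seqs, coxl_seqs = coxl_seqs, pairs = pairs,
         s16_matrix = s16_mat, scoxl_matrix = cox_mat, truth = truth)
  })
}

# Reverse codon table built once from the standard genetic code, stops
# excluded so planted reading frames are stop-free.
.codons_by_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
})

.reverse_translate <- function(aa) {
  codons <- vapply(strsplit(aa, "")[[1]], function(a) {
    opts <- .codons_by_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

.MOTIF_PATTERNS <- c(TYPE_II = "AYRGAGR", ATYPICAL_II = "PYRGAGR",
                     TYPE_I = "AY[A-Z]CSFR")
.MOTIF_CLASSES <- c("TYPE_I", "TYPE_II", "ATYPICAL_II", "UNCLASSIFIED")

# Amino-acid alphabet without stop; 'P' and motif residues allowed.
.AA20 <- setdiff(names(.codons_by_aa), "*")

# Largest-remainder apportionment of n among fractions (deterministic).
.apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
  }
  as.integer(base)
}

.random_aa_background <- function(len, forbid = .MOTIF_PATTERNS) {
  repeat {
    aa <- paste(sample(.AA20, len, replace = TRUE), collapse = "")
    if (!any(vapply(forbid, function(p) grepl(p, aa), logical(1))))
      return(aa)
  }
}

#' Simulate a coxL clone library with planted active-site signatures
#'
#' Each clone is a stop-free coding sequence carrying exactly one planted
#' seven-residue active-site signature (type I `AY.CSFR` with a concrete
#' wildcard residue, type II `AYRGAGR`, atypical type II `PYRGAGR`), or none
#' for the `UNCLASSIFIED` fraction, embedded at a random in-frame position.
#' Class counts follow `class_mix` exactly (largest-remainder apportionment).
#' With `frame_shift = TRUE`, clones receive random 0/1/2-base frame offsets
#' and random reverse-complement orientation, so the signature is only
#' recoverable by six-frame translation.
#'
#' @param n_clones number of clones (> 0).
#' @param class_mix named fractions over
#'   `TYPE_I`, `TYPE_II`, `ATYPICAL_II`, `UNCLASSIFIED`; must sum to 1.
#' @param frame_shift randomize reading frame and orientation.
#' @param seed integer seed.
#' @param aa_length clone length in amino acids before reverse translation.
#' @param sample_id sample label used in the emitted sample map.
#' @param scenario_id label stored in the truth record.
#' @return list with `sequences` (named nucleotide character vector),
#'   `sample_map` (data frame `seq_id`, `sample_id`), `classes` (per-clone
#'   planted class/frame/offset table) and `truth` (planted class counts).
#' @examples
#' lib <- simulate_clone_library(24, c(TYPE_I = 1), seed = 1)
#' length(lib$sequences)
#' @export
simulate_clone_library <- function(n_clones, class_mix, frame_shift = FALSE,
                                   seed = 1L, aa_length = 90L,
                                   sample_id = "S1",
                                   scenario_id = "clone_library") {
  n_clones <- .check_count(n_clones, "n_clones", min = 1L)
  aa_length <- .check_count(aa_length, "aa_length", min = 30L)
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% .MOTIF_CLASSES))
    .stopf("class_mix must be named with classes among: %s",
           paste(.MOTIF_CLASSES, collapse = ", "))
  if (abs(sum(class_mix) - 1) > 1e-9)
    .stopf("class_mix fractions must sum to 1 (got %.10f)", sum(class_mix))

  .with_scenario_seed(seed, scenario_id, {
    counts <- setNames(rep(0L, length(.MOTIF_CLASSES)), .MOTIF_CLASSES)
    counts[names(class_mix)] <- .apportion(n_clones, as.numeric(class_mix))
    classes <- rep(names(counts), counts)
    classes <- classes[sample.int(length(classes))]  # shuffle order

    ids <- sprintf("clone%04d", seq_len(n_clones))
    seqs <- character(n_clones)
    rec <- data.frame(seq_id = ids, class = classes,
                      frame_offset = 0L, revcomp = FALSE,
                      motif = NA_character_, motif_start_aa = NA_integer_,
                      stringsAsFactors = FALSE)
    for (i in seq_len(n_clones)) {
      aa <- .random_aa_background(aa_length)
      cls <- classes[i]
      if (cls != "UNCLASSIFIED") {
        motif <- switch(cls,
          TYPE_I = paste0("AY", sample(setdiff(.AA20, c("R")), 1L), "CSFR"),
          TYPE_II = "AYRGAGR",
          ATYPICAL_II = "PYRGAGR")
        pos <- sample.int(aa_length - 7L + 1L, 1L)
        aa <- paste0(substr(aa, 1, pos - 1), motif,
                     substr(aa, pos + 7, aa_length))
        rec$motif[i] <- motif
        rec$motif_start_aa[i] <- pos - 1L  # 0-based
      }
      nt <- .reverse_translate(aa)
      if (frame_shift) {
        off <- sample(0:2, 1L)
        if (off > 0)
          nt <- paste0(paste(sample(.BASES, off, replace = TRUE),
                             collapse = ""), nt)
        rec$frame_offset[i] <- off
        if (runif(1) < 0.5) {
          nt <- .revcomp_chr(nt)
          rec$revcomp[i] <- TRUE
        }
      }
      seqs[i] <- nt
    }
    names(seqs) <- ids
    truth <- new_sim_truth(scenario_id, list(
      n_clones = n_clones, counts = as.list(counts),
      frame_shift = as.numeric(frame_shift)), seed)
    list(sequences = seqs,
         sample_map = data.frame(seq_id = ids, sample_id = sample_id,
                                 stringsAsFactors = FALSE),
         classes = rec, truth = truth)
  })
}

.revcomp_chr <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(comp, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
}

#' Simulate a flask headspace CO decay time series
#'
#' Headspace CO mixing ratio follows `c(t) = c0 exp(-k t) (1 + e)` with
#' multiplicative Gaussian noise `e ~ N(0, cv)`, matching the relative (<5%)
#' reproducibility of reduced-gas analyzers. Values below the gas
#' chromatographic detection floor are flagged censored.
#'
#' @param k_per_h true first-order uptake rate constant (1/h, >= 0).
#' @param c0_ppmv initial mixing ratio (ppmv, > 0).
#' @param times_h strictly increasing sampling times (h).
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param floor_ppbv detection floor in ppbv (default 25).
#' @param seed integer seed.
#' @param flask_id,headspace_l,soil_dw_g,culture_cfu,temperature_k,pressure_kpa
#'   flask metadata forwarded to [decay_curve()].
#' @param scenario_id label stored in the truth record.
#' @return list with `curve` (a [decay_curve()]) and `truth`.
#' @examples
#' sim <- simulate_decay_series(0.5, 1, seq(0, 1, 0.125), cv = 0, seed = 1)
#' fit_decay(sim$curve)$k_per_h
#' @export
simulate_decay_series <- function(k_per_h, c0_ppmv, times_h, cv = 0.05,
                                  floor_ppbv = 25, seed = 1L,
                                  flask_id = "flask1", headspace_l = 0.5,
                                  soil_dw_g = NA_real_,
                                  culture_cfu = NA_real_,
                                  temperature_k = 298.15,
                                  pressure_kpa = 101.325,
                                  scenario_id = "decay") {
  k_per_h <- .check_number(k_per_h, "k_per_h", lower = 0)
  c0_ppmv <- .check_number(c0_ppmv, "c0_ppmv", lower = 0, strict_lower = TRUE)
  if (cv < 0) .stopf("cv must be >= 0 (got %g)", cv)
  if (length(times_h) < 2L || any(diff(times_h) <= 0))
    .stopf("times_h must be strictly increasing with >= 2 points")

  .with_scenario_seed(seed, scenario_id, {
    eps <- if (cv > 0) rnorm(length(times_h), 0, cv) else 0
    co <- c0_ppmv * exp(-k_per_h * times_h) * (1 + eps)
    co <- pmax(co, 1e-9)
    curve <- decay_curve(flask_id = flask_id, times_h = times_h,
                         co_ppmv = co, floor_ppbv = floor_ppbv,
                         headspace_l = headspace_l, soil_dw_g = soil_dw_g,
                         culture_cfu = culture_cfu,
                         temperature_k = temperature_k,
                         pressure_kpa = pressure_kpa)
    truth <- new_sim_truth(scenario_id, list(
      true_k_per_h = k_per_h, c0_ppmv = c0_ppmv, cv = cv,
      floor_ppbv = floor_ppbv), seed)
    list(curve = curve, truth = truth)
  })
}

#' Simulate a qPCR run from a log-linear standard model
#'
#' Standards span 10^1 to 10^9 copies per reaction; quantification cycles
#' follow `Cq = intercept_cq - log10(copies) / log10(1 + efficiency)` plus
#' Gaussian noise, so the standard-curve slope is
#' `-1 / log10(1 + efficiency)` (-3.32 cycles/log at perfect doubling).
#'
#' @param efficiency amplification efficiency in (0, 1].
#' @param intercept_cq Cq at 1 copy (the curve intercept).
#' @param sd_cq Gaussian noise SD on Cq (>= 0).
#' @param unknown_copies true copies/reaction of the unknowns (all > 0).
#' @param seed integer seed.
#' @param standard_logs log10 copy levels for the standards.
#' @param scenario_id label stored in the truth record.
#' @return list with `records` (data frame `well`, `role`, `copies`, `cq`;
#'   `copies` is `NA` for unknowns) and `truth`.
#' @examples
#' run <- simulate_qpcr_run(0.7, 40, sd_cq = 0, unknown_copies = 1e5, seed = 1)
#' fit_standard_curve(run$records)$efficiency
#' @export
simulate_qpcr_run <- function(efficiency, intercept_cq = 40, sd_cq = 0.1,
                              unknown_copies = numeric(), seed = 1L,
                              standard_logs = 1:9,
                              scenario_id = "qpcr") {
  efficiency <- .check_number(efficiency, "efficiency", 0, 1,
                              strict_lower = TRUE)
  if (sd_cq < 0) .stopf("sd_cq must be >= 0")
  if (length(unknown_copies) && any(unknown_copies <= 0))
    .stopf("unknown_copies must all be > 0")

  .with_scenario_seed(seed, scenario_id, {
    slope <- -1 / log10(1 + efficiency)
    std_copies <- 10^standard_logs
    all_copies <- c(std_copies, unknown_copies)
    cq <- intercept_cq + slope * log10(all_copies) +
      rnorm(length(all_copies), 0, sd_cq)
    n_std <- length(std_copies)
    records <- data.frame(
      well = sprintf("w%02d", seq_along(all_copies)),
      role = rep(c("standard", "unknown"),
                 c(n_std, length(unknown_copies))),
      copies = c(std_copies, rep(NA_real_, length(unknown_copies))),
      cq = cq, stringsAsFactors = FALSE)
    truth <- new_sim_truth(scenario_id, list(
      true_efficiency = efficiency, intercept_cq = intercept_cq,
      sd_cq = sd_cq, true_slope = slope,
      unknown_copies = as.numeric(unknown_copies)), seed)
    list(records = records, truth = truth)
  })
}

#' Simulate an OTU-by-station table with a planted environmental gradient
#'
#' OTU abundances respond linearly to two planted gradients (soil water
#' content and CO uptake activity) with OTU-specific loadings, plus Gaussian
#' noise. Five nuisance soil variables (pH, C, N, P, K) are emitted with the
#' collinearity structure of temperate soil surveys: K, P and pH track water
#' content, C and N track CO uptake. At `noise_sd = 0` the abundance matrix
#' is an exact linear function of (water, CO uptake), so a redundancy
#' analysis constrained on the two true gradients explains all variance.
#'
#' @param n_otus number of OTUs (>= 2).
#' @param n_stations number of stations (>= 4); the default 9 mirrors a
#'   3 land-use x 3 station design.
#' @param env_effect strength of the planted gradient response.
#' @param noise_sd SD of additive abundance noise.
#' @param seed integer seed.
#' @param scenario_id label stored in the truth record.
#' @return list with `abundance` (station x OTU matrix), `env` (station
#'   data frame with `water`, `co_uptake`, `pH`, `C`, `N`, `P`, `K`) and
#'   `truth` (loadings, gradients, constrained fraction at zero noise = 1).
#' @examples
#' sim <- simulate_community_env(12, 9, env_effect = 2, noise_sd = 0, seed = 1)
#' dim(sim$abundance)
#' @export
simulate_community_env <- function(n_otus, n_stations = 9, env_effect = 2,
                                   noise_sd = 0.25, seed = 1L,
                                   scenario_id = "community_env") {
  n_otus <- .check_count(n_otus, "n_otus", min = 2L)
  n_stations <- .check_count(n_stations, "n_stations", min = 4L)
  if (noise_sd < 0) .stopf("noise_sd must be >= 0")

  .with_scenario_seed(seed, scenario_id, {
    stations <- sprintf("st%02d", seq_len(n_stations))
    otus <- sprintf("OTU%03d", seq_len(n_otus))
    zscale <- function(v) as.numeric(scale(v))
    water <- zscale(runif(n_stations, -1, 1))
    co <- zscale(runif(n_stations, -1, 1))
    a <- runif(n_otus, -1, 1)
    b <- runif(n_otus, -1, 1)
    base <- 20
    Y <- base + env_effect * (outer(water, a) + outer(co, b))
    if (noise_sd > 0)
      Y <- pmax(Y + matrix(rnorm(n_otus * n_stations, 0, noise_sd),
                           n_stations, n_otus), 0)
    dimnames(Y) <- list(stations, otus)

    mix <- function(g, rho) rho * g + sqrt(1 - rho^2) * zscale(rnorm(n_stations))
    env <- data.frame(
      station = stations,
      water = 25 + 8 * water,                 # % gravimetric
      co_uptake = 1500 + 900 * co,            # pmol g-1(dw) h-1
      pH = 6.0 + 0.5 * mix(water, 0.5),
      C = 150 + 60 * mix(co, 0.6),            # mg g-1
      N = 8 + 3 * mix(co, 0.6),
      P = 120 + 40 * mix(water, 0.5),
      K = 200 + 60 * mix(water, 0.5),
      stringsAsFactors = FALSE)
    truth <- new_sim_truth(scenario_id, list(
      env_effect = env_effect, noise_sd = noise_sd,
      constrained_fraction_noiseless = 1,
      water_gradient = water, co_gradient = co,
      loadings_water = a, loadings_co = b), seed)
    list(abundance = Y, env = env, truth = truth)
  })
}
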