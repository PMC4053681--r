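# Shared constants and small internal helpers.

# Ideal gas constant, J mol-1 K-1 (CODATA).
GAS_CONSTANT <- 8.314462618

# Exact molar unit factors; all internal arithmetic is in mol.
UNIT_MOL <- c(mol = 1, mmol = 1e-3, umol = 1e-6, nmol = 1e-9,
              pmol = 1e-12, fmol = 1e-15, amol = 1e-18, zmol = 1e-21)

#' Convert between molar unit prefixes
#'
#' The population-band arithmetic mixes nmol (soil uptake rates), pmol
#' (per-gram rates) and zmol (cell-specific rates, 1 zmol = 1e-21 mol);
#' conversions go through mol with exact factors.
#'
#' @param x numeric vector of quantities.
#' @param from,to unit names among `mol`, `mmol`, `umol`, `nmol`, `pmol`,
#'   `fmol`, `amol`, `zmol`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_mol(1, "pmol", "zmol")  # 1e9
#' @export
convert_mol <- function(x, from, to) {
  from <- match.arg(from, names(UNIT_MOL))
  to <- match.arg(to, names(UNIT_MOL))
  x * UNIT_MOL[[from]] / UNIT_MOL[[to]]
}

# Deterministic small hash of a string onto [0, 2^20), used to give every
# generator scenario its own RNG stream derived from (seed, scenario_id).
.scenario_offset <- function(scenario_id) {
  codes <- utf8ToInt(as.character(scenario_id))
  if (length(codes) == 0L) return(0L)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 1048576
  as.integer(h)
}

# Run `expr` under a local RNG stream seeded from (seed, scenario_id),
# restoring the caller's RNG state afterwards.
.with_scenario_seed <- function(seed, scenario_id, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  mixed <- (as.integer(seed) %% 1000000L) * 1021L + .scenario_offset(scenario_id)
  set.seed(mixed %% .Machine$integer.max)
  force(expr)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != floor(x))
    .stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("`%s` must be a single finite number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    .stopf("`%s` = %g is outside its allowed range", name, x)
  as.numeric(x)
}
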