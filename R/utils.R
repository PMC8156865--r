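# Internal helpers shared across modules.

# Positive scalar integer check used by the geometry and config validators.
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == trunc(x)
}

stop_geometry <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "elasticgrade_geometry_error")
}

stop_parameter <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "elasticgrade_parameter_error")
}

stop_contract <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "elasticgrade_contract_error")
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All package randomness flows through this.
with_seed <- function(seed, expr) {
  if (!is_count(seed, min = 0L)) {
    stop_parameter("`seed` must be a single non-negative integer (got %s)",
                   paste(seed, collapse = ","))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 32-bit-safe combination of two seeds (member x image, etc.).
combine_seeds <- function(a, b) {
  a <- as.double(a) %% 2147483647
  b <- as.double(b) %% 2147483647
  as.integer((a * 7919 + b * 104729 + 12345) %% 2147483647)
}

# Deterministic small integer derived from a string id (for per-image seeds).
id_seed <- function(id) {
  codes <- utf8ToInt(as.character(id))
  h <- 5381
  for (cc in codes) h <- (h * 33 + cc) %% 2147483647
  as.integer(h)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Validate a class-probability vector (length >= 2, entries >= 0, sums to 1).
check_prob_vector <- function(p, tol = 1e-6, what = "probability vector") {
  if (!is.numeric(p) || length(p) < 2L) {
    stop_contract("%s must be a numeric vector of length >= 2", what)
  }
  if (any(!is.finite(p)) || any(p < -tol)) {
    stop_contract("%s has negative or non-finite entries", what)
  }
  if (abs(sum(p) - 1) > tol) {
    stop_contract("%s sums to %.8f, not 1 (tolerance %g)", what, sum(p), tol)
  }
  invisible(p)
}
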