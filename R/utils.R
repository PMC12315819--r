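# Internal helpers: parameter validation, seeded evaluation, seed derivation.

stop_param <- function(field, msg) {
  stop(structure(
    class = c("dualspot_param_error", "error", "condition"),
    list(message = sprintf("invalid parameter `%s`: %s", field, msg),
         call = sys.call(-1))
  ))
}

check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop_param(field, msg)
  invisible(TRUE)
}

check_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                             allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(TRUE))
    stop_param(field, "must not be NULL")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(field, "must be a single finite number")
  if (x < lower) stop_param(field, sprintf("must be >= %g", lower))
  if (x > upper) stop_param(field, sprintf("must be <= %g", upper))
  invisible(TRUE)
}

# Evaluate `code` under a given RNG seed without disturbing the caller's
# RNG stream. A NULL seed evaluates as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a child seed from a base seed and an index
#'
#' Deterministic integer mixing so that, e.g., each step of a dilution series
#' gets its own reproducible RNG stream from one base seed. Result is always
#' in `[1, 2^31 - 2]`.
#'
#' @param base integer base seed.
#' @param k nonnegative integer index.
#' @return an integer seed.
#' @export
#' @examples
#' derive_seed(42, 0)
#' derive_seed(42, 1)
derive_seed <- function(base, k) {
  check_scalar_num(base, "base")
  check_scalar_num(k, "k", lower = 0)
  m <- 2147483647 # 2^31 - 1, prime
  s <- ((abs(base) %% m) * 48271 + (k + 1) * 16807) %% m
  s <- (s * 69621) %% m
  as.integer(if (s == 0) 1 else s)
}
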