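# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of (params, seed) without
#' disturbing the session RNG.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic sub-seed derivation (e.g. one RNG stream per channel or per
# animal) kept inside 32-bit signed integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2654435761 + 97 * as.numeric(k)) %% 2147483587L) + 1L
}

# Structured error, so callers can distinguish failure modes by class.
abort_acq <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "acquant_error")))
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_acq(sprintf("`%s` must be a single finite number", name), "acquant_bad_param")
  if (positive && x <= 0)
    abort_acq(sprintf("`%s` must be > 0", name), "acquant_bad_param")
  if (nonneg && x < 0)
    abort_acq(sprintf("`%s` must be >= 0", name), "acquant_bad_param")
  invisible(x)
}
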