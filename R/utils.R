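# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generator calls do not
#' perturb unrelated randomness.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# fold string labels into a 32-bit-safe substream seed
derive_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  s <- as.numeric(seed) %% 2147480009
  for (ch in utf8ToInt(labels)) s <- (s * 31 + ch) %% 2147480009
  as.integer(s)
}

# deterministic per-label value in [-1, 1], used for cross-source biases
unit_hash <- function(label, salt = 0) {
  s <- derive_seed(97 + salt, label)
  (s %% 20011) / 20011 * 2 - 1
}

# wrap longitudes into [-180, 180)
wrap_lon <- function(lon) ((lon + 180) %% 360) - 180

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
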