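#' Derive a reproducible child seed from a base seed and a stream name
#'
#' Each stochastic component of the package draws from its own named stream so
#' that adding one generator to a workflow never perturbs the random numbers
#' seen by another. The child seed is a deterministic 31-bit hash of the base
#' seed and the stream label.
#'
#' @param seed Integer base seed.
#' @param name Character stream label (e.g. `"sim_brood"`).
#' @return A single integer in `[0, 2^31 - 1)`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "sim_brood")
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.character(name), length(name) == 1L)
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(name)) {
    # 31-bit multiplicative string hash, kept in double-precision exact range
    h <- (h * 31 + code) %% 2147483629
  }
  as.integer(h)
}

# Evaluate `code` under a named child RNG stream, restoring RNG state after.
with_stream <- function(seed, name, code) {
  withr::with_seed(derive_seed(seed, name), code)
}

# shared input check: single non-negative count
check_count <- function(x, arg) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x != floor(x))) {
    abort(sprintf("`%s` must contain non-negative integer counts.", arg))
  }
  invisible(x)
}
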