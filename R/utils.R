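#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the Mersenne-Twister seed, runs `code`, and restores the caller's
#' RNG state afterwards, so seeded package functions never perturb the
#' global random stream.
#'
#' @param seed single integer seed (coerced with [as.integer()]).
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be a non-missing integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

# derive a distinct 31-bit sub-seed from a base seed and an index
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 1009 + 12345) %% 2147483647)
}

# population variance: mean(x^2) - mean(x)^2, as used by the
# pair-correlation functions (no n-1 correction)
pop_var <- function(x) mean(x^2) - mean(x)^2

# standard error of the mean (returns NA for a single value)
se_mean <- function(x) stats::sd(x) / sqrt(length(x))

# tiny FNV-1a hash of a character scalar, for output manifests
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
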