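#' Run code under a temporary seed
#'
#' Evaluates `code` with the RNG seeded at `seed`, restoring the caller's RNG
#' state afterwards. A `NULL` seed evaluates the code against the current
#' stream. All stochastic functions in the package route their randomness
#' through this helper so no global state leaks between stages.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

#' Derive a stage-specific sub-seed from a global seed
#'
#' Mixes a global integer seed with a stable string tag (a polynomial byte
#' hash modulo 2^31 - 1), so adding or reordering pipeline stages never
#' shifts the random stream of the others.
#'
#' @param seed integer global seed.
#' @param tag character stage label.
#' @return integer seed in \[0, 2^31 - 2\].
#' @export
#' @examples
#' derive_seed(42, "tree") != derive_seed(42, "ncm")
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h) %% 2147483647)
}

# Benjamini-Hochberg step-up adjustment; the single adjustment route used by
# every test family in the package.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# Integer-preserving proportional rescale of a count vector to a fixed total
# (largest-remainder rounding; deterministic tie-break by index order).
scale_to_total <- function(x, total) {
  stopifnot(total >= 0, all(x >= 0))
  if (total == 0) return(rep(0, length(x)))
  if (sum(x) == 0) x <- rep(1, length(x))
  raw <- x * total / sum(x)
  fl <- floor(raw)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0) {
    ord <- order(raw - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  fl
}
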