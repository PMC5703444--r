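#' Derive a reproducible sub-stream seed
#'
#' All stochastic components of the package draw their random numbers from
#' sub-streams derived deterministically from one global seed, so that a
#' single integer reproduces an entire simulated study. The derivation is
#' `(seed * 1000003 + offset) mod (2^31 - 1)`, where `offset` is a fixed
#' per-component label hash; results always fit in a 32-bit integer.
#'
#' @param seed integer global seed.
#' @param label character label of the component (e.g. `"ages"`).
#' @return an integer seed for `set.seed()`.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offset <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 99991L
  as.integer((abs(seed) %% 2147480 * 1000003 + offset) %% 2147483647)
}

# truncated normal via inverse-cdf; exact for the mild truncation used here
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

# lower-triangular matrix from packed column-major vector of its p(p+1)/2
# free entries
ltri_from_vec <- function(v, p) {
  m <- matrix(0, p, p)
  m[lower.tri(m, diag = TRUE)] <- v
  m
}

ltri_to_vec <- function(m) m[lower.tri(m, diag = TRUE)]

# indices (within the packed vector) of the diagonal entries
ltri_diag_idx <- function(p) {
  if (p == 1L) return(1L)
  cumsum(c(1L, seq.int(p, 2L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

utils::globalVariables(c("threshold", "r2_signed", "discovery", "tier",
                         "phenotype"))
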