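#' Simulate univariate twin pairs under an ACE truth
#'
#' Fast vectorized generator for recovery studies: MZ co-twins share the A
#' factor fully, DZ co-twins at 0.5, C is shared within pair, E independent;
#' the trait has unit variance `a2 + c2 + e2 = 1`.
#'
#' @param n_mz,n_dz pair counts.
#' @param a2,c2 additive-genetic and shared-environment variance
#'   proportions.
#' @param seed integer seed.
#' @return list `phenotypes` (person_id, y) and `pedigree` (person_id,
#'   family_id, zygosity, role).
#' @export
simulate_twin_pairs <- function(n_mz, n_dz, a2, c2 = 0, seed = 1) {
  stopifnot(a2 >= 0, c2 >= 0, a2 + c2 <= 1)
  set.seed(substream_seed(seed, "twin_pairs"))
  e2 <- 1 - a2 - c2
  draw <- function(n, k) {
    ash <- stats::rnorm(n)
    a1 <- sqrt(k) * ash + sqrt(1 - k) * stats::rnorm(n)
    a2f <- sqrt(k) * ash + sqrt(1 - k) * stats::rnorm(n)
    if (k == 1) a1 <- a2f <- ash
    cc <- stats::rnorm(n)
    cbind(sqrt(a2) * a1 + sqrt(c2) * cc + sqrt(e2) * stats::rnorm(n),
          sqrt(a2) * a2f + sqrt(c2) * cc + sqrt(e2) * stats::rnorm(n))
  }
  y_mz <- if (n_mz > 0) draw(n_mz, 1) else NULL
  y_dz <- if (n_dz > 0) draw(n_dz, 0.5) else NULL
  n_fam <- n_mz + n_dz
  fam <- sprintf("F%05d", rep(seq_len(n_fam), each = 2))
  zyg <- rep(c(rep("MZ", n_mz), rep("DZ", n_dz)), each = 2)
  pid <- sprintf("P%05d", seq_len(2 * n_fam))
  y <- as.vector(t(rbind(y_mz, y_dz)))
  list(phenotypes = data.frame(person_id = pid, y = y,
                               stringsAsFactors = FALSE),
       pedigree = data.frame(person_id = pid, family_id = fam,
                             zygosity = zyg,
                             role = rep(c("twin1", "twin2"), n_fam),
                             stringsAsFactors = FALSE))
}

#' Heritability recovery across simulated univariate AE cohorts
#'
#' Simulates `n_reps` twin cohorts at a given additive-genetic proportion,
#' fits the univariate AE model by FIML to each, and returns the per-
#' replicate standardized A estimates.
#'
#' @param n_reps number of replicate cohorts.
#' @param n_mz,n_dz pair counts per cohort.
#' @param a2 generating additive proportion.
#' @param seed integer seed.
#' @param n_starts optimizer starts per fit (default 2).
#' @return numeric vector of length `n_reps` of estimated a^2.
#' @export
recovery_ae_h2 <- function(n_reps, n_mz = 115, n_dz = 183, a2 = 0.72,
                           seed = 1, n_starts = 2) {
  vapply(seq_len(n_reps), function(r) {
    sim <- simulate_twin_pairs(n_mz, n_dz, a2, seed = seed * 10000 + r)
    fit <- fit_model(sim$phenotypes, sim$pedigree, "y", components = "AE",
                     covariates = NULL, n_starts = n_starts)
    attr(standardize(fit), "h2")[1]
  }, numeric(1))
}

#' Twin-correlation recovery across simulated bivariate-normal samples
#'
#' Draws `n_reps` samples of `n_pairs` twin pairs from a bivariate normal
#' with within-pair correlation `r` and estimates the correlation with the
#' package's ML (double-entry) estimator.
#'
#' @param n_reps replicates.
#' @param n_pairs pairs per replicate.
#' @param r generating within-pair correlation.
#' @param seed integer seed.
#' @return numeric vector of estimates.
#' @export
recovery_twin_cor <- function(n_reps, n_pairs, r, seed = 1) {
  set.seed(substream_seed(seed, "twin_cor_recovery"))
  vapply(seq_len(n_reps), function(i) {
    z1 <- stats::rnorm(n_pairs)
    y2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n_pairs)
    X <- matrix(1, n_pairs, 1)
    ml_pair_cor(z1, y2, X, X, ci = FALSE)$r
  }, numeric(1))
}
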