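#' Ground-truth generating model for the synthetic cohort
#'
#' Holds the Cholesky path matrices of the additive-genetic (A), shared-
#' environment (C) and unique-environment (E) latent factors, the fixed-
#' effect mean model, per-trait scales, two-year stabilities, and the
#' additive log10-scale experimental effects acting on raw hair cortisol.
#'
#' The default is a four-trait AE model (traits, in order: perceived stress,
#' depressive symptoms, neuroticism, hair cortisol) whose standardized paths
#' are the square roots of the standardized variance components of the
#' fitted AE Cholesky decomposition the package emulates; C is zero. Trait
#' scales convert the unit-variance latent deviations to observed units
#' (liability/z units for the psychological traits, log10 pg/mg for HCC).
#'
#' @param X,Y,Z lower-triangular p x p standardized path matrices for A, C
#'   and E. `Y = NULL` means no shared-environment component.
#' @param traits character vector of trait names (HCC must be last).
#' @param trait_scales per-trait observed-unit SDs.
#' @param mean_betas 6 x p coefficient matrix of the mean model on
#'   (intercept, sex, age_c, age_c^2, sex*age_c, sex*age_c^2), in observed
#'   units; age is centered at the design mean.
#' @param stability per-trait correlation between the time-1 and time-2
#'   trait deviations.
#' @param genetic_loading per-trait proportion of the A-factor variance
#'   contributed by measured causal variants (used when genotype-derived
#'   scores are supplied to [draw_latent_traits()]).
#' @param experimental_sd named list with SDs/amplitudes of the additive
#'   log10-scale assay effects: `batch`, `storage`, `month` (sinusoid
#'   amplitude, peak March / trough September), `study`.
#' @param hcc_offset offset (pg/mg) subtracted when mapping the log10-scale
#'   latent value back to a raw concentration (default 0.1, the smallest
#'   measurable value).
#' @return an object of class `true_model`.
#' @export
true_model <- function(X = NULL, Y = NULL, Z = NULL,
                       traits = c("stress", "dep", "neuro", "hcc"),
                       trait_scales = c(0.58, 0.92, 1.01, 0.42),
                       mean_betas = NULL,
                       stability = c(0.61, 0.51, 0.58, 0.32),
                       genetic_loading = rep(0, length(traits)),
                       experimental_sd = list(batch = 0.10, storage = 0.08,
                                              month = 0.115, study = 0.105),
                       hcc_offset = 0.1) {
  p <- length(traits)
  if (is.null(X)) {
    # standardized variance components (%) of the default AE truth
    a_pct <- matrix(0, 4, 4)
    a_pct[lower.tri(a_pct, diag = TRUE)] <-
      c(53.89, 32.95, 33.78, 1.33, 22.10, 2.79, 0.03, 19.81, 1.20, 69.37)
    e_pct <- matrix(0, 4, 4)
    e_pct[lower.tri(e_pct, diag = TRUE)] <-
      c(46.12, 6.65, 12.15, 0.68, 38.30, 5.00, 0.07, 26.48, 0.21, 27.02)
    X <- sqrt(a_pct / 100)
    Z <- sqrt(e_pct / 100)
    # renormalize rows so diag(XX' + ZZ') = 1 exactly
    tot <- sqrt(rowSums(X^2) + rowSums(Z^2))
    X <- X / tot
    Z <- Z / tot
  }
  stopifnot(nrow(X) == p, is.null(Y) || nrow(Y) == p, nrow(Z) == p)
  if (is.null(mean_betas)) {
    mean_betas <- matrix(0, 6, p, dimnames = list(
      c("intercept", "sex", "age_c", "age_c2", "sex_age", "sex_age2"),
      traits))
    mean_betas["intercept", ] <- c(0, 0, 0, 0.55)
    mean_betas["sex", ] <- c(0.03, 0.15, 0.18, 0.02)
    mean_betas["age_c", ] <- c(0.04, 0.05, 0.04, 0.01)
    mean_betas["sex_age", ] <- c(0.02, 0, 0.02, 0)
  }
  sigma <- tcrossprod(X) + tcrossprod(Z) +
    (if (is.null(Y)) 0 else tcrossprod(Y))
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("implied trait covariance is not positive definite")
  structure(list(p = p, traits = traits, X = X, Y = Y, Z = Z,
                 trait_scales = trait_scales, mean_betas = mean_betas,
                 stability = stability, genetic_loading = genetic_loading,
                 experimental_sd = experimental_sd, hcc_offset = hcc_offset),
            class = "true_model")
}

# one standardized A/C/E factor-score draw for every person, with the
# family-sharing structure: MZ co-twins share A fully, all other relative
# pairs within a family share A at 0.5; C is identical within family; E is
# independent. Vectorized: person i draws a_i = w_i f_fam + sqrt(1 - w_i^2)
# ind_i with w = 1 for MZ co-twins (the independent part vanishes, so they
# coincide), w = 0.5 for a sibling in an MZ family, and w = sqrt(0.5) in
# DZ/sibling-only families.
draw_ace_scores <- function(cohort, p) {
  persons <- cohort$persons
  n <- nrow(persons)
  fam <- factor(persons$family_id, levels = unique(persons$family_id))
  fidx <- as.integer(fam)
  n_fam <- nlevels(fam)
  mz_fam <- tapply(persons$zygosity == "MZ", fidx, any)
  is_mz <- persons$zygosity == "MZ"
  w <- as.numeric(ifelse(mz_fam[fidx],
                         ifelse(is_mz, 1, 0.5),
                         sqrt(0.5)))
  f_a <- matrix(stats::rnorm(n_fam * p), n_fam, p)
  f_c <- matrix(stats::rnorm(n_fam * p), n_fam, p)
  a <- w * f_a[fidx, , drop = FALSE] +
    sqrt(1 - w^2) * matrix(stats::rnorm(n * p), n, p)
  list(a = a, c = f_c[fidx, , drop = FALSE],
       e = matrix(stats::rnorm(n * p), n, p))
}

#' Draw latent trait values for a cohort
#'
#' Generates per-person trait values from the Cholesky-structured A/C/E
#' model: standardized factor scores with twin-family sharing (MZ co-twins
#' identical A, DZ co-twins and siblings correlated 0.5, C shared within
#' family, E independent) are premultiplied by the path matrices, scaled to
#' observed units and shifted by the sex/age mean model. Retested persons
#' receive a second-time-point value whose deviation correlates with the
#' first at the model's per-trait stability.
#'
#' @param cohort a [build_cohort()] result.
#' @param truth a [true_model()].
#' @param seed integer seed.
#' @param genetic_scores optional n x p matrix of standardized genotype-
#'   derived scores mixed into the A factors at `truth$genetic_loading`.
#' @return a list with `t1` and `t2` (n x p trait matrices in observed
#'   units; `t2` is `NA` for persons without a retest), `dev_t1`
#'   (standardized deviations), and `truth`.
#' @export
draw_latent_traits <- function(cohort, truth, seed = 1,
                               genetic_scores = NULL) {
  stopifnot(inherits(cohort, "twin_cohort"), inherits(truth, "true_model"))
  set.seed(substream_seed(seed, "latent"))
  persons <- cohort$persons
  n <- nrow(persons)
  p <- truth$p

  mix <- function(sc) {
    if (is.null(genetic_scores)) return(sc)
    g2 <- truth$genetic_loading
    sc$a <- sweep(genetic_scores, 2, sqrt(g2), `*`) +
      sweep(sc$a, 2, sqrt(1 - g2), `*`)
    sc
  }
  deviation <- function(sc) {
    d <- tcrossprod(sc$a, truth$X) + tcrossprod(sc$e, truth$Z)
    if (!is.null(truth$Y)) d <- d + tcrossprod(sc$c, truth$Y)
    d
  }
  dev1 <- deviation(mix(draw_ace_scores(cohort, p)))
  dev2_new <- deviation(mix(draw_ace_scores(cohort, p)))
  rho <- truth$stability
  dev2 <- sweep(dev1, 2, rho, `*`) + sweep(dev2_new, 2, sqrt(1 - rho^2), `*`)

  mean_part <- function(age) {
    agec <- age - cohort$design$age_mean
    w <- cbind(1, persons$sex, agec, agec^2, persons$sex * agec,
               persons$sex * agec^2)
    w %*% truth$mean_betas
  }
  t1 <- mean_part(persons$age_t1) + sweep(dev1, 2, truth$trait_scales, `*`)
  t2 <- mean_part(ifelse(persons$retest, persons$age_t2, persons$age_t1)) +
    sweep(dev2, 2, truth$trait_scales, `*`)
  t2[!persons$retest, ] <- NA_real_
  colnames(t1) <- colnames(t2) <- colnames(dev1) <- truth$traits
  rownames(t1) <- rownames(t2) <- persons$person_id
  list(t1 = t1, t2 = t2, dev_t1 = dev1, truth = truth)
}
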