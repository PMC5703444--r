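# REML -2 log-likelihood in the eigenbasis of K for variance ratio
# lambda = sigma2_g / sigma2_e; returns the profiled criterion and the GLS
# pieces at that lambda
reml_pieces <- function(lambda, yt, Wt, d) {
  w <- 1 / (lambda * d + 1)
  sw <- sqrt(w)
  Xw <- Wt * sw
  yw <- yt * sw
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  nc <- length(yt) - ncol(Wt)
  sigma2_e <- rss / nc
  xtx <- crossprod(Xw)
  crit <- nc * log(sigma2_e) + sum(log(lambda * d + 1)) +
    determinant(xtx, logarithm = TRUE)$modulus[1]
  list(crit = crit, beta = fit$coefficients, sigma2_e = sigma2_e,
       xtx = xtx, rss = rss, yw = yw, Xw = Xw)
}

#' Family-aware mixed-model association of a polygenic score
#'
#' Fits `y = W gamma + s beta + g + e` with `g ~ N(0, sigma2_g K)` and
#' `e ~ N(0, sigma2_e I)` by REML, working in the eigenbasis of the
#' relatedness matrix so the variance-ratio profile is one-dimensional.
#' Reports the Wald test of the score coefficient with a one-sided p-value
#' for the hypothesis of a *positive* association, and the signed
#' incremental R2 of the score on the fixed-effect (GLS-whitened) scale:
#' `sign(beta) * (R2_full - R2_null)`, the null model dropping the score but
#' keeping the covariates and the fitted variance ratio.
#'
#' @param y phenotype vector.
#' @param score polygenic score vector.
#' @param covariates matrix or data.frame of covariates (an intercept is
#'   added).
#' @param K relatedness matrix (see [pedigree_kinship()]); must be PSD.
#' @param eigenK optional precomputed `eigen(K, symmetric = TRUE)` for reuse
#'   across many calls.
#' @param constrain_g0 fix `sigma2_g = 0` (the fit then equals OLS).
#' @return one-row data.frame: `beta`, `se`, `z`, `p_one_sided`,
#'   `p_two_sided`, `r2_signed`, `sigma2_g`, `sigma2_e`, `n`, `n_dropped`.
#' @export
mixed_assoc <- function(y, score, covariates = NULL, K, eigenK = NULL,
                        constrain_g0 = FALSE) {
  W <- if (is.null(covariates)) matrix(1, length(y), 1) else
    cbind(1, as.matrix(covariates))
  ok <- stats::complete.cases(cbind(y, score, W))
  n_dropped <- sum(!ok)
  y <- y[ok]
  score <- score[ok]
  W <- W[ok, , drop = FALSE]
  if (is.null(eigenK)) {
    Ks <- K[ok, ok]
    ek <- eigen(Ks, symmetric = TRUE)
  } else {
    if (n_dropped > 0)
      stop("precomputed eigenK requires complete cases")
    ek <- eigenK
  }
  if (min(ek$values) < -1e-6) stop("K is not positive semidefinite")
  d <- pmax(ek$values, 0)
  U <- ek$vectors
  yt <- as.vector(crossprod(U, y))
  Xfull <- cbind(W, prs = score)
  Wt_full <- crossprod(U, Xfull)
  Wt_null <- crossprod(U, W)

  if (constrain_g0) {
    lambda <- 0
  } else {
    opt <- stats::optimize(function(ll) reml_pieces(exp(ll), yt, Wt_full, d)$crit,
                           c(-12, 12), tol = 1e-8)
    lambda <- exp(opt$minimum)
    if (reml_pieces(0, yt, Wt_full, d)$crit <= opt$objective) lambda <- 0
  }
  full <- reml_pieces(lambda, yt, Wt_full, d)
  vcov_beta <- full$sigma2_e * chol2inv(chol(full$xtx))
  j <- ncol(Xfull)
  beta <- unname(full$beta[j])
  se <- sqrt(vcov_beta[j, j])
  z <- beta / se
  p_one <- stats::pnorm(z, lower.tail = FALSE)
  null <- reml_pieces(lambda, yt, Wt_null, d)
  tss <- sum((full$yw - mean(full$yw))^2)
  r2_full <- 1 - full$rss / tss
  r2_null <- 1 - null$rss / tss
  data.frame(beta = beta, se = se, z = z,
             p_one_sided = p_one,
             p_two_sided = 2 * min(p_one, 1 - p_one),
             r2_signed = sign(beta) * (r2_full - r2_null),
             sigma2_g = lambda * full$sigma2_e,
             sigma2_e = full$sigma2_e,
             n = length(y), n_dropped = n_dropped)
}

#' PRS association sweep over phenotypes and thresholds
#'
#' Runs [mixed_assoc()] for every phenotype x threshold x discovery-trait
#' combination and annotates significance tiers (`**` p < 0.01, `*`
#' p < 0.05, `#` p < 0.1, one-sided).
#'
#' @param phenotypes data.frame of phenotype columns (one per trait),
#'   persons aligned with `profiles` rows and `K`.
#' @param profiles named list (per discovery trait) of person x threshold
#'   score matrices from [score_at_thresholds()].
#' @param covariates covariate matrix (no intercept column).
#' @param K relatedness matrix.
#' @return data.frame with one row per cell: `discovery`, `phenotype`,
#'   `threshold`, `n_variants`, association columns, `tier`.
#' @export
threshold_sweep <- function(phenotypes, profiles, covariates, K) {
  rows <- list()
  for (d in names(profiles)) {
    prof <- profiles[[d]]
    nv <- attr(prof, "n_variants")
    for (ph in names(phenotypes)) {
      for (k in seq_len(ncol(prof))) {
        res <- mixed_assoc(phenotypes[[ph]], prof[, k], covariates, K)
        res$discovery <- d
        res$phenotype <- ph
        res$threshold <- as.numeric(colnames(prof)[k])
        res$n_variants <- unname(nv[k])
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  out$tier <- ifelse(out$p_one_sided < 0.01, "**",
                     ifelse(out$p_one_sided < 0.05, "*",
                            ifelse(out$p_one_sided < 0.1, "#", "")))
  front <- c("discovery", "phenotype", "threshold", "n_variants")
  out[c(front, setdiff(names(out), front))]
}
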