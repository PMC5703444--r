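# pack/unpack the covariance path parameters (the mean coefficients are
# concentrated out of the optimization by GLS)
pack_paths <- function(params, components, p) {
  c(if ("A" %in% components) ltri_to_vec(params$X),
    if ("C" %in% components) ltri_to_vec(params$Y),
    ltri_to_vec(params$Z))
}

unpack_paths <- function(theta, components, p) {
  nt <- p * (p + 1) / 2
  pos <- 0
  take <- function(k) {
    out <- theta[pos + seq_len(k)]
    pos <<- pos + k
    out
  }
  X <- if ("A" %in% components) ltri_from_vec(take(nt), p) else NULL
  Y <- if ("C" %in% components) ltri_from_vec(take(nt), p) else NULL
  Z <- ltri_from_vec(take(nt), p)
  list(X = X, Y = Y, Z = Z)
}

path_bounds <- function(components, p) {
  nt <- p * (p + 1) / 2
  ncmp <- length(components)
  lower <- rep(-Inf, ncmp * nt)
  didx <- ltri_diag_idx(p)
  for (i in seq_len(ncmp)) lower[(i - 1) * nt + didx] <- 0
  lower
}

# OLS per-trait residual SDs and mean-model coefficients, used for starts
start_stats <- function(units) {
  d <- units$data
  W <- units$W
  p <- units$p
  sds <- numeric(p)
  beta <- matrix(0, units$q, p)
  resid <- matrix(NA_real_, nrow(d), p)
  for (j in seq_len(p)) {
    y <- d[[units$traits[j]]]
    ok <- !is.na(y)
    fit <- stats::lm.fit(W[ok, , drop = FALSE], y[ok])
    sds[j] <- stats::sd(fit$residuals)
    beta[, j] <- fit$coefficients
    resid[ok, j] <- fit$residuals
  }
  list(sds = sds, beta = beta, resid = resid)
}

# clip a symmetric matrix to the positive-definite cone and return its
# lower-triangular Cholesky factor
chol_pd <- function(S, floor_frac = 1e-3) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, floor_frac * max(abs(e$values), 1e-8))
  t(chol(e$vectors %*% diag(v, nrow = length(v)) %*% t(e$vectors)))
}

# moment-estimator start: within-person and cross-twin residual covariances
# solved for A/C/E the classic way, projected to the PD cone
moment_start <- function(units, ss, comps) {
  d <- units$data
  p <- units$p
  S_w <- stats::cov(ss$resid, use = "pairwise.complete.obs")
  S_w[is.na(S_w)] <- 0
  cross <- function(zyg) {
    i1 <- which(d$zygosity == zyg & d$role == "twin1")
    m1 <- d$family_id[i1]
    i2 <- which(d$zygosity == zyg & d$role == "twin2")
    i2 <- i2[match(m1, d$family_id[i2])]
    ok <- !is.na(i2)
    if (sum(ok) < 5) return(matrix(0, p, p))
    S <- stats::cov(ss$resid[i1[ok], , drop = FALSE],
                    ss$resid[i2[ok], , drop = FALSE],
                    use = "pairwise.complete.obs")
    S[is.na(S)] <- 0
    (S + t(S)) / 2
  }
  S_mz <- cross("MZ")
  S_dz <- cross("DZ")
  if (setequal(comps, c("A", "C", "E"))) {
    A0 <- 2 * (S_mz - S_dz)
    C0 <- 2 * S_dz - S_mz
  } else if (setequal(comps, c("A", "E"))) {
    A0 <- (S_mz + 2 * S_dz) / 2
    C0 <- NULL
  } else {
    A0 <- NULL
    C0 <- (S_mz + S_dz) / 2
  }
  E0 <- S_w - (if (is.null(A0)) 0 else A0) - (if (is.null(C0)) 0 else C0)
  list(X = if ("A" %in% comps) chol_pd(A0) else NULL,
       Y = if ("C" %in% comps) chol_pd(C0) else NULL,
       Z = chol_pd(E0))
}

#' Fit a Cholesky ACE/AE/CE twin model by FIML
#'
#' Minimizes the full-information -2 log-likelihood ([neg2ll_fiml()]) over
#' the free lower-triangular paths, using box-constrained quasi-Newton
#' optimization (Cholesky diagonals constrained `>= 0` to resolve the
#' triangular sign indeterminacy). The mean-model coefficients enter the
#' likelihood linearly and are concentrated out by GLS at every step, which
#' shrinks the search space considerably. Starting points: a moment
#' estimator built from the observed within-person and cross-twin
#' covariances, followed by diagonal starts at fractions of the observed
#' per-trait residual SDs.
#'
#' @param phenotypes data.frame with `person_id`, trait columns, and (unless
#'   `covariates = NULL`) `sex` and `age`.
#' @param pedigree data.frame with `person_id`, `family_id`, `zygosity`,
#'   `role`.
#' @param traits character vector of trait columns, ordered (HCC last by the
#'   package's convention).
#' @param components `"ACE"`, `"AE"` or `"CE"` (E is always present).
#' @param covariates `c("sex", "age")` expands to the standard mean model
#'   (intercept, sex, age, age^2, sex x age, sex x age^2 with age centered at
#'   the sample mean); `NULL` fits intercept-only means.
#' @param sibling_mode how singleton siblings enter the likelihood; see
#'   `build_twin_units()`.
#' @param n_starts number of starting points (default 5).
#' @param maxit,factr,pgtol optimizer controls (see [stats::optim()]).
#' @return object of class `cholesky_fit`: paths `X`/`Y`/`Z`, `beta`,
#'   `minus2ll`, `n_free_params`, `converged`, per-start log, and the
#'   likelihood-unit structure (reused for profiling and LRTs).
#' @export
fit_model <- function(phenotypes, pedigree, traits, components = "ACE",
                      covariates = c("sex", "age"),
                      sibling_mode = "independent",
                      n_starts = 5, maxit = 2000, factr = 4.5e4,
                      pgtol = 1e-6) {
  comps <- strsplit(toupper(components), "")[[1]]
  if (!"E" %in% comps) stop("E must always be present")
  stopifnot(all(comps %in% c("A", "C", "E")))
  units <- build_twin_units(phenotypes, pedigree, traits, covariates,
                            sibling_mode)
  p <- units$p
  q <- units$q
  ss <- start_stats(units)

  weight_sets <- list(c(A = 1/3, C = 1/3, E = 1/3),
                      c(A = 0.6, C = 0.1, E = 0.3),
                      c(A = 0.2, C = 0.2, E = 0.6),
                      c(A = 0.45, C = 0.45, E = 0.1))
  diag_start <- function(w) {
    w <- w[comps] / sum(w[comps])
    list(X = if ("A" %in% comps) diag(ss$sds * sqrt(w[["A"]]), p, p) else NULL,
         Y = if ("C" %in% comps) diag(ss$sds * sqrt(w[["C"]]), p, p) else NULL,
         Z = diag(ss$sds * sqrt(w[["E"]]), p, p))
  }
  starts <- c(list(moment_start(units, ss, comps)),
              lapply(weight_sets, diag_start))
  starts <- starts[seq_len(min(n_starts, length(starts)))]

  obj <- function(theta) {
    neg2ll_concentrated(unpack_paths(theta, comps, p), units)$value
  }
  lower <- path_bounds(comps, p)

  fits <- lapply(starts, function(start) {
    th0 <- pmax(pack_paths(start, comps, p), lower)
    run <- function(th) tryCatch(
      stats::optim(th, obj, method = "L-BFGS-B", lower = lower,
                   control = list(maxit = maxit, factr = factr,
                                  pgtol = pgtol)),
      error = function(e) list(par = th, value = Inf, convergence = 99L,
                               message = conditionMessage(e)))
    fit <- run(th0)
    if (fit$convergence != 0 && is.finite(fit$value)) {
      # a line-search failure (code 52) at a point a restart cannot improve
      # is convergence in all but name; otherwise keep the better endpoint
      fit2 <- run(fit$par)
      if (fit2$convergence == 0 || fit2$value <= fit$value + 1e-6) {
        if (fit2$convergence != 0 && abs(fit2$value - fit$value) < 1e-6)
          fit2$convergence <- 0L
        fit <- fit2
      }
    }
    fit
  })
  conv <- vapply(fits, function(f) f$convergence == 0, logical(1))
  vals <- vapply(fits, function(f) f$value, numeric(1))
  if (!any(conv)) {
    stop("no start converged; per-start (-2lnL, code): ",
         paste(sprintf("(%.3f, %d)", vals,
                       vapply(fits, function(f) f$convergence, integer(1))),
               collapse = " "))
  }
  best <- which(conv)[which.min(vals[conv])]
  pars <- unpack_paths(fits[[best]]$par, comps, p)
  sol <- neg2ll_concentrated(pars, units)
  pars$beta <- sol$beta
  dimnames(pars$beta) <- list(units$covariate_names, units$traits)

  structure(list(
    X = pars$X, Y = pars$Y, Z = pars$Z, beta = pars$beta,
    minus2ll = fits[[best]]$value,
    n_free_params = length(fits[[best]]$par) + p * q,
    n_cov_params = length(fits[[best]]$par),
    converged = TRUE, components = comps, traits = units$traits,
    p = p, q = q, n_units = units$n_units, n_persons = units$n_persons,
    units = units,
    start_log = data.frame(start = seq_along(fits), minus2ll = vals,
                           code = vapply(fits, function(f) f$convergence,
                                         integer(1)))
  ), class = "cholesky_fit")
}

#' @export
print.cholesky_fit <- function(x, ...) {
  cat(sprintf("Cholesky %s fit: %d traits, %d likelihood units, -2lnL = %.3f (%d free parameters)\n",
              paste(x$components, collapse = ""), x$p, x$n_units,
              x$minus2ll, x$n_free_params))
  invisible(x)
}

#' Upper-tail chi-square probability
#'
#' @param x non-negative statistic.
#' @param df degrees of freedom (>= 1).
#' @return `P(Chi2_df >= x)`.
#' @export
chisq_sf <- function(x, df) {
  if (any(df < 1)) stop("df must be >= 1")
  if (any(x < 0)) stop("x must be >= 0")
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Likelihood-ratio test between nested Cholesky fits
#'
#' The difference in -2 log-likelihood between a nested sub-model (e.g. AE)
#' and the full model (e.g. ACE) is referred to a chi-square whose degrees
#' of freedom equal the difference in free parameter counts (for a dropped
#' p x p factor, its p(p+1)/2 paths).
#'
#' @param full,nested `cholesky_fit` objects, `nested`'s components a strict
#'   subset of `full`'s on the same traits.
#' @return list `delta_chi2`, `df`, `p`.
#' @export
compare_lrt <- function(full, nested) {
  stopifnot(inherits(full, "cholesky_fit"), inherits(nested, "cholesky_fit"))
  if (!all(nested$components %in% full$components) ||
      length(nested$components) >= length(full$components) ||
      !identical(full$traits, nested$traits))
    stop("models are not nested")
  delta <- nested$minus2ll - full$minus2ll
  if (delta < -1e-6)
    warning("nested model fits better than the full model; optimization issue")
  delta <- max(delta, 0)
  df <- full$n_free_params - nested$n_free_params
  list(delta_chi2 = delta, df = df, p = chisq_sf(delta, df))
}

#' Standardized variance components of a Cholesky fit
#'
#' Expresses each squared path as a percentage of the trait's total model
#' variance: entry (j, k) of component A is `100 * X[j,k]^2 / Sigma[j,j]`
#' (likewise C, E), so each trait's entries across all components sum to
#' 100%.
#'
#' @param fit a `cholesky_fit` (or a bare params list with `X`/`Y`/`Z`).
#' @return named list of p x p percentage matrices (one per component) with
#'   attribute `h2` (per-trait A-row sums / 100) and `total_var`.
#' @export
standardize <- function(fit) {
  paths <- list(A = fit$X, C = fit$Y, E = fit$Z)
  paths <- paths[!vapply(paths, is.null, logical(1))]
  sigma_diag <- Reduce(`+`, lapply(paths, function(m) rowSums(m^2)))
  if (any(sigma_diag <= 0)) stop("zero total variance for a trait")
  out <- lapply(paths, function(m) 100 * m^2 / sigma_diag)
  traits <- fit$traits %||% paste0("t", seq_along(sigma_diag))
  out <- lapply(out, function(m) {
    dimnames(m) <- list(traits, traits)
    m
  })
  attr(out, "h2") <- if (is.null(out$A)) rep(0, length(sigma_diag)) else
    rowSums(out$A) / 100
  attr(out, "total_var") <- sigma_diag
  out
}

component_cor <- function(m) {
  v <- diag(m)
  r <- m / sqrt(outer(v, v))
  r[v <= 0, ] <- NA_real_
  r[, v <= 0] <- NA_real_
  diag(r)[v > 0] <- 1
  r
}

#' Genetic, environmental and phenotypic correlation matrices
#'
#' `rA[j,k] = A[j,k] / sqrt(A[j,j] A[k,k])` with `A = XX'` (likewise rC,
#' rE); `rP` from the total model covariance. Correlations for a trait with
#' zero component variance are reported missing.
#'
#' @param fit a `cholesky_fit` or bare params list.
#' @return named list of correlation matrices (`rA`, `rC` when present,
#'   `rE`, `rP`).
#' @export
component_correlations <- function(fit) {
  A <- if (is.null(fit$X)) NULL else tcrossprod(fit$X)
  C <- if (is.null(fit$Y)) NULL else tcrossprod(fit$Y)
  E <- tcrossprod(fit$Z)
  sigma <- Reduce(`+`, Filter(Negate(is.null), list(A, C, E)))
  out <- list()
  if (!is.null(A)) out$rA <- component_cor(A)
  if (!is.null(C)) out$rC <- component_cor(C)
  out$rE <- component_cor(E)
  out$rP <- component_cor(sigma)
  traits <- fit$traits
  if (!is.null(traits))
    out <- lapply(out, function(m) {
      dimnames(m) <- list(traits, traits)
      m
    })
  out
}

# profiled -2lnL with one free path parameter fixed (mean coefficients are
# concentrated out)
profile_value <- function(fit, index, value) {
  comps <- fit$components
  p <- fit$p
  n_paths <- fit$n_cov_params
  free <- setdiff(seq_len(n_paths), index)
  theta0 <- pack_paths(fit[c("X", "Y", "Z")], comps, p)
  lower <- path_bounds(comps, p)
  obj <- function(th_free) {
    th <- numeric(n_paths)
    th[index] <- value
    th[free] <- th_free
    neg2ll_concentrated(unpack_paths(th, comps, p), fit$units)$value
  }
  if (!length(free))
    return(neg2ll_concentrated(unpack_paths(value, comps, p),
                               fit$units)$value)
  opt <- stats::optim(theta0[free], obj, method = "L-BFGS-B",
                      lower = lower[free],
                      control = list(maxit = 1000, factr = 4.5e4))
  opt$value
}

#' Profile-likelihood confidence interval
#'
#' Likelihood-based interval for a free parameter of a Cholesky fit or for
#' the heritability of a univariate model: the bounds are the values at
#' which the profiled -2 log-likelihood (re-optimizing all other
#' parameters) rises by the chi-square(1) quantile above its minimum. A
#' bound that runs into the parameter-space boundary (e.g. a variance path
#' at 0) is reported at the boundary and flagged one-sided. For derived
#' quantities of multivariate fits use [bootstrap_ci()]; the method used is
#' recorded in the result.
#'
#' @param fit a `cholesky_fit` carrying its likelihood units.
#' @param quantity an integer index into the packed path-parameter vector
#'   (column-major lower triangles, components in A, C, E order) or `"h2"`
#'   for a univariate model's heritability.
#' @param level confidence level (default 0.95).
#' @return list `lower`, `upper`, `level`, `method`, `boundary` flags.
#' @export
profile_ci <- function(fit, quantity = "h2", level = 0.95) {
  crit <- stats::qchisq(level, 1)
  target <- fit$minus2ll + crit

  if (identical(quantity, "h2")) {
    if (fit$p != 1)
      stop("profile h2 is implemented for univariate fits; use bootstrap_ci()")
    std <- standardize(fit)
    h2_hat <- attr(std, "h2")[1]
    total <- attr(std, "total_var")[1]
    prof <- function(h2) {
      # reparameterize: fix the A share, optimize the total variance (the
      # mean coefficients concentrate out)
      obj <- function(lv) {
        v <- exp(lv)
        pars <- list(
          X = if ("A" %in% fit$components) matrix(sqrt(h2 * v), 1, 1) else NULL,
          Y = if ("C" %in% fit$components) matrix(0, 1, 1) else NULL,
          Z = matrix(sqrt((1 - h2) * v), 1, 1))
        neg2ll_concentrated(pars, fit$units)$value
      }
      stats::optim(log(total), obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12))$value
    }
    bounds01 <- c(1e-8, 1 - 1e-8)
    find <- function(side) {
      lim <- if (side < 0) bounds01[1] else bounds01[2]
      f_lim <- prof(lim) - target
      if (f_lim < 0) return(list(value = if (side < 0) 0 else 1, boundary = TRUE))
      root <- stats::uniroot(function(h) prof(h) - target,
                             lower = min(h2_hat, lim), upper = max(h2_hat, lim),
                             tol = 1e-4)
      list(value = root$root, boundary = FALSE)
    }
    lo <- find(-1)
    hi <- find(1)
    return(list(lower = lo$value, upper = hi$value, level = level,
                method = "profile", estimate = h2_hat,
                boundary = c(lower = lo$boundary, upper = hi$boundary)))
  }

  stopifnot(is.numeric(quantity), length(quantity) == 1)
  index <- as.integer(quantity)
  theta_hat <- pack_paths(fit[c("X", "Y", "Z")], fit$components,
                          fit$p)[index]
  lower_bound <- path_bounds(fit$components, fit$p)[index]
  step <- 0.5 * abs(theta_hat) + 0.2
  find <- function(dir) {
    v <- theta_hat
    for (i in 1:30) {
      v_try <- v + dir * step * 1.6^(i - 1)
      if (dir < 0 && v_try <= lower_bound) {
        if (profile_value(fit, index, lower_bound) - target < 0)
          return(list(value = lower_bound, boundary = TRUE))
        v_try <- lower_bound
      }
      if (profile_value(fit, index, v_try) - target >= 0) {
        root <- stats::uniroot(function(x) profile_value(fit, index, x) - target,
                               lower = min(v_try, theta_hat),
                               upper = max(v_try, theta_hat), tol = 1e-4)
        return(list(value = root$root, boundary = FALSE))
      }
      if (identical(v_try, lower_bound))
        return(list(value = lower_bound, boundary = TRUE))
    }
    list(value = NA_real_, boundary = TRUE)
  }
  lo <- find(-1)
  hi <- find(1)
  list(lower = lo$value, upper = hi$value, level = level, method = "profile",
       estimate = theta_hat,
       boundary = c(lower = lo$boundary, upper = hi$boundary))
}

#' Family-resampling bootstrap confidence interval
#'
#' Percentile interval for any statistic of a refitted model, resampling
#' whole families with replacement (preserving twin structure). Offered as
#' the fallback interval method for derived quantities of multivariate fits
#' (multivariate heritabilities, genetic correlations).
#'
#' @param phenotypes,pedigree,traits,components,covariates as [fit_model()].
#' @param statistic function of a `cholesky_fit` returning a scalar.
#' @param B number of bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed.
#' @return list `lower`, `upper`, `level`, `method = "bootstrap"`, `B`.
#' @export
bootstrap_ci <- function(phenotypes, pedigree, traits, statistic,
                         components = "AE", covariates = c("sex", "age"),
                         B = 200, level = 0.95, seed = 1) {
  set.seed(substream_seed(seed, "bootstrap"))
  fams <- unique(pedigree$family_id)
  stat <- numeric(B)
  for (b in seq_len(B)) {
    pick <- sample(fams, length(fams), replace = TRUE)
    ped_b <- do.call(rbind, lapply(seq_along(pick), function(i) {
      pd <- pedigree[pedigree$family_id == pick[i], , drop = FALSE]
      pd$family_id <- sprintf("B%05d", i)
      pd
    }))
    ped_b$new_id <- paste0(ped_b$person_id, "_", seq_len(nrow(ped_b)))
    ph_b <- merge(ped_b[c("person_id", "new_id")], phenotypes,
                  by = "person_id")
    ph_b$person_id <- ph_b$new_id
    ped_b$person_id <- ped_b$new_id
    fit_b <- fit_model(ph_b, ped_b, traits, components, covariates,
                       n_starts = 1)
    stat[b] <- statistic(fit_b)
  }
  qs <- stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE)
  list(lower = unname(qs[1]), upper = unname(qs[2]), level = level,
       method = "bootstrap", B = B)
}
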