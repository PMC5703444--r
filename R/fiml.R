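#' Expected twin-pair covariance under a Cholesky ACE model
#'
#' For lower-triangular path matrices `X`, `Y`, `Z` (A = XX', C = YY',
#' E = ZZ'), the expected 2p x 2p covariance of a twin pair has the
#' within-person covariance A + C + E on the diagonal blocks and the
#' cross-twin covariance A + C (MZ) or 0.5 A + C (DZ) off the diagonal.
#'
#' @param params list with lower-triangular `X`, `Y` (or `NULL`), `Z`.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return symmetric 2p x 2p covariance matrix, persons as the outer blocks.
#' @export
expected_pair_cov <- function(params, zygosity) {
  k <- switch(zygosity, MZ = 1, DZ = 0.5,
              stop("unknown zygosity: ", zygosity))
  A <- tcrossprod(params$X)
  C <- if (is.null(params$Y)) 0 * A else tcrossprod(params$Y)
  E <- tcrossprod(params$Z)
  R <- matrix(c(1, k, k, 1), 2, 2)
  J <- matrix(1, 2, 2)
  kronecker(R, A) + kronecker(J, C) + kronecker(diag(2), E)
}

# Build the grouped likelihood-unit structure used by neg2ll_fiml.
#
# Likelihood units are MZ pairs, DZ pairs, and singletons (unpaired twins,
# triplet-derived singletons, extra siblings). By default singletons enter
# as independent records; sibling_mode = "dz_like" instead keeps whole
# families together with A-relatedness 0.5 between all non-MZ member pairs.
# Units are grouped by (relatedness matrix, observed-entry pattern) so the
# -2 log-likelihood is computed with one covariance inversion per group.
build_twin_units <- function(phenotypes, pedigree, traits,
                             covariates = c("sex", "age"),
                             sibling_mode = c("independent", "dz_like")) {
  sibling_mode <- match.arg(sibling_mode)
  d <- merge(phenotypes, pedigree[c("person_id", "family_id", "zygosity",
                                    "role")], by = "person_id")
  d <- d[rowSums(!is.na(d[traits])) > 0, , drop = FALSE]
  if (!nrow(d)) stop("no persons with observed traits")
  p <- length(traits)

  if (!is.null(covariates)) {
    stopifnot(all(c("sex", "age") %in% names(d)))
    agec <- d$age - mean(d$age, na.rm = TRUE)
    W <- cbind(1, d$sex, agec, agec^2, d$sex * agec, d$sex * agec^2)
    colnames(W) <- c("intercept", "sex", "age_c", "age_c2", "sex_age",
                     "sex_age2")
  } else {
    W <- matrix(1, nrow(d), 1, dimnames = list(NULL, "intercept"))
  }
  q <- ncol(W)

  units <- list()
  for (fid in unique(d$family_id)) {
    rows <- which(d$family_id == fid)
    if (sibling_mode == "dz_like") {
      m <- length(rows)
      R <- matrix(0.5, m, m)
      diag(R) <- 1
      mz <- d$zygosity[rows] == "MZ"
      R[mz, mz] <- 1
      units[[length(units) + 1L]] <- list(rows = rows, R = R)
    } else {
      tw <- rows[d$role[rows] %in% c("twin1", "twin2") &
                   d$zygosity[rows] %in% c("MZ", "DZ")]
      if (length(tw) == 2) {
        k <- if (d$zygosity[tw[1]] == "MZ") 1 else 0.5
        units[[length(units) + 1L]] <-
          list(rows = tw, R = matrix(c(1, k, k, 1), 2, 2))
        rows <- setdiff(rows, tw)
      }
      for (r in rows)
        units[[length(units) + 1L]] <- list(rows = r, R = matrix(1, 1, 1))
    }
  }

  Ymat <- as.matrix(d[traits])
  keys <- vapply(units, function(u) {
    paste(length(u$rows), paste(round(u$R, 3), collapse = ","),
          paste(as.integer(t(!is.na(Ymat[u$rows, , drop = FALSE]))),
                collapse = ""), sep = "|")
  }, character(1))

  groups <- lapply(split(seq_along(units), keys), function(ix) {
    m <- length(units[[ix[1]]]$rows)
    mask <- as.vector(t(!is.na(Ymat[units[[ix[1]]]$rows, , drop = FALSE])))
    col_slot <- rep(seq_len(m), each = p)[mask]
    col_trait <- rep(seq_len(p), m)[mask]
    rm <- vapply(ix, function(i) units[[i]]$rows, integer(m))
    rowmat <- if (m == 1) matrix(rm, ncol = 1) else t(rm)
    Yg <- matrix(t(Ymat[as.vector(t(rowmat)), , drop = FALSE]),
                 nrow = length(ix), byrow = TRUE)[, mask, drop = FALSE]
    Wg <- lapply(seq_len(m), function(s) W[rowmat[, s], , drop = FALSE])
    # sufficient statistics for the GLS concentration of the mean model
    CYY <- crossprod(Yg)
    CWW <- lapply(seq_len(m), function(s)
      lapply(seq_len(m), function(s2) crossprod(Wg[[s]], Wg[[s2]])))
    CWY <- lapply(seq_len(m), function(s) crossprod(Wg[[s]], Yg))
    list(R = units[[ix[1]]]$R, mask = mask, col_slot = col_slot,
         col_trait = col_trait, Y = Yg, W = Wg, n = length(ix),
         CYY = CYY, CWW = CWW, CWY = CWY)
  })

  list(groups = groups, p = p, q = q, traits = traits,
       covariate_names = colnames(W), n_units = length(units),
       n_persons = nrow(d), data = d, W = W)
}

# expected covariance of one likelihood unit given its relatedness matrix
unit_cov <- function(A, C, E, R) {
  m <- nrow(R)
  J <- matrix(1, m, m)
  kronecker(R, A) + kronecker(J, C) + kronecker(diag(m), E)
}

#' Full-information ML -2 log-likelihood of a Cholesky twin model
#'
#' Sums, over likelihood units (twin pairs and singletons), the multivariate
#' normal deviance of each unit's *observed* trait entries:
#' `k log(2 pi) + log det(Sigma_obs) + (y - mu)' Sigma_obs^{-1} (y - mu)`,
#' where `Sigma_obs` is the sub-matrix of the expected unit covariance for
#' the observed entries and `mu` comes from the per-person covariate mean
#' model. Missing traits are marginalized out by subsetting, so unpaired
#' twins and singletons contribute through their observed entries alone.
#'
#' @param params list with lower-triangular `X` (or `NULL`), `Y` (or
#'   `NULL`), `Z`, and `beta` (q x p mean coefficients).
#' @param units structure from `build_twin_units()`.
#' @param optimizer_safe if `TRUE`, a singular observed covariance returns a
#'   large penalty instead of an error.
#' @return scalar -2 log-likelihood.
#' @export
neg2ll_fiml <- function(params, units, optimizer_safe = FALSE) {
  p <- units$p
  zero <- matrix(0, p, p)
  A <- if (is.null(params$X)) zero else tcrossprod(params$X)
  C <- if (is.null(params$Y)) zero else tcrossprod(params$Y)
  E <- tcrossprod(params$Z)
  beta <- params$beta
  total <- 0
  for (g in units$groups) {
    sigma <- unit_cov(A, C, E, g$R)[g$mask, g$mask, drop = FALSE]
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) {
      if (optimizer_safe) return(1e12)
      stop("singular observed covariance in a likelihood unit")
    }
    mu_slot <- lapply(g$W, function(w) w %*% beta)
    M <- matrix(0, g$n, length(g$col_slot))
    for (cc in seq_along(g$col_slot))
      M[, cc] <- mu_slot[[g$col_slot[cc]]][, g$col_trait[cc]]
    Rsd <- g$Y - M
    vinv <- chol2inv(ch)
    quad <- sum(Rsd * (Rsd %*% vinv))
    total <- total + g$n * (length(g$col_slot) * log(2 * pi) +
                              2 * sum(log(diag(ch)))) + quad
  }
  total
}

# -2 log-likelihood concentrated over the mean coefficients: for fixed
# covariance paths the mean model is linear, so its GLS solution is closed
# form and the optimizer searches the path parameters only. Returns the
# criterion with the solved beta attached.
neg2ll_concentrated <- function(paths, units, optimizer_safe = TRUE) {
  p <- units$p
  q <- units$q
  zero <- matrix(0, p, p)
  A <- if (is.null(paths$X)) zero else tcrossprod(paths$X)
  C <- if (is.null(paths$Y)) zero else tcrossprod(paths$Y)
  E <- tcrossprod(paths$Z)
  pq <- p * q
  Amat <- matrix(0, pq, pq)
  bvec <- numeric(pq)
  syy <- 0
  const <- 0
  for (g in units$groups) {
    sigma <- unit_cov(A, C, E, g$R)[g$mask, g$mask, drop = FALSE]
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) {
      if (optimizer_safe) return(list(value = 1e12, beta = NULL))
      stop("singular observed covariance in a likelihood unit")
    }
    vinv <- chol2inv(ch)
    const <- const + g$n * (length(g$col_slot) * log(2 * pi) +
                              2 * sum(log(diag(ch))))
    syy <- syy + sum(vinv * g$CYY)
    m <- nrow(g$R)
    for (s in seq_len(m)) {
      idx_s <- which(g$col_slot == s)
      for (s2 in seq_len(m)) {
        idx_s2 <- which(g$col_slot == s2)
        # p x p matrix of vinv entries for (slot s, trait j) x (slot s2, j2)
        Vb <- matrix(0, p, p)
        Vb[cbind(rep(g$col_trait[idx_s], each = length(idx_s2)),
                 rep(g$col_trait[idx_s2], length(idx_s)))] <-
          as.vector(t(vinv[idx_s, idx_s2, drop = FALSE]))
        Amat <- Amat + kronecker(Vb, g$CWW[[s]][[s2]])
      }
      # right-hand side: trait block j at slot s gets CWY[[s]] %*% vinv[c(s,j), ]
      Bs <- g$CWY[[s]] %*% t(vinv[idx_s, , drop = FALSE])
      for (k in seq_along(idx_s)) {
        j <- g$col_trait[idx_s[k]]
        bvec[(j - 1) * q + seq_len(q)] <-
          bvec[(j - 1) * q + seq_len(q)] + Bs[, k]
      }
    }
  }
  betav <- tryCatch(solve(Amat, bvec), error = function(e) NULL)
  if (is.null(betav)) {
    if (optimizer_safe) return(list(value = 1e12, beta = NULL))
    stop("mean-model normal equations are singular")
  }
  list(value = const + syy - sum(bvec * betav),
       beta = matrix(betav, q, p))
}
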