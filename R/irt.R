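#' Graded-response category probabilities
#'
#' Samejima graded-response model with a logistic link: for an item with
#' discrimination `a` and ordered thresholds `b_1 < ... < b_{K-1}`, the
#' probability of responding in category `k` at latent value `theta` is
#' `P(X >= k) - P(X >= k+1)` with `P(X >= k+1) = plogis(a (theta - b_k))`.
#'
#' @param theta numeric vector of latent values.
#' @param a discrimination (> 0, or 0 for a totally uninformative item).
#' @param b strictly increasing numeric vector of thresholds.
#' @return a `length(theta) x K` matrix of category probabilities.
#' @export
grm_probs <- function(theta, a, b) {
  if (is.unsorted(b, strictly = TRUE)) stop("thresholds must be strictly increasing")
  if (a < 0) stop("discrimination must be non-negative")
  pstar <- sapply(b, function(bk) stats::plogis(a * (theta - bk)))
  pstar <- matrix(pstar, nrow = length(theta))
  cbind(1, pstar) - cbind(pstar, 0)
}

# sample one response per theta from a GRM item
grm_sample <- function(theta, a, b) {
  u <- stats::runif(length(theta))
  s <- sapply(b, function(bk) stats::plogis(a * (theta - bk)))
  s <- matrix(s, nrow = length(theta))
  1L + rowSums(u < s)
}

gh_nodes <- function(n_quad) {
  gh <- pracma::gaussHermite(n_quad)
  list(theta = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

# n x Q log-likelihood matrix of response patterns over quadrature nodes
pattern_loglik <- function(resp, pars, theta) {
  n <- nrow(resp)
  ll <- matrix(0, n, length(theta))
  for (j in seq_along(pars)) {
    item <- names(pars)[j]
    if (!item %in% colnames(resp)) next
    x <- resp[[item]]
    logp <- log(pmax(grm_probs(theta, pars[[j]]$a, pars[[j]]$b), 1e-300))
    for (k in seq_len(ncol(logp))) {
      rows <- which(!is.na(x) & x == k)
      if (length(rows))
        ll[rows, ] <- ll[rows, ] + matrix(logp[, k], length(rows),
                                          length(theta), byrow = TRUE)
    }
  }
  ll
}

# starting values from observed cumulative category proportions
grm_start <- function(x) {
  tab <- tabulate(x[!is.na(x)], nbins = max(x, na.rm = TRUE))
  cum <- rev(cumsum(rev(tab)))[-1] / sum(tab)
  cum <- pmin(pmax(cum, 0.01), 0.99)
  list(a = 1, b = sort(-stats::qlogis(cum)))
}

# pack (a, b) into an unconstrained vector and back: a = exp(la),
# b = (b1, b1 + exp(d2), ...) guarantees a > 0 and increasing thresholds
grm_pack <- function(a, b) c(log(a), b[1], if (length(b) > 1) log(diff(b)))
grm_unpack <- function(par) {
  # clamp before exponentiating: keeps a and the threshold gaps in a sane
  # psychometric range and keeps the floored minimum gap representable next
  # to the largest admissible threshold (a huge gap followed by a 1e-6 one
  # would otherwise be absorbed by floating point)
  par <- pmin(pmax(par, -10), 10)
  a <- exp(par[1])
  b <- cumsum(c(par[2], if (length(par) > 2) pmax(exp(par[-(1:2)]), 1e-6)))
  list(a = a, b = b)
}

#' Calibrate graded-response item parameters by marginal maximum likelihood
#'
#' Fits the graded-response model to one or more instruments by an EM
#' algorithm that integrates the standard-normal latent trait over fixed
#' Gauss-Hermite quadrature. When several instruments are supplied they are
#' calibrated concurrently on one latent scale: all items enter one response
#' matrix and the persons who completed more than one instrument anchor the
#' common metric (an error is raised if no such overlap exists). The latent
#' distribution is fixed standard normal, which identifies the scale.
#'
#' @param tables named list of wide response tables (each with a `person_id`
#'   column and one integer column per item; categories coded 1..K, `NA` for
#'   missing). A single data.frame is treated as one instrument.
#' @param n_quad number of Gauss-Hermite quadrature nodes (default 61).
#' @param tol EM convergence tolerance on the marginal log-likelihood.
#' @param max_iter maximum EM iterations; non-convergence is an error whose
#'   message carries the log-likelihood trace.
#' @return an object of class `irt_calibration`: per-item discrimination and
#'   thresholds, instrument membership, quadrature settings, the
#'   log-likelihood trace and convergence flag.
#' @export
irt_calibrate <- function(tables, n_quad = 61, tol = 1e-5, max_iter = 500) {
  if (is.data.frame(tables)) tables <- list(instrument = tables)
  stopifnot(all(vapply(tables, function(t) "person_id" %in% names(t),
                       logical(1))))
  if (length(tables) > 1) {
    answered <- lapply(tables, function(t) {
      t$person_id[rowSums(!is.na(t[setdiff(names(t), "person_id")])) > 0]
    })
    overlap <- Reduce(intersect, answered)
    if (length(overlap) == 0)
      stop("concurrent calibration requires persons with responses on ",
           "every instrument (zero overlap)")
  }
  instrument_of <- unlist(lapply(names(tables), function(nm) {
    stats::setNames(rep(nm, ncol(tables[[nm]]) - 1),
                    setdiff(names(tables[[nm]]), "person_id"))
  }))
  resp <- Reduce(function(x, y) merge(x, y, by = "person_id", all = TRUE),
                 tables)
  items <- setdiff(names(resp), "person_id")
  resp_m <- resp[items]

  # collapse empty categories so every fitted item has contiguous codes
  for (j in items) {
    x <- resp_m[[j]]
    lev <- sort(unique(x[!is.na(x)]))
    if (length(lev) < 2) stop("item ", j, " has fewer than two observed categories")
    if (!identical(lev, seq_len(max(lev)))) {
      warning("item ", j, ": empty categories collapsed")
      resp_m[[j]] <- match(x, lev)
    }
  }

  quad <- gh_nodes(n_quad)
  pars <- lapply(resp_m, grm_start)
  names(pars) <- items
  keep <- rowSums(!is.na(resp_m)) > 0
  resp_fit <- resp_m[keep, , drop = FALSE]

  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    llm <- pattern_loglik(resp_fit, pars, quad$theta)
    m <- apply(llm, 1, max)
    lik <- exp(llm - m)
    marg <- as.vector(lik %*% quad$w)
    ll <- sum(log(marg) + m)
    ll_trace <- c(ll_trace, ll)
    post <- lik * rep(quad$w, each = nrow(lik)) / marg

    for (j in items) {
      x <- resp_fit[[j]]
      K <- length(pars[[j]]$b) + 1
      counts <- matrix(0, length(quad$theta), K)
      for (k in seq_len(K)) {
        rows <- which(!is.na(x) & x == k)
        if (length(rows)) counts[, k] <- colSums(post[rows, , drop = FALSE])
      }
      nll <- function(par) {
        if (any(!is.finite(par))) return(1e10)   # stray NaN from line search
        up <- grm_unpack(par)
        -sum(counts * log(pmax(grm_probs(quad$theta, up$a, up$b), 1e-300)))
      }
      opt <- stats::optim(grm_pack(pars[[j]]$a, pars[[j]]$b), nll,
                          method = "BFGS",
                          control = list(maxit = 50, reltol = 1e-10))
      pars[[j]] <- grm_unpack(opt$par)
    }
    if (it > 1 && abs(ll_trace[it] - ll_trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("EM did not converge in ", max_iter, " iterations; log-likelihood ",
         "trace: ", paste(round(utils::tail(ll_trace, 5), 4), collapse = ", "))
  structure(list(pars = pars, instrument = instrument_of[items],
                 n_quad = n_quad, loglik = ll_trace, converged = converged),
            class = "irt_calibration")
}

#' Expected a-posteriori latent scores
#'
#' Scores response patterns under a calibrated graded-response model: the
#' posterior mean of the standard-normal latent trait given the responses,
#' computed by Gauss-Hermite quadrature. Persons with no scored item get
#' `NA`.
#'
#' @param responses wide response table (`person_id` plus item columns).
#' @param calibration an [irt_calibrate()] result.
#' @return data.frame with `person_id`, `score` and `n_items` (number of
#'   non-missing responses used).
#' @export
irt_eap_score <- function(responses, calibration) {
  stopifnot(inherits(calibration, "irt_calibration"))
  items <- intersect(names(calibration$pars), names(responses))
  if (length(items) == 0) stop("no calibrated items found in the responses")
  for (j in items) {
    K <- length(calibration$pars[[j]]$b) + 1
    x <- responses[[j]]
    if (any(!is.na(x) & (x < 1 | x > K)))
      stop("item ", j, ": response outside the calibrated categories")
  }
  quad <- gh_nodes(calibration$n_quad)
  llm <- pattern_loglik(responses[items], calibration$pars, quad$theta)
  m <- apply(llm, 1, max)
  lik <- exp(llm - m)
  wpost <- lik * rep(quad$w, each = nrow(lik))
  score <- as.vector(wpost %*% quad$theta) / as.vector(wpost %*% rep(1, length(quad$theta)))
  n_items <- rowSums(!is.na(responses[items]))
  score[n_items == 0] <- NA_real_
  data.frame(person_id = responses$person_id, score = score,
             n_items = n_items)
}
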