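#' Offset log10 transformation of raw hair cortisol
#'
#' Adds the smallest measurable concentration to every value before taking
#' log10, so that zero concentrations remain finite. Missing values
#' propagate; negative inputs are an error.
#'
#' @param x raw concentrations (pg/mg), `>= 0` or `NA`.
#' @param offset value added before the log; `NULL` uses the smallest
#'   positive observed value. Default 0.1.
#' @return `log10(x + offset)`.
#' @export
log10_offset_transform <- function(x, offset = 0.1) {
  bad <- which(!is.na(x) & x < 0)
  if (length(bad))
    stop("negative concentration at record(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (is.null(offset)) {
    pos <- x[!is.na(x) & x > 0]
    if (!length(pos)) stop("no positive values to derive the offset from")
    offset <- min(pos)
  }
  log10(x + offset)
}

#' Winsorize at three standard deviations
#'
#' Values beyond `mean +/- 3 SD` are replaced by the corresponding bound.
#' Mean and SD are computed on the input itself, outliers included. Note
#' that the operation is idempotent only on inputs that need no clipping:
#' once values are moved to a bound, the SD of the clipped data is smaller,
#' so a second application would shrink the bounds further. The transform is
#' applied exactly once per dataset, as is standard.
#'
#' @param x numeric vector (usually log10-scale HCC).
#' @param n_sd number of SDs defining the bounds (default 3).
#' @return list with `values` (clipped vector), `n_clipped`, and `bounds`.
#' @export
winsorize_3sd <- function(x, n_sd = 3) {
  obs <- x[!is.na(x)]
  if (length(obs) < 2) stop("winsorization needs at least two non-missing values")
  m <- mean(obs)
  s <- stats::sd(obs)
  lo <- m - n_sd * s
  hi <- m + n_sd * s
  n_clipped <- sum(!is.na(x) & (x < lo | x > hi))
  list(values = pmin(pmax(x, lo), hi), n_clipped = n_clipped,
       bounds = c(lower = lo, upper = hi))
}

as_factor_frame <- function(factors, n) {
  f <- as.data.frame(factors, stringsAsFactors = FALSE)
  stopifnot(nrow(f) == n)
  f[] <- lapply(f, factor)
  f
}

#' Screen experimental covariates of log-HCC
#'
#' Fits the full joint linear model of log-HCC on all experimental factors
#' and reports, per factor, the percentage increase in residual variance
#' when that factor is dropped from the full model, together with the
#' partial F-test p-value. The variance-increase convention is
#' `(Var_reduced - Var_full) / Var_full * 100` with variances computed as
#' mean squared residuals.
#'
#' @param log_hcc numeric response.
#' @param factors data.frame (or list) of categorical covariates; by
#'   convention ordered batch, storage, month, study.
#' @return data.frame with one row per factor: `factor`, `var_increase_pct`,
#'   `F`, `df`, `p`.
#' @export
covariate_screen <- function(log_hcc, factors) {
  f <- as_factor_frame(factors, length(log_hcc))
  single <- vapply(f, function(x) nlevels(droplevels(x[!is.na(log_hcc)])) < 2,
                   logical(1))
  if (any(single)) {
    warning("excluding single-level factor(s): ",
            paste(names(f)[single], collapse = ", "))
    f <- f[!single]
  }
  if (!ncol(f)) stop("no usable factors")
  dat <- cbind(y = log_hcc, f)
  full <- stats::lm(y ~ ., data = dat, na.action = stats::na.exclude)
  v_full <- mean(stats::residuals(full)^2, na.rm = TRUE)
  rows <- lapply(names(f), function(nm) {
    reduced <- stats::update(full, stats::as.formula(paste(". ~ . -", nm)))
    v_red <- mean(stats::residuals(reduced)^2, na.rm = TRUE)
    a <- stats::anova(reduced, full)
    data.frame(factor = nm,
               var_increase_pct = 100 * (v_red - v_full) / v_full,
               F = a$F[2], df = a$Df[2], p = a$`Pr(>F)`[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Residualize fixed experimental effects out of log-HCC
#'
#' OLS regression of the response on dummy-coded experimental factors; the
#' residuals (orthogonal to every design column) carry forward to all
#' downstream analyses.
#'
#' @param y numeric response (log10-scale HCC).
#' @param factors data.frame of categorical covariates.
#' @return numeric residual vector (`NA` where `y` is missing).
#' @export
residualize_fixed_effects <- function(y, factors) {
  f <- as_factor_frame(factors, length(y))
  usable <- vapply(f, function(x) nlevels(droplevels(x[!is.na(y)])) >= 2,
                   logical(1))
  if (!any(usable)) return(y - mean(y, na.rm = TRUE))
  dat <- cbind(y = y, f[usable])
  mm <- stats::model.matrix(~ ., data = f[usable])
  qrm <- qr(mm[!is.na(y), , drop = FALSE])
  if (qrm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; aliased levels: ",
         paste(aliased, collapse = ", "))
  }
  fit <- stats::lm(y ~ ., data = dat, na.action = stats::na.exclude)
  as.numeric(stats::residuals(fit))
}

#' Combine instrument scores on one z-scale
#'
#' z-standardizes scores within each instrument (mean 0, SD 1 among that
#' instrument's respondents) and concatenates them into a single column, the
#' standard way of harmonizing sum scores from different questionnaires
#' measuring the same construct.
#'
#' @param scores_by_instrument named list of data.frames with columns
#'   `person_id` and `score`.
#' @return data.frame `person_id`, `instrument`, `z`, with the per-
#'   instrument centers/scales in attribute `scaling` (reusable for scoring
#'   later measurements on the same metric).
#' @export
z_combine <- function(scores_by_instrument) {
  stopifnot(length(scores_by_instrument) >= 1)
  scaling <- list()
  out <- lapply(names(scores_by_instrument), function(nm) {
    d <- scores_by_instrument[[nm]]
    s <- d$score[!is.na(d$score)]
    if (length(s) < 2) stop("instrument ", nm, " has fewer than two scored persons")
    if (stats::sd(s) == 0) stop("instrument ", nm, " has zero score variance")
    scaling[[nm]] <<- c(center = mean(s), scale = stats::sd(s))
    data.frame(person_id = d$person_id, instrument = nm,
               z = (d$score - mean(s)) / stats::sd(s),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "scaling") <- scaling
  res
}
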