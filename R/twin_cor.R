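# ML machinery for the exchangeable bivariate normal twin-pair model:
# common covariate-adjusted means and variance across twin order, one
# within-pair correlation r. For fixed r the mean coefficients and the
# variance profile out by GLS on whitened pairs, leaving a 1-D profile
# likelihood in r (equivalent to the double-entry intraclass correlation
# when there are no covariates).
pair_profile_neg2ll <- function(r, y1, y2, X1, X2) {
  n <- length(y1)
  s <- sqrt(1 - r^2)
  ys <- c(y1, (y2 - r * y1) / s)
  Xs <- rbind(X1, (X2 - r * X1) / s)
  rss <- sum(stats::lm.fit(Xs, ys)$residuals^2)
  v <- rss / (2 * n)
  2 * n * log(v) + n * log(1 - r^2) + 2 * n + 2 * n * log(2 * pi)
}

ml_pair_cor <- function(y1, y2, X1, X2, level = 0.95, ci = TRUE) {
  opt <- stats::optimize(pair_profile_neg2ll, c(-0.999, 0.999),
                         y1 = y1, y2 = y2, X1 = X1, X2 = X2, tol = 1e-8)
  r_hat <- opt$minimum
  out <- list(r = r_hat, minus2ll = opt$objective, n_pairs = length(y1))
  if (ci) {
    target <- opt$objective + stats::qchisq(level, 1)
    f <- function(r) pair_profile_neg2ll(r, y1, y2, X1, X2) - target
    lo <- if (f(-0.999) < 0) -1 else
      stats::uniroot(f, c(-0.999, r_hat), tol = 1e-6)$root
    hi <- if (f(0.999) < 0) 1 else
      stats::uniroot(f, c(r_hat, 0.999), tol = 1e-6)$root
    out$ci <- c(lower = lo, upper = hi)
    out$level <- level
  }
  out
}

# design row per twin; `age` is expected to be pre-centered by the caller
pair_design <- function(d, covariates) {
  if (is.null(covariates)) return(matrix(1, nrow(d), 1))
  cbind(1, d$sex, d$age, d$age^2, d$sex * d$age, d$sex * d$age^2)
}

#' Maximum-likelihood twin correlations
#'
#' Within-pair correlation per trait and zygosity group from a bivariate
#' normal with covariate-adjusted means and equal variances across twin
#' order (the double-entry intraclass correlation), with profile-likelihood
#' confidence intervals.
#'
#' @param phenotypes data.frame with `person_id`, trait columns, and `sex`,
#'   `age` when covariates are used.
#' @param pedigree data.frame with `person_id`, `family_id`, `zygosity`,
#'   `role`.
#' @param traits trait column names.
#' @param covariates `c("sex", "age")` for the standard sex/age mean model,
#'   or `NULL` for intercept-only.
#' @param level confidence level.
#' @param ci compute profile CIs (default TRUE).
#' @return data.frame: `trait`, `zygosity`, `r`, `ci_lower`, `ci_upper`,
#'   `n_pairs`.
#' @export
twin_correlations <- function(phenotypes, pedigree, traits,
                              covariates = c("sex", "age"), level = 0.95,
                              ci = TRUE) {
  d <- merge(phenotypes, pedigree[c("person_id", "family_id", "zygosity",
                                    "role")], by = "person_id")
  rows <- list()
  for (zyg in c("MZ", "DZ")) {
    t1 <- d[d$zygosity == zyg & d$role == "twin1", ]
    t2 <- d[d$zygosity == zyg & d$role == "twin2", ]
    m <- merge(t1, t2, by = "family_id", suffixes = c(".1", ".2"))
    for (tr in traits) {
      ok <- !is.na(m[[paste0(tr, ".1")]]) & !is.na(m[[paste0(tr, ".2")]])
      if (sum(ok) < 3)
        stop("fewer than 3 complete ", zyg, " pairs for trait ", tr)
      mm <- m[ok, ]
      if (is.null(covariates)) {
        X1 <- X2 <- matrix(1, nrow(mm), 1)
      } else {
        # age centered over the doubled sample so both members share the basis
        ac <- mean(c(mm$age.1, mm$age.2))
        X1 <- pair_design(data.frame(sex = mm$sex.1, age = mm$age.1 - ac),
                          covariates)
        X2 <- pair_design(data.frame(sex = mm$sex.2, age = mm$age.2 - ac),
                          covariates)
      }
      est <- ml_pair_cor(mm[[paste0(tr, ".1")]], mm[[paste0(tr, ".2")]],
                         X1, X2, level = level, ci = ci)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, zygosity = zyg, r = est$r,
        ci_lower = if (ci) est$ci["lower"] else NA_real_,
        ci_upper = if (ci) est$ci["upper"] else NA_real_,
        n_pairs = est$n_pairs, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-year stability correlation
#'
#' Pearson correlation between the time-1 and time-2 values of a trait on
#' the retest subsample, with the usual Fisher-z interval.
#'
#' @param prepared data.frame with `person_id`, `time_point` and the trait
#'   column (long format).
#' @param trait trait column name.
#' @param level confidence level.
#' @return list `r`, `ci`, `n`.
#' @export
stability_correlation <- function(prepared, trait, level = 0.95) {
  w1 <- prepared[prepared$time_point == 1, c("person_id", trait)]
  w2 <- prepared[prepared$time_point == 2, c("person_id", trait)]
  m <- merge(w1, w2, by = "person_id", suffixes = c(".1", ".2"))
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3) stop("fewer than 3 complete retest records")
  ct <- stats::cor.test(m[[2]], m[[3]], conf.level = level)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int), n = nrow(m))
}

#' Median age-split reanalysis
#'
#' Assigns whole families to the younger or older half by the family's mean
#' age relative to the cohort median (so no family straddles the split) and
#' reruns the Cholesky fit in each half.
#'
#' @param phenotypes,pedigree,traits,components,covariates as [fit_model()].
#' @param min_families smallest admissible number of families per half.
#' @param ... passed to [fit_model()].
#' @return list with `younger` and `older` (each: `fit`, `standardized`,
#'   `h2`, `correlations`, `n_persons`, `mean_age`) and `median_age`.
#' @export
median_split_fit <- function(phenotypes, pedigree, traits, components = "AE",
                             covariates = c("sex", "age"),
                             min_families = 20, ...) {
  d <- merge(phenotypes, pedigree[c("person_id", "family_id")],
             by = "person_id")
  if (any(is.na(d$age))) stop("age must be available for all persons")
  med <- stats::median(d$age)
  fam_age <- tapply(d$age, d$family_id, mean)
  young_f <- names(fam_age)[fam_age <= med]
  old_f <- names(fam_age)[fam_age > med]
  if (min(length(young_f), length(old_f)) < min_families)
    stop("too few families in one half of the split")
  run <- function(fams) {
    ped <- pedigree[pedigree$family_id %in% fams, ]
    ph <- phenotypes[phenotypes$person_id %in% ped$person_id, ]
    fit <- fit_model(ph, ped, traits, components, covariates, ...)
    std <- standardize(fit)
    list(fit = fit, standardized = std, h2 = attr(std, "h2"),
         correlations = component_correlations(fit),
         n_persons = fit$n_persons,
         mean_age = mean(ph$age))
  }
  list(younger = run(young_f), older = run(old_f), median_age = med)
}
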