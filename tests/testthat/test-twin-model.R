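random_paths <- function(p, seed, with_c = FALSE) {
  set.seed(seed)
  lt <- function() {
    m <- matrix(0, p, p)
    m[lower.tri(m, TRUE)] <- rnorm(p * (p + 1) / 2, 0.4, 0.25)
    diag(m) <- abs(diag(m)) + 0.3
    m
  }
  list(X = lt(), Y = if (with_c) lt() else NULL, Z = lt())
}

test_that("expected pair covariance has the ACE block structure", {
  p1 <- list(X = matrix(1), Y = NULL, Z = matrix(1e-8))
  expect_equal(expected_pair_cov(p1, "MZ"), matrix(1, 2, 2), tolerance = 1e-8)
  expect_equal(expected_pair_cov(p1, "DZ"),
               matrix(c(1, 0.5, 0.5, 1), 2, 2), tolerance = 1e-8)
  expect_error(expected_pair_cov(p1, "XX"), "zygosity")
  for (s in 1:5) {
    pr <- random_paths(3, s, with_c = TRUE)
    smz <- expected_pair_cov(pr, "MZ")
    sdz <- expected_pair_cov(pr, "DZ")
    expect_equal(smz, t(smz))
    expect_gte(min(eigen(smz, symmetric = TRUE)$values), -1e-10)
    expect_equal(smz[1:3, 4:6] - sdz[1:3, 4:6], 0.5 * tcrossprod(pr$X))
  }
})

make_toy_units <- function(seed = 1) {
  set.seed(seed)
  ph <- data.frame(person_id = c("a", "b", "c", "d", "e"),
                   t1 = rnorm(5), t2 = c(rnorm(4), NA), t3 = rnorm(5))
  ped <- data.frame(person_id = c("a", "b", "c", "d", "e"),
                    family_id = c("f1", "f1", "f2", "f2", "f3"),
                    zygosity = c("MZ", "MZ", "DZ", "DZ", "singleton"),
                    role = c("twin1", "twin2", "twin1", "twin2", "singleton"))
  list(ph = ph, ped = ped)
}

test_that("FIML deviance equals the brute-force joint-normal density", {
  toy <- make_toy_units(21)
  units <- cortwin:::build_twin_units(toy$ph, toy$ped, c("t1", "t2", "t3"),
                                      covariates = NULL)
  for (s in 1:5) {
    pr <- random_paths(3, 100 + s)
    params <- c(pr, list(beta = matrix(rnorm(3), 1, 3)))
    got <- neg2ll_fiml(params, units)
    mu_pair <- c(params$beta, params$beta)
    want <- 0
    for (fam in list(c("a", "b"), c("c", "d"))) {
      zyg <- toy$ped$zygosity[match(fam[1], toy$ped$person_id)]
      y <- as.vector(t(as.matrix(toy$ph[match(fam, toy$ph$person_id),
                                        c("t1", "t2", "t3")])))
      want <- want + brute_mvn_neg2ll(y, mu_pair, expected_pair_cov(params, zyg))
    }
    y_s <- as.numeric(toy$ph[toy$ph$person_id == "e", c("t1", "t2", "t3")])
    S_w <- tcrossprod(params$X) + tcrossprod(params$Z)
    want <- want + brute_mvn_neg2ll(y_s, as.vector(params$beta), S_w)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("FIML deviance is additive over duplicated families", {
  toy <- make_toy_units(22)
  pr <- c(random_paths(3, 7), list(beta = matrix(0, 1, 3)))
  u1 <- cortwin:::build_twin_units(toy$ph, toy$ped, c("t1", "t2", "t3"),
                                   covariates = NULL)
  ph2 <- rbind(toy$ph,
               transform(toy$ph, person_id = paste0(person_id, "_2")))
  ped2 <- rbind(toy$ped,
                transform(toy$ped, person_id = paste0(person_id, "_2"),
                          family_id = paste0(family_id, "_2")))
  u2 <- cortwin:::build_twin_units(ph2, ped2, c("t1", "t2", "t3"),
                                   covariates = NULL)
  expect_equal(neg2ll_fiml(pr, u2), 2 * neg2ll_fiml(pr, u1),
               tolerance = 1e-10)
})

test_that("univariate AE FIML recovers the generating heritability", {
  h2 <- recovery_ae_h2(20, n_mz = 115, n_dz = 183, a2 = 0.72, seed = 31,
                       n_starts = 1)
  expect_lt(abs(mean(h2) - 0.72), 0.04)
})

test_that("no familial resemblance drives the A paths to zero", {
  sim <- simulate_twin_pairs(1000, 1000, a2 = 0, seed = 32)
  fit <- fit_model(sim$phenotypes, sim$pedigree, "y", "AE",
                   covariates = NULL, n_starts = 1)
  expect_lt(attr(standardize(fit), "h2")[1], 0.05)
})

test_that("4-variate AE fit recovers the generating standardized components", {
  tm <- true_model()
  co <- build_cohort(cohort_design(232, 346, 28, 102, retest_fraction = 0),
                     seed = 33)
  lt <- draw_latent_traits(co, tm, seed = 33)
  ph <- data.frame(person_id = co$persons$person_id, lt$t1)
  fit <- fit_model(ph, co$persons, tm$traits, "AE", covariates = NULL,
                   n_starts = 1)
  std <- standardize(fit)
  truth_pct <- list(A = 100 * tm$X^2, E = 100 * tm$Z^2)
  errs <- c(abs(std$A - truth_pct$A)[lower.tri(tm$X, TRUE)],
            abs(std$E - truth_pct$E)[lower.tri(tm$X, TRUE)])
  expect_lt(median(errs), 3)
  # estimates invariant to family order and twin-label swaps
  perm <- sample(nrow(ph))
  fit_p <- fit_model(ph[perm, ], co$persons[perm, ], tm$traits, "AE",
                     covariates = NULL, n_starts = 1)
  expect_equal(fit_p$minus2ll, fit$minus2ll, tolerance = 1e-4)
  ped_sw <- co$persons
  sw <- ped_sw$role == "twin1"
  ped_sw$role[ped_sw$role == "twin2"] <- "twin1"
  ped_sw$role[sw] <- "twin2"
  fit_sw <- fit_model(ph, ped_sw, tm$traits, "AE", covariates = NULL,
                      n_starts = 1)
  expect_equal(fit_sw$minus2ll, fit$minus2ll, tolerance = 1e-4)
  expect_equal(attr(standardize(fit_sw), "h2"), attr(std, "h2"),
               tolerance = 1e-3)
})

test_that("likelihood-ratio test counts df and floors the statistic", {
  fake <- function(m2ll, nfree, comps) {
    structure(list(minus2ll = m2ll, n_free_params = nfree,
                   components = comps, traits = letters[1:4]),
              class = "cholesky_fit")
  }
  full <- fake(1000, 54, c("A", "C", "E"))
  ae <- fake(1013.66, 44, c("A", "E"))
  res <- compare_lrt(full, ae)
  expect_equal(res$df, 10)   # the dropped 4x4 lower-triangular C factor
  expect_equal(res$delta_chi2, 13.66)
  expect_equal(round(res$p, 2), 0.19)
  same <- compare_lrt(full, fake(1000, 44, c("A", "E")))
  expect_equal(same$delta_chi2, 0)
  expect_equal(same$p, 1)
  expect_error(compare_lrt(ae, full), "not nested")
})

test_that("nested fits never beat the full model and misspecified C is rejected", {
  for (s in 1:2) {
    sim <- simulate_twin_pairs(600, 900, a2 = 0.6, seed = 40 + s)
    ace <- fit_model(sim$phenotypes, sim$pedigree, "y", "ACE",
                     covariates = NULL, n_starts = 1)
    ae <- fit_model(sim$phenotypes, sim$pedigree, "y", "AE",
                    covariates = NULL, n_starts = 1)
    ce <- fit_model(sim$phenotypes, sim$pedigree, "y", "CE",
                    covariates = NULL, n_starts = 1)
    expect_gte(ae$minus2ll - ace$minus2ll, -1e-4)
    expect_gte(ce$minus2ll - ace$minus2ll, -1e-4)
    # dropping A when a2 > 0 must hurt; dropping C must not
    expect_lt(compare_lrt(ace, ce)$p, 0.01)
    expect_gt(compare_lrt(ace, ae)$p, 0.001)
  }
})

test_that("chi-square survival matches canonical quantiles", {
  expect_equal(chisq_sf(0, 5), 1)
  expect_equal(round(chisq_sf(3.841, 1), 3), 0.05)
  expect_equal(round(chisq_sf(13.66, 10), 2), 0.19)
  expect_error(chisq_sf(-1, 2), "x must be")
  expect_error(chisq_sf(1, 0), "df")
})

test_that("standardization sums to 100% per trait and round-trips", {
  p1 <- list(X = matrix(sqrt(0.5)), Z = matrix(sqrt(0.5)),
             traits = "y", Y = NULL)
  std <- standardize(p1)
  expect_equal(unname(std$A[1, 1]), 50)
  expect_equal(unname(std$E[1, 1]), 50)
  pr <- random_paths(4, 55, with_c = TRUE)
  pr$traits <- letters[1:4]
  std4 <- standardize(pr)
  tot <- std4$A + std4$C + std4$E
  expect_equal(unname(rowSums(tot)), rep(100, 4), tolerance = 1e-6)
  # rebuilding paths from the standardized table is a fixed point
  rebuilt <- list(X = sqrt(std4$A / 100), Y = sqrt(std4$C / 100),
                  Z = sqrt(std4$E / 100), traits = letters[1:4])
  expect_equal(standardize(rebuilt)$A, std4$A, tolerance = 1e-10)
})

test_that("component correlations follow the path algebra", {
  prd <- list(X = diag(c(1, 2, 0.5)), Y = NULL, Z = diag(3) * 0.3)
  expect_equal(component_correlations(prd)$rA, diag(3))
  pr <- random_paths(3, 77)
  cc <- component_correlations(pr)
  A <- tcrossprod(pr$X)
  expect_equal(cc$rA[2, 1], A[2, 1] / sqrt(A[1, 1] * A[2, 2]))
  expect_true(all(abs(cc$rP) <= 1 + 1e-12))
  # zero component variance -> missing correlation
  pr0 <- list(X = diag(c(1, 0)), Y = NULL, Z = diag(2))
  expect_true(is.na(component_correlations(pr0)$rA[2, 1]))
})
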