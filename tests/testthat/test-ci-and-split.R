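test_that("profile intervals nest across levels and flag boundaries", {
  sim <- simulate_twin_pairs(115, 183, a2 = 0.72, seed = 51)
  fit <- fit_model(sim$phenotypes, sim$pedigree, "y", "AE",
                   covariates = NULL, n_starts = 1)
  ci95 <- profile_ci(fit, "h2", level = 0.95)
  ci99 <- profile_ci(fit, "h2", level = 0.99)
  expect_lt(ci95$lower, ci95$estimate)
  expect_gt(ci95$upper, ci95$estimate)
  expect_lte(ci99$lower, ci95$lower)
  expect_gte(ci99$upper, ci95$upper)
  expect_identical(ci95$method, "profile")

  # a free path parameter interval brackets its estimate
  cip <- profile_ci(fit, 1)
  expect_lt(cip$lower, cip$estimate)
  expect_gt(cip$upper, cip$estimate)

  # null heritability: the lower bound sits at the boundary and is flagged
  sim0 <- simulate_twin_pairs(250, 250, a2 = 0, seed = 52)
  fit0 <- fit_model(sim0$phenotypes, sim0$pedigree, "y", "AE",
                    covariates = NULL, n_starts = 1)
  ci0 <- profile_ci(fit0, "h2")
  expect_equal(ci0$lower, 0)
  expect_true(ci0$boundary[["lower"]])
})

test_that("profile h2 intervals achieve near-nominal coverage", {
  n_reps <- 300
  covered <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    sim <- simulate_twin_pairs(115, 183, a2 = 0.72, seed = 60000 + r)
    fit <- fit_model(sim$phenotypes, sim$pedigree, "y", "AE",
                     covariates = NULL, n_starts = 1)
    ci <- profile_ci(fit, "h2")
    covered[r] <- ci$lower <= 0.72 && ci$upper >= 0.72
  }
  expect_gte(mean(covered), 0.915)
  expect_lte(mean(covered), 0.985)
})

test_that("twin correlation estimator hits the degenerate and null cases", {
  set.seed(53)
  n <- 300
  ph <- data.frame(person_id = sprintf("p%04d", seq_len(2 * n)))
  ph$y <- rnorm(2 * n)
  ped <- data.frame(person_id = ph$person_id,
                    family_id = sprintf("f%04d", rep(seq_len(n), each = 2)),
                    zygosity = rep(c("MZ", "DZ"), each = n),
                    role = rep(c("twin1", "twin2"), n))
  # identical co-twin values -> correlation at the upper edge
  i1 <- seq(1, 2 * n, 2)
  ph$y[i1 + 1] <- ph$y[i1]
  tc <- twin_correlations(ph, ped, "y", covariates = NULL)
  expect_true(all(tc$r > 0.99))
  # independent co-twin values -> near zero at n = 2000 pairs
  sim <- simulate_twin_pairs(2000, 0, a2 = 0, seed = 54)
  tc0 <- cortwin:::ml_pair_cor(
    sim$phenotypes$y[seq(1, 4000, 2)], sim$phenotypes$y[seq(2, 4000, 2)],
    matrix(1, 2000, 1), matrix(1, 2000, 1), ci = FALSE)
  expect_lt(abs(tc0$r), 0.05)
})

test_that("covariate-adjusted twin correlations remove mean structure", {
  set.seed(55)
  n <- 800
  age <- runif(n, 10, 30)
  sex <- rbinom(n, 1, 0.5)
  lat <- matrix(rnorm(2 * n), n, 2)
  lat[, 2] <- 0.5 * lat[, 1] + sqrt(0.75) * lat[, 2]
  mk <- function(member) 0.08 * (age - 15) + 0.5 * sex + lat[, member]
  ph <- data.frame(person_id = sprintf("p%04d", seq_len(2 * n)),
                   y = as.vector(rbind(mk(1), mk(2))),
                   sex = rep(sex, each = 2), age = rep(age, each = 2))
  ped <- data.frame(person_id = ph$person_id,
                    family_id = sprintf("f%04d", rep(seq_len(n), each = 2)),
                    zygosity = "MZ", role = rep(c("twin1", "twin2"), n))
  ped$zygosity[seq_len(n)] <- "MZ"
  ped2 <- ped
  ped2$zygosity <- rep(rep(c("MZ", "DZ"), each = 2), length.out = 2 * n)
  raw <- cortwin:::ml_pair_cor(ph$y[seq(1, 2 * n, 2)], ph$y[seq(2, 2 * n, 2)],
                               matrix(1, n, 1), matrix(1, n, 1), ci = FALSE)
  adj <- twin_correlations(ph, ped2, "y", covariates = c("sex", "age"),
                           ci = FALSE)
  # the shared age/sex means inflate the raw correlation; adjustment removes it
  expect_gt(raw$r, 0.55)
  expect_lt(abs(adj$r[adj$zygosity == "MZ"] - 0.5), 0.07)
})

test_that("stability correlation behaves at the edges and recovers truth", {
  prep <- data.frame(person_id = rep(sprintf("p%03d", 1:50), 2),
                     time_point = rep(1:2, each = 50),
                     y = c(rnorm(50), rnorm(50)))
  prep$y[51:100] <- prep$y[1:50]
  expect_equal(stability_correlation(prep, "y")$r, 1)
  set.seed(56)
  prep$y[51:100] <- rnorm(50)
  expect_lt(abs(stability_correlation(prep, "y")$r), 0.35)
  expect_error(stability_correlation(prep[c(1, 51), ], "y"), "fewer than 3")

  # generator truth: HCC two-year stability 0.32 on a large retest sample
  tm <- true_model()
  co <- build_cohort(cohort_design(1250, 1250, 0, 0, retest_fraction = 1),
                     seed = 57)
  lt <- draw_latent_traits(co, tm, seed = 57)
  long <- rbind(
    data.frame(person_id = co$persons$person_id, time_point = 1,
               hcc = lt$t1[, "hcc"]),
    data.frame(person_id = co$persons$person_id, time_point = 2,
               hcc = lt$t2[, "hcc"]))
  st <- stability_correlation(long, "hcc")
  expect_lt(abs(st$r - 0.32), 0.03)
  expect_equal(st$n, 5000)
})

test_that("median split keeps families intact and detects age-varying heritability", {
  # two age strata with different generating heritabilities
  sy <- simulate_twin_pairs(300, 300, a2 = 0.35, seed = 58)
  so <- simulate_twin_pairs(300, 300, a2 = 0.85, seed = 59)
  so$phenotypes$person_id <- paste0("o", so$phenotypes$person_id)
  so$pedigree$person_id <- paste0("o", so$pedigree$person_id)
  so$pedigree$family_id <- paste0("o", so$pedigree$family_id)
  ph <- rbind(cbind(sy$phenotypes, age = 12, sex = 0),
              cbind(so$phenotypes, age = 17, sex = 0))
  ph$age <- ph$age + rep(runif(nrow(ph) / 2, -1, 1), each = 2)
  ped <- rbind(sy$pedigree, so$pedigree)
  res <- median_split_fit(ph, ped, "y", components = "AE",
                          covariates = NULL, n_starts = 1)
  # no family straddles the halves
  fams_y <- unique(ped$family_id[ped$person_id %in%
                                   res$younger$fit$units$data$person_id])
  fams_o <- unique(ped$family_id[ped$person_id %in%
                                   res$older$fit$units$data$person_id])
  expect_length(intersect(fams_y, fams_o), 0)
  expect_lt(res$younger$h2[1], res$older$h2[1])
  expect_lt(abs(unname(res$younger$h2[1]) - 0.35), 0.12)
  expect_lt(abs(unname(res$older$h2[1]) - 0.85), 0.12)
})

test_that("family bootstrap intervals bracket the estimate and record the method", {
  sim <- simulate_twin_pairs(120, 120, a2 = 0.6, seed = 61)
  fit <- fit_model(sim$phenotypes, sim$pedigree, "y", "AE",
                   covariates = NULL, n_starts = 1)
  h2_hat <- attr(standardize(fit), "h2")[1]
  ci <- bootstrap_ci(sim$phenotypes, sim$pedigree, "y",
                     statistic = function(f) attr(standardize(f), "h2")[1],
                     components = "AE", covariates = NULL, B = 30, seed = 61)
  expect_identical(ci$method, "bootstrap")
  expect_lt(ci$lower, h2_hat)
  expect_gt(ci$upper, h2_hat)
  expect_true(ci$lower >= 0 && ci$upper <= 1)
})
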