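toy_variants <- function(ids, chrom = 1L, pos = NULL) {
  data.frame(id = ids, chrom = chrom,
             pos = pos %||% seq(1e4, by = 1e4, length.out = length(ids)),
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Hardy-Weinberg exact test matches an independent enumeration", {
  cases <- list(c(0, 90, 10), c(50, 25, 25), c(10, 80, 10), c(3, 1, 96),
                c(57, 14, 50))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 brute_hwe(cs[1], cs[2], cs[3]), tolerance = 1e-12)
  }
  # the classic pathological case: zero heterozygotes among 100 persons
  expect_lt(hwe_exact_test(0, 90, 10), 1e-6)
  # equilibrium-consistent counts are unremarkable
  expect_gt(hwe_exact_test(50, 25, 25), 0.05)
})

test_that("QC drops variants and persons for the stated reasons", {
  set.seed(71)
  n <- 100
  m <- 40
  G <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(sprintf("p%03d", 1:n), paste0("v", 1:m)))
  G[1:7, 2] <- NA                       # variant call rate 93%
  G[, 3] <- rbinom(n, 1, 0.005)         # MAF below 1%
  G[, 4] <- c(rep(0, 90), rep(2, 10))   # HWE failure
  G[5, 1:10] <- NA                      # person call rate 31/40 < 0.95
  qc <- qc_filter(G, toy_variants(paste0("v", 1:m)))
  expect_false("p005" %in% rownames(qc$G))
  expect_false(any(c("v2", "v3", "v4") %in% qc$variants$id))
  expect_true(all(c("v1", "v5", "v6") %in% qc$variants$id))
  ex <- qc$exclusions
  expect_equal(ex$reason[ex$id == "v2"], "call_rate")
  expect_equal(ex$reason[ex$id == "v3"], "maf")
  expect_equal(ex$reason[ex$id == "v4"], "hwe")
  expect_equal(ex$reason[ex$id == "p005"], "call_rate")
  # an all-clean panel passes unchanged
  G2 <- matrix(rbinom(n * 4, 2, 0.4), n, 4,
               dimnames = list(sprintf("p%03d", 1:n), paste0("w", 1:4)))
  qc2 <- qc_filter(G2, toy_variants(paste0("w", 1:4)))
  expect_identical(qc2$G, G2)
  expect_equal(nrow(qc2$exclusions), 0)
})

test_that("allele harmonization aligns, flips, and drops as specified", {
  v <- toy_variants(paste0("v", 1:7))
  v$ref <- c("A", "A", "A", "C", "A", "A", "A")
  v$alt <- c("G", "G", "T", "G", "G", "G", "G")
  stats <- data.frame(SNP = paste0("v", 1:7),
                      A1 = c("G", "A", "A", "C", "C", "T", "C"),
                      A2 = c("A", "G", "T", "G", "T", "C", "A"),
                      BETA = c(0.2, 0.2, 0.2, 0.2, 0.3, 0.3, 0.4),
                      P = rep(0.01, 7), stringsAsFactors = FALSE)
  h <- harmonize_alleles(stats, v)
  eff <- setNames(h$effects$beta, h$effects$id)
  expect_equal(unname(eff["v1"]), 0.2)    # A1 is the counted allele
  expect_equal(unname(eff["v2"]), -0.2)   # counted allele is A2 -> flip
  expect_false("v3" %in% h$effects$id)    # A/T strand-ambiguous
  expect_false("v4" %in% h$effects$id)    # C/G strand-ambiguous
  expect_equal(unname(eff["v5"]), 0.3)    # strand flip, effect allele = ALT
  expect_equal(unname(eff["v6"]), -0.3)   # strand flip + swapped -> sign flip
  expect_false("v7" %in% h$effects$id)    # C/A does not match A/G at all
  expect_setequal(h$dropped$reason[h$dropped$id %in% c("v3", "v4")],
                  "strand_ambiguous")
  expect_equal(h$dropped$reason[h$dropped$id == "v7"], "allele_mismatch")
})

test_that("clumping matches the exhaustive greedy oracle on an LD panel", {
  co <- build_cohort(cohort_design(30, 30, 2, 5), seed = 72)
  g <- emit_genotypes_and_gwas(co, 50, 10, 800, seed = 72,
                               ld_block_size = 5, ld_rho = 0.85)
  h <- harmonize_alleles(g$sumstats$neuro, g$variants)
  kept <- clump(h$effects, g$G, g$variants, r2_max = 0.1)
  oracle <- brute_clump(h$effects, g$G, g$variants, r2_max = 0.1)
  expect_identical(kept, oracle)
  # independent variants are all retained
  set.seed(73)
  Gi <- matrix(rbinom(4000, 2, 0.5), 200, 20,
               dimnames = list(NULL, paste0("s", 1:20)))
  effi <- data.frame(id = paste0("s", 1:20), beta = 1,
                     p = runif(20, 1e-6, 0.9))
  kepti <- clump(effi, Gi, toy_variants(paste0("s", 1:20)), r2_max = 0.5)
  expect_setequal(kepti, effi$id)
  # of two perfectly correlated variants only the more significant survives
  Gd <- cbind(a = Gi[, 1], b = Gi[, 1])
  effd <- data.frame(id = c("a", "b"), beta = 1, p = c(1e-8, 1e-4))
  expect_identical(clump(effd, Gd, toy_variants(c("a", "b"))), "a")
  # clumped sets are nested as the r2 ceiling loosens
  kept_tight <- clump(h$effects, g$G, g$variants, r2_max = 0.1)
  kept_loose <- clump(h$effects, g$G, g$variants, r2_max = 0.5)
  expect_true(all(kept_tight %in% kept_loose))
})

test_that("threshold scoring sums beta-weighted dosages with nesting", {
  G <- matrix(c(2, 1,
                1, 0), 2, 2, byrow = FALSE,
              dimnames = list(c("p1", "p2"), c("v1", "v2")))
  eff <- data.frame(id = c("v1", "v2"), beta = c(0.5, -0.2),
                    p = c(0.001, 0.3))
  sc <- score_at_thresholds(G, eff, thresholds = c(0.01, 1),
                            standardize = FALSE)
  expect_equal(unname(sc["p1", "1"]), 2 * 0.5 + 1 * -0.2)   # = 0.8
  expect_equal(unname(sc[, "0.01"]), unname(G[, "v1"] * 0.5))
  # threshold-1 score = threshold-0.5 score + contribution of (0.5, 1]
  eff2 <- data.frame(id = c("v1", "v2"), beta = c(0.5, -0.2),
                     p = c(0.4, 0.9))
  sc2 <- score_at_thresholds(G, eff2, thresholds = c(0.5, 1),
                             standardize = FALSE)
  expect_equal(sc2[, "1"], sc2[, "0.5"] + G[, "v2"] * -0.2)
  expect_true(all(diff(attr(sc2, "n_variants")) >= 0))
  # all-zero effects give all-zero scores; bad thresholds are an error
  sc0 <- score_at_thresholds(G, transform(eff, beta = 0), thresholds = 1,
                             standardize = FALSE)
  expect_true(all(sc0 == 0))
  expect_error(score_at_thresholds(G, eff, thresholds = c(0, 0.5)),
               "thresholds")
})

test_that("scores are invariant to variant order and allele relabeling", {
  set.seed(74)
  G <- matrix(rbinom(600, 2, 0.4), 60, 10,
              dimnames = list(sprintf("p%02d", 1:60), paste0("v", 1:10)))
  eff <- data.frame(id = paste0("v", 1:10), beta = rnorm(10),
                    p = runif(10))
  sc <- score_at_thresholds(G, eff, thresholds = c(0.5, 1))
  sc_perm <- score_at_thresholds(G[, 10:1], eff[10:1, ],
                                 thresholds = c(0.5, 1))
  expect_equal(sc, sc_perm)
  # relabel ref/alt (dosage 2 - G) with sign-flipped beta: standardized
  # scores identical
  sc_flip <- score_at_thresholds(2 - G, transform(eff, beta = -beta),
                                 thresholds = c(0.5, 1))
  expect_equal(unclass(sc)[, ], unclass(sc_flip)[, ], tolerance = 1e-10)
})

test_that("pedigree kinship encodes MZ/DZ/unrelated structure", {
  ped <- data.frame(person_id = c("a", "b", "c"),
                    family_id = c("f1", "f1", "f2"),
                    zygosity = c("MZ", "MZ", "singleton"))
  K <- pedigree_kinship(ped)
  expect_equal(unname(K), rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  ped_s <- data.frame(person_id = letters[1:4], family_id = letters[1:4],
                      zygosity = "singleton")
  expect_equal(unname(pedigree_kinship(ped_s)), diag(4))
  co <- build_cohort(cohort_design(10, 10, 2, 5), seed = 75)
  Kc <- pedigree_kinship(co$persons)
  expect_gte(min(eigen(Kc, symmetric = TRUE)$values), -1e-10)
  bad <- data.frame(person_id = c("a", "b", "c"), family_id = "f1",
                    zygosity = "MZ")
  expect_error(pedigree_kinship(bad), "inconsistent zygosity")
})

test_that("genotype-based kinship approximates the pedigree expectation", {
  co <- build_cohort(cohort_design(0, 400, 0, 0, retest_fraction = 0),
                     seed = 76)
  g <- emit_genotypes_and_gwas(co, m_variants = 2000, n_causal = 0,
                               discovery_n = 100, seed = 76)
  f <- colMeans(g$G) / 2
  Xs <- sweep(sweep(g$G, 2, 2 * f, `-`), 2, sqrt(2 * f * (1 - f)), `/`)
  K_emp <- tcrossprod(Xs) / ncol(g$G)
  per <- co$persons
  i1 <- which(per$role == "twin1")
  i2 <- which(per$role == "twin2")
  i2 <- i2[match(per$family_id[i1], per$family_id[i2])]
  expect_lt(abs(mean(K_emp[cbind(i1, i2)]) - 0.5), 0.05)
})

test_that("ancestry PCs separate populations and stay flat under homogeneity", {
  set.seed(77)
  f1 <- runif(300, 0.2, 0.8)
  f2 <- pmin(pmax(f1 + runif(300, -0.25, 0.25), 0.05), 0.95)
  G <- rbind(sapply(f1, function(p) rbinom(120, 2, p)),
             sapply(f2, function(p) rbinom(120, 2, p)))
  dimnames(G) <- list(sprintf("p%03d", 1:240), sprintf("v%03d", 1:300))
  pcs <- pca_ancestry(G, n_pcs = 3)
  expect_gt(abs(cor(pcs[, 1], rep(c(0, 1), each = 120))), 0.9)
  # homogeneous population: no dominant axis
  Gh <- matrix(rbinom(200 * 400, 2, 0.4), 200, 400,
               dimnames = list(sprintf("h%03d", 1:200), sprintf("w%03d", 1:400)))
  ph <- pca_ancestry(Gh, n_pcs = 5)
  ev <- attr(ph, "eigenvalues")
  expect_lt(ev[1] / median(ev), 2)
  expect_equal(ncol(pca_ancestry(G, n_pcs = 0)), 0)
  expect_error(pca_ancestry(G[, 1:2], n_pcs = 5), "fewer variants")
})

test_that("mixed association reduces to OLS without a genetic component", {
  set.seed(78)
  co <- build_cohort(cohort_design(40, 60, 0, 10, retest_fraction = 0),
                     seed = 78)
  K <- pedigree_kinship(co$persons)
  n <- nrow(K)
  W <- cbind(sex = co$persons$sex, age = co$persons$age_t1)
  s <- rnorm(n)
  y <- 0.2 * s + rnorm(n)
  res0 <- mixed_assoc(y, s, W, K, constrain_g0 = TRUE)
  ols <- summary(lm(y ~ W + s))
  expect_equal(res0$beta, ols$coefficients["s", 1], tolerance = 1e-8)
  expect_equal(res0$se, ols$coefficients["s", 2], tolerance = 1e-8)
  # two-sided consistency
  res <- mixed_assoc(y, s, W, K)
  expect_equal(res$p_two_sided,
               2 * min(res$p_one_sided, 1 - res$p_one_sided))
  expect_equal(sign(res$r2_signed), sign(res$beta))
})

test_that("an orthogonalized score is exactly null", {
  set.seed(79)
  n <- 150
  y <- rnorm(n)
  W <- cbind(x = rnorm(n))
  s <- residuals(lm(rnorm(n) ~ y + W))
  K <- diag(n)
  dimnames(K) <- list(sprintf("p%03d", 1:n), sprintf("p%03d", 1:n))
  res <- mixed_assoc(y, s, W, K, constrain_g0 = TRUE)
  expect_equal(res$beta, 0, tolerance = 1e-10)
  expect_equal(res$p_one_sided, 0.5, tolerance = 1e-8)
  expect_equal(res$r2_signed, 0, tolerance = 1e-10)
})

test_that("PRS finds the matched trait and not an independent one", {
  design <- cohort_design(75, 110, 9, 33)   # ~432 persons
  co <- build_cohort(design, seed = 80)
  g <- emit_genotypes_and_gwas(co, m_variants = 800, n_causal = 60,
                               discovery_n = 8000, seed = 80)
  tm <- true_model(genetic_loading = c(0, 0.35, 0, 0))  # dep only, generous
  lt <- draw_latent_traits(co, tm, seed = 80, genetic_scores = g$scores)
  h <- harmonize_alleles(g$sumstats$mdd, g$variants)
  kept <- clump(h$effects, g$G, g$variants)
  sc <- score_at_thresholds(g$G, h$effects[h$effects$id %in% kept, ])
  K <- pedigree_kinship(co$persons)
  hit <- mixed_assoc(lt$t1[, "dep"], sc[, "1"], NULL, K)
  null <- mixed_assoc(lt$t1[, "stress"], sc[, "1"], NULL, K)
  expect_lt(hit$p_one_sided, 0.05)
  expect_lt(hit$p_one_sided, null$p_one_sided)
  expect_gt(null$p_one_sided, 0.05)
})

test_that("threshold sweep covers the full grid with duplicated phenotypes equal", {
  set.seed(81)
  n <- 80
  ped <- data.frame(person_id = sprintf("p%03d", 1:n),
                    family_id = sprintf("f%03d", rep(1:40, each = 2)),
                    zygosity = rep(c("MZ", "DZ"), 20)[rep(1:40, each = 2)])
  K <- pedigree_kinship(ped)
  prof <- matrix(rnorm(n * 8), n, 8,
                 dimnames = list(ped$person_id,
                                 c("5e-08", "1e-05", "0.001", "0.01",
                                   "0.05", "0.1", "0.5", "1")))
  attr(prof, "n_variants") <- setNames(1:8, colnames(prof))
  phen <- data.frame(a = rnorm(n), b = rnorm(n), a2 = 0)
  phen$a2 <- phen$a
  sw <- threshold_sweep(phen, list(d1 = prof), covariates = NULL, K = K)
  expect_equal(nrow(sw), 3 * 8)
  ra <- sw[sw$phenotype == "a", setdiff(names(sw), "phenotype")]
  ra2 <- sw[sw$phenotype == "a2", setdiff(names(sw), "phenotype")]
  rownames(ra) <- rownames(ra2) <- NULL
  expect_equal(ra, ra2)
  expect_true(all(sw$tier %in% c("", "#", "*", "**")))
})

test_that("one-sided type-I error is calibrated under family structure", {
  n_reps <- 1000
  ped <- data.frame(person_id = sprintf("p%03d", 1:120),
                    family_id = sprintf("f%03d", rep(1:60, each = 2)),
                    zygosity = rep(rep(c("MZ", "DZ"), 30), each = 2))
  K <- pedigree_kinship(ped)
  ek <- eigen(K, symmetric = TRUE)
  set.seed(82)
  hits <- logical(n_reps)
  a <- sqrt(0.5)
  for (r in seq_len(n_reps)) {
    fam <- rnorm(60)
    share <- ifelse(ped$zygosity == "MZ", 1, sqrt(0.5))
    y <- a * (share * fam[rep(1:60, each = 2)] +
                sqrt(1 - share^2) * rnorm(120)) + sqrt(0.5) * rnorm(120)
    s <- rnorm(120)
    hits[r] <- mixed_assoc(y, s, NULL, K, eigenK = ek)$p_one_sided < 0.05
  }
  expect_gte(mean(hits), 0.035)
  expect_lte(mean(hits), 0.065)
})
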