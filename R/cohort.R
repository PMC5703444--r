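#' Specify a twin-cohort design
#'
#' Describes the family composition and demographics of a simulated twin
#' cohort. The defaults reproduce the composition of the study cohort the
#' package emulates: 116 MZ twin pairs, 173 ordinary DZ pairs plus 14
#' triplet sets (each treated as a DZ pair with one additional singleton),
#' and 51 additional singleton siblings, for 671 persons in total; ages are
#' truncated-normal with mean 14.5 and SD 2.4 years on 10.1--31.1;
#' roughly 62% of the cohort is female; about 22% of persons are re-measured
#' two years later; all 16--19-year-olds complete both stress instruments.
#'
#' @param n_mz_pairs number of monozygotic twin pairs.
#' @param n_dz_pairs number of dizygotic twin pairs *not* derived from
#'   triplet sets.
#' @param n_triplet_sets number of triplet sets; each contributes one DZ
#'   pair plus one singleton in the same family.
#' @param n_extra_siblings number of singleton siblings attached to existing
#'   twin families.
#' @param female_fraction probability that a person (or MZ pair) is female.
#' @param age_mean,age_sd,age_range mean, SD and truncation range (years) of
#'   the age distribution.
#' @param overlap_fraction proportion of 16--19-year-olds who complete both
#'   stress instruments.
#' @param retest_fraction proportion of persons measured at a second time
#'   point two years later.
#' @param n_batches,n_storage_groups,n_months,n_study_phases,n_waves numbers
#'   of levels of the experimental assay covariates (batch, storage-time
#'   group, assay month, study phase) and of genotyping waves.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_mz_pairs = 116, n_dz_pairs = 173,
                          n_triplet_sets = 14, n_extra_siblings = 51,
                          female_fraction = 419 / 671,
                          age_mean = 14.5, age_sd = 2.4,
                          age_range = c(10.1, 31.1),
                          overlap_fraction = 1.0,
                          retest_fraction = 146 / 671,
                          n_batches = 35, n_storage_groups = 5,
                          n_months = 12, n_study_phases = 6, n_waves = 2) {
  counts <- c(n_mz_pairs, n_dz_pairs, n_triplet_sets, n_extra_siblings)
  if (any(counts < 0)) stop("family counts must be non-negative")
  fr <- c(female_fraction, overlap_fraction, retest_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (age_range[1] > age_range[2]) stop("invalid age range")
  structure(list(
    n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
    n_triplet_sets = n_triplet_sets, n_extra_siblings = n_extra_siblings,
    female_fraction = female_fraction, age_mean = age_mean, age_sd = age_sd,
    age_range = age_range, overlap_fraction = overlap_fraction,
    retest_fraction = retest_fraction, n_batches = n_batches,
    n_storage_groups = n_storage_groups, n_months = n_months,
    n_study_phases = n_study_phases, n_waves = n_waves
  ), class = "cohort_design")
}

#' Build a simulated twin cohort
#'
#' Generates the family/pedigree skeleton of a twin cohort: families with
#' zygosity and role labels, sex (MZ co-twins always share sex), ages
#' (co-twins and triplet-derived singletons share the family age; other
#' singleton siblings draw their own), retest indicators, genotyping wave,
#' and uniformly random assay labels (batch, storage group, month, study
#' phase) per person and time point, mirroring random assay batching
#' irrespective of time point or twin pair.
#'
#' @param design a [cohort_design()].
#' @param seed integer seed.
#' @return an object of class `twin_cohort` with elements `persons` (one row
#'   per person), `assay` (one row per person x measured time point with the
#'   experimental labels) and `design`.
#' @export
build_cohort <- function(design = cohort_design(), seed = 1) {
  stopifnot(inherits(design, "cohort_design"))
  n_fam_units <- design$n_mz_pairs + design$n_dz_pairs + design$n_triplet_sets
  if (n_fam_units == 0 && design$n_extra_siblings == 0)
    stop("empty cohort: all family counts are zero")
  if (n_fam_units == 0)
    stop("extra siblings need at least one twin family to attach to")
  set.seed(substream_seed(seed, "cohort"))

  fam_zyg <- c(rep("MZ", design$n_mz_pairs),
               rep("DZ", design$n_dz_pairs),
               rep("DZT", design$n_triplet_sets)) # DZT = triplet-derived
  n_fam <- length(fam_zyg)
  fam_id <- sprintf("F%04d", seq_len(n_fam))
  fam_age <- rtruncnorm(n_fam, design$age_mean, design$age_sd,
                        design$age_range[1], design$age_range[2])

  # twin pairs, vectorized: MZ co-twins share one sex draw, DZ draw their own
  is_mz <- fam_zyg == "MZ"
  sex1 <- stats::rbinom(n_fam, 1, design$female_fraction)
  sex2 <- ifelse(is_mz, sex1,
                 stats::rbinom(n_fam, 1, design$female_fraction))
  persons <- data.frame(
    family_id = rep(fam_id, each = 2),
    zygosity = rep(ifelse(is_mz, "MZ", "DZ"), each = 2),
    role = rep(c("twin1", "twin2"), n_fam),
    sex = as.vector(rbind(sex1, sex2)),
    age_t1 = rep(fam_age, each = 2),
    stringsAsFactors = FALSE)
  # each triplet set contributes one additional singleton of the same age
  trip <- which(fam_zyg == "DZT")
  if (length(trip)) {
    persons <- rbind(persons, data.frame(
      family_id = fam_id[trip], zygosity = "singleton", role = "singleton",
      sex = stats::rbinom(length(trip), 1, design$female_fraction),
      age_t1 = fam_age[trip], stringsAsFactors = FALSE))
  }

  if (design$n_extra_siblings > 0) {
    host <- sample(fam_id, design$n_extra_siblings, replace = TRUE)
    sib_age <- rtruncnorm(design$n_extra_siblings, design$age_mean,
                          design$age_sd, design$age_range[1],
                          design$age_range[2])
    persons <- rbind(persons, data.frame(
      family_id = host, zygosity = "singleton", role = "singleton",
      sex = stats::rbinom(design$n_extra_siblings, 1, design$female_fraction),
      age_t1 = sib_age, stringsAsFactors = FALSE
    ))
  }
  persons <- persons[order(persons$family_id), , drop = FALSE]
  persons$person_id <- sprintf("P%04d", seq_len(nrow(persons)))
  n <- nrow(persons)

  persons$retest <- stats::runif(n) < design$retest_fraction
  persons$age_t2 <- ifelse(persons$retest, persons$age_t1 + 2, NA_real_)
  persons$genotyping_wave <- paste0("wave", sample.int(design$n_waves, n,
                                                       replace = TRUE))
  persons$both_stress <- persons$age_t1 >= 16 & persons$age_t1 < 19 &
    stats::runif(n) < design$overlap_fraction

  draw_labels <- function(k) data.frame(
    batch = paste0("b", sample.int(design$n_batches, k, replace = TRUE)),
    storage_group = paste0("s", sample.int(design$n_storage_groups, k,
                                           replace = TRUE)),
    month = month.abb[sample.int(design$n_months, k, replace = TRUE)],
    study_phase = paste0("ph", sample.int(design$n_study_phases, k,
                                          replace = TRUE)),
    stringsAsFactors = FALSE
  )
  assay <- cbind(data.frame(person_id = persons$person_id, time_point = 1L),
                 draw_labels(n))
  if (any(persons$retest)) {
    assay <- rbind(assay, cbind(
      data.frame(person_id = persons$person_id[persons$retest],
                 time_point = 2L),
      draw_labels(sum(persons$retest))))
  }

  rownames(persons) <- NULL
  cols <- c("person_id", "family_id", "zygosity", "role", "sex", "age_t1",
            "age_t2", "retest", "both_stress", "genotyping_wave")
  structure(list(persons = persons[, cols], assay = assay, design = design,
                 seed = seed),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  z <- table(x$persons$zygosity)
  cat(sprintf("twin_cohort: %d persons in %d families (%s)\n",
              nrow(x$persons), length(unique(x$persons$family_id)),
              paste(names(z), z, sep = "=", collapse = ", ")))
  invisible(x)
}
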