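#' Ground-truth item parameters for the questionnaire instruments
#'
#' Builds a graded-response item bank for the five instruments the cohort
#' emulates: two stress scales (a 30-item child/adolescent scale with four
#' response categories administered under age 16, and a 10-item adult scale
#' with five categories from age 16), a 34-item depressive-symptoms
#' screener with three categories administered at all ages, and two
#' neuroticism scales (20 binary junior items under 16, 12 five-category
#' adult items from 16). Discriminations are log-normal(0, 0.3); thresholds
#' are equally spaced and centered, jittered per item.
#'
#' @param seed integer seed.
#' @param threshold_jitter SD of the per-item location jitter.
#' @return named list of instruments; each instrument is a named list of
#'   items with elements `a` and `b`, plus attributes `trait` and `ages`.
#' @export
irt_truth_default <- function(seed = 1, threshold_jitter = 0.3) {
  set.seed(substream_seed(seed, "irt_truth"))
  spec <- list(
    DLSS   = list(n = 30, K = 4, trait = "stress", ages = c(0, 16)),
    PSS    = list(n = 10, K = 5, trait = "stress", ages = c(16, Inf)),
    SPHERE = list(n = 34, K = 3, trait = "dep",    ages = c(0, Inf)),
    JEPQ   = list(n = 20, K = 2, trait = "neuro",  ages = c(0, 16)),
    NEO    = list(n = 12, K = 5, trait = "neuro",  ages = c(16, Inf))
  )
  lapply(spec, function(s) {
    items <- lapply(seq_len(s$n), function(i) {
      base <- if (s$K == 2) 0 else seq(-1.2, 1.2, length.out = s$K - 1)
      list(a = stats::rlnorm(1, 0, 0.3),
           b = base + stats::rnorm(1, 0, threshold_jitter))
    })
    names(items) <- sprintf("i%02d", seq_len(s$n))
    attr(items, "trait") <- s$trait
    attr(items, "ages") <- s$ages
    items
  })
}

#' Emit ordinal questionnaire item responses
#'
#' Samples graded-response item data for every instrument at each measured
#' time point. Instruments are assigned by age at measurement (child scales
#' under 16, adult scales from 16); persons flagged as the 16--19-year-old
#' overlap subgroup complete both stress instruments at time 1, which later
#' anchors the concurrent IRT calibration. Whole-instrument missingness is
#' injected at configurable per-instrument rates.
#'
#' @param latent a [draw_latent_traits()] result; liabilities are the trait
#'   values divided by the model's trait scales (unit-variance metric).
#' @param cohort a [build_cohort()] result.
#' @param irt_truth item bank from [irt_truth_default()].
#' @param seed integer seed.
#' @param missing_rates named vector of whole-instrument missingness
#'   probabilities per trait; defaults emulate the study (1/671 stress,
#'   55/671 depressive symptoms, 51/671 neuroticism).
#' @return named list of long response tables (one per instrument:
#'   `person_id`, `time_point`, item columns).
#' @export
emit_items <- function(latent, cohort, irt_truth = irt_truth_default(),
                       seed = 1,
                       missing_rates = c(stress = 1, dep = 55, neuro = 51) / 671) {
  set.seed(substream_seed(seed, "items"))
  persons <- cohort$persons
  truth <- latent$truth
  theta <- function(tp, trait) {
    m <- if (tp == 1L) latent$t1 else latent$t2
    m[, trait] / truth$trait_scales[match(trait, truth$traits)]
  }
  age_at <- function(tp) if (tp == 1L) persons$age_t1 else persons$age_t2

  miss <- lapply(names(missing_rates), function(tr)
    stats::runif(nrow(persons)) < missing_rates[[tr]])
  names(miss) <- names(missing_rates)

  out <- list()
  for (instr in names(irt_truth)) {
    bank <- irt_truth[[instr]]
    trait <- attr(bank, "trait")
    ages <- attr(bank, "ages")
    tabs <- list()
    for (tp in c(1L, 2L)) {
      age <- age_at(tp)
      eligible <- !is.na(age) & age >= ages[1] & age < ages[2]
      if (instr %in% c("DLSS", "PSS") && tp == 1L)
        eligible <- eligible | persons$both_stress
      take <- which(eligible & !miss[[trait]])
      if (!length(take)) next
      th <- theta(tp, trait)[take]
      resp <- lapply(bank, function(it) grm_sample(th, it$a, it$b))
      tabs[[as.character(tp)]] <- cbind(
        data.frame(person_id = persons$person_id[take], time_point = tp),
        as.data.frame(resp))
    }
    out[[instr]] <- do.call(rbind, tabs)
    rownames(out[[instr]]) <- NULL
  }
  out
}
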