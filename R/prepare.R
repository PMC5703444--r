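sum_score <- function(tab) {
  items <- setdiff(names(tab), c("person_id", "time_point"))
  data.frame(person_id = tab$person_id,
             score = rowSums(tab[items]), stringsAsFactors = FALSE)
}

score_tp <- function(items, instruments, calibration, tp) {
  tabs <- lapply(instruments, function(nm) {
    t <- items[[nm]]
    t[t$time_point == tp, setdiff(names(t), "time_point"), drop = FALSE]
  })
  resp <- Reduce(function(x, y) merge(x, y, by = "person_id", all = TRUE),
                 tabs)
  if (is.null(resp) || nrow(resp) == 0)
    return(data.frame(person_id = character(), score = numeric()))
  irt_eap_score(resp, calibration)[c("person_id", "score")]
}

#' Prepare the four analysis phenotypes
#'
#' Turns raw simulated (or equivalently formatted user) measurements into
#' the analysis phenotypes: residualized log10 hair cortisol (offset log
#' transform, winsorization at 3 SD computed on time-1 values, OLS
#' residualization on the dummy-coded batch/storage/month/study factors with
#' coefficients shared across time points), an IRT stress liability from the
#' concurrent calibration of the two stress instruments (the overlap
#' subgroup anchors the common scale), an IRT depressive-symptoms liability,
#' and a combined neuroticism z-score (per-instrument sum scores
#' z-standardized within instrument at time 1, the same scaling applied to
#' time-2 sums). Time-2 measurements are scored with the time-1
#' calibrations.
#'
#' @param cohort a `twin_cohort` (provides sex and ages).
#' @param hcc_table output of [emit_hcc_raw()] (or a table with the same
#'   columns).
#' @param items named list of long item-response tables as produced by
#'   [emit_items()].
#' @param offset offset for the log transform (default 0.1).
#' @param n_quad,tol IRT calibration settings (see [irt_calibrate()]).
#' @return list: `prepared` (long data.frame `person_id`, `time_point`,
#'   `sex`, `age`, `stress`, `dep`, `neuro`, `hcc_log`, `hcc_resid`),
#'   `calibrations`, `winsor` (clip info), `n_clipped`.
#' @export
prepare_phenotypes <- function(cohort, hcc_table, items, offset = 0.1,
                               n_quad = 61, tol = 1e-5) {
  persons <- cohort$persons
  hcc <- hcc_table
  hcc$hcc_log <- log10_offset_transform(hcc$hcc_raw, offset)
  t1 <- hcc$time_point == 1
  win <- winsorize_3sd(hcc$hcc_log[t1])
  hcc$hcc_log[t1] <- win$values
  hcc$hcc_log[!t1] <- pmin(pmax(hcc$hcc_log[!t1], win$bounds["lower"]),
                           win$bounds["upper"])
  hcc$hcc_resid <- residualize_fixed_effects(
    hcc$hcc_log, hcc[c("batch", "storage_group", "month", "study_phase")])

  wide_t1 <- function(nm) {
    t <- items[[nm]]
    t[t$time_point == 1, setdiff(names(t), "time_point"), drop = FALSE]
  }
  cal_stress <- irt_calibrate(list(DLSS = wide_t1("DLSS"),
                                   PSS = wide_t1("PSS")),
                              n_quad = n_quad, tol = tol)
  cal_dep <- irt_calibrate(list(SPHERE = wide_t1("SPHERE")),
                           n_quad = n_quad, tol = tol)

  neuro_t1 <- list(JEPQ = sum_score(wide_t1("JEPQ")),
                   NEO = sum_score(wide_t1("NEO")))
  neuro_z1 <- z_combine(neuro_t1)
  scaling <- attr(neuro_z1, "scaling")
  neuro_t2 <- lapply(c(JEPQ = "JEPQ", NEO = "NEO"), function(nm) {
    t <- items[[nm]]
    t2 <- t[t$time_point == 2, , drop = FALSE]
    if (!nrow(t2)) return(NULL)
    s <- sum_score(t2)
    s$z <- (s$score - scaling[[nm]]["center"]) / scaling[[nm]]["scale"]
    s[c("person_id", "z")]
  })
  neuro_z2 <- do.call(rbind, Filter(Negate(is.null), neuro_t2))

  assemble_tp <- function(tp) {
    base <- data.frame(person_id = persons$person_id,
                       sex = persons$sex,
                       age = if (tp == 1) persons$age_t1 else persons$age_t2,
                       stringsAsFactors = FALSE)
    base <- base[!is.na(base$age), ]
    st <- score_tp(items, c("DLSS", "PSS"), cal_stress, tp)
    dp <- score_tp(items, "SPHERE", cal_dep, tp)
    nz <- if (tp == 1) neuro_z1[c("person_id", "z")] else neuro_z2
    names(st)[2] <- "stress"
    names(dp)[2] <- "dep"
    if (!is.null(nz)) names(nz)[2] <- "neuro"
    h <- hcc[hcc$time_point == tp, c("person_id", "hcc_log", "hcc_resid")]
    out <- Reduce(function(x, y) merge(x, y, by = "person_id", all.x = TRUE),
                  list(base, st, dp, nz, h))
    out$time_point <- tp
    out
  }
  prepared <- rbind(assemble_tp(1), assemble_tp(2))
  cols <- c("person_id", "time_point", "sex", "age", "stress", "dep",
            "neuro", "hcc_log", "hcc_resid")
  list(prepared = prepared[cols],
       calibrations = list(stress = cal_stress, dep = cal_dep),
       winsor = win$bounds, n_clipped = win$n_clipped)
}
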