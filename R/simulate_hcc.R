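#' Emit raw hair cortisol concentrations
#'
#' Maps the latent log10-scale HCC trait to raw concentrations per person
#' and time point: additive batch, storage, month and study-phase effects
#' are applied on the log10 scale, the result is exponentiated and the
#' measurement offset subtracted, flooring at zero (concentrations cannot
#' be negative). This inverts the downstream `log10(raw + offset)`
#' preprocessing exactly when all experimental effects are zero.
#'
#' Effect values are drawn once per level under the sub-stream seed: batch
#' and study effects i.i.d. normal; storage effects decrease linearly with
#' storage-time group (older samples lose cortisol); month effects follow a
#' sinusoid peaking in March and bottoming in September.
#'
#' @param latent a [draw_latent_traits()] result (its `hcc` column is used),
#'   or a named list with `t1`/`t2` matrices containing an `hcc` column.
#' @param cohort the [build_cohort()] result whose `assay` table supplies
#'   the per-measurement labels.
#' @param truth the [true_model()] (experimental-effect SDs and offset).
#' @param seed integer seed.
#' @return data.frame: `person_id`, `time_point`, assay labels, `hcc_raw`
#'   (pg/mg), with the per-level effect values attached as attribute
#'   `effects`.
#' @export
emit_hcc_raw <- function(latent, cohort, truth, seed = 1) {
  set.seed(substream_seed(seed, "hcc"))
  design <- cohort$design
  es <- truth$experimental_sd
  effects <- list(
    batch = stats::setNames(stats::rnorm(design$n_batches, 0, es$batch),
                            paste0("b", seq_len(design$n_batches))),
    storage_group = stats::setNames(
      es$storage * seq(1, -1, length.out = design$n_storage_groups),
      paste0("s", seq_len(design$n_storage_groups))),
    month = stats::setNames(
      es$month * cos(2 * pi * (seq_len(12) - 3) / 12), month.abb),
    study_phase = stats::setNames(stats::rnorm(design$n_study_phases, 0,
                                               es$study),
                                  paste0("ph", seq_len(design$n_study_phases)))
  )
  assay <- cohort$assay
  idx <- match(assay$person_id, cohort$persons$person_id)
  lat <- ifelse(assay$time_point == 1L, latent$t1[idx, "hcc"],
                latent$t2[idx, "hcc"])
  shift <- effects$batch[assay$batch] +
    effects$storage_group[assay$storage_group] +
    effects$month[assay$month] +
    effects$study_phase[assay$study_phase]
  raw <- pmax(10^(lat + shift) - truth$hcc_offset, 0)
  out <- cbind(assay, hcc_raw = as.numeric(raw))
  attr(out, "effects") <- effects
  out
}
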