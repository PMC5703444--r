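#' Descriptive statistics table
#'
#' Mean (SD) of age, the three psychological phenotypes and raw hair
#' cortisol, overall and by sex.
#'
#' @param prepared time-1 wide phenotype data.frame with `person_id`, `sex`,
#'   `age`, `stress`, `dep`, `neuro`.
#' @param hcc_raw data.frame `person_id`, `hcc_raw` (time-1 raw pg/mg).
#' @return data.frame: `variable`, then `mean`/`sd`/`n` per stratum (total,
#'   male, female).
#' @export
descriptives <- function(prepared, hcc_raw) {
  d <- merge(prepared, hcc_raw[c("person_id", "hcc_raw")], by = "person_id",
             all.x = TRUE)
  strata <- list(total = rep(TRUE, nrow(d)), male = d$sex == 0,
                 female = d$sex == 1)
  if (any(vapply(strata, sum, numeric(1)) == 0)) stop("empty sex stratum")
  vars <- c(age = "age", stress = "stress", dep = "dep", neuro = "neuro",
            hcc_raw = "hcc_raw")
  out <- data.frame(variable = names(vars), stringsAsFactors = FALSE)
  for (s in names(strata)) {
    sub <- d[strata[[s]], ]
    out[[paste0(s, "_mean")]] <- vapply(vars, function(v)
      mean(sub[[v]], na.rm = TRUE), numeric(1))
    out[[paste0(s, "_sd")]] <- vapply(vars, function(v)
      stats::sd(sub[[v]], na.rm = TRUE), numeric(1))
    out[[paste0(s, "_n")]] <- vapply(vars, function(v)
      sum(!is.na(sub[[v]])), numeric(1))
  }
  out
}

flatten_decomposition <- function(std, cors) {
  traits <- rownames(std[[1]])
  rows <- list()
  for (comp in names(std)) {
    m <- std[[comp]]
    for (j in seq_along(traits)) for (k in seq_len(j)) {
      rows[[length(rows) + 1L]] <- data.frame(
        block = "standardized_pct", component = comp, trait = traits[j],
        factor = traits[k], value = m[j, k], stringsAsFactors = FALSE)
    }
  }
  for (cn in names(cors)) {
    m <- cors[[cn]]
    for (j in seq_along(traits)) for (k in seq_len(j - 1)) {
      rows[[length(rows) + 1L]] <- data.frame(
        block = "correlation", component = cn, trait = traits[j],
        factor = traits[k], value = m[j, k], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Signed-R2 sweep plot
#'
#' Visualizes the PRS association sweep: signed incremental R2 against the
#' inclusion threshold, one panel per phenotype, one bar color per discovery
#' trait, with one-sided significance tiers annotated above the bars.
#'
#' @param sweep result of [threshold_sweep()].
#' @return a ggplot object.
#' @export
plot_prs_sweep <- function(sweep) {
  sweep$threshold <- factor(sweep$threshold,
                            levels = sort(unique(sweep$threshold)))
  ggplot2::ggplot(sweep, ggplot2::aes(x = threshold, y = r2_signed,
                                      fill = discovery)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_text(ggplot2::aes(label = tier),
                       position = ggplot2::position_dodge(width = 0.8),
                       vjust = -0.2, size = 3) +
    ggplot2::facet_wrap(~phenotype) +
    ggplot2::labs(x = "p-value threshold", y = "signed incremental R²",
                  fill = "discovery trait") +
    ggplot2::theme_minimal()
}

#' Assemble and write the study report
#'
#' Renders the pipeline outputs into deterministic TSV tables (rounded to 2
#' decimals at render time only) with a JSON sidecar of unrounded values and
#' a provenance block (seed, configuration hash, package version). Rerunning
#' on identical inputs reproduces the files byte for byte. A missing PRS
#' stage yields a partial report with an explicit gap entry; missing core
#' stages are an error naming the stage to rerun.
#'
#' @param results list as returned by [run_study()] (fields `descriptives`,
#'   `twin`, optionally `prs`, plus `seed` and `config`).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
assemble_report <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(results$descriptives))
    stop("missing stage: descriptives; rerun the preparation stage")
  if (is.null(results$twin))
    stop("missing stage: twin modelling; rerun the twinfit stage")
  paths <- character(0)
  rnd <- function(d) {
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], round, 2)
    d
  }
  emit <- function(d, name) {
    p <- file.path(out_dir, name)
    write_tsv(rnd(d), p)
    paths <<- c(paths, p)
  }
  emit(results$descriptives, "descriptives.tsv")
  emit(results$twin$correlations_table, "twin_correlations.tsv")
  emit(results$twin$decomposition_table, "decomposition.tsv")
  gaps <- character(0)
  if (!is.null(results$prs)) {
    emit(results$prs$sweep, "prs_sweep.tsv")
  } else {
    gaps <- c(gaps, "prs")
  }
  sidecar <- list(
    provenance = list(
      seed = results$seed,
      config_hash = prov_hash(paste(deparse(results$config), collapse = "")),
      package_version = as.character(utils::packageVersion("cortwin"))),
    gaps = gaps,
    descriptives = results$descriptives,
    twin_correlations = results$twin$correlations_table,
    decomposition = results$twin$decomposition_table,
    model_selection = results$twin$selection,
    prs_sweep = results$prs$sweep
  )
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(sidecar, jp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  invisible(c(paths, jp))
}

#' Run the full synthetic twin study end to end
#'
#' Orchestrates the pipeline: cohort simulation, genotype/GWAS simulation,
#' latent traits, raw HCC and questionnaire items; phenotype preparation;
#' covariate screening; ACE/AE/CE Cholesky fits with LRT model selection;
#' twin correlations, stabilities and the median age-split reanalysis; and
#' (optionally) the PRS pipeline on the genotyped subsample. All randomness
#' derives from `seed`.
#'
#' @param seed integer global seed.
#' @param design a [cohort_design()].
#' @param truth a [true_model()].
#' @param m_variants,n_causal,discovery_n genotype/GWAS simulation sizes.
#' @param genotyped_fraction fraction of the cohort with genotypes (the PRS
#'   target subsample); the study default emulates 432/671.
#' @param irt_quad,irt_tol IRT calibration settings used by the pipeline.
#' @param n_starts optimizer starts per Cholesky fit (default 2: the moment
#'   start plus one diagonal start).
#' @param run_prs run the PRS stage (default TRUE).
#' @param median_split run the age median-split reanalysis (default TRUE).
#' @param out_dir if non-NULL, [assemble_report()] writes the tables there.
#' @return list with elements `cohort`, `truth`, `prepared`, `screen`,
#'   `descriptives`, `twin` (fits, selection, decomposition, correlation
#'   tables, stability, median split) and `prs` (QC report, profiles,
#'   sweep), plus `seed` and `config`.
#' @export
run_study <- function(seed = 1, design = cohort_design(),
                      truth = true_model(genetic_loading = c(0, 0.10, 0.10, 0.05)),
                      m_variants = 2000, n_causal = 50, discovery_n = 4000,
                      genotyped_fraction = 432 / 671,
                      irt_quad = 31, irt_tol = 1e-4, n_starts = 2,
                      run_prs = TRUE, median_split = TRUE, out_dir = NULL) {
  cohort <- build_cohort(design, seed)
  geno <- emit_genotypes_and_gwas(cohort, m_variants, n_causal, discovery_n,
                                  seed)
  latent <- draw_latent_traits(cohort, truth, seed,
                               genetic_scores = geno$scores)
  hcc_table <- emit_hcc_raw(latent, cohort, truth, seed)
  items <- emit_items(latent, cohort, irt_truth_default(seed), seed)
  prep <- prepare_phenotypes(cohort, hcc_table, items, n_quad = irt_quad,
                             tol = irt_tol)

  t1 <- hcc_table$time_point == 1
  screen <- covariate_screen(
    log10_offset_transform(hcc_table$hcc_raw[t1], truth$hcc_offset),
    hcc_table[t1, c("batch", "storage_group", "month", "study_phase")])

  wide1 <- prep$prepared[prep$prepared$time_point == 1, ]
  traits <- c("stress", "dep", "neuro", "hcc_resid")
  pedigree <- cohort$persons

  fits <- list(ACE = fit_model(wide1, pedigree, traits, "ACE",
                               n_starts = n_starts),
               AE = fit_model(wide1, pedigree, traits, "AE",
                              n_starts = n_starts),
               CE = fit_model(wide1, pedigree, traits, "CE",
                              n_starts = n_starts))
  lrt_ae <- compare_lrt(fits$ACE, fits$AE)
  lrt_ce <- compare_lrt(fits$ACE, fits$CE)
  chosen <- if (lrt_ae$p > 0.05) "AE" else if (lrt_ce$p > 0.05) "CE" else "ACE"
  fit <- fits[[chosen]]
  std <- standardize(fit)
  cors <- component_correlations(fit)

  tc <- twin_correlations(wide1, pedigree, traits)
  stab <- lapply(stats::setNames(traits, traits), function(tr)
    stability_correlation(prep$prepared, tr))
  corr_table <- do.call(rbind, lapply(traits, function(tr) {
    mz <- tc[tc$trait == tr & tc$zygosity == "MZ", ]
    dz <- tc[tc$trait == tr & tc$zygosity == "DZ", ]
    data.frame(trait = tr,
               r_mz = mz$r, r_mz_lo = mz$ci_lower, r_mz_hi = mz$ci_upper,
               r_dz = dz$r, r_dz_lo = dz$ci_lower, r_dz_hi = dz$ci_upper,
               h2 = attr(std, "h2")[match(tr, traits)],
               stability = stab[[tr]]$r,
               stability_lo = stab[[tr]]$ci[1],
               stability_hi = stab[[tr]]$ci[2],
               stringsAsFactors = FALSE)
  }))

  split_res <- if (median_split)
    median_split_fit(wide1, pedigree, traits, components = chosen,
                     n_starts = n_starts) else NULL

  prs_res <- NULL
  if (run_prs) {
    set.seed(substream_seed(seed, "genotyped_subset"))
    gsub <- sort(sample.int(nrow(cohort$persons),
                            round(genotyped_fraction * nrow(cohort$persons))))
    pid <- cohort$persons$person_id[gsub]
    fam <- cohort$persons$family_id[gsub]
    qc <- qc_filter(geno$G[gsub, , drop = FALSE], geno$variants, fam)
    fam_qc <- fam[match(rownames(qc$G), pid)]
    pcs <- pca_ancestry(qc$G, fam_qc, n_pcs = 5, seed = seed)
    ped_qc <- cohort$persons[match(rownames(qc$G),
                                   cohort$persons$person_id), ]
    K <- pedigree_kinship(ped_qc)
    profiles <- list()
    for (d in names(geno$sumstats)) {
      harm <- harmonize_alleles(geno$sumstats[[d]], qc$variants)
      idx <- clump(harm$effects, qc$G, qc$variants)
      profiles[[d]] <- score_at_thresholds(
        qc$G, harm$effects[harm$effects$id %in% idx, ])
    }
    ph <- wide1[match(rownames(qc$G), wide1$person_id), ]
    agec <- ph$age - mean(ph$age)
    covar <- cbind(sex = ph$sex, age = agec, age2 = agec^2,
                   sexage = ph$sex * agec, sexage2 = ph$sex * agec^2,
                   pcs,
                   wave = as.integer(factor(ped_qc$genotyping_wave)) - 1)
    sweep <- threshold_sweep(ph[c("stress", "dep", "neuro", "hcc_resid")],
                             profiles, covar, K)
    prs_res <- list(qc = qc$exclusions, profiles = profiles, sweep = sweep,
                    n_genotyped = nrow(qc$G))
  }

  desc <- descriptives(wide1, hcc_table[t1, c("person_id", "hcc_raw")])

  results <- list(
    cohort = cohort, truth = truth, prepared = prep, screen = screen,
    descriptives = desc,
    twin = list(fits = fits,
                selection = list(chosen = chosen, lrt_ae = lrt_ae,
                                 lrt_ce = lrt_ce),
                standardized = std, correlations = cors,
                correlations_table = corr_table,
                decomposition_table = flatten_decomposition(std, cors),
                median_split = split_res),
    prs = prs_res, seed = seed,
    config = list(design = unclass(design), m_variants = m_variants,
                  n_causal = n_causal, discovery_n = discovery_n,
                  genotyped_fraction = genotyped_fraction))
  if (!is.null(out_dir)) assemble_report(results, out_dir)
  results
}
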