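#' Hardy-Weinberg exact test
#'
#' Exact two-sided test of Hardy-Weinberg proportions for a biallelic
#' variant by full enumeration of heterozygote counts conditional on the
#' allele count: the p-value sums the probabilities of all heterozygote
#' counts no more probable than the observed one.
#'
#' @param n_het observed heterozygotes.
#' @param n_hom1,n_hom2 observed counts of the two homozygote classes.
#' @return exact p-value.
#' @export
hwe_exact_test <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  if (n == 0) return(1)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # unnormalized log-probabilities of each possible heterozygote count
  logp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, hets)]
  sum(pr[pr <= p_obs + 1e-12])
}

#' Quality-control filter for genotypes
#'
#' Drops persons with call rate below `call_rate`, then variants with call
#' rate below `call_rate`, minor allele frequency below `maf_min`, or
#' Hardy-Weinberg exact-test p below `hwe_p_min`. HWE is computed on one
#' person per family (the first by id) to avoid relatedness inflation.
#'
#' @param G person x variant dosage matrix (0..2, `NA` missing), rownames =
#'   person ids, colnames = variant ids.
#' @param variants variant table aligned with `colnames(G)` (columns `id`,
#'   `chrom`, `pos`, `ref`, `alt`).
#' @param family optional vector of family ids aligned with `rownames(G)`;
#'   `NULL` treats every person as their own family.
#' @param call_rate,maf_min,hwe_p_min thresholds (defaults 0.95, 0.01, 1e-6).
#' @return list `G`, `variants` (filtered) and `exclusions` (data.frame
#'   `type`, `id`, `reason`, `value`).
#' @export
qc_filter <- function(G, variants, family = NULL, call_rate = 0.95,
                      maf_min = 0.01, hwe_p_min = 1e-6) {
  stopifnot(ncol(G) == nrow(variants))
  if (is.null(family)) family <- rownames(G)
  excl <- list()
  note <- function(type, id, reason, value)
    excl[[length(excl) + 1L]] <<- data.frame(type = type, id = id,
                                             reason = reason, value = value,
                                             stringsAsFactors = FALSE)
  p_rate <- rowMeans(!is.na(G))
  for (i in which(p_rate < call_rate))
    note("person", rownames(G)[i], "call_rate", p_rate[i])
  keep_p <- p_rate >= call_rate
  G <- G[keep_p, , drop = FALSE]
  family <- family[keep_p]

  v_rate <- colMeans(!is.na(G))
  f <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  reps <- !duplicated(family)
  Gr <- round(G[reps, , drop = FALSE])
  hwe <- vapply(seq_len(ncol(G)), function(j) {
    x <- Gr[, j]
    x <- x[!is.na(x)]
    hwe_exact_test(sum(x == 1), sum(x == 0), sum(x == 2))
  }, numeric(1))

  keep_v <- rep(TRUE, ncol(G))
  for (j in seq_len(ncol(G))) {
    if (v_rate[j] < call_rate) {
      note("variant", variants$id[j], "call_rate", v_rate[j])
      keep_v[j] <- FALSE
    } else if (is.na(maf[j]) || maf[j] < maf_min) {
      note("variant", variants$id[j], "maf", maf[j])
      keep_v[j] <- FALSE
    } else if (hwe[j] < hwe_p_min) {
      note("variant", variants$id[j], "hwe", hwe[j])
      keep_v[j] <- FALSE
    }
  }
  if (!any(keep_v) || nrow(G) == 0) stop("no data left after QC")
  list(G = G[, keep_v, drop = FALSE],
       variants = variants[keep_v, , drop = FALSE],
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(type = character(), id = character(),
                    reason = character(), value = numeric()))
}

flip_strand <- function(a) chartr("ACGT", "TGCA", a)

#' Harmonize GWAS effect alleles with target genotypes
#'
#' Aligns per-variant discovery effect sizes to the target's counted (ALT)
#' allele: matching alleles keep the effect, swapped alleles flip its sign,
#' strand flips are resolved by complementing, strand-ambiguous (A/T, C/G)
#' variants are removed, and irreconcilable allele pairs are dropped with a
#' reason.
#'
#' @param stats summary-statistics data.frame with columns `SNP`, `A1`
#'   (effect allele), `A2`, `BETA`, `P`.
#' @param variants target variant table (`id`, `ref`, `alt`).
#' @return list `effects` (data.frame `id`, `beta`, `p` on the counted-ALT
#'   scale) and `dropped` (data.frame `id`, `reason`).
#' @export
harmonize_alleles <- function(stats, variants) {
  m <- merge(stats, variants[c("id", "ref", "alt")],
             by.x = "SNP", by.y = "id")
  dropped <- list()
  keep <- logical(nrow(m))
  beta <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    a1 <- m$A1[i]; a2 <- m$A2[i]
    if (a1 == flip_strand(a2)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(id = m$SNP[i], reason = "strand_ambiguous")
      next
    }
    if (a1 == m$alt[i] && a2 == m$ref[i]) {
      beta[i] <- m$BETA[i]; keep[i] <- TRUE
    } else if (a1 == m$ref[i] && a2 == m$alt[i]) {
      beta[i] <- -m$BETA[i]; keep[i] <- TRUE
    } else if (flip_strand(a1) == m$alt[i] && flip_strand(a2) == m$ref[i]) {
      beta[i] <- m$BETA[i]; keep[i] <- TRUE
    } else if (flip_strand(a1) == m$ref[i] && flip_strand(a2) == m$alt[i]) {
      beta[i] <- -m$BETA[i]; keep[i] <- TRUE
    } else {
      dropped[[length(dropped) + 1L]] <-
        data.frame(id = m$SNP[i], reason = "allele_mismatch")
    }
  }
  list(effects = data.frame(id = m$SNP[keep], beta = beta[keep],
                            p = m$P[keep], stringsAsFactors = FALSE),
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(id = character(), reason = character()))
}

#' Greedy LD clumping
#'
#' Keeps the most significant variant per correlated region: variants are
#' visited in order of ascending p (ties broken by chromosome, position,
#' id) and accepted unless their squared genotype correlation with an
#' already-accepted variant within `window_kb` exceeds `r2_max`.
#'
#' @param effects aligned effect table (`id`, `p`) from
#'   [harmonize_alleles()].
#' @param G target dosage matrix providing the LD estimates.
#' @param variants variant table (`id`, `chrom`, `pos`).
#' @param r2_max maximum allowed squared correlation (default 0.1).
#' @param window_kb window in kilobases (default 500).
#' @return character vector of retained (index) variant ids.
#' @export
clump <- function(effects, G, variants, r2_max = 0.1, window_kb = 500) {
  v <- merge(effects, variants[c("id", "chrom", "pos")], by = "id")
  v <- v[order(v$p, v$chrom, v$pos, v$id), ]
  kept <- character(0)
  kept_chrom <- integer(0)
  kept_pos <- numeric(0)
  for (i in seq_len(nrow(v))) {
    near <- which(kept_chrom == v$chrom[i] &
                    abs(kept_pos - v$pos[i]) <= window_kb * 1000)
    ok <- TRUE
    for (k in near) {
      r <- stats::cor(G[, v$id[i]], G[, kept[k]],
                      use = "pairwise.complete.obs")
      if (!is.na(r) && r^2 > r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      kept <- c(kept, v$id[i])
      kept_chrom <- c(kept_chrom, v$chrom[i])
      kept_pos <- c(kept_pos, v$pos[i])
    }
  }
  kept
}

#' Polygenic scores at nested p-value thresholds
#'
#' `score_i(t) = sum over variants with p <= t of beta * dosage_i`; missing
#' dosages are imputed to twice the counted-allele frequency in the target
#' sample, and the variant sets are nested across increasing thresholds.
#' Scores are z-standardized per threshold by default.
#'
#' @param G target dosage matrix (persons x variants).
#' @param effects aligned effect table (`id`, `beta`, `p`), typically
#'   restricted to clumped index variants.
#' @param thresholds p-value inclusion thresholds in (0, 1].
#' @param standardize z-standardize each threshold's scores (default TRUE).
#' @return matrix persons x thresholds with attribute `n_variants` (variants
#'   included per threshold).
#' @export
score_at_thresholds <- function(G, effects,
                                thresholds = c(5e-8, 1e-5, 0.001, 0.01,
                                               0.05, 0.1, 0.5, 1.0),
                                standardize = TRUE) {
  if (any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must lie in (0, 1]")
  eff <- effects[effects$id %in% colnames(G), , drop = FALSE]
  Gs <- G[, eff$id, drop = FALSE]
  f <- colMeans(Gs, na.rm = TRUE) / 2
  for (j in seq_len(ncol(Gs)))
    Gs[is.na(Gs[, j]), j] <- 2 * f[j]
  out <- matrix(0, nrow(G), length(thresholds),
                dimnames = list(rownames(G), as.character(thresholds)))
  nv <- integer(length(thresholds))
  for (k in seq_along(thresholds)) {
    sel <- eff$p <= thresholds[k]
    nv[k] <- sum(sel)
    if (nv[k] > 0)
      out[, k] <- Gs[, sel, drop = FALSE] %*% eff$beta[sel]
    if (standardize && nv[k] > 0 && stats::sd(out[, k]) > 0)
      out[, k] <- (out[, k] - mean(out[, k])) / stats::sd(out[, k])
  }
  attr(out, "n_variants") <- stats::setNames(nv, as.character(thresholds))
  out
}
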