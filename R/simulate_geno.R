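#' Emit family-structured genotypes and a simulated discovery GWAS
#'
#' Generates biallelic target-cohort genotypes by Mendelian transmission
#' (four founder haplotypes per family; MZ co-twins receive identical
#' gametes, DZ co-twins and siblings independent ones, so genotype sharing
#' is 1 for MZ and 0.5 in expectation otherwise) and, for each discovery
#' trait, per-variant summary statistics estimated by marginal regression in
#' an independent simulated discovery population.
#'
#' Variants are laid out on a grid of positions and can be organized into
#' LD blocks: within a block, haplotype alleles follow a Markov copying
#' process with correlation `ld_rho` and a common allele frequency, giving
#' block-wise LD sufficient for clumping; between blocks variants are
#' independent (transmission is per block, i.e. recombination occurs at
#' block boundaries).
#'
#' @param cohort a [build_cohort()] result.
#' @param m_variants number of variants.
#' @param n_causal causal variants per discovery trait (0 gives a null
#'   GWAS with uniform p-values).
#' @param discovery_n discovery-population size.
#' @param seed integer seed.
#' @param maf_range allele-frequency range of the counted (ALT) allele.
#' @param ld_block_size variants per LD block (1 = independent variants).
#' @param ld_rho within-block haplotype copying probability.
#' @param h2_discovery named vector: variance of each discovery phenotype
#'   explained by its causal set.
#' @param trait_map named character vector mapping discovery traits to
#'   target traits whose A factors the causal variants drive.
#' @return object of class `geno_data`: `variants` (id, chrom, pos, ref,
#'   alt, freq), `G` (person x variant ALT-dosage matrix), `sumstats`
#'   (per-discovery-trait data.frame with SNP/CHR/BP/A1/A2/FREQ/BETA/SE/P),
#'   `scores` (person x target-trait standardized true genetic scores) and
#'   `causal` (per-trait causal variant ids).
#' @export
emit_genotypes_and_gwas <- function(cohort, m_variants = 2000, n_causal = 50,
                                    discovery_n = 4000, seed = 1,
                                    maf_range = c(0.05, 0.5),
                                    ld_block_size = 1, ld_rho = 0.8,
                                    h2_discovery = c(cortisol = 0.3,
                                                     mdd = 0.3, neuro = 0.3),
                                    trait_map = c(cortisol = "hcc",
                                                  mdd = "dep",
                                                  neuro = "neuro")) {
  if (any(maf_range <= 0 | maf_range >= 1))
    stop("allele frequencies must lie strictly inside (0, 1)")
  if (m_variants < n_causal) stop("m_variants must be >= n_causal")
  set.seed(substream_seed(seed, "geno"))
  persons <- cohort$persons
  n <- nrow(persons)

  n_blocks <- ceiling(m_variants / ld_block_size)
  block <- rep(seq_len(n_blocks), each = ld_block_size)[seq_len(m_variants)]
  freq_block <- stats::runif(n_blocks, maf_range[1], maf_range[2])
  freq <- freq_block[block]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m_variants, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  variants <- data.frame(
    id = sprintf("rs%06d", seq_len(m_variants)),
    chrom = 1L + (block - 1L) %/% 100L,        # 100 blocks per chromosome
    pos = 10000L * (1L + (block - 1L) %% 100L) +
      stats::ave(block, block, FUN = seq_along) * 50L,
    ref = ref, alt = unname(alt), freq = freq, stringsAsFactors = FALSE)

  draw_haplos <- function(k) {
    # k haplotypes x m variants of 0/1 alleles with block-Markov LD
    h <- matrix(stats::rbinom(k * m_variants, 1, rep(freq, each = k)),
                k, m_variants)
    if (ld_block_size > 1) {
      for (j in 2:m_variants) {
        if (block[j] == block[j - 1]) {
          copy <- stats::runif(k) < ld_rho
          h[copy, j] <- h[copy, j - 1]
        }
      }
    }
    h
  }

  G <- matrix(0L, n, m_variants,
              dimnames = list(persons$person_id, variants$id))
  for (fid in unique(persons$family_id)) {
    idx <- which(persons$family_id == fid)
    founders <- draw_haplos(4L)          # maternal 1:2, paternal 3:4
    gamete <- function() {
      pick_m <- sample(1:2, n_blocks, replace = TRUE)
      pick_p <- sample(3:4, n_blocks, replace = TRUE)
      founders[cbind(pick_m[block], seq_len(m_variants))] +
        founders[cbind(pick_p[block], seq_len(m_variants))]
    }
    mz <- which(persons$zygosity[idx] == "MZ")
    g_mz <- if (length(mz)) gamete() else NULL
    for (k in seq_along(idx)) {
      G[idx[k], ] <- if (k %in% mz) g_mz else gamete()
    }
  }

  # causal architecture and true standardized scores on the target cohort
  sdx <- sqrt(2 * freq * (1 - freq))
  target_traits <- latent_trait_names(cohort)
  scores <- matrix(0, n, length(target_traits),
                   dimnames = list(persons$person_id, target_traits))
  causal <- list()
  weights <- list()
  for (d in names(trait_map)) {
    if (n_causal > 0) {
      cs <- sort(sample.int(m_variants, n_causal))
      w <- stats::rnorm(n_causal)
      w <- w / sqrt(sum(w^2))
      causal[[d]] <- variants$id[cs]
      weights[[d]] <- list(idx = cs, w = w)
      gs <- sweep(G[, cs, drop = FALSE], 2, 2 * freq[cs], `-`) %*%
        (w / sdx[cs])
      gs <- (gs - mean(gs)) / stats::sd(gs)
      if (trait_map[[d]] %in% target_traits)
        scores[, trait_map[[d]]] <- gs
    } else {
      causal[[d]] <- character(0)
      weights[[d]] <- list(idx = integer(0), w = numeric(0))
    }
  }

  # discovery GWAS: marginal per-variant regression in an unrelated panel
  sumstats <- list()
  for (d in names(trait_map)) {
    Xd <- draw_haplos(discovery_n) + draw_haplos(discovery_n)
    wd <- weights[[d]]
    g <- if (length(wd$idx)) {
      raw <- sweep(Xd[, wd$idx, drop = FALSE], 2, 2 * freq[wd$idx], `-`) %*%
        (wd$w / sdx[wd$idx])
      as.vector(raw) / stats::sd(raw)
    } else 0
    h2 <- h2_discovery[[d]] %||% 0.3
    y <- sqrt(h2) * g + sqrt(1 - h2) * stats::rnorm(discovery_n)
    xm <- colMeans(Xd)
    xc <- sweep(Xd, 2, xm, `-`)
    vx <- colSums(xc^2)
    beta <- as.vector(crossprod(xc, y - mean(y))) / vx
    rss <- sum((y - mean(y))^2) - beta^2 * vx
    se <- sqrt(rss / (discovery_n - 2) / vx)
    z <- beta / se
    sumstats[[d]] <- data.frame(
      SNP = variants$id, CHR = variants$chrom, BP = variants$pos,
      A1 = variants$alt, A2 = variants$ref, FREQ = xm / 2,
      BETA = beta, SE = se,
      P = pmin(pmax(2 * stats::pnorm(-abs(z)), 1e-300), 1),
      stringsAsFactors = FALSE)
  }

  structure(list(variants = variants, G = G, sumstats = sumstats,
                 scores = scores, causal = causal),
            class = "geno_data")
}

# trait names used for the genetic-score matrix; kept in one place so the
# generator and the true model agree
latent_trait_names <- function(cohort) c("stress", "dep", "neuro", "hcc")
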