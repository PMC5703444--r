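# Independent oracles, deliberately coded differently from the package paths
# they check.

# joint-normal -2 log-likelihood via determinant + solve (no Cholesky reuse)
brute_mvn_neg2ll <- function(y, mu, S) {
  obs <- !is.na(y)
  y <- y[obs]
  mu <- mu[obs]
  S <- S[obs, obs, drop = FALSE]
  as.numeric(length(y) * log(2 * pi) +
               determinant(S, logarithm = TRUE)$modulus +
               t(y - mu) %*% solve(S) %*% (y - mu))
}

# exhaustive greedy clumping oracle (quadratic scan, no windows bookkeeping)
brute_clump <- function(effects, G, variants, r2_max = 0.1, window_kb = 500) {
  v <- merge(effects, variants[c("id", "chrom", "pos")], by = "id")
  v <- v[order(v$p, v$chrom, v$pos, v$id), ]
  acc <- character(0)
  for (i in seq_len(nrow(v))) {
    ok <- TRUE
    for (a in acc) {
      va <- v[v$id == a, ]
      if (va$chrom == v$chrom[i] &&
          abs(va$pos - v$pos[i]) <= window_kb * 1000 &&
          stats::cor(G[, v$id[i]], G[, a])^2 > r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) acc <- c(acc, v$id[i])
  }
  acc
}

# Hardy-Weinberg exact p by direct enumeration of genotype tables
brute_hwe <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  na <- 2 * n_hom1 + n_het    # copies of allele 1
  probs <- sapply(seq(na %% 2, min(na, 2 * n - na), by = 2), function(h) {
    h1 <- (na - h) / 2
    h2 <- n - h - h1
    exp(lfactorial(n) - lfactorial(h1) - lfactorial(h) - lfactorial(h2) +
          h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
          lfactorial(2 * n))
  })
  probs <- probs / sum(probs)
  obs <- which(seq(na %% 2, min(na, 2 * n - na), by = 2) == n_het)
  sum(probs[probs <= probs[obs] + 1e-12])
}

# quick standardized-path truth used across twin-model tests: the package's
# default generating model (A and E shares per trait)
default_truth_paths <- function() {
  tm <- true_model()
  list(X = tm$X, Z = tm$Z)
}
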