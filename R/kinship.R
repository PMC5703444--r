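#' Pedigree relatedness matrix
#'
#' Expected additive-genetic relationship matrix from the pedigree: 1 on the
#' diagonal and for MZ co-twins, 0.5 for DZ co-twins and full siblings
#' within a family, 0 between families. Symmetric positive semidefinite by
#' construction.
#'
#' @param pedigree data.frame with `person_id`, `family_id`, `zygosity`.
#' @return n x n matrix with person ids as dimnames.
#' @export
pedigree_kinship <- function(pedigree) {
  n <- nrow(pedigree)
  K <- matrix(0, n, n, dimnames = list(pedigree$person_id,
                                       pedigree$person_id))
  for (fid in unique(pedigree$family_id)) {
    idx <- which(pedigree$family_id == fid)
    mz <- pedigree$zygosity[idx] == "MZ"
    if (sum(mz) > 2)
      stop("inconsistent zygosity: family ", fid,
           " has more than two MZ-labelled members")
    K[idx, idx] <- 0.5
    K[idx[mz], idx[mz]] <- 1
  }
  diag(K) <- 1
  K
}

#' Ancestry principal components
#'
#' PCA of the column-standardized dosage matrix. Axes are estimated on one
#' member per family (chosen under the seed) to avoid relatedness-driven
#' components, then every person is projected onto them. Orientation is
#' made deterministic by flipping each axis so its largest-magnitude variant
#' loading is positive.
#'
#' @param G persons x variants dosage matrix (QC-passed).
#' @param family family ids aligned with `rownames(G)`; `NULL` treats
#'   persons as unrelated.
#' @param n_pcs number of components (default 5; 0 gives a zero-column
#'   matrix).
#' @param seed seed for the per-family representative choice.
#' @return persons x n_pcs score matrix with attribute `eigenvalues`.
#' @export
pca_ancestry <- function(G, family = NULL, n_pcs = 5, seed = 1) {
  if (ncol(G) < n_pcs) stop("fewer variants than requested PCs")
  if (n_pcs == 0)
    return(matrix(0, nrow(G), 0, dimnames = list(rownames(G), NULL)))
  if (is.null(family)) family <- rownames(G) %||% as.character(seq_len(nrow(G)))
  set.seed(substream_seed(seed, "pca"))
  reps <- vapply(split(seq_len(nrow(G)), family),
                 function(ix) ix[sample.int(length(ix), 1)], integer(1))
  f <- colMeans(G, na.rm = TRUE) / 2
  sdx <- sqrt(pmax(2 * f * (1 - f), 1e-12))
  std <- function(M) {
    M <- sweep(M, 2, 2 * f, `-`)
    M[is.na(M)] <- 0
    sweep(M, 2, sdx, `/`)
  }
  Xr <- std(G[reps, , drop = FALSE])
  sv <- svd(Xr, nu = 0, nv = n_pcs)
  V <- sv$v
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  scores <- std(G) %*% V
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  attr(scores, "eigenvalues") <- (sv$d^2 / (nrow(Xr) - 1))[seq_len(min(n_pcs, length(sv$d)))]
  scores
}
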