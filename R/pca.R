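#' Principal components of a genotype matrix for stratification adjustment
#'
#' Computes ancestry principal components the way genotype-PCA tools for
#' stratification correction do: missing genotypes are mean-imputed, each SNP
#' column is centred on its mean and scaled by `sqrt(p(1-p))` where
#' `p = (1 + sum g) / (2 + 2n)` is the posterior effect-allele frequency
#' (the +1/+2 pseudo-counts keep near-monomorphic SNPs from blowing up the
#' scale), and the top-`k` left singular vectors of the standardized matrix
#' are returned as per-individual scores.
#'
#' @param genotypes individuals x SNPs numeric matrix with values 0/1/2 or NA.
#' @param k number of components; `k = 0` returns a zero-column matrix.
#' @return individuals x `k` matrix of orthonormal PC scores (columns satisfy
#'   `crossprod(pcs) == I` to numerical precision).
#' @details Monomorphic SNP columns carry no ancestry information and are
#'   dropped with a warning. Requesting more components than the rank of the
#'   standardized matrix is an error.
#' @export
eigenstrat_pcs <- function(genotypes, k) {
  assert_that(k >= 0, "'k' must be >= 0")
  n <- nrow(genotypes)
  if (k == 0) return(matrix(numeric(0), nrow = n, ncol = 0))
  G <- genotypes
  storage.mode(G) <- "double"
  # mean-impute missing before standardization
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  v <- apply(G, 2, stats::var)
  mono <- v == 0 | is.na(v)
  if (any(mono)) {
    warning(sprintf("dropping %d monomorphic SNP column(s) before PCA: %s",
                    sum(mono), paste(colnames(G)[mono], collapse = ", ")))
    G <- G[, !mono, drop = FALSE]
  }
  assert_that(ncol(G) >= 2, "need >= 2 non-monomorphic SNP columns for PCA")
  p_hat <- (1 + colSums(G)) / (2 + 2 * n)
  X <- sweep(G, 2, colMeans(G), "-")
  X <- sweep(X, 2, sqrt(p_hat * (1 - p_hat)), "/")
  sv <- svd(X, nu = min(n, ncol(X)), nv = 0)
  rank <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1])
  assert_that(k <= rank,
              sprintf("k = %d exceeds the rank (%d) of the standardized genotype matrix",
                      k, rank))
  pcs <- sv$u[, seq_len(k), drop = FALSE]
  colnames(pcs) <- paste0("PC", seq_len(k))
  pcs
}
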