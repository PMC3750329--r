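#' Centered-PCA baseline embedding
#'
#' Centers the data by subtracting the column means and projects onto the
#' top-m right singular directions, ordered by decreasing singular value.
#' Serves as the linear, global-structure baseline against the nonlinear
#' t-SNE map. The sign of each component is fixed deterministically by
#' making its largest-magnitude loading positive.
#'
#' @param X n x d data matrix.
#' @param m output dimension, `m <= min(n, d)`.
#' @return An `embedding` with `method = "pca"`, plus `rotation` (d x m
#'   loadings) and `center` for reconstruction.
#' @export
run_pca <- function(X, m = 2L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  if (m > min(dim(X))) {
    stop(sprintf("m = %d exceeds min(n, d) = %d", m, min(dim(X))))
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0, nv = m)
  V <- sv$v
  for (j in seq_len(m)) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  structure(list(Y = Xc %*% V, m = as.integer(m), method = "pca",
                 final_cost = NULL, rotation = V, center = ctr,
                 sdev = sv$d[seq_len(m)] / sqrt(max(1, nrow(X) - 1))),
            class = "embedding")
}
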