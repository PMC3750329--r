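#' Pairwise squared Euclidean distances
#'
#' @param X n x d numeric matrix, finite.
#' @return Symmetric n x n matrix of squared distances, zero diagonal.
#' @export
pairwise_sq_dists <- function(X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  s <- rowSums(X^2)
  D <- outer(s, s, "+") - 2 * tcrossprod(X)
  D[D < 0] <- 0 # numerical negatives
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

#' t-SNE optimization settings
#'
#' Defaults follow the standard published schedule for exact t-SNE:
#' perplexity 30 (the recommended range being roughly 5-50), 1000
#' gradient-descent iterations at learning rate 200, momentum 0.5 switching
#' to 0.8 at iteration 250, early exaggeration of the input affinities by 4
#' for the first 100 iterations, and a small Gaussian initialization
#' (sd 1e-4). `min_prob_floor` guards the KL cost against log(0).
#'
#' @param perplexity smooth effective-neighbor count steering each point's
#'   Gaussian bandwidth; must satisfy `perplexity <= n - 1` at run time.
#' @param n_iter,learning_rate,momentum_early,momentum_late,momentum_switch_iter
#'   gradient-descent schedule.
#' @param early_exaggeration_factor,early_exaggeration_iter multiply the
#'   high-dimensional affinities by this factor for the first iterations,
#'   which lets tight clusters form before fine-tuning.
#' @param init_sd sd of the random initial map.
#' @param seed seed for the initial map.
#' @param min_prob_floor floor applied to low-dimensional probabilities in
#'   the cost (and gradient) to avoid log(0).
#' @param cal_tol calibration tolerance on the log2 entropy scale; 1e-7
#'   keeps the realized perplexity within ~1e-4 of the target absolutely.
#' @param cal_max_iter binary-search iterations per point.
#' @return A `tsne_config` list.
#' @export
tsne_config <- function(perplexity = 30, n_iter = 1000, learning_rate = 200,
                        momentum_early = 0.5, momentum_late = 0.8,
                        momentum_switch_iter = 250,
                        early_exaggeration_factor = 4,
                        early_exaggeration_iter = 100,
                        init_sd = 1e-4, seed = 1L, min_prob_floor = 1e-12,
                        cal_tol = 1e-7, cal_max_iter = 50L) {
  if (perplexity < 1) stop("perplexity must be >= 1")
  if (n_iter < 1) stop("n_iter must be >= 1")
  structure(list(perplexity = perplexity, n_iter = as.integer(n_iter),
                 learning_rate = learning_rate,
                 momentum_early = momentum_early,
                 momentum_late = momentum_late,
                 momentum_switch_iter = as.integer(momentum_switch_iter),
                 early_exaggeration_factor = early_exaggeration_factor,
                 early_exaggeration_iter = as.integer(early_exaggeration_iter),
                 init_sd = init_sd, seed = as.integer(seed),
                 min_prob_floor = min_prob_floor,
                 cal_tol = cal_tol, cal_max_iter = as.integer(cal_max_iter)),
            class = "tsne_config")
}

#' Calibrate high-dimensional affinities to a fixed perplexity
#'
#' For each point i the Gaussian precision beta_i = 1/(2 sigma_i^2) is tuned
#' by binary search (doubling/halving to bracket, then bisection) until the
#' entropy of the conditional neighbor distribution p_{j|i} matches
#' log2(perplexity) to `tol`. The conditionals are then symmetrized,
#' p_ij = (p_{j|i} + p_{i|j}) / 2, and divided by n so the joint matrix P is
#' a probability distribution over ordered pairs (each conditional row sums
#' to 1, so the symmetrized sum is n, not 1 — the division restores a valid
#' KL reference distribution).
#'
#' @param D n x n matrix of squared distances ([pairwise_sq_dists()]).
#' @param perplexity target perplexity, `1 <= perplexity <= n - 1`.
#' @param tol tolerance on `|log2 realized - log2 target|`.
#' @param max_iter binary-search iterations per point.
#' @return An `affinity_matrix`: list with `P` (symmetric joint, sums to 1),
#'   `P_cond` (row-stochastic conditionals, zero diagonal), `sigmas`,
#'   `perplexity`, `realized_perplexity` (per-row `2^H`).
#' @export
calibrate_affinities <- function(D, perplexity, tol = 1e-7, max_iter = 50L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L || ncol(D) != n) stop("D must be a square matrix with n >= 2")
  if (perplexity < 1) stop("perplexity must be >= 1")
  if (perplexity > n - 1) {
    stop(sprintf(
      "perplexity %g infeasible: effective neighbors exceed the %d available points",
      perplexity, n - 1L))
  }
  res <- .cpp_calibrate(D, perplexity, tol, as.integer(max_iter))
  P_cond <- res$P_cond
  P <- (P_cond + t(P_cond)) / (2 * n)
  structure(list(P = P, P_cond = P_cond,
                 sigmas = sqrt(1 / (2 * res$beta)),
                 perplexity = perplexity,
                 realized_perplexity = as.numeric(res$realized_perplexity)),
            class = "affinity_matrix")
}

#' Low-dimensional Student-t affinities
#'
#' q_ij proportional to (1 + ||y_i - y_j||^2)^-1, normalized over all
#' ordered pairs; the heavy tail relieves the crowding problem that a
#' Gaussian low-dimensional kernel suffers from.
#'
#' @param Y n x m map-point matrix, n >= 2.
#' @return Symmetric n x n matrix with zero diagonal summing to 1.
#' @export
low_dim_affinities <- function(Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2L) stop("need at least 2 map points")
  if (!all(is.finite(Y))) stop("Y must be finite")
  num <- 1 / (1 + pairwise_sq_dists(Y))
  diag(num) <- 0
  num / sum(num)
}

#' Kullback-Leibler cost of an embedding
#'
#' `sum_{i != j} p_ij log(p_ij / q_ij)` with the conventions
#' `0 * log(0/q) = 0` and q floored at `min_prob_floor`. Zero iff P = Q;
#' the asymmetry of KL is what makes the map preserve local structure:
#' placing close input points far apart is expensive, the converse cheap.
#'
#' @param P,Q same-shape affinity matrices.
#' @param min_prob_floor floor for Q entries.
#' @return Nonnegative scalar.
#' @export
kl_cost <- function(P, Q, min_prob_floor = 1e-12) {
  if (!identical(dim(P), dim(Q))) stop("P and Q must have identical shape")
  pos <- P > 0
  sum(P[pos] * log(P[pos] / pmax(Q[pos], min_prob_floor)))
}

#' Analytic t-SNE gradient
#'
#' `dKL/dy_i = 4 sum_j (p_ij - q_ij) (y_i - y_j) (1 + ||y_i - y_j||^2)^-1`.
#'
#' @param P high-dimensional joint affinities.
#' @param Y current n x m map.
#' @param min_prob_floor floor for Q entries, as in [kl_cost()].
#' @return n x m gradient matrix.
#' @export
tsne_gradient <- function(P, Y, min_prob_floor = 1e-12) {
  Y <- as.matrix(Y)
  if (nrow(P) != nrow(Y) || ncol(P) != nrow(Y)) {
    stop("P must be n x n with n = nrow(Y)")
  }
  .cpp_tsne_grad(P, Y, min_prob_floor, FALSE)$grad
}

#' Exact t-SNE embedding
#'
#' Full pipeline: squared distances, per-point perplexity calibration,
#' symmetrized and normalized joint affinities, then momentum gradient
#' descent on the KL divergence with early exaggeration. Exact O(n^2) in
#' time and memory, intended for desk-scale inputs (a warning is issued
#' beyond 30,000 points, where tree-based approximations are the right
#' tool).
#'
#' @param X n x d data matrix (n >= 4).
#' @param m output dimension, typically 2 (visualization) or 10.
#' @param cfg a [tsne_config()].
#' @return An `embedding`: list with `Y` (n x m), `m`, `method = "tsne"`,
#'   `final_cost` (KL on the un-exaggerated affinities).
#' @export
run_tsne <- function(X, m = 2L, cfg = tsne_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("t-SNE needs at least 4 points")
  if (n > 30000L) {
    warning("exact t-SNE stores n^2 doubles; n = ", n,
            " will need >", round(8 * n^2 / 2^30, 1), " GiB per matrix")
  }
  if (cfg$perplexity > n - 1) {
    stop(sprintf(
      "perplexity %g infeasible: effective neighbors exceed the %d available points",
      cfg$perplexity, n - 1L))
  }
  D <- pairwise_sq_dists(X)
  aff <- calibrate_affinities(D, cfg$perplexity, tol = cfg$cal_tol,
                              max_iter = cfg$cal_max_iter)
  Y0 <- with_seed(cfg$seed,
                  matrix(stats::rnorm(n * m, sd = cfg$init_sd), n, m))
  res <- .cpp_tsne_loop(aff$P, Y0, cfg$n_iter, cfg$learning_rate,
                        cfg$momentum_early, cfg$momentum_late,
                        cfg$momentum_switch_iter,
                        cfg$early_exaggeration_factor,
                        cfg$early_exaggeration_iter, cfg$min_prob_floor)
  structure(list(Y = res$Y, m = as.integer(m), method = "tsne",
                 final_cost = res$final_cost),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %s, %d points in %d-D%s\n", x$method, nrow(x$Y),
              x$m,
              if (!is.null(x$final_cost)) sprintf(", KL = %.4f", x$final_cost)
              else ""))
  invisible(x)
}

#' Write an embedding to TSV
#'
#' Columns: `voxel` (0-based row index) then `coordinate_1..m`.
#' @param emb an `embedding`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embedding_tsv <- function(emb, path) {
  df <- data.frame(voxel = seq_len(nrow(emb$Y)) - 1L, emb$Y)
  names(df) <- c("voxel", paste0("coordinate_", seq_len(emb$m)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an embedding TSV written by [write_embedding_tsv()]
#' @param path TSV path.
#' @param method method tag to record.
#' @return An `embedding`.
#' @export
read_embedding_tsv <- function(path, method = "tsne") {
  df <- utils::read.delim(path)
  Y <- as.matrix(df[grep("^coordinate_", names(df))])
  structure(list(Y = unname(Y), m = ncol(Y), method = method,
                 final_cost = NULL), class = "embedding")
}
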