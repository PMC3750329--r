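#' k-means parcellation with a best-of-restarts protocol
#'
#' Lloyd iterations from initial centers drawn uniformly without replacement
#' from the data rows, repeated `restarts` times from distinct sub-seeds;
#' the restart with the smallest within-cluster sum of squares (WCSS) wins.
#' Empty clusters are repaired by promoting the point currently farthest
#' from its assigned center to a new center. Deterministic given `seed`.
#'
#' @param X n x m numeric matrix.
#' @param k number of clusters, `1 <= k <= n`.
#' @param restarts independent restarts (default 10).
#' @param seed master seed; restart r runs from a sub-seed derived from it.
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @return A `clustering_result`: `labels` (0-based, in `[0, k)`), `k`,
#'   `wcss`, `centers`, `restarts_run`, `best_restart`, and `wcss_by_restart`.
#' @export
kmeans_restarts <- function(X, k, restarts = 10L, seed = 1L, max_iter = 300L) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop(sprintf("k = %d exceeds n = %d points", k, n))
  best <- NULL
  wcss_log <- numeric(restarts)
  for (r in seq_len(restarts)) {
    fit <- with_seed(derive_seed(seed, paste0("kmeans-restart-", r)),
                     lloyd_once(X, k, max_iter))
    wcss_log[r] <- fit$wcss
    if (is.null(best) || fit$wcss < best$wcss) {
      best <- fit
      best_r <- r
    }
  }
  structure(list(labels = best$labels - 1L, k = k, wcss = best$wcss,
                 centers = best$centers, restarts_run = as.integer(restarts),
                 best_restart = as.integer(best_r),
                 wcss_by_restart = wcss_log,
                 wcss_trace = best$trace),
            class = "clustering_result")
}

# distances from every row of X to every center (squared)
dist_to_centers <- function(X, C) {
  D <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
  D[D < 0] <- 0
  D
}

# one Lloyd run; labels 1-based internally
lloyd_once <- function(X, k, max_iter) {
  n <- nrow(X)
  centers <- X[sample.int(n, k), , drop = FALSE]
  labels <- integer(n)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    D <- dist_to_centers(X, centers)
    new_labels <- max.col(-D, ties.method = "first")
    # repair empty clusters: farthest point from its center becomes a center
    repeat {
      sizes <- tabulate(new_labels, nbins = k)
      empt <- which(sizes == 0L)
      if (length(empt) == 0L) break
      d_own <- D[cbind(seq_len(n), new_labels)]
      d_own[sizes[new_labels] == 1L] <- -Inf # don't orphan singletons
      far <- which.max(d_own)
      centers[empt[1L], ] <- X[far, ]
      D[, empt[1L]] <- rowSums(sweep(X, 2, centers[empt[1L], ])^2)
      new_labels[far] <- empt[1L]
      new_labels <- max.col(-D, ties.method = "first")
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(X[new_labels == j, , drop = FALSE])
    }
    trace <- c(trace, sum((X - centers[new_labels, , drop = FALSE])^2))
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  list(labels = labels, centers = centers,
       wcss = trace[length(trace)], trace = trace)
}

#' Number of clusters implied by an annotation level
#'
#' The cluster count is tied to the anatomy under study: k equals the
#' number of distinct structures present among the voxels at that level
#' (structures with no surviving voxels cannot be recovered and are not
#' counted).
#'
#' @param labels_at_level term-id vector for the voxels at one level.
#' @return Integer k.
#' @export
choose_k <- function(labels_at_level) {
  if (length(labels_at_level) == 0L) stop("empty label vector")
  length(unique(labels_at_level))
}
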