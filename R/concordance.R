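#' Class-by-cluster contingency table
#'
#' Cross-tabulates anatomical class labels (rows) against cluster
#' assignments (columns). Classes and clusters are indexed in first-seen
#' order; the label-to-index maps are returned for reporting.
#'
#' @param class_labels vector of class (annotation) labels.
#' @param cluster_labels vector of cluster ids, same length.
#' @return A `contingency_table`: `counts` (r x c integer matrix),
#'   `row_totals`, `col_totals`, `N`, `class_levels`, `cluster_levels`.
#' @export
contingency <- function(class_labels, cluster_labels) {
  if (length(class_labels) != length(cluster_labels)) {
    stop("class and cluster label vectors must have equal length")
  }
  if (length(class_labels) == 0L) stop("empty label vectors")
  cls <- unique(class_labels)
  clu <- unique(cluster_labels)
  counts <- matrix(0L, nrow = length(cls), ncol = length(clu))
  tab <- table(factor(class_labels, levels = cls),
               factor(cluster_labels, levels = clu))
  counts[] <- as.integer(tab)
  structure(list(counts = counts,
                 row_totals = as.integer(rowSums(counts)),
                 col_totals = as.integer(colSums(counts)),
                 N = length(class_labels),
                 class_levels = cls, cluster_levels = clu),
            class = "contingency_table")
}

check_table <- function(t) {
  if (!inherits(t, "contingency_table")) t <- do.call(contingency, t)
  if (t$N == 0L) stop("empty contingency table")
  t
}

#' Purity of a clustering against class labels
#'
#' Each cluster is assigned to its most frequent class; purity is the
#' proportion of correctly assigned samples. Ties go to the smallest class
#' index for determinism. Purity cannot trade quality against the number of
#' clusters: splitting never decreases it.
#'
#' @param t a [contingency()] table.
#' @return Value in (0, 1].
#' @export
purity <- function(t) {
  t <- check_table(t)
  sum(apply(t$counts, 2, max)) / t$N
}

#' Normalized mutual information
#'
#' `I(class; cluster) / ((H(class) + H(cluster)) / 2)` with natural
#' logarithms and `0 log 0 = 0`; the normalization base cancels. Equals 1
#' for identical partitions (defined as 1 when both entropies vanish) and 0
#' when the table factorizes into its marginals.
#'
#' @param t a [contingency()] table.
#' @return Value in [0, 1].
#' @export
nmi <- function(t) {
  t <- check_table(t)
  N <- t$N
  p_ij <- t$counts / N
  p_i <- t$row_totals / N
  p_j <- t$col_totals / N
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hi <- h(p_i); hj <- h(p_j)
  if (hi == 0 && hj == 0) return(1)
  pos <- p_ij > 0
  mi <- sum(p_ij[pos] * log(p_ij[pos] / outer(p_i, p_j)[pos]))
  mi / ((hi + hj) / 2)
}

#' Adjusted Rand index
#'
#' Hubert-Arabie adjustment of the pair-counting Rand index: the fraction
#' of voxel pairs on which the two partitions agree (same class & same
#' cluster, or different class & different cluster), rescaled so that the
#' expected value under random labeling with fixed marginals is 0 and
#' identical partitions score 1.
#'
#' @param t a [contingency()] table built from at least 2 samples.
#' @return Value in [-1, 1].
#' @export
ari <- function(t) {
  t <- check_table(t)
  if (t$N < 2L) stop("ARI needs at least 2 samples")
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(t$counts))
  a <- sum(ch2(t$row_totals))
  b <- sum(ch2(t$col_totals))
  expected <- a * b / ch2(t$N)
  denom <- (a + b) / 2 - expected
  if (denom == 0) {
    # both partitions all singletons or single-block: identical iff index matches
    return(if (sum_ij == a && a == b) 1 else 0)
  }
  (sum_ij - expected) / denom
}

#' S-index: subset-consistency of two parcellations
#'
#' Voxel-weighted containment, `sum_ij (n_ij / N) * n_ij / min(n_i., n_.j)`.
#' Each class-cluster overlap is scored by how close it is to a pure subset
#' relation (1 when one side contains the other) and overlaps are averaged
#' with voxel weights. The index equals 1 whenever every cluster nests
#' inside a class or vice versa, and penalizes relationships that overlap
#' without being subset relations — which plain purity does not.
#'
#' @param t a [contingency()] table.
#' @return Value in (0, 1].
#' @export
s_index <- function(t) {
  t <- check_table(t)
  mins <- outer(t$row_totals, t$col_totals, pmin)
  sum((t$counts / t$N) * (t$counts / mins))
}

#' All four concordance measures at once
#'
#' @param class_labels anatomical labels (one per voxel).
#' @param cluster_labels cluster assignments.
#' @return A `concordance_scores` list: `nmi`, `ari`, `purity`, `s_index`.
#' @export
score_all <- function(class_labels, cluster_labels) {
  t <- contingency(class_labels, cluster_labels)
  structure(list(nmi = nmi(t), ari = ari(t), purity = purity(t),
                 s_index = s_index(t)),
            class = "concordance_scores")
}

#' @export
print.concordance_scores <- function(x, ...) {
  cat(sprintf("NMI %.4f | S-index %.4f | ARI %.4f | Purity %.4f\n",
              x$nmi, x$s_index, x$ari, x$purity))
  invisible(x)
}
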