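# Independent brute-force oracles. These deliberately use naive loops and
# textbook formulas, never the package's optimized code paths.

bf_sq_dists <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sum((X[i, ] - X[j, ])^2)
  }
  D
}

bf_low_dim_q <- function(Y) {
  n <- nrow(Y)
  num <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) num[i, j] <- 1 / (1 + sum((Y[i, ] - Y[j, ])^2))
  }
  num / sum(num)
}

bf_kl <- function(P, Q) {
  tot <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    if (i != j && P[i, j] > 0) tot <- tot + P[i, j] * log(P[i, j] / Q[i, j])
  }
  tot
}

# ancestor by naive parent-link walk on the raw term table
bf_ancestor <- function(tree, id, level) {
  terms <- tree$terms
  row <- terms[terms$id == id, ]
  while (row$level > level) row <- terms[terms$id == row$parent_id, ]
  stopifnot(row$level == level)
  row$id
}

# sigma for one distance row by scanning a fine beta grid
bf_sigma_grid <- function(d_row, perplexity, betas) {
  ent <- vapply(betas, function(b) {
    p <- exp(-b * (d_row - min(d_row)))
    p <- p / sum(p)
    -sum(p[p > 0] * log(p[p > 0]))
  }, numeric(1))
  b <- betas[which.min(abs(ent - log(perplexity)))]
  sqrt(1 / (2 * b))
}

bf_purity <- function(cls, clu) {
  correct <- 0
  for (g in unique(clu)) {
    correct <- correct + max(table(cls[clu == g]))
  }
  correct / length(cls)
}

bf_nmi <- function(cls, clu) {
  n <- length(cls)
  mi <- 0
  for (a in unique(cls)) for (b in unique(clu)) {
    nij <- sum(cls == a & clu == b)
    if (nij > 0) {
      mi <- mi + (nij / n) * log(nij * n / (sum(cls == a) * sum(clu == b)))
    }
  }
  h <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log(p))
  }
  hc <- h(cls); hk <- h(clu)
  if (hc == 0 && hk == 0) return(1)
  mi / ((hc + hk) / 2)
}

# ARI by exhaustive enumeration of all point pairs
bf_ari <- function(cls, clu) {
  n <- length(cls)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_c <- cls[i] == cls[j]
    same_k <- clu[i] == clu[j]
    if (same_c && same_k) s11 <- s11 + 1
    else if (!same_c && !same_k) s00 <- s00 + 1
    else if (same_c) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  a <- s11 + s10  # same-class pairs
  b <- s11 + s01  # same-cluster pairs
  tot <- choose(n, 2)
  expected <- a * b / tot
  denom <- (a + b) / 2 - expected
  if (denom == 0) return(if (s10 + s01 == 0) 1 else 0)
  (s11 - expected) / denom
}

bf_s_index <- function(cls, clu) {
  n <- length(cls)
  tot <- 0
  for (a in unique(cls)) for (b in unique(clu)) {
    nij <- sum(cls == a & clu == b)
    if (nij > 0) {
      tot <- tot + (nij / n) * nij / min(sum(cls == a), sum(clu == b))
    }
  }
  tot
}
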