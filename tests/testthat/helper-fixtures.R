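# Small in-code fixtures shared across test files.

# linear chain root -> ... -> leaf, ids 1..(depth+1)
chain_tree <- function(depth) {
  ids <- seq_len(depth + 1L)
  ontology_tree(data.frame(
    id = ids, acronym = paste0("C", ids - 1L),
    name = paste("chain level", ids - 1L), level = ids - 1L,
    parent_id = c(NA_integer_, ids[-length(ids)]),
    color = rep("#336699", depth + 1L)))
}

# hand-built tree reaching level 6 with a designated "cord" subtree to
# exclude: root(1) -> brain(2), cord(3); brain -> chain down to level 6;
# plus a shallow level-3 term under brain for the min-level filter.
filter_tree <- function() {
  df <- data.frame(
    id        = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L),
    acronym   = c("NP", "Br", "SpC", "b2", "b3", "b4", "b5", "b6", "s4", "s5"),
    name      = paste("t", 1:10),
    level     = c(0L, 1L, 1L, 2L, 3L, 4L, 5L, 6L, 2L, 3L),
    parent_id = c(NA, 1L, 1L, 2L, 4L, 5L, 6L, 7L, 3L, 9L),
    color     = rep("#AABBCC", 10))
  # deepen the cord side to level 6 so its voxels fail only the exclusion
  extra <- data.frame(
    id = c(11L, 12L, 13L), acronym = c("s6", "s7", "s8"),
    name = paste("t", 11:13), level = c(4L, 5L, 6L),
    parent_id = c(10L, 11L, 12L), color = rep("#AABBCC", 3))
  ontology_tree(rbind(df, extra))
}

# seeded random tree: random child counts per node, depth <= max_depth
random_tree <- function(seed, max_depth = 8L, max_kids = 3L) {
  with_seed(seed, {
    rows <- data.frame(id = 1L, acronym = "r", name = "root", level = 0L,
                       parent_id = NA_integer_, color = "#000000")
    frontier <- 1L
    next_id <- 2L
    for (lev in seq_len(max_depth)) {
      new_frontier <- integer(0)
      for (p in frontier) {
        nk <- sample.int(max_kids + 1L, 1L) - 1L # 0..max_kids children
        if (lev == 1L) nk <- max(nk, 1L)         # keep the tree non-trivial
        if (nk == 0L) next
        ids <- next_id + seq_len(nk) - 1L
        next_id <- next_id + nk
        rows <- rbind(rows, data.frame(
          id = ids, acronym = paste0("n", ids), name = paste0("n", ids),
          level = lev, parent_id = p, color = "#000000"))
        new_frontier <- c(new_frontier, ids)
      }
      frontier <- new_frontier
      if (length(frontier) == 0L) break
    }
    ontology_tree(rows)
  })
}

# small, fast synthetic atlas for pipeline-level tests
small_spec <- function(seed = 1L, ...) {
  synthetic_spec(dims = c(14L, 10L, 6L), n_genes = 40L,
                 branching = c(3L, 2L, 1L, 1L, 4L), seed = seed, ...)
}

# Gaussian blob mixture with known labels
make_blobs <- function(n_per, centers, sd_within, d, seed) {
  with_seed(seed, {
    k <- nrow(centers)
    X <- do.call(rbind, lapply(seq_len(k), function(i) {
      matrix(stats::rnorm(n_per * d, sd = sd_within), n_per, d) +
        matrix(centers[i, ], n_per, d, byrow = TRUE)
    }))
    list(X = X, labels = rep(seq_len(k), each = n_per))
  })
}
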