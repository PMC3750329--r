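test_that("generated ontology has the branching-product term counts", {
  tr <- generate_ontology(synthetic_spec(branching = c(3L, 2L, 2L, 1L, 2L)))
  counts <- table(tr$terms$level)
  expect_equal(unname(counts[as.character(0:5)]),
               c(1L, 3L, 6L, 12L, 12L, 24L), ignore_attr = TRUE)
  tr1 <- generate_ontology(synthetic_spec(branching = 3L))
  expect_equal(nrow(tr1$terms), 4L)
})

test_that("spec validation rejects bad parameters", {
  expect_error(synthetic_spec(branching = c(3L, 0L)), "branching")
  expect_error(synthetic_spec(marker_fraction = 1.2), "marker_fraction")
  expect_error(synthetic_spec(noise_sd = -1), "noise_sd")
})

test_that("identical specs give bit-identical atlases", {
  a1 <- generate_atlas(small_spec(seed = 21))
  a2 <- generate_atlas(small_spec(seed = 21))
  expect_identical(a1$tree$terms, a2$tree$terms)
  expect_identical(a1$annotation$labels, a2$annotation$labels)
  expect_identical(a1$expression$volumes, a2$expression$volumes)
  a3 <- generate_atlas(small_spec(seed = 22))
  expect_false(identical(a1$expression$volumes, a3$expression$volumes))
})

test_that("annotation partitions level-1 blocks contiguously along x", {
  spec <- synthetic_spec(dims = c(8L, 6L, 4L), n_genes = 4L,
                         branching = c(3L, 2L, 1L, 1L, 4L), margin = 1L)
  tr <- generate_ontology(spec)
  ann <- generate_annotation(spec, tr)
  lab <- ann$labels
  # interior x-planes map to a single level-1 ancestor each
  l1_of_plane <- sapply(2:7, function(x) {
    ids <- unique(as.vector(lab[x, , ]))
    ids <- ids[ids != 0L]
    u <- unique(ancestors_at_level(tr, ids, 1L))
    expect_length(u, 1L)
    u
  })
  # blocks are contiguous: ancestor changes only at block boundaries
  expect_equal(length(rle(l1_of_plane)$values), 3L)
  # margins are background
  expect_true(all(lab[1, , ] == 0L) && all(lab[8, , ] == 0L))
  expect_true(all(lab[, 1, ] == 0L) && all(lab[, 6, ] == 0L))
})

test_that("label histogram matches a brute-force recount", {
  atlas <- generate_atlas(small_spec(seed = 13))
  lab <- atlas$annotation$labels
  hist1 <- table(lab[lab != 0L])
  counts <- integer(0)
  for (x in seq_len(dim(lab)[1])) for (y in seq_len(dim(lab)[2])) {
    for (z in seq_len(dim(lab)[3])) {
      id <- lab[x, y, z]
      if (id != 0L) {
        key <- as.character(id)
        counts[key] <- if (is.na(counts[key])) 1L else counts[key] + 1L
      }
    }
  }
  expect_equal(as.integer(hist1[names(counts)]), unname(counts))
})

test_that("annotation errors when an axis cannot hold the segments", {
  spec <- synthetic_spec(dims = c(6L, 4L, 3L), branching = c(5L, 2L, 1L, 1L, 2L))
  tr <- generate_ontology(spec)
  expect_error(generate_annotation(spec, tr), "segments")
})

test_that("zero noise collapses each leaf structure to one expression vector", {
  spec <- small_spec(seed = 31, noise_sd = 0)
  atlas <- generate_atlas(spec)
  ds <- build_dataset(atlas$annotation, atlas$expression, atlas$tree)
  for (id in unique(ds$label_native)[1:5]) {
    rows <- ds$X[ds$label_native == id, , drop = FALSE]
    expect_lt(max(apply(rows, 2, function(v) diff(range(v)))), 1e-12)
  }
})

test_that("marker genes are high inside their target structure only", {
  spec <- small_spec(seed = 41, marker_fraction = 0.25, noise_sd = 0.2)
  atlas <- generate_atlas(spec)
  ds <- build_dataset(atlas$annotation, atlas$expression, atlas$tree)
  targets <- attr(atlas$expression, "marker_target")
  marker_genes <- which(targets != 0L)
  expect_gt(length(marker_genes), 0L)
  for (g in marker_genes) {
    inside <- ds$label_native %in% subtree_ids(atlas$tree, targets[g])
    if (any(inside) && any(!inside)) {
      expect_gt(mean(ds$X[inside, g]), mean(ds$X[!inside, g]))
    }
  }
})

test_that("structure means respect the hierarchy: within-block < between-block", {
  spec <- small_spec(seed = 51, signal_sd = 5, noise_sd = 0.01)
  atlas <- generate_atlas(spec)
  ds <- build_dataset(atlas$annotation, atlas$expression, atlas$tree)
  leaves <- sort(unique(ds$label_native))
  M <- t(sapply(leaves, function(id) colMeans(ds$X[ds$label_native == id, , drop = FALSE])))
  l1 <- ancestors_at_level(atlas$tree, leaves, 1L)
  within <- between <- c()
  for (i in seq_along(leaves)) for (j in seq_along(leaves)) {
    if (i < j) {
      d <- sqrt(sum((M[i, ] - M[j, ])^2))
      if (l1[i] == l1[j]) within <- c(within, d) else between <- c(between, d)
    }
  }
  expect_lt(mean(within), mean(between))
})

test_that("ground-truth labels equal up-propagated leaf annotations", {
  atlas <- generate_atlas(small_spec(seed = 61))
  leaf <- atlas$truth$level_5
  for (lev in c(0L, 1L, 3L)) {
    expect_identical(atlas$truth[[paste0("level_", lev)]],
                     ancestors_at_level(atlas$tree, atlas$truth$level_5, lev))
  }
})

test_that("k-means on raw data recovers level-1 blocks when signal dominates", {
  # single-child intermediate levels keep within-block substructure small,
  # so a 10:1 signal-to-noise ratio realizes the well-separated regime
  spec <- synthetic_spec(dims = c(14L, 10L, 6L), n_genes = 40L,
                         branching = c(3L, 1L, 1L, 1L, 4L),
                         signal_sd = 5, noise_sd = 0.5, seed = 71L)
  atlas <- generate_atlas(spec)
  ds <- build_dataset(atlas$annotation, atlas$expression, atlas$tree)
  cl <- kmeans_restarts(ds$X, k = 3L, restarts = 10L, seed = 8L)
  expect_gte(ari(contingency(ds$label_l1, cl$labels)), 0.99)
})

test_that("a synthetic atlas round-trips through its on-disk form", {
  spec <- synthetic_spec(dims = c(8L, 6L, 4L), n_genes = 3L,
                         branching = c(2L, 1L, 1L, 1L, 2L), seed = 3L)
  atlas <- generate_atlas(spec)
  dir <- withr::local_tempdir()
  write_synthetic_atlas(atlas, dir)
  tr <- read_ontology_json(file.path(dir, "ontology.json"))
  expect_identical(tr$terms$id, atlas$tree$terms$id)
  ann <- read_nrrd(file.path(dir, "annotation.nrrd"))
  expect_identical(ann, atlas$annotation$labels)
  v1 <- read_nrrd(file.path(dir, "expr_g0001.nrrd"))
  expect_equal(v1, atlas$expression$volumes[[1]], tolerance = 1e-15)
})
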