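# Seeded synthetic atlases: a level-wise subdivided ontology, a grid-like
# annotation volume (transversal segments x longitudinal zones, echoing the
# prosomeric organization of the neural tube), and expression volumes whose
# structure-specific signal lies near a low-dimensional latent manifold with
# regionally restricted marker genes on top.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generator calls never
#' perturb user-level random streams.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a stable sub-seed from a master seed and a stage tag
#'
#' Counter-free scheme: the tag is hashed, so adding a stage never shifts
#' another stage's stream. Result stays inside 32-bit integer range.
#' @keywords internal
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 1009)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

#' Specification of a synthetic atlas
#'
#' The defaults emulate a scaled-down embryonic (E11.5-like) grid: a
#' 24 x 20 x 12 voxel volume with a one-voxel background margin
#' (~4000 labeled voxels), 200 genes, and an ontology whose level-wise
#' branching `c(3, 2, 1, 1, 4)` yields 3 level-1 vesicles, 6 level-3
#' transversal segments along the x (anterior-posterior) axis and 4 level-5
#' longitudinal zones per segment stacked along the y axis — the
#' roof/alar/basal/floor arrangement.
#'
#' @param dims grid dims (x, y, z).
#' @param n_genes number of genes d.
#' @param branching integer vector of child counts per level; its length is
#'   the ontology depth. Levels 1-3 subdivide along x, levels 4-5 along y,
#'   deeper levels cycle z, x, y.
#' @param signal_sd scale of the hierarchical latent walk; the step at level
#'   l has sd `signal_sd * 2^(-l)`, so coarse divisions carry the largest
#'   expression contrasts.
#' @param noise_sd per-voxel additive Gaussian observation noise.
#' @param marker_fraction fraction of genes that are regionally restricted
#'   markers rather than graded latent responses.
#' @param marker_mean expression energy of a marker gene inside its target
#'   structure (~0 outside).
#' @param latent_dim dimension of the latent positions the non-marker genes
#'   respond to.
#' @param margin width (voxels) of the background frame around the brain.
#' @param seed master seed; identical specs produce bit-identical atlases.
#' @return A `synthetic_spec` list; `n_transversal` and `n_longitudinal`
#'   (level-3 segments, level-5 zones per segment) are derived from
#'   `branching`.
#' @export
synthetic_spec <- function(dims = c(24L, 20L, 12L), n_genes = 200L,
                           branching = c(3L, 2L, 1L, 1L, 4L),
                           signal_sd = 4, noise_sd = 2,
                           marker_fraction = 0.1, marker_mean = 5,
                           latent_dim = 8L, margin = 1L, seed = 1L) {
  dims <- as.integer(dims)
  branching <- as.integer(branching)
  if (length(dims) != 3L || any(dims < 1L)) stop("dims must be 3 positive integers")
  if (length(branching) < 1L || any(branching < 1L)) {
    stop("branching entries must all be >= 1")
  }
  if (marker_fraction < 0 || marker_fraction > 1) {
    stop("marker_fraction must lie in [0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  depth <- length(branching)
  structure(list(
    dims = dims, n_genes = as.integer(n_genes), branching = branching,
    n_transversal = prod(branching[seq_len(min(3L, depth))]),
    n_longitudinal = if (depth >= 4L) prod(branching[4:min(5L, depth)]) else 1L,
    signal_sd = signal_sd, noise_sd = noise_sd,
    marker_fraction = marker_fraction, marker_mean = marker_mean,
    latent_dim = as.integer(latent_dim), margin = as.integer(margin),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# axis each level subdivides: 1-3 along x, 4-5 along y, deeper cycle z,x,y
axis_for_level <- function(level) {
  if (level <= 3L) 1L else if (level <= 5L) 2L else c(3L, 1L, 2L)[(level - 6L) %% 3L + 1L]
}

#' Generate the synthetic ontology
#'
#' Builds a rooted tree in which every term at level l has
#' `spec$branching[l + 1]` children, ids assigned breadth-first from 1.
#' Sibling colors share a hue family: level-1 terms get evenly spaced hues
#' and descendants inherit the parent hue with a small seeded jitter, so
#' developmentally related structures look similar — the convention of
#' colorized reference atlases.
#'
#' @param spec a [synthetic_spec()].
#' @return An [ontology_tree()].
#' @export
generate_ontology <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(derive_seed(spec$seed, "ontology"), {
    rows <- list(data.frame(
      id = 1L, acronym = "NP", name = "neural plate", level = 0L,
      parent_id = NA_integer_, color = "#B0B0B0", hue = 0,
      stringsAsFactors = FALSE))
    parents <- rows[[1L]]
    next_id <- 2L
    for (lev in seq_along(spec$branching)) {
      kids_n <- spec$branching[lev]
      out <- vector("list", nrow(parents))
      for (p in seq_len(nrow(parents))) {
        if (lev == 1L) {
          hues <- (seq_len(kids_n) - 1) / kids_n
        } else {
          hues <- (parents$hue[p] + stats::runif(kids_n, -0.04, 0.04)) %% 1
        }
        ids <- next_id + seq_len(kids_n) - 1L
        next_id <- next_id + kids_n
        acr <- paste0(parents$acronym[p], ".", seq_len(kids_n))
        out[[p]] <- data.frame(
          id = ids, acronym = acr,
          name = paste("structure", acr), level = lev,
          parent_id = parents$id[p],
          color = toupper(grDevices::hsv(hues, 0.55 + 0.07 * (lev %% 3),
                                         0.95 - 0.05 * (lev %% 2))),
          hue = hues, stringsAsFactors = FALSE)
      }
      parents <- do.call(rbind, out)
      rows[[lev + 1L]] <- parents
    }
    terms <- do.call(rbind, rows)
    terms$hue <- NULL
    ontology_tree(terms)
  })
}

#' Generate the synthetic annotation volume
#'
#' Partitions the interior of the grid (inside the background margin) by
#' recursive contiguous splitting: each term's box is divided among its
#' children along the level's axis into near-equal runs. The result is the
#' grid-like arrangement of level-1 blocks along x, level-3 transversal
#' slabs within them, and level-5 longitudinal bands along y; every interior
#' voxel carries a maximal-depth term, margins stay background 0.
#'
#' @param spec a [synthetic_spec()].
#' @param tree tree from [generate_ontology()] with compatible branching.
#' @return An [annotation_volume()].
#' @export
generate_annotation <- function(spec, tree) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(tree, "ontology_tree"))
  d <- spec$dims
  m <- spec$margin
  lo <- c(m + 1L, m + 1L, m + 1L)
  hi <- d - m
  if (any(hi < lo)) stop("margin leaves no interior voxels")
  labels <- array(0L, dim = d)
  terms <- tree$terms

  split_range <- function(lo, hi, k) {
    len <- hi - lo + 1L
    if (len < k) {
      stop(sprintf("cannot place %d segments on an axis run of %d voxels", k, len))
    }
    cuts <- lo - 1L + floor(len * (0:k) / k)
    lapply(seq_len(k), function(i) c(cuts[i] + 1L, cuts[i + 1L]))
  }

  assign_box <- function(term_id, box) {
    kids <- terms$id[!is.na(terms$parent_id) & terms$parent_id == term_id]
    if (length(kids) == 0L) {
      labels[box[1, 1]:box[2, 1], box[1, 2]:box[2, 2], box[1, 3]:box[2, 3]] <<-
        term_id
      return(invisible(NULL))
    }
    kids <- sort(kids)
    ax <- axis_for_level(terms$level[match(kids[1L], terms$id)])
    runs <- split_range(box[1, ax], box[2, ax], length(kids))
    for (i in seq_along(kids)) {
      sub <- box
      sub[, ax] <- runs[[i]]
      assign_box(kids[i], sub)
    }
  }
  assign_box(tree$root_id, rbind(lo, hi))
  annotation_volume(labels, resolution_um = 100)
}

#' Generate synthetic expression volumes
#'
#' Expression model. Every ontology term s receives a latent position
#' z_s in R^latent_dim by a hierarchical Gaussian walk down the tree
#' (child = parent + N(0, signal_sd^2 * 4^(-level) I)), so structures
#' sharing ancestors sit close in latent space and the leaf means lie near a
#' latent_dim-dimensional manifold. A non-marker gene g responds through a
#' random linear map passed through a softplus, mu_g(s) =
#' log(1 + exp(w_g' z_s + b_g)), which keeps energies nonnegative without
#' truncating the signal. A fraction `marker_fraction` of genes are instead
#' regionally restricted markers: energy `marker_mean` inside one randomly
#' chosen structure's subtree and 0 elsewhere. The observed voxel value is
#' its structure mean plus N(0, noise_sd^2) noise, clipped at zero;
#' background voxels are exactly 0.
#'
#' @param spec a [synthetic_spec()].
#' @param tree tree from [generate_ontology()].
#' @param ann annotation from [generate_annotation()].
#' @return An [expression_volume_set()].
#' @export
generate_expression <- function(spec, tree, ann) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(tree, "ontology_tree"),
            inherits(ann, "annotation_volume"))
  with_seed(derive_seed(spec$seed, "expression"), {
    terms <- tree$terms
    n_terms <- nrow(terms)
    # latent walk in BFS (level, id) order for reproducibility
    ord <- order(terms$level, terms$id)
    Z <- matrix(0, nrow = n_terms, ncol = spec$latent_dim,
                dimnames = list(terms$id, NULL))
    for (i in ord) {
      if (is.na(terms$parent_id[i])) next
      p <- as.character(terms$parent_id[i])
      Z[as.character(terms$id[i]), ] <- Z[p, ] +
        stats::rnorm(spec$latent_dim, sd = spec$signal_sd * 2^(-terms$level[i]))
    }

    d <- spec$n_genes
    n_marker <- round(spec$marker_fraction * d)
    marker_idx <- if (n_marker > 0) sort(sample.int(d, n_marker)) else integer(0)

    leaf_ids <- terms$id[!terms$id %in% terms$parent_id[!is.na(terms$parent_id)]]
    leaf_ids <- sort(leaf_ids)
    n_leaf <- length(leaf_ids)
    M <- matrix(0, nrow = n_leaf, ncol = d, dimnames = list(leaf_ids, NULL))

    candidate_targets <- terms$id[terms$level >= 1L]
    marker_target <- integer(d)
    for (g in seq_len(d)) {
      if (g %in% marker_idx) {
        tgt <- candidate_targets[sample.int(length(candidate_targets), 1L)]
        marker_target[g] <- tgt
        inside <- leaf_ids %in% subtree_ids(tree, tgt)
        M[inside, g] <- spec$marker_mean
      } else {
        w <- stats::rnorm(spec$latent_dim) / sqrt(spec$latent_dim)
        b <- stats::rnorm(1)
        eta <- Z[as.character(leaf_ids), , drop = FALSE] %*% w + b
        M[, g] <- log1p(exp(pmin(eta, 30))) # stable softplus
      }
    }

    coords <- voxel_order(spec$dims)
    lab <- ann$labels[coords + 1L]
    keep <- lab != 0L
    leaf_row <- match(lab[keep], leaf_ids)
    if (anyNA(leaf_row)) stop("annotation contains non-leaf labels")
    n_vox <- sum(keep)
    noise <- matrix(stats::rnorm(n_vox * d, sd = spec$noise_sd), n_vox, d)
    vox_vals <- pmax(M[leaf_row, , drop = FALSE] + noise, 0)

    sel <- coords[keep, , drop = FALSE] + 1L
    vols <- vector("list", d)
    for (g in seq_len(d)) {
      v <- array(0, dim = spec$dims)
      v[sel] <- vox_vals[, g]
      vols[[g]] <- v
    }
    ev <- expression_volume_set(sprintf("g%04d", seq_len(d)), vols)
    attr(ev, "marker_target") <- marker_target
    ev
  })
}

#' Generate a complete synthetic atlas with ground truth
#'
#' Runs [generate_ontology()], [generate_annotation()] and
#' [generate_expression()] and records, for every labeled voxel in canonical
#' flattening order, its ground-truth term id at every ontology level.
#'
#' @param spec a [synthetic_spec()].
#' @return A `synthetic_atlas` list: `spec`, `tree`, `annotation`,
#'   `expression`, and `truth` (data frame `x,y,z,level_0..level_L`).
#' @export
generate_atlas <- function(spec) {
  tree <- generate_ontology(spec)
  ann <- generate_annotation(spec, tree)
  expr <- generate_expression(spec, tree, ann)
  coords <- voxel_order(spec$dims)
  lab <- ann$labels[coords + 1L]
  keep <- lab != 0L
  lab <- lab[keep]
  coords <- coords[keep, , drop = FALSE]
  depth <- max(tree$terms$level)
  truth <- data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3])
  for (lev in 0:depth) {
    truth[[paste0("level_", lev)]] <- ancestors_at_level(tree, lab, lev)
  }
  structure(list(spec = spec, tree = tree, annotation = ann,
                 expression = expr, truth = truth),
            class = "synthetic_atlas")
}

#' Write a synthetic atlas to a directory
#'
#' Writes `ontology.json`, `annotation.nrrd`, one `expr_<gene>.nrrd` per
#' gene, and `truth.tsv` — the on-disk shape the pipeline readers consume.
#'
#' @param atlas a `synthetic_atlas`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ontology_json(atlas$tree, file.path(dir, "ontology.json"))
  write_nrrd(atlas$annotation$labels, file.path(dir, "annotation.nrrd"),
             type = "int")
  for (g in seq_along(atlas$expression$gene_ids)) {
    write_nrrd(atlas$expression$volumes[[g]],
               file.path(dir, paste0("expr_", atlas$expression$gene_ids[g], ".nrrd")))
  }
  utils::write.table(atlas$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
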