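#' Annotation volume
#'
#' A dense 3-D integer array assigning each voxel of the reference grid an
#' ontology term id; 0 marks background / unannotated voxels. Axis semantics
#' follow the reference-grid convention: x = anterior-to-posterior,
#' y = superior-to-inferior, z = left-to-right.
#'
#' @param labels 3-D integer array of term ids (0 = background).
#' @param resolution_um voxel edge length in micrometres.
#' @return An object of class `annotation_volume` with fields `dims`,
#'   `resolution_um` and `labels`.
#' @export
annotation_volume <- function(labels, resolution_um = 100) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3-D array")
  if (any(dim(labels) < 1L)) stop("all dims must be positive")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L)) {
    stop("labels must be nonnegative integers (0 = background)")
  }
  structure(list(dims = dim(labels), resolution_um = resolution_um,
                 labels = labels),
            class = "annotation_volume")
}

#' Expression volume set
#'
#' One dense 3-D nonnegative array of expression energy per gene, all on the
#' same grid as the annotation volume. Expression energy is the per-voxel
#' scalar summarizing in situ hybridization signal on the reference grid.
#'
#' @param gene_ids character vector of gene identifiers, length d.
#' @param volumes list of d 3-D numeric arrays, identical dims.
#' @return An object of class `expression_volume_set`.
#' @export
expression_volume_set <- function(gene_ids, volumes) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != length(volumes)) {
    stop("gene_ids and volumes must have the same length")
  }
  if (length(volumes) == 0L) stop("at least one gene volume is required")
  d0 <- dim(volumes[[1L]])
  for (v in volumes) {
    if (length(dim(v)) != 3L || !identical(dim(v), d0)) {
      stop("all expression volumes must be 3-D arrays with identical dims")
    }
    if (!all(is.finite(v)) || any(v < 0)) {
      stop("expression energies must be finite and >= 0")
    }
  }
  structure(list(gene_ids = gene_ids, dims = d0, volumes = volumes),
            class = "expression_volume_set")
}

#' Enumerate voxel coordinates in canonical flattening order
#'
#' Row-major over (x, y, z) with z fastest: x is the slowest index, z the
#' fastest. All voxel indices are 0-based so coordinates round-trip through
#' exported tables unambiguously.
#'
#' @param dims integer vector (x, y, z).
#' @return n x 3 integer matrix of 0-based (x, y, z) indices.
#' @keywords internal
voxel_order <- function(dims) {
  g <- expand.grid(z = seq_len(dims[3]) - 1L,
                   y = seq_len(dims[2]) - 1L,
                   x = seq_len(dims[1]) - 1L)
  as.matrix(g[, c("x", "y", "z")])
}

#' Assemble the analysis-ready voxel-by-gene dataset
#'
#' Applies the three annotation filters and builds the n x d expression
#' matrix together with multi-level anatomical labels:
#' \enumerate{
#'   \item background voxels (label 0) are dropped;
#'   \item voxels whose annotation lies inside any excluded subtree are
#'     dropped (e.g. the spinal cord when only the brain is under study);
#'   \item voxels annotated at a level shallower than `min_level` are
#'     dropped (their annotation is too coarse to place them in the
#'     transversal-by-longitudinal grid of interest).
#' }
#' Surviving annotations are up-propagated to levels 1, 3 and 5, giving each
#' voxel one label per granularity on a single root path.
#'
#' @param ann an [annotation_volume()].
#' @param expr an [expression_volume_set()] on the same grid.
#' @param tree the [ontology_tree()] the labels refer to.
#' @param exclude_subtrees integer vector of term ids whose whole subtrees
#'   are removed.
#' @param min_level minimum annotation level retained (default 5).
#' @return An object of class `voxel_dataset`: list with `X` (n x d matrix,
#'   gene ids as colnames), `coords` (n x 3, 0-based), `label_native`,
#'   `label_l1`, `label_l3`, `label_l5`, and `gene_ids`.
#' @export
build_dataset <- function(ann, expr, tree, exclude_subtrees = integer(0),
                          min_level = 5L) {
  stopifnot(inherits(ann, "annotation_volume"),
            inherits(expr, "expression_volume_set"),
            inherits(tree, "ontology_tree"))
  if (!identical(as.integer(ann$dims), as.integer(expr$dims))) {
    stop("annotation and expression grids have different dims")
  }
  coords <- voxel_order(ann$dims)
  flat_idx <- coords + 1L # 1-based array indexing
  lab <- ann$labels[flat_idx]

  nonzero <- lab != 0L
  present <- unique(lab[nonzero])
  unknown <- present[!as.character(present) %in% names(tree$.index)]
  if (length(unknown) > 0L) {
    stop("annotation ids absent from ontology: ",
         paste(unknown, collapse = ", "))
  }
  excluded_ids <- integer(0)
  for (id in exclude_subtrees) excluded_ids <- c(excluded_ids, subtree_ids(tree, id))

  keep <- nonzero
  keep[keep] <- !(lab[keep] %in% excluded_ids) &
    term_level(tree, lab[keep]) >= min_level

  lab_keep <- lab[keep]
  coords_keep <- coords[keep, , drop = FALSE]
  n <- length(lab_keep)
  d <- length(expr$gene_ids)
  X <- matrix(0, nrow = n, ncol = d, dimnames = list(NULL, expr$gene_ids))
  sel <- flat_idx[keep, , drop = FALSE]
  for (g in seq_len(d)) X[, g] <- expr$volumes[[g]][sel]
  if (!all(is.finite(X)) || any(X < 0)) {
    stop("expression matrix must be finite and >= 0")
  }

  structure(list(
    X = X,
    coords = coords_keep,
    label_native = lab_keep,
    label_l1 = ancestors_at_level(tree, lab_keep, 1L),
    label_l3 = ancestors_at_level(tree, lab_keep, 3L),
    label_l5 = ancestors_at_level(tree, lab_keep, 5L),
    gene_ids = expr$gene_ids
  ), class = "voxel_dataset")
}

#' @export
print.voxel_dataset <- function(x, ...) {
  cat(sprintf(
    "voxel_dataset: %d voxels x %d genes; %d / %d / %d structures at levels 1 / 3 / 5\n",
    nrow(x$X), ncol(x$X), length(unique(x$label_l1)),
    length(unique(x$label_l3)), length(unique(x$label_l5))))
  invisible(x)
}

#' Export a voxel dataset to TSV
#'
#' Columns: `x,y,z,label_native,label_l1,label_l3,label_l5,` then one column
#' per gene. Coordinates are 0-based grid indices.
#'
#' @param ds a `voxel_dataset`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_tsv <- function(ds, path) {
  df <- data.frame(x = ds$coords[, 1], y = ds$coords[, 2], z = ds$coords[, 3],
                   label_native = ds$label_native, label_l1 = ds$label_l1,
                   label_l3 = ds$label_l3, label_l5 = ds$label_l5,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(ds$X, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a voxel dataset written by [write_dataset_tsv()]
#'
#' @param path TSV path.
#' @return A `voxel_dataset`.
#' @export
read_dataset_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- c("x", "y", "z", "label_native", "label_l1", "label_l3", "label_l5")
  if (!all(meta %in% names(df))) {
    stop("dataset TSV lacks required columns: ",
         paste(setdiff(meta, names(df)), collapse = ", "))
  }
  gene_cols <- setdiff(names(df), meta)
  structure(list(
    X = as.matrix(df[gene_cols]),
    coords = as.matrix(df[c("x", "y", "z")]),
    label_native = as.integer(df$label_native),
    label_l1 = as.integer(df$label_l1),
    label_l3 = as.integer(df$label_l3),
    label_l5 = as.integer(df$label_l5),
    gene_ids = gene_cols
  ), class = "voxel_dataset")
}

#' Labels of a voxel dataset at one ontology level
#'
#' @param ds a `voxel_dataset`.
#' @param level 1, 3 or 5.
#' @return integer vector of term ids.
#' @export
dataset_labels <- function(ds, level) {
  switch(as.character(level),
         "1" = ds$label_l1, "3" = ds$label_l3, "5" = ds$label_l5,
         stop("level must be 1, 3 or 5"))
}
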