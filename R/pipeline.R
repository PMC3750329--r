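# End-to-end experiment runner: methods x dims x ontology levels, with
# per-combination sub-seeds derived from one master seed so results are
# reproducible and adding a method never shifts another method's stream.

#' Configure a concordance experiment
#'
#' @param spec a [synthetic_spec()] used to generate the input atlas, or
#'   `NULL` when `dataset` is given directly.
#' @param dataset an existing [build_dataset()] result (overrides `spec`).
#' @param methods subset of `c("raw", "pca", "tsne")`; `"raw"` clusters the
#'   untransformed expression matrix.
#' @param dims output dimensions for the reduction methods, subset of
#'   `c(2, 10)` by convention (ignored for `"raw"`).
#' @param levels ontology levels to score against, subset of `c(1, 3, 5)`.
#' @param tsne a [tsne_config()]; its seed is overridden per combination.
#' @param kmeans_restarts restarts per clustering (default 10).
#' @param seed master seed.
#' @param dataset_name tag written into the report rows.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(spec = synthetic_spec(), dataset = NULL,
                              methods = c("raw", "pca", "tsne"),
                              dims = c(2L, 10L), levels = c(1L, 3L, 5L),
                              tsne = tsne_config(), kmeans_restarts = 10L,
                              seed = 1L, dataset_name = "synthetic") {
  methods <- match.arg(methods, c("raw", "pca", "tsne"), several.ok = TRUE)
  levels <- as.integer(levels)
  if (length(methods) == 0L || length(levels) == 0L) {
    stop("methods and levels must be non-empty")
  }
  if (!all(levels %in% c(1L, 3L, 5L))) stop("levels must be among 1, 3, 5")
  if (any(methods != "raw") && length(dims) == 0L) {
    stop("dims required for reduction methods")
  }
  structure(list(spec = spec, dataset = dataset, methods = methods,
                 dims = as.integer(dims), levels = levels, tsne = tsne,
                 kmeans_restarts = as.integer(kmeans_restarts),
                 seed = as.integer(seed), dataset_name = dataset_name),
            class = "experiment_config")
}

# canonical combination order; fixed so sub-seed streams are stable
method_dim_grid <- function(cfg) {
  full <- rbind(data.frame(method = "raw", dim = NA_integer_),
                expand.grid(method = c("pca", "tsne"),
                            dim = c(2L, 10L), stringsAsFactors = FALSE))
  keep <- full$method %in% cfg$methods &
    (is.na(full$dim) | full$dim %in% cfg$dims)
  full[keep, , drop = FALSE]
}

#' Run the full methods-by-levels concordance experiment
#'
#' For every configured (method, dim) the representation is computed once —
#' raw expression, centered PCA, or exact t-SNE — and reused across levels.
#' At each ontology level, k is tied to the number of structures present,
#' k-means with restarts partitions the representation, and the partition
#' is scored against the anatomical labels with NMI, S-index, ARI and
#' purity. A combination that fails (e.g. infeasible perplexity) yields an
#' error row and the run continues; the call errors only if every
#' combination fails.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir optional directory; when given, `report.tsv` (scores to 4
#'   decimals), per-combination embedding TSVs and a log file are written.
#' @return A `concordance_report` data frame with one row per
#'   (method, dim, level): columns `dataset, level, method, dim, nmi,
#'   s_index, ari, purity, k, n, seed, error`.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  if (!is.null(cfg$dataset)) {
    ds <- cfg$dataset
  } else {
    say("generating synthetic atlas (seed %d)", cfg$spec$seed)
    atlas <- generate_atlas(cfg$spec)
    ds <- build_dataset(atlas$annotation, atlas$expression, atlas$tree)
  }
  say("dataset: %d voxels x %d genes", nrow(ds$X), ncol(ds$X))

  grid <- method_dim_grid(cfg)
  rows <- list()
  n_ok <- 0L
  for (i in seq_len(nrow(grid))) {
    method <- grid$method[i]
    dim_i <- grid$dim[i]
    tag <- if (is.na(dim_i)) method else paste0(method, dim_i)
    t0 <- Sys.time()
    rep_mat <- tryCatch({
      switch(method,
             raw = ds$X,
             pca = run_pca(ds$X, dim_i)$Y,
             tsne = {
               tc <- cfg$tsne
               tc$seed <- derive_seed(cfg$seed, paste0("embed-", tag))
               run_tsne(ds$X, dim_i, tc)$Y
             })
    }, error = function(e) e)
    if (inherits(rep_mat, "error")) {
      say("representation %s FAILED: %s", tag, conditionMessage(rep_mat))
      for (lev in cfg$levels) {
        rows[[length(rows) + 1L]] <- report_row(cfg, lev, method, dim_i,
                                                err = conditionMessage(rep_mat),
                                                n = nrow(ds$X))
      }
      next
    }
    say("representation %s ready (%.1f s)", tag,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    if (!is.null(out_dir) && method != "raw") {
      emb <- structure(list(Y = rep_mat, m = ncol(rep_mat), method = method,
                            final_cost = NULL), class = "embedding")
      write_embedding_tsv(emb, file.path(out_dir, paste0("embedding_", tag, ".tsv")))
    }
    for (lev in cfg$levels) {
      row <- tryCatch({
        labels <- dataset_labels(ds, lev)
        k <- choose_k(labels)
        cl <- kmeans_restarts(rep_mat, k, restarts = cfg$kmeans_restarts,
                              seed = derive_seed(cfg$seed,
                                                 paste0("kmeans-", tag, "-L", lev)))
        sc <- score_all(labels, cl$labels)
        say("  level %d: k = %d, NMI %.4f, S %.4f, ARI %.4f, purity %.4f",
            lev, k, sc$nmi, sc$s_index, sc$ari, sc$purity)
        report_row(cfg, lev, method, dim_i, sc = sc, k = k, n = nrow(ds$X))
      }, error = function(e) {
        say("  level %d FAILED: %s", lev, conditionMessage(e))
        report_row(cfg, lev, method, dim_i, err = conditionMessage(e),
                   n = nrow(ds$X))
      })
      if (is.na(row$error)) n_ok <- n_ok + 1L
      rows[[length(rows) + 1L]] <- row
    }
  }
  report <- do.call(rbind, rows)
  if (n_ok == 0L) stop("every configured combination failed")
  class(report) <- c("concordance_report", class(report))
  if (!is.null(out_dir)) {
    write_report_tsv(report, file.path(out_dir, "report.tsv"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  report
}

report_row <- function(cfg, level, method, dim, sc = NULL, k = NA_integer_,
                       n = NA_integer_, err = NA_character_) {
  data.frame(dataset = cfg$dataset_name, level = level, method = method,
             dim = dim,
             nmi = if (is.null(sc)) NA_real_ else sc$nmi,
             s_index = if (is.null(sc)) NA_real_ else sc$s_index,
             ari = if (is.null(sc)) NA_real_ else sc$ari,
             purity = if (is.null(sc)) NA_real_ else sc$purity,
             k = k, n = n, seed = cfg$seed, error = err,
             stringsAsFactors = FALSE)
}

#' Write a concordance report with 4-decimal scores
#'
#' @param report a `concordance_report`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  out <- report
  for (col in c("nmi", "s_index", "ari", "purity")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.4f", out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an embedding scatter colored by ontology annotation
#'
#' Writes a TSV (`x, y, acronym, color_hex`) and, when a cairo-capable
#' device is available, an SVG in which each voxel is drawn as its
#' structure acronym in its ontology color — the atlas-style display where
#' related structures share hues. The TSV is the canonical artifact; the
#' SVG is a thin rendering of it.
#'
#' @param emb a 2-D `embedding`.
#' @param labels per-voxel term ids to display.
#' @param tree the [ontology_tree()] providing acronyms and colors.
#' @param out_prefix path prefix; writes `<prefix>.tsv` and `<prefix>.svg`.
#' @return Invisibly, the TSV path.
#' @export
export_scatter <- function(emb, labels, tree, out_prefix) {
  if (emb$m != 2L) stop("scatter export needs a 2-D embedding")
  if (length(labels) != nrow(emb$Y)) stop("one label per map point required")
  idx <- tree$.index[as.character(labels)]
  if (anyNA(idx)) stop("labels contain ids absent from the ontology")
  df <- data.frame(x = emb$Y[, 1], y = emb$Y[, 2],
                   acronym = tree$terms$acronym[idx],
                   color_hex = tree$terms$color[idx])
  tsv <- paste0(out_prefix, ".tsv")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  render_text_scatter(df, paste0(out_prefix, ".svg"))
  invisible(tsv)
}

#' Export an embedding scatter by longitudinal zone
#'
#' Displays each voxel by the longitudinal zone (e.g. F=floor, B=basal,
#' A=alar, R=roof) of its level-5 structure rather than the structure
#' itself, supporting the comparison of longitudinal-zone versus
#' transversal-segment organization in the map.
#'
#' @param emb a 2-D `embedding`.
#' @param labels_l5 per-voxel level-5 term ids.
#' @param tree the [ontology_tree()].
#' @param zone_map named character vector mapping level-5 term id -> zone
#'   tag.
#' @param out_prefix path prefix; writes `<prefix>.tsv` and `<prefix>.svg`.
#' @return Invisibly, the TSV path.
#' @export
export_zone_scatter <- function(emb, labels_l5, tree, zone_map, out_prefix) {
  if (emb$m != 2L) stop("scatter export needs a 2-D embedding")
  if (length(zone_map) == 0L) stop("zone_map must be non-empty")
  zones <- zone_map[as.character(labels_l5)]
  if (anyNA(zones)) {
    offenders <- sort(unique(labels_l5[is.na(zones)]))
    stop("zone_map lacks entries for level-5 term(s): ",
         paste(offenders, collapse = ", "))
  }
  idx <- tree$.index[as.character(labels_l5)]
  df <- data.frame(x = emb$Y[, 1], y = emb$Y[, 2], acronym = unname(zones),
                   color_hex = tree$terms$color[idx])
  tsv <- paste0(out_prefix, ".tsv")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  render_text_scatter(df, paste0(out_prefix, ".svg"))
  invisible(tsv)
}

# draw each point as its acronym in its color; silently skipped when no
# cairo SVG device exists in the R build
render_text_scatter <- function(df, svg_path) {
  if (!isTRUE(unname(capabilities("cairo")))) {
    return(invisible(NULL))
  }
  grDevices::svg(svg_path, width = 8, height = 8)
  on.exit(grDevices::dev.off())
  graphics::plot(df$x, df$y, type = "n", xlab = "dimension 1",
                 ylab = "dimension 2", main = "embedding")
  graphics::text(df$x, df$y, labels = df$acronym, col = df$color_hex,
                 cex = 0.5)
  invisible(svg_path)
}

#' Longitudinal-zone map for a synthetic atlas
#'
#' In the generated atlas the level-5 children of each level-4 slab are its
#' longitudinal bands stacked along y. This helper tags each level-5 term
#' with its band: with 4 bands the tags are `R`, `A`, `B`, `F`
#' (roof/alar/basal/floor, superior to inferior); otherwise `Z1..Zk`.
#'
#' @param tree tree from [generate_ontology()].
#' @param n_longitudinal number of bands per slab.
#' @return Named character vector: level-5 term id -> zone tag.
#' @export
synthetic_zone_map <- function(tree, n_longitudinal = 4L) {
  l5 <- tree$terms[tree$terms$level == 5L, , drop = FALSE]
  if (nrow(l5) == 0L) stop("ontology has no level-5 terms")
  tags <- if (n_longitudinal == 4L) c("R", "A", "B", "F")
          else paste0("Z", seq_len(n_longitudinal))
  out <- character(nrow(l5))
  for (p in unique(l5$parent_id)) {
    kids <- sort(l5$id[l5$parent_id == p])
    out[match(kids, l5$id)] <- tags[seq_along(kids)]
  }
  stats::setNames(out, l5$id)
}

#' Read an experiment configuration from flat YAML
#'
#' Schema: a top-level `schema: genoanat-experiment-v1` key, then the
#' fields of [experiment_config()] (`methods`, `dims`, `levels`, `seed`,
#' `kmeans_restarts`, `dataset_name`), an optional `tsne:` block of
#' [tsne_config()] overrides, and an optional `atlas:` block of
#' [synthetic_spec()] overrides.
#'
#' @param path YAML path.
#' @return An [experiment_config()].
#' @export
read_experiment_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!identical(y$schema, "genoanat-experiment-v1")) {
    stop("unsupported or missing config schema (want genoanat-experiment-v1)")
  }
  spec <- do.call(synthetic_spec, y$atlas %||% list())
  tsne <- do.call(tsne_config, y$tsne %||% list())
  args <- y[setdiff(names(y), c("schema", "atlas", "tsne"))]
  do.call(experiment_config, c(list(spec = spec, tsne = tsne), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
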