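#' Construct an anatomical ontology tree
#'
#' An ontology tree is a rooted, level-numbered hierarchy of named, colored
#' brain structures. The root sits at level 0 (the undivided neural plate in
#' a developmental atlas) and every child is exactly one level deeper than
#' its parent, so "level" is both a tree depth and an anatomical granularity:
#' low levels are coarse divisions (forebrain/midbrain/hindbrain), deeper
#' levels are transversal segments and longitudinal zones.
#'
#' @param terms data frame with columns `id` (integer, unique), `acronym`,
#'   `name` (character), `level` (integer >= 0), `parent_id` (integer, `NA`
#'   only for the root) and `color` (RGB hex string such as `"#A0C846"`).
#' @return An object of class `ontology_tree`: a list with elements `terms`
#'   (the validated data frame) and `root_id`.
#' @examples
#' tr <- ontology_tree(data.frame(
#'   id = c(1L, 2L, 3L), acronym = c("NP", "F", "M"),
#'   name = c("neural plate", "forebrain", "midbrain"),
#'   level = c(0L, 1L, 1L), parent_id = c(NA, 1L, 1L),
#'   color = c("#888888", "#FF0000", "#00FF00")))
#' ancestor_at_level(tr, 2L, 0L)
#' @export
ontology_tree <- function(terms) {
  stopifnot(is.data.frame(terms))
  required <- c("id", "acronym", "name", "level", "parent_id", "color")
  missing_cols <- setdiff(required, names(terms))
  if (length(missing_cols) > 0L) {
    stop("ontology terms lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  terms$id <- as.integer(terms$id)
  terms$level <- as.integer(terms$level)
  terms$parent_id <- as.integer(terms$parent_id)
  if (anyDuplicated(terms$id)) stop("ontology term ids must be unique")
  roots <- which(is.na(terms$parent_id))
  if (length(roots) != 1L) {
    stop("ontology must have exactly one root (found ", length(roots), ")")
  }
  if (terms$level[roots] != 0L) stop("root term must be at level 0")
  non_root <- terms[-roots, , drop = FALSE]
  if (nrow(non_root) > 0L) {
    pidx <- match(non_root$parent_id, terms$id)
    if (anyNA(pidx)) {
      bad <- non_root$id[is.na(pidx)]
      stop("unresolved parent_id for term(s): ", paste(bad, collapse = ", "))
    }
    if (any(non_root$level != terms$level[pidx] + 1L)) {
      bad <- non_root$id[non_root$level != terms$level[pidx] + 1L]
      stop("level must equal parent level + 1; violated by term(s): ",
           paste(bad, collapse = ", "))
    }
  }
  tree <- structure(
    list(terms = terms, root_id = terms$id[roots]),
    class = "ontology_tree"
  )
  # acyclicity follows from the level invariant, but make lookups cheap too
  tree$.index <- stats::setNames(seq_len(nrow(terms)), terms$id)
  tree
}

#' @export
print.ontology_tree <- function(x, ...) {
  cat(sprintf("ontology_tree: %d terms, depth %d, root id %d\n",
              nrow(x$terms), max(x$terms$level), x$root_id))
  invisible(x)
}

term_row <- function(tree, term_id) {
  i <- tree$.index[as.character(term_id)]
  if (is.na(i)) stop("unknown ontology term id: ", term_id)
  i
}

#' Level of an ontology term
#'
#' @param tree an `ontology_tree`.
#' @param term_id integer term id (vectorized).
#' @return integer level(s).
#' @export
term_level <- function(tree, term_id) {
  idx <- tree$.index[as.character(term_id)]
  if (anyNA(idx)) {
    stop("unknown ontology term id: ",
         paste(term_id[is.na(idx)], collapse = ", "))
  }
  unname(tree$terms$level[idx])
}

#' Up-propagate a term to a coarser ontology level
#'
#' Walks parent links from `term_id` until the requested level is reached.
#' Because every child is one level below its parent, the ancestor at a given
#' level is unique; up-propagation is how a voxel annotated at a fine level
#' is re-expressed at a coarse one (e.g. its level-1 brain vesicle).
#'
#' @param tree an `ontology_tree`.
#' @param term_id integer id of the starting term.
#' @param level target level, `0 <= level <= term_level(tree, term_id)`.
#' @return The id of the ancestor at `level` (the term itself when `level`
#'   equals its own level).
#' @export
ancestor_at_level <- function(tree, term_id, level) {
  i <- term_row(tree, term_id)
  lev <- tree$terms$level[i]
  if (level > lev) {
    stop(sprintf(
      "cannot down-propagate: term %d is at level %d, requested level %d",
      term_id, lev, level))
  }
  if (level < 0L) stop("level must be >= 0")
  while (lev > level) {
    i <- term_row(tree, tree$terms$parent_id[i])
    lev <- tree$terms$level[i]
  }
  tree$terms$id[i]
}

#' Map many terms to their ancestors at one level
#'
#' Vectorized [ancestor_at_level()] over a label vector; repeated ids are
#' resolved once. Used to up-propagate whole annotation columns.
#'
#' @inheritParams ancestor_at_level
#' @param term_ids integer vector of term ids.
#' @return integer vector of ancestor ids, same length as `term_ids`.
#' @export
ancestors_at_level <- function(tree, term_ids, level) {
  uniq <- unique(term_ids)
  anc <- vapply(uniq, function(id) ancestor_at_level(tree, id, level), integer(1))
  anc[match(term_ids, uniq)]
}

#' All descendants of a term (including itself)
#'
#' @inheritParams ancestor_at_level
#' @return integer vector of ids in the subtree rooted at `term_id`.
#' @export
subtree_ids <- function(tree, term_id) {
  term_row(tree, term_id) # validates
  out <- term_id
  frontier <- term_id
  repeat {
    kids <- tree$terms$id[!is.na(tree$terms$parent_id) &
                            tree$terms$parent_id %in% frontier]
    if (length(kids) == 0L) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Read an ontology from JSON
#'
#' Expects a JSON array of objects with fields `id`, `acronym`, `name`,
#' `level`, `parent_id` (`null` for the root) and `color_hex`, the flat
#' structure-graph shape used by public atlas APIs. Invariants (single root,
#' parent resolution, level numbering) are validated on load.
#'
#' @param path path to a JSON file.
#' @return An `ontology_tree`.
#' @export
read_ontology_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.data.frame(raw)) stop("ontology JSON must be an array of objects")
  if ("color_hex" %in% names(raw) && !"color" %in% names(raw)) {
    raw$color <- raw$color_hex
  }
  ontology_tree(raw[c("id", "acronym", "name", "level", "parent_id", "color")])
}

#' Write an ontology to JSON
#'
#' Inverse of [read_ontology_json()].
#'
#' @param tree an `ontology_tree`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ontology_json <- function(tree, path) {
  out <- tree$terms
  names(out)[names(out) == "color"] <- "color_hex"
  jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
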