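#' Write a 3-D volume as ASCII NRRD
#'
#' Minimal NRRD writer for dense 3-D arrays, restricted to the plain-text
#' (`encoding: text`) variant of the format so volumes remain diffable and
#' portable. Values are stored fastest-axis-first (x fastest), which matches
#' R's column-major array layout directly.
#'
#' @param vol 3-D numeric or integer array.
#' @param path output `.nrrd` path.
#' @param type NRRD sample type, `"double"` or `"int"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(vol, path, type = c("double", "int")) {
  type <- match.arg(type)
  d <- dim(vol)
  if (length(d) != 3L) stop("volume must be a 3-D array")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(d, collapse = " ")),
    "encoding: text",
    ""
  ), con)
  vals <- as.vector(vol)
  if (type == "int") {
    fmt <- format(as.integer(vals), scientific = FALSE, trim = TRUE)
  } else {
    fmt <- format(vals, digits = 17, scientific = TRUE, trim = TRUE)
  }
  # one grid line per x-run keeps files greppable without hurting parsers
  writeLines(vapply(split(fmt, rep(seq_len(d[2] * d[3]), each = d[1])),
                    paste, character(1), collapse = " "), con)
  invisible(path)
}

#' Read an ASCII NRRD volume written by [write_nrrd()]
#'
#' Supports `dimension: 3` with `encoding: text`/`ascii` only.
#'
#' @param path `.nrrd` path.
#' @return A 3-D array (integer when the header type is integral).
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "NRRD")) stop("not an NRRD file: ", path)
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop("malformed NRRD: no blank line after header")
  header <- lines[2:(blank - 1)]
  header <- header[!startsWith(header, "#")]
  kv <- strsplit(header, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), character(1))
  get <- function(k) vals[match(k, keys)]
  if (as.integer(get("dimension")) != 3L) stop("only 3-D NRRD supported")
  if (!get("encoding") %in% c("text", "txt", "ascii")) {
    stop("only text-encoded NRRD supported (got ", get("encoding"), ")")
  }
  sizes <- as.integer(strsplit(get("sizes"), " +")[[1]])
  nums <- scan(text = lines[(blank + 1):length(lines)], quiet = TRUE)
  if (length(nums) != prod(sizes)) {
    stop("NRRD data length ", length(nums), " != prod(sizes) ", prod(sizes))
  }
  arr <- array(nums, dim = sizes)
  if (get("type") %in% c("int", "short", "long", "uchar", "unsigned int")) {
    storage.mode(arr) <- "integer"
  }
  arr
}

#' Write a sparse CSV fallback for tiny volumes
#'
#' Columns `voxel_x,voxel_y,voxel_z,value` with 0-based coordinates; only
#' nonzero voxels are written. Intended for hand-built fixtures where a
#' full NRRD grid is overkill.
#'
#' @param vol 3-D array.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_volume_csv <- function(vol, path) {
  d <- dim(vol)
  if (length(d) != 3L) stop("volume must be a 3-D array")
  idx <- which(vol != 0, arr.ind = TRUE)
  df <- data.frame(voxel_x = idx[, 1] - 1L, voxel_y = idx[, 2] - 1L,
                   voxel_z = idx[, 3] - 1L, value = vol[idx])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV volume written by [write_volume_csv()]
#'
#' @param path CSV path.
#' @param dims grid dims (x, y, z); required because the CSV is sparse.
#' @param integer_values coerce values to integer (for annotations).
#' @return A 3-D array with zeros at unlisted voxels.
#' @export
read_volume_csv <- function(path, dims, integer_values = FALSE) {
  df <- utils::read.csv(path)
  need <- c("voxel_x", "voxel_y", "voxel_z", "value")
  if (!all(need %in% names(df))) {
    stop("volume CSV needs columns ", paste(need, collapse = ","))
  }
  if (any(df$voxel_x >= dims[1] | df$voxel_y >= dims[2] | df$voxel_z >= dims[3] |
            df$voxel_x < 0 | df$voxel_y < 0 | df$voxel_z < 0)) {
    stop("voxel coordinate outside dims")
  }
  arr <- array(if (integer_values) 0L else 0, dim = dims)
  arr[cbind(df$voxel_x, df$voxel_y, df$voxel_z) + 1L] <-
    if (integer_values) as.integer(df$value) else df$value
  arr
}
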