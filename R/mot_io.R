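# Readers and writers for MOTChallenge-style comma-separated txt files:
# frame, id, bb_left, bb_top, width, height, conf, class_id, visibility.
# Nine-column dialect on write; 7-10 columns tolerated on read (extra
# columns ignored, missing conf/class/visibility filled with -1).
# Coordinates stay as floats, top-left origin, 1-based frames.

#' Read a MOTChallenge-style txt file
#'
#' @param path File path.
#' @param role `"detections"` (ids may be -1), `"ground_truth"` or
#'   `"tracks"` (ids must be >= 1).
#' @return Tibble with columns `frame, id, left, top, width, height, conf,
#'   class_id, visibility`, sorted by frame then id. An empty file yields
#'   an empty tibble.
#' @export
read_mot <- function(path, role = c("detections", "ground_truth", "tracks")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  empty <- tibble::tibble(frame = integer(0), id = integer(0),
                          left = numeric(0), top = numeric(0),
                          width = numeric(0), height = numeric(0),
                          conf = numeric(0), class_id = integer(0),
                          visibility = numeric(0))
  if (file.size(path) == 0L) return(empty)
  dt <- data.table::fread(path, header = FALSE, sep = ",", fill = TRUE,
                          colClasses = "numeric", data.table = FALSE,
                          showProgress = FALSE)
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) < 6L) {
    stop(sprintf("%s: need at least 6 comma-separated columns", path),
         call. = FALSE)
  }
  pad <- function(k) if (ncol(dt) >= k) dt[[k]] else rep(-1, nrow(dt))
  out <- tibble::tibble(
    frame = dt[[1]], id = dt[[2]], left = dt[[3]], top = dt[[4]],
    width = dt[[5]], height = dt[[6]], conf = pad(7),
    class_id = pad(8), visibility = pad(9)
  )
  bad <- which(!stats::complete.cases(out[, 1:6]) | out$frame < 1 |
                 out$width <= 0 | out$height <= 0 |
                 out$frame != floor(out$frame))
  if (length(bad)) {
    stop(sprintf("%s: malformed record at line %d (frame >= 1 and width, height > 0 required)",
                 path, bad[1]), call. = FALSE)
  }
  if (role %in% c("ground_truth", "tracks") && any(out$id < 1)) {
    stop(sprintf("%s: %s records need id >= 1 (line %d)", path, role,
                 which(out$id < 1)[1]), call. = FALSE)
  }
  out$frame <- as.integer(out$frame)
  out$id <- as.integer(out$id)
  out$class_id <- as.integer(out$class_id)
  dplyr::arrange(out, .data$frame, .data$id)
}

#' Write records as a MOTChallenge-style txt file
#'
#' Rows are ordered by frame then id, with fixed decimal formatting
#' (2 decimals for geometry, 4 for confidence), so identical inputs
#' produce byte-identical files.
#'
#' @param records Tibble with at least `frame, id, left, top, width,
#'   height`; `conf`, `class_id`, `visibility` default to -1.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mot <- function(records, path) {
  records <- tibble::as_tibble(records)
  req <- c("frame", "id", "left", "top", "width", "height")
  if (!all(req %in% names(records))) {
    stop("records need columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) > 0L &&
      (any(records$width <= 0) || any(records$height <= 0))) {
    stop("records contain non-positive box sizes", call. = FALSE)
  }
  fill <- function(col) {
    if (col %in% names(records)) {
      v <- records[[col]]
      v[is.na(v)] <- -1
      v
    } else rep(-1, nrow(records))
  }
  r <- tibble::tibble(
    frame = as.integer(records$frame), id = as.integer(records$id),
    left = records$left, top = records$top, width = records$width,
    height = records$height, conf = fill("conf"),
    class_id = as.integer(fill("class_id")),
    visibility = as.integer(fill("visibility"))
  )
  r <- dplyr::arrange(r, .data$frame, .data$id)
  lines <- sprintf("%d,%d,%.2f,%.2f,%.2f,%.2f,%.4f,%d,%d",
                   r$frame, r$id, r$left, r$top, r$width, r$height,
                   r$conf, r$class_id, r$visibility)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a per-detection appearance-embedding sidecar
#'
#' A plain numeric table (whitespace- or comma-separated), one row per
#' detection in file order. Rows are L2-normalised on load.
#'
#' @param path File path.
#' @param expected_rows Required row count (e.g. the number of detection
#'   records); `NULL` skips the check.
#' @return Numeric matrix with unit-norm rows.
#' @export
read_embeddings <- function(path, expected_rows = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- as.matrix(data.table::fread(path, header = FALSE,
                                   data.table = FALSE))
  storage.mode(m) <- "double"
  if (anyNA(m)) stop(path, ": non-numeric embedding entries", call. = FALSE)
  if (!is.null(expected_rows) && nrow(m) != expected_rows) {
    stop(sprintf("%s: %d embedding rows but %d detections", path, nrow(m),
                 expected_rows), call. = FALSE)
  }
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    stop(sprintf("%s: zero-vector embedding at row %d cannot be normalized",
                 path, which(nrm == 0)[1]), call. = FALSE)
  }
  m / nrm
}

#' Write an embedding matrix sidecar
#'
#' @param embeddings Numeric matrix, one row per detection.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  m <- as.matrix(embeddings)
  lines <- apply(m, 1, function(r) paste(sprintf("%.8f", r), collapse = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read and write flat run-configuration files
#'
#' Run configs are flat YAML key-value files whose keys mirror
#' [tracker_config()] and [scene_config()] field names.
#'
#' @param path File path.
#' @param config Named list of configuration values.
#' @return `read_run_config()` returns a named list; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
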