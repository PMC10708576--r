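# MOTChallenge CSV I/O. Files are comma-separated with columns
# frame, id, bb_left, bb_top, bb_width, bb_height, conf, x, y, z
# (the last three are -1 placeholders; raw detections use id = -1).
# File frame indices are 1-based per the format convention; everything
# in memory is 0-based, and the conversion lives only in this module.

#' Read a MOTChallenge CSV file
#'
#' Accepts 9- or 10-column detection/ground-truth/track files. Frame
#' indices are converted to the package's 0-based convention.
#'
#' @param path Path to a `det.txt`/`gt.txt`-style file.
#' @return Data frame with columns `frame` (0-based), `id`, `x`, `y`, `w`,
#'   `h`, `conf`.
#' @export
read_mot <- function(path) {
  if (!file.exists(path)) stop("read_mot: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(frame = integer(0), id = integer(0), x = numeric(0),
                      y = numeric(0), w = numeric(0), h = numeric(0),
                      conf = numeric(0)))
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  rows <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- suppressWarnings(as.numeric(trimws(parts[[i]])))
    if (!(length(p) %in% c(9L, 10L)) || anyNA(p)) {
      stop("read_mot: malformed record at ", path, ":", i,
           " (expected 9-10 numeric columns, got '", lines[i], "')")
    }
    rows[[i]] <- p[1:7]
  }
  m <- do.call(rbind, rows)
  if (any(m[, 1] < 1)) stop("read_mot: frame indices must be >= 1 in ", path)
  if (any(m[, 5] < 0) || any(m[, 6] < 0)) {
    stop("read_mot: negative box dimensions in ", path)
  }
  data.frame(frame = as.integer(m[, 1]) - 1L, id = as.integer(m[, 2]),
             x = m[, 3], y = m[, 4], w = m[, 5], h = m[, 6], conf = m[, 7])
}

#' Write a MOTChallenge CSV file
#'
#' Records are sorted by `(frame, id)`; frames are written 1-based. Box
#' coordinates are printed with 4 decimals and confidences with 6, which
#' bounds the round-trip error at the printed precision.
#'
#' @param records Data frame with columns `frame` (0-based), `x, y, w, h`,
#'   and optionally `id` (default -1, raw detections) and `conf`/`score`
#'   (default 1).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mot <- function(records, path) {
  df <- as.data.frame(records)
  if (is.null(df$id)) df$id <- -1L
  if (is.null(df$conf)) df$conf <- if (is.null(df$score)) 1 else df$score
  df <- df[order(df$frame, df$id), , drop = FALSE]
  lines <- sprintf("%d,%d,%.4f,%.4f,%.4f,%.4f,%.6f,-1,-1,-1",
                   df$frame + 1L, df$id, df$x, df$y, df$w, df$h, df$conf)
  writeLines(lines, path)
  invisible(path)
}

#' Read detections from a MOT file
#'
#' Like [read_mot()] but returns the tracker's detection format (the `id`
#' column is dropped, `conf` becomes `score`).
#'
#' @param path Path to a `det.txt`-style file.
#' @return A detections data frame (`frame, x, y, w, h, score`).
#' @export
read_mot_detections <- function(path) {
  m <- read_mot(path)
  detections(m$frame, m$x, m$y, m$w, m$h, pmin(pmax(m$conf, 0), 1))
}

#' Write a flat key-value manifest
#'
#' @param values Named list of scalars.
#' @param path Output path; one `key = value` per line.
#' @return The path, invisibly.
#' @export
write_manifest <- function(values, path) {
  lines <- vapply(names(values), function(k) {
    sprintf("%s = %s", k, format(values[[k]], digits = 12, scientific = FALSE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a key-value manifest
#'
#' @param path Path written by [write_manifest()].
#' @return Named list; values parsed as numbers where possible.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("read_manifest: malformed line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (is.na(num)) val else num
  }
  out
}

#' Read an image-sequence directory
#'
#' Loads all PNG frames of a directory in lexicographic order as grayscale
#' matrices (colour frames are averaged over channels).
#'
#' @param dir Directory of PNG frames.
#' @return List of H x W matrices in `[0, 1]`.
#' @export
read_frames_png <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("read_frames_png: no PNG frames in ", dir)
  lapply(files, function(f) to_gray(png::readPNG(f)))
}
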