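#' Write a thermal video to multi-page TIFF plus a JSON sidecar
#'
#' Frames go to a multi-page TIFF (one page per frame, 32-bit samples of
#' the temperature normalized to a fixed range recorded in the sidecar);
#' timestamps, phase annotation and metadata go to a JSON sidecar next to
#' the TIFF. Because TIFF samples are quantized, the writer snaps the
#' frames onto the stored grid and returns the quantized video invisibly;
#' a write-then-read round trip reproduces that returned object exactly.
#' The quantization step is below 2e-8 deg C for a 50 deg C range.
#'
#' @param video a [thermal_video()].
#' @param path TIFF file path; the sidecar is written at the same path
#'   with extension `.json`.
#' @return Invisibly, the quantized [thermal_video()] as stored on disk.
#' @export
write_thermal_video <- function(video, path) {
  stopifnot(inherits(video, "thermal_video"))
  if (any(!is.finite(video$frames))) {
    bad <- which(apply(video$frames, 1, function(f) any(!is.finite(f))))
    stop("non-finite temperatures in frames: ", paste(bad, collapse = ", "))
  }
  lo <- floor(min(video$frames)) - 1
  hi <- ceiling(max(video$frames)) + 1
  n <- dim(video$frames)[1]
  # 32-bit integer samples: the writer quantizes to truncation levels of
  # x * (2^32 - 1) and the reader returns k / 2^32. Writing
  # (k + 0.5) / (2^32 - 1) centers each stored level with half-quantum
  # margin, verified to make the write-read cycle an exact, idempotent
  # fixed point.
  qdiv <- 2^32
  pages <- vector("list", n)
  frames_q <- video$frames
  for (f in seq_len(n)) {
    xn <- (video$frames[f, , ] - lo) / (hi - lo)
    k <- round(xn * qdiv)
    pages[[f]] <- (k + 0.5) / (qdiv - 1)
    frames_q[f, , ] <- lo + (k / qdiv) * (hi - lo)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  # reals serialized as %.17g strings so the sidecar round-trips doubles
  # exactly
  sidecar <- list(n_frames = n,
                  n_rows = dim(video$frames)[2],
                  n_cols = dim(video$frames)[3],
                  range_lo = lo, range_hi = hi,
                  timestamps = sprintf("%.17g", video$timestamps),
                  phases = lapply(video$phases,
                                  function(p) sprintf("%.17g", p)),
                  meta = video$meta)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  out <- video
  out$frames <- frames_q
  invisible(out)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Read a thermal video written by [write_thermal_video()]
#'
#' @param path TIFF file path with its `.json` sidecar alongside.
#' @return A [thermal_video()].
#' @export
read_thermal_video <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    stop("missing sidecar metadata file: ", sp)
  }
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (length(pages) != meta$n_frames) {
    stop(sprintf("TIFF has %d pages but sidecar declares %d frames",
                 length(pages), meta$n_frames))
  }
  lo <- meta$range_lo; hi <- meta$range_hi
  frames <- array(NA_real_,
                  c(meta$n_frames, meta$n_rows, meta$n_cols))
  for (f in seq_along(pages)) {
    frames[f, , ] <- lo + pages[[f]] * (hi - lo)
  }
  if (any(!is.finite(frames))) {
    bad <- which(apply(frames, 1, function(x) any(!is.finite(x))))
    stop("non-finite temperatures in frames: ", paste(bad, collapse = ", "))
  }
  phases <- lapply(meta$phases, as.numeric)
  thermal_video(frames, as.numeric(meta$timestamps), phases,
                meta = as.list(meta$meta))
}

#' Write / read a tumor mask as 8-bit PNG
#'
#' Tumor pixels are stored as 255, healthy pixels as 0.
#'
#' @param mask logical matrix.
#' @param path PNG file path.
#' @return `write_mask()`: invisibly, `path`; `read_mask()`: a logical
#'   matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Write / read a polygon vertex list as CSV
#'
#' The on-disk convention is 1-based `(x, y)` columns (x = column,
#' y = row), matching common image tooling; in memory the package uses
#' 0-based `(row, col)` with pixel centers at integers. Conversion happens
#' here, at the file boundary only.
#'
#' @param polygon `k x 2` matrix, 0-based `(row, col)`.
#' @param path CSV path.
#' @return `write_polygon()`: invisibly, `path`; `read_polygon()`: a
#'   `k x 2` matrix, 0-based `(row, col)`.
#' @export
write_polygon <- function(polygon, path) {
  polygon <- as.matrix(polygon)
  utils::write.csv(data.frame(x = polygon[, 2] + 1, y = polygon[, 1] + 1),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_polygon
#' @export
read_polygon <- function(path) {
  d <- utils::read.csv(path)
  cbind(row = d$y - 1, col = d$x - 1)
}

#' Write / read paired control points as CSV
#'
#' Columns are `frame_label, x, y, pair_id` with 1-based `(x, y)` image
#' coordinates on disk (see [write_polygon()] for the convention).
#'
#' @param src,dst `n x 2` matrices, 0-based `(row, col)`, in the source
#'   and target frames.
#' @param path CSV path.
#' @param frames length-2 character: labels of the two frames.
#' @return `write_control_points()`: invisibly, `path`;
#'   `read_control_points()`: list with `src`, `dst` matrices and
#'   `frames`.
#' @export
write_control_points <- function(src, dst, path,
                                 frames = c("visible", "thermal")) {
  n <- nrow(src)
  d <- data.frame(
    frame_label = rep(frames, each = n),
    x = c(src[, 2], dst[, 2]) + 1,
    y = c(src[, 1], dst[, 1]) + 1,
    pair_id = rep(seq_len(n), 2))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_control_points
#' @export
read_control_points <- function(path) {
  d <- utils::read.csv(path)
  labs <- unique(d$frame_label)
  if (length(labs) != 2) stop("expected exactly two frame labels")
  pick <- function(lab) {
    s <- d[d$frame_label == lab, ]
    s <- s[order(s$pair_id), ]
    cbind(row = s$y - 1, col = s$x - 1)
  }
  list(src = pick(labs[1]), dst = pick(labs[2]), frames = labs)
}

#' Write / read a per-pixel feature table as CSV
#'
#' Missing values (e.g. rejected recovery fits) are stored as empty
#' fields and read back as `NA`.
#'
#' @param table a feature `data.frame` from [extract_td_features()] or
#'   [extract_fd_features()].
#' @param path CSV path.
#' @return `write_feature_table()`: invisibly, `path`;
#'   `read_feature_table()`: a `data.frame`.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path)
}
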