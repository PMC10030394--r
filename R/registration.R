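#' 2-D affine map between image coordinate frames
#'
#' Represents `x -> A x + t` between two named coordinate frames.
#' Coordinates are 0-based `(row, col)` with pixel centers at integers.
#'
#' @param matrix 2x2 linear part, invertible.
#' @param offset length-2 translation.
#' @param source_frame,target_frame frame labels (e.g. `"visible"`,
#'   `"thermal"`).
#' @return An object of class `affine_map`.
#' @export
affine_map <- function(matrix = diag(2), offset = c(0, 0),
                       source_frame = "visible",
                       target_frame = "thermal") {
  matrix <- base::matrix(as.numeric(matrix), 2, 2)
  if (abs(det(matrix)) < 1e-12) {
    stop("affine linear part must be invertible")
  }
  structure(list(matrix = matrix, offset = as.numeric(offset),
                 source_frame = source_frame,
                 target_frame = target_frame),
            class = "affine_map")
}

#' @export
print.affine_map <- function(x, ...) {
  cat(sprintf("Affine map: %s -> %s\n", x$source_frame, x$target_frame))
  cat("  linear part:\n")
  print(signif(x$matrix, 6))
  cat("  offset:", signif(x$offset, 6), "\n")
  if (!is.null(attr(x, "rms_residual"))) {
    cat(sprintf("  least-squares RMS residual: %.4g px\n",
                attr(x, "rms_residual")))
  }
  invisible(x)
}

#' Apply an affine map to points
#'
#' @param map an [affine_map()].
#' @param points `n x 2` matrix of `(row, col)` points.
#' @return `n x 2` matrix of mapped points.
#' @export
apply_affine <- function(map, points) {
  points <- rbind(points)
  t(map$matrix %*% t(points)) +
    matrix(map$offset, nrow(points), 2, byrow = TRUE)
}

#' Invert an affine map
#'
#' @param map an [affine_map()].
#' @return The inverse [affine_map()] (frames swapped).
#' @export
invert_affine <- function(map) {
  Ai <- solve(map$matrix)
  affine_map(Ai, -as.vector(Ai %*% map$offset),
             source_frame = map$target_frame,
             target_frame = map$source_frame)
}

#' Estimate the least-squares affine transform from paired landmarks
#'
#' Finds `A, t` minimizing `sum_i || A src_i + t - dst_i ||^2` by ordinary
#' least squares on the design `[src, 1]`. With exactly three
#' non-collinear pairs the fit is exact.
#'
#' @param src_points,dst_points `n x 2` matrices of corresponding points
#'   (`n >= 3`), `(row, col)` coordinates.
#' @param source_frame,target_frame frame labels for the result.
#' @return An [affine_map()] with attributes `residuals` (n x 2) and
#'   `rms_residual`.
#' @export
estimate_affine <- function(src_points, dst_points,
                            source_frame = "visible",
                            target_frame = "thermal") {
  src_points <- as.matrix(src_points)
  dst_points <- as.matrix(dst_points)
  if (nrow(src_points) < 3 || nrow(dst_points) != nrow(src_points)) {
    stop("need at least 3 corresponding point pairs")
  }
  if (points_collinear(src_points)) {
    stop("source points are collinear: the affine map is not identifiable")
  }
  X <- cbind(src_points, 1)
  # one QR solve per target coordinate
  beta <- qr.solve(X, dst_points)      # 3 x 2: rows = (row-coef, col-coef, 1)
  A <- t(beta[1:2, , drop = FALSE])    # 2 x 2 linear part
  off <- as.numeric(beta[3, ])
  fit <- X %*% beta
  res <- dst_points - fit
  out <- affine_map(A, off, source_frame, target_frame)
  attr(out, "residuals") <- res
  attr(out, "rms_residual") <- sqrt(mean(res^2))
  out
}

#' Rasterize a polygon onto a pixel grid
#'
#' Marks pixels whose centers fall inside the polygon under the even-odd
#' rule; centers lying exactly on an edge count as inside. Pixel centers
#' sit at integer 0-based `(row, col)` coordinates.
#'
#' @param polygon `k x 2` vertex matrix, `(row, col)`.
#' @param grid_shape `c(n_rows, n_cols)`.
#' @return Logical `n_rows x n_cols` matrix.
#' @export
rasterize_polygon <- function(polygon, grid_shape) {
  polygon <- as.matrix(polygon)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  pr <- rep(0:(nr - 1), times = nc)
  pc <- rep(0:(nc - 1), each = nr)
  inside <- point_in_polygon(pr, pc, polygon)
  matrix(inside, nr, nc)
}

# Vectorized even-odd crossing test with an explicit on-edge override.
point_in_polygon <- function(pr, pc, poly, edge_tol = 1e-9) {
  n <- nrow(poly)
  jj <- c(2:n, 1)
  inside <- rep(FALSE, length(pr))
  onedge <- rep(FALSE, length(pr))
  for (e in seq_len(n)) {
    r1 <- poly[e, 1]; c1 <- poly[e, 2]
    r2 <- poly[jj[e], 1]; c2 <- poly[jj[e], 2]
    # crossing test in (c = x, r = y) convention: ray toward +c
    cross <- ((r1 > pr) != (r2 > pr)) &
      (pc < (c2 - c1) * (pr - r1) / (r2 - r1) + c1)
    inside <- xor(inside, cross)
    # on-segment test
    dr <- r2 - r1; dc <- c2 - c1
    len2 <- dr^2 + dc^2
    if (len2 > 0) {
      tpar <- ((pr - r1) * dr + (pc - c1) * dc) / len2
      tpar <- pmin(pmax(tpar, 0), 1)
      d2 <- (pr - (r1 + tpar * dr))^2 + (pc - (c1 + tpar * dc))^2
      onedge <- onedge | d2 <= edge_tol^2
    }
  }
  inside | onedge
}

#' Transfer a tumor boundary onto the thermal pixel grid
#'
#' Maps the polygon vertices pointwise through the affine transform and
#' rasterizes the result on the target grid. Pixels mapped outside the
#' grid are clipped.
#'
#' @param polygon `k x 2` vertex matrix in the map's source frame.
#' @param map an [affine_map()].
#' @param grid_shape `c(n_rows, n_cols)` of the target (thermal) grid.
#' @return List with `polygon` (mapped vertices) and `mask` (logical
#'   image on the target grid).
#' @export
transfer_boundary <- function(polygon, map, grid_shape) {
  mapped <- apply_affine(map, as.matrix(polygon))
  if (max(mapped[, 1]) < 0 || min(mapped[, 1]) > grid_shape[1] - 1 ||
      max(mapped[, 2]) < 0 || min(mapped[, 2]) > grid_shape[2] - 1) {
    stop("mapped polygon lies entirely outside the target grid")
  }
  mask <- rasterize_polygon(mapped, grid_shape)
  if (!any(mask)) {
    stop("mapped polygon contains no pixel centers on the target grid")
  }
  list(polygon = mapped, mask = mask)
}
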