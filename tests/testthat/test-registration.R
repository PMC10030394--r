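test_that("pure scaling and identity configurations are solved exactly", {
  src <- rbind(c(0, 0), c(1, 0), c(0, 1))
  est <- estimate_affine(src, 2 * src)
  expect_equal(est$matrix, diag(2) * 2, tolerance = 1e-12)
  expect_equal(est$offset, c(0, 0), tolerance = 1e-12)
  expect_equal(attr(est, "rms_residual"), 0, tolerance = 1e-12)

  src4 <- rbind(c(0, 0), c(3, 1), c(1, 4), c(5, 5))
  est2 <- estimate_affine(src4, src4)
  expect_equal(est2$matrix, diag(2), tolerance = 1e-12)
  expect_equal(est2$offset, c(0, 0), tolerance = 1e-12)
})

test_that("least-squares estimate matches the normal-equations oracle", {
  set.seed(11)
  A <- matrix(c(1.3, -0.2, 0.15, 0.85), 2)
  off <- c(4, -7)
  src <- matrix(runif(20, 0, 50), 10, 2)
  dst <- t(A %*% t(src)) + rep(off, each = 10) +
    matrix(rnorm(20, 0, 0.4), 10, 2)
  est <- estimate_affine(src, dst)
  orc <- affine_oracle(src, dst)
  expect_equal(est$matrix, orc$A, tolerance = 1e-9)
  expect_equal(est$offset, orc$offset, tolerance = 1e-9)
})

test_that("pre-translating source points only shifts the offset by -A v", {
  set.seed(3)
  src <- matrix(runif(16, 0, 30), 8, 2)
  dst <- matrix(runif(16, 0, 30), 8, 2)
  base <- estimate_affine(src, dst)
  v <- c(5, -3)
  shifted <- estimate_affine(sweep(src, 2, -v), dst)
  expect_equal(shifted$matrix, base$matrix, tolerance = 1e-9)
  expect_equal(shifted$offset,
               base$offset - as.vector(base$matrix %*% v),
               tolerance = 1e-9)
})

test_that("degenerate landmark configurations are refused", {
  line <- cbind(1:5, 2 * (1:5) + 1)
  expect_error(estimate_affine(line, line + 1), "collinear")
  expect_error(estimate_affine(line[1:2, ], line[1:2, ]), "3")
})

test_that("affine maps compose with their inverse to the identity", {
  m <- affine_map(matrix(c(1.5, 0.3, -0.2, 0.8), 2), c(2, 9))
  inv <- invert_affine(m)
  pts <- matrix(runif(20, -10, 10), 10, 2)
  expect_equal(apply_affine(inv, apply_affine(m, pts)), pts,
               tolerance = 1e-9)
})

test_that("rasterization matches an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    # vertices off the integer grid so edge conventions cannot differ
    poly <- cbind(runif(k, 0.3, 14.3), runif(k, 0.3, 14.3)) + 0.123
    area <- abs(thermoseg:::polygon_area(poly))
    if (area < 1) next
    got <- rasterize_polygon(poly, c(16, 16))
    pr <- rep(0:15, times = 16); pc <- rep(0:15, each = 16)
    # mgcv::in.out wants a closed boundary loop in (x, y)
    bnd <- rbind(poly[, c(2, 1)], poly[1, c(2, 1)])
    want <- mgcv::in.out(bnd, cbind(pc, pr))
    expect_identical(as.vector(got), as.vector(want))
  }
})

test_that("rasterized pixel count is consistent with polygon area", {
  poly <- default_polygon <- thermoseg:::default_tumor_polygon(32, 32)
  mask <- rasterize_polygon(poly, c(32, 32))
  area <- abs(thermoseg:::polygon_area(poly))
  per <- sum(sqrt(rowSums((poly - poly[c(2:nrow(poly), 1), ])^2)))
  expect_lte(abs(sum(mask) - area), per)
})

test_that("boundary transfer under identity and translation behaves as maps", {
  rect <- rbind(c(2, 3), c(2, 8), c(6, 8), c(6, 3))
  idm <- affine_map(diag(2), c(0, 0))
  tb <- transfer_boundary(rect, idm, c(16, 16))
  expect_identical(tb$mask, rasterize_polygon(rect, c(16, 16)))

  shift <- affine_map(diag(2), c(2, 3))     # +2 rows, +3 cols
  tb2 <- transfer_boundary(rect, shift, c(16, 16))
  base <- rasterize_polygon(rect, c(16, 16))
  shifted <- matrix(FALSE, 16, 16)
  shifted[3:16, 4:16] <- base[1:14, 1:13]
  expect_identical(tb2$mask, shifted)

  far <- affine_map(diag(2), c(100, 100))
  expect_error(transfer_boundary(rect, far, c(16, 16)), "outside")
})

test_that("mapped-polygon rasterization agrees with brute-force testing", {
  tri <- rbind(c(1.2, 1.7), c(9.4, 3.1), c(4.6, 11.3))
  m <- affine_map(matrix(c(0.9, 0.2, -0.1, 1.1), 2), c(1.5, 0.5))
  tb <- transfer_boundary(tri, m, c(16, 16))
  mapped <- apply_affine(m, tri)
  pip_oracle <- function(r, c, poly) {     # scalar even-odd crossing test
    n <- nrow(poly); inside <- FALSE; j <- n
    for (i in seq_len(n)) {
      ri <- poly[i, 1]; ci <- poly[i, 2]
      rj <- poly[j, 1]; cj <- poly[j, 2]
      if ((ri > r) != (rj > r) &&
          c < (cj - ci) * (r - ri) / (rj - ri) + ci) inside <- !inside
      j <- i
    }
    inside
  }
  brute <- matrix(FALSE, 16, 16)
  for (r in 0:15) for (cc in 0:15) {
    brute[r + 1, cc + 1] <- pip_oracle(r, cc, mapped)
  }
  expect_identical(tb$mask, brute)
  expect_equal(tb$polygon, mapped)
})
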