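test_that("gradient magnitude follows the difference stencil", {
  expect_true(all(gradient_magnitude(matrix(9, 8, 8)) == 0))

  # vertical step of height h gives magnitude h on adjacent columns
  h <- 120
  img <- cbind(matrix(0, 8, 4), matrix(h, 8, 4))
  g <- gradient_magnitude(img)
  expect_equal(g[4, 4], h)
  expect_equal(g[4, 5], h)
  expect_equal(g[4, 2], 0)

  # invariant under 90-degree rotation (transpose for a symmetric image)
  set.seed(2)
  m <- matrix(sample(0:255, 100, TRUE), 10, 10)
  expect_equal(gradient_magnitude(t(m)), t(gradient_magnitude(m)))

  expect_error(gradient_magnitude(matrix(0, 2, 5)), "3x3")
})

test_that("init_contour finds and encloses a dark disk", {
  img <- disk_slice(radius = 30)
  ct <- init_contour(img, "auto", seed_point = c(63.5, 63.5))
  r <- sqrt((ct$points[, 1] - 63.5)^2 + (ct$points[, 2] - 63.5)^2)
  expect_gte(min(r), 31)           # encloses the disk with ~3-voxel margin
  expect_lte(max(r), 38)
  expect_gte(nrow(ct$points), 8)

  # all-bright slice has no dark region
  expect_error(init_contour(matrix(200, 64, 64), "auto"),
               "initialization error")

  # circle method: radius is a quarter of the smaller slice dimension
  cc <- init_contour(matrix(0, 100, 100), "circle", seed_point = c(50, 50))
  rc <- sqrt((cc$points[, 1] - 50)^2 + (cc$points[, 2] - 50)^2)
  expect_equal(mean(rc), 25, tolerance = 1e-6)
  expect_error(init_contour(matrix(0, 100, 100), "circle"), "seed_point")
})

test_that("snake converges onto a sharp dark disk within 1 voxel RMS", {
  img <- disk_slice(radius = 30)     # contrast 120, no noise
  init <- init_contour(img, "auto", seed_point = c(63.5, 63.5))
  fin <- evolve_snake(img, init, snake_params())
  r <- sqrt((fin$points[, 1] - 63.5)^2 + (fin$points[, 2] - 63.5)^2)
  # disk = pixels with r <= 30, so the boundary sits at 30.5
  expect_lt(sqrt(mean((r - 30.5)^2)), 1.0)
})

test_that("snake energy is non-increasing between resampling events", {
  img <- disk_slice(radius = 30)
  init <- init_contour(img, "auto", seed_point = c(63.5, 63.5))
  fin <- evolve_snake(img, init, snake_params())
  tr <- attr(fin, "trace")
  de <- diff(tr$energy)
  keep <- !tr$resampled[-nrow(tr)]   # exclude steps straddling a resample
  expect_true(all(de[keep] <= 1e-9))
})

test_that("a contour on a strong edge with zero internal weights is a fixed point", {
  # straight vertical edge; points placed on the saturated-gradient ridge
  img <- cbind(matrix(0, 64, 32), matrix(200, 64, 32))
  p <- snake_params(alpha = 0, beta = 0, iterations = 4)
  f <- chondroquant:::edge_field(img, p)
  ridge_x <- which.max(f[32, ]) - 1
  pts <- rbind(cbind(10:50, ridge_x), cbind(50:10, ridge_x))
  ct <- new_contour(pts, 0L)
  fin <- evolve_snake(img, ct, p)
  expect_equal(unname(fin$points), unname(ct$points), tolerance = 1e-12)
})

test_that("bright nuclei near the border spoil the unfiltered snake", {
  v <- bordered_disk_volume(seed = 3L)
  raw <- v$data[5, , ]
  filt <- median3d(v, 3)$data[5, , ]
  init <- init_contour(raw, "auto", seed_point = c(63.5, 63.5),
                       slice_index = 4L)
  rms <- function(ct) {
    r <- sqrt((ct$points[, 1] - 63.5)^2 + (ct$points[, 2] - 63.5)^2)
    sqrt(mean((r - 30.5)^2))
  }
  e_filt <- rms(evolve_snake(filt, init, snake_params()))
  e_raw <- rms(evolve_snake(raw, init, snake_params()))
  expect_lt(e_filt, 1.2)
  expect_gt(e_raw, e_filt)
})

test_that("apply_mask zeroes the exterior and copies the interior bit-exactly", {
  v <- random_volume(c(8L, 8L, 8L), seed = 4L)
  full <- new_mask(array(TRUE, c(8, 8, 8)))
  expect_identical(apply_mask(v, full)$data, v$data)
  empty <- new_mask(array(FALSE, c(8, 8, 8)))
  expect_true(all(apply_mask(v, empty)$data == 0L))
  half <- new_mask(array(rep(c(TRUE, FALSE), each = 4 * 64), c(8, 8, 8)))
  got <- apply_mask(v, half)$data
  expect_identical(got[, , 1:4], v$data[, , 1:4])
  expect_true(all(got[, , 5:8] == 0L))
  expect_error(apply_mask(v, new_mask(array(TRUE, c(2, 2, 2)))), "shape")
})

test_that("a single-slice volume segments to the filled final contour", {
  img <- disk_slice(radius = 30)
  v <- new_volume(array(as.integer(img), c(1L, 128L, 128L)))
  init <- init_contour(img, "auto", seed_point = c(63.5, 63.5),
                       slice_index = 0L)
  mask <- segment_element(v, v, snake_params(), init)
  ct <- attr(mask, "contours")[[1L]]
  fill <- chondroquant:::cq_fill_polygon(ct$points, 128L, 128L)
  expect_identical(mask$data[1, , ], fill)
  # mask roughly matches the disk
  expect_gt(sum(mask$data), 2500)
  expect_lt(sum(mask$data), 3300)
})
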