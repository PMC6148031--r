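make_profile <- function(ratio, z = seq_along(ratio) - 1L) {
  data.frame(z = z, ratio = ratio)
}

test_that("per-slice areas follow voxel counts and the size filter", {
  h <- 1.05
  d <- c(3L, 20L, 20L)
  cls <- array(0L, d)
  cls[2, 1:10, 1:20] <- 1L                    # 200 ECM voxels in slice 1
  lab <- array(0L, d)
  # one 100-voxel surviving nucleus in slice 1, one 4-voxel reject in slice 2
  cls[2, 11:15, 1:20] <- 2L; lab[2, 11:15, 1:20] <- 1L
  cls[3, 1:2, 1:2] <- 2L; lab[3, 1:2, 1:2] <- 2L
  cm <- structure(list(data = cls, k = 3L, voxel_size_um = h),
                  class = "cq_classmap")
  labels <- new_labels(lab, h)
  tab <- blob_metrics(labels, h)
  kept <- filter_blobs(tab, 27L)
  pr <- per_slice_profile(cm, labels, kept)
  expect_equal(pr$nuclei_area_um2[pr$z == 1], 100 * h^2)   # 110.25
  expect_equal(pr$ecm_area_um2[pr$z == 1], 200 * h^2)
  expect_equal(pr$ratio[pr$z == 1], 0.5)
  # the rejected blob contributes nothing; no ECM -> ratio undefined
  expect_equal(pr$nuclei_area_um2[pr$z == 2], 0)
  expect_true(is.na(pr$ratio[pr$z == 2]))
  # conservation: summed nucleus area equals surviving voxels
  expect_equal(sum(pr$nuclei_area_um2) / h^2, 100)
})

test_that("parabola fitting is exact on noiseless quadratics", {
  z <- 0:100
  ratio <- (z - 50)^2 / 1000 + 0.01
  fit <- fit_parabola(make_profile(ratio, z))
  expect_equal(fit$a, 1 / 1000, tolerance = 1e-9)
  expect_equal(fit$b, -100 / 1000, tolerance = 1e-9)
  expect_equal(fit$c, 2500 / 1000 + 0.01, tolerance = 1e-9)
  expect_equal(fit$vertex_z, 50, tolerance = 1e-9)
  expect_true(fit$convex)

  flat <- fit_parabola(make_profile(rep(0.5, 20)))
  expect_equal(flat$a, 0, tolerance = 1e-10)
  expect_equal(flat$b, 0, tolerance = 1e-10)
  expect_true(is.na(flat$vertex_z))

  expect_error(fit_parabola(make_profile(c(1, 2))), "fit error")
  # nesting: the quadratic residual never exceeds the best constant fit
  set.seed(6)
  r <- runif(40)
  fit2 <- fit_parabola(make_profile(r))
  pred <- fit2$c + fit2$b * (0:39) + fit2$a * (0:39)^2
  expect_lte(sum((r - pred)^2), sum((r - mean(r))^2) + 1e-12)
})

test_that("zone boundaries are recovered from a stepped density profile", {
  set.seed(15)
  n <- 200
  dens <- c(rep(80, 50), rep(40, 110), rep(80, 40)) + rnorm(n, 0, 4)
  z <- detect_zones(dens, window = 10L)
  expect_true(z$detected)
  expect_lt(abs(z$z1 - 49), 10)
  expect_lt(abs(z$z2 - 159), 10)

  # uniform density: no zonation
  u <- detect_zones(rep(50, 200), window = 10L)
  expect_false(u$detected)

  # z_offset shifts boundaries to absolute slice indices
  z2 <- detect_zones(dens, window = 10L, z_offset = 30L)
  expect_equal(z2$z1 - z$z1, 30L)

  expect_error(detect_zones(rep(1, 20), window = 10L), "5 x window")
})

test_that("element summaries respect counts, volumes and densities", {
  h <- 10  # 10 um voxels for easy arithmetic
  d <- c(100L, 20L, 20L)
  mask <- new_mask(array(TRUE, d), h)        # 100*400 voxels * 1e-6 mm3
  # fabricate a blob table: 1000 cells spread along z
  set.seed(2)
  zc <- runif(1000, 0, 99) * h
  tab <- data.frame(blob_id = 1:1000, voxel_count = 30L,
                    centroid_z_um = zc, centroid_y_um = 100, centroid_x_um = 100)
  zones <- structure(list(z1 = 19L, z2 = 79L, detected = TRUE),
                     class = "cq_zones")
  s <- summarize_element(mask, tab, zones, h)
  expect_equal(s$cell_number, 1000)
  expect_equal(s$element_volume_mm3, 100 * 400 * (h * 1e-3)^3)  # 0.04 mm3
  expect_equal(s$density_cells_per_mm3, 1000 / s$element_volume_mm3)
  expect_equal(s$average_cell_size_um3, s$element_volume_mm3 * 1e9 / 1000)
  # zone bookkeeping is exact
  expect_equal(sum(s$zones$cell_number), 1000)
  expect_equal(sum(s$zones$volume_mm3), s$element_volume_mm3, tolerance = 1e-12)
  expect_equal(s$zones$density,
               ifelse(s$zones$volume_mm3 > 0,
                      s$zones$cell_number / s$zones$volume_mm3, 0))
  # zero cells: density 0, size undefined
  s0 <- summarize_element(mask, tab[0, ], zones, h)
  expect_equal(s0$density_cells_per_mm3, 0)
  expect_true(is.na(s0$average_cell_size_um3))
})
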