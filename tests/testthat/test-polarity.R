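test_that("deviation angles follow the plane convention", {
  # axis order (z, y, x); plane xy has normal along z
  expect_equal(deviation_angle(c(0, 1, 0), "xy"), 0)
  expect_equal(deviation_angle(c(1, 0, 0), "xy"), 90)
  expect_equal(deviation_angle(c(1, 1, 0) / sqrt(2), "xy"), 45)
  # sign-flip invariance
  expect_equal(deviation_angle(c(-1, -1, 0) / sqrt(2), "xy"), 45)
  # other named planes
  expect_equal(deviation_angle(c(0, 0, 1), "yz"), 90)
  expect_equal(deviation_angle(c(0, 1, 0), "zx"), 90)
  expect_error(deviation_angle(c(1, 1, 0), "xy"), "unit")
  expect_error(reference_plane(c(2, 0, 0)), "unit")
})

test_that("local surface tangents recover flat and spherical geometry", {
  # flat face of a box: normal along x exactly
  a <- array(FALSE, c(20, 20, 20)); a[5:15, 5:15, 5:10] <- TRUE
  m <- new_mask(a, 1.0)
  n <- local_surface_tangent(m, c(9, 9, 9.4), patch_radius_um = 3)
  expect_equal(abs(n[3]), 1, tolerance = 1e-9)

  # digital sphere, point near the pole: normal within 5 deg of radial
  d <- c(90L, 90L, 90L)
  ai <- arrayInd(seq_len(prod(d)), d)
  r2 <- (ai[, 1] - 45)^2 + (ai[, 2] - 45)^2 + (ai[, 3] - 45)^2
  sph <- new_mask(array(r2 <= 40^2, d), 1.0)
  n2 <- local_surface_tangent(sph, c(44 + 38, 44, 44), patch_radius_um = 8)
  ang <- acos(min(1, abs(n2[1]))) * 180 / pi
  expect_lt(ang, 5)

  # degenerate patch
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_error(local_surface_tangent(new_mask(one, 1.0), c(2, 2, 2),
                                     patch_radius_um = 0.1),
               "degenerate-surface")
})

test_that("polarity records flag unpolarized cells and in-plane orientations", {
  a <- array(FALSE, c(20, 20, 20)); a[2:19, 2:19, 2:19] <- TRUE
  mask <- new_mask(a, 1.0)
  tab <- data.frame(blob_id = 1:2, voxel_count = 50L,
                    centroid_z_um = c(10, 10), centroid_y_um = c(10, 8),
                    centroid_x_um = c(10, 12),
                    orient_z = c(0, 1), orient_y = c(1, 0), orient_x = 0,
                    elongation = c(1.0, 2.5))
  pol <- polarity_map(tab, mask, plane = "xy", superficial_max_um = 2)
  expect_identical(pol$records$is_polarized, c(FALSE, TRUE))
  expect_equal(pol$aggregates$fraction_polarized, 0.5)
  expect_equal(pol$records$deviation_deg, c(0, 90))
  # in-plane polarized blob enters the aggregates
  expect_equal(pol$aggregates$mean_deviation_polarized_deg, 90)

  # all spherical blobs: nothing polarized, aggregate flagged
  tab$elongation <- 1
  pol0 <- polarity_map(tab, mask, plane = "xy")
  expect_equal(pol0$aggregates$fraction_polarized, 0)
  expect_true(is.na(pol0$aggregates$mean_deviation_polarized_deg))

  # empty table
  pe <- polarity_map(tab[0, ], mask)
  expect_identical(nrow(pe$records), 0L)
})

test_that("orientation and surface alignment recover the generator model", {
  fx <- polarity_fixture()
  tr <- fx$truth; bl <- fx$blobs
  expect_gt(nrow(bl), 30)
  nn <- chondroquant:::cq_nearest(
    as.matrix(bl[, c("centroid_z_um", "centroid_y_um", "centroid_x_um")]),
    tr$centers_um)
  ok <- nn$distance < 4
  expect_gt(mean(ok), 0.9)
  ang <- vapply(which(ok), function(i) {
    v <- as.numeric(bl[i, c("orient_z", "orient_y", "orient_x")])
    u <- tr$orientations[nn$index[i], ]
    acos(min(1, abs(sum(v * u)))) * 180 / pi
  }, 0)
  el2 <- bl$elongation[ok] >= 2
  expect_gt(sum(el2), 10)
  expect_lt(mean(ang[el2]), 10)

  pol <- polarity_map(bl, fx$mask, plane = "xy", superficial_max_um = 15)
  zb <- tr$zone_boundaries_slice
  sl <- pol$records$centroid_slice
  sup_epi <- (sl <= zb[1] | sl >= zb[2]) &
    pol$records$surface_distance_um <= 15
  expect_gt(sum(sup_epi), 5)
  expect_lt(mean(pol$records$surface_alignment_deg[sup_epi], na.rm = TRUE), 15)

  # diaphyseal nuclei align with z; plane xy normal is z
  dia <- pol$records$is_polarized & sl > zb[1] & sl < zb[2]
  expect_gte(mean(pol$records$deviation_deg[dia]), 80)
})
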