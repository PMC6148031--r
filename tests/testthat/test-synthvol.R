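test_that("phantom generation is deterministic and honours zero density", {
  s <- phantom_spec(grid_shape = c(80L, 96L, 96L), capsule_radius_um = 30,
                    element_length_um = 62, voxel_size_um = 1.0, seed = 5L)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$centers_um, b$truth$centers_um)

  s0 <- phantom_spec(grid_shape = c(80L, 96L, 96L), capsule_radius_um = 30,
                     element_length_um = 62, voxel_size_um = 1.0,
                     density_diaphysis = 0, density_epiphysis = 0, seed = 5L)
  z <- generate_phantom(s0)
  expect_identical(nrow(z$truth$centers_um), 0L)
  expect_gt(sum(z$truth$cartilage_mask$data), 0)
  # capsule still present: a dark ECM region exists
  expect_gt(sum(z$volume$data < 100 & z$truth$cartilage_mask$data), 1000)
})

test_that("truth mask volume converges to the analytic capsule volume", {
  analytic <- pi * 0.03^2 * (0.062 - 0.06) + 4 / 3 * pi * 0.03^3
  vols <- sapply(c(2.0, 1.0), function(h) {
    s <- phantom_spec(grid_shape = c(round(84 / h), round(84 / h), round(84 / h)),
                      capsule_radius_um = 30, element_length_um = 62,
                      voxel_size_um = h, density_diaphysis = 0,
                      density_epiphysis = 0, seed = 1L)
    generate_phantom(s)$truth$element_volume_mm3
  })
  expect_lt(abs(vols[2] - analytic) / analytic, 0.02)
  expect_lt(abs(vols[2] - analytic), abs(vols[1] - analytic))
})

test_that("drawn counts follow the requested zonal densities", {
  ph <- small_phantom(seed = 9L)
  tr <- ph$truth
  lambda <- c(80000, 40000, 80000) * tr$zone_volumes_mm3
  # drawn counts within 4 sigma of their Poisson means
  expect_true(all(abs(tr$zone_counts - lambda) <= 4 * sqrt(lambda) + 1))
  # truth densities consistent with counts/volumes (exact by construction)
  expect_equal(unname(tr$zone_counts / tr$zone_volumes_mm3),
               unname(tr$zone_densities), tolerance = 1e-9)
  # nominal diaphysis:epiphysis ratio is one half
  expect_equal(40000 / 80000, 0.5)
})

test_that("doubling the epiphyseal density doubles the expected count", {
  base <- small_phantom(seed = 21L)
  dbl <- generate_phantom(phantom_spec(
    grid_shape = c(128L, 128L, 128L), capsule_radius_um = 40,
    element_length_um = 110, voxel_size_um = 1.0, psf_sigma_voxels = 0,
    noise_sigma = 0, density_epiphysis = 160000, seed = 22L))
  e1 <- sum(base$truth$zone_counts[c("epiphysis_proximal", "epiphysis_distal")])
  e2 <- sum(dbl$truth$zone_counts[c("epiphysis_proximal", "epiphysis_distal")])
  lambda2 <- 2 * 80000 * sum(base$truth$zone_volumes_mm3[c(1, 3)])
  expect_lt(abs(e2 - lambda2), 3 * sqrt(lambda2) + 3 * sqrt(e1))
})

test_that("nuclei lie inside the cartilage mask and centres inside the capsule", {
  ph <- small_phantom(seed = 13L)   # noise- and blur-free
  nuc <- ph$volume$data == 160L
  expect_true(all(ph$truth$cartilage_mask$data[nuc]))
  ctr_vox <- round(ph$truth$centers_um) + 1
  inside <- mapply(function(z, y, x) ph$truth$cartilage_mask$data[z, y, x],
                   ctr_vox[, 1], ctr_vox[, 2], ctr_vox[, 3])
  expect_true(all(inside))
  # intensity ordering that reproduces the bright-border artifact
  expect_lt(ph$truth$spec$intensities[["ecm"]],
            ph$truth$spec$intensities[["nucleus"]])
  expect_lt(ph$truth$spec$intensities[["nucleus"]],
            ph$truth$spec$intensities[["rim"]])
})

test_that("truth_report summarises counts, densities and volume", {
  ph <- small_phantom(seed = 9L)
  rep <- truth_report(ph$truth)
  expect_identical(rep$n_cells, nrow(ph$truth$centers_um))
  expect_equal(rep$overall_density_cells_per_mm3,
               rep$n_cells / rep$element_volume_mm3)
  # empty truth
  s0 <- phantom_spec(grid_shape = c(80L, 96L, 96L), capsule_radius_um = 30,
                     element_length_um = 62, voxel_size_um = 1.0,
                     density_diaphysis = 0, density_epiphysis = 0, seed = 2L)
  rep0 <- truth_report(generate_phantom(s0)$truth)
  expect_identical(rep0$n_cells, 0L)
  expect_equal(rep0$overall_density_cells_per_mm3, 0)
  expect_true(all(unlist(rep0$zone_densities_cells_per_mm3) == 0))
  # JSON output is valid
  p <- tempfile(fileext = ".json")
  truth_report(ph$truth, p)
  expect_identical(jsonlite::read_json(p)$n_cells, rep$n_cells)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(capsule_radius_um = 200), "fit")
  expect_error(phantom_spec(element_length_um = 100), "twice")
  expect_error(phantom_spec(epiphysis_fraction = 0.7), "epiphysis_fraction")
  expect_error(phantom_spec(intensities = c(background = 20, ecm = 200,
                                            nucleus = 160, surroundings = 180,
                                            rim = 100)), "ordering")
})
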