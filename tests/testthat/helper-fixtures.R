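# Shared fixtures.  The two full-scale phantom pipeline runs are expensive
# (a few minutes each) and are shared across test files via this cache.

.cq_test_cache <- new.env(parent = emptyenv())

# full-scale default-phantom pipeline run, slimmed to what tests consume
acceptance_run <- function(seed) {
  key <- paste0("run", seed)
  if (!is.null(.cq_test_cache[[key]])) return(.cq_test_cache[[key]])
  rep <- run_pipeline(pipeline_config(phantom = TRUE, seed = seed,
                                      write_artifacts = FALSE),
                      keep_volumes = TRUE)
  ob <- attr(rep, "objects")
  slim <- list(
    report = rep,
    mask = ob$mask,
    truth = ob$truth,
    blobs = ob$blobs,
    profile = ob$profile,
    zones = ob$zones,
    parabola = ob$parabola,
    summary = ob$summary,
    polarity = ob$polarity)
  attr(slim$report, "objects") <- NULL
  .cq_test_cache[[key]] <- slim
  slim
}

# mid-scale phantom with elongated nuclei for orientation recovery
polarity_fixture <- function() {
  if (!is.null(.cq_test_cache$polarity)) return(.cq_test_cache$polarity)
  spec <- phantom_spec(grid_shape = c(256L, 192L, 192L),
                       capsule_radius_um = 60, element_length_um = 220,
                       nucleus_semi_axes_um = c(6, 2.75, 2.75), seed = 11L)
  ph <- generate_phantom(spec)
  mask <- ph$truth$cartilage_mask
  masked <- apply_mask(ph$volume, mask)
  cm <- kmeans_classify(masked)
  labels <- split_blobs(class_binary(cm, 2L))
  blobs <- filter_blobs(blob_metrics(labels), 27L)
  out <- list(truth = ph$truth, mask = mask, blobs = blobs)
  .cq_test_cache$polarity <- out
  out
}

# small noise-free phantom for geometric checks
small_phantom <- function(seed = 3L, ...) {
  spec <- phantom_spec(grid_shape = c(128L, 128L, 128L),
                       capsule_radius_um = 40, element_length_um = 110,
                       voxel_size_um = 1.0, psf_sigma_voxels = 0,
                       noise_sigma = 0, seed = seed, ...)
  generate_phantom(spec)
}

random_mask <- function(d, p, seed) {
  set.seed(seed)
  new_mask(array(runif(prod(d)) < p, dim = d), 1.0)
}

random_volume <- function(d, seed, maxval = 255L) {
  set.seed(seed)
  new_volume(array(sample.int(maxval + 1L, prod(d), replace = TRUE) - 1L,
                   dim = d), 1.0)
}

disk_slice <- function(ny = 128L, nx = 128L, cy = (ny - 1) / 2,
                       cx = (nx - 1) / 2, radius = 30, inside = 60,
                       outside = 180) {
  yy <- matrix(0:(ny - 1), ny, nx)
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  r <- sqrt((yy - cy)^2 + (xx - cx)^2)
  out <- matrix(outside, ny, nx)
  out[r <= radius] <- inside
  out
}

# thin volume holding a dark disk with small bright nuclei just inside
# its border (the configuration that defeats an unfiltered snake)
bordered_disk_volume <- function(seed, n_spots = 12L) {
  set.seed(seed)
  nz <- 9L; ny <- 128L; nx <- 128L
  vol <- array(180L, c(nz, ny, nx))
  yy <- matrix(0:(ny - 1), ny, nx)
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  r <- sqrt((yy - 63.5)^2 + (xx - 63.5)^2)
  for (z in 1:nz) { s <- vol[z, , ]; s[r <= 30] <- 60L; vol[z, , ] <- s }
  th <- runif(n_spots) * 2 * pi
  for (k in seq_len(n_spots)) {
    cy <- 63.5 + 27 * sin(th[k]); cx <- 63.5 + 27 * cos(th[k])
    for (z in 3:7) {
      d2 <- (yy - cy)^2 + (xx - cx)^2 + (z - 5)^2
      s <- vol[z, , ]; s[d2 <= 4] <- 200L; vol[z, , ] <- s
    }
  }
  new_volume(vol, 1.0)
}
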