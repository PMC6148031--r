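#' Specification of a synthetic cartilage phantom
#'
#' The phantom emulates a PTA-stained cartilaginous element as imaged by
#' propagation phase-contrast microCT: a weakly stained (dark) capsule of
#' extracellular matrix containing bright ellipsoidal nuclei, embedded in
#' brighter stained tissue, with a thin bright rim along the inside of the
#' cartilage border (the border artifact that must not be counted as
#' cells).  The capsule is a cylinder with hemispherical caps, axis along
#' z, centred in the grid.  Each epiphysis occupies the terminal
#' `epiphysis_fraction` of the element length; cell counts are drawn
#' Poisson per zone at the given densities and placed by hard-core
#' rejection sampling (minimum centre separation 1.5 x the largest nucleus
#' semi-axis).  Nucleus orientations follow the zonal model: diaphyseal
#' nuclei align with the element axis, epiphyseal nuclei within
#' `superficial_depth_um` of the surface align with the local surface
#' tangent, deeper epiphyseal nuclei are isotropic.  The painted volume is
#' blurred with a Gaussian PSF and corrupted with additive Gaussian noise.
#'
#' @param grid_shape integer `(nz, ny, nx)` voxel grid.
#' @param voxel_size_um isotropic voxel size, micrometres.
#' @param capsule_radius_um capsule (cylinder/cap) radius.
#' @param element_length_um total element length along z, caps included.
#' @param epiphysis_fraction fraction of the length forming each epiphysis.
#' @param density_diaphysis,density_epiphysis cell densities, cells mm^-3.
#' @param nucleus_semi_axes_um ellipsoid semi-axes `(a, b, c)`, micrometres.
#' @param intensities named vector: `background`, `ecm`, `nucleus`,
#'   `surroundings`, `rim` (8-bit scale).
#' @param rim_thickness_voxels thickness of the bright border rim.
#' @param tissue_margin_um stained-tissue shell thickness around the capsule;
#'   beyond it the field is `background` (agarose/air).
#' @param superficial_depth_um depth below the surface within which
#'   epiphyseal nuclei follow the surface-tangent orientation rule.
#' @param psf_sigma_voxels Gaussian PSF sigma, voxels.
#' @param noise_sigma additive Gaussian noise sigma, intensity units.
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return A validated list of class `cq_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(512L, 256L, 256L),
                         voxel_size_um = 1.05,
                         capsule_radius_um = 90,
                         element_length_um = 500,
                         epiphysis_fraction = 0.2,
                         density_diaphysis = 40000,
                         density_epiphysis = 80000,
                         nucleus_semi_axes_um = c(4.0, 2.5, 2.5),
                         intensities = c(background = 20, ecm = 60,
                                         nucleus = 160, surroundings = 180,
                                         rim = 200),
                         rim_thickness_voxels = 2,
                         tissue_margin_um = 40,
                         superficial_depth_um = 15,
                         psf_sigma_voxels = 0.7,
                         noise_sigma = 8.0,
                         seed = 42L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_size_um = voxel_size_um,
               capsule_radius_um = capsule_radius_um,
               element_length_um = element_length_um,
               epiphysis_fraction = epiphysis_fraction,
               density_diaphysis = density_diaphysis,
               density_epiphysis = density_epiphysis,
               nucleus_semi_axes_um = as.numeric(nucleus_semi_axes_um),
               intensities = intensities,
               rim_thickness_voxels = rim_thickness_voxels,
               tissue_margin_um = tissue_margin_um,
               superficial_depth_um = superficial_depth_um,
               psf_sigma_voxels = psf_sigma_voxels,
               noise_sigma = noise_sigma,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3L || any(grid_shape < 1L))
      stop("grid_shape must be three positive integers")
    if (voxel_size_um <= 0) stop("voxel_size_um must be positive")
    if (density_diaphysis < 0 || density_epiphysis < 0)
      stop("densities must be >= 0")
    if (epiphysis_fraction < 0 || epiphysis_fraction > 0.5)
      stop("epiphysis_fraction must lie in [0, 0.5]")
    if (length(nucleus_semi_axes_um) != 3L || any(nucleus_semi_axes_um <= 0))
      stop("nucleus_semi_axes_um must be three positive values")
    need <- c("background", "ecm", "nucleus", "surroundings", "rim")
    if (!all(need %in% names(intensities)))
      stop("intensities must name ", paste(need, collapse = ", "))
    if (!(intensities["ecm"] < intensities["nucleus"] &&
          intensities["nucleus"] < intensities["rim"]))
      stop("require ecm < nucleus < rim intensity ordering")
    if (element_length_um < 2 * capsule_radius_um)
      stop("element_length_um must be at least twice the capsule radius")
    # capsule must fit with a 5-voxel margin
    margin <- 5 * voxel_size_um
    if (element_length_um + 2 * margin > grid_shape[1L] * voxel_size_um ||
        2 * capsule_radius_um + 2 * margin > grid_shape[2L] * voxel_size_um ||
        2 * capsule_radius_um + 2 * margin > grid_shape[3L] * voxel_size_um)
      stop("capsule does not fit in the grid with a 5-voxel margin")
  })
  structure(spec, class = "cq_phantom_spec")
}

# distance from each voxel of slice iz to the capsule axis segment, in um;
# r2d2 is the (ny, nx) matrix of squared in-plane distances to the axis
capsule_rho_slice <- function(zc, z_cap1, z_cap2, r2d2) {
  dz <- if (zc < z_cap1) z_cap1 - zc else if (zc > z_cap2) zc - z_cap2 else 0
  sqrt(r2d2 + dz * dz)
}

# orthonormal basis with first axis v (unit); deterministic for fixed v
basis_from_axis <- function(v) {
  h <- if (abs(v[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u2 <- h - sum(h * v) * v
  u2 <- u2 / sqrt(sum(u2^2))
  u3 <- c(v[2L] * u2[3L] - v[3L] * u2[2L],
          v[3L] * u2[1L] - v[1L] * u2[3L],
          v[1L] * u2[2L] - v[2L] * u2[1L])
  cbind(v, u2, u3)
}

#' Generate a synthetic cartilage phantom with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a [new_volume()]) and `truth`
#'   (class `cq_phantom_truth`: nucleus `centers_um` (z,y,x), unit
#'   `orientations`, `zone_of_cell`, `cartilage_mask`, per-zone
#'   `zone_counts`/`zone_volumes_mm3`/`zone_densities`,
#'   `element_volume_mm3`, and the true zone boundary slices
#'   `zone_boundaries_slice`).
#' @export
generate_phantom <- function(spec) {
  spec <- validate_phantom_spec(spec)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  nz <- spec$grid_shape[1L]; ny <- spec$grid_shape[2L]; nx <- spec$grid_shape[3L]
  h <- spec$voxel_size_um
  R <- spec$capsule_radius_um
  L <- spec$element_length_um
  ints <- spec$intensities

  yc <- (ny - 1) / 2 * h; xc <- (nx - 1) / 2 * h
  z0 <- ((nz - 1) * h - L) / 2          # proximal element tip, um
  z_cap1 <- z0 + R; z_cap2 <- z0 + L - R
  rim_um <- spec$rim_thickness_voxels * h

  yy <- ((seq_len(ny) - 1) * h - yc)
  xx <- ((seq_len(nx) - 1) * h - xc)
  r2d2 <- outer(yy^2, xx^2, `+`)

  zb1 <- z0 + spec$epiphysis_fraction * L   # proximal zone boundary, um
  zb2 <- z0 + (1 - spec$epiphysis_fraction) * L

  vol <- array(0L, dim = c(nz, ny, nx))
  cart <- array(FALSE, dim = c(nz, ny, nx))
  zone_slice_counts <- c(epiphysis_proximal = 0, diaphysis = 0,
                         epiphysis_distal = 0)
  zone_of_z <- character(nz)
  for (iz in seq_len(nz)) {
    zc <- (iz - 1) * h
    rho <- capsule_rho_slice(zc, z_cap1, z_cap2, r2d2)
    inside <- rho <= R
    slice <- matrix(ints[["background"]], ny, nx)
    slice[rho <= R + spec$tissue_margin_um] <- ints[["surroundings"]]
    slice[inside] <- ints[["ecm"]]
    slice[inside & rho > R - rim_um] <- ints[["rim"]]
    vol[iz, , ] <- as.integer(slice)
    cart[iz, , ] <- inside
    zone_of_z[iz] <- if (zc < zb1) "epiphysis_proximal"
      else if (zc > zb2) "epiphysis_distal" else "diaphysis"
    zone_slice_counts[zone_of_z[iz]] <-
      zone_slice_counts[zone_of_z[iz]] + sum(inside)
  }
  voxel_mm3 <- (h * 1e-3)^3
  zone_volumes_mm3 <- zone_slice_counts * voxel_mm3
  element_volume_mm3 <- sum(zone_volumes_mm3)

  axes <- spec$nucleus_semi_axes_um
  a_max <- max(axes)
  min_sep <- 1.5 * a_max
  dens <- c(epiphysis_proximal = spec$density_epiphysis,
            diaphysis = spec$density_diaphysis,
            epiphysis_distal = spec$density_epiphysis)

  zones <- names(zone_volumes_mm3)
  draw_counts <- setNames(integer(3L), zones)
  for (zn in zones)
    draw_counts[zn] <- rpois(1L, dens[[zn]] * zone_volumes_mm3[[zn]])

  n_total <- sum(draw_counts)
  centers <- matrix(numeric(0), 0L, 3L)
  orients <- matrix(numeric(0), 0L, 3L)
  zone_of_cell <- character(0)

  if (n_total > 0L) {
    # candidate voxels per zone (for uniform placement inside the capsule)
    cart_idx <- which(cart)
    ai <- arrayInd(cart_idx, dim(cart))
    vz <- (ai[, 1L] - 1) * h
    cand_zone <- ifelse(vz < zb1, "epiphysis_proximal",
                        ifelse(vz > zb2, "epiphysis_distal", "diaphysis"))
    centers <- matrix(NA_real_, n_total, 3L)
    orients <- matrix(NA_real_, n_total, 3L)
    zone_of_cell <- character(n_total)
    k <- 0L
    for (zn in zones) {
      pool <- cart_idx[cand_zone == zn]
      pool_ai <- ai[cand_zone == zn, , drop = FALSE]
      n_zone <- draw_counts[[zn]]
      if (n_zone == 0L || length(pool) == 0L) next
      placed <- 0L
      attempts <- 0L
      max_attempts <- 1e4 * n_zone
      while (placed < n_zone) {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop("packing error: could not place ", n_zone,
               " nuclei in zone ", zn)
        j <- sample.int(length(pool), 1L)
        ctr <- (pool_ai[j, ] - 1) * h + runif(3L, -h / 2, h / 2)
        # zone membership of the jittered centre
        czone <- if (ctr[1L] < zb1) "epiphysis_proximal"
          else if (ctr[1L] > zb2) "epiphysis_distal" else "diaphysis"
        if (czone != zn) next
        rho <- capsule_rho(ctr, z_cap1, z_cap2, yc, xc)
        if (rho > R) next
        # orientation by the zonal model
        depth <- R - rho
        if (zn == "diaphysis") {
          v <- c(1, 0, 0)
        } else if (depth <= spec$superficial_depth_um) {
          nvec <- surface_normal(ctr, z_cap1, z_cap2, yc, xc, rho)
          r3 <- rnorm(3L)
          tv <- r3 - sum(r3 * nvec) * nvec
          nt <- sqrt(sum(tv^2))
          if (nt < 1e-8) next
          v <- tv / nt
        } else {
          r3 <- rnorm(3L)
          v <- r3 / sqrt(sum(r3^2))
        }
        # containment: ellipsoid (plus half a voxel) inside the rim-free core
        B <- basis_from_axis(v)
        nvec <- surface_normal(ctr, z_cap1, z_cap2, yc, xc, rho)
        ext_n <- sqrt(sum((axes * as.numeric(crossprod(B, nvec)))^2))
        if (rho > R - rim_um - ext_n - 0.5 * h) next
        # hard-core separation against all accepted centres
        if (k + placed > 0L) {
          prev <- centers[seq_len(k + placed), , drop = FALSE]
          d2 <- (prev[, 1L] - ctr[1L])^2 + (prev[, 2L] - ctr[2L])^2 +
                (prev[, 3L] - ctr[3L])^2
          if (any(d2 < min_sep^2)) next
        }
        placed <- placed + 1L
        centers[k + placed, ] <- ctr
        orients[k + placed, ] <- v
        zone_of_cell[k + placed] <- zn
      }
      k <- k + placed
    }
    # paint nuclei
    box_r <- ceiling((a_max + h) / h)
    for (i in seq_len(n_total)) {
      ctr <- centers[i, ]
      B <- basis_from_axis(orients[i, ])
      ci <- round(ctr / h) + 1
      zr <- max(1L, ci[1L] - box_r):min(nz, ci[1L] + box_r)
      yr <- max(1L, ci[2L] - box_r):min(ny, ci[2L] + box_r)
      xr <- max(1L, ci[3L] - box_r):min(nx, ci[3L] + box_r)
      g <- expand.grid(z = zr, y = yr, x = xr)
      d <- cbind((g$z - 1) * h - ctr[1L], (g$y - 1) * h - ctr[2L],
                 (g$x - 1) * h - ctr[3L])
      u <- d %*% B
      inside <- (u[, 1L] / axes[1L])^2 + (u[, 2L] / axes[2L])^2 +
                (u[, 3L] / axes[3L])^2 <= 1
      if (any(inside)) {
        lin <- g$z[inside] + nz * ((g$y[inside] - 1) + ny * (g$x[inside] - 1))
        vol[lin] <- as.integer(ints[["nucleus"]])
      }
    }
  }

  # PSF blur and noise
  out <- as.numeric(vol)
  if (spec$psf_sigma_voxels > 0)
    out <- cq_gauss3d(out, dim(vol), spec$psf_sigma_voxels)
  if (spec$noise_sigma > 0)
    out <- out + rnorm(length(out), sd = spec$noise_sigma)
  out <- as.integer(pmin(255, pmax(0, round(out))))
  vol <- array(out, dim = c(nz, ny, nx))

  zone_counts <- setNames(integer(3L), zones)
  for (zn in zones) zone_counts[zn] <- sum(zone_of_cell == zn)
  truth <- structure(list(
    centers_um = centers,
    orientations = orients,
    zone_of_cell = zone_of_cell,
    cartilage_mask = new_mask(cart, h),
    zone_counts = zone_counts,
    zone_volumes_mm3 = zone_volumes_mm3,
    zone_densities = ifelse(zone_volumes_mm3 > 0,
                            zone_counts / zone_volumes_mm3, 0),
    element_volume_mm3 = element_volume_mm3,
    zone_boundaries_slice = c(z1 = zb1 / h, z2 = zb2 / h),
    spec = spec), class = "cq_phantom_truth")
  list(volume = new_volume(vol, h, 8L), truth = truth)
}

capsule_rho <- function(p, z_cap1, z_cap2, yc, xc) {
  dz <- if (p[1L] < z_cap1) z_cap1 - p[1L]
        else if (p[1L] > z_cap2) p[1L] - z_cap2 else 0
  sqrt(dz^2 + (p[2L] - yc)^2 + (p[3L] - xc)^2)
}

# outward unit normal of the capsule surface nearest to interior point p
surface_normal <- function(p, z_cap1, z_cap2, yc, xc, rho) {
  ax <- c(min(max(p[1L], z_cap1), z_cap2), yc, xc)
  d <- p - ax
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9) return(c(0, 1, 0))
  d / nd
}

#' @export
print.cq_phantom_truth <- function(x, ...) {
  cat(sprintf("<cq_phantom_truth> %d nuclei, element %.5f mm^3\n",
              nrow(x$centers_um), x$element_volume_mm3))
  for (zn in names(x$zone_counts))
    cat(sprintf("  %-19s n = %4d  density = %8.0f cells/mm^3\n", zn,
                x$zone_counts[[zn]], x$zone_densities[[zn]]))
  invisible(x)
}

#' Summarise phantom ground truth as a JSON-ready list
#'
#' @param truth a `cq_phantom_truth`.
#' @param path optional path; when given, the summary is written as JSON.
#' @return The summary list, invisibly when `path` is given.
#' @export
truth_report <- function(truth, path = NULL) {
  stopifnot(inherits(truth, "cq_phantom_truth"))
  n <- nrow(truth$centers_um)
  # orientation statistic: mean absolute angle to the element axis, per zone
  ax_angle <- if (n > 0)
    acos(pmin(1, abs(truth$orientations[, 1L]))) * 180 / pi else numeric(0)
  orient_stats <- lapply(names(truth$zone_counts), function(zn) {
    sel <- truth$zone_of_cell == zn
    list(zone = zn,
         mean_axis_angle_deg = if (any(sel)) mean(ax_angle[sel]) else NA)
  })
  rep <- list(
    n_cells = n,
    element_volume_mm3 = truth$element_volume_mm3,
    overall_density_cells_per_mm3 =
      if (truth$element_volume_mm3 > 0) n / truth$element_volume_mm3 else 0,
    zone_counts = as.list(truth$zone_counts),
    zone_volumes_mm3 = as.list(truth$zone_volumes_mm3),
    zone_densities_cells_per_mm3 = as.list(truth$zone_densities),
    zone_boundaries_slice = as.list(truth$zone_boundaries_slice),
    orientation = orient_stats)
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}
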