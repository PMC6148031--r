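#' Per-slice area profile of nuclei and extracellular matrix
#'
#' For each z slice of the segmented element, computes the area of cell
#' nuclei (counting only voxels of blobs that survived the minimum-size
#' filter, so the profile is consistent with the cell counts), the area
#' of the ECM class, their ratio (defined only where ECM area is
#' positive), plus helper columns used by zonation: cartilage area and
#' the number of surviving blobs intersecting the slice.
#'
#' @param classmap a [kmeans_classify()] result (class 1 = ECM).
#' @param labels the restored blob [new_labels()] volume.
#' @param table the size-filtered [blob_metrics()] table.
#' @param voxel_size_um voxel size; defaults to the classmap's.
#' @param cartilage_mask optional [new_mask()] of the element; when
#'   missing, the non-background classes define the element extent.
#' @return A data frame of class `cq_zone_profile`: `z` (0-based slice),
#'   `nuclei_area_um2`, `ecm_area_um2`, `ratio`, `cartilage_area_um2`,
#'   `cells_intersecting`, `cell_density_per_mm3`.
#' @export
per_slice_profile <- function(classmap, labels, table, voxel_size_um = NULL,
                              cartilage_mask = NULL) {
  stopifnot(inherits(classmap, "cq_classmap"), inherits(labels, "cq_labels"))
  h <- if (is.null(voxel_size_um)) classmap$voxel_size_um else voxel_size_um
  d <- dim(classmap$data)
  nz <- d[1L]
  keep_ids <- table$blob_id
  surv <- array(labels$data %in% keep_ids & labels$data > 0L, dim = d)
  nuc_vox <- rowSums(surv, dims = 1L)
  ecm_vox <- rowSums(classmap$data == 1L, dims = 1L)
  cart_vox <- if (!is.null(cartilage_mask))
    rowSums(cartilage_mask$data, dims = 1L)
  else rowSums(classmap$data > 0L, dims = 1L)
  # distinct surviving blobs intersecting each slice
  idx <- which(surv)
  cells <- integer(nz)
  if (length(idx)) {
    z_of <- ((idx - 1L) %% nz) + 1L
    lab_of <- labels$data[idx]
    key <- unique(z_of + nz * (lab_of - 1L))
    cells <- tabulate(((key - 1L) %% nz) + 1L, nbins = nz)
  }
  present <- cart_vox > 0L
  dens <- ifelse(cart_vox > 0L, cells / (cart_vox * h^3 * 1e-9), NA_real_)
  out <- data.frame(z = which(present) - 1L,
                    nuclei_area_um2 = nuc_vox[present] * h^2,
                    ecm_area_um2 = ecm_vox[present] * h^2,
                    ratio = ifelse(ecm_vox[present] > 0,
                                   nuc_vox[present] / ecm_vox[present],
                                   NA_real_),
                    cartilage_area_um2 = cart_vox[present] * h^2,
                    cells_intersecting = cells[present],
                    cell_density_per_mm3 = dens[present])
  structure(out, class = c("cq_zone_profile", "data.frame"),
            voxel_size_um = h)
}

#' Fit a second-order polynomial to the nuclei/ECM area ratio
#'
#' Ordinary least squares of `ratio ~ a z^2 + b z + c` over slices with a
#' defined ratio.  The vertex (`-b / 2a`) of a convex fit sits in the
#' centre of the diaphysis, where the relative nucleus content is lowest.
#'
#' @param profile a [per_slice_profile()] data frame (or any data frame
#'   with columns `z` and `ratio`).
#' @return A list of class `cq_parabola`: `a`, `b`, `c`, `vertex_z`
#'   (NA when `a = 0`), `convex` (`a > 0`), `n_points`.
#' @export
fit_parabola <- function(profile) {
  ok <- is.finite(profile$ratio)
  if (sum(ok) < 3L) stop("fit error: fewer than 3 slices with defined ratio")
  z <- profile$z[ok]; r <- profile$ratio[ok]
  fit <- lm(r ~ z + I(z^2))
  cf <- coef(fit)
  a <- unname(cf[3L]); b <- unname(cf[2L]); c0 <- unname(cf[1L])
  if (is.na(a)) a <- 0
  # a numerically indistinguishable from zero leaves the vertex undefined
  vertex <- if (abs(a) > 1e-12) -b / (2 * a) else NA_real_
  structure(list(a = a, b = b, c = c0, vertex_z = vertex,
                 convex = is.finite(a) && a > 0, n_points = sum(ok)),
            class = "cq_parabola")
}

#' @export
print.cq_parabola <- function(x, ...) {
  cat(sprintf("<cq_parabola> ratio ~ %.3e z^2 + %.3e z + %.3e\n",
              x$a, x$b, x$c))
  cat(sprintf("  vertex z = %s, %s, n = %d\n",
              if (is.na(x$vertex_z)) "undefined"
              else sprintf("%.1f", x$vertex_z),
              if (x$convex) "convex" else "not convex", x$n_points))
  invisible(x)
}

#' Detect epiphysis-diaphysis zone boundaries from a density profile
#'
#' The per-slice cell density is smoothed with a centred moving average
#' of half-width `window`; the zone boundaries are the positions of the
#' largest magnitude of the discrete derivative, one in the proximal and
#' one in the distal half (ties resolved toward the element ends).
#' Slices whose cartilage cross-section is reduced (below
#' `min_area_frac` of the maximum, i.e. near the rounded element tips,
#' where the intersecting-cells density estimate is biased and unstable)
#' are excluded from the search, and candidate positions must carry a
#' full `window`-sized block on both sides.
#' Slices strictly between `z1` and `z2` are diaphysis, the rest
#' epiphysis.  When no change is found (maximum derivative magnitude
#' below 1e-12) the whole element is labeled diaphysis and flagged.
#'
#' @param density numeric per-slice cell density (one value per element
#'   slice, in element-slice order).
#' @param window moving-average half-width, slices.
#' @param area optional per-slice cartilage areas for the eligibility
#'   rule.
#' @param min_area_frac minimum area fraction for eligibility.
#' @param z_offset 0-based slice index of the first profile entry, so the
#'   returned boundaries are absolute slice indices.
#' @return A list of class `cq_zones`: `z1`, `z2` (absolute slice
#'   indices), `detected` flag, `smoothed` density.
#' @export
detect_zones <- function(density, window = 10L, area = NULL,
                         min_area_frac = 0.9, z_offset = 0L) {
  n <- length(density)
  if (n < 5L * window)
    stop("element must span at least 5 x window slices")
  density[!is.finite(density)] <- 0
  w <- as.integer(window)
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    mean(density[lo:hi])
  }, 0)
  eligible <- rep(TRUE, n)
  if (!is.null(area)) eligible <- area >= min_area_frac * max(area)
  el_idx <- which(eligible)
  lo <- min(el_idx); hi <- max(el_idx)
  # step statistic on the eligible range only: difference of the mean
  # density over the w slices right and left of each inter-slice position
  # (the boxcar derivative; a single-sample difference of the moving
  # average would be dominated by Poisson noise in the per-slice counts,
  # and blocks must not reach into the unstable element tips)
  x <- density[lo:hi]
  m <- length(x)
  cs <- c(0, cumsum(x))
  dv_local <- vapply(seq_len(m - 1L), function(i) {
    lw <- min(w, i); rw <- min(w, m - i)
    (cs[i + rw + 1L] - cs[i + 1L]) / rw - (cs[i + 1L] - cs[i - lw + 1L]) / lw
  }, 0)
  dv <- rep(0, n - 1L)
  dv[(lo:(hi - 1L))] <- dv_local      # dv[i] sits between slices i and i+1
  mid <- (lo + hi) %/% 2L
  pick <- function(cand, toward_end) {
    cand <- cand[cand >= 1L & cand <= length(dv)]
    if (!length(cand)) return(NA_integer_)
    mag <- abs(dv[cand])
    best <- which(mag == max(mag))
    i <- if (toward_end == "low") best[1L] else best[length(best)]
    cand[i]
  }
  c_lo <- min(lo + w - 1L, mid); c_hi <- max(hi - w, mid + 1L)
  i1 <- pick(c_lo:mid, "low")
  i2 <- pick((mid + 1L):c_hi, "high")
  detected <- !is.na(i1) && !is.na(i2) &&
    max(abs(dv[i1]), abs(dv[i2])) > 1e-12
  if (!detected) {
    return(structure(list(z1 = NA_integer_, z2 = NA_integer_,
                          detected = FALSE, smoothed = sm),
                     class = "cq_zones"))
  }
  structure(list(z1 = i1 - 1L + z_offset, z2 = i2 - 1L + z_offset,
                 detected = TRUE, smoothed = sm),
            class = "cq_zones")
}

#' @export
print.cq_zones <- function(x, ...) {
  if (x$detected)
    cat(sprintf("<cq_zones> boundaries at slices z1 = %d, z2 = %d\n",
                x$z1, x$z2))
  else
    cat("<cq_zones> zonation not detected; whole element diaphysis\n")
  invisible(x)
}

zone_of_slice <- function(z, zones) {
  if (!zones$detected) return(rep("diaphysis", length(z)))
  ifelse(z <= zones$z1, "epiphysis_proximal",
         ifelse(z >= zones$z2, "epiphysis_distal", "diaphysis"))
}

#' Element-level quantification
#'
#' Computes cell number, element volume (cartilage-mask voxels times the
#' voxel volume), overall density, average cell size (element volume
#' divided by cell number) and the per-zone breakdown, with cells
#' assigned to zones by their centroid slice.
#'
#' @param mask the element [new_mask()].
#' @param table the size-filtered [blob_metrics()] table.
#' @param zones a [detect_zones()] result (the no-zonation flag yields a
#'   whole-element diaphysis).
#' @param voxel_size_um voxel size; defaults to the mask's.
#' @return A list of class `cq_summary`: `cell_number`,
#'   `element_volume_mm3`, `density_cells_per_mm3`,
#'   `average_cell_size_um3` (NA for zero cells), and `zones`, a data
#'   frame with `zone`, `volume_mm3`, `cell_number`, `density`.
#' @export
summarize_element <- function(mask, table, zones, voxel_size_um = NULL) {
  stopifnot(inherits(mask, "cq_mask"))
  h <- if (is.null(voxel_size_um)) mask$voxel_size_um else voxel_size_um
  voxel_mm3 <- (h * 1e-3)^3
  slice_vox <- rowSums(mask$data, dims = 1L)
  nzall <- length(slice_vox)
  zlab <- zone_of_slice(seq_len(nzall) - 1L, zones)
  zone_names <- c("epiphysis_proximal", "diaphysis", "epiphysis_distal")
  zvol <- vapply(zone_names, function(zn)
    sum(slice_vox[zlab == zn]) * voxel_mm3, 0)
  cell_slice <- round(table$centroid_z_um / h)
  czone <- zone_of_slice(cell_slice, zones)
  zcount <- vapply(zone_names, function(zn) sum(czone == zn), 0L)
  total_vol <- sum(zvol)
  n_cells <- nrow(table)
  structure(list(
    cell_number = n_cells,
    element_volume_mm3 = total_vol,
    density_cells_per_mm3 = if (total_vol > 0) n_cells / total_vol else 0,
    average_cell_size_um3 = if (n_cells > 0) total_vol * 1e9 / n_cells
                            else NA_real_,
    zones = data.frame(zone = zone_names, volume_mm3 = unname(zvol),
                       cell_number = unname(zcount),
                       density = ifelse(zvol > 0, zcount / zvol, 0)),
    zonation_detected = zones$detected),
    class = "cq_summary")
}

#' @export
print.cq_summary <- function(x, ...) {
  cat(sprintf("<cq_summary> %d cells in %.5f mm^3 -> %.0f cells/mm^3\n",
              x$cell_number, x$element_volume_mm3, x$density_cells_per_mm3))
  cat(sprintf("  average cell size %.0f um^3 (element volume / count)\n",
              x$average_cell_size_um3))
  print(x$zones, row.names = FALSE)
  invisible(x)
}
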