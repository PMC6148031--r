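#' Reference plane for deviation angles
#'
#' Named planes follow the (z, y, x) axis order: plane `"xy"` has unit
#' normal along z, `"yz"` along x, `"zx"` along y.  An explicit unit
#' normal `(z, y, x)` may be given instead.
#'
#' @param plane `"xy"`, `"yz"`, `"zx"`, or a length-3 unit normal.
#' @return A list of class `cq_plane` with the unit `normal`.
#' @export
reference_plane <- function(plane = "xy") {
  if (is.character(plane)) {
    normal <- switch(match.arg(plane, c("xy", "yz", "zx")),
                     xy = c(1, 0, 0),   # z normal
                     yz = c(0, 0, 1),   # x normal
                     zx = c(0, 1, 0))   # y normal
    name <- plane
  } else {
    normal <- as.numeric(plane)
    if (length(normal) != 3L || abs(sqrt(sum(normal^2)) - 1) > 1e-6)
      stop("parameter error: normal must be a unit 3-vector")
    name <- "custom"
  }
  structure(list(name = name, normal = normal), class = "cq_plane")
}

#' Deviation angle between an orientation and a reference plane
#'
#' `90 - acos(|orientation . normal|)` in degrees: 0 when the vector lies
#' in the plane, 90 when it is along the plane normal.  Invariant to the
#' sign of the orientation.
#'
#' @param orientation unit 3-vector `(z, y, x)`.
#' @param plane a [reference_plane()] (or an argument accepted by it).
#' @return Angle in degrees, in `[0, 90]`.
#' @export
deviation_angle <- function(orientation, plane = "xy") {
  if (!inherits(plane, "cq_plane")) plane <- reference_plane(plane)
  orientation <- as.numeric(orientation)
  if (length(orientation) != 3L ||
      abs(sqrt(sum(orientation^2)) - 1) > 1e-6)
    stop("parameter error: orientation must be a unit 3-vector")
  d <- min(1, abs(sum(orientation * plane$normal)))
  90 - acos(d) * 180 / pi
}

# surface voxels: mask voxels with at least one 6-neighbour outside the
# mask (voxels beyond the volume border count as outside)
surface_voxels <- function(mask) {
  m <- mask$data
  d <- dim(m)
  shift <- function(arr, ax, by) {
    n <- d[ax]
    idx <- seq_len(n) + by
    pad <- idx < 1L | idx > n
    idx[pad] <- 1L
    out <- switch(ax, arr[idx, , , drop = FALSE],
                  arr[, idx, , drop = FALSE], arr[, , idx, drop = FALSE])
    if (any(pad)) {
      switch(ax,
             out[pad, , ] <- FALSE,
             out[, pad, ] <- FALSE,
             out[, , pad] <- FALSE)
    }
    out
  }
  interior <- m
  for (ax in 1:3) for (by in c(-1L, 1L))
    interior <- interior & shift(m, ax, by)
  which(m & !interior)
}

#' Local tangent plane of the cartilage surface
#'
#' Least-squares plane through the surface voxels (mask boundary voxels)
#' lying within `patch_radius_um` of the surface point nearest to
#' `point_um`; returns the unit plane normal with its sign toward the
#' mask exterior.
#'
#' @param mask the element [new_mask()].
#' @param point_um query point `(z, y, x)` in micrometres.
#' @param patch_radius_um patch radius around the nearest surface voxel.
#' @return Unit normal 3-vector `(z, y, x)`.
#' @export
local_surface_tangent <- function(mask, point_um, patch_radius_um = 10) {
  stopifnot(inherits(mask, "cq_mask"))
  h <- mask$voxel_size_um
  sv <- surface_voxels(mask)
  if (!length(sv)) stop("degenerate-surface error: mask has no surface")
  co <- (arrayInd(sv, dim(mask$data)) - 1) * h
  nn <- cq_nearest(matrix(point_um, 1L), co)
  p0 <- co[nn$index[1L], ]
  d2 <- (co[, 1L] - p0[1L])^2 + (co[, 2L] - p0[2L])^2 + (co[, 3L] - p0[3L])^2
  patch <- co[d2 <= patch_radius_um^2, , drop = FALSE]
  if (nrow(patch) < 3L)
    stop("degenerate-surface error: fewer than 3 surface voxels in patch")
  ctr <- colMeans(patch)
  C <- crossprod(sweep(patch, 2L, ctr)) / nrow(patch)
  e <- eigen(C, symmetric = TRUE)
  normal <- e$vectors[, 3L]
  if (e$values[2L] < 1e-12)
    stop("degenerate-surface error: patch is collinear")
  # orient toward the exterior: step one voxel along the normal and test
  probe <- round((ctr + normal * h) / h) + 1
  d <- dim(mask$data)
  inside_grid <- all(probe >= 1) && all(probe <= d)
  if (inside_grid && mask$data[probe[1L], probe[2L], probe[3L]])
    normal <- -normal
  normal
}

#' Per-cell polarity records and aggregates
#'
#' For each blob: the deviation angle of its principal orientation from
#' the reference plane, a polarized flag (elongation at or above
#' `elongation_min`; deviation angles of non-polarized cells are
#' unreliable because their principal axis is ill-conditioned), the
#' distance from the centroid to the nearest cartilage-surface voxel,
#' and, for superficial cells (surface distance at most
#' `superficial_max_um`), the angle between the orientation and the local
#' surface tangent plane.
#'
#' @param table a [blob_metrics()] table with orientations.
#' @param mask the element segmentation [new_mask()].
#' @param plane a [reference_plane()] or its argument.
#' @param elongation_min polarized-cell elongation threshold.
#' @param superficial_max_um superficial-cell depth threshold.
#' @param patch_radius_um tangent-plane patch radius.
#' @param zones optional [detect_zones()] result for per-zone aggregates.
#' @return A list of class `cq_polarity`: `records` (data frame) and
#'   `aggregates` (per-slice mean deviation among polarized cells,
#'   fraction polarized per zone, mean surface alignment among
#'   superficial cells).
#' @export
polarity_map <- function(table, mask, plane = "xy", elongation_min = 1.2,
                         superficial_max_um = 15, patch_radius_um = 10,
                         zones = NULL) {
  stopifnot(inherits(mask, "cq_mask"))
  if (!inherits(plane, "cq_plane")) plane <- reference_plane(plane)
  h <- mask$voxel_size_um
  n <- nrow(table)
  if (n == 0L) {
    rec <- data.frame(blob_id = integer(0), deviation_deg = numeric(0),
                      is_polarized = logical(0),
                      surface_distance_um = numeric(0),
                      surface_alignment_deg = numeric(0))
    return(structure(list(records = rec,
                          aggregates = list(fraction_polarized = NA_real_,
                                            mean_surface_alignment_deg = NA_real_,
                                            per_slice = data.frame())),
                     class = "cq_polarity"))
  }
  ori <- as.matrix(table[, c("orient_z", "orient_y", "orient_x")])
  dev <- 90 - acos(pmin(1, abs(ori %*% plane$normal))) * 180 / pi
  polarized <- is.infinite(table$elongation) |
    table$elongation >= elongation_min
  sv <- surface_voxels(mask)
  co <- (arrayInd(sv, dim(mask$data)) - 1) * h
  cent <- as.matrix(table[, c("centroid_z_um", "centroid_y_um",
                              "centroid_x_um")])
  nn <- cq_nearest(cent, co)
  sdist <- nn$distance
  align <- rep(NA_real_, n)
  superficial <- sdist <= superficial_max_um
  for (i in which(superficial)) {
    p0 <- co[nn$index[i], ]
    d2 <- (co[, 1L] - p0[1L])^2 + (co[, 2L] - p0[2L])^2 +
          (co[, 3L] - p0[3L])^2
    patch <- co[d2 <= patch_radius_um^2, , drop = FALSE]
    if (nrow(patch) < 3L) next
    ctr <- colMeans(patch)
    C <- crossprod(sweep(patch, 2L, ctr)) / nrow(patch)
    e <- eigen(C, symmetric = TRUE)
    if (e$values[2L] < 1e-12) next
    nrm <- e$vectors[, 3L]
    # alignment with the tangent plane = deviation from the plane whose
    # normal is the surface normal
    align[i] <- 90 - acos(min(1, abs(sum(ori[i, ] * nrm)))) * 180 / pi
  }
  rec <- data.frame(blob_id = table$blob_id,
                    deviation_deg = as.numeric(dev),
                    is_polarized = polarized,
                    elongation = table$elongation,
                    surface_distance_um = sdist,
                    surface_alignment_deg = align,
                    centroid_slice = round(table$centroid_z_um / h))
  per_slice <- if (any(polarized)) {
    sl <- rec$centroid_slice[polarized]
    data.frame(slice = sort(unique(sl)),
               mean_deviation_deg = vapply(sort(unique(sl)), function(s)
                 mean(rec$deviation_deg[polarized][sl == s]), 0),
               n = vapply(sort(unique(sl)), function(s) sum(sl == s), 0L))
  } else data.frame()
  agg <- list(
    fraction_polarized = mean(polarized),
    mean_deviation_polarized_deg =
      if (any(polarized)) mean(rec$deviation_deg[polarized]) else NA_real_,
    mean_surface_alignment_deg =
      if (any(is.finite(align))) mean(align, na.rm = TRUE) else NA_real_,
    n_superficial = sum(superficial),
    per_slice = per_slice)
  if (!is.null(zones)) {
    zl <- zone_of_slice(rec$centroid_slice, zones)
    agg$fraction_polarized_by_zone <- vapply(
      c("epiphysis_proximal", "diaphysis", "epiphysis_distal"),
      function(zn) if (any(zl == zn)) mean(polarized[zl == zn]) else NA_real_,
      0)
  }
  structure(list(records = rec, aggregates = agg, plane = plane),
            class = "cq_polarity")
}

#' @export
print.cq_polarity <- function(x, ...) {
  cat(sprintf("<cq_polarity> %d cells, %.0f%% polarized\n",
              nrow(x$records), 100 * x$aggregates$fraction_polarized))
  if (is.finite(x$aggregates$mean_surface_alignment_deg))
    cat(sprintf("  mean superficial surface alignment %.1f deg (n = %d)\n",
                x$aggregates$mean_surface_alignment_deg,
                x$aggregates$n_superficial))
  invisible(x)
}
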