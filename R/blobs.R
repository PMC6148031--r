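#' Blob-analysis parameters
#'
#' Defaults implement the published counting rule: one erosion with the
#' 3x3x3 cube, 26-connectivity labeling, and a minimum blob size of
#' 27 voxels (the "3 pixels" linear minimum cubed, applied inclusively).
#'
#' @param erosion_se `"cube3"` (3x3x3 cube) or `"cross3"`
#'   (6-neighbourhood cross).
#' @param erosion_iterations number of erosion passes.
#' @param connectivity 6, 18 or 26.
#' @param min_voxels minimum voxel count for a blob to count as a cell.
#' @return A list of class `cq_blob_params`.
#' @export
blob_params <- function(erosion_se = c("cube3", "cross3"),
                        erosion_iterations = 1L, connectivity = 26L,
                        min_voxels = 27L) {
  erosion_se <- match.arg(erosion_se)
  if (erosion_iterations < 0L) stop("erosion_iterations must be >= 0")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  if (min_voxels < 1L) stop("min_voxels must be >= 1")
  structure(list(erosion_se = erosion_se,
                 erosion_iterations = as.integer(erosion_iterations),
                 connectivity = as.integer(connectivity),
                 min_voxels = as.integer(min_voxels)),
            class = "cq_blob_params")
}

#' Binary erosion of a mask
#'
#' A voxel is kept iff the structuring element centred there fits
#' entirely inside the mask; voxels beyond the volume border count as
#' background.  Erosion splits touching nuclei at thin necks and deletes
#' the thin bright border rim of the cartilage, which must not be counted.
#'
#' @param mask a [new_mask()].
#' @param params a [blob_params()] (uses `erosion_se` and
#'   `erosion_iterations`).
#' @return The eroded mask.
#' @export
erode_mask <- function(mask, params = blob_params()) {
  stopifnot(inherits(mask, "cq_mask"))
  d <- dim(mask$data)
  out <- cq_erode(as.integer(mask$data), d, params$erosion_se,
                  params$erosion_iterations)
  new_mask(array(out != 0L, dim = d), mask$voxel_size_um)
}

#' Binary dilation of a mask
#'
#' Dual of [erode_mask()]: a voxel is set iff the structuring element
#' centred there hits the mask.  Used by the pipeline to pad the
#' segmentation outward by the thickness of the bright border of the
#' cartilaginous element, so that the border lies inside the mask (as in
#' the published segmentation, whose erosion step then removes it).
#'
#' @param mask a [new_mask()].
#' @param iterations number of dilation passes.
#' @param se `"cube3"` or `"cross3"`.
#' @return The dilated mask.
#' @export
dilate_mask <- function(mask, iterations = 1L, se = c("cube3", "cross3")) {
  stopifnot(inherits(mask, "cq_mask"))
  se <- match.arg(se)
  d <- dim(mask$data)
  out <- cq_dilate(as.integer(mask$data), d, se, as.integer(iterations))
  new_mask(array(out != 0L, dim = d), mask$voxel_size_um)
}

#' Connected-component labeling
#'
#' Maximal connected components under the chosen connectivity; ids `1..N`
#' are assigned in order of each component's first-encountered voxel in
#' (z, y, x) scan order (z fastest).
#'
#' @param mask a [new_mask()].
#' @param connectivity 6, 18 or 26.
#' @return A [new_labels()] volume.
#' @export
label_blobs <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "cq_mask"))
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  d <- dim(mask$data)
  lab <- cq_label(as.integer(mask$data), d, as.integer(connectivity))
  new_labels(array(lab, dim = d), mask$voxel_size_um)
}

#' Erosion-based splitting with geodesic restore
#'
#' Erodes the mask, labels the surviving cores, then grows each core
#' label back over the original mask by a mask-constrained breadth-first
#' dilation.  Components that vanish entirely under erosion (thin
#' structures such as the bright border rim) are never restored and drop
#' out; touching nuclei whose erosion cores separate are restored as two
#' blobs split along the BFS watershed.  Blob voxel counts therefore
#' refer to the full (pre-erosion) nucleus extents.
#'
#' @param mask a [new_mask()] (e.g. the nucleus-class binary).
#' @param params a [blob_params()].
#' @return A [new_labels()] volume of restored blobs.
#' @export
split_blobs <- function(mask, params = blob_params()) {
  stopifnot(inherits(mask, "cq_mask"))
  d <- dim(mask$data)
  if (params$erosion_iterations == 0L)
    return(label_blobs(mask, params$connectivity))
  eroded <- cq_erode(as.integer(mask$data), d, params$erosion_se,
                     params$erosion_iterations)
  markers <- cq_label(eroded, d, params$connectivity)
  restored <- cq_restore_labels(markers, as.integer(mask$data), d,
                                params$connectivity)
  new_labels(array(restored, dim = d), mask$voxel_size_um)
}

#' Per-blob shape metrics
#'
#' Computes, for every labeled blob, the voxel count, physical volume,
#' centroid, second-central-moment eigenvalues/eigenvectors, elongation
#' `sqrt(lambda1/lambda2)` and the principal orientation (unit eigenvector
#' of the largest eigenvalue, sign fixed to non-negative z, then y, then x
#' component).  Moments are computed from voxel centres in micrometres
#' (voxel `(iz, iy, ix)` sits at `(iz, iy, ix) * voxel_size`).  Blobs with
#' `lambda2 = 0` (lines, single voxels) get infinite elongation.
#'
#' @param labels a [new_labels()] volume.
#' @param voxel_size_um voxel size; defaults to the labels' own.
#' @return A data frame of class `cq_blobs`, one row per blob: `blob_id`,
#'   `voxel_count`, `volume_um3`, `centroid_{z,y,x}_um`,
#'   `lambda{1,2,3}_um2`, orientation `orient_{z,y,x}`, `elongation`.
#' @export
blob_metrics <- function(labels, voxel_size_um = NULL) {
  stopifnot(inherits(labels, "cq_labels"))
  h <- if (is.null(voxel_size_um)) labels$voxel_size_um else voxel_size_um
  n <- max(labels$data)
  empty <- data.frame(blob_id = integer(0), voxel_count = integer(0),
                      volume_um3 = numeric(0), centroid_z_um = numeric(0),
                      centroid_y_um = numeric(0), centroid_x_um = numeric(0),
                      lambda1_um2 = numeric(0), lambda2_um2 = numeric(0),
                      lambda3_um2 = numeric(0), orient_z = numeric(0),
                      orient_y = numeric(0), orient_x = numeric(0),
                      elongation = numeric(0))
  if (n == 0L) return(structure(empty, class = c("cq_blobs", "data.frame"),
                                voxel_size_um = h))
  idx <- which(labels$data > 0L)
  lab <- labels$data[idx]
  co <- (arrayInd(idx, dim(labels$data)) - 1) * h  # (z, y, x) um
  counts <- tabulate(lab, nbins = n)
  sums <- rowsum(co, lab)
  cent <- sums / counts
  d <- co - cent[lab, , drop = FALSE]
  m <- rowsum(cbind(d[, 1L]^2, d[, 2L]^2, d[, 3L]^2,
                    d[, 1L] * d[, 2L], d[, 1L] * d[, 3L],
                    d[, 2L] * d[, 3L]), lab) / counts
  lam <- matrix(0, n, 3L)
  ori <- matrix(0, n, 3L)
  for (b in seq_len(n)) {
    C <- matrix(c(m[b, 1L], m[b, 4L], m[b, 5L],
                  m[b, 4L], m[b, 2L], m[b, 6L],
                  m[b, 5L], m[b, 6L], m[b, 3L]), 3L, 3L)
    e <- eigen(C, symmetric = TRUE)
    lam[b, ] <- pmax(e$values, 0)
    v <- e$vectors[, 1L]
    # canonical sign: non-negative z component, then y, then x
    s <- sign(v[1L])
    if (s == 0) s <- sign(v[2L])
    if (s == 0) s <- sign(v[3L])
    if (s == 0) s <- 1
    ori[b, ] <- v * s
  }
  elong <- ifelse(lam[, 2L] > 0, sqrt(lam[, 1L] / lam[, 2L]), Inf)
  structure(data.frame(blob_id = seq_len(n), voxel_count = counts,
                       volume_um3 = counts * h^3,
                       centroid_z_um = cent[, 1L], centroid_y_um = cent[, 2L],
                       centroid_x_um = cent[, 3L],
                       lambda1_um2 = lam[, 1L], lambda2_um2 = lam[, 2L],
                       lambda3_um2 = lam[, 3L],
                       orient_z = ori[, 1L], orient_y = ori[, 2L],
                       orient_x = ori[, 3L], elongation = elong),
            class = c("cq_blobs", "data.frame"), voxel_size_um = h)
}

#' Minimum-size filter for blobs
#'
#' Keeps blobs with `voxel_count >= min_voxels`.  The default of 27
#' implements the published rule that objects counted as cells must
#' exceed 3 pixels linear size, i.e. 3^3 = 27 voxels, inclusively.
#'
#' @param table a [blob_metrics()] table.
#' @param min_voxels inclusive voxel-count threshold.
#' @return The filtered table.
#' @export
filter_blobs <- function(table, min_voxels = 27L) {
  if (min_voxels < 1L) stop("min_voxels must be >= 1")
  out <- table[table$voxel_count >= min_voxels, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(table),
            voxel_size_um = attr(table, "voxel_size_um"))
}

#' Number of detected cells
#' @param table a (filtered) blob table.
#' @return Integer count.
#' @export
count_cells <- function(table) nrow(table)
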