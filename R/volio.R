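#' Construct a grayscale volume
#'
#' A volume is a 3D array of non-negative integer intensities with
#' slices-first axis order `(nz, ny, nx)` (z = tomographic slice index,
#' 0-based in all coordinate conventions) and an isotropic voxel size in
#' micrometres.
#'
#' @param data 3D integer array, dimensions `(nz, ny, nx)`.
#' @param voxel_size_um positive isotropic voxel edge length in micrometres.
#' @param bit_depth 8 or 16; inferred from the data range when `NULL`.
#' @return An object of class `cq_volume` with elements `data`,
#'   `voxel_size_um` and `bit_depth`.
#' @export
new_volume <- function(data, voxel_size_um = 1.0, bit_depth = NULL) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array (nz, ny, nx)")
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      is.na(voxel_size_um) || voxel_size_um <= 0)
    stop("voxel_size_um must be a positive scalar")
  storage.mode(data) <- "integer"
  rng <- range(data)
  if (rng[1L] < 0L) stop("intensities must be non-negative")
  if (is.null(bit_depth)) bit_depth <- if (rng[2L] > 255L) 16L else 8L
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (rng[2L] > 2^bit_depth - 1)
    stop("intensities exceed the declared bit depth")
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um),
                 bit_depth = bit_depth),
            class = "cq_volume")
}

#' @export
print.cq_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cq_volume> %d x %d x %d voxels (z,y,x), %d-bit, voxel %.4g um\n",
              d[1L], d[2L], d[3L], x$bit_depth, x$voxel_size_um))
  cat(sprintf("  intensity range [%d, %d]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a binary mask volume
#'
#' @param data 3D logical (or 0/1) array.
#' @param voxel_size_um voxel size in micrometres.
#' @return An object of class `cq_mask`.
#' @export
new_mask <- function(data, voxel_size_um = 1.0) {
  if (length(dim(data)) != 3L) stop("mask data must be a 3D array")
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1))) stop("mask values must be exactly 0/1")
    data <- array(data != 0, dim = dim(data))
  }
  if (!is.logical(data)) stop("mask must be logical or 0/1")
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um)),
            class = "cq_mask")
}

#' @export
print.cq_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cq_mask> %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              d[1L], d[2L], d[3L], sum(x$data), 100 * mean(x$data)))
  invisible(x)
}

#' Construct a label volume
#'
#' Voxel value 0 marks background; values `1..N` identify blobs with
#' contiguous ids.
#'
#' @param data 3D integer array of labels.
#' @param voxel_size_um voxel size in micrometres.
#' @return An object of class `cq_labels`.
#' @export
new_labels <- function(data, voxel_size_um = 1.0) {
  if (length(dim(data)) != 3L) stop("label data must be a 3D array")
  storage.mode(data) <- "integer"
  if (min(data) < 0L) stop("labels must be non-negative")
  n <- max(data)
  if (n > 0L) {
    present <- sort(unique(data[data > 0L]))
    if (!identical(present, seq_len(n)))
      stop("label ids must be contiguous 1..N")
  }
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um)),
            class = "cq_labels")
}

#' @export
print.cq_labels <- function(x, ...) {
  cat(sprintf("<cq_labels> %s voxels, %d blobs\n",
              paste(dim(x$data), collapse = " x "), max(x$data)))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a multi-page grayscale TIFF stack
#'
#' Pages become z-slices of the returned volume: shape
#' `(pages, height, width)`.  The voxel size is taken from a JSON sidecar
#' (key `voxel_size_um`); when no sidecar is given, `<path>.json` is used
#' if present, else the voxel size defaults to 1 micrometre.
#'
#' @param path TIFF file path.
#' @param sidecar optional path to a JSON sidecar.
#' @return A [new_volume()] object with unmodified intensities.
#' @export
read_tiff_stack <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- vapply(pages, function(p) {
    b <- attr(p, "bits.per.sample")
    if (is.null(b)) NA_integer_ else as.integer(b[1L])
  }, integer(1L))
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1L))))
    stop("format error: non-grayscale (multi-channel) TIFF page")
  if (length(unique(bits[!is.na(bits)])) > 1L)
    stop("format error: mixed bit depth across pages")
  dims <- vapply(pages, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("format error: pages differ in size")
  nz <- length(pages); ny <- dims[1L, 1L]; nx <- dims[2L, 1L]
  arr <- array(0L, dim = c(nz, ny, nx))
  for (p in seq_len(nz)) arr[p, , ] <- as.integer(pages[[p]])
  voxel <- 1.0
  sc <- if (is.null(sidecar)) sidecar_path(path) else sidecar
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc)
    if (!is.null(meta$voxel_size_um)) voxel <- as.numeric(meta$voxel_size_um)
  } else if (!is.null(sidecar)) {
    stop("sidecar not found: ", sidecar)
  }
  bd <- bits[1L]
  if (is.na(bd)) bd <- if (max(arr) > 255L) 16L else 8L
  new_volume(arr, voxel_size_um = voxel, bit_depth = bd)
}

#' Write a volume as a multi-page grayscale TIFF stack
#'
#' Data are written bit-exactly at the volume's declared bit depth with a
#' JSON sidecar (`<path>.json`) holding the voxel size.
#'
#' @param volume a [new_volume()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(volume, path) {
  stopifnot(inherits(volume, "cq_volume"))
  maxval <- 2^volume$bit_depth - 1
  d <- dim(volume$data)
  pages <- lapply(seq_len(d[1L]), function(p)
    array(volume$data[p, , ], d[2:3]) / maxval)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = volume$bit_depth,
                            compression = "none"), silent = TRUE)
  if (inherits(ok, "try-error")) stop("I/O error writing ", path)
  jsonlite::write_json(list(voxel_size_um = volume$voxel_size_um,
                            bit_depth = volume$bit_depth,
                            shape = dim(volume$data)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a mask volume as an 8-bit TIFF (0/255)
#' @param mask a [new_mask()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "cq_mask"))
  arr <- array(ifelse(mask$data, 255L, 0L), dim = dim(mask$data))
  write_tiff_stack(new_volume(arr, mask$voxel_size_um, 8L), path)
}

#' Read a 0/255 mask TIFF back to a mask volume
#' @param path TIFF file path.
#' @param sidecar optional JSON sidecar path.
#' @return A [new_mask()] object.
#' @export
read_mask_tiff <- function(path, sidecar = NULL) {
  v <- read_tiff_stack(path, sidecar)
  new_mask(v$data != 0L, v$voxel_size_um)
}

#' Write a label volume as a 16-bit TIFF
#' @param labels a [new_labels()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels_tiff <- function(labels, path) {
  stopifnot(inherits(labels, "cq_labels"))
  if (max(labels$data) > 65535L) stop("more than 65535 labels")
  write_tiff_stack(new_volume(labels$data, labels$voxel_size_um, 16L), path)
}

#' Write tabular records as RFC-4180 CSV
#'
#' @param rows a data frame, or a list of named rows sharing one schema.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) {
    if (!is.list(rows)) stop("rows must be a data frame or list of rows")
    if (length(rows)) {
      nms <- lapply(rows, names)
      if (any(vapply(nms, function(n) !identical(n, nms[[1L]]), logical(1L))))
        stop("schema error: ragged rows")
      rows <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
    } else {
      rows <- data.frame()
    }
  }
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table()]
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_table_csv <- function(path) read.csv(path)
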