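#' Active-contour (snake) parameters
#'
#' Defaults follow the published pipeline settings: gradient threshold 30
#' and 50 iterations.  `gradient_threshold` acts as a saturation cap on
#' the external force: the edge attraction at a pixel is
#' `min(gradient_magnitude, threshold) / threshold`, so all gradients at
#' or above the threshold are equally attractive.  This reproduces the
#' reported failure mode on unfiltered data, where nucleus edges compete
#' with the cartilage border.  `edge_sigma` is a numerical choice of this
#' implementation: the saturated gradient map is Gaussian-smoothed to give
#' the discrete greedy snake a capture range of a few voxels.
#'
#' @param gradient_threshold saturation cap on gradient magnitude.
#' @param iterations number of greedy evolution rounds.
#' @param alpha continuity weight.
#' @param beta curvature weight.
#' @param search_radius greedy neighbourhood half-width, voxels.
#' @param resample_spacing target point spacing, voxels; the contour is
#'   resampled to uniform spacing every 5 iterations.
#' @param edge_sigma Gaussian smoothing sigma for the edge map, voxels.
#' @return A list of class `cq_snake_params`.
#' @export
snake_params <- function(gradient_threshold = 30, iterations = 50,
                         alpha = 1.0, beta = 1.0, search_radius = 2L,
                         resample_spacing = 2.0, edge_sigma = 2.0) {
  if (iterations < 1) stop("iterations must be >= 1")
  if (alpha < 0 || beta < 0) stop("weights must be >= 0")
  if (gradient_threshold < 0) stop("gradient_threshold must be >= 0")
  if (search_radius < 1) stop("search_radius must be >= 1")
  structure(list(gradient_threshold = gradient_threshold,
                 iterations = as.integer(iterations),
                 alpha = alpha, beta = beta,
                 search_radius = as.integer(search_radius),
                 resample_spacing = resample_spacing,
                 edge_sigma = edge_sigma),
            class = "cq_snake_params")
}

#' Gradient magnitude of a 2D slice
#'
#' Central differences in the interior (`I[i+1] - I[i-1]`), one-sided
#' differences at the borders; magnitude is the Euclidean norm of the two
#' components.  A clean intensity step of height `h` therefore produces
#' magnitude `h` on the columns adjacent to the step.
#'
#' @param slice_image numeric matrix `(ny, nx)`.
#' @return Matrix of gradient magnitudes, same shape.
#' @export
gradient_magnitude <- function(slice_image) {
  ny <- nrow(slice_image); nx <- ncol(slice_image)
  if (ny < 3L || nx < 3L) stop("slice must be at least 3x3")
  s <- slice_image
  gy <- s[c(2:ny, ny), ] - s[c(1, 1:(ny - 1)), ]
  gx <- s[, c(2:nx, nx)] - s[, c(1, 1:(nx - 1))]
  sqrt(gy^2 + gx^2)
}

#' Construct a contour
#'
#' @param points n x 2 matrix of `(y, x)` sub-voxel coordinates (0-based),
#'   ordered counter-clockwise around a closed simple polygon.
#' @param slice_index 0-based z index the contour belongs to.
#' @return An object of class `cq_contour`.
#' @export
new_contour <- function(points, slice_index = 0L) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("contour points must be an n x 2 matrix")
  if (nrow(points) < 8L) stop("contour must have at least 8 points")
  if (polygon_area(points) < 0) points <- points[rev(seq_len(nrow(points))), ]
  structure(list(slice_index = as.integer(slice_index), points = points),
            class = "cq_contour")
}

# signed area (shoelace); positive for counter-clockwise order in (y, x)
# with the x axis treated as abscissa
polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 2L] * p[j, 1L] - p[j, 2L] * p[, 1L]) / 2
}

resample_closed_polygon <- function(p, spacing) {
  n <- nrow(p)
  j <- c(2:n, 1)
  seg <- sqrt((p[j, 1L] - p[, 1L])^2 + (p[j, 2L] - p[, 2L])^2)
  cum <- c(0, cumsum(seg))
  L <- cum[n + 1L]
  m <- max(8L, round(L / spacing))
  t <- L * (seq_len(m) - 1L) / m
  idx <- findInterval(t, cum, rightmost.closed = TRUE)
  idx[idx > n] <- n
  f <- (t - cum[idx]) / ifelse(seg[idx] > 0, seg[idx], 1)
  cbind(p[idx, 1L] + f * (p[j, 1L][idx] - p[idx, 1L]),
        p[idx, 2L] + f * (p[j, 2L][idx] - p[idx, 2L]))
}

otsu_threshold <- function(x) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  nb <- 256L
  br <- seq(lo, hi, length.out = nb + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = nb)
  mids <- (br[-1L] + br[-(nb + 1L)]) / 2
  w <- cumsum(h); mu <- cumsum(h * mids)
  tot <- w[nb]; mu_t <- mu[nb]
  w1 <- w[-nb]; mu1 <- mu[-nb]
  between <- (mu1 * tot - mu_t * w1)^2 / (w1 * (tot - w1))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# 2D binary dilation by an L-inf ball of the given radius (max filter)
dilate2d <- function(m, radius) {
  for (r in seq_len(radius)) {
    ny <- nrow(m); nx <- ncol(m)
    up <- m[c(1, 1:(ny - 1)), ]; dn <- m[c(2:ny, ny), ]
    out <- m | up | dn
    out <- out | out[, c(1, 1:(nx - 1))] | out[, c(2:nx, nx)]
    m <- out
  }
  m
}

#' Initialise a contour on a slice
#'
#' Method `auto` exploits the fact that cartilage is weakly stained:
#' the slice is Otsu-thresholded, the largest connected below-threshold
#' region (or the one containing `seed_point`) is taken, dilated by 3
#' voxels, and its convex hull is returned, resampled at
#' `resample_spacing`.  Method `circle` places a circle of radius one
#' quarter of the smaller slice dimension around `seed_point`.  Method
#' `polygon` resamples a user polygon.
#'
#' @param slice_image numeric matrix `(ny, nx)`.
#' @param method one of `"auto"`, `"circle"`, `"polygon"`.
#' @param seed_point optional `(y, x)` point (0-based); required for
#'   `circle`, used to select the region for `auto`.
#' @param polygon n x 2 `(y, x)` matrix for method `polygon`.
#' @param slice_index 0-based z index recorded on the contour.
#' @param resample_spacing contour point spacing, voxels.
#' @return A [new_contour()].
#' @export
init_contour <- function(slice_image, method = c("auto", "circle", "polygon"),
                         seed_point = NULL, polygon = NULL, slice_index = 0L,
                         resample_spacing = 2.0) {
  method <- match.arg(method)
  ny <- nrow(slice_image); nx <- ncol(slice_image)
  if (method == "circle") {
    if (is.null(seed_point)) stop("circle method requires seed_point")
    r <- min(ny, nx) / 4
    n <- max(16L, round(2 * pi * r / resample_spacing))
    th <- 2 * pi * (seq_len(n) - 1L) / n
    pts <- cbind(seed_point[1L] + r * sin(th), seed_point[2L] + r * cos(th))
    return(new_contour(pts, slice_index))
  }
  if (method == "polygon") {
    if (is.null(polygon)) stop("polygon method requires polygon")
    return(new_contour(resample_closed_polygon(as.matrix(polygon),
                                               resample_spacing), slice_index))
  }
  thr <- otsu_threshold(slice_image)
  if (!is.null(seed_point)) {
    # the cartilage is darker than its immediate surroundings but an image
    # may contain still darker background (agarose, air): raise the
    # threshold by recursive Otsu splits until the seed is in the dark phase
    sv <- slice_image[round(seed_point[1L]) + 1L, round(seed_point[2L]) + 1L]
    tries <- 0L
    while (sv >= thr && tries < 8L) {
      upper <- slice_image[slice_image >= thr]
      if (length(unique(upper)) < 2L) break
      new_thr <- otsu_threshold(upper)
      if (new_thr <= thr) break
      thr <- new_thr
      tries <- tries + 1L
    }
  }
  below <- slice_image < thr
  if (!any(below)) stop("initialization error: no below-threshold region")
  lab <- array(cq_label(as.integer(array(below, c(1L, ny, nx))),
                        c(1L, ny, nx), 26L), dim = c(ny, nx))
  if (!is.null(seed_point)) {
    id <- lab[round(seed_point[1L]) + 1L, round(seed_point[2L]) + 1L]
    if (id == 0L) id <- which.max(tabulate(lab[lab > 0L]))
  } else {
    id <- which.max(tabulate(lab[lab > 0L]))
  }
  region <- dilate2d(lab == id, 3L)
  ij <- which(region, arr.ind = TRUE)
  pts0 <- cbind(ij[, 1L] - 1, ij[, 2L] - 1)  # (y, x), 0-based
  hull <- chull(pts0[, 2L], pts0[, 1L])      # (x, y) axes for chull
  hull_pts <- pts0[hull, , drop = FALSE]
  new_contour(resample_closed_polygon(hull_pts, resample_spacing), slice_index)
}

# saturated, smoothed edge-attraction field in [0, 1]
edge_field <- function(slice_image, params) {
  g <- gradient_magnitude(slice_image)
  f <- if (params$gradient_threshold > 0)
    pmin(g, params$gradient_threshold) / params$gradient_threshold
  else (g > 0) * 1.0
  if (params$edge_sigma > 0) {
    f <- matrix(cq_gauss3d(as.numeric(f), c(1L, nrow(f), ncol(f)),
                           params$edge_sigma), nrow(f), ncol(f))
    mx <- max(f)
    if (mx > 1e-12) f <- f / mx
  }
  f
}

#' Evolve a snake on one slice
#'
#' Greedy discrete (Williams-Shah style) evolution: for each of
#' `iterations` rounds every point may move within the
#' `(2*search_radius+1)^2` neighbourhood to strictly decrease the contour
#' energy `E = alpha * continuity + beta * curvature - edge_attraction`,
#' where the edge attraction is the saturated gradient
#' `min(gradient_magnitude, gradient_threshold) / gradient_threshold`
#' (Gaussian-smoothed, see [snake_params()]).  Moves are accepted
#' sequentially and only when they lower the total energy, so the energy
#' trace is non-increasing between resampling events.  The contour is
#' resampled to uniform spacing every 5 iterations.
#'
#' @param slice_image numeric matrix `(ny, nx)`.
#' @param init a [new_contour()] inside the slice.
#' @param params a [snake_params()].
#' @return The final contour, with attribute `trace` (per-iteration
#'   energy, point count, resample flags) and attribute `edge_support`
#'   (mean raw saturated gradient sampled at the final points).
#' @export
evolve_snake <- function(slice_image, init, params = snake_params()) {
  stopifnot(inherits(init, "cq_contour"))
  f <- edge_field(slice_image, params)
  res <- cq_snake(f, init$points, params$iterations, params$alpha,
                  params$beta, params$search_radius,
                  params$resample_spacing, 5L)
  if (isTRUE(res$collapsed))
    stop("convergence error: contour collapsed below 8 points")
  out <- new_contour(res$points, init$slice_index)
  attr(out, "trace") <- data.frame(iteration = seq_along(res$energy),
                                   energy = res$energy,
                                   n_points = res$n_points,
                                   resampled = res$resampled == 1L)
  raw <- if (params$gradient_threshold > 0)
    pmin(gradient_magnitude(slice_image), params$gradient_threshold) /
      params$gradient_threshold
  else gradient_magnitude(slice_image)
  attr(out, "edge_support") <- mean(cq_bilinear(raw, out$points))
  out
}

contour_mask <- function(contour, ny, nx) {
  cq_fill_polygon(contour$points, ny, nx)
}

#' Segment a cartilaginous element by slice-propagated snakes
#'
#' The snake is evolved on the initial slice of the *filtered* volume and
#' then propagated outward in both z directions, each slice's final
#' contour initialising the next slice.  Propagation on a side terminates
#' where the element is absent: contour area below `min_area` voxels,
#' contour collapse, or mean raw edge support along the contour below
#' `min_edge_support` (a featureless slice).  The mask is the union of
#' filled contour interiors (even-odd rule, a pixel is inside if its
#' centre is inside).
#'
#' @param volume the original volume (defines shape and voxel size).
#' @param filtered the median-filtered volume, same shape.
#' @param params a [snake_params()].
#' @param init a [new_contour()] on a middle slice (its `slice_index`).
#' @param min_area minimum contour area in voxels.
#' @param min_edge_support minimum mean saturated gradient at the contour.
#' @return A [new_mask()]; attribute `contours` holds the per-slice
#'   contours.
#' @export
segment_element <- function(volume, filtered, params = snake_params(), init,
                            min_area = 20, min_edge_support = 0.15) {
  stopifnot(inherits(volume, "cq_volume"), inherits(filtered, "cq_volume"))
  if (!identical(dim(volume$data), dim(filtered$data)))
    stop("parameter error: filtered shape differs from volume")
  d <- dim(volume$data)
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
  z0 <- init$slice_index
  if (z0 < 0L || z0 >= nz) stop("init slice outside volume")

  mask <- array(FALSE, dim = d)
  contours <- vector("list", nz)

  first <- tryCatch(
    evolve_snake(filtered$data[z0 + 1L, , ], init, params),
    error = function(e) NULL)
  if (is.null(first) || abs(polygon_area(first$points)) < min_area)
    stop("segmentation error: initial slice failed to converge")
  mask[z0 + 1L, , ] <- contour_mask(first, ny, nx)
  contours[[z0 + 1L]] <- first

  for (dir in c(1L, -1L)) {
    prev <- first
    z <- z0 + dir
    while (z >= 0L && z < nz) {
      nxt <- tryCatch(
        evolve_snake(filtered$data[z + 1L, , ],
                     new_contour(prev$points, z), params),
        error = function(e) NULL)
      if (is.null(nxt)) break
      if (abs(polygon_area(nxt$points)) < min_area) break
      if (attr(nxt, "edge_support") < min_edge_support) break
      mask[z + 1L, , ] <- contour_mask(nxt, ny, nx)
      contours[[z + 1L]] <- nxt
      prev <- nxt
      z <- z + dir
    }
  }
  out <- new_mask(mask, volume$voxel_size_um)
  attr(out, "contours") <- contours
  out
}

#' Apply a transparent-zero mask
#'
#' Voxels outside the mask are set to zero; voxels inside are copied
#' bit-exactly from the (original, unfiltered) volume.
#'
#' @param volume a [new_volume()].
#' @param mask a [new_mask()] of the same shape.
#' @return The masked volume.
#' @export
apply_mask <- function(volume, mask) {
  stopifnot(inherits(volume, "cq_volume"), inherits(mask, "cq_mask"))
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("parameter error: mask shape differs from volume")
  dat <- volume$data
  dat[!mask$data] <- 0L
  new_volume(dat, volume$voxel_size_um, volume$bit_depth)
}

#' Export contours as a data frame (slice, point index, y, x)
#' @param mask a mask returned by [segment_element()].
#' @return A data frame of contour points.
#' @export
contours_table <- function(mask) {
  cs <- attr(mask, "contours")
  if (is.null(cs)) return(data.frame(slice = integer(0), point = integer(0),
                                     y = numeric(0), x = numeric(0)))
  do.call(rbind, lapply(cs[!vapply(cs, is.null, logical(1L))], function(ct)
    data.frame(slice = ct$slice_index,
               point = seq_len(nrow(ct$points)) - 1L,
               y = ct$points[, 1L], x = ct$points[, 2L])))
}
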