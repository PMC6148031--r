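#' K-means classification parameters
#'
#' @param k number of classes; the pipeline default of 3 separates
#'   background, extracellular matrix and nuclei.
#' @param init `"optimal"` (deterministic: Lloyd started from the exact
#'   1-D contiguous-partition optimum computed by dynamic programming on
#'   the intensity histogram -- in one dimension the k-means optimum is
#'   contiguous in sorted order, so this attains the global minimum of
#'   the within-class sum of squares), `"percentile"` (deterministic:
#'   for k = 3 the 1st/50th/99th intensity percentiles), or `"random"`
#'   (seeded draw of k distinct observed intensities).  `"optimal"` is
#'   the default because on masked volumes the nucleus class holds far
#'   less mass than the ECM class and percentile-started Lloyd can settle
#'   in a local optimum that splits the ECM mode instead.
#' @param max_iter Lloyd iteration cap.
#' @param tol relative centroid movement below which iteration stops.
#' @param seed RNG seed for random init.
#' @return A list of class `cq_kmeans_params`.
#' @export
kmeans_params <- function(k = 3L, init = c("optimal", "percentile", "random"),
                          max_iter = 100L, tol = 1e-4, seed = 1L) {
  init <- match.arg(init)
  if (k < 1L) stop("k must be >= 1")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  structure(list(k = as.integer(k), init = init,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "cq_kmeans_params")
}

# weighted 1-D Lloyd iterations on the intensity histogram; exactly
# equivalent to voxel-wise Lloyd because voxels sharing an intensity are
# interchangeable.  values: sorted unique intensities; w: their counts.
lloyd_1d <- function(values, w, centroids, max_iter, tol) {
  k <- length(centroids)
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    centroids <- sort(centroids)
    assign_cls <- assign_nearest(values, centroids)
    # empty-cluster repair: reseed at the value farthest from its centroid
    repeat {
      sizes <- vapply(seq_len(k), function(j) sum(w[assign_cls == j]), 0)
      empty <- which(sizes == 0)
      if (!length(empty)) break
      dist <- abs(values - centroids[assign_cls])
      centroids[empty[1L]] <- values[which.max(dist)]
      centroids <- sort(centroids)
      assign_cls <- assign_nearest(values, centroids)
    }
    objective <- c(objective,
                   sum(w * (values - centroids[assign_cls])^2))
    new_c <- vapply(seq_len(k), function(j) {
      sel <- assign_cls == j
      sum(w[sel] * values[sel]) / sum(w[sel])
    }, 0)
    move <- max(abs(new_c - centroids) / pmax(abs(centroids), 1e-12))
    centroids <- new_c
    if (move < tol) break
  }
  centroids <- sort(centroids)
  assign_cls <- assign_nearest(values, centroids)
  list(centroids = centroids, assign = assign_cls, objective = objective,
       iterations = length(objective))
}

# exact weighted 1-D k-means by dynamic programming over contiguous
# partitions of the sorted values; returns the segment means
dp_optimal_1d <- function(values, w, k) {
  V <- length(values)
  S0 <- c(0, cumsum(w)); S1 <- c(0, cumsum(w * values))
  S2 <- c(0, cumsum(w * values^2))
  seg_cost <- function(i, j) {  # vectorised over i (1-based, inclusive)
    s0 <- S0[j + 1L] - S0[i]; s1 <- S1[j + 1L] - S1[i]
    s2 <- S2[j + 1L] - S2[i]
    pmax(0, s2 - s1^2 / pmax(s0, .Machine$double.eps))
  }
  D <- matrix(Inf, k, V)
  B <- matrix(1L, k, V)
  for (j in seq_len(V)) D[1L, j] <- seg_cost(1L, j)
  if (k > 1L) for (kk in 2:k) {
    for (j in kk:V) {
      i <- kk:j                        # start of the last segment
      tot <- D[kk - 1L, i - 1L] + seg_cost(i, j)
      best <- which.min(tot)
      D[kk, j] <- tot[best]
      B[kk, j] <- i[best]
    }
  }
  # backtrack segment boundaries
  bounds <- integer(k + 1L); bounds[k + 1L] <- V
  j <- V
  for (kk in k:1) {
    i <- if (kk > 1L) B[kk, j] else 1L
    bounds[kk] <- i - 1L
    j <- i - 1L
  }
  vapply(seq_len(k), function(kk) {
    i <- bounds[kk] + 1L; j2 <- bounds[kk + 1L]
    sum(w[i:j2] * values[i:j2]) / sum(w[i:j2])
  }, 0)
}

# nearest-centroid class (1-based); equidistant values go to the lower
# class id.  centroids must be sorted ascending.
assign_nearest <- function(values, centroids) {
  k <- length(centroids)
  if (k == 1L) return(rep(1L, length(values)))
  mids <- (centroids[-k] + centroids[-1L]) / 2
  cls <- rep(1L, length(values))
  for (m in mids) cls <- cls + (values > m)
  cls
}

#' Classify a masked volume by intensity K-means
#'
#' Lloyd iterations on scalar voxel intensities until the relative
#' centroid movement falls below `tol` or `max_iter` is reached; empty
#' clusters are reseeded at the intensity farthest from its centroid.
#' Final classes are renumbered by ascending centroid, so with k = 3
#' class 0 is background (the zeroed exterior anchors it), class 1 the
#' extracellular matrix and class 2 the bright nuclei.  Classification
#' runs on the whole masked volume including the zeroed exterior,
#' mirroring the pipeline order (mask, then K-means).
#'
#' @param masked a [new_volume()], typically the transparent-zero masked
#'   original volume.
#' @param params a [kmeans_params()].
#' @return An object of class `cq_classmap`: `data` (labels `0..k-1`),
#'   `centroids` (ascending), `objective` (final value),
#'   `objective_trace` (per Lloyd iteration), `iterations`.
#' @export
kmeans_classify <- function(masked, params = kmeans_params()) {
  stopifnot(inherits(masked, "cq_volume"))
  k <- params$k
  counts <- tabulate(as.integer(masked$data) + 1L,
                     nbins = max(masked$data) + 1L)
  values <- which(counts > 0L) - 1L
  w <- counts[counts > 0L]
  if (length(values) < k)
    stop("degenerate-input error: fewer than k distinct intensities")
  if (params$init == "optimal") {
    # on very wide 16-bit histograms the quadratic DP is reduced to the
    # 4096 most massive values before Lloyd polishing
    if (length(values) > 4096L) {
      ord <- order(w, decreasing = TRUE)[seq_len(4096L)]
      sel <- sort(ord)
      centroids <- dp_optimal_1d(as.numeric(values[sel]),
                                 as.numeric(w[sel]), k)
    } else {
      centroids <- dp_optimal_1d(as.numeric(values), as.numeric(w), k)
    }
  } else if (params$init == "percentile") {
    probs <- if (k == 3L) c(0.01, 0.5, 0.99) else (seq_len(k) - 0.5) / k
    cum <- cumsum(w)
    centroids <- vapply(probs, function(p)
      values[which(cum >= p * cum[length(cum)])[1L]], 0)
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(params$seed)
    centroids <- sort(sample(values, k))
  }
  fit <- lloyd_1d(as.numeric(values), as.numeric(w), as.numeric(centroids),
                  params$max_iter, params$tol)
  # label every voxel via the value -> class lookup
  lut <- integer(max(masked$data) + 1L)
  lut[values + 1L] <- fit$assign - 1L
  lab <- array(lut[as.integer(masked$data) + 1L], dim = dim(masked$data))
  structure(list(data = lab, centroids = fit$centroids, k = k,
                 objective = fit$objective[length(fit$objective)],
                 objective_trace = fit$objective,
                 iterations = fit$iterations,
                 voxel_size_um = masked$voxel_size_um),
            class = "cq_classmap")
}

#' @export
print.cq_classmap <- function(x, ...) {
  cat(sprintf("<cq_classmap> k = %d, centroids: %s\n", x$k,
              paste(sprintf("%.2f", x$centroids), collapse = ", ")))
  cat(sprintf("  objective %.6g after %d Lloyd iterations\n",
              x$objective, x$iterations))
  invisible(x)
}

#' Binary mask of one class
#'
#' @param classmap a [kmeans_classify()] result.
#' @param class_id class id in `0..k-1` (with k = 3: 0 background, 1 ECM,
#'   2 nuclei).
#' @return A [new_mask()].
#' @export
class_binary <- function(classmap, class_id) {
  stopifnot(inherits(classmap, "cq_classmap"))
  if (length(class_id) != 1L || !class_id %in% (seq_len(classmap$k) - 1L))
    stop("parameter error: invalid class id")
  new_mask(classmap$data == class_id, classmap$voxel_size_um)
}
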