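# Independent brute-force oracles for the voxel kernels.  These are
# deliberately naive re-derivations from the definitions; they share no
# code with the package internals.

reflect_index <- function(i, n) {
  if (n == 1L) return(1L)
  # 0-based symmetric reflection without edge duplication, then 1-based
  i <- i - 1L
  while (i < 0L || i >= n) {
    if (i < 0L) i <- -i
    if (i >= n) i <- 2L * n - 2L - i
  }
  i + 1L
}

# per-voxel sort-and-pick median over an axis-aligned ellipsoid
# neighbourhood with reflect padding; lower median for even counts
oracle_median3d <- function(arr, radius) {
  d <- dim(arr)
  off <- expand.grid(dz = -radius[1]:radius[1], dy = -radius[2]:radius[2],
                     dx = -radius[3]:radius[3])
  keep <- rep(TRUE, nrow(off))
  s <- rep(0, nrow(off))
  for (ax in 1:3) {
    dd <- off[[ax]]
    if (radius[ax] > 0) s <- s + (dd / radius[ax])^2
    else keep <- keep & dd == 0
  }
  off <- off[keep & s <= 1 + 1e-12, ]
  out <- arr
  for (iz in seq_len(d[1])) for (iy in seq_len(d[2])) for (ix in seq_len(d[3])) {
    vals <- mapply(function(dz, dy, dx) {
      arr[reflect_index(iz + dz, d[1]), reflect_index(iy + dy, d[2]),
          reflect_index(ix + dx, d[3])]
    }, off$dz, off$dy, off$dx)
    v <- sort(vals)
    out[iz, iy, ix] <- v[(length(v) - 1L) %/% 2L + 1L]
  }
  out
}

se_offsets_oracle <- function(se) {
  if (se == "cube3") expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  else data.frame(dz = c(0, -1, 1, 0, 0, 0, 0), dy = c(0, 0, 0, -1, 1, 0, 0),
                  dx = c(0, 0, 0, 0, 0, -1, 1))
}

# definitional erosion: keep a voxel iff the SE centred there fits inside
oracle_erode <- function(arr, se = "cube3", iterations = 1L) {
  d <- dim(arr)
  off <- se_offsets_oracle(se)
  for (it in seq_len(iterations)) {
    out <- array(FALSE, d)
    for (iz in seq_len(d[1])) for (iy in seq_len(d[2])) for (ix in seq_len(d[3])) {
      if (!arr[iz, iy, ix]) next
      ok <- TRUE
      for (k in seq_len(nrow(off))) {
        z <- iz + off$dz[k]; y <- iy + off$dy[k]; x <- ix + off$dx[k]
        if (z < 1 || z > d[1] || y < 1 || y > d[2] || x < 1 || x > d[3] ||
            !arr[z, y, x]) { ok <- FALSE; break }
      }
      out[iz, iy, ix] <- ok
    }
    arr <- out
  }
  arr
}

conn_offsets_oracle <- function(connectivity) {
  off <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  ad <- abs(off$dz) + abs(off$dy) + abs(off$dx)
  if (connectivity == 6) off[ad == 1, ]
  else if (connectivity == 18) off[ad >= 1 & ad <= 2, ]
  else off[ad >= 1, ]
}

# queue-based flood fill labeling
oracle_label <- function(arr, connectivity = 26L) {
  d <- dim(arr)
  off <- conn_offsets_oracle(connectivity)
  lab <- array(0L, d)
  nid <- 0L
  for (lin in which(arr)) {
    if (lab[lin] > 0L) next
    nid <- nid + 1L
    queue <- lin
    lab[lin] <- nid
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      ci <- arrayInd(cur, d)
      for (k in seq_len(nrow(off))) {
        z <- ci[1] + off$dz[k]; y <- ci[2] + off$dy[k]; x <- ci[3] + off$dx[k]
        if (z < 1 || z > d[1] || y < 1 || y > d[2] || x < 1 || x > d[3]) next
        if (arr[z, y, x] && lab[z, y, x] == 0L) {
          lab[z, y, x] <- nid
          queue <- c(queue, (x - 1L) * d[1] * d[2] + (y - 1L) * d[1] + z)
        }
      }
    }
  }
  lab
}

# two labelings agree up to a permutation of ids
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fg <- a > 0
  key <- paste(a[fg], b[fg])
  length(unique(key)) == length(unique(a[fg])) &&
    length(unique(key)) == length(unique(b[fg]))
}

# exhaustive optimum over contiguous 3-partitions of sorted values
# (the 1-D k-means optimum is contiguous in sorted order)
oracle_kmeans3_objective <- function(values) {
  v <- sort(values)
  n <- length(v)
  sse <- function(x) if (length(x)) sum((x - mean(x))^2) else 0
  best <- Inf
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) {
    s <- sse(v[1:i]) + sse(v[(i + 1):j]) + sse(v[(j + 1):n])
    if (s < best) best <- s
  }
  best
}
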