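test_that("erosion matches definitional cases", {
  # 3x3x3 solid cube in a 5^3 grid: only the centre survives
  a <- array(FALSE, c(5, 5, 5)); a[2:4, 2:4, 2:4] <- TRUE
  er <- erode_mask(new_mask(a), blob_params())
  expect_identical(which(er$data), which(array(seq_len(125), c(5,5,5)) == 63))

  # empty stays empty; erosion is antiextensive and decreasing
  expect_equal(sum(erode_mask(new_mask(array(FALSE, c(4, 4, 4))))$data), 0)
  m <- random_mask(c(10L, 10L, 10L), 0.7, seed = 5L)
  e1 <- erode_mask(m, blob_params(erosion_iterations = 1L))
  e2 <- erode_mask(m, blob_params(erosion_iterations = 2L))
  expect_true(all(m$data[e1$data]))
  expect_true(all(e1$data[e2$data]))
})

test_that("erosion and labeling match brute-force oracles on random masks", {
  for (seed in 1:6) {
    d <- c(sample(5:10, 1), sample(5:10, 1), sample(5:10, 1))
    m <- random_mask(d, runif(1, 0.2, 0.6), seed = 100 + seed)
    for (se in c("cube3", "cross3")) {
      got <- erode_mask(m, blob_params(erosion_se = se))$data
      expect_identical(got, oracle_erode(m$data, se), info = paste(se, seed))
    }
    for (conn in c(6L, 18L, 26L)) {
      got <- label_blobs(m, conn)$data
      expect_true(same_partition(got, oracle_label(m$data, conn)),
                  info = paste("conn", conn, "seed", seed))
    }
  }
})

test_that("connectivity semantics follow the adjacency definition", {
  a <- array(FALSE, c(1, 2, 2)); a[1, 1, 1] <- TRUE; a[1, 2, 2] <- TRUE
  m <- new_mask(a)
  expect_equal(max(label_blobs(m, 6L)$data), 2L)
  expect_equal(max(label_blobs(m, 26L)$data), 1L)
  full <- new_mask(array(TRUE, c(3, 3, 3)))
  expect_equal(max(label_blobs(full, 6L)$data), 1L)
})

test_that("erosion splits two balls joined by a thin neck", {
  d <- c(24L, 24L, 24L)
  a <- array(FALSE, d)
  cz <- c(12, 12); cy <- c(7, 17); cx <- c(12, 12)
  for (b in 1:2) {
    for (iz in 1:24) for (iy in 1:24) for (ix in 1:24)
      if ((iz - cz[b])^2 + (iy - cy[b])^2 + (ix - cx[b])^2 <= 25)
        a[iz, iy, ix] <- TRUE
  }
  m <- new_mask(a)
  expect_equal(max(label_blobs(m, 26L)$data), 1L)   # one fused blob
  er <- erode_mask(m, blob_params())
  expect_equal(max(label_blobs(er, 26L)$data), 2L)  # split by erosion
  # geodesic restore keeps the split and re-covers the original voxels
  lab <- split_blobs(m, blob_params())
  expect_equal(max(lab$data), 2L)
  expect_identical(lab$data > 0L, m$data)
})

test_that("split_blobs deletes thin sheets but restores solid blobs", {
  d <- c(20L, 20L, 20L)
  a <- array(FALSE, d)
  a[5:18, 5:18, 5] <- TRUE          # 1-voxel-thick sheet (rim-like)
  a[10:14, 10:14, 12:16] <- TRUE    # solid 5^3 blob
  lab <- split_blobs(new_mask(a), blob_params())
  tab <- blob_metrics(lab)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$voxel_count, 125L)
  # without erosion both components are labeled
  expect_equal(max(split_blobs(new_mask(a),
                  blob_params(erosion_iterations = 0L))$data), 2L)
})

test_that("blob voxel counts are conserved", {
  m <- random_mask(c(12L, 12L, 12L), 0.3, seed = 41L)
  lab <- label_blobs(m, 26L)
  tab <- blob_metrics(lab)
  expect_equal(sum(tab$voxel_count), sum(m$data))
})

test_that("blob metrics compute physical moments", {
  h <- 1.05
  # single voxel at (z, y, x) = (2, 3, 4), 0-based
  a <- array(0L, c(6, 6, 6)); a[3, 4, 5] <- 1L
  tab <- blob_metrics(new_labels(a, h))
  expect_equal(tab$centroid_z_um, 2 * h)
  expect_equal(tab$centroid_y_um, 3 * h)
  expect_equal(tab$centroid_x_um, 4 * h)
  expect_equal(tab$volume_um3, h^3)      # 1.157625
  expect_equal(c(tab$lambda1_um2, tab$lambda2_um2, tab$lambda3_um2),
               c(0, 0, 0))

  # axis-aligned 1x1x9 rod: orientation along x, infinite elongation
  b <- array(0L, c(3, 3, 11)); b[2, 2, 2:10] <- 1L
  rod <- blob_metrics(new_labels(b, 1.0))
  expect_equal(abs(rod$orient_x), 1, tolerance = 1e-9)
  expect_true(is.infinite(rod$elongation))
  expect_equal(sqrt(rod$orient_z^2 + rod$orient_y^2 + rod$orient_x^2), 1,
               tolerance = 1e-9)

  # 45-degree digital rod: orientation within 5 degrees of (0,1,1)/sqrt(2)
  cdim <- c(3L, 14L, 14L)
  cc <- array(0L, cdim)
  for (i in 2:13) cc[2, i, i] <- 1L
  diag_rod <- blob_metrics(new_labels(cc, 1.0))
  v <- c(diag_rod$orient_z, diag_rod$orient_y, diag_rod$orient_x)
  ang <- acos(min(1, abs(sum(v * c(0, 1, 1) / sqrt(2))))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("the 27-voxel minimum-size rule is inclusive", {
  # blobs of sizes 1, 26, 27, 100 in well-separated x slabs
  a <- array(0L, c(4, 7, 160))
  a[1, 1, 1] <- 1L
  idx26 <- arrayInd(1:26, c(4, 7)); for (k in 1:26) a[idx26[k,1], idx26[k,2], 10] <- 2L
  idx27 <- arrayInd(1:27, c(4, 7)); for (k in 1:27) a[idx27[k,1], idx27[k,2], 30] <- 3L
  a[1:4, 1:5, 50:54] <- 4L                          # 100 voxels
  tab <- blob_metrics(new_labels(a, 1.0))
  expect_equal(sort(tab$voxel_count), c(1L, 26L, 27L, 100L))
  kept <- filter_blobs(tab, 27L)
  expect_equal(count_cells(kept), 2L)
  expect_equal(sort(kept$voxel_count), c(27L, 100L))
  # min 1 is the identity; empty in, empty out
  expect_equal(count_cells(filter_blobs(tab, 1L)), 4L)
  empty <- blob_metrics(new_labels(array(0L, c(2, 2, 2))))
  expect_equal(count_cells(filter_blobs(empty, 27L)), 0L)
  expect_error(filter_blobs(tab, 0L), "min_voxels")
})

test_that("counts add over disjoint elements", {
  m1 <- random_mask(c(8L, 8L, 8L), 0.1, seed = 1L)
  m2 <- random_mask(c(8L, 8L, 8L), 0.1, seed = 2L)
  t1 <- blob_metrics(label_blobs(m1, 26L))
  t2 <- blob_metrics(label_blobs(m2, 26L))
  expect_equal(count_cells(t1) + count_cells(t2),
               count_cells(rbind(t1, t2)))
})
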