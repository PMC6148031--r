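test_that("well-separated modes are recovered exactly", {
  set.seed(8)
  vals <- sample(c(10L, 100L, 200L), 4^3, TRUE)
  v <- new_volume(array(vals, c(4, 4, 4)))
  for (ini in c("optimal", "percentile")) {
    cm <- kmeans_classify(v, kmeans_params(init = ini))
    expect_equal(cm$centroids, c(10, 100, 200))
    expect_equal(cm$objective, 0)
    expect_true(all((v$data == 10) == (cm$data == 0)))
    expect_true(all((v$data == 100) == (cm$data == 1)))
    expect_true(all((v$data == 200) == (cm$data == 2)))
  }
})

test_that("k = 1 returns the mean intensity", {
  v <- random_volume(c(4L, 4L, 4L), seed = 3L)
  cm <- kmeans_classify(v, kmeans_params(k = 1L))
  expect_equal(cm$centroids, mean(v$data))
  expect_true(all(cm$data == 0))
})

test_that("Lloyd objective equals the exhaustive contiguous-partition optimum", {
  # volumes up to 512 voxels with three clear intensity modes
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(c(64L, 125L, 512L), 1L)
    d <- round(n^(1 / 3))
    vals <- as.integer(round(c(rnorm(n %/% 3, 40, 8),
                               rnorm(n %/% 3, 120, 8),
                               rnorm(n - 2 * (n %/% 3), 210, 8))))
    vals <- pmin(255L, pmax(0L, sample(vals)))
    for (ini in c("percentile", "optimal")) {
      cm <- kmeans_classify(new_volume(array(vals, c(n, 1, 1))),
                            kmeans_params(init = ini))
      expect_equal(cm$objective, oracle_kmeans3_objective(vals),
                   tolerance = 1e-9, info = paste(ini, "seed", seed))
    }
  }
})

test_that("the Lloyd objective is non-increasing every iteration", {
  set.seed(12)
  vals <- as.integer(round(runif(400, 0, 255)))
  cm <- kmeans_classify(new_volume(array(vals, c(400, 1, 1))),
                        kmeans_params(init = "percentile"))
  expect_true(all(diff(cm$objective_trace) <= 1e-9))
  expect_gte(cm$iterations, 1L)
})

test_that("percentile init is deterministic across runs", {
  v <- random_volume(c(6L, 6L, 6L), seed = 77L)
  a <- kmeans_classify(v, kmeans_params(init = "percentile"))
  b <- kmeans_classify(v, kmeans_params(init = "percentile"))
  expect_identical(a$data, b$data)
  expect_identical(a$centroids, b$centroids)
})

test_that("class binaries partition the grid", {
  v <- random_volume(c(5L, 5L, 5L), seed = 10L)
  cm <- kmeans_classify(v)
  m0 <- class_binary(cm, 0L)$data
  m1 <- class_binary(cm, 1L)$data
  m2 <- class_binary(cm, 2L)$data
  expect_true(all(m0 + m1 + m2 == 1L))
  expect_error(class_binary(cm, 3L), "class id")

  # all-one-class map has an empty nucleus binary
  cm1 <- kmeans_classify(new_volume(array(rep(c(1L, 2L, 3L), 9), c(27, 1, 1))),
                         kmeans_params(k = 3L))
  expect_equal(sum(class_binary(cm1, 2L)$data), 9)
})

test_that("degenerate inputs are rejected", {
  v <- new_volume(array(5L, c(3, 3, 3)))
  expect_error(kmeans_classify(v, kmeans_params(k = 3L)), "distinct")
})
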