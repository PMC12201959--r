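test_that("prevalence threshold rounds half away from zero with a floor of 1", {
  expect_identical(prevalenceThreshold(164, 0.05), 8L)
  expect_identical(prevalenceThreshold(100, 0.05), 5L)
  expect_identical(prevalenceThreshold(10, 0.05), 1L)
  expect_identical(prevalenceThreshold(30, 0.05), 2L)  # 1.5 rounds up
  expect_identical(prevalenceThreshold(5, 0.01), 1L)   # floor clamp
  expect_error(prevalenceThreshold(100, 0))
  expect_error(prevalenceThreshold(100, 1))
})

mkIdscn <- function(mask, id = "P1", R = 4L) {
  m <- matrix(FALSE, R, R)
  for (e in mask) { m[e[1], e[2]] <- m[e[2], e[1]] <- TRUE }
  new("IDSCN", patientId = id, z = matrix(0, R, R),
      p = matrix(1, R, R), mask = m, familySize = as.integer(choose(R, 2)),
      alpha = 0.001)
}

test_that("edge prevalence counts patients per edge", {
  ids <- list(mkIdscn(list(c(1, 2)), "P1"),
              mkIdscn(list(c(1, 2), c(2, 3)), "P2"),
              mkIdscn(list(), "P3"))
  prev <- edgePrevalence(ids)
  cnt <- prevalenceCounts(prev)
  expect_identical(cnt[1, 2], 2L)
  expect_identical(cnt[2, 3], 1L)
  expect_identical(cnt[1, 3], 0L)
  expect_error(edgePrevalence(list(ids[[1]], mkIdscn(list(), R = 5L))),
               "shape")

  empty <- edgePrevalence(list(mkIdscn(list()), mkIdscn(list())))
  expect_true(all(prevalenceCounts(empty) == 0L))
})

test_that("feature edges are selected by prevalence with canonical tie-break", {
  ids <- c(lapply(1:3, function(i) mkIdscn(list(c(1, 3), c(2, 4)), paste0("A", i))),
           list(mkIdscn(list(c(1, 3), c(1, 2)), "B")))
  prev <- edgePrevalence(ids)
  sel <- selectFeatureEdges(prev, 1L)
  # counts: (1,3)=4, (2,4)=3, (1,2)=1; ties impossible here, so add one
  expect_identical(sel$count, c(4L, 3L, 1L))
  expect_identical(sel$i, c(1L, 2L, 1L))

  # tie between (1,2) and (2,4) at equal counts orders by (i, j)
  ids2 <- list(mkIdscn(list(c(1, 2), c(2, 4)), "P1"),
               mkIdscn(list(c(1, 2), c(2, 4)), "P2"))
  sel2 <- selectFeatureEdges(edgePrevalence(ids2), 1L)
  expect_identical(sel2$i, c(1L, 2L))
  expect_identical(sel2$j, c(2L, 4L))

  expect_error(selectFeatureEdges(prev, 99L), "threshold")
})

test_that("feature matrix aligns patients and edges", {
  set.seed(12)
  zs <- lapply(1:3, function(i) {
    z <- matrix(rnorm(16), 4L); z <- z + t(z); diag(z) <- 0; z
  })
  ids <- lapply(1:3, function(i)
    new("IDSCN", patientId = paste0("P", i), z = zs[[i]],
        p = matrix(1, 4, 4), mask = matrix(FALSE, 4, 4),
        familySize = 6L, alpha = 0.001))
  edges <- data.frame(i = c(1L, 2L), j = c(3L, 4L), count = c(3L, 2L))
  fm <- featureMatrix(ids, edges)
  expect_identical(dim(featureZ(fm)), c(3L, 2L))
  expect_identical(rownames(featureZ(fm)), c("P1", "P2", "P3"))
  expect_equal(featureZ(fm)[2L, 1L], zs[[2]][1L, 3L])

  one <- featureMatrix(ids, edges[1L, ])
  expect_identical(ncol(featureZ(one)), 1L)
  expect_equal(featureZ(one)[, 1L],
               vapply(zs, function(z) z[1L, 3L], numeric(1)),
               ignore_attr = TRUE)
})

test_that("mean silhouette matches the cluster-package oracle", {
  skip_if_not_installed("cluster")
  set.seed(13)
  X <- rbind(matrix(rnorm(40), 20L), matrix(rnorm(30, 4), 15L))
  d <- dist(X)
  for (k in 2:4) {
    lab <- kmeans(X, k, nstart = 5)$cluster
    mine <- meanSilhouette(as.matrix(d), lab)
    oracle <- mean(cluster::silhouette(lab, d)[, 3L])
    expect_equal(mine, oracle, tolerance = 1e-12)
  }
})

test_that("model selection recovers two well-separated clouds exactly", {
  set.seed(14)
  X <- rbind(matrix(rnorm(20L * 3L, 0, 0.5), 20L),
             matrix(rnorm(20L * 3L, 10, 0.5), 20L))
  truth <- rep(1:2, each = 20L)
  res <- clusterSubtypes(X, kMin = 2L, kMax = 6L, nRestarts = 25L, seed = 3L)
  expect_identical(chosenK(res), 2L)
  lab <- subtypeLabels(res)
  expect_true(all(lab[1:20] == lab[1L]) && all(lab[21:40] == lab[21L]) &&
                lab[1L] != lab[21L])
  # chosen k maximizes the silhouette over the whole grid
  sil <- silhouetteByK(res)
  expect_true(all(sil <= sil["2"] + 1e-12))
  expect_true(all(sil >= -1 & sil <= 1))

  # subtype 1 is the larger cluster
  X2 <- rbind(matrix(rnorm(30L * 2L, 0, 0.3), 30L),
              matrix(rnorm(10L * 2L, 8, 0.3), 10L))
  res2 <- clusterSubtypes(X2, kMax = 5L, nRestarts = 20L, seed = 4L)
  expect_identical(as.integer(table(subtypeLabels(res2))), c(30L, 10L))
  expect_true(all(subtypeLabels(res2)[1:30] == 1L))
})

test_that("clustering is deterministic given the seed and rejects degenerate input", {
  set.seed(15)
  X <- matrix(rnorm(120), 40L)
  a <- clusterSubtypes(X, kMax = 5L, nRestarts = 10L, seed = 7L)
  b <- clusterSubtypes(X, kMax = 5L, nRestarts = 10L, seed = 7L)
  expect_identical(subtypeLabels(a), subtypeLabels(b))
  expect_identical(silhouetteByK(a), silhouetteByK(b))

  same <- matrix(1, 10L, 3L)
  expect_error(clusterSubtypes(same, kMax = 3L), "identical")
  expect_error(clusterSubtypes(X, kMax = 40L))  # kMax must be < n
})
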