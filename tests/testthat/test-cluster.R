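test_that("SOM training is deterministic and fits a tight population", {
  withr::local_seed(2)
  data <- matrix(rnorm(2000 * 4, mean = 3, sd = 0.5), 2000, 4,
                 dimnames = list(NULL, paste0("ch", 1:4)))
  cfg <- som_config(grid = c(3, 3), seed = 42)
  m1 <- train_som(data, cfg)
  m2 <- train_som(data, cfg)
  expect_identical(m1$weights, m2$weights)
  # quantization error no worse than 2x the population spread; k-means as
  # an independent reference for the attainable error
  km <- stats::kmeans(data, centers = 9, nstart = 3)
  qe_kmeans <- mean(sqrt(rowSums((data - km$centers[km$cluster, ])^2)))
  expect_lt(m1$quantization_error, 2 * 0.5 * sqrt(4))
  expect_lt(m1$quantization_error, 2 * qe_kmeans)
  # all node weights near the population mean
  expect_true(all(abs(m1$weights - 3) < 3 * 0.5))
})

test_that("separated populations occupy distinct pure nodes", {
  g <- gaussian_clouds(n_per = 300, sep = 10, sd = 1)
  m <- train_som(g$data, som_config(grid = c(2, 2), seed = 7))
  asn <- assign_cells(m, g$data)
  occupied <- sort(unique(asn$node))
  expect_gte(length(occupied), 3)
  # each occupied node is pure for one population (brute-force labeling)
  truth_center <- oracle_nearest(m$weights[occupied, , drop = FALSE], g$centers)
  for (i in seq_along(occupied)) {
    cells <- which(asn$node == occupied[i])
    expect_true(all(g$labels[cells] == truth_center[i]))
  }
})

test_that("training requires enough finite cells", {
  data <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(NULL, paste0("ch", 1:4)))
  expect_error(train_som(data, som_config(grid = c(5, 5))), "at least")
  data[1, 1] <- NA
  expect_error(train_som(data, som_config(grid = c(2, 2))), "non-finite")
})

test_that("consensus metaclustering handles the degenerate k values", {
  g <- gaussian_clouds(n_per = 100)
  m <- train_som(g$data, som_config(grid = c(3, 3), seed = 1))
  expect_error(metacluster(m, k = 10), "exceeds")
  m1 <- metacluster(m, k = 9)
  expect_equal(m1$metacluster, 1:9)
  m2 <- metacluster(m, k = 1)
  expect_equal(m2$metacluster, rep(1L, 9))
})

test_that("metaclustering recovers separated populations exactly", {
  g <- gaussian_clouds(n_per = 300, sep = 10, sd = 1)
  m <- train_som(g$data, som_config(grid = c(3, 3), seed = 3))
  m <- metacluster(m, k = 3, seed = 4)
  asn <- assign_cells(m, g$data)
  # exact recovery up to at most a stray boundary cell caught by an
  # interstitial node
  expect_gte(oracle_ari(asn$metacluster, g$labels), 0.99)
})

test_that("cell assignment equals a brute-force nearest-node search", {
  g <- gaussian_clouds(n_per = 400, sep = 6, sd = 2, seed = 9)
  m <- train_som(g$data, som_config(grid = c(4, 4), seed = 13))
  m <- metacluster(m, k = 5, seed = 13)
  asn <- assign_cells(m, g$data[1:1000, ])
  expect_equal(asn$node, unname(oracle_nearest(g$data[1:1000, ], m$weights)))
  expect_equal(asn$metacluster, m$metacluster[asn$node])
  # a cell equal to a node weight lands on that node
  one <- assign_cells(m, m$weights[7, , drop = FALSE])
  expect_equal(one$node, 7)
  # empty sample -> empty assignment
  empty <- assign_cells(m, g$data[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
  # channel mismatch names the missing channels
  bad <- g$data[1:5, 1:3]
  expect_error(assign_cells(m, bad), "ch4")
})

test_that("assigning the training cells reproduces their training BMUs", {
  g <- gaussian_clouds(n_per = 200)
  m <- train_som(g$data, som_config(grid = c(3, 3), seed = 21))
  asn <- assign_cells(m, g$data)
  expect_equal(asn$node, m$training_bmu)
})

test_that("metacluster counts conserve the sample's cell count", {
  sn <- small_normalized()
  co <- sn$cohort
  clust_ch <- panel_channels(co$panel, "clustering")
  ids <- co$manifest$sample_id[co$manifest$sample_role == "patient"][1:4]
  pooled <- do.call(rbind, lapply(sn$normalized[ids],
                                  function(t) t$data[, clust_ch]))
  m <- metacluster(train_som(pooled, som_config(seed = 2)), k = 10, seed = 2)
  for (sid in ids) {
    asn <- assign_cells(m, sn$normalized[[sid]]$data[, clust_ch])
    expect_equal(nrow(asn), nrow(sn$normalized[[sid]]$data))
    expect_equal(sum(table(asn$metacluster)), nrow(asn))
  }
})

test_that("sub-clustering separates structure and flags its absence", {
  panel <- panel_config(data.frame(name = paste0("ch", 1:4),
                                   role = c("clustering", "clustering",
                                            "excluded", "functional")))
  # two separated populations in the surface channels: perfect recovery
  g <- gaussian_clouds(n_per = 250, sep = 8, sd = 1, seed = 31)
  two <- g$data[g$labels != 3, ]
  sc <- subcluster(two, panel, som_config(grid = c(2, 2), seed = 5), k = 2)
  expect_equal(oracle_ari(sc$assignment$metacluster, g$labels[g$labels != 3]), 1.0)
  # all surface channels (including the excluded one) are used
  expect_setequal(sc$model$channels, c("ch1", "ch2", "ch3"))
  # determinism
  sc2 <- subcluster(two, panel, som_config(grid = c(2, 2), seed = 5), k = 2)
  expect_identical(sc$assignment, sc2$assignment)
  # one homogeneous population forced into k=2: low consensus score
  withr::local_seed(6)
  homog <- matrix(rnorm(600 * 3, 2, 0.4), 600, 3,
                  dimnames = list(NULL, paste0("ch", 1:3)))
  sc3 <- subcluster(homog, panel, som_config(grid = c(3, 3), seed = 6), k = 2)
  expect_lt(sc3$model$consensus$score,
            sc$model$consensus$score)
  expect_error(subcluster(two[0, ], panel), "empty")
})

test_that("metaclustering of the synthetic cohort is stable across seeds", {
  sn <- small_normalized()
  co <- sn$cohort
  clust_ch <- panel_channels(co$panel, "clustering")
  ids <- co$manifest$sample_id[
    (co$manifest$sample_role == "patient" & co$manifest$timepoint_h == 0) |
      co$manifest$sample_role == "healthy_donor"]
  pooled <- do.call(rbind, lapply(sn$normalized[ids],
                                  function(t) t$data[, clust_ch]))
  labels <- lapply(1:3, function(s) {
    m <- metacluster(train_som(pooled, som_config(seed = s)), k = 10, seed = s)
    assign_cells(m, pooled)$metacluster
  })
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gte(oracle_ari(labels[[i]], labels[[j]]), 0.8)
  }
})

test_that("SOM results are stable across seeds on structured data", {
  g <- gaussian_clouds(n_per = 300, sep = 8, sd = 1.2, seed = 44)
  labels <- lapply(1:3, function(s) {
    m <- metacluster(train_som(g$data, som_config(grid = c(3, 3), seed = s)),
                     k = 3, seed = s)
    assign_cells(m, g$data)$metacluster
  })
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gte(oracle_ari(labels[[i]], labels[[j]]), 0.8)
  }
})
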