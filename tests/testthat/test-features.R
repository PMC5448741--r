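test_that("connection density and cost follow their defining arithmetic", {
  expect_equal(connection_density(0, 3, 2), 0)
  expect_equal(connection_density(60, 20, 10), 2.0)
  expect_equal(connection_density(7, 1.5, 2.0), 2.0)
  expect_error(connection_density(5, -1, 2), "positive")
  expect_error(connection_density(-1, 1, 2), "non-negative")

  expect_equal(connection_cost(2.0, 50), 100.0)
  expect_equal(connection_cost(0, NA), 0)
  expect_equal(connection_cost(0.5, 12.5), 6.25)
  expect_error(connection_cost(-0.1, 10), "non-negative")
  expect_error(connection_cost(1, NA), "positive")
})

test_that("region-wise aggregation is the mean of the four incident pairs", {
  expect_equal(regionwise_aggregate(c(1, 1, 1, 1)), 1)
  expect_equal(regionwise_aggregate(c(0, 0, 0, 0)), 0)
  expect_equal(regionwise_aggregate(c(2, 4, 6, 8)), 5)
  expect_error(regionwise_aggregate(c(1, 2, 3)), "exactly 4")
})

test_that("tract strength applies the 0.01 voxel-exclusion rule", {
  tab <- function(ratios, any = 1000) {
    cbind(OMPFC = round(ratios * any), hippocampus = 0, insula = 0,
          thalamus = 0, any_hits = any)
  }
  expect_equal(tract_strength(tab(c(0.5, 0.3, 0.005)), "OMPFC"), 0.4)
  expect_equal(tract_strength(tab(c(1, 1, 1)), "OMPFC"), 1.0)
  # brute-force over the four voxels: 0.009 and 0 fall below the cut
  expect_equal(tract_strength(tab(c(0.02, 0.009, 0.04, 0.0)), "OMPFC"), 0.03)
  # voxels with no sample reaching any target are dropped before ratios
  t2 <- tab(c(0.5, 0.3)); t2[2, "any_hits"] <- 0; t2[2, "OMPFC"] <- 0
  expect_equal(tract_strength(t2, "OMPFC"), 0.5)
  expect_warning(s <- tract_strength(tab(c(0.005, 0.002)), "OMPFC"), "0.01")
  expect_equal(s, 0)
  expect_error(tract_strength(matrix(numeric(0), 0, 5), "OMPFC"), "at least one voxel")
})

test_that("network efficiency matches hand-computed small graphs", {
  rois <- roi_names()
  dm <- matrix(0, 5, 5, dimnames = list(rois, rois))
  tri <- rois[1:3]
  dm[tri, tri] <- 1; diag(dm) <- 0
  expect_equal(network_efficiency(dm, tri), 1.0)

  # path A-B-C: d(A,C) = 2 via B, so E = (4*1 + 2*0.5)/6 = 5/6
  dm2 <- matrix(0, 5, 5, dimnames = list(rois, rois))
  dm2["amygdala", "OMPFC"] <- dm2["OMPFC", "amygdala"] <- 1
  dm2["OMPFC", "hippocampus"] <- dm2["hippocampus", "OMPFC"] <- 1
  expect_equal(network_efficiency(dm2, c("amygdala", "OMPFC", "hippocampus")), 5 / 6)

  dm3 <- matrix(0, 5, 5, dimnames = list(rois, rois))
  expect_equal(network_efficiency(dm3), 0)
  expect_error(network_efficiency(dm3, "amygdala"), "at least 2")
})

test_that("efficiency is monotone in density and depends only on the induced subgraph", {
  set.seed(401)
  for (rep in 1:30) {
    dm <- random_density_matrix()
    e0 <- network_efficiency(dm)
    i <- sample(1:4, 1); j <- sample((i + 1):5, 1)
    dm2 <- dm
    dm2[i, j] <- dm2[j, i] <- dm[i, j] + stats::rexp(1)
    expect_gte(network_efficiency(dm2) - e0, -1e-12)

    nodes <- sample(roi_names(), 3)
    dm3 <- dm
    out <- setdiff(roi_names(), nodes)
    dm3[out, ] <- dm3[, out] <- 99  # outside entries must not matter
    diag(dm3) <- 0
    expect_equal(network_efficiency(dm, nodes), network_efficiency(dm3, nodes))
  }
})

test_that("extract_features returns the 23 canonical features", {
  rec <- make_record()
  f <- extract_features(rec)
  expect_length(f, 23)
  expect_identical(names(f), feature_names())
  expect_equal(unname(f["amygdala_volume"]), 3.0)   # left + right sum
  # all pairs share count 40, length 50: check one pair-wise value by hand
  expect_equal(unname(f["conn_density_amygdala"]),
               mean(40 / (1.5 + c(20, 3.5, 7, 8))))
  expect_equal(unname(f["conn_cost_amygdala"]),
               50 * mean(40 / (1.5 + c(20, 3.5, 7, 8))))
})

test_that("a record with zero counts has zero connectivity and network features but intact local features", {
  rec <- make_record(count = 0)
  f <- extract_features(rec)
  conn <- grep("^(conn_|net_)", names(f), value = TRUE)
  expect_true(all(f[conn] == 0))
  expect_equal(unname(f["amygdala_volume"]), 3.0)
  expect_gt(f["gm_density_OMPFC"], 0)
})

test_that("hemisphere-symmetric records give hemisphere values unchanged by averaging", {
  rec <- make_record(symmetric = TRUE)
  f <- extract_features(rec)
  # left-hemisphere pair density equals the hemisphere-averaged feature
  expect_equal(unname(f["conn_density_OMPFC"]),
               mean(40 / (20 + c(1.5, 3.5, 7, 8))))
  expect_equal(unname(f["gm_density_insula"]), 0.48)
})

test_that("doubling streamline counts doubles densities, costs and efficiencies; tract strength is hit-scale invariant", {
  rec <- make_record()
  rec2 <- rec
  rec2$streamline_count <- rec$streamline_count * 2
  f1 <- extract_features(rec)
  f2 <- extract_features(rec2)
  scaled <- grep("^(conn_|net_)", names(f1), value = TRUE)
  expect_equal(f2[scaled], 2 * f1[scaled])
  fixed <- setdiff(names(f1), scaled)
  expect_equal(f2[fixed], f1[fixed])

  rec3 <- rec
  rec3$seed_table <- lapply(rec$seed_table, function(m) m * 7)
  f3 <- extract_features(rec3)
  ts <- grep("^tract_strength", names(f1), value = TRUE)
  expect_equal(f3[ts], f1[ts])
})

test_that("incomplete records fail naming the missing field", {
  rec <- make_record()
  rec$seed_table <- NULL
  expect_error(extract_features(rec), "seed_table")
})
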