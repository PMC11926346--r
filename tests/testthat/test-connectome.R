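test_that("connectome constructor validates and symmetrizes", {
  m <- matrix(c(0, 1, 1, 0), 2)
  c <- connectome(m)
  expect_s3_class(c, "connectome")
  expect_identical(c$weights[1, 2], 1)

  bad <- m; bad[1, 2] <- -0.2
  expect_error(connectome(bad), "negative weight")
  bad <- m; bad[1, 2] <- NA
  expect_error(connectome(bad), "NA/NaN")
  expect_error(connectome(matrix(0, 2, 3)), "square")
  asym <- m; asym[1, 2] <- 1.1
  expect_error(connectome(asym), "asymmetry")
  # asymmetry within tolerance is averaged
  near <- m; near[1, 2] <- 1 + 1e-10
  expect_equal(connectome(near)$weights[2, 1], connectome(near)$weights[1, 2])
})

test_that("edge density counts nonzero upper-triangle pairs", {
  c <- toy_connectome(c(0.9, 0.5, 0, 0.4, 0, 0.1))  # 4 nodes, 4 of 6 edges
  expect_equal(edge_density(c), 4 / 6)
})

test_that("consistency filter retains low-CoV edges with documented ties", {
  # 3 subjects, 5 edges with hand-computed CoV ranks; edge 6 absent everywhere
  base <- c(1.0, 1.0, 1.0, 1.0, 1.0, 0)
  spread <- list(c(0.02, 0.05, 0.10, 0.18, 0.30, 0),
                 c(-0.02, -0.05, -0.10, -0.18, -0.30, 0),
                 c(0, 0, 0, 0, 0, 0))
  cohort <- lapply(seq_along(spread), function(i) {
    toy_connectome(base + spread[[i]], id = paste0("s", i))
  })
  covs <- sapply(1:5, function(e) {
    vals <- sapply(spread, function(s) 1 + s[e])
    sd(vals) / mean(vals)
  })
  expect_true(all(diff(covs) > 0))  # strictly increasing by construction
  mask <- consistency_filter(cohort, percentile = 0.4)
  ut <- mask[upper.tri(mask)]
  # CoV quantile(0.4) falls between the 2nd and 3rd edge: first two retained
  expect_identical(which(ut), c(1L, 2L))

  # identical subjects: all present edges tie at CoV 0 and are all retained
  same <- lapply(1:3, function(i) toy_connectome(c(1, 2, 3, 0, 0, 0),
                                                 id = paste0("t", i)))
  mask0 <- consistency_filter(same, percentile = 0.1)
  expect_equal(sum(mask0[upper.tri(mask0)]), 3)

  # percentile 1 retains every present edge
  mask1 <- consistency_filter(cohort, percentile = 1)
  expect_equal(sum(mask1[upper.tri(mask1)]), 5)

  relabeled <- cohort
  relabeled[[2]]$region_labels <- rev(relabeled[[2]]$region_labels)
  expect_error(consistency_filter(relabeled), "mismatched")
})

test_that("proportional thresholding keeps the k strongest edges", {
  c <- toy_connectome(c(0.9, 0.5, 0, 0.4, 0, 0.1),
                      labels = c("A", "B", "C", "D"))
  thr <- threshold_by_density(c, 2 / 6)  # floor(2) = 2 edges
  expect_equal(sum(thr$weights[upper.tri(thr$weights)] > 0), 2)
  expect_equal(thr$weights["A", "B"], 0.9)  # AB strongest, kept with weight
  expect_equal(thr$weights["A", "C"], 0.5)
  expect_equal(thr$weights["B", "D"], 0)

  # k arithmetic at the study's scale: 94 regions, 30% -> 1311 edges
  dense <- random_connectome(94, density = 1, seed = 3)
  thr94 <- threshold_by_density(dense, 0.30)
  expect_equal(sum(thr94$weights[upper.tri(thr94$weights)] > 0),
               floor(0.30 * 94 * 93 / 2))
  expect_equal(floor(0.30 * 94 * 93 / 2), 1311)

  # idempotence at own density
  d <- edge_density(c)
  expect_equal(threshold_by_density(c, d)$weights, c$weights)
  # above current density: warning, unchanged
  expect_warning(out <- threshold_by_density(c, 0.99), "exceeds")
  expect_equal(out$weights, c$weights)
  expect_error(threshold_by_density(c, 0.01), "zero edges")
})

test_that("thresholded edge sets are nested across densities", {
  for (seed in 1:5) {
    c <- random_connectome(12, density = 0.8, seed = seed)
    prev <- NULL
    for (d in c(0.1, 0.2, 0.4, 0.6)) {
      thr <- threshold_by_density(c, d)
      edges <- which(thr$weights[upper.tri(thr$weights)] > 0)
      if (!is.null(prev)) expect_true(all(prev %in% edges))
      prev <- edges
    }
  }
})

test_that("spectral normalization fixes the largest singular value at 1", {
  norm2 <- spectral_normalize(toy_connectome(2, n = 2))
  expect_equal(norm2$weights, matrix(c(0, 1, 1, 0), 2,
                                     dimnames = list(c("A", "B"), c("A", "B"))))
  for (seed in 1:5) {
    r <- spectral_normalize(random_connectome(10, seed = seed))
    expect_equal(norm(r$weights, "2"), 1, tolerance = 1e-10)
    # idempotence
    expect_equal(spectral_normalize(r)$weights, r$weights, tolerance = 1e-12)
    # zero pattern preserved
    orig <- random_connectome(10, seed = seed)
    expect_identical(r$weights == 0, orig$weights == 0)
  }
  expect_error(spectral_normalize(toy_connectome(rep(0, 6))), "all-zero")
})

test_that("node lesioning removes a region and commutes", {
  chain <- toy_connectome(c(1, 0, 1), labels = c("A", "B", "C"))
  les <- lesion_node(chain, "B")
  expect_identical(les$region_labels, c("A", "C"))
  expect_true(all(les$weights == 0))  # A and C were only linked through B

  c <- random_connectome(8, seed = 2)
  ab <- lesion_node(lesion_node(c, "R3"), "R7")
  ba <- lesion_node(lesion_node(c, "R7"), "R3")
  both <- lesion_node(c, c("R3", "R7"))
  expect_equal(ab$weights, ba$weights)
  expect_equal(ab$weights, both$weights)
  expect_error(lesion_node(c, "nope"), "unknown region")
})

test_that("connectome matrix files round-trip bit-stably", {
  c <- random_connectome(7, seed = 5, id = "sub-x")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_connectome(c, path)
  back <- read_connectome_matrix(path, subject_id = "sub-x")
  expect_identical(back$weights, c$weights)
  expect_identical(back$region_labels, c$region_labels)
})

test_that("edge lists parse with density and error on bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("A\tB\t0.5", path)
  c <- read_connectome_matrix(path, region_labels = c("A", "B", "C"))
  expect_equal(edge_density(c), 1 / 3)
  expect_equal(c$weights["A", "B"], 0.5)

  writeLines(c("A\tB\t0.5", "B\tA\t0.7"), path)
  expect_error(read_connectome_matrix(path, region_labels = c("A", "B", "C")),
               "conflicting duplicate")

  writeLines(c("region\tA\tB", "A\t0\t-0.2", "B\t-0.2\t0"), path)
  expect_error(read_connectome_matrix(path), "negative weight")
})
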