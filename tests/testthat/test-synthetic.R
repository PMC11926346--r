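test_that("base connectomes honor density, bounds and determinism", {
  p4 <- aging_model_params(n_regions = 4, base_density = 1, seed = 3)
  c4 <- generate_base_connectome(p4, 11)
  expect_equal(sum(c4$weights[upper.tri(c4$weights)] > 0), 6)

  p94 <- aging_model_params(n_regions = 94, base_density = 0.6, seed = 3)
  c94 <- generate_base_connectome(p94, 11)
  expect_equal(sum(c94$weights[upper.tri(c94$weights)] > 0),
               round(0.6 * 94 * 93 / 2))
  expect_equal(round(0.6 * 94 * 93 / 2), 2623)
  expect_true(all(c94$weights >= 0 & c94$weights <= 1))
  expect_equal(c94$weights, t(c94$weights))
  expect_true(all(diag(c94$weights) == 0))

  again <- generate_base_connectome(p94, 11)
  expect_identical(again$weights, c94$weights)
  other <- generate_base_connectome(p94, 12)
  expect_false(identical(other$weights, c94$weights))

  expect_error(aging_model_params(n_regions = 1), "n_regions")
  expect_error(aging_model_params(base_density = 0), "base_density")
})

test_that("aging degradation follows the bounded decay law", {
  params <- aging_model_params(n_regions = 20, seed = 5)
  base <- generate_base_connectome(params, 1)

  # age zero is the identity
  expect_identical(apply_aging_degradation(base, 0, params)$weights,
                   base$weights)
  expect_error(apply_aging_degradation(base, -1, params), "age")

  # uniform attenuation (bias 0, no noise): every weight scaled by exp(-r a)
  uni <- aging_model_params(n_regions = 20, seed = 5, weak_edge_bias = 0,
                            edge_noise_sd = 0)
  aged <- apply_aging_degradation(base, 40, uni, degradation_seed = 9)
  f <- exp(-uni$attenuation_rate * 40)
  expect_equal(aged$weights, base$weights * f, tolerance = 1e-12)

  # with weak-edge bias and no noise, weaker edges lose a larger fraction
  bias <- aging_model_params(n_regions = 20, seed = 5, weak_edge_bias = 3,
                             edge_noise_sd = 0)
  aged_b <- apply_aging_degradation(base, 40, bias, degradation_seed = 9)
  ut <- upper.tri(base$weights)
  nz <- base$weights[ut] > 0
  ratio <- (aged_b$weights[ut] / base$weights[ut])[nz]
  w <- base$weights[ut][nz]
  ord <- order(w)
  expect_true(all(diff(ratio[ord]) >= -1e-12))  # retained fraction increasing in w

  # monotone in age for a fixed degradation seed, no new edges, bounded
  prev <- base
  for (a in c(10, 30, 60, 90)) {
    cur <- apply_aging_degradation(base, a, params, degradation_seed = 7)
    expect_true(all(cur$weights <= prev$weights + 1e-15))
    expect_true(all((cur$weights == 0) == (base$weights == 0)))
    prev <- cur
  }
})

test_that("cohorts are reproducible with coupled scores and metadata", {
  params <- aging_model_params(n_regions = 20, seed = 8)
  co <- generate_cohort(10, c(18, 88), params)
  expect_length(co$connectomes, 10)
  expect_equal(nrow(co$metadata), 10)
  expect_named(co$metadata,
               c("subject_id", "age", "sex", "education", "group",
                 "global_cognition", "memory", "visual_stm", "executive",
                 "psychomotor"))
  co2 <- generate_cohort(10, c(18, 88), params)
  expect_identical(co2$metadata, co$metadata)
  expect_identical(co2$connectomes[[7]]$weights, co$connectomes[[7]]$weights)

  # zero coupling: scores decorrelated from network integrity (null band)
  null_p <- aging_model_params(n_regions = 20, seed = 9,
                               cognition_coupling = 0)
  con <- generate_cohort(200, c(18, 88), null_p)
  mean_w <- vapply(con$connectomes, function(x) {
    mean(x$weights[upper.tri(x$weights)])
  }, numeric(1))
  expect_lt(abs(cor(mean_w, con$metadata$memory)), 0.2)
})

test_that("old groups have lower mean edge weight under strong attenuation", {
  params <- aging_model_params(n_regions = 30, seed = 4,
                               attenuation_rate = 0.05, weak_edge_bias = 0)
  ages <- c(runif(50, 20, 40), runif(50, 55, 80))
  co <- generate_cohort(100, ages, params,
                       group = rep(c("young", "old"), each = 50))
  mean_w <- vapply(co$connectomes, function(x) {
    mean(x$weights[upper.tri(x$weights)])
  }, numeric(1))
  g <- co$metadata$group
  res <- permutation_group_test(mean_w[g == "old"], mean_w[g == "young"],
                                n_perm = 999, seed = 2, n_boot = 100)
  expect_lt(res$difference, 0)
  expect_lt(res$p, 0.05)
})

test_that("cohorts round-trip through a directory", {
  params <- aging_model_params(n_regions = 10, seed = 2)
  co <- generate_cohort(3, c(20, 70), params)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$metadata$age, co$metadata$age)
  expect_identical(back$connectomes[[2]]$weights, co$connectomes[[2]]$weights)
})

test_that("planted modules are complete, guarded and deterministic", {
  params <- aging_model_params(seed = 42, weight_sigma = 0.75, n_modules = 19,
                               module_mixing = 0.25, between_scale = 0.4)
  planted <- planted_module(params)
  expect_length(planted, 5)
  tmpl <- cohort_template(params)
  expect_true(all(tmpl$modules[planted] == tmpl$modules[planted[1]]))
  expect_identical(planted_module(params), planted)
  # guard: if any 5-region module avoids the 20 strongest edges, the
  # chosen one does
  w <- tmpl$weights
  ut <- which(upper.tri(w), arr.ind = TRUE)
  top <- unique(as.vector(ut[order(w[ut], decreasing = TRUE)[1:20], ]))
  sizes <- table(tmpl$modules)
  five <- as.integer(names(sizes)[sizes == 5])
  clean_exists <- any(vapply(five, function(k) {
    !any(which(tmpl$modules == k) %in% top)
  }, logical(1)))
  if (clean_exists) expect_length(intersect(planted, top), 0)
})
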