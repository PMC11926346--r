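test_that("protocol enforces the washout and delay-range invariants", {
  p <- reservoir_protocol()
  expect_equal(p$washout, 1000)
  expect_equal(p$T - p$washout, 19000)
  expect_error(reservoir_protocol(T = 100, washout_fraction = 0.05),
               "washout")
  expect_error(reservoir_protocol(tau_mc = 6:40), "subset")
  expect_error(reservoir_protocol(tau_curve = 0:35), "delays")
})

test_that("drives are deterministic, in range and unbiased", {
  p <- tiny_protocol(T = 100000, n_trials = 2, seed = 7)
  d1 <- sample_drive(p, 10, 1)
  d2 <- sample_drive(p, 10, 1)
  expect_identical(d1, d2)
  d3 <- sample_drive(p, 10, 2)
  expect_false(identical(d1$u, d3$u))
  expect_length(d1$u, 100000)
  expect_length(d1$w_in, 10)
  expect_true(all(d1$u > 0 & d1$u < 1))
  expect_lt(abs(mean(d1$u) - 0.5), 0.01)  # law of large numbers band
  expect_error(sample_drive(p, 10, 3), "trial_index")
})

test_that("reservoir states follow the tanh recurrence exactly", {
  p <- reservoir_protocol(T = 40, washout_fraction = 0.1, tau_curve = 1:3,
                          tau_mc = 1:3, n_trials = 1, master_seed = 1)
  drive <- sample_drive(p, 2, 1)
  W <- matrix(c(0, 0.6, 0.6, 0), 2) / 0.6 * 0.5  # sigma_max = 0.5
  R <- simulate_reservoir(W, drive$w_in, drive$u, p)
  expect_equal(dim(R), c(2, 40 - 4))
  # hand-iterated oracle
  r <- c(0, 0)
  states <- matrix(0, 2, 40)
  for (t in 1:40) {
    states[, t] <- r
    r <- tanh(drive$w_in * drive$u[t] + W %*% r)
  }
  expect_equal(R, states[, 5:40], tolerance = 1e-12)
  expect_true(all(abs(R) < 1))

  # decoupled nodes: each state is a pointwise function of the last input
  R0 <- simulate_reservoir(matrix(0, 2, 2), drive$w_in, drive$u, p)
  expect_equal(R0[, 2], tanh(drive$w_in * drive$u[5]), tolerance = 1e-12)

  expect_error(simulate_reservoir(W * 10, drive$w_in, drive$u, p),
               "not spectrally normalized")
})

test_that("readout training equals minimum-norm least squares", {
  set.seed(1)
  # a target inside the row space is reproduced perfectly
  R <- matrix(rnorm(5 * 60), 5)
  fit <- train_readout(R, R[3, ])
  expect_gt(cor(fit$prediction, R[3, ]), 1 - 1e-9)

  for (i in 1:20) {
    R <- matrix(rnorm(5 * 50), 5)
    y <- rnorm(50)
    fit <- train_readout(R, y)
    ref <- ref_min_norm_readout(R, y)
    expect_equal(fit$prediction, ref$prediction, tolerance = 1e-8)
  }

  # duplicated row: singular R R^T, still the minimum-norm solution
  R <- matrix(rnorm(4 * 50), 4)
  R[4, ] <- R[1, ]
  y <- rnorm(50)
  fit <- train_readout(R, y)
  ref <- ref_min_norm_readout(R, y)
  expect_true(all(is.finite(fit$w_out)))
  expect_equal(fit$prediction, ref$prediction, tolerance = 1e-8)
  expect_equal(fit$w_out, ref$w_out, tolerance = 1e-6)

  expect_error(train_readout(matrix(rnorm(10), 2), rnorm(4)), "target length")
})

test_that("forgetting curves match an independent reference pipeline", {
  p <- tiny_protocol(T = 300, seed = 13)
  c <- spectral_normalize(random_connectome(5, density = 0.8, seed = 3))
  for (trial in 1:2) {
    got <- forgetting_curve(c, p, trial)
    ref <- ref_forgetting_curve(c$weights, p, trial)
    expect_equal(got, ref, tolerance = 1e-10)
  }
  # single-node restriction agrees with the reference on that node's row
  got1 <- forgetting_curve(c, p, 1, node_subset = "R2")
  expect_true(all(got1 >= -1 & got1 <= 1))
})

test_that("memory capacity sums the stated delay range", {
  p <- reservoir_protocol()
  curve <- setNames(rep(0, 35), 1:35)
  expect_equal(memory_capacity(curve, p), 0)
  curve[] <- 1
  expect_equal(memory_capacity(curve, p), 30)
  curve[] <- 0
  curve["6"] <- 0.8
  curve["7"] <- 0.5
  expect_equal(memory_capacity(curve, p), 1.3)
  curve["10"] <- -0.2
  expect_equal(memory_capacity(curve, p), 1.1)
  expect_equal(memory_capacity(curve, p, clip_negative = TRUE), 1.3)
  expect_equal(memory_capacity(curve, p, squared = TRUE),
               0.8^2 + 0.5^2 + 0.2^2)
  expect_error(memory_capacity(curve[1:10], p), "missing delays")
})

test_that("global memory capacity averages trials reproducibly", {
  p1 <- tiny_protocol(T = 300, n_trials = 1, seed = 5)
  c <- spectral_normalize(random_connectome(6, seed = 4))
  single <- global_memory_capacity(c, p1)
  expect_equal(single$mc,
               memory_capacity(forgetting_curve(c, p1, 1), p1))

  p4 <- tiny_protocol(T = 300, n_trials = 4, seed = 5)
  multi <- global_memory_capacity(c, p4)
  per <- vapply(1:4, function(t) {
    memory_capacity(forgetting_curve(c, p4, t), p4)
  }, numeric(1))
  expect_equal(multi$per_trial, per, tolerance = 1e-12)
  expect_equal(multi$mc, mean(per), tolerance = 1e-12)
  expect_identical(global_memory_capacity(c, p4)$mc, multi$mc)
})

test_that("trial averaging reduces variance across master seeds", {
  c <- spectral_normalize(random_connectome(8, seed = 1))
  single <- vapply(1:12, function(s) {
    global_memory_capacity(c, tiny_protocol(T = 200, n_trials = 1,
                                            seed = s))$mc
  }, numeric(1))
  avg4 <- vapply(1:12, function(s) {
    global_memory_capacity(c, tiny_protocol(T = 200, n_trials = 4,
                                            seed = 100 + s))$mc
  }, numeric(1))
  expect_lt(sd(avg4) / sd(single), 1)
})

test_that("regional capacities use single-node readouts", {
  p <- tiny_protocol(T = 400, n_trials = 1, seed = 6)
  c <- spectral_normalize(random_connectome(6, seed = 9))
  reg <- regional_memory_capacities(c, p)
  expect_named(reg, c$region_labels)

  # matches the reference single-node pipeline
  for (i in c(1, 4)) {
    ref_curve <- forgetting_curve(c, p, 1, node_subset = i)
    expect_equal(unname(reg[i]), memory_capacity(ref_curve, p),
                 tolerance = 1e-10)
  }

  # in-sample subset property: no region beats the full readout by more
  # than numerical slack
  glob <- global_memory_capacity(c, p)
  expect_true(all(reg <= glob$mc + 0.05))

  # memoryless reservoir: all regional capacities near zero
  z <- connectome(matrix(0, 6, 6), paste0("R", 1:6))
  reg0 <- regional_memory_capacities(z, tiny_protocol(T = 2000, n_trials = 1))
  expect_true(all(abs(reg0) < 0.5))
})

test_that("lesional capacities equal full-minus-lesioned with shared drives", {
  p <- tiny_protocol(T = 300, n_trials = 2, seed = 8)
  c <- spectral_normalize(random_connectome(10, density = 0.7, seed = 12))
  delta <- lesional_memory_capacities(c, p)
  expect_named(delta, c$region_labels)

  full <- global_memory_capacity(c, p)$mc
  brute <- vapply(seq_len(10), function(i) {
    les <- spectral_normalize(lesion_node(c, c$region_labels[i]))
    full - global_memory_capacity(les, p, drive_dim = 10,
                                  drive_subset = setdiff(1:10, i))$mc
  }, numeric(1))
  expect_equal(unname(delta), brute, tolerance = 1e-12)
})

test_that("lesioning an isolated node leaves capacity almost unchanged", {
  # node 5 is isolated: the coupling matrix and sigma_max are unaffected by
  # its removal, so the only change is the loss of its (memoryless) state
  # row from the readout -- a small in-sample contribution that shrinks
  # with the series length
  w <- matrix(0, 5, 5)
  w[1, 2] <- w[2, 1] <- 0.8
  w[2, 3] <- w[3, 2] <- 0.5
  w[3, 4] <- w[4, 3] <- 0.3
  c <- spectral_normalize(connectome(w, paste0("R", 1:5)))
  p <- tiny_protocol(T = 3000, n_trials = 1, seed = 3)
  delta <- lesional_memory_capacities(c, p)
  # the lesioned coupling matrix is exactly the original minus row/col 5
  les <- spectral_normalize(lesion_node(c, "R5"))
  expect_equal(les$weights, c$weights[1:4, 1:4], tolerance = 1e-12)
  # so the delta reduces exactly to dropping node 5's row from the readout
  mc_full <- memory_capacity(forgetting_curve(c, p, 1), p)
  mc_sub <- memory_capacity(forgetting_curve(c, p, 1, node_subset = 1:4), p)
  expect_equal(unname(delta["R5"]), mc_full - mc_sub, tolerance = 1e-10)
})

test_that("curves and capacities respect their bounds on random inputs", {
  p <- tiny_protocol(T = 250, n_trials = 1, seed = 2)
  for (seed in 1:8) {
    c <- spectral_normalize(random_connectome(7, density = 0.6, seed = seed))
    curve <- forgetting_curve(c, p, 1)
    expect_true(all(curve >= -1 & curve <= 1))
    mc <- memory_capacity(curve, p)
    expect_lte(mc, length(p$tau_mc))
    expect_gt(mc, -1)
  }
})
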