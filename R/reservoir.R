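#' Reservoir simulation protocol
#'
#' Bundles every hyperparameter of the memory-capacity measurement. Defaults
#' follow the standard protocol for connectome reservoirs: 20,000 uniform(0,1)
#' input steps fed to all nodes through standard-normal input weights, tanh
#' units, the initial 5% of steps discarded as washout, forgetting curve over
#' delays 1..35, memory capacity summed over delays 6..35, averaged over 10
#' trials with fresh input series and input weights per trial.
#'
#' @param T input length in steps.
#' @param washout_fraction fraction of initial steps discarded; must satisfy
#'   `floor(washout_fraction * T) >= max(tau_curve)` so every delayed target
#'   is defined post-washout.
#' @param tau_curve integer delays of the forgetting curve.
#' @param tau_mc integer delays summed into memory capacity; must be a subset
#'   of `tau_curve`.
#' @param n_trials number of trials averaged.
#' @param master_seed integer master seed; all drives are substreams of it.
#' @return list of class `reservoir_protocol` (extra element `washout`, the
#'   number of discarded steps).
#' @export
reservoir_protocol <- function(T = 20000, washout_fraction = 0.05,
                               tau_curve = 1:35, tau_mc = 6:35,
                               n_trials = 10, master_seed = 42L) {
  washout <- floor(washout_fraction * T)
  if (any(tau_curve < 1)) stopf("delays must be >= 1")
  if (washout < max(tau_curve)) {
    stopf("washout (%d steps) must be >= max delay (%d)",
          washout, max(tau_curve))
  }
  if (!all(tau_mc %in% tau_curve)) {
    stopf("tau_mc must be a subset of tau_curve")
  }
  if (n_trials < 1) stopf("n_trials must be >= 1")
  structure(list(T = as.integer(T), washout_fraction = washout_fraction,
                 washout = as.integer(washout),
                 tau_curve = as.integer(tau_curve),
                 tau_mc = as.integer(tau_mc),
                 n_trials = as.integer(n_trials),
                 master_seed = as.integer(master_seed)),
            class = "reservoir_protocol")
}

#' Sample one trial's drive: input series and input weights
#'
#' The input series is i.i.d. uniform(0, 1); the input weight vector is
#' i.i.d. standard normal. Both are deterministic functions of
#' `(master_seed, trial_index)`, so trials are shared across subjects and
#' across the global, regional and lesional computations: between-subject
#' and between-density contrasts are never confounded by drive sampling.
#'
#' @param protocol a [reservoir_protocol()]
#' @param n_regions reservoir size (length of the input weight vector)
#' @param trial_index trial number, 1-based, `<= n_trials`
#' @return list with `u` (length `T`) and `w_in` (length `n_regions`)
#' @export
sample_drive <- function(protocol, n_regions, trial_index) {
  if (trial_index < 1 || trial_index > protocol$n_trials) {
    stopf("trial_index %d outside 1..%d", trial_index, protocol$n_trials)
  }
  seed <- substream_seed(protocol$master_seed, "drive", trial_index)
  with_seed(seed, {
    list(u = runif(protocol$T), w_in = rnorm(n_regions))
  })
}

check_normalized <- function(w) {
  smax <- norm(w, type = "2")
  if (smax > 1 + 1e-9) {
    stopf("connectome is not spectrally normalized (largest singular value %g)",
          smax)
  }
  invisible(smax)
}

#' Simulate the reservoir and return post-washout states
#'
#' Iterates `r(t+1) = tanh(W_in u(t) + W r(t))` from `r = 0` and discards the
#' first `floor(washout_fraction * T)` states. Column `j` of the result is
#' the state at input step `washout + j`.
#'
#' @param W a spectrally normalized `connectome` (or bare matrix)
#' @param w_in input weight vector
#' @param u input series
#' @param protocol a [reservoir_protocol()]
#' @return `n_regions x n_signal` state matrix, `n_signal = T - washout`
#' @export
simulate_reservoir <- function(W, w_in, u, protocol) {
  m <- as_connectome_matrix(W)
  check_normalized(m)
  if (length(w_in) != nrow(m)) stopf("w_in length does not match reservoir size")
  if (length(u) != protocol$T) stopf("input length %d != protocol T %d",
                                     length(u), protocol$T)
  .sim_states_cpp(m, w_in, u, protocol$washout)
}

#' Train the linear readout for one delayed target
#'
#' Computes `W_out = y R^T X_R`, where `X_R` is the Moore-Penrose
#' pseudoinverse of `R R^T` (singular values below `1e-12 * s_max` treated as
#' zero), i.e. the minimum-norm least-squares readout. No ridge penalty.
#'
#' @param R state matrix (`n x n_signal`), or a single activation row
#' @param target delayed input series aligned to the columns of `R`
#' @return list with `w_out` (readout weights) and `prediction`
#'   (`w_out %*% R`)
#' @export
train_readout <- function(R, target) {
  if (is.vector(R)) R <- matrix(R, nrow = 1)
  if (ncol(R) != length(target)) {
    stopf("target length %d does not match n_signal %d",
          length(target), ncol(R))
  }
  G <- R %*% t(R)
  smax <- norm(G, type = "2")
  X <- if (smax == 0) matrix(0, nrow(G), ncol(G)) else
    MASS::ginv(G, tol = 1e-12)
  w_out <- drop(target %*% t(R) %*% X)
  list(w_out = w_out, prediction = drop(w_out %*% R))
}

# correlation with the degenerate-case policy rho := 0
safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  r <- cor(a, b)
  if (!is.finite(r)) 0 else r
}

#' Forgetting curve of a connectome reservoir for one trial
#'
#' For each delay `tau` in `tau_curve`, trains an independent linear readout
#' to reproduce `y_tau(t) = u(t - tau)` and records the Pearson correlation
#' `rho(y_hat_tau, y_tau)` on the post-washout series. With `node_subset` of
#' length 1 this is the regional forgetting curve of that node (readout
#' restricted to the node's own activation series).
#'
#' @param W spectrally normalized `connectome`
#' @param protocol a [reservoir_protocol()]
#' @param trial_index trial number (selects the drive substream)
#' @param node_subset optional region labels restricting the readout
#' @return named numeric vector `rho` indexed by delay
#' @export
forgetting_curve <- function(W, protocol, trial_index = 1,
                             node_subset = NULL) {
  m <- as_connectome_matrix(W)
  check_normalized(m)
  drive <- sample_drive(protocol, nrow(m), trial_index)
  if (!is.null(node_subset)) {
    idx <- if (is.character(node_subset)) {
      match(node_subset, rownames(m))
    } else {
      as.integer(node_subset)
    }
    if (anyNA(idx)) stopf("unknown node(s) in node_subset")
    R <- .sim_states_cpp(m, drive$w_in, drive$u, protocol$washout)
    R <- R[idx, , drop = FALSE]
    rho <- vapply(protocol$tau_curve, function(tau) {
      j <- seq_len(ncol(R))
      y <- drive$u[protocol$washout + j - tau]
      fit <- train_readout(R, y)
      safe_cor(fit$prediction, y)
    }, numeric(1))
  } else {
    out <- .trial_curves_cpp(m, drive$w_in, drive$u, protocol$washout,
                             protocol$tau_curve, TRUE, FALSE)
    rho <- drop(out$global)
  }
  names(rho) <- protocol$tau_curve
  rho
}

#' Memory capacity from a forgetting curve
#'
#' `MC = sum of rho(tau) over tau in tau_mc` (default 6..35). The correlation
#' is summed unsquared and unclipped; set `squared = TRUE` for the classic
#' squared-correlation definition or `clip_negative = TRUE` to floor each
#' term at 0.
#'
#' @param curve named vector from [forgetting_curve()]
#' @param protocol a [reservoir_protocol()]
#' @param squared sum `rho^2` instead of `rho`
#' @param clip_negative floor each term at zero
#' @export
memory_capacity <- function(curve, protocol, squared = FALSE,
                            clip_negative = FALSE) {
  want <- as.character(protocol$tau_mc)
  if (!all(want %in% names(curve))) {
    stopf("curve is missing delays: %s",
          paste(setdiff(want, names(curve)), collapse = ", "))
  }
  rho <- unname(curve[want])
  if (clip_negative) rho <- pmax(rho, 0)
  if (squared) rho <- rho^2
  sum(rho)
}

# Shared worker: per-trial curves for global and/or regional readouts.
# drive_dim/drive_subset let a lesioned network reuse the full network's
# input-weight stream (components of removed nodes are dropped), so
# lesional deltas are not confounded by fresh input-weight draws.
trial_curve_set <- function(m, protocol, do_global, do_regional,
                            drive_dim = NULL, drive_subset = NULL) {
  n <- nrow(m)
  if (is.null(drive_dim)) drive_dim <- n
  g <- matrix(NA_real_, protocol$n_trials, length(protocol$tau_curve))
  r <- if (do_regional) {
    array(NA_real_, c(n, length(protocol$tau_curve), protocol$n_trials))
  }
  for (t in seq_len(protocol$n_trials)) {
    drive <- sample_drive(protocol, drive_dim, t)
    w_in <- if (is.null(drive_subset)) drive$w_in else drive$w_in[drive_subset]
    out <- .trial_curves_cpp(m, w_in, drive$u, protocol$washout,
                             protocol$tau_curve, do_global, do_regional)
    if (do_global) g[t, ] <- drop(out$global)
    if (do_regional) r[, , t] <- out$regional
  }
  colnames(g) <- protocol$tau_curve
  list(global = g, regional = r)
}

mc_from_rho <- function(rho_by_tau, protocol) {
  keep <- match(protocol$tau_mc, protocol$tau_curve)
  sum(rho_by_tau[keep])
}

#' Global memory capacity, averaged over trials
#'
#' Runs `n_trials` independent trials (fresh input series and input weights
#' per trial) and averages the per-trial memory capacities.
#'
#' @param W spectrally normalized `connectome`
#' @param protocol a [reservoir_protocol()]
#' @param drive_dim,drive_subset advanced: sample the input-weight vector at
#'   dimension `drive_dim` and keep components `drive_subset` (used by
#'   [lesional_memory_capacities()] to share drives with the full network).
#' @return list of class `global_mc`: `mc` (trial mean), `per_trial`, `sd`,
#'   and `curve` (trial-averaged forgetting curve).
#' @export
global_memory_capacity <- function(W, protocol,
                                   drive_dim = NULL, drive_subset = NULL) {
  m <- as_connectome_matrix(W)
  check_normalized(m)
  res <- trial_curve_set(m, protocol, TRUE, FALSE,
                         drive_dim, drive_subset)
  per_trial <- apply(res$global, 1, mc_from_rho, protocol = protocol)
  structure(list(mc = mean(per_trial), per_trial = per_trial,
                 sd = if (length(per_trial) > 1) sd(per_trial) else 0,
                 curve = colMeans(res$global)),
            class = "global_mc")
}

#' @export
print.global_mc <- function(x, ...) {
  cat(sprintf("global memory capacity: %.4f (sd %.4f over %d trials)\n",
              x$mc, x$sd, length(x$per_trial)))
  invisible(x)
}

#' Regional memory capacities
#'
#' For each region, the readout is trained and evaluated using only that
#' region's activation series (same trials and drives as the global
#' computation).
#'
#' @inheritParams global_memory_capacity
#' @return named numeric vector of per-region memory capacities
#' @export
regional_memory_capacities <- function(W, protocol) {
  m <- as_connectome_matrix(W)
  check_normalized(m)
  res <- trial_curve_set(m, protocol, FALSE, TRUE)
  keep <- match(protocol$tau_mc, protocol$tau_curve)
  per_trial <- apply(res$regional[, keep, , drop = FALSE], c(1, 3), sum)
  mc <- rowMeans(per_trial)
  names(mc) <- if (inherits(W, "connectome")) W$region_labels else
    rownames(m) %||% paste0("R", seq_len(nrow(m)))
  mc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lesional memory capacities
#'
#' For each region `i`, `delta_MC_i = MC(full) - MC(network with region i
#' removed)`. The lesioned network is re-normalized spectrally before
#' simulation, and reuses the full network's drive substreams (the removed
#' region's input-weight component is dropped), so the contrast isolates the
#' structural effect of the lesion.
#'
#' @inheritParams global_memory_capacity
#' @return named numeric vector of per-region `delta_MC`
#' @export
lesional_memory_capacities <- function(W, protocol) {
  if (!inherits(W, "connectome")) W <- connectome(W)
  if (n_regions(W) < 3) stopf("lesional analysis needs >= 3 regions")
  full <- global_memory_capacity(W, protocol)
  n <- n_regions(W)
  delta <- vapply(seq_len(n), function(i) {
    les <- spectral_normalize(lesion_node(W, W$region_labels[i]))
    part <- global_memory_capacity(les, protocol,
                                   drive_dim = n,
                                   drive_subset = setdiff(seq_len(n), i))
    full$mc - part$mc
  }, numeric(1))
  names(delta) <- W$region_labels
  delta
}
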