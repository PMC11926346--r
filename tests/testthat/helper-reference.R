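# Shared fixtures and independent oracle implementations.

# small symmetric toy connectome with given upper-triangle weights
toy_connectome <- function(w_upper, n = NULL, labels = NULL, id = "toy") {
  if (is.null(n)) n <- (1 + sqrt(1 + 8 * length(w_upper))) / 2
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- w_upper
  m <- m + t(m)
  if (is.null(labels)) labels <- LETTERS[seq_len(n)]
  dimnames(m) <- list(labels, labels)
  connectome(m, labels, id)
}

# random symmetric nonnegative matrix (for property tests)
random_connectome <- function(n, density = 0.5, seed = 1, id = "rand") {
  set.seed(seed)
  npairs <- n * (n - 1) / 2
  w <- ifelse(runif(npairs) < density, runif(npairs), 0)
  toy_connectome(w, n, paste0("R", seq_len(n)), id)
}

# short protocol for unit tests: washout 30 covers delays up to 8
tiny_protocol <- function(T = 300, n_trials = 2, seed = 42L,
                          tau_curve = 1:8, tau_mc = 2:8) {
  reservoir_protocol(T = T, washout_fraction = 0.1, tau_curve = tau_curve,
                     tau_mc = tau_mc, n_trials = n_trials,
                     master_seed = seed)
}

# independent minimum-norm least squares through the SVD of R (a different
# computational route than the package's pinv(R R^T) formula)
ref_min_norm_readout <- function(R, y, tol = 1e-10) {
  sv <- svd(R)
  keep <- sv$d > tol * max(sv$d)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  w <- drop(y %*% sv$v %*% (t(sv$u) * dinv))
  list(w_out = w, prediction = drop(w %*% R))
}

# independently coded forgetting-curve pipeline: plain R loop for the
# dynamics, SVD route for the readout
ref_forgetting_curve <- function(W, protocol, trial_index) {
  m <- if (inherits(W, "connectome")) W$weights else W
  drive <- sample_drive(protocol, nrow(m), trial_index)
  T <- protocol$T
  washout <- protocol$washout
  r <- rep(0, nrow(m))
  R <- matrix(0, nrow(m), T - washout)
  for (t in seq_len(T)) {
    if (t > washout) R[, t - washout] <- r
    if (t < T) r <- tanh(drive$w_in * drive$u[t] + drop(m %*% r))
  }
  rho <- vapply(protocol$tau_curve, function(tau) {
    y <- drive$u[washout + seq_len(ncol(R)) - tau]
    pred <- ref_min_norm_readout(R, y)$prediction
    if (sd(pred) == 0 || sd(y) == 0) 0 else cor(pred, y)
  }, numeric(1))
  names(rho) <- protocol$tau_curve
  rho
}
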