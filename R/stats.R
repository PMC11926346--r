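#' Nonparametric permutation test for a two-group mean difference
#'
#' Statistic: `mean(a) - mean(b)`. Group labels are shuffled without
#' replacement; the two-tailed p-value uses the add-one convention
#' `p = (1 + #{|perm| >= |obs|}) / (n_perm + 1)`, so p is never 0 and is
#' bounded below by `1/(n_perm + 1)`. Also reports Cohen's d (pooled sd) and
#' a percentile-bootstrap 95% CI of the difference.
#'
#' @param a,b numeric vectors (both length >= 2)
#' @param n_perm number of permutations (default 10000)
#' @param seed integer seed
#' @param exact enumerate all group assignments instead of sampling; p is
#'   then the exact proportion `#{|perm| >= |obs|} / n_assignments`
#' @param n_boot bootstrap resamples for the CI (default 2000)
#' @return list of class `group_test`: `difference`, `p`, `ci`, `cohen_d`,
#'   `n_perm`
#' @export
permutation_group_test <- function(a, b, n_perm = 10000, seed = 1L,
                                   exact = FALSE, n_boot = 2000) {
  if (length(a) < 2 || length(b) < 2) stopf("both groups need >= 2 values")
  if (n_perm < 1) stopf("n_perm must be >= 1")
  pooled <- c(a, b)
  na <- length(a); nb <- length(b)
  obs <- mean(a) - mean(b)
  if (exact) {
    combs <- combn(na + nb, na)
    stats <- apply(combs, 2, function(idx) {
      mean(pooled[idx]) - mean(pooled[-idx])
    })
    p <- mean(abs(stats) >= abs(obs) - 1e-12)
    n_perm <- ncol(combs)
  } else {
    stats <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(na + nb, na)
        mean(pooled[idx]) - mean(pooled[-idx])
      }, numeric(1))
    })
    p <- (1 + sum(abs(stats) >= abs(obs) - 1e-12)) / (n_perm + 1)
  }
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  d <- if (sp == 0) 0 else obs / sp
  ci <- with_seed(substream_seed(seed, "boot"), {
    boots <- vapply(seq_len(n_boot), function(i) {
      mean(a[sample.int(na, na, replace = TRUE)]) -
        mean(b[sample.int(nb, nb, replace = TRUE)])
    }, numeric(1))
    quantile(boots, c(0.025, 0.975), names = FALSE)
  })
  structure(list(difference = obs, p = p, ci = ci, cohen_d = d,
                 n_perm = n_perm),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("difference %.4f (95%% CI %.4f..%.4f), p = %.4g, Cohen's d = %.3f\n",
              x$difference, x$ci[1], x$ci[2], x$p, x$cohen_d))
  invisible(x)
}

#' Per-density group differences in global memory capacity
#'
#' Runs [permutation_group_test()] at every density of the common grid,
#' comparing two groups of capacity profiles.
#'
#' @param profiles list of `capacity_profile` (one per subject)
#' @param groups factor/character vector of length `length(profiles)` with
#'   exactly two levels; the difference is level1 minus level2
#' @param n_perm permutations per density
#' @param seed integer seed
#' @return data.frame: density, difference, ci_low, ci_high, p, cohen_d
#' @export
density_difference_curve <- function(profiles, groups, n_perm = 10000,
                                     seed = 1L) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stopf("groups must have exactly two levels")
  grid <- profiles[[1]]$densities
  for (p in profiles) {
    if (!identical(p$densities, grid)) stopf("profiles on mismatched grids")
  }
  mc <- vapply(profiles, function(p) p$global_mc, numeric(length(grid)))
  if (length(grid) == 1) mc <- matrix(mc, nrow = 1)
  if (anyNA(mc)) stopf("missing memory capacity values in profiles")
  lv <- levels(groups)
  out <- lapply(seq_along(grid), function(i) {
    r <- permutation_group_test(mc[i, groups == lv[1]],
                                mc[i, groups == lv[2]],
                                n_perm = n_perm,
                                seed = substream_seed(seed, grid[i]))
    data.frame(density = grid[i], difference = r$difference,
               ci_low = r$ci[1], ci_high = r$ci[2], p = r$p,
               cohen_d = r$cohen_d)
  })
  do.call(rbind, out)
}

#' Linear model of a band AUC on age with sex as covariate
#'
#' Ordinary least squares `auc ~ age + sex`; reports the coefficients, the
#' model's explained variance (R^2, percent) and the two-sided p-value of the
#' age coefficient.
#'
#' @param auc dependent values (one band AUC per subject)
#' @param age ages in years
#' @param sex covariate (factor or numeric)
#' @return list: `coefficients`, `explained_variance_pct`, `p_age`, `fit`
#' @export
auc_linear_model <- function(auc, age, sex) {
  df <- data.frame(auc = auc, age = age, sex = sex)
  fit <- if (length(unique(sex)) < 2) {
    lm(auc ~ age, data = df)  # covariate constant: drop it, not an error
  } else {
    lm(auc ~ age + sex, data = df)
  }
  sm <- summary(fit)
  if (fit$rank < length(coef(fit))) warnf("collinear design: rank-deficient fit")
  list(coefficients = coef(fit),
       explained_variance_pct = 100 * sm$r.squared,
       p_age = sm$coefficients["age", "Pr(>|t|)"],
       fit = fit)
}

# partial correlation of x and y given z, by residualizing both on z
partial_cor_test <- function(x, y, z) {
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(estimate = 0, p.value = 1, degenerate = TRUE))
  }
  rx <- resid(lm(x ~ z))
  ry <- resid(lm(y ~ z))
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(estimate = 0, p.value = 1, degenerate = TRUE))
  }
  ct <- cor.test(rx, ry)
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       degenerate = FALSE)
}

#' Regional age associations with FDR correction
#'
#' For each region, the partial Pearson correlation between regional memory
#' capacity and age controlling for sex (both residualized on sex), followed
#' by Benjamini-Hochberg correction across regions at level `q`. Regions with
#' constant capacity get `p = 1`.
#'
#' @param regional_mc subjects x regions matrix (or data.frame) of regional
#'   memory capacities
#' @param age ages in years
#' @param sex covariate
#' @param q FDR level (default 0.05)
#' @return data.frame: region, r (partial correlation), p, q_value,
#'   significant, sign
#' @export
regional_age_association <- function(regional_mc, age, sex, q = 0.05) {
  regional_mc <- as.matrix(regional_mc)
  if (nrow(regional_mc) != length(age)) {
    stopf("regional_mc rows (%d) must match length(age) (%d)",
          nrow(regional_mc), length(age))
  }
  z <- if (is.numeric(sex)) sex else as.numeric(as.factor(sex))
  res <- lapply(seq_len(ncol(regional_mc)), function(j) {
    partial_cor_test(regional_mc[, j], age, z)
  })
  p <- vapply(res, `[[`, numeric(1), "p.value")
  r <- vapply(res, `[[`, numeric(1), "estimate")
  qv <- p.adjust(p, method = "BH")
  data.frame(region = colnames(regional_mc) %||%
               paste0("R", seq_len(ncol(regional_mc))),
             r = r, p = p, q_value = qv,
             significant = qv < q,
             sign = sign(r),
             stringsAsFactors = FALSE)
}

#' Partial least squares regression with VIP predictor selection
#'
#' PLS1 via NIPALS with deflation on standardized predictors and response.
#' Variable importance in projection:
#' `VIP_j = sqrt(P * sum_a SS_a w_ja^2 / sum_a SS_a)` with `w_a` the unit
#' weight vectors and `SS_a` the response variance explained by latent
#' variable `a`. Predictors with `VIP > 1` are flagged as significant
#' contributors.
#'
#' @param predictors numeric matrix/data.frame (columns standardized
#'   internally)
#' @param response numeric response vector
#' @param n_lv number of latent variables (must not exceed the predictor
#'   rank)
#' @return list of class `vip_result`: `vip` (named), `n_lv`, `significant`
#'   (names with VIP > 1), `weights`, `ss`, plus regression coefficients on
#'   the standardized scale.
#' @export
pls_vip <- function(predictors, response, n_lv) {
  X <- scale(as.matrix(predictors))
  if (any(!is.finite(X))) {
    stopf("constant or non-finite predictor column(s): %s",
          paste(colnames(X)[!is.finite(colSums(X))], collapse = ", "))
  }
  y <- drop(scale(response))
  P <- ncol(X)
  rk <- qr(X)$rank
  if (n_lv > rk) stopf("n_lv (%d) exceeds predictor rank (%d)", n_lv, rk)
  n <- nrow(X)
  Wmat <- matrix(0, P, n_lv)
  ss <- numeric(n_lv)
  Xd <- X; yd <- y
  sstot <- sum(y^2)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      ss[a] <- 0
      break
    }
    w <- w / nw
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xd, t_a)) / tt
    q_a <- sum(yd * t_a) / tt
    ss[a] <- q_a^2 * tt / sstot
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - q_a * t_a
    Wmat[, a] <- w
  }
  denom <- sum(ss)
  vip <- if (denom == 0) rep(1, P) else
    sqrt(P * drop(Wmat^2 %*% ss) / denom)
  names(vip) <- colnames(X) %||% paste0("X", seq_len(P))
  structure(list(vip = vip, n_lv = n_lv,
                 significant = names(vip)[vip > 1],
                 weights = Wmat, ss = ss),
            class = "vip_result")
}

#' @export
print.vip_result <- function(x, ...) {
  cat(sprintf("PLS with %d latent variables; %d/%d predictors with VIP > 1\n",
              x$n_lv, length(x$significant), length(x$vip)))
  print(round(sort(x$vip, decreasing = TRUE), 3))
  invisible(x)
}
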