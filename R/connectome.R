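#' Construct a connectome object
#'
#' A connectome is a weighted, symmetric, nonnegative region-by-region matrix
#' with a zero diagonal. It is the coupling matrix of the reservoir: region
#' `i` and region `j` interact with strength `weights[i, j]`.
#'
#' @param weights square numeric matrix, symmetric, nonnegative, zero diagonal.
#'   Asymmetry up to `tol` is repaired by averaging with the transpose; larger
#'   asymmetry is an error.
#' @param region_labels character vector of region names; defaults to the
#'   matrix dimnames or `R1..Rn`.
#' @param subject_id identifier carried through the pipeline.
#' @param tol symmetrization tolerance.
#' @return an object of class `connectome` with elements `weights`,
#'   `region_labels`, `subject_id`.
#' @export
connectome <- function(weights, region_labels = NULL, subject_id = "subject",
                       tol = 1e-9) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stopf("weights must be a numeric matrix")
  }
  if (nrow(weights) != ncol(weights)) {
    stopf("weights must be square (got %d x %d)", nrow(weights), ncol(weights))
  }
  if (anyNA(weights)) {
    bad <- which(is.na(weights), arr.ind = TRUE)[1, ]
    stopf("NA/NaN weight at [%d, %d]", bad[1], bad[2])
  }
  if (any(weights < 0)) {
    bad <- which(weights < 0, arr.ind = TRUE)[1, ]
    stopf("negative weight %g at [%d, %d]", weights[bad[1], bad[2]],
          bad[1], bad[2])
  }
  asym <- max(abs(weights - t(weights)))
  if (asym > tol) {
    stopf("matrix asymmetry %g exceeds tolerance %g", asym, tol)
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(region_labels)) {
    region_labels <- rownames(weights)
    if (is.null(region_labels)) {
      region_labels <- paste0("R", seq_len(nrow(weights)))
    }
  }
  if (length(region_labels) != nrow(weights)) {
    stopf("%d region labels for a %d-region matrix",
          length(region_labels), nrow(weights))
  }
  dimnames(weights) <- list(region_labels, region_labels)
  structure(list(weights = weights,
                 region_labels = as.character(region_labels),
                 subject_id = as.character(subject_id)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome '%s': %d regions, density %.3f, weight range [%g, %g]\n",
              x$subject_id, n_regions(x), edge_density(x),
              min(x$weights), max(x$weights)))
  invisible(x)
}

#' Number of regions of a connectome
#' @param c a `connectome`
#' @export
n_regions <- function(c) length(c$region_labels)

#' Edge density of a connectome
#'
#' Fraction of the `n (n - 1) / 2` possible undirected edges with nonzero
#' weight.
#' @param c a `connectome`
#' @export
edge_density <- function(c) {
  n <- n_regions(c)
  ut <- c$weights[upper.tri(c$weights)]
  sum(ut > 0) / length(ut)
}

as_connectome_matrix <- function(c) {
  if (inherits(c, "connectome")) c$weights else c
}

#' Cohort-level edge consistency filter
#'
#' Computes, for every edge present in at least one subject, the coefficient
#' of variation (sd / mean) of its weight across subjects (absent edges count
#' as weight 0), and retains the edges whose CoV is at or below the given
#' percentile of the CoV distribution. The returned mask is applied to every
#' subject before density thresholding so that all subjects share a common
#' reliable edge set.
#'
#' @param cohort list of `connectome` objects with identical region labels.
#' @param percentile CoV percentile defining the cut (default 0.10).
#' @return logical matrix (`edge_mask` class attribute) with `TRUE` for
#'   retained edges; symmetric, diagonal `FALSE`.
#' @export
consistency_filter <- function(cohort, percentile = 0.10) {
  if (length(cohort) < 2) stopf("consistency_filter needs >= 2 subjects")
  labels <- cohort[[1]]$region_labels
  for (s in cohort) {
    if (!identical(s$region_labels, labels)) {
      stopf("mismatched region labels across cohort (subject '%s')",
            s$subject_id)
    }
  }
  n <- length(labels)
  arr <- vapply(cohort, function(s) s$weights[upper.tri(s$weights)],
                numeric(n * (n - 1) / 2))
  mu <- rowMeans(arr)
  sdev <- apply(arr, 1, sd)
  present <- mu > 0
  cov <- rep(NA_real_, length(mu))
  cov[present] <- sdev[present] / mu[present]
  cut <- quantile(cov[present], percentile, names = FALSE)
  keep_ut <- present & !is.na(cov) & cov <= cut
  mask <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  mask[upper.tri(mask)] <- keep_ut
  mask <- mask | t(mask)
  structure(mask, class = c("edge_mask", class(mask)))
}

#' Apply an edge mask to a connectome
#' @param c a `connectome`
#' @param mask logical matrix from [consistency_filter()]
#' @export
apply_edge_mask <- function(c, mask) {
  w <- c$weights
  w[!mask] <- 0
  connectome(w, c$region_labels, c$subject_id)
}

#' Proportional density thresholding
#'
#' Keeps the `k = floor(target_density * n (n - 1) / 2)` strongest undirected
#' edges at their original weights and zeroes the rest; weights are never
#' binarized. Ties are broken deterministically by (weight descending, row
#' index, column index), which makes retained edge sets nested across
#' densities.
#'
#' @param c a `connectome`
#' @param target_density fraction in (0, 1].
#' @return thresholded `connectome`. If `target_density` exceeds the current
#'   density a warning is issued and the input is returned unchanged.
#' @export
threshold_by_density <- function(c, target_density) {
  if (!is.numeric(target_density) || length(target_density) != 1 ||
      target_density <= 0 || target_density > 1) {
    stopf("target_density must be a single value in (0, 1]")
  }
  n <- n_regions(c)
  npairs <- n * (n - 1) / 2
  k <- floor(target_density * npairs)
  if (k < 1) stopf("target_density %g yields zero edges", target_density)
  cur <- edge_density(c)
  if (target_density > cur + 1e-12) {
    warnf("target density %.4f exceeds current density %.4f; returning input",
          target_density, cur)
    return(c)
  }
  ut <- which(upper.tri(c$weights), arr.ind = TRUE)
  w <- c$weights[upper.tri(c$weights)]
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(k)]
  out <- matrix(0, n, n)
  out[ut[keep, , drop = FALSE]] <- w[keep]
  out <- out + t(out)
  dimnames(out) <- dimnames(c$weights)
  connectome(out, c$region_labels, c$subject_id)
}

#' Spectral normalization
#'
#' Divides all weights by the largest singular value of the matrix so the
#' result has unit spectral norm, which keeps the tanh reservoir dynamics at
#' the edge of stability.
#'
#' @param c a `connectome`
#' @export
spectral_normalize <- function(c) {
  w <- c$weights
  if (all(w == 0)) stopf("cannot spectrally normalize an all-zero matrix")
  smax <- norm(w, type = "2")
  connectome(w / smax, c$region_labels, c$subject_id)
}

#' Remove a region and all its connections
#'
#' @param c a `connectome`
#' @param region region label (or vector of labels) to delete.
#' @return connectome over the remaining regions, weights untouched.
#' @export
lesion_node <- function(c, region) {
  idx <- match(region, c$region_labels)
  if (anyNA(idx)) {
    stopf("unknown region label(s): %s",
          paste(region[is.na(idx)], collapse = ", "))
  }
  keep <- setdiff(seq_along(c$region_labels), idx)
  if (length(keep) < 2) stopf("lesioning would leave fewer than 2 regions")
  connectome(c$weights[keep, keep, drop = FALSE],
             c$region_labels[keep], c$subject_id)
}
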