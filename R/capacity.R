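#' Density bands used for AUC summaries
#'
#' Low 2-10%, medium 11-20%, high 21-30% connection density.
#' @export
density_bands <- function() {
  list(low = 2:10, medium = 11:20, high = 21:30)
}

#' Memory capacity of one subject across a density grid
#'
#' For each density on the grid (percent of possible edges), the connectome
#' is proportionally thresholded, spectrally normalized, and its global (and
#' optionally regional) memory capacity computed. Drive substreams are shared
#' across densities within a subject, so density differences are not
#' confounded by drive noise. Densities exceeding the subject's available
#' density are recorded as missing, never extrapolated.
#'
#' @param c a `connectome` (unnormalized, already consistency-masked if a
#'   cohort mask is used)
#' @param protocol a [reservoir_protocol()]
#' @param densities integer percent grid (default 1:30)
#' @param regional also compute per-region memory capacities
#' @return list of class `capacity_profile`: `subject_id`, `densities`,
#'   `global_mc` (per density, NA where missing), `global_sd`, `regional_mc`
#'   (region x density matrix or NULL).
#' @export
subject_capacity_profile <- function(c, protocol, densities = 1:30,
                                     regional = FALSE) {
  if (length(densities) == 0) stopf("density grid is empty")
  if (is.unsorted(densities, strictly = TRUE)) {
    stopf("density grid must be strictly increasing")
  }
  avail <- edge_density(c)
  n <- n_regions(c)
  gmc <- gsd <- rep(NA_real_, length(densities))
  rmc <- if (regional) {
    matrix(NA_real_, n, length(densities),
           dimnames = list(c$region_labels, densities))
  }
  for (i in seq_along(densities)) {
    d <- densities[i] / 100
    if (d > avail + 1e-12) next  # missing, not extrapolated
    thr <- spectral_normalize(threshold_by_density(c, d))
    g <- global_memory_capacity(thr, protocol)
    gmc[i] <- g$mc
    gsd[i] <- g$sd
    if (regional) rmc[, i] <- regional_memory_capacities(thr, protocol)
  }
  structure(list(subject_id = c$subject_id, densities = densities,
                 global_mc = gmc, global_sd = gsd, regional_mc = rmc),
            class = "capacity_profile")
}

#' Band area under the memory-capacity-vs-density curve
#'
#' Trapezoidal integration of global memory capacity over the band's density
#' range in percent units (bands: low 2-10, medium 11-20, high 21-30).
#'
#' @param profile a [subject_capacity_profile()] result
#' @param band `"low"`, `"medium"` or `"high"`, or an integer density range
#' @return AUC in units of MC x percent
#' @export
band_auc <- function(profile, band = c("low", "medium", "high")) {
  rng <- if (is.character(band)) {
    density_bands()[[match.arg(band)]]
  } else {
    as.integer(band)
  }
  idx <- match(rng, profile$densities)
  if (anyNA(idx)) {
    stopf("band densities not on the profile grid: %s",
          paste(rng[is.na(idx)], collapse = ", "))
  }
  y <- profile$global_mc[idx]
  if (anyNA(y)) {
    stopf("missing memory capacity inside band at densities: %s",
          paste(rng[is.na(y)], collapse = ", "))
  }
  x <- profile$densities[idx]
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

#' Capacity profiles for a whole cohort
#'
#' Optionally applies a cohort-level consistency mask first, then computes
#' one [subject_capacity_profile()] per subject.
#'
#' @param connectomes list of `connectome`
#' @param protocol a [reservoir_protocol()]
#' @param densities percent grid
#' @param regional also compute regional memory capacities
#' @param mask optional [consistency_filter()] mask applied to every subject
#' @return list of `capacity_profile`
#' @export
cohort_capacity_profiles <- function(connectomes, protocol, densities = 1:30,
                                     regional = FALSE, mask = NULL) {
  lapply(connectomes, function(c) {
    if (!is.null(mask)) c <- apply_edge_mask(c, mask)
    subject_capacity_profile(c, protocol, densities, regional)
  })
}

#' Long-format table of cohort capacity profiles
#'
#' @param profiles list of `capacity_profile`
#' @return data.frame with columns subject_id, density, global_mc, global_sd
#' @export
capacity_long_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(subject_id = p$subject_id, density = p$densities,
               global_mc = p$global_mc, global_sd = p$global_sd,
               stringsAsFactors = FALSE)
  }))
}

#' Per-subject feature table: band AUCs (and optional regional features)
#'
#' One row per subject with `auc_low`, `auc_medium`, `auc_high`, plus, when
#' regional capacities were computed, the per-region memory capacity averaged
#' over the high band (the density range where aging effects concentrate).
#'
#' @param profiles list of `capacity_profile`
#' @param regional_band band over which regional capacities are averaged
#' @return data.frame keyed by `subject_id`
#' @export
capacity_feature_table <- function(profiles, regional_band = "high") {
  safe_auc <- function(p, band) {
    tryCatch(band_auc(p, band), error = function(e) NA_real_)
  }
  rows <- lapply(profiles, function(p) {
    row <- data.frame(subject_id = p$subject_id,
                      auc_low = safe_auc(p, "low"),
                      auc_medium = safe_auc(p, "medium"),
                      auc_high = safe_auc(p, "high"),
                      stringsAsFactors = FALSE)
    if (!is.null(p$regional_mc)) {
      rng <- if (is.character(regional_band)) {
        density_bands()[[regional_band]]
      } else {
        regional_band
      }
      idx <- match(rng, p$densities)
      reg <- rowMeans(p$regional_mc[, idx, drop = FALSE])
      row <- cbind(row, as.data.frame(t(reg)))
    }
    row
  })
  do.call(rbind, rows)
}
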