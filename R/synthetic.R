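#' Parameters of the synthetic aging-cohort generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' cohorts of 94-region symmetric nonnegative connectomes that share a
#' cohort-level anatomical template (as real cohorts share anatomy), with
#' heavy-tailed weights over a spatially modular geometric graph,
#' subject-level multiplicative weight variation, an age-dependent
#' degradation that concentrates on weak edges, and cognitive scores noisily
#' coupled to network integrity.
#'
#' The cohort template places regions uniformly in a unit cube, groups them
#' into spatial modules (k-means on the coordinates), draws
#' `round(base_density * n(n-1)/2)` edges with probability decaying with
#' inter-region distance and down-weighted between modules, and assigns
#' log-normal weights damped by distance and by module boundaries. Weights
#' are scaled to a maximum of 1. Heavy-tailed weights concentrate the
#' network's spectral structure on a strong sparse backbone, which is what
#' makes its memory capacity sensitive to the noisy degradation of the
#' remaining weak edges.
#'
#' The aging law multiplies each edge weight `w` by
#' `exp(-attenuation_rate * age * (1 - w)^weak_edge_bias * eps)`, with
#' `eps` log-normal with scale `edge_noise_sd`. The factor is in (0, 1],
#' decreases with age, and (for `weak_edge_bias > 0`) spares the strongest
#' edges, so degradation concentrates on weak, peripheral connections;
#' `weak_edge_bias = 0` gives uniform expected attenuation.
#'
#' @param n_regions number of regions (default 94).
#' @param base_density fraction of possible undirected edges present in the
#'   template (default 0.35, typical of deterministic-tractography
#'   connectomes).
#' @param weight_sigma log-scale sd of the log-normal edge weights (default
#'   2: heavy-tailed, streamline-count-like).
#' @param distance_scale length scale of the geometric decay of edge
#'   probability and weight (unit cube; default 1).
#' @param n_modules number of spatial modules (default 13).
#' @param module_mixing relative probability of between-module edges
#'   (default 0.5).
#' @param between_scale multiplicative weight penalty for between-module
#'   edges (default 0.7).
#' @param subject_sd log-scale sd of per-subject multiplicative edge-weight
#'   variation around the template (default 0.35).
#' @param attenuation_rate per-year decay rate of the aging law (default
#'   0.025 / year).
#' @param weak_edge_bias exponent >= 0 sparing strong edges (default 3).
#' @param edge_noise_sd log-scale sd of the per-edge aging noise `eps`
#'   (default 1: degradation is strongly heterogeneous across edges, the
#'   main driver of the age effect on memory capacity).
#' @param cognition_coupling slope linking standardized network integrity
#'   (mean edge weight) to cognitive scores (default 0.5).
#' @param cognition_noise_sd additive score noise sd (default 1).
#' @param affected_regions optional region indices; when given, only edges
#'   incident to these regions undergo aging attenuation (plants a
#'   regionally localized effect; see [planted_module()]).
#' @param isolate_affected when `TRUE` (and `affected_regions` is set), the
#'   template severs all edges between affected and unaffected regions, so
#'   the planted effect cannot propagate outside the affected set even
#'   dynamically. Used by planted-signal validation scenarios, where the
#'   premise is that *only* the affected regions carry the effect.
#' @param seed integer cohort seed; fixes the template and all subject
#'   substreams.
#' @return a list of class `aging_model_params`.
#' @export
aging_model_params <- function(n_regions = 94, base_density = 0.35,
                               weight_sigma = 2, distance_scale = 1,
                               n_modules = 13, module_mixing = 0.5,
                               between_scale = 0.7, subject_sd = 0.35,
                               attenuation_rate = 0.025,
                               weak_edge_bias = 3,
                               edge_noise_sd = 1,
                               cognition_coupling = 0.5,
                               cognition_noise_sd = 1,
                               affected_regions = NULL,
                               isolate_affected = FALSE,
                               seed = 1L) {
  if (n_regions < 2) stopf("n_regions must be >= 2")
  if (base_density <= 0 || base_density > 1) {
    stopf("base_density must be in (0, 1]")
  }
  if (weak_edge_bias < 0) stopf("weak_edge_bias must be >= 0")
  if (attenuation_rate < 0) stopf("attenuation_rate must be >= 0")
  structure(list(n_regions = n_regions, base_density = base_density,
                 weight_sigma = weight_sigma,
                 distance_scale = distance_scale,
                 n_modules = n_modules, module_mixing = module_mixing,
                 between_scale = between_scale, subject_sd = subject_sd,
                 attenuation_rate = attenuation_rate,
                 weak_edge_bias = weak_edge_bias,
                 edge_noise_sd = edge_noise_sd,
                 cognition_coupling = cognition_coupling,
                 cognition_noise_sd = cognition_noise_sd,
                 affected_regions = affected_regions,
                 isolate_affected = isTRUE(isolate_affected),
                 seed = as.integer(seed)),
            class = "aging_model_params")
}

#' Cohort-level connectome template
#'
#' Deterministic given `params$seed`. Returns the template weights (upper
#' triangle scaled to max 1), region coordinates and module assignment.
#'
#' @param params an [aging_model_params()] object
#' @return list with `weights` (n x n symmetric matrix), `positions`
#'   (n x 3), `modules` (integer vector)
#' @export
cohort_template <- function(params) {
  n <- params$n_regions
  npairs <- n * (n - 1) / 2
  m <- round(params$base_density * npairs)
  with_seed(substream_seed(params$seed, "template"), {
    pos <- matrix(runif(3 * n), ncol = 3)
    k <- min(params$n_modules, max(1, n %/% 3))
    modules <- if (k > 1) {
      stats::kmeans(pos, k, nstart = 5)$cluster
    } else {
      rep(1L, n)
    }
    d <- as.matrix(dist(pos))
    dv <- d[upper.tri(d)]
    ij <- which(upper.tri(d), arr.ind = TRUE)
    within <- modules[ij[, 1]] == modules[ij[, 2]]
    prob <- exp(-dv / params$distance_scale) *
      ifelse(within, 1, params$module_mixing)
    pick <- sample.int(npairs, m, prob = prob)
    w <- rep(0, npairs)
    w[pick] <- exp(rnorm(m, 0, params$weight_sigma) -
                     dv[pick] / params$distance_scale) *
      ifelse(within[pick], 1, params$between_scale)
    if (isTRUE(params$isolate_affected) &&
        length(params$affected_regions)) {
      cross <- xor(ij[, 1] %in% params$affected_regions,
                   ij[, 2] %in% params$affected_regions)
      w[cross] <- 0
    }
    w <- w / max(w)
    x <- matrix(0, n, n)
    x[upper.tri(x)] <- w
    x <- x + t(x)
    labels <- paste0("R", seq_len(n))
    dimnames(x) <- list(labels, labels)
    list(weights = x, positions = pos, modules = modules)
  })
}

#' Generate one base (undegraded) connectome
#'
#' The subject's connectome is the cohort template with per-edge
#' multiplicative log-normal variation (`subject_sd`), rescaled to a maximum
#' weight of 1. All subjects of a cohort share the template's topology, so
#' regional statistics are comparable across subjects.
#'
#' @param params an [aging_model_params()] object
#' @param subject_seed integer seed for this subject's weight variation
#' @param subject_id identifier
#' @param template optional precomputed [cohort_template()] (avoids
#'   recomputation in cohort loops)
#' @return a `connectome`
#' @export
generate_base_connectome <- function(params, subject_seed,
                                     subject_id = "subject",
                                     template = NULL) {
  if (is.null(template)) template <- cohort_template(params)
  tm <- template$weights
  ut <- upper.tri(tm)
  wv <- tm[ut]
  noise <- with_seed(subject_seed,
                     exp(rnorm(length(wv), 0, params$subject_sd)))
  wv <- wv * ifelse(wv > 0, noise, 0)
  wv <- wv / max(wv)
  x <- matrix(0, nrow(tm), ncol(tm), dimnames = dimnames(tm))
  x[ut] <- wv
  x <- x + t(x)
  connectome(x, rownames(tm), subject_id)
}

#' Apply age-dependent degradation to a connectome
#'
#' Each edge weight `w` becomes
#' `w * exp(-attenuation_rate * age * (1 - w)^weak_edge_bias * eps)` with
#' `eps = exp(rnorm(0, edge_noise_sd))` drawn once per edge from
#' `degradation_seed`. At `age = 0` the connectome is returned exactly
#' unchanged. Symmetry, nonnegativity and the zero pattern are preserved and
#' no weight ever increases. When `params$affected_regions` is set, only
#' edges incident to those regions are degraded.
#'
#' @param base a `connectome`
#' @param age age in years (>= 0)
#' @param params an [aging_model_params()] object
#' @param degradation_seed seed for the per-edge noise (defaults to a
#'   substream of `params$seed` and the subject id)
#' @export
apply_aging_degradation <- function(base, age, params,
                                    degradation_seed = NULL) {
  if (age < 0) stopf("age must be >= 0")
  if (age == 0) return(base)
  if (is.null(degradation_seed)) {
    degradation_seed <- substream_seed(params$seed, base$subject_id, "aging")
  }
  w <- base$weights
  ut <- upper.tri(w)
  wv <- w[ut]
  eps <- with_seed(degradation_seed,
                   exp(rnorm(length(wv), 0, params$edge_noise_sd)))
  expo <- params$attenuation_rate * age *
    (1 - wv)^params$weak_edge_bias * eps
  if (!is.null(params$affected_regions)) {
    idx <- which(ut, arr.ind = TRUE)
    touched <- idx[, 1] %in% params$affected_regions |
      idx[, 2] %in% params$affected_regions
    expo[!touched] <- 0
  }
  wv <- wv * exp(-expo)
  out <- matrix(0, nrow(w), ncol(w))
  out[ut] <- wv
  out <- out + t(out)
  dimnames(out) <- dimnames(w)
  connectome(out, base$region_labels, base$subject_id)
}

#' Pick a complete spatial module to carry a planted regional effect
#'
#' Returns the indices of a template module whose size is closest to `size`
#' (first `size` members if larger). Degrading the edges incident to a
#' complete module concentrates the effect on regions whose connection
#' strength is mostly internal, so regions outside the module keep almost
#' all of their own connectivity.
#'
#' @param params an [aging_model_params()] object
#' @param size target module size (default 5)
#' @return integer vector of region indices
#' @export
planted_module <- function(params, size = 5) {
  tmpl <- cohort_template(params)
  sizes <- table(tmpl$modules)
  cand <- as.integer(names(sizes)[sizes == size])
  if (!length(cand)) {
    cand <- as.integer(names(sizes)[which.min(abs(sizes - size))])
  }
  # regions on the strongest edges set the spectral norm; degrading them
  # would rescale the whole network, so modules touching them are excluded
  w <- tmpl$weights
  ut <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(w[ut], decreasing = TRUE)
  top_regions <- unique(as.vector(ut[ord[seq_len(min(20, nrow(ut)))], ]))
  # among candidate modules, take the one whose members keep the largest
  # minimum share of their strength inside the module, while no OUTSIDE
  # region depends heavily on its edges into the module (degrading the
  # module's incident edges would otherwise carry the effect to that
  # region too)
  module_score <- function(k, gate_top) {
    C <- which(tmpl$modules == k)
    if (gate_top && any(C %in% top_regions)) return(-Inf)
    s_in <- rowSums(w[C, C, drop = FALSE])
    s_all <- rowSums(w[C, , drop = FALSE])
    intra <- min(s_in / pmax(s_all, 1e-12))
    out <- setdiff(seq_len(nrow(w)), C)
    spill <- max(rowSums(w[out, C, drop = FALSE]) /
                   pmax(rowSums(w[out, , drop = FALSE]), 1e-12))
    intra - 2 * spill
  }
  score <- vapply(cand, module_score, numeric(1), gate_top = TRUE)
  if (all(!is.finite(score))) {
    # every candidate touches a top edge: keep the isolation score, drop
    # only the spectral gate
    score <- vapply(cand, module_score, numeric(1), gate_top = FALSE)
  }
  head(which(tmpl$modules == cand[which.max(score)]), size)
}

#' Generate a synthetic cohort of connectomes with metadata
#'
#' All subjects share the cohort template; each gets multiplicative weight
#' variation (subject seed = substream of the cohort seed and subject
#' index), then aging degradation at the subject's age. Cognitive scores are
#' `cognition_coupling * scale(mean edge weight) + noise`. Sex is assigned
#' at random and has no simulated effect; it is only a downstream covariate.
#'
#' @param n_subjects number of subjects (>= 2)
#' @param age_sampler either a function `n -> ages`, a numeric range
#'   `c(lo, hi)` sampled uniformly, or a vector of `n_subjects` fixed ages.
#' @param params an [aging_model_params()] object
#' @param group optional character vector of group labels per subject.
#' @param score_names names of the cognitive score columns.
#' @return list with `connectomes` (list of `connectome`), `metadata`
#'   (data.frame: subject_id, age, sex, education, group, scores) and
#'   `template` (the [cohort_template()] used).
#' @export
generate_cohort <- function(n_subjects, age_sampler, params,
                            group = NULL,
                            score_names = c("global_cognition", "memory",
                                            "visual_stm", "executive",
                                            "psychomotor")) {
  if (n_subjects < 2) stopf("n_subjects must be >= 2")
  ages <- with_seed(substream_seed(params$seed, "ages"), {
    if (is.function(age_sampler)) {
      age_sampler(n_subjects)
    } else if (length(age_sampler) == n_subjects && n_subjects != 2) {
      age_sampler
    } else if (length(age_sampler) == 2) {
      runif(n_subjects, age_sampler[1], age_sampler[2])
    } else {
      stopf("age_sampler must be a function, a range, or one age per subject")
    }
  })
  if (any(ages < 0)) stopf("ages must be >= 0")
  if (is.null(group)) group <- rep("all", n_subjects)
  ids <- sprintf("sub-%03d", seq_len(n_subjects))
  template <- cohort_template(params)
  connectomes <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    base <- generate_base_connectome(
      params, substream_seed(params$seed, i), subject_id = ids[i],
      template = template)
    connectomes[[i]] <- apply_aging_degradation(
      base, ages[i], params,
      degradation_seed = substream_seed(params$seed, i, "aging"))
  }
  mean_w <- vapply(connectomes, function(x) {
    mean(x$weights[upper.tri(x$weights)])
  }, numeric(1))
  meta <- with_seed(substream_seed(params$seed, "meta"), {
    sex <- sample(c("M", "F"), n_subjects, replace = TRUE)
    education <- round(runif(n_subjects, 8, 22))
    integrity <- if (sd(mean_w) > 0) as.numeric(scale(mean_w)) else
      rep(0, n_subjects)
    scores <- vapply(score_names, function(nm) {
      params$cognition_coupling * integrity +
        rnorm(n_subjects, 0, params$cognition_noise_sd)
    }, numeric(n_subjects))
    data.frame(subject_id = ids, age = ages, sex = sex,
               education = education, group = group, scores,
               stringsAsFactors = FALSE)
  })
  list(connectomes = connectomes, metadata = meta, template = template)
}

#' Write a cohort (connectomes + metadata) to a directory
#' @param cohort result of [generate_cohort()]
#' @param dir output directory (created if missing)
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (c in cohort$connectomes) {
    write_connectome(c, file.path(dir, paste0(c$subject_id, ".tsv")))
  }
  write_cohort_metadata(cohort$metadata, file.path(dir, "cohort.tsv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir cohort directory
#' @export
read_cohort <- function(dir) {
  meta <- read_cohort_metadata(file.path(dir, "cohort.tsv"))
  connectomes <- lapply(meta$subject_id, function(id) {
    read_connectome_matrix(file.path(dir, paste0(id, ".tsv")),
                           subject_id = id)
  })
  list(connectomes = connectomes, metadata = meta)
}
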