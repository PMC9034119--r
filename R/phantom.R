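#' Phantom configuration
#'
#' Defines a synthetic resting-state phantom: K spatially smooth "network"
#' maps (unions of Gaussian nodes) on a common grid, per-subject time series
#' generated as linear mixtures of those maps plus Gaussian noise, patient
#' lesions that attenuate or delete network nodes distal to the lesion site,
#' and behavior scores generated from a sparse non-negative linear model on
#' standardized component distances.
#'
#' The brain mask is an ellipsoid inscribed in the grid; its most inferior
#' slab is designated "cerebellum" so exclusion-mask logic is exercisable.
#'
#' @param grid_shape integer length-3; voxel grid dimensions.
#' @param n_components number of planted network maps K.
#' @param n_timepoints time series length T.
#' @param n_controls,n_patients cohort sizes.
#' @param smoothness_fwhm Gaussian node FWHM in voxels.
#' @param noise_sd additive Gaussian noise SD, in the same arbitrary units as
#'   the mixed signal (planted time courses have unit variance).
#' @param lesion_spec per-patient list; each element is a list of lesions,
#'   each lesion a list with `component` (index), `attenuation` in \[0,1\]
#'   (0 = node fully deleted, 1 = untouched) and `nodes` (indices of the
#'   component's nodes to attenuate; default all but the first, emulating
#'   preserved tissue near the lesion with distal disconnection). `NULL`
#'   gives each patient one fully deleted component (attenuation 0), cycling
#'   through components.
#' @param behavior_spec named list of cognitive domains; each a list with
#'   `coefs` (non-negative length-K vector), `intercept`, `noise_sd`.
#'   `NULL` gives the four standard domains with a 3-sparse attention model.
#' @param seed integer; every random draw in the phantom flows from it.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(12, 12, 12),
                           n_components = 5,
                           n_timepoints = 120,
                           n_controls = 10,
                           n_patients = 3,
                           smoothness_fwhm = 2.5,
                           noise_sd = 0.4,
                           lesion_spec = NULL,
                           behavior_spec = NULL,
                           seed = 1) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
            n_components >= 1, n_timepoints >= 8,
            n_controls >= 1, n_patients >= 0, noise_sd >= 0)
  if (is.null(lesion_spec)) {
    lesion_spec <- lapply(seq_len(n_patients), function(p) {
      list(list(component = ((p - 1L) %% n_components) + 1L,
                attenuation = 0, nodes = NULL))
    })
  }
  if (length(lesion_spec) != n_patients)
    stop("lesion_spec must have one entry per patient")
  for (pl in lesion_spec) for (ls in pl) {
    if (ls$component < 1 || ls$component > n_components)
      stop(sprintf("lesion references nonexistent component %d", ls$component))
    if (ls$attenuation < 0 || ls$attenuation > 1)
      stop("attenuation factor must lie in [0,1]")
  }
  if (is.null(behavior_spec)) {
    k3 <- pmin(n_components, 3L)
    att <- numeric(n_components)
    att[seq_len(k3)] <- c(0.8, 0.5, 0.3)[seq_len(k3)]
    zero <- numeric(n_components)
    behavior_spec <- list(
      memory    = list(coefs = zero, intercept = 0, noise_sd = 0.3),
      language  = list(coefs = zero, intercept = 0, noise_sd = 0.3),
      executive = list(coefs = zero, intercept = 0, noise_sd = 0.3),
      attention = list(coefs = att,  intercept = 0, noise_sd = 0.3))
  }
  for (d in behavior_spec) {
    if (any(d$coefs < 0)) stop("planted behavior coefficients must be non-negative")
    if (length(d$coefs) != n_components) stop("behavior coefs must have length K")
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 n_components = as.integer(n_components),
                 n_timepoints = as.integer(n_timepoints),
                 n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 smoothness_fwhm = smoothness_fwhm,
                 noise_sd = noise_sd,
                 lesion_spec = lesion_spec,
                 behavior_spec = behavior_spec,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

## Ellipsoidal brain mask inscribed in the grid, plus a "cerebellum" slab
## (inferior ~20% of in-mask z range) usable as an exclusion mask.
phantom_masks <- function(grid_shape) {
  d <- grid_shape
  ctr <- (d + 1) / 2
  ax <- (d - 1) / 2
  ix <- array(0, dim = d)
  co <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  r2 <- ((co$x - ctr[1]) / ax[1])^2 + ((co$y - ctr[2]) / ax[2])^2 +
        ((co$z - ctr[3]) / ax[3])^2
  brain <- array(r2 <= 1, dim = d)
  zmin <- min(co$z[as.vector(brain)])
  zmax <- max(co$z[as.vector(brain)])
  zcut <- zmin + floor(0.2 * (zmax - zmin))
  cereb <- brain & array(rep(seq_len(d[3]) <= zcut, each = d[1] * d[2]), dim = d)
  list(brain = brain, cerebellum = cereb)
}

## Gaussian kernel of one node over the whole grid (vectorized).
node_kernel <- function(grid_shape, center, sigma) {
  co <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                    z = seq_len(grid_shape[3]))
  d2 <- (co$x - center[1])^2 + (co$y - center[2])^2 + (co$z - center[3])^2
  array(exp(-d2 / (2 * sigma^2)), dim = grid_shape)
}

#' Generate ground-truth template networks
#'
#' Plants K spatially smooth maps, each the union of 2-5 Gaussian nodes at
#' distinct in-mask locations, with pairwise spatial correlation < 0.3.
#' Returns both the raw mixing maps (zero off-node, so a deleted node carries
#' no signal) and their Z-scored versions (mean 0, sd 1 within the brain
#' mask), which serve as the ground-truth templates.
#'
#' @param config a [phantom_config()].
#' @return an object of class `phantom_truth` with elements `raw_maps` and
#'   `zmaps` (voxels-in-mask x K matrices), `mask`, `cerebellum`, `nodes`
#'   (per-component list of node centers and sigma), `config`.
#' @export
make_template_networks <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_shape
  K <- config$n_components
  sigma <- config$smoothness_fwhm / (2 * sqrt(2 * log(2)))
  masks <- phantom_masks(d)
  brain <- masks$brain
  mask_idx <- which(brain, arr.ind = TRUE)
  nv <- nrow(mask_idx)
  set.seed(derive_seed(config$seed, 11))
  max_try <- 60L
  for (attempt in seq_len(max_try)) {
    n_nodes <- sample(2:5, K, replace = TRUE)
    if (K == 1 && config$grid_shape[1] < 8) n_nodes <- 2L
    centers <- list()
    all_ctr <- matrix(numeric(0), ncol = 3)
    ok <- TRUE
    for (k in seq_len(K)) {
      ck <- matrix(numeric(0), ncol = 3)
      guard <- 0L
      while (nrow(ck) < n_nodes[k]) {
        guard <- guard + 1L
        if (guard > 500L) { ok <- FALSE; break }
        cand <- mask_idx[sample.int(nv, 1), ]
        ## same-component nodes may sit closer than nodes of different
        ## components: cross-component overlap is what caps ICA recovery
        sep_own <- if (nrow(ck)) sqrt(rowSums((ck - matrix(cand, nrow(ck), 3, byrow = TRUE))^2)) else Inf
        sep_oth <- if (nrow(all_ctr)) sqrt(rowSums((all_ctr - matrix(cand, nrow(all_ctr), 3, byrow = TRUE))^2)) else Inf
        if (all(sep_own >= 2.2 * sigma) && all(sep_oth >= 3.5 * sigma)) ck <- rbind(ck, cand)
      }
      if (!ok) break
      centers[[k]] <- ck
      all_ctr <- rbind(all_ctr, ck)
    }
    if (!ok) next
    raw <- vapply(seq_len(K), function(k) {
      m <- Reduce(`+`, lapply(seq_len(nrow(centers[[k]])), function(j)
        node_kernel(d, centers[[k]][j, ], sigma)))
      m[!brain] <- 0
      vectorize(m, brain)
    }, numeric(nv))
    raw <- matrix(raw, nrow = nv, ncol = K)
    if (K > 1) {
      cc <- abs(stats::cor(raw))
      if (max(cc[upper.tri(cc)]) >= 0.3) next
    }
    zmaps <- apply(raw, 2, zscore_vec)
    zmaps <- matrix(zmaps, nrow = nv, ncol = K)
    return(structure(list(raw_maps = raw, zmaps = zmaps, mask = brain,
                          cerebellum = masks$cerebellum,
                          nodes = lapply(centers, function(cc)
                            list(centers = cc, sigma = sigma)),
                          config = config),
                     class = "phantom_truth"))
  }
  stop("grid too small to place the requested node sets with correlation < 0.3")
}

## Per-component attenuation vector over mask voxels for one patient.
## Attenuation multiplies the spatial map inside the selected nodes' regions
## (voxels within 2 sigma of the node center), so a component can stay
## intact proximally and be lost distally.
attenuation_vectors <- function(truth, lesions) {
  K <- truth$config$n_components
  nv <- nrow(truth$raw_maps)
  att <- matrix(1, nv, K)
  for (ls in lesions) {
    k <- ls$component
    nd <- truth$nodes[[k]]
    sel <- ls$nodes
    if (is.null(sel)) sel <- setdiff(seq_len(nrow(nd$centers)), 1L)
    if (length(sel) == 0L) sel <- seq_len(nrow(nd$centers))
    if (any(sel < 1 | sel > nrow(nd$centers)))
      stop("lesion node selector out of range")
    region <- rep(FALSE, nv)
    idx <- which(truth$mask, arr.ind = TRUE)
    for (j in sel) {
      d2 <- rowSums((idx - matrix(nd$centers[j, ], nrow(idx), 3, byrow = TRUE))^2)
      region <- region | (d2 <= (2 * nd$sigma)^2)
    }
    att[region, k] <- att[region, k] * ls$attenuation
  }
  att
}

## Smooth, mutually orthogonal unit-variance time courses (K x T).
make_timecourses <- function(K, T, seed) {
  set.seed(seed)
  w <- matrix(stats::rnorm(T * max(K, 1)), nrow = T)
  win <- max(3L, round(T / 15))
  sm <- apply(w, 2, function(x)
    as.numeric(stats::filter(x, rep(1 / win, win), sides = 2, circular = TRUE)))
  sm <- scale(sm, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(sm))[, seq_len(K), drop = FALSE]
  Q <- scale(Q, center = TRUE, scale = TRUE)  # mean 0, sd 1 columns
  t(Q)
}

#' Generate one subject's 4D time series
#'
#' Mixes the planted raw maps with smooth near-orthogonal unit-variance time
#' courses and adds Gaussian noise. For patients, the lesion specification
#' multiplies the selected nodes of the selected components by the
#' attenuation factor before mixing, emulating distal disconnection.
#'
#' @param truth a `phantom_truth` from [make_template_networks()].
#' @param subject_kind `"control"` or `"patient"`.
#' @param config the [phantom_config()].
#' @param subject_index 1-based index within its cohort; determines the
#'   subject's noise/time-course seed so subjects differ reproducibly.
#' @param noise_sd optional override of `config$noise_sd`.
#' @return an object of class `phantom_subject`: list with `data` (in-mask
#'   voxels x T matrix), `timecourses` (K x T), `kind`, `attenuation`
#'   (voxels x K), `mask`.
#' @export
make_subject_series <- function(truth, subject_kind = c("control", "patient"),
                                config, subject_index = 1L, noise_sd = NULL) {
  subject_kind <- match.arg(subject_kind)
  stopifnot(inherits(truth, "phantom_truth"))
  K <- config$n_components
  T <- config$n_timepoints
  nv <- nrow(truth$raw_maps)
  if (is.null(noise_sd)) noise_sd <- config$noise_sd
  kind_off <- if (subject_kind == "control") 100L else 200L
  tc <- make_timecourses(K, T, derive_seed(config$seed, kind_off, subject_index, 1))
  att <- if (subject_kind == "patient") {
    lesions <- config$lesion_spec[[subject_index]]
    attenuation_vectors(truth, lesions)
  } else matrix(1, nv, K)
  M <- truth$raw_maps * att
  X <- M %*% tc
  if (noise_sd > 0) {
    set.seed(derive_seed(config$seed, kind_off, subject_index, 2))
    X <- X + noise_sd * matrix(stats::rnorm(nv * T), nv, T)
  }
  structure(list(data = X, timecourses = tc, kind = subject_kind,
                 attenuation = att, mask = truth$mask),
            class = "phantom_subject")
}

## Ball mask (logical vector over mask voxels and full volume) around a center.
ball_mask <- function(mask, center, radius) {
  idx <- which(mask | !mask, arr.ind = TRUE)  # all voxels
  d2 <- rowSums((idx - matrix(center, nrow(idx), 3, byrow = TRUE))^2)
  vol <- array(d2 <= radius^2, dim = dim(mask))
  vol & mask
}

#' Generate per-patient lesion masks
#'
#' Places the tumour core at the first (preserved, proximal) node of the
#' patient's first lesioned component and grows the oedema as a concentric
#' shell, both clipped to the brain mask.
#'
#' @param truth a `phantom_truth`.
#' @param config the [phantom_config()].
#' @param core_radius,oedema_radius ball radii in voxels.
#' @return list (one per patient) of lists with logical volumes `tm`
#'   (tumour core) and `tm_o` (tumour + oedema).
#' @export
make_lesion_masks <- function(truth, config, core_radius = 1.6,
                              oedema_radius = 3.0) {
  lapply(seq_len(config$n_patients), function(p) {
    ls <- config$lesion_spec[[p]][[1]]
    ctr <- truth$nodes[[ls$component]]$centers[1, ]
    tm <- ball_mask(truth$mask, ctr, core_radius)
    tm_o <- ball_mask(truth$mask, ctr, oedema_radius)
    tm_o <- tm_o | tm
    list(tm = tm, tm_o = tm_o)
  })
}

#' Generate behavior scores from a planted linear model
#'
#' For each cognitive domain, `score_p = intercept + sum_k coef_k *
#' delta_cs[p, k] + noise`, with non-negative planted coefficients.
#'
#' @param truth a `phantom_truth` (supplies the seed lineage and K).
#' @param delta_cs_matrix patients x components matrix of standardized
#'   component distances.
#' @param config the [phantom_config()] carrying `behavior_spec`.
#' @return data.frame with columns `patient`, `domain`, `score`.
#' @export
make_behavior_scores <- function(truth, delta_cs_matrix, config) {
  stopifnot(is.matrix(delta_cs_matrix),
            ncol(delta_cs_matrix) == config$n_components)
  if (any(!is.finite(delta_cs_matrix)))
    stop("delta_cs_matrix must be finite")
  np <- nrow(delta_cs_matrix)
  out <- list()
  for (i in seq_along(config$behavior_spec)) {
    dn <- names(config$behavior_spec)[i]
    sp <- config$behavior_spec[[i]]
    set.seed(derive_seed(config$seed, 777, i))
    eps <- if (sp$noise_sd > 0) stats::rnorm(np, 0, sp$noise_sd) else numeric(np)
    sc <- sp$intercept + as.numeric(delta_cs_matrix %*% sp$coefs) + eps
    out[[i]] <- data.frame(patient = seq_len(np), domain = dn, score = sc,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a complete phantom cohort
#'
#' Convenience wrapper: templates, control and patient time series, lesion
#' masks, and the set of planted-altered component indices per patient.
#'
#' @param config a [phantom_config()].
#' @return list with `truth`, `controls`, `patients` (lists of
#'   `phantom_subject`), `lesions`, `true_altered` (list of integer vectors).
#' @export
generate_phantom <- function(config) {
  truth <- make_template_networks(config)
  controls <- lapply(seq_len(config$n_controls), function(i)
    make_subject_series(truth, "control", config, i))
  patients <- lapply(seq_len(config$n_patients), function(i)
    make_subject_series(truth, "patient", config, i))
  lesions <- make_lesion_masks(truth, config)
  true_altered <- lapply(config$lesion_spec, function(pl)
    sort(unique(vapply(pl, function(ls) as.integer(ls$component), integer(1)))))
  list(truth = truth, controls = controls, patients = patients,
       lesions = lesions, true_altered = true_altered, config = config)
}
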