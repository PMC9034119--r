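#' Component mask parameters
#'
#' Rules turning a Z-scored template map into the representative analysis
#' mask on which cosine similarity is computed: threshold at `Z >
#' z_thresh`, keep only connected clusters of at least `min_cluster_voxels`
#' voxels, then remove exclusion-mask voxels (e.g. cerebellum).
#'
#' @param z_thresh Z threshold (default 1).
#' @param min_cluster_voxels minimum connected-cluster extent (default 200;
#'   "at least" semantics, a cluster exactly at the minimum survives).
#' @param exclusion_mask optional logical 3D array (same grid as the brain
#'   mask) of voxels to drop after cluster filtering.
#' @param connectivity 6, 18 or 26-neighborhood for cluster labeling.
#' @return an object of class `mask_params`.
#' @export
mask_params <- function(z_thresh = 1, min_cluster_voxels = 200L,
                        exclusion_mask = NULL, connectivity = 6L) {
  if (min_cluster_voxels < 1) stop("min_cluster_voxels must be >= 1")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  structure(list(z_thresh = z_thresh,
                 min_cluster_voxels = as.integer(min_cluster_voxels),
                 exclusion_mask = exclusion_mask,
                 connectivity = as.integer(connectivity)),
            class = "mask_params")
}

## Label connected components of a logical 3D volume. Returns an integer
## array (0 outside). Uses the voxel adjacency graph and igraph components.
label_clusters <- function(vol, connectivity = 6L) {
  d <- dim(vol)
  idx <- which(vol)
  lab <- array(0L, dim = d)
  if (length(idx) == 0L) return(lab)
  pos <- arrayInd(idx, d)
  key <- (pos[, 1] - 1L) + d[1] * ((pos[, 2] - 1L) + d[2] * (pos[, 3] - 1L))
  offs <- switch(as.character(connectivity),
    "6" = rbind(c(1,0,0), c(0,1,0), c(0,0,1)),
    "18" = {
      o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      o <- o[rowSums(abs(o)) %in% c(1, 2), , drop = FALSE]
      o[o %*% c(1, 10, 100) > 0, , drop = FALSE]  # half-space: each pair once
    },
    "26" = {
      o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
      o[o %*% c(1, 10, 100) > 0, , drop = FALSE]
    })
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    np <- sweep(pos, 2, offs[r, ], `+`)
    ok <- np[, 1] >= 1 & np[, 1] <= d[1] & np[, 2] >= 1 & np[, 2] <= d[2] &
          np[, 3] >= 1 & np[, 3] <= d[3]
    if (!any(ok)) next
    nk <- (np[ok, 1] - 1L) + d[1] * ((np[ok, 2] - 1L) + d[2] * (np[ok, 3] - 1L))
    from <- which(ok)
    to <- match(nk, key)
    keep <- !is.na(to)
    if (any(keep)) edges[[length(edges) + 1L]] <- cbind(from[keep], to[keep])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Build the representative component mask
#'
#' Threshold at `Z > z_thresh`, connected-component labeling, removal of
#' clusters below `min_cluster_voxels`, then removal of exclusion-mask
#' voxels (in that order).
#'
#' @param template template component (list with `map`, Z-scored over mask
#'   voxels) or a bare map vector.
#' @param brain_mask logical 3D array locating the mask voxels on the grid.
#' @param params a [mask_params()].
#' @return list of class `component_mask`: `mask` (logical vector over brain
#'   mask voxels), `n_voxels`, `usable` (FALSE when the final mask is
#'   empty), `n_clusters_kept`, `n_clusters_dropped`.
#' @export
build_component_mask <- function(template, brain_mask, params = mask_params()) {
  map <- if (is.list(template)) template$map else template
  supra <- devectorize(as.numeric(map > params$z_thresh), brain_mask) > 0
  lab <- label_clusters(supra, params$connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= params$min_cluster_voxels)
  vol <- array(lab %in% keep, dim = dim(lab))
  if (!is.null(params$exclusion_mask)) {
    stopifnot(identical(dim(params$exclusion_mask), dim(brain_mask)))
    vol <- vol & !params$exclusion_mask
  }
  mask_vec <- vectorize(vol, brain_mask) > 0
  n <- sum(mask_vec)
  if (n == 0L)
    warning("component mask empty after filtering; component marked unusable")
  structure(list(mask = mask_vec, n_voxels = n, usable = n > 0L,
                 n_clusters_kept = length(keep),
                 n_clusters_dropped = length(sizes) - length(keep)),
            class = "component_mask")
}

#' Cosine similarity between template and subject maps
#'
#' The alteration statistic's core: the normalized dot product of the two
#' mask-restricted map vectors. Sensitive to both the spatial pattern and
#' the magnitude of the component (Z values are used, not binarized maps).
#'
#' @param template_map,subject_map numeric vectors over brain-mask voxels.
#' @param mask `component_mask` (or logical vector) restricting both maps;
#'   `NULL` uses all voxels.
#' @return cosine similarity in \[-1, 1\].
#' @export
cosine_similarity <- function(template_map, subject_map, mask = NULL) {
  if (is.list(template_map)) template_map <- template_map$map
  if (is.list(subject_map)) subject_map <- subject_map$map
  if (!is.null(mask)) {
    mv <- if (inherits(mask, "component_mask")) mask$mask else mask
    template_map <- template_map[mv]
    subject_map <- subject_map[mv]
  }
  if (length(template_map) != length(subject_map))
    stop("maps must share the mask voxels")
  nt <- sqrt(sum(template_map^2))
  ns <- sqrt(sum(subject_map^2))
  if (nt == 0 || ns == 0)
    stop("cosine similarity undefined for a zero-norm vector")
  sum(template_map * subject_map) / (nt * ns)
}

#' Healthy-control cosine-similarity distribution
#'
#' Stores the control CS values of one component together with their sample
#' mean and standard deviation (n-1 denominator) — the normative
#' distribution every patient value is scored against.
#'
#' @param cs_values numeric vector of control CS values (>= 3).
#' @param component_id id carried through.
#' @return object of class `cs_distribution` with `values`, `mu`, `sigma`,
#'   `usable` (FALSE when sigma is 0).
#' @export
control_distribution <- function(cs_values, component_id = NA_integer_) {
  cs_values <- cs_values[is.finite(cs_values)]
  if (length(cs_values) < 3)
    stop("need at least 3 controls with defined CS")
  mu <- mean(cs_values)
  sigma <- stats::sd(cs_values)
  usable <- sigma > 0
  if (!usable)
    warning("zero-variance control CS distribution; component unusable")
  structure(list(component_id = component_id, values = cs_values,
                 mu = mu, sigma = sigma, usable = usable),
            class = "cs_distribution")
}

#' Subsampled permutation test for one patient component
#'
#' Each of `n_perm` iterations draws `subsample` controls without
#' replacement, computes their CS mean and SD, and checks whether the
#' patient CS lies more than `sd_mult` subsample SDs from the subsample mean
#' (two-sided, strict inequality). The component is significant when this
#' 3-SD exceedance holds in at least `1 - alpha` of the iterations.
#' When fewer controls than `subsample` are available the subsample size is
#' reduced to `ceiling(0.65 * n)` with a warning (the 200-of-308 proportion).
#'
#' @param patient_cs patient cosine similarity (scalar).
#' @param dist a [control_distribution()].
#' @param n_perm number of Monte-Carlo iterations (default 50000).
#' @param subsample controls drawn per iteration (default 200).
#' @param sd_mult SD multiple defining exceedance (default 3).
#' @param alpha significance level on the exceedance fraction (default 0.05).
#' @param seed RNG seed.
#' @param exhaustive if TRUE, enumerate all `choose(n, k)` subsamples instead
#'   of Monte-Carlo sampling (small control sets only).
#' @return object of class `alteration_result`: `cs`, `delta_cs_sigma`,
#'   `flagged_fraction`, `significant`, `untestable`, `n_perm`, `subsample`.
#' @export
permutation_test <- function(patient_cs, dist, n_perm = 50000L,
                             subsample = 200L, sd_mult = 3, alpha = 0.05,
                             seed = 1L, exhaustive = FALSE) {
  if (!dist$usable) {
    return(structure(list(cs = patient_cs, delta_cs_sigma = NA_real_,
                          flagged_fraction = NA_real_, significant = FALSE,
                          untestable = TRUE, n_perm = 0L, subsample = NA_integer_),
                     class = "alteration_result"))
  }
  x <- dist$values
  n <- length(x)
  k <- subsample
  if (k > n) {
    k <- as.integer(ceiling(0.65 * n))
    warning(sprintf("subsample %d exceeds %d controls; reduced to %d",
                    subsample, n, k))
  }
  if (exhaustive) {
    combs <- utils::combn(n, k)
    mu <- colMeans(matrix(x[combs], nrow = k))
    ss <- apply(matrix(x[combs], nrow = k), 2, stats::sd)
    exceed <- abs(patient_cs - mu) > sd_mult * ss
    frac <- mean(exceed)
    n_it <- ncol(combs)
  } else {
    set.seed(seed)
    exceed <- logical(n_perm)
    ## draw all subsample index sets, then vectorized moments
    S <- matrix(0L, nrow = k, ncol = n_perm)
    for (i in seq_len(n_perm)) S[, i] <- sample.int(n, k)
    V <- matrix(x[S], nrow = k)
    mu <- colMeans(V)
    ss <- sqrt((colSums(V^2) - k * mu^2) / (k - 1))
    frac <- mean(abs(patient_cs - mu) > sd_mult * ss)
    n_it <- n_perm
  }
  structure(list(cs = patient_cs,
                 delta_cs_sigma = delta_cs(patient_cs, dist),
                 flagged_fraction = frac,
                 significant = frac >= 1 - alpha,
                 untestable = FALSE, n_perm = n_it, subsample = k),
            class = "alteration_result")
}

#' Standardized component distance
#'
#' `(CS_patient - mu_controls) / sigma_controls`: how many control SDs the
#' patient's component similarity lies from the control mean. Negative
#' values mean less similar to the template than the average control.
#'
#' @param patient_cs scalar CS.
#' @param dist a [control_distribution()].
#' @return numeric scalar.
#' @export
delta_cs <- function(patient_cs, dist) {
  if (!dist$usable || dist$sigma == 0)
    stop("delta CS undefined: control distribution has zero variance")
  (patient_cs - dist$mu) / dist$sigma
}

#' Out-of-mask spillover report
#'
#' Automated version of the manual post-hoc check that flagged components
#' are not simply displaced outside the analysis mask: the fraction of a
#' subject map's suprathreshold voxels lying outside the component mask.
#'
#' @param subject_map Z-scored map over brain-mask voxels.
#' @param comp_mask `component_mask`.
#' @param z_thresh suprathreshold cutoff (default 1).
#' @return fraction in \[0,1\] (NA when the subject map has no
#'   suprathreshold voxels).
#' @export
outside_mask_fraction <- function(subject_map, comp_mask, z_thresh = 1) {
  if (is.list(subject_map)) subject_map <- subject_map$map
  supra <- subject_map > z_thresh
  if (!any(supra)) return(NA_real_)
  mv <- if (inherits(comp_mask, "component_mask")) comp_mask$mask else comp_mask
  sum(supra & !mv) / sum(supra)
}

#' Patient-by-component alteration matrix with network aggregation
#'
#' Collects per-patient, per-component significance into a boolean matrix
#' and aggregates by network: the percentage of patients with at least one
#' altered component per network, and the mean percentage of altered
#' components per network across patients.
#'
#' @param results list of lists: `results[[p]][[c]]` an
#'   `alteration_result`.
#' @param networks optional character vector assigning each component to a
#'   network name.
#' @return list with `matrix` (components x patients, logical),
#'   `patient_pct` and `component_pct` (named by network, when `networks`
#'   given).
#' @export
patient_alteration_matrix <- function(results, networks = NULL) {
  np <- length(results)
  nc <- length(results[[1]])
  M <- matrix(FALSE, nrow = nc, ncol = np)
  for (p in seq_len(np)) for (c in seq_len(nc)) {
    r <- results[[p]][[c]]
    M[c, p] <- isTRUE(r$significant)
  }
  out <- list(matrix = M)
  if (!is.null(networks)) {
    stopifnot(length(networks) == nc)
    nets <- unique(networks)
    out$patient_pct <- vapply(nets, function(nw)
      100 * mean(colSums(M[networks == nw, , drop = FALSE]) > 0), numeric(1))
    out$component_pct <- vapply(nets, function(nw)
      100 * mean(colMeans(M[networks == nw, , drop = FALSE])), numeric(1))
    names(out$patient_pct) <- names(out$component_pct) <- nets
  }
  out
}
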