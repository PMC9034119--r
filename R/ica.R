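#' Two-stage PCA reduction and concatenation
#'
#' Standard group-ICA reduction: each subject's voxels x time matrix is
#' reduced to `n_subject_pcs` temporal principal components, the reduced data
#' are concatenated across subjects, and a group-level PCA retains
#' `n_group_pcs` dimensions. The returned group matrix is whitened: its rows
#' (group dimensions) have zero mean, unit variance and zero pairwise
#' correlation over voxels.
#'
#' @param stack list of voxels-in-mask x time matrices, all sharing the same
#'   mask and voxel order.
#' @param n_subject_pcs temporal PCs retained per subject.
#' @param n_group_pcs group-level dimensions retained.
#' @return list with `whitened` (`n_group_pcs` x voxels matrix),
#'   `explained_variance` (fraction of concatenated variance retained at the
#'   group stage), `subject_basis` (per-subject temporal loadings, for
#'   back-projection), `singular_values`.
#' @export
reduce_and_concatenate <- function(stack, n_subject_pcs, n_group_pcs) {
  stopifnot(length(stack) >= 1)
  nv <- nrow(stack[[1]])
  if (!all(vapply(stack, nrow, integer(1)) == nv))
    stop("all subjects must share the mask and voxel order")
  v <- apply(stack[[1]], 1, stats::var)
  reduced <- vector("list", length(stack))
  bases <- vector("list", length(stack))
  for (s in seq_along(stack)) {
    X <- stack[[s]]
    if (n_subject_pcs > ncol(X))
      stop("n_subject_pcs exceeds the number of timepoints")
    X <- X - rowMeans(X)            # remove voxel means over time
    sv <- svd(X, nu = n_subject_pcs, nv = n_subject_pcs)
    if (sum(sv$d > 1e-10 * sv$d[1]) < n_subject_pcs)
      stop("rank deficiency: subject data rank below n_subject_pcs")
    ## temporal reduction: keep the voxel dimension, drop time to p spatial
    ## eigenmaps scaled by their singular values
    reduced[[s]] <- diag(sv$d[seq_len(n_subject_pcs)], n_subject_pcs) %*%
      t(sv$u[, seq_len(n_subject_pcs), drop = FALSE])
    bases[[s]] <- sv$v[, seq_len(n_subject_pcs), drop = FALSE]
  }
  G <- do.call(rbind, reduced)      # (sum n_subject_pcs) x voxels
  if (n_group_pcs > nrow(G))
    stop("n_group_pcs exceeds the concatenated dimension")
  G <- G - rowMeans(G)
  sv <- svd(t(G), nu = n_group_pcs, nv = 0)
  pos <- sum(sv$d > 1e-10 * sv$d[1])
  if (pos < n_group_pcs)
    stop("rank deficiency: group data rank below n_group_pcs")
  ## left singular vectors are orthonormal over voxels; scale rows to unit
  ## variance so the output is white
  W <- sqrt(nv - 1) * t(sv$u[, seq_len(n_group_pcs), drop = FALSE])
  ev <- sum(sv$d[seq_len(n_group_pcs)]^2) / sum(sv$d^2)
  list(whitened = W, explained_variance = ev, subject_basis = bases,
       singular_values = sv$d)
}

## Symmetric decorrelation: W <- (W W')^{-1/2} W.
sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
                     nrow(W)) %*% t(e$vectors) %*% W
}

## Orient each spatial component so its skewness is positive; scale rows to
## unit variance. Returns the adjusted source matrix and the sign/scale
## applied (so the unmixing matrix can be kept consistent).
orient_components <- function(S) {
  sgn <- numeric(nrow(S))
  for (i in seq_len(nrow(S))) {
    x <- S[i, ] - mean(S[i, ])
    sk <- mean(x^3) / (stats::sd(x)^3)
    sgn[i] <- if (sk < 0) -1 else 1
    S[i, ] <- sgn[i] * S[i, ] / stats::sd(S[i, ])
  }
  list(S = S, sign = sgn)
}

#' Infomax spatial ICA
#'
#' Full-batch natural-gradient Infomax with the logistic nonlinearity,
#' learning-rate annealing (the rate is halved whenever the weight change
#' increases) and symmetric decorrelation of the unmixing matrix at every
#' step, which keeps the extracted components exactly empirically
#' uncorrelated on whitened input.
#'
#' @param reduced whitened matrix (dimensions x voxels) from
#'   [reduce_and_concatenate()].
#' @param n_components number of components to extract (must not exceed
#'   `nrow(reduced)`).
#' @param seed integer; fixes the random orthogonal initialization.
#' @param lr initial learning rate (default 0.1); the symmetric
#'   decorrelation step keeps large rates stable, and the rate is halved
#'   whenever the gradient magnitude grows.
#' @param max_iter,tol convergence controls on the maximum absolute weight
#'   change.
#' @return list with `maps` (components x voxels, unit variance, positive
#'   skewness), `unmixing` (n_components x n_components), `converged`,
#'   `iterations`.
#' @export
infomax_ica <- function(reduced, n_components, seed = 1, lr = NULL,
                        max_iter = 2000L, tol = 1e-5) {
  p <- nrow(reduced)
  if (n_components > p)
    stop("n_components exceeds the whitened dimension")
  X <- reduced[seq_len(n_components), , drop = FALSE]
  if (n_components < p) {
    ## restrict to the top-n whitened subspace (rows are already ordered by
    ## group-PCA variance)
    X <- reduced[seq_len(n_components), , drop = FALSE]
  }
  nv <- ncol(X)
  n <- n_components
  if (is.null(lr)) lr <- 0.1
  set.seed(seed)
  W0 <- matrix(stats::rnorm(n * n), n, n)
  W <- sym_decorrelate(W0)
  last_delta <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Y <- W %*% X
    G <- 1 - 2 / (1 + exp(-Y))        # logistic score: 1 - 2*sigmoid(y)
    grad <- diag(n) + (G %*% t(Y)) / nv
    ## under symmetric decorrelation only the skew part of the natural
    ## gradient moves W (rotations); its magnitude is the scale-free
    ## convergence measure
    skew <- (grad - t(grad)) / 2
    delta <- max(abs(skew))
    if (delta < tol) { converged <- TRUE; break }
    Wn <- W + lr * grad %*% W
    if (!all(is.finite(Wn))) {
      lr <- lr / 2
      if (lr < 1e-12) stop("Infomax numerical blow-up persisted under annealing")
      next
    }
    Wn <- sym_decorrelate(Wn)
    if (delta > last_delta * 1.2) lr <- lr / 2
    last_delta <- delta
    W <- Wn
  }
  if (!converged)
    warning(sprintf("Infomax did not converge in %d iterations (grad=%.2e)",
                    max_iter, last_delta))
  S <- W %*% X
  ori <- orient_components(S)
  list(maps = ori$S, unmixing = diag(ori$sign, n) %*% W,
       converged = converged, iterations = it)
}

#' ICASSO-style stability analysis
#'
#' Repeats Infomax `n_runs` times from distinct random initializations,
#' pools all components, clusters them by absolute spatial correlation
#' (average-linkage agglomeration into `n_components` clusters), scores each
#' cluster with the stability index Iq (mean intra-cluster similarity minus
#' mean similarity to non-members) and returns the central solution: each
#' cluster's centrotype, the member maximizing summed intra-cluster
#' similarity (ties broken by lowest run index).
#'
#' @param reduced whitened matrix from [reduce_and_concatenate()].
#' @param n_components components per run and number of clusters.
#' @param n_runs number of ICA restarts (>= 2).
#' @param seed base seed; run r uses `seed + (r-1)` unless `run_seeds` is
#'   given.
#' @param run_seeds optional explicit per-run seeds (e.g. identical seeds to
#'   produce duplicate runs).
#' @return list with `templates`: list of template components (each a list
#'   with `id`, `map` — Z-scored over mask voxels —, `iq`, `label`),
#'   `clusters`: per-cluster membership, centrotype and Iq, `runs`:
#'   per-run convergence info.
#' @export
icasso_stability <- function(reduced, n_components, n_runs = 10L, seed = 1,
                             run_seeds = NULL) {
  if (is.null(run_seeds)) run_seeds <- seed + seq_len(n_runs) - 1L
  if (length(run_seeds) != n_runs || n_runs < 2)
    stop("need n_runs >= 2 seeds")
  runs <- lapply(run_seeds, function(s)
    infomax_ica(reduced, n_components, seed = s))
  allmaps <- do.call(rbind, lapply(runs, `[[`, "maps"))
  run_of <- rep(seq_len(n_runs), each = n_components)
  M <- nrow(allmaps)
  sim <- abs(stats::cor(t(allmaps)))
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(hc, k = n_components)
  if (length(unique(cl)) < n_components)
    stop("degenerate clustering: empty cluster")
  clusters <- vector("list", n_components)
  templates <- vector("list", n_components)
  for (c in seq_len(n_components)) {
    memb <- which(cl == c)
    intra <- if (length(memb) > 1) {
      sm <- sim[memb, memb]
      mean(sm[upper.tri(sm)])
    } else 1
    extra <- if (length(memb) < M) mean(sim[memb, -memb, drop = FALSE]) else 0
    iq <- intra - extra
    ## centrotype: member with max summed intra-cluster similarity;
    ## ties -> lowest run index
    score <- rowSums(sim[memb, memb, drop = FALSE])
    best <- memb[order(-score, run_of[memb])][1]
    clusters[[c]] <- list(members = memb, runs = run_of[memb],
                          centrotype = best, iq = iq)
    templates[[c]] <- list(id = c, map = zscore_vec(allmaps[best, ]),
                           iq = iq, label = "network-candidate")
  }
  ## order clusters by decreasing Iq for a stable, quality-first numbering
  ord <- order(-vapply(clusters, `[[`, numeric(1), "iq"))
  clusters <- clusters[ord]
  templates <- templates[ord]
  for (c in seq_along(templates)) templates[[c]]$id <- c
  list(templates = templates, clusters = clusters,
       runs = lapply(runs, function(r)
         list(converged = r$converged, iterations = r$iterations)))
}

#' Filter template components by external labels
#'
#' The manual artifact-vs-network labeling is consumed as an input table;
#' this keeps only components labeled as network candidates.
#'
#' @param templates list of template components (with `id`).
#' @param labels data.frame with columns `id` and `label`
#'   (`"artifact"` or `"network"`).
#' @return the surviving templates (possibly empty, with a warning).
#' @export
select_network_components <- function(templates, labels) {
  ids <- vapply(templates, `[[`, numeric(1), "id")
  if (!all(c("id", "label") %in% names(labels)))
    stop("labels must have columns id and label")
  unknown <- setdiff(labels$id, ids)
  if (length(unknown))
    stop(sprintf("unknown component id(s) in label file: %s",
                 paste(unknown, collapse = ", ")))
  missing <- setdiff(ids, labels$id)
  if (length(missing))
    stop(sprintf("missing label for component id(s): %s",
                 paste(missing, collapse = ", ")))
  bad <- setdiff(unique(labels$label), c("artifact", "network"))
  if (length(bad))
    stop(sprintf("unrecognized label(s): %s", paste(bad, collapse = ", ")))
  keep_ids <- labels$id[labels$label == "network"]
  out <- templates[ids %in% keep_ids]
  if (length(out) == 0L)
    warning("all components labeled artifact; no network candidates remain")
  out
}
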