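#' Guided back-reconstruction configuration
#'
#' Controls the one-unit reference-guided ICA: the objective is the weighted
#' sum `lambda * J(y) + (1 - lambda) * rho(y, template)^2`, where `J` is the
#' squared log-cosh negentropy approximation and `rho` the Pearson
#' correlation with the template map.
#'
#' @param lambda_weight mixing weight strictly inside (0,1); small values
#'   favor template correspondence (the `lambda -> 0` limit is dual
#'   regression), large values favor independence.
#' @param tol convergence tolerance on the weight-vector change.
#' @param max_iter iteration cap.
#' @param step initial gradient-ascent step size.
#' @param seed integer (reserved; the optimization itself is deterministic,
#'   initialized at the template projection).
#' @return an object of class `gig_config`.
#' @export
gig_config <- function(lambda_weight = 0.5, tol = 1e-6, max_iter = 1000L,
                       step = 0.5, seed = 1L) {
  if (!(lambda_weight > 0 && lambda_weight < 1))
    stop("lambda_weight must lie strictly inside (0,1)")
  structure(list(lambda_weight = lambda_weight, tol = tol,
                 max_iter = as.integer(max_iter), step = step,
                 seed = as.integer(seed)),
            class = "gig_config")
}

#' Whiten a subject's data to an orthonormal spatial basis
#'
#' Temporal PCA of the voxels x time matrix: returns `n_pcs` basis rows that
#' are zero-mean, unit-variance and uncorrelated over voxels, so any unit
#' vector `w` yields a candidate source `y = w' B` with (empirical) zero mean
#' and unit variance.
#'
#' @param series voxels-in-mask x time matrix.
#' @param n_pcs retained dimensions (must not exceed the data rank).
#' @return list with `basis` (`n_pcs` x voxels).
#' @export
whiten_subject <- function(series, n_pcs) {
  nv <- nrow(series)
  X <- series - rowMeans(series)
  ## also remove the spatial mean per timepoint so every candidate source
  ## y = w'B is zero-mean over voxels (spatial-ICA convention)
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X, nu = 0, nv = 0)
  r <- sum(sv$d > 1e-10 * sv$d[1])
  if (n_pcs > r)
    stop(sprintf("requested %d PCs but data rank is %d", n_pcs, r))
  sv <- svd(X, nu = n_pcs, nv = 0)
  B <- sqrt(nv - 1) * t(sv$u[, seq_len(n_pcs), drop = FALSE])
  list(basis = B, d = sv$d)
}

## E[log cosh(nu)] for standard normal nu (Gauss-Hermite closed value).
GAUSS_LOGCOSH <- 0.3745672974551902

## Negentropy approximation J(y) = (mean(logcosh(y)) - E[logcosh(nu)])^2
## for a zero-mean unit-variance y.
negentropy_logcosh <- function(y) (mean(log(cosh(y))) - GAUSS_LOGCOSH)^2

#' One-unit reference-guided ICA
#'
#' Extracts a single subject-specific source constrained toward a template
#' map: maximizes `F(w) = lambda * J(y) + (1 - lambda) * rho(y, t)^2` over
#' unit vectors `w`, with `y = w' B` on the whitened basis `B` and `t` the
#' template map. `J` is the squared log-cosh negentropy approximation and
#' `rho` the Pearson correlation. The ascent starts from the normalized
#' projection of the template onto the basis (the dual-regression solution)
#' and renormalizes `w` each step; the step size is halved whenever the
#' objective decreases.
#'
#' @param whitened output of [whiten_subject()].
#' @param template list with at least `id` and `map` (Z-scored over the same
#'   mask voxels as the subject data), or a bare numeric map vector.
#' @param config a [gig_config()].
#' @return an object of class `subject_component`: list with `id`, `map`
#'   (Z-scored), `correspondence` (Pearson correlation with the template,
#'   sign-flipped to non-negative with a `sign_flipped` flag), `negentropy`,
#'   `converged`, `iterations`.
#' @export
guided_one_unit <- function(whitened, template, config = gig_config()) {
  B <- whitened$basis
  tpl <- if (is.list(template)) template$map else template
  id <- if (is.list(template) && !is.null(template$id)) template$id else NA_integer_
  if (length(tpl) != ncol(B))
    stop("template must live on the same mask/voxel order as the subject data")
  nv <- ncol(B)
  zt <- zscore_vec(tpl)
  lam <- config$lambda_weight
  proj <- as.numeric(B %*% zt)
  w <- proj / sqrt(sum(proj^2))
  step <- config$step
  objective <- function(w) {
    y <- as.numeric(crossprod(B, w))
    y <- y - mean(y)
    y <- y / sqrt(mean(y^2))
    rho <- sum(y * zt) / sqrt(sum(y^2) * sum(zt^2))
    list(F = lam * negentropy_logcosh(y) + (1 - lam) * rho^2, y = y, rho = rho)
  }
  cur <- objective(w)
  converged <- FALSE
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    y <- cur$y
    ## gradient of J: 2*(E G - E G(nu)) * B tanh(y)/nv
    gJ <- 2 * (mean(log(cosh(y))) - GAUSS_LOGCOSH) * as.numeric(B %*% tanh(y)) / nv
    ## gradient of rho^2: 2*rho * B zt / ||zt|| (projected; y normalized)
    gR <- 2 * cur$rho * as.numeric(B %*% zt) / sqrt(sum(zt^2) * nv)
    g <- lam * gJ + (1 - lam) * gR
    ## project out the radial direction (w is constrained to the sphere)
    g <- g - sum(g * w) * w
    repeat {
      wn <- w + step * g
      wn <- wn / sqrt(sum(wn^2))
      nxt <- objective(wn)
      if (nxt$F >= cur$F - 1e-14 || step < 1e-10) break
      step <- step / 2
    }
    delta <- sqrt(sum((wn - w)^2))
    w <- wn
    cur <- nxt
    if (delta < config$tol) { converged <- TRUE; break }
  }
  y <- cur$y
  rho <- cur$rho
  flipped <- FALSE
  if (rho < 0) { y <- -y; rho <- -rho; flipped <- TRUE }
  structure(list(id = id, map = zscore_vec(y), correspondence = rho,
                 negentropy = negentropy_logcosh(y), converged = converged,
                 iterations = it, sign_flipped = flipped),
            class = "subject_component")
}

#' Back-reconstruct all template components in one subject
#'
#' Applies [guided_one_unit()] once per template, preserving the matching
#' contract: component `i` of every subject is estimated under, and
#' comparable with, template `i`. Per-component failures are recorded and the
#' run continues; an error is raised only if every component fails.
#'
#' @param series voxels-in-mask x time matrix for one subject.
#' @param templates non-empty list of template components.
#' @param config a [gig_config()].
#' @param n_pcs subject PCA order; default `length(templates) + 5`, capped at
#'   the data rank headroom `min(T - 1, voxels)`.
#' @return list of `subject_component` (NULL entries for failed components,
#'   with a warning).
#' @export
backreconstruct_all <- function(series, templates, config = gig_config(),
                                n_pcs = NULL) {
  if (length(templates) == 0L) stop("templates must be non-empty")
  if (is.null(n_pcs))
    n_pcs <- min(length(templates) + 5L, ncol(series) - 1L, nrow(series))
  wh <- whiten_subject(series, n_pcs)
  out <- vector("list", length(templates))
  failed <- 0L
  for (i in seq_along(templates)) {
    res <- tryCatch(guided_one_unit(wh, templates[[i]], config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("component %d failed: %s", i, conditionMessage(res)))
      failed <- failed + 1L
      out[i] <- list(NULL)
    } else out[[i]] <- res
  }
  if (failed == length(templates))
    stop("back-reconstruction failed for every component")
  out
}

#' Dual-regression subject maps
#'
#' The classical two-step least-squares alternative used as an unguided
#' reference: regress the subject data on the template spatial maps to get
#' time courses, then regress the data on those time courses to get subject
#' spatial maps. Serves as the pure-correspondence limit of the guided
#' objective.
#'
#' @param series voxels-in-mask x time matrix.
#' @param templates list of template components or a voxels x K matrix.
#' @return voxels x K matrix of Z-scored subject maps.
#' @export
dual_regression <- function(series, templates) {
  Mt <- if (is.matrix(templates)) templates else
    vapply(templates, `[[`, numeric(nrow(series)), "map")
  Mt <- matrix(Mt, nrow = nrow(series))
  X <- series - rowMeans(series)
  A <- qr.coef(qr(cbind(1, Mt)), X)[-1, , drop = FALSE]   # K x T time courses
  S <- qr.coef(qr(cbind(1, t(A))), t(X))[-1, , drop = FALSE] # K x voxels
  apply(t(S), 2, zscore_vec)
}
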