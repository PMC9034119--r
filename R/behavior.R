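#' Aggregate neuropsychological test Z-scores into domain scores
#'
#' Each cognitive domain score is the arithmetic mean of the Z-scores of the
#' tests assigned to that domain (positive = good performance). Missing
#' tests are averaged over; patients with no completed test in any domain
#' are excluded.
#'
#' @param test_z data.frame with columns `patient`, `test`, `z`.
#' @param domain_assignment data.frame with columns `test`, `domain`; every
#'   test must map to exactly one domain.
#' @return data.frame with columns `patient`, `domain`, `score`, `n_tests`;
#'   patient/domain pairs with no available test are omitted, and patients
#'   with no tests at all are dropped with a message.
#' @export
aggregate_domains <- function(test_z, domain_assignment) {
  stopifnot(all(c("patient", "test", "z") %in% names(test_z)),
            all(c("test", "domain") %in% names(domain_assignment)))
  if (anyDuplicated(domain_assignment$test))
    stop("every test must map to exactly one domain")
  unmapped <- setdiff(unique(test_z$test), domain_assignment$test)
  if (length(unmapped))
    stop(sprintf("test(s) with no domain assignment: %s",
                 paste(unmapped, collapse = ", ")))
  d <- merge(test_z, domain_assignment, by = "test")
  d <- d[is.finite(d$z), ]
  dropped <- setdiff(unique(test_z$patient), unique(d$patient))
  if (length(dropped))
    message(sprintf("excluded patient(s) with no completed tests: %s",
                    paste(dropped, collapse = ", ")))
  agg <- stats::aggregate(z ~ patient + domain, data = d,
                          FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(patient = agg$patient, domain = agg$domain,
                    score = agg$z[, 1], n_tests = as.integer(agg$z[, 2]),
                    stringsAsFactors = FALSE)
  out[order(out$patient, out$domain), ]
}

#' Non-negative least-squares brain-behavior model
#'
#' Predicts one cognitive domain score from the patients' standardized
#' component distances under a non-negativity constraint on the component
#' coefficients, which acts as implicit feature selection. The intercept is
#' always included and unconstrained; optional demographic covariates
#' (e.g. age, education) enter sign-free. Both are realized as +/- column
#' pairs inside the single non-negative solver.
#'
#' @param delta_cs_matrix patients x components numeric matrix (finite).
#' @param scores numeric vector of domain scores (one per patient, n >= 5).
#' @param demographics optional patients x q matrix of sign-free covariates.
#' @return object of class `rsn_nnls` with `coefficients` (non-negative,
#'   per component), `intercept`, `demographic_coefs`, `support` (indices of
#'   strictly positive component coefficients), `fitted`, plus the inputs
#'   needed by [model_diagnostics()].
#' @export
nnls_fit <- function(delta_cs_matrix, scores, demographics = NULL) {
  X <- as.matrix(delta_cs_matrix)
  y <- as.numeric(scores)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < 5) stop("need at least 5 patients")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("predictors and scores must be finite")
  if (all(X == 0)) stop("rank-0 design")
  n <- nrow(X); K <- ncol(X)
  C <- cbind(X, 1, -1)
  q <- 0L
  if (!is.null(demographics)) {
    D <- as.matrix(demographics)
    stopifnot(nrow(D) == n)
    q <- ncol(D)
    C <- cbind(C, D, -D)
  }
  dup <- which(duplicated(t(X), MARGIN = 1))
  if (length(dup))
    message("duplicate predictor columns detected; coefficient split between them is arbitrary, predictions are not affected")
  sol <- pracma::lsqnonneg(C, y)
  x <- sol$x
  beta <- x[seq_len(K)]
  intercept <- x[K + 1] - x[K + 2]
  demo <- if (q > 0) x[K + 2 + seq_len(q)] - x[K + 2 + q + seq_len(q)] else numeric(0)
  support <- which(beta > 1e-10)
  if (length(support) == 0L)
    warning("all component coefficients are zero; model reduces to the intercept")
  fitted <- as.numeric(X %*% beta + intercept +
                       if (q > 0) as.matrix(demographics) %*% demo else 0)
  structure(list(coefficients = beta, intercept = intercept,
                 demographic_coefs = demo, support = support,
                 fitted = fitted, X = X, y = y,
                 demographics = demographics),
            class = "rsn_nnls")
}

#' @export
coef.rsn_nnls <- function(object, ...) {
  c(`(Intercept)` = object$intercept,
    stats::setNames(object$coefficients,
                    paste0("comp", seq_along(object$coefficients))))
}

#' @export
predict.rsn_nnls <- function(object, newdata = NULL, newdemo = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  out <- as.numeric(as.matrix(newdata) %*% object$coefficients + object$intercept)
  if (length(object$demographic_coefs) && !is.null(newdemo))
    out <- out + as.numeric(as.matrix(newdemo) %*% object$demographic_coefs)
  out
}

#' @export
residuals.rsn_nnls <- function(object, ...) object$y - object$fitted

#' @export
print.rsn_nnls <- function(x, ...) {
  cat("Non-negative least-squares brain-behavior model\n")
  cat(sprintf("  %d patients, %d components, support size %d\n",
              nrow(x$X), ncol(x$X), length(x$support)))
  cat(sprintf("  intercept %.3f; nonzero coefficients: %s\n", x$intercept,
              if (length(x$support))
                paste(sprintf("comp%d=%.3f", x$support,
                              x$coefficients[x$support]), collapse = ", ")
              else "none"))
  invisible(x)
}

#' Model diagnostics and acceptance rule
#'
#' Goodness of fit is the squared Pearson correlation between prediction and
#' observation; coefficient precision is the coefficient of variation of
#' each nonzero estimate under a case-resampling bootstrap over patients. A
#' model is accepted when R-squared >= 0.5 and every CV is below 200%.
#' A coefficient that drops to zero in more than half of the resamples makes
#' the CV infinite and the model rejected.
#'
#' @param model an [nnls_fit()] result.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param r2_min,cv_max acceptance thresholds (defaults 0.5 and 200).
#' @param skip_cv_if_rejected if TRUE (default), the bootstrap is skipped
#'   when R-squared already fails the threshold (the acceptance decision is
#'   unaffected).
#' @return list with `r_squared`, `cv_percent` (named by supported
#'   component), `accepted`, `n_boot`.
#' @export
model_diagnostics <- function(model, n_boot = 1000L, seed = 1L,
                              r2_min = 0.5, cv_max = 200,
                              skip_cv_if_rejected = TRUE) {
  stopifnot(inherits(model, "rsn_nnls"))
  y <- model$y
  yh <- model$fitted
  r2 <- if (stats::sd(yh) == 0 || stats::sd(y) == 0) 0 else
    stats::cor(yh, y)^2
  if (length(model$support) == 0L)
    return(list(r_squared = r2, cv_percent = numeric(0), accepted = FALSE,
                n_boot = 0L))
  if (skip_cv_if_rejected && r2 < r2_min)
    return(list(r_squared = r2, cv_percent = NULL, accepted = FALSE,
                n_boot = 0L))
  n <- nrow(model$X)
  set.seed(seed)
  B <- matrix(NA_real_, nrow = n_boot, ncol = length(model$support))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(nnls_fit(model$X[idx, , drop = FALSE], y[idx],
                            if (!is.null(model$demographics))
                              model$demographics[idx, , drop = FALSE] else NULL),
                   error = function(e) NULL)
    if (!is.null(fb)) B[b, ] <- fb$coefficients[model$support]
  }
  est <- model$coefficients[model$support]
  cv <- vapply(seq_along(model$support), function(j) {
    bj <- B[, j][!is.na(B[, j])]
    if (mean(bj <= 1e-10) > 0.5) return(Inf)
    100 * stats::sd(bj) / abs(est[j])
  }, numeric(1))
  names(cv) <- paste0("comp", model$support)
  list(r_squared = r2, cv_percent = cv,
       accepted = r2 >= r2_min && all(cv < cv_max),
       n_boot = n_boot)
}
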