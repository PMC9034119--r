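#' Frame-wise displacement
#'
#' Power-style head-motion summary: per frame, the sum of absolute
#' differential translations plus the rotation arc lengths at a fixed head
#' radius. The first frame is defined as 0.
#'
#' @param params matrix (volumes x 6): three translations in mm, three
#'   rotations in radians. A warning is issued when any rotation exceeds
#'   pi in magnitude (degrees suspected).
#' @param head_radius_mm rotation-to-arc radius (default 50).
#' @return object of class `motion_trace` with `fd` (length = volumes,
#'   leading 0), `mean_fd`, `median_fd`.
#' @export
framewise_displacement <- function(params, head_radius_mm = 50) {
  params <- as.matrix(params)
  if (ncol(params) != 6) stop("expected 6 rigid-body parameter columns")
  if (nrow(params) < 2) stop("need at least 2 volumes")
  if (any(abs(params[, 4:6]) > pi))
    warning("rotation magnitudes exceed pi; parameters may be in degrees, radians expected")
  dtr <- abs(diff(params[, 1:3, drop = FALSE]))
  drot <- abs(diff(params[, 4:6, drop = FALSE]))
  fd <- c(0, rowSums(dtr) + head_radius_mm * rowSums(drot))
  structure(list(fd = fd, mean_fd = mean(fd), median_fd = stats::median(fd)),
            class = "motion_trace")
}

#' Compare head motion between two groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test on per-subject summary
#' FD values; exact for small untied samples, normal approximation with tie
#' correction otherwise.
#'
#' @param group1,group2 numeric vectors of per-subject summary FD.
#' @return list with `statistic` (Mann-Whitney U for group1), `p`.
#' @export
compare_motion <- function(group1, group2) {
  if (!length(group1) || !length(group2)) stop("both groups must be non-empty")
  if (length(unique(c(group1, group2))) == 1L) {
    warning("all values tied; p = 1")
    return(list(statistic = length(group1) * length(group2) / 2, p = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(group1, group2,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
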