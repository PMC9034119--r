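#' Binarize a component map at a Z threshold
#'
#' Voxels with `Z > z_thresh` are included (strict inequality). The default
#' threshold of 1 is deliberately tolerant, to absorb spatial shifts of a
#' network caused by mass effect.
#'
#' @param template a template component (list with `map`) or a numeric map
#'   vector, Z-scored over mask voxels.
#' @param z_thresh threshold (default 1).
#' @return logical vector over mask voxels; warns when empty.
#' @export
binarize_component <- function(template, z_thresh = 1) {
  map <- if (is.list(template)) template$map else template
  out <- map > z_thresh
  if (!any(out)) warning("binarized component mask is empty")
  out
}

#' Normalized spatial overlap of a component with atlas networks
#'
#' Fraction of component-mask voxels falling inside each atlas network,
#' using the component-mask size as denominator; fractions over the
#' networks plus the `"outside"` remainder sum to 1.
#'
#' @param component_mask logical vector over mask voxels (non-empty).
#' @param atlas list with `labels` (integer vector over the same mask
#'   voxels, 0 = unlabeled) and `names` (network name per positive label).
#' @return named numeric vector of fractions, including `"outside"`.
#' @export
normalized_overlap <- function(component_mask, atlas) {
  if (length(component_mask) != length(atlas$labels))
    stop("grid mismatch between component mask and atlas")
  n <- sum(component_mask)
  if (n == 0L) stop("empty component mask: overlap undefined")
  lab <- atlas$labels[component_mask]
  counts <- vapply(seq_along(atlas$names),
                   function(l) sum(lab == l), numeric(1))
  out <- c(counts / n, outside = sum(lab == 0) / n)
  names(out) <- c(atlas$names, "outside")
  out
}

#' Assign a component to its best-matching network
#'
#' Argmax of the normalized overlaps (the `"outside"` mass never wins);
#' assignments with best overlap below `threshold` are flagged low
#' confidence. Exact ties are broken lexicographically by network name and
#' reported in the result.
#'
#' @param overlaps named fractions from [normalized_overlap()] (one atlas) or
#'   a list of such vectors (several atlases; the maximum overlap across
#'   atlases is used per network).
#' @param threshold low-confidence cutoff (default 0.5).
#' @param id optional component id carried through.
#' @return list with `id`, `network`, `overlap`, `low_confidence`, `tie`.
#' @export
assign_network <- function(overlaps, threshold = 0.5, id = NA_integer_) {
  if (is.list(overlaps)) {
    nets <- sort(unique(unlist(lapply(overlaps, function(o)
      setdiff(names(o), "outside")))))
    ov <- vapply(nets, function(nm)
      max(vapply(overlaps, function(o)
        if (nm %in% names(o)) o[[nm]] else 0, numeric(1))), numeric(1))
  } else {
    ov <- overlaps[setdiff(names(overlaps), "outside")]
  }
  if (length(ov) == 0L) stop("no networks in overlap vector")
  best <- max(ov)
  cand <- sort(names(ov)[ov == best])
  list(id = id, network = cand[1], overlap = unname(best),
       low_confidence = best < threshold, tie = length(cand) > 1)
}
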