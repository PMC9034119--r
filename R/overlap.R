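#' Tissue partition of the brain
#'
#' Splits the analysis mask into mutually exclusive tumour core, oedema and
#' normal-appearing tissue from the two input masks: tumour core (TM) and
#' tumour-plus-oedema (TM+O). Oedema is the set difference `tm_o \\ tm`,
#' normal tissue is `brain \\ tm_o`.
#'
#' @param tm logical 3D tumour-core mask.
#' @param tm_o logical 3D tumour+oedema mask (must contain `tm`).
#' @param brain logical 3D analysis mask (must contain `tm_o`).
#' @return object of class `tissue_partition` with logical volumes `tm`,
#'   `oedema`, `normal`, `brain`.
#' @export
tissue_partition <- function(tm, tm_o, brain) {
  tm <- as.array(tm) > 0; tm_o <- as.array(tm_o) > 0; brain <- as.array(brain) > 0
  stopifnot(identical(dim(tm), dim(brain)), identical(dim(tm_o), dim(brain)))
  if (any(tm & !tm_o)) stop("tumour core must be contained in the tumour+oedema mask")
  if (any(tm_o & !brain)) stop("tumour+oedema mask must be contained in the brain mask")
  structure(list(tm = tm, oedema = tm_o & !tm, normal = brain & !tm_o,
                 brain = brain),
            class = "tissue_partition")
}

#' Expected altered-network mask
#'
#' For overlap analyses the *expected* (template) maps of the altered
#' components are used, not the patient's own possibly-missing maps: each
#' altered component's template is binarized with the same mask rules as the
#' analysis mask, and the union is taken.
#'
#' @param altered_ids integer ids of altered components.
#' @param templates list of template components (ids must cover
#'   `altered_ids`).
#' @param brain_mask logical 3D array.
#' @param params a [mask_params()].
#' @return list with `per_component` (named list of logical vectors over
#'   mask voxels) and `union` (logical vector); empty with a warning when no
#'   components are altered.
#' @export
expected_altered_mask <- function(altered_ids, templates, brain_mask,
                                  params = mask_params()) {
  ids <- vapply(templates, `[[`, numeric(1), "id")
  if (!all(altered_ids %in% ids))
    stop("altered ids must be a subset of template ids")
  nv <- sum(brain_mask)
  if (length(altered_ids) == 0L) {
    warning("empty altered set; union mask is empty")
    return(list(per_component = list(), union = rep(FALSE, nv)))
  }
  per <- lapply(altered_ids, function(i) {
    cm <- build_component_mask(templates[[which(ids == i)]], brain_mask, params)
    cm$mask
  })
  names(per) <- as.character(altered_ids)
  list(per_component = per, union = Reduce(`|`, per))
}

#' Percentage overlap of an altered mask with a tissue mask
#'
#' `100 * |altered intersect tissue| / |altered|`, with the altered-mask
#' extent as the reference denominator.
#'
#' @param altered logical vector (over mask voxels) or logical volume.
#' @param tissue logical vector/volume on the same support.
#' @return percentage in \[0, 100\].
#' @export
overlap_percent <- function(altered, tissue) {
  a <- as.vector(altered) > 0
  t <- as.vector(tissue) > 0
  if (length(a) != length(t)) stop("grid mismatch between altered and tissue masks")
  if (!any(a)) stop("overlap undefined for an empty altered mask")
  100 * sum(a & t) / sum(a)
}

#' Per-patient tissue overlap report
#'
#' Percentage of the altered-network mask falling in tumour core, oedema and
#' normal-appearing tissue, per component and for the union mask. The three
#' percentages sum to exactly 100 whenever the altered mask lies inside the
#' brain mask.
#'
#' @param altered output of [expected_altered_mask()].
#' @param partition a [tissue_partition()].
#' @param brain_mask logical 3D array locating the mask voxels.
#' @return data.frame with rows per component plus `"UNION"`, columns
#'   `unit`, `tm_pct`, `oedema_pct`, `normal_pct`, `n_voxels`.
#' @export
patient_overlap_report <- function(altered, partition, brain_mask) {
  tm_v <- vectorize(partition$tm, brain_mask) > 0
  oe_v <- vectorize(partition$oedema, brain_mask) > 0
  no_v <- vectorize(partition$normal, brain_mask) > 0
  br_v <- vectorize(partition$brain, brain_mask) > 0
  one <- function(mask_vec, unit) {
    if (any(mask_vec & !br_v))
      stop("altered mask has voxels outside the brain mask (grid/registration problem)")
    data.frame(unit = unit,
               tm_pct = overlap_percent(mask_vec, tm_v),
               oedema_pct = overlap_percent(mask_vec, oe_v),
               normal_pct = overlap_percent(mask_vec, no_v),
               n_voxels = sum(mask_vec),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(names(altered$per_component), function(nm)
    one(altered$per_component[[nm]], nm))
  rows[[length(rows) + 1L]] <- one(altered$union, "UNION")
  do.call(rbind, rows)
}

#' Spearman correlation between alteration depth and lesion overlap
#'
#' Rank correlation (tie-corrected) between per-component standardized
#' distances and their percentage overlap with a tissue mask, with a
#' two-sided p-value (exact for small untied samples, asymptotic otherwise).
#'
#' @param delta_cs numeric vector of standardized distances.
#' @param overlap numeric vector of overlap percentages (same length,
#'   n >= 4).
#' @return list with `rho`, `p`.
#' @export
spearman_alteration_vs_overlap <- function(delta_cs, overlap) {
  ok <- is.finite(delta_cs) & is.finite(overlap)
  x <- delta_cs[ok]; y <- overlap[ok]
  if (length(x) < 4) stop("need at least 4 paired finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for constant input")
  rho <- stats::cor(rank(x), rank(y))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = "two.sided"))
  list(rho = unname(rho), p = ct$p.value)
}
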