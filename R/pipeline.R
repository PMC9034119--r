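#' Greedy component matching by absolute spatial correlation
#'
#' Matches estimated maps to reference maps: repeatedly pairs the highest
#' remaining absolute correlation. Adequate for well-separated components
#' (planted phantoms); used to align ICA output with ground truth and to
#' report recovery quality.
#'
#' @param est voxels x K matrix of estimated maps.
#' @param ref voxels x K matrix of reference maps.
#' @return list with `perm` (`perm[j]` = index of the estimated map matched
#'   to reference j) and `corr` (absolute correlation per reference).
#' @export
match_maps <- function(est, ref) {
  K <- ncol(ref)
  cc <- abs(stats::cor(est, ref))   # est x ref
  perm <- integer(K); corr <- numeric(K)
  for (step in seq_len(K)) {
    ij <- arrayInd(which.max(cc), dim(cc))
    perm[ij[2]] <- ij[1]
    corr[ij[2]] <- cc[ij[1], ij[2]]
    cc[ij[1], ] <- -1; cc[, ij[2]] <- -1
  }
  list(perm = perm, corr = corr)
}

#' Default end-to-end pipeline configuration
#'
#' Desk-scale defaults: a 12-cubed phantom with K = 5 networks, T = 120
#' timepoints, 10 controls and 3 patients; mask rules scaled to the phantom
#' grid (minimum cluster 10 voxels, cerebellum excluded); subsampled
#' permutation testing with 2000 iterations.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @return nested configuration list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    phantom = list(grid_shape = c(12, 12, 12), n_components = 5,
                   n_timepoints = 120, n_controls = 10, n_patients = 3,
                   smoothness_fwhm = 2.5, noise_sd = 0.4),
    ica = list(n_subject_pcs = 10, n_group_pcs = 8, n_runs = 5),
    gig = list(lambda_weight = 0.5, tol = 1e-6, max_iter = 1000),
    mask = list(z_thresh = 1, min_cluster_voxels = 10, connectivity = 6,
                exclude_cerebellum = TRUE),
    perm = list(n_perm = 2000, subsample = NULL, sd_mult = 3, alpha = 0.05),
    behavior = list(n_boot = 200)
  )
}

## Merge user config over defaults (shallow, two levels).
merge_config <- function(config) {
  base <- default_config(if (!is.null(config$seed)) config$seed else 1L)
  for (sec in names(config)) {
    if (is.list(config[[sec]]) && sec %in% names(base)) {
      for (k in names(config[[sec]])) base[[sec]][[k]] <- config[[sec]][[k]]
    } else base[[sec]] <- config[[sec]]
  }
  base
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full alteration-mapping pipeline on a synthetic phantom
#'
#' Executes phantom generation, group template ICA (two-stage PCA + Infomax
#' + ICASSO stability), synthetic-atlas network labeling, guided
#' back-reconstruction of controls and patients, control CS distributions,
#' patient alteration testing, lesion-overlap reporting and behavior
#' modelling. When `out_dir` is given, writes TSV/JSON reports and a
#' manifest recording every seed, parameter and output file hash; two runs
#' with the same configuration produce bit-identical manifests.
#'
#' @param config nested list (see [default_config()]) or a path to a YAML
#'   file with the same structure; missing entries take defaults.
#' @param out_dir optional output directory.
#' @return (invisibly) a list with all stage results: `phantom`,
#'   `templates`, `assignments`, `cs_distributions`, `alterations`,
#'   `delta_cs` (patients x components, template order aligned to planted
#'   truth), `alteration_matrix`, `overlap`, `behavior`, `recovery`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config)
  pc <- do.call(phantom_config, c(cfg$phantom, list(seed = cfg$seed)))
  ph <- generate_phantom(pc)
  K <- pc$n_components
  nv <- sum(ph$truth$mask)

  ## --- group template ICA on the controls
  stack <- lapply(ph$controls, `[[`, "data")
  red <- reduce_and_concatenate(stack,
                                n_subject_pcs = min(cfg$ica$n_subject_pcs,
                                                    pc$n_timepoints),
                                n_group_pcs = min(cfg$ica$n_group_pcs,
                                                  cfg$ica$n_subject_pcs *
                                                    pc$n_controls))
  ic <- icasso_stability(red$whitened, n_components = K,
                         n_runs = cfg$ica$n_runs,
                         seed = derive_seed(cfg$seed, 21))
  templates <- ic$templates

  ## align template numbering with the planted truth (reporting convenience;
  ## the matching contract itself is per-template, not order-dependent)
  est <- vapply(templates, `[[`, numeric(nv), "map")
  mm <- match_maps(est, ph$truth$zmaps)
  templates <- templates[mm$perm]
  for (i in seq_len(K)) templates[[i]]$id <- i

  ## --- synthetic atlas labeling
  raw <- ph$truth$raw_maps
  win <- apply(raw, 1, which.max)
  peak <- raw[cbind(seq_len(nv), win)]
  labels <- ifelse(peak > 0.3, win, 0L)
  atlas <- list(labels = labels, names = paste0("NET", seq_len(K)))
  assignments <- lapply(templates, function(tc) {
    bm <- binarize_component(tc, cfg$mask$z_thresh)
    if (!any(bm)) return(list(id = tc$id, network = NA_character_,
                              overlap = NA_real_, low_confidence = TRUE,
                              tie = FALSE))
    assign_network(normalized_overlap(bm, atlas), id = tc$id)
  })

  ## --- component analysis masks
  excl <- if (isTRUE(cfg$mask$exclude_cerebellum)) ph$truth$cerebellum else NULL
  mp <- mask_params(z_thresh = cfg$mask$z_thresh,
                    min_cluster_voxels = cfg$mask$min_cluster_voxels,
                    exclusion_mask = excl,
                    connectivity = cfg$mask$connectivity)
  cmasks <- lapply(templates, build_component_mask,
                   brain_mask = ph$truth$mask, params = mp)

  ## --- guided back-reconstruction
  gcfg <- gig_config(lambda_weight = cfg$gig$lambda_weight,
                     tol = cfg$gig$tol, max_iter = cfg$gig$max_iter)
  br <- function(sub) backreconstruct_all(sub$data, templates, gcfg)
  ctrl_maps <- lapply(ph$controls, br)
  pat_maps <- lapply(ph$patients, br)

  ## --- control CS distributions
  cs_of <- function(maps, i) cosine_similarity(templates[[i]], maps[[i]], cmasks[[i]])
  dists <- lapply(seq_len(K), function(i) {
    if (!cmasks[[i]]$usable)
      return(structure(list(component_id = i, values = numeric(0),
                            mu = NA_real_, sigma = NA_real_, usable = FALSE),
                       class = "cs_distribution"))
    control_distribution(vapply(ctrl_maps, cs_of, numeric(1), i = i), i)
  })

  ## --- patient alteration testing
  sub_n <- cfg$perm$subsample
  alterations <- lapply(seq_len(pc$n_patients), function(p) {
    lapply(seq_len(K), function(i) {
      if (!cmasks[[i]]$usable || !dists[[i]]$usable)
        return(structure(list(cs = NA_real_, delta_cs_sigma = NA_real_,
                              flagged_fraction = NA_real_, significant = FALSE,
                              untestable = TRUE, n_perm = 0L,
                              subsample = NA_integer_),
                         class = "alteration_result"))
      suppressWarnings(permutation_test(
        cs_of(pat_maps[[p]], i), dists[[i]],
        n_perm = cfg$perm$n_perm,
        subsample = if (is.null(sub_n)) length(dists[[i]]$values) + 1L else sub_n,
        sd_mult = cfg$perm$sd_mult, alpha = cfg$perm$alpha,
        seed = derive_seed(cfg$seed, 31, p, i)))
    })
  })
  dcs <- t(vapply(alterations, function(pr)
    vapply(pr, `[[`, numeric(1), "delta_cs_sigma"), numeric(K)))
  dcs <- matrix(dcs, nrow = pc$n_patients, ncol = K)
  nets <- vapply(assignments, function(a)
    if (is.na(a$network)) "unassigned" else a$network, character(1))
  amat <- patient_alteration_matrix(alterations, networks = nets)

  ## --- lesion overlap
  overlap <- lapply(seq_len(pc$n_patients), function(p) {
    altered_ids <- which(vapply(alterations[[p]], function(r)
      isTRUE(r$significant), logical(1)))
    if (!length(altered_ids)) return(NULL)
    am <- expected_altered_mask(altered_ids, templates, ph$truth$mask, mp)
    part <- tissue_partition(ph$lesions[[p]]$tm, ph$lesions[[p]]$tm_o,
                             ph$truth$mask)
    rep <- patient_overlap_report(am, part, ph$truth$mask)
    rep$patient <- p
    rep
  })

  ## --- behavior linkage (planted scores, then refit)
  beh <- NULL
  if (pc$n_patients >= 5) {
    scores <- make_behavior_scores(ph$truth, dcs, pc)
    beh <- lapply(split(scores, scores$domain), function(sd0) {
      fit <- nnls_fit(dcs, sd0$score[order(sd0$patient)])
      diag <- model_diagnostics(fit, n_boot = cfg$behavior$n_boot,
                                seed = derive_seed(cfg$seed, 41))
      list(fit = fit, diagnostics = diag)
    })
  }

  res <- list(phantom = ph, templates = templates, assignments = assignments,
              component_masks = cmasks, cs_distributions = dists,
              alterations = alterations, delta_cs = dcs,
              alteration_matrix = amat, overlap = overlap, behavior = beh,
              recovery = list(template_truth_corr = mm$corr,
                              iq = vapply(templates, `[[`, numeric(1), "iq")),
              explained_variance = red$explained_variance,
              config = cfg)

  if (!is.null(out_dir)) res$manifest <- write_pipeline_outputs(res, out_dir)
  invisible(res)
}

## Serialize pipeline reports and a deterministic manifest (seeds, params,
## output hashes; no timestamps).
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  K <- length(res$templates)
  files <- character(0)

  stab <- data.frame(id = vapply(res$templates, `[[`, numeric(1), "id"),
                     iq = round(vapply(res$templates, `[[`, numeric(1), "iq"), 10),
                     truth_corr = round(res$recovery$template_truth_corr, 10))
  files <- c(files, write_tsv(stab, file.path(out_dir, "template_stability.tsv")))

  asg <- do.call(rbind, lapply(res$assignments, function(a)
    data.frame(id = a$id, network = a$network,
               overlap = round(a$overlap, 10),
               low_confidence = a$low_confidence)))
  files <- c(files, write_tsv(asg, file.path(out_dir, "network_assignments.tsv")))

  alt <- do.call(rbind, lapply(seq_along(res$alterations), function(p)
    do.call(rbind, lapply(seq_len(K), function(i) {
      r <- res$alterations[[p]][[i]]
      data.frame(patient = p, component = i, cs = round(r$cs, 10),
                 delta_cs_sigma = round(r$delta_cs_sigma, 10),
                 flagged_fraction = round(r$flagged_fraction, 10),
                 significant = r$significant, untestable = r$untestable)
    }))))
  files <- c(files, write_tsv(alt, file.path(out_dir, "alterations.tsv")))

  am <- as.data.frame(res$alteration_matrix$matrix * 1L)
  names(am) <- paste0("patient", seq_len(ncol(am)))
  am <- cbind(component = seq_len(K), am)
  files <- c(files, write_tsv(am, file.path(out_dir, "alteration_matrix.tsv")))

  ov <- do.call(rbind, Filter(Negate(is.null), res$overlap))
  if (!is.null(ov)) {
    num <- vapply(ov, is.numeric, logical(1))
    ov[num] <- lapply(ov[num], round, 10)
    files <- c(files, write_tsv(ov, file.path(out_dir, "overlap.tsv")))
  }

  if (!is.null(res$behavior)) {
    bj <- lapply(res$behavior, function(m)
      list(coefficients = round(m$fit$coefficients, 10),
           intercept = round(m$fit$intercept, 10),
           support = m$fit$support,
           r_squared = round(m$diagnostics$r_squared, 10),
           cv_percent = if (is.null(m$diagnostics$cv_percent)) NULL else
             round(m$diagnostics$cv_percent, 6),
           accepted = m$diagnostics$accepted))
    bp <- file.path(out_dir, "behavior_models.json")
    jsonlite::write_json(bj, bp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, bp)
  }

  manifest <- list(config = cfg,
                   package_version = as.character(utils::packageVersion("rsnmap")),
                   outputs = lapply(stats::setNames(files, basename(files)),
                                    function(f) unname(tools::md5sum(f))))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}
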