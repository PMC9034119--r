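test_that("cluster-extent filtering keeps only clusters at or above the minimum", {
  mask <- cube_mask(12)
  vol <- array(-0.1, dim = c(12, 12, 12))
  vol <- set_block(vol, c(1, 1, 1), c(5, 5, 10), 2)    # 250 voxels
  vol <- set_block(vol, c(8, 8, 1), c(5, 5, 6), 2)     # 150 voxels
  cm <- build_component_mask(vectorize(vol, mask), mask,
                             mask_params(z_thresh = 1, min_cluster_voxels = 200))
  expect_equal(cm$n_voxels, 250)
  expect_equal(cm$n_clusters_kept, 1)
  expect_equal(cm$n_clusters_dropped, 1)
  # the surviving voxels are exactly the large block
  expect_true(all(devectorize(cm$mask, mask)[1:5, 1:5, 1:10] == 1))

  # boundary semantics: a cluster of exactly 200 voxels survives
  v2 <- array(-0.1, dim = c(12, 12, 12))
  v2 <- set_block(v2, c(1, 1, 1), c(5, 5, 8), 2)       # 200 voxels
  cm2 <- build_component_mask(vectorize(v2, mask), mask,
                              mask_params(1, 200))
  expect_equal(cm2$n_voxels, 200)
})

test_that("exclusion mask is applied after cluster filtering", {
  mask <- cube_mask(12)
  vol <- array(-0.1, dim = c(12, 12, 12))
  vol <- set_block(vol, c(1, 1, 1), c(5, 6, 7), 2)     # 210 voxels
  excl <- array(FALSE, dim = c(12, 12, 12))
  excl[1:5, 1:6, 1] <- TRUE                            # 30 of them excluded
  cm <- build_component_mask(vectorize(vol, mask), mask,
                             mask_params(1, 200, exclusion_mask = excl))
  # cluster passes the 210 >= 200 filter first, then loses 30 voxels;
  # exclusion-first ordering would have dropped it entirely
  expect_equal(cm$n_voxels, 180)
  expect_true(cm$usable)
  # all suprathreshold voxels inside the exclusion mask -> unusable
  excl2 <- array(FALSE, dim = c(12, 12, 12)); excl2[1:5, 1:6, 1:7] <- TRUE
  expect_warning(
    cm2 <- build_component_mask(vectorize(vol, mask), mask,
                                mask_params(1, 200, exclusion_mask = excl2)),
    "unusable")
  expect_false(cm2$usable)
})

test_that("connected-component labeling respects the neighborhood convention", {
  vol <- array(FALSE, dim = c(5, 5, 5))
  vol[1, 1, 1] <- TRUE; vol[2, 2, 1] <- TRUE   # diagonal in-plane neighbors
  lab6 <- rsnmap:::label_clusters(vol, 6L)
  expect_equal(length(unique(lab6[lab6 > 0])), 2)
  lab18 <- rsnmap:::label_clusters(vol, 18L)
  expect_equal(length(unique(lab18[lab18 > 0])), 1)
  vol[1, 1, 1] <- FALSE; vol[1, 1, 2] <- TRUE  # corner-diagonal to (2,2,1)
  lab18b <- rsnmap:::label_clusters(vol, 18L)
  expect_equal(length(unique(lab18b[lab18b > 0])), 2)
  lab26 <- rsnmap:::label_clusters(vol, 26L)
  expect_equal(length(unique(lab26[lab26 > 0])), 1)
})

test_that("cosine similarity identities and hand case", {
  x <- c(0.3, -1.2, 2.2, 0.7)
  expect_equal(cosine_similarity(x, x), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  # invariance to positive rescaling of either map
  expect_equal(cosine_similarity(3.7 * x, x), 1)
  expect_equal(cosine_similarity(c(1, 2, 2), 0.1 * c(2, 1, 2)), 8 / 9)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
  # mask restriction
  m <- c(TRUE, TRUE, TRUE, FALSE)
  expect_equal(cosine_similarity(c(1, 2, 2, 9), c(2, 1, 2, -9), m), 8 / 9)
})

test_that("control distribution stores sample moments", {
  d <- control_distribution(c(0.8, 0.9, 1.0), 1)
  expect_equal(d$mu, 0.9)
  expect_equal(d$sigma, 0.1)
  expect_true(d$usable)
  expect_error(control_distribution(c(0.9, 0.8)), "at least 3")
  expect_warning(dz <- control_distribution(rep(0.5, 5)), "unusable")
  expect_false(dz$usable)
})

test_that("delta CS standardizes against the control distribution", {
  d <- control_distribution(c(0.85, 0.9, 0.95), 1)
  expect_equal(delta_cs(d$mu, d), 0)
  d2 <- structure(list(values = 1, mu = 0.9, sigma = 0.05, usable = TRUE),
                  class = "cs_distribution")
  expect_equal(delta_cs(0.7, d2), -4)
  dz <- suppressWarnings(control_distribution(rep(0.5, 5)))
  expect_error(delta_cs(0.4, dz), "zero variance")
})

test_that("permutation test behaves at the center and tail of the null", {
  set.seed(42)
  d <- control_distribution(rnorm(30, 0.9, 0.02), 1)
  center <- permutation_test(d$mu, d, n_perm = 2000, subsample = 20, seed = 1)
  expect_lt(center$flagged_fraction, 0.05)
  expect_false(center$significant)
  far <- permutation_test(d$mu - 100 * d$sigma, d, n_perm = 2000,
                          subsample = 20, seed = 1)
  expect_equal(far$flagged_fraction, 1)
  expect_true(far$significant)
  # reproducibility under a fixed seed
  rerun <- permutation_test(d$mu - 100 * d$sigma, d, n_perm = 2000,
                            subsample = 20, seed = 1)
  expect_identical(far$flagged_fraction, rerun$flagged_fraction)
  # subsample reduction warning when controls are scarce
  expect_warning(
    small <- permutation_test(0.5, d, n_perm = 100, subsample = 100, seed = 2),
    "reduced to 20")
  expect_equal(small$subsample, 20L)
})

test_that("Monte-Carlo matches exhaustive enumeration on a small control set", {
  set.seed(7)
  vals <- rnorm(8, 0.9, 0.03)
  d <- control_distribution(vals, 1)
  pat <- d$mu - 2.2 * d$sigma      # sits in the transition window
  ex <- suppressWarnings(permutation_test(pat, d, subsample = 6,
                                          exhaustive = TRUE))
  mc <- suppressWarnings(permutation_test(pat, d, n_perm = 20000,
                                          subsample = 6, seed = 3))
  expect_equal(ex$n_perm, choose(8, 6))
  expect_lt(abs(ex$flagged_fraction - mc$flagged_fraction), 0.02)
})

test_that("alteration matrix aggregates by network", {
  mk <- function(sig) structure(list(significant = sig, untestable = FALSE),
                                class = "alteration_result")
  # 1 patient, 4 VIS components of which 2 altered
  res <- list(list(mk(TRUE), mk(TRUE), mk(FALSE), mk(FALSE)))
  agg <- patient_alteration_matrix(res, networks = rep("VIS", 4))
  expect_equal(unname(agg$patient_pct["VIS"]), 100)
  expect_equal(unname(agg$component_pct["VIS"]), 50)
  # no significant results: zero matrix
  res0 <- list(list(mk(FALSE), mk(FALSE)), list(mk(FALSE), mk(FALSE)))
  agg0 <- patient_alteration_matrix(res0, networks = c("A", "B"))
  expect_true(all(!agg0$matrix))
  expect_equal(unname(agg0$patient_pct), c(0, 0))
})

test_that("spillover fraction reports suprathreshold mass outside the mask", {
  cm <- structure(list(mask = c(TRUE, TRUE, FALSE, FALSE)),
                  class = "component_mask")
  expect_equal(outside_mask_fraction(c(2, 0, 2, 0), cm), 0.5)
  expect_equal(outside_mask_fraction(c(2, 2, 0, 0), cm), 0)
  expect_true(is.na(outside_mask_fraction(c(0, 0, 0, 0), cm)))
})
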