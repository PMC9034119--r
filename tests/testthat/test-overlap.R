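mk_partition <- function(side = 10) {
  brain <- cube_mask(side)
  tm <- array(FALSE, dim = rep(side, 3)); tm[1:2, 1:2, 1:2] <- TRUE
  tmo <- array(FALSE, dim = rep(side, 3)); tmo[1:4, 1:4, 1:4] <- TRUE
  list(brain = brain, tm = tm, tmo = tmo,
       part = tissue_partition(tm, tmo, brain))
}

test_that("tissue partition derives disjoint exhaustive classes", {
  p <- mk_partition()
  expect_equal(sum(p$part$tm), 8)
  expect_equal(sum(p$part$oedema), 64 - 8)
  expect_true(all((p$part$tm + p$part$oedema + p$part$normal) ==
                  p$part$brain))
  expect_false(any(p$part$tm & p$part$oedema))
  # invariant violations
  bad_tm <- array(FALSE, dim = c(10, 10, 10)); bad_tm[9, 9, 9] <- TRUE
  expect_error(tissue_partition(bad_tm, p$tmo, p$brain), "contained")
  small_brain <- array(FALSE, dim = c(10, 10, 10)); small_brain[1, 1, 1] <- TRUE
  expect_error(tissue_partition(p$tm, p$tmo, small_brain), "contained")
})

test_that("overlap percentage uses the altered mask as denominator", {
  tissue <- c(rep(TRUE, 10), rep(FALSE, 90))
  altered <- rep(TRUE, 100)
  expect_equal(overlap_percent(altered, tissue), 10)
  expect_equal(overlap_percent(tissue, tissue), 100)
  expect_equal(overlap_percent(c(rep(FALSE, 90), rep(TRUE, 10)), tissue), 0)
  expect_error(overlap_percent(rep(FALSE, 100), tissue), "empty")
  # monotone under growth of the tissue mask
  t2 <- tissue; t2[11:30] <- TRUE
  expect_gte(overlap_percent(altered, t2), overlap_percent(altered, tissue))
})

test_that("expected altered mask is the union of template-derived masks", {
  side <- 12
  mask <- cube_mask(side)
  v1 <- array(-0.1, dim = rep(side, 3)); v1 <- set_block(v1, c(1, 1, 1), c(5, 5, 4), 2)
  v2 <- array(-0.1, dim = rep(side, 3)); v2 <- set_block(v2, c(7, 7, 7), c(5, 5, 4), 2)
  tpls <- list(list(id = 1, map = vectorize(v1, mask)),
               list(id = 2, map = vectorize(v2, mask)))
  mp <- mask_params(1, 50)
  am <- expected_altered_mask(c(1, 2), tpls, mask, mp)
  expect_equal(sum(am$per_component[["1"]]), 100)
  expect_equal(sum(am$union), 200)           # disjoint: union = sum
  am1 <- expected_altered_mask(1, tpls, mask, mp)
  expect_equal(am1$union, am1$per_component[["1"]])
  # overlapping components: union smaller than the sum
  v3 <- array(-0.1, dim = rep(side, 3)); v3 <- set_block(v3, c(3, 3, 1), c(5, 5, 4), 2)
  tpls3 <- list(tpls[[1]], list(id = 2, map = vectorize(v3, mask)))
  am3 <- expected_altered_mask(c(1, 2), tpls3, mask, mp)
  expect_lt(sum(am3$union), 200)
  expect_warning(am0 <- expected_altered_mask(integer(0), tpls, mask, mp),
                 "empty")
  expect_false(any(am0$union))
  expect_error(expected_altered_mask(5, tpls, mask, mp), "subset")
})

test_that("tissue overlap report closes to exactly 100 percent", {
  p <- mk_partition(12)
  v <- array(-0.1, dim = rep(12, 3)); v <- set_block(v, c(1, 1, 1), c(6, 6, 3), 2)
  tpls <- list(list(id = 1, map = vectorize(v, p$brain)))
  am <- expected_altered_mask(1, tpls, p$brain, mask_params(1, 50))
  rep <- patient_overlap_report(am, p$part, p$brain)
  expect_equal(rep$tm_pct + rep$oedema_pct + rep$normal_pct,
               rep(100, nrow(rep)))
  expect_equal(rep$unit, c("1", "UNION"))
  # altered fully inside normal tissue -> {0, 0, 100}
  v2 <- array(-0.1, dim = rep(12, 3)); v2 <- set_block(v2, c(6, 6, 6), c(5, 5, 3), 2)
  am2 <- expected_altered_mask(1, list(list(id = 1, map = vectorize(v2, p$brain))),
                               p$brain, mask_params(1, 50))
  r2 <- patient_overlap_report(am2, p$part, p$brain)
  expect_equal(unlist(r2[1, c("tm_pct", "oedema_pct", "normal_pct")]),
               c(tm_pct = 0, oedema_pct = 0, normal_pct = 100))
})

test_that("report built from templates ignores subject-map damage", {
  # two phantom patients with different attenuation depths but the same
  # altered set produce identical overlap reports
  mk <- function(att) phantom_config(
    grid_shape = c(12, 12, 12), n_components = 3, n_patients = 1,
    noise_sd = 0.4, seed = 31,
    lesion_spec = list(list(list(component = 1, attenuation = att))))
  ph_a <- generate_phantom(mk(0))
  ph_b <- generate_phantom(mk(0.6))
  tpls <- truth_templates(ph_a$truth)
  mp <- mask_params(1, 5)
  rep_of <- function(ph) {
    am <- expected_altered_mask(1, tpls, ph$truth$mask, mp)
    part <- tissue_partition(ph$lesions[[1]]$tm, ph$lesions[[1]]$tm_o,
                             ph$truth$mask)
    patient_overlap_report(am, part, ph$truth$mask)
  }
  expect_equal(rep_of(ph_a), rep_of(ph_b))
})

test_that("Spearman correlation of alteration vs overlap", {
  x <- c(-5, -4, -3, -2, -1)
  y <- c(50, 40, 30, 20, 10)
  # deeper alteration (more negative x) with larger overlap: monotone
  # decreasing pairs give rho = -1
  r <- spearman_alteration_vs_overlap(x, y)
  expect_equal(r$rho, -1)
  expect_lt(r$p, 0.05)
  r2 <- spearman_alteration_vs_overlap(x, rev(y))
  expect_equal(r2$rho, 1)
  expect_error(spearman_alteration_vs_overlap(rep(1, 5), y), "constant")
  expect_error(spearman_alteration_vs_overlap(x[1:3], y[1:3]), "at least 4")
})
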