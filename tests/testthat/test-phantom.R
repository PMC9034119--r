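test_that("planted maps are smooth, separated and Z-scored", {
  cfg <- phantom_config(n_components = 2, grid_shape = c(20, 20, 20), seed = 1)
  tr <- make_template_networks(cfg)
  expect_equal(ncol(tr$zmaps), 2)
  expect_lt(abs(cor(tr$zmaps[, 1], tr$zmaps[, 2])), 0.3)
  for (k in 1:2) {
    expect_equal(mean(tr$zmaps[, k]), 0, tolerance = 1e-12)
    expect_equal(sd(tr$zmaps[, k]), 1, tolerance = 1e-12)
    expect_gte(nrow(tr$nodes[[k]]$centers), 2)
    expect_lte(nrow(tr$nodes[[k]]$centers), 5)
  }
  k1 <- phantom_config(n_components = 1, seed = 2)
  t1 <- make_template_networks(k1)
  expect_equal(mean(t1$zmaps[, 1]), 0, tolerance = 1e-12)
  expect_equal(sd(t1$zmaps[, 1]), 1, tolerance = 1e-12)
})

test_that("phantom generation is fully reproducible from the seed", {
  cfg <- phantom_config(seed = 7)
  a <- make_template_networks(cfg)
  b <- make_template_networks(cfg)
  expect_identical(a$zmaps, b$zmaps)
  s1 <- make_subject_series(a, "control", cfg, 1)
  s1b <- make_subject_series(b, "control", cfg, 1)
  expect_identical(s1$data, s1b$data)
  s2 <- make_subject_series(a, "control", cfg, 2)
  expect_false(identical(s1$data, s2$data))
})

test_that("noiseless unlesioned data has numerical rank exactly K", {
  cfg <- phantom_config(n_components = 4, seed = 3)
  tr <- make_template_networks(cfg)
  s <- make_subject_series(tr, "control", cfg, 1, noise_sd = 0)
  d <- svd(s$data, nu = 0, nv = 0)$d
  expect_equal(sum(d > 1e-8 * d[1]), 4)
})

test_that("attenuation deletes exactly the selected distal nodes", {
  mk <- function(att) phantom_config(
    n_components = 1, n_patients = 1, seed = 9,
    lesion_spec = list(list(list(component = 1, attenuation = att,
                                 nodes = 2L))))
  cfg <- mk(0)
  tr <- make_template_networks(cfg)
  pat <- make_subject_series(tr, "patient", cfg, 1, noise_sd = 0)
  ref_cfg <- mk(1)
  ref <- make_subject_series(make_template_networks(ref_cfg),
                             "patient", ref_cfg, 1, noise_sd = 0)
  att <- pat$attenuation[, 1]
  expect_true(any(att == 0))
  # with the single component deleted there, node-2 voxels carry no signal
  expect_true(all(abs(pat$data[att == 0, ]) < 1e-12))
  # voxels outside the attenuated region are bit-identical to the
  # attenuation-1 twin (same seeds, same time courses)
  expect_identical(pat$data[att == 1, ], ref$data[att == 1, ])
  expect_false(isTRUE(all.equal(pat$data, ref$data)))
})

test_that("lesion and behavior specs are validated", {
  expect_error(phantom_config(n_components = 2, n_patients = 1,
                              lesion_spec = list(list(list(component = 5,
                                                           attenuation = 0)))),
               "nonexistent component")
  expect_error(phantom_config(n_components = 2, n_patients = 1,
                              lesion_spec = list(list(list(component = 1,
                                                           attenuation = 1.4)))),
               "attenuation")
  bs <- list(memory = list(coefs = c(-1, 0), intercept = 0, noise_sd = 0))
  expect_error(phantom_config(n_components = 2, behavior_spec = bs),
               "non-negative")
})

test_that("behavior scores follow the planted linear model", {
  K <- 3
  bs <- list(dom0 = list(coefs = rep(0, K), intercept = 2.5, noise_sd = 0),
             dom1 = list(coefs = c(0, 1.2, 0), intercept = 0, noise_sd = 0),
             domn = list(coefs = rep(0, K), intercept = 0, noise_sd = 0.5))
  cfg <- phantom_config(n_components = K, n_patients = 6, behavior_spec = bs,
                        seed = 4)
  tr <- make_template_networks(cfg)
  set.seed(11)
  dcs <- matrix(rnorm(6 * K), 6, K)
  sc <- make_behavior_scores(tr, dcs, cfg)
  # zero coefficients, zero noise: every score equals the intercept
  expect_equal(sc$score[sc$domain == "dom0"], rep(2.5, 6))
  # single nonzero coefficient, zero noise: perfectly collinear
  expect_equal(sc$score[sc$domain == "dom1"], 1.2 * dcs[, 2])
  # with noise, a refit cannot be perfect
  noisy <- sc$score[sc$domain == "domn"]
  expect_gt(sd(noisy), 0)
  expect_error(make_behavior_scores(tr, matrix(Inf, 6, K), cfg), "finite")
})

test_that("lesion masks partition cleanly inside the brain", {
  cfg <- phantom_config(seed = 5)
  ph <- generate_phantom(cfg)
  for (p in seq_along(ph$lesions)) {
    les <- ph$lesions[[p]]
    expect_true(all(les$tm[les$tm] %in% TRUE))
    expect_true(all(!les$tm[!ph$truth$mask]))   # tm inside brain
    expect_true(all(les$tm_o | !les$tm))        # tm subset of tm_o
  }
  expect_equal(ph$true_altered[[1]], 1L)
})
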