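# Shared fixture builders: everything is generated in code at test time.

# Small phantom with truth-derived templates (skips group ICA where the test
# targets a downstream stage).
truth_templates <- function(truth) {
  lapply(seq_len(ncol(truth$zmaps)), function(i)
    list(id = i, map = truth$zmaps[, i], iq = 1, label = "network-candidate"))
}

# A full-cube brain mask of the given side (every voxel in-mask), for tests
# that construct maps voxel by voxel.
cube_mask <- function(side) array(TRUE, dim = rep(side, 3))

# Place a cuboid of given dims with corner at `at` into a volume.
set_block <- function(vol, at, dims, value) {
  vol[at[1]:(at[1] + dims[1] - 1),
      at[2]:(at[2] + dims[2] - 1),
      at[3]:(at[3] + dims[3] - 1)] <- value
  vol
}

# Goodman-Kruskal gamma: tie-aware rank correlation (1 for any
# non-decreasing association; ties contribute neither way).
gk_gamma <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  (conc - disc) / (conc + disc)
}
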