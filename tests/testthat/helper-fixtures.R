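# Shared fixtures, built in code at test time.

# A small patient volume with a rectangular "lesion" of known SUVs.
toy_volume <- function(values = c(2, 4, 6), spacing = c(10, 10, 10)) {
  pet <- array(0, c(4, 3, 3))
  mask <- array(0L, c(4, 3, 3))
  pet[seq_along(values), 2, 2] <- values
  mask[seq_along(values), 2, 2] <- 1L
  patient_volume(pet, array(0.3, c(4, 3, 3)), mask, spacing,
                 patient_id = "toy")
}

# Directly constructed separable ROI tensors: class 1 carries a brighter
# central blob. Much faster than rendering full cohorts for network tests.
separable_rois <- function(n, v = 16, channels = 2, signal = 3,
                           seed = 1) {
  set.seed(seed)
  labels <- rep(0:1, length.out = n)
  ctr <- (v %/% 2 - 2):(v %/% 2 + 2)
  rois <- lapply(seq_len(n), function(i) {
    x <- array(rnorm(channels * v^3, 0, 0.5), c(channels, v, v, v))
    x[1, ctr, ctr, ctr] <- x[1, ctr, ctr, ctr] + 1 + signal * labels[i]
    x
  })
  list(x = rois, labels = labels)
}

# A miniature simulated cohort for pipeline contract tests.
quick_cohort_config <- function(seed = 11, n_unlabeled = 6) {
  cohort_config(n_labeled = 14, n_unlabeled = n_unlabeled,
                train_fraction = 10 / 14, grid_voxels = 24,
                effect_size = 2, seed = seed)
}

quick_net_config <- function(seed = 1, epochs = 2) {
  network_config(input_voxels = 16, max_epochs = epochs, batch_size = 4,
                 val_fraction = 0, dropout_rate = 0, seed = seed)
}

# Independent trilinear interpolation oracle (0-based continuous coords).
trilinear_oracle <- function(vol, p) {
  d <- dim(vol)
  i0 <- pmin(pmax(floor(p), 0), d - 2)
  f <- p - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
      (if (dz) f[3] else 1 - f[3])
    acc <- acc + w * vol[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  unname(acc)
}

# Two-sided Fisher p-value by exhaustive hypergeometric enumeration.
fisher_enum <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  p_obs <- dhyper(tab[1, 1], rs[1], rs[2], cs[1])
  ks <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  probs <- dhyper(ks, rs[1], rs[2], cs[1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
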