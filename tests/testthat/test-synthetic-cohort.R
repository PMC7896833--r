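test_that("patient simulation is deterministic and records scanner geometry", {
  cfg <- cohort_config(grid_voxels = 24)
  p1 <- simulate_patient("nonrelapse", scanner_profiles("discovery_vct"),
                         rng_seed = 7, config = cfg)
  p2 <- simulate_patient("nonrelapse", scanner_profiles("discovery_vct"),
                         rng_seed = 7, config = cfg)
  expect_identical(p1$volume$pet, p2$volume$pet)
  expect_identical(p1$volume$ct, p2$volume$ct)
  expect_identical(p1$volume$mask, p2$volume$mask)

  # full-size grid: the fine-spacing preset needs the physical extent
  p3 <- simulate_patient("relapse", scanner_profiles("biograph_vision"),
                         rng_seed = 1, config = cohort_config())
  expect_equal(p3$volume$spacing, c(1.6, 1.6, 1.5))
  expect_true(all(p3$volume$pet >= 0))
  expect_gt(sum(p3$volume$mask), 0)

  profs <- scanner_profiles()
  expect_length(profs, 3)
  expect_equal(profs$discovery_vct$voxel_size, rep(5.47, 3))
  expect_equal(profs$discovery_mi$voxel_size, c(2.7, 2.7, 2.79))
})

test_that("zero effect size leaves the class phenotypes indistinguishable", {
  set.seed(42)
  suv_r <- replicate(200, simulate_lesion_params("relapse", 0)$suv_mean)
  suv_n <- replicate(200, simulate_lesion_params("nonrelapse", 0)$suv_mean)
  expect_gt(t.test(log(suv_r), log(suv_n))$p.value, 0.05)
})

test_that("lesion separability is non-decreasing in effect size", {
  auc_of <- function(es) {
    set.seed(99)
    sr <- replicate(250, simulate_lesion_params("relapse", es)$suv_mean)
    sn <- replicate(250, simulate_lesion_params("nonrelapse", es)$suv_mean)
    mean(outer(sr, sn, ">") + 0.5 * outer(sr, sn, "=="))
  }
  aucs <- vapply(c(0, 1, 2), auc_of, numeric(1))
  expect_true(all(diff(aucs) >= 0))
  expect_gt(aucs[3], 0.8)
})

test_that("survival generator matches its exponential model", {
  cfg <- cohort_config()
  # no-censoring regime: sample mean within 3 SE of 1/hazard
  cfg_nc <- cfg
  cfg_nc$censor_horizon_labeled <- 1e5
  cfg_nc$followup_max_labeled <- 2e5
  draws <- vapply(1:2000, function(i)
    simulate_survival("relapse", cfg_nc, rng_seed = i)$pfs_months,
    numeric(1))
  se <- (1 / cfg$hazard_relapse) / sqrt(2000)
  expect_lt(abs(mean(draws) - 1 / cfg$hazard_relapse), 3 * se)

  # equal hazards: class-conditional event-time distributions agree
  cfg_eq <- cfg_nc
  cfg_eq$hazard_nonrelapse <- cfg_eq$hazard_relapse
  d_r <- vapply(1:1000, function(i)
    simulate_survival("relapse", cfg_eq, rng_seed = i)$pfs_months,
    numeric(1))
  d_n <- vapply(1:1000, function(i)
    simulate_survival("nonrelapse", cfg_eq, rng_seed = 5000 + i)$pfs_months,
    numeric(1))
  expect_gt(suppressWarnings(ks.test(d_r, d_n)$p.value), 0.01)

  # labeled follow-up respects the censoring horizon
  s <- simulate_survival("nonrelapse", cfg, rng_seed = 3, labeled = TRUE)
  expect_gte(s$followup_months, 24)
  su <- simulate_survival("nonrelapse", cfg, rng_seed = 3, labeled = FALSE)
  expect_lt(su$followup_months, 24)
})

test_that("cohort stratification preserves counts, ratios and scanner mix", {
  coh <- simulate_cohort(cohort_config(relapse_prevalence = 0.25),
                         keep_volumes = FALSE)
  cl <- coh$clinical
  expect_equal(sum(cl$split == "train"), 64)
  expect_equal(sum(cl$split == "test"), 20)
  expect_equal(sum(cl$split == "unlabeled"), 83)
  expect_equal(as.numeric(table(cl$scanner[cl$split == "unlabeled"])[
    c("discovery_vct", "discovery_mi", "biograph_vision")]),
    c(39, 29, 15))

  truth <- coh$truth
  prev <- function(split) {
    ids <- cl$patient_id[cl$split == split]
    mean(truth$latent_class[match(ids, truth$patient_id)] == "relapse")
  }
  expect_lte(abs(prev("train") - prev("test")), 1 / 20)

  expect_error(simulate_cohort(cohort_config(relapse_prevalence = 1e-4),
                               keep_volumes = FALSE),
               "single class")
})

test_that("unlabeled patients expose no latent class or outcome", {
  coh <- simulate_cohort(quick_cohort_config(), keep_volumes = FALSE)
  unl <- coh$clinical[coh$clinical$split == "unlabeled", ]
  expect_false("latent_class" %in% names(coh$clinical))
  expect_true(all(is.na(unl$event)))
  expect_true(all(is.na(unl$pfs_months)))
  expect_true(all(is.na(unl$followup_months)))
  # the withheld truth table still carries them for oracle checks
  expect_true(all(c("latent_class", "event") %in% names(coh$truth)))
})

test_that("oversized lesions are rejected with the offending axes named", {
  cfg <- cohort_config(grid_voxels = 12)
  expect_error(
    simulate_patient("relapse", scanner_profiles("biograph_vision"),
                     rng_seed = 2, config = cfg),
    "does not fit")
})
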