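# Independent evaluation of the risk formulas for the oracle checks.
logi <- function(z) ifelse(z > 0, log1p(exp(-z)), -z + log1p(exp(z)))

test_that("risk estimators match direct formula evaluation", {
  sp <- c(1, -1); sn <- c(-2)
  expect_equal(pn_risk(sp, sn, 0.5),
               0.5 * mean(logi(sp)) + 0.5 * mean(logi(-sn)),
               tolerance = 1e-12)
  # constant-zero scorer gives ln 2 for any prior and all three estimators
  z5 <- rep(0, 5)
  for (pr in c(0.2, 0.5, 0.8)) {
    expect_equal(pn_risk(z5, z5, pr), log(2), tolerance = 1e-12)
    expect_equal(pu_risk(z5, z5, pr), log(2), tolerance = 1e-12)
    expect_equal(nu_risk(z5, z5, pr), log(2), tolerance = 1e-12)
  }
  # perfect separation limit
  expect_lt(pn_risk(rep(50, 3), rep(-50, 3), 0.5), 1e-9)
  expect_error(pn_risk(numeric(0), sn, 0.5), "positive")
  expect_error(pu_risk(sp, numeric(0), 0.5), "unlabeled")
})

test_that("the gamma combination hits PN/PU/NU exactly at its endpoints", {
  set.seed(12)
  sp <- rnorm(7); sn <- rnorm(5); su <- rnorm(11)
  for (pr in c(0.3, 0.6)) {
    expect_identical(pnu_risk(sp, sn, su, 0, pr), pn_risk(sp, sn, pr))
    expect_identical(pnu_risk(sp, sn, su, 1, pr), pu_risk(sp, su, pr))
    expect_identical(pnu_risk(sp, sn, su, -1, pr), nu_risk(sn, su, pr))
    g <- 0.4
    expect_equal(pnu_risk(sp, sn, su, g, pr),
                 (1 - g) * pn_risk(sp, sn, pr) + g * pu_risk(sp, su, pr),
                 tolerance = 1e-12)
    g <- -0.4
    expect_equal(pnu_risk(sp, sn, su, g, pr),
                 (1 + g) * pn_risk(sp, sn, pr) - g * nu_risk(sn, su, pr),
                 tolerance = 1e-12)
  }
  expect_equal(pnu_risk(rep(0, 3), rep(0, 3), rep(0, 3), 0.5, 0.4), log(2),
               tolerance = 1e-12)
  expect_error(pnu_risk(rnorm(3), rnorm(3), numeric(0), 0.5, 0.5),
               "unlabeled")
})

test_that("risks are invariant to permutation and duplication, and the
           clamp zeroes negative implicit terms", {
  set.seed(13)
  sp <- rnorm(9); sn <- rnorm(6); su <- rnorm(14)
  expect_equal(pn_risk(sp, sn, 0.4), pn_risk(sample(sp), rev(sn), 0.4))
  expect_equal(pu_risk(c(sp, sp), c(su, su), 0.4), pu_risk(sp, su, 0.4))
  # bracket forced negative: corrected risk reduces to the positive term
  sp_big <- rep(100, 4); su_big <- rep(20, 6)
  expect_equal(pu_risk(sp_big, su_big, 0.5, nonneg_correction = TRUE),
               0.5 * mean(logi(sp_big)), tolerance = 1e-12)
  expect_lt(pu_risk(sp_big, su_big, 0.5, nonneg_correction = FALSE),
            pu_risk(sp_big, su_big, 0.5, nonneg_correction = TRUE))
  expect_gte(pu_risk(sp, su, 0.4), 0)
  expect_gte(nu_risk(sn, su, 0.4), 0)
})

test_that("the uncorrected PU risk is unbiased for the population risk", {
  # scorer s(x) = x; positives ~ N(1,1), negatives ~ N(-1,1), prior 0.4
  pr <- 0.4
  pop_term <- function(mu, s) integrate(function(x) logi(s * x) *
                                          dnorm(x, mu, 1), -Inf, Inf)$value
  pop_pn <- pr * pop_term(1, 1) + (1 - pr) * pop_term(-1, -1)
  set.seed(14)
  reps <- vapply(1:10000, function(i) {
    sp <- rnorm(10, 1)
    su <- ifelse(rbinom(20, 1, pr) == 1, rnorm(20, 1), rnorm(20, -1))
    pu_risk(sp, su, pr, nonneg_correction = FALSE)
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - pop_pn), 3 * se)
})

test_that("fit_pnu matches a dense grid-search oracle on a 1-D toy", {
  set.seed(15)
  xp <- 1 + rnorm(20, 0, 0.1)
  xn <- -1 + rnorm(20, 0, 0.1)
  xu <- c(1 + rnorm(20, 0, 0.1), -1 + rnorm(20, 0, 0.1))
  cfg <- pnu_config(gamma_grid = c(0, 0.3, 0.5), l2_penalty = 1e-3,
                    prior_pos = 0.5)
  fit <- fit_pnu(xp, xn, xu, cfg)
  expect_gt(fit$coefficients$weights, 0)

  # oracle: dense search over (weight, bias) at the fitted gamma
  obj <- function(w, b) {
    pnu_risk(w * xp + b, w * xn + b, w * xu + b, fit$gamma, 0.5) +
      cfg$l2_penalty * w^2
  }
  grid <- seq(-5, 5, by = 0.05)
  coarse <- outer(grid, grid, Vectorize(obj))
  best <- arrayInd(which.min(coarse), dim(coarse))
  fine_w <- seq(grid[best[1]] - 0.05, grid[best[1]] + 0.05, by = 1e-3)
  fine_b <- seq(grid[best[2]] - 0.05, grid[best[2]] + 0.05, by = 1e-3)
  fine <- outer(fine_w, fine_b, Vectorize(obj))
  risk_fit <- obj(fit$coefficients$weights, fit$coefficients$bias)
  expect_lt(abs(risk_fit - min(fine)), 1e-4)
})

test_that("with no unlabeled data the fit reduces to PN classification", {
  set.seed(16)
  x <- rbind(matrix(rnorm(20, 1.5), 10, 2), matrix(rnorm(20, -1.5), 10, 2))
  y <- rep(c(1, 0), each = 10)
  fit <- fit_pnu(x[y == 1, ], x[y == 0, ], NULL,
                 pnu_config(gamma_grid = 0, l2_penalty = 1e-3))
  expect_equal(fit$gamma, 0)
  ours <- predict(fit, x, type = "label") == "positive"
  rr <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                       lambda = 1e-3)
  theirs <- as.vector(predict(rr, x, type = "class")) == "1"
  expect_equal(ours, theirs)
})

test_that("fitting is invariant to duplicating every training point and
           never worse than the zero scorer", {
  set.seed(17)
  xp <- matrix(rnorm(30, 1), 10, 3); xn <- matrix(rnorm(30, -1), 10, 3)
  xu <- matrix(rnorm(60, 0), 20, 3)
  cfg <- pnu_config(gamma = 0.5, prior_pos = 0.5)
  f1 <- fit_pnu(xp, xn, xu, cfg)
  f2 <- fit_pnu(rbind(xp, xp), rbind(xn, xn), rbind(xu, xu), cfg)
  expect_equal(f1$coefficients$weights, f2$coefficients$weights,
               tolerance = 1e-10)
  expect_equal(f1$coefficients$bias, f2$coefficients$bias,
               tolerance = 1e-10)
  expect_lte(f1$risk, log(2) + 1e-9)
  expect_error(fit_pnu(matrix(1, 5, 2), matrix(1, 5, 2), NULL, cfg),
               "degenerate")
})

test_that("implicit labels follow the sign rule with ties negative", {
  fit <- structure(list(coefficients = list(weights = 1, bias = 0),
                        loss = "logistic", d = 1),
                   class = "pnu_fit")
  lab <- assign_implicit_labels(fit, c(2, -3, 0))
  expect_equal(lab$label, c("positive", "negative", "negative"))
  expect_equal(lab$confidence[3], 0.5)
  expect_equal(lab$confidence[1], 1 / (1 + exp(-2)))
})

test_that("PNU models persist to JSON and score identically", {
  set.seed(19)
  xp <- matrix(rnorm(20, 1), 10, 2); xn <- matrix(rnorm(20, -1), 10, 2)
  fit <- fit_pnu(xp, xn, NULL, pnu_config(gamma = 0))
  path <- file.path(withr::local_tempdir(), "pnu.json")
  write_pnu(fit, path)
  back <- read_pnu(path)
  xnew <- matrix(rnorm(10), 5, 2)
  expect_equal(predict(back, xnew), predict(fit, xnew), tolerance = 1e-12)
  expect_equal(back$gamma, fit$gamma)
})

test_that("implicit labels recover the latent classes in a separable
           regime", {
  accs <- vapply(1:5, function(s) {
    set.seed(100 + s)
    feat <- function(cls, n) t(vapply(seq_len(n), function(i) {
      p <- simulate_lesion_params(cls, effect_size = 2.5)
      c(log(p$suv_mean), log(p$radii_mm), log(p$texture_sd))
    }, numeric(5)))
    xp <- feat("relapse", 25); xn <- feat("nonrelapse", 25)
    tru <- rep(c("positive", "negative"), each = 30)
    xu <- rbind(feat("relapse", 30), feat("nonrelapse", 30))
    fit <- fit_pnu(xp, xn, xu, pnu_config(seed = s))
    mean(assign_implicit_labels(fit, xu)$label == tru)
  }, numeric(1))
  expect_gte(mean(accs), 0.8)
})
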