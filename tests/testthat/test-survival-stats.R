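test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3, 4), c(0, 1, 0, 1))
  s_at <- function(t) km$surv[max(which(km$time <= t))]
  expect_equal(s_at(1.5), 1)          # censoring only
  expect_equal(s_at(2.5), 2 / 3)      # 3 at risk at t = 2
  expect_equal(s_at(5), 0)            # 1 at risk at t = 4
  expect_equal(km$surv[1], 1)         # S(0) = 1
  expect_true(all(diff(km$surv) <= 0))

  expect_equal(km_estimate(c(3, 5, 8), c(0, 0, 0))$surv, c(1, 1, 1, 1))
  km1 <- km_estimate(5, 1)
  expect_equal(km1$surv[km1$time == 5], 0)
  expect_error(km_estimate(c(1, -2), c(1, 1)), "positive")
})

test_that("log-rank agrees with the hypergeometric hand table", {
  # identical groups: exactly no signal
  t0 <- c(2, 4, 6, 8); e0 <- c(1, 1, 0, 1)
  lr0 <- logrank_test(t0, e0, t0, e0)
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)

  ta <- 1:3; tb <- 4:6
  lr <- logrank_test(ta, rep(1, 3), tb, rep(1, 3))
  # hand computation of sum(O - E) and sum(V) per distinct event time
  n_a <- 3; n_b <- 3; oe <- 0; v <- 0
  for (t in 1:6) {
    d <- 1; n <- n_a + n_b
    e_a <- d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
    o_a <- as.numeric(t <= 3)
    oe <- oe + o_a - e_a
    if (t <= 3) n_a <- n_a - 1 else n_b <- n_b - 1
  }
  expect_equal(lr$chi2, oe^2 / v, tolerance = 1e-10)
  # symmetry under group swap
  lr_sw <- logrank_test(tb, rep(1, 3), ta, rep(1, 3))
  expect_equal(lr$chi2, lr_sw$chi2, tolerance = 1e-12)
  expect_error(logrank_test(1:3, rep(0, 3), 4:6, rep(0, 3)), "no events")
})

test_that("time-dependent AUC equals brute-force concordance without
           censoring", {
  set.seed(41)
  n <- 40
  time <- rexp(n, 0.05) + 0.1
  event <- rep(1, n)
  marker <- -time + rnorm(n, 0, 5)
  t_eval <- unname(quantile(time, 0.45))
  got <- time_dependent_auc(marker, time, event, t_eval)
  cases <- which(time <= t_eval); controls <- which(time > t_eval)
  cmp <- outer(marker[cases], marker[controls],
               function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(got$auc, mean(cmp), tolerance = 1e-12)

  # perfect and uninformative markers
  expect_equal(time_dependent_auc(-time, time, event, t_eval)$auc, 1)
  expect_equal(time_dependent_auc(rep(2, n), time, event, t_eval)$auc, 0.5)
  expect_error(time_dependent_auc(marker, time, event, max(time) + 1),
               "range")
  expect_true(all(got$roc$sensitivity >= 0 & got$roc$sensitivity <= 1))
})

test_that("IPCW weighting keeps the AUC in range under censoring", {
  set.seed(42)
  n <- 120
  time <- rexp(n, 0.04)
  cens <- runif(n, 5, 60)
  obs <- pmin(time, cens); event <- as.integer(time <= cens)
  marker <- -log(time) + rnorm(n, 0, 0.8)
  a <- time_dependent_auc(marker, obs, event, 24)
  expect_true(a$auc >= 0 && a$auc <= 1)
  expect_gt(a$auc, 0.5)               # informative marker
})

test_that("Cox log-HR matches a partial-likelihood grid-search oracle", {
  # 12 patients, one binary covariate, no ties
  time <- c(1.1, 2.3, 3.2, 4.7, 5.1, 6.9, 7.4, 8.8, 9.6, 10.3, 11.9, 13.4)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(1, 1, 1, 0, 1, 0, 1, 1, 0, 0, 0, 0)
  fit <- cox_fit(data.frame(x = x), time, event)

  # manual partial likelihood (no ties, so Efron = Breslow)
  pl <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
  grid <- seq(-5, 5, by = 0.01)
  b0 <- grid[which.max(vapply(grid, pl, numeric(1)))]
  fine <- seq(b0 - 0.01, b0 + 0.01, by = 1e-5)
  b_star <- fine[which.max(vapply(fine, pl, numeric(1)))]
  expect_lt(abs(fit$table$coef - b_star), 1e-4)

  expect_error(cox_fit(data.frame(x = x, x2 = x), time, event),
               "singular|collinear")
  expect_error(cox_fit(data.frame(x = rep(1, 12)), time, event),
               "constant")
})

test_that("Cox confidence intervals cover the true hazard ratio", {
  hr_true <- 3
  covered <- vapply(1:20, function(r) {
    set.seed(300 + r)
    x <- rbinom(300, 1, 0.5)
    time <- rexp(300, 0.05 * hr_true^x)
    tab <- cox_fit(data.frame(x = x), time, rep(1, 300))$table
    tab$ci_lo <= hr_true && hr_true <= tab$ci_hi
  }, logical(1))
  expect_gte(sum(covered), 17)
})

test_that("classification metrics reproduce the known confusion matrices", {
  # TP 7, FN 1, TN 10, FP 2 at n = 20
  truth <- c(rep(1, 8), rep(0, 12))
  pred <- c(rep(1, 7), 0, rep(0, 10), 1, 1)
  m <- classification_metrics(pred, truth)
  expect_equal(m$sensitivity, 87.5)
  expect_equal(m$specificity, 83 + 1 / 3, tolerance = 1e-10)
  expect_equal(m$accuracy, 85)

  mp <- classification_metrics(truth, truth)
  expect_equal(unlist(mp), c(sensitivity = 100, specificity = 100,
                             accuracy = 100))
  m2 <- classification_metrics(rep(1, 10), rep(c(1, 0), 5))
  expect_equal(m2$sensitivity, 100)
  expect_equal(m2$specificity, 0)
  expect_equal(m2$accuracy, 50)
  expect_error(classification_metrics(rep(1, 4), rep(0, 4)),
               "sensitivity")
})

test_that("Fisher's exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  set.seed(43)
  for (i in 1:6) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact(tab), fisher_enum(tab), tolerance = 1e-12)
  }
  extreme <- matrix(c(10, 0, 0, 10), 2)
  expect_lt(fisher_exact(extreme), 1e-4)
  expect_equal(fisher_exact(extreme), fisher_enum(extreme),
               tolerance = 1e-12)
  expect_warning(p <- fisher_exact(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_equal(p, 1)
})

test_that("univariate screening dichotomizes at the median and is
           consistent with the log-rank test", {
  set.seed(44)
  n <- 60
  time <- rexp(n, 0.05); event <- rbinom(n, 1, 0.8)
  grp <- rbinom(n, 1, 0.5)
  vars <- data.frame(psi_group = grp, noise = rnorm(n),
                     flat = rep(2, n))
  expect_warning(res <- univariate_screen(vars, time, event), "constant")
  lr <- logrank_test(time[grp == 1], event[grp == 1],
                     time[grp == 0], event[grp == 0])
  expect_equal(res$p[res$variable == "psi_group"], lr$p,
               tolerance = 1e-12)
  expect_false("flat" %in% res$variable)

  # median cutoff splits 1..10 into two groups of five
  v10 <- data.frame(v = 1:10)
  r10 <- univariate_screen(v10, time = rexp(10, 0.1) + 0.1,
                           event = rep(1, 10))
  expect_equal(r10$cutoff, 5.5)
})
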