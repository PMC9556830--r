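test_that("fit_cox matches a grid search of the written-out partial likelihood", {
  time <- c(2, 5, 7, 11, 13, 17)
  event <- rep(1, 6)
  x <- c(1, 0, 1, 0, 1, 0)
  surv <- data.frame(sample_id = paste0("s", 1:6), time_months = time,
                     event = event)
  fit <- fit_cox(x, surv)
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, cox_log_pl, numeric(1), time = time, event = event, x = x)
  expect_equal(fit$beta, grid[which.max(ll)], tolerance = 1e-4)
  expect_equal(fit$HR, exp(fit$beta), tolerance = 1e-12)
  expect_equal(fit$se_HR, fit$HR * fit$se_beta, tolerance = 1e-12)
  expect_equal(fit$n_events, 6)
  expect_true(fit$converged)
})

test_that("a null covariate stays within two standard errors at large n", {
  set.seed(21)
  surv <- rand_surv(2000)
  x <- rnorm(2000)
  fit <- fit_cox(x, surv)
  expect_lt(abs(fit$beta), 2 * fit$se_beta)
  expect_gt(fit$p_value, 0.001)
})

test_that("fit_cox rejects uninformative or degenerate inputs", {
  surv <- data.frame(sample_id = paste0("s", 1:10),
                     time_months = 1:10, event = rep(0, 10))
  expect_error(fit_cox(rnorm(10), surv), "2 observed events")
  surv$event <- rep(1, 10)
  expect_error(fit_cox(rep(3, 10), surv), "constant")
  expect_error(fit_cox(c(Inf, rnorm(9)), surv), "finite")
})

test_that("perfect separation is flagged as non-converged", {
  # covariate perfectly ordered with event times: monotone likelihood
  surv <- data.frame(sample_id = paste0("s", 1:8),
                     time_months = 1:8, event = rep(1, 8))
  fit <- fit_cox(8:1, surv)
  expect_false(fit$converged)
})

test_that("km_curve is the product-limit estimator", {
  surv <- data.frame(sample_id = paste0("s", 1:4),
                     time_months = c(1, 2, 3, 4), event = rep(1, 4))
  km <- km_curve(surv, rep("all", 4))$all
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))

  # no events: flat at 1
  surv$event <- 0
  expect_true(all(km_curve(surv, rep("all", 4))$all$surv == 1))

  # a censored subject leaves the risk set at its censoring time
  surv2 <- data.frame(sample_id = paste0("s", 1:3),
                      time_months = c(1, 2, 3), event = c(0, 1, 1))
  km2 <- km_curve(surv2, rep("all", 3))$all
  expect_equal(km2$surv[km2$time == 2], 0.5)  # risk set of 2, one event
  expect_error(km_curve(surv2, factor(rep("a", 3), levels = c("a", "b"))),
               "empty group")
})

test_that("logrank_test equals the hand-tabulated O/E/V oracle", {
  # 8-subject instance with censoring and both groups
  time <- c(3, 5, 5, 8, 10, 12, 15, 18)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  group <- c("a", "b", "a", "b", "a", "b", "a", "b")
  surv <- data.frame(sample_id = paste0("s", 1:8),
                     time_months = time, event = event)
  lr <- logrank_test(surv, group)
  expect_equal(lr$chi_square, naive_logrank_chisq(time, event, group),
               tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(lr$chi_square, 1, lower.tail = FALSE))
})

test_that("identical groups give chi-square 0 and p 1", {
  surv1 <- data.frame(sample_id = paste0("a", 1:5),
                      time_months = c(1, 3, 4, 7, 9), event = c(1, 1, 0, 1, 1))
  surv <- rbind(surv1, transform(surv1, sample_id = paste0("b", 1:5)))
  lr <- logrank_test(surv, rep(c("g1", "g2"), each = 5))
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)
})

test_that("log-rank p-values are uniform under the null", {
  set.seed(22)
  p <- replicate(400, {
    surv <- rand_surv(100)
    logrank_test(surv, sample(rep(c("a", "b"), 50)))$p_value
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("time-dependent AUC is 1 for a perfect ranking and matches the
           binary ROC reduction without censoring", {
  set.seed(23)
  surv <- rand_surv(120, censor_hazard = 0)   # no censoring
  score <- -surv$time_months                  # perfect risk ranking
  qs <- quantile(surv$time_months, c(0.3, 0.6))
  expect_equal(unname(time_dependent_auc(score, surv, qs)), c(1, 1))

  noisy <- score + rnorm(120, sd = 40)
  for (t in qs) {
    auc <- time_dependent_auc(noisy, surv, t)
    expect_equal(unname(auc),
                 binary_auc(noisy, as.integer(surv$time_months <= t)),
                 tolerance = 1e-10)
  }
})

test_that("a random score has AUC near one half", {
  set.seed(24)
  aucs <- replicate(100, {
    surv <- rand_surv(500)
    t <- unname(quantile(surv$time_months, 0.5))
    time_dependent_auc(rnorm(500), surv, t)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("AUC horizons beyond follow-up are rejected", {
  surv <- rand_surv(50)
  expect_error(time_dependent_auc(rnorm(50), surv,
                                  max(surv$time_months) + 1),
               "beyond")
})

test_that("predict_survival: S(0) = 1, monotone in t, null model matches KM", {
  set.seed(25)
  n <- 500
  x <- cbind(x1 = rnorm(n))
  surv <- rand_surv(n, lp = 0.4 * x[, 1])
  fit <- fit_cox(x, surv)
  hz <- unname(quantile(surv$time_months, c(0.25, 0.5, 0.75)))
  p <- predict_survival(fit, x, horizons = c(1e-9, hz))
  expect_true(all(p > 0 & p <= 1))
  expect_equal(unname(p[, 1]), rep(1, n), tolerance = 1e-6)
  expect_true(all(diff(t(p)) <= 1e-12))   # non-increasing across horizons

  # a (near) null model's predictions track the overall KM curve
  surv0 <- rand_surv(n)
  fit0 <- fit_cox(cbind(z = rnorm(n)), surv0)
  km <- km_curve(surv0, rep("all", n))$all
  hz0 <- unname(quantile(surv0$time_months, c(0.3, 0.6)))
  p0 <- predict_survival(fit0, cbind(z = rep(0, n))[1, , drop = FALSE],
                         horizons = hz0)
  km_at <- vapply(hz0, function(t) min(km$surv[km$time <= t]), numeric(1))
  expect_true(all(abs(p0 - km_at) < 0.02))
})

test_that("log-rank and univariate Cox agree in order of magnitude on
           two-group data", {
  set.seed(26)
  g <- rep(c(0, 1), each = 150)
  surv <- rand_surv(300, lp = -0.6 * g)
  lr <- logrank_test(surv, g)
  cx <- fit_cox(g, surv)
  expect_lt(abs(log10(lr$p_value) - log10(cx$p_value)), 1)
})
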