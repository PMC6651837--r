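test_that("basic goodness-of-fit statistics match hand evaluation", {
  perfect <- tibble::tibble(observed = c(-5, -6, -7), predicted = c(-5, -6, -7))
  m <- qsar_metrics(perfect)
  expect_equal(m$r2, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$mae, 0)
  expect_equal(m$dmax, 0)

  resid11 <- tibble::tibble(observed = c(1, -1), predicted = c(0, 0))
  m2 <- qsar_metrics(resid11)
  expect_equal(m2$rmse, 1)
  expect_equal(m2$mae, 1)

  hand <- tibble::tibble(observed = c(0, 1, 2), predicted = c(0, 1, 1))
  expect_equal(qsar_metrics(hand)$r2, 0.5)            # SSE 1, SST 2
  # printed convention: denominator about the mean predicted value
  expect_equal(qsar_metrics(hand, convention = "as_printed")$r2,
               1 - 1 / sum((c(0, 1, 2) - 2 / 3)^2))
  expect_error(qsar_metrics(tibble::tibble(observed = c(1, 1),
                                           predicted = c(0, 2))),
               "zero-variance")
})

test_that("residual summaries respect their mutual orderings", {
  set.seed(44)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    d <- tibble::tibble(observed = rnorm(n), predicted = rnorm(n))
    m <- qsar_metrics(d)
    expect_gte(m$rmse, m$mae)
    expect_gte(m$dmax, m$mae)
    expect_gte(m$dmax, m$rmse / sqrt(n))
  }
})

test_that("through-origin regression matches closed forms and a generic solver", {
  y <- c(1, 2, 3, 5)
  same <- origin_regression(y, y)
  expect_equal(same$k, 1); expect_equal(same$k_prime, 1)
  expect_equal(same$ro2, 1); expect_equal(same$ro2_prime, 1)
  doubled <- origin_regression(y, 2 * y)
  expect_equal(doubled$k, 0.5)
  set.seed(4)
  yh <- y + rnorm(4, sd = 0.3)
  orr <- origin_regression(y, yh)
  expect_equal(orr$k, unname(coef(lm(y ~ yh + 0))), tolerance = 1e-12)
  expect_equal(orr$k_prime, unname(coef(lm(yh ~ y + 0))), tolerance = 1e-12)
  expect_error(origin_regression(c(0, 0), c(1, 2)), "all-zero")
})

test_that("the rm2 family reproduces its defining identities", {
  same <- rm2_family(0.8, 0.8, 0.8)
  expect_equal(same$rm2, 0.8)
  expect_equal(same$rm2_delta, 0)
  tab5 <- rm2_family(0.879, 0.876, 0.876)
  expect_equal(round(tab5$rm2, 2), 0.83)
  perfect <- rm2_family(1, 1, 1)
  expect_equal(perfect$rm2, 1); expect_equal(perfect$rm2_mean, 1)
  expect_equal(perfect$rm2_delta, 0)
  # the printed linear convention omits the radical
  lin <- rm2_family(0.879, 0.876, 0.876, convention = "as_printed")
  expect_equal(lin$rm2, 0.879 * (1 - 0.003))
})

test_that("external predictivity statistics match a direct-formula evaluation", {
  perfect <- external_metrics(c(-5, -6), c(0, 1, 2), c(0, 1, 2))
  expect_equal(unlist(perfect), c(qf1 = 1, qf2 = 1, qf3 = 1, ccc = 1))
  # constant prediction at the external mean zeroes qF2
  em <- external_metrics(c(0, 2), c(0, 1, 2), c(1, 1, 1))
  expect_equal(em$qf2, 0)
  # 3-point hand case: y = (0,1,2), yhat = (0,2,2), train mean 1
  y <- c(0, 1, 2); yh <- c(0, 2, 2); tr <- c(0, 1, 2)  # mean(tr) = 1
  em3 <- external_metrics(tr, y, yh)
  sse <- (0 - 0)^2 + (1 - 2)^2 + (2 - 2)^2              # 1
  expect_equal(em3$qf1, 1 - sse / sum((y - 1)^2))       # 1 - 1/2
  expect_equal(em3$qf2, 1 - sse / sum((y - mean(y))^2)) # 1 - 1/2
  expect_equal(em3$qf3, 1 - (sse / 3) / (sum((tr - 1)^2) / 3))
  num <- 2 * sum((y - mean(y)) * (yh - mean(yh)))
  den <- sum((y - mean(y))^2) + sum((yh - mean(yh))^2) +
    3 * (mean(y) - mean(yh))^2
  expect_equal(em3$ccc, num / den)
})

test_that("qF2 never exceeds qF1 and CCC is 1 only for identity", {
  set.seed(77)
  for (i in 1:20) {
    tr <- rnorm(15, -6); y <- rnorm(8, -6); yh <- y + rnorm(8, sd = 0.4)
    em <- external_metrics(tr, y, yh)
    expect_lte(em$qf2, em$qf1 + 1e-12)
    expect_lt(em$ccc, 1)
    expect_gte(em$ccc, -1)
  }
})

test_that("10-fold cross-validation pools out-of-fold predictions", {
  d <- simulate_linear_table(n = 50, noise_sd = 0, seed = 19)
  q <- kfold_cv(function(dd) fit_pls(dd, n_components = 5), d, seed = 19)
  expect_equal(q, 1, tolerance = 1e-8)
  folds <- make_folds(50, k = 10, seed = 19)
  expect_equal(sort(unique(folds)), 1:10)
  expect_equal(length(folds), 50)
  expect_true(all(table(folds) == 5))
  expect_error(make_folds(5, k = 10), "more folds")
})

test_that("cross-validation on permuted responses carries no signal", {
  d <- simulate_linear_table(n = 60, noise_sd = 0.2, seed = 3)
  qnull <- vapply(1:20, function(s) {
    dd <- d
    set.seed(s)
    dd$logPe <- sample(dd$logPe)
    kfold_cv(function(x) fit_pls(x, n_components = 2), dd, seed = s)
  }, numeric(1))
  expect_lte(median(qnull), 0.1)
})

test_that("Y-scrambling averages near zero for an honest model and is seeded", {
  d <- simulate_linear_table(n = 80, noise_sd = 0.3, seed = 29)
  sc <- y_scramble(function(dd) fit_pls(dd, n_components = 2), d, seed = 29)
  expect_equal(length(sc$rs2), 25)   # default repetition count
  expect_lt(sc$rs2_mean, 0.15)
  sc2 <- y_scramble(function(dd) fit_pls(dd, n_components = 2), d, seed = 29)
  expect_identical(sc$rs2, sc2$rs2)
})

test_that("perfect predictions satisfy every stringent criterion", {
  d <- tibble::tibble(observed = c(-5, -5.5, -6.5, -7),
                      predicted = c(-5, -5.5, -6.5, -7))
  m <- qsar_metrics(d, train_observed = c(-5, -6, -7))
  m$qcv2 <- 1
  cr <- check_criteria(m)
  expect_true(all(cr$pass[!is.na(cr$pass)]))
  expect_equal(nrow(cr), 7)
})

test_that("criteria verdicts reproduce the published pass/fail pattern", {
  # training-stage values printed for the ensemble model
  hsvr <- tibble::tibble(r2 = 0.88, qcv2 = 0.80, ro2 = 0.88, k = 1.00,
                         ro2_prime = 0.88, rm2 = 0.83, rm2_prime = 0.84,
                         rm2_mean = 0.83, rm2_delta = 0.01)
  cr_h <- check_criteria(hsvr)
  expect_true(all(cr_h$pass[!is.na(cr_h$pass)]))
  # the linear model's printed training values fail everything except the
  # origin-regression pair of criteria
  pls <- tibble::tibble(r2 = 0.61, qcv2 = 0.76, ro2 = 0.61, k = 1.02,
                        ro2_prime = 0.38, rm2 = 0.23, rm2_prime = 0.60,
                        rm2_mean = 0.42, rm2_delta = 0.29)
  cr_p <- check_criteria(pls)
  passed <- cr_p$criterion[!is.na(cr_p$pass) & cr_p$pass]
  expect_setequal(passed, c("origin slope and ro2", "|ro2 - r'o2| < 0.30"))
})

test_that("cross-assay calibration matches textbook least squares", {
  d <- tibble::tibble(pe = c(-6, -5, -4), po = c(-6, -5, -4))
  cal <- calibrate_cross_assay(d, "pe", "po")
  expect_equal(cal$slope, 1); expect_equal(cal$r, 1)
  # orthogonalized response has zero correlation
  set.seed(8)
  x <- rnorm(20)
  y <- rnorm(20)
  y <- y - x * sum(x * (y - mean(y))) / sum((x - mean(x))^2)
  d2 <- tibble::tibble(x = x, y = y)
  expect_lt(abs(calibrate_cross_assay(d2, "x", "y")$r), 0.3)
  # 5-point fabricated pairs against closed-form OLS
  x5 <- c(-7.1, -6.3, -5.8, -5.0, -4.2)
  y5 <- c(-6.8, -6.5, -5.5, -5.2, -3.9)
  cal5 <- calibrate_cross_assay(tibble::tibble(x = x5, y = y5), "x", "y")
  b <- sum((x5 - mean(x5)) * (y5 - mean(y5))) / sum((x5 - mean(x5))^2)
  a <- mean(y5) - b * mean(x5)
  r <- cor(x5, y5)
  tstat <- r * sqrt(3) / sqrt(1 - r^2)
  expect_equal(cal5$slope, b, tolerance = 1e-12)
  expect_equal(cal5$intercept, a, tolerance = 1e-12)
  expect_equal(cal5$r, r, tolerance = 1e-12)
  expect_equal(cal5$p_slope, 2 * pt(-abs(tstat), df = 3), tolerance = 1e-12)
  expect_error(calibrate_cross_assay(tibble::tibble(x = c(1, 1, 1),
                                                    y = 1:3), "x", "y"),
               "zero-variance")
})
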