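test_that("noiseless linear data is fitted exactly with enough components", {
  set.seed(21)
  d <- tibble::tibble(id = sprintf("c%02d", 1:20),
                      A = rnorm(20), B = rnorm(20))
  d$logPe <- 2 * d$A - d$B
  fit <- fit_pls(d, n_components = 2)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  expect_equal(unname(fit$coefficients), c(2, -1), tolerance = 1e-8)
})

test_that("full-component PLS equals ordinary least squares", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 30; p <- 4
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("d", 1:p)))
    y <- drop(X %*% rnorm(p)) + rnorm(n, sd = 0.5)
    d <- dplyr::bind_cols(tibble::tibble(id = sprintf("c%02d", 1:n), logPe = y),
                          tibble::as_tibble(as.data.frame(X)))
    fit <- fit_pls(d, n_components = p)
    # normal-equations oracle
    Xi <- cbind(1, X)
    beta <- solve(crossprod(Xi), crossprod(Xi, y))
    expect_equal(unname(fit$coefficients), unname(beta[-1]), tolerance = 1e-8)
    expect_equal(fit$intercept, unname(beta[1]), tolerance = 1e-8)
  }
})

test_that("generating coefficients are recovered within 3 standard errors", {
  truth <- c(logP = 0.24, logD = 0.23, PSA = -0.22, FPSA = -0.25, mu = -0.16)
  d <- simulate_linear_table(n = 200, noise_sd = 0.1, seed = 17)
  fit <- fit_pls(d, n_components = 5)
  X <- cbind(1, as.matrix(d[names(truth)]))
  sigma2 <- sum(fit$residuals^2) / (nrow(d) - ncol(X))
  se <- sqrt(diag(solve(crossprod(X))) * sigma2)[-1]
  expect_true(all(abs(fit$coefficients - truth) <= 3 * se))
})

test_that("training r2 is non-decreasing in the number of components", {
  d <- simulate_linear_table(n = 80, noise_sd = 0.4, seed = 5)
  r2 <- vapply(1:5, function(a) {
    glance(fit_pls(d, n_components = a))$r.squared
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
})

test_that("PLS prediction is affine in the descriptors", {
  d <- simulate_linear_table(n = 50, seed = 9)
  fit <- fit_pls(d, n_components = 3)
  x1 <- d[3, ]; x2 <- d[17, ]
  for (alpha in c(0.25, 0.5, 0.9)) {
    mix <- x1
    for (nm in fit$descriptors) {
      mix[[nm]] <- alpha * x1[[nm]] + (1 - alpha) * x2[[nm]]
    }
    expect_equal(predict(fit, mix),
                 alpha * predict(fit, x1) + (1 - alpha) * predict(fit, x2),
                 tolerance = 1e-10)
  }
})

test_that("cross-validated component selection picks a valid dimension", {
  d <- simulate_linear_table(n = 60, noise_sd = 0.3, seed = 12)
  fit <- fit_pls(d, n_components = "cv", seed = 12)
  expect_gte(fit$n_components, 1L)
  expect_lte(fit$n_components, 5L)
  expect_equal(nrow(fit$cv), 5)
  expect_equal(fit$n_components, which.max(fit$cv$qcv2))
})

test_that("the frozen published model reproduces its printed coefficients", {
  m <- paper_pls_model()
  expect_equal(length(m$coefficients), 5)
  expect_equal(unname(m$coefficients["logD"]), 0.228889)
  origin <- c(logP = 0, logD = 0, PSA = 0, FPSA = 0, mu = 0)
  expect_equal(predict(m, origin), -6.13473)
  expect_equal(predict(m, c(logP = 1, logD = 0, PSA = 0, FPSA = 0, mu = 0)),
               -5.896477)
  expect_equal(predict(m, c(logP = 1, logD = 1, PSA = 1, FPSA = 1, mu = 1)),
               -6.286663)
  expect_error(predict(m, c(logP = 1)), "missing descriptors")
})

test_that("PLS models round-trip through JSON bit-identically", {
  tmp <- withr::local_tempfile(fileext = ".json")
  m <- paper_pls_model()
  write_pls_model(m, tmp)
  back <- read_pls_model(tmp)
  expect_identical(back$coefficients, m$coefficients)
  expect_identical(back$intercept, m$intercept)
  grid <- tibble::tibble(logP = rnorm(5), logD = rnorm(5), PSA = rnorm(5),
                         FPSA = rnorm(5), mu = rnorm(5))
  expect_identical(predict(back, grid), predict(m, grid))
})

test_that("NIPALS agrees with an independent PLS implementation", {
  d <- simulate_linear_table(n = 60, noise_sd = 0.3, seed = 23)
  cols <- descriptor_names(d)
  fit <- fit_pls(d, n_components = 2)
  ref <- mixOmics::pls(as.matrix(d[cols]), d$logPe, ncomp = 2,
                       mode = "regression", scale = FALSE)
  pred_ref <- predict(ref, as.matrix(d[cols]))$predict[, 1, 2]
  expect_equal(unname(fit$fitted), unname(pred_ref), tolerance = 1e-6)
})

test_that("tidy and glance summarize a PLS fit", {
  d <- simulate_linear_table(n = 40, seed = 2)
  fit <- fit_pls(d, n_components = 2)
  td <- tidy(fit)
  expect_tibble(td)
  expect_equal(td$term, c(descriptor_names(d), "(Intercept)"))
  gl <- glance(fit)
  expect_equal(gl$n, 40L)
  expect_gt(gl$r.squared, 0.5)
})
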