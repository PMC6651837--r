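test_that("the RBF kernel matches its closed form and is symmetric", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), 3.7), 1)
  expect_equal(rbf_kernel(0, 1, 1), exp(-1), tolerance = 1e-12)
  set.seed(1)
  u <- rnorm(4); v <- rnorm(4)
  expect_equal(rbf_kernel(u, v, 0.3), rbf_kernel(v, u, 0.3))
  expect_error(rbf_kernel(1:2, 1:3, 1), "dimension")
})

test_that("the RBF kernel matrix is positive semi-definite", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 3), 20, 3)
    K <- pampaqsar:::.rbf_cross(X, X, gamma = runif(1, 0.05, 2))
    expect_equal(K, t(K), tolerance = 1e-12)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})

test_that("an SVR with a tight tube and large cost fits noiseless linear data", {
  d <- tibble::tibble(id = sprintf("c%02d", 1:10),
                      x = seq(-1, 1, length.out = 10))
  d$logPe <- d$x
  spec <- svr_spec("epsilon", cost = 1000, gamma = 1, epsilon = 0.01,
                   descriptors = "x")
  fit <- train_svr(d, spec)
  rmse <- sqrt(mean((predict(fit, d) - d$logPe)^2))
  expect_lte(rmse, 0.02)
})

test_that("a single training point is predicted within the tube", {
  d <- tibble::tibble(id = "only", x = 0.3, logPe = -5.5)
  fit <- train_svr(d, svr_spec("epsilon", cost = 10, gamma = 1,
                               epsilon = 0.1, descriptors = "x"))
  expect_lte(abs(predict(fit, d) - (-5.5)), 0.1 + 1e-8)
})

test_that("duplicating every training row leaves predictions unchanged", {
  set.seed(3)
  d <- tibble::tibble(id = sprintf("c%02d", 1:15), x = rnorm(15))
  d$logPe <- sin(d$x)
  spec <- svr_spec("epsilon", cost = 10, gamma = 0.5, epsilon = 0.05,
                   descriptors = "x")
  fit1 <- train_svr(d, spec)
  d2 <- dplyr::bind_rows(d, dplyr::mutate(d, id = paste0(id, "_dup")))
  fit2 <- train_svr(d2, spec)
  expect_equal(predict(fit1, d), predict(fit2, d), tolerance = 1e-4)
})

test_that("grid search agrees with an independent exhaustive loop", {
  d <- linear_in_A(n = 30, p_noise = 1, noise_sd = 0.2, seed = 14)
  grid <- svr_grid(cost = c(1, 10, 100), gamma = c(0.1, 0.5, 1),
                   epsilon = 0.1, modes = "epsilon")
  gs <- grid_search(d, "A", grid = grid, folds = 5, seed = 14)
  # brute-force oracle: re-evaluate every cell with the same folds
  brute <- vapply(seq_len(nrow(grid)), function(i) {
    sp <- svr_spec("epsilon", cost = grid$cost[i], gamma = grid$gamma[i],
                   epsilon = grid$epsilon[i], descriptors = "A")
    kfold_cv(function(dd) train_svr(dd, sp), d, k = 5, seed = 14)
  }, numeric(1))
  expect_equal(gs$score, max(brute), tolerance = 1e-12)
  expect_equal(gs$scores$qcv2, brute, tolerance = 1e-12)
  best <- which.max(brute)
  expect_equal(gs$spec$cost, grid$cost[best])
  expect_equal(gs$spec$gamma, grid$gamma[best])
})

test_that("grid search returns a single-cell grid and breaks ties canonically", {
  d <- linear_in_A(n = 20, p_noise = 0, noise_sd = 0.1, seed = 8)
  one <- svr_grid(cost = 4, gamma = 0.25, epsilon = 0.1, modes = "epsilon")
  gs <- grid_search(d, "A", grid = one, folds = 4, seed = 8)
  expect_equal(gs$spec$cost, 4)
  # duplicate rows score identically; the first canonical row must win
  two <- dplyr::bind_rows(one, one)
  gs2 <- grid_search(d, "A", grid = two, folds = 4, seed = 8)
  expect_equal(gs2$scores$qcv2[1], gs2$scores$qcv2[2])
  expect_equal(gs2$spec$cost, 4)
  expect_error(grid_search(d, "A", grid = one[0, ]), "empty grid")
})

test_that("an ensemble of identical members collapses to the member prediction", {
  d <- linear_in_A(n = 40, p_noise = 1, noise_sd = 0.1, seed = 10)
  hsvr <- build_hsvr(d, candidate_subsets = list("A", "A"),
                     grid = tiny_grid(), folds = 5, seed = 10)
  member_pred <- predict(hsvr$members[[1]], d)
  ens_pred <- predict(hsvr, d)
  expect_lte(sqrt(mean((ens_pred - member_pred)^2)), 0.05)
})

test_that("with regime-informative subsets the ensemble matches its best member", {
  d <- simulate_bilinear_table(n = 120, noise_sd = 0.2, seed = 11)
  hsvr <- build_hsvr(d, candidate_subsets = list(c("logD", "FPSA", "mu"),
                                                 c("logP", "logD", "PSA")),
                     grid = tiny_grid(), folds = 5, seed = 11)
  member_rmse <- vapply(hsvr$members, function(m) {
    sqrt(mean((predict(m, d) - d$logPe)^2))
  }, numeric(1))
  hsvr_rmse <- sqrt(mean((predict(hsvr, d) - d$logPe)^2))
  expect_lte(hsvr_rmse, min(member_rmse) + 0.05)
})

test_that("an always-true acceptance rule stops at the first canonical ensemble", {
  d <- linear_in_A(n = 30, p_noise = 2, noise_sd = 0.2, seed = 12)
  hsvr <- build_hsvr(d, candidate_subsets = list("A", "noise1", "noise2"),
                     grid = tiny_grid(), folds = 5, seed = 12,
                     acceptance_rule = function(r2, qcv2) TRUE)
  expect_equal(length(hsvr$members), 2L)
  expect_equal(hsvr$selection_log$members[1], "1+2")
  expect_true(hsvr$accepted)
  expect_equal(nrow(hsvr$selection_log), 1)
})

test_that("an impossible acceptance rule returns the best ensemble flagged unaccepted", {
  d <- linear_in_A(n = 30, p_noise = 1, noise_sd = 0.3, seed = 13)
  expect_warning(
    hsvr <- build_hsvr(d, candidate_subsets = list("A", "noise1"),
                       grid = tiny_grid(), folds = 5, seed = 13,
                       acceptance_rule = function(r2, qcv2) FALSE),
    "unaccepted")
  expect_false(hsvr$accepted)
  expect_false(any(hsvr$selection_log$accepted))
})

test_that("predictions are invariant to member order and survive serialization", {
  d <- simulate_bilinear_table(n = 80, noise_sd = 0.2, seed = 15)
  subsets <- list(c("logD", "FPSA"), c("logP", "PSA"))
  h1 <- build_hsvr(d, candidate_subsets = subsets, grid = tiny_grid(),
                   folds = 5, seed = 15,
                   acceptance_rule = function(r2, qcv2) TRUE)
  h2 <- build_hsvr(d, candidate_subsets = rev(subsets), grid = tiny_grid(),
                   folds = 5, seed = 15,
                   acceptance_rule = function(r2, qcv2) TRUE)
  expect_equal(predict(h1, d), predict(h2, d), tolerance = 1e-8)

  tmp <- withr::local_tempfile(fileext = ".json")
  write_hsvr_model(h1, tmp)
  back <- read_hsvr_model(tmp)
  expect_equal(predict(back, d), predict(h1, d), tolerance = 1e-10)
})

test_that("tidy and glance expose the ensemble structure", {
  d <- linear_in_A(n = 30, p_noise = 1, noise_sd = 0.2, seed = 16)
  h <- build_hsvr(d, candidate_subsets = list("A", "noise1"),
                  grid = tiny_grid(), folds = 5, seed = 16,
                  acceptance_rule = function(r2, qcv2) TRUE)
  td <- tidy(h)
  expect_equal(td$level, c("member", "member", "meta"))
  gl <- glance(h)
  expect_equal(gl$n_members, 2L)
  expect_true(is.numeric(gl$r2))
})
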