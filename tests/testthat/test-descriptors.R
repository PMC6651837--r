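test_that("replicate averaging takes the mean of close measurements and rejects divergent ones", {
  expect_equal(average_replicates(c(-5.1, -5.3), 0.5), -5.2)
  expect_equal(average_replicates(-6.0), -6.0)
  expect_error(average_replicates(c(-5.0, -7.0), 0.5), "divergent")
  expect_error(average_replicates(numeric(0)), "no measurements")
  # spread exactly at the window is still acceptable
  expect_equal(average_replicates(c(-5.0, -5.5), 0.5), -5.25)
})

test_that("normalization centers and scales with the n-1 standard deviation", {
  tbl <- tibble::tibble(id = letters[1:3], logP = c(1, 2, 3))
  z <- normalize_descriptors(tbl)
  expect_equal(z$logP, c(-1, 0, 1))
  s <- norm_stats(z)
  expect_equal(s$center, 2)
  expect_equal(s$scale, 1)
})

test_that("normalized columns have mean 0 and unit sample sd; the transform round-trips", {
  set.seed(42)
  tbl <- tibble::tibble(id = sprintf("c%02d", 1:20),
                        a = rnorm(20, 5, 3), b = runif(20, -2, 9))
  z <- normalize_descriptors(tbl)
  expect_equal(mean(z$a), 0, tolerance = 1e-12)
  expect_equal(sd(z$a), 1, tolerance = 1e-12)
  expect_equal(mean(z$b), 0, tolerance = 1e-12)
  expect_equal(sd(z$b), 1, tolerance = 1e-12)
  back <- denormalize_descriptors(z)
  expect_equal(back$a, tbl$a, tolerance = 1e-12)
  expect_equal(back$b, tbl$b, tolerance = 1e-12)
})

test_that("re-normalizing with its own statistics is the test-set pathway and is exact", {
  tbl <- tibble::tibble(id = letters[1:4], x = c(2, 4, 6, 8))
  z <- normalize_descriptors(tbl)
  # applying the training stats to already-raw data reproduces z
  z2 <- normalize_descriptors(tbl, stats = norm_stats(z))
  expect_equal(z2$x, z$x)
  # a fresh single-row table can be normalized only with supplied stats
  one <- tibble::tibble(id = "new", x = 5)
  expect_error(normalize_descriptors(one), "at least 2")
  z1 <- normalize_descriptors(one, stats = norm_stats(z))
  expect_equal(z1$x, (5 - 5) / sd(c(2, 4, 6, 8)))
})

test_that("constant descriptors are rejected with a zero-scale error", {
  tbl <- tibble::tibble(id = letters[1:3], x = c(5, 5, 5))
  expect_error(normalize_descriptors(tbl), "zero scale")
})

test_that("screening drops missing, non-discriminating, and rank-correlated descriptors", {
  set.seed(7)
  n <- 30
  tbl <- tibble::tibble(
    id = sprintf("c%02d", 1:n),
    A = rnorm(n))
  tbl$B <- 2 * tbl$A                       # perfect monotone correlation
  tbl$C <- sample(tbl$A)                   # permutation: rank-independent of A
  tbl$has_na <- c(NA, rnorm(n - 1))
  tbl$flat <- rep(3.3, n)
  out <- screen_descriptors(tbl)
  kept <- descriptor_names(out)
  expect_false("has_na" %in% kept)
  expect_false("flat" %in% kept)
  expect_length(intersect(c("A", "B"), kept), 1)   # exactly one survives
  expect_true("C" %in% kept)
  log <- attr(out, "screen_log")
  expect_setequal(log$descriptor, setdiff(names(tbl)[-1], c(kept, "id")))
})

test_that("no surviving descriptor pair exceeds the Spearman threshold", {
  set.seed(11)
  n <- 40
  base <- rnorm(n)
  tbl <- tibble::tibble(id = sprintf("c%02d", 1:n),
                        d1 = base,
                        d2 = base + rnorm(n, sd = 0.1),
                        d3 = -base + rnorm(n, sd = 0.2),
                        d4 = rnorm(n), d5 = rnorm(n))
  out <- screen_descriptors(tbl, spearman_r2_threshold = 0.64)
  kept <- descriptor_names(out)
  if (length(kept) >= 2) {
    rho2 <- cor(as.matrix(out[kept]), method = "spearman")^2
    diag(rho2) <- 0
    expect_lt(max(rho2), 0.64)
  }
})

test_that("ion classes follow the pKa rules relative to 7", {
  expect_equal(classify_ion_class(c(9.2, 3.1)), "zwitterion")
  expect_equal(classify_ion_class(c(8.1, 9.5)), "base")
  expect_equal(classify_ion_class(c(3.0, 5.1)), "acid")
  expect_equal(classify_ion_class(4.2), "neutral")   # single pKa, literal rule
  expect_equal(classify_ion_class(9.9), "neutral")
  expect_error(classify_ion_class(numeric(0)), "empty")
  # boundary pKa of exactly 7 counts as above by default, below if configured
  expect_equal(classify_ion_class(c(7, 3)), "zwitterion")
  expect_equal(classify_ion_class(c(7, 3), boundary = "below"), "acid")
})

test_that("generated pKa profiles are classified back to their true labels", {
  pk <- simulate_pka_profiles(n = 120, seed = 5)
  got <- classify_ion_class(pk$pka)
  expect_equal(got$ion_class, pk$true_class)
  expect_equal(got$flag, lengths(pk$pka) == 1L)
})

test_that("descriptor tables round-trip through CSV including pKa lists", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  tbl <- tibble::tibble(id = c("a", "b"), logPe = c(-5.2, -6.4),
                        pka = list(c(9.2, 3.1), 4.2),
                        logP = c(1.2, 3.4), PSA = c(60.5, 130.1))
  write_descriptor_table(tbl, tmp)
  back <- read_descriptor_table(tmp)
  expect_equal(back$pka, tbl$pka)
  expect_equal(back$PSA, tbl$PSA)
  expect_error(as_descriptor_table(tibble::tibble(id = c("x", "x"), v = 1:2)),
               "duplicate")
})
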