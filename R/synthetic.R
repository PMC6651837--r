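#' Default synthetic descriptor correlation structure
#'
#' Five descriptors (logP, logD, PSA, FPSA, mu) with standard-Gaussian
#' marginals and the two correlations characteristic of permeability
#' descriptor sets: the two hydrophobicity measures correlate at 0.66
#' and the two polarity measures at 0.79, the rest independent. Standard
#' marginals keep centering-and-scaling near-identity at large n, so
#' worked examples in normalized units stay on the published model's
#' scale.
#'
#' @return A 5x5 positive-definite correlation matrix.
#' @export
default_descriptor_correlation <- function() {
  nm <- c("logP", "logD", "PSA", "FPSA", "mu")
  R <- diag(5)
  dimnames(R) <- list(nm, nm)
  R["logP", "logD"] <- R["logD", "logP"] <- 0.66
  R["PSA", "FPSA"] <- R["FPSA", "PSA"] <- 0.79
  R
}

.simulate_descriptors <- function(n, correlation, seed) {
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) abort("correlation matrix is not positive definite")
  set.seed(seed)
  X <- MASS::mvrnorm(n, mu = rep(0, ncol(correlation)), Sigma = correlation)
  colnames(X) <- colnames(correlation)
  X
}

#' Simulate a descriptor table with a linear response
#'
#' Multivariate-Gaussian descriptors with a configurable correlation
#' structure and a response that is an affine combination of them plus
#' Gaussian noise; the ground truth every linear-recovery test is scored
#' against. Deterministic per seed.
#'
#' @param n Number of compounds.
#' @param correlation Positive-definite correlation matrix with named
#'   dimnames; default [default_descriptor_correlation()].
#' @param coefficients Named generating coefficients (names must be
#'   descriptor names). Default mirrors the magnitudes of the published
#'   linear permeability model.
#' @param intercept Generating intercept. Default -6.13.
#' @param noise_sd Gaussian noise standard deviation, log10 units.
#'   Default 0.3.
#' @param seed Integer seed.
#' @return A descriptor-table tibble with `id`, `logPe`, and the
#'   descriptor columns; the generating parameters are attached as
#'   attribute `"ground_truth"`.
#' @export
simulate_linear_table <- function(n = 200,
                                  correlation = default_descriptor_correlation(),
                                  coefficients = c(logP = 0.24, logD = 0.23,
                                                   PSA = -0.22, FPSA = -0.25,
                                                   mu = -0.16),
                                  intercept = -6.13, noise_sd = 0.3, seed = 1) {
  stopifnot(noise_sd >= 0, all(names(coefficients) %in% colnames(correlation)))
  X <- .simulate_descriptors(n, correlation, seed)
  y <- intercept + drop(X[, names(coefficients), drop = FALSE] %*% coefficients) +
    rnorm(n, sd = noise_sd)
  out <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("cmpd%04d", seq_len(n)), logPe = y),
    tibble::as_tibble(as.data.frame(X)))
  attr(out, "ground_truth") <- list(effect = "linear",
                                    coefficients = coefficients,
                                    intercept = intercept,
                                    noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a descriptor table with a hydrophobicity-breakpoint response
#'
#' Emulates the bilinear dependence of permeability on hydrophobicity:
#' the response rises along the hydrophobicity descriptor up to a
#' breakpoint and falls beyond it, with additional linear terms in the
#' remaining descriptors and Gaussian noise. A purely linear model cannot
#' represent the regime change, which is exactly the gap the
#' hierarchical SVR is built to close; this generator is the benchmark
#' on which that comparison is made.
#'
#' @inheritParams simulate_linear_table
#' @param hydrophobicity Descriptor carrying the bilinear effect.
#'   Default `"logD"`.
#' @param breakpoint Location of the maximum along the hydrophobicity
#'   axis, normalized units. Default 1.0.
#' @param slope_up,slope_down Slopes below and beyond the breakpoint.
#'   Defaults +0.5 and -0.7.
#' @param coefficients Linear coefficients of the remaining descriptors.
#' @return As [simulate_linear_table()].
#' @export
simulate_bilinear_table <- function(n = 300,
                                    correlation = default_descriptor_correlation(),
                                    hydrophobicity = "logD",
                                    breakpoint = 1.0,
                                    slope_up = 0.5, slope_down = -0.7,
                                    coefficients = c(PSA = -0.22, FPSA = -0.25,
                                                     mu = -0.16),
                                    intercept = -6.13, noise_sd = 0.3, seed = 1) {
  stopifnot(noise_sd >= 0, hydrophobicity %in% colnames(correlation),
            !hydrophobicity %in% names(coefficients))
  X <- .simulate_descriptors(n, correlation, seed)
  h <- X[, hydrophobicity]
  ridge <- ifelse(h <= breakpoint,
                  slope_up * h,
                  slope_up * breakpoint + slope_down * (h - breakpoint))
  lin <- if (length(coefficients) > 0L) {
    drop(X[, names(coefficients), drop = FALSE] %*% coefficients)
  } else 0
  y <- intercept + ridge + lin + rnorm(n, sd = noise_sd)
  out <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("cmpd%04d", seq_len(n)), logPe = y),
    tibble::as_tibble(as.data.frame(X)))
  attr(out, "ground_truth") <- list(effect = "bilinear",
                                    hydrophobicity = hydrophobicity,
                                    breakpoint = breakpoint,
                                    slope_up = slope_up,
                                    slope_down = slope_down,
                                    coefficients = coefficients,
                                    intercept = intercept,
                                    noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate pKa profiles with known ion classes
#'
#' Constructs pKa lists that satisfy the ion-class rules exactly --
#' zwitterions get one pKa above and one below 7, acids two below, bases
#' two above, neutrals a single value -- so the classifier can be
#' round-trip tested against known labels.
#'
#' @param n Number of compounds.
#' @param class_mix Named proportions over
#'   `c("zwitterion", "acid", "base", "neutral")`, summing to 1.
#' @param seed Integer seed.
#' @return A tibble with `id`, `pka` (list-column), and `true_class`.
#' @export
simulate_pka_profiles <- function(n = 100,
                                  class_mix = c(zwitterion = 0.25, acid = 0.25,
                                                base = 0.25, neutral = 0.25),
                                  seed = 1) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8,
            all(names(class_mix) %in% c("zwitterion", "acid", "base", "neutral")))
  set.seed(seed)
  counts <- floor(n * class_mix)
  short <- n - sum(counts)
  if (short > 0) {
    top <- order(n * class_mix - counts, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1
  }
  labels <- rep(names(counts), counts)
  pka <- lapply(labels, function(cl) {
    switch(cl,
           zwitterion = c(runif(1, 7.5, 12), runif(1, 2, 6.5)),
           acid = sort(runif(2, 2, 6.5)),
           base = sort(runif(2, 7.5, 12)),
           neutral = runif(1, 2, 12))
  })
  tibble::tibble(id = sprintf("cmpd%04d", seq_len(n)),
                 pka = pka, true_class = labels)
}
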