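#' Seeded k-fold assignments
#'
#' Uniform random fold assignment with a recorded seed; every index
#' appears in exactly one fold and fold sizes differ by at most one.
#'
#' @param n Number of observations.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1..k`.
#' @export
make_folds <- function(n, k = 10, seed = 1) {
  if (k > n) abort("more folds than observations")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Goodness-of-fit statistics for a prediction set
#'
#' Computes the squared correlation coefficient (r2 for a training set,
#' q2 for an external set), residual summaries (maximum absolute residual
#' Dmax, MAE, residual standard deviation s, RMSE), the
#' through-the-origin regression slopes k and k' with their ro2 / r'o2,
#' and the rm2 family. When `train_observed` is supplied the external
#' prediction statistics qF1², qF2², qF3² and the concordance correlation
#' coefficient (CCC) are added.
#'
#' Two conventions exist for the r2 denominator: the `"conventional"`
#' total sum of squares about the mean *observed* value (default; gives
#' r2 = 1 for a perfect fit), and the `"as_printed"` variant about the
#' mean *predicted* value.
#'
#' @param data A data frame holding observed and predicted values.
#' @param observed,predicted Column names. Defaults `"observed"`,
#'   `"predicted"`.
#' @param train_observed Optional numeric vector of training-set observed
#'   responses, enabling the external statistics.
#' @param convention r2 denominator convention (see above).
#' @return A one-row tibble of class `pampa_metrics` with columns `n`,
#'   `r2`, `dmax`, `mae`, `s`, `rmse`, `k`, `k_prime`, `ro2`,
#'   `ro2_prime`, `rm2`, `rm2_prime`, `rm2_mean`, `rm2_delta`, and (when
#'   `train_observed` is given) `qf1`, `qf2`, `qf3`, `ccc`, `n_train`.
#' @examples
#' d <- tibble::tibble(observed = c(0, 1, 2), predicted = c(0, 1, 1))
#' qsar_metrics(d)$r2   # 0.5
#' @export
qsar_metrics <- function(data, observed = "observed", predicted = "predicted",
                         train_observed = NULL,
                         convention = c("conventional", "as_printed")) {
  convention <- match.arg(convention)
  y <- data[[observed]]
  yhat <- data[[predicted]]
  if (length(y) != length(yhat) || length(y) < 2L) {
    abort("observed and predicted must have equal length >= 2")
  }
  if (!all(is.finite(y)) || !all(is.finite(yhat))) abort("non-finite values")

  res <- y - yhat
  sse <- sum(res^2)
  sst <- if (convention == "conventional") sum((y - mean(y))^2)
         else sum((y - mean(yhat))^2)
  if (sst < .Machine$double.eps) abort("zero-variance denominator in r2")

  # through-origin statistics are undefined for an all-zero vector; report
  # them as NA rather than refusing the residual summaries
  orr <- tryCatch(origin_regression(y, yhat),
                  error = function(e) tibble::tibble(
                    k = NA_real_, ro2 = NA_real_,
                    k_prime = NA_real_, ro2_prime = NA_real_))
  rm2 <- rm2_family(1 - sse / sum((y - mean(y))^2), orr$ro2, orr$ro2_prime)

  out <- tibble::tibble(
    n = length(y),
    r2 = 1 - sse / sst,
    dmax = max(abs(res)),
    mae = mean(abs(res)),
    s = sd(res),
    rmse = sqrt(mean(res^2)),
    k = orr$k, k_prime = orr$k_prime,
    ro2 = orr$ro2, ro2_prime = orr$ro2_prime)
  out <- dplyr::bind_cols(out, rm2)

  if (!is.null(train_observed)) {
    ext <- external_metrics(train_observed, y, yhat)
    out <- dplyr::bind_cols(out, ext)
    out$n_train <- length(train_observed)
  }
  class(out) <- c("pampa_metrics", class(out))
  out
}

#' Through-the-origin regression slopes and correlations
#'
#' `k` is the slope of observed regressed on predicted through the
#' origin, with `ro2` its zero-intercept determination coefficient;
#' `k_prime` and `ro2_prime` exchange the roles of observed and
#' predicted. These feed the rm2 family and the slope criterion of the
#' stringent validation checks.
#'
#' @param y,yhat Observed and predicted numeric vectors.
#' @return A one-row tibble with `k`, `ro2`, `k_prime`, `ro2_prime`.
#' @export
origin_regression <- function(y, yhat) {
  if (sum(yhat^2) < .Machine$double.eps || sum(y^2) < .Machine$double.eps) {
    abort("all-zero vector: through-origin slope undefined")
  }
  k <- sum(y * yhat) / sum(yhat^2)
  ro2 <- 1 - sum((y - k * yhat)^2) / sum((y - mean(y))^2)
  k_prime <- sum(y * yhat) / sum(y^2)
  ro2_prime <- 1 - sum((yhat - k_prime * y)^2) / sum((yhat - mean(yhat))^2)
  tibble::tibble(k = k, ro2 = ro2, k_prime = k_prime, ro2_prime = ro2_prime)
}

#' The rm2 family of modified determination coefficients
#'
#' rm2 = r2 (1 - sqrt(|r2 - ro2|)) and its primed counterpart with
#' r'o2, plus their mean and absolute difference. The radical
#' (square-root) form is the standard definition and the default; the
#' `"as_printed"` convention omits the square root.
#'
#' @param r2,ro2,ro2_prime Determination coefficients (see
#'   [origin_regression()]).
#' @param convention `"radical"` (default) or `"as_printed"`.
#' @return One-row tibble with `rm2`, `rm2_prime`, `rm2_mean`,
#'   `rm2_delta`.
#' @examples
#' rm2_family(0.879, 0.876, 0.876)$rm2   # ~0.83
#' @export
rm2_family <- function(r2, ro2, ro2_prime,
                       convention = c("radical", "as_printed")) {
  convention <- match.arg(convention)
  gap <- function(a) if (convention == "radical") sqrt(abs(r2 - a)) else abs(r2 - a)
  rm2 <- r2 * (1 - gap(ro2))
  rm2_prime <- r2 * (1 - gap(ro2_prime))
  tibble::tibble(rm2 = rm2, rm2_prime = rm2_prime,
                 rm2_mean = (rm2 + rm2_prime) / 2,
                 rm2_delta = abs(rm2 - rm2_prime))
}

#' External-set predictivity statistics
#'
#' qF1² references the external deviations to the training mean, qF2² to
#' the external mean, qF3² compares per-sample mean squared error against
#' the training-set response variance, and CCC is the concordance
#' correlation coefficient penalizing both location and scale shifts.
#'
#' @param train_y Observed responses of the fitting (training) set.
#' @param y,yhat Observed and predicted responses of the external set.
#' @return One-row tibble with `qf1`, `qf2`, `qf3`, `ccc`.
#' @export
external_metrics <- function(train_y, y, yhat) {
  n_ext <- length(y)
  n_tr <- length(train_y)
  sse <- sum((y - yhat)^2)
  ybar_tr <- mean(train_y)
  ybar_ext <- mean(y)
  yhatbar_ext <- mean(yhat)
  qf1 <- 1 - sse / sum((y - ybar_tr)^2)
  qf2 <- 1 - sse / sum((y - ybar_ext)^2)
  qf3 <- 1 - (sse / n_ext) / (sum((train_y - ybar_tr)^2) / n_tr)
  ccc <- 2 * sum((y - ybar_ext) * (yhat - yhatbar_ext)) /
    (sum((y - ybar_ext)^2) + sum((yhat - yhatbar_ext)^2) +
       n_ext * (ybar_ext - yhatbar_ext)^2)
  tibble::tibble(qf1 = qf1, qf2 = qf2, qf3 = qf3, ccc = ccc)
}

#' 10-fold cross-validated q-squared
#'
#' Splits the data into `k` seeded random folds, refits the model on each
#' training complement via `model_factory`, pools the out-of-fold
#' predictions, and scores them with the conventional r2 formula.
#'
#' @param model_factory Function taking a data-frame subset and returning
#'   a fitted model with a `predict(model, newdata)` method.
#' @param data The full (normalized) descriptor table.
#' @param response Response column name. Default `"logPe"`.
#' @param k Number of folds. Default 10.
#' @param seed Fold seed. Default 1.
#' @return The pooled out-of-fold q-squared (qCV2), a single number.
#' @export
kfold_cv <- function(model_factory, data, response = "logPe", k = 10, seed = 1) {
  n <- nrow(data)
  fold_id <- make_folds(n, k = k, seed = seed)
  pred <- numeric(n)
  for (f in unique(fold_id)) {
    te <- fold_id == f
    fit <- model_factory(data[!te, , drop = FALSE])
    pred[te] <- predict(fit, data[te, , drop = FALSE])
  }
  y <- data[[response]]
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Y-scrambling (response permutation) test
#'
#' Refits the model on randomly permuted responses with the descriptors
#' unaltered, recording the training r2 of each scrambled refit; their
#' mean estimates the chance correlation the modeling pipeline can
#' manufacture from noise. A sound model yields a near-zero average.
#'
#' @inheritParams kfold_cv
#' @param reps Number of scrambling repetitions. Default 25.
#' @return A list with `rs2_mean` and the per-repetition `rs2` vector.
#' @export
y_scramble <- function(model_factory, data, response = "logPe",
                       reps = 25, seed = 1) {
  stopifnot(reps >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  y <- data[[response]]
  rs2 <- vapply(seq_len(reps), function(r) {
    scrambled <- data
    scrambled[[response]] <- sample(y)
    fit <- model_factory(scrambled)
    pred <- predict(fit, scrambled)
    ys <- scrambled[[response]]
    max(0, 1 - sum((ys - pred)^2) / sum((ys - mean(ys))^2))
  }, numeric(1))
  list(rs2_mean = mean(rs2), rs2 = rs2)
}

#' Stringent model-validation criteria
#'
#' Applies the seven combined acceptance criteria for a predictive QSAR
#' model to a metrics row:
#' (i) determination coefficients (r2, qCV2, q2, qF1-3 as available) all
#' at least 0.70; (ii) |r2 - qCV2| < 0.10; (iii) (r2 - ro2)/r2 < 0.10 and
#' 0.85 <= k <= 1.15; (iv) |ro2 - r'o2| < 0.30; (v) rm2 >= 0.65;
#' (vi) mean rm2 >= 0.65 and delta rm2 < 0.20; (vii) CCC >= 0.85.
#' A criterion whose inputs are absent from the report is marked
#' not-evaluable (`NA`) rather than failed.
#'
#' @param metrics A one-row metrics tibble (see [qsar_metrics()]);
#'   columns beyond those available are optional: `r2`, `qcv2`, `qf1`,
#'   `qf2`, `qf3`, `k`, `ro2`, `ro2_prime`, `rm2`, `rm2_mean`,
#'   `rm2_delta`, `ccc`.
#' @return A tibble of class `pampa_criteria` with columns `criterion`
#'   (label), `pass` (logical, `NA` when not evaluable), and `detail`.
#' @export
check_criteria <- function(metrics) {
  m <- as.list(metrics)
  g <- function(nm) {
    v <- m[[nm]]
    if (is.null(v) || length(v) == 0L || is.na(v)) NULL else v
  }
  rows <- list()
  add <- function(criterion, pass, detail) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      criterion = criterion, pass = pass, detail = detail)
  }

  # (15) all available determination coefficients >= 0.70
  dets <- purrr::compact(purrr::map(c("r2", "qcv2", "qf1", "qf2", "qf3"), g))
  if (length(dets) == 0L) {
    add("determination >= 0.70", NA, "no coefficients available")
  } else {
    vals <- unlist(dets)
    add("determination >= 0.70", all(vals >= 0.70),
        paste(sprintf("%.2f", vals), collapse = ", "))
  }
  # (16) |r2 - qcv2| < 0.10
  if (is.null(g("r2")) || is.null(g("qcv2"))) {
    add("|r2 - qCV2| < 0.10", NA, "qCV2 not available")
  } else {
    d <- abs(g("r2") - g("qcv2"))
    add("|r2 - qCV2| < 0.10", d < 0.10, sprintf("gap %.3f", d))
  }
  # (17) (r2 - ro2)/r2 < 0.10 and 0.85 <= k <= 1.15
  if (is.null(g("r2")) || is.null(g("ro2")) || is.null(g("k"))) {
    add("origin slope and ro2", NA, "r2/ro2/k not available")
  } else {
    rel <- (g("r2") - g("ro2")) / g("r2")
    ok <- rel < 0.10 && g("k") >= 0.85 && g("k") <= 1.15
    add("origin slope and ro2", ok,
        sprintf("(r2-ro2)/r2 = %.3f, k = %.2f", rel, g("k")))
  }
  # (18) |ro2 - r'o2| < 0.30
  if (is.null(g("ro2")) || is.null(g("ro2_prime"))) {
    add("|ro2 - r'o2| < 0.30", NA, "not available")
  } else {
    d <- abs(g("ro2") - g("ro2_prime"))
    add("|ro2 - r'o2| < 0.30", d < 0.30, sprintf("gap %.3f", d))
  }
  # (19) rm2 >= 0.65
  if (is.null(g("rm2"))) {
    add("rm2 >= 0.65", NA, "not available")
  } else {
    add("rm2 >= 0.65", g("rm2") >= 0.65, sprintf("rm2 = %.2f", g("rm2")))
  }
  # (20) <rm2> >= 0.65 and delta rm2 < 0.20
  if (is.null(g("rm2_mean")) || is.null(g("rm2_delta"))) {
    add("<rm2> and delta rm2", NA, "not available")
  } else {
    ok <- g("rm2_mean") >= 0.65 && g("rm2_delta") < 0.20
    add("<rm2> and delta rm2", ok,
        sprintf("<rm2> = %.2f, delta = %.2f", g("rm2_mean"), g("rm2_delta")))
  }
  # (21) CCC >= 0.85
  if (is.null(g("ccc"))) {
    add("CCC >= 0.85", NA, "not available")
  } else {
    add("CCC >= 0.85", g("ccc") >= 0.85, sprintf("CCC = %.2f", g("ccc")))
  }

  out <- dplyr::bind_rows(rows)
  class(out) <- c("pampa_criteria", class(out))
  out
}

#' Cross-assay calibration regression
#'
#' Ordinary least-squares line relating two permeability measurement
#' systems (e.g. intrinsic permeability measured on one membrane
#' formulation against effective permeability on another), with the
#' Pearson correlation and the two-sided t-test p-value for a nonzero
#' slope (n - 2 degrees of freedom). Used to justify challenging a model
#' with compounds assayed under a different protocol.
#'
#' @param data A data frame.
#' @param x,y Column names of the two measurement scales.
#' @return One-row tibble: `slope`, `intercept`, `r`, `p_slope`, `n`.
#' @export
calibrate_cross_assay <- function(data, x, y) {
  xv <- data[[x]]; yv <- data[[y]]
  if (length(xv) < 3L) abort("need at least 3 paired measurements")
  if (var(xv) < .Machine$double.eps || var(yv) < .Machine$double.eps) {
    abort("zero-variance input")
  }
  fit <- lm(yv ~ xv)
  n <- length(xv)
  b <- unname(coef(fit)[2])
  sigma2 <- sum(residuals(fit)^2) / (n - 2)
  se_b <- sqrt(sigma2 / sum((xv - mean(xv))^2))
  # exact-fit lines (se 0) get p = 0 rather than a 0/0 warning path
  tstat <- if (se_b == 0) Inf else b / se_b
  tibble::tibble(slope = b,
                 intercept = unname(coef(fit)[1]),
                 r = cor(xv, yv),
                 p_slope = 2 * pt(-abs(tstat), df = n - 2),
                 n = n)
}

#' @export
print.pampa_criteria <- function(x, ...) {
  cat("Stringent validation criteria:\n")
  mark <- ifelse(is.na(x$pass), "  - (n/a)",
                 ifelse(x$pass, "  X pass ", "    FAIL "))
  cat(paste0(mark, " ", format(x$criterion, width = 24), " ", x$detail,
             collapse = "\n"), "\n")
  invisible(x)
}
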