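#' Fit a partial least squares regression (NIPALS)
#'
#' Latent-variable linear regression robust to collinearity among
#' descriptors. Components are extracted by the NIPALS algorithm
#' (convergence tolerance 1e-10, at most 500 iterations per component)
#' and the final model is re-expressed as per-descriptor coefficients
#' plus an intercept in the supplied (normalized) descriptor basis, so a
#' fitted model is a plain linear equation. With `n_components = "cv"`
#' the number of components is chosen to maximize the 10-fold
#' cross-validated q-squared.
#'
#' @param data A descriptor table with the response column present.
#' @param response Response column name. Default `"logPe"`.
#' @param cols Descriptor columns to use. Default all.
#' @param n_components Integer number of latent components, or `"cv"`.
#' @param seed Fold seed when `n_components = "cv"`. Default 1.
#' @param tol,max_iter NIPALS convergence controls.
#' @return An object of class `pampa_pls`: `descriptors`, `coefficients`
#'   (named, per descriptor), `intercept`, `n_components`, `fitted`,
#'   `residuals`, and `cv` (tibble of per-dimension qCV2 when selected by
#'   CV).
#' @examples
#' tbl <- simulate_linear_table(n = 50, seed = 1)
#' fit <- fit_pls(tbl, n_components = 2)
#' tidy(fit)
#' @export
fit_pls <- function(data, response = "logPe", cols = descriptor_names(data),
                    n_components = "cv", seed = 1,
                    tol = 1e-10, max_iter = 500) {
  X <- as.matrix(data[cols])
  y <- data[[response]]
  if (nrow(X) != length(y) || nrow(X) < 3L) {
    abort("need at least 3 compounds with a response")
  }
  max_nc <- qr(scale(X, scale = FALSE))$rank
  cv_tbl <- NULL
  if (identical(n_components, "cv")) {
    qcv <- vapply(seq_len(max_nc), function(a) {
      kfold_cv(function(d) fit_pls(d, response = response, cols = cols,
                                   n_components = a, tol = tol,
                                   max_iter = max_iter),
               data, response = response, k = 10, seed = seed)
    }, numeric(1))
    cv_tbl <- tibble::tibble(n_components = seq_len(max_nc), qcv2 = qcv)
    n_components <- which.max(qcv)
  }
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > max_nc) {
    abort(sprintf("n_components must be in 1..%d (rank of centered X)", max_nc))
  }

  core <- .nipals_pls1(X, y, n_components, tol = tol, max_iter = max_iter)
  beta <- drop(core$beta)
  names(beta) <- cols
  intercept <- mean(y) - sum(colMeans(X) * beta)
  fitted <- drop(X %*% beta) + intercept

  structure(list(descriptors = cols,
                 coefficients = beta,
                 intercept = intercept,
                 n_components = n_components,
                 fitted = fitted,
                 residuals = y - fitted,
                 cv = cv_tbl),
            class = "pampa_pls")
}

# PLS1 via NIPALS on centered data; returns coefficients in the X basis.
.nipals_pls1 <- function(X, y, ncomp, tol = 1e-10, max_iter = 500) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  p <- ncol(Xc)
  W <- matrix(0, p, ncomp)   # weights
  P <- matrix(0, p, ncomp)   # X loadings
  q <- numeric(ncomp)        # y loadings
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    if (sqrt(sum(w^2)) < .Machine$double.eps) {
      abort("NIPALS: residual X carries no covariance with y; reduce n_components")
    }
    w <- w / sqrt(sum(w^2))
    t_score <- drop(Xc %*% w)
    # iterate to the dominant covariance direction (single-response NIPALS
    # converges immediately; the loop guards degenerate numerics)
    for (it in seq_len(max_iter)) {
      q_a <- sum(yc * t_score) / sum(t_score^2)
      u <- yc / q_a
      w_new <- drop(crossprod(Xc, u))
      w_new <- w_new / sqrt(sum(w_new^2))
      delta <- sqrt(sum((w_new - w)^2))
      w <- w_new
      t_score <- drop(Xc %*% w)
      if (delta < tol) break
    }
    p_load <- drop(crossprod(Xc, t_score)) / sum(t_score^2)
    q[a] <- sum(yc * t_score) / sum(t_score^2)
    Xc <- Xc - tcrossprod(t_score, p_load)
    yc <- yc - t_score * q[a]
    W[, a] <- w
    P[, a] <- p_load
  }
  beta <- W %*% solve(crossprod(P, W), q)
  list(beta = beta, W = W, P = P, q = q)
}

#' Predict from a PLS model
#'
#' @param object A `pampa_pls` model.
#' @param newdata A data frame (or named numeric vector) covering the
#'   model's descriptors, on the same (normalized) scale the model was
#'   fitted on.
#' @param ... Unused.
#' @return Numeric vector of predicted log Pe values.
#' @examples
#' predict(paper_pls_model(),
#'         tibble::tibble(logP = 1, logD = 0, PSA = 0, FPSA = 0, mu = 0))
#' @export
predict.pampa_pls <- function(object, newdata, ...) {
  if (is.numeric(newdata) && !is.matrix(newdata)) {
    newdata <- as.data.frame(as.list(newdata))
  }
  missing <- setdiff(object$descriptors, names(newdata))
  if (length(missing) > 0L) {
    abort(paste0("missing descriptors: ", paste(missing, collapse = ", ")))
  }
  X <- as.matrix(newdata[object$descriptors])
  drop(X %*% object$coefficients) + object$intercept
}

#' The frozen published PLS permeability model
#'
#' The published five-descriptor linear model for PAMPA log Pe:
#'
#' log Pe = 0.238253 logP + 0.228889 logD - 0.215243 PSA
#'          - 0.24652 FPSA - 0.157312 mu - 6.13473
#'
#' The descriptors are on the centered-and-scaled (normalized) scale of
#' the original training set, whose normalization statistics were not
#' published: absolute predictions for new compounds therefore require
#' user-supplied normalization statistics, and worked examples are posed
#' directly in normalized coordinates. The latent dimension of the
#' published fit is likewise unstated; the frozen object records the
#' coefficients, which fully determine its predictions.
#'
#' @return A `pampa_pls` model with the printed coefficients.
#' @examples
#' m <- paper_pls_model()
#' predict(m, c(logP = 0, logD = 0, PSA = 0, FPSA = 0, mu = 0))  # -6.13473
#' @export
paper_pls_model <- function() {
  beta <- c(logP = 0.238253, logD = 0.228889, PSA = -0.215243,
            FPSA = -0.24652, mu = -0.157312)
  structure(list(descriptors = names(beta),
                 coefficients = beta,
                 intercept = -6.13473,
                 n_components = 1L,
                 fitted = NULL, residuals = NULL, cv = NULL),
            class = "pampa_pls")
}

#' @export
print.pampa_pls <- function(x, ...) {
  cat("PLS permeability model (", x$n_components, " component",
      if (x$n_components > 1) "s", ")\n", sep = "")
  eq <- paste(sprintf("%+.6g*%s", x$coefficients, x$descriptors),
              collapse = " ")
  cat("  logPe =", eq, sprintf("%+.6g", x$intercept), "\n")
  invisible(x)
}

#' @describeIn fit_pls Tidy the coefficients: one row per term.
#' @param x A `pampa_pls` model.
#' @method tidy pampa_pls
#' @export
tidy.pampa_pls <- function(x, ...) {
  tibble::tibble(term = c(x$descriptors, "(Intercept)"),
                 estimate = unname(c(x$coefficients, x$intercept)))
}

#' @describeIn fit_pls One-row model summary.
#' @method glance pampa_pls
#' @export
glance.pampa_pls <- function(x, ...) {
  if (is.null(x$residuals)) {
    return(tibble::tibble(n_components = x$n_components,
                          n = NA_integer_, r.squared = NA_real_,
                          rmse = NA_real_))
  }
  y <- x$fitted + x$residuals
  tibble::tibble(
    n_components = x$n_components,
    n = length(y),
    r.squared = 1 - sum(x$residuals^2) / sum((y - mean(y))^2),
    rmse = sqrt(mean(x$residuals^2)))
}

#' Serialize models to JSON
#'
#' Models round-trip through plain-text JSON so fitted objects can be
#' stored and shared without binary artifacts.
#'
#' @param model A `pampa_pls` or `pampa_hsvr` model.
#' @param path File path to write.
#' @return `path`, invisibly; readers return the model object.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pampa_pls"))
  payload <- list(type = "pampa_pls",
                  descriptors = model$descriptors,
                  coefficients = as.list(model$coefficients),
                  intercept = model$intercept,
                  n_components = model$n_components)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(p$type, "pampa_pls"))
  beta <- unlist(p$coefficients)[p$descriptors]
  structure(list(descriptors = p$descriptors,
                 coefficients = beta,
                 intercept = p$intercept,
                 n_components = as.integer(p$n_components),
                 fitted = NULL, residuals = NULL, cv = NULL),
            class = "pampa_pls")
}
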