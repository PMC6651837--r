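#' Radial basis function kernel
#'
#' `exp(-gamma * ||u - v||^2)`, the kernel used by every SVR in the
#' permeability ensemble.
#'
#' @param u,v Numeric vectors of equal length.
#' @param gamma Positive kernel width.
#' @return Kernel value in (0, 1].
#' @examples
#' rbf_kernel(0, 1, 1)   # exp(-1)
#' @export
rbf_kernel <- function(u, v, gamma) {
  if (length(u) != length(v)) abort("dimension mismatch in rbf_kernel")
  stopifnot(gamma > 0)
  exp(-gamma * sum((u - v)^2))
}

# kernel matrix between row sets (rows of A vs rows of B)
.rbf_cross <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Specify an SVR configuration
#'
#' Bundles the regression mode (epsilon-SVR or nu-SVR), cost C, RBF
#' kernel width gamma, the tube width epsilon or support-vector fraction
#' nu, and the descriptor subset the model sees.
#'
#' @param mode `"epsilon"` or `"nu"`.
#' @param cost Positive cost C.
#' @param gamma Positive kernel width.
#' @param epsilon Non-negative tube width (epsilon mode only).
#' @param nu Fraction in (0, 1] (nu mode only).
#' @param descriptors Character vector of descriptor names.
#' @return A list of class `pampa_svr_spec`.
#' @export
svr_spec <- function(mode = c("epsilon", "nu"), cost = 1, gamma = 0.1,
                     epsilon = 0.1, nu = 0.5, descriptors = character(0)) {
  mode <- match.arg(mode)
  stopifnot(cost > 0, gamma > 0)
  if (mode == "epsilon") {
    stopifnot(epsilon >= 0)
    nu <- NA_real_
  } else {
    stopifnot(nu > 0, nu <= 1)
    epsilon <- NA_real_
  }
  structure(list(mode = mode, cost = cost, gamma = gamma,
                 epsilon = epsilon, nu = nu, descriptors = descriptors),
            class = "pampa_svr_spec")
}

#' Train a single support vector regression
#'
#' Solves the epsilon-insensitive (or nu-parameterized) SVR with an RBF
#' kernel on the spec's descriptor subset. The returned object stores the
#' support vectors, dual coefficients, and offset, so predictions are
#' evaluated by the package's own kernel expansion and the model
#' serializes to plain JSON.
#'
#' @param data Normalized descriptor table containing the response.
#' @param spec A [svr_spec()] (its `descriptors` must be non-empty).
#' @param response Response column name. Default `"logPe"`.
#' @return An object of class `pampa_svr`.
#' @export
train_svr <- function(data, spec, response = "logPe") {
  stopifnot(inherits(spec, "pampa_svr_spec"))
  if (length(spec$descriptors) == 0L) abort("spec has an empty descriptor subset")
  X <- as.matrix(data[spec$descriptors])
  y <- data[[response]]
  fit <- tryCatch({
    if (spec$mode == "epsilon") {
      e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                 cost = spec$cost, gamma = spec$gamma,
                 epsilon = spec$epsilon, scale = FALSE)
    } else {
      e1071::svm(X, y, type = "nu-regression", kernel = "radial",
                 cost = spec$cost, gamma = spec$gamma,
                 nu = spec$nu, scale = FALSE)
    }
  }, error = function(e) {
    # libSVM reports an empty model when every point fits inside the tube
    # of the flat function; the degenerate solution is the constant fit
    if (grepl("empty", conditionMessage(e), ignore.case = TRUE)) {
      return(NULL)
    }
    abort(sprintf("SVR solver failed (mode=%s, C=%g, gamma=%g): %s",
                  spec$mode, spec$cost, spec$gamma, conditionMessage(e)))
  })
  if (is.null(fit)) {
    return(structure(list(spec = spec,
                          support_vectors = X[1, , drop = FALSE],
                          dual_coefs = 0,
                          rho = -mean(y)),
                     class = "pampa_svr"))
  }
  structure(list(spec = spec,
                 support_vectors = unname(as.matrix(fit$SV)),
                 dual_coefs = as.numeric(fit$coefs),
                 rho = as.numeric(fit$rho)),
            class = "pampa_svr")
}

#' @rdname train_svr
#' @param object A fitted `pampa_svr`.
#' @param newdata Data frame covering the spec's descriptors.
#' @param ... Unused.
#' @export
predict.pampa_svr <- function(object, newdata, ...) {
  missing <- setdiff(object$spec$descriptors, names(newdata))
  if (length(missing) > 0L) {
    abort(paste0("missing descriptors: ", paste(missing, collapse = ", ")))
  }
  X <- as.matrix(newdata[object$spec$descriptors])
  K <- .rbf_cross(X, object$support_vectors, object$spec$gamma)
  drop(K %*% object$dual_coefs) - object$rho
}

#' Default SVR hyper-parameter lattice
#'
#' Both regression modes are scanned: cost C over powers of two from 2^-2
#' to 2^10 (step 2^2), kernel width gamma from 2^-8 to 2^2 (step 2^2),
#' epsilon in {0.01, 0.05, 0.1, 0.2} for epsilon-SVR and nu in
#' {0.25, 0.5, 0.75} for nu-SVR. Rows are in canonical order (mode, C,
#' gamma, epsilon/nu ascending), which also defines the deterministic
#' tie-break of [grid_search()].
#'
#' @param cost,gamma,epsilon,nu Lattice values.
#' @param modes Modes to scan. Default both.
#' @return A tibble with columns `mode`, `cost`, `gamma`, `epsilon`, `nu`.
#' @export
svr_grid <- function(cost = 2^seq(-2, 10, by = 2),
                     gamma = 2^seq(-8, 2, by = 2),
                     epsilon = c(0.01, 0.05, 0.1, 0.2),
                     nu = c(0.25, 0.5, 0.75),
                     modes = c("epsilon", "nu")) {
  parts <- list()
  if ("epsilon" %in% modes) {
    parts$eps <- tidyr::expand_grid(mode = "epsilon",
                                    cost = sort(cost), gamma = sort(gamma),
                                    epsilon = sort(epsilon)) |>
      dplyr::mutate(nu = NA_real_)
  }
  if ("nu" %in% modes) {
    parts$nu <- tidyr::expand_grid(mode = "nu",
                                   cost = sort(cost), gamma = sort(gamma),
                                   nu = sort(nu)) |>
      dplyr::mutate(epsilon = NA_real_)
  }
  out <- dplyr::bind_rows(parts)
  dplyr::select(out, "mode", "cost", "gamma", "epsilon", "nu")
}

#' Grid search SVR runtime parameters by cross-validation
#'
#' Every lattice point is scored by k-fold cross-validated q-squared with
#' seeded folds (all parameters alternated in parallel, i.e. a full
#' factorial scan); the argmax is returned, ties resolved by the first
#' row in canonical lattice order.
#'
#' @param data Normalized descriptor table with the response.
#' @param descriptors Descriptor subset for every candidate.
#' @param grid A lattice tibble from [svr_grid()].
#' @param response Response column name. Default `"logPe"`.
#' @param folds Number of CV folds. Default 10.
#' @param seed Fold seed. Default 1.
#' @return A list: `spec` (the winning [svr_spec()]), `score` (its
#'   qCV2), and `scores` (the grid with a `qcv2` column).
#' @export
grid_search <- function(data, descriptors, grid = svr_grid(),
                        response = "logPe", folds = 10, seed = 1) {
  if (nrow(grid) == 0L) abort("empty grid")
  row_spec <- function(i) {
    r <- grid[i, ]
    if (r$mode == "epsilon") {
      svr_spec("epsilon", cost = r$cost, gamma = r$gamma,
               epsilon = r$epsilon, descriptors = descriptors)
    } else {
      svr_spec("nu", cost = r$cost, gamma = r$gamma, nu = r$nu,
               descriptors = descriptors)
    }
  }
  qcv2 <- vapply(seq_len(nrow(grid)), function(i) {
    spec <- row_spec(i)
    kfold_cv(function(d) train_svr(d, spec, response = response),
             data, response = response,
             k = min(folds, nrow(data)), seed = seed)
  }, numeric(1))
  best <- which.max(qcv2)  # first index on ties = canonical order
  out_grid <- grid
  out_grid$qcv2 <- qcv2
  list(spec = row_spec(best), score = qcv2[best], scores = out_grid)
}

#' Build a hierarchical SVR ensemble
#'
#' One SVR is grid-searched per candidate descriptor subset; member
#' combinations are then tried in Occam's-razor order -- two-member
#' ensembles first, then three, then four, within each size by smaller
#' total descriptor count, then canonical subset order. For each
#' candidate ensemble a meta-SVR is grid-searched on the members'
#' training predictions, and the first ensemble whose training r2 and
#' 10-fold qCV2 satisfy `acceptance_rule` is returned. If none is
#' accepted the best-scoring ensemble is returned flagged unaccepted.
#' Every attempt is recorded in the selection log.
#'
#' @param data Normalized training descriptor table with the response.
#' @param candidate_subsets List of descriptor-name vectors (>= 2).
#' @param grid Lattice for the member searches. Default [svr_grid()].
#' @param meta_grid Lattice for the meta-SVR. Defaults to `grid`.
#' @param response Response column name. Default `"logPe"`.
#' @param acceptance_rule Function `(r2, qcv2) -> logical`; default
#'   requires r2 >= 0.70 and |r2 - qcv2| < 0.10 (the stringent-criteria
#'   thresholds applied at the training stage).
#' @param max_members Largest ensemble size tried. Default 4.
#' @param folds,seed Cross-validation controls.
#' @return An object of class `pampa_hsvr`: `members` (list of
#'   `pampa_svr`), `meta` (`pampa_svr` over member-prediction space),
#'   `accepted` (logical), `r2`, `qcv2`, and `selection_log` (tibble).
#' @export
build_hsvr <- function(data, candidate_subsets, grid = svr_grid(),
                       meta_grid = grid, response = "logPe",
                       acceptance_rule = NULL, max_members = 4,
                       folds = 10, seed = 1) {
  if (length(candidate_subsets) < 2L) abort("need at least 2 candidate subsets")
  if (is.null(acceptance_rule)) {
    acceptance_rule <- function(r2, qcv2) r2 >= 0.70 && abs(r2 - qcv2) < 0.10
  }
  y <- data[[response]]

  # one tuned SVR per subset
  tuned <- lapply(candidate_subsets, function(subset) {
    gs <- grid_search(data, subset, grid = grid, response = response,
                      folds = folds, seed = seed)
    list(spec = gs$spec, qcv2 = gs$score,
         model = train_svr(data, gs$spec, response = response))
  })

  sizes <- 2:min(max_members, length(candidate_subsets))
  combos <- list()
  for (m in sizes) {
    cmb <- utils::combn(length(candidate_subsets), m, simplify = FALSE)
    total_desc <- vapply(cmb, function(ix)
      sum(lengths(candidate_subsets[ix])), numeric(1))
    combos <- c(combos, cmb[order(total_desc)])  # stable: canonical on ties
  }

  log_rows <- list()
  best <- NULL
  fit_ensemble <- function(ix) {
    members <- lapply(tuned[ix], `[[`, "model")
    member_specs <- lapply(tuned[ix], `[[`, "spec")
    meta_feats <- vapply(members, function(mm) predict(mm, data),
                         numeric(nrow(data)))
    meta_tbl <- tibble::as_tibble(as.data.frame(meta_feats))
    names(meta_tbl) <- paste0("member_", seq_along(ix))
    meta_tbl[[response]] <- y
    gs <- grid_search(meta_tbl, names(meta_tbl)[seq_along(ix)],
                      grid = meta_grid, response = response,
                      folds = folds, seed = seed)
    meta <- train_svr(meta_tbl, gs$spec, response = response)
    model <- structure(list(members = members, meta = meta,
                            member_specs = member_specs,
                            subset_index = ix,
                            response = response),
                       class = "pampa_hsvr")
    pred <- predict(model, data)
    r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
    qcv2 <- kfold_cv(function(d) {
      mem <- lapply(member_specs, function(sp) train_svr(d, sp, response = response))
      mf <- vapply(mem, function(mm) predict(mm, d), numeric(nrow(d)))
      mt <- tibble::as_tibble(as.data.frame(mf))
      names(mt) <- paste0("member_", seq_along(ix))
      mt[[response]] <- d[[response]]
      mspec <- meta$spec
      mdl <- structure(list(members = mem,
                            meta = train_svr(mt, mspec, response = response),
                            member_specs = member_specs, subset_index = ix,
                            response = response),
                       class = "pampa_hsvr")
      mdl
    }, data, response = response, k = min(folds, nrow(data)), seed = seed)
    list(model = model, r2 = r2, qcv2 = qcv2)
  }

  for (ci in seq_along(combos)) {
    ix <- combos[[ci]]
    cand <- fit_ensemble(ix)
    ok <- isTRUE(acceptance_rule(cand$r2, cand$qcv2))
    log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
      attempt = ci,
      members = paste(ix, collapse = "+"),
      n_members = length(ix),
      n_descriptors = sum(lengths(candidate_subsets[ix])),
      r2 = cand$r2, qcv2 = cand$qcv2, accepted = ok)
    if (is.null(best) || cand$r2 > best$r2) best <- c(cand, list(accepted = ok))
    if (ok) {
      best <- c(cand, list(accepted = TRUE))
      break
    }
  }
  sel_log <- dplyr::bind_rows(log_rows)
  model <- best$model
  model$accepted <- best$accepted
  model$r2 <- best$r2
  model$qcv2 <- best$qcv2
  model$selection_log <- sel_log
  if (!model$accepted) {
    warn("no ensemble satisfied the acceptance rule; returning best-scoring ensemble flagged unaccepted")
  }
  model
}

#' Predict from a hierarchical SVR ensemble
#'
#' Each member SVR predicts from its own descriptor subset; the meta-SVR
#' then predicts from the vector of member predictions.
#'
#' @param object A `pampa_hsvr` model.
#' @param newdata Data frame covering the union of member descriptor
#'   subsets (normalized with the training statistics).
#' @param ... Unused.
#' @return Numeric vector of predicted log Pe values.
#' @export
predict.pampa_hsvr <- function(object, newdata, ...) {
  feats <- vapply(object$members, function(mm) predict(mm, newdata),
                  numeric(nrow(newdata)))
  if (is.null(dim(feats))) feats <- matrix(feats, nrow = nrow(newdata))
  mt <- tibble::as_tibble(as.data.frame(feats))
  names(mt) <- paste0("member_", seq_along(object$members))
  predict(object$meta, mt)
}

#' @export
print.pampa_hsvr <- function(x, ...) {
  cat(sprintf("Hierarchical SVR: %d members -> meta-SVR (%s)\n",
              length(x$members),
              if (isTRUE(x$accepted)) "accepted" else "unaccepted"))
  for (i in seq_along(x$members)) {
    sp <- x$members[[i]]$spec
    cat(sprintf("  member %d: %s-SVR C=%g gamma=%g on {%s}\n", i, sp$mode,
                sp$cost, sp$gamma, paste(sp$descriptors, collapse = ", ")))
  }
  if (!is.null(x$r2)) {
    cat(sprintf("  training r2 = %.3f, qCV2 = %.3f\n", x$r2, x$qcv2))
  }
  invisible(x)
}

#' @describeIn build_hsvr Member-level summary: one row per member plus
#'   the meta model, with mode, cost, gamma, and descriptor subset.
#' @param x A `pampa_hsvr` model.
#' @param ... Unused.
#' @method tidy pampa_hsvr
#' @export
tidy.pampa_hsvr <- function(x, ...) {
  rows <- lapply(seq_along(x$members), function(i) {
    sp <- x$members[[i]]$spec
    tibble::tibble(level = "member", label = paste0("member_", i),
                   mode = sp$mode, cost = sp$cost, gamma = sp$gamma,
                   epsilon = sp$epsilon, nu = sp$nu,
                   descriptors = paste(sp$descriptors, collapse = ";"))
  })
  sp <- x$meta$spec
  rows[[length(rows) + 1L]] <- tibble::tibble(
    level = "meta", label = "meta", mode = sp$mode, cost = sp$cost,
    gamma = sp$gamma, epsilon = sp$epsilon, nu = sp$nu,
    descriptors = paste(sp$descriptors, collapse = ";"))
  dplyr::bind_rows(rows)
}

#' @describeIn build_hsvr One-row fit summary (r2, qCV2, acceptance).
#' @method glance pampa_hsvr
#' @export
glance.pampa_hsvr <- function(x, ...) {
  tibble::tibble(n_members = length(x$members),
                 r2 = x$r2 %||% NA_real_,
                 qcv2 = x$qcv2 %||% NA_real_,
                 accepted = isTRUE(x$accepted))
}

# --- JSON serialization -----------------------------------------------------

.svr_payload <- function(m) {
  list(mode = m$spec$mode, cost = m$spec$cost, gamma = m$spec$gamma,
       epsilon = m$spec$epsilon, nu = m$spec$nu,
       descriptors = as.list(m$spec$descriptors),
       support_vectors = m$support_vectors,
       dual_coefs = m$dual_coefs, rho = m$rho)
}

.svr_from_payload <- function(p) {
  spec <- if (identical(p$mode, "epsilon")) {
    svr_spec("epsilon", cost = p$cost, gamma = p$gamma, epsilon = p$epsilon,
             descriptors = unlist(p$descriptors))
  } else {
    svr_spec("nu", cost = p$cost, gamma = p$gamma, nu = p$nu,
             descriptors = unlist(p$descriptors))
  }
  sv <- p$support_vectors
  if (!is.matrix(sv)) sv <- matrix(unlist(sv), ncol = length(p$descriptors))
  structure(list(spec = spec, support_vectors = sv,
                 dual_coefs = as.numeric(unlist(p$dual_coefs)),
                 rho = as.numeric(p$rho)),
            class = "pampa_svr")
}

#' @rdname write_pls_model
#' @export
write_hsvr_model <- function(model, path) {
  stopifnot(inherits(model, "pampa_hsvr"))
  members <- lapply(model$members, .svr_payload)
  names(members) <- paste0("member_", seq_along(members))
  payload <- list(type = "pampa_hsvr",
                  response = model$response,
                  members = members,
                  meta = .svr_payload(model$meta))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_hsvr_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(p$type, "pampa_hsvr"))
  members <- unname(lapply(p$members, .svr_from_payload))
  structure(list(members = members,
                 meta = .svr_from_payload(p$meta),
                 member_specs = lapply(members, `[[`, "spec"),
                 response = p$response,
                 accepted = NA, r2 = NULL, qcv2 = NULL,
                 selection_log = NULL),
            class = "pampa_hsvr")
}
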