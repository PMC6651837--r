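# 10-fold CV r2 of an ordinary linear fit on a descriptor subset; the
# shared fitness currency of the GFA and RFE searches.
.cv_r2_linear <- function(data, response, subset, folds = 10, seed = 1) {
  X <- as.matrix(data[subset])
  y <- data[[response]]
  fit_fun <- function(Xtr, ytr) {
    fit <- lm.fit(cbind(1, Xtr), ytr)
    coef(fit)
  }
  pred_fun <- function(beta, Xte) drop(cbind(1, Xte) %*% beta)
  fold_id <- make_folds(length(y), k = min(folds, length(y)), seed = seed)
  pred <- numeric(length(y))
  for (f in unique(fold_id)) {
    te <- fold_id == f
    beta <- fit_fun(X[!te, , drop = FALSE], y[!te])
    beta[is.na(beta)] <- 0
    pred[te] <- pred_fun(beta, X[te, , drop = FALSE])
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Descriptor-subset search by genetic function approximation
#'
#' A genetic algorithm over descriptor subsets: individuals are subsets,
#' fitness is the 10-fold cross-validated r-squared of a linear fit
#' penalized by subset size (a lack-of-fit style Occam's-razor bias),
#' selection is by tournament, crossover is one-point on the membership
#' bitmask, and each gene mutates independently. Deterministic given
#' `seed`.
#'
#' @param data A screened, normalized descriptor table.
#' @param response Name of the response column. Default `"logPe"`.
#' @param cols Descriptor pool. Default all descriptor columns.
#' @param population_size,generations GA size controls. Defaults 100, 200.
#' @param subset_size_range Allowed subset sizes, length-2 integer.
#'   Default `c(1, 5)`.
#' @param mutation_rate Per-gene flip probability. Default 0.01.
#' @param size_penalty Fitness penalty per descriptor. Default 0.005.
#' @param n_keep Number of top subsets to return. Default 10.
#' @param seed Integer seed controlling the whole search.
#' @return A tibble of class `pampa_selection`, columns `subset`
#'   (list-column of descriptor-name vectors), `size`, `fitness`,
#'   sorted by decreasing fitness.
#' @export
gfa_select <- function(data, response = "logPe", cols = descriptor_names(data),
                       population_size = 100, generations = 200,
                       subset_size_range = c(1, 5),
                       mutation_rate = 0.01, size_penalty = 0.005,
                       n_keep = 10, seed = 1) {
  if (length(cols) == 0L) abort("empty descriptor pool")
  if (population_size < 2) abort("population must have at least 2 individuals")
  p <- length(cols)
  lo <- max(1L, subset_size_range[1])
  hi <- min(p, subset_size_range[2])

  if (p == 1L) {
    fit <- .cv_r2_linear(data, response, cols, seed = seed) - size_penalty
    out <- tibble::tibble(subset = list(cols), size = 1L, fitness = fit)
    class(out) <- c("pampa_selection", class(out))
    return(out)
  }

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }

  withr_seed({
    clamp <- function(mask) {
      sz <- sum(mask)
      if (sz < lo) mask[sample(which(!mask), lo - sz)] <- TRUE
      if (sz > hi) mask[sample(which(mask), sz - hi)] <- FALSE
      mask
    }
    random_mask <- function() {
      m <- rep(FALSE, p)
      m[sample(p, sample(lo:hi, 1))] <- TRUE
      m
    }
    fitness_cache <- new.env(parent = emptyenv())
    eval_mask <- function(mask) {
      key <- paste(which(mask), collapse = ",")
      if (!is.null(fitness_cache[[key]])) return(fitness_cache[[key]])
      f <- .cv_r2_linear(data, response, cols[mask], seed = seed) -
        size_penalty * sum(mask)
      fitness_cache[[key]] <- f
      f
    }

    pop <- replicate(population_size, random_mask(), simplify = FALSE)
    fit <- vapply(pop, eval_mask, numeric(1))

    for (g in seq_len(generations)) {
      newpop <- list(pop[[which.max(fit)]])  # elitism
      while (length(newpop) < population_size) {
        tourney <- function() {
          cand <- sample(population_size, 2)
          pop[[cand[which.max(fit[cand])]]]
        }
        a <- tourney(); b <- tourney()
        cut <- sample(p - 1L, 1)
        child <- c(a[seq_len(cut)], b[(cut + 1L):p])
        flip <- runif(p) < mutation_rate
        child[flip] <- !child[flip]
        if (!any(child)) child[sample(p, 1)] <- TRUE
        newpop[[length(newpop) + 1L]] <- clamp(child)
      }
      pop <- newpop
      fit <- vapply(pop, eval_mask, numeric(1))
    }

    keys <- vapply(pop, function(m) paste(which(m), collapse = ","), character(1))
    uniq <- !duplicated(keys)
    pop <- pop[uniq]; fit <- fit[uniq]
    ord <- order(fit, decreasing = TRUE)
    take <- head(ord, n_keep)
    out <- tibble::tibble(
      subset = lapply(pop[take], function(m) cols[m]),
      size = vapply(pop[take], sum, integer(1)),
      fitness = fit[take])
    class(out) <- c("pampa_selection", class(out))
    out
  })
}

#' Recursive feature elimination ranking
#'
#' Starting from the full descriptor pool, each descriptor is left out in
#' turn and the model is refit; the descriptor whose omission degrades
#' cross-validated performance least (i.e. contributes least) is
#' eliminated, and the procedure recurses on the survivors. The result is
#' a full elimination order from least to most contributory.
#'
#' @param data Normalized descriptor table.
#' @param response Response column name. Default `"logPe"`.
#' @param cols Descriptor pool (at least 2).
#' @param score_fun Scoring function `function(data, response, subset)`
#'   returning a goodness score (larger is better); defaults to 10-fold
#'   cross-validated linear-model r-squared with seeded folds.
#' @param seed Fold seed for the default scorer.
#' @return A tibble of class `pampa_selection` with columns `descriptor`
#'   (elimination order, least contributory first), `step`, and
#'   `score_without` (the score of the model fitted without it at the
#'   step it was eliminated).
#' @export
rfe_rank <- function(data, response = "logPe", cols = descriptor_names(data),
                     score_fun = NULL, seed = 1) {
  if (length(cols) < 2L) abort("need at least 2 descriptors for RFE")
  if (is.null(score_fun)) {
    score_fun <- function(data, response, subset) {
      .cv_r2_linear(data, response, subset, seed = seed)
    }
  }
  remaining <- cols
  order_out <- character(0)
  score_out <- numeric(0)
  while (length(remaining) > 1L) {
    scores <- vapply(remaining, function(nm) {
      tryCatch(score_fun(data, response, setdiff(remaining, nm)),
               error = function(e) abort(paste0(
                 "model fit failed while scoring elimination of `", nm, "`: ",
                 conditionMessage(e))))
    }, numeric(1))
    # the descriptor whose removal leaves the best model contributes least
    victim <- remaining[which.max(scores)]
    order_out <- c(order_out, victim)
    score_out <- c(score_out, max(scores))
    remaining <- setdiff(remaining, victim)
  }
  out <- tibble::tibble(
    descriptor = c(order_out, remaining),
    step = seq_along(cols),
    score_without = c(score_out, NA_real_))
  class(out) <- c("pampa_selection", class(out))
  out
}

#' Published descriptor-subset presets
#'
#' The two descriptor combinations used by the member models of the
#' published permeability ensemble: `"svr_a"` = logD, FPSA, mu and
#' `"svr_b"` = logP, logD, PSA; `"pls"` is their union, the five
#' descriptors of the interpretable linear model.
#'
#' @param which One of `"svr_a"`, `"svr_b"`, `"pls"`.
#' @return Character vector of descriptor names.
#' @export
descriptor_preset <- function(which = c("svr_a", "svr_b", "pls")) {
  which <- match.arg(which)
  switch(which,
         svr_a = c("logD", "FPSA", "mu"),
         svr_b = c("logP", "logD", "PSA"),
         pls = c("logP", "logD", "PSA", "FPSA", "mu"))
}
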