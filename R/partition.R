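#' Training/test split sizes at a target ratio
#'
#' @param n_total Total number of compounds.
#' @param train_fraction Fraction assigned to training; half rounds up.
#'   Default 0.8, the conventional 4:1 split.
#' @return A named list with `n_train` and `n_test`.
#' @examples
#' split_size(182)        # 146 training, 36 test
#' @export
split_size <- function(n_total, train_fraction = 0.8) {
  stopifnot(n_total >= 2, train_fraction > 0, train_fraction < 1)
  n_train <- floor(n_total * train_fraction + 0.5)  # half rounds up
  n_test <- n_total - n_train
  if (n_train == 0L || n_test == 0L) {
    abort("degenerate split: one set would be empty")
  }
  list(n_train = as.integer(n_train), n_test = as.integer(n_test))
}

#' Kennard-Stone train/test partition
#'
#' Deterministic max-min selection in descriptor space: the two compounds
#' at maximal Euclidean distance seed the training set; each subsequent
#' pick is the candidate whose minimum distance to the already-selected
#' training compounds is largest. Remaining compounds form the test set.
#' Ties are broken by the lowest input index, so the partition is fully
#' reproducible and invariant (up to that tie rule) under row permutation.
#'
#' @param data A descriptor table, normally normalized first.
#' @param n_train Number of training compounds, or `NULL` to use
#'   `split_size(nrow(data), train_fraction)`.
#' @param train_fraction Used when `n_train` is `NULL`. Default 0.8.
#' @param cols Descriptor columns defining the space. Default all.
#' @param space Distance space: `"descriptor"` (default) for the raw
#'   normalized columns, or `"pc"` for principal-component scores.
#' @param k Number of components when `space = "pc"`. Default 3.
#' @return A tibble with columns `id` and `set` (`"train"` or `"test"`),
#'   in the input row order; the training pick order is attached as
#'   attribute `"ks_order"`.
#' @examples
#' tbl <- tibble::tibble(id = c("a", "b", "c"), x = c(0, 1, 10))
#' kennard_stone(tbl, n_train = 2)   # a and c train
#' @export
kennard_stone <- function(data, n_train = NULL, train_fraction = 0.8,
                          cols = descriptor_names(data),
                          space = c("descriptor", "pc"), k = 3) {
  space <- match.arg(space)
  n <- nrow(data)
  if (n < 2L) abort("need at least 2 compounds")
  if (is.null(n_train)) n_train <- split_size(n, train_fraction)$n_train
  stopifnot(n_train >= 2, n_train <= n)

  X <- as.matrix(data[cols])
  if (space == "pc") {
    cs <- pca_project(data, k = k, cols = cols)
    X <- as.matrix(cs$scores[, -1])
  }
  D <- as.matrix(dist(X))

  # seed: maximal-distance pair, lowest indices on ties
  flat <- which(D == max(D), arr.ind = TRUE)
  flat <- flat[flat[, 1] < flat[, 2], , drop = FALSE]
  flat <- flat[order(flat[, 1], flat[, 2]), , drop = FALSE]
  selected <- as.integer(flat[1, ])

  candidates <- setdiff(seq_len(n), selected)
  min_d <- pmin(D[, selected[1]], D[, selected[2]])
  while (length(selected) < n_train) {
    pick <- candidates[which.max(min_d[candidates])]  # which.max -> lowest index tie rule
    selected <- c(selected, pick)
    candidates <- setdiff(candidates, pick)
    min_d <- pmin(min_d, D[, pick])
  }

  set <- rep("test", n)
  set[selected] <- "train"
  out <- tibble::tibble(id = data$id, set = set)
  attr(out, "ks_order") <- data$id[selected]
  out
}

#' Flag applicability-domain outliers by atom counts
#'
#' Compounds much larger than the modeled chemical space -- more than 26
#' carbon and more than 34 hydrogen atoms (both conditions required) --
#' are flagged as outside the applicability domain. Flagging is an
#' annotation: outliers are held out of training and evaluated as their
#' own set, not discarded.
#'
#' @param data A descriptor table with `n_carbon` and `n_hydrogen` columns.
#' @param max_carbon,max_hydrogen Thresholds; strictly-greater counts in
#'   both elements flag the compound. Defaults 26 and 34.
#' @return Character vector of outlier compound ids. Compounds with a
#'   missing count are skipped with a warning.
#' @export
flag_outliers <- function(data, max_carbon = 26, max_hydrogen = 34) {
  if (!all(c("n_carbon", "n_hydrogen") %in% names(data))) {
    abort("`n_carbon` and `n_hydrogen` columns are required")
  }
  miss <- is.na(data$n_carbon) | is.na(data$n_hydrogen)
  if (any(miss)) {
    warn(paste0("skipping compounds with missing atom counts: ",
                paste(data$id[miss], collapse = ", ")))
  }
  keep <- !miss & data$n_carbon > max_carbon & data$n_hydrogen > max_hydrogen
  data$id[keep]
}

#' Partition with outlier annotation
#'
#' Runs [flag_outliers()] (when atom counts are present), removes the
#' flagged compounds from the Kennard-Stone pool, and returns a
#' three-way partition.
#'
#' @inheritParams kennard_stone
#' @param outlier_ids Optional explicit outlier ids; computed from atom
#'   counts when `NULL` and counts are present.
#' @return Tibble with `id` and `set` in `c("train", "test", "outlier")`.
#' @export
partition_compounds <- function(data, n_train = NULL, train_fraction = 0.8,
                                cols = descriptor_names(data),
                                space = c("descriptor", "pc"), k = 3,
                                outlier_ids = NULL) {
  space <- match.arg(space)
  if (is.null(outlier_ids)) {
    outlier_ids <- if (all(c("n_carbon", "n_hydrogen") %in% names(data))) {
      flag_outliers(data)
    } else character(0)
  }
  pool <- data[!data$id %in% outlier_ids, ]
  ks <- kennard_stone(pool, n_train = n_train, train_fraction = train_fraction,
                      cols = cols, space = space, k = k)
  out <- tibble::tibble(id = data$id,
                        set = ifelse(data$id %in% outlier_ids, "outlier",
                                     ks$set[match(data$id, ks$id)]))
  attr(out, "ks_order") <- attr(ks, "ks_order")
  out
}

#' Chemical-space PCA projection
#'
#' Centered principal-component analysis of the descriptor block, used to
#' visualize the chemical space occupied by training, test, and outlier
#' compounds and to report how much variance the leading components carry.
#'
#' @param data A descriptor table.
#' @param k Number of components to keep. Default 3.
#' @param cols Descriptor columns. Default all.
#' @return A list of class `pampa_chemical_space`: `scores` (tibble with
#'   `id` and `PC1..PCk`), `loadings` (descriptor-by-component matrix),
#'   `variance_explained` (fractions, length k), and
#'   `cumulative_variance` (scalar, sum over the k kept components).
#' @export
pca_project <- function(data, k = 3, cols = descriptor_names(data)) {
  X <- as.matrix(data[cols])
  if (nrow(X) < 2L) abort("need at least 2 compounds for PCA")
  if (all(apply(X, 2, var) < .Machine$double.eps)) {
    abort("degenerate descriptor matrix: no variance")
  }
  k <- as.integer(k)
  stopifnot(k >= 1, k <= min(nrow(X) - 1L, ncol(X)))
  fit <- prcomp(X, center = TRUE, scale. = FALSE)
  varfrac <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- tibble::as_tibble(fit$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(id = data$id), scores)
  structure(list(scores = scores,
                 loadings = fit$rotation[, seq_len(k), drop = FALSE],
                 variance_explained = varfrac[seq_len(k)],
                 cumulative_variance = sum(varfrac[seq_len(k)])),
            class = "pampa_chemical_space")
}

#' @export
print.pampa_chemical_space <- function(x, ...) {
  cat(sprintf("Chemical space: %d compounds, %d components (%.1f%% of variance)\n",
              nrow(x$scores), length(x$variance_explained),
              100 * x$cumulative_variance))
  invisible(x)
}
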