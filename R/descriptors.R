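#' Descriptor tables
#'
#' A descriptor table is an ordinary tibble with one row per compound:
#' a character `id` column (unique), an optional `logPe` response column
#' (log10 effective permeability, cm/s), optional `smiles`, `pka`
#' (semicolon-separated pKa list or a list-column of numeric vectors),
#' optional `n_carbon` / `n_hydrogen` atom counts, and any number of
#' numeric molecular-descriptor columns (logP, logD, PSA, FPSA, mu, ...).
#' All verbs in the package take such a tibble first and return a tibble,
#' so they chain with the pipe.
#'
#' @param data A data frame to validate.
#' @return `as_descriptor_table()` returns the validated tibble.
#' @examples
#' tbl <- tibble::tibble(id = c("a", "b"), logPe = c(-5, -6),
#'                       logP = c(1, 2), PSA = c(40, 90))
#' as_descriptor_table(tbl)
#' descriptor_names(tbl)
#' @export
as_descriptor_table <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"id" %in% names(data)) {
    abort("a descriptor table needs an `id` column")
  }
  data$id <- as.character(data$id)
  if (anyDuplicated(data$id)) {
    dup <- unique(data$id[duplicated(data$id)])
    abort(paste0("duplicate compound ids: ", paste(dup, collapse = ", ")))
  }
  if (length(descriptor_names(data)) == 0L) {
    abort("no numeric descriptor columns found")
  }
  data
}

# columns that are never treated as molecular descriptors
.reserved_cols <- c("id", "smiles", "logPe", "pka", "n_carbon", "n_hydrogen",
                    "set", "ion_class")

#' @rdname as_descriptor_table
#' @return `descriptor_names()` returns the character vector of descriptor
#'   column names (numeric, non-reserved).
#' @export
descriptor_names <- function(data) {
  nm <- setdiff(names(data), .reserved_cols)
  nm[vapply(data[nm], is.numeric, logical(1))]
}

#' Read / write descriptor tables as CSV
#'
#' CSV dialect: header row, UTF-8, `.` decimal separator; required `id`
#' column, `logPe` for training tables; optional `smiles`, `pka`
#' (semicolon-separated values within one cell), `n_carbon`, `n_hydrogen`.
#'
#' @param path Path to a CSV file.
#' @return A descriptor-table tibble; `pka`, when present, is parsed into a
#'   list-column of numeric vectors.
#' @export
read_descriptor_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  tbl <- as_descriptor_table(raw)
  if ("pka" %in% names(tbl) && is.character(tbl$pka)) {
    tbl$pka <- parse_pka(tbl$pka)
  }
  tbl
}

#' @rdname read_descriptor_table
#' @param data A descriptor table.
#' @export
write_descriptor_table <- function(data, path) {
  out <- data
  if ("pka" %in% names(out) && is.list(out$pka)) {
    out$pka <- vapply(out$pka, function(p) paste(p, collapse = ";"), character(1))
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Parse semicolon-separated pKa strings
#'
#' @param x Character vector, each element like `"9.2;3.1"` (empty string or
#'   NA for compounds without measured pKa).
#' @return List of numeric vectors (possibly empty).
#' @export
parse_pka <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(numeric(0))
    as.numeric(strsplit(trimws(s), ";", fixed = TRUE)[[1]])
  })
}

#' Average replicate measurements that are in close range
#'
#' Repeated permeability measurements for the same compound are combined by
#' their arithmetic mean, but only when they agree: if the spread
#' (max - min) exceeds `closeness_window` the replicates are considered
#' divergent and an error is raised rather than silently averaging
#' incompatible assays.
#'
#' @param measurements Numeric vector of replicate log Pe values (non-empty).
#' @param closeness_window Maximum tolerated spread, in log10 units.
#'   Default 0.5.
#' @return The mean of the replicates (a single number).
#' @examples
#' average_replicates(c(-5.1, -5.3))
#' @export
average_replicates <- function(measurements, closeness_window = 0.5) {
  if (length(measurements) == 0L) {
    abort("no measurements supplied")
  }
  if (anyNA(measurements)) abort("missing values in replicate measurements")
  spread <- max(measurements) - min(measurements)
  if (spread > closeness_window) {
    abort(sprintf(
      "divergent replicates: spread %.3f exceeds closeness window %.3f",
      spread, closeness_window))
  }
  mean(measurements)
}

#' Center-and-scale descriptor normalization
#'
#' Each descriptor column is normalized to (x - mean) / s, with s the
#' sample standard deviation (n - 1 denominator). When `stats` is omitted
#' the statistics are computed from `data` itself (the training-set case);
#' supplying the training statistics normalizes a test, outlier, or
#' prediction table on the training scale without information leakage.
#' The statistics used are attached as the `"norm_stats"` attribute and
#' retrievable with [norm_stats()].
#'
#' @param data A descriptor table.
#' @param stats Optional normalization statistics from a previous call
#'   (a `pampa_norm_stats` tibble with columns `descriptor`, `center`,
#'   `scale`), as returned by [norm_stats()].
#' @param cols Descriptor columns to normalize; defaults to all of them.
#' @return The tibble with normalized descriptor columns and a
#'   `"norm_stats"` attribute.
#' @examples
#' tbl <- tibble::tibble(id = letters[1:3], logP = c(1, 2, 3))
#' z <- normalize_descriptors(tbl)
#' z$logP            # -1 0 1
#' norm_stats(z)
#' @export
normalize_descriptors <- function(data, stats = NULL, cols = descriptor_names(data)) {
  if (length(cols) == 0L) abort("no descriptor columns to normalize")
  if (is.null(stats)) {
    if (nrow(data) < 2L) {
      abort("need at least 2 compounds to estimate normalization statistics")
    }
    center <- vapply(data[cols], mean, numeric(1))
    scale <- vapply(data[cols], sd, numeric(1))
    bad <- cols[!is.finite(scale) | scale <= 0]
    if (length(bad) > 0L) {
      abort(paste0("constant descriptor(s) with zero scale: ",
                   paste(bad, collapse = ", ")))
    }
    stats <- tibble::tibble(descriptor = cols, center = unname(center),
                            scale = unname(scale))
    class(stats) <- c("pampa_norm_stats", class(stats))
  } else {
    missing <- setdiff(cols, stats$descriptor)
    if (length(missing) > 0L) {
      abort(paste0("no normalization statistics for: ",
                   paste(missing, collapse = ", ")))
    }
    stats <- stats[match(cols, stats$descriptor), ]
  }
  for (j in seq_along(cols)) {
    data[[cols[j]]] <- (data[[cols[j]]] - stats$center[j]) / stats$scale[j]
  }
  attr(data, "norm_stats") <- stats
  data
}

#' @rdname normalize_descriptors
#' @export
norm_stats <- function(data) {
  s <- attr(data, "norm_stats")
  if (is.null(s)) abort("no normalization statistics attached; run normalize_descriptors() first")
  s
}

#' @rdname normalize_descriptors
#' @description `denormalize_descriptors()` inverts the transform, mapping a
#'   normalized table back to original descriptor units.
#' @export
denormalize_descriptors <- function(data, stats = norm_stats(data)) {
  for (j in seq_len(nrow(stats))) {
    nm <- stats$descriptor[j]
    if (nm %in% names(data)) {
      data[[nm]] <- data[[nm]] * stats$scale[j] + stats$center[j]
    }
  }
  attr(data, "norm_stats") <- NULL
  data
}

#' Screen descriptors for missingness, discrimination, and intercorrelation
#'
#' Three sequential filters mirror standard QSAR descriptor hygiene:
#' (1) any descriptor missing for at least one compound is dropped;
#' (2) descriptors with little or no discrimination are dropped --
#' variance at or below `variance_tol`, or more than `max_identical_frac`
#' of values identical; (3) pairwise Spearman rank correlations are
#' computed and, while any pair has rho-squared at or above
#' `spearman_r2_threshold`, one member of the worst-offending pair is
#' removed. The member dropped is the one with the higher mean rho-squared
#' against all remaining descriptors (ties: the later column), so the most
#' independent descriptors survive, deterministically.
#'
#' @param data A descriptor table.
#' @param variance_tol Variance at or below this is "no discrimination".
#'   Default `1e-12`.
#' @param max_identical_frac Drop a descriptor when more than this fraction
#'   of its values are identical. Default 0.9.
#' @param spearman_r2_threshold Squared Spearman correlation at or above
#'   which a pair is considered redundant. Default 0.64.
#' @return The tibble with offending descriptor columns removed; dropped
#'   names and reasons are attached as attribute `"screen_log"` (a tibble).
#' @export
screen_descriptors <- function(data,
                               variance_tol = 1e-12,
                               max_identical_frac = 0.9,
                               spearman_r2_threshold = 0.64) {
  stopifnot(spearman_r2_threshold > 0, spearman_r2_threshold <= 1)
  cols <- descriptor_names(data)
  log <- tibble::tibble(descriptor = character(0), reason = character(0))

  drop <- function(nm, why) {
    log <<- dplyr::bind_rows(log, tibble::tibble(descriptor = nm, reason = why))
    cols <<- setdiff(cols, nm)
  }

  for (nm in cols) if (anyNA(data[[nm]])) drop(nm, "missing values")
  for (nm in cols) {
    x <- data[[nm]]
    if (var(x) <= variance_tol) {
      drop(nm, "no variance")
    } else if (max(table(x)) / length(x) > max_identical_frac) {
      drop(nm, "insufficient discrimination")
    }
  }
  if (length(cols) == 0L) abort("all descriptors removed by screening")

  # iterative Spearman de-correlation
  repeat {
    if (length(cols) < 2L) break
    rho2 <- cor(as.matrix(data[cols]), method = "spearman")^2
    diag(rho2) <- 0
    worst <- max(rho2)
    if (worst < spearman_r2_threshold) break
    idx <- which(rho2 == worst, arr.ind = TRUE)[1, ]
    pair <- cols[sort(idx)]
    mean_rho2 <- rowMeans(rho2)[pair]
    # higher mean correlation goes; tie -> later column order
    victim <- if (mean_rho2[2] >= mean_rho2[1]) pair[2] else pair[1]
    drop(victim, sprintf("spearman rho^2 %.3f with %s",
                         worst, setdiff(pair, victim)))
  }
  if (length(cols) == 0L) abort("all descriptors removed by screening")

  out <- data[, c(intersect(names(data), .reserved_cols), cols)]
  attr(out, "screen_log") <- log
  out
}

#' Classify a compound's ion class from its pKa profile
#'
#' Compounds are grouped into the four classes used for permeability
#' analysis at physiological pH: a single pKa value means neutral;
#' otherwise the largest and smallest pKa are compared with 7 -- largest
#' above and smallest below gives a zwitterion, both below an acid, both
#' above a base. A pKa exactly at 7 is treated as above 7 by default
#' (`boundary = "above"`), configurable to `"below"`. Note the literal
#' single-pKa rule labels every monoprotic compound neutral regardless of
#' its pKa; the `flag` column marks those calls so they can be audited.
#'
#' @param pka A numeric vector of pKa values (one compound), or a list of
#'   such vectors (many compounds).
#' @param boundary How to treat a pKa of exactly 7: `"above"` (default) or
#'   `"below"`.
#' @return For a single profile, a length-1 character value in
#'   `c("zwitterion", "acid", "base", "neutral")`. For a list, a tibble
#'   with columns `ion_class` and `flag` (TRUE when the single-pKa neutral
#'   rule fired).
#' @examples
#' classify_ion_class(c(9.2, 3.1))  # zwitterion
#' classify_ion_class(c(8.1, 9.5))  # base
#' classify_ion_class(4.2)          # neutral (single pKa)
#' @export
classify_ion_class <- function(pka, boundary = c("above", "below")) {
  boundary <- match.arg(boundary)
  if (is.list(pka)) {
    cls <- vapply(pka, classify_ion_class, character(1), boundary = boundary)
    return(tibble::tibble(
      ion_class = cls,
      flag = vapply(pka, function(p) length(p) == 1L, logical(1))))
  }
  if (length(pka) == 0L) abort("empty pKa profile")
  if (length(pka) == 1L) return("neutral")
  gt7 <- function(x) if (boundary == "above") x >= 7 else x > 7
  hi <- gt7(max(pka))
  lo <- gt7(min(pka))
  if (hi && !lo) "zwitterion" else if (!hi && !lo) "acid" else "base"
}

#' Annotate a descriptor table with ion classes
#'
#' @param data A descriptor table with a `pka` list-column (or
#'   semicolon-separated character column).
#' @inheritParams classify_ion_class
#' @return `data` with `ion_class` (character) added.
#' @export
add_ion_class <- function(data, boundary = c("above", "below")) {
  boundary <- match.arg(boundary)
  if (!"pka" %in% names(data)) abort("no `pka` column present")
  pka <- if (is.character(data$pka)) parse_pka(data$pka) else data$pka
  data$ion_class <- classify_ion_class(pka, boundary = boundary)$ion_class
  data
}
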