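#' Classify permeability from log Pe
#'
#' Compounds with log Pe at or above -6.0 (log10 cm/s) are classed as
#' highly permeable, below it as poorly permeable; the boundary itself is
#' inclusive on the high side.
#'
#' @param log_pe Numeric vector of log10 effective permeability values.
#' @param threshold Class boundary. Default -6.0.
#' @return Character vector in `c("high", "low")`.
#' @examples
#' classify_permeability(c(-5.9, -6.0, -6.1))
#' @export
classify_permeability <- function(log_pe, threshold = -6.0) {
  if (anyNA(log_pe) || !all(is.finite(log_pe))) abort("log Pe must be finite")
  ifelse(log_pe >= threshold, "high", "low")
}

#' Descriptor rule screen for likely permeability
#'
#' Applies the physicochemical screens associated with passive membrane
#' permeability: polar surface area above 120 A^2 marks a compound as
#' likely poorly permeable (optionally the looser 140 A^2 threshold);
#' PSA below 60 A^2 combined with a distribution coefficient in
#' -0.5 < logD < 4.5 (and, when `use_logp_rule`, a partition coefficient
#' in 0 < logP < 5) marks it likely well permeable; a neutral ion class
#' is recorded as a favorable flag. Anything else is indeterminate. The
#' two definite outcomes are mutually exclusive by construction since
#' their PSA conditions cannot both hold.
#'
#' @param data A data frame with a `PSA` column and optionally `logP`,
#'   `logD`, `ion_class` columns, in original (unnormalized) units.
#' @param psa_poor PSA threshold for the poor screen. Default 120; set
#'   140 for the looser published alternative.
#' @param psa_good Upper PSA bound of the good screen. Default 60.
#' @param use_logp_rule Also require 0 < logP < 5 in the good screen.
#'   Default `FALSE` (the logD form is the better-performing screen).
#' @return `data` with columns `screen_outcome` (`"likely_poor"`,
#'   `"likely_good"`, `"indeterminate"`) and `triggered_rules`
#'   (semicolon-joined rule names).
#' @export
rule_screen <- function(data, psa_poor = 120, psa_good = 60,
                        use_logp_rule = FALSE) {
  if (!"PSA" %in% names(data)) abort("a `PSA` column is required")
  if (any(data$PSA < 0, na.rm = TRUE)) abort("PSA must be non-negative")
  n <- nrow(data)
  logd <- if ("logD" %in% names(data)) data$logD else rep(NA_real_, n)
  logp <- if ("logP" %in% names(data)) data$logP else rep(NA_real_, n)
  ion <- if ("ion_class" %in% names(data)) data$ion_class else rep(NA_character_, n)

  outcome <- rep("indeterminate", n)
  rules <- vector("list", n)
  for (i in seq_len(n)) {
    fired <- character(0)
    if (!is.na(data$PSA[i]) && data$PSA[i] > psa_poor) {
      fired <- c(fired, sprintf("PSA>%g", psa_poor))
      outcome[i] <- "likely_poor"
    } else {
      good <- !is.na(data$PSA[i]) && data$PSA[i] < psa_good &&
        !is.na(logd[i]) && logd[i] > -0.5 && logd[i] < 4.5
      if (good) fired <- c(fired, sprintf("PSA<%g", psa_good), "-0.5<logD<4.5")
      if (good && use_logp_rule) {
        good <- !is.na(logp[i]) && logp[i] > 0 && logp[i] < 5
        if (good) fired <- c(fired, "0<logP<5")
      }
      if (good) outcome[i] <- "likely_good"
    }
    if (!is.na(ion[i]) && ion[i] == "neutral") {
      fired <- c(fired, "neutral_ion_class")
    }
    rules[[i]] <- fired
  }
  data$screen_outcome <- outcome
  data$triggered_rules <- vapply(rules, paste, character(1), collapse = ";")
  data
}

#' Summarize log Pe by ion class
#'
#' Five-number-plus-mean summaries of log Pe per ion class, and two-sided
#' Mann-Whitney (Wilcoxon rank-sum) comparisons of the neutral class
#' against each other class -- rank-based because permeability
#' distributions are bounded and skewed.
#'
#' @param data A data frame with `logPe` and `ion_class` columns.
#' @param reference Class compared against the others. Default
#'   `"neutral"`.
#' @return A list with `summary` (tibble: class, n, min, q25, median,
#'   mean, q75, max) and `tests` (tibble: class, p_value vs. the
#'   reference). Classes with fewer than 2 members are skipped with a
#'   warning.
#' @export
ion_class_summary <- function(data, reference = "neutral") {
  stopifnot(all(c("logPe", "ion_class") %in% names(data)))
  counts <- table(data$ion_class)
  small <- names(counts)[counts < 2]
  if (length(small) > 0L) {
    warn(paste0("skipping ion classes with <2 members: ",
                paste(small, collapse = ", ")))
    data <- data[!data$ion_class %in% small, ]
  }
  if (length(unique(data$ion_class)) < 2L) {
    abort("need at least 2 ion classes with 2+ members")
  }
  summ <- data |>
    dplyr::group_by(.data$ion_class) |>
    dplyr::summarise(n = dplyr::n(),
                     min = min(.data$logPe),
                     q25 = unname(quantile(.data$logPe, 0.25)),
                     median = median(.data$logPe),
                     mean = mean(.data$logPe),
                     q75 = unname(quantile(.data$logPe, 0.75)),
                     max = max(.data$logPe),
                     .groups = "drop")
  others <- setdiff(unique(data$ion_class), reference)
  tests <- if (reference %in% data$ion_class) {
    ref_y <- data$logPe[data$ion_class == reference]
    purrr::map_dfr(others, function(cl) {
      p <- suppressWarnings(
        wilcox.test(ref_y, data$logPe[data$ion_class == cl],
                    alternative = "two.sided", exact = FALSE))$p.value
      tibble::tibble(class = cl, p_value = p)
    })
  } else {
    tibble::tibble(class = character(0), p_value = numeric(0))
  }
  list(summary = summ, tests = tests)
}
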