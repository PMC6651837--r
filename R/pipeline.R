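#' Pipeline configuration
#'
#' Assembles the knobs of the end-to-end workflow with the package's
#' documented defaults, so the standard analysis path needs no
#' arguments. Any element can be overridden via `...`.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A named list of class `pampa_config`.
#' @export
pampa_config <- function(...) {
  cfg <- list(
    response = "logPe",
    train_fraction = 0.8,
    variance_tol = 1e-12,
    max_identical_frac = 0.9,
    spearman_r2_threshold = 0.64,
    closeness_window = 0.5,
    pka_boundary = "above",
    distance_space = "descriptor",
    select_method = "gfa+rfe",
    max_subset_size = 5,
    gfa_population = 100,
    gfa_generations = 200,
    size_penalty = 0.005,
    fit_models = c("pls", "hsvr"),
    pls_components = "cv",
    grid = NULL,              # NULL -> svr_grid() default lattice
    candidate_subsets = NULL, # NULL -> derive from selection
    folds = 10,
    y_scramble_reps = 25,
    metric_convention = "conventional",
    rm2_convention = "radical",
    seed = 1)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L) {
    abort(paste0("unknown config fields: ", paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = c("pampa_config", "list"))
}

#' Run the full two-QSAR permeability workflow
#'
#' Executes the canonical pipeline on a descriptor table: normalization
#' (training statistics only), descriptor screening, Kennard-Stone
#' partitioning with applicability-domain outlier annotation, descriptor
#' selection, PLS and/or HSVR fitting, internal and external validation
#' with the stringent criteria, and the permeability rule screen. Every
#' stochastic stage derives its seed from `config$seed`, and the
#' returned bundle records the configuration and its hash so two runs
#' with the same inputs are numerically identical.
#'
#' @param data A descriptor table (or path to its CSV).
#' @param config A [pampa_config()].
#' @param out_dir Optional directory; when given, models (JSON),
#'   predictions (CSV), metric and criteria reports (JSON), and a
#'   provenance log are written there.
#' @return A list of class `pampa_run`: `partition`, `models`,
#'   `predictions` (tibble: id, set, observed, per-model predictions),
#'   `metrics` (tibble with one row per model x set), `criteria` (named
#'   list of criteria tibbles), `scramble` (named list), `rules`,
#'   `config`, `config_hash`.
#' @export
run_pampa_pipeline <- function(data, config = pampa_config(), out_dir = NULL) {
  if (is.character(data)) data <- read_descriptor_table(data)
  data <- as_descriptor_table(data)
  response <- config$response
  if (!response %in% names(data)) {
    abort(sprintf("response column `%s` absent from input", response))
  }
  cfg_hash <- rlang::hash(config)

  raw <- data
  if ("pka" %in% names(data)) data <- add_ion_class(data, boundary = config$pka_boundary)

  screened <- screen_descriptors(data,
                                 variance_tol = config$variance_tol,
                                 max_identical_frac = config$max_identical_frac,
                                 spearman_r2_threshold = config$spearman_r2_threshold)
  part <- partition_compounds(screened,
                              train_fraction = config$train_fraction,
                              space = config$distance_space)
  sets <- split(screened$id, part$set[match(screened$id, part$id)])
  train <- screened[screened$id %in% sets$train, ]
  norm_train <- normalize_descriptors(train)
  stats <- norm_stats(norm_train)
  norm_all <- normalize_descriptors(screened, stats = stats)

  cols <- descriptor_names(norm_train)
  selection <- NULL
  if (length(cols) > 1L && config$select_method != "none") {
    if (grepl("gfa", config$select_method)) {
      selection <- gfa_select(norm_train, response = response, cols = cols,
                              population_size = config$gfa_population,
                              generations = config$gfa_generations,
                              subset_size_range = c(1, config$max_subset_size),
                              size_penalty = config$size_penalty,
                              seed = config$seed)
      cols <- selection$subset[[1]]
    }
    if (grepl("rfe", config$select_method) && length(cols) > 1L) {
      selection <- rfe_rank(norm_train, response = response, cols = cols,
                            seed = config$seed)
    }
  }

  models <- list()
  if ("pls" %in% config$fit_models) {
    models$pls <- fit_pls(norm_train, response = response, cols = cols,
                          n_components = config$pls_components,
                          seed = config$seed)
  }
  if ("hsvr" %in% config$fit_models) {
    subsets <- config$candidate_subsets
    if (is.null(subsets)) {
      subsets <- if (length(cols) >= 2L) {
        # complementary halves of the selected pool, echoing the
        # local-model / local-model split of the published ensemble
        half <- ceiling(length(cols) / 2)
        unique(list(cols[seq_len(half)], cols[seq(half, length(cols))], cols))
      } else list(cols, cols)
    }
    grid <- config$grid %||% svr_grid()
    models$hsvr <- build_hsvr(norm_train, candidate_subsets = subsets,
                              grid = grid, response = response,
                              folds = config$folds, seed = config$seed)
  }

  preds <- tibble::tibble(id = norm_all$id,
                          set = part$set[match(norm_all$id, part$id)],
                          observed = norm_all[[response]])
  for (nm in names(models)) {
    preds[[paste0("pred_", nm)]] <- predict(models[[nm]], norm_all)
  }

  metrics <- list(); criteria <- list(); scramble <- list()
  train_y <- preds$observed[preds$set == "train"]
  for (nm in names(models)) {
    qcv2 <- if (nm == "pls") {
      kfold_cv(function(d) fit_pls(d, response = response, cols = cols,
                                   n_components = models$pls$n_components),
               norm_train, response = response,
               k = min(config$folds, nrow(norm_train)), seed = config$seed)
    } else models$hsvr$qcv2
    sc <- y_scramble(
      if (nm == "pls") {
        function(d) fit_pls(d, response = response, cols = cols,
                            n_components = models$pls$n_components)
      } else {
        function(d) {
          specs <- models$hsvr$member_specs
          mem <- lapply(specs, function(sp) train_svr(d, sp, response = response))
          mf <- vapply(mem, function(mm) predict(mm, d), numeric(nrow(d)))
          mt <- tibble::as_tibble(as.data.frame(mf))
          names(mt) <- paste0("member_", seq_along(mem))
          mt[[response]] <- d[[response]]
          structure(list(members = mem,
                         meta = train_svr(mt, models$hsvr$meta$spec,
                                          response = response),
                         member_specs = specs, response = response),
                    class = "pampa_hsvr")
        }
      },
      norm_train, response = response,
      reps = config$y_scramble_reps, seed = config$seed)
    scramble[[nm]] <- sc
    for (s in intersect(c("train", "test", "outlier"), unique(preds$set))) {
      sub <- preds[preds$set == s, ]
      if (nrow(sub) < 2L) next
      m <- qsar_metrics(sub, observed = "observed",
                        predicted = paste0("pred_", nm),
                        train_observed = if (s == "train") NULL else train_y,
                        convention = config$metric_convention)
      m$qcv2 <- if (s == "train") qcv2 else NA_real_
      m$rs2_mean <- if (s == "train") sc$rs2_mean else NA_real_
      m$model <- nm; m$set <- s
      metrics[[paste(nm, s, sep = "_")]] <- m
      criteria[[paste(nm, s, sep = "_")]] <- check_criteria(m)
    }
  }
  metrics <- dplyr::bind_rows(metrics)

  # the rule screen needs PSA in raw angstrom^2 units; skip when the input
  # is already on a normalized scale (negative PSA values)
  rules <- if ("PSA" %in% names(raw) && all(raw$PSA >= 0, na.rm = TRUE)) {
    out <- raw
    out$permeability_class <- classify_permeability(raw[[response]])
    rule_screen(out)
  } else NULL

  run <- structure(list(partition = part,
                        selection = selection,
                        norm_stats = stats,
                        models = models,
                        predictions = preds,
                        metrics = metrics,
                        criteria = criteria,
                        scramble = scramble,
                        rules = rules,
                        config = config,
                        config_hash = cfg_hash),
                   class = "pampa_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @rdname run_pampa_pipeline
#' @param run A `pampa_run` bundle.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tag <- function(nm) file.path(out_dir, nm)
  utils::write.csv(run$partition, tag("partition.csv"), row.names = FALSE)
  utils::write.csv(run$predictions, tag("predictions.csv"), row.names = FALSE)
  jsonlite::write_json(run$metrics, tag("metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    lapply(run$criteria, function(cr) as.data.frame(cr)),
    tag("criteria.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(run$models$pls)) write_pls_model(run$models$pls, tag("pls_model.json"))
  if (!is.null(run$models$hsvr)) write_hsvr_model(run$models$hsvr, tag("hsvr_model.json"))
  if (!is.null(run$rules)) utils::write.csv(run$rules, tag("rules.csv"), row.names = FALSE)
  prov <- list(package = "pampaqsar",
               version = as.character(utils::packageVersion("pampaqsar")),
               r_version = R.version.string,
               config = unclass(run$config),
               config_hash = run$config_hash,
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, tag("provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pampa_run <- function(x, ...) {
  cat("Two-QSAR permeability run (config", substr(x$config_hash, 1, 8), ")\n")
  cat("  partition:", paste(names(table(x$partition$set)),
                            table(x$partition$set), collapse = ", "), "\n")
  cat("  models:", paste(names(x$models), collapse = ", "), "\n")
  if (nrow(x$metrics) > 0) {
    print(dplyr::select(x$metrics, "model", "set", "n", "r2", "rmse",
                        dplyr::any_of(c("qcv2", "ccc"))))
  }
  invisible(x)
}
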