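#' Read / write per-residue score tables
#'
#' Delimited-text exchange format: header
#' `protein_id, chain, resno, icode, <predictor...>, label` with optional
#' `R` (surface count) column.
#'
#' @param path file path.
#' @return [read_score_table()]: a score tibble.
#' @export
read_score_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           protein_id = readr::col_character(),
                           chain = readr::col_character(),
                           icode = readr::col_character(),
                           .default = readr::col_guess()))
  out$icode[is.na(out$icode)] <- ""
  if (anyDuplicated(out[, c("protein_id", "chain", "resno", "icode")])) {
    abort("duplicate (protein, residue) rows in score table")
  }
  out
}

#' @rdname read_score_table
#' @param table score tibble.
#' @export
write_score_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' Serialize a fitted integration model
#'
#' Regression models are written as plain-text JSON with inspectable
#' coefficients; tree ensembles store their hyperparameters in the JSON
#' header and the fitted ensemble in an RDS sidecar (`<path>.rds`).
#'
#' @param model fitted `ispip_*` model.
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  meta <- list(format = "ispip_model", version = 1L,
               class = class(model)[1], predictors = model$predictors)
  if (!is.null(model$coefficients)) {
    meta$coefficients <- as.list(model$coefficients)
  } else {
    meta$hyperparameters <- model[setdiff(
      names(model), c("fit", "predictors", "coefficients"))]
    saveRDS(model$fit, paste0(path, ".rds"))
    meta$ensemble_file <- paste0(basename(path), ".rds")
  }
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  meta <- jsonlite::read_json(path)
  if (!identical(meta$format, "ispip_model")) abort("not an ispip model file")
  predictors <- unlist(meta$predictors)
  if (!is.null(meta$coefficients)) {
    coefs <- unlist(meta$coefficients)
    return(new_model(meta$class, NULL, predictors,
                     list(coefficients = coefs)))
  }
  fit <- readRDS(file.path(dirname(path), meta$ensemble_file))
  new_model(meta$class, fit, predictors,
            purrr::map(meta$hyperparameters, function(v) {
              if (is.list(v)) unlist(v) else v
            }))
}

#' Run the full integration workflow
#'
#' The staged pipeline: load (or accept) a labelled score table,
#' normalize, split proteins into test set and grouped CV folds, select
#' and fit the integration model by cross-validated average F-score,
#' predict the test proteins, and evaluate under the dynamic cutoff. A
#' leakage guard asserts on every run that no test protein appears in
#' any training fold. All outputs land in `out_dir` together with a
#' manifest (config hash, seed, package version) such that rerunning the
#' same configuration reproduces the metric files byte-identically.
#'
#' @param scores score tibble or path to one (see [read_score_table()]).
#' @param family model family passed to [cross_validate()].
#' @param grid optional hyperparameter grid.
#' @param test test-set specification for [split_dataset()].
#' @param folds CV folds.
#' @param normalization [normalize_scores()] mode.
#' @param rounding dynamic-cutoff rounding convention.
#' @param seed master seed; every stage derives a named substream.
#' @param out_dir output directory, created if needed; `NULL` skips
#'   writing.
#' @return list with `model`, `cv`, `split`, `predictions` (test-set
#'   tibble with `prediction` column), `evaluation`
#'   (`ispip_evaluation`), `manifest`.
#' @export
run_pipeline <- function(scores, family = "logistic", grid = NULL,
                         test = 0.2, folds = 5,
                         normalization = "none",
                         rounding = "round", seed = 0, out_dir = NULL) {
  table <- if (is.character(scores)) read_score_table(scores) else scores
  if (!"label" %in% names(table)) {
    abort("training stage requires a `label` column in the score table")
  }
  check_labelled(table, both_classes = TRUE)
  predictors <- score_columns(table)
  table <- normalize_scores(table, predictors, mode = normalization)

  split <- split_dataset(unique(table$protein_id), test = test,
                         folds = folds, seed = seed)
  train <- table |> filter(!.data$protein_id %in% split$test_ids)
  test_tbl <- table |> filter(.data$protein_id %in% split$test_ids)

  # leakage guard: a test protein must never reach a training fold
  leaked <- intersect(split$test_ids, split$folds$protein_id)
  if (length(leaked) > 0 ||
      any(train$protein_id %in% split$test_ids)) {
    abort("leakage guard tripped: test protein present in training folds")
  }

  cv <- cross_validate(train, family, grid = grid,
                       fold_assignment = split$folds, seed = seed,
                       predictors = predictors)
  predictions <- add_predictions(test_tbl, cv$model)
  evaluation <- evaluate_predictions(predictions, "prediction",
                                     rounding = rounding)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ispip")),
    seed = seed, family = family, folds = folds,
    normalization = normalization, rounding = rounding,
    predictors = predictors,
    n_proteins = length(unique(table$protein_id)),
    test_ids = split$test_ids,
    config_hash = digest::digest(list(family, grid, test, folds,
                                      normalization, rounding, seed))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_model(cv$model, file.path(out_dir, "model.json"))
    write_score_table(predictions, file.path(out_dir, "predictions.csv"))
    readr::write_csv(evaluation$per_protein,
                     file.path(out_dir, "metrics_per_protein.csv"))
    readr::write_csv(glance(evaluation), file.path(out_dir, "summary.csv"))
    readr::write_csv(split$folds, file.path(out_dir, "folds.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(model = cv$model, cv = cv, split = split,
       predictions = predictions, evaluation = evaluation,
       manifest = manifest)
}
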