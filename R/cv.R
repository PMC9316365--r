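#' Split proteins into a test set and grouped cross-validation folds
#'
#' Splitting is always by protein, never by residue: residues of one
#' protein stay together in the test set or in a single fold, so no
#' protein leaks between training and evaluation. With 141 proteins,
#' `test = 31` and five folds this reproduces the canonical
#' 31-test / 5 x 22 layout.
#'
#' @param protein_ids character vector of unique protein ids.
#' @param test number of test proteins, a fraction in (0, 1), or an
#'   explicit character vector of test ids.
#' @param folds number of cross-validation folds over the remaining
#'   (training) proteins.
#' @param seed RNG seed; the split is deterministic given the seed.
#' @return list with `test_ids` (character) and `folds` (tibble
#'   `protein_id`, `fold`), folds near-equal in size.
#' @export
split_dataset <- function(protein_ids, test = 0.2, folds = 5, seed = 0) {
  if (anyDuplicated(protein_ids)) abort("duplicate protein ids")
  n <- length(protein_ids)
  if (is.character(test)) {
    unknown <- setdiff(test, protein_ids)
    if (length(unknown) > 0) {
      abort(sprintf("unknown test ids: %s", paste(unknown, collapse = ", ")))
    }
    test_ids <- test
  } else {
    n_test <- if (test < 1) round_half_up(test * n) else as.integer(test)
    if (n_test >= n) abort("test set would consume every protein")
    test_ids <- with_substream(seed, "split_test",
                               sample(protein_ids, n_test))
  }
  train_ids <- setdiff(protein_ids, test_ids)
  if (length(train_ids) < folds) {
    abort(sprintf("need at least %d training proteins for %d folds",
                  folds, folds))
  }
  shuffled <- with_substream(seed, "split_folds", sample(train_ids))
  fold <- rep(seq_len(folds), length.out = length(shuffled))
  list(
    test_ids = sort(test_ids),
    folds = tibble(protein_id = shuffled, fold = sort(fold)) |>
      arrange(.data$protein_id)
  )
}

# fit one model family at one hyperparameter point
fit_family <- function(table, family, params = list(), predictors, seed = 0) {
  switch(family,
    linear = fit_linear(table, predictors),
    logistic = fit_logistic(table, predictors),
    forest = fit_forest(table, predictors,
                        trees = params$trees %||% 100,
                        max_depth = params$max_depth %||% 10,
                        alpha = params$alpha %||% 0,
                        seed = seed),
    boosted = fit_boosted(table, predictors,
                          loss = params$loss %||% "logloss",
                          learning_rate = params$learning_rate %||% 0.1,
                          iterations = params$iterations %||% 100,
                          max_depth = params$max_depth %||% 3,
                          seed = seed),
    abort(sprintf("unknown model family '%s'", family))
  )
}

default_grid <- function(family) {
  switch(family,
    linear = ,
    logistic = tibble(.point = 1L),
    forest = tidyr::expand_grid(trees = 100, max_depth = 10, alpha = 0),
    boosted = tidyr::expand_grid(loss = c("logloss", "squared"),
                                 learning_rate = c(0.05, 0.1, 0.3),
                                 iterations = c(50, 100, 200),
                                 max_depth = c(3, 6))
  )
}

# mean per-protein F-score under the dynamic cutoff
mean_f_score <- function(table, scores, rounding = "round") {
  table$..pred <- scores
  ev <- evaluate_predictions(table, "..pred", rounding = rounding)
  ev$summary$f_score
}

#' Grouped five-fold cross-validation by average per-protein F-score
#'
#' The model-selection loop of the integrator: hyperparameter points are
#' scored by fitting on four folds and computing the average per-protein
#' F-score of the held-out fold under the dynamic cutoff, averaged over
#' the five rotations. The winning point (ties resolved toward the
#' simplest model: fewer trees, then smaller depth, then grid order) is
#' refit on all training proteins.
#'
#' For the closed-form regressions (linear, logistic) the grid is a
#' single point, but the same machinery yields five fold-fitted candidate
#' coefficient vectors; `regression_final = "best_fold"` returns the
#' candidate with the highest held-out F (the selection-by-CV reading of
#' the procedure), `"refit_all"` (default) refits on all training data.
#'
#' @param table labelled score tibble with `protein_id` and `R` columns.
#' @param family `"linear"`, `"logistic"`, `"forest"` or `"boosted"`.
#' @param grid tibble of hyperparameter combinations (columns matching
#'   the fitter's arguments); `NULL` uses the family default.
#' @param folds number of folds (ignored when `fold_assignment` given).
#' @param fold_assignment optional tibble (`protein_id`, `fold`) fixing
#'   the grouped folds, e.g. from [split_dataset()].
#' @param seed RNG seed driving fold assignment and the tree fits.
#' @param regression_final see above; only affects linear/logistic.
#' @param predictors predictor columns (default [score_columns()]).
#' @return list with `model` (the refit winner), `best` (one-row tibble
#'   of winning hyperparameters and mean CV F-score), `cv_results`
#'   (per-grid-point mean F), `fold_assignment`, `fold_f` (per-fold
#'   held-out F of the winner), `family`.
#' @export
cross_validate <- function(table, family, grid = NULL, folds = 5,
                           fold_assignment = NULL, seed = 0,
                           regression_final = c("refit_all", "best_fold"),
                           predictors = score_columns(table)) {
  regression_final <- match.arg(regression_final)
  check_labelled(table, both_classes = TRUE)
  ids <- unique(table$protein_id)
  if (length(ids) < folds) abort("need at least `folds` labelled proteins")
  if (is.null(fold_assignment)) {
    fold_assignment <- split_dataset(ids, test = character(0), folds = folds,
                                     seed = seed)$folds
  }
  table$fold <- NULL
  table <- table |> left_join(fold_assignment, by = "protein_id")
  if (anyNA(table$fold)) abort("proteins missing from fold assignment")

  grid <- grid %||% default_grid(family)
  # tie-break ordering: simplest model first (which.max takes the first max)
  grid <- grid |> arrange(dplyr::across(dplyr::any_of(
    c("trees", "iterations", "max_depth", "learning_rate"))))

  fold_ids <- sort(unique(table$fold))
  eval_point <- function(params) {
    fold_stats <- purrr::map(fold_ids, function(f) {
      tr <- table |> filter(.data$fold != f)
      ho <- table |> filter(.data$fold == f)
      m <- fit_family(tr, family, params, predictors, seed = seed)
      list(f = mean_f_score(ho, predict(m, ho)), model = m)
    })
    list(mean_f = mean(purrr::map_dbl(fold_stats, "f")),
         fold_f = purrr::map_dbl(fold_stats, "f"),
         models = purrr::map(fold_stats, "model"))
  }

  points <- purrr::map(seq_len(nrow(grid)), function(i) {
    as.list(grid[i, setdiff(names(grid), ".point"), drop = FALSE])
  })
  results <- purrr::map(points, eval_point)
  mean_f <- purrr::map_dbl(results, "mean_f")
  best_i <- which.max(mean_f)  # first max = simplest by grid order
  best_params <- points[[best_i]]

  if (family %in% c("linear", "logistic") &&
      regression_final == "best_fold") {
    fold_f <- results[[best_i]]$fold_f
    model <- results[[best_i]]$models[[which.max(fold_f)]]
  } else {
    model <- fit_family(table, family, best_params, predictors, seed = seed)
  }

  cv_results <- grid |>
    select(-dplyr::any_of(".point")) |>
    mutate(mean_f = mean_f)
  best <- cv_results[best_i, , drop = FALSE]
  list(model = model, best = best, cv_results = cv_results,
       fold_assignment = fold_assignment,
       fold_f = results[[best_i]]$fold_f, family = family)
}
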