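#' Normalize predictor score columns to \[0, 1\]
#'
#' Upstream predictors emit per-residue interface likelihoods that the
#' integration models expect on a common \[0, 1\] scale.
#'
#' @param table score tibble: one row per residue with a `protein_id`
#'   column and one numeric column per predictor.
#' @param predictors character vector of predictor column names; default
#'   all numeric columns other than `resno` and `label`.
#' @param mode `"none"` asserts scores are already in \[0, 1\];
#'   `"minmax_global"` rescales each column over the whole table;
#'   `"minmax_per_protein"` rescales within each protein. Constant
#'   columns map to 0.5.
#' @return the table with predictor columns rescaled.
#' @export
normalize_scores <- function(table,
                             predictors = score_columns(table),
                             mode = c("none", "minmax_global",
                                      "minmax_per_protein")) {
  mode <- match.arg(mode)
  for (p in predictors) {
    v <- table[[p]]
    if (is.null(v)) abort(sprintf("predictor column '%s' not found", p))
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      abort(sprintf("non-numeric or missing score in column '%s' (row %s)",
                    p, bad %||% NA))
    }
  }
  minmax <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(rep(0.5, length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }
  if (mode == "none") {
    for (p in predictors) {
      if (any(table[[p]] < 0 | table[[p]] > 1)) {
        abort(sprintf("column '%s' outside [0, 1]; choose a minmax mode", p))
      }
    }
    return(table)
  }
  if (mode == "minmax_global") {
    return(table |> mutate(across(dplyr::all_of(predictors), minmax)))
  }
  table |>
    group_by(.data$protein_id) |>
    mutate(across(dplyr::all_of(predictors), minmax)) |>
    ungroup()
}

#' Predictor columns of a score table
#'
#' @param table score tibble.
#' @return names of the numeric columns holding predictor scores (all
#'   numeric columns except the residue-identity and label bookkeeping
#'   columns).
#' @export
score_columns <- function(table) {
  reserved <- c("protein_id", "chain", "resno", "icode", "resid", "label",
                "fold", "R", "surface")
  nm <- setdiff(names(table), reserved)
  nm[vapply(table[nm], is.numeric, logical(1))]
}

check_labelled <- function(table, both_classes = FALSE) {
  if (!"label" %in% names(table)) abort("score table has no `label` column")
  stopifnot_binary(table$label, "label")
  if (both_classes && length(unique(table$label)) < 2) {
    abort("labels are single-class; both classes required")
  }
}

new_model <- function(class, fit, predictors, extra = list()) {
  structure(c(list(fit = fit, predictors = predictors), extra),
            class = c(class, "ispip_model"))
}

#' Fit the linear integration model
#'
#' Ordinary least squares of the 0/1 interface label on the predictor
#' scores, `I(x) = b0 + sum_j b_j x_j`; predictions are clipped to
#' \[0, 1\]. On a rank-deficient design the fit falls back to a small
#' ridge penalty so coefficients stay finite.
#'
#' @param table labelled score tibble.
#' @param predictors predictor columns (default [score_columns()]).
#' @return an object of class `ispip_linear`.
#' @export
fit_linear <- function(table, predictors = score_columns(table)) {
  check_labelled(table)
  x <- as.matrix(table[, predictors, drop = FALSE])
  y <- table$label
  if (length(unique(y)) < 2) {
    warn("all labels identical; returning intercept-only model")
    coefs <- c(`(Intercept)` = unique(y)[1],
               stats::setNames(rep(0, length(predictors)), predictors))
    return(new_model("ispip_linear", NULL, predictors,
                     list(coefficients = coefs)))
  }
  xf <- cbind(`(Intercept)` = 1, x)
  qrx <- qr(xf)
  if (qrx$rank < ncol(xf)) {
    # ridge fallback keeps every predictor identifiable
    lam <- 1e-8 * nrow(xf)
    coefs <- drop(solve(crossprod(xf) + lam * diag(ncol(xf)), crossprod(xf, y)))
  } else {
    fit <- stats::lm.fit(xf, y)
    coefs <- fit$coefficients
  }
  names(coefs) <- c("(Intercept)", predictors)
  new_model("ispip_linear", NULL, predictors, list(coefficients = coefs))
}

#' Fit the logistic integration model
#'
#' Maximum-likelihood logistic regression of the interface label on the
#' predictor scores, `P(i | x) = 1 / (1 + exp(-(b0 + sum_j b_j x_j)))`.
#' Perfect separation (detected by non-convergence or exploding
#' coefficients) is handled by refitting with a small L2 penalty so the
#' returned coefficients are finite while the score ordering is preserved.
#'
#' @inheritParams fit_linear
#' @param max_abs_coef coefficient magnitude beyond which separation is
#'   assumed and the penalized refit kicks in.
#' @return an object of class `ispip_logistic`.
#' @export
fit_logistic <- function(table, predictors = score_columns(table),
                         max_abs_coef = 30) {
  check_labelled(table, both_classes = TRUE)
  x <- as.matrix(table[, predictors, drop = FALSE])
  y <- table$label
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, x), y, family = stats::binomial(),
                   control = stats::glm.control(maxit = 100, epsilon = 1e-10))
  )
  coefs <- fit$coefficients
  separated <- !fit$converged || any(!is.finite(coefs)) ||
    any(abs(coefs) > max_abs_coef)
  if (separated) {
    # glmnet needs >= 2 columns; pad single-predictor designs with a
    # zero column whose coefficient is dropped afterwards
    xg <- if (ncol(x) < 2) cbind(x, .pad = 0) else x
    pen <- glmnet::glmnet(xg, y, family = "binomial", alpha = 0,
                          lambda = 1e-4, standardize = FALSE)
    coefs <- as.numeric(glmnet::coef.glmnet(pen))[seq_len(ncol(x) + 1)]
  }
  names(coefs) <- c("(Intercept)", predictors)
  new_model("ispip_logistic", NULL, predictors,
            list(coefficients = coefs, separated = separated))
}

#' Fit the random-forest integration model
#'
#' Bootstrap-aggregated probability trees: each tree is a depth-bounded
#' CART classifier grown on a bootstrap resample (via [rpart::rpart()]),
#' optionally cost-complexity pruned at `alpha`; the per-residue
#' prediction is the mean terminal-node positive fraction across trees.
#' Defaults follow the optimized configuration: 100 trees, depth 10,
#' no pruning.
#'
#' @inheritParams fit_linear
#' @param trees number of trees.
#' @param max_depth maximum tree depth (levels).
#' @param alpha cost-complexity pruning parameter (rpart `cp`); 0 = none.
#' @param mtry predictors sampled per tree (default all; with three
#'   predictor channels per-tree feature subsampling buys little).
#' @param seed RNG seed; fits are deterministic given the seed.
#' @return an object of class `ispip_forest`.
#' @export
fit_forest <- function(table, predictors = score_columns(table),
                       trees = 100, max_depth = 10, alpha = 0,
                       mtry = length(predictors), seed = 0) {
  check_labelled(table, both_classes = TRUE)
  if (trees < 1 || max_depth < 1) abort("`trees` and `max_depth` must be >= 1")
  if (alpha < 0) abort("`alpha` must be >= 0")
  df <- as.data.frame(table[, c(predictors, "label")])
  df$label <- factor(df$label, levels = c(0, 1))
  n <- nrow(df)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0,
                               minsplit = 5, minbucket = 2,
                               xval = 0, maxsurrogate = 0,
                               maxcompete = 0)
  ensemble <- with_substream(seed, "forest", {
    purrr::map(seq_len(trees), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      feats <- if (mtry < length(predictors)) {
        sample(predictors, mtry)
      } else {
        predictors
      }
      fml <- stats::as.formula(paste("label ~", paste(feats, collapse = " + ")))
      tr <- rpart::rpart(fml, data = df[idx, , drop = FALSE],
                         method = "class", control = ctrl)
      if (alpha > 0) tr <- rpart::prune(tr, cp = alpha)
      tr
    })
  })
  new_model("ispip_forest", ensemble, predictors,
            list(trees = trees, max_depth = max_depth, alpha = alpha,
                 seed = seed))
}

#' Fit the gradient-boosted-tree integration model
#'
#' Histogram-based gradient boosting over depth-bounded regression trees
#' (via [xgboost::xgb.train()] with `tree_method = "hist"`); successive
#' trees fit the gradient of the loss so the ensemble learns from the
#' residuals of its predecessors. Raw predictions are mapped to \[0, 1\]
#' (sigmoid link for log-loss; clipping for squared error).
#'
#' @inheritParams fit_forest
#' @param loss `"logloss"` (binomial deviance) or `"squared"` (squared
#'   error on the 0/1 label).
#' @param learning_rate shrinkage per boosting step.
#' @param iterations boosting rounds; 0 returns the constant base-rate
#'   model.
#' @param max_depth maximum tree depth.
#' @return an object of class `ispip_boosted`.
#' @export
fit_boosted <- function(table, predictors = score_columns(table),
                        loss = c("logloss", "squared"),
                        learning_rate = 0.1, iterations = 100,
                        max_depth = 3, seed = 0) {
  check_labelled(table, both_classes = TRUE)
  loss <- match.arg(loss)
  if (iterations < 0) abort("`iterations` must be >= 0")
  x <- as.matrix(table[, predictors, drop = FALSE])
  y <- as.numeric(table$label)
  base <- mean(y)
  if (iterations == 0) {
    return(new_model("ispip_boosted", NULL, predictors,
                     list(loss = loss, base_rate = base,
                          iterations = 0L, learning_rate = learning_rate,
                          max_depth = max_depth, seed = seed)))
  }
  objective <- if (loss == "logloss") "binary:logistic" else "reg:squarederror"
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  booster <- xgboost::xgb.train(
    params = list(objective = objective, eta = learning_rate,
                  max_depth = max_depth, tree_method = "hist",
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = iterations, verbose = 0
  )
  new_model("ispip_boosted", booster, predictors,
            list(loss = loss, base_rate = base,
                 iterations = as.integer(iterations),
                 learning_rate = learning_rate,
                 max_depth = max_depth, seed = seed))
}

#' Construct regression models from known coefficients
#'
#' Builds a linear or logistic integration model directly from an
#' intercept and named predictor coefficients — e.g. to apply published
#' parameter sets without refitting.
#'
#' @param intercept intercept b0.
#' @param coefficients named numeric vector of predictor coefficients.
#' @return an `ispip_linear` / `ispip_logistic` model.
#' @export
linear_model <- function(intercept, coefficients) {
  if (is.null(names(coefficients))) abort("coefficients must be named")
  coefs <- c(`(Intercept)` = intercept, coefficients)
  new_model("ispip_linear", NULL, names(coefficients),
            list(coefficients = coefs))
}

#' @rdname linear_model
#' @export
logistic_model <- function(intercept, coefficients) {
  if (is.null(names(coefficients))) abort("coefficients must be named")
  coefs <- c(`(Intercept)` = intercept, coefficients)
  new_model("ispip_logistic", NULL, names(coefficients),
            list(coefficients = coefs))
}

check_predictors <- function(object, table) {
  missing <- setdiff(object$predictors, names(table))
  if (length(missing) > 0) {
    abort(sprintf("score table lacks predictor column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  as.matrix(table[, object$predictors, drop = FALSE])
}

#' Per-residue interface likelihoods from a fitted integration model
#'
#' All four families return likelihoods in \[0, 1\]: logistic through its
#' sigmoid, linear clipped, forest as a mean leaf fraction, boosted via
#' its link (or clipped for the squared-error loss).
#'
#' @param object a fitted `ispip_*` model.
#' @param table score tibble containing the model's predictor columns.
#' @param ... unused.
#' @return numeric vector of likelihoods, one per row of `table`.
#' @name predict-models
NULL

#' @rdname predict-models
#' @export
predict.ispip_linear <- function(object, table, ...) {
  x <- check_predictors(object, table)
  eta <- drop(cbind(1, x) %*% object$coefficients)
  pmin(1, pmax(0, eta))
}

#' @rdname predict-models
#' @export
predict.ispip_logistic <- function(object, table, ...) {
  x <- check_predictors(object, table)
  stats::plogis(drop(cbind(1, x) %*% object$coefficients))
}

#' @rdname predict-models
#' @export
predict.ispip_forest <- function(object, table, ...) {
  check_predictors(object, table)
  df <- as.data.frame(table[, object$predictors, drop = FALSE])
  probs <- purrr::map(object$fit, function(tr) {
    stats::predict(tr, newdata = df, type = "prob")[, "1"]
  })
  Reduce(`+`, probs) / length(probs)
}

#' @rdname predict-models
#' @export
predict.ispip_boosted <- function(object, table, ...) {
  x <- check_predictors(object, table)
  if (object$iterations == 0L || is.null(object$fit)) {
    return(rep(object$base_rate, nrow(x)))
  }
  p <- stats::predict(object$fit, xgboost::xgb.DMatrix(x))
  if (object$loss == "squared") p <- pmin(1, pmax(0, p))
  p
}

#' Attach a model's predictions to a score table
#'
#' @param table score tibble.
#' @param model fitted `ispip_*` model.
#' @param column name of the new prediction column.
#' @return `table` with the prediction column appended.
#' @export
add_predictions <- function(table, model, column = "prediction") {
  table[[column]] <- predict(model, table)
  table
}

#' @export
print.ispip_model <- function(x, ...) {
  cat("<", class(x)[1], "> predictors: ",
      paste(x$predictors, collapse = ", "), "\n", sep = "")
  if (!is.null(x$coefficients)) {
    print(round(x$coefficients, 4))
  } else if (inherits(x, "ispip_forest")) {
    cat(sprintf("trees = %d, max_depth = %d, alpha = %g\n",
                x$trees, x$max_depth, x$alpha))
  } else if (inherits(x, "ispip_boosted")) {
    cat(sprintf("loss = %s, eta = %g, iterations = %d, max_depth = %d\n",
                x$loss, x$learning_rate, x$iterations, x$max_depth))
  }
  invisible(x)
}
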