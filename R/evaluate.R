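#' Dynamic top-N classification cutoff
#'
#' The per-protein number of top-ranked residues called interfacial,
#' `N = 6.1 * R^0.3`, where `R` is the protein's surface-exposed residue
#' count. The power law is rounded to an integer; rounding convention is
#' configurable since the scaling relation itself is silent on it.
#'
#' @param R surface-residue count(s), positive integers.
#' @param rounding `"round"` (half-up, default), `"floor"` or `"ceiling"`.
#' @return integer N, at least 1, same length as `R`.
#' @export
dynamic_cutoff <- function(R, rounding = c("round", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  if (any(R <= 0)) abort("`R` must be positive")
  raw <- 6.1 * R^0.3
  n <- switch(rounding,
              round = round_half_up(raw),
              floor = floor(raw),
              ceiling = ceiling(raw))
  as.integer(pmax(1, n))
}

#' Call the N top-scoring residues positive
#'
#' Exactly `min(N, length(scores))` residues are called positive — those
#' with the highest likelihoods. Ties at rank N are broken by position in
#' the table (first listed wins), which keeps calls deterministic.
#'
#' @param scores per-residue likelihoods.
#' @param N number of positives to call.
#' @return integer 0/1 vector of calls.
#' @export
classify_top_n <- function(scores, N) {
  if (N < 0) abort("`N` must be non-negative")
  n <- length(scores)
  calls <- integer(n)
  k <- min(N, n)
  if (k > 0) {
    ord <- order(-scores, seq_len(n))  # ties -> earlier row
    calls[ord[seq_len(k)]] <- 1L
  }
  calls
}

#' Confusion counts from binary calls and labels
#'
#' @param calls integer 0/1 predicted calls.
#' @param labels integer 0/1 ground truth.
#' @return one-row tibble with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(calls, labels) {
  if (length(calls) != length(labels)) abort("length mismatch")
  stopifnot_binary(calls, "calls")
  stopifnot_binary(labels, "labels")
  tibble(
    TP = sum(calls == 1L & labels == 1L),
    FP = sum(calls == 1L & labels == 0L),
    FN = sum(calls == 0L & labels == 1L),
    TN = sum(calls == 0L & labels == 0L)
  )
}

#' Single-threshold classification metrics
#'
#' Precision, recall, F-score and the Matthews correlation coefficient
#' from confusion counts:
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F = 2*precision*recall/(precision+recall)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any metric whose denominator vanishes is defined 0 and flagged in the
#' `degenerate` column so averages over proteins stay well defined.
#'
#' @param counts tibble with `TP`, `FP`, `FN`, `TN` (one or more rows).
#' @return tibble with `precision`, `recall`, `f_score`, `mcc`,
#'   `degenerate` appended to the counts.
#' @export
compute_metrics <- function(counts) {
  if (any(unlist(counts[, c("TP", "FP", "FN", "TN")]) < 0)) {
    abort("confusion counts must be non-negative")
  }
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  fn <- as.numeric(counts$FN); tn <- as.numeric(counts$TN)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f_score <- safe_div(2 * precision * recall, precision + recall)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- safe_div(tp * tn - fp * fn, mcc_den)
  degenerate <- (tp + fp) == 0 | (tp + fn) == 0 | mcc_den == 0
  counts |>
    mutate(precision = precision, recall = recall, f_score = f_score,
           mcc = mcc, degenerate = degenerate)
}

#' Evaluate per-residue predictions protein by protein
#'
#' The single-threshold evaluation of an interface predictor: for every
#' protein the dynamic cutoff `N = 6.1 R^0.3` fixes how many top-scoring
#' residues are called positive, confusion counts and metrics are
#' computed per protein, and unweighted means across proteins are
#' reported alongside pooled ROC and precision-recall curves.
#'
#' @param table labelled score tibble containing a prediction column and
#'   a per-protein surface count, either as an `R` column or supplied via
#'   `surface`.
#' @param score_col name of the prediction column to evaluate.
#' @param surface optional tibble (`protein_id`, `R`) overriding/providing
#'   surface counts.
#' @param cutoff `"dynamic"` (default) applies [dynamic_cutoff()];
#'   a single integer applies a fixed N to every protein.
#' @param rounding rounding convention for the dynamic cutoff.
#' @return object of class `ispip_evaluation`: list with `per_protein`
#'   (metrics tibble, one row per protein), `summary` (one-row tibble of
#'   unweighted means), `roc` and `pr` (pooled [roc_pr_curves()] output),
#'   `score_col`.
#' @export
evaluate_predictions <- function(table, score_col, surface = NULL,
                                 cutoff = "dynamic",
                                 rounding = c("round", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  check_labelled(table)
  if (!score_col %in% names(table)) {
    abort(sprintf("score column '%s' not found", score_col))
  }
  if (!is.null(surface)) {
    table <- table[setdiff(names(table), "R")] |>
      left_join(surface[, c("protein_id", "R")], by = "protein_id")
  }
  if (!"R" %in% names(table)) {
    abort("surface count R missing; provide `surface` or an `R` column")
  }
  if (anyNA(table$R)) {
    missing <- unique(table$protein_id[is.na(table$R)])
    abort(sprintf("surface count R missing for protein(s): %s",
                  paste(utils::head(missing, 3), collapse = ", ")))
  }

  per_protein <- table |>
    group_by(.data$protein_id) |>
    group_modify(function(d, key) {
      N <- if (identical(cutoff, "dynamic")) {
        dynamic_cutoff(d$R[1], rounding = rounding)
      } else {
        as.integer(cutoff)
      }
      calls <- classify_top_n(d[[score_col]], N)
      compute_metrics(confusion(calls, d$label)) |>
        mutate(N = N, R = d$R[1], n_residues = nrow(d),
               n_interface = sum(d$label), .before = 1)
    }) |>
    ungroup()

  summary <- per_protein |>
    summarise(n_proteins = dplyr::n(),
              across(c("precision", "recall", "f_score", "mcc"), mean),
              n_degenerate = sum(.data$degenerate))

  curves <- if (length(unique(table$label)) == 2) {
    roc_pr_curves(table[[score_col]], table$label)
  } else {
    NULL
  }

  structure(list(per_protein = per_protein, summary = summary,
                 roc = curves$roc, pr = curves$pr, score_col = score_col),
            class = "ispip_evaluation")
}

#' @export
print.ispip_evaluation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<ispip_evaluation> '%s': %d proteins | mean F = %.3f, mean MCC = %.3f",
    x$score_col, s$n_proteins, s$f_score, s$mcc))
  if (!is.null(x$roc)) {
    cat(sprintf(" | pooled ROC-AUC = %.3f, PR-AUC = %.3f",
                attr(x$roc, "auc"), attr(x$pr, "auc")))
  }
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Per-protein metric rows of an evaluation
#' @param x `ispip_evaluation` object.
#' @param ... unused.
#' @return tibble of per-protein metrics.
#' @export
tidy.ispip_evaluation <- function(x, ...) x$per_protein

#' One-row evaluation summary
#' @param x `ispip_evaluation` object.
#' @param ... unused.
#' @return one-row tibble with mean metrics and pooled AUCs.
#' @export
glance.ispip_evaluation <- function(x, ...) {
  out <- x$summary
  out$roc_auc <- if (!is.null(x$roc)) attr(x$roc, "auc") else NA_real_
  out$pr_auc <- if (!is.null(x$pr)) attr(x$pr, "auc") else NA_real_
  out
}

#' Coefficient tibbles for the regression models
#' @param x fitted `ispip_linear` or `ispip_logistic` model.
#' @param ... unused.
#' @return tibble with `term` and `estimate`.
#' @export
tidy.ispip_model <- function(x, ...) {
  if (!is.null(x$coefficients)) {
    return(tibble(term = names(x$coefficients),
                  estimate = unname(x$coefficients)))
  }
  if (inherits(x, "ispip_forest")) {
    return(tibble(term = c("trees", "max_depth", "alpha"),
                  estimate = c(x$trees, x$max_depth, x$alpha)))
  }
  tibble(term = c("learning_rate", "iterations", "max_depth"),
         estimate = c(x$learning_rate, x$iterations, x$max_depth))
}
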