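new_curve <- function(df, kind, auc) {
  structure(df, class = c("ispip_curve", class(df)), kind = kind, auc = auc)
}

#' ROC and precision-recall curves with trapezoidal AUC
#'
#' Sweeps the decision threshold over every distinct score value from
#' high to low and records, at each threshold, the true/false positive
#' rates (ROC) and precision/recall (PR). Both AUCs are trapezoidal
#' integrals of the stored points; with this construction the ROC-AUC
#' equals the Mann-Whitney rank statistic `U / (n_pos * n_neg)` (ties
#' counted half), the standard probabilistic reading of the ROC area.
#' The PR curve is prepended with `(recall = 0, precision = first-point
#' precision)`; no further interpolation is applied.
#'
#' @param scores per-residue likelihoods (pooled across proteins).
#' @param labels 0/1 ground truth of the same length.
#' @return list with elements `roc` and `pr`, each a tibble of
#'   (`x`, `y`, `threshold`) points carrying attributes `"kind"` and
#'   `"auc"`.
#' @export
roc_pr_curves <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("length mismatch")
  stopifnot_binary(labels, "labels")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present to build curves")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tps <- cumsum(y == 1L)
  fps <- cumsum(y == 0L)
  # one curve point per distinct threshold (last index of each tie run)
  last <- c(which(diff(s) != 0), length(s))
  thr <- s[last]
  tpr <- tps[last] / n_pos
  fpr <- fps[last] / n_neg
  precision <- tps[last] / (tps[last] + fps[last])

  roc <- tibble(x = c(0, fpr), y = c(0, tpr),
                threshold = c(Inf, thr))
  pr <- tibble(x = c(0, tpr), y = c(precision[1], precision),
               threshold = c(Inf, thr))
  list(
    roc = new_curve(roc, "ROC", trapezoid_auc(roc$x, roc$y)),
    pr = new_curve(pr, "PR", trapezoid_auc(pr$x, pr$y))
  )
}

#' Trapezoidal area under an ordered curve
#'
#' @param x,y curve coordinates with `x` non-decreasing.
#' @return the trapezoidal integral of `y` over `x`.
#' @export
trapezoid_auc <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Area under a stored curve
#' @param curve an `ispip_curve`.
#' @return the curve's trapezoidal AUC.
#' @export
curve_auc <- function(curve) attr(curve, "auc")

#' Per-protein threshold-free AUCs
#'
#' Complements the pooled curves of [roc_pr_curves()]: each protein with
#' both classes present gets its own ROC-AUC and PR-AUC, suitable for
#' macro-averaging.
#'
#' @param table labelled score tibble with `protein_id`.
#' @param score_col prediction column to evaluate.
#' @return tibble (`protein_id`, `roc_auc`, `pr_auc`); proteins with a
#'   single class carry `NA`.
#' @export
per_protein_auc <- function(table, score_col) {
  table |>
    group_by(.data$protein_id) |>
    group_modify(function(d, key) {
      if (length(unique(d$label)) < 2) {
        return(tibble(roc_auc = NA_real_, pr_auc = NA_real_))
      }
      cv <- roc_pr_curves(d[[score_col]], d$label)
      tibble(roc_auc = curve_auc(cv$roc), pr_auc = curve_auc(cv$pr))
    }) |>
    ungroup()
}

#' Paired bootstrap test for an AUC difference
#'
#' Compares the pooled ROC-AUC of two score columns on the same residues
#' by resampling proteins with replacement (residues of a protein stay
#' together, respecting the grouped structure of the data). The p-value
#' is the two-sided bootstrap sign-reversal fraction of the resampled
#' AUC difference.
#'
#' @param table labelled score tibble with `protein_id` and both score
#'   columns.
#' @param score_a,score_b names of the two prediction columns.
#' @param reps bootstrap replicates (at least 100).
#' @param seed RNG seed; the test is deterministic given the seed.
#' @return one-row tibble with `auc_a`, `auc_b`, `delta_auc`, `p_value`,
#'   `reps`.
#' @export
auc_difference_test <- function(table, score_a, score_b, reps = 1000,
                                seed = 0) {
  if (reps < 100) abort("`reps` must be at least 100")
  check_labelled(table, both_classes = TRUE)
  pooled_auc <- function(d, col) {
    curve_auc(roc_pr_curves(d[[col]], d$label)$roc)
  }
  auc_a <- pooled_auc(table, score_a)
  auc_b <- pooled_auc(table, score_b)
  delta <- auc_a - auc_b

  groups <- split(seq_len(nrow(table)), table$protein_id)
  boot <- with_substream(seed, "auc_boot", {
    purrr::map_dbl(seq_len(reps), function(r) {
      idx <- unlist(groups[sample.int(length(groups), replace = TRUE)],
                    use.names = FALSE)
      d <- table[idx, ]
      if (length(unique(d$label)) < 2) return(NA_real_)
      pooled_auc(d, score_a) - pooled_auc(d, score_b)
    })
  })
  boot <- boot[!is.na(boot)]
  p <- min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))
  tibble(auc_a = auc_a, auc_b = auc_b, delta_auc = delta,
         p_value = p, reps = reps)
}
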