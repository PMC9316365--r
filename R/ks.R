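#' One-sample Kolmogorov-Smirnov normality test
#'
#' `D = sup |ECDF(x) - Phi((x - mean)/sd)|` against a reference normal.
#' With `mean`/`sd` supplied the classical KS distribution applies; when
#' they are estimated from the sample the classical p-value is
#' conservative (the estimated-parameter caveat), and setting
#' `lilliefors = TRUE` switches to the Lilliefors-corrected test
#' ([nortest::lillie.test()]).
#'
#' @param values numeric sample, n >= 5.
#' @param mean,sd reference normal parameters; `NULL` (default) estimates
#'   them from the sample.
#' @param lilliefors apply the Lilliefors correction for estimated
#'   parameters.
#' @return one-row tibble with `statistic` (D), `p_value`, `method`.
#' @export
ks_one_sample <- function(values, mean = NULL, sd = NULL,
                          lilliefors = FALSE) {
  if (length(values) < 5) abort("need at least 5 values")
  if (stats::sd(values) == 0) abort("sample is constant")
  if (lilliefors) {
    ht <- nortest::lillie.test(values)
    return(tibble(statistic = unname(ht$statistic),
                  p_value = ht$p.value, method = "lilliefors"))
  }
  m <- mean %||% base::mean(values)
  s <- sd %||% stats::sd(values)
  ht <- suppressWarnings(stats::ks.test(values, "pnorm", m, s))
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = if (is.null(mean) || is.null(sd)) {
           "ks_estimated_params"
         } else {
           "ks_reference"
         })
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic two-sided p-value;
#' the distribution-free comparison used to decide whether two
#' per-protein F-score distributions differ.
#'
#' @param a,b numeric samples, each n >= 3.
#' @return one-row tibble with `statistic` (D), `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) abort("each sample needs >= 3 values")
  ht <- suppressWarnings(stats::ks.test(a, b))
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value)
}
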