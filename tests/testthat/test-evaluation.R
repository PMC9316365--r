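test_that("dynamic cutoff follows N = 6.1 R^0.3 with half-up rounding", {
  expect_identical(dynamic_cutoff(1), 6L)    # 6.1 -> 6
  expect_identical(dynamic_cutoff(100), 24L) # 24.28 -> 24
  # against a direct high-precision evaluation for R = 1..1000
  R <- 1:1000
  expected <- as.integer(pmax(1, floor(6.1 * exp(0.3 * log(R)) + 0.5)))
  expect_identical(dynamic_cutoff(R), expected)
  expect_true(all(diff(dynamic_cutoff(R)) >= 0))
  # rounding conventions differ where they should
  expect_identical(dynamic_cutoff(1, rounding = "floor"), 6L)
  expect_identical(dynamic_cutoff(1, rounding = "ceiling"), 7L)
  expect_error(dynamic_cutoff(0), "positive")
})

test_that("top-N classification calls exactly N residues with stable ties", {
  s <- c(0.9, 0.5, 0.5, 0.1)
  expect_equal(classify_top_n(s, 2), c(1L, 1L, 0L, 0L))  # first 0.5 wins
  expect_equal(classify_top_n(s, 0), rep(0L, 4))
  expect_equal(classify_top_n(s, 10), rep(1L, 4))
  expect_error(classify_top_n(s, -1), "non-negative")
  # TP + FP always equals min(N, n)
  for (i in 1:20) {
    set.seed(i)
    n <- sample(5:60, 1)
    sc <- round(runif(n), 1)  # force ties
    lab <- rbinom(n, 1, 0.3)
    N <- sample(0:(n + 5), 1)
    cts <- confusion(classify_top_n(sc, N), lab)
    expect_equal(cts$TP + cts$FP, min(N, n))
  }
})

test_that("confusion counts equal the exhaustive tally", {
  expect_equal(unlist(confusion(rep(c(1L, 0L), c(5, 15)),
                                rep(c(1L, 0L), c(5, 15)))),
               c(TP = 5L, FP = 0L, FN = 0L, TN = 15L))
  lab <- rep(c(1L, 0L), c(5, 15))
  expect_equal(unlist(confusion(1L - lab, lab))[c("TP", "TN")],
               c(TP = 0L, TN = 0L))
  for (i in 1:10) {
    set.seed(i)
    calls <- rbinom(50, 1, 0.4); labs <- rbinom(50, 1, 0.2)
    expect_equal(unlist(confusion(calls, labs)),
                 oracle_confusion(calls, labs))
  }
  expect_error(confusion(c(0L, 2L), c(0L, 1L)), "0/1")
})

test_that("metrics match their defining formulas and conventions", {
  perfect <- compute_metrics(tibble::tibble(TP = 10, FP = 0, FN = 0, TN = 90))
  expect_equal(unlist(perfect[, c("precision", "recall", "f_score", "mcc")]),
               c(precision = 1, recall = 1, f_score = 1, mcc = 1))

  m <- compute_metrics(tibble::tibble(TP = 3, FP = 1, FN = 2, TN = 4))
  o <- oracle_metrics(3, 1, 2, 4)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f_score, o[["f_score"]])
  expect_equal(m$mcc, o[["mcc"]])
  expect_equal(m$mcc, 10 / sqrt(600))

  deg <- compute_metrics(tibble::tibble(TP = 0, FP = 0, FN = 3, TN = 7))
  expect_true(deg$degenerate)
  expect_equal(c(deg$precision, deg$f_score, deg$mcc), c(0, 0, 0))
  expect_error(compute_metrics(tibble::tibble(TP = -1, FP = 0, FN = 0,
                                              TN = 0)), "non-negative")
})

test_that("MCC is invariant under class+call swap; F is not", {
  set.seed(5)
  calls <- rbinom(200, 1, 0.3); labs <- rbinom(200, 1, 0.2)
  a <- compute_metrics(confusion(calls, labs))
  b <- compute_metrics(confusion(1L - calls, 1L - labs))
  expect_equal(a$mcc, b$mcc)
  expect_false(isTRUE(all.equal(a$f_score, b$f_score)))
})

test_that("pooled ROC-AUC equals the Mann-Whitney statistic", {
  # exhaustive pair comparison on a small toy case
  s8 <- c(0.9, 0.8, 0.8, 0.6, 0.5, 0.4, 0.2, 0.1)
  l8 <- c(1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L)
  cv <- roc_pr_curves(s8, l8)
  expect_equal(curve_auc(cv$roc), oracle_auc_pairs(s8, l8))

  for (i in 1:20) {
    set.seed(i)
    n <- sample(50:2000, 1)
    sc <- round(runif(n), sample(1:3, 1))  # heavy ties
    lab <- rbinom(n, 1, runif(1, 0.05, 0.5))
    if (length(unique(lab)) < 2) next
    expect_equal(curve_auc(roc_pr_curves(sc, lab)$roc),
                 oracle_auc_mw(sc, lab), tolerance = 1e-12)
  }
})

test_that("curve endpoints and degenerate inputs behave as specified", {
  sep <- c(0.9, 0.8, 0.2, 0.1)
  lab <- c(1L, 1L, 0L, 0L)
  cv <- roc_pr_curves(sep, lab)
  expect_equal(curve_auc(cv$roc), 1)
  expect_equal(curve_auc(cv$pr), 1)
  expect_equal(cv$roc$x[1], 0)
  expect_equal(cv$roc$y[1], 0)
  expect_equal(utils::tail(cv$roc$x, 1), 1)
  expect_equal(utils::tail(cv$roc$y, 1), 1)
  # PR curve starts at recall 0 with the first point's precision
  expect_equal(cv$pr$x[1], 0)
  expect_equal(cv$pr$y[1], cv$pr$y[2])
  expect_error(roc_pr_curves(sep, c(1L, 1L, 1L, 1L)), "both classes")

  # no-skill scores: ROC-AUC near 0.5, PR-AUC near prevalence
  roc0 <- pr0 <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    sc <- runif(1e4); lab <- rbinom(1e4, 1, 0.2)
    cv0 <- roc_pr_curves(sc, lab)
    roc0[s] <- curve_auc(cv0$roc); pr0[s] <- curve_auc(cv0$pr)
  }
  expect_lt(abs(mean(roc0) - 0.5), 0.02)
  expect_lt(abs(mean(pr0) - 0.2), 0.03)
})

test_that("one-sample KS is calibrated and detects gross misfit", {
  rejections <- sapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(1000, mean = 2, sd = 3)
    ks_one_sample(x, mean = 2, sd = 3)$p_value < 0.05
  })
  expect_lte(mean(rejections), 0.10)

  set.seed(1)
  two_point <- sample(c(0, 1), 200, replace = TRUE)
  expect_lt(ks_one_sample(two_point)$p_value, 0.001)

  set.seed(2)
  d <- replicate(20, ks_one_sample(rnorm(50))$statistic)
  expect_true(all(d >= 0 & d <= 1))
  expect_error(ks_one_sample(rep(1, 10)), "constant")
  expect_error(ks_one_sample(c(1, 2)), "at least 5")
  # Lilliefors flag routes to the corrected test
  set.seed(3)
  expect_equal(ks_one_sample(rnorm(100), lilliefors = TRUE)$method,
               "lilliefors")
})

test_that("two-sample KS D equals the brute-force ECDF sup", {
  same <- c(1, 2, 3, 4)
  r <- ks_two_sample(same, same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)
  for (i in 1:10) {
    set.seed(i)
    a <- round(rnorm(sample(3:20, 1)), 1)
    b <- round(rnorm(sample(3:20, 1), 0.5), 1)
    expect_equal(ks_two_sample(a, b)$statistic, oracle_ks_d(a, b))
  }
  expect_error(ks_two_sample(numeric(0), 1:5), ">= 3")
})

test_that("bootstrap AUC difference test is sane and deterministic", {
  tab <- simulate_scores(30, len_range = c(40, 80), seed = 12)
  tab$perfect <- tab$label + 0.0
  set.seed(99)
  tab$random <- runif(nrow(tab))

  r_same <- auc_difference_test(tab, "template_based", "template_based",
                                reps = 200, seed = 1)
  expect_equal(r_same$delta_auc, 0)
  expect_gte(r_same$p_value, 0.99)

  r <- auc_difference_test(tab, "perfect", "random", reps = 200, seed = 1)
  expect_lt(r$p_value, 0.01)
  cv <- roc_pr_curves(tab$perfect, tab$label)
  cv2 <- roc_pr_curves(tab$random, tab$label)
  expect_equal(r$delta_auc, curve_auc(cv$roc) - curve_auc(cv2$roc))

  r2 <- auc_difference_test(tab, "perfect", "random", reps = 200, seed = 1)
  expect_identical(r, r2)
  expect_error(auc_difference_test(tab, "perfect", "random", reps = 50),
               "at least 100")
})

test_that("protein-level evaluation applies the dynamic cutoff and averages", {
  # one perfect protein -> all metrics 1 (N chosen to match positives)
  one <- tibble::tibble(protein_id = "p1", chain = "A", resno = 1:50,
                        icode = "", label = rep(c(1L, 0L), c(6, 44)),
                        pred = rep(c(0.9, 0.1), c(6, 44)), R = 1L)
  # R = 1 -> N = 6 = exact number of interfacial residues
  ev <- evaluate_predictions(one, "pred")
  expect_equal(ev$per_protein$N, 6L)
  expect_equal(ev$summary$f_score, 1)
  expect_equal(ev$summary$mcc, 1)

  # averages over proteins are unweighted elementwise means
  two <- dplyr::bind_rows(
    one,
    tibble::tibble(protein_id = "p2", chain = "A", resno = 1:30,
                   icode = "", label = rep(c(1L, 0L), c(6, 24)),
                   pred = c(rep(0.9, 3), rep(0.1, 27)), R = 1L))
  ev2 <- evaluate_predictions(two, "pred")
  expect_equal(ev2$summary$f_score,
               mean(ev2$per_protein$f_score))
  expect_equal(nrow(tidy(ev2)), 2)
  g <- glance(ev2)
  expect_true(all(c("roc_auc", "pr_auc") %in% names(g)))

  expect_error(evaluate_predictions(dplyr::select(one, -R), "pred"),
               "surface count")
  # fixed-N mode
  ev3 <- evaluate_predictions(one, "pred", cutoff = 3L)
  expect_equal(ev3$per_protein$TP + ev3$per_protein$FP, 3)

  # per-protein AUCs complement the pooled curves
  pp <- per_protein_auc(two, "pred")
  expect_equal(nrow(pp), 2)
  expect_equal(pp$roc_auc[1], 1)
})
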