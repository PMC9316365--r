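sim_small <- function(n = 30, seed = 1, ...) {
  simulate_scores(n, len_range = c(40, 80), seed = seed, ...)
}

test_that("score normalization modes behave as documented", {
  tab <- tibble::tibble(protein_id = rep(c("p1", "p2"), each = 3),
                        chain = "A", resno = rep(1:3, 2), icode = "",
                        s1 = c(0.1, 0.5, 0.9, 0.2, 0.4, 0.6),
                        s2 = c(2, 4, 6, 1, 1, 1),
                        label = rep(c(0L, 1L), 3))
  # identity when already in range
  expect_equal(normalize_scores(tab, "s1", mode = "none")$s1, tab$s1)
  expect_error(normalize_scores(tab, "s2", mode = "none"), "outside")
  # affine rescale
  expect_equal(normalize_scores(tab, "s2", mode = "minmax_global")$s2,
               c(1, 3, 5, 0, 0, 0) / 5)
  # constant column convention within protein p2
  per <- normalize_scores(tab, "s2", mode = "minmax_per_protein")
  expect_equal(per$s2, c(0, 0.5, 1, 0.5, 0.5, 0.5))
  # missing-score contract
  tab$s1[2] <- NA
  expect_error(normalize_scores(tab, "s1"), "row 2")
})

test_that("linear fit is exact on perfect and degenerate designs", {
  tab <- tibble::tibble(protein_id = "p", chain = "A", resno = 1:8,
                        icode = "", s1 = c(0, 1, 0, 1, 0, 1, 0, 1),
                        label = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L))
  # label equals the predictor exactly -> b0 = 0, b1 = 1
  m <- fit_linear(tab, "s1")
  expect_equal(unname(m$coefficients), c(0, 1), tolerance = 1e-10)

  allzero <- tab
  allzero$label <- 0L
  expect_warning(m0 <- fit_linear(allzero, "s1"), "intercept-only")
  expect_equal(unname(m0$coefficients), c(0, 0))
})

test_that("linear fit matches the closed-form normal equations", {
  set.seed(42)
  n <- 1e4
  x <- matrix(runif(3 * n), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(0.05, 0.2, 0.3, 0.35)
  y <- as.integer(runif(n) < cbind(1, x) %*% beta)
  tab <- tibble::as_tibble(as.data.frame(x))
  tab$protein_id <- "p"; tab$label <- y
  m <- fit_linear(tab, c("a", "b", "c"))
  # independent oracle: solve the normal equations directly
  xf <- cbind(1, x)
  beta_ne <- solve(t(xf) %*% xf, t(xf) %*% y)
  expect_equal(unname(m$coefficients), unname(drop(beta_ne)),
               tolerance = 1e-8)
  # and the generating coefficients are recovered to first order
  expect_true(all(abs(unname(m$coefficients) - beta) < 0.05))
})

test_that("logistic fit recovers generating coefficients", {
  set.seed(7)
  n <- 2e4
  b <- c(-2, 1.3, 2.8, 1.4)
  x <- matrix(runif(3 * n), ncol = 3,
              dimnames = list(NULL, c("x1", "x2", "x3")))
  p <- plogis(drop(cbind(1, x) %*% b))
  tab <- tibble::as_tibble(as.data.frame(x))
  tab$protein_id <- "p"
  tab$label <- rbinom(n, 1, p)
  m <- fit_logistic(tab, c("x1", "x2", "x3"))
  expect_true(all(abs(unname(m$coefficients) - b) < 0.15))
})

test_that("logistic fit handles no-signal and separated data", {
  set.seed(3)
  n <- 5e3
  tab <- tibble::tibble(protein_id = "p", chain = "A", resno = 1:n,
                        icode = "", s1 = runif(n),
                        label = rbinom(n, 1, 0.3))
  m <- fit_logistic(tab, "s1")
  expect_lt(abs(m$coefficients[["s1"]]), 0.2)
  expect_equal(m$coefficients[["(Intercept)"]], qlogis(0.3),
               tolerance = 0.15)

  # perfect separation: finite coefficients, ordering preserved
  sep <- tibble::tibble(protein_id = "p", chain = "A", resno = 1:40,
                        icode = "", s1 = c(runif(20, 0, 0.4),
                                           runif(20, 0.6, 1)),
                        label = rep(c(0L, 1L), each = 20))
  ms <- fit_logistic(sep, "s1")
  expect_true(all(is.finite(ms$coefficients)))
  pr <- predict(ms, sep)
  expect_true(all(pr[sep$label == 1] > max(pr[sep$label == 0])))

  sep$label <- 1L
  expect_error(fit_logistic(sep, "s1"), "single-class")
})

test_that("published coefficient fixtures evaluate as expected", {
  logm <- logistic_model(0, c(predus = 1.28, ispred = 2.821,
                              dockpred = 1.424))
  at <- function(v) tibble::tibble(predus = v[1], ispred = v[2],
                                   dockpred = v[3])
  expect_equal(predict(logm, at(c(0, 0, 0))), 0.5)
  expect_equal(predict(logm, at(c(1, 1, 1))), 1 / (1 + exp(-5.525)),
               tolerance = 1e-12)
  expect_equal(predict(logm, at(c(1, 1, 1))), 0.9960, tolerance = 1e-4)

  linm <- linear_model(0, c(predus = 0.196, ispred = 0.313,
                            dockpred = 0.313))
  expect_equal(predict(linm, at(c(1, 1, 1))), 0.822)
  # linear predictions are clipped to [0, 1]
  big <- linear_model(0, c(predus = 2, ispred = 2, dockpred = 2))
  expect_equal(predict(big, at(c(1, 1, 1))), 1)
  expect_equal(predict(linear_model(-1, c(predus = 0.1, ispred = 0.1,
                                          dockpred = 0.1)),
                       at(c(0, 0, 0))), 0)

  expect_error(predict(logm, tibble::tibble(predus = 1)), "dockpred")
})

test_that("forest behaves like averaged probability trees", {
  # single stump on a perfectly splitting predictor
  tab <- tibble::tibble(protein_id = "p", chain = "A", resno = 1:100,
                        icode = "",
                        s1 = rep(c(0.2, 0.8), each = 50),
                        label = rep(c(0L, 1L), each = 50))
  m <- fit_forest(tab, "s1", trees = 1, max_depth = 1, seed = 5)
  p <- predict(m, tab)
  # leaf fractions on each side of the split (bootstrap keeps purity)
  expect_true(all(p[tab$s1 < 0.5] < 0.5))
  expect_true(all(p[tab$s1 > 0.5] > 0.5))
  expect_equal(length(unique(p)), 2)

  expect_error(fit_forest(tab, "s1", trees = 0), ">= 1")
  expect_error(fit_forest(tab, "s1", alpha = -1), ">= 0")

  # duplicated feature column leaves predictions essentially unchanged
  tab2 <- sim_small(10, seed = 9)
  tab2dup <- tab2
  tab2dup$dup <- tab2dup$template_based
  m1 <- fit_forest(tab2, c("template_based", "template_free", "docking"),
                   trees = 30, seed = 1)
  m2 <- fit_forest(tab2dup, c("template_based", "dup", "template_free",
                              "docking"), trees = 30, seed = 1)
  expect_equal(cor(predict(m1, tab2), predict(m2, tab2dup)), 1,
               tolerance = 0.02)
})

test_that("forest on pure-noise features scores near class prevalence", {
  aucs <- sapply(1:10, function(s) {
    set.seed(100 + s)
    n <- 1500
    tab <- tibble::tibble(protein_id = "p", chain = "A", resno = 1:n,
                          icode = "", s1 = runif(n), s2 = runif(n),
                          label = rbinom(n, 1, 0.15))
    split <- rep(c(TRUE, FALSE), length.out = n)
    m <- fit_forest(tab[split, ], c("s1", "s2"), trees = 30, seed = s)
    te <- tab[!split, ]
    curve_auc(roc_pr_curves(predict(m, te), te$label)$pr)
  })
  expect_lt(abs(mean(aucs) - 0.15), 0.05)
})

test_that("boosting contracts: base rate at 0 iterations, non-increasing loss", {
  tab <- sim_small(8, seed = 4)
  m0 <- fit_boosted(tab, iterations = 0)
  expect_equal(unique(predict(m0, tab)), mean(tab$label))

  # step-function relationship: training log-loss non-increasing in rounds
  set.seed(2)
  n <- 2000
  step <- tibble::tibble(protein_id = "p", chain = "A", resno = 1:n,
                         icode = "", s1 = runif(n))
  step$label <- rbinom(n, 1, ifelse(step$s1 > 0.6, 0.9, 0.1))
  logloss <- function(p, y) -mean(y * log(p) + (1 - y) * log(1 - p))
  losses <- sapply(c(1, 5, 20, 80), function(k) {
    m <- fit_boosted(step, "s1", iterations = k, seed = 0)
    logloss(pmin(pmax(predict(m, step), 1e-12), 1 - 1e-12), step$label)
  })
  expect_true(all(diff(losses) <= 1e-8))
})

test_that("boosted trees capture interactions that defeat the linear model", {
  gains <- sapply(1:5, function(s) {
    tab <- make_interaction_table(5e3, seed = 200 + s)
    half <- rep(c(TRUE, FALSE), length.out = nrow(tab))
    tr <- tab[half, ]; te <- tab[!half, ]
    mb <- fit_boosted(tr, c("f1", "f2"), iterations = 100, max_depth = 3,
                      seed = s)
    ml <- fit_linear(tr, c("f1", "f2"))
    pr_b <- curve_auc(roc_pr_curves(predict(mb, te), te$label)$pr)
    pr_l <- curve_auc(roc_pr_curves(predict(ml, te), te$label)$pr)
    pr_b - pr_l
  })
  expect_true(all(gains >= 0.1))
})

test_that("all four families predict inside [0, 1] and logistic is monotone", {
  tab <- sim_small(12, seed = 6)
  preds <- c("template_based", "template_free", "docking")
  models <- list(fit_linear(tab, preds), fit_logistic(tab, preds),
                 fit_forest(tab, preds, trees = 20, seed = 1),
                 fit_boosted(tab, preds, iterations = 30, seed = 1))
  for (m in models) {
    p <- predict(m, tab)
    expect_true(all(p >= 0 & p <= 1))
  }
  # logistic prediction strictly increases in a predictor with b_j > 0
  logm <- models[[2]]
  stopifnot(logm$coefficients[["template_based"]] > 0)
  grid <- tibble::tibble(template_based = seq(0, 1, 0.1),
                         template_free = 0.5, docking = 0.5)
  expect_true(all(diff(predict(logm, grid)) > 0))
})

test_that("fits are deterministic given the seed", {
  tab <- sim_small(10, seed = 3)
  f1 <- predict(fit_forest(tab, trees = 15, seed = 7), tab)
  f2 <- predict(fit_forest(tab, trees = 15, seed = 7), tab)
  expect_identical(f1, f2)
  b1 <- predict(fit_boosted(tab, iterations = 20, seed = 7), tab)
  b2 <- predict(fit_boosted(tab, iterations = 20, seed = 7), tab)
  expect_identical(b1, b2)
})
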