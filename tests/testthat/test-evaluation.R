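# TNR-TPR analysis, enrichment, consensus.

test_that("curve endpoints and perfect/inverted integrals", {
  cv <- tnr_tpr_curve(c(4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cv$tpr[1], 0)
  expect_equal(cv$tnr[1], 1)
  expect_equal(max(cv$tpr), 1)
  expect_equal(curve_integral(cv), 1)
  inv <- tnr_tpr_curve(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(curve_integral(inv), 0)
  expect_error(tnr_tpr_curve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  # TPR is non-decreasing along the sweep
  sc <- qsarvs:::qv_with_seed(3, runif(50))
  lb <- qsarvs:::qv_with_seed(4, runif(50) < 0.3)
  cv <- tnr_tpr_curve(sc, lb)
  expect_true(all(diff(cv$tpr) >= 0))
})

test_that("random scores give an integral near one half", {
  v <- qsarvs:::qv_with_seed(7, list(s = runif(20000), l = runif(20000) < 0.01))
  expect_equal(curve_integral(tnr_tpr_curve(v$s, v$l)), 0.5, tolerance = 0.05)
})

test_that("partial integral matches closed forms and is monotone in tpr_max", {
  perfect <- tnr_tpr_curve(c(4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(integral_to_cutoff(perfect, 0.25), 0.25)
  # diagonal TNR = 1 - TPR: integral to 0.25 is 0.21875
  diag_curve <- structure(list(tpr = c(0, 1), tnr = c(1, 0), thresholds = c(NA, 0),
                               P = 1, N = 1), class = "tnr_tpr_curve")
  expect_equal(integral_to_cutoff(diag_curve, 0.25), 0.21875)
  expect_equal(integral_to_cutoff(diag_curve, 1), 0.5)
  v <- qsarvs:::qv_with_seed(8, list(s = runif(500), l = runif(500) < 0.2))
  cv <- tnr_tpr_curve(v$s, v$l)
  ints <- vapply(seq(0.05, 1, 0.05), integral_to_cutoff, numeric(1),
                 curve = cv)
  expect_true(all(diff(ints) >= -1e-12))
  expect_equal(ints[length(ints)], curve_integral(cv))
})

test_that("full integral equals an independent concordance computation", {
  skip_if_not_installed("pROC")
  for (seed in 1:5) {
    v <- qsarvs:::qv_with_seed(seed + 20, {
      s <- round(runif(300), 2)  # ties included
      l <- runif(300) < 0.15
      list(s = s, l = l)
    })
    ours <- curve_integral(tnr_tpr_curve(v$s, v$l))
    ref <- as.numeric(pROC::auc(pROC::roc(v$l, v$s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("enrichment follows its defining arithmetic", {
  # 10 actives / 90 inactives; reaching TPR 0.9 requires taking the top 10
  # ranked compounds, of which one is inactive
  scores <- c(seq(1, 0.91, by = -0.01), seq(0.5, 0.5 - 0.89 * 0.001, length.out = 90))
  labels <- c(rep(TRUE, 8), FALSE, TRUE, TRUE, rep(FALSE, 89))
  en <- enrichment(scores, labels, tpr_target = 0.9)
  expect_equal(unname(en$confusion["TP"]), 9)
  expect_equal(unname(en$confusion["FP"]), 1)
  expect_equal(en$enrichment, (9 / 10) / (10 / 100))
  # perfect classifier: ENR = 1 / base fraction
  sc <- c(rep(1, 5), rep(0, 45))
  lb <- rep(c(TRUE, FALSE), c(5, 45))
  expect_equal(enrichment(sc, lb, 0.25)$enrichment, 10)
  # random scores: ENR near 1
  v <- qsarvs:::qv_with_seed(9, list(s = runif(20000), l = runif(20000) < 0.05))
  expect_equal(enrichment(v$s, v$l, 0.25)$enrichment, 1, tolerance = 0.25)
})

test_that("enrichment never exceeds its theoretical maximum", {
  for (seed in 1:10) {
    v <- qsarvs:::qv_with_seed(seed + 40, {
      n <- 200
      l <- runif(n) < 0.1
      if (!any(l)) l[1] <- TRUE
      if (all(l)) l[1] <- FALSE
      s <- runif(n) + ifelse(l, runif(1), 0)
      list(s = s, l = l)
    })
    en <- enrichment(v$s, v$l, 0.25)
    expect_lte(en$enrichment, length(v$l) / sum(v$l) + 1e-9)
    expect_gte(en$enrichment, 0)
  }
})

test_that("consensus prediction averages and respects fingerprints", {
  d <- separable_set(n = 100, seed = 16)
  m1 <- qsar_train(d$x, d$y, "dt")
  m2 <- qsar_train(d$x, d$y, "svr")
  cons <- consensus_predict(list(m1, m2), d$x)
  expect_equal(cons, (predict(m1, d$x) + predict(m2, d$x)) / 2)
  # identical models: consensus is the single model exactly
  expect_equal(consensus_predict(list(m1, m1, m1), d$x), predict(m1, d$x))
  expect_equal(consensus_predict(list(m1), d$x), predict(m1, d$x))
  # permutation invariance over models
  m3 <- qsar_train(d$x, d$y, "kn",
                   spec = model_spec("kn", rows = 2L, cols = 2L,
                                     epochs = 10L, seed = 2))
  expect_equal(consensus_predict(list(m1, m2, m3), d$x),
               consensus_predict(list(m3, m1, m2), d$x))
  # fingerprint mismatch refuses to predict
  x2 <- d$x; colnames(x2) <- c("other", "names")
  m4 <- qsar_train(x2, d$y, "dt")
  expect_error(consensus_predict(list(m1, m4), d$x), "fingerprint")
})

test_that("consensus ranking enumerates subsets and normalises Diff", {
  d <- separable_set(n = 200, seed = 17)
  tr <- 1:120; ind <- 121:200
  models <- list(
    ann = list(qsar_train(d$x[tr, ], d$y[tr], "ann", seed = 1,
                          spec = model_spec("ann", epochs = 50L, seed = 1))),
    svr = list(qsar_train(d$x[tr, ], d$y[tr], "svr", seed = 1)),
    dt = list(qsar_train(d$x[tr, ], d$y[tr], "dt", seed = 1)),
    kn = list(qsar_train(d$x[tr, ], d$y[tr], "kn",
                         spec = model_spec("kn", rows = 3L, cols = 3L,
                                           epochs = 20L, seed = 1))))
  rk <- consensus_ranking(models, d$x[ind, ], d$active[ind])
  expect_equal(nrow(rk$table), 15)
  expect_equal(rk$table$rank, 1:15)
  expect_true(all(diff(rk$table$ENR) <= 1e-12))
  expect_equal(rk$diff,
               100 * (rk$best_consensus$ENR - rk$best_single$ENR) / rk$ratio)

  # identical predictors in every slot: all subsets tie, Diff = 0
  base <- models$dt[[1]]
  same <- list(a = list(base), b = list(base), c = list(base))
  rk0 <- consensus_ranking(same, d$x[ind, ], d$active[ind])
  expect_equal(length(unique(round(rk0$table$ENR, 9))), 1)
  expect_equal(rk0$diff, 0)
  # parsimony tie-break: fewer methods rank first on equal ENR
  expect_equal(rk0$table$n_methods[1], 1)
})

test_that("Diff arithmetic matches the benchmark-scale example", {
  # ENR_consensus 40 vs best single 39 at ratio 948: Diff ~ 0.11%
  expect_equal(round(100 * (40 - 39) / 948, 2), 0.11)
})
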