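# The four learner types and the cross-validated training layer.

test_that("model specs carry the documented defaults", {
  svr <- model_spec("svr")
  expect_equal(svr$C, 1)
  expect_equal(svr$gamma, 0.1)
  expect_gt(svr$epsilon, 0)
  ann <- model_spec("ann")
  expect_gt(ann$eta, 0)
  expect_gt(ann$alpha, 0)
  expect_error(model_spec("ann", bogus = 1), "unknown")
})

test_that("ANN separates a wide-margin fixture within 200 epochs", {
  d <- separable_set(n = 500, seed = 5)
  tr <- 1:300; mo <- 301:400; ind <- 401:500
  bal <- tr[oversample_actives(d$active[tr])]
  m <- qsar_train(d$x[bal, ], d$y[bal], "ann", d$x[mo, ], d$y[mo],
                  spec = model_spec("ann", epochs = 200L, seed = 7))
  int <- curve_integral(tnr_tpr_curve(predict(m, d$x[ind, ]), d$active[ind]))
  expect_gte(int, 0.95)
  # monitoring log was kept and the returned model is the best checkpoint
  log <- m$training_log
  expect_true(nrow(log) >= 1)
  expect_equal(m$fit$best_monitor, max(log$monitor_objective, na.rm = TRUE))
})

test_that("ANN with zero epochs returns a finite-prediction initial model", {
  d <- separable_set(n = 60, seed = 6)
  m <- qsar_train(d$x, d$y, "ann",
                  spec = model_spec("ann", epochs = 0L, seed = 1))
  p <- predict(m, d$x)
  expect_true(all(is.finite(p)))
})

test_that("training is bit-reproducible under a fixed seed", {
  d <- separable_set(n = 200, seed = 8)
  args <- list(d$x[1:120, ], d$y[1:120], "ann", d$x[121:160, ], d$y[121:160])
  m1 <- do.call(qsar_train, c(args, list(seed = 42)))
  m2 <- do.call(qsar_train, c(args, list(seed = 42)))
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$fit$w, m2$fit$w)
  kn1 <- qsar_train(d$x, d$y, "kn", seed = 9,
                    spec = model_spec("kn", rows = 3L, cols = 3L,
                                      epochs = 20L, seed = 9))
  kn2 <- qsar_train(d$x, d$y, "kn", seed = 9,
                    spec = model_spec("kn", rows = 3L, cols = 3L,
                                      epochs = 20L, seed = 9))
  expect_identical(kn1$fit$W, kn2$fit$W)
})

test_that("SVR reproduces a flat target and separates the fixture", {
  d <- separable_set(n = 200, seed = 9)
  flat <- qsar_train(d$x, rep(4.2, 200), "svr")
  expect_true(all(abs(predict(flat, d$x) - 4.2) <= 0.1 + 1e-8))
  tr <- 1:150; ind <- 151:200
  bal <- tr[oversample_actives(d$active[tr])]
  m <- qsar_train(d$x[bal, ], d$y[bal], "svr", seed = 2)
  int <- curve_integral(tnr_tpr_curve(predict(m, d$x[ind, ]), d$active[ind]))
  expect_gte(int, 0.95)
  expect_error(qsar_train(matrix(1, 10, 2), rep(3, 10), "svr"),
               "degenerate")
})

test_that("SVR grid search selects by monitoring objective with stated ties", {
  d <- separable_set(n = 300, seed = 10)
  tr <- 1:200; mo <- 201:300
  g1 <- grid_search_svm(d$x[tr, ], d$y[tr], d$x[mo, ], d$y[mo],
                        C_grid = 2, gamma_grid = 0.5)
  expect_equal(g1$spec$C, 2)
  expect_equal(g1$spec$gamma, 0.5)
  gs <- grid_search_svm(d$x[tr, ], d$y[tr], d$x[mo, ], d$y[mo],
                        C_grid = c(0.25, 1, 4), gamma_grid = c(0.1, 1))
  expect_equal(nrow(gs$grid), 6)
  # reported winner achieves the max objective; ties resolved to smallest C
  best_obj <- max(gs$grid$objective)
  winners <- gs$grid[gs$grid$objective == best_obj, ]
  expect_equal(gs$spec$C, min(winners$C))
})

test_that("decision tree leaves score by active fraction on the pIC50 scale", {
  x <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1)
  y <- rep(c(6, 3), c(10, 10))
  m <- qsar_train(x, y, "dt", spec = model_spec("dt", min_leaf = 2L))
  p <- predict(m, x)
  # pure leaves: scores 1 and 0 mapped to p_base + s * p_span
  expect_equal(unique(p[1:10]), 3 + 1 * 4)
  expect_equal(unique(p[11:20]), 3 + 0 * 4)
  # constant features: root-only tree predicting the overall active fraction
  xc <- matrix(1, 20, 1)
  mc <- qsar_train(xc, y, "dt")
  expect_equal(unique(predict(mc, xc)), 3 + 0.5 * 4)
})

test_that("Kohonen map: 1x1 grid predicts the global mean", {
  d <- separable_set(n = 80, seed = 11)
  m <- qsar_train(d$x, d$y, "kn",
                  spec = model_spec("kn", rows = 1L, cols = 1L,
                                    epochs = 5L, seed = 3))
  expect_equal(unique(round(predict(m, d$x), 9)),
               round(mean(d$y), 9))
})

test_that("Kohonen map separates two well-separated clusters on a 2x1 grid", {
  v <- qsarvs:::qv_with_seed(12, {
    x <- rbind(matrix(rnorm(60, 0, 0.05), ncol = 2),
               matrix(rnorm(60, 5, 0.05), ncol = 2))
    list(x = x, y = rep(c(3, 6), each = 30))
  })
  m <- qsar_train(v$x, v$y, "kn",
                  spec = model_spec("kn", rows = 2L, cols = 1L,
                                    epochs = 50L, seed = 4))
  p <- predict(m, v$x)
  expect_equal(unique(p[1:30]), 3)
  expect_equal(unique(p[31:60]), 6)
})

test_that("prediction contracts: width check, batch equality, order invariance", {
  d <- separable_set(n = 100, seed = 13)
  m <- qsar_train(d$x, d$y, "svr")
  expect_error(predict(m, d$x[, 1, drop = FALSE]), "width")
  single <- vapply(1:5, function(i)
    predict(m, d$x[i, , drop = FALSE]), numeric(1))
  batch <- predict(m, d$x[1:5, ])
  expect_equal(batch, single)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(predict(m, d$x[perm, ]), batch[perm])
})

test_that("all four learners beat random on the separable fixture", {
  d <- separable_set(n = 400, seed = 14)
  tr <- 1:240; mo <- 241:320; ind <- 321:400
  bal <- tr[oversample_actives(d$active[tr])]
  ints <- c(
    ann = curve_integral(tnr_tpr_curve(predict(
      qsar_train(d$x[bal, ], d$y[bal], "ann", d$x[mo, ], d$y[mo], seed = 1),
      d$x[ind, ]), d$active[ind])),
    svr = curve_integral(tnr_tpr_curve(predict(
      qsar_train(d$x[bal, ], d$y[bal], "svr", seed = 1),
      d$x[ind, ]), d$active[ind])),
    dt = curve_integral(tnr_tpr_curve(predict(
      qsar_train(d$x[tr, ], d$y[tr], "dt", seed = 1),
      d$x[ind, ]), d$active[ind])),
    kn = curve_integral(tnr_tpr_curve(predict(
      qsar_train(d$x[tr, ], d$y[tr], "kn", seed = 1,
                 spec = model_spec("kn", rows = 4L, cols = 4L,
                                   epochs = 30L, seed = 1)),
      d$x[ind, ]), d$active[ind])))
  expect_true(all(ints > 0.6))
  expect_gte(ints["ann"], 0.95)
  expect_gte(ints["svr"], 0.95)
})

test_that("cross-validated training yields one model per split with roles", {
  n <- 240
  rec <- p_activity_transform(data.frame(
    compound_id = sprintf("c%03d", 1:n),
    is_active = rep(c(TRUE, FALSE), c(40, 200))))
  x <- qsarvs:::qv_with_seed(15, cbind(
    f1 = ifelse(rec$is_active, 1, 0) + rnorm(n, sd = 0.2),
    f2 = rnorm(n)))
  rownames(x) <- rec$compound_id
  ds <- qsar_dataset(x, rec)
  labels <- partition_dataset(rec$compound_id, rec$is_active, 4, seed = 6)
  plan <- make_cv_plan(4, "full")
  cv <- qsar_cv_train(ds, plan, labels, "dt", seed = 6)
  expect_length(cv$models, 12)
  objs <- qsar_cv_objectives(cv, ds)
  expect_length(objs, 12)
  expect_true(all(objs >= 0 & objs <= 1))
  expect_gt(mean(objs), 0.6)
})
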