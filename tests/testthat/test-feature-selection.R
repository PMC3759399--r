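# Column scoring and sequential forward selection.

test_that("information gain covers the canonical cases", {
  expect_equal(information_gain(1:4, c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(information_gain(rep(2, 6), rep(c(TRUE, FALSE), 3)), 0)
  expect_error(information_gain(1:4, rep(TRUE, 4)), "both classes")
})

test_that("information gain equals the exhaustive threshold oracle", {
  expect_equal(information_gain(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE)),
               brute_ig(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE)))
  for (seed in 1:20) {
    v <- qsarvs:::qv_with_seed(seed, list(
      x = round(runif(20), 2),
      y = sample(c(TRUE, FALSE), 20, replace = TRUE, prob = c(0.3, 0.7))))
    if (all(v$y) || !any(v$y)) next
    expect_equal(information_gain(v$x, v$y), brute_ig(v$x, v$y),
                 tolerance = 1e-12)
  }
})

test_that("F-score covers the canonical cases and the brute-force oracle", {
  expect_equal(f_score(c(0, 1, 2, 3), c(TRUE, TRUE, FALSE, FALSE)), 2.0)
  expect_equal(f_score(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 0)
  expect_equal(f_score(c(1, 1, 2, 2), c(TRUE, TRUE, FALSE, FALSE)), Inf)
  expect_error(f_score(1:4, c(TRUE, FALSE, FALSE, FALSE)), "two members")
  for (seed in 1:20) {
    v <- qsarvs:::qv_with_seed(seed + 50, list(
      x = rnorm(24), y = rep(c(TRUE, FALSE), c(8, 16))))
    expect_equal(f_score(v$x, v$y), brute_fscore(v$x, v$y),
                 tolerance = 1e-12)
  }
})

# small synthetic feature matrix with a planted informative group
planted_matrix <- function(n = 60, seed = 3) {
  qsarvs:::qv_with_seed(seed, {
    act <- rep(c(TRUE, FALSE, FALSE, FALSE), n / 4)  # interleaved classes
    informative <- ifelse(act, 2, 0) + rnorm(n, sd = 0.1)
    noise <- matrix(rnorm(n * 4), n)
    fm <- cbind(informative, noise)
    colnames(fm) <- paste0("g", 1:5)
    attr(fm, "groups") <- data.frame(group = 1:5,
                                     name = paste0("g", 1:5),
                                     start = 1:5, end = 1:5)
    class(fm) <- c("feature_matrix", class(fm))
    list(fm = fm, active = act)
  })
}

test_that("group ranking puts the informative group first under IG and FS", {
  pm <- planted_matrix()
  for (method in c("IG", "FS")) {
    rk <- rank_groups(pm$fm, pm$active, method)
    expect_equal(rk$name[1], "g1")
  }
  # all-constant matrix: zero scores, original order kept
  cm <- pm$fm; cm[, ] <- 1
  rk <- rank_groups(cm, pm$active, "IG")
  expect_true(all(rk$score == 0))
  expect_equal(rk$group, 1:5)
})

test_that("duplicating a column never changes a group's score (max aggregation)", {
  pm <- planted_matrix()
  fm2 <- cbind(unclass(pm$fm), dup = unclass(pm$fm)[, 1])
  attr(fm2, "groups") <- data.frame(group = 1:5, name = paste0("g", 1:5),
                                    start = 1:5, end = c(1:4, 6))
  # group 5 now holds (noise4, duplicate-of-informative): its score becomes
  # the informative column's, but group 1's is unchanged
  class(fm2) <- c("feature_matrix", class(fm2))
  for (method in c("IG", "FS")) {
    r1 <- rank_groups(pm$fm, pm$active, method)
    r2 <- rank_groups(fm2, pm$active, method)
    expect_equal(r2$score[r2$group == 1], r1$score[r1$group == 1])
    expect_equal(r2$score[r2$group == 5], r1$score[r1$group == 1])
  }
})

# trainer/objective pair over the planted matrix: hold out a third, score by
# full-range TNR-TPR integral of a decision tree
planted_eval <- function(pm) {
  n <- nrow(pm$fm)
  tr <- seq_len(floor(2 * n / 3))
  te <- setdiff(seq_len(n), tr)
  y <- ifelse(pm$active, 6, 3)
  trainer <- function(groups) {
    cols <- as.integer(groups)
    qsar_train(unclass(pm$fm)[tr, cols, drop = FALSE], y[tr], "dt")
  }
  objective <- function(model) {
    cols <- match(model$feature_names, colnames(pm$fm))
    pred <- predict(model, unclass(pm$fm)[te, cols, drop = FALSE])
    curve_integral(tnr_tpr_curve(pred, pm$active[te]))
  }
  list(trainer = trainer, objective = objective)
}

test_that("SFFS picks the informative group in round 1 and terminates on stall", {
  pm <- planted_matrix(n = 120, seed = 13)
  ev <- planted_eval(pm)
  traj <- sffs(1:5, ev$trainer, ev$objective, patience = 3)
  expect_equal(traj$rounds$added[1], "1")
  expect_true(1 %in% traj$selected)
  # best-so-far sequence is non-decreasing
  best_seq <- cummax(traj$rounds$objective_mean)
  expect_true(all(diff(best_seq) >= 0))
  # stall-based termination: last `patience` recorded rounds show no
  # improvement over the best
  expect_lte(nrow(traj$rounds),
             which.max(traj$rounds$objective_mean) + 3 + 1)
})

test_that("SFFS stops after exactly `patience` non-improving rounds", {
  # constant objective: round 1 improves (from -Inf), then stalls
  counter <- new.env(); counter$n <- 0L
  trainer <- function(groups) groups
  objective <- function(model) 0.5
  traj <- sffs(1:20, trainer, objective, patience = 10)
  expect_equal(nrow(traj$rounds), 11)  # 1 improving + 10 stalled
  expect_equal(traj$selected, 1L)
  expect_equal(traj$best_objective, 0.5)
})

test_that("SFFS with a single group runs exactly one round", {
  traj <- sffs(7L, function(g) g, function(m) 0.9, patience = 10)
  expect_equal(nrow(traj$rounds), 1)
  expect_equal(traj$selected, 7L)
})

test_that("SFFS skips failing candidates and logs them", {
  trainer <- function(groups) {
    if (3 %in% groups) stop("degenerate")
    groups
  }
  objective <- function(model) length(model) * 0.1
  traj <- sffs(1:3, trainer, objective, patience = 2)
  expect_false(3 %in% traj$selected)
  expect_true(any(grepl("group 3", traj$failed)))
})

test_that("prefix-size selection returns the best-evaluated prefix", {
  pm <- planted_matrix(n = 120, seed = 17)
  ev <- planted_eval(pm)
  rk <- rank_groups(pm$fm, pm$active, "IG")
  sel <- select_top_groups(rk, ev$trainer, ev$objective, sizes = c(1, 2, 4))
  expect_true(rk$group[1] %in% sel$groups)
  expect_equal(sel$objective, max(sel$evaluations$objective))
})
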