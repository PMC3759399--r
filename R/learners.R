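# The four QSAR learners behind one fitting interface: feed-forward neural
# network (simple propagation), epsilon-SVR with RBF kernel, CART-style
# decision tree, and a Kohonen self-organising map, all predicting on the
# pIC50 scale.

#' Model specification
#'
#' Hyperparameter container for [qsar_train()]. Method defaults follow the
#' package's standard settings: ANN with one hidden layer of 32 sigmoid
#' units, learning rate `eta = 0.2`, momentum `alpha = 0.5`, up to 300
#' epochs checked against the monitoring objective every `check_every`
#' epochs with a patience of 10 checks; SVR with `C = 1`, `gamma = 0.1`
#' (the descriptor-selection defaults) and `epsilon = 0.1`; decision tree
#' with Gini splitting, `min_leaf = 5`, `max_depth = 30`; Kohonen map on a
#' 10 x 10 grid, 100 epochs, initial neighbourhood radius half the grid
#' diagonal decaying linearly, learning rate 0.5 to 0.01.
#'
#' @param method `"ann"`, `"svr"`, `"dt"` or `"kn"`.
#' @param ... overrides of the method's default hyperparameters.
#' @param seed integer seed for all stochastic initialisation.
#' @return list of class `"model_spec"`.
#' @export
model_spec <- function(method = c("ann", "svr", "dt", "kn"), ..., seed = 1L) {
  method <- match.arg(method)
  defaults <- switch(method,
    ann = list(hidden = 32L, eta = 0.2, alpha = 0.5, epochs = 300L,
               check_every = 5L, patience = 10L),
    svr = list(C = 1, gamma = 0.1, epsilon = 0.1),
    dt = list(min_leaf = 5L, max_depth = 30L, p_base = 3, p_span = 4),
    kn = list(rows = 10L, cols = 10L, epochs = 100L,
              lr_start = 0.5, lr_end = 0.01))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("unknown ", method, " hyperparameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  defaults[names(over)] <- over
  structure(c(list(method = method, seed = as.integer(seed)), defaults),
            class = "model_spec")
}

# min-max normalisation fitted on training columns only
qv_fit_norm <- function(x) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  span <- hi - lo
  span[span == 0] <- 1
  list(lo = lo, span = span)
}

qv_apply_norm <- function(x, norm) {
  sweep(sweep(x, 2, norm$lo, "-"), 2, norm$span, "/")
}

qv_fingerprint <- function(colnames_) {
  if (is.null(colnames_)) return(NA_real_)
  qv_hash_id(paste(colnames_, collapse = "|"))
}

#' Train a QSAR model
#'
#' Fits one of the four learner types to descriptor rows and pIC50/pEC50
#' targets. Features are min-max normalised to `[0, 1]` using the training
#' rows only. The ANN and SVR learners expect the training partition to be
#' balanced beforehand with [oversample_actives()]; the tree and Kohonen map
#' need no oversampling. For the ANN a monitoring partition drives early
#' termination: training halts when the monitoring TNR-TPR integral has not
#' improved for `patience` consecutive checks and the best-on-monitor
#' weights are returned.
#'
#' @param x numeric matrix of descriptor rows (training partition).
#' @param y numeric vector of pIC50 targets.
#' @param method learner type, see [model_spec()].
#' @param monitor_x,monitor_y optional monitoring partition (required for
#'   ANN early termination).
#' @param spec a [model_spec()]; built from `method` and `seed` if omitted.
#' @param seed convenience override of `spec$seed`.
#' @param active_cutoff pIC50 value above which a compound counts as active
#'   when the monitoring objective needs hard labels.
#' @return object of class `"qsar_model"` with `print`, `summary` and
#'   `predict` methods.
#' @examples
#' x <- matrix(rnorm(40), 20, 2)
#' y <- 3 + (x[, 1] > 0) * 3
#' m <- qsar_train(x, y, "dt")
#' predict(m, x[1:2, , drop = FALSE])
#' @export
qsar_train <- function(x, y, method = c("ann", "svr", "dt", "kn"),
                       monitor_x = NULL, monitor_y = NULL, spec = NULL,
                       seed = NULL, active_cutoff = 3.5) {
  method <- match.arg(method)
  if (is.null(spec)) spec <- model_spec(method, seed = seed %||% 1L)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  stopifnot(inherits(spec, "model_spec"), spec$method == method,
            nrow(x) == length(y))
  x <- as.matrix(x)
  norm <- qv_fit_norm(x)
  xn <- qv_apply_norm(x, norm)
  mon_xn <- if (!is.null(monitor_x)) qv_apply_norm(as.matrix(monitor_x), norm)
  fit <- switch(method,
    ann = qv_train_ann(xn, y, mon_xn, monitor_y, spec, active_cutoff),
    svr = qv_train_svr(xn, y, spec),
    dt = qv_train_dt(xn, y, spec, active_cutoff),
    kn = qv_train_kn(xn, y, spec))
  structure(list(method = method, spec = spec, fit = fit$fit, norm = norm,
                 n_features = ncol(x), fingerprint = qv_fingerprint(colnames(x)),
                 feature_names = colnames(x),
                 training_log = fit$log, active_cutoff = active_cutoff),
            class = "qsar_model")
}

#' @rdname qsar_train
#' @param object,x a qsar_model.
#' @param newdata descriptor matrix with the same columns as training.
#' @param ... ignored.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("feature width ", ncol(newdata), " does not match model (",
         object$n_features, ")", call. = FALSE)
  if (!is.null(colnames(newdata)) && !is.na(object$fingerprint) &&
      qv_fingerprint(colnames(newdata)) != object$fingerprint)
    stop("descriptor-set fingerprint mismatch", call. = FALSE)
  xn <- qv_apply_norm(newdata, object$norm)
  out <- switch(object$method,
    ann = qv_predict_ann(object$fit, xn),
    svr = if (!is.null(object$fit$constant))
      rep(object$fit$constant, nrow(xn))
    else as.numeric(stats::predict(object$fit, xn)),
    dt = object$spec$p_base +
      stats::predict(object$fit, as.data.frame(xn))[, "TRUE"] *
        object$spec$p_span,
    kn = qv_predict_kn(object$fit, xn))
  unname(out)
}

#' @rdname qsar_train
#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("<qsar_model %s: %d features, seed %d>\n",
              toupper(x$method), x$n_features, x$spec$seed))
  invisible(x)
}

#' @rdname qsar_train
#' @export
summary.qsar_model <- function(object, ...) {
  print(object)
  if (!is.null(object$training_log) && nrow(object$training_log)) {
    cat("training log (last checks):\n")
    print(utils::tail(object$training_log, 5))
  }
  invisible(object)
}

## --- ANN: one hidden sigmoid layer, simple propagation with momentum -----

qv_sigmoid <- function(z) 1 / (1 + exp(-z))

qv_train_ann <- function(xn, y, mon_xn, mon_y, spec, active_cutoff) {
  d <- ncol(xn); h <- spec$hidden
  # target scaled to (0,1) for the sigmoid output
  ylo <- min(y); yspan <- max(y) - ylo
  if (yspan == 0) yspan <- 1
  yt <- (y - ylo) / yspan
  w <- qv_with_seed(spec$seed, list(
    W1 = matrix(stats::runif(d * h, -0.5, 0.5), d, h),
    b1 = stats::runif(h, -0.5, 0.5),
    W2 = matrix(stats::runif(h, -0.5, 0.5), h, 1),
    b2 = stats::runif(1, -0.5, 0.5)))
  vel <- lapply(w, function(m) m * 0)
  n <- nrow(xn)
  fwd <- function(w, X) {
    H <- qv_sigmoid(sweep(X %*% w$W1, 2, w$b1, "+"))
    O <- qv_sigmoid(H %*% w$W2 + w$b2)
    list(H = H, O = O)
  }
  monitor <- !is.null(mon_xn) && !is.null(mon_y)
  best <- list(w = w, obj = -Inf, epoch = 0L)
  log <- data.frame(epoch = integer(), train_mse = numeric(),
                    monitor_objective = numeric())
  stall <- 0L
  epoch <- 0L
  while (epoch < spec$epochs) {
    epoch <- epoch + 1L
    f <- fwd(w, xn)
    err <- f$O[, 1] - yt
    dO <- err * f$O[, 1] * (1 - f$O[, 1])          # n
    gW2 <- crossprod(f$H, dO) / n                  # h x 1
    gb2 <- mean(dO)
    dH <- (dO %*% t(w$W2)) * f$H * (1 - f$H)       # n x h
    gW1 <- crossprod(xn, dH) / n
    gb1 <- colMeans(dH)
    g <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    for (nm in names(w)) {
      vel[[nm]] <- spec$alpha * vel[[nm]] - spec$eta * g[[nm]]
      w[[nm]] <- w[[nm]] + vel[[nm]]
    }
    if (epoch %% spec$check_every == 0L || epoch == spec$epochs) {
      mse <- mean(err^2)
      mobj <- NA_real_
      if (monitor) {
        pred <- ylo + yspan * fwd(w, mon_xn)$O[, 1]
        mobj <- curve_integral(tnr_tpr_curve(pred, mon_y > active_cutoff - 0.5))
        if (mobj > best$obj) {
          best <- list(w = w, obj = mobj, epoch = epoch)
          stall <- 0L
        } else stall <- stall + 1L
      }
      log <- rbind(log, data.frame(epoch = epoch, train_mse = mse,
                                   monitor_objective = mobj))
      if (monitor && stall >= spec$patience) break
    }
  }
  final_w <- if (monitor && best$obj > -Inf) best$w else w
  list(fit = list(w = final_w, ylo = ylo, yspan = yspan,
                  best_epoch = if (monitor) best$epoch else epoch,
                  best_monitor = if (monitor) best$obj else NA_real_),
       log = log)
}

qv_predict_ann <- function(fit, xn) {
  H <- qv_sigmoid(sweep(xn %*% fit$w$W1, 2, fit$w$b1, "+"))
  as.numeric(fit$ylo + fit$yspan * qv_sigmoid(H %*% fit$w$W2 + fit$w$b2))
}

## --- SVR: epsilon-insensitive regression, RBF kernel (e1071) -------------

qv_train_svr <- function(xn, y, spec) {
  if (stats::var(as.numeric(xn)) == 0 && nrow(xn) > 1)
    stop("degenerate kernel matrix: all training rows identical",
         call. = FALSE)
  if (stats::var(y) == 0)  # flat target: no support vectors exist
    return(list(fit = list(constant = y[1]), log = NULL))
  fit <- e1071::svm(xn, y, type = "eps-regression", kernel = "radial",
                    cost = spec$C, gamma = spec$gamma,
                    epsilon = spec$epsilon, scale = FALSE)
  list(fit = fit, log = NULL)
}

#' Grid search for SVR hyperparameters
#'
#' Exhaustively trains an SVR at every (C, gamma) grid point and selects the
#' pair with the best monitoring objective (partial TNR-TPR integral); ties
#' go to the smaller C, then the smaller gamma.
#'
#' @param x,y training rows and pIC50 targets (oversampled beforehand).
#' @param monitor_x,monitor_y monitoring partition.
#' @param C_grid,gamma_grid candidate values; defaults are powers of two,
#'   `2^(-3..9)` and `2^(-9..1)`.
#' @param epsilon tube width.
#' @param tpr_max upper TPR bound of the monitoring objective integral (1 =
#'   full range).
#' @param active_cutoff pIC50 activity cutoff for monitoring labels.
#' @param seed seed stored in the winning spec.
#' @return list with `spec` (the winning [model_spec()]), `objective`, and
#'   the full evaluation `grid`.
#' @export
grid_search_svm <- function(x, y, monitor_x, monitor_y,
                            C_grid = 2^(-3:9), gamma_grid = 2^(-9:1),
                            epsilon = 0.1, tpr_max = 1,
                            active_cutoff = 3.5, seed = 1L) {
  stopifnot(length(C_grid) > 0, length(gamma_grid) > 0)
  grid <- expand.grid(C = C_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$objective <- NA_real_
  mon_lab <- monitor_y > active_cutoff - 0.5
  for (i in seq_len(nrow(grid))) {
    m <- qsar_train(x, y, "svr",
                    spec = model_spec("svr", C = grid$C[i],
                                      gamma = grid$gamma[i],
                                      epsilon = epsilon, seed = seed))
    pred <- predict(m, monitor_x)
    grid$objective[i] <- integral_to_cutoff(tnr_tpr_curve(pred, mon_lab),
                                            tpr_max)
  }
  ord <- order(-grid$objective, grid$C, grid$gamma)
  best <- grid[ord[1], ]
  list(spec = model_spec("svr", C = best$C, gamma = best$gamma,
                         epsilon = epsilon, seed = seed),
       objective = best$objective, grid = grid)
}

## --- DT: CART with Gini splitting, leaf score = active fraction ----------

qv_train_dt <- function(xn, y, spec, active_cutoff) {
  lab <- factor(y > spec$p_base, levels = c(FALSE, TRUE))
  df <- as.data.frame(xn)
  fit <- rpart::rpart(lab ~ ., data = cbind(df, lab = lab),
                      method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        minbucket = spec$min_leaf, maxdepth = spec$max_depth,
                        cp = 0, xval = 0))
  list(fit = fit, log = NULL)
}

## --- KN: batch self-organising map with Gaussian neighbourhood -----------

qv_train_kn <- function(xn, y, spec) {
  nr <- spec$rows; nc <- spec$cols
  n_nodes <- nr * nc
  d <- ncol(xn)
  gx <- rep(seq_len(nr), nc)
  gy <- rep(seq_len(nc), each = nr)
  grid_d2 <- outer(gx, gx, "-")^2 + outer(gy, gy, "-")^2
  W <- qv_with_seed(spec$seed,
                    matrix(stats::runif(n_nodes * d), n_nodes, d))
  sigma0 <- max(sqrt(nr^2 + nc^2) / 2, 0.5)
  sigma_end <- 0.5
  x2 <- rowSums(xn^2)
  winners <- integer(nrow(xn))
  for (ep in seq_len(spec$epochs)) {
    frac <- if (spec$epochs > 1) (ep - 1) / (spec$epochs - 1) else 1
    sigma <- sigma0 + frac * (sigma_end - sigma0)
    lr <- spec$lr_start + frac * (spec$lr_end - spec$lr_start)
    # batch update: winner per sample, then Gaussian-kernel weighted pull
    dists <- outer(x2, rowSums(W^2), "+") - 2 * xn %*% t(W)
    winners <- max.col(-dists, ties.method = "first")
    K <- exp(-grid_d2 / (2 * sigma^2))        # node x node
    H <- K[, winners, drop = FALSE]           # node x sample
    wsum <- rowSums(H)
    target <- (H %*% xn) / pmax(wsum, 1e-12)
    W <- W + lr * (target - W)
  }
  dists <- outer(x2, rowSums(W^2), "+") - 2 * xn %*% t(W)
  winners <- max.col(-dists, ties.method = "first")
  node_value <- rep(NA_real_, n_nodes)
  agg <- rowsum(y, winners)
  cnt <- table(winners)
  node_value[as.integer(rownames(agg))] <- agg[, 1] / as.integer(cnt)
  # empty nodes inherit the nearest populated node's value
  if (anyNA(node_value)) {
    filled <- which(!is.na(node_value))
    for (i in which(is.na(node_value))) {
      node_value[i] <- node_value[filled[which.min(grid_d2[i, filled])]]
    }
  }
  list(fit = list(W = W, node_value = node_value, rows = nr, cols = nc),
       log = data.frame(epoch = spec$epochs,
                        n_empty = sum(!seq_len(n_nodes) %in% winners)))
}

qv_predict_kn <- function(fit, xn) {
  dists <- outer(rowSums(xn^2), rowSums(fit$W^2), "+") - 2 * xn %*% t(fit$W)
  fit$node_value[max.col(-dists, ties.method = "first")]
}

#' Train a cross-validated model set
#'
#' Trains one model per split of a cross-validation plan: partition labels
#' assign each row to the training, monitoring or independent role; ANN/SVR
#' training partitions are balanced by [oversample_actives()] first. Seeds
#' are derived per split from the base seed.
#'
#' @param dataset a [qsar_dataset()].
#' @param plan a [make_cv_plan()].
#' @param labels partition labels from [partition_dataset()].
#' @param method learner type.
#' @param spec optional shared [model_spec()].
#' @param group_cols optional column indices restricting the descriptor set.
#' @param seed base seed.
#' @return list of class `"qsar_cv"`: per split, the trained model plus the
#'   row roles used.
#' @export
qsar_cv_train <- function(dataset, plan, labels, method, spec = NULL,
                          group_cols = NULL, seed = 1L) {
  x_all <- dataset$features
  if (!is.null(group_cols)) x_all <- x_all[, group_cols, drop = FALSE]
  y_all <- dataset$records$p_activity
  act <- dataset$records$is_active
  models <- vector("list", length(plan$splits))
  for (si in seq_along(plan$splits)) {
    split <- plan$splits[[si]]
    roles <- split_roles(labels, split)
    tr <- which(roles == "train"); mo <- which(roles == "monitor")
    idx <- if (method %in% c("ann", "svr")) tr[oversample_actives(act[tr])]
           else tr
    sp <- spec
    sseed <- as.integer((as.double(seed) * 131 + si) %% 2147483647)
    if (!is.null(sp)) sp$seed <- sseed
    models[[si]] <- list(
      model = qsar_train(x_all[idx, , drop = FALSE], y_all[idx], method,
                         monitor_x = x_all[mo, , drop = FALSE],
                         monitor_y = y_all[mo], spec = sp, seed = sseed),
      split = split, roles = roles)
  }
  structure(list(models = models, method = method, plan_mode = plan$mode),
            class = "qsar_cv")
}

#' Independent-partition objectives of a cross-validated model set
#'
#' @param cv a [qsar_cv_train()] result.
#' @param dataset the dataset it was trained on.
#' @param group_cols the column restriction used at training time.
#' @param tpr_max upper TPR bound of the integral (1 = full range).
#' @return numeric vector, one TNR-TPR integral per split.
#' @export
qsar_cv_objectives <- function(cv, dataset, group_cols = NULL, tpr_max = 1) {
  x_all <- dataset$features
  if (!is.null(group_cols)) x_all <- x_all[, group_cols, drop = FALSE]
  act <- dataset$records$is_active
  vapply(cv$models, function(m) {
    ind <- which(m$roles == "independent")
    pred <- predict(m$model, x_all[ind, , drop = FALSE])
    integral_to_cutoff(tnr_tpr_curve(pred, act[ind]), tpr_max)
  }, numeric(1))
}
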