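# Model quality: TNR-TPR curve, partial integral, enrichment, consensus
# prediction, and consensus ranking across learner subsets.

#' TNR-TPR curve
#'
#' Sweeps prediction score thresholds from high to low, recording at each
#' step the true-positive rate TPR = TP / (TP + FN) and true-negative rate
#' TNR = TN / (TN + FP). The result is the conventional ROC curve rotated
#' 90 degrees clockwise: specificity against sensitivity. Tied scores are
#' handled as a single threshold step (no intra-tie interpolation) and the
#' curve always contains the endpoints (0, 1) and (1, TNR at the lowest
#' threshold).
#'
#' @param scores numeric prediction scores (higher = more active).
#' @param labels logical vector, `TRUE` for actives.
#' @return object of class `"tnr_tpr_curve"`: list with `tpr`, `tnr`,
#'   `thresholds` (NA for the (0, 1) anchor), and the positive/negative
#'   counts `P`, `N`.
#' @examples
#' curve <- tnr_tpr_curve(c(0.9, 0.8, 0.4, 0.2), c(TRUE, TRUE, FALSE, FALSE))
#' curve_integral(curve)   # 1: perfect ranking
#' @export
tnr_tpr_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  P <- sum(labels); N <- sum(!labels)
  if (P == 0L || N == 0L)
    stop("curve needs both classes present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  cum_tp <- cumsum(l)
  cum_fp <- cumsum(!l)
  last <- c(which(diff(s) != 0), length(s))  # atomic tie blocks
  tpr <- c(0, cum_tp[last] / P)
  tnr <- c(1, (N - cum_fp[last]) / N)
  structure(list(tpr = tpr, tnr = tnr,
                 thresholds = c(NA_real_, s[last]), P = P, N = N),
            class = "tnr_tpr_curve")
}

#' @rdname tnr_tpr_curve
#' @param x a tnr_tpr_curve.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tnr_tpr_curve <- function(x, ...) {
  graphics::plot(x$tpr, x$tnr, type = "l", xlab = "TPR (sensitivity)",
                 ylab = "TNR (specificity)", xlim = c(0, 1), ylim = c(0, 1),
                 ...)
  graphics::abline(1, -1, lty = 3, col = "grey50")
  invisible(x)
}

#' @rdname tnr_tpr_curve
#' @param curve a tnr_tpr_curve.
#' @export
curve_integral <- function(curve) integral_to_cutoff(curve, 1)

#' Partial integral of a TNR-TPR curve
#'
#' Trapezoidal integral of TNR over TPR from 0 to `tpr_max`; the virtual
#' screening objective focuses on the early part of the ranking, e.g.
#' TPR in \[0, 0.25\] where a perfect model scores 0.25 and a random one
#' 0.21875. At `tpr_max = 1` this is the full AUC (0.5 for a random
#' predictor).
#'
#' @param curve a [tnr_tpr_curve()].
#' @param tpr_max upper integration bound in (0, 1].
#' @return the integral, at most `tpr_max`.
#' @export
integral_to_cutoff <- function(curve, tpr_max = 0.25) {
  stopifnot(tpr_max > 0, tpr_max <= 1)
  tpr <- curve$tpr; tnr <- curve$tnr
  if (tpr_max < max(tpr)) {
    ix <- which(tpr >= tpr_max)[1]
    if (tpr[ix] > tpr_max) {
      f <- (tpr_max - tpr[ix - 1]) / (tpr[ix] - tpr[ix - 1])
      tnr_cut <- tnr[ix - 1] + f * (tnr[ix] - tnr[ix - 1])
      tpr <- c(tpr[seq_len(ix - 1)], tpr_max)
      tnr <- c(tnr[seq_len(ix - 1)], tnr_cut)
    } else {
      tpr <- tpr[seq_len(ix)]; tnr <- tnr[seq_len(ix)]
    }
  }
  sum(diff(tpr) * (head(tnr, -1) + tail(tnr, -1)) / 2)
}

#' Enrichment at a sensitivity target
#'
#' Finds the largest threshold whose TPR reaches `tpr_target` and reports
#' the enrichment factor there: the fraction of actives among the selected
#' compounds divided by the baseline active fraction,
#' ENR = (TP / (TP + FP)) / (P / (P + N)). A perfect model reaches the
#' theoretical maximum (P + N) / P; a random one sits near 1.
#'
#' @inheritParams tnr_tpr_curve
#' @param tpr_target sensitivity to reach, in (0, 1].
#' @return list of class `"enrichment_report"`: `tpr_target`,
#'   `achieved_tpr`, `enrichment`, `confusion` (TP/FP/TN/FN at the cutoff),
#'   `cutoff` and `baseline` active fraction.
#' @export
enrichment <- function(scores, labels, tpr_target = 0.25) {
  stopifnot(tpr_target > 0, tpr_target <= 1)
  labels <- as.logical(labels)
  curve <- tnr_tpr_curve(scores, labels)
  ok <- which(curve$tpr >= tpr_target & !is.na(curve$thresholds))
  if (!length(ok))
    stop("no threshold reaches TPR ", tpr_target, call. = FALSE)
  ix <- ok[1]
  cutoff <- curve$thresholds[ix]
  sel <- scores >= cutoff
  TP <- sum(sel & labels); FP <- sum(sel & !labels)
  FN <- sum(!sel & labels); TN <- sum(!sel & !labels)
  baseline <- curve$P / (curve$P + curve$N)
  structure(list(tpr_target = tpr_target, achieved_tpr = TP / curve$P,
                 enrichment = (TP / (TP + FP)) / baseline,
                 confusion = c(TP = TP, FP = FP, TN = TN, FN = FN),
                 cutoff = cutoff, baseline = baseline),
            class = "enrichment_report")
}

#' @rdname enrichment
#' @param x an enrichment_report.
#' @param ... ignored.
#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("<enrichment %.1f at TPR >= %.2f (achieved %.3f), baseline %.4f>\n",
              x$enrichment, x$tpr_target, x$achieved_tpr, x$baseline))
  invisible(x)
}

#' Consensus prediction
#'
#' Unweighted mean of the predicted pIC50 values over a set of trained
#' models (typically all cross-validation models of one or more learner
#' types). All models must share the descriptor-set fingerprint.
#'
#' @param models list of [qsar_train()] models.
#' @param newdata descriptor matrix.
#' @return numeric vector of averaged pIC50 predictions.
#' @export
consensus_predict <- function(models, newdata) {
  stopifnot(length(models) >= 1)
  fps <- vapply(models, function(m) m$fingerprint, numeric(1))
  if (length(unique(fps[!is.na(fps)])) > 1)
    stop("models carry different descriptor-set fingerprints", call. = FALSE)
  preds <- vapply(models, function(m) predict(m, newdata),
                  numeric(nrow(as.matrix(newdata))))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

#' Consensus ranking over learner subsets
#'
#' Evaluates every non-empty subset of the supplied learner types (15
#' subsets for four) on independent data: each subset's consensus
#' prediction is scored by the partial TNR-TPR integral (INT) and the
#' enrichment (ENR) at `tpr_target`, and subsets are ranked by ENR (ties:
#' fewer methods first). `diff` reports the ENR gain of the best
#' multi-method consensus over the best single method, normalised by the
#' inactives-to-actives ratio and expressed in percent.
#'
#' @param method_models named list: one entry per learner type, each a list
#'   of trained models (e.g. the cross-validation models).
#' @param newdata independent descriptor rows.
#' @param labels logical actives vector for `newdata`.
#' @param tpr_target sensitivity cutoff (default 0.25).
#' @param ratio inactives-to-actives ratio used for the `diff`
#'   normalisation; defaults to the rounded ratio of `labels`.
#' @return object of class `"consensus_ranking"`: data.frame `table`
#'   (methods, n_methods, INT, ENR, rank), `best_single`, `best_consensus`,
#'   and `diff` (percent).
#' @export
consensus_ranking <- function(method_models, newdata, labels,
                              tpr_target = 0.25, ratio = NULL) {
  stopifnot(length(method_models) >= 1, !is.null(names(method_models)))
  labels <- as.logical(labels)
  if (is.null(ratio)) ratio <- round(sum(!labels) / sum(labels))
  methods <- names(method_models)
  m <- length(methods)
  subsets <- lapply(seq_len(2^m - 1), function(mask)
    methods[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0])
  tab <- data.frame(methods = vapply(subsets, paste, character(1),
                                     collapse = " "),
                    n_methods = lengths(subsets),
                    INT = NA_real_, ENR = NA_real_,
                    stringsAsFactors = FALSE)
  # average the per-method consensus scores rather than re-predicting per
  # subset: mean over all models of the included methods
  per_method <- lapply(method_models, consensus_predict, newdata = newdata)
  n_models <- vapply(method_models, length, integer(1))
  for (i in seq_along(subsets)) {
    sel <- subsets[[i]]
    w <- n_models[sel] / sum(n_models[sel])
    score <- Reduce(`+`, Map(function(p, wi) p * wi, per_method[sel], w))
    tab$INT[i] <- integral_to_cutoff(tnr_tpr_curve(score, labels),
                                     tpr_target)
    tab$ENR[i] <- enrichment(score, labels, tpr_target)$enrichment
  }
  ord <- order(-tab$ENR, tab$n_methods)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  best_single <- tab[tab$n_methods == 1, ][1, ]
  best_cons <- if (any(tab$n_methods > 1)) tab[tab$n_methods > 1, ][1, ]
               else best_single
  structure(list(table = tab, best_single = best_single,
                 best_consensus = best_cons, ratio = ratio,
                 tpr_target = tpr_target,
                 diff = 100 * (best_cons$ENR - best_single$ENR) / ratio),
            class = "consensus_ranking")
}

#' @rdname consensus_ranking
#' @param x a consensus_ranking.
#' @param ... ignored.
#' @export
print.consensus_ranking <- function(x, ...) {
  cat(sprintf("<consensus_ranking: %d subsets at TPR %.2f, Diff = %.2f%%>\n",
              nrow(x$table), x$tpr_target, x$diff))
  print(utils::head(x$table, 5))
  invisible(x)
}
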