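# Descriptor column scoring (information gain, F-score) and sequential
# forward selection over descriptor groups.

qv_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Information gain of a descriptor column
#'
#' Change in class entropy achieved by the best single binary threshold on
#' the column: IG = H(labels) - min over thresholds of the weighted
#' conditional entropy. Candidate thresholds are the midpoints between
#' consecutive distinct sorted values, so the score is exact for the
#' single-split discretisation.
#'
#' @param x numeric column values.
#' @param labels logical (active) vector.
#' @return score in bits, within `[0, H(labels)]`.
#' @examples
#' information_gain(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))  # 1 bit
#' @export
information_gain <- function(x, labels) {
  stopifnot(length(x) == length(labels))
  if (all(labels) || !any(labels))
    stop("information gain needs both classes present", call. = FALSE)
  n <- length(x)
  h0 <- qv_entropy(c(sum(labels), n - sum(labels)))
  ord <- order(x)
  xs <- x[ord]; ys <- labels[ord]
  cum_a <- cumsum(ys)
  boundary <- which(diff(xs) > 0)  # split after position i
  if (!length(boundary)) return(0)
  n_left <- boundary
  a_left <- cum_a[boundary]
  a_tot <- sum(ys)
  h_cond <- vapply(seq_along(boundary), function(j) {
    nl <- n_left[j]; al <- a_left[j]
    nr <- n - nl; ar <- a_tot - al
    (nl * qv_entropy(c(al, nl - al)) + nr * qv_entropy(c(ar, nr - ar))) / n
  }, numeric(1))
  max(0, h0 - min(h_cond))
}

#' F-score of a descriptor column
#'
#' Between-class separation over pooled within-class variance:
#' \deqn{F = \frac{(\bar x^+ - \bar x)^2 + (\bar x^- - \bar x)^2}
#'            {s_+^2 + s_-^2}}
#' with sample variances (n - 1 denominator) within the active and inactive
#' classes. A zero denominator yields `Inf` when the class means differ and
#' 0 when they coincide.
#'
#' @inheritParams information_gain
#' @return non-negative score (possibly `Inf`).
#' @examples
#' f_score(c(0, 1, 2, 3), c(TRUE, TRUE, FALSE, FALSE))  # 2
#' @export
f_score <- function(x, labels) {
  stopifnot(length(x) == length(labels))
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("F-score needs at least two members per class", call. = FALSE)
  xp <- x[labels]; xm <- x[!labels]
  num <- (mean(xp) - mean(x))^2 + (mean(xm) - mean(x))^2
  den <- stats::var(xp) + stats::var(xm)
  if (den == 0) return(if (num == 0) 0 else Inf)
  num / den
}

#' Rank descriptor groups by discriminating power
#'
#' Scores every column with information gain or F-score and aggregates to
#' the group level by the maximum over member columns, so any single
#' discriminating bin promotes its group. Groups are returned in descending
#' score order; ties keep the original group order.
#'
#' @param fm a feature matrix (see [assemble_feature_matrix()]).
#' @param labels logical (active) vector aligned with rows.
#' @param method `"IG"` or `"FS"`.
#' @return data.frame with columns `group`, `name`, `score`, ordered best
#'   first.
#' @export
rank_groups <- function(fm, labels, method = c("IG", "FS")) {
  method <- match.arg(method)
  groups <- feature_groups(fm)
  scorer <- if (method == "IG") information_gain else f_score
  col_scores <- apply(fm, 2, function(col) {
    if (length(unique(col)) == 1L) return(0)
    scorer(col, labels)
  })
  g_scores <- vapply(seq_len(nrow(groups)), function(g)
    max(col_scores[groups$start[g]:groups$end[g]]), numeric(1))
  ord <- order(-g_scores, groups$group)
  data.frame(group = groups$group[ord], name = groups$name[ord],
             score = g_scores[ord], stringsAsFactors = FALSE)
}

#' Sequential forward feature selection over descriptor groups
#'
#' Deterministic greedy search: starting from the empty set, each round adds
#' the single group that maximises the mean objective of the models trained
#' on the candidate set; the search stops when all groups are selected or
#' when the best objective seen has not improved for `patience` consecutive
#' rounds. The final answer is the best cumulative set ever seen. Candidates
#' whose training fails are skipped and logged in the trajectory.
#'
#' @param groups vector of group identifiers to search over.
#' @param trainer `function(group_set)` training the model set (typically a
#'   reduced cross-validation) on those groups; its return value is passed
#'   to `objective`.
#' @param objective `function(models)` returning the per-model objective
#'   values (e.g. TNR-TPR integrals); their mean is the round score.
#' @param patience rounds without improvement before termination.
#' @param max_rounds optional hard cap on the number of rounds (compute
#'   budget control); `Inf` runs to the patience rule or exhaustion.
#' @return object of class `"sffs_trajectory"`: list with `rounds`
#'   (data.frame: round, added group, objective mean and sd), `selected`
#'   (best cumulative group set) and `best_objective`.
#' @export
sffs <- function(groups, trainer, objective, patience = 10L,
                 max_rounds = Inf) {
  selected <- c()
  remaining <- groups
  best_obj <- -Inf
  best_set <- c()
  stall <- 0L
  rounds <- data.frame(round = integer(), added = character(),
                       objective_mean = numeric(), objective_sd = numeric(),
                       improved = logical(), stringsAsFactors = FALSE)
  failed <- character()
  r <- 0L
  while (length(remaining) && stall < patience && r < max_rounds) {
    r <- r + 1L
    cand_mean <- rep(-Inf, length(remaining))
    cand_sd <- rep(NA_real_, length(remaining))
    for (ci in seq_along(remaining)) {
      cand <- c(selected, remaining[ci])
      vals <- tryCatch(objective(trainer(cand)), error = function(e) e)
      if (inherits(vals, "error")) {
        failed <- c(failed, paste0("round ", r, " group ", remaining[ci],
                                   ": ", conditionMessage(vals)))
        next
      }
      cand_mean[ci] <- mean(vals)
      cand_sd[ci] <- stats::sd(vals)
    }
    if (all(!is.finite(cand_mean))) break
    pick <- which.max(cand_mean)  # ties resolved to the lower group index
    selected <- c(selected, remaining[pick])
    improved <- cand_mean[pick] > best_obj
    if (improved) {
      best_obj <- cand_mean[pick]
      best_set <- selected
      stall <- 0L
    } else stall <- stall + 1L
    rounds <- rbind(rounds, data.frame(
      round = r, added = as.character(remaining[pick]),
      objective_mean = cand_mean[pick], objective_sd = cand_sd[pick],
      improved = improved, stringsAsFactors = FALSE))
    remaining <- remaining[-pick]
  }
  structure(list(rounds = rounds, selected = best_set,
                 best_objective = best_obj, failed = failed,
                 patience = patience),
            class = "sffs_trajectory")
}

#' @rdname sffs
#' @param x an sffs_trajectory.
#' @param ... ignored.
#' @export
print.sffs_trajectory <- function(x, ...) {
  cat(sprintf("<sffs: %d rounds, best objective %.4f, %d group(s) selected>\n",
              nrow(x$rounds), x$best_objective, length(x$selected)))
  invisible(x)
}

#' Pick a top-ranked descriptor set by reduced cross-validation
#'
#' For filter rankings (IG/FS) the number of groups to keep is chosen by
#' evaluating nested prefixes of the ranking and keeping the prefix with the
#' highest mean objective.
#'
#' @param ranking output of [rank_groups()].
#' @param trainer,objective as in [sffs()].
#' @param sizes prefix sizes to evaluate (clipped to the ranking length).
#' @return list with `groups` (chosen set), `size`, `objective`, and the
#'   per-size evaluation table.
#' @export
select_top_groups <- function(ranking, trainer, objective,
                              sizes = c(1, 2, 4, 8, 16, 32, 60)) {
  sizes <- unique(pmin(sizes, nrow(ranking)))
  evals <- data.frame(size = sizes, objective = NA_real_)
  for (i in seq_along(sizes)) {
    grp <- ranking$group[seq_len(sizes[i])]
    evals$objective[i] <- mean(objective(trainer(grp)))
  }
  best <- which.max(evals$objective)
  list(groups = ranking$group[seq_len(sizes[best])], size = sizes[best],
       objective = evals$objective[best], evaluations = evals)
}
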