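# Cross-validation plans: stratified partitioning with training, monitoring
# and independent roles.

# Scoped seeding: evaluates code under a given seed and restores the global
# RNG state afterwards.
qv_with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% 2147483647L)
  code
}

# Derived-stream RNG handle: each draw uses a fresh deterministic sub-seed.
qv_rng <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed) %% 2147483647L
  e$counter <- 0L
  e
}

qv_subseed <- function(rng) {
  rng$counter <- rng$counter + 1L
  as.integer((as.double(rng$seed) * 48271 + rng$counter) %% 2147483647)
}

qv_sample <- function(rng, x, size) {
  qv_with_seed(qv_subseed(rng), sample(x, size))
}

# Deterministic polynomial string hash with a seed-dependent multiplicative
# finaliser (a plain additive seed would shift all hashes equally and leave
# their ordering unchanged).
qv_hash_id <- function(ids, seed = 0L) {
  mult <- 48271 + 2 * (as.integer(seed) %% 10000L)
  vapply(as.character(ids), function(s) {
    h <- 0
    for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
    (((h * mult) %% 2147483647) * 69621) %% 2147483647
  }, numeric(1), USE.NAMES = FALSE)
}

#' Build a cross-validation plan
#'
#' In `full` mode the data are divided into `k` partitions and every ordered
#' (independent, monitoring) pair with distinct partitions becomes one
#' training configuration: the named partitions are held out and the
#' remaining `k - 2` partitions train the model, so `k = 10` yields
#' 10 x 9 = 90 splits, each training on 80% of the data. In `reduced` mode
#' (used during descriptor selection) the independent partition is fixed to
#' partition 1 and only the monitoring partition cycles, giving `k - 1`
#' splits; the default `k = 6` yields the 5-split reduced design.
#'
#' @param k number of partitions (`>= 3`); default 10 in full mode, 6 in
#'   reduced mode.
#' @param mode `"full"` or `"reduced"`.
#' @param seed provenance seed recorded in the plan (partitioning itself is
#'   seeded in [partition_dataset()]).
#' @return object of class `"cv_plan"`: list with `k`, `mode`, `seed` and
#'   `splits`, each split a list with `independent`, `monitoring` and
#'   `training` partition indices (1-based).
#' @examples
#' length(make_cv_plan(10, "full")$splits)    # 90
#' length(make_cv_plan(mode = "reduced")$splits) # 5
#' @export
make_cv_plan <- function(k = NULL, mode = c("full", "reduced"), seed = 0L) {
  mode <- match.arg(mode)
  if (is.null(k)) k <- if (mode == "full") 10L else 6L
  k <- as.integer(k)
  if (k < 3L) stop("cross-validation needs k >= 3 partitions", call. = FALSE)
  splits <- list()
  if (mode == "full") {
    for (ind in seq_len(k)) {
      for (mon in setdiff(seq_len(k), ind)) {
        splits[[length(splits) + 1L]] <-
          list(independent = ind, monitoring = mon,
               training = setdiff(seq_len(k), c(ind, mon)))
      }
    }
  } else {
    for (mon in 2:k) {
      splits[[length(splits) + 1L]] <-
        list(independent = 1L, monitoring = mon,
             training = setdiff(seq_len(k), c(1L, mon)))
    }
  }
  structure(list(k = k, mode = mode, seed = as.integer(seed),
                 splits = splits), class = "cv_plan")
}

#' @rdname make_cv_plan
#' @param plan a cv_plan.
#' @param path JSON file path.
#' @export
write_cv_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname make_cv_plan
#' @export
read_cv_plan <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  structure(list(k = x$k, mode = x$mode, seed = x$seed,
                 splits = lapply(x$splits, function(s)
                   list(independent = as.integer(s$independent),
                        monitoring = as.integer(s$monitoring),
                        training = as.integer(unlist(s$training))))),
            class = "cv_plan")
}

#' @rdname make_cv_plan
#' @param x a cv_plan.
#' @param ... ignored.
#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan: %s mode, k = %d, %d training configurations>\n",
              x$mode, x$k, length(x$splits)))
  invisible(x)
}

#' Assign compounds to partitions
#'
#' Actives and inactives are partitioned separately (stratified) so every
#' partition carries its share of each class, with sizes differing by at
#' most one within a class. Assignment is keyed by a seeded hash of the
#' compound id, so it is reproducible across row orderings of the same
#' compound set.
#'
#' @param compound_ids character vector.
#' @param is_active logical vector aligned with `compound_ids`.
#' @param k number of partitions.
#' @param seed integer seed.
#' @return integer vector of partition labels in `1..k`.
#' @export
partition_dataset <- function(compound_ids, is_active, k, seed) {
  stopifnot(length(compound_ids) == length(is_active), !missing(seed))
  k <- as.integer(k)
  if (sum(is_active) < k || sum(!is_active) < k)
    stop("each class needs at least k = ", k, " members", call. = FALSE)
  labels <- integer(length(compound_ids))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(is_active == cls)
    h <- qv_hash_id(compound_ids[idx], seed)
    ord <- order(h, compound_ids[idx])
    labels[idx[ord]] <- rep_len(seq_len(k), length(idx))
  }
  labels
}

#' Row roles under one split
#'
#' @param labels partition labels from [partition_dataset()].
#' @param split one element of a [make_cv_plan()]'s `splits`.
#' @return character vector: `"train"`, `"monitor"` or `"independent"`.
#' @export
split_roles <- function(labels, split) {
  roles <- rep("train", length(labels))
  roles[labels == split$monitoring] <- "monitor"
  roles[labels == split$independent] <- "independent"
  roles
}
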