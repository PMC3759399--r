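# Activity labelling, assay set-algebra curation, dataset statistics and
# class-imbalance handling.

#' pIC50 / pEC50 activity transform
#'
#' Maps assay outcomes onto the common training scale
#' p = -log10(potency / 1 M). Actives with a measured IC50/EC50 use it
#' directly; actives without one are assigned a representative 1 uM
#' (p = 6); inactives are set to 1 mM (p = 3). The scale therefore runs from
#' 3 (inactive) through 4.6 (25 uM) to 7 (0.1 uM) on typical screens.
#'
#' @param records data.frame with columns `compound_id`, `is_active`
#'   (logical) and optionally `potency_uM` (numeric, NA when unmeasured).
#' @return the same data.frame with columns `potency_uM` (filled) and
#'   `p_activity` added.
#' @examples
#' p_activity_transform(data.frame(compound_id = c("a", "b", "c"),
#'                                 is_active = c(TRUE, TRUE, FALSE),
#'                                 potency_uM = c(25, NA, NA)))
#' @export
p_activity_transform <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("compound_id", "is_active") %in% names(records)))
  if (is.null(records$potency_uM)) records$potency_uM <- NA_real_
  if (any(!is.na(records$potency_uM) & records$potency_uM <= 0))
    stop("potency must be positive", call. = FALSE)
  act <- records$is_active
  records$potency_uM[act & is.na(records$potency_uM)] <- 1
  records$potency_uM[!act] <- 1000
  records$p_activity <- -log10(records$potency_uM * 1e-6)
  records
}

#' Assay outcome table
#'
#' @param assay_id assay identifier (AID).
#' @param outcomes data.frame with columns `compound_id` and `outcome`
#'   (`"active"`/`"inactive"`); one outcome per compound.
#' @return object of class `"assay_table"`.
#' @export
assay_table <- function(assay_id, outcomes) {
  stopifnot(all(c("compound_id", "outcome") %in% names(outcomes)),
            all(outcomes$outcome %in% c("active", "inactive")))
  if (anyDuplicated(outcomes$compound_id))
    stop("duplicate compound in assay ", assay_id, call. = FALSE)
  structure(list(assay_id = as.character(assay_id),
                 outcomes = outcomes), class = "assay_table")
}

#' @rdname assay_table
#' @param path CSV with columns `compound_id`, `assay_id`, `outcome`
#'   (and optionally `potency_uM`); may hold several assays.
#' @return `read_assay_tables` returns a named list of assay tables.
#' @export
read_assay_tables <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(compound_id = "character",
                                       assay_id = "character"))
  tabs <- lapply(split(df, df$assay_id), function(d)
    assay_table(d$assay_id[1], d[, setdiff(names(d), "assay_id"),
                                 drop = FALSE]))
  tabs[order(names(tabs))]
}

assay_set <- function(tab, which = c("active", "inactive")) {
  which <- match.arg(which)
  tab$outcomes$compound_id[tab$outcomes$outcome == which]
}

#' Curation recipes
#'
#' A curation recipe defines the active set of a screening campaign as a set
#' expression (union / intersect / subtract) over the active and inactive
#' compound sets of its primary, confirmatory and counter assays; the
#' inactive set is taken from a designated (usually primary) assay. The nine
#' benchmark campaign recipes ship with the package as JSON files.
#'
#' @param said campaign (summary assay) identifier.
#' @param expression nested list set expression: either
#'   `list(assay = "AID", set = "active"|"inactive")` or
#'   `list(op = "union"|"intersect"|"subtract", args = list(...))`.
#'   `subtract` takes the first argument minus the union of the rest.
#' @param inactive_source assay id supplying the inactive set.
#' @return object of class `"curation_recipe"`.
#' @export
curation_recipe <- function(said, expression, inactive_source) {
  structure(list(said = as.character(said), expression = expression,
                 inactive_source = as.character(inactive_source)),
            class = "curation_recipe")
}

#' @rdname curation_recipe
#' @param path JSON recipe file.
#' @export
read_recipe <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  curation_recipe(x$said, x$expression, x$inactive_source)
}

#' @rdname curation_recipe
#' @param name shipped recipe name (a SAID, e.g. `"435008"`).
#' @export
shipped_recipe <- function(name) {
  read_recipe(system.file("extdata", "recipes", paste0("said_", name, ".json"),
                          package = "qsarvs", mustWork = TRUE))
}

#' @rdname curation_recipe
#' @export
shipped_recipes <- function() {
  files <- list.files(system.file("extdata", "recipes", package = "qsarvs"),
                      full.names = TRUE)
  sort(sub("^said_(.*)\\.json$", "\\1", basename(files)))
}

qv_eval_set_expr <- function(expr, tables) {
  if (!is.null(expr$assay)) {
    tab <- tables[[as.character(expr$assay)]]
    if (is.null(tab))
      stop("recipe references unknown assay '", expr$assay, "'",
           call. = FALSE)
    return(assay_set(tab, expr$set %||% "active"))
  }
  args <- lapply(expr$args, qv_eval_set_expr, tables = tables)
  switch(expr$op,
    union = Reduce(union, args),
    intersect = Reduce(intersect, args),
    subtract = setdiff(args[[1]], Reduce(union, args[-1])),
    stop("unknown set operator '", expr$op, "'", call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Curate active/inactive sets from assay tables
#'
#' Evaluates a recipe's set expression to obtain the curated active
#' compounds and takes the inactives of the designated source assay minus
#' any curated active, so the two sets are disjoint by construction.
#'
#' @param recipe a [curation_recipe()].
#' @param tables named list of [assay_table()] objects (names = assay ids).
#' @return list with `active_ids`, `inactive_ids` and `said`.
#' @export
curate <- function(recipe, tables) {
  stopifnot(inherits(recipe, "curation_recipe"))
  names(tables) <- vapply(tables, function(t) t$assay_id, character(1))
  active <- qv_eval_set_expr(recipe$expression, tables)
  src <- tables[[recipe$inactive_source]]
  if (is.null(src))
    stop("recipe references unknown assay '", recipe$inactive_source, "'",
         call. = FALSE)
  inactive <- setdiff(assay_set(src, "inactive"), active)
  if (!length(active))
    warning("curated active set for ", recipe$said, " is empty",
            call. = FALSE)
  list(said = recipe$said, active_ids = sort(unique(active)),
       inactive_ids = sort(unique(inactive)))
}

#' Dataset composition statistics
#'
#' Hit rate and inactives-to-actives ratio of a curated campaign, with the
#' presentation rounding used throughout (hit rate to two decimals in
#' percent, ratio to the nearest integer).
#'
#' @param active_ids,inactive_ids curated compound id vectors (or counts).
#' @return list with `n_active`, `n_inactive`, `hit_rate` (percent) and
#'   `inactive_to_active_ratio`.
#' @examples
#' dataset_stats(230, 218071)   # hit rate 0.11, ratio 948
#' @export
dataset_stats <- function(active_ids, inactive_ids) {
  n_a <- if (length(active_ids) == 1L && is.numeric(active_ids))
    as.integer(active_ids) else length(active_ids)
  n_i <- if (length(inactive_ids) == 1L && is.numeric(inactive_ids))
    as.integer(inactive_ids) else length(inactive_ids)
  if (n_a == 0L) stop("ratio undefined: no active compounds", call. = FALSE)
  list(n_active = n_a, n_inactive = n_i,
       hit_rate = round(100 * n_a / (n_a + n_i), 2),
       inactive_to_active_ratio = round(n_i / n_a))
}

#' Reduce inactive counts in training and monitoring partitions
#'
#' For descriptor selection the training and monitoring partitions keep all
#' actives but sample a fixed number of inactives without replacement
#' (defaults 30,000 and 10,000); the independent partition is never altered.
#'
#' @param dataset a [qsar_dataset()].
#' @param roles character vector assigning each row `"train"`, `"monitor"`
#'   or `"independent"`.
#' @param n_train,n_monitor inactive counts to retain (fewer available =>
#'   keep all).
#' @param seed integer seed (mandatory).
#' @return logical vector marking retained rows.
#' @export
reduce_inactives <- function(dataset, roles, n_train = 30000L,
                             n_monitor = 10000L, seed) {
  stopifnot(!missing(seed), length(roles) == nrow(dataset$features))
  keep <- rep(TRUE, length(roles))
  rng <- qv_rng(seed)
  for (cfg in list(c("train", n_train), c("monitor", n_monitor))) {
    role <- cfg[[1]]; n_keep <- as.integer(cfg[[2]])
    idx <- which(roles == role & !dataset$records$is_active)
    if (length(idx) > n_keep) {
      drop <- qv_sample(rng, idx, length(idx) - n_keep)
      keep[drop] <- FALSE
    }
  }
  keep
}

#' Oversample actives to balance a training partition
#'
#' Replicates active rows cyclically until actives match inactives, the
#' balancing applied to ANN/SVR training partitions (monitoring and
#' independent data are never oversampled).
#'
#' @param is_active logical vector over training rows.
#' @return integer vector of row indices for the balanced partition
#'   (original order preserved, replicated actives appended).
#' @export
oversample_actives <- function(is_active) {
  n <- length(is_active)
  act <- which(is_active)
  n_inact <- n - length(act)
  if (!length(act) || length(act) >= n_inact) return(seq_len(n))
  extra <- rep_len(act, n_inact - length(act))
  c(seq_len(n), extra)
}

#' Assemble a QSAR dataset
#'
#' Binds a feature matrix to aligned activity records; the unit of training
#' and evaluation.
#'
#' @param features a feature matrix (see [assemble_feature_matrix()]).
#' @param records activity records (see [p_activity_transform()]); matched
#'   to the feature rows by `compound_id`.
#' @param provenance free-form list (recipe, config, seeds) carried along.
#' @return object of class `"qsar_dataset"`.
#' @export
qsar_dataset <- function(features, records, provenance = list()) {
  idx <- match(rownames(features), records$compound_id)
  if (anyNA(idx))
    stop("activity record missing for: ",
         paste(head(rownames(features)[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  records <- records[idx, , drop = FALSE]
  if (!any(records$is_active) || all(records$is_active))
    stop("dataset needs at least one active and one inactive", call. = FALSE)
  structure(list(features = features, records = records,
                 provenance = provenance), class = "qsar_dataset")
}

#' @rdname qsar_dataset
#' @param x a qsar_dataset.
#' @param ... ignored.
#' @export
print.qsar_dataset <- function(x, ...) {
  s <- dataset_stats(sum(x$records$is_active), sum(!x$records$is_active))
  cat(sprintf(paste0("<qsar_dataset: %d compounds x %d descriptors, ",
                     "%d actives / %d inactives (hit rate %.2f%%)>\n"),
              nrow(x$features), ncol(x$features), s$n_active, s$n_inactive,
              s$hit_rate))
  invisible(x)
}
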