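# Deterministic generators for toy molecule libraries, activity records and
# assay outcome tables, so every pipeline stage is testable without external
# downloads. The generators emulate the structure of public HTS campaigns
# (large libraries, active:inactive ratios around 1:100-1:1000, activity
# driven by molecular structure) without aiming for chemical realism.

#' Fixture specification
#'
#' @param n_compounds library size.
#' @param seed mandatory integer seed; the same spec always produces the
#'   same library and labels.
#' @param base_active_fraction target fraction of actives, in (0, 1).
#' @param noise label-flip probability applied after the activity rule.
#' @param activity_rule list naming the descriptor that drives activity:
#'   `group` (descriptor group name from [descriptor_config()]); compounds
#'   above the (1 - base fraction) quantile of the group's first bin are
#'   active.
#' @param n_heavy integer range of heavy-atom counts per molecule.
#' @param elements fragment alphabet with sampling weights.
#' @param measured_fraction fraction of actives carrying a measured potency
#'   (the rest are assigned the representative 1 uM during transform).
#' @return list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_compounds, seed,
                         base_active_fraction = 0.01, noise = 0,
                         activity_rule = list(group = "ac2d.effective_polarizability"),
                         n_heavy = c(5L, 14L),
                         elements = c(C = 0.62, N = 0.12, O = 0.12,
                                      S = 0.06, F = 0.04, Cl = 0.04),
                         measured_fraction = 0.7) {
  stopifnot(!missing(seed),
            base_active_fraction > 0, base_active_fraction < 1,
            noise >= 0, noise < 1)
  structure(list(n_compounds = as.integer(n_compounds),
                 seed = as.integer(seed),
                 base_active_fraction = base_active_fraction,
                 noise = noise, activity_rule = activity_rule,
                 n_heavy = as.integer(n_heavy), elements = elements,
                 measured_fraction = measured_fraction),
            class = "fixture_spec")
}

# one random valence-valid molecule with template geometry: atoms are added
# to a random open attachment point at ideal bond length in a direction
# repelled from existing neighbours
qv_random_molecule <- function(id, n_heavy, elements) {
  el_names <- names(elements)
  val_tab <- stats::setNames(element_param(el_names, "valence"), el_names)
  cov_tab <- stats::setNames(element_param(el_names, "cov_r"), el_names)
  el <- character(n_heavy); el[1] <- sample(el_names, 1, prob = elements)
  xyz <- matrix(0, n_heavy, 3)
  free <- val_tab[[el[1]]]
  bonds <- data.frame(from = integer(), to = integer(), order = numeric())
  for (i in seq_len(n_heavy)[-1]) {
    open <- which(free[seq_len(i - 1)] >= 1)
    if (!length(open)) { el <- el[seq_len(i - 1)]; xyz <- xyz[seq_len(i - 1), , drop = FALSE]; break }
    parent <- if (length(open) == 1L) open else sample(open, 1)
    el[i] <- sample(el_names, 1, prob = elements)
    ord <- 1
    if (free[parent] >= 2 && val_tab[[el[i]]] >= 2 && stats::runif(1) < 0.2)
      ord <- 2
    # direction away from the parent's bonded neighbours
    nb <- c(bonds$to[bonds$from == parent], bonds$from[bonds$to == parent])
    dir <- stats::rnorm(3)
    if (length(nb)) {
      away <- xyz[parent, ] - colMeans(xyz[nb, , drop = FALSE])
      if (sum(away^2) > 1e-9) dir <- dir + 2 * away / sqrt(sum(away^2))
    }
    dir <- dir / sqrt(sum(dir^2))
    blen <- cov_tab[[el[parent]]] + cov_tab[[el[i]]]
    xyz[i, ] <- xyz[parent, ] + dir * blen
    bonds <- rbind(bonds, data.frame(from = parent, to = i, order = ord))
    free[parent] <- free[parent] - ord
    free <- c(free, val_tab[[el[i]]] - ord)
  }
  n <- length(el)
  molecule(data.frame(element = el, charge = 0L,
                      x = xyz[seq_len(n), 1], y = xyz[seq_len(n), 2],
                      z = xyz[seq_len(n), 3]),
           bonds, id = id)
}

#' Generate a toy molecule library
#'
#' Valence-valid random molecules with deterministic template 3D geometry
#' (ideal bond lengths, repulsion-spread directions). The same spec yields
#' the same library.
#'
#' @param spec a [fixture_spec()].
#' @param sdf_path optional path; when given the library is also written as
#'   an SDF file.
#' @return list of [molecule()] objects.
#' @export
generate_library <- function(spec, sdf_path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  mols <- qv_with_seed(spec$seed, {
    lapply(seq_len(spec$n_compounds), function(i)
      qv_random_molecule(sprintf("CMP%06d", i),
                         sample(spec$n_heavy[1]:spec$n_heavy[2], 1),
                         spec$elements))
  })
  if (!is.null(sdf_path)) write_sdf(mols, sdf_path)
  mols
}

#' Generate activity records for a library
#'
#' Activity follows the spec's descriptor rule: the driving descriptor is
#' evaluated for every molecule and compounds above its
#' (1 - base fraction) quantile are active, after which labels are flipped
#' with the noise probability. Actives draw potencies log-uniformly from
#' the 0.1-25 uM range (a fraction left unmeasured); inactives are set to
#' 1 mM. Records are returned pIC50-transformed.
#'
#' @param library list of molecules from [generate_library()].
#' @param spec the [fixture_spec()].
#' @param features optional precomputed feature matrix covering the rule's
#'   descriptor group (saves re-encoding).
#' @return data.frame of activity records (compound_id, is_active,
#'   potency_uM, p_activity) with attribute `"rule_group"`.
#' @export
generate_activity <- function(library, spec, features = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  cfg <- descriptor_config()
  gname <- spec$activity_rule$group
  if (!gname %in% cfg$name) stop("unknown rule group '", gname, "'",
                                 call. = FALSE)
  if (is.null(features)) {
    cfg_rule <- cfg[cfg$name == gname, , drop = FALSE]
    class(cfg_rule) <- c("descriptor_config", "data.frame")
    features <- assemble_feature_matrix(library, cfg_rule)
    v <- features[, 1]
  } else {
    gm <- feature_groups(features)
    g <- gm[gm$name == gname, ]
    v <- features[, g$start]
  }
  ids <- vapply(library, function(m) m$id, character(1))
  v <- v[match(ids, rownames(features))]
  thr <- stats::quantile(v, 1 - spec$base_active_fraction, names = FALSE)
  active <- v > thr
  qv_with_seed(spec$seed + 1L, {
    if (spec$noise > 0) {
      flip <- stats::runif(length(active)) < spec$noise
      active <- xor(active, flip)
    }
    pot <- rep(NA_real_, length(active))
    n_act <- sum(active)
    if (n_act) {
      p <- 10^stats::runif(n_act, log10(0.1), log10(25))
      p[stats::runif(n_act) > spec$measured_fraction] <- NA
      pot[active] <- p
    }
    rec <- p_activity_transform(
      data.frame(compound_id = ids, is_active = active, potency_uM = pot,
                 stringsAsFactors = FALSE))
    attr(rec, "rule_group") <- gname
    rec
  })
}

#' Generate assay tables for a curation scenario
#'
#' Emits primary/confirmatory/counter outcome tables with planted overlaps
#' together with the ground-truth curated sets, for exercising the
#' set-algebra engine. Two scenarios ship: `"subtract"` (one confirmatory
#' screen minus one counter screen) and `"kcnq2"` (a confirmatory screen
#' minus three counter screens, the shape of the KCNQ2 potentiator recipe).
#'
#' @param scenario `"subtract"` or `"kcnq2"`.
#' @param seed integer seed.
#' @param n_compounds library size.
#' @return list with `tables` (named list of [assay_table()]), `recipe`
#'   (a [curation_recipe()]) and `expected` (list of active_ids /
#'   inactive_ids ground truth).
#' @export
generate_assay_tables <- function(scenario = c("subtract", "kcnq2"), seed,
                                  n_compounds = 500L) {
  scenario <- match.arg(scenario)
  stopifnot(!missing(seed))
  qv_with_seed(seed, {
    ids <- sprintf("CID%05d", seq_len(n_compounds))
    primary_active <- sample(ids, max(20L, round(n_compounds * 0.1)))
    primary <- assay_table("primary", data.frame(
      compound_id = ids,
      outcome = ifelse(ids %in% primary_active, "active", "inactive"),
      stringsAsFactors = FALSE))
    confirmed <- sample(primary_active, round(length(primary_active) * 0.6))
    confirm <- assay_table("confirm", data.frame(
      compound_id = primary_active,
      outcome = ifelse(primary_active %in% confirmed, "active", "inactive"),
      stringsAsFactors = FALSE))
    n_counter <- if (scenario == "subtract") 1L else 3L
    counters <- list()
    planted <- character()
    for (ci in seq_len(n_counter)) {
      hits <- sample(confirmed, max(1L, round(length(confirmed) * 0.12)))
      planted <- union(planted, hits)
      counters[[paste0("counter", ci)]] <- assay_table(
        paste0("counter", ci),
        data.frame(compound_id = primary_active,
                   outcome = ifelse(primary_active %in% hits,
                                    "active", "inactive"),
                   stringsAsFactors = FALSE))
    }
    expr <- list(op = "subtract", args = c(
      list(list(assay = "confirm", set = "active")),
      lapply(names(counters), function(nm) list(assay = nm, set = "active"))))
    recipe <- curation_recipe(paste0("toy_", scenario), expr, "primary")
    expected_active <- sort(setdiff(confirmed, planted))
    expected_inactive <- sort(setdiff(setdiff(ids, primary_active),
                                      expected_active))
    list(tables = c(list(primary = primary, confirm = confirm), counters),
         recipe = recipe,
         expected = list(active_ids = expected_active,
                         inactive_ids = expected_inactive))
  })
}

#' The standard end-to-end synthetic benchmark fixture
#'
#' A library with one informative descriptor group (activity is a threshold
#' on that group's first bin), a 1:100 active:inactive ratio, and n = 5,000
#' compounds by default: the package's scaled-down stand-in for a curated
#' HTS campaign. Returns the assembled dataset ready for splitting,
#' selection, training and evaluation.
#'
#' @param seed integer seed.
#' @param n_compounds library size.
#' @param base_active_fraction active fraction (default 0.01, i.e. 1:100).
#' @param config descriptor configuration for the feature matrix.
#' @return a [qsar_dataset()]; provenance records spec and rule group.
#' @export
standard_fixture <- function(seed, n_compounds = 5000L,
                             base_active_fraction = 0.01,
                             config = descriptor_config()) {
  spec <- fixture_spec(n_compounds = n_compounds, seed = seed,
                       base_active_fraction = base_active_fraction)
  lib <- generate_library(spec)
  fm <- assemble_feature_matrix(lib, config)
  rec <- generate_activity(lib, spec, features = fm)
  qsar_dataset(fm, rec,
               provenance = list(fixture = unclass(spec),
                                 rule_group = attr(rec, "rule_group")))
}
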