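# Fixed-length molecular descriptor encoding: scalar properties plus 2D/3D
# autocorrelation and radial-distribution fingerprints of per-atom
# properties, each optionally weighted by van der Waals surface area.

#' Descriptor configuration
#'
#' Builds the ordered list of descriptor groups that defines the feature
#' vector layout. The default catalogue has 60 groups and 1,284 values: six
#' scalar descriptors plus, for each of the nine per-atom properties, an
#' unweighted and a VdW-surface-weighted variant of the three encoders
#' (2D autocorrelation over 11 topological-distance bins, 3D autocorrelation
#' over 12 x 1.0 Angstrom bins, radial distribution function on 48 grid
#' points), i.e. 6 + 9 x 2 x (11 + 12 + 48).
#'
#' @param include_3d keep the geometry-based groups (3D autocorrelation and
#'   RDF). Set `FALSE` for libraries without coordinates, leaving
#'   6 + 9 x 2 x 11 = 204 values.
#' @param ac2d_bins,ac3d_bins,ac3d_width,rdf_bins,rdf_step,rdf_b encoder
#'   resolution parameters (bond counts, Angstrom, Angstrom^-2).
#' @return data.frame of class `"descriptor_config"` with one row per group
#'   (columns `name`, `kind`, `property_id`, `weighted`, `n_bins`,
#'   `bin_width`, `rdf_b`); `sum(cfg$n_bins)` is the feature-vector length.
#' @examples
#' cfg <- descriptor_config()
#' nrow(cfg)            # 60 groups
#' sum(cfg$n_bins)      # 1284 values
#' @export
descriptor_config <- function(include_3d = TRUE,
                              ac2d_bins = 11L,
                              ac3d_bins = 12L, ac3d_width = 1.0,
                              rdf_bins = 48L, rdf_step = 0.1, rdf_b = 100) {
  scalars <- c("mw", "hbd", "hba", "logp", "charge", "tpsa")
  rows <- data.frame(name = scalars, kind = "scalar", property_id = scalars,
                     weighted = FALSE, n_bins = 1L, bin_width = NA_real_,
                     rdf_b = NA_real_, stringsAsFactors = FALSE)
  kinds <- if (include_3d) c("ac2d", "ac3d", "rdf") else "ac2d"
  for (prop in QV_ATOM_PROPERTIES) {
    for (w in c(FALSE, TRUE)) {
      for (kind in kinds) {
        nb <- switch(kind, ac2d = ac2d_bins, ac3d = ac3d_bins, rdf = rdf_bins)
        bw <- switch(kind, ac2d = 1, ac3d = ac3d_width, rdf = rdf_step)
        rows <- rbind(rows, data.frame(
          name = paste0(kind, ".", prop, if (w) ".w" else ""),
          kind = kind, property_id = prop, weighted = w,
          n_bins = as.integer(nb), bin_width = bw,
          rdf_b = if (kind == "rdf") rdf_b else NA_real_,
          stringsAsFactors = FALSE))
      }
    }
  }
  class(rows) <- c("descriptor_config", "data.frame")
  rows
}

#' @rdname descriptor_config
#' @param cfg a descriptor configuration.
#' @param path JSON file path.
#' @export
write_descriptor_config <- function(cfg, path) {
  jsonlite::write_json(as.data.frame(cfg), path, digits = NA)
  invisible(path)
}

#' @rdname descriptor_config
#' @export
read_descriptor_config <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  cfg$n_bins <- as.integer(cfg$n_bins)
  class(cfg) <- c("descriptor_config", "data.frame")
  cfg
}

#' 2D autocorrelation fingerprint
#'
#' Sum of atom-property products over unordered atom pairs binned by
#' topological (bond count) distance: bin d holds
#' \eqn{\sum_{i \le j, d_{ij}=d} p_i p_j}. Bin 0 holds the self-pair terms
#' \eqn{p_i^2}; unreachable pairs and pairs beyond `n_bins - 1` bonds are
#' ignored.
#'
#' @param mol a [molecule()].
#' @param property_values numeric vector aligned with the atoms of `mol`.
#' @param n_bins number of distance bins (bin d = exactly d bonds).
#' @param atom_mask optional logical vector marking the atoms that
#'   participate in pairs (see [participating_atoms()]).
#' @return numeric vector of length `n_bins`.
#' @export
autocorrelation_2d <- function(mol, property_values, n_bins = 11L,
                               atom_mask = NULL) {
  stopifnot(length(property_values) == n_atoms(mol))
  d <- topological_distances(mol)
  qv_pair_bins(property_values, d, n_bins, width = 1, atom_mask)
}

#' 3D autocorrelation fingerprint
#'
#' As [autocorrelation_2d()] but binned on Euclidean distance; bin k covers
#' the half-open interval \[k w, (k+1) w). Self-pairs fall in bin 0; pairs
#' beyond the covered range are ignored.
#'
#' @inheritParams autocorrelation_2d
#' @param bin_width bin width in Angstrom.
#' @return numeric vector of length `n_bins`.
#' @export
autocorrelation_3d <- function(mol, property_values, n_bins = 12L,
                               bin_width = 1.0, atom_mask = NULL) {
  stopifnot(length(property_values) == n_atoms(mol))
  xyz <- coords(mol)  # errors without geometry
  d <- as.matrix(stats::dist(xyz))
  qv_pair_bins(property_values, d, n_bins, width = bin_width, atom_mask)
}

# shared pair-binning core: self-pairs in bin 0, unordered pairs once
qv_pair_bins <- function(p, d, n_bins, width, atom_mask) {
  keep <- if (is.null(atom_mask)) seq_along(p) else which(atom_mask)
  out <- numeric(n_bins)
  if (!length(keep)) return(out)
  p <- p[keep]
  d <- d[keep, keep, drop = FALSE]
  out[1] <- sum(p^2)
  n <- length(p)
  if (n > 1) {
    ut <- upper.tri(d)
    bin <- floor(d[ut] / width)
    prod <- tcrossprod(p)[ut]
    ok <- is.finite(bin) & bin >= 0 & bin < n_bins
    # distance-zero coincident pairs still land in bin 0 alongside self terms
    if (any(ok)) {
      agg <- rowsum(prod[ok], bin[ok])
      out[as.integer(rownames(agg)) + 1L] <- out[as.integer(rownames(agg)) + 1L] +
        agg[, 1]
    }
  }
  out
}

#' Radial distribution function fingerprint
#'
#' Gaussian-smoothed distribution of atom-property products over interatomic
#' distances: \eqn{g(r_k) = \sum_{i<j} p_i p_j e^{-B (r_k - d_{ij})^2}},
#' evaluated on a fixed grid.
#'
#' @inheritParams autocorrelation_2d
#' @param r_grid distance grid in Angstrom.
#' @param B smoothing parameter in Angstrom^-2.
#' @return numeric vector of length `length(r_grid)`.
#' @export
radial_distribution <- function(mol, property_values,
                                r_grid = seq(0.1, 4.8, by = 0.1), B = 100,
                                atom_mask = NULL) {
  stopifnot(length(property_values) == n_atoms(mol))
  xyz <- coords(mol)
  keep <- if (is.null(atom_mask)) seq_len(n_atoms(mol)) else which(atom_mask)
  p <- property_values[keep]
  if (length(p) < 2) return(numeric(length(r_grid)))
  d <- as.matrix(stats::dist(xyz[keep, , drop = FALSE]))
  ut <- upper.tri(d)
  dij <- d[ut]
  prods <- tcrossprod(p)[ut]
  as.numeric(exp(-B * outer(r_grid, dij, "-")^2) %*% prods)
}

#' VdW-surface weighting of a property vector
#'
#' Elementwise product of property values and per-atom van der Waals surface
#' areas, producing the weighted variant fed to any encoder.
#'
#' @param property_values numeric vector.
#' @param vdw_surface_areas numeric vector of equal length (Angstrom^2).
#' @return numeric vector.
#' @export
weighted_property <- function(property_values, vdw_surface_areas) {
  if (length(property_values) != length(vdw_surface_areas))
    stop("property and surface-area vectors differ in length", call. = FALSE)
  property_values * vdw_surface_areas
}

#' Atoms participating in descriptor pairs
#'
#' By default heavy atoms and polar hydrogens (bonded to N, O, S or P) enter
#' the pairwise encoders; apolar hydrogens are excluded. Implicit hydrogens
#' never appear as pair partners (they carry no geometry) but do contribute
#' to the per-atom property values.
#'
#' @param mol a [molecule()].
#' @param include_h `"polar"` (default), `"all"`, or `"none"`.
#' @return logical vector over atoms.
#' @export
participating_atoms <- function(mol, include_h = c("polar", "all", "none")) {
  include_h <- match.arg(include_h)
  el <- mol$atoms$element
  mask <- el != "H"
  if (include_h == "all") mask[] <- TRUE
  if (include_h == "polar" && any(!mask)) {
    polar_partner <- c("N", "O", "S", "P")
    for (i in which(!mask)) {
      nb <- c(mol$bonds$to[mol$bonds$from == i], mol$bonds$from[mol$bonds$to == i])
      if (any(el[nb] %in% polar_partner)) mask[i] <- TRUE
    }
  }
  mask
}

#' Scalar molecular descriptors
#'
#' The six whole-molecule scalars: molecular weight (implicit hydrogens
#' included), hydrogen-bond donor count (N/O atoms bearing at least one
#' hydrogen), hydrogen-bond acceptor count (N/O atoms), octanol/water
#' partition coefficient, net formal charge, and topological polar surface
#' area. logP uses a reduced atomic-contribution scheme with
#' Wildman-Crippen-style per-element terms; TPSA sums published Ertl
#' fragment contributions for the N/O/S/P environments the molecule model
#' can express (see the methods vignette for the exact tables and their
#' limits).
#'
#' @param mols a [molecule()] or list of molecules.
#' @return matrix with columns `mw`, `hbd`, `hba`, `logp`, `charge`, `tpsa`,
#'   one row per molecule.
#' @export
scalar_descriptors <- function(mols) {
  if (is_molecule(mols)) mols <- list(mols)
  out <- t(vapply(mols, function(m) {
    env <- qv_atom_env(m)
    el <- m$atoms$element
    mw <- sum(element_param(el, "mass")) +
      sum(m$atoms$n_implicit_h) * element_param("H", "mass")
    no <- el %in% c("N", "O")
    c(mw = mw,
      hbd = sum(no & env$n_h > 0),
      hba = sum(no),
      logp = qv_logp(m, env),
      charge = sum(m$atoms$charge),
      tpsa = qv_tpsa(m, env))
  }, numeric(6)))
  rownames(out) <- vapply(mols, function(m) m$id, character(1))
  out
}

# per-atom bonding environment: total attached hydrogens, double/triple/
# aromatic bond involvement, bonded-to-heteroatom flags
qv_atom_env <- function(m) {
  n <- n_atoms(m)
  el <- m$atoms$element
  n_h <- as.integer(m$atoms$n_implicit_h)
  n_double <- integer(n); n_triple <- integer(n); aromatic <- logical(n)
  het_neighbour <- logical(n)
  h_parent <- logical(n)   # heteroatom-bonded explicit hydrogens
  if (nrow(m$bonds)) {
    het <- !(el %in% c("C", "H"))
    for (k in seq_len(nrow(m$bonds))) {
      i <- m$bonds$from[k]; j <- m$bonds$to[k]; o <- m$bonds$order[k]
      if (el[i] == "H") n_h[j] <- n_h[j] + 1L
      if (el[j] == "H") n_h[i] <- n_h[i] + 1L
      if (el[i] == "H" && het[j]) h_parent[i] <- TRUE
      if (el[j] == "H" && het[i]) h_parent[j] <- TRUE
      if (o == 2) { n_double[i] <- n_double[i] + 1L
                    n_double[j] <- n_double[j] + 1L }
      if (o == 3) { n_triple[i] <- n_triple[i] + 1L
                    n_triple[j] <- n_triple[j] + 1L }
      if (o == 1.5) { aromatic[i] <- TRUE; aromatic[j] <- TRUE }
      if (het[j]) het_neighbour[i] <- TRUE
      if (het[i]) het_neighbour[j] <- TRUE
    }
  }
  list(n_h = n_h, n_double = n_double, n_triple = n_triple,
       aromatic = aromatic, het_neighbour = het_neighbour,
       h_on_het = h_parent)
}

# Reduced octanol/water partition coefficient: coarse Wildman-Crippen-style
# atomic contributions (per heavy atom plus attached hydrogens).
qv_logp <- function(m, env = qv_atom_env(m)) {
  el <- m$atoms$element
  contrib <- numeric(length(el))
  for (i in seq_along(el)) {
    contrib[i] <- switch(el[i],
      H = if (env$h_on_het[i]) -0.2677 else 0,  # C-bound H counted below
      C = if (env$aromatic[i]) 0.2955 else 0.1441,
      N = -0.6,
      O = if (env$n_double[i] > 0) -0.1188 else -0.2893,
      F = 0.4202, Cl = 0.6895, Br = 0.8456, I = 0.8857,
      S = 0.6482, P = 0.8612, 0)
    if (el[i] == "C")
      contrib[i] <- contrib[i] + 0.1230 * env$n_h[i]
    if (el[i] %in% c("N", "O", "S"))
      contrib[i] <- contrib[i] - 0.2677 * m$atoms$n_implicit_h[i]
  }
  sum(contrib)
}

# Reduced topological polar surface area: published Ertl fragment values for
# the nitrogen/oxygen/sulfur/phosphorus environments expressible here.
qv_tpsa <- function(m, env = qv_atom_env(m)) {
  el <- m$atoms$element
  total <- 0
  for (i in seq_along(el)) {
    nh <- env$n_h[i]; nd <- env$n_double[i]; nt <- env$n_triple[i]
    q <- m$atoms$charge[i]
    total <- total + switch(el[i],
      N = {
        if (q > 0) {
          if (nh >= 3) 27.64 else if (nh == 2) 16.61
          else if (nh == 1) 13.97 else 0.00
        } else if (env$aromatic[i]) {
          if (nh > 0) 15.79 else 12.89
        } else if (nt > 0) 23.79
        else if (nd > 0) { if (nh > 0) 23.85 else 12.36 }
        else if (nh >= 2) 26.02 else if (nh == 1) 12.03 else 3.24
      },
      O = {
        if (q < 0) 23.06
        else if (env$aromatic[i]) 13.14
        else if (nd > 0) 17.07
        else if (nh > 0) 20.23 else 9.23
      },
      S = {
        if (nd > 0) 32.09 else if (nh > 0) 38.80 else 25.30
      },
      P = 13.59,
      0)
  }
  total
}

#' Assemble the feature matrix for a molecule library
#'
#' Encodes every molecule under a descriptor configuration into one row of a
#' compounds x descriptors matrix. Molecules failing any group (e.g. missing
#' 3D coordinates when a geometry group is configured) are excluded with a
#' warning and listed in the `"failed"` attribute.
#'
#' @param mols list of [molecule()] objects.
#' @param config a [descriptor_config()].
#' @param include_h hydrogen participation policy, see
#'   [participating_atoms()].
#' @return numeric matrix of class `"feature_matrix"`; rownames are compound
#'   ids, attribute `"groups"` maps columns to descriptor groups, attribute
#'   `"failed"` names excluded compounds.
#' @examples
#' \donttest{
#' lib <- generate_library(fixture_spec(n_compounds = 5, seed = 1))
#' fm <- assemble_feature_matrix(lib, descriptor_config())
#' dim(fm)
#' }
#' @export
assemble_feature_matrix <- function(mols, config = descriptor_config(),
                                    include_h = "polar") {
  stopifnot(inherits(config, "descriptor_config"))
  total <- sum(config$n_bins)
  scal_idx <- which(config$kind == "scalar")
  needs_props <- any(config$kind != "scalar")
  scalars <- if (length(scal_idx)) scalar_descriptors(mols) else NULL
  rows <- vector("list", length(mols))
  failed <- character()
  for (mi in seq_along(mols)) {
    m <- mols[[mi]]
    row <- tryCatch(
      qv_encode_molecule(m, config, scalars[mi, ], include_h),
      error = function(e) e)
    if (inherits(row, "error")) {
      failed <- c(failed, paste0(m$id, ": ", conditionMessage(row)))
      rows[mi] <- list(NULL)
    } else rows[[mi]] <- row
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (length(failed))
    warning(length(failed), " molecule(s) excluded from feature matrix",
            call. = FALSE)
  fm <- do.call(rbind, rows[keep])
  if (is.null(fm)) fm <- matrix(numeric(0), 0, total)
  rownames(fm) <- vapply(mols[keep], function(m) m$id, character(1))
  colnames(fm) <- qv_column_names(config)
  structure(fm, groups = qv_group_map(config), failed = failed,
            class = c("feature_matrix", class(fm)))
}

qv_column_names <- function(config) {
  unlist(lapply(seq_len(nrow(config)), function(g) {
    if (config$n_bins[g] == 1L) config$name[g]
    else paste0(config$name[g], ".", seq_len(config$n_bins[g]) - 1L)
  }))
}

qv_group_map <- function(config) {
  ends <- cumsum(config$n_bins)
  data.frame(group = seq_len(nrow(config)), name = config$name,
             start = c(1L, head(ends, -1L) + 1L), end = ends,
             stringsAsFactors = FALSE)
}

# Per-molecule encoding with cached pair data: topological and Euclidean
# pair distances and the RDF Gaussian kernel are computed once and shared by
# all property variants, which is what makes full-library featurisation
# tractable.
qv_encode_molecule <- function(m, config, scalar_row, include_h) {
  out <- numeric(sum(config$n_bins))
  pos <- 1L
  cache <- NULL
  for (g in seq_len(nrow(config))) {
    nb <- config$n_bins[g]
    kind <- config$kind[g]
    if (kind == "scalar") {
      out[pos] <- scalar_row[[config$property_id[g]]]
    } else {
      if (is.null(cache)) cache <- qv_pair_cache(m, config, include_h)
      p <- cache$props[[config$property_id[g]]][cache$keep]
      if (config$weighted[g]) p <- p * cache$vdw
      prods <- if (length(p) > 1) p[cache$pi] * p[cache$pj] else numeric(0)
      vec <- numeric(nb)
      vec[1] <- if (kind != "rdf") sum(p^2) else 0
      if (length(prods)) {
        if (kind == "ac2d" || kind == "ac3d") {
          bin <- if (kind == "ac2d") cache$bin2d
                 else floor(cache$deucl / config$bin_width[g])
          ok <- is.finite(bin) & bin >= 0 & bin < nb
          if (any(ok)) {
            agg <- rowsum(prods[ok], bin[ok])
            ix <- as.integer(rownames(agg)) + 1L
            vec[ix] <- vec[ix] + agg[, 1]
          }
        } else {
          vec <- as.numeric(cache$rdf_kernel %*% prods)
        }
      }
      out[pos:(pos + nb - 1L)] <- vec
    }
    pos <- pos + nb
  }
  out
}

qv_pair_cache <- function(m, config, include_h) {
  props <- atom_property_table(m)
  mask <- participating_atoms(m, include_h)
  keep <- which(mask)
  n <- length(keep)
  cache <- list(props = props, keep = keep,
                vdw = props$vdw_surface_area[keep])
  if (n > 1) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    cache$pi <- pairs[, 1]; cache$pj <- pairs[, 2]
    if (any(config$kind == "ac2d")) {
      dt <- topological_distances(m)[keep, keep, drop = FALSE]
      cache$bin2d <- dt[upper.tri(dt)]
    }
    if (any(config$kind %in% c("ac3d", "rdf"))) {
      d3 <- as.matrix(stats::dist(coords(m)[keep, , drop = FALSE]))
      cache$deucl <- d3[upper.tri(d3)]
    }
    rg <- which(config$kind == "rdf")
    if (length(rg)) {
      r_grid <- seq_len(config$n_bins[rg[1]]) * config$bin_width[rg[1]]
      cache$rdf_kernel <- exp(-config$rdf_b[rg[1]] *
                                outer(r_grid, cache$deucl, "-")^2)
    }
  } else {
    cache$pi <- integer(0); cache$pj <- integer(0)
  }
  cache
}

#' @rdname assemble_feature_matrix
#' @param fm a feature matrix.
#' @export
feature_groups <- function(fm) attr(fm, "groups")

#' Persist or load a feature matrix as CSV
#'
#' @param fm a feature matrix.
#' @param path CSV file path (header = `group.bin` names, first column the
#'   compound id).
#' @return `write_feature_csv` returns `path` invisibly; `read_feature_csv`
#'   the matrix (group metadata is rebuilt from the supplied config).
#' @export
write_feature_csv <- function(fm, path) {
  df <- data.frame(compound_id = rownames(fm), as.data.frame(unclass(fm)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @param config the descriptor configuration the matrix was built with.
#' @export
read_feature_csv <- function(path, config = descriptor_config()) {
  df <- utils::read.csv(path, check.names = FALSE)
  fm <- as.matrix(df[, -1, drop = FALSE])
  rownames(fm) <- df[[1]]
  structure(fm, groups = qv_group_map(config), failed = character(),
            class = c("feature_matrix", class(fm)))
}
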