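# Molecular graph data model and SDF V2000 I/O.

#' Construct a molecule
#'
#' A molecule is an atom/bond graph with optional 3D coordinates, the
#' substrate for all descriptor calculations. Implicit hydrogen counts are
#' derived from the default valence of each element, adjusted for formal
#' charge; they participate in atom-property iterations but are not explicit
#' graph nodes.
#'
#' @param atoms data.frame with columns `element` (symbol), `charge`
#'   (integer formal charge, e) and optionally `x`, `y`, `z` (Angstrom).
#'   Coordinates must be all present or all absent.
#' @param bonds data.frame with columns `from`, `to` (1-based atom indices)
#'   and `order` (1, 2, 3, or 1.5 for aromatic). May have zero rows.
#' @param id compound identifier string.
#' @return object of class `"molecule"`.
#' @examples
#' m <- molecule(data.frame(element = c("C", "O"), charge = 0),
#'               data.frame(from = 1, to = 2, order = 2), id = "CO")
#' n_atoms(m)
#' @export
molecule <- function(atoms, bonds = NULL, id = "mol") {
  stopifnot(is.data.frame(atoms), all(c("element") %in% names(atoms)))
  if (is.null(atoms$charge)) atoms$charge <- 0L
  atoms$charge <- as.integer(atoms$charge)
  element_param(atoms$element, "z")  # validates symbols
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(from = integer(), to = integer(), order = numeric())
  }
  bonds <- as.data.frame(bonds)
  stopifnot(all(c("from", "to", "order") %in% names(bonds)))
  n <- nrow(atoms)
  if (nrow(bonds)) {
    if (any(bonds$from < 1 | bonds$from > n | bonds$to < 1 | bonds$to > n))
      stop("bond endpoint out of range", call. = FALSE)
    if (any(bonds$from == bonds$to))
      stop("self-bond not allowed", call. = FALSE)
    key <- paste(pmin(bonds$from, bonds$to), pmax(bonds$from, bonds$to))
    if (anyDuplicated(key)) stop("duplicate bond", call. = FALSE)
  }
  has_xyz <- all(c("x", "y", "z") %in% names(atoms)) &&
    !anyNA(atoms$x) && !anyNA(atoms$y) && !anyNA(atoms$z)
  if (any(c("x", "y", "z") %in% names(atoms)) && !has_xyz &&
      !all(is.na(atoms$x)))
    stop("coordinates must be all present or all absent", call. = FALSE)
  m <- structure(
    list(atoms = atoms, bonds = bonds, id = as.character(id),
         has_coords = has_xyz),
    class = "molecule")
  m$atoms$n_implicit_h <- implicit_h_counts(m)
  m
}

#' @rdname molecule
#' @param x,object a molecule.
#' @export
is_molecule <- function(x) inherits(x, "molecule")

#' @rdname molecule
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' @rdname molecule
#' @export
has_coords <- function(x) isTRUE(x$has_coords)

#' @rdname molecule
#' @param ... ignored.
#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d atoms, %d bonds, %s, net charge %+d>\n",
              x$id, n_atoms(x), nrow(x$bonds),
              if (has_coords(x)) "3D" else "2D",
              sum(x$atoms$charge)))
  invisible(x)
}

#' @rdname molecule
#' @export
coords <- function(x) {
  if (!has_coords(x)) stop("molecule '", x$id, "' carries no 3D coordinates",
                           call. = FALSE)
  as.matrix(x$atoms[, c("x", "y", "z")])
}

# Implicit hydrogens from default valence, charge-adjusted: N+/O+ gain a
# bond, N-/O- lose one, charged carbon loses |q|, monovalent atoms none.
implicit_h_counts <- function(mol) {
  a <- mol$atoms
  val <- element_param(a$element, "valence")
  adj <- ifelse(a$element == "C" | a$element == "H",
                val - abs(a$charge), val + a$charge)
  bsum <- numeric(nrow(a))
  if (nrow(mol$bonds)) {
    bs <- rowsum(c(mol$bonds$order, mol$bonds$order),
                 c(mol$bonds$from, mol$bonds$to))
    bsum[as.integer(rownames(bs))] <- bs[, 1]
  }
  pmax(0L, as.integer(round(adj - bsum + 1e-9)))
}

# Degree-ordered hybridisation from bond orders: any triple or two doubles ->
# sp; any double/aromatic -> sp2; else sp3. Heteroatoms with a lone pair
# conjugated into an adjacent pi system (N/O/S single-bonded to a
# double-bonded or aromatic atom, as in amides and carboxyls) count as sp2.
atom_hybridisation <- function(mol) {
  n <- n_atoms(mol)
  hyb <- rep("sp3", n)
  if (nrow(mol$bonds)) {
    b <- mol$bonds
    for (i in seq_len(nrow(b))) {
      for (at in c(b$from[i], b$to[i])) {
        if (b$order[i] == 3) hyb[at] <- "sp"
        else if (b$order[i] >= 1.5 && hyb[at] == "sp3") hyb[at] <- "sp2"
        else if (b$order[i] == 2 && hyb[at] == "sp2") hyb[at] <- "sp"
      }
    }
    el <- mol$atoms$element
    for (i in which(hyb == "sp3" & el %in% c("N", "O", "S"))) {
      nb <- c(b$to[b$from == i], b$from[b$to == i])
      if (any(hyb[nb] != "sp3")) hyb[i] <- "sp2"
    }
  }
  hyb
}

#' Topological distance matrix
#'
#' Shortest-path distances in bond counts between all atom pairs, required by
#' the 2D autocorrelation encoder. Pairs in different connected components
#' are unreachable and reported as `Inf`.
#'
#' @param mol a [molecule()].
#' @return integer-valued symmetric matrix with zero diagonal; `Inf` marks
#'   unreachable pairs.
#' @examples
#' m <- molecule(data.frame(element = c("C", "C"), charge = 0),
#'               data.frame(from = 1, to = 2, order = 1))
#' topological_distances(m)
#' @export
topological_distances <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(matrix(numeric(0), 0, 0))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(mol$bonds))
    g <- igraph::add_edges(g, rbind(mol$bonds$from, mol$bonds$to))
  d <- igraph::distances(g)
  dimnames(d) <- NULL
  d
}

#' Read molecules from an SDF (V2000) file
#'
#' Parses a multi-record V2000 SDF. Records whose connection table fails to
#' parse are skipped with a warning and counted; V3000 records are a hard
#' error. An all-zero coordinate block is taken to mean "no 3D
#' information" and yields a molecule without coordinates.
#'
#' @param source path to an SDF file.
#' @return list of [molecule()] objects; attribute `"n_skipped"` carries the
#'   number of unparseable records.
#' @export
read_sdf <- function(source) {
  if (!file.exists(source)) stop("cannot read '", source, "'", call. = FALSE)
  lines <- readLines(source, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    out <- list(); attr(out, "n_skipped") <- 0L; return(out)
  }
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- list()
  skipped <- 0L
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:ends[r]]
    rec <- rec[!grepl("^\\$\\$\\$\\$", rec)]
    if (all(!nzchar(trimws(rec)))) next
    if (any(grepl("V3000", rec, fixed = TRUE)))
      stop("V3000 record (#", r, ") is not supported", call. = FALSE)
    m <- tryCatch(parse_sdf_record(rec, r), error = function(e) NULL)
    if (is.null(m)) {
      skipped <- skipped + 1L
      warning("skipping unparseable SDF record #", r, call. = FALSE)
    } else out[[length(out) + 1L]] <- m
  }
  attr(out, "n_skipped") <- skipped
  out
}

# One V2000 record -> molecule. Fixed-width connection-table parse; M CHG
# property lines override atom-line charge codes. Parsed in-package because
# the general SDF container classes reject single-atom and bond-free
# records, which are legal inputs here.
parse_sdf_record <- function(rec, idx) {
  if (length(rec) < 4) stop("truncated record")
  natoms <- suppressWarnings(as.integer(substr(rec[4], 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(rec[4], 4, 6)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1 ||
      length(rec) < 4 + natoms + nbonds)
    stop("malformed counts line")
  al <- rec[4 + seq_len(natoms)]
  xyz <- suppressWarnings(cbind(as.numeric(substr(al, 1, 10)),
                                as.numeric(substr(al, 11, 20)),
                                as.numeric(substr(al, 21, 30))))
  elements <- trimws(substr(al, 31, 34))
  if (anyNA(xyz) || any(!nzchar(elements))) stop("malformed atom block")
  charges <- parse_sdf_charges(rec, natoms)
  atoms <- data.frame(element = elements, charge = charges,
                      stringsAsFactors = FALSE)
  if (any(abs(xyz) > 0)) {
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  }
  bonds <- NULL
  if (nbonds > 0) {
    bl <- rec[4 + natoms + seq_len(nbonds)]
    ord <- as.numeric(substr(bl, 7, 9))
    ord[ord == 4] <- 1.5  # aromatic flag
    bonds <- data.frame(from = as.integer(substr(bl, 1, 3)),
                        to = as.integer(substr(bl, 4, 6)),
                        order = ord)
    if (anyNA(bonds)) stop("malformed bond block")
  }
  id <- trimws(rec[1])
  if (!nzchar(id)) id <- paste0("record_", idx)
  molecule(atoms, bonds, id = id)
}

parse_sdf_charges <- function(rec, n) {
  # atom-line charge codes (field 6): 1..3 -> +3..+1, 5..7 -> -1..-3
  natoms <- as.integer(substr(rec[4], 1, 3))
  atom_lines <- rec[5:(4 + natoms)]
  code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  code[is.na(code)] <- 0L
  charges <- ifelse(code >= 1 & code <= 3, 4L - code,
                    ifelse(code >= 5 & code <= 7, 4L - code, 0L))
  chg_lines <- grep("^M  CHG", rec, value = TRUE)
  if (length(chg_lines)) {
    charges[] <- 0L  # M CHG supersedes all atom-line codes
    for (ln in chg_lines) {
      f <- as.integer(regmatches(ln, gregexpr("-?[0-9]+", ln))[[1]])
      k <- f[1]
      pairs <- matrix(f[-1], ncol = 2, byrow = TRUE)[seq_len(k), , drop = FALSE]
      charges[pairs[, 1]] <- pairs[, 2]
    }
  }
  as.integer(charges)
}

#' Write molecules to an SDF (V2000) file
#'
#' @param mols a molecule or list of molecules.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (is_molecule(mols)) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in mols) {
    a <- m$atoms
    nb <- nrow(m$bonds)
    lines <- c(m$id, "  qsarvs", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nb))
    xyz <- if (has_coords(m)) coords(m) else matrix(0, nrow(a), 3)
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              xyz[, 1], xyz[, 2], xyz[, 3], a$element))
    if (nb) {
      ord <- m$bonds$order
      ord_out <- ifelse(ord == 1.5, 4L, as.integer(ord))
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                m$bonds$from, m$bonds$to, ord_out))
    }
    chg <- which(a$charge != 0L)
    if (length(chg)) {
      for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
        lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(grp)),
                                 paste0(sprintf("%4d%4d", grp, a$charge[grp]),
                                        collapse = "")))
      }
    }
    lines <- c(lines, "M  END", "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}
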