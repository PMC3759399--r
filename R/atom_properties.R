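# Per-atom chemical properties: damped partial-equalisation (PEOE) sigma and
# pi charges, orbital electronegativities, distance-damped effective
# polarizability, and van der Waals surface areas.

QV_ATOM_PROPERTIES <- c("identity", "sigma_charge", "pi_charge",
                        "total_charge", "sigma_electronegativity",
                        "pi_electronegativity", "lone_pair_electronegativity",
                        "effective_polarizability", "vc2003_charge")

peoe_sigma_params <- function(elements, hyb) {
  tab <- qv_param_table("peoe_sigma")
  key <- paste(tab$element, tab$hyb)
  idx <- match(paste(elements, hyb), key)
  any_idx <- match(paste(elements, "any"), key)
  idx[is.na(idx)] <- any_idx[is.na(idx)]
  # sp carbons/nitrogens etc. that lack an "sp" row fall back to sp2, then sp3
  for (fb in c("sp2", "sp3")) {
    fbi <- match(paste(elements, fb), key)
    idx[is.na(idx)] <- fbi[is.na(idx)]
  }
  if (anyNA(idx))
    stop("no sigma electronegativity parameters for element(s): ",
         paste(unique(elements[is.na(idx)]), collapse = ", "), call. = FALSE)
  tab[idx, c("a", "b", "c")]
}

# Damped partial equalisation of orbital electronegativity. Implicit
# hydrogens are expanded into pseudo-atoms for the iteration and their final
# charge folded back into the parent heavy atom, so the per-atom charges sum
# exactly to the molecular formal charge.
peoe_sigma_charges <- function(mol, n_iter = 6, damping = 0.5) {
  a <- mol$atoms
  n <- nrow(a)
  elements <- a$element
  hyb <- atom_hybridisation(mol)
  parent <- seq_len(n)
  bf <- mol$bonds$from; bt <- mol$bonds$to
  nh <- a$n_implicit_h
  for (i in which(nh > 0)) {
    for (k in seq_len(nh[i])) {
      elements <- c(elements, "H"); hyb <- c(hyb, "any")
      parent <- c(parent, i)
      bf <- c(bf, i); bt <- c(bt, length(elements))
    }
  }
  m <- length(elements)
  par <- peoe_sigma_params(elements, hyb)
  q <- c(as.numeric(a$charge), rep(0, m - n))
  chi_plus <- par$a + par$b + par$c
  chi_plus[elements == "H"] <- 20.02
  if (length(bf)) {
    for (it in seq_len(n_iter)) {
      chi <- par$a + par$b * q + par$c * q^2
      dchi <- chi[bt] - chi[bf]
      denom <- ifelse(dchi > 0, chi_plus[bf], chi_plus[bt])
      dq <- dchi / denom * damping^it
      q <- q + tabulate_transfer(bf, bt, dq, m)
    }
  }
  as.numeric(rowsum(q, parent)[, 1])
}

tabulate_transfer <- function(bf, bt, dq, m) {
  out <- numeric(m)
  tf <- rowsum(dq, bf); out[as.integer(rownames(tf))] <- tf[, 1]
  tt <- rowsum(-dq, bt)
  out[as.integer(rownames(tt))] <- out[as.integer(rownames(tt))] + tt[, 1]
  out
}

# Pi charge equalisation over bonds of order >= 1.5, same damped scheme,
# starting from zero pi charge; elements without pi parameters do not
# exchange pi density.
peoe_pi_charges <- function(mol, n_iter = 6, damping = 0.5) {
  n <- n_atoms(mol)
  q <- numeric(n)
  b <- mol$bonds[mol$bonds$order >= 1.5, , drop = FALSE]
  if (!nrow(b)) return(q)
  tab <- qv_param_table("peoe_pi")
  idx <- match(mol$atoms$element, tab$element)
  keep <- !is.na(idx[b$from]) & !is.na(idx[b$to])
  b <- b[keep, , drop = FALSE]
  if (!nrow(b)) return(q)
  a_ <- tab$a[idx]; b_ <- tab$b[idx]; c_ <- tab$c[idx]
  chi_plus <- a_ + b_ + c_
  for (it in seq_len(n_iter)) {
    chi <- a_ + b_ * q + c_ * q^2
    dchi <- chi[b$to] - chi[b$from]
    denom <- ifelse(dchi > 0, chi_plus[b$from], chi_plus[b$to])
    dq <- dchi / denom * damping^it
    q <- q + tabulate_transfer(b$from, b$to, dq, n)
  }
  q
}

atom_electronegativity <- function(mol, kind, q_total) {
  el <- mol$atoms$element
  if (kind == "sigma") {
    par <- peoe_sigma_params(el, atom_hybridisation(mol))
    return(par$a + par$b * q_total + par$c * q_total^2)
  }
  tab <- qv_param_table(if (kind == "pi") "peoe_pi" else "lone_pair")
  idx <- match(el, tab$element)
  chi <- numeric(length(el))
  ok <- !is.na(idx)
  chi[ok] <- tab$a[idx[ok]] + tab$b[idx[ok]] * q_total[ok] +
    tab$c[idx[ok]] * q_total[ok]^2
  chi
}

# Effective polarizability: distance-damped sum of atomic contributions,
# alpha_i = sum_j alpha_j * damp^d(i,j), implicit hydrogens at distance
# d(i, parent) + 1.
effective_polarizability <- function(mol, damp = 0.5) {
  n <- n_atoms(mol)
  alpha <- element_param(mol$atoms$element, "polarizability")
  alpha_h <- element_param("H", "polarizability")
  d <- topological_distances(mol)
  w <- damp^d
  w[!is.finite(d)] <- 0
  base <- as.numeric(w %*% alpha)
  h_contrib <- as.numeric(w %*% (mol$atoms$n_implicit_h * alpha_h * damp))
  base + h_contrib
}

# Van der Waals surface per atom: sphere area minus spherical caps occluded
# by bonded neighbours (explicit at geometric or ideal distance, implicit H
# at ideal distance). Never negative.
vdw_surface_areas <- function(mol) {
  a <- mol$atoms
  n <- nrow(a)
  r <- element_param(a$element, "vdw_r")
  cov <- element_param(a$element, "cov_r")
  r_h <- element_param("H", "vdw_r")
  cov_h <- element_param("H", "cov_r")
  area <- 4 * pi * r^2
  cap <- function(r1, r2, d) {
    # area of the cap of sphere 1 buried in sphere 2
    if (d >= r1 + r2) return(0)
    if (d + r1 <= r2) return(4 * pi * r1^2)
    h <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
    max(0, 2 * pi * r1 * h)
  }
  if (nrow(mol$bonds)) {
    xyz <- if (has_coords(mol)) coords(mol) else NULL
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$from[k]; j <- mol$bonds$to[k]
      d <- if (!is.null(xyz)) sqrt(sum((xyz[i, ] - xyz[j, ])^2)) else
        cov[i] + cov[j]
      area[i] <- area[i] - cap(r[i], r[j], d)
      area[j] <- area[j] - cap(r[j], r[i], d)
    }
  }
  for (i in which(a$n_implicit_h > 0)) {
    d <- cov[i] + cov_h
    area[i] <- area[i] - a$n_implicit_h[i] * cap(r[i], r_h, d)
  }
  pmax(area, 0)
}

#' Compute a per-atom chemical property
#'
#' Evaluates one of the nine catalogued per-atom properties (or the van der
#' Waals surface area used for fingerprint weighting) for every atom of a
#' molecule. Sigma charges come from a damped partial-equalisation iteration
#' over orbital electronegativities; pi charges from the analogous iteration
#' over the pi system; electronegativities are the orbital polynomials
#' evaluated at the converged total charge. The VC2003 charge is served as
#' the total partial-equalisation charge (a documented substitute model).
#'
#' @param mol a [molecule()].
#' @param property_id one of `"identity"` (atomic number), `"sigma_charge"`,
#'   `"pi_charge"`, `"total_charge"`, `"sigma_electronegativity"`,
#'   `"pi_electronegativity"`, `"lone_pair_electronegativity"`,
#'   `"effective_polarizability"`, `"vc2003_charge"`, `"vdw_surface_area"`.
#' @return numeric vector, one value per atom. Charges in e,
#'   electronegativities in eV, polarizability in Angstrom^3, areas in
#'   Angstrom^2.
#' @examples
#' m <- molecule(data.frame(element = c("C", "O"), charge = 0),
#'               data.frame(from = 1, to = 2, order = 2))
#' compute_atom_properties(m, "total_charge")
#' @export
compute_atom_properties <- function(mol, property_id) {
  stopifnot(is_molecule(mol))
  property_id <- match.arg(property_id,
                           c(QV_ATOM_PROPERTIES, "vdw_surface_area"))
  switch(property_id,
    identity = element_param(mol$atoms$element, "z"),
    sigma_charge = peoe_sigma_charges(mol),
    pi_charge = peoe_pi_charges(mol),
    total_charge = peoe_sigma_charges(mol) + peoe_pi_charges(mol),
    sigma_electronegativity =
      atom_electronegativity(mol, "sigma",
                             peoe_sigma_charges(mol) + peoe_pi_charges(mol)),
    pi_electronegativity =
      atom_electronegativity(mol, "pi",
                             peoe_sigma_charges(mol) + peoe_pi_charges(mol)),
    lone_pair_electronegativity =
      atom_electronegativity(mol, "lp",
                             peoe_sigma_charges(mol) + peoe_pi_charges(mol)),
    effective_polarizability = effective_polarizability(mol),
    vc2003_charge = peoe_sigma_charges(mol) + peoe_pi_charges(mol),
    vdw_surface_area = vdw_surface_areas(mol))
}

#' Per-atom property table
#'
#' All nine catalogued atom properties plus the van der Waals surface area,
#' one row per atom. Total charges sum to the molecular formal charge.
#'
#' @param mol a [molecule()].
#' @return data.frame with one column per property.
#' @export
atom_property_table <- function(mol) {
  qs <- peoe_sigma_charges(mol)
  qp <- peoe_pi_charges(mol)
  qt <- qs + qp
  data.frame(
    identity = element_param(mol$atoms$element, "z"),
    sigma_charge = qs,
    pi_charge = qp,
    total_charge = qt,
    sigma_electronegativity = atom_electronegativity(mol, "sigma", qt),
    pi_electronegativity = atom_electronegativity(mol, "pi", qt),
    lone_pair_electronegativity = atom_electronegativity(mol, "lp", qt),
    effective_polarizability = effective_polarizability(mol),
    vc2003_charge = qt,
    vdw_surface_area = vdw_surface_areas(mol))
}
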