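# Shared hand-built molecule fixtures and brute-force oracles.

mol_water <- function() {
  molecule(data.frame(element = c("O", "H", "H"), charge = 0L,
                      x = c(0, 0.9572, -0.24), y = c(0, 0, 0.9266),
                      z = c(0, 0, 0)),
           data.frame(from = c(1, 1), to = c(2, 3), order = 1), id = "water")
}

mol_ethane <- function() {
  molecule(data.frame(element = c("C", "C"), charge = 0L),
           data.frame(from = 1, to = 2, order = 1), id = "ethane")
}

mol_benzene <- function() {
  # kekulized 6-ring, planar ideal geometry
  ang <- 2 * pi * (0:5) / 6
  molecule(data.frame(element = "C", charge = 0L,
                      x = 1.39 * cos(ang), y = 1.39 * sin(ang), z = 0),
           data.frame(from = 1:6, to = c(2:6, 1),
                      order = rep(c(2, 1), 3)), id = "benzene")
}

mol_acetate <- function() {
  molecule(data.frame(element = c("C", "C", "O", "O"),
                      charge = c(0L, 0L, 0L, -1L)),
           data.frame(from = c(1, 2, 2), to = c(2, 3, 4),
                      order = c(1, 2, 1)), id = "acetate")
}

mol_disconnected <- function() {
  molecule(data.frame(element = c("C", "O"), charge = 0L), NULL,
           id = "disconnected")
}

# random geometric molecule with n atoms, unit properties optional
random_test_molecule <- function(n, seed) {
  qv <- qsarvs:::qv_with_seed
  qv(seed, {
    el <- sample(c("C", "N", "O"), n, replace = TRUE)
    xyz <- matrix(rnorm(n * 3, sd = 2), n, 3)
    bonds <- if (n > 1)
      data.frame(from = 1:(n - 1), to = 2:n, order = 1) else NULL
    molecule(data.frame(element = el, charge = 0L,
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
             bonds, id = paste0("rnd", seed))
  })
}

# brute-force double-loop encoders (independent of the package's vectorised
# implementations)
brute_ac2d <- function(d, p, n_bins) {
  out <- numeric(n_bins)
  n <- length(p)
  for (i in seq_len(n)) {
    for (j in i:n) {
      dd <- d[i, j]
      if (is.finite(dd) && dd < n_bins) {
        out[dd + 1] <- out[dd + 1] + p[i] * p[j]
      }
    }
  }
  out
}

brute_ac3d <- function(xyz, p, n_bins, width) {
  out <- numeric(n_bins)
  n <- length(p)
  for (i in seq_len(n)) {
    for (j in i:n) {
      dd <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      b <- floor(dd / width)
      if (b < n_bins) out[b + 1] <- out[b + 1] + p[i] * p[j]
    }
  }
  out
}

brute_rdf <- function(xyz, p, r_grid, B) {
  out <- numeric(length(r_grid))
  n <- length(p)
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dd <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      out <- out + p[i] * p[j] * exp(-B * (r_grid - dd)^2)
    }
  }
  out
}

# exhaustive information-gain oracle: try every threshold between sorted
# values directly from entropy definitions
brute_ig <- function(x, y) {
  ent <- function(lab) {
    if (!length(lab)) return(0)
    p <- mean(lab)
    if (p == 0 || p == 1) return(0)
    -p * log2(p) - (1 - p) * log2(1 - p)
  }
  h0 <- ent(y)
  cuts <- sort(unique(x))
  if (length(cuts) < 2) return(0)
  thr <- (head(cuts, -1) + tail(cuts, -1)) / 2
  best <- min(vapply(thr, function(t) {
    l <- x <= t
    mean(l) * ent(y[l]) + mean(!l) * ent(y[!l])
  }, numeric(1)))
  h0 - best
}

brute_fscore <- function(x, y) {
  xp <- x[y]; xm <- x[!y]
  num <- (mean(xp) - mean(x))^2 + (mean(xm) - mean(x))^2
  den <- var(xp) + var(xm)
  if (den == 0) return(if (num == 0) 0 else Inf)
  num / den
}

# tiny two-feature separable regression set for learner checks
separable_set <- function(n = 400, seed = 5, margin = 0.1) {
  qsarvs:::qv_with_seed(seed, {
    x <- cbind(a = runif(n), b = runif(n))
    act <- x[, "a"] > 0.75 + margin * 0   # wide-margin threshold
    y <- ifelse(act, 6, 3)
    list(x = x, y = y, active = act)
  })
}
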