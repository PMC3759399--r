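# Descriptor encoders, configuration and feature-matrix assembly.

test_that("default configuration has 60 groups and 1,284 values", {
  cfg <- descriptor_config()
  expect_equal(nrow(cfg), 60)
  expect_equal(sum(cfg$n_bins), 1284)
  expect_equal(sum(cfg$kind == "scalar"), 6)
  # 9 properties x 2 weightings x 3 encoders
  expect_equal(sum(cfg$kind != "scalar"), 54)
  cfg2d <- descriptor_config(include_3d = FALSE)
  expect_equal(sum(cfg2d$n_bins), 6 + 9 * 2 * 11)
})

test_that("descriptor configuration survives a JSON round trip", {
  cfg <- descriptor_config()
  path <- tempfile(fileext = ".json")
  write_descriptor_config(cfg, path)
  back <- read_descriptor_config(path)
  expect_equal(as.data.frame(back), as.data.frame(cfg))
})

test_that("scalar descriptors match stated conventions", {
  methane <- molecule(data.frame(element = "C", charge = 0L), id = "methane")
  s <- scalar_descriptors(methane)
  expect_equal(s[1, "mw"], 16.04, tolerance = 0.01)
  expect_equal(unname(s[1, c("hbd", "hba", "charge")]), c(0, 0, 0))
  s <- scalar_descriptors(mol_water())
  expect_equal(unname(s[1, c("hbd", "hba")]), c(1, 1))
  s <- scalar_descriptors(mol_acetate())
  expect_equal(unname(s[1, "charge"]), -1)
  expect_equal(unname(s[1, "hba"]), 2)
})

test_that("2D autocorrelation matches hand evaluation", {
  two <- mol_ethane()
  expect_equal(autocorrelation_2d(two, c(1, 2), 4), c(5, 2, 0, 0))
  expect_equal(autocorrelation_2d(two, c(0, 0), 4), rep(0, 4))
  one <- molecule(data.frame(element = "C", charge = 0L), id = "one")
  expect_equal(autocorrelation_2d(one, 3, 3), c(9, 0, 0))
})

test_that("3D autocorrelation bins on half-open Euclidean intervals", {
  pair <- function(d) molecule(
    data.frame(element = c("C", "C"), charge = 0L,
               x = c(0, d), y = 0, z = 0),
    data.frame(from = 1, to = 2, order = 1), id = "pair")
  expect_equal(autocorrelation_3d(pair(1.5), c(1, 1), 3), c(2, 1, 0))
  # exact boundary 1.0 A goes to bin 1 (half-open convention)
  expect_equal(autocorrelation_3d(pair(1.0), c(1, 1), 3), c(2, 1, 0))
  expect_equal(autocorrelation_3d(pair(0.99), c(1, 1), 3), c(3, 0, 0))
  flat <- mol_ethane()
  expect_error(autocorrelation_3d(flat, c(1, 1)), "coordinates")
})

test_that("radial distribution matches its closed form", {
  pair <- molecule(data.frame(element = c("C", "C"), charge = 0L,
                              x = c(0, 1), y = 0, z = 0),
                   data.frame(from = 1, to = 2, order = 1), id = "pair")
  g <- radial_distribution(pair, c(1, 1), r_grid = c(1.0, 1.1), B = 100)
  expect_equal(g[1], 1.0)
  expect_equal(g[2], exp(-1), tolerance = 1e-12)
  one <- molecule(data.frame(element = "C", charge = 0L, x = 0, y = 0, z = 0),
                  id = "one")
  expect_equal(radial_distribution(one, 1), numeric(48))
})

test_that("VdW-surface weighting is an elementwise product", {
  expect_equal(weighted_property(c(1, 2), c(3, 4)), c(3, 8))
  expect_equal(weighted_property(c(1, 2), c(1, 1)), c(1, 2))
  expect_equal(weighted_property(c(1, 2), c(0, 0)), c(0, 0))
  expect_error(weighted_property(c(1, 2), 1), "length")
})

test_that("encoders agree with brute-force double-loop oracles", {
  for (seed in 1:5) {
    m <- random_test_molecule(7, seed)
    p <- qsarvs:::qv_with_seed(seed + 100, runif(7, -1, 2))
    d <- topological_distances(m)
    expect_equal(autocorrelation_2d(m, p, 8), brute_ac2d(d, p, 8),
                 tolerance = 1e-14)
    xyz <- coords(m)
    expect_equal(autocorrelation_3d(m, p, 10, 1.0),
                 brute_ac3d(xyz, p, 10, 1.0))
    rg <- seq(0.1, 4.8, 0.1)
    expect_equal(radial_distribution(m, p, rg, B = 100),
                 brute_rdf(xyz, p, rg, 100), tolerance = 1e-12)
  }
})

test_that("descriptors are invariant to atom permutation", {
  m <- random_test_molecule(6, 9)
  perm <- c(4, 1, 6, 2, 5, 3)
  inv <- order(perm)
  a2 <- m$atoms[perm, ]
  b2 <- data.frame(from = inv[m$bonds$from], to = inv[m$bonds$to],
                   order = m$bonds$order)
  m2 <- molecule(a2, b2, id = m$id)
  cfg <- descriptor_config()
  fm1 <- assemble_feature_matrix(list(m), cfg)
  fm2 <- assemble_feature_matrix(list(m2), cfg)
  expect_equal(unclass(fm1)[1, ], unclass(fm2)[1, ], tolerance = 1e-9)
})

test_that("geometry descriptors are invariant to rotation and translation", {
  m <- random_test_molecule(6, 12)
  theta <- 0.83
  rot <- matrix(c(cos(theta), sin(theta), 0,
                  -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  xyz <- coords(m) %*% rot
  xyz <- sweep(xyz, 2, c(5, -2, 1.5), "+")
  a2 <- m$atoms
  a2$x <- xyz[, 1]; a2$y <- xyz[, 2]; a2$z <- xyz[, 3]
  m2 <- molecule(a2, m$bonds, id = m$id)
  p <- seq_len(6) / 2
  expect_equal(autocorrelation_3d(m, p, 12), autocorrelation_3d(m2, p, 12),
               tolerance = 1e-9)
  expect_equal(radial_distribution(m, p), radial_distribution(m2, p),
               tolerance = 1e-9)
})

test_that("feature matrix assembly enforces layout and reports failures", {
  lib <- generate_library(fixture_spec(n_compounds = 6, seed = 41))
  fm <- assemble_feature_matrix(lib, descriptor_config())
  expect_equal(ncol(fm), 1284)
  expect_equal(nrow(feature_groups(fm)), 60)
  expect_false(anyNA(fm))

  cfg_scalar <- descriptor_config()[1:6, ]
  class(cfg_scalar) <- c("descriptor_config", "data.frame")
  fm6 <- assemble_feature_matrix(lib, cfg_scalar)
  expect_equal(ncol(fm6), 6)

  # a molecule without geometry fails the 3D groups and is excluded
  flat <- molecule(data.frame(element = c("C", "O"), charge = 0L),
                   data.frame(from = 1, to = 2, order = 1), id = "flat")
  expect_warning(fm2 <- assemble_feature_matrix(c(lib, list(flat)),
                                                descriptor_config()),
                 "excluded")
  expect_equal(nrow(fm2), length(lib))
  expect_match(attr(fm2, "failed"), "flat")
})

test_that("feature CSV round trip preserves values and layout", {
  lib <- generate_library(fixture_spec(n_compounds = 4, seed = 51))
  cfg <- descriptor_config(include_3d = FALSE)
  fm <- assemble_feature_matrix(lib, cfg)
  path <- tempfile(fileext = ".csv")
  write_feature_csv(fm, path)
  back <- read_feature_csv(path, cfg)
  expect_equal(unclass(back)[, ], unclass(fm)[, ], tolerance = 1e-12)
  expect_equal(feature_groups(back), feature_groups(fm))
})
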