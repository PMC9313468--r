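test_that("field fitting follows the extent/3 sigma rule and is rigid-motion invariant", {
  u <- mkUnit(rbind(c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0), c(0, -3, 0)))
  f <- fitField(u)
  expect_equal(f@center, c(0, 0, 0))
  ## two in-plane extents of 3 -> sigma 1; flat third axis floored at 1
  expect_equal(sort(f@sigmas), c(1, 1, 1))

  ## rotation + translation leave the sigmas untouched
  u2 <- mkUnit(matrix(rnorm(60, sd = 5), 20, 3))
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz2 <- as.matrix(residues(u2)[, c("x", "y", "z")]) %*% t(rot) + 10
  f1 <- fitField(u2)
  f2 <- fitField(mkUnit(xyz2))
  expect_equal(f1@sigmas, f2@sigmas, tolerance = 1e-9)

  ## degenerate geometry
  line <- mkUnit(cbind(1:5, 0, 0))
  expect_error(fitField(line), "degenerate")
  dup <- mkUnit(rbind(c(0, 0, 0), c(1, 1, 1))[rep(1:2, 5), ])
  expect_error(fitField(dup), "degenerate")
})

test_that("theoretical profile is the normalised Gaussian at the effective atoms", {
  ## residue at centre vs residue 3 sigma out along one axis
  u <- mkUnit(rbind(c(0, 0, 0), c(6, 0, 0)))
  f <- methods::new("GaussianField", center = c(0, 0, 0), axes = diag(3),
                    sigmas = c(2, 2, 2))
  t <- theoreticalProfile(u, f)
  v <- profileValues(t)
  expect_equal(v[1] / v[2], exp(4.5), tolerance = 1e-12)
  expect_equal(sum(v), 1)

  ## symmetric cross: all residues equidistant from centre -> uniform
  u4 <- mkUnit(rbind(c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0), c(0, -3, 0)))
  expect_equal(profileValues(theoreticalProfile(u4)), rep(0.25, 4))

  ## invariance of the whole profile under rigid motion (field refitted)
  u2 <- mkUnit(matrix(rnorm(90, sd = 6), 30, 3))
  th <- 1.1
  rot <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  xyz2 <- as.matrix(residues(u2)[, c("x", "y", "z")]) %*% t(rot) - 7
  expect_equal(profileValues(theoreticalProfile(mkUnit(xyz2))),
               profileValues(theoreticalProfile(u2)), tolerance = 1e-8)
  expect_true(all(profileValues(theoreticalProfile(u2)) > 0))
})

test_that("observed profile implements the pairwise contact aggregation", {
  ## contact weight vanishes continuously at the cutoff, both exponents
  u <- mkUnit(rbind(c(0, 0, 0), c(9, 0, 0), c(4.5, 50, 0)),
              h = c(0.2, 0.8, 0.4))
  for (ex in c(8, 9)) {
    o <- suppressWarnings(observedProfile(u, cutoff = 9, exponent = ex))
    ## residues 1-2 exactly at cutoff, residue 3 isolated: all raw zero,
    ## floored -> uniform
    expect_equal(profileValues(o), rep(1 / 3, 3))
  }
  expect_warning(observedProfile(u), "floored")

  ## two near-coincident residues with h = 0.5: O = [0.5, 0.5]
  u2 <- mkUnit(rbind(c(0, 0, 0), c(1e-6, 0, 0)), h = c(0.5, 0.5))
  expect_equal(profileValues(observedProfile(u2)), c(0.5, 0.5),
               tolerance = 1e-9)

  ## 3-residue toy against the hand double-loop oracle
  u3 <- mkUnit(rbind(c(0, 0, 0), c(3, 0, 0), c(9, 0, 0)),
               h = c(0.2, 0.8, 0.4))
  expect_equal(profileValues(observedProfile(u3)), oracleObserved(u3),
               tolerance = 1e-14)

  ## property: equals the naive O(N^2) oracle on random units
  for (seed in 1:5) {
    n <- sample(5:80, 1)
    ru <- randomUnit(n, seed)
    expect_equal(profileValues(suppressWarnings(observedProfile(ru))),
                 oracleObserved(ru), tolerance = 1e-12)
    expect_equal(profileValues(suppressWarnings(observedProfile(ru, exponent = 9))),
                 oracleObserved(ru, exponent = 9), tolerance = 1e-12)
  }

  ## missing hydrophobicities are refused
  uNA <- mkUnit(rbind(c(0, 0, 0), c(3, 0, 0)), h = c(NA, 0.5))
  expect_error(observedProfile(uNA), "assignScale")
})

test_that("uniform profile is 1/N", {
  expect_equal(profileValues(uniformProfile(4)), rep(0.25, 4))
  expect_equal(profileValues(uniformProfile(1)), 1)
  for (n in c(2, 7, 33)) expect_equal(sum(profileValues(uniformProfile(n))), 1)
  expect_error(uniformProfile(0), ">= 1")
})

test_that("membrane blend follows M = [T + K (Tmax - T)_n]_n", {
  t <- fodm:::newProfile(c(0.5, 0.3, 0.2), "T")

  expect_equal(profileValues(membraneProfile(t, 0)), c(0.5, 0.3, 0.2))

  ## hand-computed example: K = 1
  expect_equal(profileValues(membraneProfile(t, 1)), c(0.25, 0.35, 0.40),
               tolerance = 1e-12)

  ## very large K turns the maximum of T into the minimum of M
  m <- profileValues(membraneProfile(t, 1e6))
  expect_equal(which.min(m), which.max(profileValues(t)))

  ## oracle property across k, including monotone approach to the inversion
  set.seed(42)
  tv <- randomSimplex(12)
  tr <- fodm:::newProfile(tv, "T")
  for (k in c(0, 0.3, 1, 2.5, 7)) {
    expect_equal(profileValues(membraneProfile(tr, k)), oracleMembrane(tv, k),
                 tolerance = 1e-12)
  }

  ## degenerate all-equal T: inversion undefined, M falls back to T
  tu <- fodm:::newProfile(rep(0.25, 4), "T")
  expect_message(mu <- membraneProfile(tu, 2), "all-equal")
  expect_equal(profileValues(mu), rep(0.25, 4))

  expect_error(membraneProfile(t, -1), ">= 0")
})

test_that("profiles normalise, tabulate and serialise", {
  st <- syntheticGlobule(n = 30, seed = 2)
  u <- makeUnit(st)
  tab <- profileTable(u, k = 0.5)
  expect_equal(nrow(tab), 30)
  expect_named(tab, c("sequential_index", "chain_id", "seq_id",
                      "residue_name", "T", "O", "R", "M"))
  for (col in c("T", "O", "R", "M")) expect_equal(sum(tab[[col]]), 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  profileTable(u, file = f)
  expect_equal(nrow(utils::read.delim(f)), 30)
})
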