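test_that("KL divergence matches closed-form values and simplex properties", {
  expect_equal(klDivergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(klDivergence(c(1, 0), c(0.5, 0.5)), 1)
  ## 0.75 log2 1.5 + 0.25 log2 0.5
  expect_equal(klDivergence(c(0.75, 0.25), c(0.5, 0.5)),
               0.75 * log2(1.5) - 0.25, tolerance = 1e-12)
  expect_equal(round(klDivergence(c(0.75, 0.25), c(0.5, 0.5)), 5), 0.18872)

  expect_error(klDivergence(c(1, 0), c(1, 0, 0)), "length mismatch")
  expect_error(klDivergence(c(0.5, 0.5), c(1, 0)), "infinite divergence")

  ## non-negativity, zero iff equal, over random simplex draws
  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    p <- randomSimplex(n); q <- randomSimplex(n)
    expect_gte(klDivergence(p, q), 0)
    expect_equal(klDivergence(p, p), 0)
    if (max(abs(p - q)) > 1e-6) expect_gt(klDivergence(p, q), 0)
  }
  ## 0 log 0 convention: zero-mass entries contribute nothing
  expect_equal(klDivergence(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)), 1)
})

test_that("relative distance locates O between the T and R references", {
  set.seed(11)
  t <- randomSimplex(10)
  r <- rep(0.1, 10)
  expect_equal(relativeDistance(t, t, r), 0)    # O = T
  expect_equal(relativeDistance(r, t, r), 1)    # O = R
  expect_message(expect_equal(relativeDistance(r, r, r), 0), "identical")

  ## RD < 0.5 exactly when O is closer (in KL) to T than to R
  for (i in 1:25) {
    n <- sample(3:30, 1)
    o <- randomSimplex(n); t <- randomSimplex(n)
    rd <- relativeDistance(o, t)
    expect_gte(rd, 0); expect_lte(rd, 1)
    closer <- klDivergence(o, t) < klDivergence(o, uniformProfile(n))
    expect_equal(rd < 0.5, closer)
  }
})

test_that("K optimisation scans the grid and matches a denser scan", {
  set.seed(5)
  tv <- randomSimplex(10)
  t <- fodm:::newProfile(tv, "T")

  ## O = T: no membrane component needed
  opt <- optimizeK(fodm:::newProfile(tv, "O"), t)
  expect_equal(opt$kOpt, 0)
  expect_equal(opt$dkl, 0)

  ## O = the normalised inversion: the scan runs to its ceiling
  inv <- (max(tv) - tv) / sum(max(tv) - tv)
  inv[inv == 0] <- 1e-9
  oInv <- fodm:::newProfile(inv / sum(inv), "O")
  optInv <- optimizeK(oInv, t)
  expect_equal(optInv$kOpt, 10)
  expect_true(all(diff(optInv$curve$dkl) < 0))   # monotone decrease

  ## curve shape is returned for inspection
  expect_named(optInv$curve, c("k", "dkl"))
  expect_equal(nrow(optInv$curve), 101)

  ## coarse grid optimum within one step of a 10x denser scan
  for (i in 1:10) {
    o <- fodm:::newProfile(randomSimplex(10), "O")
    coarse <- optimizeK(o, t, step = 0.1)
    dense <- optimizeK(o, t, step = 0.01)
    expect_lte(abs(coarse$kOpt - dense$kOpt), 0.1)
  }
  expect_error(optimizeK(t, t, step = 0), "> 0")
})

test_that("RD against the optimised membrane distribution", {
  set.seed(9)
  tv <- randomSimplex(8)
  t <- fodm:::newProfile(tv, "T")

  expect_equal(rdKopt(t, t, membraneProfile(t, 0)), 0)

  ## O built as M(2): the grid recovers K = 2 and RD_Kopt = 1
  m2 <- membraneProfile(t, 2)
  o <- fodm:::newProfile(profileValues(m2), "O")
  opt <- optimizeK(o, t)
  expect_equal(opt$kOpt, 2)
  expect_equal(rdKopt(o, t, membraneProfile(t, opt$kOpt)), 1)

  ## composition check on a 10-residue toy: the ratio of the two divergences
  o10 <- fodm:::newProfile(randomSimplex(10), "O")
  t10 <- fodm:::newProfile(randomSimplex(10), "T")
  k10 <- optimizeK(o10, t10)
  m10 <- membraneProfile(t10, k10$kOpt)
  expect_equal(rdKopt(o10, t10, m10),
               klDivergence(o10, t10) /
                 (klDivergence(o10, t10) + klDivergence(o10, m10)))
})

test_that("fragment status excises and renormalises the parent profiles", {
  st <- syntheticGlobule(n = 60, seed = 4)
  u <- makeUnit(st)
  t <- theoreticalProfile(u)
  o <- observedProfile(u)

  ## whole-unit mask reproduces the whole-unit statistics exactly
  whole <- fodStatus(u)
  frag <- fragmentStatus(t, o, seq_len(60), subsetLabel = "whole")
  expect_equal(frag@rd, whole@rd)
  expect_equal(frag@kOpt, whole@kOpt)
  expect_equal(frag@dklOT, whole@dklOT)

  ## a strict subset: equals the hand-composed computation
  mask <- 5:25
  tf <- profileValues(t)[mask]; tf <- tf / sum(tf)
  of <- profileValues(o)[mask]; of <- of / sum(of)
  r <- fragmentStatus(t, o, mask)
  expect_equal(r@rd, klDivergence(of, tf) /
                 (klDivergence(of, tf) +
                  klDivergence(of, rep(1 / length(mask), length(mask)))))
  expect_equal(r@n, length(mask))

  ## result carries labels through a SubsetSpec
  spec <- fodm:::newSubset("zone:membrane", mask)
  expect_equal(fragmentStatus(t, o, spec)@subsetLabel, "zone:membrane")

  expect_error(fragmentStatus(t, o, 3L), "at least 2")
  expect_error(fragmentStatus(t, o, c(1L, 1000L)), "index range")
})

test_that("profile correlation resamples unequal segments linearly", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(profileCorrelation(a, a), 1)
  expect_equal(profileCorrelation(a, -a + 10), -1)

  ## a linear ramp correlates perfectly with a longer linear ramp
  expect_equal(profileCorrelation(seq(0, 1, length.out = 5),
                                  seq(2, 7, length.out = 12)), 1)

  expect_error(profileCorrelation(c(1, 1, 1), a), "zero variance")
  expect_error(profileCorrelation(c(1, 2), a), "at least 3")
})
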