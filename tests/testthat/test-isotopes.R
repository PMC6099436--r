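test_that("single-element patterns are table lookups", {
  p <- isotope_pattern("C")
  expect_equal(p$mass, c(12.0, 13.0034), tolerance = 1e-4)
  expect_equal(p$abundance, c(0.9893, 0.0107))
  cl <- isotope_pattern("Cl")
  expect_equal(cl$abundance[2] / cl$abundance[1], 0.2424 / 0.7576,
               tolerance = 1e-9)
})

test_that("the dichloro pattern matches the binomial expansion", {
  p <- isotope_pattern("Cl2")
  rel <- p$abundance / p$abundance[1]
  expect_equal(rel, c(1, 0.6399155, 0.1023730), tolerance = 1e-6)
  # spacings are the 37Cl-35Cl mass difference
  expect_equal(diff(p$mass), rep(1.99705, 2), tolerance = 1e-4)
})

test_that("convolution equals exhaustive isotopologue enumeration", {
  for (fstr in c("C3H5Cl2N", "C2H4ClO", "C4Cl2", "CHNOS", "C2H2S2")) {
    got <- isotope_pattern(fstr, prune = 0)
    want <- oracle_pattern(fstr)
    # compare on the oracle's bins above enumeration noise
    keep <- want$abundance > 1e-12
    expect_equal(got$abundance[keep], want$abundance[keep],
                 tolerance = 1e-9, info = fstr)
    expect_equal(got$mass[keep], want$mass[keep], tolerance = 1e-6,
                 info = fstr)
  }
})

test_that("convolution is commutative in the element order", {
  a <- isotope_pattern("C6H5Cl2NO")
  b <- isotope_pattern(as_formula(c(O = 1, N = 1, Cl = 2, H = 5, C = 6)))
  expect_equal(a$abundance, b$abundance, tolerance = 1e-12)
  expect_equal(a$mass, b$mass, tolerance = 1e-12)
})

test_that("abundances are normalized and pruning never removes the base peak", {
  p <- isotope_pattern("C17H18Cl2N", prune = 0)
  expect_equal(sum(p$abundance), 1, tolerance = 1e-9)
  expect_true(all(diff(p$mass) > 0))
  # aggressive pruning keeps (only) the base peak, whose absolute
  # abundance fraction is preserved rather than renormalized
  hard <- isotope_pattern("C17H18Cl2N", prune = 0.999)
  expect_equal(nrow(hard), 1L)
  expect_equal(hard$abundance, max(isotope_pattern("C17H18Cl2N")$abundance))
  expect_error(isotope_pattern(""), "empty")
})

test_that("CHNO-only formulas never fake a chlorine A+2 signal", {
  # the A+2/A ratio of chlorine-free organics stays far below the 0.32 of a
  # monochloro signature (it can edge past 0.05 at 30 carbons with several
  # oxygens from 13C2 + 18O, but never approaches a halogen ratio)
  set.seed(11)
  for (i in 1:20) {
    f <- c(C = sample(1:30, 1), H = sample(1:40, 1),
           N = sample(0:4, 1), O = sample(0:6, 1))
    p <- isotope_pattern(as_formula(f[f > 0]), prune = 0)
    if (nrow(p) >= 3) {
      expect_lt(p$abundance[3] / p$abundance[1], 0.1)
    }
  }
})

test_that("chlorine signatures are the pure-Cl binomial ratios", {
  expect_equal(chlorine_signature(0)$intensity, 1)
  expect_equal(chlorine_signature(1)$intensity, c(1, 0.32), tolerance = 1e-3)
  expect_equal(chlorine_signature(2)$intensity, c(1, 0.640, 0.102),
               tolerance = 1e-3)
  expect_equal(chlorine_signature(2)$mz, c(0, 1.99705, 3.9941),
               tolerance = 1e-5)
  expect_error(chlorine_signature(-1), "non-negative")
})

test_that("envelope scoring is proportional in missing and deviant peaks", {
  cl2 <- chlorine_signature(2)
  exact <- data.frame(mz = c(0, 1.99705, 3.9941),
                      intensity = c(1, 0.64, 0.10))
  expect_equal(envelope_match_score(exact, cl2), 1.0)
  # lone peak: two of three expected peaks missing
  lone <- data.frame(mz = 0, intensity = 1)
  expect_lt(envelope_match_score(lone, cl2), 0.5)
  # within intensity tolerance
  cl1 <- chlorine_signature(1)
  obs <- data.frame(mz = c(0, 1.997), intensity = c(1, 0.32))
  expect_equal(envelope_match_score(obs, cl1, intensity_tol = 0.15), 1.0)
  # a 13C2 satellite at +2.0067 must not pass for a 37Cl peak at +1.9970
  c13 <- data.frame(mz = c(0, 2.0067), intensity = c(1, 0.32))
  expect_lt(envelope_match_score(c13, cl1), 1.0)
})
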