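test_that("calibration fits recover exact lines", {
  c1 <- fit_calibration(data.frame(concentration = c(0, 10),
                                   area = c(0, 1000)))
  expect_equal(c1$slope, 100)
  expect_equal(c1$intercept, 0)
  c2 <- fit_calibration(data.frame(concentration = c(0, 5, 10),
                                   area = c(5, 505, 1005)))
  expect_equal(c2$slope, 100, tolerance = 1e-12)
  expect_equal(c2$intercept, 5, tolerance = 1e-12)
  expect_equal(c2$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_calibration(data.frame(concentration = c(5, 5),
                                          area = c(1, 2))), "distinct")
})

test_that("quantification round-trips concentrations through the curve", {
  set.seed(5)
  conc <- c(1, 20, 150, 800)
  curve <- fit_calibration(data.frame(concentration = conc,
                                      area = 42 + 317 * conc))
  # forward-simulate areas at known extract concentrations, then invert;
  # the ug/g result is conc(ug/L) * V/m
  for (cc in c(0.5, 12.3, 431)) {
    area <- 42 + 317 * cc
    got <- quantify(area, curve, sample_mass_g = 1, extract_volume_L = 0.002)
    expect_equal(as.numeric(got), cc * 0.002, tolerance = 1e-9)
  }
  # worked example: area 21450 on a zero-intercept slope-100 curve
  c100 <- fit_calibration(data.frame(concentration = c(0, 10),
                                     area = c(0, 1000)))
  expect_equal(as.numeric(quantify(21450, c100, 1, 0.002)), 0.429)
  expect_equal(as.numeric(quantify(0, c100, 1, 0.002)), 0)
  expect_warning(q <- quantify(-5, c100, 1, 0.002), "clipped")
  expect_equal(as.numeric(q), 0)
  expect_error(quantify(100, c100, sample_mass_g = 0), "mass")
})

test_that("replicate statistics use the sample SD and integer RSD", {
  s <- replicate_stats(c(1.3, 1.8, 2.4))
  expect_equal(s$mean, mean(c(1.3, 1.8, 2.4)))
  expect_equal(s$sd, stats::sd(c(1.3, 1.8, 2.4)))
  expect_equal(s$rsd_percent, round(s$rsd_exact))
  expect_equal(replicate_stats(c(2, 2, 2))$rsd_percent, 0)
  expect_error(replicate_stats(3.14), ">= 2")
  # RSD is scale-invariant
  v <- c(0.8, 1.1, 1.4)
  expect_equal(replicate_stats(v)$rsd_exact,
               replicate_stats(v * 1e3)$rsd_exact, tolerance = 1e-12)
})

test_that("control ratios reproduce the reported values", {
  expect_equal(control_ratio(184, 100), 1.84)
  expect_equal(control_ratio(51000, 1000), 51)
  expect_equal(control_ratio(7, 7), 1)
  nd <- control_ratio(100, 0)
  expect_true(is.na(nd))
  expect_true(attr(nd, "not_detected_in_gm"))
})

test_that("provenance classification is total and matches the narrative", {
  # absent from GM control => plant-made
  expect_equal(classify_provenance(TRUE, FALSE, FALSE, FALSE)$call,
               "true_metabolite")
  # very high root/GM ratios => plant metabolism dominates
  expect_equal(classify_provenance(TRUE, TRUE, TRUE, FALSE, 378)$call,
               "metabolite_dominant")
  expect_equal(classify_provenance(TRUE, TRUE, TRUE, FALSE, 491)$call,
               "metabolite_dominant")
  # intermediate ratios => both mechanisms contribute
  expect_equal(classify_provenance(TRUE, TRUE, TRUE, FALSE, 51)$call, "mixed")
  expect_equal(classify_provenance(TRUE, TRUE, TRUE, FALSE, 25)$call, "mixed")
  # low ratio => plant-independent transformation leads
  expect_equal(classify_provenance(TRUE, TRUE, TRUE, FALSE, 1.84)$call,
               "transformation_leaning")
  # gates
  expect_equal(classify_provenance(TRUE, TRUE, TRUE, TRUE, 10)$call,
               "contamination_suspect")
  expect_equal(classify_provenance(TRUE, TRUE, TRUE, FALSE, 0.5,
                                   is_parent = TRUE)$call, "parent")
  expect_error(classify_provenance(TRUE, TRUE, TRUE, FALSE, NA), "ratio")
  # totality over the flag/ratio lattice
  for (root in c(TRUE, FALSE)) for (leaf in c(TRUE, FALSE))
    for (gm in c(TRUE, FALSE)) for (neg in c(TRUE, FALSE))
      for (r in if (gm) c(0.1, 5, 99, 100, 1e4) else NA) {
        call <- classify_provenance(root, leaf, gm, neg, r)$call
        expect_true(call %in% c("parent", "true_metabolite",
                                "metabolite_dominant", "mixed",
                                "transformation_leaning",
                                "contamination_suspect"))
      }
})

test_that("translocation factors separate leaf- and root-accumulating drugs", {
  expect_equal(round(translocation_factor(2.63, 0.91), 2), 2.89)
  expect_equal(round(translocation_factor(0.52, 4.29), 2), 0.12)
  expect_equal(translocation_factor(1, 1), 1)
  und <- translocation_factor(1, 0)
  expect_true(is.na(und) && attr(und, "undefined"))
})
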