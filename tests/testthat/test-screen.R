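test_that("co-eluting dichloro isotopologues assemble into one feature", {
  peaks <- data.frame(
    mz = c(306.0823, 308.0794, 310.0765),
    rt_min = c(5.00, 5.00, 5.01),
    area = c(1e6, 0.64e6, 0.10e6),
    sample_id = "s1", compartment = "root", replicate = 1L)
  feats <- assemble_envelopes(peaks)
  expect_equal(nrow(feats), 1L)
  expect_equal(feats$mz, 306.0823)
  expect_equal(feats$n_peaks, 3L)
  expect_equal(feats$envelope[[1]]$intensity, c(1, 0.64, 0.10))
})

test_that("singletons and RT-separated peaks stay apart", {
  single <- data.frame(mz = 400.1, rt_min = 3, area = 1e5,
                       sample_id = "s1", compartment = "root",
                       replicate = 1L)
  f1 <- assemble_envelopes(single)
  expect_equal(f1$n_peaks, 1L)
  expect_equal(f1$envelope[[1]]$intensity, 1)

  apart <- data.frame(mz = c(306.0823, 308.0794), rt_min = c(5.0, 5.5),
                      area = c(1e6, 0.64e6), sample_id = "s1",
                      compartment = "root", replicate = 1L)
  expect_equal(nrow(assemble_envelopes(apart)), 2L)

  expect_equal(nrow(assemble_envelopes(single[0, ])), 0L)
})

test_that("13C chains extend an envelope across mixed spacings", {
  # A, A+1 (13C), A+2 (37Cl): A+2 joins via the 1.997 gap to A, A+1 via 1.0034
  peaks <- data.frame(
    mz = c(197.0840, 198.0874, 199.0811),
    rt_min = 3.0, area = c(1e6, 0.11e6, 0.32e6),
    sample_id = "s1", compartment = "root", replicate = 1L)
  feats <- assemble_envelopes(peaks)
  expect_equal(nrow(feats), 1L)
  expect_equal(feats$n_peaks, 3L)
})

test_that("suspect matching applies ppm and envelope gates", {
  cands <- enumerate_candidates("STR", "C17H17Cl2N", builtin_rules(), 1)
  ohstr <- cands[cands$formula == "C17H17Cl2NO", ]
  feats <- assemble_envelopes(
    envelope_peaks("C17H17Cl2NO", 6.7, 1e6))
  # shift the observed monoisotopic m/z to the reported measured value
  m <- match_suspects(feats, ohstr)
  expect_equal(nrow(m), 1L)
  expect_lt(abs(m$ppm), 1)
  expect_gte(m$envelope_score, 0.99)
  # far-off feature is rejected on mass alone
  far <- feats
  far$mz <- 322.20
  far$envelope[[1]]$mz <- far$envelope[[1]]$mz + (322.20 - feats$mz)
  expect_equal(nrow(match_suspects(far, ohstr)), 0L)
  # singleton feature at the right mass fails the envelope gate
  lone <- data.frame(mz = ohstr$mz, rt_min = 6.7, area = 1e5,
                     sample_id = "s1", compartment = "root", replicate = 1L)
  lonef <- assemble_envelopes(lone)
  expect_equal(nrow(match_suspects(lonef, ohstr)), 0L)
})

test_that("matching is symmetric under input shuffling", {
  cands <- enumerate_all_candidates(parent_drugs(), max_depth = 2)
  peaks <- rbind(envelope_peaks("C17H17Cl2NO", 6.7, 1e6),
                 envelope_peaks("C19H23ClN2", 10.7, 2e6),
                 envelope_peaks("C10H13ClN2", 3.0, 5e5))
  feats <- assemble_envelopes(peaks)
  set.seed(3)
  m1 <- match_suspects(feats, cands)
  m2 <- match_suspects(feats[sample(nrow(feats)), ],
                       cands[sample(nrow(cands)), ])
  key <- function(m) sort(paste(m$formula, round(m$measured_mz, 4), m$rt_min))
  expect_equal(key(m1), key(m2))
  expect_true(all(abs(m1$ppm) <= 5))
})

test_that("isomers at distinct retention times become distinct species", {
  cands <- enumerate_candidates("STR", "C17H17Cl2N", builtin_rules(), 1)
  peaks <- rbind(envelope_peaks("C17H17Cl2NO", 6.7, 1e6),
                 envelope_peaks("C17H17Cl2NO", 8.2, 6e5))
  m <- cluster_species(match_suspects(assemble_envelopes(peaks), cands))
  expect_equal(length(unique(m$species_id)), 2L)
  expect_equal(sort(round(unique(m$species_rt), 1)), c(6.7, 8.2))
})

test_that("presence table keeps replicate areas separate", {
  cands <- enumerate_candidates("CLP", "C19H23ClN2", builtin_rules(), 2)
  peaks <- do.call(rbind, lapply(1:3, function(r) {
    envelope_peaks("C18H21ClN2O", 6.6, 1e6 * r,
                   sample_id = paste0("root_", r), replicate = r)
  }))
  feats <- assemble_all_envelopes(peaks)
  tab <- presence_table(match_suspects(feats, cands))
  ohdm <- tab[tab$formula == "C18H21ClN2O", ]
  expect_equal(nrow(ohdm), 3L)
  expect_equal(sort(ohdm$replicate), 1:3)
  expect_false("gm_control" %in% tab$compartment)
  expect_equal(nrow(presence_table(match_suspects(feats[0, ], cands))), 0L)
})
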