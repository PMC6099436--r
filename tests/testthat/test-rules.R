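test_that("builtin rules carry the expected element deltas", {
  rules <- builtin_rules()
  expect_equal(rules$hydroxylation$delta, c(O = 1))
  expect_equal(rules$demethylation$delta, c(C = -1, H = -2))
  # amino-acid condensation: residue formula minus water
  phe <- rules$conj_Phe$delta
  expect_equal(phe[c("C", "H", "N", "O")], c(C = 9, H = 9, N = 1, O = 1))
  tyr <- rules$conj_Tyr$delta
  expect_equal(tyr[["O"]], 2)
  expect_equal(format_formula(rules$cleavage_mCPP$product), "C10H13ClN2")
  # hydroxylating sertraline gives the observed metabolite mass
  ohstr <- apply_delta("C17H17Cl2N", rules$hydroxylation$delta)
  expect_equal(round(protonated_mz(ohstr), 4), 322.0760)
})

test_that("depth-0 enumeration returns exactly the parent", {
  cands <- enumerate_candidates("CLP", "C19H23ClN2", builtin_rules(), 0)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$chain, "")
  expect_equal(cands$formula, "C19H23ClN2")
  expect_equal(round(cands$mz, 4), 315.1623)
})

test_that("depth-2 enumeration of clomipramine finds the reported trio", {
  cands <- enumerate_candidates("CLP", "C19H23ClN2", builtin_rules(), 2)
  mz4 <- round(cands$mz[match(c("C19H23ClN2O", "C18H21ClN2", "C18H21ClN2O"),
                              cands$formula)], 4)
  expect_equal(mz4, c(331.1572, 301.1466, 317.1415))
})

test_that("depth-3 enumeration covers all eleven detected metabolite formulas", {
  cands <- enumerate_all_candidates(parent_drugs(), builtin_rules(), 3)
  metabolites <- unique(table2$formula[!table2$name %in%
                                         c("STR", "CLP", "TZN")])
  expect_true(all(metabolites %in% cands$formula))
  # the triple-step conjugates appear at depth 3
  expect_true("C25H24Cl2N2O" %in% cands$formula)
  expect_true("C25H24Cl2N2O2" %in% cands$formula)
})

test_that("enumeration is order-independent and duplicate-free", {
  rules <- builtin_rules()
  a <- enumerate_candidates("STR", "C17H17Cl2N", rules, 3)
  b <- enumerate_candidates("STR", "C17H17Cl2N", rev(rules), 3)
  expect_setequal(a$formula, b$formula)
  expect_false(any(duplicated(a$formula)))
  # every enumerated formula is parseable with non-negative counts
  for (fstr in a$formula) expect_true(all(parse_formula(fstr) >= 0))
})

test_that("conjugation is capped at one per chain", {
  cands <- enumerate_candidates("STR", "C17H17Cl2N", builtin_rules(), 3)
  two_conj <- vapply(strsplit(cands$chain, "+", fixed = TRUE), function(ch)
    sum(grepl("^conj_", ch)) > 1, logical(1))
  expect_false(any(two_conj))
})

test_that("the cleavage rule fires only from trazodone itself", {
  cands <- enumerate_all_candidates(parent_drugs(), builtin_rules(), 3)
  cleaved <- cands[grepl("cleavage_mCPP", cands$chain) |
                     grepl("cleavage_mCPP", cands$alt_chains), ]
  expect_true(all(cleaved$parent == "TZN"))
  expect_true("C10H13ClN2" %in% cleaved$formula)
})

test_that("suspect lists load with computed m/z and reject bad formulas", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,formula,parent",
               "mCPP,C10H13ClN2,TZN",
               "OH-STR,C17H17Cl2NO,STR"), path)
  sl <- load_suspect_list(path)
  expect_equal(nrow(sl), 2L)
  expect_equal(round(sl$mz[1], 4), 197.0840)
  expect_equal(sl$source, rep("suspect_list", 2))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("name,formula", empty)
  expect_equal(nrow(load_suspect_list(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,formula", "weird,Xx2"), bad)
  expect_error(load_suspect_list(bad), "row 1")
})

test_that("the shipped reconstructed suspect list is readable and consistent", {
  path <- system.file("extdata", "suspects_reconstructed.csv",
                      package = "phytoscreen")
  sl <- load_suspect_list(path)
  expect_gte(nrow(sl), 21L)
  expect_true(all(table2$formula %in% sl$formula))
})
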