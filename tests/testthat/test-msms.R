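spec_for <- function(name) {
  row <- table2[table2$name == name, ]
  frag <- as.numeric(strsplit(row$fragments, "/", fixed = TRUE)[[1]])
  list(precursor_mz = protonated_mz(row$formula),
       compound_label = name,
       fragments = data.frame(mz = frag, intensity = rev(seq_along(frag))))
}

test_that("neutral losses explain the reported backbone fragments", {
  # sertraline: methylamine loss
  ann <- annotate_losses(spec_for("STR"))
  expect_true("-CH3NH2" %in% ann$loss[ann$fragment_mz == 275.0])
  # hydroxy-sertraline: stacked methylamine + water loss
  ann <- annotate_losses(spec_for("OH-STR (isomer 1)"))
  losses <- ann$loss[ann$fragment_mz == 273.0]
  expect_true(any(grepl("CH3NH2", losses) & grepl("H2O", losses)))
  # hydroxy-clomipramine: water loss to 313.2
  ann <- annotate_losses(spec_for("OH-CLP (isomer 1)"))
  expect_true("-H2O" %in% ann$loss[ann$fragment_mz == 313.2])
  # hydroxy-demethyl-clomipramine: water loss to 299.1
  ann <- annotate_losses(spec_for("OH-DM-CLP"))
  expect_true("-H2O" %in% ann$loss[ann$fragment_mz == 299.1])
})

test_that("an empty loss library leaves every fragment unexplained", {
  empty <- default_loss_library()[0, ]
  ann <- annotate_losses(spec_for("CLP"), losses = empty)
  expect_equal(nrow(ann), 3L)
  expect_true(all(is.na(ann$loss)))
})

test_that("shared fragments are symmetric and link metabolites to parents", {
  clp <- spec_for("CLP")
  ohclp <- spec_for("OH-CLP (isomer 1)")
  ab <- shared_fragments(clp, ohclp)
  ba <- shared_fragments(ohclp, clp)
  expect_equal(ab$mz_a, ba$mz_b)
  expect_true(86.1 %in% ab$mz_a)
  # conjugate keeps the parent backbone ion
  sf <- shared_fragments(spec_for("DM-STR+Phe"), spec_for("STR"))
  expect_true(275.0 %in% sf$mz_a)
  # disjoint spectra share nothing
  expect_equal(nrow(shared_fragments(spec_for("TZN"), spec_for("STR"))), 0L)
})

test_that("conjugate marker ions are flagged", {
  hits <- flag_diagnostics(spec_for("DM-STR+Tyr"))
  expect_true("tyrosine conjugate marker" %in% hits$meaning)
  hits <- flag_diagnostics(spec_for("OH-DM-STR+Phe"))
  expect_true("phenylalanine conjugate marker" %in% hits$meaning)
  none <- flag_diagnostics(list(precursor_mz = 400,
                                fragments = data.frame(mz = 390.2,
                                                       intensity = 1)))
  expect_equal(nrow(none), 0L)
})

test_that("every reported product ion is loss-annotated or diagnostic", {
  for (nm in table2$name) {
    sp <- spec_for(nm)
    ann <- annotate_losses(sp)
    diag <- flag_diagnostics(sp)
    for (fmz in sp$fragments$mz) {
      explained <- any(!is.na(ann$loss[ann$fragment_mz == fmz])) ||
        any(abs(diag$fragment_mz - fmz) < 1e-9)
      expect_true(explained, info = paste(nm, fmz))
    }
  }
})

test_that("MGF files round-trip through write and read", {
  spectra <- generate_msms()
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(spectra, path)
  back <- read_mgf(path)
  expect_length(back, length(spectra))
  for (i in seq_along(spectra)) {
    expect_equal(back[[i]]$precursor_mz, spectra[[i]]$precursor_mz,
                 tolerance = 1e-8)
    expect_equal(back[[i]]$compound_label, spectra[[i]]$compound_label)
    expect_equal(back[[i]]$fragments$mz, spectra[[i]]$fragments$mz,
                 tolerance = 1e-6)
  }
})
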