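# Reference data used across tests: the detected compound panel as printed
# (formula, RT, theoretical and measured m/z, ppm, product ions), and an
# exhaustive isotopologue-enumeration oracle independent of the package's
# convolution code.

table2 <- data.frame(
  name = c("STR", "OH-STR (isomer 1)", "OH-STR (isomer 2)",
           "DM-STR+Phe", "DM-STR+Tyr", "OH-DM-STR+Phe",
           "CLP", "DM-CLP", "OH-CLP (isomer 1)", "OH-CLP (isomer 2)",
           "OH-DM-CLP", "TZN", "OH-TZN", "mCPP"),
  formula = c("C17H17Cl2N", "C17H17Cl2NO", "C17H17Cl2NO",
              "C25H24Cl2N2O", "C25H24Cl2N2O2", "C25H24Cl2N2O2",
              "C19H23ClN2", "C18H21ClN2", "C19H23ClN2O", "C19H23ClN2O",
              "C18H21ClN2O", "C19H22ClN5O", "C19H22ClN5O2", "C10H13ClN2"),
  rt = c(10.2, 6.7, 8.2, 13.1, 12.7, 12.5, 10.7, 10.4, 6.8, 7.0, 6.6,
         5.5, 6.3, 3.0),
  mz_theor = c(306.0811, 322.0760, 322.0760, 439.1330, 455.1290, 455.1290,
               315.1623, 301.1466, 331.1572, 331.1572, 317.1415, 372.1586,
               388.1535, 197.0840),
  mz_meas = c(306.0823, 322.0762, 322.0763, 439.1332, 455.1281, 455.1281,
              315.1638, 301.1469, 331.1584, 331.1582, 317.1421, 372.1597,
              388.1540, 197.0843),
  ppm = c(3.9, 0.6, 0.9, 0.5, -2.0, -2.0, 4.8, 1.0, 3.6, 3.0, 1.9, 3.0,
          1.3, 1.5),
  fragments = c("275.0", "273.0", "273.0", "275.0/165.1/91.1",
                "275.0/181.1/107.1", "273.0/165.1", "270.1/242.1/86.1",
                "270.1/242.1/72.1", "313.2/86.1", "313.2/86.1", "299.1/86.1",
                "176.1/148.1", "176.1/148.1", "154.0"),
  # the three amino-acid conjugate rows' printed theoretical m/z cannot be
  # derived from their printed sum formulas; exact-mass checks skip them
  formula_consistent = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE,
                         TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

# parent-drug concentration table: mean (ug/g), SD, printed integer RSD
table1 <- data.frame(
  compound = rep(c("Sertraline", "Clomipramine", "Trazodone"), each = 2),
  compartment = rep(c("root", "leaf"), 3),
  mean = c(4.29, 0.52, 1.83, 1.14, 0.91, 2.63),
  sd = c(0.98, 0.14, 0.50, 0.25, 0.15, 0.37),
  rsd_printed = c(23, 26, 27, 22, 17, 14)
)

# Exhaustive isotopologue enumeration: every combination of isotopes over
# every atom, aggregated into the same unit-spaced nominal bins as
# isotope_pattern(). Exponential in atom count -- only for tiny formulas.
oracle_pattern <- function(formula) {
  iso <- phytoscreen:::.ISOTOPES
  f <- as_formula(formula)
  masses <- 0
  abunds <- 1
  for (el in names(f)) {
    for (k in seq_len(f[[el]])) {
      masses <- as.vector(outer(masses, iso[[el]]$mass, `+`))
      abunds <- as.vector(outer(abunds, iso[[el]]$abundance, `*`))
    }
  }
  bin <- round(masses - min(masses))
  ab <- tapply(abunds, bin, sum)
  m <- tapply(masses * abunds, bin, sum) / ab
  out <- data.frame(mass = as.numeric(m), abundance = as.numeric(ab))
  out[order(out$mass), , drop = FALSE]
}

# build a peak table row-set for one compound's envelope at given rt/area
envelope_peaks <- function(formula, rt, area, sample_id = "s1",
                           compartment = "root", replicate = 1L,
                           min_rel = 0.01) {
  ion <- apply_delta(formula, c(H = 1))
  pat <- isotope_pattern(ion, prune = min_rel)
  data.frame(mz = pat$mass - phytoscreen:::.ELECTRON_MASS,
             rt_min = rt, area = area * pat$abundance / max(pat$abundance),
             sample_id = sample_id, compartment = compartment,
             replicate = replicate, stringsAsFactors = FALSE)
}
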