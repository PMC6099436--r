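# Frozen physical constants. All mass arithmetic in the package flows from
# these tables so that theoretical m/z values are bit-stable across platforms.

#' @name phytoscreen-constants
#' @title Physical constants used by phytoscreen
#' @description Monoisotopic atomic masses (Da), isotopic compositions and the
#'   electron mass are frozen in the package (IUPAC 2021 atomic masses,
#'   CODATA electron mass) rather than taken from an external library, so that
#'   computed exact masses are reproducible to well beyond the 4 decimal
#'   places at which high-resolution instruments report m/z.
#' @keywords internal
NULL

# mass of the lightest (and for these elements most abundant) isotope
.MONO_MASS <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  F  = 18.9984031627,
  P  = 30.97376151,
  S  = 31.97207069,
  Cl = 34.96885271,
  Br = 78.9183376,
  I  = 126.904473,
  Na = 22.98976928,
  K  = 38.9637064864
)

.ELECTRON_MASS <- 0.00054857990907
.PROTON_MASS   <- .MONO_MASS[["H"]] - .ELECTRON_MASS  # 1.0072764520

# Natural isotopic composition per element: exact isotope masses (Da) and
# abundances (fractions summing to 1). Monoisotopic-only elements carry a
# single entry. Abundances: IUPAC representative values.
.ISOTOPES <- list(
  H = data.frame(mass = c(1.0078250319, 2.0141017781),
                 abundance = c(0.999885, 0.000115)),
  C = data.frame(mass = c(12.0, 13.0033548351),
                 abundance = c(0.9893, 0.0107)),
  N = data.frame(mass = c(14.0030740052, 15.0001088989),
                 abundance = c(0.99636, 0.00364)),
  O = data.frame(mass = c(15.9949146221, 16.9991315650, 17.9991596129),
                 abundance = c(0.99757, 0.00038, 0.00205)),
  F = data.frame(mass = 18.9984031627, abundance = 1.0),
  P = data.frame(mass = 30.97376151, abundance = 1.0),
  S = data.frame(mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708071),
                 abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Cl = data.frame(mass = c(34.96885271, 36.96590260),
                  abundance = c(0.7576, 0.2424)),
  Br = data.frame(mass = c(78.9183376, 80.9162906),
                  abundance = c(0.5069, 0.4931)),
  I = data.frame(mass = 126.904473, abundance = 1.0),
  Na = data.frame(mass = 22.98976928, abundance = 1.0),
  K = data.frame(mass = c(38.9637064864, 39.963998166, 40.9618252579),
                 abundance = c(0.932581, 0.000117, 0.067302))
)

# Spacings (Da) between successive isotopologue peaks used when grouping
# co-eluting centroids into envelopes: 13C-12C and 37Cl-35Cl.
.SPACING_C13  <- 1.0033548351
.SPACING_CL37 <- 1.9970498900
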