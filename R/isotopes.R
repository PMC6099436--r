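# Isotope pattern prediction by elemental convolution, and envelope scoring
# against chlorine signatures.

#' Theoretical isotope pattern of a molecular formula
#'
#' Convolves the natural isotopic composition of every atom in the formula
#' and aggregates the resulting isotopologues into unit-spaced nominal-mass
#' bins (the resolution at which chromatographic isotope envelopes are read).
#' Abundances are normalized to sum to 1 before pruning; entries below
#' \code{prune} times the most abundant entry are then dropped. The most
#' abundant entry is never pruned.
#'
#' @inheritParams format_formula
#' @param prune relative abundance threshold in [0, 1); default \code{1e-4}.
#' @param aggregate aggregate isotopologues into nominal-mass bins
#'   (default TRUE). With FALSE the exact isotopologue masses are returned,
#'   merged only when equal to 1e-5 Da.
#' @return data.frame with columns \code{mass} (Da, strictly increasing) and
#'   \code{abundance} (fractions; sum to 1 before pruning). Binned masses are
#'   abundance-weighted means of their isotopologues.
#' @examples
#' isotope_pattern("Cl")   # 3:1 A/A+2 signature of one chlorine
#' isotope_pattern("Cl2")  # ~9.8 : 6.3 : 1
#' @export
isotope_pattern <- function(f, prune = 1e-4, aggregate = TRUE) {
  f <- as_formula(f)
  if (length(f) == 0L) stop("isotope pattern of the empty formula is undefined")
  stopifnot(prune >= 0, prune < 1)
  dist <- data.frame(mass = 0, abundance = 1)
  for (el in names(f)) {
    dist <- .convolve_dist(dist, .element_power(.ISOTOPES[[el]], f[[el]]))
  }
  if (aggregate) dist <- .bin_nominal(dist)
  dist$abundance <- dist$abundance / sum(dist$abundance)
  keep <- dist$abundance >= prune * max(dist$abundance)
  dist <- dist[keep, , drop = FALSE]
  rownames(dist) <- NULL
  dist
}

# distribution of n atoms of one element, by binary exponentiation
.element_power <- function(iso, n) {
  out <- data.frame(mass = 0, abundance = 1)
  base <- data.frame(mass = iso$mass, abundance = iso$abundance)
  while (n > 0) {
    if (n %% 2 == 1) out <- .convolve_dist(out, base)
    n <- n %/% 2
    if (n > 0) base <- .convolve_dist(base, base)
  }
  out
}

# exact convolution of two (mass, abundance) distributions; terms whose
# masses agree to 1e-5 Da are merged, and terms below 1e-15 of the maximum
# are dropped to keep the term count bounded.
.convolve_dist <- function(a, b) {
  mass <- outer(a$mass, b$mass, `+`)
  ab <- outer(a$abundance, b$abundance)
  key <- round(as.vector(mass), 5)
  agg_ab <- tapply(as.vector(ab), key, sum)
  agg_m <- tapply(as.vector(mass) * as.vector(ab), key, sum) / agg_ab
  out <- data.frame(mass = as.numeric(agg_m), abundance = as.numeric(agg_ab))
  out <- out[out$abundance >= 1e-15 * max(out$abundance), , drop = FALSE]
  out[order(out$mass), , drop = FALSE]
}

# aggregate isotopologues into unit-spaced bins indexed by the nominal mass
# shift from the lightest entry; bin mass = abundance-weighted mean
.bin_nominal <- function(dist) {
  k <- round(dist$mass - min(dist$mass))
  ab <- tapply(dist$abundance, k, sum)
  m <- tapply(dist$mass * dist$abundance, k, sum) / ab
  out <- data.frame(mass = as.numeric(m), abundance = as.numeric(ab))
  out[order(out$mass), , drop = FALSE]
}

#' Expected chlorine isotope signature
#'
#' Relative intensities at +1.99705 Da spacings expected from the binomial
#' distribution over \eqn{^{35}Cl/^{37}Cl} for a compound carrying
#' \code{n_cl} chlorine atoms, ignoring all other elements. One chlorine
#' gives the classic 3:1 (exactly 1 : 0.320) A/A+2 doublet, two chlorines
#' the 9:6:1 (exactly 1 : 0.640 : 0.102) triplet.
#'
#' @param n_cl number of chlorine atoms (non-negative integer).
#' @return an envelope data.frame with columns \code{mz} (offsets from the
#'   monoisotopic peak, Da) and \code{intensity} (relative, base peak = 1).
#' @examples
#' chlorine_signature(2)
#' @export
chlorine_signature <- function(n_cl) {
  if (length(n_cl) != 1L || is.na(n_cl) || n_cl < 0 || n_cl != round(n_cl)) {
    stop("n_cl must be a single non-negative integer")
  }
  p35 <- .ISOTOPES$Cl$abundance[1]
  p37 <- .ISOTOPES$Cl$abundance[2]
  k <- 0:n_cl
  ab <- choose(n_cl, k) * p35^(n_cl - k) * p37^k
  data.frame(mz = k * .SPACING_CL37, intensity = ab / ab[1])
}

#' Convert an isotope distribution to an envelope
#'
#' Rescales an \code{\link{isotope_pattern}} result to the envelope
#' convention used for matching: m/z offsets relative to the monoisotopic
#' (lowest-mass) entry and intensities relative to the base (most abundant)
#' peak.
#'
#' @param dist data.frame with \code{mass} and \code{abundance} columns.
#' @param min_rel drop entries below this fraction of the base peak
#'   (default 0.05): envelope peaks that a real centroid table would not
#'   reliably contain should not count against an observed envelope.
#' @return data.frame with columns \code{mz} (offset, Da) and
#'   \code{intensity} (base = 1).
#' @export
pattern_to_envelope <- function(dist, min_rel = 0.05) {
  stopifnot(all(c("mass", "abundance") %in% names(dist)), nrow(dist) >= 1)
  env <- data.frame(mz = dist$mass - dist$mass[1],
                    intensity = dist$abundance / max(dist$abundance))
  env[env$intensity >= min_rel, , drop = FALSE]
}

#' Score an observed envelope against an expected one
#'
#' Deterministic proportional score in [0, 1]. Each expected peak earns full
#' credit when an observed peak lies within \code{mz_tol} of its offset from
#' the base peak and its relative intensity deviates by at most
#' \code{intensity_tol}; intensity deviations beyond the tolerance lose
#' credit proportionally (relative to the expected intensity) and a missing
#' peak earns none. The score is the mean credit over expected peaks.
#' Observed peaks with no expected counterpart (e.g. \eqn{^{13}C} satellites
#' when scoring against a pure-chlorine signature) are not penalized.
#'
#' @param observed,expected envelopes: data.frames with \code{mz} and
#'   \code{intensity} columns, intensities relative to the base peak
#'   (base = 1). \code{mz} may be absolute (observed) or offsets (expected);
#'   both are re-referenced to their first peak before comparison.
#' @param intensity_tol allowed absolute deviation of relative intensity
#'   (default 0.15).
#' @param mz_tol allowed deviation of the peak offset in Da (default 0.005;
#'   tight enough that a two-\eqn{^{13}C} satellite at +2.0067 Da is not
#'   mistaken for a \eqn{^{37}Cl} peak at +1.9970 Da).
#' @return a score in [0, 1].
#' @export
envelope_match_score <- function(observed, expected,
                                 intensity_tol = 0.15, mz_tol = 0.005) {
  stopifnot(nrow(observed) >= 1, nrow(expected) >= 1,
            intensity_tol >= 0, mz_tol > 0)
  obs_off <- observed$mz - observed$mz[1]
  exp_off <- expected$mz - expected$mz[1]
  credit <- vapply(seq_along(exp_off), function(i) {
    d <- abs(obs_off - exp_off[i])
    hit <- which(d <= mz_tol)
    if (!length(hit)) return(0)
    j <- hit[which.min(d[hit])]
    dev <- abs(observed$intensity[j] - expected$intensity[i])
    excess <- max(0, dev - intensity_tol)
    max(0, 1 - excess / expected$intensity[i])
  }, numeric(1))
  mean(credit)
}
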