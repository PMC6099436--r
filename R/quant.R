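# External calibration, replicate statistics, control ratios and provenance
# classification.

#' Fit an external calibration curve
#'
#' Ordinary least-squares line of peak area on standard concentration,
#' via \code{stats::lm}.
#'
#' @param points data.frame with columns \code{concentration} (ug/L) and
#'   \code{area}, at two or more distinct concentration levels.
#' @return list of class \code{calibration_curve} with \code{slope}
#'   (area per ug/L), \code{intercept} (area) and \code{r_squared}.
#' @examples
#' fit_calibration(data.frame(concentration = c(0, 5, 10),
#'                            area = c(5, 505, 1005)))
#' @export
fit_calibration <- function(points) {
  stopifnot(all(c("concentration", "area") %in% names(points)))
  if (length(unique(points$concentration)) < 2L) {
    stop("calibration needs at least 2 distinct concentration levels")
  }
  fit <- stats::lm(area ~ concentration, data = points)
  ss_tot <- sum((points$area - mean(points$area))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(
    slope = unname(stats::coef(fit)[["concentration"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    r_squared = r2
  ), class = "calibration_curve")
}

#' Convert a peak area to a tissue concentration
#'
#' Inverts the calibration curve to an extract concentration (ug/L) and
#' rescales to the plant-material basis:
#' \code{(area - intercept) / slope * extract_volume_L / sample_mass_g},
#' giving ug per g of tissue. Negative back-calculated concentrations
#' (area below the intercept) are clipped to 0 and flagged.
#'
#' @param area integrated peak area.
#' @param curve a \code{calibration_curve} from
#'   \code{\link{fit_calibration}}.
#' @param sample_mass_g extracted tissue mass in g (> 0); the experiment
#'   extracted 1 g of separated root or leaf material.
#' @param extract_volume_L extraction solvent volume in L; 2 mL of
#'   acetonitrile, i.e. 0.002.
#' @return concentration in ug/g with attribute \code{clipped} (logical).
#' @export
quantify <- function(area, curve, sample_mass_g = 1, extract_volume_L = 0.002) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration slope must be > 0")
  if (sample_mass_g <= 0) stop("sample mass must be > 0")
  conc <- (area - curve$intercept) / curve$slope * extract_volume_L / sample_mass_g
  clipped <- conc < 0
  if (any(clipped)) {
    warning("negative back-calculated concentration clipped to 0")
    conc[clipped] <- 0
  }
  structure(conc, clipped = clipped)
}

#' Replicate mean, SD and RSD
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and
#' relative standard deviation of replicate concentrations. The RSD is
#' reported rounded to an integer percentage, as concentration tables
#' conventionally print it; full precision is kept in \code{rsd_exact}.
#'
#' @param values numeric vector of replicate values (length >= 2).
#' @return data.frame with \code{mean}, \code{sd}, \code{rsd_percent}
#'   (integer) and \code{rsd_exact}.
#' @examples
#' replicate_stats(c(1.3, 1.8, 2.4))
#' @export
replicate_stats <- function(values) {
  if (length(values) < 2L) stop("replicate statistics need >= 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  rsd <- if (m > 0) s / m * 100 else NA_real_
  data.frame(mean = m, sd = s, rsd_percent = round(rsd), rsd_exact = rsd)
}

#' Root-to-control peak-area ratio
#'
#' Ratio of a metabolite's integrated peak area in the root extract to its
#' area in the growing-medium control — the quantity that separates
#' plant-made metabolites from plant-independent transformation products.
#'
#' @param root_area area in the root extract.
#' @param gm_area area in the growing-medium control; 0 (or \code{NA})
#'   means the compound was not detected there and no finite ratio exists.
#' @return the ratio, or \code{NA} with attribute
#'   \code{not_detected_in_gm = TRUE} when \code{gm_area} is 0/\code{NA}.
#' @export
control_ratio <- function(root_area, gm_area) {
  stopifnot(root_area >= 0)
  if (is.na(gm_area) || gm_area == 0) {
    return(structure(NA_real_, not_detected_in_gm = TRUE))
  }
  if (gm_area < 0) stop("gm_area must be >= 0")
  root_area / gm_area
}

#' Classify the provenance of a detected compound
#'
#' Encodes the control logic of the uptake experiment as a total function
#' over detection flags and the root/GM area ratio:
#' \itemize{
#'   \item detected in the negative control: \code{contamination_suspect}
#'     (tap-water-grown plants must be blank);
#'   \item an administered compound: \code{parent};
#'   \item absent from the growing-medium control: \code{true_metabolite}
#'     (the plant is the only possible source);
#'   \item present in the GM control with ratio >= \code{r_dominant}:
#'     \code{metabolite_dominant} (plant metabolism dominates, the medium
#'     contributes marginally);
#'   \item ratio in [\code{r_mixed}, \code{r_dominant}): \code{mixed}
#'     (plant metabolism and plant-independent transformation both
#'     contribute);
#'   \item ratio < \code{r_mixed}: \code{transformation_leaning} (formation
#'     outside the plant with subsequent uptake is the simpler reading).
#' }
#' The thresholds are interpretation, not measurement, and are deliberately
#' configurable.
#'
#' @param detected_root,detected_leaf,detected_gm,detected_negative logical
#'   detection flags per compartment.
#' @param ratio root/GM area ratio; required iff \code{detected_gm}.
#' @param is_parent whether the compound was administered.
#' @param r_dominant,r_mixed classification thresholds (defaults 100 and 5).
#' @return a list of class \code{provenance_call} with \code{call} and
#'   \code{ratio}.
#' @export
classify_provenance <- function(detected_root, detected_leaf, detected_gm,
                                detected_negative, ratio = NA_real_,
                                is_parent = FALSE,
                                r_dominant = 100, r_mixed = 5) {
  stopifnot(is.logical(detected_root), is.logical(detected_leaf),
            is.logical(detected_gm), is.logical(detected_negative),
            r_dominant > r_mixed, r_mixed > 0)
  if (detected_gm && is.na(ratio)) {
    stop("compound detected in GM control but no root/GM ratio supplied")
  }
  call <- if (detected_negative) {
    "contamination_suspect"
  } else if (is_parent) {
    "parent"
  } else if (!detected_gm) {
    "true_metabolite"
  } else if (ratio >= r_dominant) {
    "metabolite_dominant"
  } else if (ratio >= r_mixed) {
    "mixed"
  } else {
    "transformation_leaning"
  }
  structure(list(call = call,
                 ratio = if (detected_gm) ratio else NA_real_),
            class = "provenance_call")
}

#' Leaf-to-root translocation factor
#'
#' Ratio of leaf to root tissue concentration. Values above 1 indicate a
#' leaf-accumulating compound, values below 1 a root-retained one.
#'
#' @param leaf_conc,root_conc tissue concentrations (same units).
#' @return the ratio; \code{NA} with attribute \code{undefined = TRUE} when
#'   \code{root_conc} is 0.
#' @export
translocation_factor <- function(leaf_conc, root_conc) {
  stopifnot(leaf_conc >= 0, root_conc >= 0)
  if (root_conc == 0) return(structure(NA_real_, undefined = TRUE))
  leaf_conc / root_conc
}
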