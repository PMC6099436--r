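# Synthetic LC-HRMS dataset emulating the hydroponic antidepressant uptake
# experiment: root and leaf extracts, a growing-medium control and a
# negative control, with full chlorine isotope envelopes, ppm-scale mass
# jitter and random noise peaks. Every true peak is recorded in a ground
# truth manifest so pipeline recovery can be asserted.

#' Default compound panel of the simulated uptake experiment
#'
#' The three administered antidepressants and their eleven observed
#' metabolite species (structural isomer pairs at distinct retention times
#' count separately). Retention times and product ions follow the reported
#' detections; per-compartment base areas are in arbitrary intensity units
#' with ratios encoding the observed translocation patterns (sertraline
#' root-retained, trazodone leaf-accumulating, clomipramine intermediate)
#' and the reported root/GM-control area ratios (51, 378, 491, 1.84, 25).
#' \code{gm_fraction} is the GM-control area as a fraction of the root base
#' area: the reciprocal of the targeted root/GM ratio for GM-shared
#' metabolites, > 1 for the administered drugs (the growing medium is the
#' dosing solution itself), 0 for true metabolites.
#'
#' @return data.frame with columns \code{name}, \code{formula}, \code{rt}
#'   (min), \code{root_area}, \code{leaf_area}, \code{gm_fraction},
#'   \code{is_parent}, \code{expected_call}, \code{fragments}
#'   (\code{"/"}-separated product-ion m/z values).
#' @export
cress_compounds <- function() {
  df <- data.frame(
    name = c("STR", "OH-STR (isomer 1)", "OH-STR (isomer 2)",
             "DM-STR+Phe", "DM-STR+Tyr", "OH-DM-STR+Phe",
             "CLP", "DM-CLP", "OH-CLP (isomer 1)", "OH-CLP (isomer 2)",
             "OH-DM-CLP", "TZN", "OH-TZN", "mCPP"),
    formula = c("C17H17Cl2N", "C17H17Cl2NO", "C17H17Cl2NO",
                "C25H24Cl2N2O", "C25H24Cl2N2O2", "C25H24Cl2N2O2",
                "C19H23ClN2", "C18H21ClN2", "C19H23ClN2O", "C19H23ClN2O",
                "C18H21ClN2O", "C19H22ClN5O", "C19H22ClN5O2", "C10H13ClN2"),
    rt = c(10.2, 6.7, 8.2, 13.1, 12.7, 12.5,
           10.7, 10.4, 6.8, 7.0, 6.6, 5.5, 6.3, 3.0),
    root_area = c(4.29e6, 1.0e6, 0.6e6, 0.20e6, 0.15e6, 0.12e6,
                  1.83e6, 0.5e6, 1.5e6, 1.4e6, 0.3e6, 0.91e6, 0.25e6, 0.8e6),
    leaf_area = c(0.52e6, 0.20e6, 0.012e6, 0, 0, 0,
                  1.14e6, 0.3e6, 0.8e6, 0.7e6, 0.1e6, 2.63e6, 0, 0.4e6),
    gm_fraction = c(2, 1 / 51, 0, 0, 0, 0,
                    2, 1 / 1.84, 1 / 378, 1 / 491, 0, 2, 0, 1 / 25),
    is_parent = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                  TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    expected_call = c("parent", "mixed", "true_metabolite",
                      "true_metabolite", "true_metabolite", "true_metabolite",
                      "parent", "transformation_leaning",
                      "metabolite_dominant", "metabolite_dominant",
                      "true_metabolite", "parent", "true_metabolite",
                      "mixed"),
    fragments = c("275.0", "273.0", "273.0",
                  "275.0/165.1/91.1", "275.0/181.1/107.1", "273.0/165.1",
                  "270.1/242.1/86.1", "270.1/242.1/72.1", "313.2/86.1",
                  "313.2/86.1", "299.1/86.1", "176.1/148.1", "176.1/148.1",
                  "154.0"),
    stringsAsFactors = FALSE
  )
  df$mz <- vapply(df$formula, protonated_mz, numeric(1), USE.NAMES = FALSE)
  df
}

#' Simulation configuration
#'
#' Defaults encode the emulated experimental design: 3 culture replicates
#' for root and leaf extracts, one growing-medium control and one negative
#' control; 2 ppm mass jitter (instrument accuracy at the level of the
#' reported mass errors, 0.5-4.8 ppm); 20 percent area noise (the level of
#' the reported biological RSDs, 14-27 percent); 200 chlorine-free noise
#' peaks per sample.
#'
#' Mass error is modeled the way a time-of-flight instrument produces it:
#' one calibration shift per isotope envelope (drawn from a Gaussian with
#' \code{mass_jitter_ppm_sd}), plus sub-ppm per-peak centroiding scatter,
#' with the total clamped at \code{mass_jitter_ppm_max} — the largest mass
#' error observed in the emulated study (4.8 ppm). Isotopologue spacings are
#' therefore far more precise than absolute masses, as in real spectra, and
#' every true species stays inside a 5 ppm screening window.
#'
#' @param seed RNG seed; a fixed seed makes the dataset fully reproducible.
#' @param mass_jitter_ppm_sd Gaussian m/z calibration jitter, ppm.
#' @param mass_jitter_ppm_max bound on the total m/z error, ppm.
#' @param centroid_ppm_sd per-peak centroiding scatter, ppm.
#' @param intensity_noise_cv log-normal coefficient of variation applied to
#'   each compound's area per sample.
#' @param envelope_noise_sd relative Gaussian noise on individual envelope
#'   peak intensities.
#' @param n_noise_peaks noise peaks per sample.
#' @param replicates culture replicates for root and leaf.
#' @param rt_jitter_sd retention-time jitter per feature, minutes.
#' @param noise_min_ppm minimum ppm distance of any noise peak from every
#'   true isotopologue and every enumerated suspect m/z.
#' @param emit_min_rel weakest isotopologue emitted, relative to the base
#'   peak (emulates the centroiding intensity floor).
#' @param noise_mz_range,noise_rt_range ranges noise peaks are drawn from.
#' @return a named list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 42L, mass_jitter_ppm_sd = 2,
                       mass_jitter_ppm_max = 4.8, centroid_ppm_sd = 0.3,
                       intensity_noise_cv = 0.2, envelope_noise_sd = 0.05,
                       n_noise_peaks = 200L, replicates = 3L,
                       rt_jitter_sd = 0.01, noise_min_ppm = 20,
                       emit_min_rel = 0.005,
                       noise_mz_range = c(100, 600),
                       noise_rt_range = c(0.3, 17)) {
  structure(list(
    seed = as.integer(seed), mass_jitter_ppm_sd = mass_jitter_ppm_sd,
    mass_jitter_ppm_max = mass_jitter_ppm_max,
    centroid_ppm_sd = centroid_ppm_sd,
    intensity_noise_cv = intensity_noise_cv,
    envelope_noise_sd = envelope_noise_sd,
    n_noise_peaks = as.integer(n_noise_peaks),
    replicates = as.integer(replicates), rt_jitter_sd = rt_jitter_sd,
    noise_min_ppm = noise_min_ppm, emit_min_rel = emit_min_rel,
    noise_mz_range = noise_mz_range, noise_rt_range = noise_rt_range
  ), class = "sim_config")
}

#' Generate the synthetic uptake-experiment dataset
#'
#' For each compartment and replicate, emits a centroided peak table in
#' which every compound present in that compartment contributes its full
#' [M+H]+ isotope envelope (intensities from \code{\link{isotope_pattern}},
#' areas log-normally perturbed, m/z Gaussian-jittered in ppm) plus
#' chlorine-free random noise peaks kept at least \code{noise_min_ppm} away
#' from every true isotopologue m/z \emph{and} every suspect candidate m/z
#' enumerable from the administered drugs — so a noise peak can never be an
#' exact-mass match. The negative control receives noise only; the
#' growing-medium control receives \code{gm_fraction} times the root base
#' area for GM-present compounds.
#'
#' @param config a \code{\link{sim_config}}.
#' @param compounds a compound panel (default
#'   \code{\link{cress_compounds}()}).
#' @param exclusion_candidates candidate data.frame whose theoretical m/z
#'   values noise must avoid; default: the built-in rules enumerated at
#'   depth 3 from the three parent drugs.
#' @return list with \code{peaks} (one data.frame for all samples, columns
#'   \code{mz}, \code{rt_min}, \code{area}, \code{sample_id},
#'   \code{compartment}, \code{replicate}, \code{truth}) and
#'   \code{manifest} (list: \code{compounds} with expected per-compartment
#'   presence and provenance calls, and the configuration echo).
#' @export
generate_dataset <- function(config = sim_config(),
                             compounds = cress_compounds(),
                             exclusion_candidates = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(exclusion_candidates)) {
    exclusion_candidates <- enumerate_all_candidates(parent_drugs())
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed, kind = "Mersenne-Twister")

  # theoretical envelopes of all compounds (ion composition M + H, minus
  # one electron for the m/z scale)
  env <- lapply(seq_len(nrow(compounds)), function(i) {
    ion <- apply_delta(compounds$formula[i], c(H = 1))
    pat <- isotope_pattern(ion, prune = config$emit_min_rel)
    data.frame(mz = pat$mass - .ELECTRON_MASS,
               rel = pat$abundance / max(pat$abundance))
  })
  exclusion_mz <- sort(unique(c(
    unlist(lapply(env, `[[`, "mz")),
    exclusion_candidates$mz
  )))

  samples <- rbind(
    expand.grid(compartment = c("root", "leaf"),
                replicate = seq_len(config$replicates),
                stringsAsFactors = FALSE),
    data.frame(compartment = c("gm_control", "negative_control"),
               replicate = 1L)
  )
  samples$sample_id <- paste0(samples$compartment, "_", samples$replicate)

  all_rows <- list()
  for (si in seq_len(nrow(samples))) {
    comp <- samples$compartment[si]
    for (i in seq_len(nrow(compounds))) {
      base <- switch(comp,
        root = compounds$root_area[i],
        leaf = compounds$leaf_area[i],
        gm_control = compounds$gm_fraction[i] * compounds$root_area[i],
        negative_control = 0)
      if (base <= 0) next
      area <- base * exp(stats::rnorm(1, 0, config$intensity_noise_cv))
      rt <- compounds$rt[i] + stats::rnorm(1, 0, config$rt_jitter_sd)
      e <- env[[i]]
      npk <- nrow(e)
      rel <- e$rel * pmax(0.05, 1 + stats::rnorm(npk, 0, config$envelope_noise_sd))
      rel[1] <- e$rel[1]  # the monoisotopic peak anchors the envelope
      shift <- stats::rnorm(1, 0, config$mass_jitter_ppm_sd)
      ppm <- shift + stats::rnorm(npk, 0, config$centroid_ppm_sd)
      ppm <- pmax(-config$mass_jitter_ppm_max,
                  pmin(config$mass_jitter_ppm_max, ppm))
      mz <- e$mz * (1 + ppm * 1e-6)
      all_rows <- c(all_rows, list(data.frame(
        mz = mz, rt_min = rt + stats::rnorm(npk, 0, 0.002),
        area = area * rel, sample_id = samples$sample_id[si],
        compartment = comp, replicate = samples$replicate[si],
        truth = compounds$name[i], stringsAsFactors = FALSE)))
    }
    # noise peaks, rejection-sampled away from every true/suspect m/z
    nn <- config$n_noise_peaks
    if (nn > 0) {
      mz <- .draw_noise_mz(nn, exclusion_mz, config$noise_min_ppm,
                           config$noise_mz_range)
      all_rows <- c(all_rows, list(data.frame(
        mz = mz,
        rt_min = stats::runif(nn, config$noise_rt_range[1],
                              config$noise_rt_range[2]),
        area = exp(stats::rnorm(nn, log(2e4), 1)),
        sample_id = samples$sample_id[si], compartment = comp,
        replicate = samples$replicate[si], truth = NA_character_,
        stringsAsFactors = FALSE)))
    }
  }
  peaks <- do.call(rbind, all_rows)
  rownames(peaks) <- NULL

  manifest <- list(
    compounds = data.frame(
      name = compounds$name, formula = compounds$formula,
      theoretical_mz = compounds$mz, rt = compounds$rt,
      in_root = compounds$root_area > 0,
      in_leaf = compounds$leaf_area > 0,
      in_gm = compounds$gm_fraction > 0,
      in_negative = FALSE,
      is_parent = compounds$is_parent,
      expected_call = compounds$expected_call,
      target_gm_ratio = ifelse(compounds$gm_fraction > 0,
                               1 / compounds$gm_fraction, NA_real_),
      stringsAsFactors = FALSE),
    config = unclass(config),
    n_species = nrow(compounds)
  )
  list(peaks = peaks, manifest = manifest)
}

# uniform m/z draws at least min_ppm away from every excluded mass
.draw_noise_mz <- function(n, exclusion_mz, min_ppm, mz_range) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::runif(n - length(out), mz_range[1], mz_range[2])
    ok <- vapply(draw, function(x) {
      i <- findInterval(x, exclusion_mz)
      near <- exclusion_mz[pmax(1, pmin(length(exclusion_mz), c(i, i + 1L)))]
      all(abs(x - near) / x * 1e6 >= min_ppm)
    }, logical(1))
    out <- c(out, draw[ok])
  }
  out[seq_len(n)]
}

#' Write a generated dataset to disk
#'
#' One CSV peak table per sample plus a JSON ground-truth manifest, in the
#' dialect \code{\link{read_peak_table}} consumes.
#'
#' @param dataset result of \code{\link{generate_dataset}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in unique(dataset$peaks$sample_id)) {
    sub <- dataset$peaks[dataset$peaks$sample_id == sid,
                         c("mz", "rt_min", "area", "sample_id",
                           "compartment", "replicate")]
    utils::write.csv(sub, file.path(dir, paste0(sid, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(dataset$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Generate MS2 spectra for a compound panel
#'
#' One spectrum per compound: precursor = theoretical [M+H]+ m/z, fragments
#' from the panel's product-ion list with fixed descending intensities.
#' Compounds with no fragments yield an empty spectrum with a warning.
#'
#' @param compounds compound panel (default \code{\link{cress_compounds}()}).
#' @return list of spectra in the \code{\link{read_mgf}} layout.
#' @export
generate_msms <- function(compounds = cress_compounds()) {
  lapply(seq_len(nrow(compounds)), function(i) {
    frag_mz <- suppressWarnings(
      as.numeric(strsplit(compounds$fragments[i], "/", fixed = TRUE)[[1]]))
    frag_mz <- frag_mz[!is.na(frag_mz)]
    if (!length(frag_mz)) {
      warning("compound ", compounds$name[i], " has no fragments")
    }
    intensity <- if (length(frag_mz)) {
      100 * 0.6^(seq_along(frag_mz) - 1)
    } else {
      numeric(0)
    }
    list(precursor_mz = compounds$mz[i],
         compound_label = compounds$name[i],
         rt_min = compounds$rt[i],
         fragments = data.frame(mz = frag_mz, intensity = intensity))
  })
}
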