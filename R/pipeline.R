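# End-to-end orchestration: candidates -> envelopes -> suspect matches ->
# halogen screen -> MS2 annotation -> provenance classification.

#' Pipeline configuration
#'
#' Collects every tolerance and threshold of the screening pipeline. The
#' defaults are the package's reference configuration: 5 ppm exact-mass
#' window (the largest reported mass error is 4.8 ppm), 0.05 min co-elution
#' tolerance, envelope score 0.7, enumeration depth 3 with at most one
#' amino-acid conjugation, provenance thresholds 100 (dominant) and 5
#' (mixed).
#'
#' @param parents named character vector of administered drugs
#'   (name -> formula).
#' @param rules transformation rule set.
#' @param max_depth enumeration depth.
#' @param group_limits per-group application caps for enumeration.
#' @param ppm_tol exact-mass tolerance, ppm.
#' @param rt_tol co-elution tolerance for envelope assembly, minutes.
#' @param mz_pair_tol isotopologue spacing tolerance, Da.
#' @param min_envelope_score minimum isotope-envelope score for a match.
#' @param intensity_tol,mz_tol envelope scoring tolerances.
#' @param fragment_tol MS2 fragment tolerance, Da.
#' @param halogen_threshold chlorine-signature score threshold.
#' @param species_rt_gap RT gap separating isomer species, minutes.
#' @param r_dominant,r_mixed provenance classification thresholds on the
#'   root/GM area ratio.
#' @param suspect_list optional path to an explicit suspect-list CSV merged
#'   into the enumerated candidates.
#' @return named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(parents = parent_drugs(),
                            rules = builtin_rules(), max_depth = 3L,
                            group_limits = c(conjugation = 1L),
                            ppm_tol = 5, rt_tol = 0.05,
                            mz_pair_tol = 0.005,
                            min_envelope_score = 0.7,
                            intensity_tol = 0.15, mz_tol = 0.005,
                            fragment_tol = 0.1, halogen_threshold = 0.7,
                            species_rt_gap = 0.1,
                            r_dominant = 100, r_mixed = 5,
                            suspect_list = NULL) {
  stopifnot(ppm_tol > 0, rt_tol > 0, mz_pair_tol > 0, fragment_tol > 0,
            min_envelope_score >= 0, min_envelope_score <= 1,
            halogen_threshold >= 0, halogen_threshold <= 1,
            r_dominant > r_mixed, r_mixed > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Enumerates suspect candidates from the administered drugs, assembles
#' isotope envelopes from the centroided peak tables, matches candidates by
#' exact mass and envelope, clusters matches into isomer species, screens
#' unmatched features for chlorine signatures, annotates MS2 spectra where
#' provided, and classifies every identified species' provenance against
#' the growing-medium and negative controls.
#'
#' @param input either a directory containing per-sample peak-table CSVs
#'   (and optionally an \code{.mgf} file of MS2 spectra), or a list with
#'   elements \code{peaks} (a peak data.frame) and optionally \code{msms}
#'   (a list of spectra).
#' @param config a \code{\link{pipeline_config}}.
#' @return list of class \code{screen_result}: \code{candidates},
#'   \code{features}, \code{matches}, \code{species} (one row per
#'   identified species with per-compartment presence and areas),
#'   \code{halogen_hits}, \code{annotations}, \code{provenance},
#'   \code{config}.
#' @export
run_pipeline <- function(input, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  loaded <- .load_input(input)
  if (is.null(loaded$peaks) || nrow(loaded$peaks) == 0L) {
    stop("no peak tables found in input")
  }
  candidates <- enumerate_all_candidates(config$parents, config$rules,
                                         config$max_depth,
                                         config$group_limits)
  if (!is.null(config$suspect_list)) {
    extra <- load_suspect_list(config$suspect_list)
    shared <- intersect(names(candidates), names(extra))
    candidates <- rbind(candidates[shared], extra[shared])
  }
  features <- assemble_all_envelopes(loaded$peaks, rt_tol = config$rt_tol,
                                     mz_pair_tol = config$mz_pair_tol)
  matches <- match_suspects(features, candidates, ppm_tol = config$ppm_tol,
                            min_envelope_score = config$min_envelope_score,
                            intensity_tol = config$intensity_tol,
                            mz_tol = config$mz_tol)
  matches <- cluster_species(matches, gap = config$species_rt_gap)
  species <- .species_summary(matches)
  halogen_hits <- detect_halogenated(features,
                                     score_threshold = config$halogen_threshold,
                                     matches = matches,
                                     intensity_tol = config$intensity_tol,
                                     mz_tol = config$mz_tol)
  annotations <- if (!is.null(loaded$msms)) {
    .annotate_spectra(loaded$msms, species, config)
  } else {
    NULL
  }
  provenance <- .classify_species(species, config)
  structure(list(candidates = candidates, features = features,
                 matches = matches, species = species,
                 halogen_hits = halogen_hits, annotations = annotations,
                 provenance = provenance, config = config),
            class = "screen_result")
}

.load_input <- function(input) {
  if (is.list(input) && !is.null(input$peaks)) {
    return(list(peaks = input$peaks, msms = input$msms))
  }
  if (!is.character(input) || !dir.exists(input)) {
    stop("input must be a directory or a list with a 'peaks' element")
  }
  files <- list.files(input, pattern = "\\.(csv|tsv)$", full.names = TRUE)
  files <- files[!grepl("manifest", basename(files))]
  if (!length(files)) stop("no peak-table CSV/TSV files in ", input)
  peaks <- do.call(rbind, lapply(files, read_peak_table))
  mgf <- list.files(input, pattern = "\\.mgf$", full.names = TRUE)
  msms <- if (length(mgf)) unlist(lapply(mgf, read_mgf), recursive = FALSE)
  list(peaks = peaks, msms = msms)
}

# one row per identified species: per-compartment detection flags and mean
# monoisotopic areas (replicate mean); candidate names sharing the species'
# formula are joined with "|"
.species_summary <- function(matches) {
  empty <- data.frame(
    species_id = character(0), name = character(0), parent = character(0),
    formula = character(0),
    theoretical_mz = numeric(0), species_rt = numeric(0),
    measured_mz = numeric(0), mean_ppm = numeric(0),
    detected_root = logical(0), detected_leaf = logical(0),
    detected_gm = logical(0), detected_negative = logical(0),
    area_root = numeric(0), area_leaf = numeric(0), area_gm = numeric(0),
    is_parent = logical(0), ambiguous = logical(0))
  if (nrow(matches) == 0L) return(empty)
  rows <- lapply(split(matches, matches$species_id), function(m) {
    comp_area <- function(comp) {
      sub <- m[m$compartment == comp, ]
      if (!nrow(sub)) return(NA_real_)
      # replicate totals first (a species has one feature per sample), then
      # the replicate mean
      mean(tapply(sub$area, sub$replicate, sum))
    }
    data.frame(
      species_id = m$species_id[1],
      name = paste(sort(unique(m$name)), collapse = "|"),
      parent = paste(sort(unique(m$parent)), collapse = "|"),
      formula = m$formula[1],
      theoretical_mz = m$theoretical_mz[1],
      species_rt = m$species_rt[1],
      measured_mz = mean(m$measured_mz),
      mean_ppm = mean(m$ppm),
      detected_root = any(m$compartment == "root"),
      detected_leaf = any(m$compartment == "leaf"),
      detected_gm = any(m$compartment == "gm_control"),
      detected_negative = any(m$compartment == "negative_control"),
      area_root = comp_area("root"),
      area_leaf = comp_area("leaf"),
      area_gm = comp_area("gm_control"),
      is_parent = any(m$chain == "", na.rm = TRUE),
      ambiguous = any(m$ambiguous),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$theoretical_mz, out$species_rt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.classify_species <- function(species, config) {
  if (nrow(species) == 0L) {
    return(data.frame(species_id = character(0), name = character(0),
                      formula = character(0), species_rt = numeric(0),
                      call = character(0), gm_ratio = numeric(0)))
  }
  rows <- lapply(seq_len(nrow(species)), function(i) {
    s <- species[i, ]
    ratio <- if (s$detected_gm) {
      as.numeric(control_ratio(s$area_root, s$area_gm))
    } else {
      NA_real_
    }
    pc <- classify_provenance(s$detected_root, s$detected_leaf,
                              s$detected_gm, s$detected_negative,
                              ratio = ratio, is_parent = s$is_parent,
                              r_dominant = config$r_dominant,
                              r_mixed = config$r_mixed)
    data.frame(species_id = s$species_id, name = s$name,
               formula = s$formula, species_rt = s$species_rt,
               call = pc$call, gm_ratio = ratio, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# match MS2 spectra to identified species by precursor m/z; annotate losses
# and diagnostics; link to the parent drug spectrum by shared fragments
.annotate_spectra <- function(spectra, species, config) {
  if (!length(spectra) || nrow(species) == 0L) return(NULL)
  prec <- vapply(spectra, `[[`, numeric(1), "precursor_mz")
  parent_spec <- function(parent_name) {
    idx <- which(vapply(spectra, function(sp)
      identical(sp$compound_label, parent_name), logical(1)))
    if (length(idx)) spectra[[idx[1]]] else NULL
  }
  rows <- list()
  for (si in seq_along(spectra)) {
    sp <- spectra[[si]]
    d_ppm <- abs(ppm_error(species$theoretical_mz, sp$precursor_mz))
    hit <- which(d_ppm <= 10)
    if (!length(hit)) next
    # prefer the species closest in RT when the spectrum carries one
    if (length(hit) > 1L && !is.na(sp$rt_min)) {
      hit <- hit[which.min(abs(species$species_rt[hit] - sp$rt_min))]
    } else {
      hit <- hit[which.min(d_ppm[hit])]
    }
    s <- species[hit, ]
    losses <- annotate_losses(sp, tol = config$fragment_tol)
    diags <- flag_diagnostics(sp, tol = config$fragment_tol)
    parents <- unique(strsplit(s$parent, "|", fixed = TRUE)[[1]])
    shared_mz <- numeric(0)
    for (p in parents) {
      ps <- parent_spec(p)
      if (!is.null(ps) && !identical(ps$compound_label, sp$compound_label)) {
        sf <- shared_fragments(sp, ps, tol = config$fragment_tol)
        shared_mz <- c(shared_mz, sf$mz_a)
      }
    }
    for (fmz in unique(losses$fragment_mz)) {
      lh <- losses$loss[losses$fragment_mz == fmz & !is.na(losses$loss)]
      dh <- diags$meaning[abs(diags$fragment_mz - fmz) < 1e-9]
      rows <- c(rows, list(data.frame(
        species_id = s$species_id, spectrum = si,
        compound_label = if (is.null(sp$compound_label)) NA_character_ else sp$compound_label,
        precursor_mz = sp$precursor_mz, fragment_mz = fmz,
        losses = paste(lh, collapse = ";"),
        diagnostics = paste(dh, collapse = ";"),
        shared_with_parent = fmz %in% shared_mz,
        explained = length(lh) > 0 || length(dh) > 0,
        stringsAsFactors = FALSE)))
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count identified species
#'
#' Number of distinct identified species — candidate formulas at distinct
#' retention times — detected in the plant compartments (root or leaf).
#'
#' @param result a \code{screen_result} from \code{\link{run_pipeline}}.
#' @return integer count.
#' @export
n_identified_species <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  sp <- result$species
  sum(sp$detected_root | sp$detected_leaf)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n")
  cat("  candidates screened :", nrow(x$candidates), "\n")
  cat("  features            :", nrow(x$features), "\n")
  cat("  identified species  :", n_identified_species(x), "\n")
  cat("  halogen hits        :", nrow(x$halogen_hits),
      sprintf("(%d unknown)", sum(x$halogen_hits$suspect == "unknown")), "\n")
  if (!is.null(x$provenance) && nrow(x$provenance)) {
    tab <- table(x$provenance$call)
    cat("  provenance calls    :",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a report bundle
#'
#' Writes the pipeline result as TSV tables (candidates, matches, species,
#' halogen hits, annotations, provenance) plus a JSON summary.
#'
#' @param result a \code{screen_result}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "screen_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (is.null(df)) return()
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wr(result$candidates, "candidates")
  wr(result$matches, "matches")
  wr(result$species, "species")
  wr(result$halogen_hits, "halogen_hits")
  wr(result$annotations, "annotations")
  wr(result$provenance, "provenance")
  summary <- list(
    n_candidates = nrow(result$candidates),
    n_features = nrow(result$features),
    n_identified_species = n_identified_species(result),
    n_halogen_hits = nrow(result$halogen_hits),
    n_unknown_halogen = sum(result$halogen_hits$suspect == "unknown"),
    provenance_calls = as.list(table(result$provenance$call))
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
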