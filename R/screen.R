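# Envelope assembly from centroided peak tables and suspect matching.

#' Read a centroided peak table
#'
#' Reads the package's peak-table dialect: a CSV/TSV with columns \code{mz},
#' \code{rt_min}, \code{area}, \code{sample_id}, \code{compartment},
#' \code{replicate}. Separator is inferred from the file extension
#' (\code{.tsv} = tab, otherwise comma).
#'
#' @param path file path.
#' @return data.frame of peak rows.
#' @export
read_peak_table <- function(path) {
  stopifnot(file.exists(path))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("mz", "rt_min", "area", "sample_id", "compartment")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("peak table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  df
}

#' Group co-eluting isotopologue peaks into features
#'
#' Centroided peaks from one sample that co-elute within \code{rt_tol} and
#' are spaced by approximately k x 1.00336 Da (\eqn{^{13}C}) or
#' k x 1.99705 Da (\eqn{^{37}Cl}), k = 1 or 2, are chained into one feature.
#' The lowest-m/z peak of a group is taken as the monoisotopic peak; its
#' area is the feature area and the group's intensities relative to it form
#' the feature's envelope. Peaks that join no group become singleton
#' features with envelope [1.0].
#'
#' @param peaks data.frame of peak rows from \emph{one} sample (columns
#'   \code{mz}, \code{rt_min}, \code{area}; any others are carried through
#'   from the monoisotopic row).
#' @param rt_tol co-elution tolerance in minutes (default 0.05).
#' @param mz_pair_tol tolerance on the isotopologue spacing in Da
#'   (default 0.005).
#' @return data.frame of features: \code{mz} (monoisotopic), \code{rt_min},
#'   \code{area}, \code{n_peaks}, carried-through sample columns, and an
#'   \code{envelope} list-column of data.frames (\code{mz} absolute,
#'   \code{intensity} relative to the monoisotopic peak).
#' @export
assemble_envelopes <- function(peaks, rt_tol = 0.05, mz_pair_tol = 0.005) {
  stopifnot(rt_tol > 0, mz_pair_tol > 0)
  if (is.null(peaks) || nrow(peaks) == 0L) {
    return(.empty_features())
  }
  if (length(unique(peaks$sample_id)) > 1L) {
    stop("assemble_envelopes expects peaks from a single sample")
  }
  n <- nrow(peaks)
  ord <- order(peaks$mz)
  peaks <- peaks[ord, , drop = FALSE]
  spacings <- c(.SPACING_C13, 2 * .SPACING_C13, .SPACING_CL37, 2 * .SPACING_CL37)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  # sorted two-pointer sweep: only pairs within the largest spacing + tol
  max_gap <- max(spacings) + mz_pair_tol
  j0 <- 1L
  for (i in seq_len(n)) {
    while (peaks$mz[i] - peaks$mz[j0] > max_gap) j0 <- j0 + 1L
    if (j0 >= i) next
    for (j in j0:(i - 1L)) {
      gap <- peaks$mz[i] - peaks$mz[j]
      if (abs(peaks$rt_min[i] - peaks$rt_min[j]) > rt_tol) next
      if (any(abs(gap - spacings) <= mz_pair_tol)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  feats <- lapply(groups, function(idx) {
    idx <- idx[order(peaks$mz[idx])]
    mono <- idx[1]
    env <- data.frame(mz = peaks$mz[idx],
                      intensity = peaks$area[idx] / peaks$area[mono])
    row <- peaks[mono, , drop = FALSE]
    row$n_peaks <- length(idx)
    row$envelope <- I(list(env))
    row
  })
  out <- do.call(rbind, feats)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_features <- function() {
  data.frame(mz = numeric(0), rt_min = numeric(0), area = numeric(0),
             sample_id = character(0), compartment = character(0),
             replicate = integer(0), n_peaks = integer(0),
             envelope = I(list()))
}

#' Assemble features for every sample in a peak table
#'
#' Convenience wrapper applying \code{\link{assemble_envelopes}} per
#' \code{sample_id}.
#'
#' @inheritParams assemble_envelopes
#' @param peaks peak rows from any number of samples.
#' @return row-bound feature data.frame.
#' @export
assemble_all_envelopes <- function(peaks, rt_tol = 0.05, mz_pair_tol = 0.005) {
  if (is.null(peaks) || nrow(peaks) == 0L) return(.empty_features())
  parts <- lapply(split(peaks, peaks$sample_id), assemble_envelopes,
                  rt_tol = rt_tol, mz_pair_tol = mz_pair_tol)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Match features against suspect candidates
#'
#' A feature matches a candidate when the ppm error between the feature's
#' monoisotopic m/z and the candidate's theoretical [M+H]+ m/z is within
#' \code{ppm_tol} \emph{and} the feature's envelope scores at least
#' \code{min_envelope_score} against the theoretical isotope pattern of the
#' candidate's protonated ion. One candidate matched at several distinct
#' retention times corresponds to structural isomers; matches are returned
#' ordered by candidate m/z then RT. Features matching more than one
#' candidate formula are flagged \code{ambiguous}.
#'
#' @param features feature data.frame from
#'   \code{\link{assemble_envelopes}}.
#' @param candidates candidate data.frame
#'   (\code{\link{enumerate_candidates}} /
#'   \code{\link{load_suspect_list}}).
#' @param ppm_tol mass tolerance in ppm (default 5).
#' @param min_envelope_score minimum envelope score in [0, 1]
#'   (default 0.7).
#' @param intensity_tol,mz_tol envelope-scoring tolerances, passed to
#'   \code{\link{envelope_match_score}}.
#' @return data.frame of matches: candidate columns (\code{name},
#'   \code{parent}, \code{chain}, \code{formula}, \code{theoretical_mz}),
#'   feature columns (\code{measured_mz}, \code{rt_min}, \code{area},
#'   \code{sample_id}, \code{compartment}, \code{replicate}), \code{ppm},
#'   \code{envelope_score}, \code{ambiguous}.
#' @export
match_suspects <- function(features, candidates, ppm_tol = 5,
                           min_envelope_score = 0.7,
                           intensity_tol = 0.15, mz_tol = 0.005) {
  stopifnot(ppm_tol > 0, min_envelope_score >= 0, min_envelope_score <= 1)
  empty <- data.frame(
    name = character(0), parent = character(0), chain = character(0),
    formula = character(0), theoretical_mz = numeric(0),
    measured_mz = numeric(0), rt_min = numeric(0), area = numeric(0),
    sample_id = character(0), compartment = character(0),
    replicate = integer(0), ppm = numeric(0), envelope_score = numeric(0),
    ambiguous = logical(0))
  if (nrow(features) == 0L || nrow(candidates) == 0L) return(empty)

  # theoretical envelope per distinct candidate formula (of the [M+H]+ ion)
  formulas <- unique(candidates$formula)
  theo_env <- lapply(formulas, function(fstr) {
    ion <- apply_delta(fstr, c(H = 1))
    pattern_to_envelope(isotope_pattern(ion))
  })
  names(theo_env) <- formulas

  rows <- list()
  for (ci in seq_len(nrow(candidates))) {
    cand <- candidates[ci, ]
    ppm <- ppm_error(cand$mz, features$mz)
    hits <- which(abs(ppm) <= ppm_tol)
    for (fi in hits) {
      score <- envelope_match_score(features$envelope[[fi]],
                                    theo_env[[cand$formula]],
                                    intensity_tol = intensity_tol,
                                    mz_tol = mz_tol)
      if (score < min_envelope_score) next
      rows <- c(rows, list(data.frame(
        name = cand$name, parent = cand$parent, chain = cand$chain,
        formula = cand$formula, theoretical_mz = cand$mz,
        measured_mz = features$mz[fi], rt_min = features$rt_min[fi],
        area = features$area[fi], sample_id = features$sample_id[fi],
        compartment = features$compartment[fi],
        replicate = features$replicate[fi],
        ppm = ppm[fi], envelope_score = score,
        feature_key = paste(features$sample_id[fi], fi, sep = "#"),
        stringsAsFactors = FALSE)))
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # a feature matching candidates of more than one formula is ambiguous
  n_formula <- tapply(out$formula, out$feature_key,
                      function(x) length(unique(x)))
  out$ambiguous <- n_formula[out$feature_key] > 1L
  out$feature_key <- NULL
  out <- out[order(out$theoretical_mz, out$rt_min, out$sample_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster matched retention times into isomer species
#'
#' Within one candidate formula, matches whose retention times differ by
#' more than \code{gap} minutes belong to different structural isomers
#' (distinct species); closer RTs are the same species observed across
#' samples and replicates.
#'
#' @param matches match data.frame from \code{\link{match_suspects}}.
#' @param gap RT gap in minutes that separates species (default 0.1).
#' @return the matches with added columns \code{species_rt} (mean RT of the
#'   cluster) and \code{species_id} (\code{formula@rt}).
#' @export
cluster_species <- function(matches, gap = 0.1) {
  if (nrow(matches) == 0L) {
    matches$species_rt <- numeric(0)
    matches$species_id <- character(0)
    return(matches)
  }
  matches$species_rt <- NA_real_
  for (fstr in unique(matches$formula)) {
    idx <- which(matches$formula == fstr)
    rts <- matches$rt_min[idx]
    o <- order(rts)
    cluster <- cumsum(c(0, diff(rts[o]) > gap))
    mean_rt <- tapply(rts[o], cluster, mean)
    matches$species_rt[idx[o]] <- mean_rt[as.character(cluster)]
  }
  matches$species_id <- paste0(matches$formula, "@",
                               sprintf("%.2f", matches$species_rt))
  matches
}

#' Per-species, per-compartment presence and area summary
#'
#' For every detected species (candidate formula at a distinct retention
#' time) and compartment: whether it was detected and the monoisotopic peak
#' area in each replicate (kept separate so replicate statistics can be
#' computed downstream).
#'
#' @param matches match data.frame, typically after
#'   \code{\link{cluster_species}} (clustering is applied if the
#'   \code{species_id} column is absent).
#' @return long data.frame with one row per species x compartment x
#'   replicate: \code{species_id}, \code{name}, \code{formula},
#'   \code{species_rt}, \code{compartment}, \code{replicate}, \code{area},
#'   \code{detected}.
#' @export
presence_table <- function(matches) {
  if (!"species_id" %in% names(matches)) matches <- cluster_species(matches)
  if (nrow(matches) == 0L) {
    return(data.frame(species_id = character(0), name = character(0),
                      formula = character(0), species_rt = numeric(0),
                      compartment = character(0), replicate = integer(0),
                      area = numeric(0), detected = logical(0)))
  }
  agg <- stats::aggregate(
    area ~ species_id + name + formula + species_rt + compartment + replicate,
    data = matches, FUN = sum)
  agg$detected <- TRUE
  agg <- agg[order(agg$species_id, agg$compartment, agg$replicate), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}
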