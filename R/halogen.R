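# Untargeted chlorine-signature screening.

#' Flag features carrying chlorine isotope signatures
#'
#' The untargeted discovery step: every feature's envelope is scored against
#' the expected chlorine signatures (3:1 for one Cl, ~9.8:6.3:1 for two; see
#' \code{\link{chlorine_signature}}) and the best-scoring chlorine count at
#' or above \code{score_threshold} yields a hit. Hits whose monoisotopic m/z
#' is already explained by a suspect match carry that suspect's name; the
#' remainder are reported as unknown halogenated compounds — the mechanism by
#' which unexpected conjugates are discovered.
#'
#' Because the pure-chlorine signature ignores \eqn{^{13}C}, the observed
#' A+1 satellite is simply an unpenalized extra peak; the tight default m/z
#' tolerance of the scorer keeps the two-\eqn{^{13}C} A+2 satellite of
#' chlorine-free compounds from impersonating a \eqn{^{37}Cl} peak.
#'
#' @param features feature data.frame from
#'   \code{\link{assemble_envelopes}}.
#' @param score_threshold minimum signature score (default 0.7).
#' @param n_cl_max largest chlorine count considered (default 2).
#' @param matches optional match data.frame from
#'   \code{\link{match_suspects}}; used to attribute hits to suspects by
#'   (sample, m/z, RT).
#' @param intensity_tol,mz_tol envelope-scoring tolerances, passed to
#'   \code{\link{envelope_match_score}}.
#' @return data.frame of hits: \code{mz}, \code{rt_min}, \code{area},
#'   \code{sample_id}, \code{compartment}, \code{replicate},
#'   \code{n_cl_estimate}, \code{signature_score}, \code{suspect}
#'   (candidate name or \code{"unknown"}).
#' @export
detect_halogenated <- function(features, score_threshold = 0.7,
                               n_cl_max = 2L, matches = NULL,
                               intensity_tol = 0.15, mz_tol = 0.005) {
  stopifnot(score_threshold >= 0, score_threshold <= 1, n_cl_max >= 1)
  empty <- data.frame(mz = numeric(0), rt_min = numeric(0),
                      area = numeric(0), sample_id = character(0),
                      compartment = character(0), replicate = integer(0),
                      n_cl_estimate = integer(0),
                      signature_score = numeric(0), suspect = character(0))
  if (nrow(features) == 0L) return(empty)
  signatures <- lapply(seq_len(n_cl_max), chlorine_signature)
  rows <- list()
  for (fi in seq_len(nrow(features))) {
    scores <- vapply(signatures, function(sig) {
      envelope_match_score(features$envelope[[fi]], sig,
                           intensity_tol = intensity_tol, mz_tol = mz_tol)
    }, numeric(1))
    best <- which.max(scores)
    if (scores[best] < score_threshold) next
    rows <- c(rows, list(data.frame(
      mz = features$mz[fi], rt_min = features$rt_min[fi],
      area = features$area[fi], sample_id = features$sample_id[fi],
      compartment = features$compartment[fi],
      replicate = features$replicate[fi],
      n_cl_estimate = as.integer(best), signature_score = scores[best],
      suspect = "unknown", stringsAsFactors = FALSE)))
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  if (!is.null(matches) && nrow(matches)) {
    for (i in seq_len(nrow(out))) {
      hit <- which(matches$sample_id == out$sample_id[i] &
                     abs(matches$measured_mz - out$mz[i]) < 1e-9 &
                     abs(matches$rt_min - out$rt_min[i]) < 1e-9)
      if (length(hit)) {
        out$suspect[i] <- paste(unique(matches$name[hit]), collapse = "|")
      }
    }
  }
  out <- out[order(out$mz, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
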