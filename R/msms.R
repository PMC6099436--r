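# Neutral-loss annotation, parent-link fragments and diagnostic ions for
# MS2 spectra.

#' Default neutral-loss library
#'
#' Small neutral molecules whose loss from the protonated precursor explains
#' the product ions of the antidepressants and their metabolites: water,
#' methylamine (the classic sertraline in-source loss), formaldehyde,
#' ammonia, hydrogen chloride, dimethylamine and carbon monoxide (the latter
#' two account for the iminodibenzyl-type fragments of clomipramine).
#'
#' @return data.frame with columns \code{name}, \code{formula}, \code{mass}
#'   (monoisotopic, Da).
#' @export
default_loss_library <- function() {
  formulas <- c(H2O = "H2O", CH3NH2 = "CH5N", CH2O = "CH2O", NH3 = "NH3",
                HCl = "HCl", "NH(CH3)2" = "C2H7N", CO = "CO")
  data.frame(
    name = names(formulas),
    formula = unname(formulas),
    mass = vapply(formulas, monoisotopic_mass, numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Default diagnostic product ions
#'
#' Empirical marker fragments (m/z at the ~0.1 Da precision product-ion
#' tables are printed at): immonium/acylium ions of conjugated phenylalanine
#' (165.1, 91.1) and tyrosine (181.1, 107.1), the chlorophenylpiperazine
#' fragment (154.0), the triazolopyridinone fragments of trazodone (176.1,
#' 148.1), the aminium chain ions of clomipramine and its demethyl form
#' (86.1, 72.1), and the dechlorinated backbone ions of sertraline and
#' hydroxy-sertraline (275.0, 273.0). These are treated as empirical masses,
#' not formulas.
#'
#' @return data.frame with columns \code{mz} and \code{meaning}.
#' @export
default_diagnostic_ions <- function() {
  data.frame(
    mz = c(165.1, 181.1, 91.1, 107.1, 154.0, 176.1, 148.1, 86.1, 72.1,
           275.0, 273.0),
    meaning = c("phenylalanine conjugate marker",
                "tyrosine conjugate marker",
                "benzylium (Phe-related)",
                "hydroxybenzylium (Tyr-related)",
                "chlorophenylpiperazine fragment",
                "triazolopyridinone fragment (trazodone family)",
                "dihydrotriazolopyridinone fragment (trazodone family)",
                "aminium chain ion C5H12N+ (clomipramine family)",
                "aminium chain ion C4H10N+ (demethyl-clomipramine)",
                "sertraline backbone ion",
                "hydroxy-sertraline backbone ion"),
    stringsAsFactors = FALSE
  )
}

#' Annotate fragments by neutral losses from the precursor
#'
#' Each fragment m/z is tested against every single loss and every ordered
#' pair of losses L from the library: it is annotated with L when
#' \code{|precursor_mz - mass(L) - fragment| <= tol}. At most two stacked
#' losses are considered (the deepest chain observed is methylamine plus
#' water). Fragments explained by no loss are returned with
#' \code{loss = NA}.
#'
#' @param spectrum list with \code{precursor_mz} (Da) and \code{fragments}
#'   (data.frame with \code{mz} and optionally \code{intensity}).
#' @param losses loss library data.frame (\code{name}, \code{mass});
#'   default \code{\link{default_loss_library}()}.
#' @param tol match tolerance in Da (default 0.1, matching product ions
#'   printed to one decimal).
#' @return data.frame with one row per (fragment, explanation):
#'   \code{fragment_mz}, \code{loss} (e.g. \code{"-H2O"} or
#'   \code{"-CH3NH2-H2O"}; \code{NA} if unexplained), \code{loss_mass},
#'   \code{delta_mda} (residual, mDa).
#' @export
annotate_losses <- function(spectrum, losses = default_loss_library(),
                            tol = 0.1) {
  stopifnot(tol > 0, !is.null(spectrum$precursor_mz))
  frags <- spectrum$fragments
  if (is.null(frags) || nrow(frags) == 0L) {
    return(data.frame(fragment_mz = numeric(0), loss = character(0),
                      loss_mass = numeric(0), delta_mda = numeric(0)))
  }
  combos <- if (nrow(losses)) {
    singles <- data.frame(label = paste0("-", losses$name), mass = losses$mass)
    ij <- which(upper.tri(matrix(0, nrow(losses), nrow(losses)), diag = TRUE),
                arr.ind = TRUE)
    pairs <- data.frame(
      label = paste0("-", losses$name[ij[, 1]], "-", losses$name[ij[, 2]]),
      mass = losses$mass[ij[, 1]] + losses$mass[ij[, 2]])
    rbind(singles, pairs)
  } else {
    data.frame(label = character(0), mass = numeric(0))
  }
  rows <- lapply(seq_len(nrow(frags)), function(i) {
    fmz <- frags$mz[i]
    resid <- spectrum$precursor_mz - combos$mass - fmz
    hit <- which(abs(resid) <= tol)
    if (!length(hit)) {
      return(data.frame(fragment_mz = fmz, loss = NA_character_,
                        loss_mass = NA_real_, delta_mda = NA_real_))
    }
    data.frame(fragment_mz = fmz, loss = combos$label[hit],
               loss_mass = combos$mass[hit],
               delta_mda = 1000 * resid[hit])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fragments two spectra have in common
#'
#' Symmetric comparison used to link a metabolite to its parent drug (e.g. a
#' conjugate retaining the parent's backbone ion).
#'
#' @param a,b spectra (lists with a \code{fragments} data.frame).
#' @param tol m/z tolerance in Da (default 0.1).
#' @return data.frame with columns \code{mz_a}, \code{mz_b} for every pair
#'   within tolerance.
#' @export
shared_fragments <- function(a, b, tol = 0.1) {
  stopifnot(tol > 0)
  fa <- a$fragments$mz
  fb <- b$fragments$mz
  if (!length(fa) || !length(fb)) {
    return(data.frame(mz_a = numeric(0), mz_b = numeric(0)))
  }
  d <- abs(outer(fa, fb, `-`))
  idx <- which(d <= tol, arr.ind = TRUE)
  out <- data.frame(mz_a = fa[idx[, 1]], mz_b = fb[idx[, 2]])
  out[order(out$mz_a, out$mz_b), , drop = FALSE]
}

#' Flag diagnostic ions in a spectrum
#'
#' @param spectrum a spectrum list (see \code{\link{annotate_losses}}).
#' @param diagnostics data.frame with \code{mz} and \code{meaning}; default
#'   \code{\link{default_diagnostic_ions}()}.
#' @param tol m/z tolerance in Da (default 0.1).
#' @return data.frame of hits: \code{fragment_mz}, \code{diagnostic_mz},
#'   \code{meaning}.
#' @export
flag_diagnostics <- function(spectrum, diagnostics = default_diagnostic_ions(),
                             tol = 0.1) {
  stopifnot(tol > 0)
  frags <- spectrum$fragments
  if (is.null(frags) || nrow(frags) == 0L || nrow(diagnostics) == 0L) {
    return(data.frame(fragment_mz = numeric(0), diagnostic_mz = numeric(0),
                      meaning = character(0)))
  }
  d <- abs(outer(frags$mz, diagnostics$mz, `-`))
  idx <- which(d <= tol, arr.ind = TRUE)
  out <- data.frame(fragment_mz = frags$mz[idx[, 1]],
                    diagnostic_mz = diagnostics$mz[idx[, 2]],
                    meaning = diagnostics$meaning[idx[, 2]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$fragment_mz, out$diagnostic_mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read MS2 spectra from an MGF file
#'
#' Minimal Mascot Generic Format reader covering BEGIN IONS/END IONS blocks
#' with PEPMASS, optional TITLE/RTINSECONDS headers and m/z-intensity pairs.
#'
#' @param path MGF file path.
#' @return a list of spectra; each is a list with \code{precursor_mz},
#'   \code{compound_label} (TITLE or \code{NA}), \code{rt_min} (from
#'   RTINSECONDS, or \code{NA}) and \code{fragments} (data.frame \code{mz},
#'   \code{intensity}).
#' @export
read_mgf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  starts <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(starts) != length(ends)) stop("malformed MGF: unbalanced blocks")
  lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    headers <- grep("=", block, fixed = TRUE, value = TRUE)
    get <- function(key) {
      hit <- grep(paste0("^", key, "="), headers, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
    }
    peaks <- block[!grepl("=", block, fixed = TRUE) & nzchar(trimws(block))]
    frag <- if (length(peaks)) {
      m <- do.call(rbind, lapply(strsplit(trimws(peaks), "[ \t]+"), as.numeric))
      data.frame(mz = m[, 1], intensity = if (ncol(m) > 1) m[, 2] else 1)
    } else {
      data.frame(mz = numeric(0), intensity = numeric(0))
    }
    rtsec <- suppressWarnings(as.numeric(get("RTINSECONDS")))
    list(precursor_mz = as.numeric(strsplit(get("PEPMASS"), "[ \t]+")[[1]][1]),
         compound_label = get("TITLE"),
         rt_min = if (is.na(rtsec)) NA_real_ else rtsec / 60,
         fragments = frag)
  })
}

#' Write MS2 spectra to an MGF file
#'
#' @param spectra list of spectra (see \code{\link{read_mgf}}).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  out <- unlist(lapply(spectra, function(sp) {
    c("BEGIN IONS",
      if (!is.null(sp$compound_label) && !is.na(sp$compound_label))
        paste0("TITLE=", sp$compound_label),
      paste0("PEPMASS=", format(sp$precursor_mz, digits = 10)),
      if (!is.null(sp$rt_min) && !is.na(sp$rt_min))
        paste0("RTINSECONDS=", format(sp$rt_min * 60, digits = 8)),
      if (nrow(sp$fragments))
        paste(format(sp$fragments$mz, digits = 8, trim = TRUE),
              format(sp$fragments$intensity, digits = 6, trim = TRUE)),
      "END IONS", "")
  }))
  writeLines(out, path)
  invisible(path)
}
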