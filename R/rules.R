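# Biotransformation rules and suspect-candidate enumeration.

#' Define a biotransformation rule
#'
#' A rule is either a \emph{delta} (a signed element-count change applied to
#' the precursor formula, e.g. +O for hydroxylation) or a \emph{product}
#' (a fixed product formula reached from a specific precursor, used for
#' cleavages that no element delta can express, e.g. trazodone to
#' meta-chlorophenylpiperazine).
#'
#' @param name unique rule label.
#' @param delta named numeric vector of signed element-count changes
#'   (delta rules only).
#' @param product product formula (product rules only).
#' @param precursor formula the product rule applies to; a product rule is
#'   only triggered when the current candidate has exactly this formula.
#' @param max_applications how many times the rule may occur in one
#'   transformation chain (default 1).
#' @param group optional group label; \code{\link{enumerate_candidates}} can
#'   cap the total number of applications across a group (used to allow at
#'   most one amino-acid conjugation per candidate).
#' @return a \code{transformation_rule} object.
#' @export
transformation_rule <- function(name, delta = NULL, product = NULL,
                                precursor = NULL, max_applications = 1L,
                                group = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(delta) == is.null(product)) {
    stop("exactly one of 'delta' or 'product' must be given")
  }
  if (!is.null(product) && is.null(precursor)) {
    stop("product rules require a 'precursor' formula")
  }
  structure(list(
    name = name,
    kind = if (is.null(delta)) "product" else "delta",
    delta = delta,
    product = if (!is.null(product)) as_formula(product),
    precursor = if (!is.null(precursor)) as_formula(precursor),
    max_applications = as.integer(max_applications),
    group = group
  ), class = "transformation_rule")
}

#' Built-in biotransformation rule set
#'
#' The phase-I/II transformations observed for the three antidepressants in
#' the hydroponic cress model: hydroxylation (+O), N-demethylation (net
#' \eqn{-CH_2}), amide conjugation with amino acids (+AA \eqn{- H_2O};
#' condensation), and the cleavage of trazodone to its active metabolite
#' meta-chlorophenylpiperazine (mCPP, C10H13ClN2). Hydroxylation and
#' demethylation may each occur up to twice per chain; conjugation is capped
#' at one per chain via the \code{"conjugation"} rule group.
#'
#' @param amino_acids named character vector of amino-acid formulas to
#'   conjugate; defaults to phenylalanine and tyrosine, the residues
#'   observed. Any of the proteinogenic set can be supplied.
#' @return a named list of \code{\link{transformation_rule}} objects.
#' @examples
#' names(builtin_rules())
#' @export
builtin_rules <- function(amino_acids = c(Phe = "C9H11NO2", Tyr = "C9H11NO3")) {
  rules <- list(
    transformation_rule("hydroxylation", delta = c(O = 1),
                        max_applications = 2L),
    transformation_rule("demethylation", delta = c(C = -1, H = -2),
                        max_applications = 2L)
  )
  water <- parse_formula("H2O")
  for (aa in names(amino_acids)) {
    aaf <- as_formula(amino_acids[[aa]])
    delta <- stats::setNames(numeric(length(aaf)), names(aaf))
    delta[names(aaf)] <- aaf
    delta["H"] <- delta["H"] - water[["H"]]
    delta["O"] <- delta["O"] - water[["O"]]
    rules <- c(rules, list(transformation_rule(
      paste0("conj_", aa), delta = delta[delta != 0],
      max_applications = 1L, group = "conjugation"
    )))
  }
  rules <- c(rules, list(transformation_rule(
    "cleavage_mCPP", product = "C10H13ClN2", precursor = "C19H22ClN5O",
    max_applications = 1L
  )))
  stats::setNames(rules, vapply(rules, `[[`, character(1), "name"))
}

#' Enumerate suspect candidates from a parent drug
#'
#' Breadth-first application of transformation rules to a parent drug
#' formula, up to \code{max_depth} combined applications. Candidates reached
#' by different rule orders but with identical formulas are collapsed into
#' one candidate; all distinct chains are retained as provenance. Rule
#' applications that would drive an element count negative are silently
#' skipped. Output ordering is deterministic: by theoretical m/z, then chain.
#'
#' @param parent_name label of the parent drug.
#' @param parent_formula its molecular formula (string or
#'   \code{chem_formula}).
#' @param rules a list of \code{\link{transformation_rule}}s, e.g.
#'   \code{\link{builtin_rules}()}.
#' @param max_depth maximum number of rule applications per chain
#'   (default 3, which reaches hydroxy-demethyl conjugates).
#' @param group_limits named integer vector capping total applications per
#'   rule group (default \code{c(conjugation = 1)}).
#' @return a candidate data.frame with columns \code{name}, \code{parent},
#'   \code{chain} (rule names joined by \code{"+"}; \code{""} for the parent
#'   itself), \code{formula} (Hill string), \code{mz} (theoretical [M+H]+),
#'   \code{depth} and \code{source} (\code{"enumerated"}). \code{alt_chains}
#'   lists other chains reaching the same formula, \code{";"}-separated.
#' @examples
#' cands <- enumerate_candidates("CLP", "C19H23ClN2", builtin_rules(), 2)
#' subset(cands, chain == "hydroxylation")$mz  # 331.1572
#' @export
enumerate_candidates <- function(parent_name, parent_formula, rules,
                                 max_depth = 3L,
                                 group_limits = c(conjugation = 1L)) {
  stopifnot(max_depth >= 0)
  parent_formula <- as_formula(parent_formula)
  rules <- unname(rules)
  # frontier: list of (formula, chain)
  frontier <- list(list(formula = parent_formula, chain = character(0)))
  seen <- stats::setNames(list(list(character(0))),
                          format_formula(parent_formula))
  depth <- 0L
  while (depth < max_depth && length(frontier)) {
    nxt <- list()
    for (node in frontier) {
      for (rule in rules) {
        chain <- c(node$chain, rule$name)
        if (sum(chain == rule$name) > rule$max_applications) next
        if (!is.na(rule$group) && length(group_limits) &&
            rule$group %in% names(group_limits)) {
          in_group <- vapply(rules, function(r)
            identical(r$group, rule$group), logical(1))
          gnames <- vapply(rules[in_group], `[[`, character(1), "name")
          if (sum(chain %in% gnames) > group_limits[[rule$group]]) next
        }
        newf <- if (rule$kind == "delta") {
          tryCatch(apply_delta(node$formula, rule$delta),
                   error = function(e) NULL)
        } else {
          if (identical(format_formula(node$formula),
                        format_formula(rule$precursor))) rule$product else NULL
        }
        if (is.null(newf)) next
        key <- format_formula(newf)
        chain_str <- paste(chain, collapse = "+")
        known <- !is.null(seen[[key]])
        dup_chain <- known && any(vapply(seen[[key]], function(ch)
          identical(paste(ch, collapse = "+"), chain_str), logical(1)))
        if (dup_chain) next
        seen[[key]] <- c(seen[[key]], list(chain))
        # only expand each distinct (formula, chain) once
        nxt <- c(nxt, list(list(formula = newf, chain = chain)))
      }
    }
    frontier <- nxt
    depth <- depth + 1L
  }
  .candidates_from_seen(parent_name, seen)
}

.candidates_from_seen <- function(parent_name, seen) {
  rows <- lapply(names(seen), function(key) {
    chains <- seen[[key]]
    chain_strs <- sort(vapply(chains, paste, character(1), collapse = "+"))
    # canonical chain: shortest, then lexicographic
    canon <- chain_strs[order(nchar(chain_strs), chain_strs)][1]
    nm <- if (canon == "") parent_name else paste0(parent_name, "+", canon)
    data.frame(
      name = nm, parent = parent_name, chain = canon, formula = key,
      mz = protonated_mz(key),
      depth = if (canon == "") 0L else length(strsplit(canon, "+", fixed = TRUE)[[1]]),
      source = "enumerated",
      alt_chains = paste(setdiff(chain_strs, canon), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mz, out$chain), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate candidates for several parent drugs
#'
#' @param parents named character vector: parent drug name -> formula string.
#' @inheritParams enumerate_candidates
#' @return row-bound candidate data.frame (see
#'   \code{\link{enumerate_candidates}}).
#' @export
enumerate_all_candidates <- function(parents, rules = builtin_rules(),
                                     max_depth = 3L,
                                     group_limits = c(conjugation = 1L)) {
  out <- do.call(rbind, lapply(names(parents), function(p) {
    enumerate_candidates(p, parents[[p]], rules, max_depth, group_limits)
  }))
  rownames(out) <- NULL
  out
}

#' The three administered antidepressants
#'
#' @return named character vector of parent-drug formulas: sertraline (STR),
#'   clomipramine (CLP), trazodone (TZN).
#' @export
parent_drugs <- function() {
  c(STR = "C17H17Cl2N", CLP = "C19H23ClN2", TZN = "C19H22ClN5O")
}

#' Load an explicit suspect list
#'
#' Reads a CSV with columns \code{name}, \code{formula} and optionally
#' \code{parent} and \code{expected_rt_min}, computing each suspect's
#' theoretical [M+H]+ m/z.
#'
#' @param path CSV file path.
#' @return candidate data.frame with \code{source = "suspect_list"} (and an
#'   \code{expected_rt_min} column when present in the file); zero rows for
#'   an empty file.
#' @export
load_suspect_list <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(data.frame(name = character(0), parent = character(0),
                      chain = character(0), formula = character(0),
                      mz = numeric(0), depth = integer(0),
                      source = character(0), alt_chains = character(0)))
  }
  if (!all(c("name", "formula") %in% names(df))) {
    stop("suspect list must have 'name' and 'formula' columns")
  }
  mz <- vapply(seq_len(nrow(df)), function(i) {
    tryCatch(protonated_mz(df$formula[i]), error = function(e) {
      stop("row ", i, " of ", path, ": ", conditionMessage(e), call. = FALSE)
    })
  }, numeric(1))
  out <- data.frame(
    name = df$name,
    parent = if ("parent" %in% names(df)) df$parent else NA_character_,
    chain = NA_character_,
    formula = vapply(df$formula, function(x) format_formula(x), character(1),
                     USE.NAMES = FALSE),
    mz = mz, depth = NA_integer_, source = "suspect_list",
    alt_chains = "", stringsAsFactors = FALSE
  )
  if ("expected_rt_min" %in% names(df)) out$expected_rt_min <- df$expected_rt_min
  out
}
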