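# Global summaries: mass-shift spectrum, modification fractions,
# per-amino-acid totals and distributions, single-AA bias score.

#' Mass-shift spectrum
#'
#' PSM counts per integer mass shift, summed over positions, timepoints
#' and replicates (optionally sliced by replicate and/or timepoint).
#'
#' @param pcm a `position_counts` object.
#' @param by grouping: `"none"`, `"replicate"`, `"timepoint"` or
#'   `"sample"` (timepoint x replicate).
#' @return `data.table(mass_shift, n_psm)` plus grouping columns, sorted
#'   by mass shift.
#' @export
mass_shift_spectrum <- function(pcm, by = c("none", "replicate",
                                            "timepoint", "sample")) {
  by <- match.arg(by)
  grp <- switch(by, none = character(), replicate = "replicate",
                timepoint = "timepoint_h",
                sample = c("timepoint_h", "replicate"))
  mod <- pcm$counts[!is.na(mass_shift)]
  if (nrow(mod) == 0L) {
    return(data.table(mass_shift = integer(), n_psm = integer()))
  }
  out <- mod[, .(n_psm = sum(count)), keyby = c("mass_shift", grp)]
  out[]
}

#' Fraction of PSMs, peptides, or proteins carrying a modification
#'
#' At PSM level, the fraction of PSMs with a mass shift; at peptide
#' level, the fraction of distinct peptide sequences with at least one
#' modified PSM; at protein level (which requires the mapped count
#' matrix), the fraction of observed proteins with at least one modified
#' position. The "observed" denominator at protein level is proteins
#' with at least one mapped PSM in the same (timepoint, replicate) cell.
#'
#' @param records FDR-filtered PSM table (psm and peptide levels).
#' @param level `"psm"`, `"peptide"` or `"protein"`.
#' @param pcm `position_counts` object, required for `level = "protein"`.
#' @param pooled if `TRUE` return one pooled fraction instead of
#'   per-sample fractions.
#' @return `data.table(timepoint_h, replicate, fraction)` or, when
#'   `pooled`, a single numeric value.
#' @export
global_mod_fraction <- function(records, level = c("psm", "peptide", "protein"),
                                pcm = NULL, pooled = FALSE) {
  level <- match.arg(level)
  if (level == "protein") {
    if (is.null(pcm)) stop("protein-level fractions require the count matrix")
    cnt <- pcm$counts
    if (pooled) {
      n_obs <- length(unique(cnt$protein))
      n_mod <- length(unique(cnt[!is.na(mass_shift), protein]))
      return(if (n_obs == 0L) 0 else n_mod / n_obs)
    }
    out <- cnt[, .(
      fraction = {
        n_obs <- length(unique(protein))
        n_mod <- length(unique(protein[!is.na(mass_shift)]))
        if (n_obs == 0L) 0 else n_mod / n_obs
      }), keyby = .(timepoint_h, replicate)]
    return(out[])
  }
  records <- as.data.table(records)
  if (level == "psm") {
    if (pooled) return(if (nrow(records) == 0L) 0 else mean(!is.na(records$mass_shift)))
    out <- records[, .(fraction = mean(!is.na(mass_shift))),
                   keyby = .(timepoint_h, replicate)]
    return(out[])
  }
  # peptide level
  pep_frac <- function(dt) {
    n_pep <- length(unique(dt$peptide))
    n_mod <- length(unique(dt[!is.na(mass_shift), peptide]))
    if (n_pep == 0L) 0 else n_mod / n_pep
  }
  if (pooled) return(pep_frac(records))
  out <- records[, .(fraction = pep_frac(.SD)),
                 keyby = .(timepoint_h, replicate),
                 .SDcols = c("peptide", "mass_shift")]
  out[]
}

#' Modified PSM counts per target amino acid
#'
#' Counts of modified PSMs grouped by the residue at the modified
#' position, with percentages over all modified PSMs.
#'
#' @param pcm a `position_counts` object.
#' @return `data.table(aa, n_psm, pct)` sorted by descending count.
#' @export
aa_totals <- function(pcm) {
  mod <- pcm$counts[!is.na(mass_shift)]
  if (nrow(mod) == 0L) {
    return(data.table(aa = character(), n_psm = integer(), pct = numeric()))
  }
  out <- mod[, .(n_psm = sum(count)), by = aa]
  out[, pct := 100 * n_psm / sum(n_psm)]
  setorder(out, -n_psm, aa)
  out[]
}

#' Amino-acid distribution of one mass shift
#'
#' Length-20 vector of either PSM counts (`unit = "psm"`) or unique
#' modified (protein, position) counts (`unit = "unique_position"`) per
#' residue type, for a given mass shift. The unique-position unit counts
#' each protein position at most once regardless of its PSM count, which
#' damps the influence of single high-abundance sites.
#'
#' @param pcm a `position_counts` object.
#' @param mass_shift integer mass shift in Da.
#' @param unit `"psm"` or `"unique_position"`.
#' @param replicate optional replicate to slice on.
#' @return named numeric vector over [AA_STANDARD] (all zero when the
#'   shift is absent).
#' @export
aa_distribution <- function(pcm, mass_shift, unit = c("psm", "unique_position"),
                            replicate = NULL) {
  unit <- match.arg(unit)
  s <- as.integer(mass_shift)
  mod <- pcm$counts[!is.na(mass_shift) & mass_shift == s]
  if (!is.null(replicate)) {
    r <- as.integer(replicate)
    mod <- mod[replicate == r]
  }
  vec <- setNames(numeric(length(AA_STANDARD)), AA_STANDARD)
  if (nrow(mod) == 0L) return(vec)
  tab <- if (unit == "psm") {
    mod[, .(n = sum(count)), by = aa]
  } else {
    unique(mod[, .(protein, pos, aa)])[, .(n = .N), by = aa]
  }
  vec[tab$aa] <- tab$n
  vec
}

#' Single-amino-acid bias score of a mass shift
#'
#' Quantifies how strongly a mass shift prefers one residue type:
#' `B = (U_m + 1) / (U_nm_bar + 1)` where `U_m` is the unique-position
#' count of the most-modified amino acid and `U_nm_bar` the mean count of
#' the other 19. Counting unique positions (each protein position at most
#' once per shift) reduces bias from high-abundance single sites. Ties
#' for the maximum resolve to the alphabetically first residue and are
#' flagged.
#'
#' @param U length-20 vector of unique modified position counts; if
#'   named, names must be the standard amino acids; if unnamed, the
#'   alphabetical order of [AA_STANDARD] is assumed.
#' @param mass_shift integer label carried through to the result.
#' @return an object of class `bias_score`: `mass_shift`, `U`, `U_m`,
#'   `U_nm_bar`, `score`, `top_aa`, `tie`.
#' @export
single_aa_bias <- function(U, mass_shift = NA_integer_) {
  stopifnot(length(U) == length(AA_STANDARD), all(U >= 0))
  if (is.null(names(U))) names(U) <- AA_STANDARD
  stopifnot(setequal(names(U), AA_STANDARD))
  U <- U[AA_STANDARD]
  m <- which.max(U)   # alphabetically first on ties
  U_m <- unname(U[m])
  U_nm_bar <- mean(U[-m])
  res <- list(
    mass_shift = as.integer(mass_shift),
    U = U,
    U_m = U_m,
    U_nm_bar = U_nm_bar,
    score = (U_m + 1) / (U_nm_bar + 1),
    top_aa = names(U)[m],
    tie = sum(U == U_m) > 1L
  )
  class(res) <- "bias_score"
  res
}

#' @export
print.bias_score <- function(x, ...) {
  cat(sprintf("bias score for %+d Da: B = %.3f (top %s%s)\n",
              x$mass_shift, x$score, x$top_aa,
              if (x$tie) ", tied" else ""))
  invisible(x)
}

#' Single-AA bias scores for all observed mass shifts
#'
#' @param pcm a `position_counts` object.
#' @param by_replicate compute per replicate (default) or pooled.
#' @return `data.table(mass_shift, replicate, top_aa, score, tie)` sorted
#'   by descending score.
#' @export
bias_scores <- function(pcm, by_replicate = TRUE) {
  mod <- pcm$counts[!is.na(mass_shift)]
  if (nrow(mod) == 0L) {
    return(data.table(mass_shift = integer(), replicate = integer(),
                      top_aa = character(), score = numeric(),
                      tie = logical()))
  }
  grp <- if (by_replicate) c("mass_shift", "replicate") else "mass_shift"
  upos <- unique(mod[, c(grp, "protein", "pos", "aa"), with = FALSE])
  tab <- upos[, .(n = .N), by = c(grp, "aa")]
  out <- tab[, {
    U <- setNames(numeric(length(AA_STANDARD)), AA_STANDARD)
    U[aa] <- n
    b <- single_aa_bias(U, mass_shift[1L])
    .(top_aa = b$top_aa, score = b$score, tie = b$tie)
  }, by = grp]
  if (!by_replicate) out[, replicate := NA_integer_]
  setcolorder(out, c("mass_shift", "replicate", "top_aa", "score", "tie"))
  setorder(out, -score, mass_shift)
  out[]
}
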