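# PSM data model: table ingestion, validation, cysteine mass-shift
# correction, and probability-ranked FDR thresholding.

#' The nine sampling timepoints of the growth curve, in hours
#'
#' Batch-culture sampling times from early exponential phase (3 h
#' post-inoculation) to deep stationary phase (336 h, two weeks). All
#' temporal analyses in the package are indexed on this axis.
#'
#' @export
TIMEPOINTS_H <- c(3L, 4L, 5L, 6L, 8L, 24L, 48L, 168L, 336L)

#' The 20 standard amino-acid one-letter codes, alphabetical
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Canonical PSM table column names
#' @export
PSM_COLUMNS <- c("peptide", "protein", "mass_shift", "mod_pos",
                 "probability", "timepoint_h", "replicate", "precursor_mz")

#' Construct a PSM table
#'
#' Builds a table of peptide-spectrum matches in the canonical column
#' layout. Each row is one PSM carrying at most one modification: an
#' integer mass shift (in daltons) localized to a 1-based position within
#' the peptide. `mass_shift` and `mod_pos` must be `NA` together
#' (unmodified) or set together.
#'
#' @param peptide uppercase peptide sequences (standard 20 amino acids).
#' @param probability the search engine's correct-match probability in
#'   \[0, 1\].
#' @param timepoint_h sampling timepoint; must be one of [TIMEPOINTS_H].
#' @param replicate biological replicate index in 1..3.
#' @param protein optional protein hint ("" if unknown).
#' @param mass_shift integer mass shift in Da, `NA` for unmodified PSMs.
#' @param mod_pos 1-based modified position within the peptide, `NA` for
#'   unmodified PSMs.
#' @param precursor_mz optional positive precursor m/z.
#' @return a `data.table` with columns [PSM_COLUMNS], attribute
#'   `cys_corrected = FALSE`.
#' @seealso [read_psm_table()], [validate_psm_rows()]
#' @export
psm_table <- function(peptide, probability, timepoint_h, replicate,
                      protein = "", mass_shift = NA_integer_,
                      mod_pos = NA_integer_, precursor_mz = NA_real_) {
  dt <- data.table(
    peptide = as.character(peptide),
    protein = as.character(protein),
    mass_shift = as.integer(mass_shift),
    mod_pos = as.integer(mod_pos),
    probability = as.numeric(probability),
    timepoint_h = as.integer(timepoint_h),
    replicate = as.integer(replicate),
    precursor_mz = as.numeric(precursor_mz)
  )
  chk <- validate_psm_rows(dt)
  if (nrow(chk$rejected) > 0L) {
    stop("invalid PSM rows: ",
         paste(unique(chk$rejected$reason), collapse = ", "))
  }
  setattr(dt, "cys_corrected", FALSE)
  dt[]
}

#' Validate PSM rows against the data-model invariants
#'
#' Checks every row of a candidate PSM table: peptide drawn from the 20
#' standard uppercase amino acids, probability in \[0, 1\], timepoint on
#' the nine-point axis, replicate in 1..3, `mass_shift`/`mod_pos` both
#' present or both absent, `mod_pos` within the peptide, and positive
#' precursor m/z when given.
#'
#' @param dt a data.table/data.frame with the canonical columns (missing
#'   optional columns are tolerated and filled with `NA`).
#' @return `list(records, rejected)` where `records` holds the valid
#'   rows (typed, canonical column order) and `rejected` is a
#'   `data.table(row, reason)` keyed by input row number.
#' @export
validate_psm_rows <- function(dt) {
  dt <- as.data.table(dt)
  for (col in setdiff(PSM_COLUMNS, names(dt))) {
    dt[, (col) := if (col == "protein") "" else NA]
  }
  n <- nrow(dt)
  pep <- as.character(dt$peptide)
  prob <- suppressWarnings(as.numeric(dt$probability))
  tp <- suppressWarnings(as.numeric(dt$timepoint_h))
  rep_ <- suppressWarnings(as.numeric(dt$replicate))
  ms <- suppressWarnings(as.numeric(dt$mass_shift))
  mp <- suppressWarnings(as.numeric(dt$mod_pos))
  mz <- suppressWarnings(as.numeric(dt$precursor_mz))
  ms_na <- is.na(ms) & (is.na(dt$mass_shift) | trimws(as.character(dt$mass_shift)) == "")
  mp_na <- is.na(mp) & (is.na(dt$mod_pos) | trimws(as.character(dt$mod_pos)) == "")

  reasons <- vector("list", n)
  add <- function(bad, why) {
    for (i in which(bad)) reasons[[i]] <<- c(reasons[[i]], why)
  }
  aa_re <- paste0("^[", paste(AA_STANDARD, collapse = ""), "]+$")
  add(is.na(pep) | !grepl(aa_re, pep), "bad_peptide")
  add(is.na(prob) | prob < 0 | prob > 1, "bad_probability")
  add(is.na(tp) | !(tp %in% TIMEPOINTS_H), "bad_timepoint")
  add(is.na(rep_) | !(rep_ %in% 1:3), "bad_replicate")
  # coercion failure (non-numeric text) as opposed to genuinely empty
  add(!ms_na & is.na(ms), "bad_mass_shift")
  add(!mp_na & is.na(mp), "bad_mod_pos")
  add(!is.na(ms) & ms != round(ms), "bad_mass_shift")
  add(xor(is.na(ms) | ms_na, is.na(mp) | mp_na), "mod_fields_inconsistent")
  add(!is.na(mp) & !is.na(pep) & (mp < 1 | mp > nchar(pep)), "mod_pos_out_of_range")
  add(!is.na(mz) & mz <= 0, "bad_precursor_mz")

  bad <- vapply(reasons, function(x) !is.null(x), logical(1))
  rejected <- data.table(
    row = which(bad),
    reason = vapply(reasons[bad], function(x) paste(unique(x), collapse = ";"),
                    character(1))
  )
  records <- data.table(
    peptide = pep, protein = as.character(dt$protein),
    mass_shift = as.integer(round(ms)), mod_pos = as.integer(round(mp)),
    probability = prob, timepoint_h = as.integer(round(tp)),
    replicate = as.integer(round(rep_)), precursor_mz = mz
  )[!bad]
  setattr(records, "cys_corrected", FALSE)
  list(records = records[], rejected = rejected[])
}

#' Read a PSM table from a tab-separated file
#'
#' Reads a TSV in the canonical dialect (UTF-8, '.' decimal, empty string
#' for missing values) emitted by open-modification search postprocessing,
#' optionally remapping column names, and validates every row. Rows
#' violating the PSM invariants are excluded and reported with their row
#' numbers; a missing required column is a configuration error and stops.
#'
#' @param path path to the TSV file (header row required).
#' @param schema optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(peptide = "Peptide")`.
#' @return `list(records, rejected)` as for [validate_psm_rows()].
#' @export
read_psm_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("PSM table not found: ", path)
  raw <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               na.strings = "", encoding = "UTF-8")
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src) > 0L) {
      stop("schema refers to absent column(s): ",
           paste(missing_src, collapse = ", "))
    }
    setnames(raw, unname(schema), names(schema))
  }
  required <- setdiff(PSM_COLUMNS, c("protein", "precursor_mz"))
  missing_col <- setdiff(required, names(raw))
  if (length(missing_col) > 0L) {
    stop("missing required column(s): ", paste(missing_col, collapse = ", "))
  }
  validate_psm_rows(raw)
}

#' Write a PSM table in the canonical TSV dialect
#'
#' @param records a PSM table.
#' @param path output path.
#' @export
write_psm_table <- function(records, path) {
  out <- as.data.table(records)[, .SD, .SDcols = PSM_COLUMNS]
  fwrite(out, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Re-add the fixed carbamidomethyl mass to cysteine modifications
#'
#' During the search, carbamidomethylation (+57 Da) of cysteine is treated
#' as a static modification, so any variable mass shift reported at a Cys
#' residue is relative to Cys+57. This correction adds 57 Da back to all
#' Cys-localized mass shifts so that they are comparable with shifts at
#' other residues. Corrected shifts may leave the searched window (e.g.
#' +152 becomes +209). The correction must be applied exactly once, at
#' ingestion: a `cys_corrected` attribute guards against re-application.
#'
#' @param records a PSM table (not yet corrected).
#' @return the corrected PSM table with `cys_corrected = TRUE`.
#' @export
apply_cys_offset <- function(records) {
  if (isTRUE(attr(records, "cys_corrected"))) {
    stop("cysteine offset has already been applied to this table")
  }
  out <- copy(as.data.table(records))
  idx <- !is.na(out$mod_pos) &
    stri_sub(out$peptide, out$mod_pos, out$mod_pos) == "C"
  if (any(idx)) out[idx, mass_shift := mass_shift + 57L]
  setattr(out, "cys_corrected", TRUE)
  out[]
}

#' Probability-ranked FDR thresholding of PSMs
#'
#' Ranks PSMs by their correct-match probability (descending, stable) and
#' retains the largest prefix whose running mean of (1 - P_i) does not
#' exceed `alpha`; that running mean is the estimated false discovery
#' rate of the retained set. The running mean is not monotone, so the
#' retained prefix is the *largest* admissible one, not the first
#' crossing. Modified and unmodified PSMs are ranked together in one
#' pooled list; `by_sample = TRUE` instead thresholds each
#' (timepoint, replicate) cell independently.
#'
#' @param records a PSM table, or a bare numeric vector of probabilities.
#' @param alpha target FDR in (0, 1).
#' @param by_sample logical; per-sample thresholding.
#' @return an object of class `fdr_result`: `alpha`, `k` (retained
#'   count), `achieved_fdr` (0 when `k` is 0), `retained` (records in
#'   rank order). With `by_sample = TRUE`, a named list of such objects.
#' @export
fdr_threshold <- function(records, alpha, by_sample = FALSE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (is.numeric(records)) {
    records <- data.table(peptide = NA_character_, protein = "",
                          mass_shift = NA_integer_, mod_pos = NA_integer_,
                          probability = as.numeric(records),
                          timepoint_h = NA_integer_, replicate = NA_integer_,
                          precursor_mz = NA_real_)
  }
  records <- as.data.table(records)
  if (nrow(records) == 0L) stop("empty PSM collection")
  if (isTRUE(by_sample)) {
    keys <- unique(records[, .(timepoint_h, replicate)])
    out <- lapply(seq_len(nrow(keys)), function(i) {
      sub <- records[timepoint_h == keys$timepoint_h[i] &
                       replicate == keys$replicate[i]]
      fdr_threshold(sub, alpha)
    })
    names(out) <- sprintf("t%d_r%d", keys$timepoint_h, keys$replicate)
    return(out)
  }
  ord <- order(-records$probability)   # stable: ties keep input order
  errs <- 1 - records$probability[ord]
  run_mean <- cumsum(errs) / seq_along(errs)
  admissible <- which(run_mean <= alpha)
  k <- if (length(admissible) > 0L) max(admissible) else 0L
  res <- list(
    alpha = alpha,
    k = k,
    achieved_fdr = if (k > 0L) run_mean[k] else 0,
    retained = records[ord[seq_len(k)]]
  )
  setattr(res$retained, "cys_corrected", attr(records, "cys_corrected"))
  class(res) <- "fdr_result"
  res
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("FDR threshold alpha = %g: retained k = %d PSMs, achieved FDR = %.4g\n",
              x$alpha, x$k, x$achieved_fdr))
  invisible(x)
}

#' Sum of estimated per-PSM error probabilities
#'
#' Returns the sum of (1 - P_i) over a PSM collection; dividing by the
#' number of PSMs gives the collection's estimated error rate (the "FDR"
#' column of the summary accounting).
#'
#' @param records a PSM table or numeric vector of probabilities.
#' @return a single number (0 for an empty collection).
#' @export
error_sum <- function(records) {
  p <- if (is.numeric(records)) records else as.data.table(records)$probability
  if (length(p) == 0L) return(0)
  sum(1 - p)
}
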