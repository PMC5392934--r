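# Fixed-width sequence windows around top-ranked modified positions,
# for external sequence-logo rendering.

#' Extract sequence windows around top-ranked modified positions
#'
#' Ranks the unique modified positions of a mass shift by their summed
#' PSM counts (ties broken by protein id, then ascending position) and
#' extracts a window of `w` residues either side of each of the top `k`
#' positions. Windows truncated by a protein terminus are padded with
#' `'X'` so every window has length `2w + 1` with the modified residue at
#' the center. The position set can be partitioned on the center residue
#' (`center_aa`), e.g. asparagine-centered +1 Da windows versus all other
#' +1 Da windows (`invert = TRUE`).
#'
#' @param pcm a `position_counts` object.
#' @param prot the matching [proteome()].
#' @param mass_shift integer mass shift in Da.
#' @param center_aa optional residue type; restrict to positions of this
#'   type (or, with `invert`, its complement).
#' @param invert take the complement of `center_aa`.
#' @param k number of top positions to keep (default 50).
#' @param w half-width of the window (default 5).
#' @return an object of class `window_set`: `windows`
#'   (`data.table(protein, pos, aa, n_psm, window)`, rank order),
#'   `mass_shift`, `center_aa`, `invert`, `w`, `k_requested`, `short`
#'   (`TRUE` when fewer than `k` positions exist).
#' @export
extract_windows <- function(pcm, prot, mass_shift, center_aa = NULL,
                            invert = FALSE, k = 50L, w = 5L) {
  s <- as.integer(mass_shift)
  tab <- pcm$counts[!is.na(mass_shift) & mass_shift == s,
                    .(n_psm = sum(count)), by = .(protein, pos, aa)]
  if (!is.null(center_aa)) {
    tab <- if (invert) tab[aa != center_aa] else tab[aa == center_aa]
  }
  missing_prot <- setdiff(unique(tab$protein), names(prot$seqs))
  if (length(missing_prot) > 0L) {
    stop("proteome does not cover protein(s): ",
         paste(missing_prot, collapse = ", "))
  }
  setorder(tab, -n_psm, protein, pos)
  short <- nrow(tab) < k
  tab <- head(tab, k)
  if (nrow(tab) > 0L) {
    len <- prot$lengths[tab$protein]
    from <- tab$pos - w
    to <- tab$pos + w
    core <- stri_sub(prot$seqs[tab$protein], pmax(1L, from), pmin(len, to))
    tab[, window := paste0(strrep("X", pmax(0L, 1L - from)), core,
                           strrep("X", pmax(0L, to - len)))]
  } else {
    tab[, window := character()]
  }
  structure(list(windows = tab[], mass_shift = s, center_aa = center_aa,
                 invert = invert, w = as.integer(w),
                 k_requested = as.integer(k), short = short),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  part <- if (is.null(x$center_aa)) "any center" else {
    paste0(if (x$invert) "center != " else "center = ", x$center_aa)
  }
  cat(sprintf("window_set: %d windows of width %d for %+d Da (%s)%s\n",
              nrow(x$windows), 2L * x$w + 1L, x$mass_shift, part,
              if (x$short) " [fewer than requested]" else ""))
  invisible(x)
}

#' Write a window set as plain text or FASTA for logo tools
#'
#' @param ws a [extract_windows()] result.
#' @param path output path.
#' @param format `"text"` (one window per line) or `"fasta"`.
#' @export
write_windows <- function(ws, path, format = c("text", "fasta")) {
  format <- match.arg(format)
  wdt <- ws$windows
  lines <- if (format == "text") {
    wdt$window
  } else {
    as.vector(rbind(sprintf(">%s_%d", wdt$protein, wdt$pos), wdt$window))
  }
  writeLines(lines, path)
  invisible(path)
}
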