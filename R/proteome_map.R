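# Mapping peptides and modification calls into protein coordinates and
# accumulating per-position modified/unmodified count vectors.

#' Construct a proteome object
#'
#' @param seqs named character vector of uppercase amino-acid sequences;
#'   names are protein ids and must be unique, sequences nonempty.
#' @param source provenance label (e.g. a FASTA path).
#' @return an object of class `proteome` with elements `seqs`, `lengths`
#'   and `source`.
#' @export
proteome <- function(seqs, source = NA_character_) {
  stopifnot(is.character(seqs), length(seqs) > 0L)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) ||
      any(names(seqs) == "")) {
    stop("protein ids must be present and unique")
  }
  if (any(nchar(seqs) == 0L)) stop("empty protein sequence")
  structure(list(seqs = seqs, lengths = setNames(nchar(seqs), names(seqs)),
                 source = source),
            class = "proteome")
}

#' Read a reference proteome from FASTA
#'
#' Protein ids are the first whitespace-delimited token of each header.
#'
#' @param path FASTA file path.
#' @return a [proteome()] object.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  proteome(setNames(as.character(aa), ids), source = path)
}

#' Write a proteome to FASTA
#' @param prot a [proteome()] object.
#' @param path output FASTA path.
#' @export
write_proteome <- function(prot, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(prot$seqs), path)
  invisible(path)
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("proteome: %d proteins, %d residues (source: %s)\n",
              length(x$seqs), sum(x$lengths), x$source))
  invisible(x)
}

#' Locate a peptide in a proteome by exact substring match
#'
#' @param peptide an amino-acid string (length >= 1).
#' @param prot a [proteome()] object.
#' @return `data.table(protein, start)` of all occurrences (1-based,
#'   inclusive); zero rows when the peptide is absent.
#' @export
locate_peptide <- function(peptide, prot) {
  stopifnot(nchar(peptide) >= 1L)
  locate_peptides(peptide, prot)[, .(protein, start)]
}

# Batch peptide location. Concatenates the proteome with a separator that
# cannot occur in a peptide, locates every pattern with one stringi pass,
# and maps global offsets back to (protein, start).
locate_peptides <- function(peptides, prot) {
  peptides <- unique(peptides)
  ids <- names(prot$seqs)
  lens <- unname(prot$lengths)
  concat <- paste(prot$seqs, collapse = "*")
  starts_global <- cumsum(c(1L, head(lens + 1L, -1L)))
  hits <- stri_locate_all_fixed(concat, peptides, overlap = TRUE)
  out <- lapply(seq_along(peptides), function(i) {
    g <- hits[[i]][, 1L]
    if (length(g) == 0L || is.na(g[1L])) return(NULL)
    idx <- findInterval(g, starts_global)
    data.table(peptide = peptides[i], protein = ids[idx],
               start = g - starts_global[idx] + 1L)
  })
  res <- rbindlist(out)
  if (nrow(res) == 0L) {
    res <- data.table(peptide = character(), protein = character(),
                      start = integer())
  }
  res
}

#' Accumulate per-position modified and unmodified counts
#'
#' Maps each FDR-filtered, Cys-corrected PSM into protein coordinates and
#' accumulates counts by (protein, position, mass shift, timepoint,
#' replicate). A PSM of peptide length L with one modification contributes
#' one modified count at the modified protein position and L-1 unmodified
#' counts at the other covered positions; an unmodified PSM contributes L
#' unmodified counts. A residue carrying a modification of some other
#' shift therefore still contributes unmodified evidence at every position
#' it covers except the modified one.
#'
#' Peptides that do not occur in the proteome are skipped and logged.
#' Peptides matching more than one site are excluded by default
#' (`ambiguous = "drop"`) to avoid double counting in enrichment
#' denominators, or counted at every site with `ambiguous = "keep"`.
#'
#' @param records FDR-filtered, Cys-corrected PSM table.
#' @param prot a [proteome()] object.
#' @param ambiguous policy for multi-site peptides: `"drop"` or `"keep"`.
#' @return an object of class `position_counts`: `counts` (long
#'   `data.table`: protein, pos, aa, terminal, mass_shift (`NA` =
#'   unmodified), timepoint_h, replicate, count), `lengths`,
#'   `peptide_starts` (observed unique peptide start sites), `skipped`
#'   (peptide, reason), `annotated` flag.
#' @export
accumulate_counts <- function(records, prot, ambiguous = c("drop", "keep")) {
  ambiguous <- match.arg(ambiguous)
  records <- as.data.table(records)
  grp <- records[, .(count = .N),
                 by = .(peptide, mass_shift, mod_pos, timepoint_h, replicate)]
  loc <- locate_peptides(unique(grp$peptide), prot)
  n_hits <- loc[, .(n_hits = .N), by = peptide]
  found <- merge(data.table(peptide = unique(grp$peptide)), n_hits,
                 by = "peptide", all.x = TRUE)
  skipped <- found[is.na(n_hits), .(peptide, reason = "unmapped")]
  if (ambiguous == "drop") {
    skipped <- rbind(skipped,
                     found[!is.na(n_hits) & n_hits > 1L,
                           .(peptide, reason = "ambiguous")])
    loc <- loc[!(peptide %in% skipped$peptide)]
  }
  mapped <- merge(grp, loc, by = "peptide", allow.cartesian = TRUE)
  empty_counts <- data.table(
    protein = character(), pos = integer(), aa = character(),
    terminal = character(), mass_shift = integer(), timepoint_h = integer(),
    replicate = integer(), count = integer())
  if (nrow(mapped) == 0L) {
    res <- list(counts = empty_counts, lengths = prot$lengths,
                peptide_starts = data.table(protein = character(),
                                            start = integer()),
                skipped = skipped[], annotated = FALSE)
    class(res) <- "position_counts"
    return(res)
  }
  mapped[, L := nchar(peptide)]
  exp_dt <- mapped[rep(seq_len(.N), L)]
  exp_dt[, off := sequence(mapped$L)]
  exp_dt[, pos := start + off - 1L]
  exp_dt[, is_mod := !is.na(mod_pos) & off == mod_pos]
  exp_dt[, shift_at := fifelse(is_mod, mass_shift, NA_integer_)]
  counts <- exp_dt[, .(count = sum(count)),
                   by = .(protein, pos, mass_shift = shift_at,
                          timepoint_h, replicate)]
  counts[, aa := stri_sub(prot$seqs[protein], pos, pos)]
  counts[, terminal := NA_character_]
  setcolorder(counts, c("protein", "pos", "aa", "terminal", "mass_shift",
                        "timepoint_h", "replicate", "count"))
  setorder(counts, protein, pos, mass_shift, timepoint_h, replicate,
           na.last = TRUE)
  res <- list(
    counts = counts[],
    lengths = prot$lengths,
    peptide_starts = unique(mapped[, .(protein, start)]),
    skipped = skipped[],
    annotated = FALSE
  )
  class(res) <- "position_counts"
  res
}

#' @export
print.position_counts <- function(x, ...) {
  nm <- x$counts[!is.na(mass_shift), sum(count)]
  nu <- x$counts[is.na(mass_shift), sum(count)]
  cat(sprintf(paste0("position_counts: %d keyed rows over %d proteins; ",
                     "%d modified + %d unmodified observations%s\n"),
              nrow(x$counts), length(unique(x$counts$protein)), nm, nu,
              if (isTRUE(x$annotated)) " (termini annotated)" else ""))
  invisible(x)
}

#' Annotate terminal status of counted positions
#'
#' Flags position 1 of every protein as N-terminal and the last position
#' as C-terminal. With `met_cleavage_aware = TRUE`, proteins whose
#' annotated sequence starts with methionine additionally have position 2
#' flagged N-terminal when at least one observed peptide starts there:
#' this recovers N-terminal status for mature N termini exposed by
#' un-annotated initiator-Met cleavage. The annotated sequence itself is
#' never edited; N-terminal status is widened instead.
#'
#' @param pcm a [accumulate_counts()] result.
#' @param prot the matching [proteome()].
#' @param met_cleavage_aware widen Nt to position 2 behind a cleaved
#'   initiator Met (default `TRUE`).
#' @return the `position_counts` object with the `terminal` column filled
#'   with `"Nt"`, `"Ct"` or `"internal"`.
#' @export
annotate_termini <- function(pcm, prot, met_cleavage_aware = TRUE) {
  stopifnot(inherits(pcm, "position_counts"))
  counts <- pcm$counts
  if (nrow(counts) > 0L) {
    lens <- prot$lengths
    starts2 <- pcm$peptide_starts[start == 2L, unique(protein)]
    met_first <- names(prot$seqs)[stri_sub(prot$seqs, 1L, 1L) == "M"]
    widened <- if (met_cleavage_aware) intersect(starts2, met_first) else character()
    flag <- rep("internal", nrow(counts))
    flag[counts$pos == lens[counts$protein]] <- "Ct"
    flag[counts$pos == 1L] <- "Nt"
    flag[counts$pos == 2L & counts$protein %in% widened] <- "Nt"
    counts[, terminal := flag]
  }
  pcm$annotated <- TRUE
  pcm$met_cleavage_aware <- met_cleavage_aware
  pcm
}

#' Serialize a position count matrix as long-format TSV
#'
#' Unmodified counts are written with `mass_shift = "unmod"`.
#'
#' @param pcm a `position_counts` object.
#' @param path output path.
#' @export
write_position_counts <- function(pcm, path) {
  out <- copy(pcm$counts)
  out[, mass_shift := fifelse(is.na(mass_shift), "unmod",
                              as.character(mass_shift))]
  fwrite(out, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}
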