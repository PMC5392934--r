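library(data.table)

# Independent full-enumeration oracle for the two-sided Fisher test:
# linear-space hypergeometric point probabilities via choose(), summing
# those no larger than the observed one (1e-7 relative slack).
oracle_fet_p <- function(a, b, cc, d) {
  m <- a + b
  n <- cc + d
  k <- a + cc
  lo <- max(0, k - n)
  hi <- min(k, m)
  xs <- lo:hi
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(probs[probs <= probs[a - lo + 1] * (1 + 1e-7)])
}

# Hand-built position count matrix (bypasses peptide mapping) for unit
# tests of the downstream statistics.
manual_pcm <- function(counts, lengths, peptide_starts = NULL,
                       annotated = TRUE) {
  counts <- as.data.table(counts)
  for (col in c("aa", "terminal")) {
    if (!(col %in% names(counts))) counts[, (col) := NA_character_]
  }
  setcolorder(counts, c("protein", "pos", "aa", "terminal", "mass_shift",
                        "timepoint_h", "replicate", "count"))
  if (is.null(peptide_starts)) {
    peptide_starts <- data.table(protein = character(), start = integer())
  }
  structure(list(counts = counts, lengths = lengths,
                 peptide_starts = peptide_starts,
                 skipped = data.table(peptide = character(),
                                      reason = character()),
                 annotated = annotated),
            class = "position_counts")
}

# Simulate, FDR-filter, map and annotate in one step.
sim_to_pcm <- function(cfg, alpha = 0.01) {
  ds <- simulate_dataset(cfg)
  fdr <- fdr_threshold(apply_cys_offset(ds$psms), alpha)
  pcm <- annotate_termini(accumulate_counts(fdr$retained, ds$proteome),
                          ds$proteome)
  list(ds = ds, fdr = fdr, pcm = pcm)
}

# Minimal well-formed PSM TSV written to a temp file.
write_psm_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste(PSM_COLUMNS, collapse = "\t")
  writeLines(c(header, rows), path)
  path
}
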