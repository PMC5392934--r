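test_that("peptide location finds all exact occurrences", {
  prot <- proteome(c(P1 = "MPEPKR", P2 = "MAAAPEPKAAA"))
  hit <- locate_peptide("PEPK", proteome(c(P1 = "MPEPKR")))
  expect_equal(hit$protein, "P1")
  expect_equal(hit$start, 2L)

  expect_equal(nrow(locate_peptide("WWWW", prot)), 0L)

  # shared domain present in two proteins
  hits <- locate_peptide("PEPK", prot)
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$protein, c("P1", "P2"))
})

test_that("count accumulation books one modified and L-1 unmodified positions", {
  seq1 <- paste(rep("A", 10), collapse = "")
  seq2 <- "GGGGGGGG"
  prot <- proteome(c(P1 = paste0("M", seq1, seq2, "RR")))  # length 21
  pep <- substr(paste0("M", seq1, seq2, "RR"), 11, 18)     # start 11, len 8
  recs <- psm_table(peptide = pep, probability = 1, timepoint_h = 3L,
                    replicate = 1L, mass_shift = 16L, mod_pos = 3L)
  pcm <- accumulate_counts(recs, prot)
  mod <- pcm$counts[!is.na(mass_shift)]
  expect_equal(nrow(mod), 1L)
  expect_equal(mod$pos, 13L)
  expect_equal(mod$count, 1L)
  unmod <- pcm$counts[is.na(mass_shift)]
  expect_equal(sum(unmod$count), 7L)
  expect_setequal(unmod$pos, setdiff(11:18, 13L))

  # an unmodified PSM contributes unmodified evidence across its span
  recs2 <- psm_table(peptide = pep, probability = 1, timepoint_h = 3L,
                     replicate = 1L)
  pcm2 <- accumulate_counts(recs2, prot)
  expect_equal(pcm2$counts[, sum(count)], 8L)
  expect_true(all(is.na(pcm2$counts$mass_shift)))
})

test_that("overlapping peptides accumulate jointly at shared positions", {
  prot <- proteome(c(P1 = "MAAAKWWWKDDD"))
  # W at positions 6..8; peptides AAAKWWWK (2..9) and WWWKDDD (6..12)
  recs <- psm_table(
    peptide = c("AAAKWWWK", "WWWKDDD"),
    probability = 1, timepoint_h = 3L, replicate = 1L,
    mass_shift = c(16L, NA), mod_pos = c(5L, NA)
  )
  pcm <- accumulate_counts(recs, prot)
  at6 <- pcm$counts[pos == 6L]
  expect_equal(at6[!is.na(mass_shift), sum(count)], 1L)
  expect_equal(at6[is.na(mass_shift), sum(count)], 1L)
})

test_that("unmapped and ambiguous peptides are logged per policy", {
  prot <- proteome(c(P1 = "MAAAKGGG", P2 = "MTTTAAAK"))
  recs <- psm_table(peptide = c("AAAK", "WWWW", "GGG"),
                    probability = 1, timepoint_h = 3L, replicate = 1L)
  pcm <- accumulate_counts(recs, prot, ambiguous = "drop")
  expect_setequal(pcm$skipped$reason, c("unmapped", "ambiguous"))
  expect_equal(sort(pcm$skipped$peptide), c("AAAK", "WWWW"))
  expect_equal(unique(pcm$counts$protein), "P1")

  pcm_keep <- accumulate_counts(recs, prot, ambiguous = "keep")
  expect_false("AAAK" %in% pcm_keep$skipped$peptide)
  expect_setequal(unique(pcm_keep$counts$protein), c("P1", "P2"))
})

test_that("accumulation conserves counts and is order-invariant", {
  res <- sim_to_pcm(sim_config(n_proteins = 10, depth = 200, seed = 5))
  pcm <- res$pcm
  mapped_pep <- setdiff(unique(res$fdr$retained$peptide), pcm$skipped$peptide)
  mapped <- res$fdr$retained[peptide %in% mapped_pep]
  # total booked observations equal total mapped residues
  expect_equal(pcm$counts[, sum(count)], sum(nchar(mapped$peptide)))
  # total modified counts equal the number of mapped modified PSMs
  expect_equal(pcm$counts[!is.na(mass_shift), sum(count)],
               mapped[!is.na(mass_shift), .N])
  # rebuilding from a shuffled record order yields an identical matrix
  set.seed(1)
  shuffled <- res$fdr$retained[sample(.N)]
  pcm2 <- accumulate_counts(shuffled, res$ds$proteome)
  expect_identical(pcm$counts[, !"terminal"], pcm2$counts[, !"terminal"])
})

test_that("terminal annotation widens Nt behind a cleaved initiator Met", {
  seqs <- c(
    PM = "MSDKLNGTRWQEYHAK",   # starts M, penultimate S
    PS = "STYWDEFGHKLMNPQV"    # starts S
  )
  prot <- proteome(seqs)
  # a peptide starting at position 2 of PM (observed Met cleavage)
  recs <- psm_table(
    peptide = c(substr(seqs["PM"], 2, 9), substr(seqs["PM"], 1, 9),
                substr(seqs["PS"], 1, 8)),
    probability = 1, timepoint_h = 3L, replicate = 1L
  )
  pcm <- annotate_termini(accumulate_counts(recs, prot), prot)
  flags <- unique(pcm$counts[, .(protein, pos, terminal)])
  expect_equal(flags[protein == "PM" & pos == 1L, terminal], "Nt")
  expect_equal(flags[protein == "PM" & pos == 2L, terminal], "Nt")
  expect_equal(flags[protein == "PM" & pos == 3L, terminal], "internal")
  # a non-Met start never widens
  expect_equal(flags[protein == "PS" & pos == 1L, terminal], "Nt")
  expect_equal(flags[protein == "PS" & pos == 2L, terminal], "internal")

  # without an observed start-2 peptide, position 2 stays internal
  recs2 <- psm_table(peptide = substr(seqs["PM"], 1, 9),
                     probability = 1, timepoint_h = 3L, replicate = 1L)
  pcm2 <- annotate_termini(accumulate_counts(recs2, prot), prot)
  expect_equal(unique(pcm2$counts[protein == "PM" & pos == 2L, terminal]),
               "internal")

  # met_cleavage_aware = FALSE disables widening entirely
  pcm3 <- annotate_termini(accumulate_counts(recs, prot), prot,
                           met_cleavage_aware = FALSE)
  expect_equal(unique(pcm3$counts[protein == "PM" & pos == 2L, terminal]),
               "internal")

  # last covered position of a protein flags Ct
  recs4 <- psm_table(peptide = substr(seqs["PS"], 9, 16),
                     probability = 1, timepoint_h = 3L, replicate = 1L)
  pcm4 <- annotate_termini(accumulate_counts(recs4, prot), prot)
  expect_equal(unique(pcm4$counts[pos == 16L, terminal]), "Ct")
})
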