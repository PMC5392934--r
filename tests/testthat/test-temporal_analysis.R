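test_that("phase pooling validates its timepoint sets", {
  pp <- phase_pooling()
  expect_equal(pp$exp_timepoints, c(3L, 4L, 5L, 6L))
  expect_equal(pp$sta_timepoints, c(24L, 48L, 168L, 336L))
  expect_equal(pp$excluded, 8L)
  expect_error(phase_pooling(c(3, 24), c(24, 48)), "disjoint")
  expect_error(phase_pooling(c(3, 7), c(24, 48)), "axis")
})

test_that("fractional trajectories report fractions with missing encoded as NA", {
  mk <- function(tp, shift, n, r = 1L) {
    data.table(protein = "P1", pos = 4L, aa = "N", terminal = "internal",
               mass_shift = shift, timepoint_h = tp, replicate = r, count = n)
  }
  cnt <- rbind(mk(3L, NA, 10L), mk(24L, 1L, 3L), mk(24L, NA, 7L),
               mk(336L, 1L, 5L))
  pcm <- manual_pcm(cnt, lengths = c(P1 = 10L))
  tr <- fractional_trajectory(pcm, 1L, protein = "P1", pos = 4L,
                              replicates = 1L)
  expect_equal(nrow(tr), 9L)
  expect_equal(tr[timepoint_h == 3L, fraction], 0)
  expect_equal(tr[timepoint_h == 24L, fraction], 0.3)
  expect_equal(tr[timepoint_h == 336L, fraction], 1)
  # unobserved timepoints are NA, never 0
  expect_true(is.na(tr[timepoint_h == 48L, fraction]))
  expect_equal(tr[timepoint_h == 48L, n_mod + n_unmod], 0)

  # filter contract: a never-modified key is an error
  expect_error(fractional_trajectory(pcm, 99L, protein = "P1", pos = 4L),
               "no modification")

  # replicate_mean of identical replicates equals any single replicate
  cnt3 <- rbind(cnt, copy(cnt)[, replicate := 2L],
                copy(cnt)[, replicate := 3L])
  pcm3 <- manual_pcm(cnt3, lengths = c(P1 = 10L))
  tr_mean <- fractional_trajectory(pcm3, 1L, protein = "P1", pos = 4L,
                                   scope = "replicate_mean")
  expect_equal(tr_mean$fraction, tr$fraction)
  expect_equal(tr_mean$n_mod, as.numeric(tr$n_mod))
})

test_that("pooled trajectory phase sums agree with the phase contingency table", {
  res <- sim_to_pcm(sim_config(n_proteins = 15, depth = 600, seed = 23))
  pcm <- res$pcm
  pp <- phase_pooling()
  tab <- phase_contingency(pcm, 16L, "M", 1L, pp)
  expect_false(is.null(tab))   # Met oxidation is planted at this depth
  tr <- fractional_trajectory(pcm, 16L, aa = "M", replicates = 1L)
  expect_equal(tr[timepoint_h %in% pp$sta_timepoints, sum(n_mod)],
               unname(tab["a"]))
  expect_equal(tr[timepoint_h %in% pp$sta_timepoints, sum(n_unmod)],
               unname(tab["b"]))
  expect_equal(tr[timepoint_h %in% pp$exp_timepoints, sum(n_mod)],
               unname(tab["c"]))
  expect_equal(tr[timepoint_h %in% pp$exp_timepoints, sum(n_unmod)],
               unname(tab["d"]))
})

test_that("normalized position density maps termini to 0 and 1", {
  cnt <- data.table(
    protein = c("P1", "P1", "P1", "P2"), pos = c(1L, 6L, 11L, 1L),
    aa = "A", terminal = c("Nt", "internal", "Ct", "Nt"),
    mass_shift = 42L, timepoint_h = 3L, replicate = 1L, count = 1L)
  pcm <- manual_pcm(cnt, lengths = c(P1 = 11L, P2 = 1L))
  d <- position_density(pcm, 42L)
  expect_setequal(d, c(0, 0.5, 1, 0))   # length-1 protein contributes 0
  expect_equal(length(position_density(pcm, 99L)), 0L)

  # always within [0, 1] on simulated data
  res <- sim_to_pcm(sim_config(n_proteins = 10, depth = 300, seed = 31))
  for (s in unique(res$pcm$counts[!is.na(mass_shift), mass_shift])) {
    dd <- position_density(res$pcm, s)
    expect_true(all(dd >= 0 & dd <= 1))
  }
})

test_that("retention curves separate modification increase from retention", {
  # scenario i: acetylation rate doubles at stationary onset, no
  # differential degradation -> modified counts rise, unmodified flat
  reg_i <- list(mod_regime("ntac", 42L, "Nt", site_fraction = 1,
                           profile = "step", rate_exp = 0.1, rate_sta = 0.2))
  cfg_i <- sim_config(n_proteins = 25, depth = 1200, regimes = reg_i,
                      nt_met_cleavage_prob = 0.5,
                      isotope_artifact_rate = 0, seed = 2)
  res_i <- sim_to_pcm(cfg_i)
  cur_i <- retention_curves(res_i$pcm, res_i$ds$proteome)
  cls_i <- classify_retention(cur_i)
  expect_equal(cls_i[group == "all", scenario], "modification_increase")
  expect_gt(cls_i[group == "all", ratio_mod], 1.5)
  expect_lt(abs(log(cls_i[group == "all", ratio_unmod])), log(1.5))

  # scenario ii: constant rate but unmodified copies degraded 5x faster
  # in stationary phase -> unmodified counts fall, modified stay flat
  reg_ii <- list(mod_regime("ntac", 42L, "Nt", site_fraction = 1,
                            profile = "constant", rate = 0.2,
                            degradation_bias = 5))
  cfg_ii <- sim_config(n_proteins = 25, depth = 1200, regimes = reg_ii,
                       nt_met_cleavage_prob = 0.5,
                       isotope_artifact_rate = 0, seed = 2)
  res_ii <- sim_to_pcm(cfg_ii)
  cls_ii <- classify_retention(retention_curves(res_ii$pcm, res_ii$ds$proteome))
  expect_equal(cls_ii[group == "all", scenario], "preferential_retention")
  expect_lt(cls_ii[group == "all", ratio_unmod], 2 / 3)

  # no qualifying Nt positions: empty output with a notice
  reg0 <- list(mod_regime("mox", 16L, "M", site_fraction = 0.5,
                          profile = "constant", rate = 0.05))
  res0 <- sim_to_pcm(sim_config(n_proteins = 8, depth = 200, regimes = reg0,
                                isotope_artifact_rate = 0, seed = 4))
  expect_message(cur0 <- retention_curves(res0$pcm, res0$ds$proteome),
                 "no N-terminal")
  expect_equal(nrow(cur0), 0L)
})
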