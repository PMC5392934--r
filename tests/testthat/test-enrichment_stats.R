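test_that("two-sided Fisher exact test matches closed forms and the stats oracle", {
  # identical proportions: p = 1
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5)$p, 1)

  # margins (4,4,4,4): full enumeration gives 34/70
  expect_equal(fisher_exact_two_sided(3, 1, 1, 3)$p, 34 / 70,
               tolerance = 1e-12)

  # degenerate all-in-group table: p = 1 / C(9446, 15) analytically
  res <- fisher_exact_two_sided(15, 0, 0, 9431)
  expect_equal(res$p, exp(-lchoose(9446, 15)), tolerance = 1e-10)
  expect_gt(res$log_odds, 0)   # Haldane-corrected direction defined

  # random tables against stats::fisher.test (independent implementation)
  set.seed(11)
  for (i in 1:50) {
    tab <- rbinom(4, size = sample(c(5, 40, 400), 1), prob = runif(1, 0.1, 0.9)) + 1L
    ours <- fisher_exact_two_sided(tab)$p
    ref <- stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-8, info = paste(tab, collapse = ","))
  }

  # log-space evaluation survives far below double-denormal p-values
  deep <- fisher_exact_two_sided(759, 1110, 132, 7728)
  expect_identical(deep$p, 0)
  expect_gt(deep$log_odds, 0)

  expect_error(fisher_exact_two_sided(0, 0, 3, 4), "margins")
})

test_that("two-sided p is invariant under simultaneous row and column swap", {
  set.seed(3)
  for (i in 1:20) {
    tab <- rbinom(4, 30, 0.5) + 1L
    p1 <- fisher_exact_two_sided(tab[1], tab[2], tab[3], tab[4])$p
    p2 <- fisher_exact_two_sided(tab[4], tab[3], tab[2], tab[1])$p
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("terminal contingency assembles modified/unmodified strata", {
  cnt <- rbind(
    data.table(protein = "P1", pos = 1L, aa = "S", terminal = "Nt",
               mass_shift = c(42L, NA), timepoint_h = 3L, replicate = 1L,
               count = c(3L, 1L)),
    data.table(protein = "P1", pos = 5L, aa = "K", terminal = "internal",
               mass_shift = c(42L, NA), timepoint_h = 3L, replicate = 1L,
               count = c(1L, 7L)))
  pcm <- manual_pcm(cnt, lengths = c(P1 = 10L))
  tab <- terminal_contingency(pcm, 42L, "Nt", 1L)
  expect_equal(unclass(tab), c(a = 3L, b = 1L, c = 1L, d = 7L))

  # no qualifying terminal position: untestable
  expect_null(terminal_contingency(pcm, 42L, "Ct", 1L))
  expect_null(terminal_contingency(pcm, 99L, "Nt", 1L))

  # positions qualify only via their own shift; counts of other shifts at
  # a qualifying position are not part of the table
  cnt2 <- rbind(cnt,
                data.table(protein = "P1", pos = 1L, aa = "S",
                           terminal = "Nt", mass_shift = 16L,
                           timepoint_h = 3L, replicate = 1L, count = 5L))
  tab2 <- terminal_contingency(manual_pcm(cnt2, c(P1 = 10L)), 42L, "Nt", 1L)
  expect_equal(unclass(tab2), c(a = 3L, b = 1L, c = 1L, d = 7L))
})

test_that("phase contingency pools stationary versus exponential timepoints", {
  mk <- function(tp, shift, n) {
    data.table(protein = "P1", pos = 3L, aa = "S", terminal = "internal",
               mass_shift = shift, timepoint_h = tp, replicate = 1L,
               count = n)
  }
  cnt <- rbind(mk(3L, 42L, 4L), mk(3L, NA, 16L),
               mk(8L, 42L, 99L),   # excluded transition timepoint
               mk(24L, 42L, 9L), mk(24L, NA, 11L),
               mk(336L, 42L, 1L), mk(336L, NA, 5L))
  pcm <- manual_pcm(cnt, lengths = c(P1 = 10L))
  tab <- phase_contingency(pcm, 42L, "S", 1L)
  expect_equal(unclass(tab), c(a = 10L, b = 16L, c = 4L, d = 16L))

  # wrong residue type or absent shift: untestable
  expect_null(phase_contingency(pcm, 42L, "T", 1L))
  # one empty phase pool: untestable
  pcm_exp_only <- manual_pcm(rbind(mk(3L, 42L, 4L), mk(3L, NA, 16L)),
                             lengths = c(P1 = 10L))
  expect_null(phase_contingency(pcm_exp_only, 42L, "S", 1L))
})

test_that("equal-rate phases give well-calibrated, mostly large p-values", {
  set.seed(21)
  ps <- replicate(40, {
    n_sta <- 400L; n_exp <- 350L
    a <- rbinom(1, n_sta, 0.1)
    cc <- rbinom(1, n_exp, 0.1)
    fisher_exact_two_sided(a, n_sta - a, cc, n_exp - cc)$p
  })
  expect_gt(median(ps), 0.4)
  # discrete exact tests are conservative under the null
  expect_lte(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
})

test_that("BH filtering implements the classical step-up rule", {
  expect_equal(bh_filter(c(k1 = 0.06), 0.05), character())
  expect_equal(bh_filter(setNames(c(0.01, 0.02, 0.03, 0.04),
                                  paste0("k", 1:4)), 0.05),
               paste0("k", 1:4))
  expect_equal(bh_filter(c(a = 0.001, b = 0.9), 0.05), "a")
  # monotone in the level: larger q_star gives a superset
  set.seed(5)
  p <- setNames(runif(30)^2, paste0("k", 1:30))
  s1 <- bh_filter(p, 0.01)
  s2 <- bh_filter(p, 0.10)
  expect_true(all(s1 %in% s2))
  # step-down never rejects more than step-up at the same level
  expect_true(all(bh_filter(p, 0.05, method = "step_down") %in%
                    bh_filter(p, 0.05, method = "step_up")))
})

test_that("replicate consistency requires all replicates to pass with one sign", {
  out <- data.table(replicate = 1:3, p = c(1e-6, 1e-4, 0.003),
                    log_odds = c(1, 2, 0.5))
  v <- consistency_filter(out, mode = "raw_p")
  expect_true(v$consistent)
  expect_equal(v$direction, "group_enriched")

  out2 <- copy(out)[2, p := 0.2]
  expect_false(consistency_filter(out2, mode = "raw_p")$consistent)

  out3 <- copy(out)[2, log_odds := -2]
  expect_equal(consistency_filter(out3, mode = "raw_p")$direction,
               "discordant")

  # a missing replicate makes the key untestable, not failed
  v4 <- consistency_filter(out[1:2], mode = "raw_p")
  expect_true(is.na(v4$consistent))

  out5 <- copy(out)[, q := c(0.01, 0.04, 0.2)]
  expect_false(consistency_filter(out5, mode = "bh")$consistent)
  out5[, q := 0.01]
  expect_true(consistency_filter(out5, mode = "bh")$consistent)
})

test_that("KS comparison behaves at the boundaries and detects shifts", {
  x <- c(1, 2, 3, 4, 5)
  same <- ks_compare(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)

  disjoint <- ks_compare(c(1, 2), c(3, 4))
  expect_equal(disjoint$D, 1)

  set.seed(13)
  shifted <- ks_compare(rnorm(500), rnorm(500, mean = 1))
  expect_lt(shifted$p, 1e-10)

  expect_error(ks_compare(numeric(), x), "nonempty")
})
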