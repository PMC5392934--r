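# Seeded synthetic proteomes, tryptic digests, and PSM tables with
# planted modification regimes, so every pipeline stage is testable
# without the deposited raw data.

# Approximate E. coli proteome amino-acid frequencies (normalized at use)
AA_BACKGROUND <- c(
  A = 0.095, C = 0.012, D = 0.054, E = 0.058, F = 0.039, G = 0.074,
  H = 0.022, I = 0.060, K = 0.044, L = 0.106, M = 0.028, N = 0.040,
  P = 0.044, Q = 0.044, R = 0.055, S = 0.058, T = 0.054, V = 0.071,
  W = 0.015, Y = 0.029
)

# Monoisotopic residue masses; Cys includes the fixed carbamidomethyl
# group (+57.02146), matching the iodoacetamide sample chemistry.
RESIDUE_MONO <- c(
  A = 71.03711, C = 103.00919 + 57.02146, D = 115.02694, E = 129.04259,
  F = 147.06841, G = 57.02146, H = 137.05891, I = 113.08406, K = 128.09496,
  L = 113.08406, M = 131.04049, N = 114.04293, P = 97.05276, Q = 128.05858,
  R = 156.10111, S = 87.03203, T = 101.04768, V = 99.06841, W = 186.07931,
  Y = 163.06333
)
WATER_MONO <- 18.010565
PROTON_MONO <- 1.007276

#' Define a planted modification regime
#'
#' A regime plants one mass shift on one class of sites: a residue type,
#' the protein N terminus (the mature N-terminal residue, position 2 when
#' the initiator Met is cleaved), or the C terminus. `site_fraction`
#' picks the modifiable subset of eligible sites once per proteome; the
#' per-timepoint modification probability at modifiable sites follows one
#' of three profiles: `constant`, `step` (one exponential-phase rate, one
#' stationary-phase rate switching at 24 h), or `clock` (linear in the
#' rank of the timepoint on the nine-point axis, emulating cumulative
#' nonenzymatic damage). `degradation_bias > 1` downweights sampling of
#' unmodified copies of target peptides in stationary phase, emulating
#' preferential degradation of the unmodified form.
#'
#' @param name regime label.
#' @param mass_shift integer mass shift in Da.
#' @param target a residue type, `"Nt"`, or `"Ct"`.
#' @param site_fraction fraction of eligible sites that are modifiable.
#' @param profile `"constant"`, `"step"` or `"clock"`.
#' @param rate constant-profile rate.
#' @param rate_exp,rate_sta step-profile rates.
#' @param rate_start,rate_end clock-profile endpoint rates.
#' @param degradation_bias stationary-phase sampling penalty on
#'   unmodified copies (1 = none).
#' @return an object of class `mod_regime`.
#' @export
mod_regime <- function(name, mass_shift, target, site_fraction = 1,
                       profile = c("constant", "step", "clock"),
                       rate = NULL, rate_exp = NULL, rate_sta = NULL,
                       rate_start = NULL, rate_end = NULL,
                       degradation_bias = 1) {
  profile <- match.arg(profile)
  stopifnot(site_fraction >= 0, site_fraction <= 1, degradation_bias >= 1)
  rates <- switch(profile,
    constant = c(rate = rate),
    step = c(rate_exp = rate_exp, rate_sta = rate_sta),
    clock = c(rate_start = rate_start, rate_end = rate_end))
  if (any(vapply(rates, is.null, logical(1))) || any(is.na(rates))) {
    stop("missing rate parameter(s) for profile ", profile)
  }
  stopifnot(all(rates >= 0), all(rates <= 1))
  structure(list(name = name, mass_shift = as.integer(mass_shift),
                 target = target, site_fraction = site_fraction,
                 profile = profile, rates = rates,
                 degradation_bias = degradation_bias),
            class = "mod_regime")
}

# Per-timepoint modification probability of a regime
regime_rate <- function(regime, t) {
  switch(regime$profile,
    constant = rep(regime$rates[["rate"]], length(t)),
    step = ifelse(t >= 24L, regime$rates[["rate_sta"]],
                  regime$rates[["rate_exp"]]),
    clock = {
      idx <- match(t, TIMEPOINTS_H)
      regime$rates[["rate_start"]] +
        (regime$rates[["rate_end"]] - regime$rates[["rate_start"]]) *
        (idx - 1) / (length(TIMEPOINTS_H) - 1)
    })
}

#' Default planted modification regimes
#'
#' The default regime set emulates the dominant biological signals of the
#' growth-curve study: step-up N-terminal acetylation (+42 Da), clock-like
#' asparagine deamidation (+1 Da), constant methionine oxidation (+16
#' Da), exponential-phase-enriched tryptophan oxidation (+16 Da), and
#' constant C-terminal glutamylation (+129 Da), plus rare internal lysine
#' acetylation and internal glutamate +129 calls (as in the real
#' spectrum, where the terminally-biased shifts also occur at low
#' frequency away from the termini — without them the terminal 2x2
#' design has no out-group stratum and is untestable).
#'
#' @return a list of [mod_regime()] objects.
#' @export
default_regimes <- function() {
  list(
    mod_regime("nt_acetylation", 42L, "Nt", site_fraction = 0.6,
               profile = "step", rate_exp = 0.30, rate_sta = 0.55),
    mod_regime("asn_deamidation", 1L, "N", site_fraction = 0.3,
               profile = "clock", rate_start = 0.01, rate_end = 0.06),
    mod_regime("met_oxidation", 16L, "M", site_fraction = 0.5,
               profile = "constant", rate = 0.05),
    mod_regime("trp_oxidation", 16L, "W", site_fraction = 0.5,
               profile = "step", rate_exp = 0.04, rate_sta = 0.017),
    mod_regime("ct_glutamylation", 129L, "Ct", site_fraction = 0.15,
               profile = "constant", rate = 0.25),
    mod_regime("lys_acetylation", 42L, "K", site_fraction = 0.1,
               profile = "constant", rate = 0.02),
    mod_regime("glu_addition", 129L, "E", site_fraction = 0.05,
               profile = "constant", rate = 0.02)
  )
}

#' Full parameterization of a synthetic PSM dataset
#'
#' @param n_proteins number of proteins in the synthetic proteome.
#' @param length_mean,length_sd normal protein-length distribution
#'   (residues), truncated below at `length_min`.
#' @param length_min minimum protein length.
#' @param timepoints sampling timepoints (default [TIMEPOINTS_H]).
#' @param replicates number of biological replicates (default 3).
#' @param depth expected PSMs per (timepoint, replicate) sample.
#' @param missed_cleavages_max maximum missed tryptic cleavages.
#' @param peptide_length_range observable peptide lengths (MS
#'   detectability window).
#' @param regimes list of [mod_regime()] objects.
#' @param p_correct mixture weight of the correct-match component of the
#'   reported probability.
#' @param correct_beta Beta shape parameters of the *error* 1 - P of a
#'   correct match (concentrated near 0); incorrect matches draw P from
#'   Uniform(0, 1).
#' @param nt_met_cleavage_prob per-protein probability that the initiator
#'   methionine is cleaved (exercises Met-cleavage-aware Nt annotation).
#' @param isotope_artifact_rate base rate of spurious +1 Da calls from
#'   isotope-peak selection; the realized rate increases with precursor
#'   m/z (the 13C confound).
#' @param charges precursor charge states sampled uniformly.
#' @param seed integer seed; the proteome and the PSM sampler draw from
#'   seed-derived streams, making the dataset fully reproducible.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 40L, length_mean = 280, length_sd = 70,
                       length_min = 60L, timepoints = TIMEPOINTS_H,
                       replicates = 3L, depth = 2000L,
                       missed_cleavages_max = 2L,
                       peptide_length_range = c(6L, 40L),
                       regimes = default_regimes(),
                       p_correct = 0.95, correct_beta = c(1, 199),
                       nt_met_cleavage_prob = 0.5,
                       isotope_artifact_rate = 0.02,
                       charges = 2:3, seed = 1L) {
  stopifnot(depth > 0, p_correct >= 0, p_correct <= 1,
            all(timepoints %in% TIMEPOINTS_H),
            replicates >= 1L, replicates <= 3L,
            missed_cleavages_max >= 0L)
  for (rg in regimes) stopifnot(inherits(rg, "mod_regime"))
  structure(list(
    n_proteins = as.integer(n_proteins), length_mean = length_mean,
    length_sd = length_sd, length_min = as.integer(length_min),
    timepoints = as.integer(timepoints), replicates = as.integer(replicates),
    depth = as.integer(depth),
    missed_cleavages_max = as.integer(missed_cleavages_max),
    peptide_length_range = as.integer(peptide_length_range),
    regimes = regimes, p_correct = p_correct, correct_beta = correct_beta,
    nt_met_cleavage_prob = nt_met_cleavage_prob,
    isotope_artifact_rate = isotope_artifact_rate,
    charges = as.integer(charges), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic proteome
#'
#' Sequences are drawn residue-by-residue from an E. coli-like background
#' composition; every protein starts with methionine. Reproducible under
#' the config seed.
#'
#' @param config a [sim_config()].
#' @return a [proteome()] object with ids `SYN0001`, `SYN0002`, ...
#' @export
generate_proteome <- function(config) {
  set.seed(config$seed)
  bg <- AA_BACKGROUND / sum(AA_BACKGROUND)
  lens <- pmax(config$length_min,
               round(rnorm(config$n_proteins, config$length_mean,
                           config$length_sd)))
  seqs <- vapply(lens, function(L) {
    paste0("M", paste(sample(names(bg), L - 1L, replace = TRUE, prob = bg),
                      collapse = ""))
  }, character(1))
  names(seqs) <- sprintf("SYN%04d", seq_along(seqs))
  proteome(seqs, source = "synthetic")
}

#' Fully-tryptic in silico digest of one protein
#'
#' Cleaves after K or R except when the next residue is proline (the
#' no-proline rule); a K/R followed by P is not a cleavage site and does
#' not count as a missed cleavage. Returns all fully-tryptic products
#' with 0 to `max_missed` internal missed cleavages, with their 1-based
#' start positions.
#'
#' @param sequence nonempty amino-acid string.
#' @param max_missed maximum internal missed cleavages (default 2).
#' @return `data.table(peptide, start, missed)`.
#' @export
digest <- function(sequence, max_missed = 2L) {
  stopifnot(nchar(sequence) >= 1L)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  sites <- which(chars %in% c("K", "R"))
  sites <- sites[sites < n & chars[pmin(sites + 1L, n)] != "P"]
  bounds <- c(0L, sites, n)
  bounds <- unique(bounds)
  nfrag <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + max_missed)) {
      from <- bounds[i] + 1L
      to <- bounds[j + 1L]
      out[[length(out) + 1L]] <- data.table(
        peptide = substr(sequence, from, to),
        start = from, missed = j - i)
    }
  }
  rbindlist(out)
}

# Digest every protein; adds Nt-Met-cleaved variants of protein-initial
# peptides for proteins flagged as cleaved.
digest_proteome <- function(prot, max_missed, met_cleaved) {
  pools <- lapply(names(prot$seqs), function(id) {
    dg <- digest(prot$seqs[[id]], max_missed)
    dg[, protein := id]
    if (met_cleaved[id] && stri_sub(prot$seqs[[id]], 1L, 1L) == "M") {
      init <- dg[start == 1L & nchar(peptide) > 1L]
      if (nrow(init) > 0L) {
        init <- copy(init)
        init[, peptide := stri_sub(peptide, 2L)]
        init[, start := 2L]
        dg <- rbind(dg, init)
      }
    }
    dg
  })
  rbindlist(pools)
}

# Pick the modifiable site set of each regime (Bernoulli site_fraction,
# decided once per dataset).
plant_sites <- function(prot, regimes, met_cleaved) {
  ids <- names(prot$seqs)
  out <- list()
  for (k in seq_along(regimes)) {
    rg <- regimes[[k]]
    cand <- if (rg$target == "Nt") {
      data.table(protein = ids,
                 pos = ifelse(met_cleaved[ids] &
                                stri_sub(prot$seqs, 1L, 1L) == "M", 2L, 1L))
    } else if (rg$target == "Ct") {
      data.table(protein = ids, pos = unname(prot$lengths[ids]))
    } else {
      hits <- stri_locate_all_fixed(prot$seqs, rg$target)
      rbindlist(lapply(seq_along(ids), function(i) {
        g <- hits[[i]][, 1L]
        if (length(g) == 0L || is.na(g[1L])) return(NULL)
        data.table(protein = ids[i], pos = g)
      }))
    }
    if (is.null(cand) || nrow(cand) == 0L) next
    keep <- runif(nrow(cand)) < rg$site_fraction
    cand <- cand[keep]
    if (nrow(cand) == 0L) next
    cand[, regime := k]
    cand[, mass_shift := rg$mass_shift]
    out[[length(out) + 1L]] <- cand
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L) {
    res <- data.table(protein = character(), pos = integer(),
                      regime = integer(), mass_shift = integer())
  }
  res[, site_id := .I]
  res
}

peptide_mono_mass <- function(peptides) {
  vapply(strsplit(peptides, ""), function(ch) sum(RESIDUE_MONO[ch]),
         numeric(1)) + WATER_MONO
}

#' Simulate a PSM table with planted modification structure
#'
#' For each (timepoint, replicate) sample, peptide copies are drawn with
#' protein-level log-normal abundance weights; each drawn copy then
#' resolves its modification state: every covered modifiable site tosses
#' a Bernoulli coin at its regime's per-timepoint rate and, if several
#' succeed, one is kept uniformly (one modification per PSM). In
#' stationary phase, unmodified copies of peptides covering a site of a
#' regime with `degradation_bias > 1` are thinned by that factor,
#' emulating preferential degradation of the unmodified form (so `depth`
#' is the expected, not exact, per-sample PSM count). Reported
#' probabilities come from a correct/incorrect mixture; a small
#' m/z-dependent rate of spurious +1 Da calls emulates isotope-peak
#' selection. Precursor m/z derives from the monoisotopic peptide mass at
#' charge 2-3.
#'
#' Reproducible: same config (including seed), same table, byte for byte.
#'
#' @param config a [sim_config()].
#' @param prot the proteome generated from the same config (see
#'   [generate_proteome()]).
#' @return `list(psms, truth)`: `psms` is a canonical PSM table;
#'   `truth` is a list with `sites` (planted modifiable sites with regime
#'   names), `met_cleaved` (per-protein initiator-Met cleavage flags) and
#'   `psm_flags` (`data.table(row_id, correct, planted)` aligned with
#'   `psms`).
#' @export
simulate_psms <- function(config, prot) {
  set.seed(config$seed + 1L)
  ids <- names(prot$seqs)
  abundance <- setNames(rlnorm(length(ids), meanlog = 0, sdlog = 1), ids)
  met_cleaved <- setNames(runif(length(ids)) < config$nt_met_cleavage_prob,
                          ids)

  pool <- digest_proteome(prot, config$missed_cleavages_max, met_cleaved)
  pool <- pool[nchar(peptide) >= config$peptide_length_range[1L] &
                 nchar(peptide) <= config$peptide_length_range[2L]]
  if (nrow(pool) == 0L) stop("digest produced no observable peptides")
  pool[, pool_row := .I]
  pool[, pep_len := nchar(peptide)]
  pool[, end := start + pep_len - 1L]
  pool[, abundance := abundance[protein]]
  pool[, mz_base := peptide_mono_mass(peptide)]

  sites <- plant_sites(prot, config$regimes, met_cleaved)
  # site coverage of each pooled peptide (computed once, reused per sample)
  coverage <- if (nrow(sites) > 0L) {
    sites[pool, on = .(protein, pos >= start, pos <= end), nomatch = NULL,
          .(pool_row = i.pool_row, site_id = x.site_id, regime = x.regime,
            mass_shift = x.mass_shift, site_pos = x.pos,
            pep_start = i.start)]
  } else {
    data.table(pool_row = integer(), site_id = integer(), regime = integer(),
               mass_shift = integer(), site_pos = integer(),
               pep_start = integer())
  }
  biases <- vapply(config$regimes, `[[`, numeric(1), "degradation_bias")
  max_bias <- if (nrow(coverage) > 0L) {
    coverage[, .(bias = max(biases[regime])), by = pool_row]
  } else {
    data.table(pool_row = integer(), bias = numeric())
  }
  pool <- merge(pool, max_bias, by = "pool_row", all.x = TRUE)
  pool[is.na(bias), bias := 1]

  samples <- list()
  for (t in config$timepoints) {
    rates_t <- vapply(config$regimes, function(rg) regime_rate(rg, t),
                      numeric(1))
    sta <- t >= 24L
    for (r in seq_len(config$replicates)) {
      inst_rows <- sample(pool$pool_row, config$depth, replace = TRUE,
                          prob = pool$abundance)
      inst <- data.table(inst_id = seq_along(inst_rows),
                         pool_row = inst_rows)
      # modification state: Bernoulli per covered site, one winner per PSM
      cand <- coverage[inst, on = "pool_row", nomatch = NULL, allow.cartesian = TRUE]
      mods <- NULL
      if (nrow(cand) > 0L) {
        cand[, rate := rates_t[regime]]
        cand[, hit := runif(.N) < rate]
        cand <- cand[hit == TRUE]
        if (nrow(cand) > 0L) {
          cand[, rnd := runif(.N)]
          setorder(cand, inst_id, rnd)
          mods <- cand[!duplicated(inst_id)]
        }
      }
      inst[, mass_shift := NA_integer_]
      inst[, mod_pos := NA_integer_]
      inst[, planted := FALSE]
      if (!is.null(mods) && nrow(mods) > 0L) {
        inst[mods$inst_id, `:=`(
          mass_shift = mods$mass_shift,
          mod_pos = mods$site_pos - mods$pep_start + 1L,
          planted = TRUE)]
      }
      # stationary-phase thinning of unmodified copies of biased targets
      if (sta) {
        bias_here <- pool$bias[inst$pool_row]
        drop <- is.na(inst$mass_shift) & bias_here > 1 &
          runif(nrow(inst)) > 1 / bias_here
        inst <- inst[!drop]
      }
      # precursor m/z and the m/z-dependent +1 Da isotope artifact
      inst[, charge := sample(config$charges, .N, replace = TRUE)]
      shift_da <- fifelse(is.na(inst$mass_shift), 0, as.numeric(inst$mass_shift))
      inst[, mz := (pool$mz_base[pool_row] + shift_da +
                      PROTON_MONO * charge) / charge]
      if (config$isotope_artifact_rate > 0) {
        p_iso <- config$isotope_artifact_rate * plogis((inst$mz - 900) / 120)
        art <- is.na(inst$mass_shift) & runif(nrow(inst)) < p_iso
        if (any(art)) {
          lens_art <- pool$pep_len[inst$pool_row[art]]
          inst[art, `:=`(
            mass_shift = 1L,
            mod_pos = as.integer(ceiling(runif(sum(art)) * lens_art)))]
        }
      }
      inst[, correct := runif(.N) < config$p_correct]
      inst[, probability := fifelse(
        correct,
        1 - rbeta(.N, config$correct_beta[1L], config$correct_beta[2L]),
        runif(.N))]
      inst[, `:=`(timepoint_h = t, replicate = r)]
      samples[[length(samples) + 1L]] <- inst
    }
  }
  all_inst <- rbindlist(samples)
  psms <- data.table(
    peptide = pool$peptide[all_inst$pool_row],
    protein = pool$protein[all_inst$pool_row],
    mass_shift = all_inst$mass_shift,
    mod_pos = all_inst$mod_pos,
    probability = pmin(1, pmax(0, all_inst$probability)),
    timepoint_h = all_inst$timepoint_h,
    replicate = all_inst$replicate,
    precursor_mz = all_inst$mz
  )
  setattr(psms, "cys_corrected", FALSE)
  truth_sites <- copy(sites)
  if (nrow(truth_sites) > 0L) {
    truth_sites[, regime := vapply(config$regimes, `[[`, character(1),
                                   "name")[regime]]
  }
  list(
    psms = psms[],
    truth = list(
      sites = truth_sites[],
      met_cleaved = met_cleaved,
      psm_flags = data.table(row_id = seq_len(nrow(psms)),
                             correct = all_inst$correct,
                             planted = all_inst$planted)
    )
  )
}

#' Generate a complete synthetic dataset (proteome + PSM table + truth)
#'
#' Convenience wrapper over [generate_proteome()] and [simulate_psms()];
#' optionally writes `proteome.fasta`, `psms.tsv` and `truth_sites.tsv`
#' to a directory.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory (created if needed).
#' @return `list(proteome, psms, truth)`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  prot <- generate_proteome(config)
  sim <- simulate_psms(config, prot)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_proteome(prot, file.path(dir, "proteome.fasta"))
    write_psm_table(sim$psms, file.path(dir, "psms.tsv"))
    fwrite(sim$truth$sites, file.path(dir, "truth_sites.tsv"), sep = "\t")
  }
  list(proteome = prot, psms = sim$psms, truth = sim$truth)
}
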