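# Temporal analyses: phase pooling, fractional-modification trajectories,
# normalized-position densities, and modified-vs-unmodified retention
# curves.

#' Exponential/stationary phase pooling of timepoints
#'
#' Defaults follow the growth-curve design: exponential phase pools the
#' 3, 4, 5 and 6 h samples, stationary phase pools 24, 48, 168 and 336 h,
#' and the 8 h exponential-stationary transition sample is excluded.
#'
#' @param exp_timepoints exponential-phase timepoints (h).
#' @param sta_timepoints stationary-phase timepoints (h).
#' @param excluded excluded timepoints (h).
#' @return an object of class `phase_pooling`.
#' @export
phase_pooling <- function(exp_timepoints = c(3L, 4L, 5L, 6L),
                          sta_timepoints = c(24L, 48L, 168L, 336L),
                          excluded = 8L) {
  exp_timepoints <- as.integer(exp_timepoints)
  sta_timepoints <- as.integer(sta_timepoints)
  excluded <- as.integer(excluded)
  if (length(intersect(exp_timepoints, sta_timepoints)) > 0L) {
    stop("phase pools must be disjoint")
  }
  if (!all(c(exp_timepoints, sta_timepoints, excluded) %in% TIMEPOINTS_H)) {
    stop("phase pools must be subsets of the nine-timepoint axis")
  }
  structure(list(exp_timepoints = exp_timepoints,
                 sta_timepoints = sta_timepoints,
                 excluded = excluded),
            class = "phase_pooling")
}

#' Fractional-modification trajectory of a key
#'
#' Computes the fractional modification `n_mod / (n_mod + n_unmod)` at
#' each of the nine timepoints, either for a single protein position and
#' mass shift, or pooled over all positions of one residue type bearing
#' the mass shift (the mass shift x amino acid key used by the phase
#' analysis). Positions enter the pool only if they carry at least one
#' modification of the shift at any timepoint within the replicate. A
#' timepoint with neither modified nor unmodified counts has its fraction
#' encoded as `NA` (unobserved), never 0.
#'
#' With `scope = "replicate_mean"`, counts are first averaged across
#' replicates and then divided, which avoids 0/0 artifacts that averaging
#' per-replicate fractions would create.
#'
#' @param pcm a `position_counts` object.
#' @param mass_shift integer mass shift in Da.
#' @param protein,pos protein id and 1-based position (position-level key).
#' @param aa residue type (pooled key); give either `protein`+`pos` or `aa`.
#' @param scope `"per_replicate"` or `"replicate_mean"`.
#' @param replicates replicate indices considered.
#' @return `data.table(timepoint_h, replicate, n_mod, n_unmod, fraction)`;
#'   `replicate` is `NA` for `replicate_mean`.
#' @export
fractional_trajectory <- function(pcm, mass_shift, protein = NULL, pos = NULL,
                                  aa = NULL,
                                  scope = c("per_replicate", "replicate_mean"),
                                  replicates = 1:3) {
  scope <- match.arg(scope)
  s <- as.integer(mass_shift)
  positional <- !is.null(protein)
  if (positional && is.null(pos)) stop("positional key needs both protein and pos")
  if (!positional && is.null(aa)) stop("give either protein+pos or aa")
  prot_ <- protein; pos_ <- pos; aa_ <- aa
  per_rep <- lapply(replicates, function(r) {
    cnt <- pcm$counts[replicate == r]
    cnt <- if (positional) {
      cnt[protein == prot_ & pos == pos_]
    } else {
      cnt[aa == aa_]
    }
    qual <- unique(cnt[!is.na(mass_shift) & mass_shift == s, .(protein, pos)])
    if (nrow(qual) == 0L) return(NULL)
    sub <- cnt[qual, on = c("protein", "pos")]
    agg <- sub[, .(
      n_mod = sum(count[!is.na(mass_shift) & mass_shift == s]),
      n_unmod = sum(count[is.na(mass_shift)])
    ), by = timepoint_h]
    full <- data.table(timepoint_h = TIMEPOINTS_H)
    agg <- merge(full, agg, by = "timepoint_h", all.x = TRUE)
    agg[is.na(n_mod), n_mod := 0]
    agg[is.na(n_unmod), n_unmod := 0]
    agg[, replicate := r]
    agg
  })
  per_rep <- rbindlist(per_rep)
  if (nrow(per_rep) == 0L) {
    stop("key has no modification of this mass shift in any replicate")
  }
  if (scope == "replicate_mean") {
    per_rep <- per_rep[, .(n_mod = mean(n_mod), n_unmod = mean(n_unmod),
                           replicate = NA_integer_),
                       by = timepoint_h]
  }
  per_rep[, fraction := fifelse(n_mod + n_unmod > 0,
                                n_mod / (n_mod + n_unmod), NA_real_)]
  setcolorder(per_rep, c("timepoint_h", "replicate", "n_mod", "n_unmod",
                         "fraction"))
  setorder(per_rep, replicate, timepoint_h, na.last = FALSE)
  per_rep[]
}

#' Modified-vs-unmodified retention curves for N-terminal modification
#'
#' For every N-terminal position carrying at least one PSM of the given
#' mass shift (N-terminal acetylation, +42 Da, by default), pools
#' modified and unmodified PSM counts per timepoint and averages the
#' counts (not the fractions) across replicates. Curves are reported for
#' all qualifying positions together and split by the protein's
#' penultimate residue (position 2, the residue exposed by initiator-Met
#' cleavage). Diverging curve shapes discriminate increased modification
#' activity (modified counts rise, unmodified flat) from preferential
#' retention of the modified form (unmodified counts fall, modified
#' flat).
#'
#' @param pcm an annotated `position_counts` object (Met-cleavage-aware
#'   annotation recommended).
#' @param prot the matching [proteome()].
#' @param mass_shift integer mass shift (default +42).
#' @param penultimate residue types to report as separate groups
#'   (default S, T, A).
#' @param replicates replicate indices averaged over.
#' @return `data.table(group, timepoint_h, n_mod, n_unmod)`; zero rows
#'   (with a message) when no position qualifies.
#' @export
retention_curves <- function(pcm, prot, mass_shift = 42L,
                             penultimate = c("S", "T", "A"),
                             replicates = 1:3) {
  stopifnot(isTRUE(pcm$annotated))
  s <- as.integer(mass_shift)
  cnt <- pcm$counts[replicate %in% replicates]
  qual <- unique(cnt[terminal == "Nt" & !is.na(mass_shift) & mass_shift == s,
                     .(protein, pos)])
  if (nrow(qual) == 0L) {
    message("no N-terminal positions carry the ", s, " Da shift")
    return(data.table(group = character(), timepoint_h = integer(),
                      n_mod = numeric(), n_unmod = numeric()))
  }
  qual[, aa2 := stri_sub(prot$seqs[protein], 2L, 2L)]
  sub <- cnt[qual, on = c("protein", "pos")]
  n_rep <- length(replicates)
  curve_for <- function(sel, label) {
    ss <- sub[sel]
    if (nrow(ss) == 0L) return(NULL)
    agg <- ss[, .(
      n_mod = sum(count[!is.na(mass_shift) & mass_shift == s]) / n_rep,
      n_unmod = sum(count[is.na(mass_shift)]) / n_rep
    ), by = timepoint_h]
    full <- data.table(timepoint_h = TIMEPOINTS_H)
    agg <- merge(full, agg, by = "timepoint_h", all.x = TRUE)
    agg[is.na(n_mod), n_mod := 0]
    agg[is.na(n_unmod), n_unmod := 0]
    agg[, group := label]
    agg
  }
  out <- list(curve_for(rep(TRUE, nrow(sub)), "all"))
  for (a2 in penultimate) {
    sel <- sub$aa2 == a2
    if (!any(sel)) {
      message("no qualifying N-terminal position with penultimate ", a2)
      next
    }
    out[[length(out) + 1L]] <- curve_for(sel, a2)
  }
  out <- rbindlist(out)
  setcolorder(out, c("group", "timepoint_h", "n_mod", "n_unmod"))
  setorder(out, group, timepoint_h)
  out[]
}

#' Classify a retention curve by its phase-ratio signature
#'
#' For each group, computes the ratio of mean stationary-pool to mean
#' exponential-pool counts separately for modified and unmodified PSMs,
#' and classifies the group: `"modification_increase"` when modified
#' counts rise at least 1.5-fold, `"preferential_retention"` when
#' unmodified counts fall below 2/3 while modified counts do not,
#' `"mixed"` when both signatures co-occur, `"stable"` otherwise.
#'
#' @param curves output of [retention_curves()].
#' @param pooling a [phase_pooling()] object.
#' @return `data.table(group, ratio_mod, ratio_unmod, scenario)`.
#' @export
classify_retention <- function(curves, pooling = phase_pooling()) {
  curves <- as.data.table(curves)
  out <- curves[, {
    em <- mean(n_mod[timepoint_h %in% pooling$exp_timepoints])
    sm <- mean(n_mod[timepoint_h %in% pooling$sta_timepoints])
    eu <- mean(n_unmod[timepoint_h %in% pooling$exp_timepoints])
    su <- mean(n_unmod[timepoint_h %in% pooling$sta_timepoints])
    ratio_mod <- if (em > 0) sm / em else Inf
    ratio_unmod <- if (eu > 0) su / eu else Inf
    rise_mod <- is.finite(ratio_mod) && ratio_mod >= 1.5
    fall_unmod <- is.finite(ratio_unmod) && ratio_unmod <= 2 / 3
    fall_mod <- is.finite(ratio_mod) && ratio_mod <= 2 / 3
    scenario <- if (rise_mod && fall_unmod) {
      "mixed"
    } else if (rise_mod) {
      "modification_increase"
    } else if (fall_unmod && !fall_mod) {
      "preferential_retention"
    } else {
      "stable"
    }
    .(ratio_mod = ratio_mod, ratio_unmod = ratio_unmod, scenario = scenario)
  }, by = group]
  out[]
}

#' Normalized positions of unique modified sites
#'
#' Each unique (protein, position) bearing the mass shift contributes
#' `(position - 1) / (length - 1)`, mapping the N terminus to exactly 0
#' and the C terminus to exactly 1; length-1 proteins contribute 0.
#'
#' @param pcm a `position_counts` object.
#' @param mass_shift integer mass shift in Da.
#' @return numeric vector of normalized positions in \[0, 1\].
#' @export
position_density <- function(pcm, mass_shift) {
  s <- as.integer(mass_shift)
  upos <- unique(pcm$counts[!is.na(mass_shift) & mass_shift == s,
                            .(protein, pos)])
  if (nrow(upos) == 0L) return(numeric())
  len <- pcm$lengths[upos$protein]
  ifelse(len > 1L, (upos$pos - 1) / (len - 1), 0)
}
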