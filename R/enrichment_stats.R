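# Exact 2x2 testing machinery: two-sided Fisher's exact test with
# log-space hypergeometric sums, contingency table construction for
# terminal and growth-phase enrichment, BH filtering, replicate
# consistency, and two-sample KS comparison.

#' Construct a 2x2 contingency table
#'
#' Cell layout: `a` modified-in-group, `b` unmodified-in-group, `c`
#' modified-out-of-group, `d` unmodified-out-of-group. "Group" is the
#' terminal-position stratum for terminal tests, or the stationary-phase
#' pool for growth-phase tests.
#'
#' @param a,b,c,d nonnegative integer counts.
#' @return a named integer vector of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(!is.na(v)), all(v >= 0), all(v == round(v)))
  structure(as.integer(round(v)), names = c("a", "b", "c", "d"),
            class = "contingency_table")
}

# log(sum(exp(lx))) without overflow/underflow of intermediates
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Two-sided Fisher's exact test in log space
#'
#' Computes the two-sided p-value as the sum of hypergeometric point
#' probabilities (margins fixed) of all tables whose point probability is
#' at most that of the observed table, within a relative tolerance of
#' 1e-7 (the point-probability convention dominant in scientific
#' software). The sum is accumulated in log space, so p-values down to
#' roughly 1e-300 are representable; values below the representable
#' range are reported as 0.
#'
#' The log-odds is `log((a d)/(b c))`, with a Haldane correction of +0.5
#' added to every cell when any cell is zero (so direction remains
#' defined for degenerate tables); the correction is never applied to the
#' p-value.
#'
#' @param a a [contingency_table()], a length-4 vector `(a, b, c, d)`, or
#'   the `a` cell when `b`, `c`, `d` are given.
#' @param b,c,d remaining cells (when `a` is scalar).
#' @return `list(p, log_odds)`.
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (length(a) == 4L) {
    tab <- as.integer(a)
  } else {
    tab <- as.integer(c(a, b, c, d))
  }
  stopifnot(length(tab) == 4L, all(tab >= 0))
  a <- tab[1L]; b <- tab[2L]; cc <- tab[3L]; d <- tab[4L]
  m <- a + b            # in-group total
  n_ <- cc + d          # out-of-group total
  k <- a + cc           # modified total
  if (m == 0L || n_ == 0L || k == 0L || (b + d) == 0L) {
    stop("Fisher's exact test requires all four margins positive")
  }
  lo <- max(0L, k - n_)
  hi <- min(k, m)
  x <- lo:hi
  lp <- dhyper(x, m, n_, k, log = TRUE)
  lp_obs <- lp[a - lo + 1L]
  keep <- lp <= lp_obs + log1p(1e-7)
  p <- exp(logsumexp(lp[keep]))
  p <- min(p, 1)
  if (any(tab == 0L)) {
    lo_ratio <- log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5)))
  } else {
    lo_ratio <- log((as.numeric(a) * d) / (as.numeric(b) * cc))
  }
  list(p = p, log_odds = lo_ratio)
}

#' Terminal-enrichment contingency table for one mass shift
#'
#' Restricts to positions having at least one PSM of the given mass shift
#' anywhere in the replicate (any timepoint), then sums shift-s modified
#' and unmodified counts over qualifying terminal positions (cells a, b)
#' and over qualifying non-terminal positions, including the opposite
#' terminus (cells c, d). Counts are pooled over all timepoints. Requires
#' [annotate_termini()] to have been run.
#'
#' @param pcm an annotated `position_counts` object.
#' @param mass_shift integer mass shift in Da.
#' @param terminus `"Nt"` or `"Ct"`.
#' @param replicate replicate index.
#' @return a [contingency_table()], or `NULL` when no terminal position
#'   qualifies (untestable key).
#' @export
terminal_contingency <- function(pcm, mass_shift, terminus = c("Nt", "Ct"),
                                 replicate) {
  terminus <- match.arg(terminus)
  stopifnot(isTRUE(pcm$annotated))
  s <- as.integer(mass_shift)
  r <- as.integer(replicate)
  cnt <- pcm$counts[replicate == r]
  qual <- unique(cnt[!is.na(mass_shift) & mass_shift == s, .(protein, pos)])
  if (nrow(qual) == 0L) return(NULL)
  sub <- cnt[qual, on = c("protein", "pos")]
  in_grp <- sub$terminal == terminus
  is_s <- !is.na(sub$mass_shift) & sub$mass_shift == s
  is_u <- is.na(sub$mass_shift)
  if (!any(in_grp)) return(NULL)
  contingency_table(
    a = sum(sub$count[in_grp & is_s]),
    b = sum(sub$count[in_grp & is_u]),
    c = sum(sub$count[!in_grp & is_s]),
    d = sum(sub$count[!in_grp & is_u])
  )
}

#' Growth-phase contingency table for one mass shift x amino acid pair
#'
#' Restricts to positions of the given residue type with at least one PSM
#' of the mass shift at any timepoint in the replicate, then sums
#' modified and unmodified counts over the stationary-phase timepoint
#' pool (cells a, b) and the exponential-phase pool (cells c, d); the
#' transition timepoint is excluded.
#'
#' @param pcm a `position_counts` object.
#' @param mass_shift integer mass shift in Da.
#' @param aa single residue type.
#' @param replicate replicate index.
#' @param pooling a [phase_pooling()] object.
#' @return a [contingency_table()], or `NULL` when either phase pool is
#'   empty (untestable key).
#' @export
phase_contingency <- function(pcm, mass_shift, aa, replicate,
                              pooling = phase_pooling()) {
  s <- as.integer(mass_shift)
  r <- as.integer(replicate)
  aa_ <- as.character(aa)
  cnt <- pcm$counts[replicate == r & aa == aa_]
  qual <- unique(cnt[!is.na(mass_shift) & mass_shift == s, .(protein, pos)])
  if (nrow(qual) == 0L) return(NULL)
  sub <- cnt[qual, on = c("protein", "pos")]
  in_sta <- sub$timepoint_h %in% pooling$sta_timepoints
  in_exp <- sub$timepoint_h %in% pooling$exp_timepoints
  is_s <- !is.na(sub$mass_shift) & sub$mass_shift == s
  is_u <- is.na(sub$mass_shift)
  tab <- contingency_table(
    a = sum(sub$count[in_sta & is_s]),
    b = sum(sub$count[in_sta & is_u]),
    c = sum(sub$count[in_exp & is_s]),
    d = sum(sub$count[in_exp & is_u])
  )
  if ((tab["a"] + tab["b"]) == 0L || (tab["c"] + tab["d"]) == 0L) return(NULL)
  tab
}

#' Benjamini-Hochberg filtering of a p-value collection
#'
#' Classical BH step-up at level `q_star`: sort ascending, find the
#' largest i with `p_(i) <= (i/m) q_star`, return the keys of the first i
#' p-values. A step-down variant (sequential rejection from the smallest
#' p, stopping at the first failure) is exposed for comparison; the
#' step-up procedure is the default.
#'
#' @param p named numeric vector of p-values in \[0, 1\].
#' @param q_star target FDR level.
#' @param method `"step_up"` (default) or `"step_down"`.
#' @return character vector of significant keys.
#' @export
bh_filter <- function(p, q_star = 0.05, method = c("step_up", "step_down")) {
  method <- match.arg(method)
  stopifnot(all(p >= 0 & p <= 1))
  if (is.null(names(p))) names(p) <- as.character(seq_along(p))
  if (length(p) == 0L) return(character())
  if (method == "step_up") {
    return(names(p)[p.adjust(p, method = "BH") <= q_star])
  }
  ord <- order(p)
  m <- length(p)
  crit <- p[ord] <= (seq_len(m) / m) * q_star
  fail <- which(!crit)
  n_rej <- if (length(fail) == 0L) m else fail[1L] - 1L
  names(p)[ord[seq_len(n_rej)]]
}

#' Cross-replicate consistency verdict for one key
#'
#' A key is consistent when it passes in every expected replicate: under
#' `mode = "raw_p"` a replicate passes when its p-value is below
#' `p_threshold`; under `mode = "bh"` when its within-replicate BH
#' q-value is at most `q_star` (the caller supplies the `q` column).
#' Direction is assigned by the common sign of the per-replicate
#' log-odds, `"discordant"` when signs differ. A missing replicate makes
#' the key untestable (consistent = `NA`), not failed.
#'
#' @param outcomes `data.table`/`data.frame` with columns `replicate`,
#'   `p`, `log_odds` and (for `mode = "bh"`) `q`.
#' @param mode `"raw_p"` or `"bh"`.
#' @param p_threshold per-replicate raw p cutoff (default 0.05).
#' @param q_star per-replicate BH level (default 0.05).
#' @param replicates the replicates expected (default 1:3).
#' @return `list(consistent, direction, pass)`; `direction` is one of
#'   `"group_enriched"`, `"outgroup_enriched"`, `"discordant"`.
#' @export
consistency_filter <- function(outcomes, mode = c("raw_p", "bh"),
                               p_threshold = 0.05, q_star = 0.05,
                               replicates = 1:3) {
  mode <- match.arg(mode)
  outcomes <- as.data.table(outcomes)
  if (!all(replicates %in% outcomes$replicate)) {
    return(list(consistent = NA, direction = NA_character_,
                pass = NULL))
  }
  outcomes <- outcomes[replicate %in% replicates]
  pass <- if (mode == "raw_p") {
    outcomes$p < p_threshold
  } else {
    if (!("q" %in% names(outcomes))) stop("mode 'bh' needs a q column")
    outcomes$q <= q_star
  }
  signs <- sign(outcomes$log_odds)
  direction <- if (all(signs > 0)) {
    "group_enriched"
  } else if (all(signs < 0)) {
    "outgroup_enriched"
  } else {
    "discordant"
  }
  list(consistent = all(pass), direction = direction,
       pass = setNames(pass, outcomes$replicate))
}

empty_enrichment <- function() {
  out <- data.table(character(), integer(), integer(), integer(),
                    integer(), integer(), numeric(), numeric(), numeric(),
                    logical(), character())
  setnames(out, c("key", "replicate", "a", "b", "c", "d", "p", "log_odds",
                  "q", "consistent", "direction"))
  out
}

# Shared driver: given a per-(key, replicate) table of contingency cells,
# attach p, log_odds, within-replicate BH q, consistency and direction.
finish_enrichment <- function(res, mode, p_threshold, q_star, replicates) {
  if (nrow(res) == 0L) return(res)
  fet <- mapply(function(a, b, cc, d) fisher_exact_two_sided(a, b, cc, d),
                res$a, res$b, res$c, res$d, SIMPLIFY = FALSE)
  res[, p := vapply(fet, `[[`, numeric(1), "p")]
  res[, log_odds := vapply(fet, `[[`, numeric(1), "log_odds")]
  res[, q := p.adjust(p, method = "BH"), by = replicate]
  verdicts <- res[, {
    v <- consistency_filter(.SD, mode = mode, p_threshold = p_threshold,
                            q_star = q_star, replicates = replicates)
    .(consistent = v$consistent, direction = v$direction)
  }, by = key, .SDcols = c("replicate", "p", "log_odds", "q")]
  res <- merge(res, verdicts, by = "key", sort = FALSE)
  setcolorder(res, c("key", "replicate", "a", "b", "c", "d", "p",
                     "log_odds", "q", "consistent", "direction"))
  setorder(res, key, replicate)
  res[]
}

#' Terminal enrichment across all observed mass shifts
#'
#' Builds the terminal contingency table for every testable mass shift in
#' every replicate, computes two-sided Fisher p-values and log-odds,
#' BH-adjusts within replicate, and applies the three-replicate
#' consistency filter (raw per-replicate p < 0.05 by default, matching
#' the terminal analysis convention).
#'
#' @param pcm an annotated `position_counts` object.
#' @param terminus `"Nt"` or `"Ct"`.
#' @param replicates replicate indices (default 1:3).
#' @param mode consistency mode, `"raw_p"` (default) or `"bh"`.
#' @param p_threshold,q_star consistency cutoffs.
#' @return `data.table` with fixed column order: key, replicate, a, b, c,
#'   d, p, log_odds, q, consistent, direction. `key` is the mass shift.
#' @export
terminal_enrichment <- function(pcm, terminus = c("Nt", "Ct"),
                                replicates = 1:3, mode = c("raw_p", "bh"),
                                p_threshold = 0.05, q_star = 0.05) {
  terminus <- match.arg(terminus)
  mode <- match.arg(mode)
  shifts <- sort(unique(pcm$counts[!is.na(mass_shift), mass_shift]))
  rows <- list()
  for (s in shifts) {
    for (r in replicates) {
      tab <- terminal_contingency(pcm, s, terminus, r)
      if (is.null(tab)) next
      # all four margins must be positive for the exact test
      if ((tab["a"] + tab["b"]) == 0L || (tab["c"] + tab["d"]) == 0L ||
          (tab["a"] + tab["c"]) == 0L || (tab["b"] + tab["d"]) == 0L) next
      rows[[length(rows) + 1L]] <- data.table(
        k_ = as.character(s), replicate = r,
        a = tab[["a"]], b = tab[["b"]], c = tab[["c"]], d = tab[["d"]])
    }
  }
  res <- rbindlist(rows)
  if (nrow(res) == 0L) return(empty_enrichment())
  setnames(res, "k_", "key")
  finish_enrichment(res, mode, p_threshold, q_star, replicates)
}

#' Growth-phase enrichment across mass shift x amino acid pairs
#'
#' Builds the phase contingency table for every testable
#' (mass shift, residue) pair in every replicate, computes two-sided
#' Fisher p-values and log-odds, BH-adjusts within replicate, and applies
#' the three-replicate consistency filter (within-replicate BH q <= 0.05
#' by default, matching the phase analysis convention). Direction
#' `"group_enriched"` means stationary-phase enrichment.
#'
#' @param pcm a `position_counts` object.
#' @param pooling a [phase_pooling()] object.
#' @param replicates replicate indices (default 1:3).
#' @param mode consistency mode, `"bh"` (default) or `"raw_p"`.
#' @param p_threshold,q_star consistency cutoffs.
#' @return `data.table` in the fixed column order of
#'   [terminal_enrichment()]; `key` is `"<shift>/<aa>"`.
#' @export
phase_enrichment <- function(pcm, pooling = phase_pooling(),
                             replicates = 1:3, mode = c("bh", "raw_p"),
                             p_threshold = 0.05, q_star = 0.05) {
  mode <- match.arg(mode)
  pairs <- unique(pcm$counts[!is.na(mass_shift), .(mass_shift, aa)])
  setorder(pairs, mass_shift, aa)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    for (r in replicates) {
      tab <- phase_contingency(pcm, pairs$mass_shift[i], pairs$aa[i], r,
                               pooling)
      if (is.null(tab)) next
      # all four margins must be positive for the exact test
      if ((tab["a"] + tab["b"]) == 0L || (tab["c"] + tab["d"]) == 0L ||
          (tab["a"] + tab["c"]) == 0L || (tab["b"] + tab["d"]) == 0L) next
      rows[[length(rows) + 1L]] <- data.table(
        k_ = sprintf("%d/%s", pairs$mass_shift[i], pairs$aa[i]),
        replicate = r,
        a = tab[["a"]], b = tab[["b"]], c = tab[["c"]], d = tab[["d"]])
    }
  }
  res <- rbindlist(rows)
  if (nrow(res) == 0L) return(empty_enrichment())
  setnames(res, "k_", "key")
  finish_enrichment(res, mode, p_threshold, q_star, replicates)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS test with the asymptotic p-value, used to
#' compare precursor m/z distributions (e.g. +1 Da shifts localized to
#' asparagine against all +1 Da shifts).
#'
#' @param sample_a,sample_b nonempty numeric vectors.
#' @return `list(D, p)`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop("both samples must be nonempty")
  }
  res <- suppressWarnings(ks.test(sample_a, sample_b, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value)
}
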