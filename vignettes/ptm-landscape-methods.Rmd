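---
title: "Methods: from open-search PSMs to a temporal PTM landscape"
author: "ptmlandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from open-search PSMs to a temporal PTM landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmlandscape)
library(data.table)
```

## The problem

Open (unrestricted) modification searches assign MS/MS spectra to
peptides while allowing an arbitrary integer mass shift in a wide window
(here −200 to +200 Da, one modification per peptide-spectrum match).
Applied to a deeply sampled bacterial growth curve — nine timepoints from
early exponential growth (3 h) to deep stationary phase (336 h), in three
biological replicates — this produces, for every protein position, paired
counts of modified and unmodified observations without any
modification-specific enrichment step. Those paired counts are what make
stoichiometry estimates and temporal comparisons possible, and this
package implements the postprocessing that turns raw PSM tables into
them: FDR filtering, proteome-coordinate mapping, global summaries,
exact-test enrichment at protein termini and between growth phases, and
temporal trajectories.

## The statistical core

**FDR from match probabilities.** The search engine reports a
correct-match probability $P_i$ per PSM. PSMs are ranked by $P_i$
descending and the estimated false discovery rate of the top-$k$ prefix
is the running mean $\mathrm{FDR}(k) = \frac1k \sum_{i\le k} (1 - P_i)$.
`fdr_threshold()` retains the *largest* prefix whose running mean does
not exceed the target $\alpha$ (default 0.01). The running mean is not
monotone in $k$, so "largest admissible" and "first crossing" differ;
we take the largest, which maximizes retained data at the stated error
level. Ties in probability are kept in input order (stable sort), so
results are permutation-invariant in the quantities that matter ($k$ and
the achieved FDR). The whole dataset is thresholded as one pooled list —
modified and unmodified PSMs compete in the same ranking — with a
per-sample mode behind `by_sample = TRUE`.

**Cysteine correction.** Iodoacetamide treatment fixes +57 Da
carbamidomethylation on cysteine, and the search treats that as the Cys
baseline. Any variable shift reported at a Cys is therefore 57 Da short
relative to other residues; `apply_cys_offset()` adds it back once, at
ingestion, guarded by an attribute so a second application is an error.
Corrected shifts may leave the searched window (e.g. the +209 Da
carbamidomethyl-DTT adduct).

**Position counts.** Each uniquely-mapping PSM of length $L$ contributes
one modified count at its modified protein position and $L-1$ (or $L$,
if unmodified) unmodified counts at the other covered positions. A
residue modified by some *other* shift still counts as unmodified
evidence at every position except its own. Peptides matching no protein
or more than one site are excluded and logged (`--ambiguous keep`
reverses the latter); exclusion avoids double counting in enrichment
denominators at the cost of discarding shared peptides, and is a
documented deviation knob because the original analysis does not state
its policy.

**Terminal and phase contingency tables.** For a mass shift $s$, the
terminal test restricts to positions with at least one $s$-PSM in the
replicate and compares modified : unmodified counts at terminal versus
all other qualifying positions (two-sided Fisher). The growth-phase test
does the same per (shift, residue) pair, pooling timepoints
{3, 4, 5, 6} h as exponential and {24, 48, 168, 336} h as stationary;
the 8 h transition sample is excluded. Direction comes from the
log-odds, with a Haldane +0.5 applied to all cells only when a cell is
zero (the correction never touches the p-value).

**Exact test in log space.** `fisher_exact_two_sided()` sums
hypergeometric point probabilities (margins fixed) of all tables no more
probable than the observed one, within $10^{-7}$ relative slack — the
point-probability convention used by mainstream scientific software.
Accumulation happens in log space (`dhyper(log = TRUE)` + log-sum-exp),
so p-values remain exact down to the smallest normal double
(~$10^{-308}$); anything below is reported as 0, matching how such
values are printed in practice. The test suite checks this
implementation against full enumeration for every 2×2 table with
$N \le 40$ and against `stats::fisher.test` on random tables.

**Multiple testing and replicate consistency.** Within each replicate,
p-values are Benjamini–Hochberg adjusted across keys. We implement BH as
the classical *step-up* procedure even though the original description
says "step-down": "Benjamini–Hochberg" canonically denotes step-up,
and a true step-down pass with the same thresholds would be
anti-conservative. A step-down variant is exposed
(`bh_filter(method = "step_down")`) for comparison. A key is
*consistent* when it passes in all three replicates — raw $p < 0.05$ for
the terminal analysis, within-replicate BH $q \le 0.05$ for the phase
analysis, following each analysis' own convention; both modes are
switchable because the original wording differs between the two
sections.

**Bias score.** For each shift, the single-amino-acid bias is
$B = (U_m + 1)/(\bar U_{nm} + 1)$, where $U_m$ is the count of unique
modified positions on the most-targeted residue and $\bar U_{nm}$ the
mean over the other 19. Unique positions (each protein position counted
once per shift) damp single abundant sites.

## Temporal analyses

Fractional modification $N_{mod}/(N_{mod}+N_{unmod})$ is computed per
timepoint for any position-level or (shift, residue) pooled key with at
least one modification in the replicate. A 0/0 timepoint is encoded as
`NA` (unobserved), never 0, so plots and tests can distinguish
"unobserved" from "unmodified". Replicate averaging averages *counts*,
not fractions, which avoids 0/0 artifacts and matches how retention
curves are usually drawn.

Retention curves pool N-terminal positions bearing +42 Da
(Nt-acetylation), split by the penultimate residue — the residue exposed
by initiator-Met cleavage — and discriminate two explanations of rising
stationary-phase stoichiometry: rising modified counts with flat
unmodified counts (increased acetylation activity) versus falling
unmodified counts with flat modified counts (preferential retention of
the acetylated form). `classify_retention()` encodes this with 1.5-fold
ratio thresholds on the stationary/exponential mean-count ratios; the
thresholds are coarse by design, intended to separate the two planted
scenarios rather than to grade intermediate mixtures, which it labels
`"mixed"` or `"stable"`.

Normalized position densities use $(pos - 1)/(L - 1)$ so the N terminus
maps to exactly 0 and the C terminus to exactly 1 (the convention is
ours; the original figures do not state one). Sequence-logo inputs are
±5-residue windows around the top-50 modified positions (ranked by PSM
count, ties broken by protein id then position), padded with `X` at
protein boundaries so Nt-proximal sites remain representable; duplicate
windows are kept.

### N-terminal methionine cleavage

Mature N termini frequently lack the initiator methionine without the
annotation saying so. We never edit the annotated sequence; instead
`annotate_termini()` *widens* N-terminal status to position 2 when the
protein starts with Met and at least one observed peptide starts there.
This recovers acetylation at penultimate residues (the SecB-like case)
at the cost of occasionally flagging a genuine internal position 2.

## The synthetic data generator

`sim_config()` + `simulate_dataset()` emulate the study's design: 9
timepoints × 3 replicates, an E. coli-like background amino-acid
composition, fully-tryptic digestion after K/R but not before P with up
to 2 missed cleavages, peptides observable between 6 and 40 residues,
protein-level log-normal abundance, per-protein Bernoulli initiator-Met
cleavage (probability 0.5), and per-PSM probabilities from a
correct/incorrect mixture (95% correct matches with error
$1-P \sim \mathrm{Beta}(1, 199)$, incorrect matches uniform on [0, 1]) —
chosen so that a 1% FDR threshold retains essentially the correct
component. Precursor m/z derives from monoisotopic masses at charges
2–3, and a small m/z-dependent rate of spurious +1 Da calls emulates
the ¹³C isotope-peak confound.

Planted modification regimes define the biological signal. Each regime
targets a residue type, the mature N terminus, or the C terminus; picks
a modifiable subset of sites once (`site_fraction`); and modifies them
at a per-timepoint rate that is constant, steps up (or down) at
stationary onset, or grows linearly along the timepoint axis ("clock",
emulating cumulative nonenzymatic damage such as Asn deamidation).
`degradation_bias > 1` thins unmodified copies of target peptides in
stationary phase, emulating preferential degradation of the unmodified
form; because thinning removes sampled copies, `depth` is the expected,
not exact, stationary-phase sample size. One modification per PSM is
enforced the way the search would: every covered modifiable site tosses
its coin and one success is kept uniformly. A consequence worth knowing
is that when a peptide covers $k>1$ modifiable sites at rate $r$, the
per-site marginal is $(1-(1-r)^k)/k < r$; parameter-recovery checks
therefore use sparse site fractions (~0.1) where $k$ is almost always 1.

Default regime rates mirror the study's reported signals (step-up Nt
acetylation 0.30→0.55, clock-like Asn deamidation 0.01→0.06, constant
Met oxidation 0.05, exponential-biased Trp oxidation 0.04→0.017,
C-terminal glutamylation 0.25 on 15% of termini, plus rare internal
+42/K and +129/E so the terminal tests have an out-group stratum, as
they do in real data). What the generator does *not* model: spectra
(only their tabulated outcome), retention time and intensity,
isobaric co-elution, position-dependent detectability, shared peptides
between paralogs, and multi-modified peptides. Passing the planted
recovery tests therefore validates the bookkeeping and the statistics,
not the search engine itself.

## Numerical and design choices

* All randomness descends from one integer seed; the proteome and the
  PSM sampler use adjacent seed streams, so datasets are byte-identical
  across runs.
* Timepoint axis fixed to {3, 4, 5, 6, 8, 24, 48, 168, 336} h. (One
  description of the source sampling lists eight timepoints without 6 h;
  every reported analysis uses nine, and so do we.)
* Report tables print p-values at 3 significant digits; underflowed
  exact p-values print as 0.
* Problem sizes used by the validation suite — chosen as the smallest
  sizes at which the planted effects are comfortably detectable:
  enrichment recovery at 40 proteins × depth 3000–5000 PSMs/sample;
  null calibration at 100 seeded runs of 20 proteins × depth 400;
  retention classification at 20 seeded runs of 25 proteins × depth
  1000.
* The bias-score alphabet is fixed to the 20 standard residues;
  records containing B/J/O/U/X/Z are rejected at ingestion.

## Known limitations

* Percentages printed for individual mass shifts in the source results
  (e.g. "+1 Da, 45% of modified PSMs") use an unclear denominator; we
  report counts and fractions of modified PSMs and do not attempt to
  match them.
* Peptides mapping to multiple sites are dropped by default; proteomes
  with large duplicated families will lose coverage (switchable, at the
  cost of double counting).
* The KS comparison of m/z distributions uses the asymptotic p-value;
  with ties from integer-binned masses it is approximate (the original
  comparison operates at sample sizes where this is immaterial).
* `fdr_threshold()` trusts the reported probabilities; no recalibration
  or decoy-based validation is attempted (decoy FDR is out of scope).

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_proteins = 40, depth = 3000, seed = 11)
ds <- simulate_dataset(cfg)
recs <- apply_cys_offset(ds$psms)
fdr <- fdr_threshold(recs, alpha = 0.01)
pcm <- annotate_termini(accumulate_counts(fdr$retained, ds$proteome),
                        ds$proteome)
terminal_enrichment(pcm, "Nt")[consistent == TRUE]
phase_enrichment(pcm)[consistent == TRUE]
fractional_trajectory(pcm, 1L, aa = "N", scope = "replicate_mean")
```

The same flow, driven by files and a config object, is
`run_pipeline(pipeline_config(psms, fasta, outdir))`; see the README for
the report bundle it writes.
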