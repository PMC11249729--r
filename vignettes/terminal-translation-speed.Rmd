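---
title: "Encoded translation speed at gene termini: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoded translation speed at gene termini}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonramp)
```

## The scientific problem

The first few dozen codons of eukaryotic protein-coding genes are, on
average, slightly enriched for rare codons, which are also slow codons.
Because the effect is encoded — it survives in the sequence itself, not just
in ribosome-profiling signal — it invites two opposite readings. The
adaptive reading ("ramp") holds that slow starts are selected for, to queue
ribosomes tidily. The non-adaptive reading ("young spandrel") holds that
gene termini turn over rapidly in evolution: a terminus formed recently from
new sequence has had less time under selection, so rare, slow codons that
selection would eventually purge are still present. The second reading makes
a bundle of correlated predictions — slow starts should co-occur with poor
terminal conservation, low expression, and low ribosome density, and a
symmetric (weaker) effect should appear at the 3' end — and this package
implements the statistics needed to test all of them, plus a generator that
produces data under the turnover model with known effect sizes.

## The speed model: ribosome residence time

Per-codon speed is taken from a ribosome residence time (RRT) table: one
positive dimensionless occupancy value per sense codon, measured by ribosome
profiling (higher = slower; measured tables span roughly a three-fold
range). The package treats the table as an input (`load_rrt_table()`), never
recomputes it, and refuses to look up stop codons: every statistic here is
about sense-codon encoding. `neutralize()` returns a copy of a table with
chosen codons set to a neutral residence time (default 1.0189), which is how
the contribution of Start-like codons (ATG, ATT, TTG, ATA — all fast, all
depleted in 5' leaders) is dissected: recompute the slowdown with those
codons made neutral and see how much survives.

## The RIT statistic

For a gene with stop codon at position $N$ and window $W$:

$$\mathrm{RIT} = \log_2\!\left(
  \frac{\overline{\mathrm{RRT}}(\text{codons } 2..W)}
       {\overline{\mathrm{RRT}}(\text{codons } W{+}1..N{-}1)}\right)$$

Codon 1 is omitted because essentially every gene starts with ATG, an
unusually fast codon that would bias the ratio; the stop codon has no
residence time. The numerator therefore holds $W-1$ codons — the window
parameter is the last included position, not a count, so reporter analyses
that cover a 41-codon leader use `window = 41`. The 3'-end variant takes the
last $W$ sense codons against positions $2..N{-}W{-}1$.

**Sign convention.** Positive RIT = slow start (the window has *higher*
residence time than the body). Genes with positive RIT are classed SIT
(slow initial translation), the rest FIT; a tie at exactly zero is FIT — a
strict inequality is deterministic and the tie has measure zero for real
tables. Note that on the reciprocal "speed" scale a slow start is a ratio
below one; `genomewide_slowdown(..., scale = "speed")` reports that scale,
which differs slightly from the RRT scale (harmonic-vs-arithmetic mean
effect, about 0.1 percentage points at realistic effect sizes).

`genomewide_slowdown()` averages the per-gene RRT ratio,
$100 \times \overline{(2^{\mathrm{RIT}} - 1)}$ percent, and attaches a
paired two-sided Wilcoxon signed-rank test of the per-gene window mean
against the per-gene body mean. The pairing is within genes, which is why a
signed-rank test is correct here; between *different* gene groups the
package deliberately switches to the unpaired Mann–Whitney form (see below).
Gene-averaging (not pooling all codons) is the primary definition; it
weights each gene equally regardless of length.

## Codon-usage enrichment

`count_usage()` counts codons in the initial window (positions $2..W$), the
rest ($W{+}1..N{-}1$), or the whole gene after the initiator; the stop and
position 1 are never counted, so the two regions partition the "whole"
region exactly. `enrichment_ratios()` compares relative frequencies over all
61 sense codons — not within amino acids — because the question is about raw
usage in the window versus the body; `per_aa_frequencies()` provides the
within-amino-acid view separately. A codon never seen in the body has an
undefined ratio and is reported as `NA` rather than smoothed with a
pseudocount: inventing a smoothing constant would manufacture data.

## Terminal conservation scores

Conservation of a 40-aa window is scored from protein BLAST tabular output
against a panel of related species:

* a species **qualifies** if it has any HSP with bit-score ≥ 50;
* a qualified species **contributes** the number of window positions covered
  by the union of its HSP query intervals with bit-score ≥ 200 (the
  high-homology "red" regions of the BLAST graphic summary) — a qualified
  species with no such region contributes 0;
* the **score** is the mean contribution over qualified species: 0 (no
  homology in the window anywhere) to 40 (every species matched from the
  window's first position).

The bit-score reading of the "alignment score ≥ 200" band is a deliberate
choice: tabular BLAST output carries bit-scores, and the graphic-summary
colour key bins by that score; both thresholds are exposed as parameters.
Records based on fewer than 40 qualified species are flagged
`too_few_species` and proteins shorter than 100 aa `too_short`, rather than
silently scored.

Coordinates are 1-based closed intervals (an HSP `[35, 60]` covers positions
35..40 of the N window, contributing 6). Because local alignment finds
homology more easily mid-sequence than at sequence edges, each protein is
split at $\lfloor M/2 \rfloor$ and each half BLASTed separately; the
"middle" window is the first 40 residues of the second half (displaced 20 aa
from the true middle), so the algorithm faces the same edge-seeding problem
for N, middle and C windows alike. Second-half query coordinates are shifted
by $+\lfloor M/2 \rfloor$ before scoring. The alternative middle window (the
last 40 residues of the first half) is available via
`window_scheme(..., middle = "end_of_first_half")`. Multiple database
submissions of one species are collapsed to the subject with the best HSP
bit-score per (query, half, species), ties to the lexicographically smallest
subject id for determinism.

The implementation computes per-species interval unions; the test suite
checks it against an independent brute-force oracle (per window position,
the fraction of qualified species covering that position, summed) on a
thousand random HSP configurations, where the two formulations must agree
exactly.

## Grouping and correlation

`tertile_split()` ranks genes ascending and cuts the list into thirds;
when $n \bmod 3 \neq 0$ the spare genes go to the top-most groups — any
fixed rule works, but one must be fixed for reproducibility. Ties in the
ranking value are broken by gene id, so constant inputs still split
deterministically. `compare_groups()` runs the three pairwise two-sided
Mann–Whitney tests with Holm–Bonferroni correction. Using the unpaired form
between tertiles is a deliberate divergence from a blanket "signed-rank"
prescription: tertiles contain different genes, so there is no pairing to
exploit, and a signed-rank test would be invalid there. Genes missing from
the response table are dropped and counted, and an emptied group is an
error, not a silent degenerate comparison. Spearman correlation (average
ranks for ties) and the two-sample Kolmogorov–Smirnov test complete the
toolkit; all are the standard R implementations, surfaced with gene-id
intersection handling.

## The reporter recoder

`recode_window()` rewrites codon positions $2..W$ (default $W = 41$) of a
source gene with synonyms: `fast` takes the per-position minimum RRT,
`slow` the maximum, `medium` the synonym closest to the neutral value.
Because the objective is separable across positions, the per-position
extremum is the global extremum for the window mean — which is why the test
suite can assert optimality rather than merely improvement. Ties break to
the lexicographically smallest codon; recoding is fully deterministic. With
`avoid_starts = TRUE` (default) the recoder refuses to *introduce* Start-like
codons when any alternative synonym exists, mirroring their depletion in
natural leaders (methionine keeps ATG — it has no alternative).
`insert_collision_pair()` plants CGA-CGG (a rare, slow arginine pair that
strongly attenuates expression, believed to stall and collide ribosomes) at
a chosen position, replacing what is there — in the reporter design it
replaces the Asn-Asp pair AAT-GAT, changing the protein, which is intended.
`construct_report()` reports each construct's leader mean RRT and RIT;
because published leader averages do not always state whether the initiator
codon was included, the report exposes both conventions (`from = 1` or
`from = 2`).

## The synthetic-data generator

The generator exists so every stage is testable offline with known truth,
and its defaults are fixed study conditions, not tuning knobs.

**Genome model.** Amino acids are drawn from a configurable composition
(uniform over the 20 by default); each gene starts with ATG and ends with a
random stop. Body codons follow a one-parameter Boltzmann-style selection
family, $P(c \mid aa) \propto e^{-s\,\mathrm{RRT}(c)}$: $s = 0$ is
neutrality, larger $s$ purges slow codons harder. With probability $\tau$
a gene's terminus is "young": codons at positions $2..K{+}1$ (default
$K = 40$) are drawn uniformly among synonyms. The model is invented but
minimal — the turnover hypothesis itself prescribes no generative family —
and its virtue is that the expected slowdown is closed-form:
$\delta = 100\,\tau\,(E_u[\mathrm{RRT}]/E_s[\mathrm{RRT}] - 1)$ where
$E_u$ and $E_s$ are the uniform-regime and selected-regime mean residence
times blended over the amino-acid composition. `calibrate_selection()`
inverts this to find the $s$ producing a requested $\delta$, and
`expected_slowdown()` refines the expectation by conditioning on which genes
actually turned over and adding the second-order Jensen term
$E[\text{num}/\text{den}] \approx (E\text{num}/E\text{den})
(1 + \mathrm{Var}(\text{den})/E(\text{den})^2)$ for the finite body window —
without that term the closed form is biased by a few hundredths of a
percentage point, which matters when checking recovery of a 0.5% effect.
Gene lengths default to a truncated lognormal centred near 350 codons
(minimum 101 so every gene passes the 100-aa analysis filter), a realistic
ORF-length scale. 3'-end turnover is available symmetrically with its own
$\tau$.

**Homology model.** Per species, one subject with a single homology block
running from a sampled terminal-loss offset to the end of the query half,
with bit scores sampled around a configurable mean; blocks below the
200-bit threshold make their species qualify without contributing coverage.
The generator records each window's exact coverage by direct interval
arithmetic, so conservation scoring can be checked against the generator's
own bookkeeping, and degenerate settings (all offsets 1; all offsets past
the window) pin the extreme scores 40 and 0.

**Value tables.** Gene-level expression or density values couple to minus
the gene's expected terminal slowdown with Gaussian noise, so positive
coupling yields the empirically observed pattern: highly expressed genes
have fast, selected termini. Read counts are exponentiated around a median
of ~200 and rounded, then pass through the usual minimum-count filter (10).

All generators are pure functions of (parameters, seed).

**What the generator does not emulate.** Real amino-acid composition bias,
codon autocorrelation along genes, signal-sequence arginine enrichment
(the mitochondrial/ER effect), phylogenetic correlation between species in
the homology panel, indels, and any coupling between expression and codon
usage beyond the single covariate. Tests passing on generator output
therefore validate the statistical machinery and its calibration — not the
biological conclusions on real data, which require the measured
residence-time table and a pinned ORF release as external inputs.

## Numerical and edge-case choices

* The 303-nt minimum gene length (100 aa + stop) is applied inclusive of
  the stop codon, and the boundary is kept.
* Genes whose length is not a multiple of 3 are skipped with a warning;
  an empty FASTA is a hard error. Non-ATG starts, missing stops and internal
  stops are recorded as flags at load; only profile computation treats an
  internal stop as fatal.
* A degenerate slowdown input (all per-gene differences exactly zero)
  reports $p = 1$ rather than erroring inside the signed-rank test.
* Wilcoxon/Mann–Whitney tests use the normal approximation
  (`exact = FALSE`) throughout: gene-set sizes make exact enumeration
  pointless and ties are ubiquitous.
* U→T and case normalisation happen at the IO boundary, so mRNA-style
  inputs are accepted everywhere.
* Conservation coverage uses closed 1-based intervals and interval-union
  arithmetic; splitting an HSP into abutting pieces cannot change a score.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run entirely on generated
data: 5000-gene genomes for effect-size recovery at $\delta \in \{0.5, 1,
3\}\%$ (plus a calibrated 1.2% condition matching the effect size reported
for yeast), 1000 replicates of 200-gene null genomes for the size of the
paired test, 1000 random HSP configurations for oracle equivalence, and
1000 random proteins for recoder optimality. These sizes give Monte-Carlo
confidence intervals tight enough to detect calibration errors of a few
hundredths of a percentage point while keeping a full run in the low
minutes on one core.

## Known limitations

* Real-data headline numbers (the ~1.2% first-40 slowdown, 57% SIT
  fraction, 5694-ORF dataset, conservation-score distributions) depend on
  externally distributed inputs (a measured RRT table, a pinned ORF
  release, BLAST campaigns) and are not recomputable from this package
  alone; the package provides the loaders and statistics to reproduce them
  when those inputs are present.
* The conservation score treats species as exchangeable (equal weights); no
  phylogenetic down-weighting of related species is attempted.
* The recoder optimises the window mean only; it ignores mRNA secondary
  structure, which is a known confounder of leader recoding experiments.
* Whether the 200-unit homology threshold in the source analyses was a raw
  or bit score cannot be settled from published text; the bit-score reading
  is used and the threshold is a parameter.
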