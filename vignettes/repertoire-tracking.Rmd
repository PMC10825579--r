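---
title: "Methods: tracking VHH repertoire evolution and predicting responsive clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking VHH repertoire evolution and predicting responsive clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model behind
each stage, the tunable parameters and why their defaults are what they
are, the choices made where the design was genuinely open, what the
simulator does and does not emulate, and the known limitations.

## The biological model

An immunized camelid mounts germinal-center responses in which B-cell
lineages expressing antigen-binding VHH domains proliferate and
somatically hypermutate. Sampling blood at successive weeks and
amplicon-sequencing the VHH repertoire per isotype (IgG2 short hinge,
IgG3 long hinge) gives a time-resolved picture of every abundant
lineage. Two observable signatures separate antigen-responsive lineages
from bystanders:

* **Mutation accumulation.** A responsive lineage enters the response
  close to its germline V gene and drifts away from it week by week.
  Scoring every member sequence against its assigned germline V gene by
  local-alignment bit score, and regressing that score on the week the
  sequence first appeared, a responsive lineage shows a *negative
  slope* (ongoing mutation) and a *high intercept* (germline-like
  founder). A lineage matured before this immunization starts already
  far from germline: low intercept, flat slope.
* **Clonal turnover.** Under active selection, newly arisen clones keep
  displacing the previously dominant clone of their lineage. A lineage
  whose dominant clone never changes is not being selected on.

The pipeline quantifies both signatures per sequence cluster (a proxy
for a clonal lineage) and predicts a cluster to contain
antigen-responsive clones when the slope is negative, the intercept
exceeds a threshold, and turnover is observed.

## Stage by stage

### Read preprocessing

Paired mates are quality-trimmed by the modified-Mott rule: per-base
error probabilities $p_i = 10^{-Q_i/10}$ are converted to scores
$\ell - p_i$ (error-probability limit $\ell = 0.01$) and the
maximal-sum contiguous segment is retained; on ties the earliest,
shortest segment wins, and a read whose best segment scores $\le 0$ is
discarded. Mates are merged by scanning every gapless overlap offset of
the forward read against the reverse complement of the reverse read,
scoring matches $+1$ and mismatches $-2$, and accepting the best
overlap when it scores at least 8. At overlap mismatches the base with
the higher Phred quality wins, ties to the forward mate. The overlap
search is gapless by design: amplicon mate overlaps derive from a
single molecule and are essentially never gapped, and the retained
`gap_cost = 3` parameter documents the full scoring contract. The 3'
constant-region stub (21 nt IgG2 / 24 nt IgG3) is then removed, and a
sequence is kept only if it contains no ambiguous base, has length
divisible by three, and translates stop-free in frame 1 — frame 1
because both amplification primers begin at codon boundaries.
Pre-merged FASTA or sequence–frequency TSV inputs bypass this stage
entirely.

### Frequency-driven error cleanup

Sequencing errors scatter reads into low-frequency satellites of their
true parent. The cleanup loop repeatedly takes the most frequent
sequence as reference (RS; frequency ties broken by lexicographically
smallest sequence, for determinism), collects every same-length
sequence within Hamming distance $n$ of it, and sums their frequencies
into the RS unless they are recognizably real variants. $n$ widens with
RS frequency (3 for 2–400, 4 for 401–1,000, 5 above 1,000): an abundant
parent seeds proportionally more multi-error copies. A member whose
frequency ratio to the RS strictly exceeds the independence threshold
$r$ for its number of changes (8%, 3%, 1%, 0.2% for 1, 2, 3, $\ge 4$)
is an *independent* sequence; members whose substitution pattern
contains an independent's pattern are its *derivatives*. Both are left
in the table and processed in later iterations. The loop stops when the
top frequency is 1; untouched singletons pass through. Total frequency
is conserved exactly, and the output is byte-identical across runs.

Two points were genuinely open and are settled here:

* **"Same differential patterns"** for derivatives is read as pattern
  *superset*: a sequence carrying all of an independent variant's
  substitutions plus extras descends from that variant, not from the
  RS. An exact-equality mode exists (`derivative_mode = "exact"`) but
  equality of full patterns can only match the independent itself.
* **Frequency-1 members are never ruled independent**
  (`min_independent_freq = 2`; set 1 for the literal ratio-only rule).
  The independence thresholds exist to rescue *major* co-circulating
  variants. A sequence observed once cannot be distinguished from a
  sequencing error by any ratio; mechanically, a three-error singleton
  of a parent observed fewer than 100 times would exceed the 1%
  threshold and survive as a phantom variant. With the default, exact
  recovery of simulated ground truth is essentially perfect at
  realistic error rates.

"Base changes" are positional substitutions between equal-length
sequences; different-length sequences are never integrated. This is
deliberate: downstream clustering groups by exact length, and the
substitution-only reading gives the pattern algebra (subset/superset)
a precise meaning.

### Chronology and identifiers

Cleaned weekly tables of one isotype are full-joined on sequence
(absent weeks are zero), a maximum-frequency column is added, and rows
are numbered S1, S2, … (IgG2) or L1, L2, … (IgG3) in descending maximum
frequency. Ties are broken by earlier first-appearance week, then by
sequence, so identifiers are invariant to input order. The two isotype
tables are stacked; the same nucleotide sequence may legitimately
appear once per isotype. Irregular week sets (e.g. sampling at weeks
0, 3, 5, 9) are fully supported — downstream regression uses the
actual week values.

### Germline assignment and the bit-score scale

Each unique sequence is aligned by Smith–Waterman (affine gaps, full
dynamic program in C++) against every germline V gene, and over its
3'-terminal 60 nt against every J gene; the highest-scoring gene wins,
ties to database order. Ranking by bit score is equivalent to ranking
by smallest e-value for a fixed query and database. The default
nucleotide scoring is match $+2$ / mismatch $-3$, gap open 5 / extend
2, with Karlin–Altschul parameters $\lambda = 0.625$, $K = 0.41$ — the
conventional statistical parameters for that scoring — giving
$\text{bits} = (\lambda \cdot \text{raw} - \ln K)/\ln 2$. Absolute bit
scores are calibration-dependent: all thresholds quoted in bits
(notably the 380-bit intercept threshold) are interpreted on this
scale and exposed as parameters. `calibrate_bitscore_mutations()`
rebuilds the bits-per-amino-acid-mutation curve for any germline
database; under the defaults one amino-acid mutation (a codon swapped
to a different residue, typically 1–3 nucleotide changes) costs about
7–10 bits, so a 300-nt V gene spans roughly 540 bits (unmutated) down
to ~340 bits at 30 mutations. Sequences whose best V raw score falls
below 20 are flagged unassigned and excluded with a warning.

### Cluster isolation

Sequence "loneliness" is measured by U40: the number of *other*
equal-length unique sequences differing by fewer than 40 bases. The
reference itself is excluded from its own count (inclusion would shift
every value by one and only matters at the filter boundary). Rows with
maximum frequency 1 are dropped first — except sequences on the
protected list, e.g. clones identified empirically by phage display —
then rows with U40 < 10; U40 is computed on the full unfiltered table,
and the max-frequency filter is applied before the U40 filter, in the
order stated. Survivors are grouped by (exact length, V gene, J gene);
groups under 8 unique sequences are removed. Within a group, pairwise
distances use the Jukes–Cantor closed form $d = -\tfrac34 \ln(1 -
4p/3)$ on the proportion $p$ of differing sites (group members share
exact length, so gap-free positional differences are exact; distances
saturate to $\infty$ at $p \ge 0.75$). Sequences at $d \le 0.04$ are
linked — the threshold is inclusive, since only distances *surpassing*
it disconnect — and connected components with more than seven members
become clusters. Components are extracted by graph connectivity, not
by literally zeroing large distances, which would conflate "far" with
"identical". Any cluster containing a sequence observed at week 0 is
discarded: the animal was not pre-exposed, so week-0 lineages are
responses to something else. Clusters are ranked by their maximum
weekly summed member frequency and named `<prefix>-1`, `<prefix>-2`, …
Neighbor-joining trees of the JC69 matrix are available per cluster as
newick.

### Trajectories and hit calls

Each cluster member contributes one trajectory point per isotype at
its week of first appearance with its V-gene bit score. The regression
is unweighted per unique point — abundance is annotation, not weight —
with a frequency-weighted mode (`weighted = TRUE`) for sensitivity
analysis. The intercept is the fitted value at week 0. A cluster whose
points all share one first week has an undefined slope and fails the
slope criterion by convention (flagged, not silently dropped).

Turnover is qualitative in origin ("newly appearing sequences should
predominate weekly") and is formalized here as: for each week the
cluster is present, find the dominant member (largest pooled
IgG2+IgG3 frequency; ties to the lexicographically smaller sequence)
and its first-appearance week; the turnover index is the Spearman rank
correlation between calendar week and dominant first week. The
criterion passes when the index is positive and at least 3 distinct
sequences dominate — both configurable, and the raw dominant timeline
is returned so users can apply their own rule.

Percentage appearance of a cluster in a week is the sum of its
percentage occupancy within IgG2 and within IgG3 (so the ceiling is
200%, matching the definition as a sum of two per-isotype
percentages); a pooled-count mode with ceiling 100% is available
(`mode = "pooled"`). The maximum over post-immunization weeks ranks
clusters in the report.

A predicted hit is the conjunction: slope $< 0$, intercept $> 380$
bits, turnover pass. The intercept threshold is exposed
(`intercept_threshold`), since it is tied to the alignment-scoring
calibration above.

## The simulator

`simulate_study()` draws a germline database (random stop-free V genes
~300 nt, pairwise > 60 substitutions apart; J genes ~48 nt) and three
kinds of lineages, each with a random V/J pair, a random in-frame
junction (15–45 nt), an isotype assignment (both isotypes with
probability 0.5), and a log-normal abundance weight:

* **Responding** (default 15): first seen at one of the first three
  post-immunization timepoints, founded 0–2 amino-acid mutations from
  germline, gaining Poisson(`mutation_rate`) amino-acid mutations per
  week along a clone chain (rates drawn uniformly from 0.5–2 per
  lineage), each week's newest clone replacing the dominant with
  probability `turnover_prob = 0.6`, plus weekly minor sibling clones
  that populate the local mutational neighborhood.
* **Static** (default 15): founded `pre_maturation = 30` amino-acid
  mutations from germline — which places their intercepts around
  200–340 bits, the profile of a lineage matured before this
  immunization — with a fixed set of 11 satellite clones at least 4 nt
  from the founder (so the denoiser's independence rule, not luck,
  preserves them) and a permanently dominant founder.
* **Pre-immune** (default 5): static lineages already present in the
  week-0 sample, exercising the week-0 discard.

Weekly per-isotype samples draw `depth = 10,000` reads multinomially
over active clones (dominant weight 0.6), then inject per-copy
sequencing errors at `seq_error_rate = 0.001` per base, at most 3 per
copy — a typical error level for merged amplicon consensus reads.
Amino-acid mutations are implemented as codon replacements to a
different residue, so one mutation changes 1–3 nucleotides.

What the simulator does *not* emulate — and hence what passing tests
do and do not show about real data: no indels (clustering groups by
exact length; an indel-bearing real lineage would fragment across
length groups), no PCR chimeras or primer artifacts, no affinity-based
selection coefficients (turnover is a coin flip, not a fitness
process), no shared mutational hotspot structure between lineages, and
sequencing errors are uniform substitutions rather than
quality-correlated. Results on simulated data validate the *machinery*
— exact filter semantics, conservation, ranking, recovery of planted
dynamics — not the biological error model of any particular
instrument.

## Numerical choices and degenerate inputs

* All tie-breaks are fixed (RS choice, ID ordering, dominant-member
  choice, cluster ranking), making every stage byte-deterministic.
* Empty tables, empty isotypes, single-week clusters, saturated JC69
  distances ($p \ge 0.75 \to \infty$), and unassignable sequences all
  have defined, tested behavior rather than errors.
* The Smith–Waterman kernel uses integer arithmetic throughout; bit
  scores are exact transforms of integer raw scores.
* OLS is delegated to `stats::lm` and agrees with the closed-form
  normal equations to well below $10^{-9}$.

## Validation problem sizes

The shipped test-suite exercises: exact threshold tables; frequency
conservation on 1,000 random tables; exact ground-truth recovery on
100 seeded error-injection experiments (20 parents, frequencies
50–5,000, pairwise Hamming ≥ 10, 0.3% per-base per-copy errors); U40
against an all-pairs oracle on 50 random 200-sequence tables; JC69
closed-form and 0.04-threshold edge values; component extraction
against brute-force transitive closure on 50 random graphs; regression
against the normal equations on 100 random point sets; and end-to-end
recovery of planted responding/static/pre-immune labels on 20
full-scale simulated studies (35 lineages, 15 weeks, 10,000 reads per
sample), requiring ≥ 90% balanced accuracy and zero pre-immune
leakage.

## Known limitations

* Absolute bit-score thresholds do not transfer across alignment
  scorings; recalibrate (or use the data-driven midpoint of labelled
  hit/miss intercepts) when changing scoring parameters.
* Indel-bearing lineages fragment across length groups; an MSA-based
  indel-tolerant mode is a natural extension but is not part of the
  validated path.
* The turnover formalization is one defensible reading of a
  qualitative criterion; the raw dominant timeline is reported so
  alternatives can be applied downstream.
* D-gene segments are too short to call reliably and are not used for
  grouping.
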