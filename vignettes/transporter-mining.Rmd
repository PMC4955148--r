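---
title: "Mining and characterizing substrate-specific sugar transporters with spminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and characterizing substrate-specific sugar transporters with spminer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spminer)
```

## The problem

Filamentous fungi such as *Aspergillus niger* and *Trichoderma reesei*
take up pentoses like D-xylose through secondary transporters of the major
facilitator superfamily (MFS), sugar-porter subfamily. Most members of
that subfamily are glucose carriers, and genome annotations rarely say
which of the dozens of sugar porters in a proteome actually move xylose.
`spminer` implements the computational arm of a discovery workflow for
this situation:

1. train a function-specific profile hidden Markov model on a curated
   alignment of functionally validated xylose transporters;
2. score every protein of a proteome by Forward log-odds and keep the
   top-ranked candidates;
3. cluster the candidates with a neighbor-joining tree plus bootstrap
   supports, collapsing weakly supported nodes;
4. tabulate the sequence features known to discriminate substrate
   specificity (the first-transmembrane-span GG/FXXXG motif and its
   substrate-specific variants, the TM7 YFFYY peptide, and individual
   residues mapped through the alignment);
5. screen 1-kb upstream regions for a regulator binding motif (the
   XlnR/Xyr1 consensus by default); and
6. fit the biochemical read-outs that validate candidates: Michaelis-
   Menten uptake kinetics (Km, Vmax) from radiolabel assays and specific
   growth rates from OD time courses.

A synthetic-data module generates protein families, planted-homolog
proteomes, uptake assays and growth curves with known ground truth, so the
whole pipeline is testable without any downloads.

## The profile HMM

The model follows the classic profile architecture: one node per match
column of the training alignment, each node carrying a match state (20
emission probabilities), an insert state, and a delete state, with all
nine transition types between consecutive nodes. A column is a match
column iff its gap fraction is at most `match_gap_threshold` (default
0.5).

Emission probabilities for match state $j$ are

$$e_j(a) = \frac{c_j(a) + \alpha\,20\,q_a}{\sum_b c_j(b) + 20\alpha},$$

where $c_j(a)$ are weighted residue counts, $q_a$ is the background
frequency and $\alpha$ (default 0.5) is a Laplace-style pseudocount: with
a uniform background every residue receives $+\alpha$. Insert states emit
the background. Transition probabilities are weighted observed
state-path counts with $+\alpha$ per allowed transition. Sequence weights
are Henikoff position-based by default, so near-duplicate training
sequences do not dominate the counts.

Scores are log-odds in bits against an i.i.d. background null of the same
length, computed by the Forward algorithm in log space (a best-path
Viterbi variant with its state path is available for inspection). Two
alignment modes exist:

* **glocal** — the model must align end to end;
* **local** (default) — entry/exit is uniform over ordered match-state
  pairs, probability $2/(M(M+1))$, and flanking residues are emitted at
  background (contributing zero log-odds). This is the right mode for
  mining whole proteins with a domain-sized model.

Unknown residues (`X`) score zero everywhere. The defaults (threshold
0.5, $\alpha = 0.5$, position weights, local mode, uniform background)
are deliberately transparent and are echoed into the serialized model
file; absolute bit scores from other profile-HMM implementations will
differ, and the comparable surface across tools is the *ranking*, which
is what candidate selection uses. Ranking ties are broken by ascending
sequence id so output is deterministic. No E-value calibration is
attempted: candidates are selected by score rank, and the score
distribution of decoys in the synthetic benchmarks provides the margin
check.

The correctness argument for the dynamic programs is exhaustive: on all
toy models with up to 3 match states and sequences up to 4 residues, the
Forward and Viterbi scores are compared against a linear-space
enumeration of every state path (an independent implementation in the
test suite), to a relative tolerance of 1e-9; log-space recursion keeps
scores finite for sequences of at least 10,000 residues.

## Trees

Distances are p-distances with pairwise deletion (mismatches over
columns where neither member is gapped); a Poisson correction
$-\ln(1-p)$ is available behind a flag. The paper-of-record for this
workflow did not name its distance model, so the simplest fully testable
choice is the default.

Neighbor joining is the Saitou-Nei algorithm. Three numerical choices
are fixed for determinism and printability:

* Q-criterion ties join the pair whose subtree labels (each subtree
  labeled by its smallest leaf id) are lexicographically smallest;
* negative branch-length estimates are clamped to zero with the deficit
  moved to the sister branch, the standard practice for printable trees;
* supports are kept exact internally and rounded to integer percent for
  display.

On additive matrices NJ is exact; the tests verify topology and
path-length recovery to 1e-9 on 100 random trees with up to 8 leaves.
Bootstrap supports resample alignment columns with replacement, rebuild
the tree, and count leaf bipartitions; 100 replicates by default (the
replicate count is not prescribed by the underlying study, and 100 keeps
test runs fast while giving integer-percent resolution), with a
mandatory seed. Edges with support strictly below the collapse threshold
(default 75%) are contracted into polytomies — strictly below, so a
support of exactly 75 is retained — and collapsing is idempotent.

## Motifs and conservation

Motif patterns use a minimal language: residue letters, `X` for any
residue, and `/` for a single-position alternation (`GGLXXGYD/N` means
the last position is D or N). Matching is exact and overlapping, with
1-based inclusive coordinates on the de-gapped sequence, matching the
field's "YFFYY (332–336)" citation style.

The substrate classifier tests the three 8-mer variants of the
first-transmembrane-span motif anchored at the window start — xylose
`GGLXXGYD/N`, arabinose `XGXXFGFD`, glucose `GGFXFGWG` — and falls back
to the generic `GG/FXXXG` (positions 1 G, 2 G or F, 6 G). The three
8-mers are mutually exclusive by construction, which the tests sweep.

Residue classes follow one fixed convention: aromatic {F, W, Y},
aliphatic {A, G, I, L, V, M} (methionine counted as aliphatic, its
sulfur being unreactive), polar {S, T, N, Q, C, H, D, E, K, R}, and
proline with `X` as "other" (proline fits neither an aliphatic nor a
polar reading and is kept out of both rather than forced). Conservation
reports map reference residues or windows (e.g. the D72/R164 equivalents
of a reference transporter) across all alignment members through the
alignment columns.

Promoter scanning takes IUPAC DNA motifs and scans the 3'-terminal
`region` bases (default 1000, the conventional promoter window) of each
upstream sequence on both strands via `Biostrings`; minus-strand hits
are reported at the forward (leftmost) coordinate of the matched bases.
The binding-site consensus itself is configuration: the default
`GGCTAAA` is the published XlnR consensus, but any IUPAC string can be
supplied because the exact consensus used by a given study is often
cited rather than printed.

## Kinetics and growth

Initial uptake rates from radiolabel counts are

$$V = \frac{(A - A_0)/s}{t/60\,\mathrm{min}}\cdot\frac{1}{m_{DW}}
\quad [\mathrm{nmol\,min^{-1}\,mgDW^{-1}}],$$

with activity $A$, background $A_0$ (triplicate negative controls), Bq,
specific activity $s$ in Bq nmol$^{-1}$, incubation time $t$ in seconds
(20 s in the standard assay) and dry weight in mg. Over-corrected
(negative) rates are flagged and excluded from fits by default rather
than clamped, keeping background over-correction visible.

Michaelis-Menten parameters come from nonlinear least squares on
$V = V_{max}[S]/(K_m+[S])$ (Levenberg-Marquardt via `minpack.lm`),
pooling replicates unweighted; concentrations are handled internally in
mM with µM converted on ingest, since assay tables habitually mix the
two. Initialization is $V_{max,0} = \max V$ and $K_{m,0}$ the
concentration whose rate is nearest $V_{max,0}/2$; standard errors come
from the curvature at the optimum (a seeded bootstrap could be added,
but the curvature errors match the "±" reporting convention with the
least machinery). Every fit in the test suite is checked against an
independent zooming grid-search oracle; calibration tests over 200
seeded simulations at 5% multiplicative noise require the median
relative $K_m$ error to stay within 10% and the $V_{max}$ bias within
2%.

Specific growth rates use the standard estimator: the slope of
$\ln(\mathrm{OD})$ versus time from $T=0$ to the onset of stationary
phase. "Stationary" is qualitative in practice, so a defined rule is
used: the onset is the first time point whose OD reaches 95% of the
series maximum. Degenerate inputs follow one documented convention: if
that onset leaves fewer than three points (e.g. a flat series, which
reaches 95% of its maximum immediately), the whole series is fitted, so
a constant culture yields $\mu = 0$ rather than an error; fewer than
three points overall is an error.

## The synthetic-data module

Generators are pure functions of their parameters plus one explicit
seed (no global RNG state):

* `simulate_family()` draws a uniform-random ancestor, writes planted
  motifs in verbatim, and mutates each member independently by per-site
  substitution (default 0.1) and per-site deletion (default 0.02);
  motif sites are protected. The true alignment is kept in ancestor
  coordinates, which is why insertions are not simulated — deletions
  exercise every gap-handling path while keeping planted coordinates
  exact. Defaults (length 200, 24 members) mirror a curated training
  set of two dozen validated transporters.
* `plant_homolog_proteome()` hides one held-out family member among
  i.i.d. decoys (uniform over the 20 residues by default — matching the
  scanner's null, so rank-1 recovery is an honest margin test — with a
  background-frequency option), lengths uniform on 150–400.
* `simulate_uptake_data()` is the forward model of the kinetics fit:
  $V = V_{max}[S]/(K_m+[S])$ times $(1+\mathcal N(0,\sigma))$, truncated
  at zero.
* `simulate_od_curve()` is exponential growth with an optional hard
  carrying-capacity plateau and multiplicative noise.

What the generators do **not** emulate: phylogenetic correlation among
family members (every member descends independently from the ancestor),
insertion states, compositional bias of real proteomes, rate
heterogeneity along the sequence, and systematic (non-multiplicative)
assay error. Passing tests therefore demonstrate algorithmic
correctness and honest statistical calibration under the stated noise
model, not performance on any particular organism's proteome.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale by
design: kinetic fits use 25-point log-spaced concentration grids
covering 1–100 µM and 0.1–40 mM (8 points × 3 replicates for the noisy
calibration), growth curves 41 points over 400 h, exhaustive HMM
enumeration up to M = 3 and 4 residues, NJ exactness on trees of up to
8 leaves, and mining benchmarks with 100 decoys across 20 seeds. Every
randomized stage takes an explicit integer seed, and the pipeline
writes byte-identical outputs for identical config + seed, with a
manifest recording config echo, seed and input/output checksums.

## Known limitations

* Alignment construction is upstream (structural aligners such as
  PRALINE or Clustal Omega); the toolkit consumes alignments, it does
  not build them.
* No E-value statistics, domain-level (multi-hit) scoring, or HMMER
  file-format compatibility; scores are full-sequence bits.
* Trees are distance-based only (no ML/parsimony), unrooted, and the
  Poisson correction is the only substitution correction offered.
* Transmembrane-segment prediction is out of scope; motif windows are
  located by sequence, not by topology prediction.
* Two-component transport kinetics and inhibition models are not
  fitted.
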