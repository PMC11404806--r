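---
title: "Consensus B-cell epitope comparison across homologous immunoglobulins"
author: "epicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus B-cell epitope comparison across homologous immunoglobulins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicons)
```

## The problem

When no species-specific immunological reagent exists for an animal of
conservation concern, one practical route is to ask whether antibodies
raised against a well-characterized homolog — typically the human protein —
are likely to cross-react. For an immunoglobulin such as IgA this reduces
to three comparisons: overall sequence identity, structural overlap of the
folded domains, and, most directly relevant to antibody recognition,
similarity of the predicted B-cell *epitopes*. `epicons` implements the
epitope arm of that comparison as a reusable, fully offline pipeline, plus
the supporting distance-tree and structural-overlap metrics.

The design center is a small family of homologous heavy-chain sequences
(five partial manatee IgA records in the motivating use case) scored by
about ten independent linear-epitope prediction algorithms. Individual
predictors are noisy; the pipeline therefore looks for *consensus* at two
levels before trusting any region:

1. **Across homologs** (intra-algorithm): for one algorithm, an alignment
   column is supported when at least `minSupport` (default 3) members both
   carry a prediction covering that column *and* agree with the column's
   majority residue. Maximal runs of supported columns at least
   `minLength` (default 5, the length of the shortest epitope the design
   anticipates) become that algorithm's consensus epitopes.
2. **Across algorithms** (inter-algorithm): columns covered by consensus
   epitopes from at least `minAlgorithms` (default 3) distinct algorithms
   form the final consensus epitopes.

Both thresholds mirror the "three or more" rules of the study design this
package operationalizes.

## The conservation index

Each final epitope receives a conservation index in $[0, 1]$, the
arithmetic mean of six components. Writing $K$ for the number of members,
$A$ for the number of algorithms run, and $C$ for the epitope's columns:

* **presence** — fraction of members containing the epitope. A member
  contains it when its predictions (any algorithm) cover at least half of
  $C$.
* **position** — $\frac{1}{|C|}\sum_{c \in C} \frac{m_c}{K}$ where $m_c$
  counts members that are covered at $c$ and match the column's majority
  residue. A mismatched residue, an `X`, or an unpredicted member
  contributes 0 — this is the "penalty" for disagreement.
* **score** — mean over supporting algorithms of the epitope's mean
  prediction score, min–max normalized by that algorithm's observed score
  range (so a BepiPred-style score on $[-0.2, 1.3]$ and an ABCpred-style
  score on $[0.1, 1]$ become comparable). An algorithm whose scores are
  constant normalizes to 1.
* **iqr** — 0.25, 0.5, 0.75 or 1 according to the quartile in which the
  epitope's score component falls within the distribution over all
  epitopes scored together. Quartile boundaries use R's default inclusive
  linear-interpolation convention (`quantile(type = 7)`); values at or
  below $Q_1$ map to 0.25, at or below the median to 0.5, at or below
  $Q_3$ to 0.75, above it to 1.
* **algorithms** — supporting algorithms / $A$.
* **agreement** — $\frac{1}{|C|}\sum_{c \in C} \frac{a_c}{A}$ with $a_c$
  the number of algorithms covering column $c$ in at least one member.

The index is 1 exactly when all six components are 1: every member, every
algorithm, residue-perfect agreement, maximal scores, top quartile. Two
points here were genuinely open design choices. First, whether "the same
amino acid present in three or more sequences" demands residue identity or
mere coverage: we implement the residue-identity reading, because the
mismatch-penalty language only makes sense if residues are compared.
Second, the quartile-to-score mapping $\{0.25, 0.5, 0.75, 1\}$ is our
concretization of an "interquartile normalization" described only
verbally; it preserves the stated intent (reward epitopes whose average
scores sit high in the distribution) while staying on the $[0,1]$ scale.
Because of these reconstructions, printed index values from the motivating
study are not promised to be reproduced digit for digit; the properties
(bounds, sharpness at perfection, monotone penalties) are what the tests
enforce.

## Prediction inputs

Two ingestion schemas cover the common export styles: per-residue score
tables (`position`, `residue`, `score`) for BepiPred/DiscoTope-style
output, and per-window peptide tables (`start`, `peptide`, `score`) for
ABCpred-style output. Every row is validated against the sequence it
claims to describe. For window predictors that emit dense overlapping
candidates, `dedupeOverlaps()` reduces each transitive overlap cluster to
its highest-scoring member (ties: smaller start, then shorter length) —
a deterministic stand-in for the manual "one epitope per region" selection
the original analysts performed; it is deliberately flagged as such.

The package also re-implements the propensity-profile stage behind
BcePred-style servers: seven published per-residue scales (Parker
hydrophilicity, Karplus–Schulz flexibility, Emini accessibility,
Chou–Fasman turn propensity, a sign-flipped Janin exposed-surface
preference, Grantham polarity, Kolaskar–Tongaonkar antigenicity) smoothed
with a sliding window and affinely rescaled per sequence to $[-3, +3]$,
with threshold calling on top. A window of 7 is used uniformly — the
original server defaults are not published, and a uniform odd window keeps
the center convention trivial. Whether such servers rescale per sequence
or globally per scale is unknown; per-sequence rescaling is our recorded
assumption, and the 0 default threshold then sits mid-range. `X` residues
take the scale mean and never count as matches anywhere in the pipeline.

## Identity against reference chains

Each consensus peptide is globally aligned to each reference heavy chain,
the target is trimmed to the aligned span of the query, and identity is
exact matches divided by the *query* length. Two scoring schemes ship:

* `simple` — textbook Needleman–Wunsch (+1 match / 0 mismatch / −1 gap,
  end gaps charged, traceback preferring diagonal, then up, then left).
  This is the scheme verified against an exhaustive enumeration oracle.
* `needle` (default for epitope-vs-chain work) — EMBOSS Needle defaults:
  BLOSUM62, affine gaps with the first gap residue costing 10 and each
  further residue 0.5, end gaps free.

The simple scheme is kept because it is exactly checkable, but it
degenerates for a short query against a long target: every alignment
without target-consuming insertions carries the same number of gap
columns, so the optimum scatters matches arbitrarily and identity
saturates. The needle scheme is therefore the package default for
chain-length targets, and is cross-checked in the tests against
`Biostrings::pairwiseAlignment` in ends-free mode.

The shipped reference chains (`humanIgAChains()`) are the human IgA1 and
IgA2 heavy-chain constant regions. **They are synthetic reconstructions
from model knowledge of the corresponding UniProt entries (P01876,
P01877)**, shipped because the package must build and test without network
access; the FASTA file and its headers are labelled accordingly. They
reproduce most published per-epitope identity values exactly, but users
with connectivity should replace them with the actual database records.

Shared-amino-acid similarity against a reference epitope table counts, for
each reference epitope, the positional overlap between its interval and
the query epitope's mapped span on the chain, then reports the mode
("M"), min–max range ("R") and number of reference epitopes with at least
one shared position. Whether "shared" should additionally demand residue
identity at the overlapping positions is not specified in the source
design; positional overlap is the default, with
`requireResidueIdentity = TRUE` available as a switch.

## Trees and structure metrics

The tree stage computes a protein p-distance (mismatches over comparable
sites, gaps and `X` excluded pairwise by default, complete deletion
optional) and hands it to Saitou–Nei neighbor joining via `ape::nj`,
clamping negative branch lengths to zero with a warning. The "default
parameters" of the desktop software the motivating study used are not
printed anywhere, so p-distance with pairwise deletion is our stand-in.

Structural overlap uses the Kabsch algorithm (SVD with the determinant
correction enforcing a proper rotation) for least-squares superposition of
residue-matched C-alpha sets, reporting RMSD and the TM-score
$\mathrm{TM} = \frac{1}{L}\sum_i \frac{1}{1 + (d_i/d_0)^2}$ with
$d_0 = 1.24\,(L-15)^{1/3} - 1.8$ floored at 0.5 Å. Because published
structure-search tables rarely state which normalization length they used,
both target- and query-normalized scores are emitted. The residue matching
produced by fold-search software is not reproducible from published
tables, so those printed TM/RMSD values are treated as context, not as
machine-checkable targets.

## The synthetic generator

`simulateFamily()` draws a uniform-random ancestor, plants
non-overlapping epitope regions (placed uniformly over feasible
arrangements), and mutates each member i.i.d. per site — at the full
substitution rate outside planted regions and one tenth of it inside,
making the planted regions conserved the way real epitope-bearing domains
are assumed to be. `simulatePredictions()` emulates a deterministic
predictor applied to near-identical homologs: an algorithm that recovers a
planted epitope reports it on *every* member, with a shared ±1 start
jitter, while decoys appear at Poisson-random positions per algorithm
(default 0.5 per algorithm per 100 residues) with a lower score base.
All draws flow from one integer seed.

Defaults mirror the study conditions: 5 members, 10 algorithms,
agreement 0.9, substitution probability 0.05. The validation runs use an
ancestor of 2,500 residues with 50 planted epitopes of 8–15 residues —
large enough for stable recovery and rank statistics, small enough to run
in seconds. Under those conditions the pipeline recovers ≥ 90% of planted
epitopes (interval Jaccard ≥ 0.5) and separates planted from decoy
conservation indices by a one-sided Mann–Whitney test at far below the 1%
level, with planted epitopes averaging an index around 0.71 against
roughly 0.47 for decoys.

What the generator does *not* emulate: indels (the simulated alignment is
ungapped; the consensus machinery itself is exercised on gapped alignments
in the tests), realistic immunoglobulin domain architecture, position- or
chemistry-dependent substitution preferences, and correlated errors
between prediction algorithms. Passing the synthetic end-to-end check
therefore demonstrates that the consensus and scoring machinery behaves
correctly under the stated noise model — not that any particular predictor
is accurate on real sequences.

## Numerical conventions and edge cases

* Coordinates are 1-based inclusive everywhere user-facing; BED domain
  annotations (0-based half-open) are converted on read.
* Majority-residue ties break alphabetically; dedupe ties break by
  smaller start, then shorter length; NW traceback prefers diagonal, then
  up, then left — all choices exist purely for determinism.
* Constant propensity profiles rescale to 0; single-residue sequences are
  accepted.
* A distance-matrix pair with zero comparable sites is an error naming the
  pair, not a silent `NaN`.
* Quartile boundaries: `quantile(type = 7)`.
* Newick output carries branch lengths rounded to 6 decimals.
* Reports use dot decimals in machine output regardless of locale.

## Limitations

The conservation index is a reconstruction of a verbally described score;
its absolute values are comparable within a run, not against other
implementations. The reference chains are reconstructions (above). The
epitope-vs-chain identity depends on the alignment scheme; both schemes
are exposed and recorded in the run manifest so results are traceable to
their parameters.
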