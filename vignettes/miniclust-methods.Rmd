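---
title: "Methods: cascaded protein clustering, consensus alignments and annotation transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascaded protein clustering, consensus alignments and annotation transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miniclust)
```

miniclust rebuilds, at desk scale, the workflow behind clustered protein
sequence databases: a cascade of clustering stages of increasing
sensitivity, per-cluster alignments and consensus sequences, MSA
diversification by profile search, annotation transfer guarded by a
subalignment E-value, and quality scores for the resulting clusters.  This
vignette documents the model, the parameters that matter, the numerical
choices, and what the synthetic-data experiments do and do not show.

## The pairwise similarity engine

Every clustering decision reduces to a Smith–Waterman local alignment with
affine gaps under BLOSUM62.  Three quantities drive all thresholds:

* **identity** — identical residue pairs divided by aligned
  (residue-vs-residue) columns.  Gap columns are excluded; because coverage
  is enforced separately, this cannot mistake a short high-identity match
  for full-length similarity.
* **coverage** — aligned span length over full sequence length, per
  sequence.  "Overlap of the shorter sequence" criteria use the coverage of
  whichever sequence is shorter; set-cover levels require both coverages.
* **score per aligned residue** — raw alignment score over aligned
  columns; the similarity used for member reassignment and for MSA
  diversity filtering.

Gap penalties are open 11 / extend 1, the standard pairing with BLOSUM62 (a
gap of length $k$ costs $11 + k$).  Determinism is part of the contract:
the traceback starts at the first maximal cell in row-major order and
resolves score ties diagonal > up > left, preferring gap closure over
extension, so identical inputs give byte-identical results on every
platform.  The test suite holds the aligner to an independently written
brute-force dynamic program (exact score, identity and coverage agreement)
and to an established library aligner for scores.

One consequence of real gap costs is worth noting: bridging a single-residue
deletion costs 12 points, so for very short sequences a local alignment may
legitimately stop at the longest well-scoring segment instead of spanning
the deletion.  At the sequence lengths the package targets (tens to
thousands of residues) deletions are bridged whenever the flanking segment
recovers more than the gap cost.

## The clustering cascade

**Stage 1 — redundancy hashing.**  Sequences are mapped to a fixed
five-class physicochemical alphabet ({A,S,T,G,P}, {C}, {D,E,N,Q,X},
{K,R,H}, {M,I,L,V,F,Y,W}) and hashed with a deterministic 64-bit FNV-1a
hash.  Only equal-length sequences with equal hash share a bucket, and a
bucket member joins a cluster only after its exact column identity to the
representative reaches the 90% threshold — hashes are never trusted, so the
choice of hash function is correctness-neutral and any collision is
harmless.

**Fragment absorption.**  A cluster is dissolved into another when its
representative aligns to the target representative at ≥ 90% identity over
≥ 95% of its own length.  Candidates are processed shortest-first and only
equally long or longer representatives are eligible targets, which makes
the pass deterministic and cycle-free.  Note that absorption moves whole
clusters: if a near-duplicate full-length sequence is absorbed after itself
absorbing fragments, those fragments follow it, and their identity to the
final representative can land marginally below the nominal 90% (they
satisfied the rule against the representative that absorbed them).  This
chaining is intrinsic to cluster-level absorption; the package keeps it
because re-checking every transitively absorbed member would turn a linear
pass into a fixpoint iteration for no practical gain at these identity
levels.

**Stage 2 — greedy incremental clustering** of the remaining
representatives, longest first (ties by accession): each sequence joins the
best-scoring representative at ≥ 90% identity and ≥ 90% coverage of the
shorter sequence, or founds a new cluster.  Assignment is to the *best*
eligible representative rather than the first hit; best-hit assignment is
deterministic under the fixed processing order and gives more compact
clusters.  The fragment rule is applied again after this stage.  The
result is the 90% level.

**Stage 3 — greedy set cover with reassignment.**  The 50% and 30% levels
are both built directly from the 90%-level representatives (building 30%
from 50% was deliberately avoided — cascading through 50% degrades
quality).  An acceptance graph joins two representatives when identity
reaches the level threshold with ≥ 80% coverage on *both* sequences —
bidirectional coverage is the reading of "80% sequence length overlap"
consistent with how reference clusterings state the criterion.  Greedy set
cover repeatedly picks the uncovered vertex covering the most uncovered
vertices (ties: longer sequence, then smaller accession).  A single
reassignment pass then moves every member to the eligible representative
with the highest score per aligned residue; one pass, because reassignment
is a cleanup, not an optimization loop, and further passes change nothing
in practice once representatives are fixed.

Coarse clusters are expanded through the finer level, so every input
sequence appears in all three partitions and every coarse cluster is a
union of whole 90%-level clusters.  Thresholds are guaranteed between
representatives; expanded (non-representative) members inherit membership
transitively, and on well-separated data they satisfy the coarse thresholds
as well.

**Tie-breaking everywhere**: higher score, then longer sequence, then
lexicographically smaller accession.  Shuffling the input changes nothing.

**Incremental updates** keep identifiers stable: deprecated members are
dropped (a cluster whose representative disappeared promotes its longest
remaining member under the same identifier), new sequences are compared
against surviving representatives only — linear in new × representatives,
verified by an alignment-call counter — and the remainder is set-cover
clustered with fresh identifiers.  Accessions are immutable; a changed
sequence under an old accession is an error, not an update.

## MSAs, consensus sequences and profiles

Per-cluster MSAs are center-star alignments around the representative in
A3M encoding (uppercase/`-` in the representative's columns, lowercase
insertions between them).  A full progressive aligner would add nothing
here: every member already satisfies identity and coverage thresholds to
the center, which is exactly the regime where the star topology is
adequate — and it keeps MSA construction deterministic and dependency-free.

The consensus maximizes, per column, the pseudocount-smoothed residue
probability: observed column frequencies (raw counts, so the consensus
follows the column majority) mixed with BLOSUM62-derived conditional
exchange probabilities at weight $\alpha = 1$ count-equivalent.  Ties break
to the higher matrix self-score, then alphabetically.  Profiles (PSSMs)
instead use duplicate-collapsing sequence weights — each distinct row
counts once — so pasting the same sequence twice cannot sharpen the
profile; a single-sequence profile reproduces that sequence's matrix rows
exactly, which is the correct degenerate limit.

Consensus headers summarize a cluster as
`id|representative|n=size|top descriptions|members`, ranking up to five
distinct descriptions: reviewed sources before unreviewed, informative
before blacklisted (*hypothetical*, *unknown*, *uncharacterized*,
*putative*), then frequency, then alphabetical.

**Diversification (boost).**  A profile built from the cluster MSA is
searched iteratively (default 4 iterations) against the database of all
cluster consensus sequences; hits with Karlin–Altschul E-value
$K \cdot m \cdot N \cdot e^{-\lambda S}$ below $10^{-3}$ are merged into the
alignment and the profile rebuilt until no new hit appears.  The enriched
MSA is then filtered by BLOSUM62 score per aligned residue to the cluster
consensus at 0.0, 0.5 or 1.1 — three diversity tiers that are strictly
nested by construction (insertions are unscored; the first record is always
kept).  The search E-value cutoff and the profile weighting are exposed as
parameters because the reference pipelines do not publish their internal
values.

## Annotation transfer

Cluster-level domain matches (consumed as nine-column tables; producing
them is out of scope) are accepted per database in order of increasing
E-value when E < 0.01 and the candidate's query span overlaps already
accepted spans by < 10% of its own length — overlap is measured on the
query coordinate system, per database, so one region can carry one
annotation per database.

Transfer to a member requires the subalignment E-value

$$E_{subali} = E_{domain} + K \cdot L_{consensus} \cdot e^{-\lambda s_{subali}} < 0.01$$

with $s_{subali}$ the substitution score between member and consensus over
the annotated columns, read directly off the MSA (deletion columns
unscored; a member with no residues in the span has no homologous region
and receives nothing).  The exponential must *decrease* with alignment
quality for the guard to mean anything — a high-scoring subalignment is
strong evidence of homology and should pass.  The constructor exposes
`literal = TRUE` to reproduce the opposite sign convention for audit; with
it, good subalignments fail, which is why it is not the default.  $K =
0.041$ and $\lambda = 0.267$ are the standard gapped-BLOSUM62
Karlin–Altschul constants; both are parameters.  Transferred records carry
the subalignment E-value and MSA-mapped member coordinates.

## Cluster evaluation

Compactness is the mean and minimum pairwise identity among members,
sampling 10 members uniformly (seeded) in larger clusters.  Annotation
consistency compares the representative against every other member — the
same database-level results are obtained with a random member instead, a
property the test suite checks — for three annotation types:

* **Ontology terms**: information-content similarity
  $\mathrm{sim}(a,b) = 2\log P(\mathrm{LCA}(a,b)) / (\log P(a) + \log
  P(b))$, with the LCA taken as the common ancestor of minimal annotation
  probability (the standard resolution when the hierarchy is a DAG rather
  than a tree; ties break lexicographically).  The logarithm base cancels;
  natural log is used.  Sets of terms are compared by best-match averaging
  over both directions.  Term probabilities can be supplied or derived from
  an annotation corpus with ancestor propagation and add-one smoothing
  (root exactly 1, unobserved terms positive).
* **Keywords**: Dice coefficient — the same best-match formula under the
  identity kernel.  Non-functional keyword categories should be filtered
  upstream.
* **Names**: 1 − Levenshtein/longer-length on normalized names
  (lowercased, the word "protein" removed, whitespace collapsed); names
  starting with *uncharacterized*, *putative*, *potential*, *probable*,
  *inactive*, *likely* or *unknown* are uninformative and yield no score.

Undefined comparisons (missing annotations) are skipped, never scored
zero — zero-scoring would conflate missing data with inconsistency, since a
similarity below 1 may only mean one protein is better annotated.  Each
cluster reports worst and mean per type plus the cross-type average over
defined types; singletons are excluded.

## The synthetic-data generators

`generate_families()` emulates what clustering must recover: families grown
from independent uniform-random founders (uniform residue background —
adequate for clustering experiments; a composition-biased background would
change nothing about threshold behavior), members mutated to an exact
target identity with BLOSUM62-exchange-biased substitutions, and optional
fragments truncated (not mutated) to 30–60% of length so the fragment rule
is exercised exactly as stated.  The founder is kept as the full-length
first member: it anchors the family, and `within_identity` is defined as
divergence from it.  The canonical study conditions are 3 families × 5
members of length 200 at 95% within-family identity with fragment
probability 0.1 — small enough to verify exhaustively, large enough that
every cascade stage does real work; independent founders of this length
align far below the 30% acceptance threshold, so family recovery (adjusted
Rand index 1.0 across seeds) is the expected outcome, and the tests confirm
it at 20 seeds.

`generate_annotations()` builds a balanced term tree (probabilities
decreasing geometrically with depth) and gives all members of a family one
leaf term, one keyword set and one name, perturbed per protein with a
configurable noise rate (sibling-leaf swap, keyword drop/add, one-character
typo).  Consistency scores then decrease monotonically in the noise rate,
and clusterings that merge distinct families score lower than those that
keep them apart — the directional behaviors the evaluation module exists to
measure.  What these experiments do *not* show: real annotation corpora
have correlated, propagated and missing annotations far beyond this noise
model, and real sequence families have indels, domain shuffling and
composition bias the mutation model omits.  Passing tests certify the
machinery, not database-scale statistics.

## Numerical and degenerate-input choices

* Residues are uppercased; U/O/B/Z/J map to X with a warning; anything else
  outside the 20+X alphabet, `*` and gaps are rejected with the offending
  record named.
* Sequences longer than 14 000 residues are split into near-equal suffixed
  pieces (`acc_1`, `acc_2`, ...); pieces are independent entries
  downstream, and concatenating them reconstructs the original.
* Alignments with no positive-scoring cell return an empty result (zero
  aligned columns, zero coverage) rather than an error.
* An MSA's match-column count is defined by its first record; inconsistent
  records are format errors.
* Empty annotation sets yield NA similarities (skipped), except the keyword
  score where one empty set against a non-empty one is genuinely 0 by the
  Dice formula.
* All sampling (compactness subsampling, generators) goes through a local
  RNG scope: a seed argument never perturbs the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script run the full stack on the
canonical 15-sequence study (plus 20 reseeded replicates for family
recovery, 100 random graphs for the set-cover oracle, 200 random pairs for
the alignment oracle, and 100-case oracle sweeps for each similarity
score) — sizes chosen so the whole suite exercises every code path in
about a minute while remaining exhaustively checkable against brute-force
references.

## Known limitations

* All-vs-all dynamic programming: no k-mer prefilter or index structures,
  so practical inputs are thousands of sequences, not millions.
* Center-star MSAs assume members resemble the representative — true by
  construction here, but not a general-purpose aligner.
* Profile-search E-values reuse fixed Karlin–Altschul constants rather
  than fitting $\lambda$ per profile; fine for ranking and thresholding at
  this scale, not calibrated for borderline significance calls.
* Expanded members at coarse levels inherit membership transitively;
  thresholds are only guaranteed against representatives.
* HMM–HMM comparison, affinity propagation and single-linkage alternatives
  are deliberately out of scope.
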