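---
title: "pocketfam: methods and design"
author: "pocketfam authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pocketfam: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketfam)
```

# Scope

pocketfam implements a sequence-and-structure workflow for expanding an
enzyme family from a small curated seed set: profile-HMM screening with
two-domain confirmation, identity-based family clustering, a calibrated
profile–profile similarity network with Markov clustering,
structure-guided active-site ("pocket") fingerprint classification,
rule-based NAD/NADP cofactor-specificity prediction, and diversity-aware
representative selection on a neighbor-joining tree. Every stage can be
exercised on fully synthetic data with known ground truth; the package
ships generators for sequences, curation sets, gapped alignments and toy
CA-trace structures so the whole pipeline is reproducible offline.

This vignette documents the model choices, the default parameters and
their rationale, the synthetic generators' scope, and the numerical
decisions. It is written for users who want to understand *why* the
package behaves as it does, not just how to call it.

# The profile HMM

## Architecture

`buildProfile()` constructs a plan7-like profile HMM from a multiple
alignment:

* **Match states.** Alignment columns with gap fraction below 0.5
  become match states; more-gapped columns are treated as insertions
  relative to the model. The original column index of each match state
  is kept in the `map` slot so anchor-based coordinates survive model
  building.
* **Match emissions.** For column $k$ with observed residue counts
  $c_k(a)$, the emission is the background-mixture pseudocount estimate
  $e_k(a) = (c_k(a) + w\,q(a)) / (n_k + w)$ with pseudocount weight
  $w = 1$ and a uniform background $q(a) = 1/20$. A uniform background
  is the correct null for the package's synthetic generators, which draw
  residues uniformly; users modelling natural sequences can pass their
  own background.
* **Insert emissions** equal the background, so insertions are
  score-neutral per residue — the standard choice that makes local
  scores insensitive to unmodelled loop content.
* **Transitions.** Per inter-node junction, M/I/D events are counted
  from the rows (a row gapped at a match column is in D; residues in
  inter-node insert columns contribute MI/II/IM events) and smoothed
  with Laplace +1 over each source state's target set. There are no
  D↔I transitions (plan7).

## Local scoring model

`forwardScore()` and `viterbiScore()` implement local
(Smith–Waterman-style) scoring in log space, in C++:

* A path may enter at any match state $k_0$ and leave from any match
  state $k_1 \ge k_0$; every fragment carries the uniform entry/exit
  weight $2/(L(L+1))$, i.e. the model puts equal prior mass on each of
  the $L(L+1)/2$ fragments.
* A **no-match path** with odds 1 is always available, so the reported
  score is $\log_2(1 + \sum_{\text{paths}} \text{odds})$ for the
  forward algorithm and $\log_2 \max(1, \max_{\text{paths}})$ for
  Viterbi. The empty sequence therefore scores exactly 0 bits, and no
  sequence scores below 0: bit scores are directly comparable across
  sequences of different lengths.
* Unknown residues (`X`) score as background (odds 1).

This fragment model was chosen over HMMER's length-modelled local
alignment because it is simple enough to verify by **exhaustive path
enumeration**: the test suite enumerates every (entry, placement, exit)
combination for models of length ≤ 3 against sequences of length ≤ 5
and checks agreement with the dynamic program to $10^{-9}$ in
probability space.

## Two-domain confirmation and the 50-bit screen

`splitProfile()` cuts the seed alignment at the column carrying a
designated anchor residue of a reference sequence (the anchor column
goes to the N-terminal block) and builds one profile per block: an
N-terminal cofactor-binding model and a C-terminal catalytic model. A
database sequence is a confirmed family member only if it passes
*both* screens (`confirmTwoDomain()`), which suppresses single-domain
homologs such as lone Rossmann-fold proteins. The default acceptance
threshold is 50 bits; on synthetic families (5% per-residue mutation,
250–500 residues), true members score several hundred bits and decoys
below ~10 bits, so the threshold sits in a wide margin. When a labeled
calibration set exists, `selectThreshold()` picks the Youden-optimal
threshold instead.

# Family clustering

`pairwiseIdentity()` aligns globally (match +2, mismatch −1, gap open
10, extension 0.5) and reports identity over the alignment columns
between the first and last aligned pair (terminal gaps excluded) and
coverage as aligned pairs over the shorter length.
`greedySetCoverCluster()` then applies greedy set cover at 80%
identity / 80% coverage: the unclustered sequence with the most
qualifying unclustered neighbours becomes a representative (ties:
longer sequence, then lexicographic id), so the output is deterministic
and partitions the input. `removeRedundancy()` collapses exact
duplicates at identity 1 (hash-equivalent, verified against a hash-set
oracle) and falls back to greedy clustering below 1.

All-vs-all computations batch one `Biostrings::pairwiseAlignment` call
per subject; `greedySetCoverCluster()`, `removeRedundancy()` and
`identityDistanceMatrix()` accept a `precomputed` identity/coverage
matrix so a pipeline computes the quadratic alignment pass once.

# Profile–profile network and Markov clustering

`profileProfileCompare()` aligns two profiles' match columns by
Smith–Waterman over the co-emission score
$\log_2 \sum_a e_1(a)\,e_2(a)/q(a)$ with a 1-bit linear gap penalty.
The best-path score per column of the shorter profile is mapped to a
probability by a fixed logistic calibration
($p = \mathrm{logit}^{-1}(5\,(z - 1.5))$), frozen once against
synthetic related/unrelated profile pairs; coverage is the aligned
column fraction of the shorter profile. An edge is admitted at
probability ≥ 0.95 and coverage ≥ 0.75, weighted by their product —
the distant-homolog hit rule.

`mclCluster()` is a standard Markov clustering implementation:
self-loops at the largest incident weight, column-stochastic
normalisation, alternating expansion and inflation (default inflation
2) to convergence, attractor-row readout with merging of overlapping
attractor systems. MCL output provably refines the network's connected
components; the test suite checks this against an independent graph
library on random graphs.

# Pocket classification

`kabschSuperpose()` solves the least-squares rigid superposition in
closed form (SVD with determinant-sign correction) and refuses
degenerate inputs (fewer than 3 points, collinear geometry).
`extractPocket()` superposes a query CA trace onto the reference via an
alignment-guided correspondence, then reads each of the 21 named pocket
positions (P1–P21, with P3 the catalytic glutamate) from the
alignment-corresponding query CA when it lies within the 3 Å cutoff,
falling back to the spatially nearest CA for unaligned positions; out
of range means a gap. The alignment-guided readout keeps per-position
recovery above 95% at 1 Å coordinate noise on the synthetic scaffold,
where pure nearest-CA matching suffers neighbour confusion (adjacent
CAs sit ~3.9 Å apart).

`PocketDefinition` carries per-family **remaps** (the default synthetic
definition moves P6/P7 for family `G2`), mirroring families whose
pocket geometry shifts individual positions. `modelingGate()` admits a
query to structure-based extraction only if its best identity to a
template reaches 23%, the conventional comparative-modelling floor.

`clusterPockets()` classifies fingerprints by average-linkage
agglomeration on per-position mismatch distance (gapped positions
excluded pairwise), cut at 0.5; clusters below 15 members are flagged
not retained — small clusters of noisy fingerprints are not trusted as
groups. `makeLogo()` reports per-position residue frequencies over
non-gap symbols, information content $\log_2 20 - H$, and the gap
fraction separately, so incomplete pockets do not masquerade as
variable ones.

# Cofactor specificity rules

`classifyCofactor()` reads the six-residue window R1–R6 (reference
residues 36–41) against a configurable residue-class table
(`defaultResidueClassTable()`): **dual** when R1 is negative, R2 and R6
positive and R3 polar; **NAD** when R1 is negative and R2, R3, R6 are
all aliphatic or bulky; **NADP** when R1 is short-chain with R2/R6
positive and R3 polar; anything else — including any gapped window — is
**unknown**. R4/R5 are carried but unused. The dual and NAD predicates
are disjoint (R3 polar vs aliphatic/bulky), so the rule order cannot
mask a class; the test suite sweeps all $20^4$ (R1, R2, R3, R6)
combinations against a flat truth-table oracle. `clusterByR1()` groups
windows by the key residue R1 and sub-clusters by exact window,
labelling `"<R1>.<k>"` by decreasing size.

# Representative selection

`njTree()` wraps neighbor joining (negative branches clamped to zero
and flagged). `selectRepresentatives()` operationalises "cover the
tree" as greedy maximin patristic diversity: seed at the eligible leaf
with the largest total distance, then repeatedly add the leaf
maximising the minimum distance to the current selection, serving
groups with unmet per-group minimums first. Eligibility requires the
catalytic P3 glutamate (gaps are "incomplete active site",
substitutions "P3 not glutamate") and a pluggable solubility hook. All
ties break lexicographically, so selection is deterministic; the greedy
procedure matches an independently coded oracle on small trees. Quotas
apply by default to every group with at least one eligible leaf; an
explicitly requested group without enough eligible members raises an
error naming the group.

# Synthetic data: scope and limits

The generators are deliberately simple, indel-free models whose truth
is exact:

* `familySpec()`/`generateFamily()` draw a per-family consensus with a
  Rossmann block, linker and catalytic block; members mutate each
  position to a *different* residue with probability `mutation_rate`
  (default 0.05), so family members are naturally aligned and the
  planted 21 pocket columns and 6 cofactor columns are recorded as
  truth. No insertions or deletions are generated — alignment
  inference is not the subject under test.
* `generateCurationSet()` plants disjoint obsolete and length-violating
  subsets; `generateGappedAlignment()` plants an exact number of rows
  with gaps inside a window; `generateStructures()` places residues on
  an ideal helix-like CA scaffold (~3.8 Å spacing), applies a random
  rigid transform plus optional Gaussian coordinate noise, and records
  the exact transform.
* `runPipeline()` builds `n_groups` groups sharing one sequence
  backbone but carrying distinct planted pocket motifs and cofactor
  windows; the last group lacks the catalytic glutamate, so the
  selection stage always has ineligible leaves to reject.

These generators are for validation and demonstration: they do not
model indels, domain shuffling, compositional bias or realistic
structure geometry. Conclusions about natural sequence data require
the user's own inputs.

All generators seed a local RNG (`withSeed()`) and restore the caller's
random state, so pipeline results are byte-reproducible from the
configuration alone.

# Numerical choices

* All HMM dynamic programming runs in natural-log space with a
  numerically stable log-sum-exp; scores are converted to bits at the
  end. Profile serialization (`writeProfile()`) prints `%.17g` so
  profiles round-trip bit-exactly.
* `clusterPockets()` clamps average-linkage merge heights with a
  running maximum before `cutree()`: average linkage is mathematically
  monotone, but tied merges can leave float-noise inversions that
  `cutree()` rejects.
* Logistic calibration constants for `profileProfileCompare()` are
  frozen in code (slope 5, midpoint 1.5 bits/column) rather than
  refitted per run, so network edges are reproducible.
* The problem sizes in the acceptance checks (for example, a
  2011-record curation set or a 7224-row window table) are package
  choices exercising the implementation at realistic scale; nothing in
  the code depends on them.

# A minimal run

```{r pipeline, eval = FALSE}
cfg <- pipelineConfig(n_members = 8, n_decoys = 10, n_obsolete = 1,
                      length_range = c(250, 300),
                      min_cluster_size = 5, n_representatives = 4)
out <- runPipeline(cfg, outdir = tempfile("pocketfam_run"))
out$manifest$counts
```

The manifest records the configuration, the derived stage seeds, the
per-stage counts (which balance by construction: curation reasons are
mutually exclusive, confirmation is an intersection, clustering
partitions its input) and any warnings raised along the way.

# Limitations

* The profile HMM has no explicit length model for the unaligned
  flanks; bit scores are fragment-odds scores, not E-values.
* Cofactor rules are a fixed residue-class rule set; they classify
  windows the rules do not cover as `unknown` rather than guessing.
* The pocket classifier assumes CA-only traces and a single reference
  scaffold; side-chain geometry is out of scope.
* Greedy set cover and greedy maximin are deterministic heuristics with
  the usual approximation caveats; they are validated against oracles
  at small sizes, not proven optimal at scale.
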