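---
title: "foldprep: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foldprep: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldprep)
```

foldprep implements the computational layer around a protein structure
predictor: everything that happens before the neural network sees its input
(MSA construction, filtering, pairing, feature assembly) and after it
produces output (confidence metrics, ranking, rendering), plus the batch
control flow in between. The predictor itself is deliberately a pluggable
contract — in this package it is a scripted mock — so every algorithm here
is testable on one CPU from synthetic fixtures. This vignette explains the
models and procedures, the parameters that matter, and the design choices
made where the design was genuinely open.

## MSAs and the A3M convention

All alignment handling is query-anchored. An `msa` is a tibble of aligned
rows whose first row is the query; aligned strings follow the A3M
convention, where uppercase letters and `-` occupy *match columns* (exactly
one per query residue) and lowercase letters are *insertions* relative to
the query, occupying no query column. The two structural invariants — the
query carries no gaps or insertions, and every row has exactly as many match
columns as the query has residues — are enforced at construction, so
downstream code never revalidates.

Two identity measures coexist on purpose:

* **Identity to the query** (`query_identity()`) divides by the query
  length. This is the `qid` that assigns rows to filter buckets: a fragment
  covering half the query can never be more than 50% identical to it, which
  is the intended reading for bucket placement.
* **Pairwise identity between rows** (inside the redundancy and diversity
  filters) divides by the number of columns where *both* rows carry a
  residue. Exact duplicates therefore always score 1 and collapse, whatever
  their gap pattern.

`X` never certifies a match under either measure — an unknown residue
cannot witness identity — but does occupy a column. Coverage uses the stored
query span `(qstart, qend, qlen)` when present and otherwise falls back to
the fraction of match columns holding a residue.

Aligned FASTA, Stockholm 1.0 and Clustal inputs are converted to A3M by
turning columns where the query is gapped into insertions. Stockholm and
Clustal are parsed by small block readers (annotation lines and conservation
lines skipped); how mixed-case FASTA should be treated by the conversion is
not pinned down by the usual tools, so the converter simply uppercases
column-aligned input before converting — lowercase in a *column-aligned*
format carries no insertion semantics.

## The multi-stage diversity filter

The filter runs in three stages, each with its printed parameter set:

1. **Cluster expansion** (`stage1_cluster_filter()`): each clustered-database
   cluster is filtered *independently* at 95% maximum pairwise identity
   before its members join the MSA. Because filtering never crosses
   clusters, the same sequence arriving via two clusters survives twice.
2. **Realignment** (`qsc_filter()`): rows must score at least 0.8 bits per
   query column against the query under BLOSUM62. The score threshold only
   activates once at least 100 hits are present (`filter_min_enable`);
   below that, every hit is kept. BLOSUM62 is in half-bit units, so scores
   are divided by 2 — this scale constant makes the 0.8 threshold sit well
   below a typical self-score of ~2.6 bits/column.
3. **MSA construction** (`bucketed_diff_filter()`): every non-query row is
   assigned to one identity bucket — `[0, 0.2]`, `(0.2, 0.4]`, `(0.4, 0.6]`,
   `(0.6, 0.8]`, `(0.8, 1]`, first bucket closed, the rest left-open exactly
   as printed — and each bucket holding at least 1,000 rows is reduced,
   within the bucket only, to its 3,000 most diverse rows. Buckets below
   1,000 rows pass through unfiltered.

The "most diverse" selection is deterministic farthest-point greedy: the
first row in input order seeds the set, each step adds the row maximising
its minimum distance (1 − pairwise identity) to the rows already selected,
and ties break by input order. The 95% redundancy filter runs before the
diversity selection inside each bucket. Reading `diff 3000` as a *per
bucket* cap (rather than 3,000 spread across buckets) follows from the
filter's stated purpose: filtering inside buckets cannot eliminate
redundancy *across* buckets, and a global cap would reintroduce exactly
that coupling. A score threshold of 0 in the bucketed stage means "no score
filter": under BLOSUM62, genuinely unrelated rows score negatively, so a
literal `>= 0` cut would silently empty the low-identity buckets that the
bucket design exists to protect.

Three properties pin the implementation down and are enforced by tests:
idempotence (filtering a filtered MSA changes nothing), query preservation
(the query is always row 1), and bucket isolation (deleting an entire
bucket never changes what other buckets keep).

## Hit tables, cluster expansion and the two-database build

Homology search itself is out of scope: the pipeline consumes precomputed
hit tables (BLAST-tabular-like TSV with `cluster_id`, `taxid` and
`accession` columns added) standing in for iterative profile searches.
Hits are accepted at E-value strictly below 0.1.

For each accepted hit — a hit to a cluster *representative*, aligned in the
query frame — the cluster's members are brought into the MSA by composing
the stored member↔representative alignment with the representative-to-query
alignment through the shared representative residues. This composition
approximates profile realignment of members, the approximation being exact
wherever the member aligns to the representative without indels; member
residues falling on representative insertion positions remain insertions,
and member gaps at insertion positions are dropped (A3M has no lowercase
gap). Local hits may truncate the representative's termini, so composition
starts the residue counter at the hit's `tstart`.

`build_msas()` runs the canonical order per database — accept, expand (with
the per-cluster 95% filter), score-filter (0.8 bits, enable at 100), bucket
filter — and concatenates the two databases' survivors behind the query.
The two databases are filtered independently; nothing in the stage
semantics suggests cross-database coupling, and independent filtering keeps
the environmental database from crowding out the curated one.

`naive_search()` is exhaustive Smith–Waterman (Biostrings, BLOSUM62, gap
open 11 / extend 1) with Karlin–Altschul E-values at fixed constants
λ = 0.267, K = 0.041. It exists as deterministic test plumbing for the
search-shaped inputs of `assign_to_clusters()` and the pipeline tests, not
as a performant search engine. At these constants the asymptotic null says
a random decoy exceeds E = 0.1 about 90% of the time (exp(−0.1)); the
empirical rate on short sequences is a little lower still, which is the
expected finite-size behaviour of the Gumbel tail, and the test suite
asserts the empirically verified bound.

## Pairing MSAs for complexes

Species pairing follows the best-hit rule: hits covering less than 50% of
their chain's query are discarded; a species yields one paired block iff it
still has at least one hit for *every* chain; within a chain the smallest
E-value wins, ties broken lexicographically by target id for determinism.
One block per species — paralogous extra pairs are not emitted, matching
the "best hit per species" semantics. Blocks are ordered by summed E-value.

Genome-distance pairing (for prokaryotes, where interaction partners
cluster on the genome) maps accessions to ordinals by base-36 positional
value of the full alphanumeric accession, then greedily matches hits across
chains within each species in order of increasing total pairwise ordinal
distance, each hit used at most once, rejecting any candidate whose
pairwise distance exceeds `max_gap` (default 10 ordinals — a heuristic
default; the upstream protocol does not publish its threshold). Unlike
species mode, several blocks per species may be emitted (operon copies).
The greedy matching is verified against exhaustive minimum-distance
matching on small instances in the tests.

## Feature assembly

* **Homo-oligomers**: the MSA is copied once per chain and laid out
  block-diagonally — each row appears in one copy's column block with every
  other block gap-filled — rather than concatenating rows left-to-right.
  Separate copies preserve per-chain coevolution signal without asserting
  false inter-copy pairings.
* **Hetero-oligomers**: concatenated query first, then paired blocks as
  full-width rows, then each chain's unpaired rows block-diagonally. Paired
  rows are not deduplicated against unpaired blocks (a row present in both
  carries pairing information only in its paired form; the duplicate is
  harmless and deduplication would complicate provenance).
* **Residue index**: 0-based, consecutive within chains, jumping by
  `chain_gap` (default 200) between chains. Relative positional encoding is
  clipped at |i−j| ≥ 32, so any jump above 32 creates a chain break; 200 is
  comfortably beyond the cap and matches common practice. Gaps ≤ 32 are
  rejected with an error citing the cap.
* **Subsampling**: at most 512 cluster rows (query always included) and
  1,024 extra rows, drawn uniformly without replacement under a seed. The
  network-side assignment of extras to cluster centers serves no purpose
  without the network and is omitted.
* **Padding**: `make_fixed_size()` pads the feature width by 10% (gap
  tokens; residue-index sentinel −1). The contract that makes batches cheap
  is that a compiled shape `S` serves any query of total length ≤ `S`.

## Confidence metrics and ranking

From a predictor's PAE matrix (N×N expected positional error, not assumed
symmetric) the package computes:

* `inter_pae()`: the mean over ordered cross-chain pairs — the complex
  interface's raw error level;
* `ptm_from_pae()`: pTM = max_i mean_j 1/(1 + (PAE_ij/d0)²) with
  d0 = 1.24·(max(N, 19) − 15)^{1/3} − 1.8. The functional form and d0 are
  the upstream model's published definition (adopted as an external
  formula); clamping N at 19 keeps d0 positive for small peptides.
* `iptm_from_pae()`: the same with the inner mean restricted to chains
  other than i's.

Ranking is mean pLDDT for single chains and predicted TM-score for
complexes — ipTM when a chain partition is available, pTM otherwise — with
stable ties. The same metric drives the scheduler's early stop, so a run
stopped at threshold is stopped on the quantity it would be ranked by.

## Batch scheduling

`run_batch()` emulates the batch control flow against the predictor
contract: queries sorted ascending by total length (ties by input order),
a compile cache keyed on (configuration key, padded length, padded row
count), models in fixed order, recycling up to `num_recycles` (default 3)
per model. Configuration keys encode which models share a compiled graph:
one shared configuration without templates; models 1–2 and 3–5 as two
groups with templates.

A query reuses any cached shape at least as large as itself; a compile
event fires only when nothing fits. Early stopping has two levers: a
`stop_at_score` threshold on the ranking metric (checked after every
recycle; once met, remaining recycles, models and samples for that query
are skipped) and a `recycle_tolerance` on the predictor-reported structure
change between recycles (stops recycling for that model only). The
structure-change metric is deliberately owned by the predictor — the
contract does not fix whether it is an RMSD, a distogram distance, or
anything else — because the scheduler only needs a scalar to compare
against the tolerance. Early stop compares the *current* recycle's score,
not a best-so-far, so the event log reads as a faithful trace of what the
predictor produced when.

Seed sampling is the deterministic series `base_seed, base_seed + 1, …`;
`is_training` is passed through untouched. A predictor error marks the
query failed and the batch continues.

## Database merge and reduce

`assign_to_clusters()` aligns each new sequence against every cluster
representative and assigns it to the best-identity cluster iff identity
exceeds 30% and the alignment covers at least 90% of the *new sequence's*
length (best hit, not first hit — determinism plus the better home).
`cluster_remainder()` clusters what is left greedily: sequences visited in
descending length (ties by id), each joining the first representative it
matches at the thresholds or seeding a new cluster — the standard cascaded
clustering shape, made deterministic. `reduce_clusters()` then keeps each
cluster's 10 most diverse members by the same farthest-point selection as
the MSA filter, seeded at the representative (which is therefore always
retained). Members are compared in the representative's coordinate frame.

## Rendering

`ribbon_segments()` implements the pseudo-3D trick: project the CA trace
under a rotation, emit one 2D segment per consecutive residue pair, sort
segments by depth, and shade them by a fixed monotone map of depth — linear
from 0.5 at the farthest segment to 1.0 at the nearest (the shading
function is this package's choice; any monotone map produces the same
illusion). Drawing the sorted segments in order paints far-to-near, which
is what creates the 3D impression without a renderer. The output is
plot-ready data; the ggplot2 drawing layer is deliberately thin. The trace
is rendered as a plain CA polyline — no spline smoothing or ribbon width,
which are cosmetic and unspecified.

## Synthetic fixtures and what the tests do (and do not) show

`make_msa()` mutates a random query at exactly `round((1 − qid) · L)`
positions per row, chosen without replacement, so identity targets are hit
exactly and tests are not flaky. `make_species_hits()`, `make_pae()`,
`make_clustered_db()`, `make_cluster_table()` and `make_mock_predictor()`
realize pairing layouts, block PAE structure, clustered databases and
scripted predictor behaviour the same way: seed-deterministic, invariants
satisfied on construction.

These generators emulate the *combinatorial* structure of real data —
identity strata, species co-occurrence, cluster membership, block-shaped
error — but not its biology: no indel evolution, no compositional bias, no
correlated mutation, no real structures. Passing tests therefore certify
the algorithms' contracts (counts, thresholds, orderings, invariants,
determinism), not prediction quality on real proteins.

Problem sizes in the tests and the acceptance script are the package's
chosen study conditions: the saturated-bucket scenario uses 5,000 rows per
bucket at length 100 (25,000 rows total), the near-duplicate cluster 200
members, the clustered database 20 × 50, all generated in seconds on one
CPU.

## Numerical choices, degenerate inputs, limitations

* Bucket membership at breakpoints: first bucket closed, others left-open;
  `qid = 0.2` lands in the first bucket, exactly as the printed intervals
  read.
* Farthest-point and redundancy scans break ties by input order; all
  orderings produced by the package are stable.
* `ceiling()` on padded lengths guards against binary-representation
  artifacts (100 × 1.1 must pad to 110, not 111).
* Empty inputs: an empty hit table, an empty bucket, a query-only MSA and
  an empty database all flow through as identities or empty results, not
  errors; a single-chain partition is an error for interface metrics, which
  are undefined there.
* Known limits: composition through representatives is an approximation to
  profile realignment (exact only without member indels); the naive search
  backend is quadratic and exists for testing; genome-distance matching is
  greedy, not optimal, for more than a handful of hits; the renderer does
  not depth-sort *within* a segment, so very long segments can overlap
  incorrectly — the standard limitation of the technique.
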