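# foldprep

Everything around a protein structure predictor, minus the predictor.

Modern structure prediction pipelines spend most of their engineering not in
the neural network but around it: building a multiple sequence alignment
(MSA) that is deep, diverse and small enough to fit in memory; pairing MSAs
across chains so a complex prediction sees orthologs matched by species;
assembling model input features with residue-index chain breaks; ranking the
resulting models by PAE-derived confidence; and scheduling large batches so
that model compilation, recycling and low-value inference don't dominate the
run time. foldprep implements that computational layer as a tested R
package, against a *pluggable predictor contract* — a scripted mock in the
test suite — so every algorithm runs in seconds on one CPU from synthetic
fixtures. It is aimed at people building or studying prediction pipelines
who need the surrounding machinery to be inspectable and testable in
isolation.

## What is implemented

* **MSA I/O** — A3M (lowercase-insertion convention), aligned FASTA,
  Stockholm 1.0 and Clustal readers converging on one query-anchored `msa`
  tibble; identity/coverage primitives.
* **Diversity-aware filtering** — the three-stage filter: per-cluster 95%
  redundancy removal, a BLOSUM62 score-per-column filter (0.8 bits,
  activating at 100 hits), and a bucketed diversity filter that keeps the
  3,000 most diverse sequences *within each* query-identity bucket
  `[0,0.2], (0.2,0.4], …, (0.8,1]` (buckets under 1,000 hits pass through),
  so redundancy can never be eliminated across buckets. Diversity selection
  is deterministic farthest-point greedy over pairwise identity.
* **MSA construction pipeline** — E-value acceptance (`< 0.1`), expansion of
  hits into cluster members by composing stored member↔representative
  alignments into the query frame, and the two-database build
  (`build_msas()`); plus a naive Smith–Waterman search backend with
  Karlin–Altschul E-values as test plumbing.
* **Complex pairing** — best-hit-per-species pairing (coverage ≥ 50%,
  smallest E-value per chain, complete species only) and genome-proximity
  pairing via base-36 accession ordinals.
* **Feature assembly** — block-diagonal homo-/hetero-oligomer MSA layouts,
  residue-index vectors with chain gaps > 32 (the relative-position
  clipping cap), clipped relative-position bins, 512/1,024 MSA subsampling,
  and 10% shape padding for compile-cache reuse.
* **Confidence & ranking** — mean pLDDT, inter-chain PAE, pTM and ipTM from
  the PAE matrix (`pTM = max_i mean_j 1/(1+(PAE_ij/d0)²)`,
  `d0 = 1.24·(max(N,19)−15)^{1/3} − 1.8`); single chains rank by pLDDT,
  complexes by (i)pTM.
* **Batch scheduling** — length-sorted processing, a compile cache keyed on
  (model configuration, padded shape), recycling (default 3) and early
  stopping on a score threshold or recycle tolerance, with a full event log.
* **Database reduction** — assign new sequences to existing clusters
  (>30% identity, ≥90% self-coverage), greedily cluster the remainder, and
  keep each cluster's 10 most diverse members.
* **2D rendering** — pseudo-3D ribbon diagrams as z-sorted, z-shaded 2D
  segments, plus MSA coverage and PAE plot data (ggplot2).
* **Synthetic fixtures** — seed-deterministic generators for MSAs with exact
  identity targets, species hit layouts, block PAE matrices, clustered
  databases and scripted mock predictors.

## Worked example

```r
library(foldprep)

# a synthetic MSA: 4,000 rows at identities 0.15 / 0.5 / 0.9 to the query
m <- make_msa(4000, 100, qid_targets = c(0.15, 0.5, 0.9), seed = 42)
m
#> # An MSA: 4001 rows, query length 100

# final-stage diversity filter, capped at 300 per bucket for the example
f <- bucketed_diff_filter(m, filter_params(filter_min_enable = 1000, diff = 300))
table(cut(query_identity(f), c(-1e-9, .2, .4, .6, .8, 1)))
#> (-1e-09,0.2]    (0.2,0.4]    (0.4,0.6]    (0.6,0.8]      (0.8,1]
#>          300            0          300            0          300
```

Each populated bucket is reduced to its 300 most diverse members; empty
buckets stay empty. Confidence metrics from a block-structured PAE matrix
(two chains of 60 residues; intra-chain error 2 Å, inter-chain 6 Å):

```r
part <- rep(1:2, each = 60)
pae  <- make_pae(120, part, intra_level = 2, inter_level = 6,
                 noise_sd = 1, seed = 1)
round(c(inter_pae = inter_pae(pae, part),
        ptm  = ptm_from_pae(pae),
        iptm = iptm_from_pae(pae, part)), 4)
#> inter_pae       ptm      iptm
#>    5.9960    0.5865    0.3525
```

The mean cross-chain error recovers the generating level (~6 Å), and ipTM
is lower than pTM because it scores only the (noisier) interface. Batch
scheduling with early stop at pLDDT 85 against a scripted predictor whose
recycles yield pLDDT 62, 74, 88:

```r
script <- data.frame(model = rep(1:5, each = 3), recycle = rep(1:3, 5),
                     plddt = rep(c(62, 74, 88), 5))
out <- run_batch(list(q1 = strrep("M", 80), q2 = strrep("K", 85),
                      q3 = strrep("W", 150)),
                 make_mock_predictor(script),
                 run_config(stop_at_score = 85))
dplyr::count(out$events, event)
#>   event          n
#> 1 compile        2
#> 2 early_stop     3
#> 3 evaluate       9
```

Two compiles serve three queries (the 88-wide padded shape of `q1` also
fits `q2`; `q3` needs its own), and each query stops after three recycles
of model 1 — recycle 3 reaches pLDDT 88 ≥ 85, so models 2–5 are skipped:
9 evaluations instead of 45.

## Command line

A thin CLI wraps the file-to-file operations:

```sh
foldprep convert --in-format sto aln.sto aln.a3m
foldprep filter in.a3m out.a3m --diff 3000 --max-seq-id 0.95 --filter-min-enable 1000
foldprep pair --mode species --min-cov 0.5 chainA.tsv chainB.tsv --out paired.a3m
foldprep rank --mode complex scores/*.json
```

(`inst/exec/foldprep`; after installation, call it via
`Rscript -e 'foldprep::foldprep_main()' ...` or put the script on `PATH`.)

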