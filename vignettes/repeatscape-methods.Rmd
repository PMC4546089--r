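---
title: "Repeat discovery and genome community analysis from unassembled reads: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat discovery and genome community analysis from unassembled reads: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

Low-coverage whole-genome shotgun (WGS) reads sample a genome roughly in
proportion to the genomic abundance of the sequences they derive from.
`repeatscape` exploits this to quantify transposable-element (TE) families
without an assembly: reads are compared all-against-all, similar reads form a
weighted graph whose communities correspond to repeat families, and the share
of sampled reads falling into a family's cluster estimates that family's
genomic fraction. Around this core sit a read-depth genome-size estimator, a
community-ecology layer (rank-abundance models, Shannon statistics) that
treats TE families as species and TE copies as individuals, and phylogenetic
comparative tests (Blomberg's K, independent contrasts, PGLS) for analyzing
TE abundances across species on a tree.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data generators do
and do not emulate.

# Read preprocessing

Reads are filtered per pair: a pair survives only if **both** mates pass all
tests. Per-mate tests, in order: non-IUPAC characters (anything outside
`A,C,G,T,N` rejects the mate), minimum length (default 40 bp), minimum mean
Phred quality (default 15), maximum N percentage (default 20 %), and a
low-complexity screen. Before testing, a trailing run of `N`s at least
`trim_ns_right` (default 10) long is removed entirely; removing the whole
run (rather than at most `trim_ns_right` bases) makes filtering idempotent —
filtering the survivors is a no-op, which the tests assert.

The complexity score is the Shannon entropy of overlapping trinucleotide
counts, `100 * H3 / ln(min(64, L - 2))` with natural logarithms; a
homopolymer scores 0, a read whose 3-mers are all distinct scores 100. The
default threshold of 60 is inclusive (a score of exactly 60 passes), as are
the length and quality thresholds. This entropy definition is normative for
this package: it is testable against a hand tally and of the same order as
the screens commonly applied to Illumina data.

The organelle/contaminant screen drops a pair when **either** mate has a
local alignment to any contaminant sequence at >= 90 % identity over >= 50 bp
(configurable). Pair-level rejection is used throughout because downstream
cluster merging depends on intact mate links.

Subsampling draws `k` pairs uniformly without replacement under a caller
seed, never splitting mates, and returns pairs in their original input order
(the canonical order), so identical seeds give byte-identical outputs.

# All-vs-all similarity and graph clustering

## Alignment

Candidate read pairs are found by shared 12-mers (both strands; at least 2
shared seeds required), then aligned with a banded Smith–Waterman around the
modal seed diagonal (band halfwidth 10 by default). Scoring is match +1, mismatch −3, and affine
gaps costing 5 + 2 per gap base — the same convention as
`Biostrings::pairwiseAlignment(gapOpening = 5, gapExtension = 2)`, which
serves as the exhaustive-DP oracle in the test suite. A hit is kept when the
alignment is >= 55 bp, >= 90 % identical (matches / alignment columns), and
covers >= 55 % of the shorter read. These three thresholds are explicit
configuration; the −5/−2 gap penalties are a stated choice where the
published scoring was incomplete.

Seeding bounds sensitivity: below roughly 85 % identity, exact 12-mers
become rare and hits can be missed. For the pipeline's use cases — reads
from TE copies a few percent diverged, annotation against their own
consensus, transcript mapping of reads with sub-percent error — seeds are
plentiful. The 50–100 % identity range scanned by the genome-size threshold
grid is therefore a filter floor, not a claim that 50 %-identical alignments
are exhaustively found.

The k-mer length (12), band width, and `min_seeds` are exposed; the band
should exceed the expected cumulative indel offset between two reads
(about 0.2 indels per 100 bp read at the generator defaults, so 10 is
generous).

## Louvain clustering

The weighted graph (edge weight = best qualifying alignment score) is
partitioned by two-phase Louvain maximization of modularity

$$Q = \sum_c \left[\frac{\Sigma^{in}_c}{2m} - \left(\frac{\Sigma^{tot}_c}{2m}\right)^2\right]$$

at resolution 1. Node visit order is shuffled from the seed; ties between
equal-gain moves go to the lower community index, so runs are deterministic
given a seed. Because greedy local moving can stall in local optima — on
dense random weighted graphs of only 8 nodes, both this implementation and
igraph's reference implementation miss the exhaustively enumerated optimum
in a few percent of instances no matter how many singleton-start restarts
are used — the optimizer is a deterministic multistart that alternates
classic singleton starts with random initial partitions (an
iterated-Louvain diversification). With the default 10 restarts the
returned partition attains the enumerated maximum on all tested 4–8-node
graphs, and the reported Q is always recomputed from the returned partition
by an independent formula evaluation.

## Mate-pair merging

Louvain typically splits one repeat family into several "position blocks"
along its consensus, because 100 bp reads only align when they overlap by
>= 55 bp. Mate pairs (insert ≈ 400 bp) span adjacent blocks and are used to
merge clusters: two clusters merge when at least `min_links` mate pairs span
them, recounted and applied iteratively until a fixpoint (which closes
transitive chains). The default `min_links = 2` suits sparse, real-scale
sampling (around 0.03× coverage, where fragments almost never straddle the
junction between two distinct genomic elements). At around 1× coverage a
single genomic adjacency between copies of two different families already
yields 1–2 spanning pairs, so the recovery analyses at that depth use
`min_links = 10`: genuine same-family block links number in the hundreds
there, while cross-family junction links stay in the single digits. The
threshold is a per-run parameter, reported in the run manifest.

# Annotation and composition

Each clustered read votes for the family of its single best-scoring library
hit (>= 55 bp, >= 90 % identity by default; ties broken by library order).
The cluster's label is the plurality family; `hit_fraction` is the share of
cluster reads voting for it. The genomic fraction credited to a family is
`(cluster_size / total_sampled_reads) * hit_fraction`; the remainder of an
annotated cluster accrues to "unannotated", and all reads outside any
cluster accrue to "unclustered", so per-replicate fractions sum to exactly 1
(a conservation invariant the tests assert). Replicates re-run
sample → cluster → annotate under distinct seeds; the composition table
reports per-replicate fractions, their mean and sample SD (SD is `NA`, not
0, with a single replicate). The coverage-titration helper converts genome
coverage fractions into pair counts via
`k = level × genome_length / (2 × read_len)` and summarizes each level by
the mean coefficient of variation (SD/mean) over families with nonzero mean.

The repeat library uses a tab-separated FASTA header dialect
(`>name<TAB>superfamily<TAB>family`); a bare `>name` is accepted and mapped
to superfamily/family "unknown". Superfamilies map to coarse classes
(Class I LTR, Class I non-LTR, Class II) through an editable TSV shipped
under `extdata`.

# Genome-size estimation

Reads are mapped to a reference transcript set; each read contributes its
best qualifying alignment (>= 60 bp, >= 70 % identity by default) to exactly
one transcript (score ties to the lowest transcript index, logged).
Per-transcript coverage is `cov = N / L` (aligned bases over transcript
length); zero-coverage transcripts are excluded, the top 10 % of transcripts
by coverage are dropped (`ceiling` of the fraction; if trimming would empty
the set nothing is trimmed and a warning is raised), and

$$Cval = P \times \frac{n \times l}{\overline{cov}}$$

with ploidy `P`, total read count `n` and read length `l`. Two small biases
are inherent and deliberately uncorrected, since the published formula has
no correction: dropping the top decile pushes the mean coverage down, and
read–transcript overlaps shorter than the 60 bp floor at transcript edges
are excluded. Both shrink with transcript length and depth; at 1.5× depth
with 0.8–2 kb transcripts they total roughly +5–10 % in Cval, within the
15 % recovery band the tests enforce. A threshold-sensitivity grid re-filters
one base alignment run over length × identity thresholds and reports the
error surface against a supplied truth, with its argmin.

# Rank-abundance models and diversity

TE families are treated as species and their abundances (counts, or genome
fractions scaled to pseudo-counts, by default per million) as individuals.
All five models share one likelihood convention — Poisson log-likelihood
`sum(a_r log mu_r - mu_r)` with the factorial constant dropped (dropping it
shifts every model equally, so BIC ordering is unchanged; a test verifies
this) — and are ranked by `BIC = -2 loglik + k ln(S)`:

| Model | Expectation at rank r | k |
|---|---|---|
| Null (brokenstick) | `(J/S) Σ_{x=r}^{S} 1/x` | 0 |
| Preemption | `J α (1-α)^(r-1)` | 1 |
| Lognormal | `exp(μ + σ Φ⁻¹((S-r+0.5)/S))` | 2 |
| Zipf | `J p r^γ` | 2 |
| Mandelbrot | `J c (r+β)^γ`, β > −1 | 3 |

Fits use deterministic multistart L-BFGS-B on transformed parameters
(logit α; log σ; log p <= 0; log(β+1)), with convergence driven to
`factr = 1e2`. The Mandelbrot multistart includes the fitted Zipf solution
at β = 0, which guarantees the nesting identity
`loglik(Mandelbrot) >= loglik(Zipf)` that the tests assert on every vector.
Tied counts receive ranks by family-label order, so ranking is
deterministic. `J` is always the observed total `Σ counts` (the container's
invariant); consequently the Zipf `p` is the rank-1 share of the observed
total, and simulation-recovery checks compare the rank-1 expectation rather
than a nominal `p` whose generator total differs from the observed total.

The model-recovery simulator draws Poisson counts around a model's own
rank-expectation curve — for the lognormal, the plotting-position curve
above, not iid lognormal draws. Sorted iid draws deviate from their expected
order statistics with non-Poisson noise that, at realistic count scales,
lets the three-parameter Mandelbrot outfit the true model; generating from
the rank curve makes "data simulated from model M selects M" a
well-posed calibration, and the BIC winner rates the acceptance suite
checks (>= 80 % preemption, >= 70 % lognormal) are computed under it.

Shannon diversity is `H = -Σ p_i ln p_i` and evenness `E = H / ln S`
(reported `NA` at S = 1); both cross-checked against vegan in the tests.

# Phylogenetic signal

Contrasts follow Felsenstein's pruning algorithm; multifurcations are
resolved to zero-length branches first and zero-length branches replaced by
1e-8 (both logged in attributes). Blomberg's K uses the Brownian covariance
`C` from branch lengths, the GLS phylogenetic mean, and the ratio of
observed to Brownian-expected `MSE0/MSE`; it equals 1 on star phylogenies
for any trait (asserted numerically to 1e-6 — the identity is algebraic but
the implementation runs through `vcv()` and `solve()`). Significance uses a
one-sided permutation test: the observed statistic is the variance of the
contrasts, trait values are shuffled across tips, and
`p = (1 + #{null <= observed}) / (n_perm + 1)`; lower contrast variance
means stronger signal. Because contrasts are a linear map of tip values, the
map is computed once and permutations reduce to matrix products.

PGLS estimates `β = (XᵀC⁻¹X)⁻¹XᵀC⁻¹y` with a slope t-test on n−2 degrees of
freedom and r² defined on the Cholesky-whitened scale against the
phylogenetic mean; with identity covariance it reduces to OLS to 1e-10,
which is tested. The ordinal trend test regresses a trait on a user-supplied
phylogenetic position index (a ladderized tip order is provided as the
tree-derived default) with identity covariance; the index is an explicit
input because "phylogenetic order" is not uniquely defined by a tree.

# Synthetic data: what it does and does not emulate

`make_genome` plants, in an i.i.d. background of configurable GC, TE
families with per-family consensus length, copy number, per-copy divergence
(substitutions and indels), and random strand; copies are placed uniformly
without overlap by rejection sampling, and optional single-copy sequences
(transcripts) are embedded once each. The truth ledger records every
placement in 0-based half-open coordinates and the per-family true genomic
fraction. `simulate_reads` draws uniform fragments with Gaussian insert
sizes, R1 forward and R2 reverse-complemented, uniform substitution errors,
constant Q35 qualities, and an origin ledger. `simulate_tree_and_traits`
produces pure-birth trees (via `ape::rphylo`) with recursive Brownian
traits.

Deliberately not emulated: nested/fragmented TE copies (non-overlapping
placement keeps truth fractions unambiguous; nesting would blur them),
solo-LTR formation, insertion age structure, GC-biased or position-dependent
sequencing error, quality ramps, and indel sequencing errors. Passing the
recovery tests therefore shows the pipeline recovers planted abundances
under clean, well-separated families; on real data, diverged or nested
families and library incompleteness will push reads into "unannotated"
rather than mislabel them, because annotation requires a qualifying
library hit.

## Study conditions used by the validation suite

The composition-recovery analyses use a 1 Mb genome with three planted
superfamilies at 30 % (Gypsy: two families), 15 % (Copia: two families) and
5 % (L1: one family), consensus lengths 2.5–3 kb, 2 % per-copy divergence,
0.2 % indels, 40 % background GC; reads are 100 bp pairs at 400 ± 40 bp
insert and 0.5 % error, sampled to 1× coverage (5,000 pairs), with 20
sampling seeds and `min_links = 10`. The titration analysis reuses that
family structure on a 10 Mb genome so the lowest coverage level (0.056 %)
still implies a nonzero pair count; levels 0.056 % and 5.1 % are compared
with 3 replicates each. Genome-size recovery uses 150 kb genomes with 30
embedded transcripts of 0.8–2 kb at 1.5× depth over 20 seeds. RAD selection
uses 100 simulations per generating model; K calibration uses 500 Brownian
simulations on one 32-tip pure-birth tree, and the permutation test's type-I
error uses 200 null datasets at 199 permutations. These sizes are the
package's validation design; all are parameters of ordinary exported
functions and scale up directly.

# Known limitations

* Seed-and-extend alignment misses homology below roughly 85 % identity at
  the default k = 12; this bounds how diverged a TE copy can be and still
  join its family's cluster, mirroring the behavior of the BLAST-based
  pipelines this reimplements.
* Abundances are read-sampling estimates: families below a few times
  `1/k` of the genome are frequently missed at low coverage (that is what
  the titration quantifies).
* The genome-size estimator inherits the formula's trimming and edge biases
  discussed above.
* Louvain with multistart is still a heuristic on large graphs; only on
  enumerable graph sizes is optimum attainment verified.
* `merge_by_mates` uses an absolute link-count threshold; a link-fraction
  rule would behave differently when cluster sizes are very unbalanced.
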