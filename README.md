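# repeatscape

Transposable-element (TE) discovery and genome "community" analysis from
**unassembled** whole-genome shotgun reads.

Most plant genomes are dominated by TEs, yet assembling them is exactly what
repeats make hard. `repeatscape` sidesteps assembly: because shotgun reads
sample the genome in proportion to sequence abundance, the share of reads
that cluster together by similarity estimates the genomic fraction of the
repeat family they come from. The package implements the full pipeline and
its downstream quantitative layers:

1. **Preprocessing** — paired-aware quality/length/complexity filtering
   (trinucleotide-entropy screen), organelle/contaminant screening, and
   seeded random subsampling of read pairs.
2. **Graph clustering** — all-vs-all read comparison with a k-mer-seeded
   banded Smith–Waterman aligner (match +1 / mismatch −3, affine gaps),
   a weighted similarity graph, Louvain modularity clustering
   (`Q = Σ_c [Σin_c/2m − (Σtot_c/2m)²]`, seeded and multistarted), and
   mate-pair-link cluster merging.
3. **Annotation & composition** — per-read best-hit voting against a repeat
   consensus library (RepBase-style 3-field headers), plurality cluster
   labels, and replicate mean ± SD tables of per-family genomic fractions,
   plus a coverage-titration CV analysis.
4. **Genome size** — the read-depth estimator
   `Cval = P × n·l / mean(Cov_i)` with `Cov_i = N/L` per transcript,
   60 bp / 70 % alignment filters and a top-10 % coverage trim, plus a
   threshold-sensitivity grid.
5. **TE community ecology** — rank-abundance models (brokenstick null,
   niche preemption `Jα(1−α)^(r−1)`, lognormal, Zipf `Jpr^γ`,
   Zipf–Mandelbrot `Jc(r+β)^γ`) fitted by Poisson maximum likelihood and
   ranked by `BIC = −2·loglik + k·ln S`; Shannon diversity `H` and
   evenness `H/ln S`.
6. **Phylogenetic signal** — Felsenstein's independent contrasts,
   Blomberg's K with a one-sided PIC-variance permutation test, Brownian
   PGLS (`β = (XᵀC⁻¹X)⁻¹XᵀC⁻¹y`), and ordinal phylogenetic trend tests.
7. **Synthetic data** — generators for repeat-bearing genomes with planted
   families, paired-end reads, transcript sets, and Brownian traits on
   pure-birth trees, each with a ground-truth ledger, so every stage is
   validated by parameter recovery.

The alignment and Louvain engines are implemented in C++ (Rcpp); file
formats go through Biostrings (FASTA/FASTQ) and ape (Newick).

## Worked example

Plant three TE families (Gypsy at 20 % + 15 %, Copia at 15 %) in a 300 kb
genome, sequence it at ~1×, and recover the composition with three
replicates:

```r
library(repeatscape)

fam <- data.frame(
  name = c("RLG-1", "RLG-2", "RLC-1"),
  superfamily = c("Gypsy", "Gypsy", "Copia"),
  family = c("RLG_alpha", "RLG_beta", "RLC_gamma"),
  consensus_length = c(2500, 3000, 2500),
  copy_number = c(24, 15, 18),
  divergence = 0.02, indel_rate = 0.002)
gen <- make_genome(genome_spec(3e5, fam, background_gc = 0.4, seed = 42))
gen$ledger$fractions
#>      family superfamily    bp  fraction
#> 1 RLC_gamma       Copia 45007 0.1500233
#> 2 RLG_alpha       Gypsy 60004 0.2000133
#> 3  RLG_beta       Gypsy 45001 0.1500033

reads <- simulate_reads(gen, coverage = 1.2, read_len = 100,
                        insert_mean = 400, insert_sd = 40,
                        error_rate = 0.005, seed = 7)
run <- run_pipeline(reads, gen$library, sample_k = 1500, replicates = 3,
                    seed = 1, cluster_args = list(merge_links = 10L))
run$composition[, c("family", "superfamily", "mean", "sd")]
#>        family superfamily  mean      sd
#> 1 unannotated unannotated 0.305 0.00694
#> 2   RLG_alpha       Gypsy 0.207 0.00383
#> 3 unclustered unclustered 0.201 0.00631
#> 4   RLC_gamma       Copia 0.145 0.00154
#> 5    RLG_beta       Gypsy 0.142 0.00240
```

Each planted family is recovered within a percentage point of its true
fraction (20.0 → 20.7 %, 15.0 → 14.5 %, 15.0 → 14.2 %); single-copy
background reads land in "unclustered" (no similar partner at 1×) or in
small unannotated clusters, and per-replicate fractions always sum to 1.

Rank-abundance model selection and phylogenetic signal:

```r
vec <- rad_simulate("preemption", S = 20, J = 5000,
                    params = list(alpha = 0.3), seed = 11)
select_model(vec)
#> RAD model selection over S = 20 families:
#>       model   loglik k       BIC
#>  Preemption 26439.45 1 -52875.91
#>  Mandelbrot 26322.62 3 -52636.26
#>   Lognormal 26210.30 2 -52414.62
#>        Zipf 25919.71 2 -51833.42
#>        Null 25512.24 0 -51024.48
#> best: Preemption (delta BIC to runner-up: 239.7 )

sim <- simulate_tree_and_traits(24, birth_rate = 1, bm_sigma2 = 1, seed = 5)
k_significance(sim$tree, sim$trait, n_perm = 999, seed = 9)
#> Blomberg K = 1.0136, PIC variance = 1.177, p = 0.001 (999 perms)
```

The BIC correctly identifies the generating preemption model, and a
Brownian trait shows K ≈ 1 with significant signal against the permutation
null, as expected.

A thin command-line wrapper over these functions ships at
`inst/scripts/repeatscape.R` (subcommands `filter`, `sample`, `run`,
`genomesize`, `radfit`, `phylosignal`).

## Documentation

The methods vignette (`vignettes/repeatscape-methods.Rmd`) documents the
models and their assumptions, every tunable threshold with its default and
rationale, the numerical choices (optimizer multistarts, tie-breaking,
degenerate-input contracts), what the synthetic generators emulate and what
they deliberately do not, and known limitations.
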