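# dualseq

Tools for the computational core of a **dual RNA-seq host–pathogen
infection study**: one sequencing library per sample contains a mixture of
host (insect) and pathogen (fungal) transcripts, with the pathogen
contributing only fractions of a percent of the reads early in infection.
`dualseq` implements, as tested and reusable R functions, every stage
between raw paired-end reads and the temporal co-expression summary:

* **Sliding-window quality trimming** (window 3 nt, minimum surviving
  length 36 nt).
* A **seed-and-extend read aligner** (Rcpp core) with the linear score
  floor `f(L) = -4 - 0.5·L`, quality-scaled mismatch penalties, affine
  gaps, and a strict unique-mapping contract; score-exact against an
  exhaustive affine-gap dynamic program on small instances.
* **Sequential two-genome partitioning**: every pair is offered to the
  pathogen genome first; only the leftovers go to the host.  Pathogen
  pairs that would also map to the host are counted (`cross_mapped`) as a
  diagnostic, never reassigned.
* **Iterative reference polishing** of a strain-divergent host genome:
  align → pileup → Phred-scaled substitution calls
  (`QUAL = −10·log₁₀ P(ref genotype | bases)`, haploid independent-error
  model) → replace the reference base wherever a single-alternate call
  exceeds QUAL 5.0 (strictly) → repeat; residual multi-allelic SNPs and
  indels enter a **SNP-aware index** in which registered alleles are
  match-equivalent.
* **FPKM quantification**
  (`FPKM = count / ((len/10³)·(total/10⁶))`) with fragment-midpoint
  assignment, pooling of the sparse pathogen replicates, per-time-point
  **presence (Venn) sets**, and top-expressed-gene tables.
* **Temporal co-expression reduction**: log₂ expression relative to each
  gene's own mean, **UPGMA** average-linkage clustering, cluster count
  chosen by minimising the **Davies–Bouldin index**, and per-cluster
  activity maps on a fixed grid.
* Closed-form assay helpers: **Abbott's correction**
  `(treated − control)/(1 − control)` and qPCR **NRQ**
  (`RQ = E^(Cq_cal − Cq_s)`, normalised by the geometric mean of the
  reference genes).

A first-class synthetic-data module (`simulation_config()`,
`simulate_genomes()`, `simulate_reads()`, `simulate_expression_profiles()`)
generates two-organism read sets with recorded ground truth — strain
divergence (clustered + uniform substitutions, indels), rising pathogen
read share, planted co-expression clusters — so the whole pipeline is
testable without downloads.  The methods vignette
(`vignettes/dual-rnaseq-workflow.Rmd`) documents every model, default and
design choice.

## Worked example

```r
library(dualseq)

cfg <- simulation_config(
  seed = 42, pathogen_genome_len = 10000, host_genome_len = 30000,
  reads_per_sample = 2000, replicates_per_timepoint = 2,
  pathogen_read_fraction = c(0.005, 0.01, 0.02, 0.03),
  n_genes = c(pathogen = 10, host = 30))

res <- run_pipeline(cfg)

res$fractions$per_timepoint
#>   timepoint pathogen host pathogen_fraction
#> 1        3h       19 3967       0.004766683
#> 2       12h       44 3955       0.011002751
#> 3       48h       99 3901       0.024750000
#> 4       72h      121 3875       0.030280280

res$polish
#> polish_report:
#>  iteration snps_detected snps_applied mapping_rate
#>          1           143          143    0.9884699
#>          2             0            0    0.9947446
#>   mapping rates: raw=0.988, after_iter1=0.995, after_iter2=0.995, snp_aware=0.998
#>   residual: 0 multi-alt SNPs, 37 indels registered

head(top_expressed(res$pathogen_expr, "72h"), 3)
#>          gene_id     fpkm
#> 1 pathogen_g0002 231405.0
#> 2 pathogen_g0008 214876.0
#> 3 pathogen_g0004 198347.1
```

Reading the output: the recovered per-time-point pathogen fractions track
the configured rising share (0.5% → 3%); polishing detects 143
substitutions in the first pass and none in the second — the signature
of the iterative correction converging — while the host mapping rate
climbs from 98.8% on the raw reference to 99.8% with the final SNP-aware
index; the FPKM table ranks the pathogen genes at the last time point
(values are large because the pooled pathogen library is tiny, which is
exactly why replicates are pooled before FPKM).  `res$selection` holds the
Davies–Bouldin trace and chosen cluster count, and
`plot(res$activity, timepoint)` draws the per-cluster activity grid.

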