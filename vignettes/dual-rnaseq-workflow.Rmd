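---
title: "Dual RNA-seq host–pathogen analysis: models and design choices"
author: "dualseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual RNA-seq host–pathogen analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualseq)
```

## The analysis problem

In a dual RNA-seq infection experiment, RNA extracted from infected animals
is sequenced in bulk, so every library is a mixture of host and pathogen
transcripts.  When the pathogen is rare — an entomopathogenic fungus in the
first days of an insect infection contributes fractions of a percent of the
reads — three computational problems dominate the analysis:

1. **Read partitioning.** Reads must be assigned to the correct organism
   before quantification.  `dualseq` maps every read pair to the pathogen
   genome *first* and only offers the leftovers to the host genome.  This
   order protects the scarce pathogen signal: a pathogen read lost to the
   host genome is unrecoverable, while the reverse is diagnosed (but never
   acted on) by re-aligning pathogen-assigned pairs against the host and
   reporting the `cross_mapped` count.
2. **Reference polishing.** The sequenced host population is usually a
   local strain, not the strain of the reference assembly.  Unrepaired
   strain divergence depresses the host mapping rate and contaminates the
   unmapped pool that feeds later stages.  `dualseq` implements the
   iterative correction loop: align, pile up, call substitutions with a
   Phred-scaled site quality, rewrite the reference base wherever a
   single-alternate call exceeds quality 5.0 (strictly), and repeat; after
   the final iteration the *residual* calls — multi-allelic substitutions
   and indels, which base rewriting cannot express — are registered in a
   SNP-aware index that treats any registered allele as match-equivalent.
3. **Temporal reduction.** The host transcriptome over a handful of time
   points is summarised by clustering log-relative expression profiles
   with UPGMA, choosing the cluster count by the Davies–Bouldin index, and
   averaging member profiles into a per-cluster activity map laid out on a
   fixed grid so maps from different time points are positionally
   comparable.

Around these sit standard steps: sliding-window quality trimming, FPKM
quantification with pooling of the sparse pathogen replicates, per-time-
point presence (Venn) sets, and two closed-form wet-lab-adjacent
computations (Abbott mortality correction and NRQ qPCR normalisation).

## The aligner and its score contract

The built-in aligner is a deliberately *unspliced* seed-and-extend mapper:
the synthetic genomes are intron-free, so spliced alignment machinery
would add complexity without exercising anything.  What it preserves
exactly is the score contract of the study design:

* matches score 0; penalties are negative; a read of length $L$ is
  reported only when its best end-to-end score reaches
  $f(L) = A + B\,L$ with defaults $A=-4$, $B=-0.5$;
* mismatch penalties are quality-scaled between 2 (quality 0) and 6
  (quality ≥ 40), the convention of seed-and-extend mappers;
* gaps are affine: a gap of length $k$ costs $|g_o| + k\,|g_e|$ with
  defaults $g_o=-5$, $g_e=-3$;
* **unique mapping**: the number of distinct loci tied at the best score
  is counted (exact ties only — a deliberately conservative margin of 0),
  and reads with more than one locus are excluded from every downstream
  computation.

Candidate loci come from exact k-mer seeds (default $k=16$, both strands
via querying the reverse-complemented read); each candidate window is
scored by a full Gotoh dynamic program over a padded window (`pad` = 40 bp,
which bounds the largest recoverable indel).  Because a match scores 0, an
exact end-to-end hit is provably optimal, which gives the implementation a
cheap exact-match fast path without changing any result.  On references up
to a few kb the aligner is score-identical to an exhaustive affine-gap DP
over all positions and strands; the test suite checks this on hundreds of
randomly mutated reads.

## The site-quality model

The study design specifies only a threshold ("quality greater than 5.0"),
not a genotype-likelihood model, so the package defines its own explicit
one: a haploid site with genotype $g$ emits base $b_i$ with probability
$1-e_i$ if $b_i = g$ and $e_i/3$ otherwise, where $e_i = 10^{-Q_i/10}$ is
the base's quality-implied error rate.  With a flat prior over the four
genotypes,

$$\mathrm{QUAL} = -10\log_{10} P(\text{reference genotype}\mid \text{bases}),$$

computed in log space so deep pileups cannot underflow.  A call is emitted
when a non-reference allele has at least `min_alt_count` (default 2)
supporting reads; a correction is applied only for single-alternate
substitution calls with QUAL strictly above 5.0.

Four filters guard the caller against alignment artifacts rather than
sequencing noise:

* **Indel allele fraction** (`min_indel_fraction`, default 0.3): a genuine
  haploid indel is shown by essentially every read that spans it, whereas
  sporadic gap placements inside dense mismatch runs appear in a small
  minority of reads.  Only fraction-passing indels are called and
  registered.
* **Indel proximity masking** (`snp_gap`, default 20 bp): reads whose ends
  overhang an indel junction align the overhang as a short run of
  apparent mismatches instead of opening a gap, which otherwise produces
  confident, perfectly reproducible false substitution calls hugging
  every indel.  Substitution calls within `snp_gap` of a called indel are
  suppressed — the same idea as the SnpGap filter of standard callers.
  The cost is that true substitutions inside those windows (a few percent
  of sites at the default indel density) are left uncorrected; they
  surface again as residual calls.
* **Read-position support** (`end_prox`, default 10 bp): an alternate
  allele must reach `min_alt_count` among *read-internal* observations,
  at least `end_prox` bases from both read ends.  When a breakpoint is
  too costly to traverse at all — a deletion longer than the score floor
  allows — no gapped evidence exists for the proximity mask to key on,
  but reads overhanging the junction by a few bases still map with the
  overhang as mismatches, and those overhangs vote *consistent* phantom
  alternates at the flanking sites.  Such artifacts live exclusively near
  read ends, which is exactly the read-position bias that standard
  callers test for.  The cost is that sites covered only end-proximally
  (the outermost ~10 bp of each transcript unit) cannot be called.
* **Local depth** (`min_local_depth_ratio`, default 0.3 of the median
  depth within ±`local_depth_window` = 100 bp): a reference segment
  entirely absent from the strain receives no legitimate coverage at all,
  only the sparse junction-overhang placements above — a coverage crater.
  Substitution calls inside craters are excluded.  A stricter variant
  that also masked every call within 20 bp of any coverage anomaly was
  evaluated and rejected: it suppressed genuine substitutions around
  dense divergence faster than it removed artifacts.

Indels are *called* but never *applied*: base replacement only expresses
substitutions, so indels travel exclusively into the SNP-aware index,
where registered deletions are traversable and registered insertions
consumable at no score cost.

## What the simulator emulates — and what it does not

`simulation_config()` fixes the study conditions: two i.i.d. random
genomes at configurable GC (default 50 kb pathogen / 100 kb host), four
time points ("3h", "12h", "48h", "72h") in triplicate, 2×100 bp pairs with
a fragment length of 250 ± 30 bp, and a pathogen read share rising from
0.002% to 0.0063% across time points — the same order of magnitude and the
same rising shape as a real early-infection series, at desk-scale absolute
depth.  Host reads are always drawn from the *divergent strain* genome;
expression-weighted fragment sampling over the gene models (weight
$2^{\beta_g + \pi_{c(g),t}}$, with per-gene baselines $\beta_g \sim
N(0, 0.75^2)$ log2 units and planted cluster profiles $\pi$) makes the
planted co-expression structure recoverable from FPKM downstream.

**Divergence placement.** Host-strain substitutions default to 0.5%/bp
with 30% of them concentrated in dense hotspots (300 bp windows at
0.08 subs/bp) and the rest uniform; indels (5×10⁻⁴/bp, lengths 1–20,
insertions and deletions equally likely) are placed uniformly away from
other edits.  The hotspot layer is a deliberate design choice: real
strain divergence in outbred insect populations is clustered in haplotype
blocks, and that clustering is precisely what makes *iterative* correction
meaningful.  Under the score threshold $f(L)$ above, a 2×100 bp read
tolerates up to nine high-quality mismatches, so at a purely uniform
0.5%/bp (Poisson mean 0.5 mismatches per read) essentially no read ever
fails the threshold and a single correction pass would already be
saturating.  Hotspot reads, by contrast, genuinely fail to map until
their neighbours' evidence has corrected part of the window — the second
iteration then detects far fewer variants than the first, and the mapping
rate climbs across stages, reproducing the qualitative behaviour of the
real pipeline at desk scale.

The quality model is two-state: a flat body whose Phred matches the
configured base error rate (errors are injected per base with probability
$10^{-Q/10}$, so qualities and realised error rates agree by
construction), plus an optional low-quality 3′ tail (default 5% of reads,
15 bp at Q8) that gives the trimming rule something realistic to act on.

Not emulated, by design: spliced transcripts and introns, adapter
contamination, PCR duplicates, strand-specific chemistry, repeats (the
genomes are i.i.d., so unique mapping is the norm), and any sequence
homology between host and pathogen.  Consequently, passing tests say
nothing about spliced-alignment behaviour or about partition purity
between *homologous* genomes; the cross-mapping diagnostic exists
precisely because real genome pairs share sequence.

Read names encode the origin (organism, sample, source gene) purely for
truth-keeping; a name-scrambling test verifies that no pipeline stage
reads them.

## Quantification conventions

A fragment is the leftmost-to-rightmost span of its uniquely mapped mates
on one reference and is assigned to the gene containing its integer
midpoint $\lfloor (s + e - 1)/2 \rfloor$.  With single-exon, non-
overlapping gene models this midpoint rule is equivalent to any
proportional-overlap scheme almost everywhere, and it keeps
$\mathrm{FPKM}_g = c_g / \big((\ell_g/10^3)(N/10^6)\big)$ exactly
conservative: $\sum_g \mathrm{FPKM}_g \ell_g / 10^3 =
10^6 \cdot (\text{assigned}/N)$, which the tests assert to $10^{-9}$.
Pathogen replicates are pooled (counts and totals summed *before* FPKM)
because single-replicate pathogen columns at realistic fractions contain a
handful of fragments; host replicates stay separate.  "Present" at a time
point means FPKM strictly above a threshold whose default is 0 — the most
inclusive reading of "detected" — and is configurable because that
definition is genuinely underdetermined.

## Clustering conventions

Profiles are $\log_2$ of each gene's FPKM divided by its own across-time
mean — scale-free by construction, with a pseudocount of 1 FPKM added
before the ratio only when zeros are present.  UPGMA uses Euclidean
distance on these profiles by default (correlation distance is available):
Euclidean is the conventional companion of average linkage, and the
Davies–Bouldin index is defined over a metric space.  Ties in the merge
order are broken by the lexicographically smallest pair of smallest member
leaf indices, making the dendrogram fully deterministic.  Merge heights
are checked to be non-decreasing (a guaranteed property of UPGMA on a
metric; a violation is an error, not a warning).

The cluster count is chosen by cutting the dendrogram at every
$K \in [2, \min(\lceil n/2\rceil, 400)]$ and globally minimising the
Davies–Bouldin index

$$\mathrm{DB} = \frac1K \sum_i \max_{j\ne i}\frac{S_i+S_j}{M_{ij}},$$

with singleton scatters $S=0$ and coincident centroids flagged as
degenerate ($+\infty$ similarity).  Whether the original protocol
minimised DB globally or used it as a stopping heuristic is ambiguous;
global minimisation is implemented and the full score trace is exported so
either reading can be inspected.  Ties go to the smallest $K$.  The
activity map averages member profiles per cluster and places clusters on
a row-major near-square grid in ascending cluster id — purely
presentational, but fixed, so per-time-point maps are superimposable.

## Assay formulas

Abbott's correction is $(p_t - p_c)/(1 - p_c)$, clamped to 0 with a
warning when treated mortality falls below control, and undefined at
$p_c = 1$.  NRQ computes $RQ_{g,s} = E_g^{\,Cq_{g,\mathrm{cal}} -
Cq_{g,s}}$ against a calibrator sample (default: the first sample — the
original study does not state its calibrator, and the choice rescales all
samples by a common factor without changing ratios) and divides each
target's RQ by the geometric mean of the reference genes' RQs.
Efficiencies default to 2.0 per gene (none are reported) and are
configurable per gene.

## Problem sizes and numerical choices

The test and acceptance workloads run the full pipeline at the package's
reference desk scale: a 100 kb host genome at 0.5%/bp divergence with 30×
error-free (and separately 0.2%-error) 2×100 bp coverage for polishing;
50,000 + 500 reads for partitioning; 500 genes × 4 time points × 8 planted
clusters (centroid separation ≥ 10× the within-cluster SD, enforced by
rejection sampling) across 20 seeds for cluster-count recovery; 200 reads
≤ 60 bp against references ≤ 2 kb for aligner exactness; and 100 random
≤ 8-leaf matrices for UPGMA exactness.  These sizes keep every property
statistically comfortable — e.g. the binomial checks sit at 3 SD — while a
full run of the suite stays in the minutes range on one core.

Other numerical details: all scores are integers (quality scaling is
rounded), so "exact tie" is well-defined; QUAL values are computed in log
space; the polishing loop is fixed at 2 iterations by default to match
the two-pass design, with convergence (zero applied corrections) reached
earlier on non-divergent input; the coordinate convention is 0-based
half-open everywhere internally, converting to 1-based only in SAM, VCF
and GFF3 output.

## Interfaces

The package's functions are the interface, composed in scripts or in
`run_pipeline()`; file exchange uses the field's text formats (FASTA,
gzipped FASTQ, GFF3, SAM, VCF 4.2, TSV, JSON).  No shell entry point is
shipped: every stage is a documented R function, and an analysis of this
kind is driven from R.

## Known limitations

* The aligner is unspliced and single-threaded; it is a faithful
  desk-scale carrier of the score/uniqueness contract, not a replacement
  for a production mapper on real genomes.
* The caller is haploid by construction; the insect pool's residual
  polymorphism is routed to the SNP-aware index as multi-allelic sites
  rather than genotyped.
* QUAL values follow the package's explicit error model; they share the
  threshold semantics, not the numeric values, of `bcftools` QUALs.
* Indel proximity masking trades a few percent of true substitutions near
  indels for the elimination of systematic false corrections; at the
  default densities this is the right trade, but genomes with extreme
  indel loads would deserve a smaller `snp_gap`.
* Presence thresholds, the NRQ calibrator and per-gene efficiencies are
  configurable because the underlying choices are underdetermined by the
  study design; the defaults are documented choices, not inferences.
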