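#' Simulation configuration for the dual RNA-seq test-bed
#'
#' Builds the single configuration object that drives every synthetic-data
#' generator in the package.  The defaults emulate, at desk scale, the design
#' of a time-course infection experiment in which a fungal pathogen
#' contributes a tiny and rising share of a mixed host/pathogen read pool
#' (fractions of order 0.002--0.006%), the host strain diverges from its
#' reference genome by substitutions and small indels, and each time point is
#' sequenced in triplicate.
#'
#' Strain divergence is placed in two layers: a uniform background and a
#' configurable fraction of substitutions concentrated in dense hotspots,
#' mimicking the clustered haplotype-block divergence seen between real
#' insect populations.  The total number of substitutions is always a single
#' `Binomial(host_genome_len, snp_divergence_rate)` draw; hotspots only
#' affect placement.
#'
#' All outputs downstream of a config are fully determined by `seed`.
#'
#' @param seed integer seed; determines every simulated output.
#' @param pathogen_genome_len,host_genome_len genome lengths in bp.
#' @param gc_content fraction of G+C bases in `[0, 1]`.
#' @param snp_divergence_rate substitutions per bp between the host strain
#'   and the host reference.
#' @param indel_divergence_rate indels per bp.
#' @param indel_max_len maximum indel length in bp (lengths are uniform on
#'   `1..indel_max_len`, insertions and deletions equally likely).
#' @param snp_hotspot_fraction fraction of substitutions placed inside dense
#'   hotspots (0 disables hotspots and recovers purely uniform placement).
#' @param snp_hotspot_width,snp_hotspot_rate hotspot window size (bp) and
#'   local substitution density (per bp) inside hotspots.
#' @param read_len read length in bp (paired-end, both mates equal length).
#' @param fragment_mean,fragment_sd fragment-size distribution in bp;
#'   `fragment_mean` must be at least `read_len`.
#' @param base_error_rate per-base sequencing error rate; base qualities are
#'   set so that `10^(-Q/10)` matches the realised per-base error
#'   probability.
#' @param tail_prob,tail_len,tail_quality fraction of reads receiving a
#'   low-quality 3' tail, the tail length (bp) and its Phred quality; gives
#'   the sliding-window trimmer something realistic to act on.
#' @param timepoints ordered character vector of time-point labels.
#' @param replicates_per_timepoint biological replicates per time point.
#' @param reads_per_sample read pairs per sample.
#' @param pathogen_read_fraction per-time-point expected fraction of pairs of
#'   pathogen origin; length must equal `length(timepoints)`.
#' @param n_genes named integer vector `c(pathogen = , host = )` of
#'   single-exon gene models tiling each genome.
#' @param n_clusters number of planted co-expression clusters.
#' @param cluster_profile_sd within-cluster gene-level noise (log2 scale).
#' @param min_profile_separation minimum Euclidean distance between planted
#'   cluster centroids (log2 scale); defaults to `10 * cluster_profile_sd`
#'   so that planted clusters are recoverable by construction.
#' @param expression_dispersion standard deviation (log2) of per-gene
#'   baseline expression around the genome mean.
#'
#' @return An object of class `dualseq_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              pathogen_genome_len = 50000L,
                              host_genome_len = 100000L,
                              gc_content = 0.5,
                              snp_divergence_rate = 0.005,
                              indel_divergence_rate = 5e-4,
                              indel_max_len = 20L,
                              snp_hotspot_fraction = 0.3,
                              snp_hotspot_width = 300L,
                              snp_hotspot_rate = 0.08,
                              read_len = 100L,
                              fragment_mean = 250,
                              fragment_sd = 30,
                              base_error_rate = 0.002,
                              tail_prob = 0.05,
                              tail_len = 15L,
                              tail_quality = 8L,
                              timepoints = c("3h", "12h", "48h", "72h"),
                              replicates_per_timepoint = 3L,
                              reads_per_sample = 50000L,
                              pathogen_read_fraction = c(2e-05, 3e-05,
                                                         4.5e-05, 6.3e-05),
                              n_genes = c(pathogen = 50L, host = 100L),
                              n_clusters = 8L,
                              cluster_profile_sd = 0.2,
                              min_profile_separation = NULL,
                              expression_dispersion = 0.75) {
  if (is.null(min_profile_separation))
    min_profile_separation <- 10 * cluster_profile_sd
  cfg <- list(seed = as.integer(seed),
              pathogen_genome_len = as.integer(pathogen_genome_len),
              host_genome_len = as.integer(host_genome_len),
              gc_content = gc_content,
              snp_divergence_rate = snp_divergence_rate,
              indel_divergence_rate = indel_divergence_rate,
              indel_max_len = as.integer(indel_max_len),
              snp_hotspot_fraction = snp_hotspot_fraction,
              snp_hotspot_width = as.integer(snp_hotspot_width),
              snp_hotspot_rate = snp_hotspot_rate,
              read_len = as.integer(read_len),
              fragment_mean = fragment_mean,
              fragment_sd = fragment_sd,
              base_error_rate = base_error_rate,
              tail_prob = tail_prob,
              tail_len = as.integer(tail_len),
              tail_quality = as.integer(tail_quality),
              timepoints = as.character(timepoints),
              replicates_per_timepoint = as.integer(replicates_per_timepoint),
              reads_per_sample = as.integer(reads_per_sample),
              pathogen_read_fraction = pathogen_read_fraction,
              n_genes = n_genes,
              n_clusters = as.integer(n_clusters),
              cluster_profile_sd = cluster_profile_sd,
              min_profile_separation = min_profile_separation,
              expression_dispersion = expression_dispersion)
  validate_config(cfg)
  class(cfg) <- "dualseq_config"
  cfg
}

validate_config <- function(cfg) {
  rates <- c("gc_content", "snp_divergence_rate", "indel_divergence_rate",
             "snp_hotspot_fraction", "snp_hotspot_rate", "base_error_rate",
             "tail_prob")
  for (r in rates) {
    v <- cfg[[r]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop(sprintf("'%s' must be a single value in [0, 1]", r))
  }
  if (any(cfg$pathogen_read_fraction < 0 | cfg$pathogen_read_fraction > 1))
    stop("'pathogen_read_fraction' values must lie in [0, 1]")
  if (length(cfg$pathogen_read_fraction) != length(cfg$timepoints))
    stop("'pathogen_read_fraction' must have one entry per timepoint")
  if (cfg$fragment_mean < cfg$read_len)
    stop("'fragment_mean' must be at least 'read_len'")
  if (cfg$indel_max_len < 1L) stop("'indel_max_len' must be >= 1")
  if (cfg$replicates_per_timepoint < 1L || cfg$reads_per_sample < 1L)
    stop("replicate and read counts must be positive")
  if (!all(c("pathogen", "host") %in% names(cfg$n_genes)))
    stop("'n_genes' must be named with 'pathogen' and 'host'")
  if (cfg$host_genome_len %/% cfg$n_genes[["host"]] < cfg$read_len ||
      cfg$pathogen_genome_len %/% cfg$n_genes[["pathogen"]] < cfg$read_len)
    stop("gene models would be shorter than the read length; reduce 'n_genes'")
  if (cfg$n_clusters < 1L) stop("'n_clusters' must be >= 1")
  invisible(cfg)
}

#' @export
print.dualseq_config <- function(x, ...) {
  cat("Dual RNA-seq simulation config (seed", x$seed, ")\n")
  cat(sprintf("  genomes: pathogen %d bp, host %d bp (GC %.2f)\n",
              x$pathogen_genome_len, x$host_genome_len, x$gc_content))
  cat(sprintf("  host strain divergence: %.4g subs/bp (%.0f%% in hotspots), %.4g indels/bp (max %d bp)\n",
              x$snp_divergence_rate, 100 * x$snp_hotspot_fraction,
              x$indel_divergence_rate, x$indel_max_len))
  cat(sprintf("  reads: 2 x %d bp, %d pairs/sample, error %.3g\n",
              x$read_len, x$reads_per_sample, x$base_error_rate))
  cat(sprintf("  design: %s; %d replicates; pathogen share %s\n",
              paste(x$timepoints, collapse = "/"),
              x$replicates_per_timepoint,
              paste(signif(x$pathogen_read_fraction, 2), collapse = "/")))
  cat(sprintf("  expression: %d+%d genes, %d planted clusters (sd %.2g)\n",
              x$n_genes[["pathogen"]], x$n_genes[["host"]],
              x$n_clusters, x$cluster_profile_sd))
  invisible(x)
}
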