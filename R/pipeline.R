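#' Run the full dual RNA-seq workflow on simulated data
#'
#' End-to-end convenience wrapper used by the vignette: simulate genomes
#' and reads, trim, partition every sample between pathogen and host,
#' polish the host reference with the pooled host-partition reads,
#' re-align host reads to the polished genome, quantify FPKM (pathogen
#' replicates pooled per time point, host kept per replicate), compute
#' presence sets and organism fractions, and reduce the host temporal
#' transcriptome by UPGMA + Davies-Bouldin selection.
#'
#' @param config a [simulation_config()].
#' @param params a [score_params()].
#' @param k_max upper bound of the cluster-count search (default
#'   `min(ceiling(n/2), 400)`).
#' @param polish_iterations correction iterations for the host reference.
#' @return A list with the intermediate objects: `genomes`, `sim`,
#'   `partitions`, `fractions`, `polish`, `pathogen_expr`, `host_expr`,
#'   `presence`, `profiles`, `selection`, `activity`.
#' @export
run_pipeline <- function(config = simulation_config(),
                         params = score_params(), k_max = NULL,
                         polish_iterations = 2L) {
  genomes <- simulate_genomes(config)
  sim <- simulate_reads(genomes, config)
  path_idx <- build_index(genomes$pathogen, k = params$seed_length)
  host_idx <- build_index(genomes$host_reference, k = params$seed_length)
  meta <- data.frame(
    sample = vapply(sim$samples, `[[`, "", "id"),
    timepoint = vapply(sim$samples, `[[`, "", "timepoint"),
    replicate = vapply(sim$samples, function(s) s$replicate, 0L),
    stringsAsFactors = FALSE)
  trimmed <- lapply(sim$samples, trim_reads)
  partitions <- lapply(trimmed, partition_reads, pathogen_index = path_idx,
                       host_index = host_idx, params = params)
  names(partitions) <- meta$sample
  fractions <- organism_fractions(partitions, meta)
  # pool every sample's host-partition reads for reference polishing
  host_reads <- pool_partition_reads(trimmed, partitions, "host")
  polish <- polish_iteratively(genomes$host_reference, host_reads, params,
                               n_iterations = polish_iterations)
  gm <- genomes$truth$gene_models
  gm_path <- gm[gm$organism == "pathogen", , drop = FALSE]
  gm_host <- gm[gm$organism == "host", , drop = FALSE]
  # pathogen: count per sample, pool replicates per timepoint
  path_counts <- lapply(partitions, function(p)
    count_fragments(p$pathogen_alignments, gm_path))
  tps <- unique(meta$timepoint)
  pooled <- lapply(tps, function(tp)
    pool_replicates(path_counts[meta$timepoint == tp]))
  nonzero <- vapply(pooled, function(x) x$total > 0L, TRUE)
  pathogen_expr <- if (any(nonzero))
    expression_matrix(pooled[nonzero], gm_path,
                      data.frame(sample = tps[nonzero],
                                 organism = "pathogen",
                                 timepoint = tps[nonzero],
                                 replicate = "pooled",
                                 stringsAsFactors = FALSE)) else NULL
  # host: re-align each sample's host reads to the polished genome
  polished_idx <- build_index(polish$genome, k = params$seed_length)
  host_counts <- lapply(seq_along(trimmed), function(i) {
    ids <- names(partitions[[i]]$assignment)[
      partitions[[i]]$assignment == "host"]
    sel <- match(ids, trimmed[[i]]$read_id %||%
                   paste0("pair_", seq_along(trimmed[[i]]$r1)))
    rd <- list(r1 = trimmed[[i]]$r1[sel], q1 = trimmed[[i]]$q1[sel],
               r2 = trimmed[[i]]$r2[sel], q2 = trimmed[[i]]$q2[sel],
               read_id = ids)
    aln <- align_pairs_batch(polished_idx, rd, ids, params)
    count_fragments(aln, gm_host)
  })
  host_expr <- expression_matrix(
    host_counts, gm_host,
    data.frame(sample = meta$sample, organism = "host",
               timepoint = meta$timepoint, replicate = meta$replicate,
               stringsAsFactors = FALSE))
  # pooled host columns per timepoint for presence/clustering
  host_pooled <- lapply(tps, function(tp)
    pool_replicates(host_counts[meta$timepoint == tp]))
  host_tp_expr <- expression_matrix(
    host_pooled, gm_host,
    data.frame(sample = tps, organism = "host", timepoint = tps,
               replicate = "pooled", stringsAsFactors = FALSE))
  presence <- presence_sets(host_tp_expr)
  profiles <- log_relative_transform(host_tp_expr)
  dend <- upgma(profiles)
  selection <- select_cluster_count(dend, profiles, k_max = k_max)
  activity <- cluster_activity(profiles, selection$assignments)
  list(genomes = genomes, sim = sim, partitions = partitions,
       fractions = fractions, polish = polish,
       pathogen_expr = pathogen_expr, host_expr = host_expr,
       host_timepoint_expr = host_tp_expr, presence = presence,
       profiles = profiles, selection = selection, activity = activity)
}

# Concatenate the reads of one partition class across samples.
pool_partition_reads <- function(trimmed, partitions, class = "host") {
  pick <- function(i) {
    ids <- names(partitions[[i]]$assignment)[
      partitions[[i]]$assignment == class]
    all_ids <- trimmed[[i]]$read_id %||%
      paste0("pair_", seq_along(trimmed[[i]]$r1))
    sel <- match(ids, all_ids)
    list(r1 = trimmed[[i]]$r1[sel], q1 = trimmed[[i]]$q1[sel],
         r2 = trimmed[[i]]$r2[sel], q2 = trimmed[[i]]$q2[sel])
  }
  parts <- lapply(seq_along(trimmed), pick)
  list(r1 = unlist(lapply(parts, `[[`, "r1")),
       q1 = unlist(lapply(parts, `[[`, "q1")),
       r2 = unlist(lapply(parts, `[[`, "r2")),
       q2 = unlist(lapply(parts, `[[`, "q2")))
}
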