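#' Simulate paired-end reads for every sample of the design
#'
#' For each timepoint x replicate, draws `reads_per_sample` read pairs from
#' a mixture of the two organisms.  The number of pathogen-origin pairs is
#' `Binomial(reads_per_sample, pathogen_read_fraction[timepoint])`; host
#' pairs are drawn from the *divergent strain* genome (never the
#' reference), pathogen pairs from the pathogen genome.  Within an
#' organism, fragments are sampled expression-weighted over the gene
#' models: the weight of gene g at timepoint t is
#' `2^(baseline_g + gene_profile[g, t])`, so the planted co-expression
#' structure is recoverable from downstream FPKM estimates.
#'
#' Sequencing errors are injected per base with probability `10^(-Q/10)`
#' where Q is that base's Phred quality, so qualities and realised error
#' rates agree; a configurable fraction of reads receives a low-quality 3'
#' tail.  Fragments that do not fit their source gene are resampled.
#' Read names encode the origin for truth-keeping only; no pipeline stage
#' reads them.
#'
#' @param genomes a `genome_set` from [simulate_genomes()].
#' @param config the same [simulation_config()].
#' @param out_dir optional directory; when given, per-sample gzipped FASTQ
#'   mate files (`<sample>_R1.fastq.gz`, `_R2.fastq.gz`) are written.
#' @return A list of class `read_sim`: `samples` (list with `id`,
#'   `timepoint`, `replicate`, `read_id`, `r1`, `q1`, `r2`, `q2`),
#'   `origins` (data frame read_id/organism/gene_id/sample), and `config`.
#' @export
simulate_reads <- function(genomes, config, out_dir = NULL) {
  stopifnot(inherits(genomes, "genome_set"))
  truth <- genomes$truth
  set.seed(config$seed + 1L)
  gm <- truth$gene_models
  # host gene intervals in strain coordinates (indels shift them)
  host_rows <- gm$organism == "host"
  strain_start <- ref_to_strain(gm$start[host_rows], truth)
  strain_end <- ref_to_strain(gm$end[host_rows], truth)
  gmap <- list(
    pathogen = data.frame(gene_id = gm$gene_id[!host_rows],
                          start = gm$start[!host_rows],
                          end = gm$end[!host_rows],
                          stringsAsFactors = FALSE),
    host = data.frame(gene_id = gm$gene_id[host_rows],
                      start = strain_start, end = strain_end,
                      stringsAsFactors = FALSE))
  src_seq <- list(pathogen = genomes$pathogen[[1]],
                  host = genomes$host_strain[[1]])
  samples <- list()
  origins <- list()
  for (ti in seq_along(config$timepoints)) {
    tp <- config$timepoints[ti]
    for (rep_i in seq_len(config$replicates_per_timepoint)) {
      sid <- sprintf("%s_R%d", tp, rep_i)
      n <- config$reads_per_sample
      n_path <- rbinom(1L, n, config$pathogen_read_fraction[ti])
      parts <- list()
      for (org in c("pathogen", "host")) {
        n_org <- if (org == "pathogen") n_path else n - n_path
        if (n_org == 0L) next
        parts[[org]] <- sample_pairs(org, n_org, ti, sid, gmap[[org]],
                                     src_seq[[org]], truth, config)
      }
      r1 <- unlist(lapply(parts, `[[`, "r1"), use.names = FALSE)
      q1 <- unlist(lapply(parts, `[[`, "q1"), use.names = FALSE)
      r2 <- unlist(lapply(parts, `[[`, "r2"), use.names = FALSE)
      q2 <- unlist(lapply(parts, `[[`, "q2"), use.names = FALSE)
      ids <- unlist(lapply(parts, `[[`, "id"), use.names = FALSE)
      org_tab <- do.call(rbind, lapply(parts, `[[`, "origin"))
      samples[[sid]] <- list(id = sid, timepoint = tp, replicate = rep_i,
                             read_id = ids, r1 = r1, q1 = q1,
                             r2 = r2, q2 = q2)
      origins[[sid]] <- org_tab
    }
  }
  origins <- do.call(rbind, origins)
  rownames(origins) <- NULL
  out <- structure(list(samples = samples, origins = origins,
                        config = config), class = "read_sim")
  if (!is.null(out_dir)) write_read_sim(out, out_dir)
  out
}

sample_pairs <- function(org, n, ti, sid, genes, src, truth, config) {
  lw <- truth$baselines[genes$gene_id] +
    truth$gene_profiles[genes$gene_id, ti]
  w <- 2^(lw - max(lw))
  gi <- sample.int(nrow(genes), n, replace = TRUE, prob = w)
  glen <- genes$end - genes$start
  flen <- pmax(config$read_len,
               as.integer(round(rnorm(n, config$fragment_mean,
                                      config$fragment_sd))))
  # resample fragments longer than their source gene
  for (tries in 1:50) {
    bad <- which(flen > glen[gi])
    if (!length(bad)) break
    flen[bad] <- pmax(config$read_len,
                      as.integer(round(rnorm(length(bad), config$fragment_mean,
                                             config$fragment_sd))))
    if (tries == 50L) flen[bad] <- glen[gi[bad]]
  }
  fstart <- genes$start[gi] +
    floor(runif(n) * (glen[gi] - flen + 1L))
  frag <- substring(src, fstart + 1L, fstart + flen)
  rl <- config$read_len
  left <- substring(frag, 1L, rl)
  right <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substring(frag, flen - rl + 1L, flen))))
  swap <- runif(n) < 0.5
  r1 <- ifelse(swap, right, left)
  r2 <- ifelse(swap, left, right)
  q1 <- draw_qualities(n, rl, config)
  q2 <- draw_qualities(n, rl, config)
  r1 <- inject_errors(r1, q1, config)
  r2 <- inject_errors(r2, q2, config)
  id <- sprintf("sim|%s|%s|%s|%06d", org, sid, genes$gene_id[gi], seq_len(n))
  list(r1 = r1, q1 = q1, r2 = r2, q2 = q2, id = id,
       origin = data.frame(read_id = id, organism = org,
                           gene_id = genes$gene_id[gi], sample = sid,
                           stringsAsFactors = FALSE))
}

# Two-state quality model: a flat high-quality body whose Phred matches the
# configured base error rate, plus an optional low-quality 3' tail.
draw_qualities <- function(n, rl, config) {
  body_q <- if (config$base_error_rate > 0)
    as.integer(round(-10 * log10(config$base_error_rate))) else 40L
  body_q <- min(body_q, 40L)
  flat <- strrep(intToUtf8(body_q + 33L), rl)
  out <- rep(flat, n)
  if (config$tail_prob > 0 && config$tail_len > 0L) {
    tailed <- which(runif(n) < config$tail_prob)
    if (length(tailed)) {
      tl <- min(config$tail_len, rl)
      tq <- strrep(intToUtf8(config$tail_quality + 33L), tl)
      out[tailed] <- paste0(substring(flat, 1L, rl - tl), tq)
    }
  }
  out
}

inject_errors <- function(reads, quals, config) {
  if (config$base_error_rate <= 0) return(reads)
  bases <- c("A", "C", "G", "T")
  uq <- unique(quals)
  for (q in uq) {
    idx <- which(quals == q)
    perr <- 10^(-(utf8ToInt(q) - 33L) / 10)
    nerr <- rbinom(length(idx), nchar(reads[idx][1]), mean(perr))
    # positions drawn per read, weighted by the per-base error probability
    hit <- which(nerr > 0L)
    for (h in hit) {
      r <- idx[h]
      pos <- sample.int(length(perr), nerr[h], prob = perr)
      for (p in pos) {
        old <- substring(reads[r], p, p)
        substr(reads[r], p, p) <- sample(setdiff(bases, old), 1L)
      }
    }
  }
  reads
}

#' @export
print.read_sim <- function(x, ...) {
  ns <- length(x$samples)
  np <- sum(vapply(x$samples, function(s) length(s$r1), 0L))
  cat(sprintf("read_sim: %d samples, %d read pairs total\n", ns, np))
  tab <- table(x$origins$organism)
  cat("  origins:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
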