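#' Simulate a pathogen reference, host reference and divergent host strain
#'
#' Draws two independent random genomes (i.i.d. bases at the configured GC
#' content), then derives the sequenced host *strain* from the host
#' reference by injecting substitutions and indels.  The edits are recorded
#' as the ground truth, so that `apply_variants(host_reference, truth)`
#' reproduces the strain exactly.
#'
#' RNG contract (everything follows one `set.seed(config$seed)`, in this
#' order): pathogen genome, host genome, substitution count
#' `rbinom(1, host_genome_len, snp_divergence_rate)`, indel count
#' `rbinom(1, host_genome_len, indel_divergence_rate)`, edit placements and
#' alleles, gene/cluster assignment, cluster centroids, per-gene profiles
#' and baselines.
#'
#' Substitution placement is two-layered: a `snp_hotspot_fraction` share of
#' the substitutions is concentrated in dense windows
#' (`snp_hotspot_width` bp at `snp_hotspot_rate` per bp) and the rest is
#' uniform; edits never collide (colliding draws are resampled
#' deterministically from the same stream).  Gene models tile each genome
#' contiguously without overlap, alternating strand.
#'
#' @param config a [simulation_config()] object.
#' @return A list of class `genome_set` with elements `pathogen`,
#'   `host_reference`, `host_strain` (named character vectors of sequences)
#'   and `truth`, a `truth_set` holding `variants`, `gene_models`,
#'   `cluster_labels`, `cluster_profiles`, `gene_profiles` and `baselines`.
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "dualseq_config"))
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  pbase <- c((1 - config$gc_content) / 2, config$gc_content / 2,
             config$gc_content / 2, (1 - config$gc_content) / 2)
  draw_genome <- function(len) {
    paste(sample(bases, len, replace = TRUE, prob = pbase), collapse = "")
  }
  pathogen <- draw_genome(config$pathogen_genome_len)
  host <- draw_genome(config$host_genome_len)
  L <- config$host_genome_len

  n_snp <- rbinom(1L, L, config$snp_divergence_rate)
  n_indel <- rbinom(1L, L, config$indel_divergence_rate)

  snp_pos <- place_substitutions(L, n_snp, config)
  indels <- place_indels(L, n_indel, snp_pos, config)

  variants <- data.frame(reference = character(0), pos = integer(0),
                         type = character(0), ref = character(0),
                         alt = character(0), stringsAsFactors = FALSE)
  if (n_snp > 0L) {
    ref_b <- substring(host, snp_pos + 1L, snp_pos + 1L)
    alt_b <- vapply(ref_b, function(b) sample(setdiff(bases, b), 1L), "")
    variants <- rbind(variants,
                      data.frame(reference = "host_1", pos = snp_pos,
                                 type = "snp", ref = unname(ref_b),
                                 alt = unname(alt_b),
                                 stringsAsFactors = FALSE))
  }
  if (nrow(indels) > 0L) {
    ref_s <- character(nrow(indels))
    alt_s <- character(nrow(indels))
    for (i in seq_len(nrow(indels))) {
      if (indels$type[i] == "del") {
        ref_s[i] <- substring(host, indels$pos[i] + 1L,
                              indels$pos[i] + indels$len[i])
        alt_s[i] <- ""
      } else {
        ref_s[i] <- ""
        alt_s[i] <- paste(sample(bases, indels$len[i], replace = TRUE,
                                 prob = pbase), collapse = "")
      }
    }
    variants <- rbind(variants,
                      data.frame(reference = "host_1", pos = indels$pos,
                                 type = indels$type, ref = ref_s,
                                 alt = alt_s, stringsAsFactors = FALSE))
  }
  variants <- variants[order(variants$pos), , drop = FALSE]
  rownames(variants) <- NULL

  strain <- apply_variants(host, variants)

  gm_path <- tile_gene_models("pathogen", "pathogen_1",
                              config$pathogen_genome_len,
                              config$n_genes[["pathogen"]])
  gm_host <- tile_gene_models("host", "host_1", L, config$n_genes[["host"]])
  gene_models <- rbind(gm_path, gm_host)

  n_gene <- nrow(gene_models)
  K <- config$n_clusters
  labels <- sample(rep_len(seq_len(K), n_gene))
  names(labels) <- gene_models$gene_id
  centroids <- draw_cluster_centroids(K, length(config$timepoints),
                                      config$min_profile_separation)
  colnames(centroids) <- config$timepoints
  gene_profiles <- centroids[labels, , drop = FALSE] +
    matrix(rnorm(n_gene * ncol(centroids), 0, config$cluster_profile_sd),
           nrow = n_gene)
  rownames(gene_profiles) <- gene_models$gene_id
  baselines <- setNames(rnorm(n_gene, 0, config$expression_dispersion),
                        gene_models$gene_id)

  truth <- structure(list(variants = variants, gene_models = gene_models,
                          cluster_labels = labels,
                          cluster_profiles = centroids,
                          gene_profiles = gene_profiles,
                          baselines = baselines,
                          read_origins = NULL),
                     class = "truth_set")
  structure(list(pathogen = c(pathogen_1 = pathogen),
                 host_reference = c(host_1 = host),
                 host_strain = c(host_1 = strain),
                 truth = truth, config = config),
            class = "genome_set")
}

# Uniform + hotspot substitution placement; collisions resampled from the
# same RNG stream so the full output remains a pure function of the seed.
place_substitutions <- function(L, n_snp, config) {
  if (n_snp == 0L) return(integer(0))
  margin <- 2L
  avail <- seq.int(margin, L - 1L - margin)
  n_hot <- round(config$snp_hotspot_fraction * n_snp)
  hot_pos <- integer(0)
  if (n_hot > 0L && config$snp_hotspot_rate > 0) {
    per_hot <- config$snp_hotspot_width * config$snp_hotspot_rate
    n_windows <- max(1L, ceiling(n_hot / per_hot))
    width <- config$snp_hotspot_width
    for (tries in 1:200) {
      starts <- sort(sample(avail[avail < L - width - margin], n_windows))
      if (n_windows == 1L || all(diff(starts) >= width + 2L)) break
      if (tries == 200L) stop("could not place non-overlapping hotspots")
    }
    pool <- unlist(lapply(starts, function(s) seq.int(s, s + width - 1L)))
    hot_pos <- sort(sample(pool, min(n_hot, length(pool))))
  }
  n_bg <- n_snp - length(hot_pos)
  bg_pos <- integer(0)
  if (n_bg > 0L) {
    taken <- hot_pos
    for (tries in 1:200) {
      cand <- sample(avail, n_bg + length(bg_pos) - length(bg_pos))
      cand <- setdiff(cand, c(taken, bg_pos))
      bg_pos <- c(bg_pos, cand[seq_len(min(length(cand),
                                           n_bg - length(bg_pos)))])
      if (length(bg_pos) >= n_bg) break
      if (tries == 200L) stop("could not place substitutions without collision")
    }
  }
  sort(c(hot_pos, bg_pos))
}

place_indels <- function(L, n_indel, snp_pos, config) {
  out <- data.frame(pos = integer(0), type = character(0), len = integer(0),
                    stringsAsFactors = FALSE)
  if (n_indel == 0L) return(out)
  maxlen <- config$indel_max_len
  margin <- maxlen + 2L
  spans_taken <- cbind(snp_pos - 1L, snp_pos + 1L)  # keep indels off SNPs
  pos <- integer(0); type <- character(0); len <- integer(0)
  for (tries in 1:500) {
    need <- n_indel - length(pos)
    if (need <= 0L) break
    p <- sample(seq.int(margin, L - 1L - margin), need)
    l <- sample.int(maxlen, need, replace = TRUE)
    ty <- ifelse(runif(need) < 0.5, "ins", "del")
    for (i in seq_len(need)) {
      span <- c(p[i] - 1L, p[i] + ifelse(ty[i] == "del", l[i], 0L) + 1L)
      clash <- any(span[1] <= spans_taken[, 2] & span[2] >= spans_taken[, 1])
      if (!clash) {
        pos <- c(pos, p[i]); type <- c(type, ty[i]); len <- c(len, l[i])
        spans_taken <- rbind(spans_taken, span)
      }
    }
    if (tries == 500L && length(pos) < n_indel)
      stop("could not place indels without collision")
  }
  data.frame(pos = pos, type = type, len = len, stringsAsFactors = FALSE)
}

tile_gene_models <- function(organism, reference, L, n) {
  bounds <- floor(seq(0, L, length.out = n + 1L))
  data.frame(organism = organism,
             gene_id = sprintf("%s_g%04d", organism, seq_len(n)),
             reference = reference,
             start = as.integer(bounds[-(n + 1L)]),
             end = as.integer(bounds[-1L]),
             strand = rep_len(c("+", "-"), n),
             stringsAsFactors = FALSE)
}

draw_cluster_centroids <- function(K, T_, min_sep, scale = 1.5) {
  if (T_ < 2L) return(matrix(0, K, T_))  # no temporal shape to plant
  # widen the draw deterministically if K centroids cannot be packed at the
  # requested separation within the base scale
  for (round in 1:12) {
    for (tries in 1:100) {
      cen <- matrix(rnorm(K * T_, 0, scale), nrow = K)
      cen <- cen - rowMeans(cen)
      if (K == 1L || min(dist(cen)) >= min_sep) return(cen)
    }
    scale <- scale * 1.5
  }
  stop("could not draw cluster centroids at the requested separation")
}

#' Apply recorded variants to a reference sequence
#'
#' Reconstructs the strain sequence from the reference and a variant table
#' (`pos` 0-based; `type` one of "snp", "ins", "del"; insertions are placed
#' before the reference base at `pos`).  Used both by the simulator and by
#' the truth-consistency checks.
#'
#' @param genome a single reference sequence (character scalar) or a named
#'   vector of length 1.
#' @param variants a variant data frame as stored in a `truth_set`, or a
#'   `truth_set` itself.
#' @return The edited sequence (character scalar).
#' @export
apply_variants <- function(genome, variants) {
  if (inherits(variants, "truth_set")) variants <- variants$variants
  g <- unname(genome[[1]])
  if (nrow(variants) == 0L) return(g)
  v <- variants[order(variants$pos), , drop = FALSE]
  if (anyDuplicated(v$pos)) stop("variants collide: duplicated positions")
  pieces <- character(0)
  cur <- 1L  # 1-based cursor into the reference
  for (i in seq_len(nrow(v))) {
    p0 <- v$pos[i]
    pieces <- c(pieces, substring(g, cur, p0))
    if (v$type[i] == "snp") {
      pieces <- c(pieces, v$alt[i])
      cur <- p0 + 2L
    } else if (v$type[i] == "del") {
      cur <- p0 + nchar(v$ref[i]) + 1L
    } else {  # ins: before reference base at p0
      pieces <- c(pieces, v$alt[i])
      cur <- p0 + 1L
    }
  }
  pieces <- c(pieces, substring(g, cur, nchar(g)))
  paste(pieces, collapse = "")
}

#' Map reference coordinates to strain coordinates
#'
#' Accounts for the cumulative length changes introduced by insertions and
#' deletions; positions inside a deleted block map to the block's left edge.
#'
#' @param pos integer vector of 0-based reference positions.
#' @param variants variant table (or `truth_set`).
#' @return Integer vector of 0-based strain positions.
#' @export
ref_to_strain <- function(pos, variants) {
  if (inherits(variants, "truth_set")) variants <- variants$variants
  ind <- variants[variants$type != "snp", , drop = FALSE]
  if (nrow(ind) == 0L) return(pos)
  out <- pos
  for (i in seq_len(nrow(ind))) {
    p <- ind$pos[i]
    if (ind$type[i] == "ins") {
      l <- nchar(ind$alt[i])
      out <- out + ifelse(pos >= p, l, 0L)
    } else {
      l <- nchar(ind$ref[i])
      out <- out - pmin(pmax(pos - p, 0L), l)
    }
  }
  as.integer(out)
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set:\n")
  cat(sprintf("  pathogen: %d bp; host: %d bp; strain: %d bp\n",
              nchar(x$pathogen[[1]]), nchar(x$host_reference[[1]]),
              nchar(x$host_strain[[1]])))
  v <- x$truth$variants
  cat(sprintf("  truth: %d substitutions, %d indels, %d gene models, %d clusters\n",
              sum(v$type == "snp"), sum(v$type != "snp"),
              nrow(x$truth$gene_models), nrow(x$truth$cluster_profiles)))
  invisible(x)
}
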