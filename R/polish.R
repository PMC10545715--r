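#' Apply single-alternate substitution corrections to a genome
#'
#' A call is applied only when it is a substitution with *exactly one*
#' alternate allele and its Phred-scaled site quality is strictly greater
#' than `qual_threshold`; everything else (multi-allelic sites, indels,
#' low-quality calls) is left untouched.  Substitution-only correction
#' never changes the genome length.
#'
#' @param genome named character vector of reference sequences.
#' @param calls a `variant_calls` data frame.
#' @param qual_threshold strict lower bound on QUAL (default 5.0).
#' @return A list with `genome` (corrected), `applied` (logical per call)
#'   and `n_applied`.
#' @export
apply_corrections <- function(genome, calls, qual_threshold = 5.0) {
  snp_rows <- calls[calls$type == "snp", c("reference", "pos")]
  if (anyDuplicated(snp_rows))
    stop("overlapping calls: deduplicate before applying corrections")
  apply_idx <- which(calls$type == "snp" & calls$n_alts == 1L &
                       calls$qual > qual_threshold &
                       nchar(calls$alt) == 1L)
  out <- genome
  for (rn in unique(calls$reference[apply_idx])) {
    rows <- apply_idx[calls$reference[apply_idx] == rn]
    g <- out[[rn]]
    ch <- strsplit(g, "")[[1]]
    ch[calls$pos[rows] + 1L] <- calls$alt[rows]
    out[[rn]] <- paste(ch, collapse = "")
  }
  applied <- logical(nrow(calls))
  applied[apply_idx] <- TRUE
  list(genome = out, applied = applied, n_applied = length(apply_idx))
}

#' Iterative SNP correction of a strain-divergent reference
#'
#' Repeats `n_iterations` times: align the host-partition reads to the
#' current genome, pile up, call variants, and replace reference bases for
#' high-quality single-alternate substitutions.  Because correcting the
#' sites covered by mappable reads rescues reads that previously fell
#' below the score threshold, later iterations see both a higher mapping
#' rate and fewer remaining variants.  After the final iteration a last
#' align/call pass collects the residual calls (multi-allelic
#' substitutions and indels) into a SNP-aware index in which any
#' registered allele is match-equivalent at its site.
#'
#' @param genome named character vector (the divergent reference).
#' @param reads list with `r1`, `q1`, `r2`, `q2` (host-partition reads).
#' @param params a [score_params()] object.
#' @param n_iterations number of correction iterations (default 2).
#' @param qual_threshold strict QUAL threshold for applying a correction.
#' @param min_alt_count minimum alternate support per call.
#' @param k seed length for the per-iteration indexes.
#' @param out_dir optional directory; when given, a VCF is written per
#'   iteration (`polish.iter1.vcf`, ...) plus `polish.residual.vcf`.
#' @return An object of class `polish_report`: `genome` (corrected),
#'   `iterations` (data frame with per-iteration `snps_detected`,
#'   `snps_applied`, `mapping_rate`), `mapping_rates` (named vector over
#'   stages raw / after_iter1 / ... / snp_aware), `residual_calls`,
#'   `snp_index` and `calls` (per-iteration call tables).
#' @export
polish_iteratively <- function(genome, reads, params = score_params(),
                               n_iterations = 2L, qual_threshold = 5.0,
                               min_alt_count = 2L, k = 16L,
                               out_dir = NULL) {
  if (n_iterations < 1L) stop("'n_iterations' must be >= 1")
  allr <- c(reads$r1, reads$r2)
  allq <- c(reads$q1, reads$q2)
  it_rows <- list(); call_list <- list()
  rates <- numeric(0)
  cur <- genome
  for (it in seq_len(n_iterations)) {
    idx <- build_index(cur, k = k)
    aln <- align_reads(idx, allr, allq, params)
    rate <- mean(aln$mapped)
    pile <- compute_pileup(aln, cur, allr, allq)
    calls <- call_variants(pile, min_alt_count = min_alt_count)
    snp_calls <- calls[calls$type == "snp", , drop = FALSE]
    detected <- sum(snp_calls$qual > qual_threshold)
    corr <- apply_corrections(cur, calls, qual_threshold)
    cur <- corr$genome
    it_rows[[it]] <- data.frame(iteration = it, snps_detected = detected,
                                snps_applied = corr$n_applied,
                                mapping_rate = rate)
    call_list[[it]] <- calls
    rates <- c(rates, rate)
    if (!is.null(out_dir))
      write_vcf(calls, genome,
                file.path(out_dir, sprintf("polish.iter%d.vcf", it)))
  }
  # final pass on the corrected genome: residual calls -> SNP-aware index
  idx <- build_index(cur, k = k)
  aln <- align_reads(idx, allr, allq, params)
  rate_final <- mean(aln$mapped)
  pile <- compute_pileup(aln, cur, allr, allq)
  residual <- call_variants(pile, min_alt_count = min_alt_count)
  residual <- residual[residual$qual > qual_threshold, , drop = FALSE]
  snp_idx <- build_snp_index(cur, residual, k = k)
  aln_aware <- align_reads(snp_idx, allr, allq, params, cigar = FALSE)
  rate_aware <- mean(aln_aware$mapped)
  if (!is.null(out_dir))
    write_vcf(residual, cur, file.path(out_dir, "polish.residual.vcf"))
  stages <- c(rates, rate_final, rate_aware)
  names(stages) <- c("raw", paste0("after_iter", seq_len(n_iterations)),
                     "snp_aware")
  structure(list(genome = cur, iterations = do.call(rbind, it_rows),
                 mapping_rates = stages, residual_calls = residual,
                 snp_index = snp_idx, calls = call_list),
            class = "polish_report")
}

#' @export
print.polish_report <- function(x, ...) {
  cat("polish_report:\n")
  print(x$iterations, row.names = FALSE)
  cat("  mapping rates:",
      paste(sprintf("%s=%.3f", names(x$mapping_rates), x$mapping_rates),
            collapse = ", "), "\n")
  cat(sprintf("  residual: %d multi-alt SNPs, %d indels registered\n",
              sum(x$residual_calls$type == "snp" &
                    x$residual_calls$n_alts > 1L),
              sum(x$residual_calls$type != "snp")))
  invisible(x)
}

#' Build a SNP/indel-aware alignment index
#'
#' Registers the residual calls a correction pass cannot apply — multi-
#' allelic substitutions and indels — into the index: a read base matching
#' the reference *or any registered alternate* at a site incurs no
#' mismatch penalty, and registered indels are traversable without gap
#' penalty.  With an empty variant set the index behaves identically to a
#' plain one.
#'
#' @param genome named character vector (corrected reference).
#' @param residual_calls a `variant_calls` data frame from a final
#'   align/call pass.
#' @param k seed length.
#' @return An `aligner_index` with `snp_aware = TRUE`.
#' @export
build_snp_index <- function(genome, residual_calls, k = 16L) {
  idx <- build_index(genome, k = k)
  rc <- residual_calls
  snp <- rc[rc$type == "snp" & rc$n_alts >= 2L, , drop = FALSE]
  ins <- rc[rc$type == "ins", , drop = FALSE]
  del <- rc[rc$type == "del", , drop = FALSE]
  sid_of <- function(refn) match(refn, idx$seqnames) - 1L
  snp_sid <- integer(0); snp_pos <- integer(0); snp_alt <- character(0)
  if (nrow(snp)) {
    for (i in seq_len(nrow(snp))) {
      alts <- strsplit(snp$alt[i], ",", fixed = TRUE)[[1]]
      snp_sid <- c(snp_sid, rep(sid_of(snp$reference[i]), length(alts)))
      snp_pos <- c(snp_pos, rep(snp$pos[i], length(alts)))
      snp_alt <- c(snp_alt, alts)
    }
  }
  cpp_register_variants(idx$ptr,
                        as.integer(snp_sid), as.integer(snp_pos), snp_alt,
                        as.integer(sid_of(del$reference)),
                        as.integer(del$pos), as.integer(del$ref),
                        as.integer(sid_of(ins$reference)),
                        as.integer(ins$pos), ins$alt)
  idx$variants <- rc
  idx$snp_aware <- TRUE
  idx
}

#' Register explicit variants into an index (lower-level interface)
#'
#' @param index an `aligner_index`.
#' @param snps data frame `reference`, `pos`, `alt` (single bases).
#' @param deletions data frame `reference`, `pos`, `len`.
#' @param insertions data frame `reference`, `pos`, `seq`.
#' @return The index, now SNP/indel-aware.
#' @export
register_variants <- function(index, snps = NULL, deletions = NULL,
                              insertions = NULL) {
  sid_of <- function(refn) match(refn, index$seqnames) - 1L
  empty <- data.frame()
  s <- snps %||% empty; d <- deletions %||% empty; i <- insertions %||% empty
  cpp_register_variants(
    index$ptr,
    if (nrow(s)) as.integer(sid_of(s$reference)) else integer(0),
    if (nrow(s)) as.integer(s$pos) else integer(0),
    if (nrow(s)) as.character(s$alt) else character(0),
    if (nrow(d)) as.integer(sid_of(d$reference)) else integer(0),
    if (nrow(d)) as.integer(d$pos) else integer(0),
    if (nrow(d)) as.integer(d$len) else integer(0),
    if (nrow(i)) as.integer(sid_of(i$reference)) else integer(0),
    if (nrow(i)) as.integer(i$pos) else integer(0),
    if (nrow(i)) as.character(i$seq) else character(0))
  index$snp_aware <- TRUE
  index
}
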