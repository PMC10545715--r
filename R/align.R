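#' Alignment scoring parameters
#'
#' Scoring follows the local-score convention implied by a linear
#' score-minimum function: matches score 0, penalties are negative, and an
#' end-to-end read placement is reported only when its score reaches
#' `f(L) = threshold_const + threshold_slope * L` for read length L (the
#' defaults encode `f(L) = -4 - 0.5 L`).  Mismatch penalties are
#' quality-scaled between `mismatch_min` (quality 0) and `mismatch`
#' (quality >= 40); a gap of length k costs `gap_open + k * gap_extend`.
#'
#' @param match match score (default 0).
#' @param mismatch maximum (high-quality) mismatch penalty, `<= 0`.
#' @param mismatch_min mismatch penalty at base quality 0, `<= 0`.
#' @param gap_open,gap_extend affine gap penalties, `<= 0`.
#' @param threshold_const,threshold_slope coefficients of the linear score
#'   threshold `f(L)`.
#' @param seed_length exact-seed length k used by the index (8..31).
#' @param seed_step spacing between successive seed offsets along a read.
#' @param pad window padding (bp) around a seed diagonal for the extension
#'   DP; bounds the largest recoverable indel.
#' @return An object of class `score_params`.
#' @export
score_params <- function(match = 0, mismatch = -6, mismatch_min = -2,
                         gap_open = -5, gap_extend = -3,
                         threshold_const = -4, threshold_slope = -0.5,
                         seed_length = 16L, seed_step = 8L, pad = 40L) {
  if (match != 0) stop("'match' must be 0 under the local-score convention")
  if (any(c(mismatch, mismatch_min, gap_open, gap_extend) > 0))
    stop("penalties must be <= 0")
  if (threshold_slope > 0)
    stop("'threshold_slope' must be <= 0 (f(L) non-increasing in L)")
  structure(list(match = match, mismatch = mismatch,
                 mismatch_min = mismatch_min, gap_open = gap_open,
                 gap_extend = gap_extend, threshold_const = threshold_const,
                 threshold_slope = threshold_slope,
                 seed_length = as.integer(seed_length),
                 seed_step = as.integer(seed_step), pad = as.integer(pad)),
            class = "score_params")
}

#' Minimum acceptable alignment score for a read length
#' @param params a [score_params()] object.
#' @param len read length(s) in bp.
#' @return `threshold_const + threshold_slope * len`.
#' @export
score_min <- function(params, len) {
  params$threshold_const + params$threshold_slope * len
}

cpp_params <- function(params) {
  list(mismatch_min = as.integer(-params$mismatch_min),
       mismatch_max = as.integer(-params$mismatch),
       gap_open = as.integer(-params$gap_open),
       gap_extend = as.integer(-params$gap_extend),
       score_A = params$threshold_const, score_B = params$threshold_slope,
       seed_step = params$seed_step, pad = params$pad)
}

#' Build an exact k-mer alignment index over a genome
#'
#' Indexes every forward-strand k-mer of each sequence; queries are matched
#' on both strands by additionally seeding with the reverse-complemented
#' read (dual-query rather than dual-storage).  Sequences shorter than k
#' are kept but unplaceable (a warning is raised).
#'
#' @param genome named character vector of reference sequences (or a file
#'   path to a FASTA file).
#' @param k seed length, 8..31.
#' @return An object of class `aligner_index`.
#' @export
build_index <- function(genome, k = 16L) {
  if (length(genome) == 1L && !grepl("^[ACGTNacgtn]+$", genome) &&
      file.exists(genome))
    genome <- read_fasta(genome)
  if (is.null(names(genome)))
    names(genome) <- paste0("seq_", seq_along(genome))
  if (any(nchar(genome) < k))
    warning("sequences shorter than k are unplaceable: ",
            paste(names(genome)[nchar(genome) < k], collapse = ", "))
  ptr <- cpp_build_index(names(genome), unname(genome), as.integer(k))
  structure(list(ptr = ptr, seqnames = names(genome),
                 seqlengths = setNames(nchar(genome), names(genome)),
                 genome = genome, k = as.integer(k),
                 variants = NULL, snp_aware = FALSE),
            class = "aligner_index")
}

#' @export
print.aligner_index <- function(x, ...) {
  cat(sprintf("aligner_index: %d sequence(s), %d bp total, k = %d%s\n",
              length(x$seqnames), sum(x$seqlengths), x$k,
              if (x$snp_aware) " (SNP/indel-aware)" else ""))
  invisible(x)
}

#' Look up the forward-strand positions of one k-mer
#' @param index an [build_index()] index.
#' @param kmer a k-length string.
#' @param reference sequence name (defaults to the first).
#' @return Sorted integer vector of 0-based positions (empty when absent).
#' @export
lookup_kmer <- function(index, kmer, reference = index$seqnames[1]) {
  sid <- match(reference, index$seqnames) - 1L
  if (is.na(sid)) stop("unknown reference: ", reference)
  cpp_lookup_kmer(index$ptr, kmer, sid)
}

#' Align reads against an index
#'
#' Seed-and-extend alignment: exact k-mer seeds on both strands are
#' clustered into candidate loci, each locus is scored with an affine-gap
#' DP over a padded window (read global, reference local), and the best
#' placement is emitted only if its score reaches the linear threshold
#' `f(L)`.  `mapping_count` counts distinct loci tied at the best score
#' (exact ties only); reads with `mapping_count > 1` are flagged
#' non-unique and are excluded from downstream analyses by convention.
#'
#' @param index an `aligner_index`.
#' @param reads character vector of read sequences.
#' @param quals optional Phred+33 quality strings (all-Q40 assumed absent).
#' @param params a [score_params()] object; its `seed_step`/`pad` must
#'   match the intent of the index build.
#' @param read_id optional read names carried into the result.
#' @param cigar compute CIGAR strings and exact leftmost positions
#'   (slightly slower; required for pileups and fragment counting).
#' @return A data frame with one row per read: `read_id`, `mapped`,
#'   `reference`, `pos` (0-based leftmost), `strand`, `score`,
#'   `mapping_count`, `is_unique`, `cigar`.
#' @export
align_reads <- function(index, reads, quals = NULL, params = score_params(),
                        read_id = NULL, cigar = TRUE) {
  stopifnot(inherits(index, "aligner_index"))
  n <- length(reads)
  if (n == 0L)
    return(data.frame(read_id = character(0), mapped = logical(0),
                      reference = character(0), pos = integer(0),
                      strand = character(0), score = integer(0),
                      mapping_count = integer(0), is_unique = logical(0),
                      cigar = character(0), stringsAsFactors = FALSE))
  if (is.null(quals)) quals <- rep(NA_character_, n)
  res <- cpp_align(index$ptr, reads, quals, cpp_params(params), cigar)
  data.frame(read_id = if (is.null(read_id)) paste0("read_", seq_len(n))
             else read_id,
             mapped = res$mapped,
             reference = ifelse(is.na(res$sid), NA_character_,
                                index$seqnames[res$sid + 1L]),
             pos = res$pos, strand = res$strand, score = res$score,
             mapping_count = res$n_loci,
             is_unique = res$mapped & res$n_loci == 1L,
             cigar = res$cigar, stringsAsFactors = FALSE)
}

#' Align one read pair
#'
#' Mates are aligned jointly in the sense that both are scored against the
#' same index and reported together; concordance is not enforced.
#'
#' @inheritParams align_reads
#' @param r1,q1,r2,q2 the two mates and their qualities.
#' @return A two-row alignment data frame (`mate` column 1/2).
#' @export
align_read_pair <- function(index, r1, q1 = NULL, r2 = NULL, q2 = NULL,
                            params = score_params()) {
  out <- align_reads(index, c(r1, r2), c(q1 %||% NA_character_,
                                         q2 %||% NA_character_), params)
  out$mate <- c(1L, 2L)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sequentially partition read pairs between pathogen and host
#'
#' Implements the fixed mapping order of a dual RNA-seq design with a rare
#' pathogen: every pair is first aligned to the pathogen genome; pairs with
#' at least one uniquely mapped mate are assigned to the pathogen and are
#' never reassigned.  Only the remaining pairs are tried against the host.
#' As a diagnostic, pathogen-assigned pairs are additionally aligned to the
#' host genome and the number that would also map there is reported as
#' `cross_mapped`; this never changes the assignment.
#'
#' @param reads a list with `r1`, `q1`, `r2`, `q2` and optionally
#'   `read_id` (e.g. a trimmed sample).
#' @param pathogen_index,host_index `aligner_index` objects built with the
#'   same `params`.
#' @param params a [score_params()] object.
#' @return An object of class `partition_result`: `pathogen_alignments`
#'   and `host_alignments` (per-mate alignment rows with `pair_id`),
#'   `assignment` (per-pair factor pathogen/host/unmapped),
#'   `unmapped_ids`, `cross_mapped`, `per_organism_fractions` and
#'   `n_pairs`.
#' @export
partition_reads <- function(reads, pathogen_index, host_index,
                            params = score_params()) {
  n <- length(reads$r1)
  ids <- reads$read_id %||% paste0("pair_", seq_len(n))
  path_aln <- align_pairs_batch(pathogen_index, reads, ids, params)
  path_pair <- pair_mapped(path_aln, n)
  to_host <- which(!path_pair)
  host_reads <- list(r1 = reads$r1[to_host], q1 = reads$q1[to_host],
                     r2 = reads$r2[to_host], q2 = reads$q2[to_host])
  host_aln <- align_pairs_batch(host_index, host_reads, ids[to_host], params)
  host_pair_l <- pair_mapped(host_aln, length(to_host))
  assignment <- rep("unmapped", n)
  assignment[path_pair] <- "pathogen"
  assignment[to_host[host_pair_l]] <- "host"
  assignment <- factor(assignment, levels = c("pathogen", "host", "unmapped"))
  # diagnostic: do pathogen-assigned pairs also align to the host?
  cross <- 0L
  if (any(path_pair)) {
    pi <- which(path_pair)
    cr <- align_pairs_batch(host_index,
                            list(r1 = reads$r1[pi], q1 = reads$q1[pi],
                                 r2 = reads$r2[pi], q2 = reads$q2[pi]),
                            ids[pi], params, cigar = FALSE)
    cross <- sum(tapply(cr$mapped, cr$pair_id, any))
  }
  frac <- as.vector(table(assignment)) / n
  structure(list(
    pathogen_alignments = path_aln[path_aln$pair_id %in% ids[path_pair], ,
                                   drop = FALSE],
    host_alignments = host_aln[host_aln$pair_id %in%
                                 ids[to_host[host_pair_l]], , drop = FALSE],
    assignment = setNames(assignment, ids),
    unmapped_ids = ids[assignment == "unmapped"],
    cross_mapped = cross,
    per_organism_fractions = setNames(frac, levels(assignment)),
    n_pairs = n), class = "partition_result")
}

# Align both mates of every pair; rows interleave mate 1 then mate 2 blocks.
align_pairs_batch <- function(index, reads, ids, params, cigar = TRUE) {
  a1 <- align_reads(index, reads$r1, reads$q1, params,
                    read_id = paste0(ids, "/1"), cigar = cigar)
  a2 <- align_reads(index, reads$r2, reads$q2, params,
                    read_id = paste0(ids, "/2"), cigar = cigar)
  a1$mate <- rep(1L, nrow(a1)); a2$mate <- rep(2L, nrow(a2))
  a1$pair_id <- ids; a2$pair_id <- ids
  rbind(a1, a2)
}

# A pair is considered mapped when at least one mate is uniquely mapped.
pair_mapped <- function(aln, n) {
  if (n == 0L) return(logical(0))
  ok <- aln$mapped & aln$is_unique
  as.vector(tapply(ok, factor(aln$pair_id, levels = unique(aln$pair_id)),
                   any))[seq_len(n)]
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("partition_result: %d pairs\n", x$n_pairs))
  f <- x$per_organism_fractions
  cat(sprintf("  pathogen %.4g%%, host %.4g%%, unmapped %.4g%% (cross-mapped diagnostic: %d)\n",
              100 * f[["pathogen"]], 100 * f[["host"]],
              100 * f[["unmapped"]], x$cross_mapped))
  invisible(x)
}
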