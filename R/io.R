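#' Read and write FASTA genome files
#'
#' Thin wrappers over Biostrings, returning/accepting plain named character
#' vectors (sequences wrapped at 60 columns on output).
#'
#' @param x named character vector of sequences.
#' @param path file path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path, width = 60L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Read and write FASTQ files (Phred+33)
#'
#' Plain 4-line-per-record FASTQ; gzip is applied automatically for paths
#' ending in `.gz`.
#'
#' @param ids,seqs,quals record names, sequences, quality strings.
#' @param path file path (`.gz` for gzip).
#' @return `read_fastq` returns a list with `id`, `seq`, `qual`.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), con)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  ln <- readLines(con)
  if (length(ln) %% 4L != 0L) stop("truncated FASTQ: ", path)
  i <- seq(1L, length(ln), by = 4L)
  list(id = sub("^@", "", ln[i]), seq = ln[i + 1L], qual = ln[i + 3L])
}

#' Write a read simulation to per-sample FASTQ files
#' @param sim a `read_sim` object.
#' @param dir output directory (created if needed).
#' @export
write_read_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in sim$samples) {
    write_fastq(paste0(s$read_id, "/1"), s$r1, s$q1,
                file.path(dir, paste0(s$id, "_R1.fastq.gz")))
    write_fastq(paste0(s$read_id, "/2"), s$r2, s$q2,
                file.path(dir, paste0(s$id, "_R2.fastq.gz")))
  }
  invisible(dir)
}

#' Read and write gene models as GFF3
#'
#' Gene models are single-exon intervals; internal coordinates are 0-based
#' half-open and are converted to the 1-based inclusive GFF3 convention.
#'
#' @param gene_models data frame with `gene_id`, `reference`, `start`,
#'   `end`, `strand` (and optionally `organism`).
#' @param path file path.
#' @export
write_gene_models_gff3 <- function(gene_models, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = gene_models$reference,
    ranges = IRanges::IRanges(start = gene_models$start + 1L,
                              end = gene_models$end),
    strand = gene_models$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- gene_models$gene_id
  S4Vectors::mcols(gr)$source <- "dualseq"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_models_gff3
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(gene_id = S4Vectors::mcols(gr)$ID,
             reference = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write alignments as minimal SAM
#'
#' Emits a valid SAM file with `@SQ` header lines; FLAG carries strand and
#' mate information, MAPQ is 0 for non-unique placements and 60 otherwise.
#'
#' @param alignments alignment data frame (as returned by [align_reads()])
#'   with columns `read_id`, `mapped`, `reference`, `pos`, `strand`,
#'   `cigar`, `is_unique`; unmapped rows are written with FLAG 4.
#' @param genome named character vector of reference sequences (for `@SQ`).
#' @param reads,quals the read sequences/qualities in `alignments` row order.
#' @param path output path.
#' @export
write_sam <- function(alignments, genome, reads, quals, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  a <- alignments
  flag <- ifelse(!a$mapped, 4L, ifelse(a$strand == "-", 16L, 0L))
  mapq <- ifelse(!a$mapped, 0L, ifelse(a$is_unique, 60L, 0L))
  seq_out <- reads
  qual_out <- quals
  rev_idx <- which(a$mapped & a$strand == "-")
  if (length(rev_idx)) {
    seq_out[rev_idx] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[rev_idx])))
    qual_out[rev_idx] <- vapply(strsplit(quals[rev_idx], ""),
                                function(x) paste(rev(x), collapse = ""), "")
  }
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  a$read_id, flag,
                  ifelse(a$mapped, a$reference, "*"),
                  ifelse(a$mapped, a$pos + 1L, 0L), mapq,
                  ifelse(a$mapped, a$cigar, "*"), seq_out, qual_out)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write and read simulation configs as JSON
#' @param config a [simulation_config()] object (for writing).
#' @param path file path.
#' @export
write_config_json <- function(config, path) {
  x <- unclass(config)
  x$n_genes <- as.list(x$n_genes)  # keep names through JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$n_genes <- unlist(x$n_genes)
  do.call(simulation_config,
          x[intersect(names(x), names(formals(simulation_config)))])
}
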