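#' Write variant calls as VCF 4.2
#'
#' Positions convert from the package's 0-based convention to 1-based VCF
#' POS; multi-allelic substitutions are comma-joined on one row; indels are
#' left-anchored on the preceding reference base.  Calls must arrive sorted
#' by (reference, position).  The file round-trips through [read_vcf()].
#'
#' @param calls a `variant_calls` data frame.
#' @param genome named character vector (needed for indel anchor bases and
#'   `##contig` headers).
#' @param path output path.
#' @export
write_vcf <- function(calls, genome, path) {
  if (nrow(calls) &&
      !identical(order(calls$reference, calls$pos), seq_len(nrow(calls))))
    stop("calls must be sorted by (reference, position)")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(genome),
                   nchar(genome)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  drop <- 0L
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    g <- genome[[cl$reference]]
    if (cl$type == "snp") {
      pos1 <- cl$pos + 1L
      ref <- cl$ref
      alt <- cl$alt
    } else if (cl$type == "del") {
      if (cl$pos < 1L) { drop <- drop + 1L; next }
      len <- as.integer(cl$ref)
      pos1 <- cl$pos  # 1-based position of the anchor base at 0-based pos-1
      ref <- substring(g, cl$pos, cl$pos + len)
      alt <- substring(g, cl$pos, cl$pos)
    } else {  # ins
      if (cl$pos < 1L) { drop <- drop + 1L; next }
      pos1 <- cl$pos
      anchor <- substring(g, cl$pos, cl$pos)
      ref <- anchor
      alt <- paste0(anchor, cl$alt)
    }
    rows <- c(rows, sprintf("%s\t%d\t.\t%s\t%s\t%.4f\tPASS\t.",
                            cl$reference, pos1, ref, alt, cl$qual))
  }
  if (drop > 0L)
    warning(drop, " indel call(s) at position 0 lack an anchor base; dropped")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_vcf
#' @param path VCF path to read.
#' @return `read_vcf` returns a `variant_calls`-shaped data frame
#'   (`reference`, `pos` 0-based, `type`, `ref`, `alt`, `n_alts`, `qual`).
#' @export
read_vcf <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (!length(ln))
    return(data.frame(reference = character(0), pos = integer(0),
                      type = character(0), ref = character(0),
                      alt = character(0), n_alts = integer(0),
                      qual = numeric(0), stringsAsFactors = FALSE))
  f <- strsplit(ln, "\t", fixed = TRUE)
  out <- lapply(f, function(x) {
    pos1 <- as.integer(x[2]); ref <- x[4]; alt <- x[5]
    qual <- as.numeric(x[6])
    if (nchar(ref) == 1L && !grepl(",", alt) && nchar(alt) == 1L) {
      type <- "snp"; pos <- pos1 - 1L
    } else if (nchar(ref) == 1L && grepl(",", alt)) {
      type <- "snp"; pos <- pos1 - 1L
    } else if (nchar(ref) > nchar(alt)) {
      type <- "del"; pos <- pos1  # anchor at pos1 (1-based) = 0-based pos1
      ref <- as.character(nchar(ref) - 1L); alt <- ""
    } else {
      type <- "ins"; pos <- pos1
      alt <- substring(alt, 2L); ref <- ""
    }
    data.frame(reference = x[1], pos = pos, type = type, ref = ref,
               alt = alt, n_alts = if (type == "snp")
                 length(strsplit(alt, ",")[[1]]) else 1L,
               qual = qual, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
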