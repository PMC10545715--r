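#' Pileup of aligned reads over a genome
#'
#' Projects every aligned read through its CIGAR string onto the reference:
#' aligned bases contribute to per-site base counts and to per-genotype
#' log-likelihoods under an independent-error model (a base with Phred
#' quality Q is wrong with probability `10^(-Q/10)`, uniformly over the
#' three other bases); deletions skip reference columns and insertions are
#' recorded against their left anchor site.  Only covered sites are
#' emitted; non-ACGT read bases are skipped.
#'
#' Besides the full base counts, counts restricted to *read-internal*
#' observations (at least `end_prox` bases from both read ends) are kept:
#' reads whose ends overhang an unmappable breakpoint stack consistent
#' phantom alternates there, and those artifacts live exclusively near
#' read ends.
#'
#' @param alignments alignment data frame (from [align_reads()]); only
#'   rows with `mapped & is_unique` are used.
#' @param genome named character vector of reference sequences.
#' @param reads,quals read sequences/qualities in `alignments` row order
#'   (as read from FASTQ, i.e. original orientation).
#' @param end_prox distance (bp) from a read end below which an
#'   observation does not count as read-internal (default 10).
#' @return An object of class `pileup`: `sites` (data frame with
#'   `reference`, `pos`, `ref`, `depth`, count columns `n_A..n_T` and
#'   read-internal counts `i_A..i_T`), per-genotype log-likelihood matrix
#'   `loglik`, and indel evidence tables `insertions` / `deletions`.
#' @export
compute_pileup <- function(alignments, genome, reads, quals,
                           end_prox = 10L) {
  keep <- which(alignments$mapped & alignments$is_unique)
  a <- alignments[keep, , drop = FALSE]
  reads <- reads[keep]; quals <- quals[keep]
  if (any(!a$reference %in% names(genome)))
    stop("alignment references unknown sequence id: ",
         paste(unique(setdiff(a$reference, names(genome))), collapse = ", "))
  # orient reads to the forward reference strand
  neg <- which(a$strand == "-")
  if (length(neg)) {
    reads[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[neg])))
    quals[neg] <- vapply(strsplit(quals[neg], ""),
                         function(x) paste(rev(x), collapse = ""), "")
  }
  sid <- match(a$reference, names(genome)) - 1L
  res <- cpp_pileup(unname(genome), sid, a$pos, a$cigar, reads, quals,
                    as.integer(end_prox))
  counts <- res$counts
  colnames(counts) <- c("n_A", "n_C", "n_G", "n_T")
  internal <- res$internal
  colnames(internal) <- c("i_A", "i_C", "i_G", "i_T")
  sites <- data.frame(reference = names(genome)[res$sid + 1L],
                      pos = res$pos, ref = res$ref, depth = res$depth,
                      stringsAsFactors = FALSE)
  sites <- cbind(sites, as.data.frame(counts), as.data.frame(internal))
  ins <- data.frame(reference = names(genome)[res$ins_sid + 1L],
                    pos = res$ins_pos, seq = res$ins_seq, n = res$ins_n,
                    stringsAsFactors = FALSE)
  del <- data.frame(reference = names(genome)[res$del_sid + 1L],
                    pos = res$del_pos, len = res$del_len, n = res$del_n,
                    stringsAsFactors = FALSE)
  ll <- res$loglik
  colnames(ll) <- c("A", "C", "G", "T")
  structure(list(sites = sites, loglik = ll,
                 insertions = ins[order(ins$reference, ins$pos), ,
                                  drop = FALSE],
                 deletions = del[order(del$reference, del$pos), ,
                                 drop = FALSE]),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("pileup: %d covered sites (mean depth %.1f), %d insertion and %d deletion signatures\n",
              nrow(x$sites), mean(x$sites$depth),
              nrow(x$insertions), nrow(x$deletions)))
  invisible(x)
}

#' Construct a single pileup column from explicit observations
#'
#' Convenience for inspecting the site-quality model: builds the counts and
#' per-genotype log-likelihoods for one site from explicit base
#' observations.
#'
#' @param ref_base the reference base at the site.
#' @param bases character vector of observed bases.
#' @param quals integer vector of Phred qualities (same length).
#' @return A one-site `pileup` object.
#' @export
pileup_column <- function(ref_base, bases, quals) {
  stopifnot(length(bases) == length(quals))
  nt <- c("A", "C", "G", "T")
  keep <- bases %in% nt
  bases <- bases[keep]; quals <- pmax(quals[keep], 2L)
  e <- pmin(10^(-quals / 10), 0.75)
  ll <- vapply(nt, function(g)
    sum(ifelse(bases == g, log(1 - e), log(e / 3))), 0)
  counts <- vapply(nt, function(g) sum(bases == g), 0L)
  sites <- data.frame(reference = "seq_1", pos = 0L, ref = ref_base,
                      depth = length(bases), stringsAsFactors = FALSE)
  sites$n_A <- counts[["A"]]; sites$n_C <- counts[["C"]]
  sites$n_G <- counts[["G"]]; sites$n_T <- counts[["T"]]
  # explicit observations carry no read-end context: treat as internal
  sites$i_A <- sites$n_A; sites$i_C <- sites$n_C
  sites$i_G <- sites$n_G; sites$i_T <- sites$n_T
  structure(list(sites = sites, loglik = matrix(ll, nrow = 1,
                                                dimnames = list(NULL, nt)),
                 insertions = data.frame(), deletions = data.frame()),
            class = "pileup")
}

#' Call variants from a pileup
#'
#' Substitutions: the Phred-scaled site quality is
#' `QUAL = -10 log10 P(reference genotype | observed bases)` under the
#' haploid independent-error model with a flat prior over the four
#' genotypes.  A call is emitted at every site where some non-reference
#' base has at least `min_alt_count` supporting reads; `n_alts` counts the
#' distinct non-reference alleles passing that filter.  Indels (from
#' gapped alignments) are called with a two-hypothesis posterior at a
#' fixed per-read gap error rate; they are never applied as corrections
#' and only feed the SNP-aware index.
#'
#' Substitution calls within `snp_gap` bp of supported indel evidence are
#' suppressed: reads whose ends overhang an indel junction align their
#' flank as a run of apparent mismatches, which otherwise produces
#' confident false substitution calls hugging every indel.
#'
#' @param pile a [compute_pileup()] object.
#' @param min_alt_count minimum supporting reads for an alternate allele
#'   (default 2; guards against lone sequencing errors).  Support is
#'   counted over *read-internal* observations (see [compute_pileup()]):
#'   alleles seen only near read ends are overhang artifacts of
#'   unmappable breakpoints and are not called.
#' @param indel_error assumed per-read probability of a spurious gap.
#' @param snp_gap suppress substitution calls within this many bp of a
#'   called indel (default 20).
#' @param min_local_depth_ratio minimum site depth as a fraction of the
#'   median depth of covered sites within `local_depth_window` bp
#'   (default 0.3).  Reference segments that are absent from the
#'   sequenced strain receive no legitimate coverage, only sparse
#'   junction-overhang placements; such coverage craters are excluded
#'   from substitution calling.
#' @param local_depth_window neighbourhood half-width (bp) for the local
#'   depth median (default 100).
#' @param min_indel_fraction minimum supporting-read fraction for an indel
#'   call (default 0.3): genuine haploid indels are shown by essentially
#'   every spanning read, whereas sporadic gap placements inside dense
#'   mismatch runs stay far below this.
#' @return A data frame of class `variant_calls`: `reference`, `pos`
#'   (0-based), `type` (snp/ins/del), `ref`, `alt` (comma-joined when
#'   multi-allelic), `n_alts`, `qual`, `depth`, `alt_count`.
#' @export
call_variants <- function(pile, min_alt_count = 2L, indel_error = 1e-3,
                          snp_gap = 20L, min_indel_fraction = 0.3,
                          min_local_depth_ratio = 0.3,
                          local_depth_window = 100L) {
  stopifnot(inherits(pile, "pileup"))
  s <- pile$sites
  nt <- c("A", "C", "G", "T")
  calls <- NULL
  if (nrow(s)) {
    cm <- as.matrix(s[, c("n_A", "n_C", "n_G", "n_T")])
    im <- as.matrix(s[, c("i_A", "i_C", "i_G", "i_T")])
    ref_idx <- match(s$ref, nt)
    alt_cm <- cm
    alt_cm[cbind(seq_len(nrow(cm)), ref_idx)] <- 0L
    alt_im <- im
    alt_im[cbind(seq_len(nrow(im)), ref_idx)] <- 0L
    # alleles must be supported by read-internal observations: end-only
    # support is the signature of an overhang artifact, not a variant
    has_alt <- rowSums(alt_im >= min_alt_count) > 0L & !is.na(ref_idx)
    idx <- which(has_alt)
    if (length(idx)) {
      ll <- pile$loglik[idx, , drop = FALSE]
      lse <- apply(ll, 1L, function(r) {
        m <- max(r); m + log(sum(exp(r - m)))
      })
      lref <- ll[cbind(seq_along(idx), ref_idx[idx])]
      qual <- (lse - lref) * 10 / log(10)
      alt_str <- character(length(idx))
      n_alts <- integer(length(idx))
      alt_count <- integer(length(idx))
      for (i in seq_along(idx)) {
        ac <- alt_cm[idx[i], ]
        ai <- alt_im[idx[i], ]
        passing <- which(ai >= min_alt_count)
        ord <- passing[order(-ac[passing], nt[passing])]
        alt_str[i] <- paste(nt[ord], collapse = ",")
        n_alts[i] <- length(ord)
        alt_count[i] <- max(ac)
      }
      calls <- data.frame(reference = s$reference[idx], pos = s$pos[idx],
                          type = "snp", ref = s$ref[idx], alt = alt_str,
                          n_alts = n_alts, qual = qual,
                          depth = s$depth[idx], alt_count = alt_count,
                          stringsAsFactors = FALSE)
      # coverage-crater filter: deleted reference segments collect only
      # sparse junction-overhang placements, far below local depth
      if (min_local_depth_ratio > 0 && nrow(calls)) {
        keep <- vapply(seq_len(nrow(calls)), function(i) {
          blk <- which(s$reference == calls$reference[i])
          lo <- findInterval(calls$pos[i] - local_depth_window - 1L,
                             s$pos[blk]) + 1L
          hi <- findInterval(calls$pos[i] + local_depth_window, s$pos[blk])
          if (hi < lo) return(TRUE)
          calls$depth[i] >=
            min_local_depth_ratio * stats::median(s$depth[blk[lo:hi]])
        }, TRUE)
        calls <- calls[keep, , drop = FALSE]
      }
    }
  }
  indel_qual <- function(k, d_non) {
    e <- indel_error
    lyes <- k * log(1 - e) + d_non * log(e)
    lno <- k * log(e) + d_non * log(1 - e)
    m <- max(lyes, lno)
    lse <- m + log(exp(lyes - m) + exp(lno - m))
    (lse - lno) * 10 / log(10)
  }
  depth_at <- function(refn, pos) {
    i <- which(s$reference == refn & s$pos == pos)
    if (length(i)) s$depth[i[1]] else 0L
  }
  ind <- NULL
  ins <- pile$insertions; del <- pile$deletions
  if (nrow(ins)) {
    d_non <- pmax(mapply(depth_at, ins$reference, ins$pos) - ins$n, 0L)
    keep <- ins$n >= min_alt_count &
      ins$n >= min_indel_fraction * (ins$n + d_non)
    if (any(keep)) {
      ins <- ins[keep, , drop = FALSE]; d_non <- d_non[keep]
      ind <- rbind(ind, data.frame(
        reference = ins$reference, pos = ins$pos, type = "ins", ref = "",
        alt = ins$seq, n_alts = 1L,
        qual = mapply(indel_qual, ins$n, d_non),
        depth = d_non + ins$n, alt_count = ins$n, stringsAsFactors = FALSE))
    }
  }
  if (nrow(del)) {
    d_non <- mapply(depth_at, del$reference, del$pos)
    keep <- del$n >= min_alt_count &
      del$n >= min_indel_fraction * (del$n + d_non)
    if (any(keep)) {
      del <- del[keep, , drop = FALSE]; d_non <- d_non[keep]
      ind <- rbind(ind, data.frame(
        reference = del$reference, pos = del$pos, type = "del",
        ref = as.character(del$len), alt = "", n_alts = 1L,
        qual = mapply(indel_qual, del$n, d_non),
        depth = d_non + del$n, alt_count = del$n, stringsAsFactors = FALSE))
    }
  }
  # SnpGap-style masking of substitutions hugging called indels
  if (!is.null(calls) && nrow(calls) && !is.null(ind) && nrow(ind) &&
      snp_gap > 0L) {
    span <- ifelse(ind$type == "del", as.integer(ind$ref), 0L)
    lo <- ind$pos - snp_gap
    hi <- ind$pos + span + snp_gap
    masked <- vapply(seq_len(nrow(calls)), function(i)
      any(ind$reference == calls$reference[i] & calls$pos[i] >= lo &
            calls$pos[i] <= hi), TRUE)
    calls <- calls[!masked, , drop = FALSE]
  }
  out <- rbind(calls, ind)
  if (is.null(out))
    out <- data.frame(reference = character(0), pos = integer(0),
                      type = character(0), ref = character(0),
                      alt = character(0), n_alts = integer(0),
                      qual = numeric(0), depth = integer(0),
                      alt_count = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$reference, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Call a single site
#'
#' Applies the substitution model of [call_variants()] to one
#' [pileup_column()]; returns `NULL` when every observation supports the
#' reference.
#'
#' @inheritParams call_variants
#' @param column a one-site `pileup` from [pileup_column()].
#' @export
call_site <- function(column, min_alt_count = 2L) {
  calls <- call_variants(column, min_alt_count = min_alt_count)
  if (nrow(calls) == 0L) NULL else calls[1L, ]
}
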