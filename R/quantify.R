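#' Count fragments over gene models
#'
#' A fragment (read pair) is the leftmost-to-rightmost span of its
#' uniquely mapped mates on one reference; it is assigned to the gene
#' whose interval contains the integer midpoint
#' `floor((start + end - 1) / 2)` of that span.  Fragments whose midpoint
#' falls outside every gene contribute to the mapped total but to no
#' gene.  Pairs whose mates map uniquely to different references are
#' skipped with a warning.
#'
#' @param alignments per-mate alignment rows carrying `pair_id` (e.g. the
#'   `host_alignments` element of a [partition_reads()] result); only
#'   `mapped & is_unique` rows are used.
#' @param genes gene-model data frame (`gene_id`, `reference`, `start`,
#'   `end`, 0-based half-open).
#' @return A list with `counts` (named integer vector over all genes) and
#'   `total` (total mapped fragments).
#' @export
count_fragments <- function(alignments, genes) {
  a <- alignments[alignments$mapped & alignments$is_unique, , drop = FALSE]
  counts <- setNames(integer(nrow(genes)), genes$gene_id)
  if (nrow(a) == 0L) return(list(counts = counts, total = 0L))
  a$ref_len <- cigar_ref_length(a$cigar)
  sp_start <- tapply(a$pos, a$pair_id, min)
  sp_end <- tapply(a$pos + a$ref_len, a$pair_id, max)
  nref <- tapply(a$reference, a$pair_id, function(x) length(unique(x)))
  refs <- tapply(a$reference, a$pair_id, function(x) x[1])
  ok <- nref == 1L
  if (any(!ok)) warning(sum(!ok), " pair(s) span two references; skipped")
  sp_start <- sp_start[ok]; sp_end <- sp_end[ok]; refs <- refs[ok]
  total <- length(sp_start)
  mid <- floor((sp_start + sp_end - 1) / 2)
  for (rn in unique(refs)) {
    gi <- which(genes$reference == rn)
    if (!length(gi)) next
    sel <- refs == rn
    g <- genes[gi, ][order(genes$start[gi]), ]
    slot <- findInterval(mid[sel], g$start)
    hit <- slot >= 1L & mid[sel] < g$end[pmax(slot, 1L)]
    tab <- table(factor(g$gene_id[slot[hit]], levels = genes$gene_id))
    counts <- counts + as.integer(tab)
  }
  list(counts = counts, total = as.integer(total))
}

# Reference bases consumed by a CIGAR string (M/D/=/X consume).
cigar_ref_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg)) return(0L)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDX=]", cg))[[1]]
    sum(as.integer(sub("[MIDX=]", "", ops))[!grepl("I", ops)])
  }, integer(1), USE.NAMES = FALSE)
}

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM_g = count_g / ((length_g / 1000) * (total_mapped / 1e6))`.
#'
#' @param counts named fragment counts per gene.
#' @param gene_lengths gene lengths in bp (same order/names).
#' @param total_mapped total mapped fragments in the sample (> 0).
#' @return Numeric vector of FPKM values.
#' @export
fpkm <- function(counts, gene_lengths, total_mapped) {
  if (total_mapped <= 0) stop("empty sample: total_mapped must be > 0")
  counts / ((gene_lengths / 1000) * (total_mapped / 1e6))
}

#' Pool fragment counts across replicates
#'
#' Sums per-gene counts and mapped totals across the replicates of a time
#' point *before* FPKM computation, so pooled FPKM equals the FPKM of the
#' merged alignment set.
#'
#' @param count_list list of [count_fragments()] results over an identical
#'   gene universe.
#' @return A single `list(counts, total)`.
#' @export
pool_replicates <- function(count_list) {
  u <- names(count_list[[1]]$counts)
  for (cl in count_list)
    if (!identical(names(cl$counts), u))
      stop("replicates have mismatched gene universes")
  list(counts = Reduce(`+`, lapply(count_list, `[[`, "counts")),
       total = sum(vapply(count_list, `[[`, 0L, "total")))
}

#' Assemble an FPKM expression matrix
#'
#' @param count_tables named list of `list(counts, total)` per sample
#'   column.
#' @param gene_models gene-model data frame for the organism.
#' @param meta data frame with one row per column: `sample`, `organism`,
#'   `timepoint`, `replicate` (use `"pooled"` for pooled columns).
#' @return Object of class `expression_matrix`: `fpkm` and `counts`
#'   (genes x samples), `totals`, `meta`, `gene_models`.
#' @export
expression_matrix <- function(count_tables, gene_models, meta) {
  stopifnot(length(count_tables) == nrow(meta))
  glen <- gene_models$end - gene_models$start
  fm <- vapply(count_tables, function(ct)
    fpkm(ct$counts[gene_models$gene_id], glen, ct$total),
    numeric(nrow(gene_models)))
  cm <- vapply(count_tables, function(ct)
    as.integer(ct$counts[gene_models$gene_id]), integer(nrow(gene_models)))
  dimnames(fm) <- dimnames(cm) <- list(gene_models$gene_id, meta$sample)
  structure(list(fpkm = fm, counts = cm,
                 totals = setNames(vapply(count_tables, `[[`, 0L, "total"),
                                   meta$sample),
                 meta = meta, gene_models = gene_models),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (FPKM)\n",
              nrow(x$fpkm), ncol(x$fpkm)))
  print(utils::head(x$fpkm, 4L))
  invisible(x)
}

#' Per-time-point presence sets and Venn regions
#'
#' A gene is "present" at a time point when its FPKM exceeds `threshold`
#' (strictly).  Returns the per-time-point sets, the counts of all
#' `2^T - 1` exclusive Venn regions, the time-point-specific counts, and
#' percentages of the detected-gene universe (the union).
#'
#' @param mat an `expression_matrix` with one column per time point, or a
#'   plain genes x timepoints FPKM matrix.
#' @param threshold FPKM presence threshold (default 0).
#' @return Object of class `presence_sets`.
#' @export
presence_sets <- function(mat, threshold = 0) {
  m <- if (inherits(mat, "expression_matrix")) mat$fpkm else mat
  tp <- colnames(m)
  if (is.null(tp)) tp <- paste0("t", seq_len(ncol(m)))
  present <- m > threshold
  sets <- lapply(seq_along(tp), function(j) rownames(m)[present[, j]])
  names(sets) <- tp
  T_ <- length(tp)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), T_))[-1L, , drop = FALSE]
  region_count <- integer(nrow(combos))
  region_label <- character(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    pat <- as.logical(combos[i, ])
    region_count[i] <- sum(apply(present, 1L, function(r) all(r == pat)))
    region_label[i] <- paste(tp[pat], collapse = "&")
  }
  regions <- data.frame(region = region_label,
                        n_timepoints = rowSums(combos),
                        count = region_count, stringsAsFactors = FALSE)
  union_n <- sum(rowSums(present) > 0L)
  specific <- regions$count[regions$n_timepoints == 1L]
  names(specific) <- tp[apply(combos[regions$n_timepoints == 1L, ,
                                     drop = FALSE], 1L, which)]
  structure(list(sets = sets, regions = regions,
                 specific = specific[tp],
                 shared_all = regions$count[regions$n_timepoints == T_],
                 universe = union_n,
                 percentages = setNames(100 * regions$count /
                                          max(union_n, 1L), region_label),
                 threshold = threshold),
            class = "presence_sets")
}

#' @export
print.presence_sets <- function(x, ...) {
  cat(sprintf("presence_sets: %d detected genes (FPKM > %g)\n",
              x$universe, x$threshold))
  cat(sprintf("  in all timepoints: %d; specific: %s\n", x$shared_all,
              paste(names(x$specific), x$specific, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Per-time-point organism read fractions
#'
#' Pathogen fraction = pathogen-mapped / (pathogen-mapped + host-mapped)
#' pairs, pooled over the replicates of a time point; a per-sample
#' breakdown is included.
#'
#' @param partitions named list of [partition_reads()] results.
#' @param meta data frame with rows matching `partitions` (`sample`,
#'   `timepoint`).
#' @return List with `per_timepoint` and `per_sample` data frames.
#' @export
organism_fractions <- function(partitions, meta) {
  stopifnot(length(partitions) == nrow(meta))
  per_sample <- do.call(rbind, lapply(seq_along(partitions), function(i) {
    p <- partitions[[i]]
    tab <- table(p$assignment)
    data.frame(sample = meta$sample[i], timepoint = meta$timepoint[i],
               pathogen = as.integer(tab[["pathogen"]]),
               host = as.integer(tab[["host"]]),
               unmapped = as.integer(tab[["unmapped"]]),
               stringsAsFactors = FALSE)
  }))
  agg <- do.call(rbind, lapply(split(per_sample, per_sample$timepoint),
                               function(d) {
    data.frame(timepoint = d$timepoint[1],
               pathogen = sum(d$pathogen), host = sum(d$host),
               pathogen_fraction = sum(d$pathogen) /
                 (sum(d$pathogen) + sum(d$host)),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[match(unique(meta$timepoint), agg$timepoint), , drop = FALSE]
  rownames(agg) <- NULL
  per_sample$pathogen_fraction <-
    per_sample$pathogen / pmax(per_sample$pathogen + per_sample$host, 1L)
  list(per_timepoint = agg, per_sample = per_sample)
}

#' Top expressed genes at a time point
#'
#' @param mat an `expression_matrix` (or plain FPKM matrix).
#' @param column column (sample/time point) name or index.
#' @param n number of genes (ties broken by gene id, ascending).
#' @return Data frame `gene_id`, `fpkm`, ranked descending.
#' @export
top_expressed <- function(mat, column, n = 10L) {
  m <- if (inherits(mat, "expression_matrix")) mat$fpkm else mat
  v <- m[, column]
  if (n > length(v)) {
    warning("n exceeds gene count; returning all genes")
    n <- length(v)
  }
  ord <- order(-v, names(v))[seq_len(n)]
  data.frame(gene_id = names(v)[ord], fpkm = unname(v[ord]),
             stringsAsFactors = FALSE)
}
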