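#' Sliding-window quality trimming of paired reads
#'
#' Scans each read 5' to 3' with a window of `window` bases and truncates it
#' immediately before the first window whose mean Phred quality falls below
#' `window_quality`.  Reads shorter than `min_len` after truncation are
#' discarded; by default the mate of a discarded read is discarded with it,
#' keeping the mate files synchronous (`keep_orphans = TRUE` retains
#' orphaned mates instead).
#'
#' @param r1,q1,r2,q2 character vectors: mate-1/mate-2 sequences and
#'   Phred+33 quality strings.  Alternatively pass a single sample from
#'   [simulate_reads()] as `r1` and leave the others `NULL`.
#' @param window window size in bases (default 3).
#' @param min_len minimum surviving read length (default 36); shorter reads
#'   are removed.
#' @param window_quality mean-Phred threshold for a failing window
#'   (default 15).
#' @param keep_orphans keep a surviving mate whose partner was discarded.
#' @return A list with the surviving `r1`, `q1`, `r2`, `q2`, `read_id`
#'   (when input had ids) and a `report` list counting input, surviving and
#'   dropped pairs.
#' @export
trim_reads <- function(r1, q1 = NULL, r2 = NULL, q2 = NULL,
                       window = 3L, min_len = 36L, window_quality = 15,
                       keep_orphans = FALSE) {
  ids <- NULL
  if (is.list(r1) && !is.null(r1$r1)) {
    smp <- r1
    r1 <- smp$r1; q1 <- smp$q1; r2 <- smp$r2; q2 <- smp$q2
    ids <- smp$read_id
  }
  if (window < 1L) stop("'window' must be >= 1")
  if (min_len < window) stop("'min_len' must be >= 'window'")
  if (length(r1) != length(q1))
    stop("mate 1: sequence and quality counts differ")
  paired <- !is.null(r2)
  if (paired && (length(r2) != length(q2) || length(r1) != length(r2)))
    stop(sprintf("mismatched mate counts: %d mate-1 vs %d mate-2 reads",
                 length(r1), length(r2)))
  k1 <- trim_keep_lengths(q1, window, window_quality)
  s1 <- substring(r1, 1L, k1); t1 <- substring(q1, 1L, k1)
  ok1 <- k1 >= min_len
  if (paired) {
    k2 <- trim_keep_lengths(q2, window, window_quality)
    s2 <- substring(r2, 1L, k2); t2 <- substring(q2, 1L, k2)
    ok2 <- k2 >= min_len
    keep <- if (keep_orphans) ok1 | ok2 else ok1 & ok2
    res <- list(r1 = s1[keep], q1 = t1[keep],
                r2 = s2[keep], q2 = t2[keep])
    if (keep_orphans) {
      res$r1[!ok1[keep]] <- NA_character_; res$q1[!ok1[keep]] <- NA_character_
      res$r2[!ok2[keep]] <- NA_character_; res$q2[!ok2[keep]] <- NA_character_
    }
  } else {
    keep <- ok1
    res <- list(r1 = s1[keep], q1 = t1[keep])
  }
  if (!is.null(ids)) res$read_id <- ids[keep]
  res$report <- list(input = length(r1), surviving = sum(keep),
                     dropped = length(r1) - sum(keep),
                     truncated = sum(k1 < nchar(r1)) +
                       if (paired) sum(k2 < nchar(r2)) else 0L)
  res
}

# Length kept for each read: everything before the first window of `window`
# bases whose mean quality is below `thr` (whole read if none fails).
trim_keep_lengths <- function(quals, window, thr) {
  vapply(quals, function(q) {
    v <- utf8ToInt(q) - 33L
    n <- length(v)
    if (n < window) return(n)
    cs <- cumsum(v)
    means <- (cs[window:n] - c(0L, cs[seq_len(n - window)])) / window
    bad <- which(means < thr)
    if (!length(bad)) n else bad[1L] - 1L
  }, integer(1), USE.NAMES = FALSE)
}
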