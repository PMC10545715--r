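# Independent oracles used across the test suite.  These deliberately share
# nothing with the package internals beyond the documented scoring contract.

# Exhaustive glocal affine-gap DP: the read aligns end-to-end, the reference
# start/end are free; returns the best score over every position and strand.
oracle_dp_score_one_strand <- function(read, qual, ref, params) {
  m <- nchar(read); w <- nchar(ref)
  rb <- strsplit(read, "")[[1]]
  gb <- strsplit(ref, "")[[1]]
  q <- if (is.null(qual) || is.na(qual)) rep(40L, m) else utf8ToInt(qual) - 33L
  pen <- -params$mismatch_min +
    round((-params$mismatch + params$mismatch_min) * pmin(q, 40) / 40)
  goe <- -(params$gap_open + params$gap_extend)
  ge <- -params$gap_extend
  NEGI <- -1e8
  best_prev <- rep(0, w + 1)
  ix_prev <- rep(NEGI, w + 1)
  for (i in seq_len(m)) {
    sub <- ifelse(gb == rb[i], 0, -pen[i])
    M <- c(NEGI, best_prev[1:w] + sub)
    Ix <- pmax(best_prev - goe, ix_prev - ge)
    A <- pmax(M, Ix)
    # Iy[j] = max_{k < j} A[k] - goe - ge*(j-1-k), via running max
    ck <- A + ge * seq(0, w)
    Iy <- c(NEGI, cummax(ck)[1:w] - goe - ge * seq(1, w) + ge)
    best_prev <- pmax(A, Iy)
    ix_prev <- Ix
  }
  max(best_prev)
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""),
                ""))
}

oracle_dp_score <- function(read, qual, refs, params) {
  best <- -Inf
  for (ref in refs) {
    best <- max(best,
                oracle_dp_score_one_strand(read, qual, ref, params),
                oracle_dp_score_one_strand(oracle_revcomp(read),
                                           if (is.null(qual) || is.na(qual))
                                             qual else
                                               paste(rev(strsplit(qual,
                                                                  "")[[1]]),
                                                     collapse = ""),
                                           ref, params))
  }
  best
}

# Brute-force UPGMA: recompute every inter-cluster mean distance from the
# original matrix at each step (no Lance-Williams shortcut).
oracle_upgma <- function(d) {
  D0 <- as.matrix(d)
  n <- nrow(D0)
  clusters <- as.list(seq_len(n))
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    bh <- Inf; bi <- bj <- 0L
    bkey <- c(Inf, Inf)
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      h <- mean(D0[clusters[[i]], clusters[[j]]])
      key <- c(min(min(clusters[[i]]), min(clusters[[j]])),
               max(min(clusters[[i]]), min(clusters[[j]])))
      if (h < bh - 1e-12 ||
          (abs(h - bh) <= 1e-12 &&
             (key[1] < bkey[1] ||
                (key[1] == bkey[1] && key[2] < bkey[2])))) {
        bh <- h; bi <- i; bj <- j; bkey <- key
      }
    }
    a <- ids[bi]; b <- ids[bj]
    merge[step, ] <- if (a < 0 && b < 0) c(max(a, b), min(a, b))
      else if (a < 0) c(a, b) else if (b < 0) c(b, a)
      else c(min(a, b), max(a, b))
    height[step] <- bh
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
    ids[bi] <- step
    ids <- ids[-bj]
  }
  list(merge = merge, height = height)
}

# Direct Davies-Bouldin evaluation from the definition, all loops explicit.
oracle_db <- function(assignments, profiles) {
  ks <- sort(unique(assignments))
  K <- length(ks)
  cen <- lapply(ks, function(k)
    colMeans(profiles[assignments == k, , drop = FALSE]))
  S <- vapply(seq_len(K), function(i) {
    rows <- profiles[assignments == ks[i], , drop = FALSE]
    mean(apply(rows, 1, function(r) sqrt(sum((r - cen[[i]])^2))))
  }, 0)
  total <- 0
  for (i in seq_len(K)) {
    worst <- -Inf
    for (j in seq_len(K)) {
      if (i == j) next
      Mij <- sqrt(sum((cen[[i]] - cen[[j]])^2))
      worst <- max(worst, if (Mij == 0) Inf else (S[i] + S[j]) / Mij)
    }
    total <- total + worst
  }
  total / K
}

# Random sequence helpers shared by the suites.
random_genome <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_read <- function(read, n_sub = 0L, n_indel = 0L) {
  bases <- c("A", "C", "G", "T")
  if (n_sub > 0L) {
    for (p in sample.int(nchar(read), n_sub)) {
      old <- substring(read, p, p)
      substr(read, p, p) <- sample(setdiff(bases, old), 1L)
    }
  }
  if (n_indel > 0L) {
    for (t in seq_len(n_indel)) {
      p <- sample.int(nchar(read) - 2L, 1L)
      if (runif(1) < 0.5) {
        read <- paste0(substring(read, 1L, p),
                       sample(bases, 1L), substring(read, p + 1L))
      } else {
        read <- paste0(substring(read, 1L, p), substring(read, p + 2L))
      }
    }
  }
  read
}
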