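#' Log-relative expression profiles
#'
#' Divides each gene's FPKM row by its own across-time-point mean and
#' takes logs, making profiles shape-comparable across expression levels
#' (a constant gene maps to an all-zero row; scaling a zero-free row
#' leaves its profile unchanged).  When the matrix contains zeros a
#' pseudocount is added before forming the ratio.  All-zero rows are
#' removed and reported.
#'
#' @param mat an `expression_matrix` or plain genes x timepoints matrix
#'   (one column per time point, pooled).
#' @param pseudocount added to every entry when zeros are present
#'   (default 1 FPKM).
#' @param log_base logarithm base (default 2).
#' @return A matrix of class `profile_matrix` with attributes
#'   `log_base`, `pseudocount` (as applied), `removed` (dropped gene
#'   ids).
#' @export
log_relative_transform <- function(mat, pseudocount = 1, log_base = 2) {
  m <- if (inherits(mat, "expression_matrix")) mat$fpkm else mat
  if (ncol(m) < 2L) stop("at least two timepoints are required")
  all_zero <- rowSums(m) == 0
  if (all(all_zero)) stop("all genes have all-zero expression")
  removed <- rownames(m)[all_zero]
  m <- m[!all_zero, , drop = FALSE]
  pc <- if (any(m == 0)) pseudocount else 0
  x <- m + pc
  prof <- log(x / rowMeans(x), base = log_base)
  structure(prof, class = c("profile_matrix", class(prof)),
            log_base = log_base, pseudocount = pc, removed = removed)
}

#' UPGMA (average-linkage) agglomerative clustering
#'
#' Starting from singletons, repeatedly merges the pair of clusters with
#' the minimal mean inter-cluster distance; after a merge, distances to
#' the new cluster are size-weighted averages (the Lance-Williams update
#' for UPGMA).  Ties are broken deterministically by the lexicographically
#' smallest pair of smallest member leaf indices.  On a metric the merge
#' heights are non-decreasing; a violation beyond numerical tolerance is
#' an error.
#'
#' @param profiles a `profile_matrix` (genes x timepoints) or any numeric
#'   matrix of row vectors to cluster.
#' @param metric "euclidean" (default) or "correlation"
#'   (`1 - Pearson r`).
#' @return An object of class `upgma_dendrogram` with elements `merge`,
#'   `height`, `labels`, `order` (hclust-compatible via [as.hclust()]).
#' @export
upgma <- function(profiles, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  d <- profile_dist(profiles, metric)
  if (any(!is.finite(d))) stop("non-finite distances")
  n <- attr(d, "Size")
  if (n < 2L) stop("at least two rows are required")
  D <- as.matrix(d)
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  node_id <- -seq_len(n)       # hclust convention: negatives are leaves
  min_leaf <- seq_len(n)       # smallest member leaf index, for tie-breaks
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    Dv <- D
    Dv[!active, ] <- Inf
    Dv[, !active] <- Inf
    h <- min(Dv)
    cand <- which(Dv == h, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: smallest (min leaf, min leaf) pair
    key1 <- pmin(min_leaf[cand[, 1]], min_leaf[cand[, 2]])
    key2 <- pmax(min_leaf[cand[, 1]], min_leaf[cand[, 2]])
    pick <- order(key1, key2)[1L]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    if (step > 1L && h < height[step - 1L] - 1e-9)
      stop("non-monotone merge heights: distance input is not a metric")
    merge[step, ] <- sort_pair(node_id[i], node_id[j])
    height[step] <- h
    # Lance-Williams size-weighted average update onto slot i
    wi <- size[i] / (size[i] + size[j])
    wj <- size[j] / (size[i] + size[j])
    newd <- wi * D[i, ] + wj * D[j, ]
    D[i, ] <- newd
    D[, i] <- newd
    D[i, i] <- Inf
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    node_id[i] <- step
    min_leaf[i] <- min(min_leaf[i], min_leaf[j])
  }
  labels <- rownames(profiles)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  hc <- structure(list(merge = merge, height = height,
                       order = dendrogram_order(merge, n),
                       labels = labels, method = "average",
                       call = match.call(), dist.method = metric),
                  class = "hclust")
  structure(list(merge = merge, height = height, labels = labels,
                 order = hc$order, metric = metric, hclust = hc),
            class = "upgma_dendrogram")
}

profile_dist <- function(profiles, metric) {
  if (metric == "euclidean") dist(profiles)
  else stats::as.dist(1 - cor(t(profiles)))
}

sort_pair <- function(a, b) {
  # hclust convention: leaves (negative) precede internal nodes; a pair of
  # leaves lists the smaller observation index first
  if (a < 0 && b < 0) c(max(a, b), min(a, b))
  else if (a < 0) c(a, b)
  else if (b < 0) c(b, a)
  else c(min(a, b), max(a, b))
}

# leaf ordering by iterative expansion of the merge tree (for plotting)
dendrogram_order <- function(merge, n) {
  expand <- function(node) {
    stack <- list(node)
    out <- integer(0)
    while (length(stack)) {
      nd <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (nd < 0) out <- c(out, -nd)
      else stack <- c(stack, list(merge[nd, 2]), list(merge[nd, 1]))
    }
    out
  }
  expand(n - 1L)
}

#' @export
as.hclust.upgma_dendrogram <- function(x, ...) x$hclust

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram: %d leaves, %d merges (metric: %s)\n",
              length(x$labels), nrow(x$merge), x$metric))
  invisible(x)
}

#' Cut a dendrogram into K clusters
#' @param dend an `upgma_dendrogram`.
#' @param k number of clusters.
#' @return Named integer vector of cluster assignments.
#' @export
cut_clusters <- function(dend, k) {
  cutree(as.hclust(dend), k = k)
}

#' Davies-Bouldin index of a clustering
#'
#' `DB = (1/K) * sum_i max_{j != i} (S_i + S_j) / M_ij`, where `S_i` is
#' the mean distance of cluster i members to their centroid and `M_ij`
#' the centroid-centroid distance.  Singletons have `S = 0`; lower is
#' better.  Coincident centroids make the pair's similarity infinite; the
#' score is then `Inf` with a `degenerate` attribute set.
#'
#' @param assignments integer cluster labels per row of `profiles`.
#' @param profiles numeric matrix (rows match `assignments`).
#' @return The DB score (scalar).
#' @export
davies_bouldin <- function(assignments, profiles) {
  ks <- sort(unique(assignments))
  K <- length(ks)
  if (K < 2L) stop("at least two non-empty clusters are required")
  cen <- t(vapply(ks, function(k)
    colMeans(profiles[assignments == k, , drop = FALSE]),
    numeric(ncol(profiles))))
  S <- vapply(seq_len(K), function(i) {
    rows <- profiles[assignments == ks[i], , drop = FALSE]
    mean(sqrt(rowSums((rows - rep(cen[i, ], each = nrow(rows)))^2)))
  }, 0)
  M <- as.matrix(dist(cen))
  degenerate <- FALSE
  R <- vapply(seq_len(K), function(i) {
    r <- (S[i] + S[-i]) / M[i, -i]
    if (any(M[i, -i] == 0)) { degenerate <<- TRUE; r[M[i, -i] == 0] <- Inf }
    max(r)
  }, 0)
  structure(mean(R), degenerate = degenerate)
}

#' Choose the cluster count by Davies-Bouldin minimisation
#'
#' Cuts the dendrogram at every K in `k_min..k_max`, scores each cut and
#' returns the K minimising the index (ties: smallest K).  The full score
#' trace is retained so the selection can be inspected.
#'
#' @param dend an [upgma()] dendrogram.
#' @param profiles the matrix the dendrogram was built from.
#' @param k_min,k_max candidate range; defaults 2 to
#'   `min(ceiling(n/2), 400)`.
#' @return Object of class `cluster_selection`: `k`, `scores` (data frame
#'   K/db), `assignments` at the chosen K.
#' @export
select_cluster_count <- function(dend, profiles, k_min = 2L, k_max = NULL) {
  n <- length(dend$labels)
  if (is.null(k_max)) k_max <- min(ceiling(n / 2), 400L)
  if (k_min < 2L) stop("'k_min' must be >= 2")
  if (k_max > n - 1L) stop("'k_max' must be <= leaves - 1")
  if (k_min > k_max) stop("empty K range")
  ks <- seq.int(k_min, k_max)
  cuts <- cutree(as.hclust(dend), k = ks)
  if (length(ks) == 1L) cuts <- matrix(cuts, ncol = 1L)
  scores <- vapply(seq_along(ks), function(i)
    as.numeric(davies_bouldin(cuts[, i], profiles)), 0)
  best <- ks[which.min(scores)]  # which.min takes the first (smallest K) tie
  structure(list(k = best,
                 scores = data.frame(k = ks, db = scores),
                 assignments = setNames(cuts[, which.min(scores)],
                                        dend$labels)),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("cluster_selection: K = %d (DB = %.4f over K in %d..%d)\n",
              x$k, min(x$scores$db), min(x$scores$k), max(x$scores$k)))
  invisible(x)
}

#' @export
plot.cluster_selection <- function(x, ...) {
  plot(x$scores$k, x$scores$db, type = "b", xlab = "K",
       ylab = "Davies-Bouldin index", ...)
  graphics::abline(v = x$k, lty = 2)
  invisible(x)
}

#' Per-cluster temporal activity map
#'
#' Averages the member profiles of each cluster per time point and places
#' the clusters on a fixed row-major near-square grid in ascending
#' cluster-id order, so maps of different time points are positionally
#' comparable.
#'
#' @param profiles a `profile_matrix`.
#' @param assignments cluster labels per row of `profiles`.
#' @return Object of class `cluster_activity_map`: `activity` (clusters x
#'   timepoints), `sizes`, `grid` (per-cluster row/col).
#' @export
cluster_activity <- function(profiles, assignments) {
  if (length(assignments) != nrow(profiles))
    stop("every gene must be assigned to a cluster")
  ks <- sort(unique(assignments))
  sizes <- vapply(ks, function(k) sum(assignments == k), 0L)
  if (any(sizes == 0L)) stop("empty cluster")
  act <- rowsum(unclass(profiles), group = assignments) / sizes
  rownames(act) <- paste0("cluster_", ks)
  ncol_grid <- ceiling(sqrt(length(ks)))
  grid <- data.frame(cluster = ks,
                     row = (seq_along(ks) - 1L) %/% ncol_grid + 1L,
                     col = (seq_along(ks) - 1L) %% ncol_grid + 1L)
  structure(list(activity = act, sizes = setNames(sizes,
                                                  rownames(act)),
                 grid = grid), class = "cluster_activity_map")
}

#' @export
print.cluster_activity_map <- function(x, ...) {
  cat(sprintf("cluster_activity_map: %d clusters x %d timepoints\n",
              nrow(x$activity), ncol(x$activity)))
  invisible(x)
}

#' Heatmap of cluster activity at one time point on the fixed grid
#' @param x a `cluster_activity_map`.
#' @param timepoint column to draw (default first).
#' @param ... passed to [graphics::image()].
#' @export
plot.cluster_activity_map <- function(x, timepoint = 1L, ...) {
  g <- x$grid
  nr <- max(g$row); nc <- max(g$col)
  z <- matrix(NA_real_, nr, nc)
  z[cbind(g$row, g$col)] <- x$activity[, timepoint]
  image(t(z)[, nr:1, drop = FALSE], axes = FALSE,
        col = hcl.colors(64, "RdBu", rev = TRUE),
        main = colnames(x$activity)[timepoint], ...)
  invisible(x)
}
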