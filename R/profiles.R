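#' Simulate an FPKM matrix with planted co-expression clusters
#'
#' Matrix-level companion to the read-level simulator: draws cluster
#' centroids in centered log2 space (rejection-sampled to a minimum
#' pairwise separation), assigns genes to clusters in balanced shuffled
#' fashion, adds within-cluster gene noise and a per-gene baseline, and
#' exponentiates to an FPKM-like scale.  Used to study the
#' cluster-number selection behaviour without running the full read
#' pipeline.
#'
#' @param n_genes number of genes.
#' @param timepoints time-point labels (matrix columns).
#' @param n_clusters planted cluster count.
#' @param cluster_profile_sd within-cluster noise, log2 scale.
#' @param min_profile_separation minimum centroid separation; defaults to
#'   `10 * cluster_profile_sd` so planted clusters are well separated.
#' @param expression_dispersion per-gene baseline SD (log2).
#' @param mean_fpkm geometric-mean FPKM of the baseline.
#' @param seed RNG seed.
#' @return List with `fpkm` (genes x timepoints), `labels` (planted
#'   cluster ids), `centroids` (clusters x timepoints, centered log2).
#' @export
simulate_expression_profiles <- function(n_genes = 500L,
                                         timepoints = c("3h", "12h",
                                                        "48h", "72h"),
                                         n_clusters = 8L,
                                         cluster_profile_sd = 0.2,
                                         min_profile_separation = NULL,
                                         expression_dispersion = 0.75,
                                         mean_fpkm = 20,
                                         seed = 1L) {
  if (is.null(min_profile_separation))
    min_profile_separation <- 10 * cluster_profile_sd
  set.seed(seed)
  T_ <- length(timepoints)
  cen <- draw_cluster_centroids(n_clusters, T_, min_profile_separation)
  colnames(cen) <- timepoints
  labels <- sample(rep_len(seq_len(n_clusters), n_genes))
  prof <- cen[labels, , drop = FALSE] +
    matrix(rnorm(n_genes * T_, 0, cluster_profile_sd), nrow = n_genes)
  base <- rnorm(n_genes, log2(mean_fpkm), expression_dispersion)
  fpkm <- 2^(base + prof)
  rownames(fpkm) <- sprintf("gene_%04d", seq_len(n_genes))
  colnames(fpkm) <- timepoints
  list(fpkm = fpkm, labels = setNames(labels, rownames(fpkm)),
       centroids = cen)
}
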