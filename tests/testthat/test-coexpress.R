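test_that("log-relative transform centres rows and ignores scale", {
  m <- matrix(c(5, 5, 5, 5,
                1, 2, 4, 8), nrow = 2, byrow = TRUE,
              dimnames = list(c("flat", "ramp"), c("a", "b", "c", "d")))
  pr <- log_relative_transform(m)
  expect_equal(unname(pr["flat", ]), rep(0, 4))
  expect_equal(unname(pr["ramp", ]), log2(c(1, 2, 4, 8) / 3.75))
  pr10 <- log_relative_transform(m * 10)
  expect_equal(unname(pr10["ramp", ]), unname(pr["ramp", ]))
})

test_that("all-zero rows are removed and reported; all-zero input errors", {
  m <- matrix(c(0, 2, 3, 4,
                0, 0, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("ok", "dead"), letters[1:4]))
  pr <- log_relative_transform(m)
  expect_equal(nrow(pr), 1L)
  expect_equal(attr(pr, "removed"), "dead")
  expect_gt(attr(pr, "pseudocount"), 0)  # zeros present after row removal
  expect_equal(unname(pr["ok", ]), log2((c(0, 2, 3, 4) + 1) / mean(c(1, 3, 4, 5))))
  expect_error(log_relative_transform(m * 0), "all-zero")
})

test_that("two leaves merge at their distance", {
  m <- matrix(c(0, 0, 3, 4), nrow = 2, byrow = TRUE)
  d <- upgma(m)
  expect_equal(d$height, 5)
  expect_equal(nrow(d$merge), 1L)
})

test_that("the three-leaf recurrence averages correctly", {
  # d(A,B) = 1, d(A,C) = d(B,C) = 4: merge (A,B) at 1, then C at (4+4)/2
  D <- matrix(c(0, 1, 4,
                1, 0, 4,
                4, 4, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  # embed on a line so Euclidean distances match: A=0, B=1 won't give 4;
  # feed the distance matrix through a 1-d embedding instead
  pts <- matrix(c(0, 1, 4.5), ncol = 1,
                dimnames = list(c("A", "B", "C"), NULL))
  # d(A,B)=1, d(A,C)=4.5, d(B,C)=3.5 -> average to C = 4
  d <- upgma(pts)
  expect_equal(d$height, c(1, 4))
  expect_equal(d$merge[1, ], c(-1L, -2L))  # smaller leaf index first
  expect_equal(d$merge[2, ], c(-3L, 1L))   # leaf before internal node
})

test_that("UPGMA equals the brute-force average-linkage oracle", {
  set.seed(81)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    pts <- matrix(rnorm(n * 3), nrow = n)
    rownames(pts) <- paste0("x", seq_len(n))
    mine <- upgma(pts)
    ours <- oracle_upgma(dist(pts))
    expect_equal(mine$merge, ours$merge)
    expect_equal(mine$height, ours$height, tolerance = 1e-12)
  }
})

test_that("cuts at the extremes give singletons and one blob", {
  set.seed(82)
  pts <- matrix(rnorm(12 * 4), nrow = 12)
  rownames(pts) <- paste0("g", 1:12)
  dend <- upgma(pts)
  expect_equal(length(unique(cut_clusters(dend, 12))), 12L)
  expect_equal(length(unique(cut_clusters(dend, 1))), 1L)
})

test_that("Davies-Bouldin matches its definition", {
  # two tight clusters with zero scatter
  pts <- matrix(c(0, 0, 0, 0, 5, 5, 5, 5), nrow = 4, byrow = TRUE)
  expect_equal(as.numeric(davies_bouldin(c(1, 1, 2, 2), pts)), 0)
  # two singletons anywhere
  pts2 <- matrix(c(0, 1, 9, 4), nrow = 2, byrow = TRUE)
  expect_equal(as.numeric(davies_bouldin(c(1, 2), pts2)), 0)
  # random instances against the direct-formula oracle
  set.seed(83)
  for (rep in 1:10) {
    pr <- matrix(rnorm(30 * 4), nrow = 30)
    assn <- sample(1:3, 30, replace = TRUE)
    expect_equal(as.numeric(davies_bouldin(assn, pr)), oracle_db(assn, pr),
                 tolerance = 1e-12)
  }
  # coincident centroids are degenerate
  pts3 <- matrix(c(0, 0, 0, 0, 1, 1), nrow = 3, byrow = TRUE)
  db <- davies_bouldin(c(1, 2, 3), pts3)
  expect_true(is.infinite(db) || attr(db, "degenerate"))
})

test_that("cluster-count selection recovers planted structure", {
  sim <- simulate_expression_profiles(n_genes = 60L, n_clusters = 5L,
                                      seed = 90L)
  prof <- log_relative_transform(sim$fpkm)
  dend <- upgma(prof)
  sel <- select_cluster_count(dend, prof)
  expect_equal(sel$k, 5L)
  # trivial single-K range
  sel1 <- select_cluster_count(dend, prof, k_min = 7L, k_max = 7L)
  expect_equal(sel1$k, 7L)
  expect_equal(nrow(sel1$scores), 1L)
  expect_error(select_cluster_count(dend, prof, k_min = 10L, k_max = 5L),
               "empty K range")
})

test_that("the planted labelling scores no worse than shuffled labels", {
  hits <- 0L
  for (s in 1:10) {
    sim <- simulate_expression_profiles(n_genes = 50L, n_clusters = 4L,
                                        seed = 100L + s)
    prof <- log_relative_transform(sim$fpkm)
    truth_db <- as.numeric(davies_bouldin(sim$labels[rownames(prof)], prof))
    set.seed(s)
    rand_db <- as.numeric(davies_bouldin(sample(sim$labels), prof))
    if (truth_db <= rand_db) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("cluster activity averages members and conserves the mean", {
  set.seed(85)
  prof <- matrix(rnorm(30 * 4), nrow = 30,
                 dimnames = list(paste0("g", 1:30), c("a", "b", "c", "d")))
  assn <- sample(1:4, 30, replace = TRUE)
  act <- cluster_activity(prof, assn)
  # direct group means
  for (k in sort(unique(assn)))
    expect_equal(unname(act$activity[paste0("cluster_", k), ]),
                 unname(colMeans(prof[assn == k, , drop = FALSE])))
  # singleton cluster equals its gene's row
  assn2 <- c(rep(1L, 29), 2L)
  act2 <- cluster_activity(prof, assn2)
  expect_equal(unname(act2$activity["cluster_2", ]), unname(prof[30, ]))
  # size-weighted mean over clusters reproduces the global column means
  wm <- colSums(act$activity * act$sizes) / sum(act$sizes)
  expect_equal(unname(wm), unname(colMeans(prof)), tolerance = 1e-9)
  expect_error(cluster_activity(prof, assn[-1]), "assigned")
})

test_that("dendrogram heights are monotone on metric input", {
  set.seed(86)
  pts <- matrix(rnorm(40 * 4), nrow = 40)
  d <- upgma(pts)
  expect_true(all(diff(d$height) >= -1e-9))
})
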