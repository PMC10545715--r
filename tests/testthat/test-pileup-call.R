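# Stack a handful of reads over one locus and inspect the evidence.
test_that("pileup counts stack reference and alternate reads", {
  set.seed(41)
  g <- c(chr = random_genome(600))
  idx <- build_index(g, k = 12)
  locus <- 201L  # 1-based start of the reads
  ref_read <- substring(g, locus, locus + 59)
  alt_read <- ref_read
  substr(alt_read, 31, 31) <- setdiff(c("A", "C", "G", "T"),
                                      substring(ref_read, 31, 31))[1]
  reads <- c(rep(ref_read, 3), rep(alt_read, 2))
  quals <- rep(strrep("I", 60), 5)
  aln <- align_reads(idx, reads, quals, score_params(seed_length = 12))
  pile <- compute_pileup(aln, g, reads, quals)
  site <- pile$sites[pile$sites$pos == locus - 1L + 30L, ]
  expect_equal(site$depth, 5L)
  counts <- unlist(site[, c("n_A", "n_C", "n_G", "n_T")])
  expect_equal(sort(unname(counts[counts > 0])), c(2L, 3L))
  # a site with zero coverage is not emitted
  expect_false(any(pile$sites$pos == 599L))
})

test_that("site quality follows the independent-error posterior", {
  # 10 alternate reads at Q30: P(ref | data) = (e/3)^10 / sum over genotypes
  col <- pileup_column("A", rep("C", 10), rep(30L, 10))
  call <- call_site(col)
  e <- 1e-3
  l_ref <- 10 * log(e / 3)
  l_alt <- 10 * log(1 - e)
  lse <- log(exp(l_alt) + 3 * exp(l_ref))
  expect_equal(call$qual, (lse - l_ref) * 10 / log(10), tolerance = 1e-9)
  expect_gt(call$qual, 5)
  expect_equal(call$n_alts, 1L)
  expect_equal(call$alt, "C")
})

test_that("a single supporting observation matches the closed form", {
  col <- pileup_column("A", "G", 20L)
  call <- call_site(col, min_alt_count = 1L)
  e <- 1e-2
  # posterior of the reference genotype: (e/3) / ((1-e) + 3*(e/3))
  expect_equal(call$qual, -10 * log10(e / 3), tolerance = 1e-9)
})

test_that("all-reference columns produce no call", {
  col <- pileup_column("T", rep("T", 8), rep(35L, 8))
  expect_null(call_site(col))
})

test_that("two supported alternates give a multi-allelic call", {
  col <- pileup_column("A", c(rep("C", 5), rep("G", 5)), rep(30L, 10))
  call <- call_site(col)
  expect_equal(call$n_alts, 2L)
  expect_setequal(strsplit(call$alt, ",")[[1]], c("C", "G"))
})

test_that("alternates supported only near read ends are not called", {
  pile <- structure(list(
    sites = data.frame(reference = "chr", pos = 50L, ref = "A",
                       depth = 12L, n_A = 4L, n_C = 8L, n_G = 0L,
                       n_T = 0L, i_A = 4L, i_C = 0L, i_G = 0L, i_T = 0L,
                       stringsAsFactors = FALSE),
    loglik = matrix(c(-40, -2, -60, -60), nrow = 1,
                    dimnames = list(NULL, c("A", "C", "G", "T"))),
    insertions = data.frame(n = integer(0)),
    deletions = data.frame(n = integer(0))), class = "pileup")
  expect_equal(nrow(call_variants(pile)), 0L)
})

test_that("substitution calls hugging a called indel are suppressed", {
  pile <- structure(list(
    sites = data.frame(reference = "chr", pos = c(100L, 160L),
                       ref = c("A", "A"), depth = c(10L, 10L),
                       n_A = c(0L, 0L), n_C = c(10L, 10L),
                       n_G = c(0L, 0L), n_T = c(0L, 0L),
                       i_A = c(0L, 0L), i_C = c(8L, 8L),
                       i_G = c(0L, 0L), i_T = c(0L, 0L),
                       stringsAsFactors = FALSE),
    loglik = matrix(rep(c(-60, -1, -60, -60), 2), nrow = 2, byrow = TRUE,
                    dimnames = list(NULL, c("A", "C", "G", "T"))),
    insertions = data.frame(reference = character(0), pos = integer(0),
                            seq = character(0), n = integer(0)),
    deletions = data.frame(reference = "chr", pos = 110L, len = 5L,
                           n = 9L, stringsAsFactors = FALSE)),
    class = "pileup")
  calls <- call_variants(pile)
  # the SNP at 100 is within 20 bp of the deletion [110, 115): masked;
  # the SNP at 160 survives
  expect_false(any(calls$type == "snp" & calls$pos == 100L))
  expect_true(any(calls$type == "snp" & calls$pos == 160L))
  expect_true(any(calls$type == "del" & calls$pos == 110L))
})
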