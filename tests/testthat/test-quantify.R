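mk_aln <- function(pair_id, reference, pos, cigar = "50M", mate = 1L) {
  data.frame(read_id = paste0(pair_id, "/", mate), mapped = TRUE,
             reference = reference, pos = pos, strand = "+", score = 0L,
             mapping_count = 1L, is_unique = TRUE, cigar = cigar,
             mate = mate, pair_id = pair_id, stringsAsFactors = FALSE)
}

test_that("fragments are assigned by span midpoint", {
  genes <- data.frame(gene_id = c("g1", "g2"), reference = "chr",
                      start = c(0L, 1000L), end = c(1000L, 2000L),
                      stringsAsFactors = FALSE)
  aln <- rbind(mk_aln("p1", "chr", 100L), mk_aln("p1", "chr", 300L, mate = 2L),
               mk_aln("p2", "chr", 940L), mk_aln("p2", "chr", 1100L, mate = 2L))
  cf <- count_fragments(aln, genes)
  expect_equal(unname(cf$counts["g1"]), 1L)      # span 100-350, mid in g1
  # p2 spans 940-1150, midpoint 1044 -> g2
  expect_equal(unname(cf$counts["g2"]), 1L)
  expect_equal(cf$total, 2L)
})

test_that("intergenic fragments count toward the total only", {
  genes <- data.frame(gene_id = "g1", reference = "chr",
                      start = 0L, end = 200L, stringsAsFactors = FALSE)
  aln <- rbind(mk_aln("p1", "chr", 500L), mk_aln("p1", "chr", 600L, mate = 2L))
  cf <- count_fragments(aln, genes)
  expect_equal(sum(cf$counts), 0L)
  expect_equal(cf$total, 1L)
})

test_that("simulated fragment counts equal the truth tally", {
  cfg <- one_sample_config(seed = 23L, pathogen_read_fraction = 1,
                           base_error_rate = 0, tail_prob = 0,
                           reads_per_sample = 400L)
  gs <- simulate_genomes(cfg)
  sim <- simulate_reads(gs, cfg)
  s <- sim$samples[[1]]
  idx <- build_index(gs$pathogen)
  aln <- rbind(
    cbind(align_reads(idx, s$r1, s$q1, read_id = paste0(s$read_id, "/1")),
          mate = 1L, pair_id = s$read_id),
    cbind(align_reads(idx, s$r2, s$q2, read_id = paste0(s$read_id, "/2")),
          mate = 2L, pair_id = s$read_id))
  gm <- gs$truth$gene_models[gs$truth$gene_models$organism == "pathogen", ]
  cf <- count_fragments(aln, gm)
  truth_tab <- table(factor(sim$origins$gene_id, levels = gm$gene_id))
  expect_equal(unname(cf$counts), as.integer(truth_tab))
  expect_equal(cf$total, length(s$r1))
})

test_that("FPKM follows its defining formula", {
  expect_equal(fpkm(10, 1000, 1e6), 10)
  expect_equal(fpkm(0, 500, 1e6), 0)
  expect_equal(fpkm(7, 2500, 2e5), 14)
  expect_error(fpkm(1, 100, 0), "total_mapped")
})

test_that("FPKM satisfies conservation and scale invariance", {
  set.seed(71)
  counts <- rpois(40, 30)
  lens <- sample(200:3000, 40)
  total <- sum(counts) + 123  # some fragments hit no gene
  f <- fpkm(counts, lens, total)
  expect_equal(sum(f * lens / 1000), 1e6 * sum(counts) / total,
               tolerance = 1e-9)
  expect_equal(fpkm(2 * counts, lens, 2 * total), f)
})

test_that("replicate pooling sums counts and matches merged alignments", {
  expect_equal(pool_replicates(list(
    list(counts = c(g = 3L), total = 10L),
    list(counts = c(g = 4L), total = 20L),
    list(counts = c(g = 5L), total = 30L)))$counts[["g"]], 12L)
  single <- list(counts = c(g = 7L), total = 9L)
  expect_equal(pool_replicates(list(single)), single)
  expect_error(pool_replicates(list(list(counts = c(a = 1L), total = 1L),
                                    list(counts = c(b = 1L), total = 1L))),
               "mismatched gene universes")
  genes <- data.frame(gene_id = c("g1", "g2"), reference = "chr",
                      start = c(0L, 1000L), end = c(1000L, 2000L),
                      stringsAsFactors = FALSE)
  a1 <- rbind(mk_aln("p1", "chr", 100L), mk_aln("p1", "chr", 200L, mate = 2L))
  a2 <- rbind(mk_aln("p2", "chr", 1200L), mk_aln("p2", "chr", 1400L, mate = 2L),
              mk_aln("p3", "chr", 150L), mk_aln("p3", "chr", 220L, mate = 2L))
  pooled <- pool_replicates(list(count_fragments(a1, genes),
                                 count_fragments(a2, genes)))
  merged <- count_fragments(rbind(a1, a2), genes)
  expect_identical(pooled$counts, merged$counts)
  expect_identical(pooled$total, merged$total)
  glen <- genes$end - genes$start
  expect_equal(fpkm(pooled$counts, glen, pooled$total),
               fpkm(merged$counts, glen, merged$total))
})

test_that("Venn regions match exhaustive set enumeration", {
  set.seed(73)
  for (rep in 1:5) {
    m <- matrix(rbinom(20 * 4, 1, 0.55) * runif(80, 0, 50), nrow = 20,
                dimnames = list(sprintf("g%02d", 1:20),
                                c("3h", "12h", "48h", "72h")))
    ps <- presence_sets(m)
    sets <- lapply(1:4, function(j) rownames(m)[m[, j] > 0])
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), 4))[-1, ]
    for (i in seq_len(nrow(combos))) {
      inc <- which(as.logical(combos[i, ]))
      exc <- setdiff(1:4, inc)
      region <- Reduce(intersect, sets[inc])
      for (e in exc) region <- setdiff(region, sets[[e]])
      expect_equal(ps$regions$count[i], length(region))
    }
    # the 15 exclusive regions partition the union
    expect_equal(sum(ps$regions$count), ps$universe)
  }
})

test_that("presence membership follows the strict threshold", {
  m <- matrix(c(1, 1, 1, 1,
                0, 0, 0, 5,
                0.5, 0.5, 0.5, 0.5), nrow = 3, byrow = TRUE,
              dimnames = list(c("all", "late", "weak"),
                              c("t1", "t2", "t3", "t4")))
  ps <- presence_sets(m, threshold = 0)
  expect_equal(ps$shared_all, 2L)                 # "all" and "weak"
  expect_equal(unname(ps$specific["t4"]), 1L)     # "late"
  ps2 <- presence_sets(m, threshold = 0.7)
  expect_equal(ps2$universe, 2L)                  # "weak" now absent
})

test_that("organism fractions pool replicates per time point", {
  mk_part <- function(n_path, n_host, n_un = 0L) {
    assn <- factor(rep(c("pathogen", "host", "unmapped"),
                       c(n_path, n_host, n_un)),
                   levels = c("pathogen", "host", "unmapped"))
    structure(list(assignment = assn), class = "partition_result")
  }
  parts <- list(mk_part(10L, 90L), mk_part(0L, 100L), mk_part(5L, 95L))
  meta <- data.frame(sample = c("a1", "a2", "b1"),
                     timepoint = c("3h", "3h", "12h"),
                     stringsAsFactors = FALSE)
  fr <- organism_fractions(parts, meta)
  expect_equal(fr$per_timepoint$pathogen_fraction,
               c(10 / 200, 5 / 100))
  expect_equal(fr$per_sample$pathogen_fraction[1], 0.10)
  expect_equal(fr$per_sample$pathogen_fraction[2], 0)
})

test_that("top-expressed ranking is descending with id tie-breaks", {
  m <- matrix(c(5, 9, 9, 1), ncol = 1,
              dimnames = list(c("d", "b", "a", "c"), "3h"))
  top <- top_expressed(m, "3h", n = 3)
  expect_equal(top$gene_id, c("a", "b", "d"))
  expect_warning(top_expressed(m, "3h", n = 10), "exceeds")
})
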