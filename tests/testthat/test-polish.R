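fake_call <- function(pos, alt, qual, n_alts = 1L, type = "snp",
                      ref = "A") {
  data.frame(reference = "chr", pos = pos, type = type, ref = ref,
             alt = alt, n_alts = n_alts, qual = qual, depth = 10L,
             alt_count = 8L, stringsAsFactors = FALSE)
}

test_that("corrections respect the strict quality threshold", {
  g <- c(chr = "AAAAAAAAAA")
  above <- apply_corrections(g, fake_call(4L, "C", 5.1))
  expect_equal(above$genome[["chr"]], "AAAACAAAAA")
  expect_equal(above$n_applied, 1L)
  at <- apply_corrections(g, fake_call(4L, "C", 5.0))
  expect_equal(at$genome[["chr"]], g[["chr"]])   # 5.0 exactly: not applied
  expect_equal(at$n_applied, 0L)
})

test_that("multi-allelic and indel calls are never applied", {
  g <- c(chr = "AAAAAAAAAA")
  multi <- apply_corrections(g, fake_call(4L, "C,G", 40, n_alts = 2L))
  expect_equal(multi$n_applied, 0L)
  indel <- apply_corrections(g, fake_call(4L, "CCC", 40, type = "ins",
                                          ref = ""))
  expect_equal(indel$n_applied, 0L)
  expect_equal(nchar(indel$genome[["chr"]]), 10L)  # length conserved
})

test_that("duplicate substitution calls at one site are a hard error", {
  g <- c(chr = "AAAAAAAAAA")
  dup <- rbind(fake_call(4L, "C", 30), fake_call(4L, "G", 30))
  expect_error(apply_corrections(g, dup), "deduplicate")
})

test_that("polishing non-divergent data applies nothing and converges", {
  cfg <- one_sample_config(seed = 17L, snp_divergence_rate = 0,
                           indel_divergence_rate = 0, base_error_rate = 0,
                           tail_prob = 0, reads_per_sample = 600L)
  gs <- simulate_genomes(cfg)
  s <- simulate_reads(gs, cfg)$samples[[1]]
  host <- list(r1 = s$r1, q1 = s$q1, r2 = s$r2, q2 = s$q2)
  rep <- polish_iteratively(gs$host_reference, host)
  expect_equal(sum(rep$iterations$snps_applied), 0L)
  expect_identical(rep$genome[[1]], gs$host_reference[[1]])
})

test_that("polishing recovers injected substitutions on divergent data", {
  cfg <- one_sample_config(seed = 19L, host_genome_len = 30000L,
                           pathogen_read_fraction = 0,
                           reads_per_sample = 4500L, base_error_rate = 0,
                           tail_prob = 0, n_genes = c(pathogen = 6L,
                                                      host = 30L))
  gs <- simulate_genomes(cfg)
  s <- simulate_reads(gs, cfg)$samples[[1]]
  rep <- polish_iteratively(gs$host_reference,
                            list(r1 = s$r1, q1 = s$q1, r2 = s$r2,
                                 q2 = s$q2))
  snps <- gs$truth$variants[gs$truth$variants$type == "snp", ]
  got <- substring(rep$genome[[1]], snps$pos + 1L, snps$pos + 1L)
  expect_gt(mean(got == snps$alt), 0.85)
  # substitution-only correction conserves genome length
  expect_equal(nchar(rep$genome[[1]]), nchar(gs$host_reference[[1]]))
  # later iterations detect no more than the first
  expect_lte(rep$iterations$snps_detected[2],
             rep$iterations$snps_detected[1])
  expect_error(polish_iteratively(gs$host_reference,
                                  list(r1 = s$r1, q1 = s$q1, r2 = s$r2,
                                       q2 = s$q2), n_iterations = 0L),
               "n_iterations")
})

test_that("an empty variant set leaves the SNP-aware index plain", {
  set.seed(51)
  g <- c(chr = random_genome(3000))
  empty <- call_variants(structure(list(
    sites = data.frame(reference = character(0), pos = integer(0),
                       ref = character(0), depth = integer(0),
                       n_A = integer(0), n_C = integer(0),
                       n_G = integer(0), n_T = integer(0)),
    loglik = matrix(0, 0, 4), insertions = data.frame(n = integer(0)),
    deletions = data.frame(n = integer(0))), class = "pileup"))
  idx_plain <- build_index(g)
  idx_aware <- build_snp_index(g, empty)
  st <- sample(1:2900, 50)
  rd <- vapply(st, function(s0) mutate_read(substring(g, s0, s0 + 79),
                                            n_sub = sample(0:3, 1)), "")
  a1 <- align_reads(idx_plain, rd, cigar = FALSE)
  a2 <- align_reads(idx_aware, rd, cigar = FALSE)
  expect_equal(a1$score, a2$score)
  expect_equal(a1$pos, a2$pos)
})

test_that("registered alleles are match-equivalent; others still penalised", {
  set.seed(52)
  g <- c(chr = random_genome(2000))
  ref_read <- substring(g, 501, 580)
  p <- score_params()
  # one registered alternate at 0-based position 540
  ref_base <- substring(g, 541, 541)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  other <- setdiff(c("A", "C", "G", "T"), c(ref_base, alt_base))[1]
  idx <- build_index(g)
  idx <- register_variants(idx, snps = data.frame(reference = "chr",
                                                  pos = 540L,
                                                  alt = alt_base))
  alt_read <- ref_read; substr(alt_read, 41, 41) <- alt_base
  bad_read <- ref_read; substr(bad_read, 41, 41) <- other
  a <- align_reads(idx, c(ref_read, alt_read, bad_read), cigar = FALSE)
  expect_equal(a$score[2], a$score[1])           # registered alt: no penalty
  expect_equal(a$score[3], a$score[1] + p$mismatch)  # unregistered mismatch
})

test_that("registered deletions are traversable without gap penalty", {
  set.seed(53)
  g <- c(chr = random_genome(2000))
  # strain deletion of 18 bp at 0-based position 1000
  del_read <- paste0(substring(g, 941, 1000), substring(g, 1019, 1058))
  p <- score_params()
  idx_plain <- build_index(g)
  a_plain <- align_reads(idx_plain, del_read, params = p, cigar = FALSE)
  idx_aware <- build_index(g)
  idx_aware <- register_variants(idx_aware,
                                 deletions = data.frame(reference = "chr",
                                                        pos = 1000L,
                                                        len = 18L))
  a_aware <- align_reads(idx_aware, del_read, params = p)
  gap_cost <- p$gap_open + 18L * p$gap_extend
  expect_equal(a_plain$score[1], gap_cost)
  expect_equal(a_aware$score[1], 0L)
  expect_true(grepl("18D", a_aware$cigar[1]))
})

test_that("registered insertions are consumed without penalty", {
  set.seed(54)
  g <- c(chr = random_genome(2000))
  ins_seq <- "TTAACC"
  ins_read <- paste0(substring(g, 761, 800), ins_seq,
                     substring(g, 801, 834))
  idx <- build_index(g)
  idx <- register_variants(idx, insertions = data.frame(reference = "chr",
                                                        pos = 800L,
                                                        seq = ins_seq))
  a <- align_reads(idx, ins_read)
  expect_equal(a$score[1], 0L)
  expect_true(grepl("6I", a$cigar[1]))
})
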