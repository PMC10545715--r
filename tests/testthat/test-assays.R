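test_that("Abbott correction matches hand-computed values", {
  expect_equal(abbott_correct(0.30, 0), 0.30)
  expect_equal(abbott_correct(0.25, 0.25), 0)
  expect_equal(abbott_correct(0.40, 0.10), 0.30 / 0.90, tolerance = 1e-12)
  expect_error(abbott_correct(0.5, 1), "control")
  expect_warning(out <- abbott_correct(0.05, 0.10), "clamping")
  expect_equal(out, 0)
})

test_that("Abbott correction is monotone and bounded", {
  set.seed(91)
  control <- runif(50, 0, 0.9)
  t1 <- pmin(control + runif(50, 0, 0.1), 1)
  t2 <- pmin(t1 + runif(50, 0, 0.1), 1)
  c1 <- abbott_correct(t1, control)
  c2 <- abbott_correct(t2, control)
  expect_true(all(c2 >= c1))
  expect_true(all(c1 >= 0 & c1 <= 1))
})

test_that("NRQ is 1 everywhere when nothing varies", {
  m <- expand.grid(sample = c("s1", "s2", "s3"),
                   gene = c("tgt", "ref1"), stringsAsFactors = FALSE)
  m$role <- ifelse(m$gene == "tgt", "target", "reference")
  m$cq <- 25
  out <- nrq(m)
  expect_true(all(abs(out$nrq - 1) < 1e-12))
})

test_that("a one-cycle target shift doubles NRQ at efficiency 2", {
  m <- data.frame(sample = rep(c("cal", "s"), each = 2),
                  gene = rep(c("tgt", "ref"), 2),
                  role = rep(c("target", "reference"), 2),
                  cq = c(25, 20, 24, 20), stringsAsFactors = FALSE)
  out <- nrq(m, calibrator_sample = "cal")
  expect_equal(out$nrq[out$sample == "s"], 2, tolerance = 1e-12)
  expect_equal(out$nrq[out$sample == "cal"], 1, tolerance = 0)
})

test_that("two references normalise by their geometric mean", {
  # reference RQs of 2 and 8 in the test sample -> divisor sqrt(16) = 4
  m <- data.frame(sample = rep(c("cal", "s"), each = 3),
                  gene = rep(c("tgt", "r1", "r2"), 2),
                  role = rep(c("target", "reference", "reference"), 2),
                  cq = c(25, 20, 22, 25, 19, 19), stringsAsFactors = FALSE)
  out <- nrq(m, calibrator_sample = "cal")
  expect_equal(out$nrq[out$sample == "s"], 1 / 4, tolerance = 1e-12)
})

test_that("single-reference NRQ reduces to E^(-ddCq)", {
  set.seed(92)
  for (rep in 1:10) {
    E <- runif(1, 1.7, 2.1)
    cq <- matrix(runif(4, 18, 30), 2, 2)  # rows: samples; cols: tgt, ref
    m <- data.frame(sample = rep(c("cal", "s"), each = 2),
                    gene = rep(c("tgt", "ref"), 2),
                    role = rep(c("target", "reference"), 2),
                    cq = c(cq[1, ], cq[2, ]), efficiency = E,
                    stringsAsFactors = FALSE)
    out <- nrq(m, calibrator_sample = "cal")
    ddcq <- (cq[2, 1] - cq[1, 1]) - (cq[2, 2] - cq[1, 2])
    expect_equal(out$nrq[out$sample == "s"], E^(-ddcq), tolerance = 1e-10)
  }
})

test_that("missing reference measurements are named in the error", {
  m <- data.frame(sample = c("cal", "cal", "s"),
                  gene = c("tgt", "ref", "tgt"),
                  role = c("target", "reference", "target"),
                  cq = c(25, 20, 24), stringsAsFactors = FALSE)
  expect_error(nrq(m, calibrator_sample = "cal"), "sample 's', gene 'ref'")
})
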