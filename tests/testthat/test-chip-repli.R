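test_that("ChIP normalisation applies the pseudocount before scaling", {
  win <- makeWindows(makeGenomeLayout("nc1", 50000), 10000)
  ip <- binnedTrack(win, c(9, 5, 0, 7, 3), 10000L)
  input <- binnedTrack(win, c(4, 5, 0, 7, 3), 10000L)
  out <- normalizeChip(ip, input, ip_total = 1e6, input_total = 1e6)
  expect_equal(binValues(out)[1], 9.5 / 4.5)
  expect_equal(binValues(out)[2], 1.0)
  expect_true(is.na(binValues(out)[3]))   # zero in every sample: dropped
  expect_equal(binValues(out)[4:5], c(1, 1))
  same <- normalizeChip(ip, ip, ip_total = 2e6, input_total = 2e6)
  expect_equal(binValues(same)[-3], rep(1, 4))
})

test_that("ChIP normalisation is scale-invariant up to the offset epsilon", {
  win <- makeWindows(makeGenomeLayout("nc1", 50000), 10000)
  counts <- c(120, 300, 80, 45, 610)
  input <- binnedTrack(win, c(100, 100, 100, 100, 100), 10000L)
  r1 <- binValues(normalizeChip(binnedTrack(win, counts, 10000L), input,
                                ip_total = 1e6, input_total = 1e6))
  r2 <- binValues(normalizeChip(binnedTrack(win, counts * 100, 10000L), input,
                                ip_total = 1e8, input_total = 1e6))
  expect_equal(r1, r2, tolerance = 0.01)
})

test_that("grid mismatches are rejected", {
  w1 <- makeWindows(makeGenomeLayout("nc1", 50000), 10000)
  w2 <- makeWindows(makeGenomeLayout("nc1", 40000), 10000)
  expect_error(normalizeChip(binnedTrack(w1, rep(1, 5), 10000L),
                             binnedTrack(w2, rep(1, 4), 10000L)),
               "grids")
})

test_that("quantile normalisation replaces sorted values by rank-wise means", {
  win <- makeWindows(makeGenomeLayout("qc1", 30000), 10000)
  t1 <- binnedTrack(win, c(1, 2, 3), 10000L)
  t2 <- binnedTrack(win, c(4, 5, 6), 10000L)
  out <- quantileNormalize(list(t1, t2))
  expect_equal(binValues(out[[1]]), c(2.5, 3.5, 4.5))
  expect_equal(binValues(out[[2]]), c(2.5, 3.5, 4.5))

  same <- quantileNormalize(list(t1, t1))
  expect_equal(binValues(same[[1]]), c(1, 2, 3))

  # shared multiset and preserved within-track ranks on scrambled input
  t3 <- binnedTrack(win, c(9, 1, 5), 10000L)
  out2 <- quantileNormalize(list(t1, t3))
  expect_equal(sort(binValues(out2[[1]])), sort(binValues(out2[[2]])))
  expect_equal(order(binValues(out2[[2]])), order(c(9, 1, 5)))
})

test_that("windows missing in one sample are dropped from all samples", {
  win <- makeWindows(makeGenomeLayout("qc1", 40000), 10000)
  t1 <- binnedTrack(win, c(1, NA, 3, 4), 10000L)
  t2 <- binnedTrack(win, c(4, 5, 6, 7), 10000L)
  expect_message(out <- quantileNormalize(list(t1, t2)), "dropped")
  expect_true(is.na(binValues(out[[1]])[2]) && is.na(binValues(out[[2]])[2]))
})

test_that("loess smoothing is exact on constants and lines, and denoises steps", {
  n <- 200
  win <- makeWindows(makeGenomeLayout("lc1", n * 10000), 10000)
  const <- binnedTrack(win, rep(2.5, n), 10000L)
  expect_equal(binValues(loessSmooth(const, 0.3)), rep(2.5, n))

  ramp <- binnedTrack(win, seq(0, 10, length.out = n), 10000L)
  expect_equal(binValues(loessSmooth(ramp, 0.3)),
               seq(0, 10, length.out = n), tolerance = 1e-6)

  set.seed(77)
  clean <- rep(c(0, 4), each = n / 2)
  noisy <- clean + rnorm(n, 0, 1)
  sm <- binValues(loessSmooth(binnedTrack(win, noisy, 10000L), 0.1))
  expect_lt(mean((sm - clean)^2), mean((noisy - clean)^2))
})

test_that("chromosomes with too few points pass through unsmoothed", {
  win <- makeWindows(makeGenomeLayout("lc1", 50000), 10000)
  tr <- binnedTrack(win, c(1, 5, 2, 8, 3), 10000L)
  expect_message(out <- loessSmooth(tr), "unsmoothed")
  expect_equal(binValues(out), binValues(tr))
})

test_that("equal early and late fractions give zero replication timing", {
  n <- 50
  win <- makeWindows(makeGenomeLayout("rc1", n * 10000), 10000)
  counts <- binnedTrack(win, rep(100, n), 10000L)
  rt <- replicationTiming(counts, counts)
  expect_equal(binValues(rt@smoothed), rep(0, n), tolerance = 1e-9)
})

test_that("synthetic repli-seq recovers the planted early/late class structure", {
  cfg <- simulationConfig(seed = 4)
  r1 <- simulateRepliseq(cfg, "WT", replicate = 1)
  r2 <- simulateRepliseq(cfg, "WT", replicate = 2)
  rt <- replicationTiming(list(r1$early, r2$early), list(r1$late, r2$late))
  truth <- simulateGroundTruth(cfg)
  gr <- domainRanges(truthDomains(truth))
  kinds <- domainKind(truthDomains(truth))
  tim <- domainTrackMean(gr, rt@smoothed)
  expect_gt(mean(tim[kinds == "HMD"]), 0)
  expect_lt(mean(tim[kinds != "HMD"]), 0)
  # recovered sign per class: HMDs early (positive), every PMD class late
  expect_gt(stats::median(tim[kinds == "HMD"]), 0)
  for (k in c("PMD-K9", "PMD-K27", "PMD-hyper"))
    expect_lt(stats::median(tim[kinds == k]), 0)
})

test_that("replicate-averaged timing matches a single replicate's expectation", {
  cfg <- simulationConfig(seed = 6)
  r1 <- simulateRepliseq(cfg, "WT", replicate = 1)
  r2 <- simulateRepliseq(cfg, "WT", replicate = 2)
  rt2 <- replicationTiming(list(r1$early, r2$early), list(r1$late, r2$late))
  rt1 <- replicationTiming(r1$early, r1$late)
  ok <- !is.na(binValues(rt1@smoothed)) & !is.na(binValues(rt2@smoothed))
  expect_lt(mean(abs(binValues(rt2@smoothed)[ok] -
                     binValues(rt1@smoothed)[ok])), 0.1)
})
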