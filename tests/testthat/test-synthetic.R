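test_that("generation is bit-identical under a fixed seed and stage-keyed streams", {
  cfg <- simulationConfig(seed = 5)
  a <- simulateMethylome(cfg, "WT")
  b <- simulateMethylome(cfg, "WT")
  expect_identical(GenomicRanges::start(a$calls), GenomicRanges::start(b$calls))
  expect_identical(S4Vectors::mcols(a$calls)$meth, S4Vectors::mcols(b$calls)$meth)
  # WT and KO share one planted truth
  ko <- simulateMethylome(cfg, "KO")
  expect_identical(GenomicRanges::start(domainRanges(truthDomains(a$truth))),
                   GenomicRanges::start(domainRanges(truthDomains(ko$truth))))
  r1 <- simulateRepliseq(cfg, "WT")
  r2 <- simulateRepliseq(cfg, "WT")
  expect_identical(binValues(r1$early), binValues(r2$early))
})

test_that("zero-noise configuration puts window means exactly at the class means", {
  cfg <- simulationConfig(seed = 8, methBetaPrecision = Inf,
                          readDepthFixed = TRUE, readDepthMean = 20)
  wt <- simulateMethylome(cfg, "WT")
  gr <- domainRanges(truthDomains(wt$truth))
  kinds <- domainKind(truthDomains(wt$truth))
  m <- weightedMeanMethylation(wt$calls, gr)
  expect_true(all(m[kinds == "HMD"] == 85))
  expect_true(all(m[kinds == "PMD-K27"] == 55))
  expect_true(all(m[kinds %in% c("PMD-K9", "PMD-hyper")] == 50))
})

test_that("the default window methylome is bimodal with well-separated modes", {
  cfg <- simulationConfig(seed = 13)
  wt <- simulateMethylome(cfg, "WT")
  tr <- methylationTrack(wt$calls, cfg@layout)
  v <- binValues(tr)
  v <- v[!is.na(v)]
  d <- stats::density(v, bw = 2)
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1
  peaks <- peaks[d$y[peaks] > 0.1 * max(d$y)]
  modes <- range(d$x[peaks])
  expect_gte(length(peaks), 2L)
  expect_gt(diff(modes), 15)   # low and high mode > 15 pp apart
})

test_that("planted ChIP enrichment is recovered within Poisson sampling error", {
  cfg <- simulationConfig(seed = 17)
  truth <- simulateGroundTruth(cfg)
  gr <- domainRanges(truthDomains(truth))
  kinds <- domainKind(truthDomains(truth))
  chip <- simulateChip(cfg, "H3K9me3", "WT")
  norm <- normalizeChip(chip$ip, chip$input,
                        ip_total = 1e7, input_total = 1e7)
  m <- domainTrackMean(gr, norm)
  k9m <- m[kinds == "PMD-K9"]
  nWin <- sum(GenomicRanges::width(gr)[kinds == "PMD-K9"]) / cfg@window
  se <- 3 / sqrt(cfg@chipDepth * nWin) * 2   # rough 2-SE band on the ratio
  scaleAdj <- mean(m[kinds == "HMD"])        # totals differ from 1e7 nominal
  expect_lt(abs(mean(k9m) / scaleAdj - 3), max(0.15, se))

  flat <- simulationConfig(seed = 17,
    chipEnrichment = list(
      WT = list(H3K9me3 = c(HMD = 1, `PMD-K9` = 1, `PMD-K27` = 1,
                            `PMD-hyper` = 1)),
      KO = list(H3K9me3 = c(HMD = 1, `PMD-K9` = 1, `PMD-K27` = 1,
                            `PMD-hyper` = 1))))
  fc <- simulateChip(flat, "H3K9me3", "WT")
  fn <- normalizeChip(fc$ip, fc$input)
  expect_lt(abs(mean(binValues(fn), na.rm = TRUE) - 1), 0.05)
  expect_error(simulateChip(cfg, "H3K4me1", "WT"), "unknown mark")
})

test_that("hyper domains lose H3K9me3 and gain H3K36me2 under knockout", {
  cfg <- simulationConfig(seed = 23)
  truth <- simulateGroundTruth(cfg)
  gr <- domainRanges(truthDomains(truth))
  kinds <- domainKind(truthDomains(truth))
  k9ko <- simulateChip(cfg, "H3K9me3", "KO")
  n <- normalizeChip(k9ko$ip, k9ko$input)
  m <- domainTrackMean(gr, n)
  expect_lt(mean(m[kinds == "PMD-hyper"]), mean(m[kinds == "PMD-K9"]))
  k36ko <- simulateChip(cfg, "H3K36me2", "KO")
  n36 <- normalizeChip(k36ko$ip, k36ko$input)
  m36 <- domainTrackMean(gr, n36)
  expect_gt(mean(m36[kinds == "PMD-hyper"]), mean(m36[kinds == "PMD-K9"]))
})

test_that("symmetric repli-seq expectations centre the smoothed ratio at zero", {
  cfg <- simulationConfig(seed = 29,
    repliLog2Offset = list(
      WT = c(HMD = 0, `PMD-K9` = 0, `PMD-K27` = 0, `PMD-hyper` = 0),
      KO = c(HMD = 0, `PMD-K9` = 0, `PMD-K27` = 0, `PMD-hyper` = 0)))
  r <- simulateRepliseq(cfg, "WT")
  rt <- replicationTiming(r$early, r$late)
  expect_lt(abs(stats::median(binValues(rt@smoothed), na.rm = TRUE)), 0.05)
})

test_that("time courses follow the closed form with planted class rates", {
  cfg <- simulationConfig(seed = 37, timecourseNoiseSd = 0)
  tc <- simulateTimecourse(cfg)
  rates <- truthRates(simulateGroundTruth(cfg))
  one <- tc[tc$domain_id == rates$domain_id[1], ]
  p <- kineticParams(rates$lambda[1], rates$nu[1], rates$m0[1])
  expect_equal(one$weighted_mean_pct, 100 * decayModel(p, one$day),
               tolerance = 1e-9)
  expect_equal(one$weighted_mean_pct[one$day == 0], 100 * rates$m0[1])
  # nu = 0 series is exactly log-linear
  cfg2 <- simulationConfig(seed = 37, timecourseNoiseSd = 0,
    kineticRates = list(HMD = c(lambda = 0.3, nu = 0),
                        `PMD-K9` = c(lambda = 0.3, nu = 0),
                        `PMD-K27` = c(lambda = 0.3, nu = 0),
                        `PMD-hyper` = c(lambda = 0.3, nu = 0)))
  tc2 <- simulateTimecourse(cfg2, timepoints = 0:6)
  one2 <- tc2[tc2$domain_id == tc2$domain_id[1], ]
  expect_equal(diff(log(one2$weighted_mean_pct)), rep(-0.3, 6),
               tolerance = 1e-9)
  # long-time limit reaches the plateau
  tcL <- simulateTimecourse(cfg, timepoints = c(0, 100))
  last <- tcL[tcL$day == 100 & tcL$class == "HMD", "weighted_mean_pct"]
  expect_equal(mean(last), 100 * 0.15 / 0.40, tolerance = 0.05)
  expect_error(simulateTimecourse(cfg, timepoints = c(0, -1)), "negative")
  expect_error(simulateTimecourse(cfg, timepoints = c(1, 2)), "day 0")
})

test_that("every planted class is populated and tiles the analysable genome", {
  cfg <- simulationConfig(seed = 43)
  truth <- simulateGroundTruth(cfg)
  gr <- domainRanges(truthDomains(truth))
  kinds <- domainKind(truthDomains(truth))
  expect_true(all(c("HMD", "PMD-K9", "PMD-K27", "PMD-hyper") %in% kinds))
  merged <- GenomicRanges::reduce(gr)
  expect_equal(sum(GenomicRanges::width(merged)), sum(GenomicRanges::width(gr)))
  analysable <- subtractIntervals(
    GenomicRanges::GRanges(GenomeInfoDb::seqnames(cfg@layout),
      IRanges::IRanges(1, GenomeInfoDb::seqlengths(cfg@layout)),
      seqinfo = cfg@layout), cfg@exclusions)
  expect_equal(sum(GenomicRanges::width(merged)),
               sum(GenomicRanges::width(analysable)))
})
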