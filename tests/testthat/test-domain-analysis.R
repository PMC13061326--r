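test_that("k-means PMD classification separates planted mark classes for any seed", {
  cfg <- simulationConfig(seed = 2)
  truth <- simulateGroundTruth(cfg)
  gr <- domainRanges(truthDomains(truth))
  kinds <- domainKind(truthDomains(truth))
  pmds <- gr[kinds != "HMD"]
  k9 <- simulateChip(cfg, "H3K9me3", "WT")
  k27 <- simulateChip(cfg, "H3K27me3", "WT")
  k9n <- normalizeChip(k9$ip, k9$input)
  k27n <- normalizeChip(k27$ip, k27$input)
  want <- ifelse(kinds[kinds != "HMD"] == "PMD-K27", "K27-marked", "K9-marked")
  for (seed in c(1, 7, 123)) {
    cl <- classifyPMDs(pmds, k9n, k27n, seed = seed)
    expect_equal(as.character(cl$class), want)
  }
  # swapped feature order cannot change centroid-based labels
  clSwap <- classifyPMDs(rev(pmds), k9n, k27n, seed = 1)
  expect_equal(as.character(clSwap$class), rev(want))
})

test_that("6-point clustering equals the exhaustive minimum within-SS partition", {
  set.seed(14)
  win <- makeWindows(makeGenomeLayout("kc1", 6e5), 1e5)
  pts <- cbind(k9 = c(3.1, 2.8, 3.3, 1.0, 1.2, 0.9),
               k27 = c(0.9, 1.1, 1.0, 2.9, 3.2, 3.0))
  k9t <- binnedTrack(win, pts[, 1], 100000L)
  k27t <- binnedTrack(win, pts[, 2], 100000L)
  cl <- classifyPMDs(win, k9t, k27t, seed = 3)
  z <- scale(pts)
  best <- NULL; bestSS <- Inf
  for (mask in 1:(2^6 - 2)) {           # all non-trivial 2-partitions
    g <- as.logical(bitwAnd(mask, 2^(0:5)))
    ss <- sum(scale(z[g, , drop = FALSE], scale = FALSE)^2) +
          sum(scale(z[!g, , drop = FALSE], scale = FALSE)^2)
    if (ss < bestSS - 1e-12) { bestSS <- ss; best <- g }
  }
  got <- cl$class == cl$class[1]
  expect_true(identical(got, best) || identical(got, !best))
  expect_error(classifyPMDs(win[1], k9t, k27t), "at least 2")
})

test_that("hypermethylation calls use an inclusive percentage-point threshold", {
  res <- callHypermethylated(c(60, 60, 40), c(65, 64.9, 48))
  expect_equal(res$hyper, c(TRUE, FALSE, TRUE))
  expect_equal(res$delta, c(5, 4.9, 8))
  # monotone in threshold
  loose <- callHypermethylated(c(60, 60, 40), c(65, 64.9, 48), 4)
  expect_true(all(res$hyper <= loose$hyper))
  strict <- callHypermethylated(c(60, 60, 40), c(65, 64.9, 48), 6)
  expect_true(all(strict$hyper <= res$hyper))
  # missing means are excluded with a message
  expect_message(m <- callHypermethylated(c(60, NA), c(70, 70)), "excluded")
  expect_equal(m$excluded, c(FALSE, TRUE))
  expect_equal(m$hyper, c(TRUE, FALSE))
})

test_that("planted methylation gains are recovered exactly on the WT/KO pair", {
  cfg <- simulationConfig(seed = 31)
  wt <- simulateMethylome(cfg, "WT")
  ko <- simulateMethylome(cfg, "KO")
  gr <- domainRanges(truthDomains(wt$truth))
  kinds <- domainKind(truthDomains(wt$truth))
  mWT <- weightedMeanMethylation(wt$calls, gr)
  mKO <- weightedMeanMethylation(ko$calls, gr)
  res <- callHypermethylated(mWT, mKO)
  expect_equal(which(res$hyper), which(kinds == "PMD-hyper"))
})

test_that("pileup matrices have the scale-regions shape and constant-track value", {
  cfg <- simulationConfig(seed = 3)
  win <- makeWindows(cfg@layout, 10000)
  const <- binnedTrack(win, rep(7.5, length(win)), 10000L)
  doms <- GenomicRanges::GRanges("chrS1",
    IRanges::IRanges(c(3e6 + 1, 8e6 + 1), c(5e6, 9.5e6)), seqinfo = cfg@layout)
  mat <- pileupMatrix(doms, const)
  expect_equal(dim(mat), c(2L, 300L))
  expect_true(all(mat == 7.5))
  expect_equal(sort(attr(mat, "order")), 1:2)
  expect_equal(table(attr(mat, "section"))[["body"]], 100L)
})

test_that("pileup columns show the low body and high flanks of a step track", {
  cfg <- simulationConfig(seed = 3)
  win <- makeWindows(cfg@layout, 10000)
  doms <- GenomicRanges::GRanges("chrS1",
    IRanges::IRanges(c(3e6 + 1, 8e6 + 1), c(5e6, 9.5e6)), seqinfo = cfg@layout)
  inside <- GenomicRanges::countOverlaps(win, doms) > 0
  step <- binnedTrack(win, ifelse(inside, 10, 90), 10000L)
  mat <- pileupMatrix(doms, step, rank_values = c(2, 1))
  cm <- colMeans(mat)
  sect <- attr(mat, "section")
  expect_true(all(cm[sect == "body"] < 15))
  expect_gt(cm[1], 85)            # far upstream flank
  expect_gt(cm[300], 85)          # far downstream flank
  expect_equal(attr(mat, "order"), c(1L, 2L))  # ranked by decreasing key
})

test_that("decile analysis assigns balanced deciles and the window-level rho", {
  win <- makeWindows(makeGenomeLayout("dc1", 1e5), 1e4)
  v <- binnedTrack(win, as.numeric(1:10), 10000L)
  res <- decileAnalysis(v, v)
  expect_equal(res$deciles$n, rep(1L, 10))
  expect_equal(res$rho, 1.0)

  set.seed(99)
  win2 <- makeWindows(makeGenomeLayout("dc2", 1e7), 1e4)
  a <- binnedTrack(win2, rnorm(1000), 10000L)
  b <- binnedTrack(win2, rnorm(1000), 10000L)
  expect_lt(abs(decileAnalysis(a, b)$rho), 0.08)

  const <- binnedTrack(win, rep(1, 10), 10000L)
  expect_error(decileAnalysis(v, const), "constant")
})

test_that("Fisher's exact test matches hypergeometric enumeration on small tables", {
  expect_equal(fisherExact(matrix(c(5, 5, 5, 5), 2))$p_value, 1.0)
  expect_warning(z <- fisherExact(matrix(c(0, 0, 3, 5), 2, byrow = TRUE)),
                 "margin")
  expect_equal(z$p_value, 1)
  expect_error(fisherExact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")

  # oracle: enumerate all tables with the observed margins, sum P(table)
  # over tables no more probable than the observed one
  set.seed(12)
  for (rep in 1:12) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    xs <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(xs, m, n, k)
    pObs <- stats::dhyper(tab[1, 1], m, n, k)
    want <- sum(probs[probs <= pObs * (1 + 1e-7)])
    expect_equal(fisherExact(tab)$p_value, want, tolerance = 1e-9)
  }
})

test_that("rank-sum test is exact for small samples and guards full ties", {
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  same <- wilcoxonRankSum(c(1, 2, 3), c(3, 1, 2))
  expect_equal(same$p_value, 1.0)
  expect_warning(tied <- wilcoxonRankSum(c(2, 2), c(2, 2)), "tied")
  expect_equal(tied$p_value, 1)
  set.seed(41)
  a <- rnorm(200); b <- rnorm(200) + 1
  expect_lt(wilcoxonRankSum(a, b)$p_value, 1e-10)
})

test_that("Spearman correlation follows the rank formula with average ties", {
  x <- c(10, 20, 30); y <- c(1, 5, 9)
  expect_equal(spearmanCor(x, y)$rho, 1)
  expect_equal(spearmanCor(x, rev(y))$rho, -1)
  a <- c(3, 1, 4, 1, 5); b <- c(9, 2, 6, 5, 3)
  want <- stats::cor(rank(a), rank(b))
  expect_equal(spearmanCor(a, b)$rho, want, tolerance = 1e-12)
  expect_error(spearmanCor(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("genes map only to domains that wholly contain them", {
  doms <- domainSet(GenomicRanges::GRanges("gc1",
    IRanges::IRanges(c(1, 1001), c(1000, 2000))), c("PMD", "HMD"))
  genes <- GenomicRanges::GRanges("gc1",
    IRanges::IRanges(c(100, 950, 1500), c(300, 1100, 1800)))
  got <- assignGenesToDomains(genes, doms)
  expect_equal(got, c(1L, NA_integer_, 2L))

  set.seed(27)
  rg <- random_intervals(20, max_len = 5000)
  rd <- domainSet(random_intervals(5, max_len = 30000), "PMD")
  got <- assignGenesToDomains(rg, rd)
  dgr <- domainRanges(rd)
  want <- vapply(seq_along(rg), function(i) {
    ok <- which(as.character(GenomicRanges::seqnames(dgr)) ==
                  as.character(GenomicRanges::seqnames(rg))[i] &
                GenomicRanges::start(dgr) <= GenomicRanges::start(rg)[i] &
                GenomicRanges::end(dgr) >= GenomicRanges::end(rg)[i])
    if (length(ok)) ok[1] else NA_integer_
  }, 1L)
  expect_equal(got, want)
})
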