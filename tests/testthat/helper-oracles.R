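# Brute-force per-base oracles for interval algebra on small genomes, and
# shared builders for synthetic fixtures. Everything here is deliberately
# naive O(n * genome) code, independent of the package internals it checks.

oracle_layout <- makeGenomeLayout(c("oc1", "oc2"), c(100000, 100000))

# logical occupancy vector per chromosome
.to_mask <- function(gr, layout = oracle_layout) {
  sl <- GenomeInfoDb::seqlengths(layout)
  masks <- lapply(sl, function(n) logical(n))
  for (i in seq_along(gr)) {
    ch <- as.character(GenomicRanges::seqnames(gr))[i]
    masks[[ch]][GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- TRUE
  }
  masks
}

.from_mask <- function(masks, layout = oracle_layout) {
  out <- list()
  for (ch in names(masks)) {
    r <- rle(masks[[ch]])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    if (length(sel))
      out[[ch]] <- GenomicRanges::GRanges(
        factor(rep(ch, length(sel)), levels = GenomeInfoDb::seqnames(layout)),
        IRanges::IRanges(starts[sel], ends[sel]))
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  sort(do.call(c, unname(out)))
}

oracle_merge <- function(gr, max_gap, layout = oracle_layout) {
  # transitive closure by repeated pairwise merging
  df <- data.frame(ch = as.character(GenomicRanges::seqnames(gr)),
                   s = GenomicRanges::start(gr), e = GenomicRanges::end(gr))
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(df)) {
      j <- i + 1
      while (j <= nrow(df)) {
        gap <- max(df$s[i], df$s[j]) - min(df$e[i], df$e[j]) - 1L
        if (df$ch[i] == df$ch[j] && gap <= max_gap) {
          df$s[i] <- min(df$s[i], df$s[j]); df$e[i] <- max(df$e[i], df$e[j])
          df <- df[-j, , drop = FALSE]; merged <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  df <- df[order(match(df$ch, GenomeInfoDb::seqnames(layout)), df$s), ]
  GenomicRanges::GRanges(factor(df$ch,
                                levels = GenomeInfoDb::seqnames(layout)),
                         IRanges::IRanges(df$s, df$e))
}

oracle_subtract <- function(a, b, layout = oracle_layout) {
  ma <- .to_mask(a, layout); mb <- .to_mask(b, layout)
  .from_mask(mapply(function(x, y) x & !y, ma, mb, SIMPLIFY = FALSE), layout)
}

oracle_jaccard <- function(a, b, layout = oracle_layout) {
  ma <- .to_mask(a, layout); mb <- .to_mask(b, layout)
  i <- sum(mapply(function(x, y) sum(x & y), ma, mb))
  u <- sum(mapply(function(x, y) sum(x | y), ma, mb))
  i / u
}

random_intervals <- function(n, layout = oracle_layout, max_len = 20000) {
  chs <- sample(GenomeInfoDb::seqnames(layout), n, replace = TRUE)
  sl <- GenomeInfoDb::seqlengths(layout)
  starts <- vapply(chs, function(ch) sample.int(sl[ch] - max_len, 1L), 0L)
  widths <- sample.int(max_len, n, replace = TRUE)
  GenomicRanges::GRanges(factor(chs, levels = GenomeInfoDb::seqnames(layout)),
                         IRanges::IRanges(starts, width = widths))
}

# CpG calls whose every window mean is exactly `pct`: one CpG per kb with
# fixed depth so that pct * depth is an integer count.
flat_methylome <- function(layout, pct, depth = 20L, step = 1000L) {
  grs <- lapply(GenomeInfoDb::seqnames(layout), function(ch) {
    n <- GenomeInfoDb::seqlengths(layout)[ch]
    pos <- seq(500L, n, by = step)
    GenomicRanges::GRanges(ch, IRanges::IRanges(pos, width = 1L),
                           meth = as.integer(round(pct / 100 * depth)),
                           total = depth, seqinfo = layout)
  })
  sort(do.call(c, grs))
}

# methylome with given per-region percentages: `regions` GRanges, `pcts`
plant_methylome <- function(layout, regions, pcts, base_pct = 85,
                            depth = 20L, step = 1000L) {
  calls <- flat_methylome(layout, base_pct, depth, step)
  for (i in seq_along(regions)) {
    hit <- S4Vectors::queryHits(GenomicRanges::findOverlaps(calls, regions[i]))
    S4Vectors::mcols(calls)$meth[hit] <-
      as.integer(round(pcts[i] / 100 * depth))
  }
  calls
}

# exhaustive Viterbi oracle: enumerate all 2^n state paths
oracle_viterbi <- function(x, params) {
  n <- length(x)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  le <- matrix(0, n, 2)
  for (s in 1:2)
    le[, s] <- stats::dnorm(x, params@means[s], sqrt(params@variances[s]),
                            log = TRUE)
  le[is.na(x), ] <- 0
  lt <- log(params@transition); li <- log(params@init)
  best <- -Inf; bestPath <- NULL
  for (k in seq_len(nrow(paths))) {
    p <- paths[k, ]
    lp <- li[p[1]] + le[1, p[1]]
    if (n > 1) for (t in 2:n) lp <- lp + lt[p[t - 1], p[t]] + le[t, p[t]]
    if (lp > best) { best <- lp; bestPath <- p }
  }
  as.integer(bestPath)
}

random_hmm_params <- function() {
  m <- sort(stats::runif(2, 0, 10))
  a <- stats::runif(1, 0.6, 0.95); b <- stats::runif(1, 0.6, 0.95)
  new("HmmParams", means = m, variances = stats::runif(2, 0.5, 4),
      transition = matrix(c(a, 1 - a, 1 - b, b), 2, byrow = TRUE),
      init = c(0.5, 0.5), logLik = NA_real_, logLikTrace = numeric(),
      nIter = 0L, degenerate = FALSE)
}

small_track <- function(values, chrom = "oc1", binsize = 1000L) {
  n <- length(values)
  win <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(seq(1L, by = binsize, length.out = n),
                     width = binsize))
  binnedTrack(win, values, binsize)
}
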