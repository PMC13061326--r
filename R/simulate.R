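#' @include AllClasses.R genome-model.R tracks-io.R kinetics.R
NULL

# Every simulation stage draws from its own stream, derived from
# (master seed, stage name), so adding a stage never perturbs another
# stage's draws and WT/KO share the same planted domains.
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * (seq_along(utf8ToInt(stage)) %% 31 + 1))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

.withStageSeed <- function(seed, stage, expr) {
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(.stageSeed(seed, stage))
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  force(expr)
}

#' Default configuration of the synthetic methylome generator
#'
#' Builds a [SimulationConfig] emulating a colorectal-cancer-like methylome
#' at desk scale: a 2 x 25 Mb genome with a 500 kb unmappable block mid-
#' chromosome, megabase-scale domains with a bimodal window methylome (HMDs
#' around 85\%, PMDs around 50-55\%), H3K9me3- or H3K27me3-marked PMDs that
#' replicate late, a minority of H3K9me3 PMDs planted to gain >= 5 pp
#' methylation under DNMT1 loss (with H3K9me3 dropping to background and
#' H3K36me2 rising), and per-class decay kinetics. All values are
#' overridable; see the methods vignette for the reasoning behind each
#' default.
#'
#' @param seed Integer master seed.
#' @param chromSizes Named integer vector of chromosome sizes.
#' @param window Analysis window size in bp.
#' @param ... Named [SimulationConfig] slots to override.
#' @return A [SimulationConfig].
#' @examples
#' simulationConfig(seed = 7)
#' @export
simulationConfig <- function(seed = 1L,
                             chromSizes = c(chrS1 = 25e6, chrS2 = 25e6),
                             window = 10000L, ...) {
  layout <- makeGenomeLayout(names(chromSizes), chromSizes)
  mid <- floor(chromSizes / 2 / 1e4) * 1e4
  exclusions <- GenomicRanges::GRanges(
    names(chromSizes), IRanges::IRanges(mid - 250000 + 1, mid + 250000),
    seqinfo = layout)
  cfg <- new("SimulationConfig",
    seed = as.integer(seed), layout = layout, window = as.integer(window),
    exclusions = exclusions,
    domainMedianMb = c(HMD = 0.8, `PMD-K9` = 0.8, `PMD-K27` = 0.55),
    domainSdLog = 0.35, domainMinMb = 0.3,
    pmdClassProb = c(`PMD-K9` = 0.5, `PMD-K27` = 0.5),
    hyperFraction = 0.25,
    cpgPerKb = c(HMD = 2, `PMD-K9` = 1, `PMD-K27` = 1, `PMD-hyper` = 1),
    methMeanPct = list(
      WT = c(HMD = 85, `PMD-K9` = 50, `PMD-K27` = 55, `PMD-hyper` = 50),
      KO = c(HMD = 76, `PMD-K9` = 34, `PMD-K27` = 38, `PMD-hyper` = 58)),
    methBetaPrecision = 60, readDepthMean = 6, readDepthFixed = FALSE,
    chipDepth = 50,
    chipEnrichment = list(
      WT = list(
        H3K9me3  = c(HMD = 1.0, `PMD-K9` = 3.0, `PMD-K27` = 1.2, `PMD-hyper` = 3.0),
        H3K27me3 = c(HMD = 1.0, `PMD-K9` = 1.2, `PMD-K27` = 3.0, `PMD-hyper` = 1.0),
        H3K36me2 = c(HMD = 2.0, `PMD-K9` = 0.7, `PMD-K27` = 0.7, `PMD-hyper` = 0.7),
        H3K36me3 = c(HMD = 1.8, `PMD-K9` = 0.8, `PMD-K27` = 0.8, `PMD-hyper` = 0.8)),
      KO = list(
        H3K9me3  = c(HMD = 1.0, `PMD-K9` = 2.5, `PMD-K27` = 1.2, `PMD-hyper` = 1.0),
        H3K27me3 = c(HMD = 1.0, `PMD-K9` = 1.2, `PMD-K27` = 2.8, `PMD-hyper` = 0.8),
        H3K36me2 = c(HMD = 2.0, `PMD-K9` = 0.7, `PMD-K27` = 0.7, `PMD-hyper` = 2.0),
        H3K36me3 = c(HMD = 1.8, `PMD-K9` = 0.8, `PMD-K27` = 0.8, `PMD-hyper` = 0.8))),
    repliDepth = 50,
    repliLog2Offset = list(
      WT = c(HMD = 0.8, `PMD-K9` = -1.0, `PMD-K27` = -0.7, `PMD-hyper` = -1.0),
      KO = c(HMD = 0.8, `PMD-K9` = -0.9, `PMD-K27` = -0.7, `PMD-hyper` = -1.1)),
    kineticRates = list(
      HMD = c(lambda = 0.25, nu = 0.15),
      `PMD-K9` = c(lambda = 0.50, nu = 0.02),
      `PMD-K27` = c(lambda = 0.45, nu = 0.04),
      `PMD-hyper` = c(lambda = 0.50, nu = 0.10)),
    timecourseNoiseSd = 0.3)
  dots <- list(...)
  for (nm in names(dots)) methods::slot(cfg, nm) <- dots[[nm]]
  methods::validObject(cfg)
  cfg
}

#' Planted domain structure of a synthetic genome
#'
#' Tiles the analysable genome (layout minus exclusions) with alternating
#' HMDs and PMDs whose lengths are log-normal (truncated below), snapped to
#' the analysis window grid; PMD classes are drawn from `pmdClassProb` and a
#' `hyperFraction` share of the H3K9me3 PMDs is planted as hyper-convertible
#' (`"PMD-hyper"`). Deterministic given the config seed; both conditions and
#' all tracks of one config share this truth.
#'
#' @param config A [SimulationConfig].
#' @return A [GroundTruth].
#' @export
simulateGroundTruth <- function(config) {
  .withStageSeed(config@seed, "domains", {
    w <- config@window
    blocks <- subtractIntervals(
      GenomicRanges::GRanges(
        GenomeInfoDb::seqnames(config@layout),
        IRanges::IRanges(1L, GenomeInfoDb::seqlengths(config@layout)),
        seqinfo = config@layout),
      config@exclusions)
    drawLen <- function(class) {
      med <- config@domainMedianMb[class] * 1e6
      len <- stats::rlnorm(1, log(med), config@domainSdLog)
      len <- max(len, config@domainMinMb * 1e6)
      max(w, round(len / w) * w)
    }
    rngs <- list(); kinds <- character()
    for (b in seq_along(blocks)) {
      ch <- as.character(GenomicRanges::seqnames(blocks))[b]
      pos <- GenomicRanges::start(blocks)[b] - 1L   # 0-based cursor
      blockEnd <- GenomicRanges::end(blocks)[b]
      pos <- ceiling(pos / w) * w
      isHMD <- (b %% 2L == 1L)                      # blocks start alternately
      while (pos < blockEnd - config@domainMinMb * 1e6) {
        class <- if (isHMD) "HMD"
                 else sample(names(config@pmdClassProb), 1L,
                             prob = config@pmdClassProb)
        len <- drawLen(if (isHMD) "HMD" else class)
        end <- min(pos + len, blockEnd)
        rngs[[length(rngs) + 1L]] <-
          GenomicRanges::GRanges(ch, IRanges::IRanges(pos + 1L, end),
                                 seqinfo = config@layout)
        kinds <- c(kinds, class)
        pos <- end
        isHMD <- !isHMD
      }
      # extend the last domain of the block to the block end
      if (length(rngs) && pos < blockEnd) {
        last <- rngs[[length(rngs)]]
        GenomicRanges::end(last) <- blockEnd
        rngs[[length(rngs)]] <- last
      }
    }
    gr <- do.call(c, rngs)
    # plant the hyper subset among the K9 PMDs
    k9idx <- which(kinds == "PMD-K9")
    nHyper <- max(1L, round(config@hyperFraction * length(k9idx)))
    if (length(k9idx))
      kinds[sort(sample(k9idx, min(nHyper, length(k9idx))))] <- "PMD-hyper"
    S4Vectors::mcols(gr)$kind <- kinds
    S4Vectors::mcols(gr)$domain_id <- sprintf("D%03d", seq_along(gr))
    rates <- do.call(rbind, lapply(seq_along(gr), function(i) {
      kr <- config@kineticRates[[kinds[i]]]
      data.frame(domain_id = sprintf("D%03d", i), class = kinds[i],
                 lambda = unname(kr["lambda"]), nu = unname(kr["nu"]),
                 m0 = unname(config@methMeanPct$WT[kinds[i]]) / 100)
    }))
    new("GroundTruth", domains = new("DomainSet", ranges = gr), rates = rates)
  })
}

#' Simulate a CpG-resolution methylome
#'
#' CpG positions are laid down as a Poisson process with class-specific
#' density (PMDs are CpG-poor); each CpG's methylation propensity is drawn
#' from a beta distribution centred on its domain-class mean for the
#' requested condition (beta-binomial read noise; `methBetaPrecision = Inf`
#' switches the noise off), read depth is `1 + Poisson` (or fixed), and
#' methylated counts are binomial. Planted `"PMD-hyper"` domains sit at the
#' K9-PMD level in WT and above it by the configured gain in KO. Exclusion
#' regions carry no CpGs. Deterministic given `(seed, condition)`.
#'
#' @param config A [SimulationConfig].
#' @param condition `"WT"` (parental) or `"KO"` (DNMT1 loss).
#' @return A list: `calls` (width-1 `GRanges` with `meth`/`total`),
#'   `truth` (the shared [GroundTruth]).
#' @export
simulateMethylome <- function(config, condition = c("WT", "KO")) {
  condition <- match.arg(condition)
  truth <- simulateGroundTruth(config)
  gr <- domainRanges(truthDomains(truth))
  kinds <- domainKind(truthDomains(truth))
  minLen <- min(GenomicRanges::width(gr))
  if (minLen < config@window)
    stop("configuration error: genome too small for the requested domains")
  calls <- .withStageSeed(config@seed, paste0("methylome-", condition), {
    res <- list()
    for (i in seq_along(gr)) {
      len <- GenomicRanges::width(gr)[i]
      dens <- config@cpgPerKb[kinds[i]] / 1000
      nCpG <- stats::rpois(1, len * dens)
      if (nCpG == 0L) next
      pos <- GenomicRanges::start(gr)[i] - 1L + sort(sample.int(len, nCpG))
      m <- config@methMeanPct[[condition]][kinds[i]] / 100
      phi <- config@methBetaPrecision
      total <- if (config@readDepthFixed) rep(config@readDepthMean, nCpG)
               else 1L + stats::rpois(nCpG, config@readDepthMean - 1)
      if (is.finite(phi)) {
        p <- stats::rbeta(nCpG, m * phi, (1 - m) * phi)
        meth <- stats::rbinom(nCpG, total, p)
      } else {
        meth <- round(m * total)
      }
      res[[length(res) + 1L]] <- GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(gr))[i],
        IRanges::IRanges(pos, width = 1L),
        meth = as.integer(meth), total = as.integer(total),
        seqinfo = config@layout)
    }
    out <- do.call(c, res)
    GenomicRanges::sort(out, ignore.strand = TRUE)
  })
  list(calls = calls, truth = truth)
}

# class label per window from the ground truth (exclusions get NA)
.windowClass <- function(config, truth, windows) {
  gr <- domainRanges(truthDomains(truth))
  hit <- GenomicRanges::findOverlaps(windows, gr, ignore.strand = TRUE,
                                     select = "first")
  domainKind(truthDomains(truth))[hit]
}

#' Simulate a binned ChIP-seq experiment (IP and input)
#'
#' Input counts are flat Poisson at `chipDepth`; IP counts are Poisson with
#' mean `chipDepth x enrichment(class, mark, condition)` from the config's
#' enrichment table. Under `"KO"`, planted hyper domains sit at H3K9me3
#' background and elevated H3K36me2. Windows inside exclusions get
#' background enrichment.
#'
#' @param config A [SimulationConfig].
#' @param mark One of `"H3K9me3"`, `"H3K27me3"`, `"H3K36me2"`, `"H3K36me3"`.
#' @param condition `"WT"` or `"KO"`.
#' @param binsize Window size in bp (default the config window; use 25000
#'   for heterochromatic-domain calling).
#' @param replicate Integer replicate index (feeds the RNG stream).
#' @return A list of two [BinnedTrack]s: `ip` and `input`.
#' @export
simulateChip <- function(config, mark, condition = c("WT", "KO"),
                         binsize = NULL, replicate = 1L) {
  condition <- match.arg(condition)
  if (!mark %in% names(config@chipEnrichment[[condition]]))
    stop(sprintf("unknown mark '%s'", mark))
  if (is.null(binsize)) binsize <- config@window
  truth <- simulateGroundTruth(config)
  win <- makeWindows(config@layout, binsize)
  cls <- .windowClass(config, truth, win)
  enr <- config@chipEnrichment[[condition]][[mark]]
  mu <- ifelse(is.na(cls), 1.0, enr[cls])
  .withStageSeed(config@seed,
                 sprintf("chip-%s-%s-%d", mark, condition, replicate), {
    ip <- stats::rpois(length(win), config@chipDepth * mu)
    input <- stats::rpois(length(win), config@chipDepth)
    list(ip = binnedTrack(win, ip, binsize),
         input = binnedTrack(win, input, binsize))
  })
}

#' Simulate binned repli-seq early and late fraction counts
#'
#' Expected counts are set so the log2 early/late ratio targets the
#' configured per-class offset: positive in HMDs, negative in PMDs, and
#' hyper domains staying late under KO.
#'
#' @param config A [SimulationConfig].
#' @param condition `"WT"` or `"KO"`.
#' @param replicate Integer replicate index.
#' @return A list of two [BinnedTrack]s: `early` and `late`.
#' @export
simulateRepliseq <- function(config, condition = c("WT", "KO"),
                             replicate = 1L) {
  condition <- match.arg(condition)
  truth <- simulateGroundTruth(config)
  win <- makeWindows(config@layout, config@window)
  cls <- .windowClass(config, truth, win)
  off <- config@repliLog2Offset[[condition]]
  t <- ifelse(is.na(cls), 0, off[cls])
  .withStageSeed(config@seed,
                 sprintf("repli-%s-%d", condition, replicate), {
    early <- stats::rpois(length(win), config@repliDepth * 2^(t / 2))
    late <- stats::rpois(length(win), config@repliDepth * 2^(-t / 2))
    list(early = binnedTrack(win, early, config@window),
         late = binnedTrack(win, late, config@window))
  })
}

#' Simulate per-domain methylation time courses under DNMT1 removal
#'
#' Each planted domain follows the closed-form decay of [decayModel()] with
#' its class rates (lambda, nu) from the config, starting at its WT mean,
#' plus Gaussian observation noise in percentage points.
#'
#' @param config A [SimulationConfig].
#' @param timepoints Days of observation; must include 0 and be >= 0.
#' @return Long-format data.frame: `domain_id`, `class`, `day`,
#'   `weighted_mean_pct`.
#' @export
simulateTimecourse <- function(config,
                               timepoints = c(0, 1, 2, 3, 4, 6, 12)) {
  if (any(timepoints < 0)) stop("negative timepoint")
  if (!0 %in% timepoints) stop("timepoints must include day 0")
  truth <- simulateGroundTruth(config)
  rates <- truthRates(truth)
  .withStageSeed(config@seed, "timecourse", {
    out <- do.call(rbind, lapply(seq_len(nrow(rates)), function(i) {
      p <- kineticParams(rates$lambda[i], rates$nu[i], rates$m0[i])
      m <- 100 * decayModel(p, timepoints)
      if (config@timecourseNoiseSd > 0)
        m <- pmax(m + stats::rnorm(length(m), 0, config@timecourseNoiseSd),
                  0.05)
      data.frame(domain_id = rates$domain_id[i], class = rates$class[i],
                 day = timepoints, weighted_mean_pct = m)
    }))
    rownames(out) <- NULL
    out
  })
}
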