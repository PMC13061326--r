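#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqnames seqlevels seqinfo
NULL

#' Fixed-width genomic windows carrying one numeric value per window
#'
#' A `BinnedTrack` ties a tiling of the genome (uniform-width windows, last
#' window of each chromosome truncated) to one numeric value per window:
#' a window methylation percentage, an IP/input ratio, a read count or a
#' smoothed early/late replication-timing ratio. Missing values are `NA`.
#'
#' @slot windows A [GenomicRanges::GRanges] of tiling windows.
#' @slot values Numeric vector, one value per window (`NA` = missing).
#' @slot binSize Integer, the nominal window width in bp.
#' @export
setClass("BinnedTrack",
  slots = c(windows = "GRanges", values = "numeric", binSize = "integer"))

setValidity("BinnedTrack", function(object) {
  msg <- character()
  if (length(object@windows) != length(object@values))
    msg <- c(msg, "length(values) must equal length(windows)")
  if (length(object@binSize) != 1L || is.na(object@binSize) || object@binSize <= 0L)
    msg <- c(msg, "binSize must be a single positive integer")
  if (length(object@windows) &&
      any(GenomicRanges::width(object@windows) > object@binSize))
    msg <- c(msg, "no window may be wider than binSize")
  if (length(msg)) msg else TRUE
})

#' Labelled genomic domains (PMD/HMD, chromatin class, hypermethylation status)
#'
#' Wraps a `GRanges` whose mandatory metadata column `kind` labels each
#' interval (e.g. `"PMD"`, `"HMD"`, `"K9-domain"`). Further per-domain
#' statistics (window count, mean value) live in additional metadata columns.
#'
#' @slot ranges A [GenomicRanges::GRanges] with a `kind` metadata column.
#' @export
setClass("DomainSet", slots = c(ranges = "GRanges"))

setValidity("DomainSet", function(object) {
  if (!"kind" %in% colnames(S4Vectors::mcols(object@ranges)))
    return("ranges must carry a 'kind' metadata column")
  TRUE
})

#' Parameters of a fitted two-state Gaussian hidden Markov model
#'
#' State 1 is always the lower-mean state (for methylation tracks: the PMD
#' state; for ChIP ratio tracks: background).
#'
#' @slot means Numeric(2), per-state emission means.
#' @slot variances Numeric(2), per-state emission variances (> 0).
#' @slot transition 2x2 row-stochastic transition matrix.
#' @slot init Numeric(2), initial state distribution.
#' @slot logLik Numeric, final observed-data log-likelihood.
#' @slot logLikTrace Numeric, log-likelihood after each iteration.
#' @slot nIter Integer, Baum-Welch iterations performed.
#' @slot degenerate Logical, `TRUE` when the input carried no usable
#'   two-state structure (e.g. all values identical).
#' @export
setClass("HmmParams",
  slots = c(means = "numeric", variances = "numeric", transition = "matrix",
            init = "numeric", logLik = "numeric", logLikTrace = "numeric",
            nIter = "integer", degenerate = "logical"))

setValidity("HmmParams", function(object) {
  msg <- character()
  if (length(object@means) != 2L) msg <- c(msg, "means must have length 2")
  if (length(object@variances) != 2L || any(object@variances <= 0))
    msg <- c(msg, "variances must be two positive numbers")
  if (!all(dim(object@transition) == c(2L, 2L)) ||
      any(abs(rowSums(object@transition) - 1) > 1e-8))
    msg <- c(msg, "transition must be 2x2 with rows summing to 1")
  if (length(object@init) != 2L || abs(sum(object@init) - 1) > 1e-8)
    msg <- c(msg, "init must be a length-2 probability vector")
  if (length(msg)) msg else TRUE
})

#' Input-normalised ChIP-seq track
#'
#' A [BinnedTrack] of IP/input ratios on the counts-per-10-million scale,
#' with the pseudocount offset recorded. Windows with zero coverage in every
#' sample are set to `NA`.
#'
#' @slot scaleBasis Numeric, the per-sample scaling target in reads.
#' @slot offset Numeric, pseudocount added to every window before scaling.
#' @export
setClass("NormalizedChip", contains = "BinnedTrack",
  slots = c(scaleBasis = "numeric", offset = "numeric"))

#' Smoothed replication timing derived from repli-seq fractions
#'
#' Higher values mean earlier replication. `smoothed` holds the per-window
#' loess-smoothed log2 early/late ratio (averaged over replicates when more
#' than one was supplied); `raw` the unsmoothed per-replicate ratios.
#'
#' @slot smoothed A [BinnedTrack] of smoothed log2 early/late ratios.
#' @slot raw A list of [BinnedTrack]s, one unsmoothed ratio track per replicate.
#' @slot normalization Character record of the processing choices applied.
#' @export
setClass("ReplicationTiming",
  slots = c(smoothed = "BinnedTrack", raw = "list", normalization = "character"))

#' Forward-model rates of per-domain methylation decay
#'
#' The decay model is dm/dt = -lambda * m + nu * (1 - m): methylation is lost
#' at per-day rate `lambda` (maintenance failure) and unmethylated CpGs gain
#' methylation at per-day rate `nu` (de novo activity). The plateau is
#' nu / (lambda + nu).
#'
#' @slot lambda Per-day loss rate (>= 0).
#' @slot nu Per-day de novo gain rate (>= 0).
#' @slot m0 Initial methylation fraction in `[0, 1]`.
#' @export
setClass("KineticParams",
  slots = c(lambda = "numeric", nu = "numeric", m0 = "numeric"))

setValidity("KineticParams", function(object) {
  msg <- character()
  if (object@lambda < 0 || object@nu < 0) msg <- c(msg, "rates must be >= 0")
  if (object@lambda + object@nu <= 0)
    msg <- c(msg, "lambda + nu must be > 0 (otherwise methylation never moves)")
  if (object@m0 < 0 || object@m0 > 1) msg <- c(msg, "m0 must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Fitted log-linear decay of one domain's methylation time course
#'
#' @slot domainId Character identifier of the domain.
#' @slot slope Per-day change of log methylation over the fit window.
#' @slot intercept Intercept of the log-linear fit.
#' @slot finalLevel Weighted mean methylation (%) at the final timepoint.
#' @slot fitWindow Numeric(2), the day range used for the slope fit.
#' @export
setClass("KineticsFit",
  slots = c(domainId = "character", slope = "numeric", intercept = "numeric",
            finalLevel = "numeric", fitWindow = "numeric"))

#' Configuration of the synthetic methylome generator
#'
#' Holds everything needed to generate a deterministic synthetic genome:
#' layout, planted-domain length distributions, CpG densities, methylation
#' means and noise, read depths, ChIP enrichments, replication-timing offsets
#' and per-class decay rates. See [simulationConfig()] for defaults and units.
#'
#' @slot seed Integer master seed; every stage derives its own stream from it.
#' @slot layout [GenomeInfoDb::Seqinfo] of the synthetic genome.
#' @slot window Integer analysis window size in bp.
#' @slot exclusions `GRanges` of unmappable regions (centromere stand-ins).
#' @slot domainMedianMb Named numeric, median planted length per class (Mb).
#' @slot domainSdLog Numeric, sdlog of the log-normal length distribution.
#' @slot domainMinMb Numeric, lower truncation of planted lengths (Mb).
#' @slot pmdClassProb Named numeric, class probabilities for PMD draws.
#' @slot hyperFraction Fraction of H3K9me3 PMDs planted as hyper-convertible.
#' @slot cpgPerKb Named numeric, CpG density per kb by domain class.
#' @slot methMeanPct Named list, per-condition per-class methylation means (%).
#' @slot methBetaPrecision Beta precision of per-CpG propensities (Inf = none).
#' @slot readDepthMean Mean total reads per CpG.
#' @slot readDepthFixed Logical; `TRUE` fixes every CpG at `readDepthMean` reads.
#' @slot chipDepth Mean input reads per window for ChIP simulation.
#' @slot chipEnrichment Named list `[[condition]][[mark]]` of per-class IP/IN.
#' @slot repliDepth Mean reads per window per repli-seq fraction.
#' @slot repliLog2Offset Named list, per-condition per-class log2 E/L targets.
#' @slot kineticRates Named list, per-class `c(lambda, nu)` per-day rates.
#' @slot timecourseNoiseSd Observation noise (pp) on time-course values.
#' @export
setClass("SimulationConfig",
  slots = c(seed = "integer", layout = "Seqinfo", window = "integer",
            exclusions = "GRanges",
            domainMedianMb = "numeric", domainSdLog = "numeric",
            domainMinMb = "numeric", pmdClassProb = "numeric",
            hyperFraction = "numeric", cpgPerKb = "numeric",
            methMeanPct = "list", methBetaPrecision = "numeric",
            readDepthMean = "numeric", readDepthFixed = "logical",
            chipDepth = "numeric", chipEnrichment = "list",
            repliDepth = "numeric", repliLog2Offset = "list",
            kineticRates = "list", timecourseNoiseSd = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (abs(sum(object@pmdClassProb) - 1) > 1e-8)
    msg <- c(msg, "pmdClassProb must sum to 1")
  if (object@hyperFraction < 0 || object@hyperFraction > 1)
    msg <- c(msg, "hyperFraction must lie in [0, 1]")
  if (any(object@cpgPerKb <= 0)) msg <- c(msg, "cpgPerKb must be positive")
  rates <- unlist(object@kineticRates)
  if (any(rates < 0)) msg <- c(msg, "kinetic rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Planted ground truth of a synthetic genome
#'
#' @slot domains A [DomainSet] tiling the synthetic genome minus exclusions,
#'   with `kind` in HMD / PMD-K9 / PMD-K27 / PMD-hyper and a `domain_id` column.
#' @slot rates data.frame of per-domain kinetic rates (lambda, nu, m0).
#' @export
setClass("GroundTruth", slots = c(domains = "DomainSet", rates = "data.frame"))
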