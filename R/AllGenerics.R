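#' @include AllClasses.R
NULL

#' Accessors for BinnedTrack, DomainSet and GroundTruth objects
#'
#' `binWindows()`/`binValues()`/`binSize()` expose the windows, values and
#' nominal bin width of a [BinnedTrack]; `domainRanges()` and `domainKind()`
#' the intervals and labels of a [DomainSet]; `truthDomains()` and
#' `truthRates()` the planted domains and kinetic rates of a [GroundTruth].
#'
#' @param x A `BinnedTrack`, `DomainSet` or `GroundTruth` object.
#' @return The corresponding slot contents: a `GRanges`, numeric vector,
#'   integer scalar, character vector, `DomainSet` or `data.frame`.
#' @name accessors
#' @aliases binWindows binValues binSize domainRanges domainKind truthDomains truthRates
#' @examples
#' tr <- exampleTrack <- binnedTrack(
#'   GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 11), c(10, 20))),
#'   c(0.5, 0.7))
#' binSize(tr)
#' binValues(tr)
NULL

#' @rdname accessors
#' @export
setGeneric("binWindows", function(x) standardGeneric("binWindows"))
#' @rdname accessors
#' @export
setGeneric("binValues", function(x) standardGeneric("binValues"))
#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setGeneric("domainRanges", function(x) standardGeneric("domainRanges"))
#' @rdname accessors
#' @export
setGeneric("domainKind", function(x) standardGeneric("domainKind"))
#' @rdname accessors
#' @export
setGeneric("truthDomains", function(x) standardGeneric("truthDomains"))
#' @rdname accessors
#' @export
setGeneric("truthRates", function(x) standardGeneric("truthRates"))

#' @rdname accessors
setMethod("binWindows", "BinnedTrack", function(x) x@windows)
#' @rdname accessors
setMethod("binValues", "BinnedTrack", function(x) x@values)
#' @rdname accessors
setMethod("binSize", "BinnedTrack", function(x) x@binSize)
#' @rdname accessors
setMethod("domainRanges", "DomainSet", function(x) x@ranges)
#' @rdname accessors
setMethod("domainKind", "DomainSet",
          function(x) as.character(S4Vectors::mcols(x@ranges)$kind))
#' @rdname accessors
setMethod("truthDomains", "GroundTruth", function(x) x@domains)
#' @rdname accessors
setMethod("truthRates", "GroundTruth", function(x) x@rates)

#' @export
#' @rdname accessors
setMethod("length", "BinnedTrack", function(x) length(x@windows))
#' @export
#' @rdname accessors
setMethod("length", "DomainSet", function(x) length(x@ranges))

setMethod("show", "BinnedTrack", function(object) {
  cat(sprintf("BinnedTrack: %d windows of %d bp on %d sequence(s); %d missing\n",
              length(object), object@binSize,
              length(GenomeInfoDb::seqlevels(object@windows)),
              sum(is.na(object@values))))
})

setMethod("show", "DomainSet", function(object) {
  tab <- table(domainKind(object))
  cat(sprintf("DomainSet: %d domains (%s); total %.2f Mb\n",
              length(object),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              sum(GenomicRanges::width(object@ranges)) / 1e6))
})

setMethod("show", "HmmParams", function(object) {
  cat(sprintf(
    "HmmParams: means %.3f/%.3f, sd %.3f/%.3f, stay-prob %.4f/%.4f%s\n",
    object@means[1], object@means[2],
    sqrt(object@variances[1]), sqrt(object@variances[2]),
    object@transition[1, 1], object@transition[2, 2],
    if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "KineticParams", function(object) {
  cat(sprintf("KineticParams: lambda %.3f/day, nu %.3f/day, m0 %.3f, plateau %.3f\n",
              object@lambda, object@nu, object@m0,
              object@nu / (object@lambda + object@nu)))
})

setMethod("show", "KineticsFit", function(object) {
  cat(sprintf("KineticsFit %s: slope %.4f /day (days %g-%g), final %.2f%%\n",
              object@domainId, object@slope, object@fitWindow[1],
              object@fitWindow[2], object@finalLevel))
})

setMethod("show", "GroundTruth", function(object) {
  show(object@domains)
})

setMethod("show", "ReplicationTiming", function(object) {
  cat(sprintf("ReplicationTiming: %d windows, %d replicate(s); %s\n",
              length(object@smoothed), length(object@raw),
              paste(object@normalization, collapse = "; ")))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: seed %d, %d chromosome(s), %.0f Mb, %d bp windows\n",
              object@seed, length(GenomeInfoDb::seqnames(object@layout)),
              sum(as.numeric(GenomeInfoDb::seqlengths(object@layout))) / 1e6,
              object@window))
})
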