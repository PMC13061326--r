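#' @include AllClasses.R
NULL

# Shared coordinate conventions: all intervals are 0-based half-open (BED)
# at the user-facing file boundary, and 1-based closed inside GRanges, the
# conversion happening only in the readers/writers below. Chromosome order
# always follows the supplied layout, never lexicographic sort.

#' Construct a genome layout
#'
#' A thin wrapper around [GenomeInfoDb::Seqinfo] naming the chromosomes and
#' their sizes. The order given here is the order used everywhere downstream.
#'
#' @param chromNames Character vector of unique chromosome names.
#' @param chromSizes Integer vector of chromosome lengths in bp (> 0).
#' @return A [GenomeInfoDb::Seqinfo] object.
#' @examples
#' makeGenomeLayout(c("chr1", "chr2"), c(25e6, 25e6))
#' @export
makeGenomeLayout <- function(chromNames, chromSizes) {
  if (anyDuplicated(chromNames)) stop("chromosome names must be unique")
  if (any(chromSizes <= 0)) stop("chromosome sizes must be positive")
  GenomeInfoDb::Seqinfo(seqnames = as.character(chromNames),
                        seqlengths = as.integer(chromSizes))
}

#' Read a UCSC-style two-column chromosome-sizes table
#'
#' @param path Path to a tab-separated file: chromosome name, size in bp.
#' @return A [GenomeInfoDb::Seqinfo] object preserving the file's order.
#' @export
readChromSizes <- function(path) {
  if (!file.exists(path))
    stop(sprintf("chromosome-sizes file not found: %s", path))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "numeric"))
  makeGenomeLayout(tab$chrom, tab$size)
}

# Internal: validate a GRanges against a layout when one is attached.
.checkBounds <- function(gr, what = "interval") {
  sl <- GenomeInfoDb::seqlengths(gr)
  known <- !is.na(sl[as.character(GenomicRanges::seqnames(gr))])
  bad <- known & (GenomicRanges::end(gr) >
                  sl[as.character(GenomicRanges::seqnames(gr))] |
                  GenomicRanges::start(gr) < 1L)
  if (any(bad))
    stop(sprintf("%s outside genome bounds (first offender: %s:%d-%d)",
                 what,
                 as.character(GenomicRanges::seqnames(gr))[which(bad)[1]],
                 GenomicRanges::start(gr)[which(bad)[1]] - 1L,
                 GenomicRanges::end(gr)[which(bad)[1]]))
  invisible(gr)
}

#' Merge genomic intervals that are closer than a gap threshold
#'
#' Follows bedtools `merge -d` semantics: two intervals merge when the gap
#' between them is smaller than *or equal to* `max_gap` (so touching or
#' overlapping intervals always merge). Intervals on different chromosomes
#' never merge. The output is sorted in layout order.
#'
#' @param intervals A `GRanges`.
#' @param max_gap Maximum gap in bp across which to merge (>= 0).
#' @return A sorted, strand-free `GRanges` with pairwise gaps > `max_gap`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 151), c(100, 200)))
#' mergeIntervals(gr, max_gap = 50)  # gap of exactly 50 merges
#' @export
mergeIntervals <- function(intervals, max_gap = 0) {
  stopifnot(max_gap >= 0)
  .checkBounds(intervals)
  GenomicRanges::reduce(GenomicRanges::sort(intervals, ignore.strand = TRUE),
                        min.gapwidth = as.integer(max_gap) + 1L,
                        ignore.strand = TRUE)
}

#' Base-pair set difference of two interval sets
#'
#' @param a,b `GRanges` on the same genome.
#' @return `GRanges` covering every base of `a` not covered by `b`.
#' @export
subtractIntervals <- function(a, b) {
  .checkBounds(a); .checkBounds(b)
  if (length(b) == 0L)
    return(GenomicRanges::reduce(GenomicRanges::sort(a, ignore.strand = TRUE),
                                 ignore.strand = TRUE))
  GenomeInfoDb::seqlevels(b) <- union(GenomeInfoDb::seqlevels(b),
                                      GenomeInfoDb::seqlevels(a))
  GenomeInfoDb::seqlevels(a) <- GenomeInfoDb::seqlevels(b)
  GenomicRanges::setdiff(a, b, ignore.strand = TRUE)
}

#' Base-pair Jaccard index of two interval sets
#'
#' Intersection over union in base pairs, the measure used to compare domain
#' sets between samples (e.g. heterochromatic domains called in two cell
#' lines). Symmetric; undefined (an error) when both sets are empty.
#'
#' @param a,b `GRanges` on the same genome.
#' @return A fraction in `[0, 1]`.
#' @export
jaccardIndex <- function(a, b) {
  .checkBounds(a); .checkBounds(b)
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  a <- GenomicRanges::reduce(a, ignore.strand = TRUE)
  b <- GenomicRanges::reduce(b, ignore.strand = TRUE)
  uni <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::union(a, b, ignore.strand = TRUE))))
  if (uni == 0) stop("Jaccard undefined: both interval sets are empty")
  int <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::intersect(a, b, ignore.strand = TRUE))))
  int / uni
}

#' Tile a genome into fixed-width windows
#'
#' @param layout A [GenomeInfoDb::Seqinfo].
#' @param size Window size in bp; the last window of each chromosome is
#'   truncated at the chromosome end.
#' @return A `GRanges` of windows in layout order.
#' @examples
#' makeWindows(makeGenomeLayout("chrT", 25000), 10000)
#' @export
makeWindows <- function(layout, size) {
  stopifnot(size > 0)
  size <- as.integer(size)
  grs <- lapply(GenomeInfoDb::seqnames(layout), function(ch) {
    n <- GenomeInfoDb::seqlengths(layout)[[ch]]
    starts <- seq.int(1L, n, by = size)
    GenomicRanges::GRanges(ch,
      IRanges::IRanges(starts, pmin(starts + size - 1L, n)),
      seqinfo = layout)
  })
  do.call(c, grs)
}

#' Read and write BED intervals
#'
#' `readBed()` parses BED3/BED4/BED6 (tab-separated, no header; 0-based
#' half-open) into a `GRanges`, keeping column 4 as metadata column `name`
#' when present. `writeBed()` writes the reverse mapping; a `kind` or `name`
#' metadata column becomes BED column 4. Gzipped paths are handled
#' transparently.
#'
#' @param path File path (plain or `.gz`).
#' @param layout Optional [GenomeInfoDb::Seqinfo] to attach and bound-check
#'   against.
#' @return `readBed()`: a `GRanges`. `writeBed()`: the path, invisibly.
#' @export
readBed <- function(path, layout = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con); close(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(layout)) GenomeInfoDb::seqinfo(gr) <- layout
    return(gr)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 3L))
    stop(sprintf("malformed BED line %d: fewer than 3 fields",
                 which(ncol < 3L)[1]))
  chrom <- vapply(parts, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0) | start0 < 0 | end0 <= start0
  if (any(bad))
    stop(sprintf("malformed BED line %d: bad coordinates", which(bad)[1]))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
  if (all(ncol >= 4L))
    S4Vectors::mcols(gr)$name <- vapply(parts, `[[`, "", 4L)
  if (!is.null(layout)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(layout)
    GenomeInfoDb::seqinfo(gr) <- layout
    .checkBounds(gr, "BED interval")
  }
  gr
}

#' @rdname readBed
#' @param gr A `GRanges` (or [DomainSet], whose `kind` becomes column 4).
#' @export
writeBed <- function(gr, path) {
  if (is(gr, "DomainSet")) {
    kinds <- domainKind(gr)
    gr <- domainRanges(gr)
    S4Vectors::mcols(gr)$name <- kinds
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- S4Vectors::mcols(gr)$kind
  if (!is.null(nm)) df$name <- as.character(nm)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' Construct a DomainSet
#'
#' @param ranges A `GRanges`.
#' @param kind Character vector (recycled) labelling each interval.
#' @return A [DomainSet].
#' @export
domainSet <- function(ranges, kind) {
  S4Vectors::mcols(ranges)$kind <- rep_len(as.character(kind), length(ranges))
  new("DomainSet", ranges = ranges)
}

#' Subset a DomainSet by kind
#'
#' @param x A [DomainSet].
#' @param kind Character vector of labels to keep.
#' @return A [DomainSet] with only the requested kinds.
#' @export
domainSubset <- function(x, kind) {
  keep <- domainKind(x) %in% kind
  new("DomainSet", ranges = x@ranges[keep])
}
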