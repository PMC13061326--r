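#' @include AllClasses.R genome-model.R
NULL

#' Construct a BinnedTrack
#'
#' @param windows `GRanges` of windows (uniform width except chromosome ends).
#' @param values Numeric vector, one per window; `NA` marks missing windows.
#' @param binSize Nominal window width in bp; inferred as the maximum window
#'   width when omitted.
#' @return A [BinnedTrack].
#' @export
binnedTrack <- function(windows, values, binSize = NULL) {
  if (is.null(binSize))
    binSize <- if (length(windows)) max(GenomicRanges::width(windows)) else 1L
  new("BinnedTrack", windows = windows, values = as.numeric(values),
      binSize = as.integer(binSize))
}

# Internal: assert two tracks share the same window grid.
.sameGrid <- function(x, y) {
  if (length(x) != length(y) ||
      !identical(as.character(GenomicRanges::seqnames(binWindows(x))),
                 as.character(GenomicRanges::seqnames(binWindows(y)))) ||
      !identical(GenomicRanges::start(binWindows(x)),
                 GenomicRanges::start(binWindows(y))))
    stop("window grids do not match")
  invisible(TRUE)
}

#' Read per-CpG methylation calls
#'
#' Two tab-separated layouts are understood, both yielding one record per CpG
#' with methylated and total read counts:
#' \describe{
#'   \item{`"bismark"`}{bismark coverage: chrom, start, end, \%methylation,
#'     methylated count, unmethylated count. Both the 0-based half-open
#'     (end = start + 1) and the 1-based (end = start) position conventions
#'     are recognised and converted to 0-based.}
#'   \item{`"bedgraph"`}{chrom, start, end, \%methylation, coverage; counts
#'     are reconstructed as `round(pct / 100 * coverage)`.}
#' }
#' Gzipped files are read transparently. Records are returned sorted by
#' (chromosome, position).
#'
#' @param path File path.
#' @param format `"bismark"` or `"bedgraph"`.
#' @param layout Optional [GenomeInfoDb::Seqinfo] to attach (fixes the
#'   chromosome order and enables bound checks).
#' @return A width-1 `GRanges` with integer metadata columns `meth` and
#'   `total` (`meth <= total`, `total >= 1`).
#' @export
readMethylation <- function(path, format = c("bismark", "bedgraph"),
                            layout = NULL) {
  format <- match.arg(format)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con); close(con)
  lines <- lines[nzchar(lines)]
  need <- if (format == "bismark") 6L else 5L
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$meth <- integer()
    S4Vectors::mcols(gr)$total <- integer()
    if (!is.null(layout)) GenomeInfoDb::seqinfo(gr) <- layout
    return(gr)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < need))
    stop(sprintf("parse error at line %d: expected %d tab-separated fields",
                 which(lengths(parts) < need)[1], need))
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop(sprintf("parse error at line %d: non-numeric coordinate",
                 which(is.na(start) | is.na(end))[1]))
  if (format == "bismark") {
    meth <- as.integer(vapply(parts, `[[`, "", 5L))
    unmeth <- as.integer(vapply(parts, `[[`, "", 6L))
    total <- meth + unmeth
  } else {
    pct <- as.numeric(vapply(parts, `[[`, "", 4L))
    total <- as.integer(vapply(parts, `[[`, "", 5L))
    meth <- as.integer(round(pct / 100 * total))
  }
  if (anyNA(meth) || anyNA(total))
    stop(sprintf("parse error at line %d: non-numeric counts",
                 which(is.na(meth) | is.na(total))[1]))
  bad <- meth > total | meth < 0 | total < 1L
  if (any(bad))
    stop(sprintf("validation error at line %d: methylated reads exceed total or total < 1",
                 which(bad)[1]))
  # 1-based inputs (end == start) are converted here, at the reader boundary.
  pos0 <- ifelse(end == start, start - 1, start)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1L, width = 1L),
                               meth = meth, total = total)
  if (!is.null(layout)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(layout)
    GenomeInfoDb::seqinfo(gr) <- layout
    .checkBounds(gr, "CpG")
  }
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write per-CpG methylation calls
#'
#' The inverse of [readMethylation()]; a round trip preserves counts exactly.
#'
#' @param calls Width-1 `GRanges` with `meth` and `total` metadata columns.
#' @inheritParams readMethylation
#' @return The path, invisibly.
#' @export
writeMethylation <- function(calls, path, format = c("bismark", "bedgraph")) {
  format <- match.arg(format)
  meth <- S4Vectors::mcols(calls)$meth
  total <- S4Vectors::mcols(calls)$total
  pos0 <- GenomicRanges::start(calls) - 1L
  df <- if (format == "bismark") {
    data.frame(chrom = as.character(GenomicRanges::seqnames(calls)),
               start = pos0, end = pos0 + 1L,
               pct = round(100 * meth / total, 6),
               meth = meth, unmeth = total - meth)
  } else {
    data.frame(chrom = as.character(GenomicRanges::seqnames(calls)),
               start = pos0, end = pos0 + 1L,
               pct = round(100 * meth / total, 6), cov = total)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' Coverage-weighted mean methylation over intervals
#'
#' For each interval, 100 x (sum of methylated reads) / (sum of total reads)
#' over the CpGs it contains whose coverage reaches `min_coverage`. Intervals
#' containing no qualifying CpG get `NA`. This is the read-count weighting
#' used for all window and domain summaries; low-coverage filtering is off by
#' default (`min_coverage = 1`).
#'
#' @param calls Width-1 `GRanges` with `meth`/`total` metadata columns.
#' @param intervals `GRanges` of windows or domains.
#' @param min_coverage Minimum total reads for a CpG to contribute.
#' @return Numeric vector of percentages (or `NA`), one per interval.
#' @examples
#' cpgs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(5, 9), width = 1),
#'                                meth = c(3L, 1L), total = c(4L, 6L))
#' weightedMeanMethylation(cpgs, GenomicRanges::GRanges("chr1",
#'                         IRanges::IRanges(1, 20)))  # 100 * 4/10 = 40
#' @export
weightedMeanMethylation <- function(calls, intervals, min_coverage = 1L) {
  total <- S4Vectors::mcols(calls)$total
  keep <- total >= min_coverage
  calls <- calls[keep]
  out <- rep(NA_real_, length(intervals))
  if (length(calls) == 0L || length(intervals) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(calls, intervals, ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  methSum <- tapply(as.numeric(S4Vectors::mcols(calls)$meth[q]), s, sum)
  totSum <- tapply(as.numeric(S4Vectors::mcols(calls)$total[q]), s, sum)
  idx <- as.integer(names(methSum))
  out[idx] <- 100 * as.numeric(methSum) / as.numeric(totSum)
  out
}

#' Window methylation track from CpG calls
#'
#' Convenience composition of [makeWindows()] and
#' [weightedMeanMethylation()].
#'
#' @param calls Width-1 `GRanges` with `meth`/`total` metadata columns.
#' @param layout A [GenomeInfoDb::Seqinfo].
#' @param window Window size in bp.
#' @param min_coverage Minimum CpG coverage, as in [weightedMeanMethylation()].
#' @return A [BinnedTrack] of window methylation percentages.
#' @export
methylationTrack <- function(calls, layout, window = 10000L,
                             min_coverage = 1L) {
  win <- makeWindows(layout, window)
  binnedTrack(win, weightedMeanMethylation(calls, win, min_coverage),
              binSize = window)
}

#' Count fragments overlapping each window
#'
#' bedtools `coverage -counts` semantics: a fragment is counted in every
#' window it overlaps (not assigned to a single window by its midpoint).
#'
#' @param fragments `GRanges` of read/fragment locations.
#' @param windows `GRanges` of windows.
#' @return A [BinnedTrack] of integer counts.
#' @export
binCounts <- function(fragments, windows) {
  binnedTrack(windows,
              GenomicRanges::countOverlaps(windows, fragments,
                                           ignore.strand = TRUE))
}

#' Write a BinnedTrack as bedGraph
#'
#' Missing windows are omitted from the file.
#'
#' @param track A [BinnedTrack].
#' @param path Output path (plain or `.gz`).
#' @return The path, invisibly.
#' @export
writeBedGraph <- function(track, path) {
  keep <- !is.na(binValues(track))
  w <- binWindows(track)[keep]
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(w)),
                   start = GenomicRanges::start(w) - 1L,
                   end = GenomicRanges::end(w),
                   value = binValues(track)[keep])
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}
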