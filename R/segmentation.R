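#' @include hmm.R
NULL

# Convert runs of a given state into GRanges on the window grid.
.stateRuns <- function(windows, states, keep_state) {
  sq <- as.character(GenomicRanges::seqnames(windows))
  out <- list()
  for (ch in unique(sq)) {
    idx <- which(sq == ch)
    r <- rle(states[idx] == keep_state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    if (!length(sel)) next
    out[[ch]] <- GenomicRanges::GRanges(
      ch,
      IRanges::IRanges(GenomicRanges::start(windows)[idx[starts[sel]]],
                       GenomicRanges::end(windows)[idx[ends[sel]]]),
      seqinfo = GenomeInfoDb::seqinfo(windows))
  }
  if (!length(out))
    return(GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(windows)))
  GenomicRanges::sort(do.call(c, unname(out)), ignore.strand = TRUE)
}

# Trim each interval to [first CpG, last CpG] it contains; drop CpG-free ones.
.trimToCpGs <- function(gr, calls) {
  if (!length(gr)) return(gr)
  hits <- GenomicRanges::findOverlaps(calls, gr, ignore.strand = TRUE)
  if (!length(hits)) return(gr[0])
  s <- S4Vectors::subjectHits(hits)
  pos <- GenomicRanges::start(calls)[S4Vectors::queryHits(hits)]
  lo <- tapply(pos, s, min); hi <- tapply(pos, s, max)
  idx <- as.integer(names(lo))
  out <- gr[idx]
  GenomicRanges::start(out) <- as.integer(lo)
  GenomicRanges::end(out) <- as.integer(hi)
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

# Remove sub-minimum domains from a PMD/HMD partition by relabelling them to
# the opposite kind and merging with their neighbours, iterated to a
# fixpoint. This keeps PMD u HMD an exact partition of the analysable genome
# while realising "remove, then merge neighbours". Isolated analysable
# blocks entirely shorter than min_length are dropped.
.absorbSmallDomains <- function(dom, min_length, max_pass = 100L) {
  for (pass in seq_len(max_pass)) {
    w <- GenomicRanges::width(dom$ranges)
    small <- w < min_length
    if (!any(small)) break
    # relabel small domains that have at least one neighbour in their block
    blk <- dom$block
    hasNb <- vapply(seq_along(blk), function(i)
      any(blk == blk[i] & seq_along(blk) != i), logical(1))
    flip <- small & hasNb
    if (!any(flip)) {                 # only isolated small blocks remain
      keep <- !small
      dom$ranges <- dom$ranges[keep]; dom$kind <- dom$kind[keep]
      dom$block <- dom$block[keep]
      break
    }
    dom$kind[flip] <- ifelse(dom$kind[flip] == "PMD", "HMD", "PMD")
    dom <- .mergeSameKind(dom)
  }
  dom
}

# Merge adjacent same-kind domains within each analysable block.
.mergeSameKind <- function(dom) {
  n <- length(dom$ranges)
  if (n <= 1L) return(dom)
  grp <- cumsum(c(TRUE, dom$kind[-1] != dom$kind[-n] |
                        dom$block[-1] != dom$block[-n]))
  sq <- as.character(GenomicRanges::seqnames(dom$ranges))
  newStart <- tapply(GenomicRanges::start(dom$ranges), grp, min)
  newEnd <- tapply(GenomicRanges::end(dom$ranges), grp, max)
  first <- !duplicated(grp)
  ranges <- GenomicRanges::GRanges(
    sq[first], IRanges::IRanges(as.integer(newStart), as.integer(newEnd)),
    seqinfo = GenomeInfoDb::seqinfo(dom$ranges))
  list(ranges = ranges, kind = dom$kind[first], block = dom$block[first])
}

#' Call PMDs and HMDs from CpG-level methylation
#'
#' The full domain-segmentation pipeline: weighted window methylation (10 kb
#' default), two-state Gaussian HMM fit and Viterbi decode, low-state runs as
#' raw PMDs, trimming of each PMD to the first and last CpG it contains,
#' bridging of PMDs whose gap is smaller than twice the window size,
#' complement to HMDs, subtraction of exclusion regions (gap and centromere
#' intervals, pre-merged across gaps of up to 10 Mb), removal of domains
#' shorter than `min_length` (absorbed by their neighbours so that PMDs and
#' HMDs still partition the analysable genome), and a final trim of PMD
#' boundaries to CpG positions.
#'
#' Chromosomes bearing no CpGs are skipped with a warning. A track with no
#' two-state structure (e.g. a flat methylome) yields zero PMDs and one HMD
#' per analysable block.
#'
#' @param calls Width-1 `GRanges` of CpGs with `meth`/`total` columns.
#' @param layout A [GenomeInfoDb::Seqinfo].
#' @param exclusions `GRanges` of unmappable regions (may be empty).
#' @param window Analysis window size in bp (default 10 kb).
#' @param min_length Minimum domain length in bp (default 200 kb).
#' @param min_coverage Minimum CpG coverage for window means.
#' @param max_iter,tol,seed Passed to [fitTwoStateHMM()].
#' @return A [DomainSet] with kinds `"PMD"` and `"HMD"` and metadata columns
#'   `n_windows` and `mean_meth`.
#' @export
callPMDs <- function(calls, layout, exclusions = GenomicRanges::GRanges(),
                     window = 10000L, min_length = 200000L,
                     min_coverage = 1L, max_iter = 200L, tol = 1e-4,
                     seed = 1L) {
  win <- makeWindows(layout, window)
  cpgChroms <- unique(as.character(GenomicRanges::seqnames(calls)))
  allChroms <- GenomeInfoDb::seqnames(layout)
  skipped <- setdiff(allChroms, cpgChroms)
  if (length(skipped)) {
    warning(sprintf("no CpGs on %s; chromosome(s) skipped",
                    paste(skipped, collapse = ", ")))
    win <- win[as.character(GenomicRanges::seqnames(win)) %in% cpgChroms]
  }
  vals <- weightedMeanMethylation(calls, win, min_coverage)
  track <- binnedTrack(win, vals, binSize = window)
  excl <- if (length(exclusions)) mergeIntervals(exclusions, max_gap = 1e7)
          else exclusions

  params <- fitTwoStateHMM(track, max_iter = max_iter, tol = tol, seed = seed)
  if (params@degenerate) {
    pmds <- GenomicRanges::GRanges(seqinfo = layout)
  } else {
    states <- viterbiDecode(track, params)
    pmds <- .stateRuns(win, states, keep_state = 1L)
    pmds <- .trimToCpGs(pmds, calls)
    pmds <- mergeIntervals(pmds, max_gap = 2L * window - 1L)  # gap < 2x window
  }
  chromGr <- GenomicRanges::GRanges(
    cpgChroms, IRanges::IRanges(1L, GenomeInfoDb::seqlengths(layout)[cpgChroms]),
    seqinfo = layout)
  analysable <- subtractIntervals(chromGr, excl)
  # clamp each analysable block to the CpGs it actually contains, so that
  # trimming a block-edge PMD to its first/last CpG never strands a sliver
  # of CpG-free sequence outside every domain
  analysable <- .trimToCpGs(analysable, calls)
  pmds <- GenomicRanges::intersect(pmds, analysable, ignore.strand = TRUE)
  hmds <- subtractIntervals(analysable, pmds)

  # interleave into one sorted list labelled by kind and analysable block
  all <- c(pmds, hmds)
  kind <- c(rep("PMD", length(pmds)), rep("HMD", length(hmds)))
  ord <- GenomicRanges::order(all)
  all <- all[ord]; kind <- kind[ord]
  blockHit <- GenomicRanges::findOverlaps(all, analysable,
                                          ignore.strand = TRUE,
                                          select = "first")
  dom <- .mergeSameKind(list(ranges = all, kind = kind,
                             block = as.integer(blockHit)))

  # Alternate the sub-minimum absorption with the PMD trim-to-CpG rule until
  # both hold: trimming can shrink a borderline PMD below min_length, and
  # absorbing a small domain can move a PMD boundary off a CpG. HMDs always
  # take up the bases a trim frees, so the partition stays exact.
  for (round in 1:5) {
    dom <- .absorbSmallDomains(dom, min_length)
    isP <- dom$kind == "PMD"
    pmdsF <- .trimToCpGs(dom$ranges[isP], calls)
    analysable2 <- GenomicRanges::reduce(dom$ranges, ignore.strand = TRUE)
    hmdsF <- subtractIntervals(analysable2, pmdsF)
    res <- c(pmdsF, hmdsF)
    kinds <- c(rep("PMD", length(pmdsF)), rep("HMD", length(hmdsF)))
    ord <- GenomicRanges::order(res)
    res <- res[ord]; kinds <- kinds[ord]
    blockHit <- GenomicRanges::findOverlaps(res, analysable2,
                                            ignore.strand = TRUE,
                                            select = "first")
    dom <- .mergeSameKind(list(ranges = res, kind = kinds,
                               block = as.integer(blockHit)))
    if (all(GenomicRanges::width(dom$ranges) >= min_length)) break
  }
  res <- dom$ranges; kinds <- dom$kind

  nwin <- GenomicRanges::countOverlaps(res, win, ignore.strand = TRUE)
  meanv <- weightedMeanMethylation(calls, res, min_coverage)
  S4Vectors::mcols(res) <- S4Vectors::DataFrame(kind = kinds,
                                                n_windows = nwin,
                                                mean_meth = meanv)
  new("DomainSet", ranges = res)
}

#' Call chromatin domains from a ChIP enrichment track
#'
#' Segments an input-normalised ChIP ratio track (25 kb windows for
#' heterochromatic marks) with the same two-state HMM and returns runs of the
#' *high*-enrichment state as domains, after subtracting exclusion regions.
#' No bridging or length filtering is applied.
#'
#' @param ratio_track A [BinnedTrack] of IP/input ratios.
#' @param exclusions `GRanges` of unmappable regions.
#' @param kind Label for the emitted domains (e.g. `"K9-domain"`).
#' @param max_iter,tol,seed Passed to [fitTwoStateHMM()].
#' @return A [DomainSet]; empty when the track is degenerate (flat).
#' @export
callChromatinDomains <- function(ratio_track,
                                 exclusions = GenomicRanges::GRanges(),
                                 kind = "K9-domain", max_iter = 200L,
                                 tol = 1e-4, seed = 1L) {
  params <- fitTwoStateHMM(ratio_track, max_iter = max_iter, tol = tol,
                           seed = seed)
  win <- binWindows(ratio_track)
  if (params@degenerate) {
    gr <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(win))
    S4Vectors::mcols(gr)$kind <- character(0)
    return(new("DomainSet", ranges = gr))
  }
  states <- viterbiDecode(ratio_track, params)
  doms <- .stateRuns(win, states, keep_state = 2L)
  if (length(exclusions))
    doms <- subtractIntervals(doms, mergeIntervals(exclusions, max_gap = 1e7))
  S4Vectors::mcols(doms)$kind <- rep(kind, length(doms))
  new("DomainSet", ranges = doms)
}
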