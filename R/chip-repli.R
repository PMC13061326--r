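#' @include tracks-io.R
NULL

#' Input-normalise a binned ChIP-seq count track
#'
#' Both IP and input counts get a 0.5 pseudocount per window (so windows with
#' zero input reads never divide to infinity), are scaled to counts per 10
#' million mapped reads, and the track value is the IP/input ratio of those
#' scaled counts. Windows with zero coverage in every sample (IP and input)
#' are removed from the analysis (set to `NA`).
#'
#' @param ip,input [BinnedTrack]s of raw counts on the same window grid.
#' @param ip_total,input_total Mapped-read totals used for scaling; default
#'   to the track sums.
#' @param offset Pseudocount added to each window (default 0.5).
#' @return A [NormalizedChip]; values are ratios (> 0) or `NA`.
#' @export
normalizeChip <- function(ip, input, ip_total = NULL, input_total = NULL,
                          offset = 0.5) {
  .sameGrid(ip, input)
  ipv <- binValues(ip); inv <- binValues(input)
  if (is.null(ip_total)) ip_total <- sum(ipv, na.rm = TRUE)
  if (is.null(input_total)) input_total <- sum(inv, na.rm = TRUE)
  scale <- 1e7
  ratio <- ((ipv + offset) * scale / ip_total) /
           ((inv + offset) * scale / input_total)
  ratio[!is.na(ipv) & !is.na(inv) & ipv == 0 & inv == 0] <- NA_real_
  new("NormalizedChip", windows = binWindows(ip), values = ratio,
      binSize = binSize(ip), scaleBasis = scale, offset = offset)
}

#' Quantile-normalise tracks across samples
#'
#' Every track's sorted values are replaced by the rank-wise means across
#' samples, so all outputs share an identical multiset of values and each
#' track's within-sample rank order is preserved. Windows missing in any
#' sample are dropped from all samples (set to `NA` everywhere) and reported
#' via a message.
#'
#' @param tracks A list of two or more [BinnedTrack]s on the same grid.
#' @return A list of [BinnedTrack]s of the same length.
#' @export
quantileNormalize <- function(tracks) {
  if (length(tracks) < 2L) stop("need at least two tracks")
  for (t in tracks[-1]) .sameGrid(tracks[[1]], t)
  m <- vapply(tracks, binValues, numeric(length(tracks[[1]])))
  m <- matrix(m, ncol = length(tracks))
  complete <- stats::complete.cases(m)
  nDropped <- sum(!complete)
  if (nDropped)
    message(sprintf("quantileNormalize: %d window(s) missing in at least one sample dropped from all", nDropped))
  qn <- matrix(NA_real_, nrow(m), ncol(m))
  if (any(complete))
    qn[complete, ] <- limma::normalizeQuantiles(m[complete, , drop = FALSE])
  lapply(seq_along(tracks), function(j)
    binnedTrack(binWindows(tracks[[j]]), qn[, j],
                binSize = binSize(tracks[[j]])))
}

#' Loess-smooth a track along each chromosome
#'
#' Local linear regression of the window values on the window midpoints,
#' fitted independently per chromosome and evaluated at every non-missing
#' window. Chromosomes with too few points for a local fit are passed
#' through unsmoothed with a message.
#'
#' @param track A [BinnedTrack].
#' @param span Loess span as a fraction of the points per chromosome
#'   (default 0.05); raised automatically when it would cover fewer than 10
#'   points.
#' @return A [BinnedTrack] of smoothed values, `NA` exactly where the input
#'   was `NA`.
#' @export
loessSmooth <- function(track, span = 0.05) {
  win <- binWindows(track)
  vals <- binValues(track)
  mid <- (GenomicRanges::start(win) + GenomicRanges::end(win)) / 2
  sq <- as.character(GenomicRanges::seqnames(win))
  out <- rep(NA_real_, length(vals))
  for (ch in unique(sq)) {
    idx <- which(sq == ch & !is.na(vals))
    if (length(idx) < 10L) {
      if (length(idx))
        message(sprintf("loessSmooth: %s has %d point(s); passed through unsmoothed",
                        ch, length(idx)))
      out[idx] <- vals[idx]
      next
    }
    sp <- max(span, 10 / length(idx))
    df <- data.frame(x = mid[idx], y = vals[idx])
    fit <- stats::loess(y ~ x, data = df, span = sp, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    out[idx] <- stats::fitted(fit)
  }
  binnedTrack(win, out, binSize = binSize(track))
}

#' Replication timing from repli-seq early/late fraction counts
#'
#' Per replicate: both fractions get a 0.5 pseudocount, are scaled to reads
#' per million, and the raw timing value is log2(early/late) of the scaled
#' counts (higher = earlier replication). With two or more replicates the
#' ratio tracks are quantile-normalised across replicates. Each track is
#' then loess-smoothed per chromosome and replicates are averaged.
#'
#' @param early,late A [BinnedTrack] of counts, or a list of them (one per
#'   replicate, same grid).
#' @param span Loess span, as in [loessSmooth()].
#' @param early_totals,late_totals Optional numeric vectors of mapped-read
#'   totals per replicate; default to the track sums.
#' @return A [ReplicationTiming].
#' @export
replicationTiming <- function(early, late, span = 0.05,
                              early_totals = NULL, late_totals = NULL) {
  if (is(early, "BinnedTrack")) early <- list(early)
  if (is(late, "BinnedTrack")) late <- list(late)
  stopifnot(length(early) == length(late), length(early) >= 1L)
  nrep <- length(early)
  raw <- vector("list", nrep)
  for (r in seq_len(nrep)) {
    .sameGrid(early[[r]], late[[r]])
    ev <- binValues(early[[r]]); lv <- binValues(late[[r]])
    et <- if (is.null(early_totals)) sum(ev, na.rm = TRUE) else early_totals[r]
    lt <- if (is.null(late_totals)) sum(lv, na.rm = TRUE) else late_totals[r]
    ratio <- log2(((ev + 0.5) * 1e6 / et) / ((lv + 0.5) * 1e6 / lt))
    raw[[r]] <- binnedTrack(binWindows(early[[r]]), ratio,
                            binSize = binSize(early[[r]]))
  }
  norm <- c("pseudocount 0.5 per fraction", "RPM scaling", "log2 early/late")
  tracks <- raw
  if (nrep >= 2L) {
    tracks <- quantileNormalize(tracks)
    norm <- c(norm, "quantile normalisation across replicates")
  }
  smoothed <- lapply(tracks, loessSmooth, span = span)
  norm <- c(norm, sprintf("loess smoothing per chromosome (span %g)", span))
  sm <- rowMeans(vapply(smoothed, binValues,
                        numeric(length(smoothed[[1]]))), na.rm = FALSE)
  if (nrep >= 2L) norm <- c(norm, "replicate mean")
  new("ReplicationTiming",
      smoothed = binnedTrack(binWindows(early[[1]]), sm,
                             binSize = binSize(early[[1]])),
      raw = raw, normalization = norm)
}
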