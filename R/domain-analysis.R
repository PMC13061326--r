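#' @include tracks-io.R genome-model.R
NULL

# Overlap-width-weighted mean of a track over arbitrary query intervals.
.trackMeanOver <- function(query, track) {
  out <- rep(NA_real_, length(query))
  if (!length(query)) return(out)
  win <- binWindows(track); vals <- binValues(track)
  hits <- GenomicRanges::findOverlaps(query, win, ignore.strand = TRUE)
  if (!length(hits)) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ok <- !is.na(vals[s])
  q <- q[ok]; s <- s[ok]
  if (!length(q)) return(out)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(query[q], win[s]))
  num <- tapply(ov * vals[s], q, sum)
  den <- tapply(ov, q, sum)
  out[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  out
}

#' Per-domain mean of a binned track
#'
#' Overlap-width-weighted mean of the track values across each domain.
#'
#' @param domains A [DomainSet] or `GRanges`.
#' @param track A [BinnedTrack].
#' @return Numeric vector, one mean (or `NA`) per domain.
#' @export
domainTrackMean <- function(domains, track) {
  gr <- if (is(domains, "DomainSet")) domainRanges(domains) else domains
  .trackMeanOver(gr, track)
}

#' Classify PMDs by their dominant heterochromatic mark
#'
#' K-means (k = 2) on each PMD's mean H3K9me3 and H3K27me3 enrichment
#' (IP/input), with per-mark standardisation and multiple restarts. The
#' cluster whose centroid has the higher (raw) H3K9me3 mean is labelled
#' `"K9-marked"`, the other `"K27-marked"`, so labels never depend on input
#' order or on the arbitrary k-means numbering.
#'
#' @param pmds A [DomainSet] or `GRanges` of PMDs (>= 2 required).
#' @param k9_track,k27_track [BinnedTrack]s of normalised enrichment.
#' @param seed Integer seed for the restarts.
#' @param nstart Number of k-means restarts.
#' @return A [S4Vectors::DataFrame] with columns `mean_k9`, `mean_k27` and
#'   `class`, one row per PMD, plus a `centers` metadata element.
#' @export
classifyPMDs <- function(pmds, k9_track, k27_track, seed = 1L, nstart = 25L) {
  gr <- if (is(pmds, "DomainSet")) domainRanges(pmds) else pmds
  if (length(gr) < 2L) stop("need at least 2 PMDs to cluster")
  k9 <- .trackMeanOver(gr, k9_track)
  k27 <- .trackMeanOver(gr, k27_track)
  if (anyNA(k9) || anyNA(k27))
    stop("every PMD needs defined mark means; found NA")
  feat <- scale(cbind(k9, k27))
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  km <- stats::kmeans(feat, centers = 2L, nstart = nstart)
  if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv)
  rawCenters <- cbind(tapply(k9, km$cluster, mean),
                      tapply(k27, km$cluster, mean))
  k9cluster <- which.max(rawCenters[, 1])
  class <- ifelse(km$cluster == k9cluster, "K9-marked", "K27-marked")
  out <- S4Vectors::DataFrame(mean_k9 = k9, mean_k27 = k27, class = class)
  S4Vectors::metadata(out)$centers <- rawCenters
  out
}

#' Call hypermethylated domains from paired condition means
#'
#' A domain is hypermethylated when its mean methylation in the knockout
#' condition is at least `threshold_pp` percentage points above the parental
#' condition (inclusive boundary: a gain of exactly 5.0 pp qualifies).
#' Domains missing a mean in either condition are excluded with a message.
#'
#' @param domain_meth_wt,domain_meth_ko Numeric vectors of per-domain mean
#'   methylation (%) in the parental and knockout condition.
#' @param threshold_pp Gain threshold in percentage points (default 5).
#' @return A data.frame with columns `delta` (KO - WT, pp), `hyper`
#'   (logical) and `excluded` (logical, `TRUE` when either mean was missing).
#' @export
callHypermethylated <- function(domain_meth_wt, domain_meth_ko,
                                threshold_pp = 5.0) {
  stopifnot(length(domain_meth_wt) == length(domain_meth_ko))
  delta <- domain_meth_ko - domain_meth_wt
  excluded <- is.na(delta)
  if (any(excluded))
    message(sprintf("callHypermethylated: %d domain(s) missing a mean excluded",
                    sum(excluded)))
  hyper <- !excluded & delta >= threshold_pp
  data.frame(delta = delta, hyper = hyper, excluded = excluded)
}

#' Scale-regions pileup matrix over domains
#'
#' Every domain body is resampled to `body_length / binsize` equal-width
#' bins (deeptools scale-regions style) and flanked by `flank / binsize`
#' native-scale bins on each side; each cell is the overlap-width-weighted
#' mean of the track over that bin. Rows are ordered by `rank_values`
#' (decreasing by default); rows are never dropped. Domains shorter than one
#' bin contribute their overall mean to every body column (with a message).
#'
#' @param domains A [DomainSet] or `GRanges`.
#' @param track A [BinnedTrack].
#' @param body_length Target body size in bp (default 1 Mb).
#' @param binsize Bin width in bp (default 10 kb).
#' @param flank Flank size in bp on each side (default 1 Mb).
#' @param rank_values Optional numeric ranking key, one per domain (e.g.
#'   parental mean methylation); `NULL` keeps input order.
#' @param decreasing Sort order for `rank_values`.
#' @return A numeric matrix with one row per domain and
#'   `2 * flank/binsize + body_length/binsize` columns; attribute `"order"`
#'   records the row permutation, `"section"` labels columns as
#'   upstream/body/downstream.
#' @export
pileupMatrix <- function(domains, track, body_length = 1e6, binsize = 1e4,
                         flank = 1e6, rank_values = NULL, decreasing = TRUE) {
  gr <- if (is(domains, "DomainSet")) domainRanges(domains) else domains
  if (!length(gr)) stop("domains must be non-empty")
  nBody <- as.integer(round(body_length / binsize))
  nFlank <- as.integer(round(flank / binsize))
  sl <- GenomeInfoDb::seqlengths(gr)
  n <- length(gr)
  mat <- matrix(NA_real_, n, 2L * nFlank + nBody)
  shortSeen <- FALSE
  for (i in seq_len(n)) {
    ch <- as.character(GenomicRanges::seqnames(gr))[i]
    s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
    len <- e - s + 1L
    upStarts <- s - binsize * (nFlank:1)
    dnStarts <- e + 1L + binsize * (0:(nFlank - 1L))
    mkq <- function(starts) {
      ends <- starts + binsize - 1L
      keep <- starts >= 1L
      if (!is.na(sl[ch])) keep <- keep & ends <= sl[ch]
      out <- rep(NA_real_, length(starts))
      if (any(keep)) {
        q <- GenomicRanges::GRanges(ch, IRanges::IRanges(starts[keep],
                                                         ends[keep]))
        out[keep] <- .trackMeanOver(q, track)
      }
      out
    }
    if (len < binsize) {
      shortSeen <- TRUE
      body <- rep(.trackMeanOver(gr[i], track), nBody)
    } else {
      edges <- round(seq(s - 1, e, length.out = nBody + 1L))
      q <- GenomicRanges::GRanges(ch, IRanges::IRanges(edges[-(nBody + 1L)] + 1L,
                                                       edges[-1]))
      body <- .trackMeanOver(q, track)
    }
    mat[i, ] <- c(mkq(upStarts), body, mkq(dnStarts))
  }
  if (shortSeen)
    message("pileupMatrix: domain(s) shorter than one bin use their overall mean")
  ord <- if (is.null(rank_values)) seq_len(n)
         else order(rank_values, decreasing = decreasing)
  mat <- mat[ord, , drop = FALSE]
  attr(mat, "order") <- ord
  attr(mat, "section") <- rep(c("upstream", "body", "downstream"),
                              c(nFlank, nBody, nFlank))
  mat
}

#' Decile analysis of one track against a covariate track
#'
#' Windows are split into ten equal-size groups by the rank of the covariate
#' (ties broken deterministically by genomic position), the value track is
#' summarised per decile, and Spearman's rank correlation is computed over
#' the individual windows (not the decile means).
#'
#' @param value_track,covariate_track [BinnedTrack]s on the same grid.
#' @return A list: `deciles` (data.frame with n, mean, median, q25, q75 per
#'   decile), `rho`, `p_value`, `n` (windows used).
#' @export
decileAnalysis <- function(value_track, covariate_track) {
  .sameGrid(value_track, covariate_track)
  v <- binValues(value_track); cv <- binValues(covariate_track)
  keep <- !is.na(v) & !is.na(cv)
  v <- v[keep]; cv <- cv[keep]
  n <- length(v)
  if (n < 10L) stop("need at least 10 windows with both values defined")
  if (diff(range(cv)) == 0)
    stop("constant covariate: decile assignment undefined")
  ord <- order(cv, seq_along(cv))       # coordinate order breaks ties
  dec <- integer(n)
  dec[ord] <- ceiling(seq_len(n) * 10 / n)
  summ <- do.call(rbind, lapply(1:10, function(d) {
    x <- v[dec == d]
    data.frame(decile = d, n = length(x), mean = mean(x),
               median = stats::median(x),
               q25 = unname(stats::quantile(x, 0.25)),
               q75 = unname(stats::quantile(x, 0.75)))
  }))
  ct <- suppressWarnings(stats::cor.test(v, cv, method = "spearman",
                                         exact = FALSE))
  list(deciles = summ, rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact hypergeometric test for association between two binary domain
#' labels (e.g. hypermethylated vs not, PMD vs HMD). The two-sided p-value
#' sums the probabilities of all tables at least as extreme as the observed
#' one; `alternative = "greater"` gives the one-sided enrichment tail.
#' A zero row or column margin carries no information: p = 1 with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts (at least one
#'   nonzero cell).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A list with `odds_ratio` (conditional MLE) and `p_value`.
#' @examples
#' fisherExact(matrix(c(60, 486, 3, 553), 2, byrow = TRUE))
#' @export
fisherExact <- function(table, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) ||
      any(table != round(table)))
    stop("table must be a 2x2 matrix of non-negative integer counts")
  if (sum(table) == 0) stop("table must have at least one nonzero cell")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("a zero margin carries no information; p = 1")
    return(list(odds_ratio = NA_real_, p_value = 1))
  }
  ft <- stats::fisher.test(table, alternative = alternative)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum comparison of two groups of domain or window values, exact for
#' small untied samples and normal-approximated with tie correction
#' otherwise. When every value in both groups is identical the test carries
#' no information and p = 1 is returned with a warning.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return A list with `statistic` (the Mann-Whitney W for group `a`) and
#'   `p_value`.
#' @export
wilcoxonRankSum <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  if (length(unique(c(a, b))) == 1L) {
    warning("all values tied across both groups; p = 1")
    return(list(statistic = length(a) * length(b) / 2, p_value = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks, with the usual large-sample
#' p-value. Constant input is signalled as an error (the rank correlation is
#' undefined).
#'
#' @param a,b Paired numeric vectors, at least 3 pairs.
#' @return A list with `rho` and `p_value`.
#' @export
spearmanCor <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3L) stop("need at least 3 complete pairs")
  if (diff(range(a)) == 0 || diff(range(b)) == 0)
    stop("constant vector: rank correlation undefined")
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Assign genes to the domains that wholly contain them
#'
#' A gene belongs to a domain only when it is fully contained in it; genes
#' straddling a domain boundary stay unassigned (`NA`).
#'
#' @param genes `GRanges` of gene intervals.
#' @param domains A [DomainSet] or `GRanges`.
#' @return Integer vector: for each gene, the index of its containing domain
#'   or `NA`.
#' @export
assignGenesToDomains <- function(genes, domains) {
  gr <- if (is(domains, "DomainSet")) domainRanges(domains) else domains
  GenomicRanges::findOverlaps(genes, gr, type = "within",
                              ignore.strand = TRUE, select = "first")
}
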