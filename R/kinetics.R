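#' @include AllClasses.R domain-analysis.R
NULL

#' Construct kinetic parameters
#'
#' @param lambda Per-day methylation loss rate (maintenance failure), >= 0.
#' @param nu Per-day de novo gain rate, >= 0. `lambda + nu` must be > 0.
#' @param m0 Initial methylation fraction in `[0, 1]`.
#' @return A [KineticParams].
#' @export
kineticParams <- function(lambda, nu, m0) {
  new("KineticParams", lambda = lambda, nu = nu, m0 = m0)
}

#' Closed-form methylation decay under maintenance loss
#'
#' Solves dm/dt = -lambda * m + nu * (1 - m): methylation decays towards the
#' plateau m_inf = nu / (lambda + nu) at combined rate lambda + nu,
#'
#'   m(t) = m_inf + (m0 - m_inf) * exp(-(lambda + nu) * t).
#'
#' With nu = 0 this is pure exponential decay, log-linear with slope -lambda
#' whatever the initial level; with nu > 0 loss is slower and the level
#' plateaus higher.
#'
#' @param params A [KineticParams].
#' @param t Numeric vector of times in days (>= 0).
#' @return Methylation fraction(s) in `[0, 1]`.
#' @examples
#' decayModel(kineticParams(0.5, 0.05, 0.8), c(0, 2, 12))
#' @export
decayModel <- function(params, t) {
  stopifnot(is(params, "KineticParams"))
  if (any(t < 0)) stop("t must be >= 0")
  rate <- params@lambda + params@nu
  minf <- params@nu / rate
  minf + (params@m0 - minf) * exp(-rate * t)
}

#' Fit the log-linear early slope and plateau of one decay series
#'
#' Ordinary least squares of log weighted mean methylation on day, using
#' only the timepoints inside `fit_window` (where the decay is approximately
#' log-linear); the final level is the value at `final_day`, falling back to
#' the last available timepoint with a message. The natural log is used, so
#' the slope is in units of 1/day.
#'
#' @param days Numeric vector of timepoints in days.
#' @param values_pct Weighted mean methylation (%) per timepoint (> 0: the
#'   log must apply).
#' @param fit_window Numeric(2) day range for the slope fit (default 0-6).
#' @param final_day Day whose value is reported as the final level.
#' @param domain_id Identifier carried into the result.
#' @return A [KineticsFit].
#' @export
fitDecay <- function(days, values_pct, fit_window = c(0, 6), final_day = 12,
                     domain_id = "domain") {
  stopifnot(length(days) == length(values_pct))
  if (any(values_pct <= 0, na.rm = TRUE))
    stop("non-positive methylation value: domain must be excluded before fitting")
  inWin <- days >= fit_window[1] & days <= fit_window[2] & !is.na(values_pct)
  if (sum(inWin) < 3L)
    stop("need at least 3 timepoints inside the fit window")
  fit <- stats::lm(log(values_pct[inWin]) ~ days[inWin])
  co <- stats::coef(fit)
  if (final_day %in% days && !is.na(values_pct[match(final_day, days)])) {
    final <- values_pct[match(final_day, days)]
  } else {
    lastIdx <- max(which(!is.na(values_pct)))
    final <- values_pct[lastIdx]
    message(sprintf("fitDecay(%s): day %g absent; final level taken at day %g",
                    domain_id, final_day, days[lastIdx]))
  }
  new("KineticsFit", domainId = domain_id, slope = unname(co[2]),
      intercept = unname(co[1]), finalLevel = final,
      fitWindow = as.numeric(fit_window))
}

#' Fit decay kinetics for every domain of a long-format time course
#'
#' Applies [fitDecay()] per domain; domains with any non-positive
#' methylation value are excluded with a message.
#'
#' @param timecourse data.frame with columns `domain_id`, `day`,
#'   `weighted_mean_pct` (and optionally `class`, carried through).
#' @inheritParams fitDecay
#' @return A list: `fits` (named list of [KineticsFit]), `excluded`
#'   (character vector of domain ids), `class` (named character vector when
#'   a `class` column was present).
#' @export
fitDecayByDomain <- function(timecourse, fit_window = c(0, 6),
                             final_day = 12) {
  stopifnot(all(c("domain_id", "day", "weighted_mean_pct") %in%
                names(timecourse)))
  ids <- unique(timecourse$domain_id)
  fits <- list(); excluded <- character()
  classes <- character()
  for (id in ids) {
    sub <- timecourse[timecourse$domain_id == id, ]
    if (any(sub$weighted_mean_pct <= 0, na.rm = TRUE)) {
      excluded <- c(excluded, id)
      next
    }
    fits[[id]] <- fitDecay(sub$day, sub$weighted_mean_pct,
                           fit_window = fit_window, final_day = final_day,
                           domain_id = id)
    if ("class" %in% names(sub)) classes[id] <- as.character(sub$class[1])
  }
  if (length(excluded))
    message(sprintf("fitDecayByDomain: %d domain(s) with non-positive values excluded",
                    length(excluded)))
  list(fits = fits, excluded = excluded,
       class = if (length(classes)) classes else NULL)
}

#' Compare decay kinetics between domain classes
#'
#' Summarises fitted slopes and final levels per class (median) and runs a
#' two-sided Wilcoxon rank-sum test for every pair of classes, on both
#' quantities. Classes with no fits are skipped with a warning; single-
#' domain classes are summarised but flagged.
#'
#' @param fits_by_class Named list mapping class to a list of [KineticsFit].
#' @return A list: `summary` (data.frame of class, n, median_slope,
#'   median_final) and `tests` (data.frame of pairwise comparisons with
#'   p-values for slope and final level).
#' @export
compareClasses <- function(fits_by_class) {
  n0 <- vapply(fits_by_class, length, 0L)
  if (any(n0 == 0L)) {
    warning(sprintf("empty class(es) skipped: %s",
                    paste(names(fits_by_class)[n0 == 0L], collapse = ", ")))
    fits_by_class <- fits_by_class[n0 > 0L]
  }
  if (length(fits_by_class) < 2L) stop("need at least 2 non-empty classes")
  # locale-independent class order keeps reports byte-identical across runs
  fits_by_class <- fits_by_class[order(names(fits_by_class),
                                       method = "radix")]
  slope <- lapply(fits_by_class, function(l)
    vapply(l, function(f) f@slope, 0))
  final <- lapply(fits_by_class, function(l)
    vapply(l, function(f) f@finalLevel, 0))
  if (any(vapply(slope, length, 0L) == 1L))
    warning("class(es) with a single domain: tests on them are uninformative")
  summ <- data.frame(class = names(fits_by_class),
                     n = vapply(slope, length, 0L),
                     median_slope = vapply(slope, stats::median, 0),
                     median_final = vapply(final, stats::median, 0),
                     row.names = NULL)
  pairs <- utils::combn(names(fits_by_class), 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    data.frame(class_a = a, class_b = b,
               p_slope = wilcoxonRankSum(slope[[a]], slope[[b]])$p_value,
               p_final = wilcoxonRankSum(final[[a]], final[[b]])$p_value)
  }))
  list(summary = summ, tests = tests)
}
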