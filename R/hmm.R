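#' @include AllClasses.R tracks-io.R
NULL

# Two-state Gaussian HMM on window values. Emissions are Gaussian on the
# window summary (methylation % or IP/IN ratio) rather than on read counts:
# at the 1-3x coverages typical of domain-level WGBS the window mean is the
# stable observable, and the two-mode structure of the methylome lives at
# window resolution. Missing windows (NA) carry no emission term: they are
# bridged by transition-only propagation so a run of missing data never
# splits a domain by itself.

.splitBySeq <- function(track) {
  sq <- as.character(GenomicRanges::seqnames(binWindows(track)))
  split(binValues(track), factor(sq, levels = unique(sq)))
}

# log N(x | mean, var) matrix for one sequence; NA rows become 0 (= bridge).
.logEmissions <- function(x, means, vars) {
  le <- vapply(1:2, function(s)
    stats::dnorm(x, means[s], sqrt(vars[s]), log = TRUE), numeric(length(x)))
  le <- matrix(le, ncol = 2L)
  le[is.na(x), ] <- 0
  le
}

# Scaled forward-backward for one sequence. Returns per-position posteriors
# (gamma), pairwise posteriors summed over positions (xi_sum), and loglik.
.forwardBackward <- function(le, trans, init) {
  n <- nrow(le)
  B <- exp(le - apply(le, 1, max))      # row-rescaled emission likelihoods
  maxle <- apply(le, 1, max)
  alpha <- matrix(0, n, 2); beta <- matrix(0, n, 2); cvec <- numeric(n)
  a <- init * B[1, ]
  cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
  if (n > 1) for (t in 2:n) {
    a <- (alpha[t - 1, ] %*% trans) * B[t, ]
    cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
  }
  beta[n, ] <- 1
  if (n > 1) for (t in (n - 1):1)
    beta[t, ] <- (trans %*% (B[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, 2, 2)
  if (n > 1) for (t in 1:(n - 1)) {
    x <- trans * outer(alpha[t, ], B[t + 1, ] * beta[t + 1, ]) / cvec[t + 1]
    xi <- xi + x
  }
  list(gamma = gamma, xi = xi, loglik = sum(log(cvec)) + sum(maxle))
}

#' Fit a two-state Gaussian hidden Markov model to a binned track
#'
#' Baum-Welch maximum-likelihood estimation of a two-state HMM with Gaussian
#' emissions on the window values. Chromosomes are treated as independent
#' sequences sharing one parameter set. Initialisation is k-means (k = 2) on
#' the non-missing values with heavily diagonal transitions; iteration stops
#' when the relative log-likelihood improvement falls below `tol`. State 1 is
#' relabelled to the lower-mean state on return.
#'
#' Degenerate inputs (all non-missing values identical, or effectively a
#' single mode with zero spread) are flagged rather than fitted.
#'
#' @param track A [BinnedTrack] with at least 100 non-missing windows (fewer
#'   is allowed but warned about).
#' @param max_iter Maximum Baum-Welch iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param seed Integer seed for the k-means initialisation.
#' @return An [HmmParams]; inspect `@degenerate` before decoding.
#' @export
fitTwoStateHMM <- function(track, max_iter = 200L, tol = 1e-4, seed = 1L) {
  seqs <- .splitBySeq(track)
  obs <- unlist(seqs, use.names = FALSE)
  obs <- obs[!is.na(obs)]
  if (length(obs) < 100L)
    warning("fewer than 100 non-missing windows; estimates may be unstable")
  degenerateParams <- function(mu) {
    new("HmmParams", means = c(mu, mu), variances = c(1, 1),
        transition = matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE),
        init = c(0.5, 0.5), logLik = NA_real_, logLikTrace = numeric(),
        nIter = 0L, degenerate = TRUE)
  }
  if (length(obs) == 0L) return(degenerateParams(NA_real_))
  if (diff(range(obs)) < sqrt(.Machine$double.eps))
    return(degenerateParams(obs[1]))
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  km <- stats::kmeans(obs, centers = 2L, nstart = 5L)
  if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv)
  ord <- order(km$centers)
  means <- as.numeric(km$centers)[ord]
  vars <- vapply(ord, function(k) {
    v <- stats::var(obs[km$cluster == k])
    if (!is.finite(v) || v < 1e-6) v <- max(1e-6, 1e-4 * diff(range(obs))^2)
    v
  }, 0)
  trans <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE)
  init <- c(0.5, 0.5)
  ll_old <- -Inf; iter <- 0L; ll <- NA_real_; llTrace <- numeric()
  repeat {
    iter <- iter + 1L
    stats_acc <- list(g1 = 0, gx = c(0, 0), gx2 = c(0, 0),
                      xi = matrix(0, 2, 2), init = c(0, 0), ll = 0)
    for (x in seqs) {
      if (!length(x)) next
      fb <- .forwardBackward(.logEmissions(x, means, vars), trans, init)
      ok <- !is.na(x)     # emission updates use observed windows only
      stats_acc$gx <- stats_acc$gx + colSums(fb$gamma[ok, , drop = FALSE] * x[ok])
      stats_acc$gx2 <- stats_acc$gx2 +
        colSums(fb$gamma[ok, , drop = FALSE] * x[ok]^2)
      stats_acc$g1 <- stats_acc$g1 + colSums(fb$gamma[ok, , drop = FALSE])
      stats_acc$xi <- stats_acc$xi + fb$xi
      stats_acc$init <- stats_acc$init + fb$gamma[1, ]
      stats_acc$ll <- stats_acc$ll + fb$loglik
    }
    ll <- stats_acc$ll
    llTrace <- c(llTrace, ll)
    means_new <- stats_acc$gx / stats_acc$g1
    vars_new <- pmax(stats_acc$gx2 / stats_acc$g1 - means_new^2, 1e-6)
    trans_new <- stats_acc$xi / rowSums(stats_acc$xi)
    trans_new[!is.finite(trans_new)] <- 0.5
    init_new <- stats_acc$init / sum(stats_acc$init)
    converged <- is.finite(ll_old) &&
      abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-12)
    means <- means_new; vars <- vars_new; trans <- trans_new; init <- init_new
    ll_old <- ll
    if (converged || iter >= max_iter) break
  }
  ord <- order(means)
  new("HmmParams", means = means[ord], variances = vars[ord],
      transition = trans[ord, ord, drop = FALSE], init = init[ord],
      logLik = ll, logLikTrace = llTrace, nIter = iter, degenerate = FALSE)
}

# Viterbi for one numeric sequence; returns integer states (1 = low mean).
.viterbiSeq <- function(x, params) {
  n <- length(x)
  if (n == 0L) return(integer())
  le <- .logEmissions(x, params@means, params@variances)
  lt <- log(pmax(params@transition, 1e-300))
  delta <- matrix(-Inf, n, 2); psi <- matrix(1L, n, 2)
  delta[1, ] <- log(pmax(params@init, 1e-300)) + le[1, ]
  if (n > 1) for (t in 2:n) for (s in 1:2) {
    cand <- delta[t - 1, ] + lt[, s]
    psi[t, s] <- which.max(cand)
    delta[t, s] <- cand[psi[t, s]] + le[t, s]
  }
  states <- integer(n)
  states[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) states[t] <- psi[t + 1, states[t + 1]]
  states
}

#' Viterbi decoding of a binned track
#'
#' Computes the jointly most probable state path per chromosome under fitted
#' [HmmParams]. Missing windows contribute no emission term and are assigned
#' the state favoured by the transitions alone, so runs of missing data are
#' bridged rather than splitting domains.
#'
#' @param track A [BinnedTrack].
#' @param params An [HmmParams] from [fitTwoStateHMM()].
#' @return Integer vector of states (1 = lower-mean state), one per window.
#' @export
viterbiDecode <- function(track, params) {
  if (params@degenerate)
    stop("cannot decode with degenerate HmmParams; input had no two-state structure")
  unlist(lapply(.splitBySeq(track), .viterbiSeq, params = params),
         use.names = FALSE)
}
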