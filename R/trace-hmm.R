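# Two-state Gaussian HMM segmentation of live-cell transcription traces
# and dwell-time summaries. The EM (Baum-Welch), Viterbi and posterior
# computations are implemented here with per-trace scaled forward-backward
# recursions, pooling all traces of a population into one model.

gaussDens <- function(y, mean, sd) {
  stats::dnorm(y, mean, sd)
}

# scaled forward-backward for one trace; dens is T x 2 emission densities
forwardBackward <- function(dens, A, pi0) {
  T <- nrow(dens)
  alpha <- matrix(0, T, 2)
  beta <- matrix(0, T, 2)
  cscale <- numeric(T)
  a <- pi0 * dens[1, ]
  cscale[1] <- sum(a)
  alpha[1, ] <- a / cscale[1]
  for (t in 2:T) {
    a <- (alpha[t - 1, ] %*% A)[1, ] * dens[t, ]
    cscale[t] <- sum(a)
    if (cscale[t] <= 0 || !is.finite(cscale[t])) {
      stop("numerical underflow in forward recursion: ",
           "emission parameters degenerate")
    }
    alpha[t, ] <- a / cscale[t]
  }
  beta[T, ] <- 1
  for (t in (T - 1):1) {
    b <- A %*% (dens[t + 1, ] * beta[t + 1, ])
    beta[t, ] <- b[, 1] / cscale[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(alpha = alpha, beta = beta, gamma = gamma, cscale = cscale,
       logLik = sum(log(cscale)))
}

#' Fit a two-state Gaussian HMM to pooled intensity traces
#'
#' Maximizes the joint likelihood of all traces in the set via
#' Baum-Welch EM with a shared 2x2 transition matrix, shared Gaussian
#' emissions and shared initial distribution (one model per population,
#' which stabilizes emission estimates relative to per-trace fits).
#' Emission parameters are initialized by thresholding the pooled
#' intensities at their 70th percentile, falling back to k-means when the
#' threshold split is degenerate. Convergence when the log-likelihood
#' improvement drops below `tol` (default 1e-6) or after `maxIter`
#' (default 500) iterations. The state with the larger emission mean is
#' labelled active (state 2). The fit is deterministic given its inputs.
#'
#' @param traceSet a [TraceSet] (one population).
#' @param maxIter maximum EM iterations.
#' @param tol absolute log-likelihood improvement declaring convergence.
#'
#' @return a [TelegraphHMM].
#' @export
fitTelegraphHMM <- function(traceSet, maxIter = 500L, tol = 1e-6) {
  tr <- traces(traceSet)
  if (nrow(tr) < 10L) stop("need at least 10 frames in total")
  ys <- lapply(split(tr[order(tr$frame), c("frame", "intensity")],
                     tr$allele_id[order(tr$frame)]),
               function(d) d$intensity[order(d$frame)])
  pooled <- unlist(ys, use.names = FALSE)
  if (stats::sd(pooled) == 0) {
    stop("traces have zero variance: emissions unidentifiable")
  }

  # initialization: 70th-percentile threshold, k-means fallback
  thr <- stats::quantile(pooled, 0.7, names = FALSE)
  hi <- pooled > thr
  if (sum(hi) >= 2L && sum(!hi) >= 2L &&
      stats::sd(pooled[hi]) > 0 && stats::sd(pooled[!hi]) > 0) {
    means <- c(mean(pooled[!hi]), mean(pooled[hi]))
    sds <- c(stats::sd(pooled[!hi]), stats::sd(pooled[hi]))
  } else {
    km <- stats::kmeans(pooled, centers = range(pooled))
    ord <- order(km$centers)
    means <- as.numeric(km$centers[ord])
    sds <- vapply(ord, function(k) {
      v <- pooled[km$cluster == k]
      max(stats::sd(v), 1e-6 * diff(range(pooled)))
    }, numeric(1))
  }
  sdFloor <- 1e-4 * diff(range(pooled))
  sds <- pmax(sds, sdFloor)
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  pi0 <- c(0.5, 0.5)

  logLik <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    gSum <- numeric(2)          # sum of gamma over all frames
    gFirst <- numeric(2)        # gamma at t = 1, summed over traces
    xiSum <- matrix(0, 2, 2)    # expected transition counts
    gTransFrom <- numeric(2)    # gamma summed over t = 1..T-1
    m1 <- numeric(2)            # sum gamma * y
    m2 <- numeric(2)            # sum gamma * y^2
    ll <- 0
    for (y in ys) {
      dens <- cbind(gaussDens(y, means[1], sds[1]),
                    gaussDens(y, means[2], sds[2]))
      dens <- pmax(dens, 1e-300)
      fb <- forwardBackward(dens, A, pi0)
      T <- length(y)
      ll <- ll + fb$logLik
      gSum <- gSum + colSums(fb$gamma)
      gFirst <- gFirst + fb$gamma[1, ]
      gTransFrom <- gTransFrom + colSums(fb$gamma[-T, , drop = FALSE])
      # xi_t(i,j) proportional to alpha_t(i) A_ij dens_{t+1}(j) beta_{t+1}(j)
      for (i in 1:2) {
        for (j in 1:2) {
          xiSum[i, j] <- xiSum[i, j] +
            sum(fb$alpha[-T, i] * A[i, j] * dens[-1, j] * fb$beta[-1, j] /
                  fb$cscale[-1])
        }
      }
      m1 <- m1 + colSums(fb$gamma * y)
      m2 <- m2 + colSums(fb$gamma * y^2)
    }
    A <- xiSum / gTransFrom
    A <- A / rowSums(A)
    pi0 <- gFirst / sum(gFirst)
    means <- m1 / gSum
    sds <- pmax(sqrt(pmax(m2 / gSum - means^2, 0)), sdFloor)
    if (is.finite(logLik) && ll - logLik < tol) {
      logLik <- ll
      converged <- TRUE
      break
    }
    logLik <- ll
  }

  # active = larger emission mean
  ord <- order(means)
  methods::new("TelegraphHMM",
    transition = A[ord, ord], means = means[ord], sds = sds[ord],
    initProb = pi0[ord], logLik = logLik, nIter = iter,
    converged = converged
  )
}

#' Decode traces into active/inactive state sequences
#'
#' Viterbi decoding (hard states, so dwell statistics operate on
#' contiguous runs) plus per-frame posterior probabilities of the active
#' state from the scaled forward-backward recursions.
#'
#' @param traceSet a [TraceSet].
#' @param hmm a fitted [TelegraphHMM].
#'
#' @return data.frame `allele_id`, `frame`, `state` (0 inactive,
#'   1 active), `posterior_active` (in `[0, 1]`).
#' @export
decodeStates <- function(traceSet, hmm) {
  if (any(!is.finite(hmm@means)) || any(!is.finite(hmm@sds)) ||
      any(hmm@sds <= 0)) {
    stop("degenerate emission parameters")
  }
  tr <- traces(traceSet)
  A <- hmm@transition
  logA <- log(pmax(A, 1e-300))
  out <- lapply(split(tr, tr$allele_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    y <- d$intensity
    T <- length(y)
    dens <- cbind(gaussDens(y, hmm@means[1], hmm@sds[1]),
                  gaussDens(y, hmm@means[2], hmm@sds[2]))
    dens <- pmax(dens, 1e-300)
    logDens <- log(dens)
    # Viterbi
    delta <- matrix(-Inf, T, 2)
    psi <- matrix(0L, T, 2)
    delta[1, ] <- log(pmax(hmm@initProb, 1e-300)) + logDens[1, ]
    for (t in 2:T) {
      for (j in 1:2) {
        v <- delta[t - 1, ] + logA[, j]
        psi[t, j] <- which.max(v)
        delta[t, j] <- v[psi[t, j]] + logDens[t, j]
      }
    }
    path <- integer(T)
    path[T] <- which.max(delta[T, ])
    for (t in (T - 1):1) path[t] <- psi[t + 1, path[t + 1]]
    fb <- forwardBackward(dens, A, hmm@initProb)
    data.frame(
      allele_id = d$allele_id, frame = d$frame,
      state = path - 1L, posterior_active = fb$gamma[, 2],
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract dwell times from decoded state sequences
#'
#' Maximal runs of constant state are converted to minutes
#' (`frames * dt / 60`). Runs touching either boundary of a trace are
#' censored -- their true duration is unknown -- and are excluded from the
#' medians (including them would bias long OFF times downward); their
#' count is reported. A trace with no state change contributes a single
#' censored run.
#'
#' @param states decoded data.frame from [decodeStates()] (or any
#'   `allele_id`/`frame`/`state` table, e.g. simulation ground truth).
#' @param dt frame interval in seconds (default 100).
#'
#' @return list: `dwells` (data.frame `allele_id`, `state`, `frames`,
#'   `minutes`, `censored`), `median_active`, `median_inactive` (minutes,
#'   uncensored only), `n_censored_excluded`.
#' @export
extractDwells <- function(states, dt = 100) {
  assertScalar(dt, "dt", positive = TRUE)
  out <- lapply(split(states, states$allele_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    r <- rle(d$state)
    n <- length(r$lengths)
    cens <- rep(FALSE, n)
    cens[1L] <- TRUE
    cens[n] <- TRUE
    data.frame(
      allele_id = d$allele_id[1], state = r$values,
      frames = r$lengths, minutes = r$lengths * dt / 60,
      censored = cens, stringsAsFactors = FALSE
    )
  })
  dw <- do.call(rbind, out)
  rownames(dw) <- NULL
  unc <- dw[!dw$censored, , drop = FALSE]
  medFor <- function(s) {
    v <- unc$minutes[unc$state == s]
    if (length(v)) stats::median(v) else NA_real_
  }
  list(
    dwells = dw,
    median_active = medFor(1L),
    median_inactive = medFor(0L),
    n_censored_excluded = sum(dw$censored)
  )
}

#' Empirical cumulative distribution of dwell durations
#'
#' @param minutes numeric vector of (uncensored) dwell durations in
#'   minutes; must be non-empty.
#'
#' @return data.frame `minutes` (sorted unique durations) and `cdf`
#'   (fraction of dwells with duration at most that value).
#' @export
dwellCDF <- function(minutes) {
  if (length(minutes) == 0L) stop("no dwells: CDF undefined")
  u <- sort(unique(minutes))
  data.frame(minutes = u,
             cdf = vapply(u, function(q) mean(minutes <= q), numeric(1)))
}

#' Mean dwell times implied by a fitted HMM's transition matrix
#'
#' For a discrete-time two-state chain the mean dwell in a state is
#' `1 / P(leave)` frames; converted to minutes with the frame interval.
#'
#' @param hmm a [TelegraphHMM].
#' @param dt frame interval in seconds (default 100).
#'
#' @return named numeric: mean `inactive` and `active` dwell (minutes).
#' @export
hmmDwellMeans <- function(hmm, dt = 100) {
  A <- hmm@transition
  c(inactive = 1 / A[1, 2] * dt / 60,
    active = 1 / A[2, 1] * dt / 60)
}
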