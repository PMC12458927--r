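# Two-state relaxation-to-equilibrium model for sorted populations.
#
# Cells switch between a transcriptionally active and an inactive state
# with rates kon (inactive -> active) and koff (active -> inactive), in
# units of per day. The active fraction A obeys
#   dA/dt = kon (1 - A) - koff A = kon - (kon + koff) A,
# so A relaxes exponentially at rate lambda = kon + koff toward the
# equilibrium A_eq = kon / (kon + koff):
#   A(t) = A_eq + (A0 - A_eq) exp(-lambda (t - t0)).

#' Equilibrium active fraction of the two-state model
#'
#' @param kon,koff switching rates (per day), non-negative with
#'   `kon + koff > 0`.
#' @return `kon / (kon + koff)`.
#' @examples
#' aEq(0.052, 0.2385)   # ~0.179, i.e. 17.9% transcribing at equilibrium
#' @export
aEq <- function(kon, koff) {
  if (any(kon < 0) || any(koff < 0)) stop("rates must be >= 0")
  if (any(kon + koff == 0)) stop("kon + koff must be > 0")
  kon / (kon + koff)
}

#' Relaxation of the active fraction toward equilibrium
#'
#' Evaluates `A(t) = aEq + (a0 - aEq) exp(-lambda (t - t0))`, the solution
#' of `dA/dt = kon - (kon + koff) A` with `A(t0) = a0`. Monotone in `t`
#' and confined between `a0` and `aEq`.
#'
#' @param t time(s) in days, `t >= t0`.
#' @param t0 sorting time (days).
#' @param a0 initial active fraction at `t0`, in `[0, 1]` (vectorized).
#' @param aEq equilibrium active fraction, in `[0, 1]`.
#' @param lambda relaxation rate `kon + koff` (per day), `> 0`.
#' @return active fraction(s) at `t`.
#' @export
relaxFraction <- function(t, t0 = 0, a0, aEq, lambda) {
  assertScalar(lambda, "lambda", positive = TRUE)
  if (any(t < t0)) stop("'t' must be >= t0")
  if (any(a0 < 0 | a0 > 1) || any(aEq < 0 | aEq > 1)) {
    stop("fractions must be in [0, 1]")
  }
  aEq + (a0 - aEq) * exp(-lambda * (t - t0))
}

#' Mean residence time of an exponential state
#'
#' The mean time spent in a state left at rate `k` is `1 / k`; e.g. an
#' activation rate of 0.052 per day corresponds to a mean residence of
#' about 19.2 days in the repressed state.
#'
#' @param k switching rate (per day), `> 0`.
#' @return mean residence time in days.
#' @export
meanResidenceTime <- function(k) {
  assertScalar(k, "k", positive = TRUE)
  1 / k
}

#' Time for the relaxation to come within a tolerance of equilibrium
#'
#' Smallest `t - t0` with `|A(t) - aEq| <= tol`, i.e.
#' `log(|a0 - aEq| / tol) / lambda`, floored at 0 (a population starting
#' at, or within `tol` of, equilibrium needs no time).
#'
#' @param a0 initial active fraction.
#' @param aEq equilibrium active fraction.
#' @param lambda relaxation rate (per day), `> 0`.
#' @param tol convergence tolerance on the fraction, `> 0`.
#' @return days after `t0`.
#' @export
timeToEquilibrium <- function(a0, aEq, lambda, tol) {
  assertScalar(lambda, "lambda", positive = TRUE)
  assertScalar(tol, "tol", positive = TRUE)
  gap <- abs(a0 - aEq)
  if (gap <= tol) return(0)
  log(gap / tol) / lambda
}

checkTrajectories <- function(traj) {
  need <- c("population", "day", "fraction_transcribing", "replicate")
  if (!all(need %in% names(traj))) {
    stop("trajectories need columns: ", paste(need, collapse = ", "))
  }
  if (any(traj$fraction_transcribing < 0 | traj$fraction_transcribing > 1)) {
    stop("fractions must be in [0, 1]")
  }
  nDays <- tapply(traj$day, traj$population, function(d) length(unique(d)))
  if (any(nDays < 2L)) {
    stop("each population needs observations on >= 2 distinct days")
  }
  invisible(traj)
}

rssRelax <- function(lambda, aEqVal, a0, traj, t0, weights = NULL) {
  pred <- aEqVal + (a0[traj$population] - aEqVal) *
    exp(-lambda * (traj$day - t0))
  r <- traj$fraction_transcribing - pred
  if (is.null(weights)) sum(r^2) else sum(weights * r^2)
}

#' Jointly fit the relaxation model to sorted-population trajectories
#'
#' Minimizes the summed squared residuals of the relaxation solution over
#' all observations of all populations, which share `lambda` and `aEq`
#' while each population has its own initial fraction `A0`. In
#' `"fitted_equilibrium"` mode `aEq` is a free parameter; in
#' `"fixed_equilibrium"` mode it is held at `aEqFixed` (default 0.20, the
#' bulk-population equilibrium). `kon` and `koff` are derived from the fit
#' as `kon = aEq * lambda`, `koff = lambda - kon`.
#'
#' Optimization is multi-start box-constrained L-BFGS-B (`lambda` in
#' `[1e-4, 10]` per day, fractions in `[0, 1]`): `nStarts` initial
#' `lambda` values drawn log-uniformly on `(0.01, 2)` per day under a
#' fixed seed, with fraction starts jittered around empirical values; the
#' best converged start is returned with per-start diagnostics.
#'
#' By default the loss is unweighted least squares on fractions; with
#' `weightByCells = TRUE` residuals are weighted by the inverse binomial
#' variance implied by the `n_cells` column.
#'
#' @param traj data.frame with columns `population`, `day`,
#'   `fraction_transcribing`, `replicate` (and `n_cells` if weighting);
#'   at least two populations, each with two or more distinct days.
#' @param mode `"fitted_equilibrium"` (default) or `"fixed_equilibrium"`.
#' @param aEqFixed equilibrium used in fixed mode (default 0.20).
#' @param t0 sorting day (default 0).
#' @param nStarts number of multi-start initializations (default 20).
#' @param seed seed for the start draws (default 1).
#' @param weightByCells use inverse binomial-variance weights.
#'
#' @return a [TwoStateFit].
#' @export
fitRelaxation <- function(traj, mode = c("fitted_equilibrium",
                                         "fixed_equilibrium"),
                          aEqFixed = 0.20, t0 = 0, nStarts = 20L,
                          seed = 1L, weightByCells = FALSE) {
  mode <- match.arg(mode)
  checkTrajectories(traj)
  pops <- sort(unique(traj$population))
  if (length(pops) < 2L) {
    stop("joint fit needs >= 2 populations sharing lambda and aEq")
  }
  if (stats::var(traj$fraction_transcribing) == 0) {
    stop("all observations share one value: lambda is unidentifiable")
  }
  weights <- NULL
  if (weightByCells) {
    if (!"n_cells" %in% names(traj)) stop("weighting needs an n_cells column")
    p <- pmin(pmax(traj$fraction_transcribing, 1e-3), 1 - 1e-3)
    weights <- traj$n_cells / (p * (1 - p))
  }

  fitted <- mode == "fitted_equilibrium"
  # empirical anchors for starts
  firstDay <- min(traj$day)
  lastDay <- max(traj$day)
  a0Emp <- vapply(pops, function(p) {
    d <- traj[traj$population == p, ]
    mean(d$fraction_transcribing[d$day == min(d$day)])
  }, numeric(1))
  aEqEmp <- mean(traj$fraction_transcribing[traj$day == lastDay])

  obj <- function(theta) {
    lambda <- theta[1]
    aEqVal <- if (fitted) theta[2] else aEqFixed
    a0 <- theta[(if (fitted) 3 else 2):length(theta)]
    names(a0) <- pops
    rssRelax(lambda, aEqVal, a0, traj, t0, weights)
  }
  lower <- c(1e-4, if (fitted) 0, rep(0, length(pops)))
  upper <- c(10, if (fitted) 1, rep(1, length(pops)))

  starts <- withSeed(seed, {
    lapply(seq_len(nStarts), function(i) {
      lambda0 <- exp(stats::runif(1, log(0.01), log(2)))
      jit <- function(v) pmin(pmax(v + stats::rnorm(length(v), 0, 0.05),
                                   1e-3), 1 - 1e-3)
      c(lambda0, if (fitted) jit(aEqEmp), jit(a0Emp))
    })
  })

  best <- NULL
  diag <- data.frame(start = seq_len(nStarts), rss = NA_real_,
                     convergence = NA_integer_)
  for (i in seq_len(nStarts)) {
    res <- tryCatch(
      stats::optim(starts[[i]], obj, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(factr = 10, maxit = 1000)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    diag$rss[i] <- res$value
    diag$convergence[i] <- res$convergence
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimization starts failed")

  lambda <- best$par[1]
  aEqVal <- if (fitted) best$par[2] else aEqFixed
  a0 <- best$par[(if (fitted) 3 else 2):length(best$par)]
  names(a0) <- pops
  kon <- aEqVal * lambda
  koff <- lambda - kon
  methods::new("TwoStateFit",
    kon = kon, koff = koff, lambda = lambda, aEq = aEqVal, a0 = a0,
    t0 = t0, rss = best$value, mode = mode,
    diagnostics = list(starts = diag, nObs = nrow(traj),
                       weighted = weightByCells)
  )
}

#' Predicted relaxation curves from a fit
#'
#' @param fit a [TwoStateFit].
#' @param days numeric vector of days to evaluate.
#' @return data.frame `population`, `day`, `fraction_transcribing`.
#' @export
predictRelaxation <- function(fit, days) {
  out <- expand.grid(day = days, population = names(fit@a0),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$fraction_transcribing <- relaxFraction(
    out$day, t0 = fit@t0, a0 = fit@a0[out$population],
    aEq = fit@aEq, lambda = fit@lambda
  )
  out[, c("population", "day", "fraction_transcribing")]
}

#' Bootstrap confidence intervals for the relaxation fit
#'
#' Percentile bootstrap by sampling with replacement from the data
#' trajectories: by default the resampling unit is the replicate
#' measurement within each (population, day) cell, so every day remains
#' represented; with `unit = "trajectory"` whole replicate trajectories
#' are resampled instead (a resample leaving a population with fewer than
#' two distinct days is redrawn, at most 100 times). Each resample is
#' refit -- starting from the point estimate plus a small number of
#' perturbed starts -- and the 2.5/97.5 percentiles of every parameter
#' are reported. Seeded and reproducible.
#'
#' @param traj trajectory data.frame (see [fitRelaxation()]).
#' @param mode,aEqFixed,t0,weightByCells passed to [fitRelaxation()].
#' @param nBoot number of bootstrap resamples (>= 100).
#' @param seed RNG seed.
#' @param unit `"replicate"` (default) or `"trajectory"`.
#'
#' @return a [TwoStateFit] (the point fit) whose `ci` slot holds 95%
#'   intervals for `lambda`, `aEq`, `kon`, `koff` and each `a0`; the
#'   bootstrap parameter draws are kept in `diagnostics$bootstrap`.
#' @export
bootstrapRelaxationCI <- function(traj, mode = c("fitted_equilibrium",
                                                 "fixed_equilibrium"),
                                  aEqFixed = 0.20, t0 = 0, nBoot = 1000L,
                                  seed = 1L, unit = c("replicate",
                                                      "trajectory"),
                                  weightByCells = FALSE) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  if (nBoot < 100L) stop("'nBoot' must be >= 100")
  checkTrajectories(traj)
  fit <- fitRelaxation(traj, mode, aEqFixed = aEqFixed, t0 = t0,
                       seed = childSeed(seed, 0L),
                       weightByCells = weightByCells)
  pops <- names(fit@a0)

  cellKey <- interaction(traj$population, traj$day, drop = TRUE)
  cells <- split(seq_len(nrow(traj)), cellKey)

  refit <- function(d, bootSeed) {
    # warm starts around the point estimate keep the bootstrap cheap
    startList <- withSeed(bootSeed, {
      base <- c(fit@lambda,
                if (mode == "fitted_equilibrium") fit@aEq,
                fit@a0)
      lapply(0:2, function(k) {
        if (k == 0) return(base)
        jit <- base * exp(stats::rnorm(length(base), 0, 0.2))
        pmin(pmax(jit, 1e-4), c(10, rep(1, length(base) - 1)))
      })
    })
    fitted <- mode == "fitted_equilibrium"
    obj <- function(theta) {
      lambda <- theta[1]
      aEqVal <- if (fitted) theta[2] else aEqFixed
      a0 <- theta[(if (fitted) 3 else 2):length(theta)]
      names(a0) <- pops
      rssRelax(lambda, aEqVal, a0, d, t0)
    }
    lower <- c(1e-4, if (fitted) 0, rep(0, length(pops)))
    upper <- c(10, if (fitted) 1, rep(1, length(pops)))
    best <- NULL
    for (s in startList) {
      res <- tryCatch(
        stats::optim(s, obj, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(factr = 1e3,
                                                   maxit = 500)),
        error = function(e) NULL
      )
      if (!is.null(res) && (is.null(best) || res$value < best$value)) {
        best <- res
      }
    }
    if (is.null(best)) return(NULL)
    lambda <- best$par[1]
    aEqVal <- if (fitted) best$par[2] else aEqFixed
    a0 <- best$par[(if (fitted) 3 else 2):length(best$par)]
    c(lambda = lambda, aEq = aEqVal, kon = aEqVal * lambda,
      koff = lambda - aEqVal * lambda,
      stats::setNames(a0, paste0("a0_", pops)))
  }

  draws <- withSeed(childSeed(seed, 1L), {
    reps <- vector("list", nBoot)
    for (b in seq_len(nBoot)) {
      if (unit == "replicate") {
        idx <- unlist(lapply(cells, function(ix) {
          ix[sample.int(length(ix), length(ix), replace = TRUE)]
        }), use.names = FALSE)
        d <- traj[idx, , drop = FALSE]
      } else {
        repIds <- unique(traj$replicate)
        for (try in seq_len(100L)) {
          pick <- sample(repIds, length(repIds), replace = TRUE)
          d <- do.call(rbind, lapply(seq_along(pick), function(i) {
            di <- traj[traj$replicate == pick[i], , drop = FALSE]
            di$replicate <- i
            di
          }))
          nDays <- tapply(d$day, d$population,
                          function(x) length(unique(x)))
          if (length(nDays) == length(pops) && all(nDays >= 2L)) break
          if (try == 100L) stop("could not draw a valid resample")
        }
      }
      reps[[b]] <- refit(d, childSeed(seed, b + 1L))
    }
    do.call(rbind, reps)
  })

  ci <- lapply(colnames(draws), function(p) {
    unname(stats::quantile(draws[, p], c(0.025, 0.975), na.rm = TRUE))
  })
  names(ci) <- colnames(draws)
  fit@ci <- ci
  fit@diagnostics$bootstrap <- draws
  fit@diagnostics$nBoot <- nBoot
  fit
}
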