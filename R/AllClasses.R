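#' @import methods
NULL

#' SpotTable: localized smFISH spots with cell and compartment assignment
#'
#' Container for sub-pixel spot localizations from one imaging field.
#' Positions are 0-based (row, col) pixel-center coordinates; intensities
#' are background-subtracted integrated intensities in arbitrary units.
#' `cell_id` and `compartment` are filled by [assignCompartment()] when
#' label masks are available; before that they are `NA`.
#'
#' @slot spots data.frame with columns `channel` ("exon" or "intron"),
#'   `x`, `y` (px), `intensity` (a.u.), `cell_id` (integer or NA),
#'   `compartment` ("nuclear", "cytoplasmic" or NA).
#' @slot imageShape integer(2), image dimensions (rows, cols).
#' @slot channels character, channel names present.
#' @slot cellIds integer, the full set of cell labels in the masks (so cells
#'   without spots still enter population denominators); empty until masks
#'   are applied.
#'
#' @seealso [callSpots()], [assignCompartment()], [callTranscriptionSites()]
#' @export
setClass("SpotTable",
  representation(
    spots = "data.frame",
    imageShape = "integer",
    channels = "character",
    cellIds = "integer"
  ),
  prototype(
    spots = data.frame(
      channel = character(), x = numeric(), y = numeric(),
      intensity = numeric(), cell_id = integer(), compartment = character(),
      stringsAsFactors = FALSE
    ),
    imageShape = integer(2),
    channels = character(),
    cellIds = integer()
  )
)

setValidity("SpotTable", function(object) {
  need <- c("channel", "x", "y", "intensity", "cell_id", "compartment")
  if (!all(need %in% names(object@spots))) {
    return(paste("spots must have columns:", paste(need, collapse = ", ")))
  }
  sp <- object@spots
  if (length(object@imageShape) == 2L && nrow(sp) > 0L &&
      all(object@imageShape > 0L)) {
    if (any(sp$x < -0.5 | sp$x > object@imageShape[1] - 0.5) ||
        any(sp$y < -0.5 | sp$y > object@imageShape[2] - 0.5)) {
      return("spot positions outside image bounds")
    }
  }
  if (nrow(sp) > 0L && any(!is.finite(sp$intensity))) {
    return("spot intensities must be finite")
  }
  bad <- !sp$channel %in% c("exon", "intron")
  if (any(bad)) return("channel must be 'exon' or 'intron'")
  TRUE
})

#' TraceSet: live-cell transcription-site intensity traces
#'
#' Per-allele time series of transcription-site fluorescence, sampled at a
#' fixed frame interval (default 100 s, 512 frames per movie).
#'
#' @slot traces data.frame with columns `allele_id`, `frame` (0-based,
#'   contiguous per allele), `intensity` (a.u.) and optionally `population`.
#' @slot frameInterval numeric, seconds between frames.
#'
#' @seealso [fitTelegraphHMM()], [decodeStates()], [simulateTelegraphTrace()]
#' @export
setClass("TraceSet",
  representation(traces = "data.frame", frameInterval = "numeric"),
  prototype(
    traces = data.frame(
      allele_id = character(), frame = integer(), intensity = numeric(),
      stringsAsFactors = FALSE
    ),
    frameInterval = 100
  )
)

setValidity("TraceSet", function(object) {
  tr <- object@traces
  if (!all(c("allele_id", "frame", "intensity") %in% names(tr))) {
    return("traces must have columns allele_id, frame, intensity")
  }
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0) {
    return("frameInterval must be a single positive number (seconds)")
  }
  if (nrow(tr) > 0L) {
    if (any(!is.finite(tr$intensity))) return("intensities must be finite")
    ok <- vapply(split(tr$frame, tr$allele_id), function(f) {
      f <- sort(f)
      length(f) >= 1L && all(diff(f) == 1L)
    }, logical(1))
    if (!all(ok)) return("frames must be contiguous within each allele")
  }
  TRUE
})

#' TelegraphHMM: two-state Gaussian hidden Markov model of promoter activity
#'
#' Parameters of a two-state (inactive/active) HMM with Gaussian emissions
#' fitted to pooled intensity traces. State 1 is inactive, state 2 active;
#' by construction the active state has the larger emission mean.
#'
#' @slot transition 2x2 row-stochastic transition matrix
#'   (order: inactive, active).
#' @slot means,sds numeric(2), Gaussian emission parameters per state.
#' @slot initProb numeric(2), initial state distribution.
#' @slot logLik numeric, pooled log-likelihood at convergence.
#' @slot nIter integer, EM iterations used.
#' @slot converged logical.
#'
#' @export
setClass("TelegraphHMM",
  representation(
    transition = "matrix", means = "numeric", sds = "numeric",
    initProb = "numeric", logLik = "numeric", nIter = "integer",
    converged = "logical"
  )
)

setValidity("TelegraphHMM", function(object) {
  if (!all(dim(object@transition) == c(2L, 2L))) {
    return("transition must be 2x2")
  }
  if (any(object@transition < 0) ||
      any(abs(rowSums(object@transition) - 1) > 1e-8)) {
    return("transition rows must be probability distributions")
  }
  if (length(object@means) != 2L || length(object@sds) != 2L) {
    return("means and sds must have length 2")
  }
  if (any(object@sds <= 0)) return("emission sds must be > 0")
  if (object@means[2] < object@means[1]) {
    return("state 2 (active) must have the larger emission mean")
  }
  if (abs(sum(object@initProb) - 1) > 1e-8 || any(object@initProb < 0)) {
    return("initProb must be a probability distribution")
  }
  TRUE
})

#' TwoStateFit: relaxation-to-equilibrium model fit
#'
#' Joint fit of the two-state promoter model to sorted-population
#' trajectories of the fraction of transcribing cells. The active fraction
#' obeys dA/dt = kon - (kon + koff) A, whose solution is
#' A(t) = A_eq + (A0 - A_eq) exp(-lambda (t - t0)) with lambda = kon + koff
#' and A_eq = kon / (kon + koff).
#'
#' @slot kon,koff activation/inactivation rates (per day).
#' @slot lambda relaxation rate, kon + koff (per day).
#' @slot aEq equilibrium active fraction, kon / lambda.
#' @slot a0 named numeric, initial active fraction per population.
#' @slot t0 sorting time (days).
#' @slot rss residual sum of squares of the best fit.
#' @slot mode "fitted_equilibrium" or "fixed_equilibrium".
#' @slot ci list of per-parameter 95% percentile intervals (empty until
#'   [bootstrapRelaxationCI()] is run).
#' @slot diagnostics list: multi-start convergence information.
#'
#' @seealso [fitRelaxation()], [relaxFraction()], [bootstrapRelaxationCI()]
#' @export
setClass("TwoStateFit",
  representation(
    kon = "numeric", koff = "numeric", lambda = "numeric", aEq = "numeric",
    a0 = "numeric", t0 = "numeric", rss = "numeric", mode = "character",
    ci = "list", diagnostics = "list"
  ),
  prototype(ci = list(), diagnostics = list(), t0 = 0)
)

setValidity("TwoStateFit", function(object) {
  if (object@kon < 0 || object@koff < 0) return("rates must be >= 0")
  if (abs(object@lambda - (object@kon + object@koff)) > 1e-8) {
    return("lambda must equal kon + koff")
  }
  if (object@lambda > 0 &&
      abs(object@aEq - object@kon / object@lambda) > 1e-8) {
    return("aEq must equal kon / (kon + koff)")
  }
  if (object@aEq < 0 || object@aEq > 1) return("aEq must be in [0, 1]")
  if (any(object@a0 < 0 | object@a0 > 1)) return("a0 must be in [0, 1]")
  if (!object@mode %in% c("fitted_equilibrium", "fixed_equilibrium")) {
    return("mode must be 'fitted_equilibrium' or 'fixed_equilibrium'")
  }
  TRUE
})
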