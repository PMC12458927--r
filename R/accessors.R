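# Accessors and show methods.

#' @describeIn SpotTable-accessors spot table as a data.frame
#' @export
setGeneric("spots", function(x) standardGeneric("spots"))

#' @describeIn SpotTable-accessors image dimensions (rows, cols)
#' @export
setGeneric("imageShape", function(x) standardGeneric("imageShape"))

#' @describeIn SpotTable-accessors full set of cell labels from the masks
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @describeIn TraceSet-accessors trace table as a data.frame
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))

#' @describeIn TraceSet-accessors frame interval in seconds
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @describeIn TelegraphHMM-accessors 2x2 transition matrix
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))

#' @describeIn TelegraphHMM-accessors Gaussian emission means
#' @export
setGeneric("emissionMeans", function(x) standardGeneric("emissionMeans"))

#' @describeIn TelegraphHMM-accessors Gaussian emission sds
#' @export
setGeneric("emissionSds", function(x) standardGeneric("emissionSds"))

#' @describeIn TwoStateFit-accessors activation rate kon (per day)
#' @export
setGeneric("konRate", function(x) standardGeneric("konRate"))

#' @describeIn TwoStateFit-accessors inactivation rate koff (per day)
#' @export
setGeneric("koffRate", function(x) standardGeneric("koffRate"))

#' @describeIn TwoStateFit-accessors relaxation rate lambda = kon + koff
#' @export
setGeneric("relaxationRate", function(x) standardGeneric("relaxationRate"))

#' @describeIn TwoStateFit-accessors equilibrium active fraction
#' @export
setGeneric("equilibriumFraction",
           function(x) standardGeneric("equilibriumFraction"))

#' @describeIn TwoStateFit-accessors initial active fraction per population
#' @export
setGeneric("initialFractions", function(x) standardGeneric("initialFractions"))

#' Accessors for SpotTable objects
#'
#' @param x a [SpotTable] object
#' @name SpotTable-accessors
#' @aliases spots imageShape cellIds
NULL

#' Accessors for TraceSet objects
#'
#' @param x a [TraceSet] object
#' @name TraceSet-accessors
NULL

#' Accessors for TelegraphHMM objects
#'
#' @param x a [TelegraphHMM] object
#' @name TelegraphHMM-accessors
NULL

#' Accessors for TwoStateFit objects
#'
#' @param x a [TwoStateFit] object
#' @name TwoStateFit-accessors
NULL

#' @rdname SpotTable-accessors
#' @export
setMethod("spots", "SpotTable", function(x) x@spots)

#' @rdname SpotTable-accessors
#' @export
setMethod("imageShape", "SpotTable", function(x) x@imageShape)

#' @rdname SpotTable-accessors
#' @export
setMethod("cellIds", "SpotTable", function(x) x@cellIds)

#' @rdname TraceSet-accessors
#' @export
setMethod("traces", "TraceSet", function(x) x@traces)

#' @rdname TraceSet-accessors
#' @export
setMethod("frameInterval", "TraceSet", function(x) x@frameInterval)

#' @rdname TelegraphHMM-accessors
#' @export
setMethod("transitionMatrix", "TelegraphHMM", function(x) x@transition)

#' @rdname TelegraphHMM-accessors
#' @export
setMethod("emissionMeans", "TelegraphHMM", function(x) x@means)

#' @rdname TelegraphHMM-accessors
#' @export
setMethod("emissionSds", "TelegraphHMM", function(x) x@sds)

#' @rdname TwoStateFit-accessors
#' @export
setMethod("konRate", "TwoStateFit", function(x) x@kon)

#' @rdname TwoStateFit-accessors
#' @export
setMethod("koffRate", "TwoStateFit", function(x) x@koff)

#' @rdname TwoStateFit-accessors
#' @export
setMethod("relaxationRate", "TwoStateFit", function(x) x@lambda)

#' @rdname TwoStateFit-accessors
#' @export
setMethod("equilibriumFraction", "TwoStateFit", function(x) x@aEq)

#' @rdname TwoStateFit-accessors
#' @export
setMethod("initialFractions", "TwoStateFit", function(x) x@a0)

setMethod("show", "SpotTable", function(object) {
  sp <- object@spots
  cat(sprintf("SpotTable: %d spots (%s)\n", nrow(sp),
              paste(sprintf("%s=%d", names(table(sp$channel)),
                            as.integer(table(sp$channel))), collapse = ", ")))
  if (length(object@imageShape) == 2L && all(object@imageShape > 0)) {
    cat(sprintf("  image: %d x %d px\n",
                object@imageShape[1], object@imageShape[2]))
  }
  if (length(object@cellIds)) {
    cat(sprintf("  cells: %d labels; compartments assigned\n",
                length(object@cellIds)))
  }
  invisible(NULL)
})

setMethod("show", "TraceSet", function(object) {
  tr <- object@traces
  cat(sprintf("TraceSet: %d alleles, %d frames total, dt = %g s\n",
              length(unique(tr$allele_id)), nrow(tr), object@frameInterval))
  invisible(NULL)
})

setMethod("show", "TelegraphHMM", function(object) {
  cat("TelegraphHMM (2-state Gaussian emissions)\n")
  cat(sprintf("  emission means (inactive, active): %.4g, %.4g\n",
              object@means[1], object@means[2]))
  cat(sprintf("  P(stay inactive) = %.4f, P(stay active) = %.4f\n",
              object@transition[1, 1], object@transition[2, 2]))
  cat(sprintf("  logLik = %.2f after %d EM iterations (%s)\n",
              object@logLik, object@nIter,
              if (object@converged) "converged" else "not converged"))
  invisible(NULL)
})

setMethod("show", "TwoStateFit", function(object) {
  cat(sprintf("TwoStateFit (%s)\n", object@mode))
  cat(sprintf("  kon  = %.4g /d   koff = %.4g /d   lambda = %.4g /d\n",
              object@kon, object@koff, object@lambda))
  cat(sprintf("  A_eq = %.3f (%.1f%% transcribing at equilibrium)\n",
              object@aEq, 100 * object@aEq))
  for (p in names(object@a0)) {
    cat(sprintf("  A0[%s] = %.3f\n", p, object@a0[[p]]))
  }
  cat(sprintf("  RSS = %.4g\n", object@rss))
  if (length(object@ci)) {
    for (p in names(object@ci)) {
      cat(sprintf("  95%% CI %s: [%.4g, %.4g]\n", p,
                  object@ci[[p]][1], object@ci[[p]][2]))
    }
  }
  invisible(NULL)
})
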