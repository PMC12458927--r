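# Ground-truthed synthetic inputs for every pipeline stage: telegraph
# intensity traces, smFISH fields with label masks, sorted-population
# relaxation trajectories, and gene universes with planted overlap.

#' Simulate a two-state (telegraph) transcription intensity trace
#'
#' Simulates promoter switching as a continuous-time two-state Markov
#' process by exact event-driven (Gillespie-style) sampling of exponential
#' dwell times, then samples the state at frame midpoints to avoid aliasing
#' bias at dwell times near the frame interval. Fluorescence during active
#' frames is constant at `meanNascent * intensityPerRNA` (no birth-death of
#' individual nascent transcripts -- a deliberate simplification sufficient
#' for validating state segmentation), with additive Gaussian noise.
#'
#' The initial state is drawn from the stationary distribution, so the
#' long-run active occupancy is `kOn / (kOn + kOff)`.
#'
#' @param kOn activation rate (events per minute).
#' @param kOff inactivation rate (events per minute).
#' @param intensityPerRNA fluorescence units per nascent RNA.
#' @param meanNascent mean nascent RNA count during active periods.
#' @param noiseSd sd of additive Gaussian noise (a.u.).
#' @param dt frame interval in seconds (default 100).
#' @param nFrames trace length in frames (default 512).
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @param alleleId identifier used in the returned tables.
#'
#' @return A list with elements
#'   \item{trace}{data.frame `allele_id`, `frame`, `intensity`}
#'   \item{states}{integer vector, true state per frame (0 inactive,
#'     1 active)}
#'   \item{dwells}{data.frame of event-level dwell times in minutes
#'     (`state`, `minutes`, `censored`); the first and last dwell of the
#'     simulation window are flagged censored}
#' @seealso [simulateTelegraphTraces()] for a multi-trace [TraceSet]
#' @export
simulateTelegraphTrace <- function(kOn, kOff, intensityPerRNA = 100,
                                   meanNascent = 2, noiseSd = 0, dt = 100,
                                   nFrames = 512, seed = NULL,
                                   alleleId = "allele_1") {
  assertScalar(kOn, "kOn", positive = TRUE)
  assertScalar(kOff, "kOff", positive = TRUE)
  assertScalar(noiseSd, "noiseSd", nonneg = TRUE)
  assertScalar(dt, "dt", positive = TRUE)
  if (nFrames < 2) stop("'nFrames' must be >= 2")

  withSeed(seed, {
    dtMin <- dt / 60
    tEnd <- nFrames * dtMin
    pActive <- kOn / (kOn + kOff)
    state0 <- as.integer(stats::runif(1) < pActive)

    # exact switching times: dwell ~ Exp(kOff) when active, Exp(kOn) when
    # inactive; simulate until the window is covered
    switches <- numeric(0)
    t <- 0
    s <- state0
    dwellState <- integer(0)
    dwellLen <- numeric(0)
    while (t < tEnd) {
      rate <- if (s == 1L) kOff else kOn
      d <- stats::rexp(1, rate)
      dwellState <- c(dwellState, s)
      dwellLen <- c(dwellLen, min(d, tEnd - t))
      t <- t + d
      if (t < tEnd) switches <- c(switches, t)
      s <- 1L - s
    }
    censored <- rep(FALSE, length(dwellLen))
    censored[1L] <- TRUE                 # start dwell began before t = 0
    censored[length(censored)] <- TRUE   # last dwell truncated at t = tEnd
    dwells <- data.frame(state = dwellState, minutes = dwellLen,
                         censored = censored)

    mid <- (seq_len(nFrames) - 0.5) * dtMin
    nSwitchBefore <- findInterval(mid, switches)
    states <- as.integer((state0 + nSwitchBefore) %% 2L)

    intensity <- states * meanNascent * intensityPerRNA +
      stats::rnorm(nFrames, 0, noiseSd)
    trace <- data.frame(
      allele_id = alleleId, frame = seq_len(nFrames) - 1L,
      intensity = intensity, stringsAsFactors = FALSE
    )
    list(trace = trace, states = states, dwells = dwells)
  })
}

#' Simulate a set of telegraph traces as a TraceSet
#'
#' Convenience wrapper around [simulateTelegraphTrace()]: each trace gets a
#' child seed deterministically split from `seed`, so the whole set is a
#' pure function of its arguments.
#'
#' @param nTraces number of alleles to simulate.
#' @param ... passed to [simulateTelegraphTrace()] (rates, noise, dt, ...).
#' @param seed spec-level RNG seed.
#' @param population optional population label stored with the traces.
#'
#' @return list with `traces` (a [TraceSet]), `states` (data.frame
#'   `allele_id`, `frame`, `state`) and `dwells` (event-level dwell table
#'   with `allele_id`).
#' @export
simulateTelegraphTraces <- function(nTraces, ..., seed = 1L,
                                    population = NULL) {
  out <- vector("list", nTraces)
  for (i in seq_len(nTraces)) {
    out[[i]] <- simulateTelegraphTrace(
      ..., seed = childSeed(seed, i),
      alleleId = sprintf("allele_%03d", i)
    )
  }
  tr <- do.call(rbind, lapply(out, `[[`, "trace"))
  if (!is.null(population)) tr$population <- population
  st <- do.call(rbind, lapply(seq_along(out), function(i) {
    data.frame(allele_id = sprintf("allele_%03d", i),
               frame = seq_along(out[[i]]$states) - 1L,
               state = out[[i]]$states, stringsAsFactors = FALSE)
  }))
  dw <- do.call(rbind, lapply(seq_along(out), function(i) {
    cbind(allele_id = sprintf("allele_%03d", i), out[[i]]$dwells)
  }))
  dots <- list(...)
  dt <- if (!is.null(dots$dt)) dots$dt else 100
  list(
    traces = methods::new("TraceSet", traces = tr, frameInterval = dt),
    states = st, dwells = dw
  )
}

# Render one Gaussian spot of integrated intensity I at sub-pixel (x, y)
# (0-based row/col) into `img`, in place arithmetic on a local window.
addGaussianSpot <- function(img, x, y, intensity, sigma) {
  half <- ceiling(5 * sigma)
  r <- max(0, floor(x) - half):min(nrow(img) - 1, floor(x) + half)
  c <- max(0, floor(y) - half):min(ncol(img) - 1, floor(y) + half)
  amp <- intensity / (2 * pi * sigma^2)
  g <- amp * exp(-outer((r - x)^2, (c - y)^2, "+") / (2 * sigma^2))
  img[r + 1, c + 1] <- img[r + 1, c + 1] + g
  img
}

#' Simulate an smFISH imaging field with ground truth
#'
#' Generates a two-channel (exon, intron) field of diffraction-limited
#' spots on a noisy background, together with nucleus and cytoplasm label
#' masks and a ground-truth [SpotTable]. Cells are disjoint axis-aligned
#' rectangles arranged on a grid with elliptical nuclei; masks follow the
#' label-image convention (0 = background, k = cell k).
#'
#' Transcription sites are placed inside nuclei at the same position in
#' both channels, with exon intensity `tsNascentCount * singleRnaIntensity`
#' (and intron intensity scaled the same way). Cytoplasmic single-molecule
#' spots appear in the exon channel only, at `singleRnaIntensity` each.
#' Spots within a channel are kept at least `minSeparation` apart by
#' rejection sampling.
#'
#' @param imageShape integer(2), image size (rows, cols).
#' @param nCells number of cells; 0 gives background-only images and an
#'   empty truth table.
#' @param psfSigma Gaussian sd of the point-spread function (px).
#' @param singleRnaIntensity integrated intensity of one mRNA (a.u.).
#' @param tsNascentCounts per-cell transcription-site sizes (nascent RNA
#'   counts): either a numeric vector of length `nCells` (0 = no TS in that
#'   cell) or a list of length `nCells` of vectors (multiple TS per cell).
#' @param cytoSpotsPerCell cytoplasmic mRNA spots per cell.
#' @param background constant background level (a.u.).
#' @param noiseSd sd of additive Gaussian pixel noise (a.u.).
#' @param minSeparation minimum centre-to-centre spot distance within a
#'   channel (px); defaults to `4 * psfSigma`.
#' @param seed RNG seed.
#'
#' @return list with `exon`, `intron` (numeric matrices), `nucleusMask`,
#'   `cytoMask` (integer label matrices) and `truth` (a [SpotTable] with
#'   `cell_id`/`compartment` filled and `cellIds` set).
#' @export
simulateSmfishField <- function(imageShape = c(256L, 256L), nCells = 9L,
                                psfSigma = 1.5, singleRnaIntensity = 2000,
                                tsNascentCounts = rep(2, nCells),
                                cytoSpotsPerCell = 20L, background = 100,
                                noiseSd = 10, minSeparation = 4 * psfSigma,
                                seed = NULL) {
  assertScalar(psfSigma, "psfSigma", positive = TRUE)
  assertScalar(background, "background", nonneg = TRUE)
  assertScalar(noiseSd, "noiseSd", nonneg = TRUE)
  if (singleRnaIntensity < 0) stop("'singleRnaIntensity' must be >= 0")
  if (!is.list(tsNascentCounts)) tsNascentCounts <- as.list(tsNascentCounts)
  if (length(tsNascentCounts) != nCells) {
    stop("'tsNascentCounts' must have one entry per cell")
  }

  nr <- imageShape[1]; nc <- imageShape[2]
  withSeed(seed, {
    exon <- matrix(background, nr, nc)
    intron <- matrix(background, nr, nc)
    nucMask <- matrix(0L, nr, nc)
    cytMask <- matrix(0L, nr, nc)
    truth <- data.frame(
      channel = character(), x = numeric(), y = numeric(),
      intensity = numeric(), cell_id = integer(), compartment = character(),
      stringsAsFactors = FALSE
    )

    if (nCells > 0L) {
      gcols <- ceiling(sqrt(nCells))
      grows <- ceiling(nCells / gcols)
      ch <- floor((nr - 1) / grows)   # cell height, 1 px gutters
      cw <- floor((nc - 1) / gcols)
      if (ch < 8 || cw < 8) stop("image too small for the requested cells")

      insideEllipse <- function(x, y, cx, cy, ax, ay) {
        ((x - cx) / ax)^2 + ((y - cy) / ay)^2 <= 1
      }

      placed <- list(exon = matrix(numeric(0), ncol = 2),
                     intron = matrix(numeric(0), ncol = 2))
      placeSpot <- function(channel, sampler) {
        for (try in 1:200) {
          p <- sampler()
          pts <- placed[[channel]]
          if (nrow(pts) == 0L ||
              min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >=
                minSeparation) {
            placed[[channel]] <<- rbind(pts, p)
            return(p)
          }
        }
        stop("could not place a spot with the requested separation; ",
             "reduce spot density or minSeparation")
      }

      for (k in seq_len(nCells)) {
        gi <- (k - 1) %/% gcols
        gj <- (k - 1) %% gcols
        r0 <- gi * ch + 1; r1 <- r0 + ch - 2   # 0-based inclusive bounds
        c0 <- gj * cw + 1; c1 <- c0 + cw - 2
        cytMask[(r0:r1) + 1, (c0:c1) + 1] <- k
        cx <- (r0 + r1) / 2; cy <- (c0 + c1) / 2
        ax <- 0.35 * (r1 - r0); ay <- 0.35 * (c1 - c0)
        rr <- r0:r1; cc <- c0:c1
        ell <- outer(((rr - cx) / ax)^2, ((cc - cy) / ay)^2, "+") <= 1
        sub <- nucMask[rr + 1, cc + 1]
        sub[ell] <- k
        nucMask[rr + 1, cc + 1] <- sub

        # transcription sites inside the nucleus, both channels
        for (nasc in tsNascentCounts[[k]]) {
          if (nasc <= 0) next
          p <- placeSpot("exon", function() {
            repeat {
              q <- c(stats::runif(1, cx - ax, cx + ax),
                     stats::runif(1, cy - ay, cy + ay))
              if (insideEllipse(q[1], q[2], cx, cy, 0.8 * ax, 0.8 * ay)) {
                return(q)
              }
            }
          })
          placed$intron <- rbind(placed$intron, p)
          tsExon <- nasc * singleRnaIntensity
          exon <- addGaussianSpot(exon, p[1], p[2], tsExon, psfSigma)
          intron <- addGaussianSpot(intron, p[1], p[2], tsExon, psfSigma)
          truth <- rbind(truth,
            data.frame(channel = c("exon", "intron"), x = p[1], y = p[2],
                       intensity = tsExon, cell_id = k,
                       compartment = "nuclear", stringsAsFactors = FALSE))
        }

        # cytoplasmic single-molecule spots, exon channel only
        for (j in seq_len(cytoSpotsPerCell)) {
          p <- placeSpot("exon", function() {
            repeat {
              q <- c(stats::runif(1, r0 + 3, r1 - 3),
                     stats::runif(1, c0 + 3, c1 - 3))
              if (!insideEllipse(q[1], q[2], cx, cy, 1.1 * ax, 1.1 * ay)) {
                return(q)
              }
            }
          })
          exon <- addGaussianSpot(exon, p[1], p[2], singleRnaIntensity,
                                  psfSigma)
          truth <- rbind(truth,
            data.frame(channel = "exon", x = p[1], y = p[2],
                       intensity = singleRnaIntensity, cell_id = k,
                       compartment = "cytoplasmic", stringsAsFactors = FALSE))
        }
      }
    }

    if (noiseSd > 0) {
      exon <- exon + matrix(stats::rnorm(nr * nc, 0, noiseSd), nr, nc)
      intron <- intron + matrix(stats::rnorm(nr * nc, 0, noiseSd), nr, nc)
    }
    rownames(truth) <- NULL
    truthTable <- methods::new("SpotTable",
      spots = truth, imageShape = as.integer(imageShape),
      channels = c("exon", "intron"),
      cellIds = if (nCells > 0L) seq_len(nCells) else integer(0)
    )
    list(exon = exon, intron = intron, nucleusMask = nucMask,
         cytoMask = cytMask, truth = truthTable)
  })
}

#' Simulate sorted-population relaxation trajectories
#'
#' For each population and sampling day the true fraction of transcribing
#' cells follows the two-state relaxation solution
#' `A(t) = A_eq + (A0 - A_eq) exp(-lambda (t - t0))` with
#' `lambda = kon + koff` and `A_eq = kon / (kon + koff)`; the observed
#' fraction per replicate is `Binomial(nCellsPerPoint, A(t)) /
#' nCellsPerPoint`.
#'
#' @param kon,koff switching rates (per day).
#' @param a0ByPopulation named numeric, initial active fraction per
#'   population (names become population labels).
#' @param sampleDays strictly increasing non-negative sampling days.
#' @param nCellsPerPoint cells scored per observation.
#' @param nReplicates replicates per (population, day).
#' @param t0 sorting day (default 0).
#' @param seed RNG seed.
#'
#' @return data.frame `population`, `day`, `fraction_transcribing`,
#'   `n_cells`, `replicate`, `true_fraction`.
#' @export
simulatePopulationTrajectories <- function(kon, koff, a0ByPopulation,
                                           sampleDays = c(1, 4, 6, 10),
                                           nCellsPerPoint = 500L,
                                           nReplicates = 3L, t0 = 0,
                                           seed = NULL) {
  assertScalar(kon, "kon", positive = TRUE)
  assertScalar(koff, "koff", positive = TRUE)
  if (is.null(names(a0ByPopulation)) || any(names(a0ByPopulation) == "")) {
    stop("'a0ByPopulation' must be a named numeric vector")
  }
  if (any(a0ByPopulation < 0 | a0ByPopulation > 1)) {
    stop("initial fractions must be in [0, 1]")
  }
  if (any(sampleDays < 0) || is.unsorted(sampleDays, strictly = TRUE)) {
    stop("'sampleDays' must be non-negative and strictly increasing")
  }
  lambda <- kon + koff
  aEq <- kon / lambda
  withSeed(seed, {
    grid <- expand.grid(
      replicate = seq_len(nReplicates), day = sampleDays,
      population = names(a0ByPopulation),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    grid$true_fraction <- relaxFraction(
      grid$day, t0 = t0, a0 = a0ByPopulation[grid$population],
      aEq = aEq, lambda = lambda
    )
    grid$n_cells <- as.integer(nCellsPerPoint)
    grid$fraction_transcribing <-
      stats::rbinom(nrow(grid), grid$n_cells, grid$true_fraction) /
      grid$n_cells
    grid[, c("population", "day", "fraction_transcribing", "n_cells",
             "replicate", "true_fraction")]
  })
}

#' Simulate a gene universe with planted overlap structure
#'
#' Builds a universe of synthetic gene symbols and two member sets with
#' exactly the requested overlap, as a fixture for overlap statistics.
#'
#' @param nGenes universe size.
#' @param nSetA,nSetB set sizes.
#' @param nOverlap exact number of shared genes; must be feasible
#'   (`nOverlap <= min(nSetA, nSetB)` and
#'   `nSetA + nSetB - nOverlap <= nGenes`).
#' @param seed RNG seed.
#'
#' @return list with `universe`, `setA`, `setB` (character vectors).
#' @export
simulateGeneUniverse <- function(nGenes, nSetA, nSetB, nOverlap, seed = NULL) {
  if (nOverlap > min(nSetA, nSetB) || nSetA > nGenes || nSetB > nGenes ||
      nSetA + nSetB - nOverlap > nGenes || nOverlap < 0) {
    stop("infeasible counts: need nOverlap <= min(nSetA, nSetB) and ",
         "nSetA + nSetB - nOverlap <= nGenes")
  }
  withSeed(seed, {
    universe <- sprintf("GENE%06d", seq_len(nGenes))
    setA <- sample(universe, nSetA)
    shared <- sample(setA, nOverlap)
    onlyB <- sample(setdiff(universe, setA), nSetB - nOverlap)
    list(universe = universe, setA = sort(setA),
         setB = sort(c(shared, onlyB)))
  })
}
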