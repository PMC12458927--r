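# Shared fixtures and independent oracles used across test files.

# Build a SpotTable by hand from parallel vectors.
makeSpotTable <- function(channel, x, y, intensity,
                          cell_id = NA_integer_, compartment = NA_character_,
                          imageShape = c(100L, 100L), cellIds = integer(0)) {
  new("SpotTable",
      spots = data.frame(channel = channel, x = x, y = y,
                         intensity = intensity,
                         cell_id = as.integer(cell_id),
                         compartment = compartment,
                         stringsAsFactors = FALSE),
      imageShape = as.integer(imageShape),
      channels = unique(channel),
      cellIds = as.integer(cellIds))
}

# Independent re-implementation of greedy distance-ordered one-to-one
# matching using repeated argmin over an explicit distance matrix
# (different code path from the package's ordered-candidate sweep).
oracleGreedyMatch <- function(ix, iy, ex, ey, maxDist = 5) {
  d <- sqrt(outer(ix, ex, "-")^2 + outer(iy, ey, "-")^2)
  d[d > maxDist] <- Inf
  pairs <- NULL
  while (any(is.finite(d))) {
    k <- which(d == min(d), arr.ind = TRUE)[1, , drop = FALSE]
    pairs <- rbind(pairs, k)
    d[k[1], ] <- Inf
    d[, k[2]] <- Inf
  }
  pairs
}

# Brute-force minimum-total-distance one-to-one matching over all
# injective assignments (feasible pairs only), for tiny instances.
oracleOptimalMatch <- function(ix, iy, ex, ey, maxDist = 5) {
  d <- sqrt(outer(ix, ex, "-")^2 + outer(iy, ey, "-")^2)
  nI <- length(ix); nE <- length(ex)
  best <- NULL
  assign <- function(i, used, cur, tot) {
    if (i > nI) {
      if (is.null(best) ||
          nrow(cur %||% matrix(nrow = 0, ncol = 2)) > nrow(best$pairs) ||
          (nrow(cur %||% matrix(nrow = 0, ncol = 2)) == nrow(best$pairs) &&
             tot < best$tot)) {
        best <<- list(pairs = cur %||% matrix(nrow = 0, ncol = 2), tot = tot)
      }
      return(invisible(NULL))
    }
    assign(i + 1, used, cur, tot)  # leave intron i unmatched
    for (e in seq_len(nE)) {
      if (!used[e] && d[i, e] <= maxDist) {
        used[e] <- TRUE
        assign(i + 1, used, rbind(cur, c(i, e)), tot + d[i, e])
        used[e] <- FALSE
      }
    }
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  assign(1, logical(nE), NULL, 0)
  best
}

# Exhaustive hypergeometric tail: enumerate all size-nA subsets of a
# universe containing nB marked elements and count how often the overlap
# is >= k.
oracleHyperTail <- function(nUniverse, nSetA, nSetB, k) {
  draws <- utils::combn(nUniverse, nSetA)
  marked <- seq_len(nSetB)
  ov <- apply(draws, 2, function(s) sum(s %in% marked))
  mean(ov >= k)
}

# Brute-force most-likely state path by enumerating all 2^n paths.
oracleViterbi <- function(y, hmm) {
  n <- length(y)
  A <- transitionMatrix(hmm)
  best <- NULL
  bestLL <- -Inf
  for (code in 0:(2^n - 1)) {
    path <- as.integer(intToBits(code))[1:n]
    ll <- log(hmm@initProb[path[1] + 1]) +
      sum(dnorm(y, emissionMeans(hmm)[path + 1],
                emissionSds(hmm)[path + 1], log = TRUE))
    if (n > 1) {
      ll <- ll + sum(log(A[cbind(path[-n] + 1, path[-1] + 1)]))
    }
    if (ll > bestLL) {
      bestLL <- ll
      best <- path
    }
  }
  best
}

# Nearest-neighbour matching of called spots to ground truth (<= tol px);
# returns matched index pairs for recall/precision/RMSE computations.
matchSpotsToTruth <- function(called, truth, tol = 2) {
  if (nrow(called) == 0L || nrow(truth) == 0L) {
    return(data.frame(called = integer(), truth = integer()))
  }
  d <- sqrt(outer(called$x, truth$x, "-")^2 +
            outer(called$y, truth$y, "-")^2)
  d[d > tol] <- Inf
  out <- NULL
  while (any(is.finite(d))) {
    k <- which(d == min(d), arr.ind = TRUE)[1, ]
    out <- rbind(out, k)
    d[k[1], ] <- Inf
    d[, k[2]] <- Inf
  }
  if (is.null(out)) {
    return(data.frame(called = integer(), truth = integer()))
  }
  data.frame(called = out[, 1], truth = out[, 2])
}
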