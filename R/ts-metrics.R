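# Transcription-site calling by intron-exon colocalization, burst-size
# estimation by single-molecule normalization, and population summaries.

#' Call transcription sites by intron-exon colocalization
#'
#' Within each cell, nuclear intron spots are paired one-to-one with
#' nuclear exon spots when their Euclidean distance is at most `maxDist`
#' pixels (default 5, boundary inclusive). Candidate pairs are accepted
#' greedily in order of increasing distance, each spot used at most once;
#' ties are broken by intron intensity (descending), then input order.
#' Cross-cell pairs are never formed. The TS position is that of the
#' intron spot (it marks nascent RNA); the exon member supplies the
#' intensity used for burst-size estimation.
#'
#' @param spotTable a [SpotTable] with cell and compartment assignments.
#' @param maxDist maximum pairing distance in px (default 5).
#'
#' @return data.frame `cell_id`, `x`, `y` (intron position),
#'   `exon_intensity`, `intron_intensity`, `pair_distance`.
#' @export
callTranscriptionSites <- function(spotTable, maxDist = 5) {
  sp <- spots(spotTable)
  empty <- data.frame(
    cell_id = integer(), x = numeric(), y = numeric(),
    exon_intensity = numeric(), intron_intensity = numeric(),
    pair_distance = numeric(), stringsAsFactors = FALSE
  )
  nucl <- sp[!is.na(sp$compartment) & sp$compartment == "nuclear" &
               !is.na(sp$cell_id), , drop = FALSE]
  if (nrow(nucl) == 0L) return(empty)
  out <- list()
  for (cid in sort(unique(nucl$cell_id))) {
    introns <- nucl[nucl$cell_id == cid & nucl$channel == "intron", ,
                    drop = FALSE]
    exons <- nucl[nucl$cell_id == cid & nucl$channel == "exon", ,
                  drop = FALSE]
    if (nrow(introns) == 0L || nrow(exons) == 0L) next
    d <- sqrt(outer(introns$x, exons$x, "-")^2 +
              outer(introns$y, exons$y, "-")^2)
    cand <- which(d <= maxDist, arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    ord <- order(d[cand], -introns$intensity[cand[, 1]], cand[, 1],
                 cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    usedI <- logical(nrow(introns))
    usedE <- logical(nrow(exons))
    for (p in seq_len(nrow(cand))) {
      i <- cand[p, 1]; e <- cand[p, 2]
      if (usedI[i] || usedE[e]) next
      usedI[i] <- TRUE; usedE[e] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        cell_id = cid, x = introns$x[i], y = introns$y[i],
        exon_intensity = exons$intensity[e],
        intron_intensity = introns$intensity[i],
        pair_distance = d[i, e], stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate burst sizes (nascent RNA per transcription site)
#'
#' Converts TS exon intensities to nascent RNA counts by dividing by the
#' per-cell median intensity of cytoplasmic exon spots, which correspond
#' to single mRNA molecules. Cells with fewer than `minCytoSpots`
#' (default 5) cytoplasmic exon spots give `NA` (undefined), never zero:
#' the single-molecule calibration is considered unreliable there.
#'
#' @param ts TS table from [callTranscriptionSites()].
#' @param spotTable the assigned [SpotTable] the TS were called from.
#' @param minCytoSpots minimum cytoplasmic exon spots per cell (default 5).
#'
#' @return the TS table with `nascent_count` and
#'   `single_molecule_intensity` columns added.
#' @export
burstSizes <- function(ts, spotTable, minCytoSpots = 5) {
  sp <- spots(spotTable)
  cyt <- sp[!is.na(sp$compartment) & sp$compartment == "cytoplasmic" &
              sp$channel == "exon" & !is.na(sp$cell_id), , drop = FALSE]
  med <- tapply(cyt$intensity, cyt$cell_id, stats::median)
  n <- tapply(cyt$intensity, cyt$cell_id, length)
  ts$single_molecule_intensity <- NA_real_
  ts$nascent_count <- NA_real_
  if (nrow(ts)) {
    key <- as.character(ts$cell_id)
    ok <- key %in% names(n) & n[key] >= minCytoSpots
    ok[is.na(ok)] <- FALSE
    ts$single_molecule_intensity[ok] <- med[key[ok]]
    ts$nascent_count[ok] <- ts$exon_intensity[ok] / med[key[ok]]
  }
  ts
}

#' Per-cell summaries of transcription activity
#'
#' One row per cell (including cells without any spot, taken from the
#' mask label set stored in the [SpotTable]): TS count, cytoplasmic exon
#' spot count, whether the cell is transcribing (one or more TS), and
#' whether it passes the burst-size calibration filter.
#'
#' @param spotTable assigned [SpotTable].
#' @param ts TS table (with burst sizes if [burstSizes()] was run).
#' @param minCytoSpots burst-size eligibility threshold (default 5).
#'
#' @return data.frame `cell_id`, `n_ts`, `n_cyto_exon`, `transcribing`,
#'   `burst_eligible`.
#' @export
cellSummaries <- function(spotTable, ts, minCytoSpots = 5) {
  ids <- cellIds(spotTable)
  if (length(ids) == 0L) {
    ids <- sort(unique(stats::na.omit(spots(spotTable)$cell_id)))
  }
  if (length(ids) == 0L) stop("no cells: assign compartments first")
  sp <- spots(spotTable)
  cyt <- sp[!is.na(sp$compartment) & sp$compartment == "cytoplasmic" &
              sp$channel == "exon" & !is.na(sp$cell_id), , drop = FALSE]
  nCyto <- table(factor(cyt$cell_id, levels = ids))
  nTs <- table(factor(ts$cell_id, levels = ids))
  data.frame(
    cell_id = as.integer(ids),
    n_ts = as.integer(nTs),
    n_cyto_exon = as.integer(nCyto),
    transcribing = as.integer(nTs) >= 1L,
    burst_eligible = as.integer(nCyto) >= minCytoSpots
  )
}

#' Population summaries: percent transcribing, TS histogram, burst sizes
#'
#' A cell is transcribing when it carries one or more transcription sites.
#' The TS-per-cell histogram uses bins 0..4 and a top bin "5+"
#' (accommodating aneuploid lines with up to five or more alleles) and
#' sums to 1. Burst sizes are reported both pooled over all eligible TS
#' and as per-cell medians.
#'
#' @param cells per-cell table from [cellSummaries()].
#' @param ts TS table with `nascent_count` (from [burstSizes()]); optional
#'   if burst-size output is not needed.
#'
#' @return list: `percent_transcribing` (0-100), `n_cells`,
#'   `ts_count_histogram` (named fractions for "0".."4", "5+"),
#'   `burst_sizes` (pooled nascent counts), `burst_size_median`,
#'   `burst_size_per_cell_median` (data.frame).
#' @export
populationSummaries <- function(cells, ts = NULL) {
  if (nrow(cells) == 0L) stop("empty cell list: percentage undefined")
  pct <- 100 * mean(cells$transcribing)
  binned <- ifelse(cells$n_ts >= 5L, "5+", as.character(cells$n_ts))
  hist <- table(factor(binned, levels = c(as.character(0:4), "5+")))
  hist <- as.numeric(hist) / nrow(cells)
  names(hist) <- c(as.character(0:4), "5+")
  out <- list(
    percent_transcribing = pct,
    n_cells = nrow(cells),
    ts_count_histogram = hist
  )
  if (!is.null(ts) && "nascent_count" %in% names(ts)) {
    bs <- ts$nascent_count[!is.na(ts$nascent_count)]
    out$burst_sizes <- bs
    out$burst_size_median <- if (length(bs)) stats::median(bs) else NA_real_
    if (length(bs)) {
      perCell <- tapply(ts$nascent_count, ts$cell_id,
                        function(v) stats::median(v, na.rm = TRUE))
      perCell <- perCell[!is.na(perCell)]
      out$burst_size_per_cell_median <- data.frame(
        cell_id = as.integer(names(perCell)),
        median_burst_size = as.numeric(perCell)
      )
    }
  }
  out
}
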