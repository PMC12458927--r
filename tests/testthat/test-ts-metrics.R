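# Transcription-site calling, burst size, population summaries.

nuclearPair <- function(d, cell = 1L) {
  # an intron at (10,10) and an exon at distance d along x
  makeSpotTable(
    channel = c("intron", "exon"), x = c(10, 10 + d), y = c(10, 10),
    intensity = c(100, 300), cell_id = cell, compartment = "nuclear",
    cellIds = cell
  )
}

test_that("the 5-pixel colocalization boundary is inclusive", {
  expect_identical(nrow(callTranscriptionSites(nuclearPair(5.0))), 1L)
  expect_identical(nrow(callTranscriptionSites(nuclearPair(5.01))), 0L)
  ts <- callTranscriptionSites(nuclearPair(3))
  expect_equal(ts$pair_distance, 3)
  expect_equal(ts$x, 10)           # TS position comes from the intron
  expect_equal(ts$exon_intensity, 300)
})

test_that("competing introns resolve to the minimum-distance pairing", {
  st <- makeSpotTable(
    channel = c("intron", "intron", "exon"),
    x = c(10, 10, 10), y = c(12, 14, 10),   # introns at 2 px and 4 px
    intensity = c(50, 60, 300), cell_id = 1L, compartment = "nuclear"
  )
  ts <- callTranscriptionSites(st)
  expect_identical(nrow(ts), 1L)
  expect_equal(ts$pair_distance, 2)
  opt <- oracleOptimalMatch(c(10, 10), c(12, 14), 10, 10)
  expect_identical(nrow(opt$pairs), 1L)
  expect_equal(opt$tot, 2)
})

test_that("greedy matching agrees with an independent implementation", {
  set.seed(42)
  for (rep in 1:25) {
    nI <- sample(1:3, 1); nE <- sample(1:3, 1)
    ix <- runif(nI, 0, 12); iy <- runif(nI, 0, 12)
    ex <- runif(nE, 0, 12); ey <- runif(nE, 0, 12)
    st <- makeSpotTable(
      channel = rep(c("intron", "exon"), c(nI, nE)),
      x = c(ix, ex), y = c(iy, ey),
      intensity = runif(nI + nE, 50, 500),
      cell_id = 1L, compartment = "nuclear"
    )
    ts <- callTranscriptionSites(st)
    ref <- oracleGreedyMatch(ix, iy, ex, ey)
    expect_identical(nrow(ts), if (is.null(ref)) 0L else nrow(ref))
    if (!is.null(ref) && nrow(ref)) {
      expect_equal(sort(ts$pair_distance),
                   sort(sqrt((ix[ref[, 1]] - ex[ref[, 2]])^2 +
                               (iy[ref[, 1]] - ey[ref[, 2]])^2)))
    }
  }
})

test_that("matching never crosses cells and is channel-symmetric", {
  st <- makeSpotTable(
    channel = c("intron", "exon"), x = c(10, 11), y = c(10, 10),
    intensity = c(100, 200), cell_id = c(1L, 2L), compartment = "nuclear"
  )
  expect_identical(nrow(callTranscriptionSites(st)), 0L)

  set.seed(7)
  x <- runif(6, 0, 20); y <- runif(6, 0, 20)
  a <- makeSpotTable(rep(c("intron", "exon"), each = 3), x, y,
                     intensity = seq(100, 600, 100), cell_id = 1L,
                     compartment = "nuclear")
  swapped <- makeSpotTable(rep(c("exon", "intron"), each = 3), x, y,
                           intensity = seq(100, 600, 100), cell_id = 1L,
                           compartment = "nuclear")
  tsA <- callTranscriptionSites(a)
  tsB <- callTranscriptionSites(swapped)
  expect_equal(sort(tsA$pair_distance), sort(tsB$pair_distance))
})

test_that("burst size divides TS intensity by the single-molecule median", {
  cyto <- makeSpotTable(
    channel = "exon", x = 30 + 1:5, y = 30, cell_id = 1L,
    intensity = c(110, 115, 120, 125, 130), compartment = "cytoplasmic"
  )
  both <- combineSpotTables(nuclearPair(2), cyto)
  ts <- callTranscriptionSites(both)
  ts$exon_intensity <- 240
  bs <- burstSizes(ts, both)
  expect_equal(bs$nascent_count, 2.0)
  expect_equal(bs$single_molecule_intensity, 120)

  # a 10x outlier does not move the median-based estimate
  cytoOut <- makeSpotTable(
    channel = "exon", x = 30 + 1:6, y = 30, cell_id = 1L,
    intensity = c(110, 115, 120, 125, 130, 1200),
    compartment = "cytoplasmic"
  )
  bsOut <- burstSizes(ts, combineSpotTables(nuclearPair(2), cytoOut))
  expect_equal(bsOut$nascent_count, 240 / 122.5)
  expect_lt(abs(bsOut$nascent_count - bs$nascent_count), 0.05)

  # fewer than 5 cytoplasmic spots: undefined, not zero
  cyto4 <- makeSpotTable(
    channel = "exon", x = 30 + 1:4, y = 30, cell_id = 1L,
    intensity = c(110, 115, 125, 130), compartment = "cytoplasmic"
  )
  bs4 <- burstSizes(ts, combineSpotTables(nuclearPair(2), cyto4))
  expect_true(is.na(bs4$nascent_count))
})

test_that("population summaries count transcribing cells and bin TS", {
  cells <- data.frame(
    cell_id = 1:10,
    n_ts = c(3L, 1L, rep(0L, 8)),
    n_cyto_exon = rep(10L, 10),
    transcribing = c(TRUE, TRUE, rep(FALSE, 8)),
    burst_eligible = TRUE
  )
  s <- populationSummaries(cells)
  expect_equal(s$percent_transcribing, 20)
  expect_equal(sum(s$ts_count_histogram), 1)
  expect_equal(unname(s$ts_count_histogram["3"]), 0.1)
  expect_equal(unname(s$ts_count_histogram["0"]), 0.8)
  # a 7-TS cell lands in the "5+" bin
  cells$n_ts[3] <- 7L; cells$transcribing[3] <- TRUE
  expect_equal(unname(populationSummaries(cells)$ts_count_histogram["5+"]),
               0.1)
  # invariant to relabeling and row order
  perm <- cells[sample(nrow(cells)), ]
  perm$cell_id <- perm$cell_id + 100L
  expect_equal(populationSummaries(perm)$percent_transcribing,
               populationSummaries(cells)$percent_transcribing)
  expect_error(populationSummaries(cells[0, ]), "empty")
})

test_that("planted transcription fractions are recovered from fields", {
  nasc <- rep(0, 12); nasc[c(2, 5, 9, 12)] <- 2   # 33% of cells with a TS
  f <- simulateSmfishField(imageShape = c(360L, 360L), nCells = 12L,
                           tsNascentCounts = nasc, cytoSpotsPerCell = 12L,
                           noiseSd = 14, seed = 21)
  ex <- assignCompartment(callSpots(f$exon, "exon", 1.5),
                          f$nucleusMask, f$cytoMask)
  intr <- assignCompartment(callSpots(f$intron, "intron", 1.5),
                            f$nucleusMask, f$cytoMask)
  all <- combineSpotTables(ex, intr)
  ts <- burstSizes(callTranscriptionSites(all), all)
  s <- populationSummaries(cellSummaries(all, ts), ts)
  expect_equal(s$n_cells, 12)
  expect_equal(s$percent_transcribing, 100 * 4 / 12, tolerance = 1e-6)
  expect_gte(s$burst_size_median, 1.8)
  expect_lte(s$burst_size_median, 2.2)
})
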