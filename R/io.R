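# Readers and writers for the plain formats the pipeline exchanges:
# TIFF images and label masks, CSV spot / trace / trajectory tables,
# one-symbol-per-line gene lists, MTX or dense CSV count matrices, and
# JSON summaries.

#' Read a TIFF image or label mask as a numeric matrix
#'
#' 16-bit images are returned on their native integer scale (0..65535);
#' label masks are rounded to integer labels with `asMask = TRUE`.
#'
#' @param path TIFF file.
#' @param asMask return an integer label matrix.
#' @return numeric (or integer) matrix.
#' @export
readImage <- function(path, asMask = FALSE) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  if (asMask) {
    storage.mode(img) <- "integer"
  }
  img
}

#' Write a numeric image or label mask to 16-bit TIFF
#'
#' @param image numeric matrix; values are clipped to `[0, 65535]` and
#'   rounded.
#' @param path output file.
#' @export
writeImage <- function(image, path) {
  v <- pmin(pmax(round(image), 0), 65535) / 65535
  tiff::writeTIFF(v, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write / read a SpotTable as CSV
#'
#' Columns: `channel`, `x`, `y`, `intensity`, `cell_id`, `compartment`.
#'
#' @param spotTable a [SpotTable].
#' @param path CSV file.
#' @param imageShape integer(2), needed when reading (bounds checking).
#' @name spot-table-io
#' @export
writeSpotTable <- function(spotTable, path) {
  utils::write.csv(spots(spotTable), path, row.names = FALSE)
  invisible(path)
}

#' @rdname spot-table-io
#' @export
readSpotTable <- function(path, imageShape = integer(2)) {
  sp <- utils::read.csv(path, stringsAsFactors = FALSE)
  sp$cell_id <- as.integer(sp$cell_id)
  sp$compartment <- as.character(sp$compartment)
  methods::new("SpotTable", spots = sp,
               imageShape = as.integer(imageShape),
               channels = unique(sp$channel))
}

#' Read live-cell intensity traces from CSV
#'
#' Expects columns `allele_id`, `frame`, `intensity` and optionally
#' `population`.
#'
#' @param path CSV file.
#' @param dt frame interval in seconds (default 100).
#' @return a [TraceSet].
#' @export
readTraces <- function(path, dt = 100) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  methods::new("TraceSet", traces = tr, frameInterval = dt)
}

#' Write a TraceSet to CSV
#' @param traceSet a [TraceSet].
#' @param path CSV file.
#' @export
writeTraces <- function(traceSet, path) {
  utils::write.csv(traces(traceSet), path, row.names = FALSE)
  invisible(path)
}

#' Read sorted-population trajectories from CSV
#'
#' Expects columns `population`, `day`, `fraction_transcribing`,
#' `n_cells`, `replicate`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readTrajectories <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a gene list (one symbol per line)
#'
#' @param path TSV/text file, one gene symbol per line.
#' @return character vector (upper-cased, deduplicated).
#' @export
readGeneList <- function(path) {
  unique(toupper(trimws(readLines(path, warn = FALSE))))
}

#' Read a genes x cells count matrix
#'
#' Either MatrixMarket (`.mtx` with companion row/column name files, one
#' name per line) or a dense CSV with gene rownames in the first column.
#'
#' @param path matrix file (`.mtx` or `.csv`).
#' @param genesPath,cellsPath name files for the MTX layout.
#' @return numeric matrix with gene rownames.
#' @export
readCountMatrix <- function(path, genesPath = NULL, cellsPath = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(genesPath)) stop("MTX input needs a gene-name file")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genesPath, warn = FALSE)
    if (!is.null(cellsPath)) {
      colnames(m) <- readLines(cellsPath, warn = FALSE)
    }
    m
  } else {
    d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    as.matrix(d)
  }
}

#' Write an analysis summary as JSON
#'
#' @param x a named list of scalars/vectors.
#' @param path output file.
#' @export
writeSummaryJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
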