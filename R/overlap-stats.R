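# Background-normalized gene-set overlap and expression-variability
# statistics.

#' Harmonize two gene sets onto a common background universe
#'
#' Comparisons between gene sets derived from different assays are only
#' meaningful over genes considered in both: the background universe is
#' the intersection of the two input universes, and each set is filtered
#' to it. Gene symbols are case-folded to upper case before intersection
#' (symbol dialects differ between sources); duplicates are dropped.
#'
#' @param setA,setB character vectors of gene symbols.
#' @param universeA,universeB character vectors, the genes considered by
#'   the assay each set came from. Each set must be contained in its own
#'   universe (violations are dropped with a warning).
#'
#' @return list: `universe` (intersection), `setA`, `setB` (filtered),
#'   and `counts` (before/after sizes).
#' @export
normalizeBackground <- function(setA, universeA, setB, universeB) {
  up <- function(x) unique(toupper(x))
  setA <- up(setA); setB <- up(setB)
  universeA <- up(universeA); universeB <- up(universeB)
  if (!all(setA %in% universeA) || !all(setB %in% universeB)) {
    warning("set members missing from their own universe were dropped")
    setA <- intersect(setA, universeA)
    setB <- intersect(setB, universeB)
  }
  universe <- intersect(universeA, universeB)
  if (length(universe) == 0L) {
    stop("the intersected background universe is empty")
  }
  before <- c(setA = length(setA), setB = length(setB))
  setA <- intersect(setA, universe)
  setB <- intersect(setB, universe)
  list(
    universe = universe, setA = setA, setB = setB,
    counts = data.frame(
      set = c("setA", "setB"), before = as.integer(before),
      after = c(length(setA), length(setB))
    )
  )
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail hypergeometric test of the overlap between two sets drawn
#' from a common background universe: `p = P(X >= nOverlap)` with
#' `X ~ Hypergeometric(nUniverse, nSetB, nSetA)` (the standard enrichment
#' convention, observed value included). The overlap percentage is
#' reported relative to set A.
#'
#' @param nUniverse background universe size.
#' @param nSetA,nSetB set sizes.
#' @param nOverlap observed overlap.
#'
#' @return list: `n_universe`, `n_setA`, `n_setB`, `n_overlap`,
#'   `overlap_percent` (= `100 * nOverlap / nSetA`), `p_value`.
#' @examples
#' # 380 of 934 genes with differential H3K27me3 are also differentially
#' # expressed (1913 DEGs out of 19703 expressed genes): 40.7% overlap
#' hypergeometricOverlap(19703, 934, 1913, 380)
#' @export
hypergeometricOverlap <- function(nUniverse, nSetA, nSetB, nOverlap) {
  counts <- c(nUniverse, nSetA, nSetB, nOverlap)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (nSetA > nUniverse || nSetB > nUniverse ||
      nOverlap > min(nSetA, nSetB) ||
      nSetA + nSetB - nOverlap > nUniverse) {
    stop("infeasible counts for a hypergeometric overlap")
  }
  if (nSetA == 0L) stop("'nSetA' must be > 0 to define an overlap percent")
  p <- stats::phyper(nOverlap - 1, nSetB, nUniverse - nSetB, nSetA,
                     lower.tail = FALSE)
  list(
    n_universe = as.integer(nUniverse), n_setA = as.integer(nSetA),
    n_setB = as.integer(nSetB), n_overlap = as.integer(nOverlap),
    overlap_percent = 100 * nOverlap / nSetA, p_value = p
  )
}

#' Overlap test from explicit gene sets
#'
#' Convenience wrapper: harmonizes the sets with [normalizeBackground()]
#' and runs [hypergeometricOverlap()] on the resulting counts.
#'
#' @inheritParams normalizeBackground
#' @return as [hypergeometricOverlap()], plus `genes` (the overlapping
#'   symbols).
#' @export
overlapTest <- function(setA, universeA, setB, universeB) {
  h <- normalizeBackground(setA, universeA, setB, universeB)
  shared <- intersect(h$setA, h$setB)
  res <- hypergeometricOverlap(length(h$universe), length(h$setA),
                               length(h$setB), length(shared))
  res$genes <- sort(shared)
  res
}

#' Expression variability (CV) comparison between two gene groups
#'
#' Computes the per-gene coefficient of variation across cells
#' (`sd / mean`, sample sd with `n - 1` denominator) from a genes x cells
#' count matrix, then compares the CV distributions of two disjoint gene
#' groups (e.g. promoters with vs without differential H3K27me3) with a
#' Welch two-sided t-test. Genes with zero mean have no defined CV and
#' are excluded (and reported), never assigned an infinite value.
#'
#' @param counts numeric genes x cells matrix with rownames; non-negative.
#' @param groupA,groupB disjoint character vectors of gene ids present in
#'   the matrix rows (case-insensitive).
#' @param normalize `"none"` (raw counts, default) or `"cpm"`
#'   (counts-per-million column scaling before the CV).
#'
#' @return list: `cv_table` (data.frame `gene`, `group`, `mean`, `sd`,
#'   `cv`), `test` (`htest` from [stats::t.test()]), `p_value`,
#'   `n_zero_mean_excluded`.
#' @export
cvByGroup <- function(counts, groupA, groupB,
                      normalize = c("none", "cpm")) {
  normalize <- match.arg(normalize)
  if (is.null(rownames(counts))) stop("'counts' must have gene rownames")
  if (any(counts < 0)) stop("'counts' must be non-negative")
  rn <- toupper(rownames(counts))
  groupA <- unique(toupper(groupA))
  groupB <- unique(toupper(groupB))
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  if (!all(c(groupA, groupB) %in% rn)) {
    stop("all group genes must be rows of the matrix")
  }
  if (normalize == "cpm") {
    cs <- colSums(counts)
    if (any(cs == 0)) stop("cannot CPM-normalize all-zero cells")
    counts <- sweep(counts, 2, cs, "/") * 1e6
  }
  sel <- c(groupA, groupB)
  m <- counts[match(sel, rn), , drop = FALSE]
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  tab <- data.frame(
    gene = sel,
    group = rep(c("A", "B"), c(length(groupA), length(groupB))),
    mean = mu, sd = sdv, cv = ifelse(mu > 0, sdv / mu, NA_real_),
    row.names = NULL, stringsAsFactors = FALSE
  )
  nZero <- sum(is.na(tab$cv))
  keep <- !is.na(tab$cv)
  if (sum(keep & tab$group == "A") < 2L ||
      sum(keep & tab$group == "B") < 2L) {
    stop("each group needs >= 2 genes with a defined CV")
  }
  tt <- stats::t.test(cv ~ group, data = tab[keep, ],
                      alternative = "two.sided", var.equal = FALSE)
  list(cv_table = tab, test = tt, p_value = tt$p.value,
       n_zero_mean_excluded = nZero)
}
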