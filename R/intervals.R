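#' Construct a table of genomic intervals
#'
#' Intervals are the package's universal coordinate currency: a plain
#' data.frame with columns `chrom`, `start`, `end` (and optionally `strand`),
#' using the BED convention of 0-based, half-open coordinates. All readers
#' and pipeline stages consume and produce this shape, so intervals can be
#' built by hand, read from BED, or taken from any stage's output
#' interchangeably.
#'
#' @param chrom character vector of contig names.
#' @param start,end integer vectors; 0 <= start < end.
#' @param strand optional strand vector in `c("+", "-", "*")`; `"*"` means
#'   unstranded.
#' @param ... further per-interval columns recycled to length.
#' @return A data.frame with class `c("genomic_intervals", "data.frame")`.
#' @examples
#' genomic_intervals("chr1", 0L, 500L)
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL, ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (!is.null(strand)) df$strand <- as.character(strand)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Validate an interval table
#'
#' Checks the invariants every interval must satisfy: non-empty contig names
#' and `0 <= start < end`. Called by constructors and readers; exported so
#' pipeline steps can assert inputs.
#'
#' @param x data.frame with `chrom`, `start`, `end` columns.
#' @param index optional named integer vector of contig lengths; when given,
#'   every interval must fit inside its contig.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, index = NULL) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom) | !nzchar(x$chrom)))
    stop("interval with empty contig name")
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) at row ", bad[1],
         ": ", x$chrom[bad[1]], ":", x$start[bad[1]], "-", x$end[bad[1]])
  if (!is.null(index)) {
    len <- index[x$chrom]
    if (any(is.na(len)))
      stop("interval on contig absent from genome index: ",
           x$chrom[which(is.na(len))[1]])
    if (any(x$end > len))
      stop("interval extends past contig end on ", x$chrom[which(x$end > len)[1]])
  }
  invisible(x)
}

# 0-based half-open data.frame -> GRanges (1-based closed), internal
as_gr <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    s <- x$strand
    s[is.na(s) | !(s %in% c("+", "-"))] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(x$start + 1L, x$end),
                         strand = strand)
}

# GRanges -> 0-based half-open data.frame, internal
from_gr <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Merge overlapping and adjacent intervals
#'
#' Flattens an interval set so that no two intervals overlap or touch, the
#' precondition for base counting with [overlap_bases()].
#'
#' @param x interval data.frame.
#' @return interval data.frame sorted by (chrom, start) with overlaps merged.
#' @export
flatten_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  x$strand <- NULL
  out <- from_gr(GenomicRanges::reduce(as_gr(x)))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Count bases of intervals covered by a flattened interval set
#'
#' For each query interval, the number of its bases that fall inside the
#' (merged) reference set; each base is counted at most once. The reference
#' is flattened internally, so overlapping reference intervals are safe.
#'
#' @param a interval data.frame (queries).
#' @param s interval data.frame (reference set).
#' @return integer vector of covered base counts, one per row of `a`.
#' @examples
#' a <- genomic_intervals("chrA", 0L, 500L)
#' s <- genomic_intervals(c("chrA", "chrA"), c(400L, 450L), c(600L, 700L))
#' overlap_bases(a, s)  # 100
#' @export
overlap_bases <- function(a, s) {
  validate_intervals(a)
  if (nrow(a) == 0) return(integer(0))
  if (nrow(s) == 0) return(integer(nrow(a)))
  sf <- flatten_intervals(s)
  ga <- as_gr(a)
  gs <- as_gr(sf)
  hits <- GenomicRanges::findOverlaps(ga, gs, ignore.strand = TRUE)
  out <- integer(nrow(a))
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(ga)[qi], IRanges::ranges(gs)[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, qi, sum)
    out[as.integer(names(agg))] <- as.integer(agg)
  }
  out
}

#' Tile a genome into fixed-size non-overlapping windows
#'
#' Left-aligned tiling per contig; a trailing remainder shorter than the
#' window is dropped, so every emitted window has exactly `window` bases.
#'
#' @param index named integer vector: contig name -> length in bp.
#' @param window window size in bp (default 500, the DMR window size).
#' @return interval data.frame of windows, ordered by (contig, start).
#' @examples
#' tile_genome(c(chrA = 1500L), 500L)  # 3 windows
#' @export
tile_genome <- function(index, window = 500L) {
  stopifnot(window > 0, length(index) > 0, !is.null(names(index)))
  window <- as.integer(window)
  pieces <- lapply(names(index), function(ctg) {
    n <- index[[ctg]] %/% window
    if (n == 0) return(NULL)
    starts <- (seq_len(n) - 1L) * window
    data.frame(chrom = ctg, start = starts, end = starts + window,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
  class(out) <- c("genomic_intervals", "data.frame")
  out
}
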