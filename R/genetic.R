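# Genetic conservation of tsDMRs: overlap with conserved elements
# (phastCons-style BED) and the conservation-score (phyloP-style) binning
# that relates quantitative sequence conservation to epigenetic
# conservation.

#' Call genetic conservation by conserved-element overlap
#'
#' A region is genetically conserved when at least `min_frac` of its bases
#' overlap conserved elements (boundary inclusive: exactly 20% qualifies).
#'
#' @param regions interval data.frame.
#' @param elements conserved-element intervals (flattened internally).
#' @param min_frac minimum overlap fraction (default 0.2).
#' @return data.frame with `overlap_fraction` and `conserved`.
#' @export
genetic_conservation <- function(regions, elements, min_frac = 0.2) {
  ov <- overlap_bases(regions, elements)
  frac <- ov / (regions$end - regions$start)
  data.frame(overlap_fraction = frac, conserved = frac >= min_frac)
}

#' Epigenetic-conservation curve over conservation-score bins
#'
#' Splits each tsDMR window into fixed-size subwindows, maps each to the
#' comparison species, averages the conservation score over the orthologous
#' bases, ranks the mapped subwindows by mean score, partitions them into
#' `n_bins` equal-sized sets (a remainder is assigned one-per-bin from the
#' lowest bins; ties in score are broken by genomic order so the binning is
#' deterministic), and reports the fraction of EC members per bin.
#'
#' Epigenetic conservation is evaluated at the subwindow level by default
#' (`level = "subwindow"`): a subwindow is EC iff its own ortholog shows the
#' conserved tissue pattern via [classify_conservation()]; subwindows whose
#' orthologs lack CpGs are dropped, mirroring the CpG requirement of the
#' classifier. With `level = "parent"` every subwindow inherits its parent
#' window's EC/ENC call, which must then be present as a `status` column of
#' `dmrs`.
#'
#' @param dmrs tsDMR calls (`chrom`, `start`, `end`, `target_tissue`; plus
#'   `status` for `level = "parent"`).
#' @param chains `chain_set` to the comparison species.
#' @param score_track score track on the comparison species' assembly.
#' @param tracks named list of the comparison species' methylome tracks
#'   (needed for `level = "subwindow"`).
#' @param n_bins number of equal-sized score bins (default 100).
#' @param subwindow subwindow size in bp (default 50); window length must be
#'   divisible by it.
#' @param level `"subwindow"` or `"parent"` (see Details).
#' @param min_cover,max_span liftover rules for the subwindows, defaulting
#'   to the same 50%/1000-bp rules as full windows.
#' @return data.frame with one row per bin: `bin`, `n`, `score_min`,
#'   `score_max`, `ec_fraction`.
#' @export
phylop_ec_curve <- function(dmrs, chains, score_track, tracks = NULL,
                            n_bins = 100L, subwindow = 50L,
                            level = c("subwindow", "parent"),
                            min_cover = 0.5, max_span = 1000L) {
  level <- match.arg(level)
  wlen <- unique(dmrs$end - dmrs$start)
  if (length(wlen) != 1 || wlen %% subwindow != 0)
    stop("tsDMR length must be a single value divisible by the subwindow size")
  k <- wlen %/% subwindow
  n <- nrow(dmrs)
  sub <- data.frame(
    chrom = rep(dmrs$chrom, each = k),
    start = rep(dmrs$start, each = k) + rep((seq_len(k) - 1L) * subwindow, n),
    parent = rep(seq_len(n), each = k),
    stringsAsFactors = FALSE)
  sub$end <- sub$start + subwindow
  lifted <- liftover_intervals(chains, sub[, c("chrom", "start", "end")],
                               min_cover = min_cover, max_span = max_span)
  keep <- which(lifted$mapped)
  if (!length(keep)) stop("no subwindow mapped to the comparison species")
  tgt <- data.frame(chrom = lifted$target_chrom[keep],
                    start = lifted$target_start[keep],
                    end = lifted$target_end[keep])
  score <- mean_score(score_track, tgt)
  if (level == "subwindow") {
    if (is.null(tracks)) stop("subwindow-level EC needs methylome tracks")
    subcall <- classify_conservation(
      data.frame(target_tissue = dmrs$target_tissue[sub$parent[keep]]),
      lifted[keep, ], tracks)
    status <- subcall$status
  } else {
    if (!"status" %in% names(dmrs))
      stop("parent-level EC needs a status column on dmrs")
    status <- dmrs$status[sub$parent[keep]]
  }
  ok <- which(!is.na(score) & status %in% c("EC", "ENC"))
  if (length(ok) < n_bins)
    stop("only ", length(ok), " scored subwindows; use n_bins <= ", length(ok))
  d <- data.frame(score = score[ok], ec = status[ok] == "EC",
                  chrom = tgt$chrom[ok], start = tgt$start[ok])
  d <- d[order(d$score, d$chrom, d$start), ]
  m <- nrow(d)
  base <- m %/% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, m %% n_bins), rep(0L, n_bins - m %% n_bins))
  bin <- rep(seq_len(n_bins), times = sizes)
  data.frame(
    bin = seq_len(n_bins),
    n = sizes,
    score_min = tapply(d$score, bin, min),
    score_max = tapply(d$score, bin, max),
    ec_fraction = as.numeric(tapply(d$ec, bin, mean)),
    row.names = NULL)
}
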