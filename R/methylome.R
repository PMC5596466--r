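# Per-CpG methylation tracks. A track holds single-CpG methylation levels
# (fractions in [0,1]) for one species x tissue; region means over tracks
# drive both tsDMR calling (via 500-bp window scores) and EC classification
# of orthologous regions.

#' Create a methylome track
#'
#' @param sites data.frame with `chrom`, `pos` (0-based position of the C of
#'   a CpG on the + strand) and `level` in `[0, 1]`.
#' @param species,tissue labels.
#' @return object of class `methylome_track`; sites are sorted by
#'   (chrom, pos) with per-contig cumulative level sums precomputed.
#' @export
methylome_track <- function(sites, species = NA_character_, tissue = NA_character_) {
  stopifnot(all(c("chrom", "pos", "level") %in% names(sites)))
  if (nrow(sites)) {
    if (any(sites$level < 0 | sites$level > 1, na.rm = TRUE))
      stop("methylation level outside [0, 1]")
    if (anyNA(sites$level)) stop("missing methylation level")
    sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
    if (any(duplicated(sites[, c("chrom", "pos")])))
      stop("duplicated CpG position in track ", species, "/", tissue)
  }
  idx <- split(seq_len(nrow(sites)), sites$chrom)
  by_chrom <- lapply(idx, function(i)
    list(pos = sites$pos[i], cum = cumsum(sites$level[i])))
  structure(list(species = species, tissue = tissue,
                 sites = sites, by_chrom = by_chrom),
            class = "methylome_track")
}

#' @export
print.methylome_track <- function(x, ...) {
  cat(sprintf("methylome_track %s/%s: %d CpGs on %d contig(s)\n",
              x$species, x$tissue, nrow(x$sites), length(x$by_chrom)))
  invisible(x)
}

#' Read a methylome track from bedGraph
#'
#' CpGs may be encoded as 1-bp or 2-bp features; the start coordinate is
#' taken as the CpG position (both dialects occur in WGBS exports).
#'
#' @param path bedGraph path (chrom, pos, pos+1 or pos+2, level).
#' @param species,tissue labels attached to the track.
#' @return a `methylome_track`.
#' @export
read_methylome <- function(path, species = NA_character_, tissue = NA_character_) {
  bg <- read_bedgraph(path)
  w <- bg$end - bg$start
  if (any(w > 2))
    stop("bedGraph feature wider than 2 bp in ", path,
         ": not a per-CpG methylation track")
  methylome_track(data.frame(chrom = bg$chrom, pos = bg$start,
                             level = bg$score, stringsAsFactors = FALSE),
                  species, tissue)
}

#' Write a methylome track as bedGraph (1-bp features)
#' @param track a `methylome_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_methylome <- function(track, path) {
  write_bedgraph(data.frame(chrom = track$sites$chrom,
                            start = track$sites$pos,
                            end = track$sites$pos + 1L,
                            score = track$sites$level), path)
}

#' Mean methylation of regions over a track
#'
#' The region mean is the sum of methylation levels at CpGs with position in
#' `[start, end)` divided by the CpG count; regions without CpGs get an
#' undefined mean (`NA`) and `n_cpg = 0`.
#'
#' @param track a `methylome_track`.
#' @param x interval data.frame.
#' @return data.frame with `mean_level` and `n_cpg`, one row per region.
#' @export
region_mean <- function(track, x) {
  validate_intervals(x)
  n <- nrow(x)
  out <- data.frame(mean_level = rep(NA_real_, n), n_cpg = integer(n))
  for (ctg in unique(x$chrom)) {
    bc <- track$by_chrom[[ctg]]
    if (is.null(bc)) next
    rows <- which(x$chrom == ctg)
    lo <- findInterval(x$start[rows] - 1L, bc$pos)   # CpGs with pos < start
    hi <- findInterval(x$end[rows] - 1L, bc$pos)     # CpGs with pos < end
    cnt <- hi - lo
    cum0 <- c(0, bc$cum)
    s <- cum0[hi + 1L] - cum0[lo + 1L]
    out$n_cpg[rows] <- cnt
    out$mean_level[rows] <- ifelse(cnt > 0, s / cnt, NA_real_)
  }
  out
}

#' Categorize a methylation level into the three methylation states
#'
#' States follow the standard categorical scheme: unmethylated (0) below
#' 0.3, methylated (2) above 0.7, intermediate (1) otherwise. The
#' inequalities are strict, so the boundary values 0.3 and 0.7 are both
#' intermediate.
#'
#' @param level numeric vector of mean methylation levels in `[0, 1]`
#'   (`NA` allowed, propagated).
#' @return integer vector of states in `{0, 1, 2}`.
#' @examples
#' categorize_methylation(c(0.1, 0.3, 0.5, 0.7, 0.75))
#' @export
categorize_methylation <- function(level) {
  if (any(level < 0 | level > 1, na.rm = TRUE))
    stop("methylation level outside [0, 1]")
  ifelse(level < 0.3, 0L, ifelse(level > 0.7, 2L, 1L))
}
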