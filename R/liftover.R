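# Chain-based coordinate mapping with the pipeline's orthology rules:
# an interval maps through the single best-scoring chain overlapping it;
# it is accepted only when >= min_cover of its bases fall inside aligned
# blocks and the target envelope spans at most max_span bases.

best_chain_idx <- function(chains, chrom, start, end) {
  cand <- attr(chains, "by_target")[[chrom]]
  if (is.null(cand)) return(NA_integer_)
  keep <- cand[vapply(cand, function(i)
    chains[[i]]$tStart < end && chains[[i]]$tEnd > start, logical(1))]
  if (!length(keep)) return(NA_integer_)
  scores <- vapply(keep, function(i) chains[[i]]$score, numeric(1))
  top <- keep[scores == max(scores)]
  if (length(top) > 1) {
    ids <- vapply(top, function(i) chains[[i]]$id, character(1))
    num <- suppressWarnings(as.numeric(ids))
    top <- if (!any(is.na(num))) top[order(num)] else top[order(ids)]
  }
  top[1]
}

# covered bases and forward-strand envelope of [start, end) through one chain
map_through_chain <- function(ch, start, end) {
  bs <- ch$t_bs
  sz <- ch$blocks$size
  i <- which(bs < end & bs + sz > start)
  if (!length(i))
    return(list(covered = 0L, lo = NA_integer_, hi = NA_integer_))
  o1 <- pmax(start, bs[i]) - bs[i]
  o2 <- pmin(end, bs[i] + sz[i]) - bs[i] - 1L
  covered <- sum(o2 - o1 + 1L)
  if (ch$qStrand == "+") {
    lo <- min(ch$q_bs[i] + o1)
    hi <- max(ch$q_bs[i] + o2) + 1L
  } else {
    lo <- min(ch$qSize - 1L - (ch$q_bs[i] + o2))
    hi <- max(ch$qSize - 1L - (ch$q_bs[i] + o1)) + 1L
  }
  list(covered = as.integer(covered), lo = as.integer(lo), hi = as.integer(hi))
}

#' Map intervals to another assembly through a chain set
#'
#' For each interval, the single highest-scoring chain whose target span
#' overlaps it is selected (ties broken by lowest chain id). The covered
#' fraction is the share of the interval's bases inside that chain's aligned
#' blocks; the target interval is the forward-strand envelope of their
#' images. An interval is reported unmapped (not an error) when no chain
#' overlaps it, when `covered_fraction < min_cover`, or when the envelope
#' exceeds `max_span` bases.
#'
#' @param chains a `chain_set` from [read_chain()], target side = source
#'   assembly of `x`.
#' @param x interval data.frame on the chains' target assembly.
#' @param min_cover minimum mapped fraction of source bases (default 0.5).
#' @param max_span maximum target envelope span in bp (default 1000).
#' @return data.frame with the source columns of `x` plus `mapped`,
#'   `target_chrom`, `target_start`, `target_end`, `target_strand`,
#'   `covered_fraction`, `chain_id`; target fields are `NA` when unmapped.
#' @export
liftover_intervals <- function(chains, x, min_cover = 0.5, max_span = 1000L) {
  validate_intervals(x)
  n <- nrow(x)
  res <- data.frame(
    mapped = logical(n), target_chrom = NA_character_,
    target_start = NA_integer_, target_end = NA_integer_,
    target_strand = NA_character_, covered_fraction = 0,
    chain_id = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    i <- best_chain_idx(chains, x$chrom[k], x$start[k], x$end[k])
    if (is.na(i)) next
    ch <- chains[[i]]
    m <- map_through_chain(ch, x$start[k], x$end[k])
    frac <- m$covered / (x$end[k] - x$start[k])
    res$covered_fraction[k] <- frac
    res$chain_id[k] <- ch$id
    if (m$covered == 0L) next
    span <- m$hi - m$lo
    if (frac >= min_cover && span <= max_span) {
      res$mapped[k] <- TRUE
      res$target_chrom[k] <- ch$qName
      res$target_start[k] <- m$lo
      res$target_end[k] <- m$hi
      res$target_strand[k] <- ch$qStrand
    }
  }
  cbind(as.data.frame(x), res)
}

#' Map single base positions through a chain set
#'
#' A position maps iff it lies inside an aligned block of the best
#' overlapping chain; gap bases have no image.
#'
#' @param chains a `chain_set`.
#' @param chrom contig name(s), recycled against `pos`.
#' @param pos 0-based positions.
#' @return data.frame `chrom`, `pos`, `target_chrom`, `target_pos`,
#'   `target_strand` (`NA`s when unmapped).
#' @export
liftover_points <- function(chains, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  out <- data.frame(chrom = chrom, pos = pos,
                    target_chrom = NA_character_, target_pos = NA_integer_,
                    target_strand = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    i <- best_chain_idx(chains, chrom[k], pos[k], pos[k] + 1L)
    if (is.na(i)) next
    ch <- chains[[i]]
    j <- findInterval(pos[k], ch$t_bs)
    if (j == 0L) next
    off <- pos[k] - ch$t_bs[j]
    if (off >= ch$blocks$size[j]) next
    qpos <- ch$q_bs[j] + off
    if (ch$qStrand == "-") qpos <- ch$qSize - 1L - qpos
    out$target_chrom[k] <- ch$qName
    out$target_pos[k] <- qpos
    out$target_strand[k] <- ch$qStrand
  }
  out
}

#' Build three-way orthologous regions
#'
#' Given pairwise liftover results of the same source regions into species B
#' (e.g. mouse) and species C (e.g. human), lifts each B image onward to C
#' through `bc_chains` and accepts a region as three-way orthologous when
#' the direct C image and the via-B C image overlap by at least `min_recip`
#' of the shorter interval.
#'
#' @param ab liftover result of the source regions into species B
#'   (from [liftover_intervals()]).
#' @param ac liftover result of the same regions into species C.
#' @param bc_chains `chain_set` from B to C.
#' @param min_recip minimum reconciliation overlap fraction (default 0.9).
#' @param min_cover,max_span rules for the B-to-C liftover leg (defaults as
#'   in [liftover_intervals()]).
#' @return data.frame of accepted triples: source `chrom`/`start`/`end`,
#'   `b_chrom`/`b_start`/`b_end`, `c_chrom`/`c_start`/`c_end` (direct image),
#'   `reconciliation_overlap`, and `source_row` indexing into `ab`.
#' @export
build_threeway <- function(ab, ac, bc_chains, min_recip = 0.9,
                           min_cover = 0.5, max_span = 1000L) {
  stopifnot(nrow(ab) == nrow(ac),
            all(ab$chrom == ac$chrom), all(ab$start == ac$start),
            all(ab$end == ac$end))
  both <- which(ab$mapped & ac$mapped)
  if (!length(both))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), b_chrom = character(0),
                      b_start = integer(0), b_end = integer(0),
                      c_chrom = character(0), c_start = integer(0),
                      c_end = integer(0), reconciliation_overlap = numeric(0),
                      source_row = integer(0)))
  bimg <- data.frame(chrom = ab$target_chrom[both],
                     start = ab$target_start[both],
                     end = ab$target_end[both])
  via <- liftover_intervals(bc_chains, bimg,
                            min_cover = min_cover, max_span = max_span)
  dir_c <- ac[both, ]
  ov <- rep(0, length(both))
  ok <- via$mapped & !is.na(via$target_chrom) &
    via$target_chrom == dir_c$target_chrom
  ok[is.na(ok)] <- FALSE
  if (any(ok)) {
    lo <- pmax(via$target_start[ok], dir_c$target_start[ok])
    hi <- pmin(via$target_end[ok], dir_c$target_end[ok])
    inter <- pmax(0L, hi - lo)
    shorter <- pmin(via$target_end[ok] - via$target_start[ok],
                    dir_c$target_end[ok] - dir_c$target_start[ok])
    ov[ok] <- inter / shorter
  }
  acc <- which(ov >= min_recip)
  data.frame(chrom = ab$chrom[both][acc],
             start = ab$start[both][acc],
             end = ab$end[both][acc],
             b_chrom = bimg$chrom[acc], b_start = bimg$start[acc],
             b_end = bimg$end[acc],
             c_chrom = dir_c$target_chrom[acc],
             c_start = dir_c$target_start[acc],
             c_end = dir_c$target_end[acc],
             reconciliation_overlap = ov[acc],
             source_row = both[acc],
             stringsAsFactors = FALSE)
}
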