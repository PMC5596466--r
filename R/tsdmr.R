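# Tissue-specific hypomethylated DMR calling on fixed 500-bp windows.
# A window is a tsDMR for its target tissue when either
#   criterion 1: target mean level < 0.3 and both other tissues >= 0.3, or
#   criterion 2: target level in [0.3, 0.7] and both other tissues > 0.7
# holds, optionally gated by an upstream differential-methylation q-value
# (< q_threshold). Hypermethylated tsDMRs are deliberately not called.

#' Window methylation scores for a set of tracks
#'
#' Computes per-window mean methylation for each tissue track, the input to
#' [call_tsdmrs()].
#'
#' @param tracks named list of `methylome_track` objects (names = tissues),
#'   all from the same species/assembly.
#' @param windows interval data.frame of equal-length windows (e.g. from
#'   [tile_genome()]).
#' @return data.frame: `chrom`, `start`, `end`, one `level_<tissue>` column
#'   per track, and `n_cpg` (minimum CpG count across tissues).
#' @export
window_scores <- function(tracks, windows) {
  stopifnot(length(tracks) >= 1, !is.null(names(tracks)))
  out <- as.data.frame(windows)[, c("chrom", "start", "end")]
  ncpg <- NULL
  for (tis in names(tracks)) {
    rm_ <- region_mean(tracks[[tis]], windows)
    out[[paste0("level_", tis)]] <- rm_$mean_level
    ncpg <- if (is.null(ncpg)) rm_$n_cpg else pmin(ncpg, rm_$n_cpg)
  }
  out$n_cpg <- ncpg
  out
}

#' Call a single window against one target tissue
#'
#' @param levels named numeric vector of exactly three per-tissue mean
#'   levels.
#' @param target name of the candidate hypomethylated tissue.
#' @param qvalue optional per-window differential-methylation q-value
#'   (`NA` = no upstream filter).
#' @param q_threshold q-value cutoff (default `1e-5`).
#' @return integer criterion (1 or 2) if the window is a tsDMR for `target`,
#'   otherwise `NA`.
#' @export
call_tsdmr_window <- function(levels, target, qvalue = NA_real_,
                              q_threshold = 1e-5) {
  if (length(levels) != 3)
    stop("tsDMR criteria are defined for exactly 3 tissues")
  if (!target %in% names(levels)) stop("unknown target tissue: ", target)
  if (!is.na(qvalue) && qvalue >= q_threshold) return(NA_integer_)
  lt <- levels[[target]]
  lo <- unname(levels[setdiff(names(levels), target)])
  if (anyNA(c(lt, lo))) return(NA_integer_)
  if (lt < 0.3 && all(lo >= 0.3)) return(1L)
  if (lt >= 0.3 && lt <= 0.7 && all(lo > 0.7)) return(2L)
  NA_integer_
}

#' Call tissue-specific hypomethylated DMRs on window scores
#'
#' Applies the two hypomethylation criteria to every window for every
#' candidate target tissue. The criteria make the per-tissue call sets
#' disjoint by construction (a window hypomethylated in one tissue cannot
#' satisfy either criterion for another); this is asserted on every run.
#'
#' @param scores data.frame from [window_scores()] (or with the same
#'   `level_<tissue>` columns), optionally with a `qvalue` column.
#' @param tissues character vector of exactly three tissue names.
#' @param q_threshold upstream q-value cutoff (default `1e-5`); ignored for
#'   windows with no/`NA` q-value.
#' @return data.frame of calls: `chrom`, `start`, `end`, `target_tissue`,
#'   `criterion`.
#' @export
call_tsdmrs <- function(scores, tissues, q_threshold = 1e-5) {
  if (length(tissues) != 3)
    stop("tsDMR criteria are defined for exactly 3 tissues")
  lv <- lapply(tissues, function(t) {
    col <- paste0("level_", t)
    if (!col %in% names(scores)) stop("missing score column ", col)
    scores[[col]]
  })
  names(lv) <- tissues
  qpass <- if ("qvalue" %in% names(scores))
    is.na(scores$qvalue) | scores$qvalue < q_threshold
  else rep(TRUE, nrow(scores))
  calls <- list()
  for (t in tissues) {
    lt <- lv[[t]]
    others <- setdiff(tissues, t)
    o1 <- lv[[others[1]]]; o2 <- lv[[others[2]]]
    ok <- !is.na(lt) & !is.na(o1) & !is.na(o2) & qpass
    crit1 <- ok & lt < 0.3 & o1 >= 0.3 & o2 >= 0.3
    crit2 <- ok & lt >= 0.3 & lt <= 0.7 & o1 > 0.7 & o2 > 0.7
    hit <- which(crit1 | crit2)
    if (length(hit))
      calls[[t]] <- data.frame(
        chrom = scores$chrom[hit], start = scores$start[hit],
        end = scores$end[hit], target_tissue = t,
        criterion = ifelse(crit1[hit], 1L, 2L),
        stringsAsFactors = FALSE)
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               target_tissue = character(0), criterion = integer(0))
  rownames(out) <- NULL
  key <- paste(out$chrom, out$start)
  if (anyDuplicated(key))
    stop("internal error: window called as tsDMR for more than one tissue")
  out[order(out$chrom, out$start), , drop = FALSE]
}
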