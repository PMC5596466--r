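# Feature annotation, matched background sampling, and the shared
# enrichment statistics: per-stratum fold changes with Pearson chi-square
# tests (no continuity correction) and Benjamini-Hochberg correction.

# run expr with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Bundle genomic annotations for feature labeling
#'
#' Derives the label interval sets used by [assign_feature()]: promoters
#' (2 kb upstream to 0.5 kb downstream of each TSS, strand-aware), exons and
#' introns from the gene table, gene loci (for the intergenic complement),
#' plus the supplied CGI and repeat (TE) tracks and optional UTR tracks.
#'
#' @param genes gene table from [read_genepred()].
#' @param cgi,repeats interval data.frames (CpG islands, repeats/TEs).
#' @param utr5,utr3 optional UTR interval data.frames.
#' @param promoter_up,promoter_down promoter extent around the TSS in bp.
#' @return named list of flattened interval sets, class
#'   `annotation_bundle`.
#' @export
annotation_bundle <- function(genes, cgi = NULL, repeats = NULL,
                              utr5 = NULL, utr3 = NULL,
                              promoter_up = 2000L, promoter_down = 500L) {
  emptyiv <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0))
  prom <- data.frame(
    chrom = genes$chrom,
    start = pmax(0L, ifelse(genes$strand == "-",
                            genes$tss - promoter_down,
                            genes$tss - promoter_up)),
    end = ifelse(genes$strand == "-",
                 genes$tss + promoter_up,
                 genes$tss + promoter_down))
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i)
    data.frame(chrom = genes$chrom[i],
               start = genes$exon_starts[[i]],
               end = genes$exon_ends[[i]])))
  loci <- data.frame(chrom = genes$chrom, start = genes$txStart,
                     end = genes$txEnd)
  intron <- if (is.null(exons)) emptyiv else {
    gl <- as_gr(flatten_intervals(loci))
    ge <- as_gr(flatten_intervals(exons))
    from_gr(GenomicRanges::setdiff(gl, ge, ignore.strand = TRUE))
  }
  sets <- list(promoter = prom,
               CGI = if (is.null(cgi)) emptyiv else cgi,
               utr5 = if (is.null(utr5)) emptyiv else utr5,
               exon = if (is.null(exons)) emptyiv else exons,
               utr3 = if (is.null(utr3)) emptyiv else utr3,
               TE = if (is.null(repeats)) emptyiv else repeats,
               intron = intron,
               .loci = loci)
  out <- lapply(sets, function(s) if (nrow(s)) flatten_intervals(s) else s)
  class(out) <- "annotation_bundle"
  out
}

#' Assign one genomic-feature label per window
#'
#' A window is associated with a feature only if more than 50% of its bases
#' overlap that feature's intervals. When several features qualify the
#' fixed precedence order decides (configurable): promoter > CGI > 5'UTR >
#' exon > 3'UTR > TE > intron. Windows with no qualifying feature are
#' `intergenic` when they do not intersect a gene locus, otherwise `other`.
#'
#' @param windows interval data.frame.
#' @param bundle an [annotation_bundle()].
#' @param precedence label order tried first-to-last.
#' @param min_frac minimum covered fraction, strict (default 0.5, i.e.
#'   "> 50%").
#' @return character vector of labels.
#' @export
assign_feature <- function(windows, bundle,
                           precedence = c("promoter", "CGI", "utr5", "exon",
                                          "utr3", "TE", "intron"),
                           min_frac = 0.5) {
  n <- nrow(windows)
  len <- windows$end - windows$start
  lab <- rep(NA_character_, n)
  for (f in precedence) {
    s <- bundle[[f]]
    if (is.null(s) || nrow(s) == 0) next
    todo <- which(is.na(lab))
    if (!length(todo)) break
    frac <- overlap_bases(windows[todo, , drop = FALSE], s) / len[todo]
    lab[todo[frac > min_frac]] <- f
  }
  todo <- which(is.na(lab))
  if (length(todo)) {
    ing <- overlap_bases(windows[todo, , drop = FALSE], bundle$.loci) > 0
    lab[todo] <- ifelse(ing, "other", "intergenic")
  }
  lab
}

#' Sample a genomic-distribution-matched background
#'
#' Draws, for every feature label, exactly as many windows from the universe
#' as the target set holds with that label — uniformly without replacement
#' within each stratum, deterministically for a given seed.
#'
#' @param target_labels character labels of the target windows.
#' @param universe interval data.frame of candidate windows.
#' @param universe_labels labels of the universe windows.
#' @param seed RNG seed.
#' @param replace sample with replacement when a stratum is too small
#'   (default FALSE: such a stratum is an error naming the label).
#' @return interval data.frame of background windows with a `label` column;
#'   per-label counts equal the target's exactly.
#' @export
sample_matched <- function(target_labels, universe, universe_labels, seed,
                           replace = FALSE) {
  stopifnot(nrow(universe) == length(universe_labels))
  want <- table(target_labels)
  rows <- with_seed(seed, {
    unlist(lapply(names(want), function(lb) {
      pool <- which(universe_labels == lb)
      k <- want[[lb]]
      if (length(pool) < k && !replace)
        stop("universe stratum '", lb, "' has ", length(pool),
             " windows but ", k, " are needed")
      # sample() would misbehave on a length-1 pool
      if (length(pool) == 1 && !replace) rep(pool, k)
      else pool[sample.int(length(pool), k, replace = replace)]
    }))
  })
  out <- universe[rows, , drop = FALSE]
  out$label <- universe_labels[rows]
  rownames(out) <- NULL
  out
}

#' Distance from regions to the nearest TSS
#'
#' The shortest absolute distance from each region's start to any TSS,
#' irrespective of gene strand (the TSS itself is strand-aware: txStart on
#' `+`, txEnd on `-`). Regions on contigs without genes get `NA`.
#'
#' @param regions interval data.frame.
#' @param genes gene table from [read_genepred()].
#' @return numeric vector of distances in bp.
#' @export
nearest_tss <- function(regions, genes) {
  out <- rep(NA_real_, nrow(regions))
  for (ctg in unique(regions$chrom)) {
    tss <- sort(genes$tss[genes$chrom == ctg])
    if (!length(tss)) next
    rows <- which(regions$chrom == ctg)
    p <- regions$start[rows]
    i <- findInterval(p, tss)
    lo <- ifelse(i >= 1, abs(p - tss[pmax(i, 1)]), Inf)
    hi <- ifelse(i < length(tss), abs(tss[pmin(i + 1, length(tss))] - p), Inf)
    out[rows] <- pmin(lo, hi)
  }
  out
}

# Pearson chi-square (no continuity correction) on a 2x2 count table.
chisq2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(statistic = NA_real_, p = NA_real_))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

# shared fold/test machinery over strata counts
enrich_core <- function(stratum, obs, bg, n_obs, n_bg) {
  fold <- ifelse(bg > 0, (obs / n_obs) / (bg / n_bg),
                 ifelse(obs > 0, Inf, NA_real_))
  tests <- mapply(function(o, b) chisq2x2(o, n_obs - o, b, n_bg - b),
                  obs, bg, SIMPLIFY = FALSE)
  p <- vapply(tests, `[[`, numeric(1), "p")
  chi2 <- vapply(tests, `[[`, numeric(1), "statistic")
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_fdr(p[!is.na(p)])
  data.frame(stratum = stratum, observed = obs, background = bg,
             fold = fold, chi2 = chi2, p_value = p, q_value = q,
             stringsAsFactors = FALSE)
}

#' TSS-distance enrichment of a target set over a background
#'
#' Bins nearest-TSS distances, then per bin computes the fold enrichment
#' `(obs/n_obs)/(bg/n_bg)` and a Pearson chi-square test on the 2x2 table
#' (in-bin vs not, target vs background), BH-corrected across bins.
#'
#' @param target_dist,background_dist numeric distance vectors (`NA`s are
#'   dropped).
#' @param bin_edges ascending bin edges in bp; bins are `[e_i, e_{i+1})`.
#'   Defaults to 0-1, 1-2, 2-5, 5-10, 10-50, 50-100 and >100 kb.
#' @return data.frame per bin: `stratum`, `observed`, `background`, `fold`,
#'   `chi2`, `p_value`, `q_value`.
#' @export
distance_enrichment <- function(target_dist, background_dist,
                                bin_edges = c(0, 1, 2, 5, 10, 50, 100, Inf) * 1000) {
  target_dist <- target_dist[!is.na(target_dist)]
  background_dist <- background_dist[!is.na(background_dist)]
  lab <- paste0("[", bin_edges[-length(bin_edges)], ",", bin_edges[-1], ")")
  cut_counts <- function(d)
    table(factor(findInterval(d, bin_edges), levels = seq_along(lab)))
  obs <- as.integer(cut_counts(target_dist))
  bg <- as.integer(cut_counts(background_dist))
  keep <- obs + bg > 0
  enrich_core(lab[keep], obs[keep], bg[keep],
              length(target_dist), length(background_dist))
}

#' Feature-distribution enrichment of a target set over a background
#'
#' Same statistics as [distance_enrichment()], stratified by feature label.
#'
#' @param target_labels,background_labels character label vectors.
#' @return data.frame per label (see [distance_enrichment()]).
#' @export
feature_enrichment <- function(target_labels, background_labels) {
  labs <- sort(unique(c(target_labels, background_labels)))
  obs <- as.integer(table(factor(target_labels, levels = labs)))
  bg <- as.integer(table(factor(background_labels, levels = labs)))
  enrich_core(labs, obs, bg, length(target_labels), length(background_labels))
}

#' Read ChIP-seq peaks with summits
#'
#' Accepts the narrowPeak dialect (summit offset relative to the peak start
#' in column 10; offset -1 means no summit and such peaks are dropped) or a
#' column holding the absolute summit position.
#'
#' @param path BED-like peak file.
#' @param summit_col column index holding the summit (default 10).
#' @param summit_is_offset interpret the column as an offset from `start`
#'   (default TRUE, narrowPeak) rather than an absolute position.
#' @return interval data.frame with a `summit` column (absolute 0-based
#'   position, `start <= summit < end`).
#' @export
read_peaks <- function(path, summit_col = 10L, summit_is_offset = TRUE) {
  x <- read_bed(path, min_cols = summit_col)
  v <- suppressWarnings(as.integer(x[[paste0("V", summit_col)]]))
  if (anyNA(v)) stop("non-numeric summit column in ", path)
  summit <- if (summit_is_offset) ifelse(v < 0, NA_integer_, x$start + v) else v
  out <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    summit = summit, stringsAsFactors = FALSE)
  out <- out[!is.na(out$summit), , drop = FALSE]
  if (any(out$summit < out$start | out$summit >= out$end))
    stop("peak summit outside its peak in ", path)
  out
}

#' Peak-summit overlap of regions, compared between EC and ENC
#'
#' A region overlaps a histone mark iff it contains the summit of one of its
#' peaks (half-open: `start <= summit < end`); peaks merely overlapping the
#' region do not count. When EC/ENC group labels are given, the EC vs ENC
#' overlap rates are compared with a 2x2 Pearson chi-square test.
#'
#' @param regions interval data.frame.
#' @param peaks peak data.frame from [read_peaks()] (needs `chrom`,
#'   `summit`).
#' @param group optional character vector (`"EC"`/`"ENC"`) per region.
#' @return list with `overlap` (logical per region), `counts` (per-group
#'   overlap table when `group` given) and `p_value`.
#' @export
summit_overlap <- function(regions, peaks, group = NULL) {
  ov <- rep(FALSE, nrow(regions))
  for (ctg in unique(regions$chrom)) {
    s <- sort(peaks$summit[peaks$chrom == ctg])
    if (!length(s)) next
    rows <- which(regions$chrom == ctg)
    # any summit in [start, end): count of s < end minus count of s < start
    ov[rows] <- (findInterval(regions$end[rows] - 1L, s) -
                   findInterval(regions$start[rows] - 1L, s)) > 0
  }
  res <- list(overlap = ov, counts = NULL, p_value = NA_real_)
  if (!is.null(group)) {
    stopifnot(length(group) == nrow(regions))
    tab <- table(group, factor(ov, levels = c(TRUE, FALSE)))
    res$counts <- tab
    if (all(dim(tab) == c(2, 2)))
      res$p_value <- chisq2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])$p
  }
  res
}

#' Average signal profile around region midpoints
#'
#' Mean signal density in fixed-size bins across a window centered on each
#' region's midpoint, averaged over regions; bases without data count as 0.
#'
#' @param regions interval data.frame.
#' @param track score track (e.g. RPKM density).
#' @param flank half-window in bp (default 5000).
#' @param binsize bin width in bp (default 50).
#' @return data.frame with `offset` (bin start relative to the midpoint) and
#'   `mean_density`; `2 * flank / binsize` rows.
#' @export
signal_profile <- function(regions, track, flank = 5000L, binsize = 50L) {
  stopifnot(flank %% binsize == 0)
  nb <- 2L * flank %/% binsize
  offs <- seq(-flank, flank - binsize, by = binsize)
  mid <- (regions$start + regions$end) %/% 2L
  grid <- data.frame(
    chrom = rep(regions$chrom, each = nb),
    start = rep(mid, each = nb) + rep(offs, nrow(regions)))
  grid$end <- grid$start + binsize
  neg <- grid$start < 0  # clip leading-edge bins; they contribute 0
  grid$start[neg] <- 0L; grid$end[neg] <- pmax(1L, grid$end[neg])
  v <- mean_score(track, grid)
  v[is.na(v)] <- 0
  data.frame(offset = offs,
             mean_density = as.numeric(tapply(v, rep(seq_len(nb), nrow(regions)),
                                              mean)))
}

#' Benjamini-Hochberg FDR correction
#'
#' Standard step-up q-values: on sorted p-values,
#' `q(i) = min_{j >= i} p(j) * m / j`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
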