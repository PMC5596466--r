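# Known-motif scanning (IUPAC consensus or PWM), GC-matched background
# enrichment split by EC status, and cross-species motif turnover calls.
# Consensus matching is exact under the IUPAC classes: every sequence base
# must satisfy its consensus position's class, and an N in the sequence
# never matches a non-N consensus position.

#' Define a motif model
#'
#' @param name motif name.
#' @param consensus IUPAC consensus string (alphabet ACGTRYSWKMBDHVN), or
#'   `NULL` for PWM mode.
#' @param pwm 4-row probability matrix (rows A, C, G, T; columns sum to 1),
#'   or `NULL` for consensus mode.
#' @param threshold PWM score threshold as a fraction of the maximum
#'   achievable log-odds score (default 0.8).
#' @return object of class `motif_model`.
#' @export
motif_model <- function(name, consensus = NULL, pwm = NULL, threshold = 0.8) {
  if (is.null(consensus) == is.null(pwm))
    stop("give exactly one of consensus or pwm")
  if (!is.null(consensus)) {
    consensus <- toupper(consensus)
    if (!grepl("^[ACGTRYSWKMBDHVN]+$", consensus))
      stop("consensus contains non-IUPAC letters: ", consensus)
    len <- nchar(consensus)
  } else {
    stopifnot(is.matrix(pwm), nrow(pwm) == 4)
    rownames(pwm) <- c("A", "C", "G", "T")
    if (any(abs(colSums(pwm) - 1) > 1e-6))
      stop("PWM columns must sum to 1")
    len <- ncol(pwm)
  }
  structure(list(name = name, consensus = consensus, pwm = pwm,
                 threshold = threshold, length = len),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model", x$name, "-",
      if (!is.null(x$consensus)) x$consensus
      else paste0("PWM[", x$length, "] @", x$threshold), "\n")
  invisible(x)
}

#' Read motifs from a plain-text list
#'
#' Two whitespace-delimited columns: name, IUPAC consensus.
#'
#' @param path file path.
#' @return named list of `motif_model`s.
#' @export
read_motifs <- function(path) {
  b <- read_body_lines(path)
  f <- strsplit(b$lines, "\\s+")
  out <- lapply(f, function(x) motif_model(x[1], consensus = x[2]))
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

motif_log_odds <- function(pwm, pseudo = 0.01) {
  log2((pwm + pseudo) / (0.25 + pseudo))
}

#' Scan a sequence for motif hits
#'
#' Consensus mode reports every position where all bases satisfy their
#' IUPAC class; PWM mode reports positions with log-odds score at least
#' `threshold` of the maximum achievable score. Both strands are scanned by
#' default (reverse-strand hits are matches of the reverse complement,
#' reported in forward coordinates).
#'
#' @param sequence character string or `DNAString`.
#' @param motif a `motif_model`.
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return data.frame of hits sorted by position: `start`, `end` (0-based
#'   half-open offsets into the sequence), `strand`, `motif`, `score`
#'   (`NA` in consensus mode).
#' @export
scan_motif <- function(sequence, motif, both_strands = TRUE) {
  subj <- if (inherits(sequence, "DNAString")) sequence
  else Biostrings::DNAString(toupper(as.character(sequence)))
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), motif = character(0),
                      score = numeric(0))
  if (motif$length > length(subj)) return(empty)
  one_strand <- function(strand) {
    if (!is.null(motif$consensus)) {
      pat <- Biostrings::DNAString(motif$consensus)
      if (strand == "-") pat <- Biostrings::reverseComplement(pat)
      m <- Biostrings::matchPattern(pat, subj, fixed = "subject")
      if (!length(m)) return(empty)
      data.frame(start = Biostrings::start(m) - 1L,
                 end = Biostrings::end(m),
                 strand = strand, motif = motif$name, score = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      lo <- motif_log_odds(motif$pwm)
      if (strand == "-") lo <- Biostrings::reverseComplement(lo)
      cut <- paste0(round(100 * motif$threshold), "%")
      m <- Biostrings::matchPWM(lo, subj, min.score = cut, with.score = TRUE)
      if (!length(m)) return(empty)
      data.frame(start = Biostrings::start(m) - 1L,
                 end = Biostrings::end(m),
                 strand = strand, motif = motif$name,
                 score = S4Vectors::mcols(m)$score,
                 stringsAsFactors = FALSE)
    }
  }
  out <- one_strand("+")
  if (both_strands) out <- rbind(out, one_strand("-"))
  out[order(out$start, out$strand), , drop = FALSE]
}

# extract region sequences from a genome DNAStringSet (names = contigs)
region_seqs <- function(genome, regions) {
  miss <- setdiff(unique(regions$chrom), names(genome))
  if (length(miss)) stop("contig absent from genome: ", miss[1])
  Biostrings::DNAStringSet(lapply(seq_len(nrow(regions)), function(i)
    Biostrings::subseq(genome[[regions$chrom[i]]],
                       regions$start[i] + 1L, regions$end[i])))
}

#' Scan genomic regions for motif hits
#'
#' @param regions interval data.frame.
#' @param genome `DNAStringSet` named by contig.
#' @param motif a `motif_model`.
#' @param both_strands scan both strands (default TRUE).
#' @return data.frame of hits in genomic coordinates with a `region` column
#'   indexing the source region.
#' @export
scan_regions <- function(regions, genome, motif, both_strands = TRUE) {
  seqs <- region_seqs(genome, regions)
  out <- lapply(seq_len(nrow(regions)), function(i) {
    h <- scan_motif(seqs[[i]], motif, both_strands)
    if (!nrow(h)) return(NULL)
    h$chrom <- regions$chrom[i]
    h$start <- h$start + regions$start[i]
    h$end <- h$end + regions$start[i]
    h$region <- i
    h[, c("chrom", "start", "end", "strand", "motif", "score", "region")]
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      motif = character(0), score = numeric(0),
                      region = integer(0))
  out
}

#' GC content of regions
#' @param regions interval data.frame.
#' @param genome `DNAStringSet` named by contig.
#' @return numeric vector of G+C fractions.
#' @export
gc_content <- function(regions, genome) {
  seqs <- region_seqs(genome, regions)
  as.numeric(Biostrings::letterFrequency(seqs, "GC", as.prob = TRUE))
}

#' Sample a GC-content-matched background
#'
#' Background windows drawn from the universe so that the per-GC-bin counts
#' equal the target set's exactly; deterministic for a given seed.
#'
#' @param targets,universe interval data.frames.
#' @param genome `DNAStringSet` named by contig.
#' @param gc_bin_width GC-fraction bin width (default 0.05).
#' @param seed RNG seed.
#' @return interval data.frame of background windows with a `gc` column.
#' @export
gc_matched_background <- function(targets, universe, genome,
                                  gc_bin_width = 0.05, seed = 1L) {
  tgc <- gc_content(targets, genome)
  ugc <- gc_content(universe, genome)
  tbin <- floor(tgc / gc_bin_width)
  ubin <- floor(ugc / gc_bin_width)
  want <- table(tbin)
  rows <- with_seed(seed, {
    unlist(lapply(names(want), function(b) {
      pool <- which(ubin == as.numeric(b))
      k <- want[[b]]
      if (length(pool) < k)
        stop("universe GC bin [", as.numeric(b) * gc_bin_width, ",",
             (as.numeric(b) + 1) * gc_bin_width, ") has ", length(pool),
             " windows but ", k, " are needed")
      if (length(pool) == 1) rep(pool, k)
      else pool[sample.int(length(pool), k)]
    }))
  })
  out <- universe[rows, , drop = FALSE]
  out$gc <- ugc[rows]
  rownames(out) <- NULL
  out
}

#' Motif enrichment split by epigenetic-conservation status
#'
#' For each motif and stratum (`all`, `EC`, `ENC`): the fraction of regions
#' with at least one hit, the background fraction, their ratio (fold), and a
#' 2x2 Pearson chi-square p-value, BH-corrected across motifs within each
#' stratum. Empty strata are dropped with a warning; a motif absent from
#' both sets has undefined fold (`NA`).
#'
#' @param regions interval data.frame with a `status` column (`EC`/`ENC`).
#' @param background interval data.frame (e.g. from
#'   [gc_matched_background()]).
#' @param genome `DNAStringSet` named by contig.
#' @param motifs list of `motif_model`s.
#' @return data.frame: `motif`, `stratum`, `target_frac`, `background_frac`,
#'   `fold`, `p_value`, `q_value`.
#' @export
motif_enrichment_by_ec <- function(regions, background, genome, motifs) {
  stopifnot("status" %in% names(regions))
  strata <- list(all = seq_len(nrow(regions)),
                 EC = which(regions$status == "EC"),
                 ENC = which(regions$status == "ENC"))
  hit_frac <- function(rows, set, hits)
    if (!length(rows)) NA_real_ else mean(rows %in% hits)
  out <- list()
  for (m in motifs) {
    th <- unique(scan_regions(regions, genome, m)$region)
    bh <- unique(scan_regions(background, genome, m)$region)
    bf <- length(bh) / nrow(background)
    for (s in names(strata)) {
      rows <- strata[[s]]
      if (!length(rows)) {
        warning("stratum ", s, " is empty; omitted")
        next
      }
      tf <- mean(rows %in% th)
      fold <- if (bf > 0) tf / bf else if (tf > 0) Inf else NA_real_
      p <- chisq2x2(sum(rows %in% th), length(rows) - sum(rows %in% th),
                    length(bh), nrow(background) - length(bh))$p
      out[[length(out) + 1L]] <- data.frame(
        motif = m$name, stratum = s, target_frac = tf,
        background_frac = bf, fold = fold, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$q_value <- NA_real_
  for (s in unique(res$stratum)) {
    i <- which(res$stratum == s & !is.na(res$p_value))
    if (length(i)) res$q_value[i] <- bh_fdr(res$p_value[i])
  }
  res
}

#' Classify cross-species motif turnover for one ortholog pair
#'
#' Maps each source-region hit to the other species through the chains
#' (requiring at least `min_cover` of the hit's bases to map). The call is
#' `CONSERVED_IN_PLACE` if any mapped source hit shares at least one base
#' with a destination hit; otherwise `TURNOVER` if both regions have hits,
#' `LOSS` if only the source does, `GAIN` if only the destination does, and
#' `ABSENT_BOTH` if neither has any.
#'
#' @param src_region,dst_region single-row interval data.frames; `dst_region`
#'   must be the mapped ortholog of `src_region` (verified through the
#'   chains; a non-ortholog pair is an error).
#' @param src_hits,dst_hits hit data.frames from [scan_regions()] restricted
#'   to the pair (genomic coordinates on each species' assembly).
#' @param chains `chain_set` from source to destination species.
#' @param min_cover minimum mapped fraction of a hit (default 0.5).
#' @return one of `"CONSERVED_IN_PLACE"`, `"TURNOVER"`, `"LOSS"`, `"GAIN"`,
#'   `"ABSENT_BOTH"`.
#' @export
classify_turnover <- function(src_region, dst_region, src_hits, dst_hits,
                              chains, min_cover = 0.5) {
  reg <- liftover_intervals(chains, src_region[, c("chrom", "start", "end")])
  if (!reg$mapped[1] || reg$target_chrom[1] != dst_region$chrom[1] ||
      reg$target_start[1] >= dst_region$end[1] ||
      reg$target_end[1] <= dst_region$start[1])
    stop("dst_region is not the mapped ortholog of src_region")
  ns <- nrow(src_hits); nd <- nrow(dst_hits)
  if (ns == 0 && nd == 0) return("ABSENT_BOTH")
  if (ns > 0 && nd > 0) {
    lifted <- liftover_intervals(chains, src_hits[, c("chrom", "start", "end")],
                                 min_cover = min_cover, max_span = 1000L)
    for (i in which(lifted$mapped)) {
      same <- dst_hits$chrom == lifted$target_chrom[i] &
        dst_hits$start < lifted$target_end[i] &
        dst_hits$end > lifted$target_start[i]
      if (any(same)) return("CONSERVED_IN_PLACE")
    }
    return("TURNOVER")
  }
  if (ns > 0) "LOSS" else "GAIN"
}

#' Motif turnover calls for a table of ortholog pairs
#'
#' Scans both species' region sequences for the motif and classifies each
#' pair with [classify_turnover()].
#'
#' @param pairs data.frame with source columns `chrom`, `start`, `end` and
#'   destination columns `dst_chrom`, `dst_start`, `dst_end`.
#' @param src_genome,dst_genome `DNAStringSet`s named by contig.
#' @param motif a `motif_model`.
#' @param chains `chain_set` from source to destination species.
#' @return character vector of turnover calls, one per pair.
#' @export
motif_turnover <- function(pairs, src_genome, dst_genome, motif, chains) {
  vapply(seq_len(nrow(pairs)), function(i) {
    src <- pairs[i, c("chrom", "start", "end")]
    dst <- data.frame(chrom = pairs$dst_chrom[i], start = pairs$dst_start[i],
                      end = pairs$dst_end[i])
    classify_turnover(src, dst,
                      scan_regions(src, src_genome, motif),
                      scan_regions(dst, dst_genome, motif),
                      chains)
  }, character(1))
}
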