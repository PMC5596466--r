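# Readers/writers for the plain-text genomics formats the pipeline consumes.
# All readers skip blank lines, '#' comments, and 'track'/'browser' lines.
# Coordinates on disk follow each format's own convention; in memory
# everything is 0-based half-open.

read_body_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a BED file
#'
#' Parses BED3+ (whitespace-delimited, >= 3 columns). Columns beyond the
#' first three are preserved as character columns named `V4`, `V5`, ... so no
#' payload is lost; [write_bed()] round-trips them.
#'
#' @param path file path.
#' @param min_cols minimum number of columns required per line (default 3).
#' @return interval data.frame (0-based half-open) with any extra columns.
#' @export
read_bed <- function(path, min_cols = 3L) {
  b <- read_body_lines(path)
  if (length(b$lines) == 0)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  fields <- strsplit(b$lines, "\\s+")
  nf <- lengths(fields)
  if (any(nf < min_cols))
    stop("malformed BED line ", b$lineno[which(nf < min_cols)[1]], " in ", path,
         ": fewer than ", min_cols, " columns")
  ncol_use <- min(nf)
  mat <- t(vapply(fields, function(f) f[seq_len(ncol_use)], character(ncol_use)))
  start <- suppressWarnings(as.integer(mat[, 2]))
  end <- suppressWarnings(as.integer(mat[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", b$lineno[bad[1]], " in ", path,
         ": non-numeric coordinates")
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop("malformed BED line ", b$lineno[bad[1]], " in ", path,
         ": start >= end")
  out <- data.frame(chrom = mat[, 1], start = start, end = end,
                    stringsAsFactors = FALSE)
  if (ncol_use > 3)
    for (j in 4:ncol_use) out[[paste0("V", j)]] <- mat[, j]
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Write intervals as BED
#'
#' @param x interval data.frame; extra columns are written after chrom,
#'   start, end in their current order.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- c("chrom", "start", "end", setdiff(names(x), c("chrom", "start", "end")))
  utils::write.table(as.data.frame(x)[, cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file as a score track
#'
#' @param path file path.
#' @return a score track: data.frame `chrom`, `start`, `end`, `score`
#'   (0-based half-open runs; absent positions carry no data).
#' @export
read_bedgraph <- function(path) {
  x <- read_bed(path, min_cols = 4L)
  score <- suppressWarnings(as.numeric(x$V4))
  if (any(is.na(score))) stop("non-numeric bedGraph value in ", path)
  if (any(!is.finite(score))) stop("non-finite bedGraph value in ", path)
  data.frame(chrom = x$chrom, start = x$start, end = x$end, score = score,
             stringsAsFactors = FALSE)
}

#' Write a score track as bedGraph
#' @param x data.frame with `chrom`, `start`, `end`, `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  utils::write.table(x[, c("chrom", "start", "end", "score")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a wiggle (wig) score track
#'
#' Supports `fixedStep` and `variableStep` declarations with the usual
#' defaults (`step = 1`, `span = step` for fixedStep, `span = 1` for
#' variableStep). Wig positions are 1-based on disk and converted to the
#' package's 0-based half-open runs.
#'
#' @param path file path.
#' @return score track data.frame (`chrom`, `start`, `end`, `score`).
#' @export
read_wig <- function(path) {
  b <- read_body_lines(path)
  lines <- b$lines
  out <- list()
  mode <- NULL; chrom <- NULL; step <- 1L; span <- 1L; at <- 0L
  hdr <- grepl("^(fixedStep|variableStep)\\b", lines)
  if (!any(hdr) && length(lines))
    stop("wig file without step declaration: ", path)
  blocks <- split(seq_along(lines), cumsum(hdr))
  for (idx in blocks) {
    h <- lines[idx[1]]
    if (!grepl("^(fixedStep|variableStep)", h))
      stop("wig data before step declaration at line ", b$lineno[idx[1]])
    kv <- strsplit(h, "\\s+")[[1]]
    mode <- kv[1]
    getf <- function(key, default = NA) {
      m <- grep(paste0("^", key, "="), kv, value = TRUE)
      if (length(m)) sub(paste0(key, "="), "", m[1]) else default
    }
    chrom <- getf("chrom")
    if (is.na(chrom)) stop("wig declaration without chrom at line ", b$lineno[idx[1]])
    step <- as.integer(getf("step", "1"))
    span <- as.integer(getf("span", if (mode == "fixedStep") as.character(step) else "1"))
    body <- lines[idx[-1]]
    if (!length(body)) next
    if (mode == "fixedStep") {
      start1 <- as.integer(getf("start"))
      vals <- as.numeric(body)
      starts0 <- start1 - 1L + step * (seq_along(vals) - 1L)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = starts0, end = starts0 + span, score = vals,
        stringsAsFactors = FALSE)
    } else {
      parts <- strsplit(body, "\\s+")
      pos1 <- as.integer(vapply(parts, `[`, "", 1L))
      vals <- as.numeric(vapply(parts, `[`, "", 2L))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = pos1 - 1L, end = pos1 - 1L + span, score = vals,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               score = numeric(0))
  if (any(!is.finite(res$score))) stop("non-finite wig value in ", path)
  res
}

#' Write a score track as fixedStep wig
#'
#' Requires uniform run width per contig (runs become `span`, consecutive
#' starts the `step`); the simulator emits such tracks.
#'
#' @param x score track data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wig <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in unique(x$chrom)) {
    xi <- x[x$chrom == ctg, , drop = FALSE]
    xi <- xi[order(xi$start), , drop = FALSE]
    w <- unique(xi$end - xi$start)
    if (length(w) != 1) stop("write_wig needs uniform span per contig")
    step <- if (nrow(xi) > 1) unique(diff(xi$start)) else w
    if (length(step) != 1) stop("write_wig needs uniform step per contig")
    writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                       ctg, xi$start[1] + 1L, step, w), con)
    writeLines(format(xi$score, trim = TRUE, scientific = FALSE), con)
  }
  invisible(path)
}

#' Mean score of a track over intervals
#'
#' Per-base mean over the bases of each interval that carry data; intervals
#' with no covered base get `NA`.
#'
#' @param track score track data.frame.
#' @param x interval data.frame.
#' @return numeric vector, one mean per row of `x`.
#' @export
mean_score <- function(track, x) {
  validate_intervals(x)
  if (nrow(x) == 0) return(numeric(0))
  out <- rep(NA_real_, nrow(x))
  if (nrow(track) == 0) return(out)
  gx <- as_gr(x)
  gt <- as_gr(track)
  hits <- GenomicRanges::findOverlaps(gx, gt, ignore.strand = TRUE)
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    w <- IRanges::width(IRanges::pintersect(IRanges::ranges(gx)[qi],
                                            IRanges::ranges(gt)[si]))
    num <- tapply(w * track$score[si], qi, sum)
    den <- tapply(w, qi, sum)
    out[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  }
  out
}

#' Read a genePred-like gene table
#'
#' Tab-delimited with columns name, chrom, strand, txStart, txEnd,
#' exonStarts, exonEnds (comma-separated lists), the refGene text layout
#' minus the leading bin column. txStart/txEnd are consumed as 0-based
#' half-open.
#'
#' @param path file path.
#' @return data.frame with one row per transcript; `exon_starts` and
#'   `exon_ends` are list columns of integer vectors; `tss` is the
#'   strand-aware transcription start (txStart on `+`, txEnd on `-`).
#' @export
read_genepred <- function(path) {
  b <- read_body_lines(path)
  if (!length(b$lines))
    return(data.frame(name = character(0), chrom = character(0),
                      strand = character(0), txStart = integer(0),
                      txEnd = integer(0), tss = integer(0)))
  f <- strsplit(b$lines, "\t")
  if (any(lengths(f) < 7))
    stop("malformed genePred line ", b$lineno[which(lengths(f) < 7)[1]],
         " in ", path)
  g <- data.frame(name = vapply(f, `[`, "", 1),
                  chrom = vapply(f, `[`, "", 2),
                  strand = vapply(f, `[`, "", 3),
                  txStart = as.integer(vapply(f, `[`, "", 4)),
                  txEnd = as.integer(vapply(f, `[`, "", 5)),
                  stringsAsFactors = FALSE)
  parse_list <- function(s) as.integer(strsplit(sub(",$", "", s), ",")[[1]])
  g$exon_starts <- lapply(f, function(x) parse_list(x[6]))
  g$exon_ends <- lapply(f, function(x) parse_list(x[7]))
  if (any(g$txStart >= g$txEnd)) stop("genePred record with txStart >= txEnd")
  g$tss <- ifelse(g$strand == "-", g$txEnd, g$txStart)
  g
}

#' Write a gene table in the genePred-like layout read by [read_genepred()]
#' @param genes data.frame as returned by [read_genepred()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genepred <- function(genes, path) {
  lst <- function(v) paste0(paste(v, collapse = ","), ",")
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    paste(genes$name[i], genes$chrom[i], genes$strand[i],
          genes$txStart[i], genes$txEnd[i],
          lst(genes$exon_starts[[i]]), lst(genes$exon_ends[[i]]), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Genome index (contig lengths) from a FASTA file
#' @param path FASTA path.
#' @return named integer vector: contig -> length in bp.
#' @export
read_genome_index <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(Biostrings::width(seqs),
                  sub("\\s.*$", "", names(seqs)))
}
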