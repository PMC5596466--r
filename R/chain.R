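# UCSC chain files describe chained ungapped alignment blocks between a
# target (source) assembly and a query assembly. Header:
#   chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd id
# followed by block lines "size dt dq" (last line: "size" alone). When
# qStrand is '-', query coordinates count from the start of the
# reverse-complemented query sequence; at parse time we additionally store
# forward-strand block coordinates so all downstream arithmetic is done in
# one convention, while the original fields are kept for writing.

new_chain <- function(h, blocks) {
  ch <- list(id = h$id, score = h$score,
             tName = h$tName, tSize = h$tSize, tStrand = h$tStrand,
             tStart = h$tStart, tEnd = h$tEnd,
             qName = h$qName, qSize = h$qSize, qStrand = h$qStrand,
             qStart = h$qStart, qEnd = h$qEnd,
             blocks = blocks)
  tspan <- sum(blocks$size) + sum(blocks$dt)
  qspan <- sum(blocks$size) + sum(blocks$dq)
  if (tspan != ch$tEnd - ch$tStart)
    stop("chain ", ch$id, ": block sizes + target gaps (", tspan,
         ") != target span (", ch$tEnd - ch$tStart, ")")
  if (qspan != ch$qEnd - ch$qStart)
    stop("chain ", ch$id, ": block sizes + query gaps (", qspan,
         ") != query span (", ch$qEnd - ch$qStart, ")")
  if (ch$tStrand != "+") stop("chain ", ch$id, ": target strand must be '+'")
  if (!ch$qStrand %in% c("+", "-")) stop("chain ", ch$id, ": bad query strand")
  if (any(blocks$size <= 0)) stop("chain ", ch$id, ": block size must be > 0")
  if (any(blocks$dt < 0) || any(blocks$dq < 0))
    stop("chain ", ch$id, ": negative gap")
  n <- nrow(blocks)
  if (n > 1 && (blocks$dt[n] != 0 || blocks$dq[n] != 0)) {
    # tolerated by UCSC tools only as 0; enforce invariant
    stop("chain ", ch$id, ": last block must have dt = dq = 0")
  }
  # absolute block starts on target, and on query in strand-local coords
  ch$t_bs <- ch$tStart + cumsum(c(0, blocks$size[-n] + blocks$dt[-n]))
  q_bs <- ch$qStart + cumsum(c(0, blocks$size[-n] + blocks$dq[-n]))
  ch$q_bs <- q_bs
  # forward-strand query start of each block
  if (ch$qStrand == "+") {
    ch$q_bs_fwd <- q_bs
  } else {
    ch$q_bs_fwd <- ch$qSize - (q_bs + blocks$size)
  }
  class(ch) <- "chain"
  ch
}

#' @export
print.chain <- function(x, ...) {
  cat(sprintf("chain %s: %s:%d-%d (+) -> %s:%d-%d (%s), score %g, %d blocks\n",
              x$id, x$tName, x$tStart, x$tEnd, x$qName, x$qStart, x$qEnd,
              x$qStrand, x$score, nrow(x$blocks)))
  invisible(x)
}

#' Read a UCSC chain file
#'
#' Parses every chain, checks the block-sum invariants against the header
#' spans (an inconsistency raises an error naming the chain id), and
#' normalizes negative-strand query coordinates to forward-strand block
#' starts for internal use (original fields are retained for writing).
#'
#' @param path chain file path.
#' @return A `chain_set`: list of `chain` objects, with a target-contig
#'   index for fast lookup.
#' @export
read_chain <- function(path) {
  b <- read_body_lines(path)
  lines <- b$lines
  heads <- grep("^chain\\b", lines)
  if (!length(heads)) stop("no chain records in ", path)
  bounds <- c(heads, length(lines) + 1L)
  chains <- vector("list", length(heads))
  for (i in seq_along(heads)) {
    f <- strsplit(lines[heads[i]], "\\s+")[[1]]
    if (length(f) < 13) stop("malformed chain header at line ", b$lineno[heads[i]])
    h <- list(score = as.numeric(f[2]),
              tName = f[3], tSize = as.integer(f[4]), tStrand = f[5],
              tStart = as.integer(f[6]), tEnd = as.integer(f[7]),
              qName = f[8], qSize = as.integer(f[9]), qStrand = f[10],
              qStart = as.integer(f[11]), qEnd = as.integer(f[12]),
              id = f[13])
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    parts <- strsplit(trimws(body), "\\s+")
    n <- length(parts)
    if (n == 0) stop("chain ", h$id, ": no alignment blocks")
    if (length(parts[[n]]) != 1 || any(lengths(parts[-n]) != 3))
      stop("chain ", h$id, ": malformed block lines")
    blocks <- data.frame(
      size = as.integer(vapply(parts, `[`, "", 1)),
      dt = c(as.integer(vapply(parts[-n], `[`, "", 2)), 0L),
      dq = c(as.integer(vapply(parts[-n], `[`, "", 3)), 0L))
    chains[[i]] <- new_chain(h, blocks)
  }
  as_chain_set(chains)
}

as_chain_set <- function(chains) {
  names(chains) <- vapply(chains, `[[`, "", "id")
  attr(chains, "by_target") <- split(seq_along(chains),
                                     vapply(chains, `[[`, "", "tName"))
  class(chains) <- "chain_set"
  chains
}

#' @export
print.chain_set <- function(x, ...) {
  cat("chain_set with", length(x), "chains on",
      length(attr(x, "by_target")), "target contig(s)\n")
  invisible(x)
}

#' Write a chain set in UCSC chain format
#' @param chains a `chain_set` (or list of `chain` objects).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(sprintf("chain %s %s %d %s %d %d %s %d %s %d %d %s",
                       format(ch$score, scientific = FALSE, trim = TRUE),
                       ch$tName, ch$tSize, ch$tStrand, ch$tStart, ch$tEnd,
                       ch$qName, ch$qSize, ch$qStrand, ch$qStart, ch$qEnd,
                       ch$id), con)
    n <- nrow(ch$blocks)
    if (n > 1)
      writeLines(paste(ch$blocks$size[-n], ch$blocks$dt[-n], ch$blocks$dq[-n],
                       sep = "\t"), con)
    writeLines(as.character(ch$blocks$size[n]), con)
    writeLines("", con)
  }
  invisible(path)
}
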