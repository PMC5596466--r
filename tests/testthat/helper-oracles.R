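# Independent brute-force oracles, deliberately written as naive per-base /
# per-position walks so they share no code with the implementation.

# walk a chain base by base: returns for every target base its query image
# (forward-strand coordinates), NA for gap bases
oracle_base_map <- function(ch) {
  map <- rep(NA_integer_, ch$tEnd - ch$tStart)
  t <- ch$tStart
  q <- ch$qStart
  for (b in seq_len(nrow(ch$blocks))) {
    for (k in seq_len(ch$blocks$size[b])) {
      qq <- q
      if (ch$qStrand == "-") qq <- ch$qSize - 1L - q
      map[t - ch$tStart + 1L] <- qq
      t <- t + 1L
      q <- q + 1L
    }
    t <- t + ch$blocks$dt[b]
    q <- q + ch$blocks$dq[b]
  }
  map
}

# brute-force interval liftover through one chain using the base map
oracle_liftover <- function(ch, start, end, min_cover = 0.5, max_span = 1000) {
  map <- oracle_base_map(ch)
  idx <- (start:(end - 1L)) - ch$tStart + 1L
  idx <- idx[idx >= 1 & idx <= length(map)]
  img <- if (length(idx)) map[idx] else integer(0)
  img <- img[!is.na(img)]
  covered <- length(img)
  frac <- covered / (end - start)
  if (covered == 0) return(list(mapped = FALSE, covered_fraction = frac))
  lo <- min(img); hi <- max(img) + 1L
  mapped <- frac >= min_cover && (hi - lo) <= max_span
  list(mapped = mapped, covered_fraction = frac, lo = lo, hi = hi)
}

# naive overlap counting by per-base membership
oracle_overlap_bases <- function(a_start, a_end, s) {
  if (nrow(s) == 0) return(0L)
  sum(vapply(a_start:(a_end - 1L), function(p)
    any(s$start <= p & p < s$end), logical(1)))
}

# naive IUPAC consensus scan (forward strand only), 0-based starts
IUPAC_CLASSES <- list(A = "A", C = "C", G = "G", T = "T",
                      R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                      W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                      B = c("C", "G", "T"), D = c("A", "G", "T"),
                      H = c("A", "C", "T"), V = c("A", "C", "G"),
                      N = c("A", "C", "G", "T"))

oracle_scan_forward <- function(sequence, consensus) {
  s <- strsplit(toupper(sequence), "")[[1]]
  m <- strsplit(toupper(consensus), "")[[1]]
  hits <- integer(0)
  if (length(m) > length(s)) return(hits)
  for (i in 0:(length(s) - length(m))) {
    ok <- TRUE
    for (j in seq_along(m)) {
      if (!(s[i + j] %in% IUPAC_CLASSES[[m[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# small identity chain covering [0, len) on both assemblies
identity_chain <- function(len = 1000L, tName = "chrT", qName = "chrQ",
                           id = "1", score = 1000L) {
  path <- tempfile(fileext = ".chain")
  writeLines(c(sprintf("chain %d %s %d + 0 %d %s %d + 0 %d %s",
                       as.integer(score), tName, len, len, qName, len, len, id),
               as.character(len), ""), path)
  read_chain(path)
}

# wrap a bare chain object into a queryable chain_set
as_chain_set_for_test <- function(...) methcons:::as_chain_set(list(...))

# write chain text and parse it back
chain_from_text <- function(lines) {
  path <- tempfile(fileext = ".chain")
  writeLines(lines, path)
  read_chain(path)
}

# shared desk-scale trio for end-to-end tests (cached per test run)
trio_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 20240917L, n_contigs = 1L,
                               contig_length = 300000L, n_dmrs = 60L)
      cache <<- simulate_trio(cfg, file.path(tempdir(), "methcons_trio"))
    }
    cache
  }
})

# default-configuration trio + pipeline (acceptance scale), cached
acceptance_trio <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 90210L)
      b <- simulate_trio(cfg, file.path(tempdir(), "methcons_default_trio"))
      pl <- run_trio_pipeline(b$dir)
      cache <<- list(bundle = b, pipeline = pl)
    }
    cache
  }
})
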