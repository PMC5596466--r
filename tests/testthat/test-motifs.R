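test_that("consensus scanning finds exact hits and mismatches destroy them", {
  erg <- motif_model("Erg", consensus = "ACAGGAAGTG")
  hits <- scan_motif("TTACAGGAAGTGTT", erg)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 2L)
  expect_equal(hits$end, 12L)
  expect_equal(hits$strand, "+")
  # A->G at the first consensus position destroys the site
  expect_equal(nrow(scan_motif("TTGCAGGAAGTGTT", erg)), 0L)
  # motif longer than the sequence: empty result
  expect_equal(nrow(scan_motif("ACAG", erg)), 0L)
})

test_that("reverse-complementing a sequence mirrors its hits to the other strand", {
  set.seed(111)
  m <- motif_model("Fli1", consensus = "TCAGGAAGCC")
  for (rep in 1:10) {
    sq <- paste0(random_dna(40), "TCAGGAAGCC", random_dna(40))
    fwd <- scan_motif(sq, m)
    rev <- scan_motif(revcomp(sq), m)
    expect_equal(nrow(fwd), nrow(rev))
    expect_equal(sort(table(fwd$strand)),
                 sort(table(c("+", "-")[match(rev$strand, c("-", "+"))])))
  }
})

test_that("consensus scan equals the sliding-window IUPAC oracle", {
  set.seed(121)
  consensi <- c("ACAGGAAGTG", "CTAATTAATT", "RYSWKM", "NNCGNN", "TGASTCA")
  for (cons in consensi) {
    for (rep in 1:6) {
      sq <- random_dna(300)
      # plant one instance with ambiguity codes resolved
      inst <- paste(vapply(strsplit(cons, "")[[1]], function(ch)
        sample(IUPAC_CLASSES[[ch]], 1), ""), collapse = "")
      at <- sample(0:(300 - nchar(cons)), 1)
      sq <- paste0(substr(sq, 1, at), inst,
                   substr(sq, at + nchar(cons) + 1, 300))
      m <- motif_model("m", consensus = cons)
      got <- scan_motif(sq, m, both_strands = FALSE)
      exp <- oracle_scan_forward(sq, cons)
      expect_equal(got$start, exp)
      # reverse-strand hits equal the oracle on the reverse complement
      got2 <- scan_motif(sq, m, both_strands = TRUE)
      exp_rc <- oracle_scan_forward(sq, revcomp(cons))
      expect_equal(got2$start[got2$strand == "-"], exp_rc)
    }
  }
})

test_that("N in the sequence never matches a non-N consensus position", {
  m <- motif_model("m", consensus = "ACGT")
  expect_equal(nrow(scan_motif("AANGTAA", m)), 0L)
  # but consensus N matches any base including N
  m2 <- motif_model("m2", consensus = "ACNT")
  expect_equal(scan_motif("AACGTAA", m2, both_strands = FALSE)$start, 1L)
})

test_that("PWM mode scores hits against the log-odds threshold", {
  pwm <- matrix(0.01, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  best <- c("A", "C", "G", "T", "A", "C")
  for (j in 1:6) pwm[best[j], j] <- 0.97
  m <- motif_model("pwm6", pwm = pwm, threshold = 0.9)
  sq <- paste0("TTTTTT", paste(best, collapse = ""), "GGGGGG")
  hits <- scan_motif(sq, m, both_strands = FALSE)
  expect_equal(hits$start, 6L)
  expect_true(hits$score > 0)
  # one strong mismatch drops below 90% of the maximum
  sq2 <- paste0("TTTTTT", "GCGTAC", "GGGGGG")
  expect_equal(nrow(scan_motif(sq2, m, both_strands = FALSE)), 0L)
})

test_that("motif list IO and genomic-region scanning offset coordinates", {
  path <- tempfile()
  writeLines(c("# known motifs", "Erg\tACAGGAAGTG", "Lhx3\tCTAATTAATT"), path)
  ms <- read_motifs(path)
  expect_equal(names(ms), c("Erg", "Lhx3"))
  genome <- Biostrings::DNAStringSet(c(cA = paste0(
    strrep("T", 100), "ACAGGAAGTG", strrep("T", 90))))
  hits <- scan_regions(data.frame(chrom = "cA", start = 50L, end = 150L),
                       genome, ms$Erg)
  expect_equal(hits$start, 100L)
  expect_equal(hits$end, 110L)
  expect_equal(hits$region, 1L)
})

test_that("GC-matched background equals the target GC histogram exactly", {
  set.seed(131)
  n <- 400L
  gc_levels <- seq(0.2, 0.8, length.out = n)
  seqs <- vapply(gc_levels, function(g)
    paste(sample(c("G", "A"), 100, TRUE, prob = c(g, 1 - g)), collapse = ""),
    "")
  genome <- Biostrings::DNAStringSet(c(cA = paste(seqs, collapse = "")))
  universe <- data.frame(chrom = "cA", start = (seq_len(n) - 1L) * 100L)
  universe$end <- universe$start + 100L
  targets <- universe[sample.int(n, 60), ]
  bg <- gc_matched_background(targets, universe, genome, seed = 3)
  histo <- function(r) table(floor(gc_content(r, genome) / 0.05))
  expect_equal(histo(bg), histo(targets))
  bg2 <- gc_matched_background(targets, universe, genome, seed = 4)
  expect_equal(histo(bg2), histo(targets))
  expect_false(identical(bg$start, bg2$start))
})

test_that("motif enrichment recovers planted EC/ENC rate contrasts", {
  set.seed(141)
  erg <- "ACAGGAAGTG"
  n <- 200L
  status <- rep(c("EC", "ENC"), each = n / 2)
  plant <- ifelse(status == "EC", runif(n) < 0.8, runif(n) < 0.1)
  mk <- function(has) {
    s <- random_dna(100)
    if (has) s <- paste0(substr(s, 1, 40), erg, substr(s, 51, 100))
    s
  }
  tseq <- vapply(plant, mk, "")
  bseq <- vapply(runif(n) < 0.1, mk, "")
  genome <- Biostrings::DNAStringSet(c(cA = paste(c(tseq, bseq), collapse = "")))
  regions <- data.frame(chrom = "cA", start = (seq_len(n) - 1L) * 100L,
                        status = status)
  regions$end <- regions$start + 100L
  background <- data.frame(chrom = "cA", start = (n + seq_len(n) - 1L) * 100L)
  background$end <- background$start + 100L
  res <- motif_enrichment_by_ec(regions, background, genome,
                                list(motif_model("Erg", consensus = erg)))
  ec <- res[res$stratum == "EC", ]
  enc <- res[res$stratum == "ENC", ]
  expect_lt(abs(ec$fold - 8), 8 * 0.25)
  expect_lt(abs(enc$fold - 1), 0.6)
  expect_lt(ec$p_value, 1e-6)
  # background against itself gives fold 1 (ENC stratum empty -> warning)
  expect_warning(
    self <- motif_enrichment_by_ec(
      cbind(background, status = "EC"), background, genome,
      list(motif_model("Erg", consensus = erg))),
    "empty")
  expect_true(all(abs(self$fold - 1) < 1e-12))
  # absent motif: undefined fold
  expect_warning(
    none <- motif_enrichment_by_ec(
      cbind(background, status = "EC"), background, genome,
      list(motif_model("X", consensus = "AAAAAAAAAAAAAAAAAAAAAAAAAAAAAA"))),
    "empty")
  expect_true(all(is.na(none$fold)))
})

turnover_fixture <- function(src_core, dst_core, len = 200L) {
  # identical flanks; cores differ per scenario; identity chain
  flank <- strrep("T", 60)
  src <- paste0(flank, src_core, strrep("T", len - 60 - nchar(src_core)))
  dst <- paste0(flank, dst_core, strrep("T", len - 60 - nchar(dst_core)))
  list(src_genome = Biostrings::DNAStringSet(c(cS = src)),
       dst_genome = Biostrings::DNAStringSet(c(cT = dst)),
       chains = identity_chain(len, "cS", "cT"),
       src_region = data.frame(chrom = "cS", start = 0L, end = len),
       dst_region = data.frame(chrom = "cT", start = 0L, end = len))
}

test_that("turnover classification distinguishes the five fates", {
  erg <- motif_model("Erg", consensus = "ACAGGAAGTG")
  # identical sequences: conserved in place
  f <- turnover_fixture("ACAGGAAGTG", "ACAGGAAGTG")
  call1 <- classify_turnover(f$src_region, f$dst_region,
                             scan_regions(f$src_region, f$src_genome, erg),
                             scan_regions(f$dst_region, f$dst_genome, erg),
                             f$chains)
  expect_equal(call1, "CONSERVED_IN_PLACE")
  # site destroyed in place, new site 84 bp away inside the region: turnover
  f2 <- turnover_fixture("ACAGGAAGTG",
                         paste0("GCAGGAAGTG", strrep("T", 74), "ACAGGAAGTG"))
  call2 <- classify_turnover(f2$src_region, f2$dst_region,
                             scan_regions(f2$src_region, f2$src_genome, erg),
                             scan_regions(f2$dst_region, f2$dst_genome, erg),
                             f2$chains)
  expect_equal(call2, "TURNOVER")
  # destroyed with no replacement: loss; and symmetric gain
  f3 <- turnover_fixture("ACAGGAAGTG", "GCAGGAAGTG")
  sh <- scan_regions(f3$src_region, f3$src_genome, erg)
  dh <- scan_regions(f3$dst_region, f3$dst_genome, erg)
  expect_equal(classify_turnover(f3$src_region, f3$dst_region, sh, dh,
                                 f3$chains), "LOSS")
  # swapping src and dst maps LOSS to GAIN (identity chain is symmetric)
  back <- identity_chain(200L, "cT", "cS")
  expect_equal(classify_turnover(f3$dst_region, f3$src_region, dh, sh, back),
               "GAIN")
  # absent from both
  f4 <- turnover_fixture("TTTTTTTTTT", "TTTTTTTTTT")
  expect_equal(classify_turnover(f4$src_region, f4$dst_region,
                                 scan_regions(f4$src_region, f4$src_genome, erg),
                                 scan_regions(f4$dst_region, f4$dst_genome, erg),
                                 f4$chains), "ABSENT_BOTH")
})

test_that("turnover classification rejects non-ortholog pairs", {
  erg <- motif_model("Erg", consensus = "ACAGGAAGTG")
  f <- turnover_fixture("ACAGGAAGTG", "ACAGGAAGTG", len = 400L)
  wrong <- data.frame(chrom = "cT", start = 300L, end = 390L)
  expect_error(classify_turnover(f$src_region[, 1:3], wrong,
                                 scan_regions(f$src_region, f$src_genome, erg),
                                 data.frame(chrom = character(0),
                                            start = integer(0),
                                            end = integer(0)),
                                 identity_chain(200L, "cS", "cT")),
               "ortholog")
})
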