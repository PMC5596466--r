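fixture_genes <- function() {
  path <- tempfile()
  writeLines(c("gA\tchr1\t+\t10000\t30000\t10000,20000,\t10400,20400,",
               "gB\tchr1\t-\t50000\t60000\t50000,59000,\t50200,60000,"), path)
  read_genepred(path)
}

test_that("feature assignment follows the >50% rule with precedence", {
  genes <- fixture_genes()
  bundle <- annotation_bundle(genes,
                              cgi = data.frame(chrom = "chr1", start = 70000L,
                                               end = 70800L))
  # fully inside an intron
  expect_equal(assign_feature(data.frame(chrom = "chr1", start = 12000L,
                                         end = 12500L), bundle), "intron")
  # 300/500 promoter, rest exon: promoter has precedence and majority
  w <- data.frame(chrom = "chr1", start = 10200L, end = 10700L)
  expect_equal(assign_feature(w, bundle), "promoter")
  # majority CGI
  expect_equal(assign_feature(data.frame(chrom = "chr1", start = 70100L,
                                         end = 70600L), bundle), "CGI")
  # between gene loci, nothing qualifying: intergenic
  expect_equal(assign_feature(data.frame(chrom = "chr1", start = 40000L,
                                         end = 40500L), bundle), "intergenic")
  # exactly 50% covered does not qualify (strict majority)
  half <- data.frame(chrom = "chr1", start = 69750L, end = 70250L)
  expect_equal(assign_feature(half, bundle), "intergenic")
})

test_that("matched background reproduces the target composition exactly", {
  set.seed(41)
  universe <- data.frame(chrom = "c1", start = seq(0L, 99500L, 500L))
  universe$end <- universe$start + 500L
  ulabs <- sample(c("promoter", "intron", "intergenic"), nrow(universe),
                  TRUE, prob = c(0.2, 0.3, 0.5))
  tlabs <- c(rep("promoter", 5), rep("intron", 10))
  bg <- sample_matched(tlabs, universe, ulabs, seed = 7)
  comp <- function(labels, levels) as.integer(table(factor(labels, levels)))
  lv <- sort(unique(tlabs))
  expect_equal(comp(bg$label, lv), comp(tlabs, lv))
  # determinism and seed sensitivity
  bg2 <- sample_matched(tlabs, universe, ulabs, seed = 7)
  expect_identical(bg, bg2)
  bg3 <- sample_matched(tlabs, universe, ulabs, seed = 8)
  expect_false(identical(bg$start, bg3$start))
  expect_equal(comp(bg3$label, lv), comp(tlabs, lv))
  expect_error(sample_matched(rep("promoter", 1e5), universe, ulabs, 1),
               "promoter")
})

test_that("within-stratum sampling is uniform across resamples", {
  universe <- data.frame(chrom = "c1", start = seq(0L, 9500L, 500L))
  universe$end <- universe$start + 500L
  ulabs <- rep("x", nrow(universe))
  counts <- integer(nrow(universe))
  for (s in 1:2000) {
    bg <- sample_matched(rep("x", 2), universe, ulabs, seed = s)
    counts[match(bg$start, universe$start)] <-
      counts[match(bg$start, universe$start)] + 1L
  }
  gof <- suppressWarnings(chisq.test(counts))
  expect_gt(gof$p.value, 0.001)
})

test_that("nearest TSS distance is strand-aware and matches brute force", {
  genes <- fixture_genes()  # TSS at 10000 (+) and 60000 (-)
  d <- nearest_tss(data.frame(chrom = "chr1",
                              start = c(10000L, 60100L, 35000L),
                              end = c(10500L, 60600L, 35500L)), genes)
  expect_equal(d, c(0, 100, 25000))
  expect_true(is.na(nearest_tss(data.frame(chrom = "chrX", start = 1L,
                                           end = 2L), genes)))
  set.seed(51)
  regs <- data.frame(chrom = "chr1", start = sample.int(100000, 50))
  regs$end <- regs$start + 500L
  got <- nearest_tss(regs, genes)
  exp <- vapply(regs$start, function(s) min(abs(s - genes$tss)), numeric(1))
  expect_equal(got, exp)
})

test_that("distance enrichment is null on identical sets and detects shifts", {
  set.seed(61)
  d <- runif(500, 0, 2e5)
  null <- distance_enrichment(d, d)
  expect_true(all(abs(null$fold - 1) < 1e-12))
  expect_true(all(null$p_value > 0.999, na.rm = TRUE))
  tgt <- runif(300, 0, 999)           # all in the first kb
  bg <- runif(3000, 0, 2e5)
  got <- distance_enrichment(tgt, bg)
  first <- got[got$stratum == "[0,1000)", ]
  expect_gt(first$fold, 1)
  expect_lt(first$p_value, 0.05)
})

test_that("the chi-square kernel matches the closed-form value", {
  got <- methcons:::chisq2x2(30, 70, 10, 90)
  # hand computation, no continuity correction: n(ad-bc)^2/(r1 r2 c1 c2)
  exp_stat <- 200 * (30 * 90 - 70 * 10)^2 / (100 * 100 * 40 * 160)
  expect_equal(got$statistic, exp_stat, tolerance = 1e-12)
  expect_equal(exp_stat, 12.5)
  expect_equal(got$p, stats::pchisq(exp_stat, 1, lower.tail = FALSE))
})

test_that("summit overlap requires the summit, not just the peak", {
  regs <- data.frame(chrom = "c1", start = c(1000L, 2000L), end = c(1500L, 2500L))
  peaks <- data.frame(chrom = "c1", start = c(900L, 2400L),
                      end = c(1600L, 3000L), summit = c(1000L, 2700L))
  got <- summit_overlap(regs, peaks)
  expect_equal(got$overlap, c(TRUE, FALSE))  # summit at start counts; peak
                                             # overlapping without summit does not
  # brute-force check on random fixtures
  set.seed(71)
  regs <- data.frame(chrom = "c1", start = sample.int(10000, 30))
  regs$end <- regs$start + 500L
  smt <- sample.int(11000, 40)
  peaks <- data.frame(chrom = "c1", start = smt - 100L, end = smt + 100L,
                      summit = smt)
  got <- summit_overlap(regs, peaks)$overlap
  exp <- vapply(seq_len(30), function(i)
    any(smt >= regs$start[i] & smt < regs$end[i]), logical(1))
  expect_equal(got, exp)
})

test_that("summit overlap contrasts EC vs ENC groups", {
  set.seed(81)
  regs <- data.frame(chrom = "c1", start = seq(0L, 99500L, 500L))
  regs$end <- regs$start + 500L
  grp <- rep(c("EC", "ENC"), each = 100)
  has <- ifelse(grp == "EC", runif(200) < 0.6, runif(200) < 0.1)
  smt <- ifelse(has, regs$start + 250L, NA)
  peaks <- data.frame(chrom = "c1", start = smt - 50L, end = smt + 50L,
                      summit = smt)[has, ]
  got <- summit_overlap(regs, peaks, grp)
  expect_lt(got$p_value, 0.01)
  expect_gt(got$counts["EC", "TRUE"], got$counts["ENC", "TRUE"])
})

test_that("peak reading supports summit offsets and absolute summits", {
  path <- tempfile()
  writeLines(c("c1\t100\t600\tp1\t0\t.\t5\t-1\t-1\t250",
               "c1\t700\t900\tp2\t0\t.\t5\t-1\t-1\t-1"), path)
  pk <- read_peaks(path)
  expect_equal(nrow(pk), 1L)       # offset -1 dropped
  expect_equal(pk$summit, 350L)
  writeLines("c1\t100\t600\t599", path)
  pk2 <- read_peaks(path, summit_col = 4L, summit_is_offset = FALSE)
  expect_equal(pk2$summit, 599L)
})

test_that("signal profiles are flat on constant tracks and peak on deltas", {
  regs <- data.frame(chrom = "c1", start = seq(10000L, 50000L, 10000L))
  regs$end <- regs$start + 500L
  const <- data.frame(chrom = "c1", start = 0L, end = 100000L, score = 3)
  prof <- signal_profile(regs, const, flank = 1000L, binsize = 50L)
  expect_equal(nrow(prof), 40L)
  expect_true(all(abs(prof$mean_density - 3) < 1e-12))
  # delta at each midpoint: only the central bin is hit
  mids <- (regs$start + regs$end) %/% 2L
  delta <- data.frame(chrom = "c1", start = mids, end = mids + 1L, score = 10)
  prof2 <- signal_profile(regs, delta, flank = 1000L, binsize = 50L)
  expect_equal(which(prof2$mean_density > 0), which(prof2$offset == 0))
})

test_that("profiles are linear: mean of per-region profiles equals pooled", {
  set.seed(91)
  regs <- data.frame(chrom = "c1", start = sample(5000:90000, 6))
  regs$end <- regs$start + 500L
  tr <- data.frame(chrom = "c1", start = seq(0L, 99950L, 50L))
  tr$end <- tr$start + 50L
  tr$score <- runif(nrow(tr))
  pooled <- signal_profile(regs, tr, flank = 500L, binsize = 50L)
  singles <- lapply(seq_len(nrow(regs)), function(i)
    signal_profile(regs[i, ], tr, flank = 500L, binsize = 50L)$mean_density)
  expect_equal(pooled$mean_density, Reduce(`+`, singles) / length(singles))
})

test_that("BH correction implements the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.5)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= 0))
  # frozen against the closed-form step-up on this vector
  expect_equal(q, c(0.005, 0.02, 0.05125, 0.05125, 0.5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
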