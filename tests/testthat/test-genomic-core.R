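test_that("BED parsing reads 0-based half-open intervals and rejects bad lines", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("# comment", "track name=foo", "chrA\t0\t500"), path)
  x <- read_bed(path)
  expect_equal(nrow(x), 1L)
  expect_equal(x$chrom, "chrA")
  expect_equal(x$start, 0L)
  expect_equal(x$end, 500L)

  writeLines("chrA\t10\t5", path)
  expect_error(read_bed(path), "start >= end")
  writeLines(c("chrA\t0\t10", "chrA\t5"), path)
  expect_error(read_bed(path), "line 2")
})

test_that("BED write -> parse round-trips random intervals with payload", {
  set.seed(101)
  start <- sample.int(100000, 100)
  x <- genomic_intervals(chrom = sample(c("chr1", "chr2"), 100, TRUE),
                         start = start, end = start + sample.int(5000, 100),
                         V4 = paste0("name", 1:100),
                         V5 = as.character(sample.int(1000, 100)))
  x <- x[order(x$chrom, x$start), ]
  path <- tempfile(fileext = ".bed")
  write_bed(x, path)
  y <- read_bed(path)
  rownames(x) <- rownames(y) <- NULL
  expect_equal(as.data.frame(y), as.data.frame(x))
})

test_that("interval validation enforces the coordinate invariants", {
  expect_error(genomic_intervals("chrA", 5L, 5L), "start < end")
  expect_error(genomic_intervals("", 0L, 5L), "empty contig")
  expect_error(validate_intervals(data.frame(chrom = "chrA", start = 0L,
                                             end = 10L),
                                  index = c(chrA = 5L)), "past contig end")
})

test_that("chain parsing handles identity and gapped chains and checks sums", {
  cs <- chain_from_text(c("chain 1000 chrA 1000 + 0 100 chrB 1000 + 0 100 1",
                          "100", ""))
  ch <- cs[["1"]]
  expect_equal(ch$tEnd - ch$tStart, 100L)
  expect_equal(nrow(ch$blocks), 1L)
  expect_equal(ch$blocks$size, 100L)

  # blocks (size 40, dt 10, dq 0)(size 50): tSpan 100, qSpan 90
  cs2 <- chain_from_text(c("chain 900 chrA 500 + 0 100 chrB 500 + 0 90 7",
                           "40\t10\t0", "50", ""))
  ch2 <- cs2[["7"]]
  expect_equal(ch2$tEnd - ch2$tStart, 100L)
  expect_equal(ch2$qEnd - ch2$qStart, 90L)

  # header span inconsistent with block sums: error names the chain id
  expect_error(chain_from_text(
    c("chain 900 chrA 500 + 0 120 chrB 500 + 0 90 13", "40\t10\t0", "50", "")),
    "chain 13")
})

test_that("chain write -> parse is the identity on random chains", {
  set.seed(202)
  chains <- lapply(1:25, function(i) random_chain(id = as.character(i)))
  path <- tempfile(fileext = ".chain")
  write_chain(chains, path)
  back <- read_chain(path)
  expect_equal(length(back), 25L)
  for (i in 1:25) {
    expect_equal(back[[i]]$blocks, chains[[i]]$blocks)
    for (f in c("tStart", "tEnd", "qStart", "qEnd", "qStrand", "tSize", "qSize"))
      expect_equal(back[[i]][[f]], chains[[i]][[f]])
  }
})

test_that("overlap_bases counts each base once and matches brute force", {
  a <- genomic_intervals("chrA", 0L, 500L)
  expect_equal(overlap_bases(a, genomic_intervals("chrA", 100L, 200L)), 100L)
  s <- genomic_intervals(c("chrA", "chrA"), c(400L, 450L), c(600L, 700L))
  expect_equal(overlap_bases(a, s), 100L)
  expect_equal(overlap_bases(a, s[0, ]), 0L)

  set.seed(303)
  for (rep in 1:20) {
    as <- sample.int(5000, 1); ae <- as + sample.int(5000, 1)
    ns <- sample.int(8, 1)
    ss <- sample.int(9000, ns)
    s <- data.frame(chrom = "chrA", start = ss, end = ss + sample.int(2000, ns))
    got <- overlap_bases(data.frame(chrom = "chrA", start = as, end = ae), s)
    expect_equal(got, oracle_overlap_bases(as, ae, s))
  }
})

test_that("genome tiling drops trailing partial windows", {
  expect_equal(nrow(tile_genome(c(chrA = 1500L), 500L)), 3L)
  expect_equal(nrow(tile_genome(c(chrA = 1499L), 500L)), 2L)
  set.seed(404)
  lens <- sample(1000:10000, 5)
  names(lens) <- paste0("c", 1:5)
  tl <- tile_genome(lens, 500L)
  expect_true(all(tl$end - tl$start == 500L))
  total <- nrow(tl) * 500L
  expect_lte(total, sum(lens))
  expect_gt(total, sum(lens) - 5 * 499L)
})

test_that("wig reading handles fixedStep and variableStep and round-trips", {
  path <- tempfile(fileext = ".wig")
  writeLines(c("track type=wiggle_0",
               "fixedStep chrom=chr1 start=11 step=50 span=50",
               "1.5", "2.5", "-0.25",
               "variableStep chrom=chr2 span=2",
               "101 7", "201 8"), path)
  w <- read_wig(path)
  fs <- w[w$chrom == "chr1", ]
  expect_equal(fs$start, c(10L, 60L, 110L))
  expect_equal(fs$end, fs$start + 50L)
  expect_equal(fs$score, c(1.5, 2.5, -0.25))
  vs <- w[w$chrom == "chr2", ]
  expect_equal(vs$start, c(100L, 200L))
  expect_equal(vs$end - vs$start, c(2L, 2L))

  # fixed-step write -> read round trip
  tr <- data.frame(chrom = "chrZ", start = seq(0L, 450L, 50L),
                   end = seq(50L, 500L, 50L), score = rnorm(10))
  tr$score <- round(tr$score, 6)
  out <- tempfile(fileext = ".wig")
  write_wig(tr, out)
  back <- read_wig(out)
  expect_equal(back$start, tr$start)
  expect_equal(back$score, tr$score, tolerance = 1e-9)
})

test_that("wig reader agrees with rtracklayer on a fixedStep track", {
  path <- tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=101 step=10 span=10",
               format(seq(0.1, 1, by = 0.1))), path)
  mine <- read_wig(path)
  theirs <- rtracklayer::import.wig(path)
  expect_equal(mine$start, GenomicRanges::start(theirs) - 1L)
  expect_equal(mine$end, GenomicRanges::end(theirs))
  expect_equal(mine$score, theirs$score)
})

test_that("mean_score averages over covered bases only", {
  tr <- data.frame(chrom = "chr1", start = c(0L, 100L), end = c(50L, 150L),
                   score = c(1, 3))
  x <- data.frame(chrom = c("chr1", "chr1", "chr1"),
                  start = c(0L, 25L, 200L), end = c(150L, 125L, 300L))
  got <- mean_score(tr, x)
  expect_equal(got[1], (50 * 1 + 50 * 3) / 100)
  expect_equal(got[2], (25 * 1 + 25 * 3) / 50)
  expect_true(is.na(got[3]))
})

test_that("genePred reading computes strand-aware TSS and round-trips", {
  path <- tempfile()
  writeLines(c("gA\tchr1\t+\t1000\t5000\t1000,3000,\t1200,3200,",
               "gB\tchr1\t-\t500\t900\t500,\t900,"), path)
  g <- read_genepred(path)
  expect_equal(g$tss, c(1000L, 900L))
  expect_equal(g$exon_starts[[1]], c(1000L, 3000L))
  out <- tempfile()
  write_genepred(g, out)
  g2 <- read_genepred(out)
  expect_equal(g2$txStart, g$txStart)
  expect_equal(g2$exon_ends, g$exon_ends)
})
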