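make_bed <- function(lines) {
  tmp <- tempfile(fileext = ".bed")
  writeLines(lines, tmp)
  tmp
}

test_that("BED reads convert 0-based half-open to 1-based closed", {
  p <- make_bed(c("track name=x",
                  "# comment",
                  "chr1\t0\t54\tr1\t0\t+",
                  "chr1\t99\t153\tr2\t0\t-",
                  "chr2\t10\t64"))
  gr <- read_alignments(p, "BED")
  expect_length(gr, 3)
  expect_equal(GenomicRanges::start(gr), c(1L, 100L, 11L))
  expect_equal(GenomicRanges::end(gr), c(54L, 153L, 64L))
  expect_equal(as.character(GenomicRanges::strand(gr)), c("+", "-", "*"))
})

test_that("malformed BED lines are skipped with a warning", {
  p <- make_bed(c("chr1\t0\t54\t.\t0\t+",
                  "chr1\tfoo\t54",
                  "chr1\t60\t60", # empty interval
                  "chr1\t80"))
  expect_warning(gr <- read_alignments(p, "BED"), "3 malformed")
  expect_length(gr, 1)
})

test_that("SAM text parsing honors FLAG and CIGAR", {
  sam <- c("@HD\tVN:1.6",
           paste("r1", 0, "chr1", 11, 60, "54M", "*", 0, 0,
                 strrep("A", 54), "*", sep = "\t"),
           paste("r2", 16, "chr1", 101, 60, "10M2D5M3I10M", "*", 0, 0,
                 strrep("A", 28), "*", sep = "\t"),
           paste("r3", 4, "*", 0, 0, "*", "*", 0, 0,
                 strrep("A", 54), "*", sep = "\t"),
           paste("r4", 0, "chr1", 201, 60, "*", "*", 0, 0,
                 strrep("A", 30), "*", sep = "\t"))
  tmp <- tempfile(fileext = ".sam")
  writeLines(sam, tmp)
  gr <- read_alignments(tmp, "SAM")
  expect_length(gr, 3) # unmapped r3 dropped
  expect_equal(GenomicRanges::start(gr), c(11L, 101L, 201L))
  # 10M2D5M3I10M consumes 10+2+5+10 = 27 reference bases
  expect_equal(GenomicRanges::width(gr), c(54L, 27L, 30L))
  expect_equal(as.character(GenomicRanges::strand(gr)), c("+", "-", "+"))
})

test_that("bounds validation skips or aborts on bad coordinates", {
  p <- make_bed(c("chr1\t0\t54", "chr1\t990\t1044", "chrX\t0\t54"))
  gl <- c(chr1 = 1000L)
  expect_warning(gr <- read_alignments(p, "BED", genome_lengths = gl),
                 "2 read")
  expect_length(gr, 1)
  expect_equal(GenomeInfoDb::seqlengths(gr), gl)
  expect_error(
    suppressWarnings(read_alignments(p, "BED", genome_lengths = gl,
                                     strict = TRUE)),
    "out of bounds")
})

test_that("cap_duplicates enforces absolute and adaptive caps", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(rep(10, 8), rep(10, 2), 50, 60), width = 54),
    strand = c(rep("+", 8), rep("-", 2), "+", "+"))
  out <- cap_duplicates(gr, absolute_cap = 3)
  key <- paste(GenomicRanges::start(out), GenomicRanges::strand(out))
  expect_true(all(table(key) <= 3))
  expect_length(out, 3 + 2 + 1 + 1)
  # adaptive rule: multiplicities 8,2,1,1 -> cap = ceiling(3 + 5*sd)
  m <- c(8, 2, 1, 1)
  cap <- ceiling(mean(m) + 5 * sd(m))
  expect_length(cap_duplicates(gr, k = 5), sum(pmin(m, cap)))
  # cap of 1 keeps exactly the unique positions
  expect_length(cap_duplicates(gr, absolute_cap = 1), 4)
  expect_length(cap_duplicates(GenomicRanges::GRanges()), 0)
})

test_that("extend_reads anchors at the 5' end and clips", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(100, 500, 940), width = 54),
                               strand = c("+", "-", "+"),
                               seqlengths = c(chr1 = 1000))
  ext <- extend_reads(gr, 147)
  expect_equal(GenomicRanges::start(ext), c(100L, 407L, 940L))
  expect_equal(GenomicRanges::end(ext), c(246L, 553L, 1000L)) # clipped
  expect_equal(GenomicRanges::width(ext)[1:2], c(147L, 147L))
})

test_that("dyad_intervals centers a narrow window on the fragment midpoint", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(1000, 1947), width = 54),
                               strand = c("+", "-"),
                               seqlengths = c(chr1 = 5000))
  di <- dyad_intervals(gr, fragment_length = 147, window = 20)
  expect_true(all(GenomicRanges::width(di) == 20))
  mid <- (GenomicRanges::start(di) + GenomicRanges::end(di)) / 2
  # + read 5' at 1000 -> dyad 1073; - read 5' at 2000 -> dyad 1927
  expect_true(all(abs(mid - c(1073, 1927)) <= 1))
})

test_that("build_coverage counts overlapping reads per position", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(1, 3, 3), width = 4))
  tr <- build_coverage(gr, c(chr1 = 10L))
  expect_s3_class(tr, "coverage_track")
  expect_equal(tr$values$chr1, c(1, 1, 3, 3, 2, 2, 0, 0, 0, 0))
  expect_equal(tr$total_reads, 3)
  expect_false(tr$normalized)
})

test_that("rpm_normalize scales by 1e6/total and refuses double scaling", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 3, 3), width = 4))
  tr <- build_coverage(gr, c(chr1 = 10L))
  nr <- rpm_normalize(tr)
  expect_equal(nr$values$chr1, tr$values$chr1 * 1e6 / 3)
  expect_true(nr$normalized)
  expect_error(rpm_normalize(nr), "already")
  empty <- coverage_track(list(chr1 = numeric(10)), total_reads = 0)
  expect_error(rpm_normalize(empty), "positive")
})
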