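as_rpm_track <- function(v, kind = "coverage") {
  structure(list(values = list(chr1 = v), normalized = TRUE,
                 total_reads = 1e6, kind = kind), class = "coverage_track")
}

test_that("detect_lr equals the position-scan oracle on seeded tracks", {
  for (seed in 1:5) {
    v <- random_lr_track(5000, seed)
    lr <- detect_lr(as_rpm_track(v), q = 0.05, min_len = 50, merge_gap = 20)
    o <- oracle_lr_scan(v, q = 0.05, min_len = 50, merge_gap = 20)
    expect_equal(GenomicRanges::start(lr), unname(o[, "start"]),
                 label = paste("seed", seed))
    expect_equal(GenomicRanges::end(lr), unname(o[, "end"]))
    # LRs never contain a zero-coverage position
    for (i in seq_along(lr)) {
      expect_true(all(
        v[GenomicRanges::start(lr)[i]:GenomicRanges::end(lr)[i]] > 0))
    }
  }
})

test_that("detect_lr merge rule bridges only zero-free short gaps", {
  v <- rep(100, 400)
  v[101:140] <- 0.1 # low run A
  v[151:190] <- 0.1 # low run B, 10 bp gap
  v[201:260] <- 0.1 # low run C, 10 bp gap but with a zero inside
  v[195] <- 0
  lr <- detect_lr(as_rpm_track(v), q = 0.3, min_len = 40, merge_gap = 15)
  expect_equal(GenomicRanges::start(lr), c(101L, 201L))
  expect_equal(GenomicRanges::end(lr), c(190L, 260L))
  expect_equal(unique(lr$kind), "LR")
  expect_error(detect_lr(as_rpm_track(v), q = 1.5), "0,1")
})

test_that("common_lr equals a per-position boolean AND", {
  set.seed(42)
  mk <- function() {
    s <- sort(sample(1:900, 6))
    GenomicRanges::GRanges("chr1",
                           IRanges::IRanges(s, width = sample(30:120, 6,
                                                              replace = TRUE)))
  }
  a <- mk(); b <- mk()
  clr <- common_lr(a, b, min_len = 25)
  inA <- inB <- logical(1100)
  for (i in seq_along(a)) {
    inA[GenomicRanges::start(a)[i]:GenomicRanges::end(a)[i]] <- TRUE
  }
  for (i in seq_along(b)) {
    inB[GenomicRanges::start(b)[i]:GenomicRanges::end(b)[i]] <- TRUE
  }
  r <- rle(inA & inB)
  en <- cumsum(r$lengths); st <- en - r$lengths + 1L
  keep <- r$values & r$lengths >= 25
  expect_equal(GenomicRanges::start(clr), st[keep])
  expect_equal(GenomicRanges::end(clr), en[keep])
})

test_that("correct_bias divides out the naked profile", {
  nuc <- as_rpm_track(c(4, 8, 0, 1))
  nak <- as_rpm_track(c(2, 1, 0, 8))
  corr <- correct_bias(nuc, nak, alpha = 0.5)
  expect_equal(corr$values$chr1,
               log2(c(4.5 / 2.5, 8.5 / 1.5, 1, 1.5 / 8.5)))
  expect_equal(corr$values$chr1[3], 0) # both zero -> exactly zero
  plain <- correct_bias(nuc, nak, alpha = 0.5, log2 = FALSE)
  expect_equal(plain$values$chr1[1], 4.5 / 2.5)
  raw <- structure(nuc, class = "coverage_track")
  raw$normalized <- FALSE
  expect_error(correct_bias(raw, nak), "normalized")
  short <- as_rpm_track(c(1, 2))
  expect_error(correct_bias(nuc, short), "different genomes")
})

test_that("fft_smooth preserves the mean exactly and keeps in-band content", {
  n <- 1000
  t <- seq_len(n)
  set.seed(3)
  noisy <- as_rpm_track(2 + runif(n))
  sm <- fft_smooth(noisy, keep_fraction = 0.02)
  expect_equal(mean(sm$values$chr1), mean(noisy$values$chr1),
               tolerance = 1e-12)
  # keep_fraction 0.02 of n = 1000 keeps harmonics 0..19
  inband <- as_rpm_track(2 + sin(2 * pi * 5 * t / n))
  expect_equal(fft_smooth(inband, 0.02)$values$chr1, inband$values$chr1,
               tolerance = 1e-6)
  outband <- 2 + sin(2 * pi * 100 * t / n)
  smo <- fft_smooth(as_rpm_track(outband), 0.02)$values$chr1
  expect_equal(smo, rep(mean(outband), n), tolerance = 1e-6)
  # keep_fraction = 1 is the identity
  expect_equal(fft_smooth(noisy, 1)$values$chr1, noisy$values$chr1,
               tolerance = 1e-10)
  expect_error(fft_smooth(noisy, 0), "0,1")
})

test_that("call_nucleosomes finds local maxima with footprints", {
  n <- 1000
  v <- exp(-(seq_len(n) - 500)^2 / 200)
  calls <- call_nucleosomes(as_rpm_track(v))
  expect_length(calls, 1)
  expect_equal(calls$dyad, 500)
  # spec'd footprint fields: start = dyad - 74, end = dyad + 74
  expect_equal(GenomicRanges::start(calls), 500 - 74)
  expect_equal(GenomicRanges::end(calls), 500 + 74)
  expect_true(calls$height_score > 0.99)
  # a peak too close to the edge is dropped
  edge <- exp(-(seq_len(n) - 40)^2 / 200)
  expect_length(call_nucleosomes(as_rpm_track(edge)), 0)
})

test_that("relative-height suppression removes sidelobes, keeps twins", {
  n <- 1000
  g <- function(c, h) h * exp(-(seq_len(n) - c)^2 / 60)
  # main peak + 20% satellite 40 bp away (a filter-ringing artifact)
  v1 <- g(400, 1) + g(440, 0.2)
  c1 <- call_nucleosomes(as_rpm_track(v1), window = 74, rel_height = 0.4)
  expect_equal(c1$dyad, 400)
  # main peak + 60% co-dominant twin at the same distance survives
  v2 <- g(400, 1) + g(440, 0.6)
  c2 <- call_nucleosomes(as_rpm_track(v2), window = 74, rel_height = 0.4)
  expect_length(c2, 2)
  # window = 1 disables suppression entirely
  c3 <- call_nucleosomes(as_rpm_track(v1), window = 1)
  expect_length(c3, 2)
})

test_that("calling is invariant under adding a constant to the track", {
  n <- 1000
  g <- function(c, h) h * exp(-(seq_len(n) - c)^2 / 60)
  v <- g(300, 1) + g(340, 0.2) + g(620, 0.6) + g(700, 0.5)
  base <- call_nucleosomes(as_rpm_track(v))
  shifted <- call_nucleosomes(as_rpm_track(v + 3))
  expect_equal(shifted$dyad, base$dyad)
})

test_that("the calling threshold uses the raw track when supplied", {
  n <- 1000
  v <- exp(-(seq_len(n) - 500)^2 / 200)
  # threshold from the smoothed track itself: the peak clears it
  expect_length(call_nucleosomes(as_rpm_track(v)), 1)
  # a raw track sitting entirely above the peak raises the threshold
  raw_hi <- as_rpm_track(rep(5, n))
  expect_length(call_nucleosomes(as_rpm_track(v), raw_hi), 0)
})

test_that("classify_calls applies the overlap and height rules", {
  mk_calls <- function(dyads, scores) {
    GenomicRanges::GRanges("chr1",
                           IRanges::IRanges(dyads - 74, dyads + 74),
                           dyad = dyads, height_score = scores,
                           class = NA_character_)
  }
  # dyads 80 bp apart overlap by 67 bp (> 50): both fuzzy
  cl <- classify_calls(mk_calls(c(300, 380, 700), c(0.9, 0.9, 0.9)))
  expect_equal(cl$class, c("fuzzy", "fuzzy", "well-positioned"))
  # isolated but low height score -> fuzzy
  cl2 <- classify_calls(mk_calls(c(300, 700), c(0.9, 0.2)))
  expect_equal(cl2$class, c("well-positioned", "fuzzy"))
  # spacing 100 bp -> overlap 47 <= 50: both independent
  cl3 <- classify_calls(mk_calls(c(300, 400), c(0.9, 0.9)))
  expect_equal(cl3$class, rep("well-positioned", 2))
  empty <- GenomicRanges::GRanges(dyad = integer(0),
                                  height_score = numeric(0),
                                  class = character(0))
  expect_length(classify_calls(empty), 0)
})
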