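small_cfg <- sim_config(genome_length = 2e4, n_genes = 6,
                        n_fragments = 3e4, seed = 5)

test_that("sim_config validates its arguments", {
  expect_s3_class(small_cfg, "sim_config")
  expect_error(sim_config(protection = 1.5))
  expect_error(sim_config(fragment_range = c(180, 120)))
  expect_error(sim_config(gc = 0))
  expect_error(sim_config(ndr_motif = "AANA"), "invalid sequence")
  bad_w <- setNames(rep(1, 10), letters[1:10])
  expect_error(sim_config(cut_weights = bad_w), "136")
})

test_that("default weights cover the canonical pairs with the stated bias", {
  cw <- default_cut_weights()
  dw <- default_deg_weights()
  expect_equal(names(cw), all_tetramer_pairs())
  expect_equal(names(dw), all_tetramer_pairs())
  expect_true(all(cw > 0) && all(dw > 0))
  expect_gt(cw[["ATAG.CTAT"]], cw[["AATG.CATT"]]) # central TA > central AT
  expect_equal(unname(dw[["AAAA.TTTT"]]), max(dw)) # A/T homopolymer top
})

test_that("generate_genome is deterministic and plants NDR cassettes", {
  t1 <- generate_genome(small_cfg)
  t2 <- generate_genome(small_cfg)
  expect_identical(t1$genome, t2$genome)
  expect_identical(t1$genes, t2$genes)
  expect_equal(length(t1$genes), 6)
  expect_equal(length(t1$ndrs), 12)
  expect_true(all(GenomicRanges::width(t1$ndrs) == small_cfg$ndr_length))
  # each gene is flanked by an upstream and a downstream cassette
  gs <- GenomicRanges::start(t1$genes)
  ge <- GenomicRanges::end(t1$genes)
  ns <- GenomicRanges::start(t1$ndrs)
  ne <- GenomicRanges::end(t1$ndrs)
  expect_equal(ne[seq(1, 12, 2)], gs - 1L)
  expect_equal(ns[seq(2, 12, 2)], ge + 1L)
  # cassette sequence is the recycled motif (poly-A by default)
  for (i in seq_along(t1$ndrs)) {
    expect_equal(substr(t1$genome[[1]], ns[i], ne[i]),
                 strrep("A", small_cfg$ndr_length))
  }
  expect_error(generate_genome(sim_config(genome_length = 5e3,
                                          n_genes = 10)), "overcrowded")
})

test_that("place_nucleosomes phases arrays and avoids NDRs", {
  tr <- place_nucleosomes(generate_genome(small_cfg))
  expect_s4_class(tr$dyads, "GRanges")
  expect_true(all(tr$dyads$class %in% c("sharp", "jittered")))
  expect_true(all(GenomicRanges::width(tr$dyads) == 1))
  d <- GenomicRanges::start(tr$dyads)
  expect_equal(d, sort(d))
  # sharp dyads form 165 bp-spaced arrays inside genes
  sharp <- tr$dyads[tr$dyads$class == "sharp"]
  ov <- IRanges::overlapsAny(sharp, tr$genes, ignore.strand = TRUE)
  expect_true(all(ov))
  for (i in seq_along(tr$genes)) {
    sg <- sharp[IRanges::overlapsAny(sharp, tr$genes[i],
                                     ignore.strand = TRUE)]
    if (length(sg) > 1) {
      expect_true(all(diff(GenomicRanges::start(sg)) ==
                        small_cfg$nucleosome_spacing))
    }
  }
  # no footprint (including the jitter range for fuzzy clusters) touches
  # an NDR; footprints span dyad +/- 74
  half <- ifelse(tr$dyads$class == "sharp", 74L, 74L + small_cfg$jitter)
  foot <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(tr$dyads),
    IRanges::IRanges(d - half, d + half))
  expect_false(any(IRanges::overlapsAny(foot, tr$ndrs,
                                        ignore.strand = TRUE)))
})

test_that("occupancy_track reflects sharp and jittered footprints", {
  tr <- place_nucleosomes(generate_genome(small_cfg))
  occ <- occupancy_track(tr)[[1]]
  expect_length(occ, 2e4)
  expect_true(all(occ >= 0 & occ <= 1))
  d <- GenomicRanges::start(tr$dyads)
  cls <- tr$dyads$class
  s <- d[cls == "sharp"][1]
  expect_equal(occ[(s - 74):(s + 74)], rep(1, 149))
  j <- d[cls == "jittered"][1]
  # jitter 40 < 74: the cluster center is occupied in every jittered cell
  expect_equal(occ[j], small_cfg$fuzzy_occupancy)
  # NDRs are nucleosome-free
  ns <- GenomicRanges::start(tr$ndrs)[1]
  expect_equal(occ[ns:(ns + 149)], rep(0, 150))
})

test_that("simulate_digestion emits valid, deterministic reads", {
  tr <- place_nucleosomes(generate_genome(small_cfg))
  d1 <- simulate_digestion(tr, naked = TRUE)
  d2 <- simulate_digestion(tr, naked = TRUE)
  expect_identical(d1$reads, d2$reads)
  expect_equal(length(d1$reads), small_cfg$n_fragments)
  expect_true(all(GenomicRanges::width(d1$reads) ==
                    small_cfg$read_length))
  expect_true(all(GenomicRanges::start(d1$reads) >= 1))
  expect_true(all(GenomicRanges::end(d1$reads) <= 2e4))
  fw <- GenomicRanges::width(d1$fragments)
  expect_true(all(fw >= small_cfg$fragment_range[1] &
                    fw <= small_cfg$fragment_range[2]))
  expect_gte(d1$n_attempted, small_cfg$n_fragments)
})

test_that("emitted cut tetramers equal the genomic extraction", {
  tr <- place_nucleosomes(generate_genome(small_cfg))
  dig <- simulate_digestion(tr, naked = TRUE)
  ct <- extract_cut_tetramers(dig$reads, tr$genome)
  expect_equal(ct$n_skipped, 0L)
  lab <- paste(pmin(dig$cut_tetramers, revcomp(dig$cut_tetramers)),
               pmax(dig$cut_tetramers, revcomp(dig$cut_tetramers)),
               sep = ".")
  want <- table(factor(lab, levels = all_tetramer_pairs()))
  expect_equal(unname(ct$counts), as.integer(want))
})

test_that("nucleosomal digestion is protected inside footprints", {
  tr <- place_nucleosomes(generate_genome(small_cfg))
  nak <- simulate_digestion(tr, naked = TRUE)
  nuc <- simulate_digestion(tr, naked = FALSE)
  occ <- occupancy_track(tr)[[1]]
  core <- occ == 1
  cut_rate <- function(dig) {
    cuts <- c(GenomicRanges::start(dig$fragments),
              GenomicRanges::end(dig$fragments) + 1L)
    mean(core[cuts])
  }
  # fraction of cuts landing inside fully occupied cores drops sharply
  # (linkers are short, so residual core-edge cuts remain; measured ~3x)
  expect_lt(cut_rate(nuc), 0.5 * cut_rate(nak))
  # limiting case: protection = 0 forbids cuts wherever occupancy is 1
  cfg0 <- sim_config(genome_length = 2e4, n_genes = 6, n_fragments = 1e4,
                     seed = 5, protection = 0)
  tr0 <- place_nucleosomes(generate_genome(cfg0))
  nuc0 <- simulate_digestion(tr0, naked = FALSE)
  occ0 <- occupancy_track(tr0)[[1]]
  cuts0 <- c(GenomicRanges::start(nuc0$fragments),
             GenomicRanges::end(nuc0$fragments) + 1L)
  expect_true(all(occ0[cuts0] < 1))
})

test_that("truth_report scores perfect inputs as perfect", {
  tr <- place_nucleosomes(generate_genome(small_cfg))
  d <- GenomicRanges::start(tr$dyads)
  calls <- GenomicRanges::GRanges(
    names(tr$genome), IRanges::IRanges(d - 74, d + 74), dyad = d,
    height_score = rep(1, length(d)),
    class = ifelse(tr$dyads$class == "sharp", "well-positioned", "fuzzy"))
  planted <- tr$config$cut_weights
  stats <- data.frame(pair_label = names(planted),
                      ratio = unname(planted))
  rep <- truth_report(tr, calls = calls, lrs = tr$ndrs, stats = stats)
  val <- setNames(rep$value, rep$metric)
  expect_equal(unname(val["dyad_recovery_sharp"]), 1)
  expect_equal(unname(val["dyad_recovery_all"]), 1)
  expect_equal(unname(val["sharp_classified_well"]), 1)
  expect_equal(unname(val["jittered_classified_fuzzy"]), 1)
  expect_equal(unname(val["ndr_lr_jaccard"]), 1)
  expect_equal(unname(val["weight_ratio_spearman"]), 1)
})
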