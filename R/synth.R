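#' Default MNase endonucleolytic cut weights
#'
#' Qualitative sequence preference of the primary cut: tetramers with a
#' central d(T-A) step cut most readily, central d(A-T) next; tetramers with
#' a central purine-purine (pyrimidine-pyrimidine on the other strand) step
#' are resistant. One positive weight per canonical tetramer pair.
#'
#' @return named numeric vector over the 136 pairs.
#' @export
default_cut_weights <- function() {
  pairs <- all_tetramer_pairs()
  first <- substr(pairs, 1, 4)
  central <- substr(first, 2, 3)
  pur <- c("AA", "AG", "GA", "GG")
  w <- rep(1, length(pairs))
  w[central == "TA"] <- 10
  w[central == "AT"] <- 5
  w[central %in% pur | central %in% revcomp(pur)] <- 0.5
  names(w) <- pairs
  w
}

#' Default degradation (exonucleolytic) susceptibility weights
#'
#' Controls the fragment-survival term of the digestion simulator: stretches
#' rich in these tetramers are degraded below the recovered size range and
#' appear as low-coverage regions. A/T homopolymer tetramers are most
#' susceptible, A/T-central steps intermediate.
#'
#' @return named numeric vector over the 136 pairs.
#' @export
default_deg_weights <- function() {
  pairs <- all_tetramer_pairs()
  first <- substr(pairs, 1, 4)
  at_content <- vapply(strsplit(first, ""), function(ch) {
    sum(ch %in% c("A", "T"))
  }, numeric(1))
  central <- substr(first, 2, 3)
  w <- rep(1, length(pairs))
  w[central %in% c("AA", "TT", "AT", "TA")] <- 3
  w[at_content == 4] <- 6
  names(w) <- pairs
  w
}

# expand a 136-pair weight vector to a per-4-mer-code (1..256) lookup
expand_pair_weights <- function(weights) {
  pidx <- tetramer_pair_index()
  if (is.null(names(weights)) || !all(pidx$pairs %in% names(weights))) {
    stop("weights must be named over all 136 tetramer pairs", call. = FALSE)
  }
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  unname(weights[pidx$pairs][pidx$pair_of_code])
}

#' Configuration of the synthetic MNase-digestion experiment
#'
#' Defaults emulate a yeast-like chromosome segment: gene-dense layout,
#' poly(dA:dT) nucleosome-depleted cassettes flanking each gene, 165 bp
#' nucleosome repeat (147 bp core + ~18 bp linker), ~150 bp recovered
#' fragments and strand-specific sequence-biased cut ends.
#'
#' @param genome_length chromosome length in bp.
#' @param gc background GC fraction (yeast-like 0.38).
#' @param n_genes number of non-overlapping genes to place.
#' @param gene_length min/max gene length (bp).
#' @param intergenic min/max intergenic gap between gene cassettes (bp).
#' @param ndr_motif DNA string recycled across each NDR cassette.
#' @param ndr_length NDR cassette length upstream of TSS / downstream of TTS.
#' @param nucleosome_spacing nucleosome repeat length (bp).
#' @param jitter half-width of the uniform dyad jitter of fuzzy clusters.
#' @param fuzzy_occupancy cell-population occupancy of jittered clusters in
#'   (0,1\]; delocalized nucleosomes occupy their site in fewer cells, giving
#'   the lower, broader occupancy bumps seen for fuzzy nucleosomes in vivo.
#' @param cut_weights,deg_weights named weights over the 136 tetramer pairs.
#' @param protection multiplicative factor on cut/degradation weights inside
#'   nucleosome footprints, in \[0,1\].
#' @param fragment_range min/max recovered fragment length (bp).
#' @param exo_trim_mean mean inward trimming of fragment ends (bp); 0 = off.
#' @param digestion degradation intensity; survival of a fragment is
#'   `exp(-digestion * internal degradation mass / reference mass)`.
#' @param n_fragments reads to emit.
#' @param read_length emitted read length (bp).
#' @param seed integer seed; all generator randomness derives from it
#'   (R's default Mersenne-Twister PRNG).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e5,
                       gc = 0.38,
                       n_genes = 40,
                       gene_length = c(800, 2000),
                       intergenic = c(200, 600),
                       ndr_motif = strrep("A", 15),
                       ndr_length = 150,
                       nucleosome_spacing = 165,
                       jitter = 40,
                       fuzzy_occupancy = 0.6,
                       cut_weights = default_cut_weights(),
                       deg_weights = default_deg_weights(),
                       protection = 0.05,
                       fragment_range = c(120, 180),
                       exo_trim_mean = 0,
                       digestion = 2,
                       n_fragments = 2e5,
                       read_length = 54,
                       seed = 1L) {
  stopifnot(protection >= 0, protection <= 1,
            fuzzy_occupancy > 0, fuzzy_occupancy <= 1,
            fragment_range[1] < fragment_range[2],
            gc > 0, gc < 1, genome_length >= 1000)
  check_acgt(ndr_motif)
  expand_pair_weights(cut_weights) # validates
  expand_pair_weights(deg_weights)
  structure(list(genome_length = genome_length, gc = gc, n_genes = n_genes,
                 gene_length = gene_length, intergenic = intergenic,
                 ndr_motif = ndr_motif, ndr_length = ndr_length,
                 nucleosome_spacing = nucleosome_spacing, jitter = jitter,
                 fuzzy_occupancy = fuzzy_occupancy,
                 cut_weights = cut_weights, deg_weights = deg_weights,
                 protection = protection, fragment_range = fragment_range,
                 exo_trim_mean = exo_trim_mean, digestion = digestion,
                 n_fragments = n_fragments, read_length = read_length,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic genome with genes and NDR cassettes
#'
#' Background sequence is i.i.d. at the configured GC content; genes are
#' placed left to right, non-overlapping, each flanked by an NDR cassette
#' (the configured motif recycled) upstream of the TSS and downstream of the
#' TTS. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param chrom chromosome name.
#' @return list of class `sim_truth` with `genome` (named character),
#'   `genes`, `ndrs` (GRanges), `config`, and empty slots for dyads/reads
#'   filled by later stages.
#' @export
generate_genome <- function(config, chrom = "chrS") {
  set.seed(config$seed)
  L <- as.integer(config$genome_length)
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  chars <- sample(BASES, L, replace = TRUE, prob = p[BASES])
  gene_s <- integer(0); gene_e <- integer(0); gene_strand <- character(0)
  ndr_s <- integer(0); ndr_e <- integer(0)
  pos <- 1L
  nd <- as.integer(config$ndr_length)
  for (g in seq_len(config$n_genes)) {
    gap <- sample(config$intergenic[1]:config$intergenic[2], 1)
    glen <- sample(config$gene_length[1]:config$gene_length[2], 1)
    start_ndr <- pos + gap
    gs <- start_ndr + nd
    ge <- gs + glen - 1L
    end_ndr_e <- ge + nd
    if (end_ndr_e > L - config$intergenic[1]) {
      stop("overcrowded config: ", config$n_genes, " genes do not fit in ",
           L, " bp (placed ", g - 1L, ")", call. = FALSE)
    }
    gene_s <- c(gene_s, gs); gene_e <- c(gene_e, ge)
    gene_strand <- c(gene_strand, sample(c("+", "-"), 1))
    ndr_s <- c(ndr_s, start_ndr, ge + 1L)
    ndr_e <- c(ndr_e, gs - 1L, end_ndr_e)
    pos <- end_ndr_e + 1L
  }
  # write NDR cassettes over the background
  motif <- seq_to_chars(config$ndr_motif)
  for (i in seq_along(ndr_s)) {
    span <- ndr_s[i]:ndr_e[i]
    chars[span] <- motif[((seq_along(span) - 1L) %% length(motif)) + 1L]
  }
  genome <- setNames(paste(chars, collapse = ""), chrom)
  genes <- if (length(gene_s) > 0) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(gene_s, gene_e),
                           strand = gene_strand,
                           gene_id = sprintf("gene%03d", seq_along(gene_s)))
  } else {
    GenomicRanges::GRanges()
  }
  ndrs <- if (length(ndr_s) > 0) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(ndr_s, ndr_e),
                           kind = "NDR")
  } else {
    GenomicRanges::GRanges()
  }
  structure(list(genome = genome, genes = genes, ndrs = ndrs,
                 dyads = NULL, config = config),
            class = "sim_truth")
}

#' Plant nucleosome dyads on a synthetic genome
#'
#' Sharp, phased arrays fill each gene starting one linker downstream of the
#' TSS (dyads every `nucleosome_spacing` bp); intergenic non-NDR background
#' receives cluster centres of class "jittered" whose positional uncertainty
#' (+/- `jitter` bp across cells) enters the digestion model as fractional
#' occupancy. No footprint (including jitter range) intersects an NDR.
#'
#' @param truth a `sim_truth` from [generate_genome()].
#' @return the `sim_truth` with `dyads` filled in (GRanges, width 1, column
#'   `class` in sharp/jittered).
#' @export
place_nucleosomes <- function(truth) {
  config <- truth$config
  set.seed(config$seed + 1L)
  chrom <- names(truth$genome)
  L <- nchar(truth$genome[[1]])
  spacing <- config$nucleosome_spacing
  linker <- spacing - 147L
  dy <- integer(0); cls <- character(0)
  if (length(truth$genes) > 0) {
    for (i in seq_along(truth$genes)) {
      gs <- GenomicRanges::start(truth$genes)[i]
      ge <- GenomicRanges::end(truth$genes)[i]
      if (as.character(GenomicRanges::strand(truth$genes))[i] == "+") {
        d <- gs + linker + 74L
        while (d + 74L <= ge) {
          dy <- c(dy, d); cls <- c(cls, "sharp")
          d <- d + spacing
        }
      } else {
        d <- ge - linker - 74L
        while (d - 74L >= gs) {
          dy <- c(dy, d); cls <- c(cls, "sharp")
          d <- d - spacing
        }
      }
    }
  }
  # jittered clusters in intergenic, NDR-free background
  margin <- 74L + config$jitter
  blocked <- GenomicRanges::reduce(c(
    GenomicRanges::granges(truth$genes),
    GenomicRanges::granges(truth$ndrs)), ignore.strand = TRUE)
  free <- if (length(blocked) > 0) {
    GenomicRanges::setdiff(GenomicRanges::GRanges(chrom,
                                                  IRanges::IRanges(1, L)),
                           blocked, ignore.strand = TRUE)
  } else {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(1, L))
  }
  for (i in seq_along(free)) {
    lo <- GenomicRanges::start(free)[i] + margin
    hi <- GenomicRanges::end(free)[i] - margin
    if (hi < lo) next
    centers <- seq.int(lo, hi, by = spacing)
    dy <- c(dy, centers)
    cls <- c(cls, rep("jittered", length(centers)))
  }
  o <- order(dy)
  truth$dyads <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(dy[o], width = 1L), class = cls[o])
  truth
}

#' Planted nucleosome occupancy track
#'
#' Fraction of cells in which each position is inside a nucleosome footprint:
#' 1 within sharp footprints; for jittered clusters, `fuzzy_occupancy` times
#' the trapezoid obtained by convolving the 147 bp footprint with the
#' uniform +/- jitter. Capped at 1.
#'
#' @param truth `sim_truth` with dyads placed.
#' @return named list with one numeric vector per chromosome.
#' @export
occupancy_track <- function(truth) {
  config <- truth$config
  L <- nchar(truth$genome[[1]])
  occ <- numeric(L)
  if (is.null(truth$dyads) || length(truth$dyads) == 0) {
    return(setNames(list(occ), names(truth$genome)))
  }
  d <- GenomicRanges::start(truth$dyads)
  cls <- truth$dyads$class
  J <- config$jitter
  for (i in seq_along(d)) {
    if (cls[i] == "sharp") {
      span <- max(1L, d[i] - 74L):min(L, d[i] + 74L)
      occ[span] <- pmin(1, occ[span] + 1)
    } else {
      span <- max(1L, d[i] - 74L - J):min(L, d[i] + 74L + J)
      off <- abs(span - d[i])
      # P(|off - U(-J,J)| <= 74) on the integer lattice
      frac <- (pmin(J, off + 74L) - pmax(-J, off - 74L) + 1L) / (2L * J + 1L)
      frac[frac < 0] <- 0
      occ[span] <- pmin(1, occ[span] + config$fuzzy_occupancy * frac)
    }
  }
  setNames(list(occ), names(truth$genome))
}

#' Simulate sequence-biased MNase digestion
#'
#' Cut probability at an inter-base position is the tetramer cut weight
#' spanning it, attenuated by `protection` inside nucleosome footprints
#' (expected occupancy for jittered clusters). Fragments are drawn as cut
#' pairs whose separation falls in `fragment_range`; each candidate survives
#' recovery with probability `exp(-digestion * D / D_ref)` where D is the
#' protection-attenuated degradation mass strictly between the two cuts
#' (tetramer `deg_weights`) and D_ref the genome-average mass of one
#' fragment — over-digestible stretches drop out of the sequenced pool.
#' Optionally each end is trimmed inward by a geometric number of bases.
#' Reads of `read_length` bp are emitted from fragment 5' ends on a uniform
#' random strand.
#'
#' @param truth `sim_truth`; its `dyads` are used unless `naked = TRUE`.
#' @param naked TRUE simulates the histone-free sample (no protection).
#' @param n_fragments overrides `config$n_fragments` when given.
#' @param max_attempts_factor abort after this multiple of `n_fragments`
#'   candidate draws without filling the quota.
#' @return list with `reads` (GRanges with seqlengths), `cut_tetramers`
#'   (oriented 4-mer at each read's 5' cut), `fragments` (GRanges) and
#'   `n_attempted`.
#' @export
simulate_digestion <- function(truth, naked = FALSE, n_fragments = NULL,
                               max_attempts_factor = 200) {
  config <- truth$config
  set.seed(config$seed + if (naked) 2L else 3L)
  n_frag <- if (is.null(n_fragments)) config$n_fragments else n_fragments
  chrom <- names(truth$genome)
  seqstr <- truth$genome[[1]]
  L <- nchar(seqstr)
  codes <- base_codes(seq_to_chars(seqstr))
  kc <- kmer_codes(codes, 4L)
  w_cut <- expand_pair_weights(config$cut_weights)
  w_deg <- expand_pair_weights(config$deg_weights)
  # cut index s = cut before base s; its tetramer spans bases s-2..s+1
  smax <- L - 1L
  w <- numeric(L)
  dg <- numeric(L)
  s_range <- 3:smax
  w[s_range] <- w_cut[kc[s_range - 2L]]
  dg[s_range] <- w_deg[kc[s_range - 2L]]
  w[is.na(w)] <- 0
  dg[is.na(dg)] <- 0
  if (!naked) {
    if (is.null(truth$dyads)) stop("dyads not placed; run place_nucleosomes",
                                   call. = FALSE)
    occ <- occupancy_track(truth)[[1]]
    mult <- 1 - (1 - config$protection) * pmin(occ, 1)
    w <- w * mult
    dg <- dg * mult
  }
  fmin <- as.integer(config$fragment_range[1])
  fmax <- as.integer(config$fragment_range[2])
  d_ref <- mean(dg[s_range]) * (fmin + fmax) / 2
  w_first <- w
  w_first[seq.int(max(1L, smax - fmin + 1L), L)] <- 0 # no room for a mate
  cum_w <- cumsum(w)
  cum_dg <- cumsum(dg)
  acc_i <- integer(0); acc_j <- integer(0)
  attempted <- 0L
  max_attempts <- max_attempts_factor * n_frag
  batch <- max(1e5, 2L * n_frag)
  while (length(acc_i) < n_frag && attempted < max_attempts) {
    nb <- min(batch, max_attempts - attempted)
    attempted <- attempted + nb
    i <- sample.int(L, nb, replace = TRUE, prob = w_first)
    hi <- pmin(i + fmax, smax)
    lo <- i + fmin
    Tm <- cum_w[hi] - cum_w[lo - 1L]
    ok <- Tm > 0
    target <- cum_w[lo - 1L] + runif(nb) * Tm
    j <- findInterval(target, cum_w) + 1L
    ok <- ok & j >= lo & j <= hi
    # recovery survival against internal degradation
    S <- cum_dg[pmax(j - 1L, 1L)] - cum_dg[i]
    surv <- exp(-config$digestion * S / d_ref)
    ok <- ok & runif(nb) < surv
    acc_i <- c(acc_i, i[ok])
    acc_j <- c(acc_j, j[ok])
  }
  if (length(acc_i) < n_frag) {
    stop("digestion simulator could not draw ", n_frag, " fragments in ",
         attempted, " attempts (acceptance ",
         signif(length(acc_i) / attempted, 3), "); relax digestion or ",
         "fragment_range", call. = FALSE)
  }
  acc_i <- acc_i[seq_len(n_frag)]
  acc_j <- acc_j[seq_len(n_frag)]
  if (config$exo_trim_mean > 0) {
    wrel <- pmax(w[acc_i], 1e-9) / mean(w[s_range][w[s_range] > 0])
    t5 <- rgeom(n_frag, 1 / (1 + config$exo_trim_mean * wrel))
    wrel3 <- pmax(w[acc_j], 1e-9) / mean(w[s_range][w[s_range] > 0])
    t3 <- rgeom(n_frag, 1 / (1 + config$exo_trim_mean * wrel3))
    keep_len <- (acc_j - t3) - (acc_i + t5)
    shrink_ok <- keep_len >= config$read_length
    acc_i <- acc_i + ifelse(shrink_ok, t5, 0L)
    acc_j <- acc_j - ifelse(shrink_ok, t3, 0L)
  }
  minus <- runif(n_frag) < 0.5
  rl <- as.integer(config$read_length)
  start <- ifelse(minus, acc_j - rl, acc_i)
  end <- ifelse(minus, acc_j - 1L, acc_i + rl - 1L)
  reads <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, end),
    strand = ifelse(minus, "-", "+"))
  GenomeInfoDb::seqlengths(reads) <- setNames(L, chrom)
  tets <- all_kmers(4)
  rc_code <- tetramer_rc_codes()
  code5 <- ifelse(minus, rc_code[kc[acc_j - 2L]], kc[acc_i - 2L])
  list(reads = reads,
       cut_tetramers = tets[code5],
       fragments = GenomicRanges::GRanges(
         chrom, IRanges::IRanges(acc_i, acc_j - 1L)),
       n_attempted = attempted)
}

#' Recovery metrics against planted ground truth
#'
#' @param truth `sim_truth` with dyads placed.
#' @param calls optional GRanges from [call_nucleosomes()] (classified or
#'   not).
#' @param lrs optional GRanges of detected low-coverage regions.
#' @param stats optional enrichment table from [tetramer_enrichment()].
#' @param tol dyad matching tolerance in bp (default 20).
#' @return data.frame with columns `metric`, `value`.
#' @export
truth_report <- function(truth, calls = NULL, lrs = NULL, stats = NULL,
                         tol = 20) {
  out <- list()
  if (!is.null(calls) && !is.null(truth$dyads)) {
    td <- GenomicRanges::start(truth$dyads)
    cls <- truth$dyads$class
    cd <- if (length(calls) > 0) calls$dyad else integer(0)
    near <- function(x) {
      if (length(cd) == 0) rep(FALSE, length(x))
      else vapply(x, function(p) any(abs(cd - p) <= tol), logical(1))
    }
    sharp <- td[cls == "sharp"]
    out$dyad_recovery_sharp <- if (length(sharp)) mean(near(sharp)) else NA
    out$dyad_recovery_all <- if (length(td)) mean(near(td)) else NA
    if (length(calls) > 0 && !all(is.na(calls$class))) {
      match_class <- function(planted, want, tol_cls) {
        if (length(planted) == 0 || length(cd) == 0) return(NA_real_)
        hit <- vapply(planted, function(p) {
          dists <- abs(cd - p)
          k <- which.min(dists)
          dists[k] <= tol_cls && identical(calls$class[k], want)
        }, logical(1))
        mean(hit)
      }
      out$sharp_classified_well <- match_class(sharp, "well-positioned", tol)
      jit <- td[cls == "jittered"]
      out$jittered_classified_fuzzy <-
        match_class(jit, "fuzzy", tol + truth$config$jitter)
    }
  }
  if (!is.null(lrs) && length(truth$ndrs) > 0) {
    lr_red <- GenomicRanges::reduce(GenomicRanges::granges(lrs),
                                    ignore.strand = TRUE)
    jac <- vapply(seq_along(truth$ndrs), function(i) {
      ndr <- truth$ndrs[i]
      ov <- GenomicRanges::intersect(GenomicRanges::granges(ndr), lr_red,
                                     ignore.strand = TRUE)
      inter <- sum(GenomicRanges::width(ov))
      if (inter == 0) return(0)
      touching <- IRanges::subsetByOverlaps(lr_red, ndr)
      uni <- sum(GenomicRanges::width(GenomicRanges::reduce(
        c(GenomicRanges::granges(ndr), touching), ignore.strand = TRUE)))
      inter / uni
    }, numeric(1))
    out$ndr_lr_jaccard <- mean(jac)
  }
  if (!is.null(stats)) {
    planted <- truth$config$cut_weights[stats$pair_label]
    out$weight_ratio_spearman <-
      cor(planted, stats$ratio, method = "spearman", use = "complete.obs")
  }
  data.frame(metric = names(out), value = unlist(out, use.names = FALSE),
             row.names = NULL)
}
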