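# reverse-complement permutation on 4-mer integer codes (1..256)
tetramer_rc_codes <- function() {
  tets <- all_kmers(4)
  match(revcomp(tets), tets)
}

#' Canonical tetramer pair label
#'
#' A tetramer and its reverse complement form one strand-symmetric pair,
#' labelled `"ABCD.WXYZ"` with the lexicographically smaller member first
#' (palindromes pair with themselves, e.g. `"CTAG.CTAG"`).
#'
#' @param tetramer DNA string of length 4.
#' @return pair label string.
#' @export
canonical_pair <- function(tetramer) {
  check_acgt(tetramer)
  rc <- revcomp(tetramer)
  paste(pmin(tetramer, rc), pmax(tetramer, rc), sep = ".")
}

#' All 136 canonical tetramer pair labels
#' @return character vector, sorted.
#' @export
all_tetramer_pairs <- function() {
  tets <- all_kmers(4)
  sort(unique(paste(pmin(tets, revcomp(tets)),
                    pmax(tets, revcomp(tets)), sep = ".")))
}

# map each 4-mer code (1..256) onto its pair index (1..136)
tetramer_pair_index <- function() {
  tets <- all_kmers(4)
  labels <- paste(pmin(tets, revcomp(tets)), pmax(tets, revcomp(tets)),
                  sep = ".")
  pairs <- all_tetramer_pairs()
  list(pair_of_code = match(labels, pairs), pairs = pairs)
}

#' Cut-site tetramers at read 5' ends
#'
#' For every read, the MNase cut is at the fragment's 5' boundary; the cut
#' tetramer is the two bases upstream plus the two bases downstream of that
#' boundary, read on the fragment's strand. Counts are collapsed into the
#' 136 reverse-complement pairs. Sites whose 4 bp window runs off the
#' chromosome or contains N are skipped and tallied.
#'
#' @param reads GRanges of alignments (strand required; `*` treated as `+`).
#' @param genome named character vector / DNAStringSet.
#' @param end which fragment end to count: `"5p"` (default; the certified
#'   cleavage for single-end data), `"3p"`, or `"both"`.
#' @return list with `counts` (named integer over the 136 pairs), `n_sites`
#'   and `n_skipped`.
#' @export
extract_cut_tetramers <- function(reads, genome, end = c("5p", "3p", "both")) {
  end <- match.arg(end)
  genome <- as_genome_strings(genome)
  rc_code <- tetramer_rc_codes()
  pidx <- tetramer_pair_index()
  counts <- integer(length(pidx$pairs))
  n_sites <- 0L
  n_skipped <- 0L
  for (chrom in unique(as.character(GenomicRanges::seqnames(reads)))) {
    if (!chrom %in% names(genome)) {
      stop("genome does not cover chromosome ", chrom, call. = FALSE)
    }
    rr <- reads[GenomicRanges::seqnames(reads) == chrom]
    codes <- base_codes(seq_to_chars(genome[[chrom]]))
    kc <- kmer_codes(codes, 4L)
    L <- length(codes)
    minus <- as.character(GenomicRanges::strand(rr)) == "-"
    s5 <- ifelse(minus, GenomicRanges::end(rr) + 1L, GenomicRanges::start(rr))
    s3 <- ifelse(minus, GenomicRanges::start(rr), GenomicRanges::end(rr) + 1L)
    want <- switch(end,
                   "5p" = cbind(s5, minus),
                   "3p" = cbind(s3, !minus),
                   "both" = rbind(cbind(s5, minus), cbind(s3, !minus)))
    cut <- want[, 1]
    on_minus <- want[, 2] == 1
    # tetramer spans bases cut-2 .. cut+1
    valid <- cut >= 3L & cut <= L - 1L
    code <- rep(NA_integer_, length(cut))
    code[valid] <- kc[cut[valid] - 2L]
    code[on_minus & !is.na(code)] <- rc_code[code[on_minus & !is.na(code)]]
    ok <- !is.na(code)
    n_skipped <- n_skipped + sum(!ok)
    n_sites <- n_sites + sum(ok)
    tab <- tabulate(pidx$pair_of_code[code[ok]], nbins = length(pidx$pairs))
    counts <- counts + tab
  }
  names(counts) <- pidx$pairs
  list(counts = counts, n_sites = n_sites, n_skipped = n_skipped)
}

#' Genomic tetramer background probabilities
#'
#' Counts all overlapping 4-mers on the forward strand of every chromosome,
#' folds in reverse-complement counts by symmetry, collapses to the 136
#' canonical pairs and normalizes to sum 1.
#'
#' @param genome named character vector / DNAStringSet.
#' @return named numeric vector of probabilities over the 136 pairs.
#' @export
genome_background <- function(genome) {
  genome <- as_genome_strings(genome)
  rc_code <- tetramer_rc_codes()
  pidx <- tetramer_pair_index()
  counts <- numeric(length(pidx$pairs))
  for (chrom in names(genome)) {
    kc <- kmer_codes(base_codes(seq_to_chars(genome[[chrom]])), 4L)
    kc <- kc[!is.na(kc)]
    if (length(kc) == 0) next
    fwd <- tabulate(kc, nbins = 256L)
    both <- fwd + fwd[rc_code]
    counts <- counts + tapply(both, pidx$pair_of_code, sum)
  }
  if (sum(counts) == 0) stop("genome too short for tetramer counting",
                             call. = FALSE)
  p <- counts / sum(counts)
  names(p) <- pidx$pairs
  p
}

# two-sided binomial p-value; exact for moderate n, normal approximation
# with continuity correction beyond
binom_pvalue <- function(k, n, p0, exact_max_n = 1e5) {
  if (n <= exact_max_n) {
    binom.test(k, n, p0)$p.value
  } else {
    z <- (abs(k - n * p0) - 0.5) / sqrt(n * p0 * (1 - p0))
    min(1, 2 * pnorm(-max(0, z)))
  }
}

#' Tetramer enrichment statistics at cut sites
#'
#' Enrichment ratio of each reverse-complement-collapsed tetramer pair
#' relative to its genomic background frequency, with a two-sided binomial
#' test. Reported p-values are floored at 1e-18.
#'
#' @param counts named integer vector over the 136 pairs
#'   (from [extract_cut_tetramers()]).
#' @param n_sites total usable cut sites.
#' @param background named probability vector over the 136 pairs
#'   (from [genome_background()]).
#' @return data.frame with columns `pair_label`, `observed`, `n_sites`,
#'   `background_prob`, `ratio`, `p_value`, sorted by decreasing ratio.
#' @export
tetramer_enrichment <- function(counts, n_sites, background) {
  if (n_sites <= 0) stop("n_sites must be positive", call. = FALSE)
  pairs <- names(counts)
  if (is.null(pairs) || !all(pairs %in% names(background))) {
    stop("counts and background must be named over the same pairs",
         call. = FALSE)
  }
  bg <- background[pairs]
  ratio <- (counts / n_sites) / bg
  ratio[bg == 0] <- NA_real_
  pv <- vapply(seq_along(pairs), function(i) {
    if (bg[i] == 0) return(NA_real_)
    max(1e-18, binom_pvalue(counts[i], n_sites, bg[i]))
  }, numeric(1))
  out <- data.frame(pair_label = pairs,
                    observed = as.integer(counts),
                    n_sites = n_sites,
                    background_prob = as.numeric(bg),
                    ratio = as.numeric(ratio),
                    p_value = pv,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$ratio), ]
}
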