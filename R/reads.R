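#' Read mapped alignments from BED6 or SAM text
#'
#' BED is consumed natively (0-based half-open converted to 1-based GRanges);
#' SAM text is parsed minimally: unmapped reads (FLAG 0x4) are skipped, FLAG
#' 0x10 sets the minus strand, the reference span is taken from the CIGAR
#' (M/D/N/=/X operations) falling back to the sequence length. Malformed
#' lines are counted and reported as a warning.
#'
#' @param path input file.
#' @param format `"BED"` or `"SAM"`.
#' @param genome_lengths optional named vector of chromosome lengths used to
#'   validate coordinates.
#' @param strict when TRUE, a read on an unknown chromosome or out of bounds
#'   aborts; otherwise it is skipped with a warning.
#' @return [GenomicRanges::GRanges] of read alignments.
#' @export
read_alignments <- function(path, format = c("BED", "SAM"),
                            genome_lengths = NULL, strict = FALSE) {
  format <- match.arg(format)
  gr <- if (format == "BED") read_bed_reads(path) else read_sam_text(path)
  if (length(gr) == 0) {
    warning("no alignments parsed from ", path)
    return(gr)
  }
  if (!is.null(genome_lengths)) {
    known <- as.character(GenomicRanges::seqnames(gr)) %in%
      names(genome_lengths)
    inb <- known &
      GenomicRanges::start(gr) >= 1 &
      GenomicRanges::end(gr) <=
        unname(genome_lengths[as.character(GenomicRanges::seqnames(gr))])
    inb[is.na(inb)] <- FALSE
    if (any(!inb)) {
      msg <- paste0(sum(!inb), " read(s) on unknown chromosomes or out of ",
                    "bounds")
      if (strict) stop(msg, call. = FALSE)
      warning(msg, "; skipped")
      gr <- gr[inb]
    }
    GenomeInfoDb::seqlevels(gr) <- names(genome_lengths)
    GenomeInfoDb::seqlengths(gr) <- unname(genome_lengths)
  }
  gr
}

read_bed_reads <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf < 3
  starts <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  bad <- bad | is.na(starts) | is.na(ends) | starts < 0 | ends <= starts
  if (any(bad)) warning(sum(bad), " malformed BED line(s) skipped")
  keep <- which(!bad)
  if (length(keep) == 0) return(GenomicRanges::GRanges())
  strand <- vapply(fields[keep], function(f) {
    if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "*"
  }, character(1))
  GenomicRanges::GRanges(
    vapply(fields[keep], `[`, "", 1),
    IRanges::IRanges(start = starts[keep] + 1L, end = ends[keep]),
    strand = strand
  )
}

cigar_ref_span <- function(cigar, seq) {
  if (cigar == "*") return(nchar(seq))
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(toks) == 0) return(NA_integer_)
  op <- substring(toks, nchar(toks))
  len <- as.integer(substring(toks, 1, nchar(toks) - 1))
  sum(len[op %in% c("M", "D", "N", "=", "X")])
}

read_sam_text <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^@", lines) & nzchar(lines)]
  if (length(lines) == 0) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 11
  if (any(!ok)) warning(sum(!ok), " malformed SAM line(s) skipped")
  fields <- fields[ok]
  flag <- as.integer(vapply(fields, `[`, "", 2))
  rname <- vapply(fields, `[`, "", 3)
  pos <- as.integer(vapply(fields, `[`, "", 4))
  cig <- vapply(fields, `[`, "", 6)
  seqf <- vapply(fields, `[`, "", 10)
  mapped <- !bitwAnd(flag, 4L) & rname != "*" & !is.na(pos) & pos > 0
  if (!any(mapped)) return(GenomicRanges::GRanges())
  span <- mapply(cigar_ref_span, cig[mapped], seqf[mapped])
  GenomicRanges::GRanges(
    rname[mapped],
    IRanges::IRanges(start = pos[mapped], width = span),
    strand = ifelse(bitwAnd(flag[mapped], 16L) > 0, "-", "+")
  )
}

#' Cap over-represented duplicate reads
#'
#' Reads sharing (chromosome, start, strand) beyond a multiplicity cap are
#' discarded to damp PCR amplification artifacts. The cap defaults to
#' `ceiling(mean + k * sd)` of the multiplicity distribution; an absolute cap
#' can be given instead. Deterministic: the first `cap` occurrences in input
#' order are kept.
#'
#' @param reads GRanges of alignments.
#' @param k multiplier on the multiplicity standard deviation (default 5).
#' @param absolute_cap optional fixed cap overriding the adaptive rule.
#' @return filtered GRanges.
#' @export
cap_duplicates <- function(reads, k = 5, absolute_cap = NULL) {
  if (length(reads) == 0) return(reads)
  key <- paste(GenomicRanges::seqnames(reads), GenomicRanges::start(reads),
               GenomicRanges::strand(reads), sep = ":")
  mult <- table(key)
  cap <- if (!is.null(absolute_cap)) {
    absolute_cap
  } else {
    m <- as.numeric(mult)
    s <- stats::sd(m)
    if (is.na(s)) s <- 0
    max(1, ceiling(mean(m) + k * s))
  }
  occ <- stats::ave(rep(1L, length(reads)), key, FUN = cumsum)
  reads[occ <= cap]
}

#' Extend reads from their 5' end to a fixed length
#'
#' Standard MNase-seq fragment reconstruction: single-end reads only certify
#' the fragment's 5' cleavage, so before building occupancy they are resized
#' to the expected fragment length, anchored at the 5' end and clipped at
#' chromosome boundaries (requires seqlengths on `reads`).
#'
#' @param reads GRanges with strand and seqlengths.
#' @param width target length in bp (default 147).
#' @return resized GRanges.
#' @export
extend_reads <- function(reads, width = 147) {
  out <- suppressWarnings(
    GenomicRanges::resize(reads, width = width, fix = "start"))
  GenomicRanges::trim(out)
}

#' Dyad-window intervals from single-end reads
#'
#' For nucleosome positioning, plain coverage of full fragments is a poor
#' peak locator: convolving the dyad density with a ~147 bp box lets a tall
#' neighboring nucleosome pull the maximum tens of bp off a weaker dyad.
#' Instead, each read is extended from its 5' end to the expected fragment
#' length (the fragment midpoint then estimates the dyad to within half the
#' fragment-length spread) and trimmed to a narrow window around that
#' midpoint. Coverage of these windows is a sharp, dyad-centered occupancy
#' signal.
#'
#' @param reads GRanges with strand and seqlengths.
#' @param fragment_length expected fragment length in bp (default 147).
#' @param window width of the retained central window in bp (default 20,
#'   matching the dyad-inference uncertainty from fragment-length spread).
#' @return GRanges of dyad-window intervals.
#' @export
dyad_intervals <- function(reads, fragment_length = 147, window = 20) {
  frag <- suppressWarnings(
    GenomicRanges::resize(reads, width = fragment_length, fix = "start"))
  GenomicRanges::trim(suppressWarnings(
    GenomicRanges::resize(frag, width = window, fix = "center")))
}

#' Per-base-pair raw coverage
#'
#' The value at a position is the number of reads whose interval contains it.
#'
#' @param reads GRanges of alignments.
#' @param genome_lengths named vector of chromosome lengths.
#' @return raw `coverage_track` with `total_reads = length(reads)`.
#' @export
build_coverage <- function(reads, genome_lengths) {
  GenomeInfoDb::seqlevels(reads) <- names(genome_lengths)
  GenomeInfoDb::seqlengths(reads) <- unname(genome_lengths)
  cov <- GenomicRanges::coverage(reads)
  values <- lapply(names(genome_lengths), function(ch) {
    as.numeric(cov[[ch]])
  })
  names(values) <- names(genome_lengths)
  coverage_track(values, normalized = FALSE, total_reads = length(reads))
}
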