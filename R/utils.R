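#' @import methods
#' @importFrom stats quantile fft rbinom runif rgeom rlnorm setNames ecdf
#'   pnorm cor binom.test
#' @importFrom utils read.table write.table head tail
NULL

BASES <- c("A", "C", "G", "T")
PARAM_NAMES <- c("shift", "slide", "rise", "tilt", "roll", "twist")

# sign flips applied to shift (1) and tilt (4) when a step context is read on
# the opposite strand
STRAND_FLIP <- c(-1, 1, 1, -1, 1, 1)

#' Reverse complement of a plain character DNA string
#'
#' Thin vectorized wrapper used for k-mer bookkeeping; full sequences go
#' through [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

stop_invalid_sequence <- function(x) {
  stop("invalid sequence: non-ACGT character in '", x, "'", call. = FALSE)
}

check_acgt <- function(x) {
  if (any(!strsplit(x, "", fixed = TRUE)[[1]] %in% BASES)) {
    stop_invalid_sequence(x)
  }
  invisible(TRUE)
}

# integer codes A=0 C=1 G=2 T=3; NA for anything else (N etc.)
base_codes <- function(seq_chars) {
  match(seq_chars, BASES) - 1L
}

# encode all k-mers of a coded sequence as 1-based integers in 1..4^k;
# positions whose window contains NA (or falls off the end) are NA
kmer_codes <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(integer(0))
  out <- codes[seq_len(n - k + 1L)]
  for (j in 2:k) {
    out <- out * 4L + codes[seq.int(j, n - k + j)]
  }
  out + 1L
}

# all k-mers in code order (index i corresponds to kmer_codes value i)
all_kmers <- function(k) {
  grid <- expand.grid(rep(list(BASES), k), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; we need the last fastest
  apply(grid[, k:1, drop = FALSE], 1, paste, collapse = "")
}

seq_to_chars <- function(seq) {
  if (inherits(seq, "DNAString")) seq <- as.character(seq)
  strsplit(toupper(seq), "", fixed = TRUE)[[1]]
}

#' Moving average with NA propagation at the borders
#' @noRd
moving_average <- function(x, window) {
  if (window <= 1) return(x)
  if (window %% 2 == 0) stop("smooth_window must be odd", call. = FALSE)
  half <- (window - 1) / 2
  n <- length(x)
  out <- rep(NA_real_, n)
  cs <- cumsum(ifelse(is.na(x), 0, x))
  nas <- cumsum(is.na(x))
  idx <- seq_len(n)
  lo <- idx - half
  hi <- idx + half
  ok <- lo >= 1 & hi <= n
  sum_ok <- cs[hi[ok]] - c(0, cs)[lo[ok]]
  na_ok <- nas[hi[ok]] - c(0, nas)[lo[ok]]
  vals <- ifelse(na_ok > 0, NA_real_, sum_ok / window)
  out[ok] <- vals
  out
}
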