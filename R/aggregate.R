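#' Metagene profile of a track around anchors
#'
#' Averages a per-base track over windows centered on anchor positions (TSSs,
#' TTSs, dyads...). Minus-strand windows are reversed so offset +x always
#' points downstream in gene orientation. Out-of-bounds positions are ignored
#' and the per-offset contributing counts reported; anchors with a completely
#' empty window are skipped and tallied.
#'
#' @param track a `coverage_track` or a named list of numeric vectors.
#' @param anchors GRanges of width-1 positions with strand (`*` = `+`).
#' @param flank half-window size W in bp; profile spans offsets -W..W.
#' @return data.frame with columns `offset`, `mean`, `n`, plus attribute
#'   `n_skipped`.
#' @export
anchor_profile <- function(track, anchors, flank = 1000) {
  if (flank <= 0) stop("flank must be positive", call. = FALSE)
  if (length(anchors) == 0) stop("anchors must be non-empty", call. = FALSE)
  values <- if (inherits(track, "coverage_track")) track$values else track
  width <- 2L * flank + 1L
  sums <- numeric(width)
  counts <- integer(width)
  skipped <- 0L
  chroms <- as.character(GenomicRanges::seqnames(anchors))
  pos <- GenomicRanges::start(anchors)
  minus <- as.character(GenomicRanges::strand(anchors)) == "-"
  offs <- seq.int(-flank, flank)
  for (i in seq_along(anchors)) {
    v <- values[[chroms[i]]]
    if (is.null(v)) {
      skipped <- skipped + 1L
      next
    }
    p <- pos[i] + offs
    ok <- p >= 1 & p <= length(v)
    if (!any(ok)) {
      skipped <- skipped + 1L
      next
    }
    w <- rep(NA_real_, width)
    w[ok] <- v[p[ok]]
    if (minus[i]) w <- rev(w)
    use <- !is.na(w)
    sums[use] <- sums[use] + w[use]
    counts <- counts + use
  }
  out <- data.frame(offset = offs,
                    mean = ifelse(counts > 0, sums / counts, NA_real_),
                    n = counts)
  attr(out, "n_skipped") <- skipped
  out
}

#' Metagene profile around region midpoints
#'
#' As [anchor_profile()] with strandless anchors at
#' `floor((start + end) / 2)` of each region (0-based midpoint convention,
#' mapped onto the 1-based track).
#'
#' @param track a `coverage_track` or named list of numeric vectors.
#' @param regions GRanges (e.g. LRs or CLRs).
#' @param flank half-window size in bp.
#' @return data.frame as in [anchor_profile()].
#' @export
region_midpoint_profile <- function(track, regions, flank = 1000) {
  start0 <- GenomicRanges::start(regions) - 1L
  end0 <- GenomicRanges::end(regions) # half-open end in 0-based coords
  mid <- floor((start0 + end0) / 2) + 1L
  anchors <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(regions),
    IRanges::IRanges(start = mid, width = 1L), strand = "*")
  anchor_profile(track, anchors, flank)
}

#' Scale a vector to the 0-1 range
#'
#' `(v - min) / (max - min)`; the minimum maps to 0 and the maximum to 1.
#' Constant vectors are rejected (the scaling is undefined).
#'
#' @param v numeric vector with at least two distinct finite values.
#' @return rescaled vector (NAs preserved).
#' @export
minmax_scale <- function(v) {
  f <- v[is.finite(v)]
  if (length(unique(f)) < 2) {
    stop("minmax_scale undefined: fewer than two distinct finite values",
         call. = FALSE)
  }
  (v - min(f)) / (max(f) - min(f))
}

#' TSS/TTS anchors from gene ranges
#'
#' The TSS is the 5' end and the TTS the 3' end of each gene in strand
#' orientation.
#'
#' @param genes GRanges with strand (e.g. from [read_gff_genes()]).
#' @param site `"TSS"` or `"TTS"`.
#' @return width-1 GRanges keeping gene strand.
#' @export
gene_anchors <- function(genes, site = c("TSS", "TTS")) {
  site <- match.arg(site)
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  pos <- if (site == "TSS") {
    ifelse(minus, GenomicRanges::end(genes), GenomicRanges::start(genes))
  } else {
    ifelse(minus, GenomicRanges::start(genes), GenomicRanges::end(genes))
  }
  GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                         IRanges::IRanges(start = pos, width = 1L),
                         strand = GenomicRanges::strand(genes))
}
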