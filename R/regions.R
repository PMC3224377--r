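#' Detect low-coverage regions (LRs)
#'
#' Genomic segments of non-zero but anomalously low coverage, the footprint
#' of extensive MNase degradation. The threshold is the `q`-quantile of the
#' chromosome's non-zero values; candidate positions satisfy
#' `0 < value <= threshold`. Maximal runs are merged across gaps shorter than
#' `merge_gap` provided the gap itself contains no zero-coverage position
#' (LRs never contain uncovered bases), and runs of at least `min_len` bp are
#' kept.
#'
#' @param track r.p.m.-normalized `coverage_track`.
#' @param q quantile in (0,1); default 0.05.
#' @param min_len minimum region length (bp); default 50.
#' @param merge_gap gaps strictly shorter than this are bridged; default 20.
#' @param kind label stored on the regions (e.g. `"LR_naked"`, `"LR_nuc"`).
#' @return GRanges with `mean_signal` and `kind` metadata, sorted.
#' @export
detect_lr <- function(track, q = 0.05, min_len = 50, merge_gap = 20,
                      kind = "LR") {
  if (!(q > 0 && q < 1)) stop("q must lie in (0,1)", call. = FALSE)
  grs <- list()
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    nz <- v[v > 0]
    if (length(nz) == 0) {
      warning("chromosome ", chrom, " has no non-zero coverage")
      next
    }
    thr <- quantile(nz, q)
    mask <- v > 0 & v <= thr
    ir <- runs_to_iranges(mask)
    if (length(ir) > 1 && merge_gap > 0) {
      ir <- merge_runs_nonzero_gaps(ir, v, merge_gap)
    }
    ir <- ir[IRanges::width(ir) >= min_len]
    if (length(ir) == 0) next
    ms <- vapply(seq_along(ir), function(i) {
      mean(v[IRanges::start(ir)[i]:IRanges::end(ir)[i]])
    }, numeric(1))
    grs[[length(grs) + 1L]] <- GenomicRanges::GRanges(
      chrom, ir, mean_signal = ms, kind = kind)
  }
  if (length(grs) == 0) {
    return(GenomicRanges::GRanges(mean_signal = numeric(0),
                                  kind = character(0)))
  }
  sort(do.call(c, grs), ignore.strand = TRUE)
}

merge_runs_nonzero_gaps <- function(ir, v, merge_gap) {
  st <- IRanges::start(ir)
  en <- IRanges::end(ir)
  out_s <- st[1]
  out_e <- en[1]
  for (i in seq_along(st)[-1]) {
    gap_len <- st[i] - out_e[length(out_e)] - 1L
    gap_pos <- if (gap_len > 0) {
      (out_e[length(out_e)] + 1L):(st[i] - 1L)
    } else integer(0)
    if (gap_len < merge_gap && all(v[gap_pos] > 0)) {
      out_e[length(out_e)] <- en[i]
    } else {
      out_s <- c(out_s, st[i])
      out_e <- c(out_e, en[i])
    }
  }
  IRanges::IRanges(start = out_s, end = out_e)
}

#' Common low regions (CLRs)
#'
#' Base-pair intersection of the naked-DNA and nucleosomal-DNA LR sets;
#' fragments of at least `min_len` bp are kept.
#'
#' @param lr_naked,lr_nuc GRanges from [detect_lr()].
#' @param min_len minimum fragment length.
#' @return GRanges with `kind = "CLR"`.
#' @export
common_lr <- function(lr_naked, lr_nuc, min_len = 50) {
  ov <- GenomicRanges::intersect(
    GenomicRanges::reduce(lr_naked, ignore.strand = TRUE),
    GenomicRanges::reduce(lr_nuc, ignore.strand = TRUE),
    ignore.strand = TRUE)
  ov <- ov[GenomicRanges::width(ov) >= min_len]
  if (length(ov) > 0) ov$kind <- "CLR"
  sort(ov, ignore.strand = TRUE)
}

#' MNase bias correction of a nucleosomal coverage track
#'
#' Divides out the naked-DNA degradation profile:
#' `corrected(p) = log2((nuc(p) + alpha) / (naked(p) + alpha))`. Where both
#' signals are zero the correction is exactly zero. A plain ratio mode is
#' available behind `log2 = FALSE`.
#'
#' @param nuc_track,naked_track r.p.m.-normalized `coverage_track`s over the
#'   same genome.
#' @param alpha pseudocount in r.p.m.; default 0.5.
#' @param log2 return log2 ratio (default) or plain ratio.
#' @return `coverage_track` of kind `"bias_corrected"` (values may be
#'   negative in log mode; stored without the non-negativity check).
#' @export
correct_bias <- function(nuc_track, naked_track, alpha = 0.5, log2 = TRUE) {
  if (!isTRUE(nuc_track$normalized) || !isTRUE(naked_track$normalized)) {
    stop("both tracks must be r.p.m.-normalized before correction",
         call. = FALSE)
  }
  vals <- track_apply2(nuc_track, naked_track, function(a, b) {
    r <- (a + alpha) / (b + alpha)
    if (log2) log2(r) else r
  })
  structure(list(values = vals, normalized = TRUE,
                 total_reads = nuc_track$total_reads,
                 kind = "bias_corrected"),
            class = "coverage_track")
}

#' Low-pass FFT smoothing of a track
#'
#' Per-chromosome discrete Fourier transform keeping only the lowest
#' `keep_fraction` of frequency components (plus their conjugates), as in
#' FFT-based nucleosome-peak callers. The DC component is always kept, so
#' the track mean is preserved exactly; chromosomes shorter than 3 positions
#' are returned unchanged.
#'
#' @param track a `coverage_track` (or any track-like object).
#' @param keep_fraction fraction of components kept, in (0, 1]; default 0.02.
#' @return smoothed track of the same class.
#' @export
fft_smooth <- function(track, keep_fraction = 0.02) {
  if (!(keep_fraction > 0 && keep_fraction <= 1)) {
    stop("keep_fraction must lie in (0,1]", call. = FALSE)
  }
  vals <- lapply(track$values, function(v) {
    n <- length(v)
    if (n < 3) return(v)
    K <- max(1L, round(keep_fraction * n))
    if (2L * K - 1L >= n) return(v)
    F <- fft(v)
    mask <- rep(FALSE, n)
    mask[seq_len(K)] <- TRUE
    mask[seq.int(n - K + 2L, n)] <- TRUE
    F[!mask] <- 0
    Re(fft(F, inverse = TRUE)) / n
  })
  out <- track
  out$values <- vals
  out$kind <- paste0(track$kind, "_smoothed")
  out
}

#' Call nucleosomes from a smoothed coverage track
#'
#' Dyads are strict local maxima of the smoothed track, cleaned by
#' relative-height non-maximum suppression: maxima are accepted in decreasing
#' height order, and a remaining maximum within `window` bp of an accepted
#' one is discarded when it is lower than `rel_height` times that peak. The
#' rationale: low-pass filtering leaves ringing sidelobes around every sharp
#' occupancy peak whose amplitude is a bounded fraction of the main lobe
#' (about 22% for an ideal cutoff), so far-lower neighbors are filter
#' artifacts, while a co-dominant neighbor is genuine delocalized occupancy
#' and is kept -- the resulting overlapping calls are later classified fuzzy
#' by [classify_calls()]. Heights are measured from the chromosome minimum,
#' so adding a constant to the track leaves the calls unchanged. A call's smoothed value must also exceed the
#' `height_threshold_quantile` of the chromosome's values (computed on the
#' raw track when supplied, since smoothing redistributes mass away from the
#' empty-genome baseline). Each call gets a
#' 147 bp footprint (dyad +/- 74); footprints that would extend past a
#' chromosome edge are dropped. `height_score` is the empirical quantile
#' rank of the peak's smoothed value among all positions of the chromosome.
#'
#' @param smoothed `coverage_track` after [fft_smooth()].
#' @param raw optional unsmoothed track aligned with `smoothed`, used only
#'   for the calling threshold.
#' @param height_threshold_quantile calling threshold quantile; default 0.25.
#' @param window radius (bp) of the suppression neighborhood; default 74
#'   (half a footprint). `window = 1` gives plain three-point local maxima.
#' @param rel_height a maximum within `window` of a taller accepted peak is
#'   kept only if it reaches this fraction of that peak's height; default 0.4
#'   (about twice the ringing-sidelobe fraction of an ideal low-pass filter).
#' @return GRanges of 147 bp footprints with `dyad`, `height_score` and a
#'   placeholder `class` column (see [classify_calls()]).
#' @export
call_nucleosomes <- function(smoothed, raw = NULL,
                             height_threshold_quantile = 0.25,
                             window = 74, rel_height = 0.4) {
  grs <- list()
  for (chrom in names(smoothed$values)) {
    v <- smoothed$values[[chrom]]
    vthr <- if (is.null(raw)) v else raw$values[[chrom]]
    n <- length(v)
    if (n < 3) next
    mid <- 2:(n - 1)
    is_max <- v[mid] > v[mid - 1] & v[mid] > v[mid + 1]
    dyads <- mid[is_max]
    if (window > 1 && length(dyads) > 1) {
      hv <- v - min(v, na.rm = TRUE) # baseline-relative: shift-invariant
      ord <- dyads[order(hv[dyads], dyads, decreasing = c(TRUE, FALSE),
                         method = "radix")]
      accepted <- integer(0)
      for (d in ord) {
        near <- accepted[abs(accepted - d) < as.integer(window)]
        if (length(near) == 0 || hv[d] >= rel_height * max(hv[near])) {
          accepted <- c(accepted, d)
        }
      }
      dyads <- sort(accepted)
    }
    if (length(dyads) == 0) next
    thr <- quantile(vthr, height_threshold_quantile, na.rm = TRUE)
    dyads <- dyads[v[dyads] > thr]
    dyads <- dyads[dyads - 74 >= 1 & dyads + 74 <= n]
    if (length(dyads) == 0) next
    score <- ecdf(v)(v[dyads])
    grs[[length(grs) + 1L]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = dyads - 74L, end = dyads + 74L),
      dyad = dyads, height_score = score, class = NA_character_)
  }
  if (length(grs) == 0) {
    return(GenomicRanges::GRanges(dyad = integer(0),
                                  height_score = numeric(0),
                                  class = character(0)))
  }
  sort(do.call(c, grs), ignore.strand = TRUE)
}

#' Classify nucleosome calls as well-positioned or fuzzy
#'
#' Calls whose footprints overlap a neighboring call's footprint by more
#' than `overlap_max` bp are fuzzy (both members of the pair); isolated calls
#' are well-positioned when their height score reaches `h_min`, fuzzy
#' otherwise.
#'
#' @param calls GRanges from [call_nucleosomes()].
#' @param overlap_max maximum tolerated footprint overlap (bp); default 50.
#' @param h_min minimum height score of a well-positioned call; default 0.4.
#' @return the calls with the `class` column filled in.
#' @export
classify_calls <- function(calls, overlap_max = 50, h_min = 0.4) {
  if (length(calls) == 0) return(calls)
  cls <- rep(NA_character_, length(calls))
  for (chrom in unique(as.character(GenomicRanges::seqnames(calls)))) {
    idx <- which(as.character(GenomicRanges::seqnames(calls)) == chrom)
    idx <- idx[order(calls$dyad[idx])]
    d <- calls$dyad[idx]
    fuzzy <- rep(FALSE, length(idx))
    if (length(idx) > 1) {
      ov <- 147 - diff(d) # footprint overlap between consecutive calls
      hit <- which(ov > overlap_max)
      fuzzy[hit] <- TRUE
      fuzzy[hit + 1L] <- TRUE
    }
    cl <- ifelse(fuzzy, "fuzzy",
                 ifelse(calls$height_score[idx] >= h_min,
                        "well-positioned", "fuzzy"))
    cls[idx] <- cl
  }
  calls$class <- cls
  calls
}
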