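#' Per-base-pair signal track
#'
#' Lightweight container for one numeric vector per chromosome, used for
#' coverage, bias-corrected log-ratios, k_total and energy profiles.
#'
#' @param values named list of numeric vectors (one per chromosome).
#' @param normalized logical; TRUE once reads-per-million scaled.
#' @param total_reads mapped read count behind the track (for r.p.m.).
#' @param kind free-text label echoed into output headers.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(values, normalized = FALSE, total_reads = NA_real_,
                           kind = "coverage") {
  stopifnot(is.list(values), !is.null(names(values)))
  if (any(vapply(values, function(v) any(v < 0, na.rm = TRUE), logical(1)))) {
    stop("coverage values must be non-negative", call. = FALSE)
  }
  structure(list(values = values, normalized = normalized,
                 total_reads = total_reads, kind = kind),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track (", x$kind, "): ", length(x$values), " chromosome(s), ",
      sum(lengths(x$values)), " bp, ",
      if (isTRUE(x$normalized)) "r.p.m.-normalized" else "raw",
      ", total_reads = ", x$total_reads, "\n", sep = "")
  invisible(x)
}

#' Extract the per-position values of one chromosome
#' @param track a `coverage_track`.
#' @param chrom chromosome name; default first.
#' @export
track_values <- function(track, chrom = NULL) {
  if (is.null(chrom)) chrom <- names(track$values)[1]
  track$values[[chrom]]
}

#' Reads-per-million normalization
#'
#' Scales every value by `1e6 / total_reads`. Normalizing an
#' already-normalized track is an error (guarding against silent double
#' scaling).
#'
#' @param track raw `coverage_track` with `total_reads > 0`.
#' @return normalized `coverage_track`.
#' @export
rpm_normalize <- function(track) {
  if (isTRUE(track$normalized)) {
    stop("track is already r.p.m.-normalized", call. = FALSE)
  }
  if (is.na(track$total_reads) || track$total_reads <= 0) {
    stop("total_reads must be positive for r.p.m. normalization",
         call. = FALSE)
  }
  f <- 1e6 / track$total_reads
  coverage_track(lapply(track$values, function(v) v * f),
                 normalized = TRUE, total_reads = track$total_reads,
                 kind = track$kind)
}

track_apply2 <- function(a, b, f) {
  if (!identical(names(a$values), names(b$values)) ||
      !identical(lengths(a$values), lengths(b$values))) {
    stop("tracks cover different genomes", call. = FALSE)
  }
  mapply(f, a$values, b$values, SIMPLIFY = FALSE)
}
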