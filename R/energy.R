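# Precompute strand-adjusted elastic parameters for every raw context (all
# 16 dinucleotides or 256 tetramers), so genome-scale profiles reduce to
# integer indexing.
context_params <- function(table) {
  k <- if (table$level == "dinucleotide") 2L else 4L
  ctxs <- all_kmers(k)
  n <- length(ctxs)
  mu <- matrix(NA_real_, n, 6, dimnames = list(ctxs, PARAM_NAMES))
  theta <- array(NA_real_, c(6, 6, n))
  ktot <- numeric(n)
  for (i in seq_len(n)) {
    e <- lookup_step(table, ctxs[i])
    mu[i, ] <- e$equilibrium
    theta[, , i] <- e$theta
    ktot[i] <- e$k_total
  }
  list(k = k, contexts = ctxs, mu = mu, theta = theta, ktot = ktot)
}

context_codes_for_seq <- function(seq, k) {
  chars <- seq_to_chars(seq)
  codes <- base_codes(chars)
  kmer_codes(codes, k)
}

#' Per-step k_total profile of a sequence
#'
#' One value per base step; at the tetramer level the first and last steps,
#' where the 4-mer context does not fit, are `NA`. Steps whose context
#' contains a non-ACGT character are `NA` as well. k_total is invariant
#' under reverse complementation of the context, so no strand adjustment is
#' needed here.
#'
#' @param seq DNA string or [Biostrings::DNAString].
#' @param table a `stiffness_table`.
#' @param smooth_window odd moving-average width in steps; 1 = no smoothing.
#' @return numeric vector of length `nchar(seq) - 1`.
#' @export
ktotal_profile <- function(seq, table, smooth_window = 1) {
  chars <- seq_to_chars(seq)
  if (any(!chars %in% c(BASES, "N"))) {
    stop_invalid_sequence(paste(unique(setdiff(chars, c(BASES, "N"))),
                                collapse = ","))
  }
  cp <- context_params(table)
  n_steps <- length(chars) - 1L
  if (n_steps < 1) stop("sequence shorter than one step", call. = FALSE)
  out <- rep(NA_real_, n_steps)
  ctx <- context_codes_for_seq(paste(chars, collapse = ""), cp$k)
  # context i describes the step between bases i+(k/2-1) and i+k/2
  offset <- cp$k / 2L - 1L
  step_idx <- seq_along(ctx) + offset
  vals <- cp$ktot[ctx]
  vals[is.na(ctx)] <- NA_real_
  out[step_idx] <- vals
  moving_average(out, smooth_window)
}

# quadratic-form energy contribution of one step given raw-context params
step_energy <- function(x, mu, theta) {
  d <- x - mu
  0.5 * sum(d * (theta %*% d))
}

#' Harmonic deformation energy of one 147 bp window
#'
#' Cost of deforming the sequence's equilibrium conformation into the
#' nucleosome-wrapped target shape, summed over the 146 base steps:
#' `E = sum_s 0.5 * (x_s - mu_s)' Theta_s (x_s - mu_s)`, with `mu_s` and
#' `Theta_s` the strand-adjusted table entries for the step's context.
#'
#' @param window DNA string of length exactly 147.
#' @param table a `stiffness_table`.
#' @param shape 146 x 6 target conformation (see [nucleosome_shape()]).
#' @return energy in kcal/mol, `NA` when the window contains N.
#' @export
deformation_energy <- function(window, table, shape = nucleosome_shape()) {
  chars <- seq_to_chars(window)
  if (length(chars) != 147) {
    stop("window must be exactly 147 bp", call. = FALSE)
  }
  if (!is.matrix(shape) || nrow(shape) != 146 || ncol(shape) != 6) {
    stop("shape must be a 146 x 6 matrix", call. = FALSE)
  }
  k <- if (table$level == "dinucleotide") 2L else 4L
  e <- 0
  for (s in seq_len(146)) {
    lo <- s - (k / 2L - 1L)
    hi <- lo + k - 1L
    if (lo < 1 || hi > 147) return(NA_real_) # tetramer context off the edge
    ctx <- paste(chars[lo:hi], collapse = "")
    if (grepl("[^ACGT]", ctx)) return(NA_real_)
    entry <- lookup_step(table, ctx)
    e <- e + step_energy(shape[s, ], entry$equilibrium, entry$theta)
  }
  e
}

# per-window-position x per-context energy contribution matrix (146 x n_ctx)
energy_q_matrix <- function(cp, shape) {
  n_ctx <- length(cp$contexts)
  Q <- matrix(NA_real_, 146, n_ctx)
  for (c in seq_len(n_ctx)) {
    d <- sweep(shape, 2, cp$mu[c, ])
    Q[, c] <- 0.5 * rowSums((d %*% cp$theta[, , c]) * d)
  }
  Q
}

#' Genome-wide nucleosome deformation energy profile
#'
#' Slides a 147 bp window over each chromosome and assigns the window's
#' deformation energy to its dyad (window start + 73). Positions within 73 bp
#' of either end, and windows containing N (or, at the tetramer level,
#' windows whose outermost step context falls off the chromosome), are `NA`.
#'
#' @param genome named character vector / list of DNA strings, or a
#'   [Biostrings::DNAStringSet].
#' @param table a `stiffness_table`.
#' @param shape 146 x 6 target conformation.
#' @param stride compute every `stride`-th window (others `NA`); default 1.
#' @return named list of numeric per-position tracks (energy at dyads).
#' @export
energy_profile <- function(genome, table, shape = nucleosome_shape(),
                           stride = 1L) {
  genome <- as_genome_strings(genome)
  cp <- context_params(table)
  Q <- energy_q_matrix(cp, shape)
  out <- lapply(names(genome), function(chrom) {
    seqstr <- genome[[chrom]]
    L <- nchar(seqstr)
    track <- rep(NA_real_, L)
    if (L < 147) {
      warning("chromosome ", chrom, " shorter than 147 bp; skipped")
      return(track)
    }
    ctx <- context_codes_for_seq(seqstr, cp$k)
    offset <- cp$k / 2L - 1L
    # step s of window starting at p uses context at position p + s - 1
    n_win <- L - 146L
    e <- numeric(n_win)
    nas <- logical(n_win)
    for (s in seq_len(146)) {
      # step s of the window starting at p has context index p + s - 1 - offset
      idx <- seq.int(s - offset, s - offset + n_win - 1L)
      bad <- idx < 1 | idx > length(ctx)
      ci <- rep(NA_integer_, n_win)
      ci[!bad] <- ctx[idx[!bad]]
      q <- Q[s, ci]
      nas <- nas | is.na(ci)
      q[is.na(q)] <- 0
      e <- e + q
    }
    e[nas] <- NA_real_
    if (stride > 1L) {
      keep <- seq.int(1L, n_win, by = stride)
      masked <- rep(NA_real_, n_win)
      masked[keep] <- e[keep]
      e <- masked
    }
    track[seq_len(n_win) + 73L] <- e
    track
  })
  names(out) <- names(genome)
  out
}

#' Predict nucleosome-depleted and enriched regions from an energy track
#'
#' High-energy stretches disfavor nucleosome formation; runs of dyad
#' positions above the `depleted_quantile` of the chromosome-wide energy
#' distribution are reported as predicted depleted regions, runs below the
#' `enriched_quantile` as predicted enriched regions.
#'
#' @param energy_track named list of per-position energy vectors
#'   (from [energy_profile()]).
#' @param depleted_quantile,enriched_quantile quantiles in (0,1) with
#'   `enriched_quantile < depleted_quantile`.
#' @param min_len minimum run length in bp.
#' @return [GenomicRanges::GRanges] with metadata columns `kind`
#'   (`predicted_depleted` / `predicted_enriched`) and `mean_signal`.
#' @export
predict_regions <- function(energy_track, depleted_quantile = 0.9,
                            enriched_quantile = 0.25, min_len = 50) {
  if (!(depleted_quantile > 0 && depleted_quantile < 1 &&
        enriched_quantile > 0 && enriched_quantile < 1)) {
    stop("quantiles must lie in (0,1)", call. = FALSE)
  }
  if (enriched_quantile >= depleted_quantile) {
    stop("enriched_quantile must be below depleted_quantile", call. = FALSE)
  }
  grs <- list()
  for (chrom in names(energy_track)) {
    v <- energy_track[[chrom]]
    ok <- !is.na(v)
    if (!any(ok)) next
    hi <- quantile(v[ok], depleted_quantile)
    lo <- quantile(v[ok], enriched_quantile)
    for (spec in list(list(mask = ok & v > hi, kind = "predicted_depleted"),
                      list(mask = ok & v < lo, kind = "predicted_enriched"))) {
      ir <- runs_to_iranges(spec$mask)
      ir <- ir[IRanges::width(ir) >= min_len]
      if (length(ir) == 0) next
      ms <- vapply(seq_along(ir), function(i) {
        mean(v[IRanges::start(ir)[i]:IRanges::end(ir)[i]])
      }, numeric(1))
      grs[[length(grs) + 1L]] <- GenomicRanges::GRanges(
        chrom, ir, kind = spec$kind, mean_signal = ms)
    }
  }
  if (length(grs) == 0) {
    return(GenomicRanges::GRanges(kind = character(0),
                                  mean_signal = numeric(0)))
  }
  sort(do.call(c, grs), ignore.strand = TRUE)
}

runs_to_iranges <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  IRanges::IRanges(start = starts[r$values], end = ends[r$values])
}

# normalize genome representations to a named list of character strings
as_genome_strings <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.list(as.character(genome))
  } else if (inherits(genome, "DNAString")) {
    out <- list(chr = as.character(genome))
  } else if (is.character(genome)) {
    out <- as.list(genome)
  } else if (is.list(genome)) {
    out <- lapply(genome, as.character)
  } else {
    stop("unsupported genome representation", call. = FALSE)
  }
  if (is.null(names(out)) || any(names(out) == "")) {
    names(out) <- paste0("chr", seq_along(out))
  }
  lapply(out, toupper)
}
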