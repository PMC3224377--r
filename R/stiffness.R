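#' Canonical form of a base-step context
#'
#' DNA strand symmetry means a dinucleotide or tetramer step and its reverse
#' complement describe the same physical base-pair step read from the other
#' strand, so elastic tables store only the lexicographically smaller member
#' of each pair (10 dinucleotide, 136 tetramer contexts). When the reverse
#' complement is the stored form, equilibrium shift and tilt change sign and
#' the stiffness matrix rows/columns for those coordinates are sign-adjusted.
#'
#' @param context DNA string of length 2 (dinucleotide) or 4 (tetramer).
#' @return list with `canonical` (string) and `reversed` (logical, TRUE when
#'   the reverse complement was chosen).
#' @examples
#' canonical_context("TT")   # AA, reversed
#' canonical_context("GC")   # palindrome, not reversed
#' @export
canonical_context <- function(context) {
  if (!nchar(context) %in% c(2L, 4L)) {
    stop("context must have length 2 or 4", call. = FALSE)
  }
  check_acgt(context)
  rc <- revcomp(context)
  if (rc < context) {
    list(canonical = rc, reversed = TRUE)
  } else {
    list(canonical = context, reversed = FALSE)
  }
}

#' Stiffness matrix from a helical-parameter covariance matrix
#'
#' Inverts the 6x6 covariance of the helical parameters (shift, slide, rise,
#' tilt, roll, twist) observed in a conformational ensemble and scales by kT,
#' giving the harmonic force-constant matrix of the step.
#'
#' @param C symmetric positive-definite 6x6 covariance matrix
#'   (Angstrom^2 / deg^2 units).
#' @param kT thermal energy in kcal/mol; default 0.593 (298 K).
#' @return symmetric 6x6 stiffness matrix, kcal/mol per (Angstrom or deg)^2.
#' @export
stiffness_from_covariance <- function(C, kT = 0.593) {
  if (!is.matrix(C) || any(dim(C) != 6)) {
    stop("C must be a 6x6 matrix", call. = FALSE)
  }
  if (max(abs(C - t(C))) > 1e-9 * max(1, max(abs(C)))) {
    stop("ill-conditioned input: covariance matrix is not symmetric",
         call. = FALSE)
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    stop("ill-conditioned input: covariance matrix is singular or not ",
         "positive definite", call. = FALSE)
  }
  theta <- kT * solve(C)
  # enforce exact symmetry against round-off
  (theta + t(theta)) / 2
}

#' Product of the six pure stiffness constants
#'
#' The diagonal of a step's stiffness matrix holds the pure constants
#' k_shift, k_slide, k_rise, k_tilt, k_roll, k_twist; their product is a
#' rough scalar summary of the step's overall rigidity (larger = stiffer).
#'
#' @param step a `step_stiffness` entry or a 6x6 stiffness matrix.
#' @return positive scalar.
#' @export
k_total <- function(step) {
  theta <- if (is.matrix(step)) step else step$theta
  prod(diag(theta))
}

new_step_stiffness <- function(context, equilibrium, theta) {
  stopifnot(length(equilibrium) == 6, all(dim(theta) == c(6, 6)))
  if (max(abs(theta - t(theta))) > 1e-9) {
    stop("stiffness matrix for ", context, " is not symmetric", call. = FALSE)
  }
  if (any(diag(theta) <= 0)) {
    stop("stiffness diagonal for ", context, " must be positive",
         call. = FALSE)
  }
  names(equilibrium) <- PARAM_NAMES
  dimnames(theta) <- list(PARAM_NAMES, PARAM_NAMES)
  structure(
    list(context = context, equilibrium = equilibrium, theta = theta,
         k_diag = diag(theta), k_total = prod(diag(theta))),
    class = "step_stiffness"
  )
}

# flip an entry to the opposite strand: S mu, S theta S with S = diag(STRAND_FLIP)
flip_entry <- function(entry) {
  mu <- entry$equilibrium * STRAND_FLIP
  theta <- entry$theta * outer(STRAND_FLIP, STRAND_FLIP)
  out <- new_step_stiffness(revcomp(entry$context), mu, theta)
  out
}

n_canonical <- function(level) if (level == "dinucleotide") 10L else 136L

canonical_contexts <- function(level) {
  k <- if (level == "dinucleotide") 2L else 4L
  km <- all_kmers(k)
  sort(unique(pmin(km, revcomp(km))))
}

#' Construct a stiffness table
#'
#' @param entries named list of `step_stiffness` objects keyed by canonical
#'   context (10 dinucleotide or 136 tetramer contexts).
#' @param level `"dinucleotide"` or `"tetramer"`.
#' @param kT thermal energy used when matrices were derived (kcal/mol).
#' @return object of class `stiffness_table`.
#' @export
stiffness_table <- function(entries, level = c("dinucleotide", "tetramer"),
                            kT = 0.593) {
  level <- match.arg(level)
  want <- canonical_contexts(level)
  missing <- setdiff(want, names(entries))
  if (length(missing) > 0) {
    stop("incomplete stiffness table: missing ", length(missing),
         " canonical contexts (e.g. ", missing[1], ")", call. = FALSE)
  }
  structure(list(level = level, entries = entries[want], temperature_kT = kT),
            class = "stiffness_table")
}

#' @export
print.stiffness_table <- function(x, ...) {
  cat("stiffness_table:", x$level, "level,", length(x$entries),
      "canonical contexts, kT =", x$temperature_kT, "kcal/mol\n")
  invisible(x)
}

#' Look up a step's elastic parameters for any context
#'
#' Non-canonical contexts are resolved through reverse-complement symmetry
#' with the appropriate sign adjustments applied.
#'
#' @param table a `stiffness_table`.
#' @param context DNA string of the table's context length.
#' @return `step_stiffness` for the context as written (strand-adjusted).
#' @export
lookup_step <- function(table, context) {
  cc <- canonical_context(context)
  entry <- table$entries[[cc$canonical]]
  if (is.null(entry)) stop("context not in table: ", context, call. = FALSE)
  if (cc$reversed) flip_entry(entry) else entry
}

upper_tri_names <- function() {
  out <- character(0)
  for (i in 1:6) for (j in i:6) {
    out <- c(out, paste0("theta_", PARAM_NAMES[i], "_", PARAM_NAMES[j]))
  }
  out
}

#' Read a stiffness table from TSV
#'
#' Expected columns: `context`, the six equilibrium values `shift0 slide0
#' rise0 tilt0 roll0 twist0`, then the 21 upper-triangle stiffness entries in
#' row-major order (`theta_shift_shift`, `theta_shift_slide`, ...,
#' `theta_twist_twist`). Header line required. One row per canonical context.
#'
#' @param path TSV file path.
#' @param kT thermal energy label for the table (kcal/mol).
#' @return a `stiffness_table`.
#' @export
read_stiffness_table <- function(path, kT = 0.593) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  eq_cols <- paste0(PARAM_NAMES, "0")
  tri_cols <- upper_tri_names()
  need <- c("context", eq_cols, tri_cols)
  if (!all(need %in% names(df))) {
    stop("stiffness TSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  lens <- unique(nchar(df$context))
  if (length(lens) != 1 || !lens %in% c(2L, 4L)) {
    stop("contexts must all have length 2 or all length 4", call. = FALSE)
  }
  level <- if (lens == 2L) "dinucleotide" else "tetramer"
  entries <- list()
  for (r in seq_len(nrow(df))) {
    theta <- matrix(0, 6, 6)
    theta[upper.tri(theta, diag = TRUE)] <-
      unlist(df[r, tri_cols])[order_upper_by_row()]
    theta <- theta + t(theta) - diag(diag(theta))
    entries[[df$context[r]]] <- new_step_stiffness(
      df$context[r], unlist(df[r, eq_cols]), theta)
  }
  stiffness_table(entries, level, kT)
}

# upper.tri(.., diag=TRUE) fills column-major; for each column-major slot,
# index of the corresponding entry in the row-major TSV order
order_upper_by_row <- function() {
  rowmajor <- cbind(
    i = unlist(lapply(1:6, function(i) rep(i, 7 - i))),
    j = unlist(lapply(1:6, function(i) i:6))
  )
  order(rowmajor[, "j"], rowmajor[, "i"])
}

#' Write a stiffness table to TSV (inverse of [read_stiffness_table()])
#' @param table a `stiffness_table`.
#' @param path output path.
#' @export
write_stiffness_table <- function(table, path) {
  rows <- lapply(table$entries, function(e) {
    tri <- e$theta[upper.tri(e$theta, diag = TRUE)]
    # reorder column-major triangle into row-major output
    rowmajor <- cbind(
      i = unlist(lapply(1:6, function(i) rep(i, 7 - i))),
      j = unlist(lapply(1:6, function(i) i:6))
    )
    tri_rm <- e$theta[rowmajor]
    c(list(context = e$context),
      as.list(setNames(e$equilibrium, paste0(PARAM_NAMES, "0"))),
      as.list(setNames(tri_rm, upper_tri_names())))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled dinucleotide stiffness table
#'
#' A synthetic stand-in table at the dinucleotide level with equilibrium
#' geometry and stiffness magnitudes representative of published MD-derived
#' parameterizations (A-tract steps stiff, pyrimidine-purine steps such as
#' TA/CA/CG flexible). Shipped so the physics layer runs out of the box;
#' analyses of real data should substitute a user-supplied table via
#' [read_stiffness_table()].
#'
#' @return a `stiffness_table` (dinucleotide level).
#' @export
default_stiffness_table <- function() {
  path <- system.file("extdata", "stiffness_dinucleotide_synthetic.tsv",
                      package = "nucleoflex", mustWork = TRUE)
  read_stiffness_table(path)
}

#' Idealized nucleosome-wrapped DNA shape
#'
#' The target conformation of the 146 base steps in a 147 bp nucleosomal
#' window: sinusoidal roll and tilt with the helical periodicity of wrapped
#' DNA, constant twist and rise, zero shift and slide. This is a packaged
#' synthetic idealization of the smoothed crystallographic path; a
#' structure-derived 146x6 table can be supplied instead via
#' [read_shape_table()].
#'
#' @param amplitude_roll roll oscillation amplitude, degrees.
#' @param amplitude_tilt tilt oscillation amplitude, degrees.
#' @param twist constant twist, degrees per step.
#' @param rise constant rise, Angstrom per step.
#' @param period helical period in bp.
#' @return 146 x 6 numeric matrix with columns shift, slide, rise, tilt,
#'   roll, twist.
#' @export
nucleosome_shape <- function(amplitude_roll = 7, amplitude_tilt = 2,
                             twist = 34.5, rise = 3.35, period = 10.25) {
  j <- seq_len(146)
  phase <- 2 * pi * (j - 73.5) / period
  shape <- cbind(
    shift = rep(0, 146),
    slide = rep(0, 146),
    rise = rep(rise, 146),
    tilt = amplitude_tilt * sin(phase),
    roll = amplitude_roll * cos(phase),
    twist = rep(twist, 146)
  )
  shape
}

#' Read a nucleosome shape table (146 rows x 6 helical parameters)
#' @param path TSV with header shift slide rise tilt roll twist.
#' @return 146 x 6 matrix.
#' @export
read_shape_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (!all(PARAM_NAMES %in% names(df))) {
    stop("shape TSV needs columns ", paste(PARAM_NAMES, collapse = " "),
         call. = FALSE)
  }
  m <- as.matrix(df[, PARAM_NAMES])
  if (nrow(m) != 146) stop("shape table must have exactly 146 rows",
                           call. = FALSE)
  m
}
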