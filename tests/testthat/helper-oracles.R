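# Independent reference implementations used to cross-check the package.

# Gauss-Jordan inversion with partial pivoting (no solve()).
gj_invert <- function(M) {
  n <- nrow(M)
  A <- cbind(M, diag(n))
  for (col in seq_len(n)) {
    piv <- which.max(abs(A[col:n, col])) + col - 1L
    if (abs(A[piv, col]) < 1e-14) stop("singular matrix in gj_invert")
    if (piv != col) A[c(col, piv), ] <- A[c(piv, col), ]
    A[col, ] <- A[col, ] / A[col, col]
    for (r in seq_len(n)[-col]) {
      A[r, ] <- A[r, ] - A[r, col] * A[col, ]
    }
  }
  A[, (n + 1):(2 * n), drop = FALSE]
}

# seeded random symmetric positive-definite 6x6 matrix
random_spd6 <- function(seed) {
  set.seed(seed)
  A <- matrix(rnorm(36), 6, 6)
  A %*% t(A) + diag(runif(6, 0.5, 2))
}

# Brute-force deformation energy: assemble the full 876-dimensional
# displacement vector and the 876x876 block-diagonal stiffness matrix
# (146 blocks of 6x6) and evaluate E = 0.5 d' Theta d in one product.
oracle_window_energy <- function(window, table, shape = nucleosome_shape()) {
  chars <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  k <- if (table$level == "dinucleotide") 2L else 4L
  Theta <- matrix(0, 876, 876)
  mu <- numeric(876)
  for (s in 1:146) {
    lo <- s - (k / 2L - 1L)
    ctx <- paste(chars[lo:(lo + k - 1L)], collapse = "")
    entry <- lookup_step(table, ctx)
    idx <- (6 * (s - 1) + 1):(6 * s)
    Theta[idx, idx] <- entry$theta
    mu[idx] <- entry$equilibrium
  }
  x <- as.vector(t(shape))
  d <- x - mu
  0.5 * as.numeric(t(d) %*% Theta %*% d)
}

# exact two-sided binomial p-value by density tail summation
oracle_binom_two_sided <- function(k, n, p) {
  dk <- dbinom(k, n, p)
  di <- dbinom(0:n, n, p)
  sum(di[di <= dk * (1 + 1e-7)])
}

# random ACGT string
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# position-by-position threshold scan for low-coverage regions
oracle_lr_scan <- function(v, q = 0.05, min_len = 50, merge_gap = 20) {
  thr <- quantile(v[v > 0], q)
  low <- which(v > 0 & v <= thr)
  if (length(low) == 0) return(cbind(start = integer(0), end = integer(0)))
  # maximal runs of consecutive low positions
  br <- c(0, which(diff(low) > 1), length(low))
  st <- low[br[-length(br)] + 1]
  en <- low[br[-1]]
  # merge across short, fully covered gaps
  i <- 1
  while (i < length(st)) {
    gap <- st[i + 1] - en[i] - 1
    gap_pos <- if (gap > 0) (en[i] + 1):(st[i + 1] - 1) else integer(0)
    if (gap < merge_gap && all(v[gap_pos] > 0)) {
      en[i] <- en[i + 1]
      st <- st[-(i + 1)]
      en <- en[-(i + 1)]
    } else {
      i <- i + 1
    }
  }
  keep <- (en - st + 1) >= min_len
  cbind(start = st[keep], end = en[keep])
}

# seeded random coverage-like vector with zero stretches and a low-mean dip
random_lr_track <- function(n = 5000, seed = 1) {
  set.seed(seed)
  v <- rlnorm(n, meanlog = 2, sdlog = 0.6)
  nz <- sample(n, n %/% 20)
  v[nz] <- 0
  dip <- sample(n - 400, 3)
  for (d in dip) {
    span <- d:(d + sample(60:300, 1))
    v[span] <- runif(length(span), 1e-3, quantile(v[v > 0], 0.04))
  }
  v
}
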