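# Periodized orthogonal discrete wavelet transform.
#
# The interval-dependent thresholding needs an orthonormal multilevel DWT
# whose coefficients can be kept, shrunk, or zeroed individually and then
# inverted exactly. The transform below uses circular (periodized)
# convolution, under which the multilevel analysis operator is orthogonal for
# any orthonormal filter pair and any even length, giving machine-precision
# reconstruction. Signals whose length is not a multiple of 2^levels are
# extended by reflecting their tail and truncated after reconstruction.

# Coiflet-5 decomposition low-pass filter (30 taps, orthonormal;
# published constants).
COIF5_DEC_LO <- c(
  -9.6040101127678941e-08, -1.6237995172048338e-07,
   2.0612203985788783e-06,  3.7007277113394796e-06,
  -2.1270221672515614e-05, -4.1219861924265501e-05,
   1.4035632812373243e-04,  3.0185794166824478e-04,
  -6.3755892612588115e-04, -1.6616273039298788e-03,
   2.4315754425382886e-03,  6.7615202206204169e-03,
  -9.1595073386761625e-03, -1.9758391600965465e-02,
   3.2674799467057355e-02,  4.1287530472117834e-02,
  -1.0556315130733723e-01, -6.2037751574981960e-02,
   4.3798230665916338e-01,  7.7429362286032744e-01,
   4.2157126673075435e-01, -5.2046670253554764e-02,
  -9.1921588060086087e-02,  2.8169744270532353e-02,
   2.3408322118927783e-02, -1.0131584846900276e-02,
  -4.1593126275786402e-03,  2.1782943778456947e-03,
   3.5857774116175768e-04, -2.1208186206749400e-04)

wt_filters <- function(wavelet = "coif5") {
  if (!identical(wavelet, "coif5"))
    stop("only the 'coif5' wavelet is implemented")
  h <- COIF5_DEC_LO
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)   # quadrature mirror high-pass
  list(h = h, g = g, L = L)
}

# One analysis step on a matrix X (signals in rows, even column count N):
# returns list(a, d), each nsig x N/2, via circular convolution
# a[k] = sum_n h[n] x[(2(k-1) + n - 1) mod N + 1].
pdwt_step <- function(X, h, g) {
  N <- ncol(X); N2 <- N %/% 2L; L <- length(h)
  A <- matrix(0, nrow(X), N2); D <- A
  base <- 2L * (seq_len(N2) - 1L)
  for (n in seq_len(L)) {
    cols <- (base + (n - 1L)) %% N + 1L
    Xc <- X[, cols, drop = FALSE]
    A <- A + h[n] * Xc
    D <- D + g[n] * Xc
  }
  list(a = A, d = D)
}

# Inverse of pdwt_step (transpose of the orthogonal step).
pidwt_step <- function(A, D, h, g) {
  N2 <- ncol(A); N <- 2L * N2; L <- length(h)
  X <- matrix(0, nrow(A), N)
  base <- 2L * (seq_len(N2) - 1L)
  for (n in seq_len(L)) {
    cols <- (base + (n - 1L)) %% N + 1L
    X[, cols] <- X[, cols] + h[n] * A + g[n] * D
  }
  X
}

pad_len <- function(n, levels) {
  block <- 2L^levels
  as.integer(ceiling(n / block) * block)
}

# Multilevel periodized DWT of the rows of X. Rows shorter than a multiple of
# 2^levels are reflected-extended at the tail. Returns the approximation at
# the deepest level plus detail matrices d[[1]] (finest) .. d[[levels]].
pdwt <- function(X, levels = 5L, wavelet = "coif5") {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  flt <- wt_filters(wavelet)
  n0 <- ncol(X)
  np <- pad_len(n0, levels)
  if (np > n0) {
    ext <- X[, seq.int(n0, n0 - (np - n0) + 1L), drop = FALSE]  # reflect tail
    X <- cbind(X, ext)
  }
  d <- vector("list", levels)
  A <- X
  for (j in seq_len(levels)) {
    st <- pdwt_step(A, flt$h, flt$g)
    d[[j]] <- st$d
    A <- st$a
  }
  structure(list(a = A, d = d, levels = levels, wavelet = wavelet,
                 n_orig = n0, n_padded = np), class = "pdwt")
}

# Inverse multilevel transform; truncates back to the original length.
pidwt <- function(w) {
  stopifnot(inherits(w, "pdwt"))
  flt <- wt_filters(w$wavelet)
  A <- w$a
  for (j in rev(seq_len(w$levels)))
    A <- pidwt_step(A, w$d[[j]], flt$h, flt$g)
  A[, seq_len(w$n_orig), drop = FALSE]
}

# Circular time-localization of the level-j detail coefficients for signals
# of (padded) length np: for each coefficient index, the circular centroid of
# its analysis-row energy and the circular SD, both in samples (0-based
# time). Computed empirically by transforming the identity, so filter delay
# and wrap-around are accounted for automatically. Cached per geometry.
.wt_cache <- new.env(parent = emptyenv())

coef_time_map <- function(n_orig, levels = 5L, wavelet = "coif5") {
  key <- sprintf("%s_%d_%d", wavelet, n_orig, levels)
  if (!is.null(.wt_cache[[key]])) return(.wt_cache[[key]])
  np <- pad_len(n_orig, levels)
  W <- pdwt(diag(np), levels, wavelet)   # row t of each matrix = response to impulse at t
  ang <- 2 * pi * (seq_len(np) - 1L) / np
  z <- complex(modulus = 1, argument = ang)
  map <- vector("list", levels)
  for (j in seq_len(levels)) {
    E <- (W$d[[j]])^2                    # np x ncoef; column k = energy profile over time
    tot <- colSums(E)
    tot[tot == 0] <- 1
    m1 <- as.vector(crossprod(E, Re(z))) / tot
    m2 <- as.vector(crossprod(E, Im(z))) / tot
    R <- sqrt(m1^2 + m2^2)
    centroid <- (Arg(complex(real = m1, imaginary = m2)) / (2 * pi) * np) %% np
    circ_sd <- sqrt(pmax(-2 * log(pmax(R, 1e-12)), 0)) / (2 * pi) * np
    map[[j]] <- list(centroid = centroid, sd = circ_sd)
  }
  res <- list(map = map, n_padded = np)
  .wt_cache[[key]] <- res
  res
}

circ_dist <- function(a, b, n) {
  d <- abs(a - b) %% n
  pmin(d, n - d)
}

# Logical preserve masks per level: coefficient kept iff its time centroid
# lies within `margin_sd` circular SDs of some preserve interval (samples,
# 0-based [start, end)).
preserve_masks_from_intervals <- function(intervals_smp, n_orig, levels = 5L,
                                          wavelet = "coif5", margin_sd = 1) {
  tm <- coef_time_map(n_orig, levels, wavelet)
  lapply(seq_len(levels), function(j) {
    cen <- tm$map[[j]]$centroid
    mar <- margin_sd * stats::median(tm$map[[j]]$sd)
    keep <- rep(FALSE, length(cen))
    for (iv in intervals_smp) {
      lo <- iv[1] - mar; hi <- iv[2] + mar
      inside <- (cen >= lo & cen < hi)
      # wrap-aware: also catch centroids within the dilated interval mod np
      if (lo < 0) inside <- inside | cen >= (lo %% tm$n_padded)
      if (hi > tm$n_padded) inside <- inside | cen < (hi %% tm$n_padded)
      keep <- keep | inside
    }
    keep
  })
}
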