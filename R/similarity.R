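#' Multi-scale similarity configuration
#'
#' Collects the knobs of the wavelet similarity: the number of decomposition
#' levels `L` (default 4), the wavelet family (`"haar"`, the natural choice
#' for +/-1 step signals, or `"d4"` for Daubechies-4 with periodic
#' boundaries), the level weights `w_0..w_L` (approximation first, then the
#' detail levels; auto-normalised to sum to 1; default uniform `1/(L+1)`),
#' and which signal of the curve is compared: the cumulative ordinates
#' `y_1..y_3N` (default) or the raw +/-1 step signal.
#'
#' @param levels Number of decomposition levels `L >= 1`.
#' @param wavelet `"haar"` or `"d4"`.
#' @param weights Numeric vector of `levels + 1` nonnegative weights; any
#'   positive scaling is accepted and normalised.
#' @param signal `"cumulative"` or `"steps"`.
#' @return An object of class `tvc_config`.
#' @examples
#' tvc_config()                        # L = 4, haar, uniform weights
#' tvc_config(levels = 2, weights = c(2, 1, 1))
#' @export
tvc_config <- function(levels = 4L, wavelet = c("haar", "d4"),
                       weights = NULL, signal = c("cumulative", "steps")) {
  wavelet <- match.arg(wavelet)
  signal <- match.arg(signal)
  levels <- as.integer(levels)
  stopifnot(levels >= 1L)
  if (is.null(weights)) weights <- rep(1, levels + 1L)
  stopifnot(length(weights) == levels + 1L, all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  structure(list(levels = levels, wavelet = wavelet, weights = weights,
                 signal = signal),
            class = "tvc_config")
}

#' Resample a signal to a target length by linear interpolation
#'
#' The signal is viewed on a uniform grid over \[0, 1\] and evaluated at
#' `target_len` uniform points; endpoints are preserved exactly. Used to put
#' curves of unequal length onto a common dyadic grid before decomposition.
#'
#' @param signal Numeric vector, length >= 2.
#' @param target_len Integer >= 2.
#' @return Numeric vector of length `target_len`.
#' @examples
#' resample_signal(c(0, 1, 2, 3), 7)  # 0.0 0.5 1.0 ... 3.0
#' @export
resample_signal <- function(signal, target_len) {
  stopifnot(length(signal) >= 2L, target_len >= 2L)
  if (length(signal) == target_len) return(as.numeric(signal))
  stats::approx(x = seq(0, 1, length.out = length(signal)), y = signal,
                xout = seq(0, 1, length.out = target_len))$y
}

next_pow2 <- function(n) 2L^as.integer(ceiling(log2(n)))

# one orthonormal analysis step; returns list(a, d); x has even length
dwt_step <- function(x, wavelet) {
  n <- length(x)
  odd <- x[seq(1L, n, by = 2L)]
  even <- x[seq(2L, n, by = 2L)]
  if (wavelet == "haar") {
    return(list(a = (odd + even) / sqrt(2), d = (odd - even) / sqrt(2)))
  }
  # Daubechies-4, periodic boundary
  h <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  g <- c(h[4], -h[3], h[2], -h[1])
  k <- seq(0L, n - 1L, by = 2L)
  idx <- function(m) x[((k + m) %% n) + 1L]
  a <- h[1] * idx(0L) + h[2] * idx(1L) + h[3] * idx(2L) + h[4] * idx(3L)
  d <- g[1] * idx(0L) + g[2] * idx(1L) + g[3] * idx(2L) + g[4] * idx(3L)
  list(a = a, d = d)
}

#' Multilevel discrete wavelet decomposition
#'
#' Standard orthonormal pyramid: each level splits the current approximation
#' into a half-length approximation and detail. Requires (after resampling) a
#' dyadic signal length; if `2^L` exceeds the signal length, `L` is reduced
#' to `floor(log2(length))` with a warning.
#'
#' @param signal Numeric vector whose length is a power of two.
#' @param cfg A [tvc_config()].
#' @return Object of class `tvc_dwt`: list with `approx` (coefficients
#'   `a_L`), `details` (list `d_1 .. d_L`, finest first), `levels`, `wavelet`.
#' @examples
#' wavelet_decompose(c(1, -1), tvc_config(levels = 1))
#' @export
wavelet_decompose <- function(signal, cfg = tvc_config()) {
  n <- length(signal)
  stopifnot(n >= 2L, bitwAnd(n, n - 1L) == 0L)
  levels <- cfg$levels
  if (2L^levels > n) {
    levels <- as.integer(floor(log2(n)))
    warning(sprintf("signal length %d supports only %d level(s); L reduced",
                    n, levels), call. = FALSE)
  }
  a <- as.numeric(signal)
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    st <- dwt_step(a, cfg$wavelet)
    details[[j]] <- st$d
    a <- st$a
  }
  structure(list(approx = a, details = details, levels = levels,
                 wavelet = cfg$wavelet),
            class = "tvc_dwt")
}

#' Reconstruct a signal from its wavelet decomposition
#'
#' @param dec A `tvc_dwt` from [wavelet_decompose()].
#' @return The reconstructed numeric signal.
#' @export
wavelet_reconstruct <- function(dec) {
  a <- dec$approx
  for (j in rev(seq_len(dec$levels))) {
    a <- idwt_inverse_step(a, dec$details[[j]], dec$wavelet)
  }
  a
}

idwt_inverse_step <- function(a, d, wavelet) {
  n <- 2L * length(a)
  if (wavelet == "haar") {
    x <- numeric(n)
    x[seq(1L, n, by = 2L)] <- (a + d) / sqrt(2)
    x[seq(2L, n, by = 2L)] <- (a - d) / sqrt(2)
    return(x)
  }
  h <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  g <- c(h[4], -h[3], h[2], -h[1])
  x <- numeric(n)
  k <- seq(0L, n - 1L, by = 2L)
  for (m in 0:3) {
    pos <- ((k + m) %% n) + 1L
    x[pos] <- x[pos] + a * h[m + 1L] + d * g[m + 1L]
  }
  x
}

# Pearson correlation with the degenerate-input convention: vectors of
# length 1 or zero variance count as constant; both constant and equal -> 1,
# any other constant case -> 0.
level_correlation <- function(u, v) {
  cu <- length(u) < 2L || stats::sd(u) == 0
  cv <- length(v) < 2L || stats::sd(v) == 0
  if (cu || cv) {
    if (cu && cv && isTRUE(all.equal(u, v))) return(1)
    return(0)
  }
  stats::cor(u, v)
}

extract_signal <- function(curve, kind) {
  stopifnot(inherits(curve, "tvcurve"))
  if (kind == "cumulative") {
    as.numeric(curve$points[-1L, "y"]) # y_1 .. y_3N
  } else {
    as.numeric(curve$steps)
  }
}

#' Multi-scale similarity of two TV-curves
#'
#' Both curve signals are linearly resampled to the smallest power of two at
#' least as long as the longer signal, decomposed to `L` levels, and compared
#' level by level: the score is the weighted sum of the Pearson correlations
#' of the two approximation-coefficient vectors (weight `w_0`) and of the two
#' detail-coefficient vectors at each level `j` (weight `w_j`). With
#' normalised weights the score lies in \[-1, 1\]; a curve compared with
#' itself scores exactly 1.
#'
#' @param a,b `tvcurve` objects (see [tv_curve()]).
#' @param cfg A [tvc_config()].
#' @return Numeric similarity score in \[-1, 1\].
#' @examples
#' cv <- tv_curve(rna_record("x", "GGGGAAAACCCC", "((((....))))"))
#' multiscale_similarity(cv, cv)   # 1
#' @export
multiscale_similarity <- function(a, b, cfg = tvc_config()) {
  sa <- extract_signal(a, cfg$signal)
  sb <- extract_signal(b, cfg$signal)
  len <- next_pow2(max(length(sa), length(sb)))
  da <- wavelet_decompose(resample_signal(sa, len), cfg)
  db <- wavelet_decompose(resample_signal(sb, len), cfg)
  levels <- min(da$levels, db$levels)
  w <- cfg$weights
  if (levels != cfg$levels) { # L was reduced for a short signal
    w <- w[seq_len(levels + 1L)]
    w <- w / sum(w)
  }
  rho <- level_correlation(da$approx, db$approx)
  score <- w[1L] * rho
  for (j in seq_len(levels)) {
    score <- score + w[j + 1L] * level_correlation(da$details[[j]],
                                                   db$details[[j]])
  }
  score
}

#' Convert a similarity score to a structural distance
#'
#' The distance is one minus the similarity, so identical curves are at
#' distance 0 and the range is \[0, 2\].
#'
#' @param score Similarity in \[-1, 1\].
#' @return Distance in \[0, 2\].
#' @export
similarity_to_distance <- function(score) {
  stopifnot(all(score >= -1 - 1e-12), all(score <= 1 + 1e-12))
  1 - score
}

#' Structural distance between two RNA records
#'
#' Convenience wrapper: folds missing structures, encodes both records and
#' returns `1 - multiscale_similarity`.
#'
#' @param rec_a,rec_b [rna_record()] objects.
#' @param cfg A [tvc_config()].
#' @param backend A [fold_backend()].
#' @return Distance in \[0, 2\].
#' @export
tvc_distance <- function(rec_a, rec_b, cfg = tvc_config(),
                         backend = fold_backend("nussinov")) {
  ca <- tv_curve(ensure_structure(rec_a, backend))
  cb <- tv_curve(ensure_structure(rec_b, backend))
  similarity_to_distance(multiscale_similarity(ca, cb, cfg))
}
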