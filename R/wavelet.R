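#' Daubechies least-asymmetric LA(8) filter pair
#'
#' Returns the length-8 least-asymmetric scaling and wavelet filters in the
#' standard published ordering. The scaling filter sums to \eqn{\sqrt 2}, the
#' wavelet filter sums to 0, and the two are related by the quadrature-mirror
#' identity \eqn{h_l = (-1)^l g_{L-1-l}}.
#'
#' @return A list with components `g` (scaling filter) and `h` (wavelet
#'   filter), each a numeric vector of length 8.
#' @export
#' @examples
#' f <- la8_filters()
#' sum(f$g) # sqrt(2)
#' sum(f$h) # 0
la8_filters <- function() {
  g <- c(-0.075765714789273330, -0.029635527645998510,
          0.497618667632015450,  0.803738751805916100,
          0.297857795605277360, -0.099219543576847220,
         -0.012603967262037833,  0.032223100604042700)
  L <- length(g)
  h <- (-1)^(0:(L - 1)) * rev(g)
  list(g = g, h = h)
}

#' Nyquist frequency of a sampled time series
#'
#' @param tr_seconds Sampling interval (fMRI repetition time) in seconds.
#' @return The Nyquist frequency `1 / (2 * tr_seconds)` in Hz.
#' @export
#' @examples
#' nyquist_frequency(0.72) # 0.694 Hz
nyquist_frequency <- function(tr_seconds) {
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop("`tr_seconds` must be a single positive number")
  }
  1 / (2 * tr_seconds)
}

#' Frequency band of a dyadic wavelet decomposition level
#'
#' Level `j` of a dyadic wavelet decomposition covers the octave band
#' `(Nyquist / 2^j, Nyquist / 2^(j-1)]`. With TR = 0.72 s, level 4 covers
#' approximately 0.043-0.087 Hz, the canonical low-frequency range of
#' resting-state BOLD fluctuations.
#'
#' @param tr_seconds Sampling interval in seconds.
#' @param level Decomposition level (integer >= 1).
#' @return An object of class `waveconn_band`: a list with `level`, `f_low`
#'   and `f_high` (Hz).
#' @export
#' @examples
#' band_for_level(0.72, 4) # 0.043-0.087 Hz
band_for_level <- function(tr_seconds, level) {
  if (!is.numeric(level) || length(level) != 1L || level < 1 ||
      level != round(level)) {
    stop("`level` must be a single integer >= 1")
  }
  nyq <- nyquist_frequency(tr_seconds)
  structure(
    list(level = as.integer(level),
         f_low = nyq / 2^level,
         f_high = nyq / 2^(level - 1)),
    class = "waveconn_band"
  )
}

#' @export
print.waveconn_band <- function(x, ...) {
  cat(sprintf("Wavelet level %d band: %.4f - %.4f Hz\n",
              x$level, x$f_low, x$f_high))
  invisible(x)
}

# Number of boundary-affected coefficients at a given level for a length-L
# filter under circular filtering: L_j - 1 with L_j = (2^j - 1)(L - 1) + 1.
modwt_boundary_count <- function(level, filter_length = 8L) {
  (2^level - 1) * (filter_length - 1)
}

.as_signal_matrix <- function(x) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("signal must be a numeric vector or matrix (timepoints x regions)")
  }
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  x
}

# Apply the wavelet and scaling filters in one pass, sharing the circularly
# shifted copies of v (the expensive part for wide matrices).
.modwt_step_down <- function(v, h, g, shift) {
  n <- nrow(v)
  w_out <- matrix(0, n, ncol(v))
  v_out <- matrix(0, n, ncol(v))
  t0 <- 0:(n - 1)
  for (l in seq_along(h)) {
    idx <- ((t0 - shift * (l - 1)) %% n) + 1L
    vs <- v[idx, , drop = FALSE]
    w_out <- w_out + h[l] * vs
    v_out <- v_out + g[l] * vs
  }
  list(w = w_out, v = v_out)
}

# Inverse step uses the time-reversed index: (t + s*l) mod T.
.modwt_filter_up <- function(v, f, shift) {
  n <- nrow(v)
  out <- matrix(0, n, ncol(v))
  t0 <- 0:(n - 1)
  for (l in seq_along(f)) {
    idx <- ((t0 + shift * (l - 1)) %% n) + 1L
    out <- out + f[l] * v[idx, , drop = FALSE]
  }
  out
}

#' Maximal-overlap discrete wavelet transform (MODWT)
#'
#' Decomposes each column of a time-series matrix with the undecimated
#' pyramid algorithm and circular (periodic) boundary treatment. At level
#' `j` the filters are the LA(8) pair rescaled by `1/sqrt(2)` per stage,
#' equivalent to the standard `2^(-j/2)` rescaling of the equivalent filter.
#' All coefficient series retain the length of the input, so wavelet
#' coefficients can be correlated across regions without alignment
#' bookkeeping.
#'
#' @param x Numeric vector or `T x R` matrix (timepoints by regions).
#' @param levels Number of decomposition levels `J`; requires `T >= 2^J`.
#' @param filter Wavelet filter; only `"la8"` is implemented.
#' @param tr_seconds Optional sampling interval, stored for band bookkeeping.
#' @return An object of class `waveconn_modwt`: list with `details` (list of
#'   `J` coefficient matrices), `smooth` (level-`J` scaling coefficients),
#'   `levels`, `filter`, and `tr_seconds`.
#' @seealso [imodwt()], [modwt_mra()], [band_for_level()]
#' @export
#' @examples
#' x <- sin(2 * pi * 0.06 * (1:256) * 0.72) + rnorm(256, sd = 0.1)
#' w <- modwt(x, levels = 6, tr_seconds = 0.72)
#' sapply(w$details, stats::var)
modwt <- function(x, levels = 6L, filter = "la8", tr_seconds = NULL) {
  x <- .as_signal_matrix(x)
  n <- nrow(x)
  filter <- match.arg(filter, "la8")
  if (levels < 1 || levels != round(levels)) {
    stop("`levels` must be a positive integer")
  }
  max_level <- floor(log2(n))
  if (n < 2^levels) {
    stop(sprintf(
      "time series of length %d supports at most %d MODWT level(s), got %d",
      n, max_level, levels))
  }
  f <- la8_filters()
  gt <- f$g / sqrt(2)
  ht <- f$h / sqrt(2)
  v <- x
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    step <- .modwt_step_down(v, ht, gt, 2^(j - 1))
    details[[j]] <- step$w
    v <- step$v
    dimnames(details[[j]]) <- dimnames(x)
  }
  dimnames(v) <- dimnames(x)
  structure(
    list(details = details, smooth = v, levels = as.integer(levels),
         filter = filter, tr_seconds = tr_seconds),
    class = "waveconn_modwt"
  )
}

#' Inverse MODWT
#'
#' Reconstructs the original signal matrix from a [modwt()] decomposition
#' (perfect reconstruction up to floating-point error).
#'
#' @param w A `waveconn_modwt` object.
#' @return The reconstructed `T x R` signal matrix.
#' @export
imodwt <- function(w) {
  if (!inherits(w, "waveconn_modwt")) stop("`w` must be a waveconn_modwt object")
  dims <- dim(w$smooth)
  for (d in w$details) {
    if (!identical(dim(d), dims)) stop("coefficient matrices have mismatched shapes")
  }
  f <- la8_filters()
  gt <- f$g / sqrt(2)
  ht <- f$h / sqrt(2)
  v <- w$smooth
  for (j in rev(seq_len(w$levels))) {
    shift <- 2^(j - 1)
    v <- .modwt_filter_up(w$details[[j]], ht, shift) +
      .modwt_filter_up(v, gt, shift)
  }
  v
}

#' Multiresolution analysis (additive decomposition)
#'
#' Splits the input into per-level detail series plus a smooth series that
#' sum exactly back to the input: each component is the inverse transform of
#' the decomposition with all other levels zeroed.
#'
#' @param w A `waveconn_modwt` object.
#' @return List with `details` (list of `J` matrices) and `smooth`; their sum
#'   reconstructs the original signal.
#' @export
modwt_mra <- function(w) {
  if (!inherits(w, "waveconn_modwt")) stop("`w` must be a waveconn_modwt object")
  zero <- function(m) m * 0
  comps <- vector("list", w$levels)
  for (j in seq_len(w$levels)) {
    wj <- w
    wj$smooth <- zero(w$smooth)
    for (k in seq_len(w$levels)) if (k != j) wj$details[[k]] <- zero(w$details[[k]])
    comps[[j]] <- imodwt(wj)
  }
  ws <- w
  for (k in seq_len(w$levels)) ws$details[[k]] <- zero(w$details[[k]])
  list(details = comps, smooth = imodwt(ws))
}

#' Extract one level's wavelet coefficients
#'
#' Convenience accessor used by the connectivity stage: returns the detail
#' coefficients at `level`, optionally excluding the circular-boundary-
#' affected rows at the start of the series.
#'
#' @param w A `waveconn_modwt` object.
#' @param level Level of interest (1-based).
#' @param drop_boundary If `TRUE`, drop the first `(2^level - 1) * 7` rows,
#'   which mix the two ends of the series under circular filtering.
#' @return A coefficient matrix.
#' @export
wavelet_band_series <- function(w, level, drop_boundary = FALSE) {
  if (!inherits(w, "waveconn_modwt")) stop("`w` must be a waveconn_modwt object")
  if (level < 1 || level > w$levels) {
    stop(sprintf("`level` must be in 1..%d", w$levels))
  }
  d <- w$details[[level]]
  if (drop_boundary) {
    nb <- modwt_boundary_count(level)
    if (nb >= nrow(d) - 2L) {
      stop("dropping boundary coefficients would leave fewer than 3 timepoints")
    }
    d <- d[-seq_len(nb), , drop = FALSE]
  }
  d
}
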