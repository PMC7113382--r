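#' Regress nuisance confounds out of a time-series matrix
#'
#' Replaces every region's series with its ordinary-least-squares residual
#' against an intercept plus the supplied confound columns (motion
#' parameters, tissue signals, CompCor components, and the like). This is
#' the standard nuisance-regression step applied before wavelet
#' decomposition.
#'
#' @param signal `T x R` numeric matrix of ROI time series.
#' @param confounds `T x C` numeric matrix or data frame of confound series.
#' @return A `T x R` matrix of residuals.
#' @export
#' @examples
#' ts <- matrix(rnorm(200), 100, 2)
#' conf <- data.frame(drift = seq_len(100))
#' clean <- regress_confounds(ts, conf)
regress_confounds <- function(signal, confounds) {
  signal <- .as_signal_matrix(signal)
  if (is.data.frame(confounds)) confounds <- as.matrix(confounds)
  if (!is.matrix(confounds) || !is.numeric(confounds)) {
    stop("`confounds` must be a numeric matrix or data frame")
  }
  if (nrow(confounds) != nrow(signal)) {
    stop(sprintf("confound table has %d rows but signal has %d timepoints",
                 nrow(confounds), nrow(signal)))
  }
  if (!all(is.finite(confounds))) stop("confounds contain non-finite values")
  cn <- colnames(confounds) %||% paste0("confound_", seq_len(ncol(confounds)))
  X <- cbind(`(Intercept)` = 1, confounds)
  colnames(X) <- c("(Intercept)", cn)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("confound design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qrx, signal)
  dimnames(res) <- dimnames(signal)
  res
}
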