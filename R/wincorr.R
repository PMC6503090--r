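# Winsorized and Pearson correlation kernels.

#' Winsorize a numeric vector
#'
#' With `g = floor(gamma * n)`, the `g` smallest values are replaced by the
#' `(g+1)`-th order statistic and the `g` largest by the `(n-g)`-th order
#' statistic; element order is preserved.
#'
#' @param x Numeric vector, length >= 2.
#' @param gamma Proportion per tail, in \[0, 0.5).
#' @return Winsorized vector, same length and order as `x`.
#' @export
#' @examples
#' winsorize(c(1:9, 100), gamma = 0.1)  # 100 clamped to 9, 1 clamped to 2
winsorize <- function(x, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma >= 0.5) {
    bt_stop("gamma must lie in [0, 0.5)", "barotrend_param_error")
  }
  n <- length(x)
  if (n < 2L) bt_stop("need at least 2 values to winsorize", "barotrend_param_error")
  g <- floor(gamma * n)
  if (g == 0L) return(x)
  s <- sort.int(x, method = "quick")
  pmin(pmax(x, s[g + 1L]), s[n - g])
}

#' Winsorized correlation coefficient
#'
#' The Pearson product-moment correlation of the two independently
#' winsorized vectors (symmetric trimming proportion `gamma` per tail).
#' `gamma = 0` reduces exactly to the Pearson coefficient.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param gamma Proportion per tail, in \[0, 0.5); the study default is 0.1.
#' @return Correlation in \[-1, 1\].
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- 0.6 * x + 0.8 * rnorm(50)
#' wincorr(x, y, gamma = 0.1)
wincorr <- function(x, y, gamma = 0.1) {
  n <- length(x)
  if (length(y) != n) bt_stop("x and y must have equal length", "barotrend_param_error")
  if (n < 3L) bt_stop("need at least 3 pairs", "barotrend_param_error")
  wx <- winsorize(x, gamma)
  wy <- winsorize(y, gamma)
  sx <- sd(wx); sy <- sd(wy)
  if (sx == 0 || sy == 0) {
    bt_stop("zero winsorized variance: correlation undefined",
            "barotrend_degenerate_error")
  }
  r <- cor(wx, wy)
  # numerical clamp: cor() can exceed |1| by machine noise on exact fits
  max(-1, min(1, r))
}

#' Pearson correlation with degenerate-input guard
#'
#' @param x,y Numeric vectors of equal length >= 3, non-zero variance.
#' @return Correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  wincorr(x, y, gamma = 0)
}
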