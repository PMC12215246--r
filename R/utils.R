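#' Convert between beta values and M-values
#'
#' Beta values are methylation proportions in \[0,1\]; M-values are their
#' logit, `M = log2(beta/(1-beta))`, the unbounded scale suited to linear
#' modelling. `mToBeta` inverts the map. Base-2 logit is the array-analysis
#' convention.
#'
#' @param beta,m numeric vector or matrix.
#' @return transformed values, same shape as the input.
#' @examples
#' betaToM(0.5)       # 0
#' mToBeta(betaToM(0.9))
#' @export
betaToM <- function(beta) {
  stopifnot(is.numeric(beta))
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE))
    stop("beta values must lie strictly in (0,1) for the logit transform")
  log2(beta / (1 - beta))
}

#' @rdname betaToM
#' @export
mToBeta <- function(m) 2^m / (1 + 2^m)

# hours-of-day arithmetic: everything phase-like lives modulo 24
wrapClock <- function(h, period = 24) ((h %% period) + period) %% period

# circular difference in hours, signed, in (-period/2, period/2]
clockDiff <- function(a, b, period = 24) {
  d <- wrapClock(a - b, period)
  ifelse(d > period / 2, d - period, d)
}

# row-wise mean/sd without matrixStats
.rowSds <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  sqrt(rowSums((x - mu)^2) / (n - 1))
}

.stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
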