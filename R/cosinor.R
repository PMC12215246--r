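#' Single-harmonic cosinor fit per probe
#'
#' Fits, by ordinary least squares, `y = M + bc*cos(wt) + bs*sin(wt)` with
#' `w = 2*pi/period` and derives amplitude `A = sqrt(bc^2 + bs^2)` and
#' acrophase `phi = (period/(2*pi)) * atan2(bs, bc) mod period`, so that the
#' fitted curve peaks at clock time `phi`. Subjects are pooled as replicates
#' at each timepoint; all columns sharing a clock time enter as independent
#' observations. The intercept-only residual sum of squares is retained for
#' the zero-amplitude F test.
#'
#' @param x a [MethylExperiment], or a numeric probes x samples matrix.
#' @param times clock times (hours) per column; taken from the sample sheet
#'   (`clock_time`) when `x` is a `MethylExperiment`.
#' @param period rhythm period in hours.
#' @return `DataFrame` (one row per probe): `mesor`, `beta_cos`, `beta_sin`,
#'   `amplitude`, `acrophase` (`NA` with `phase_defined = FALSE` when the
#'   amplitude is numerically zero), `rss`, `rss0`, `n_obs`, `period`,
#'   `exact_fit`.
#' @examples
#' t <- seq(15, 39, by = 3)
#' y <- rbind(p1 = 2 + 0.5 * cos(2 * pi * (t - 20) / 24))
#' cosinorFit(y, times = t)[, c("mesor", "amplitude", "acrophase")]
#' @export
cosinorFit <- function(x, times = NULL, period = 24) {
  if (is(x, "MethylExperiment")) {
    if (is.null(times)) times <- sampleSheet(x)$clock_time
    m <- methValues(x)
  } else m <- as.matrix(x)
  .stopIfNot(!is.null(times), "clock times are required")
  .stopIfNot(length(times) == ncol(m),
             "length(times) must equal the number of samples")
  .stopIfNot(ncol(m) >= 4, "need at least 4 observations")
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  qr_x <- qr(X)
  if (qr_x$rank < 3L)
    stop("collinear cosinor design: times cover too little of the period")
  coefs <- qr.coef(qr_x, t(m))                      # 3 x P
  res <- qr.resid(qr_x, t(m))
  rss <- colSums(res^2)
  rss0 <- rowSums((m - rowMeans(m))^2)
  amp <- sqrt(coefs[2L, ]^2 + coefs[3L, ]^2)
  phi <- wrapClock((period / (2 * pi)) * atan2(coefs[3L, ], coefs[2L, ]),
                   period)
  zero_amp <- amp < .Machine$double.eps^0.5 * pmax(1, abs(coefs[1L, ]))
  phi[zero_amp] <- NA_real_
  DataFrame(probe_id = rownames(m), mesor = unname(coefs[1L, ]),
            beta_cos = unname(coefs[2L, ]), beta_sin = unname(coefs[3L, ]),
            amplitude = unname(amp), acrophase = unname(phi),
            phase_defined = unname(!zero_amp),
            rss = unname(rss), rss0 = unname(rss0),
            n_obs = ncol(m), period = period,
            exact_fit = unname(rss < .Machine$double.eps^0.5),
            row.names = rownames(m))
}

#' Zero-amplitude F test for a cosinor fit
#'
#' Tests the rhythm terms jointly against the intercept-only model:
#' `F = ((RSS0 - RSS)/2) / (RSS/(n-3))` referred to `F(2, n-3)`. Exact fits
#' (`RSS = 0`) return `p = 0` with the `exact_fit` flag already set by
#' [cosinorFit()].
#'
#' @param fit a `DataFrame` from [cosinorFit()].
#' @return the fit with columns `f_stat` and `p_rhythm` appended.
#' @examples
#' t <- rep(seq(0, 21, by = 3), 4)
#' y <- matrix(rnorm(2 * length(t)), 2,
#'             dimnames = list(c("a", "b"), NULL))
#' cosinorTest(cosinorFit(y, times = t))$p_rhythm
#' @export
cosinorTest <- function(fit) {
  .stopIfNot(all(fit$n_obs > 3), "F test needs more than 3 observations")
  df2 <- fit$n_obs - 3L
  f <- ((fit$rss0 - fit$rss) / 2) / (fit$rss / df2)
  p <- stats::pf(f, 2, df2, lower.tail = FALSE)
  p[fit$exact_fit] <- 0
  f[fit$exact_fit] <- Inf
  fit$f_stat <- f
  fit$p_rhythm <- p
  fit
}

#' Order probes by ascending acrophase
#'
#' Stable ascending sort on acrophase with ties broken by probe ID, the
#' ordering used for acrophase-sorted rhythm heatmaps.
#'
#' @param fit a `DataFrame` from [cosinorFit()].
#' @param subset optional probe IDs to order (default: all).
#' @return character vector of probe IDs.
#' @export
orderByAcrophase <- function(fit, subset = NULL) {
  ids <- if (is.null(subset)) fit$probe_id else subset
  sel <- match(ids, fit$probe_id)
  if (anyNA(sel)) stop("unknown probe ID(s): ",
                       paste(utils::head(ids[is.na(sel)], 5), collapse = ", "))
  phi <- fit$acrophase[sel]
  if (anyNA(phi))
    stop("undefined acrophase for probe(s): ",
         paste(utils::head(ids[is.na(phi)], 5), collapse = ", "))
  ids[order(phi, ids)]
}

#' Export acrophase-ordered, group-averaged heatmap matrices
#'
#' For a probe subset (typically "change"-classified sites), averages the
#' z-scored values over subjects at each timepoint within each condition
#' window and returns the two matrices with an identical row order: probes
#' sorted by ascending baseline acrophase. Rows are matched between
#' conditions so row k refers to the same probe in both.
#'
#' @param windows list of two z-scored [MethylExperiment]s from
#'   [splitConditions()].
#' @param fit_baseline cosinor fit (on the z-scored baseline window) used
#'   for the ordering.
#' @param subset probe IDs to include.
#' @return list of two probes x timepoint matrices (columns labelled by
#'   clock time) in window order.
#' @export
heatmapMatrices <- function(windows, fit_baseline, subset) {
  ord <- orderByAcrophase(fit_baseline, subset)
  lapply(windows, function(wx) {
    m <- methValues(wx)[ord, , drop = FALSE]
    idx <- sampleSheet(wx)$sampling_index
    clock <- sampleSheet(wx)$clock_time
    groups <- split(seq_len(ncol(m)), idx)
    avg <- sapply(groups, function(j) rowMeans(m[, j, drop = FALSE]))
    if (is.null(dim(avg))) avg <- matrix(avg, nrow = 1,
                                         dimnames = list(ord, names(groups)))
    colnames(avg) <- sprintf("%02.0f:00", clock[match(as.integer(colnames(avg)),
                                                      idx)])
    avg
  })
}
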