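#' Classifier configuration
#'
#' @param period rhythm period in hours.
#' @param criterion information criterion: `"aic"` (default) or `"aicc"`
#'   (small-sample corrected) or `"bic"`.
#' @param weight_cutoff minimum Akaike weight of the best model for a probe
#'   to be classified (confidence threshold; default 0.6).
#' @param fdr_alpha BH level for the optional rhythm-test eligibility
#'   pre-filter.
#' @param prefilter if `TRUE` (default), a probe must pass the cosinor
#'   zero-amplitude test, BH-adjusted at `fdr_alpha`, in at least one
#'   condition to be eligible for a rhythmic class; ineligible probes are
#'   assigned `"arrhy"`.
#' @return list of class `"ClassifierConfig"`.
#' @export
classifierConfig <- function(period = 24, criterion = c("aic", "aicc", "bic"),
                             weight_cutoff = 0.6, fdr_alpha = 0.05,
                             prefilter = TRUE) {
  criterion <- match.arg(criterion)
  .stopIfNot(weight_cutoff > 0 && weight_cutoff <= 1,
             "weight_cutoff must lie in (0,1]")
  .stopIfNot(period > 0, "period must be positive")
  structure(list(period = period, criterion = criterion,
                 weight_cutoff = weight_cutoff, fdr_alpha = fdr_alpha,
                 prefilter = prefilter),
            class = "ClassifierConfig")
}

# candidate design matrices for the five differential-rhythmicity models.
# cond is a logical vector: TRUE = second (sleep-deprivation) condition.
.rhythmDesigns <- function(times, cond, period) {
  w <- 2 * pi / period
  cb <- cos(w * times); sb <- sin(w * times)
  i1 <- as.numeric(!cond); i2 <- as.numeric(cond)
  list(
    arrhy  = cbind(mu1 = i1, mu2 = i2),
    same   = cbind(mu1 = i1, mu2 = i2, c = cb, s = sb),
    loss   = cbind(mu1 = i1, mu2 = i2, c1 = cb * i1, s1 = sb * i1),
    gain   = cbind(mu1 = i1, mu2 = i2, c2 = cb * i2, s2 = sb * i2),
    change = cbind(mu1 = i1, mu2 = i2, c1 = cb * i1, s1 = sb * i1,
                   c2 = cb * i2, s2 = sb * i2))
}

#' Fit the five candidate differential-rhythmicity models
#'
#' Per probe, ordinary least squares of five nested models over the pooled
#' two-condition observations: condition-specific means only (`arrhy`); a
#' shared 24-h harmonic (`same`); a harmonic active in the baseline only
#' (`loss`); in the sleep-deprivation condition only (`gain`); or
#' condition-specific harmonics (`change`). Mean parameter counts are
#' 2/4/4/4/6; one further parameter is charged for the residual variance in
#' the information criteria.
#'
#' @param m probes x observations matrix (both conditions concatenated,
#'   typically z-scored per window).
#' @param times clock times (hours) per observation.
#' @param cond condition label per observation (2 levels; the second level
#'   in first-appearance order is treated as sleep deprivation) or a logical
#'   vector (`TRUE` = sleep deprivation).
#' @param config a [classifierConfig()].
#' @return list with `rss` (probes x 5 matrix), `k` (mean parameter count
#'   per model), `n` (observations).
#' @export
fitCandidateModels <- function(m, times, cond, config = classifierConfig()) {
  m <- as.matrix(m)
  if (!is.logical(cond)) {
    lv <- unique(cond)
    .stopIfNot(length(lv) == 2L, "cond must have exactly two levels")
    cond <- cond == lv[2L]
  }
  .stopIfNot(any(cond) && any(!cond), "both conditions must be represented")
  for (g in list(which(cond), which(!cond)))
    if (length(unique(round(wrapClock(times[g], config$period), 8))) < 4L)
      stop("insufficient distinct times within a condition")
  designs <- .rhythmDesigns(times, cond, config$period)
  rss <- sapply(designs, function(X) {
    qr_x <- qr(X)
    colSums(qr.resid(qr_x, t(m))^2)
  })
  if (nrow(m) == 1L) rss <- matrix(rss, 1, dimnames = list(rownames(m),
                                                           names(designs)))
  list(rss = rss, k = vapply(designs, ncol, integer(1L)), n = ncol(m))
}

# information criterion from Gaussian profile likelihood;
# k counts mean parameters, +1 for the residual variance
.infoCriterion <- function(rss, k, n, criterion) {
  kk <- k + 1L
  penalty <- switch(criterion,
                    aic = 2 * kk,
                    aicc = 2 * kk + 2 * kk * (kk + 1) / pmax(n - kk - 1, 1),
                    bic = log(n) * kk)
  n * log(rss / n) + rep(penalty, each = nrow(rss))
}

#' Akaike weights from information-criterion scores
#'
#' `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)` with
#' `delta_i = IC_i - min(IC)`; numerically stable for large spreads. A model
#' with `IC = -Inf` (exact fit) takes all the weight; among several exact
#' fits the most parsimonious (fewest parameters) wins.
#'
#' @param ic numeric vector or probes x models matrix of criterion scores.
#' @param k parameter counts, used only to break exact-fit ties.
#' @return weights with the same shape, each row summing to 1.
#' @examples
#' akaikeWeights(c(m1 = 0, m2 = 2))
#' @export
akaikeWeights <- function(ic, k = NULL) {
  vec <- is.null(dim(ic))
  icm <- if (vec) matrix(ic, 1, dimnames = list(NULL, names(ic))) else ic
  if (any(rowSums(is.finite(icm) | icm == -Inf) < 1L))
    stop("each probe needs at least one finite criterion score")
  w <- matrix(0, nrow(icm), ncol(icm), dimnames = dimnames(icm))
  exact <- icm == -Inf
  has_exact <- rowSums(exact) > 0L
  if (any(has_exact)) {
    for (i in which(has_exact)) {
      cand <- which(exact[i, ])
      pick <- if (!is.null(k)) cand[which.min(k[cand])] else cand[1L]
      w[i, pick] <- 1
    }
  }
  rest <- which(!has_exact)
  if (length(rest)) {
    d <- icm[rest, , drop = FALSE]
    d <- d - apply(d, 1L, min)
    e <- exp(-d / 2)
    w[rest, ] <- e / rowSums(e)
  }
  if (vec) w[1L, ] else w
}

#' Classify probes into the five differential-rhythmicity classes
#'
#' Runs [fitCandidateModels()] on the concatenated condition windows, scores
#' the five models by the configured information criterion
#' (`n*log(RSS/n) + 2k`, with `k` including the residual variance), converts
#' scores to Akaike weights, and assigns the best model's class when its
#' weight reaches `weight_cutoff`, else `"unclassified"`. With the
#' eligibility pre-filter on, probes whose cosinor zero-amplitude test fails
#' BH correction at `fdr_alpha` in both conditions are assigned `"arrhy"`.
#' Zero-variance probes are assigned `"arrhy"` with a flag. Per-condition
#' acrophases from [cosinorFit()] on each window are attached.
#'
#' @param windows list of two [MethylExperiment]s from [splitConditions()]
#'   (typically z-scored per window), baseline first.
#' @param config a [classifierConfig()].
#' @return `DataFrame`: per-model criterion scores (`ic_*`), Akaike weights
#'   (`w_*`), `best_model`, `max_weight`, `class`, `eligible`,
#'   `zero_variance`, `acrophase_baseline`, `acrophase_sd`.
#' @examples
#' sim <- simulateMethylation(40, studyDesign(n_subjects = 4), seed = 2)
#' sw <- splitConditions(sim$methyl)
#' cl <- classifyRhythms(lapply(sw, zscoreProbes))
#' table(cl$class)
#' @export
classifyRhythms <- function(windows, config = classifierConfig()) {
  stopifnot(length(windows) == 2L)
  mats <- lapply(windows, methValues)
  .stopIfNot(identical(rownames(mats[[1L]]), rownames(mats[[2L]])),
             "windows must share probe IDs")
  times <- unlist(lapply(windows, function(wx) sampleSheet(wx)$clock_time),
                  use.names = FALSE)
  cond <- rep(c(FALSE, TRUE), vapply(mats, ncol, integer(1L)))
  m <- cbind(mats[[1L]], mats[[2L]])
  probes <- rownames(m)

  fits <- fitCandidateModels(m, times, cond, config)
  ic <- .infoCriterion(fits$rss, fits$k, fits$n, config$criterion)
  dimnames(ic) <- dimnames(fits$rss)
  zero_var <- .rowSds(m) < .Machine$double.eps^0.5
  w <- akaikeWeights(ic, fits$k)
  best <- colnames(w)[max.col(w, ties.method = "first")]
  max_w <- w[cbind(seq_len(nrow(w)), max.col(w, ties.method = "first"))]

  cls <- ifelse(max_w >= config$weight_cutoff, best, "unclassified")

  cf <- lapply(windows, function(wx)
    cosinorTest(cosinorFit(wx, period = config$period)))
  eligible <- rep(TRUE, length(probes))
  if (isTRUE(config$prefilter)) {
    q1 <- bhAdjust(cf[[1L]]$p_rhythm)
    q2 <- bhAdjust(cf[[2L]]$p_rhythm)
    eligible <- pmin(q1, q2) <= config$fdr_alpha
    cls[!eligible] <- "arrhy"
  }
  cls[zero_var] <- "arrhy"

  out <- DataFrame(probe_id = probes, row.names = probes)
  for (j in colnames(ic)) out[[paste0("ic_", j)]] <- ic[, j]
  for (j in colnames(w)) out[[paste0("w_", j)]] <- w[, j]
  out$best_model <- best
  out$max_weight <- max_w
  out$class <- cls
  out$eligible <- eligible
  out$zero_variance <- zero_var
  out$acrophase_baseline <- cf[[1L]]$acrophase
  out$acrophase_sd <- cf[[2L]]$acrophase
  out
}

#' Tabulate differential-rhythmicity classes
#'
#' Produces the count/percentage bookkeeping of a classification run:
#' per-class counts with percentages relative to classifiable sites and to
#' all submitted sites, plus the derived totals (rhythmic =
#' same + loss + gain + change; rhythmic in both = same + change).
#'
#' @param x a classification `DataFrame` from [classifyRhythms()], a factor/
#'   character vector of classes, or a named count vector with names among
#'   `c("arrhy","same","loss","gain","change","unclassified")`.
#' @return list with `table` (`data.frame`: class, n, pct_classifiable,
#'   pct_all), `n_total`, `n_classifiable`, `n_rhythmic`,
#'   `n_rhythmic_both`, `pct_rhythmic_all`.
#' @examples
#' summarizeClasses(c(same = 79163, loss = 16077, gain = 15735,
#'                    change = 5144, arrhy = 107476, unclassified = 594432))
#' @export
summarizeClasses <- function(x) {
  lv <- c("unclassified", "arrhy", "same", "loss", "gain", "change")
  counts <- if (is.numeric(x)) {
    bad <- setdiff(names(x), lv)
    if (length(bad)) stop("unknown class name(s): ", paste(bad, collapse = ", "))
    v <- stats::setNames(numeric(length(lv)), lv)
    v[names(x)] <- x
    v
  } else {
    cls <- if (is(x, "DataFrame") || is.data.frame(x)) x$class else x
    table(factor(cls, levels = lv)) |> as.numeric() |> stats::setNames(lv)
  }
  n_total <- sum(counts)
  n_class <- n_total - counts[["unclassified"]]
  n_rhythmic <- sum(counts[c("same", "loss", "gain", "change")])
  pc <- function(n, d) if (d > 0) 100 * n / d else NA_real_
  tab <- data.frame(
    class = c("not_classifiable", "arrhy", "same", "loss", "gain", "change"),
    n = as.numeric(counts[c("unclassified", "arrhy", "same", "loss", "gain",
                            "change")]),
    pct_classifiable = c(NA, vapply(counts[c("arrhy", "same", "loss", "gain",
                                             "change")], pc, 0, d = n_class)),
    pct_all = vapply(counts[c("unclassified", "arrhy", "same", "loss", "gain",
                              "change")], pc, 0, d = n_total),
    row.names = NULL)
  list(table = tab, n_total = n_total, n_classifiable = n_class,
       n_rhythmic = n_rhythmic,
       n_rhythmic_both = sum(counts[c("same", "change")]),
       pct_rhythmic_all = pc(n_rhythmic, n_total))
}
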