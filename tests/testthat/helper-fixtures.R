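# shared fixture builders; everything is generated in code at test time

# single-class truth configuration
onlyClass <- function(k, ...) {
  pr <- c(arrhy = 0, same = 0, loss = 0, gain = 0, change = 0)
  pr[k] <- 1
  planTruth(class_proportions = pr, ...)
}

# small MethylExperiment with an explicit value matrix
toyMethyl <- function(values, design = studyDesign(n_subjects = ncol(values) /
                                                     16L)) {
  sheet <- simulateSampleSheet(design)
  stopifnot(ncol(values) == nrow(sheet))
  colnames(values) <- sheet$sample_id
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("cg%05d", seq_len(nrow(values)))
  MethylExperiment(values, sheet, scale = "M")
}

# z-scored condition windows of a simulated dataset
simWindows <- function(sim) lapply(splitConditions(sim$methyl), zscoreProbes)

# independent brute-force BH step-up, used as the adjustment oracle
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# dense grid-search cosinor oracle: best phase/amplitude by RSS scan
cosinorOracle <- function(times, y, period = 24, step = 0.005) {
  w <- 2 * pi / period
  phis <- seq(0, period - step, by = step)
  best <- list(rss = Inf)
  for (phi in phis) {
    xc <- cos(w * (times - phi))
    ft <- stats::lm.fit(cbind(1, xc), y)
    rss <- sum(ft$residuals^2)
    if (rss < best$rss)
      best <- list(rss = rss, phi = phi, amp = ft$coefficients[2L],
                   mesor = ft$coefficients[1L])
  }
  if (best$amp < 0) {
    best$amp <- -best$amp
    best$phi <- (best$phi + period / 2) %% period
  }
  best
}
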