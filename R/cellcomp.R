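#' Impute missing cell counts from adjacent timepoints
#'
#' Each missing count is replaced by the arithmetic mean of the same class
#' at the two adjacent sampling indices for that subject; the flag matrix
#' marks imputed entries. Missing values at a subject's first or last
#' timepoint, or at two consecutive timepoints, cannot be imputed by this
#' rule and raise an error listing the positions.
#'
#' @param x a [CellCounts] object.
#' @return a [CellCounts] with no `NA` counts and flags where imputed.
#' @examples
#' cc <- simulateCellCounts(studyDesign(n_subjects = 2), n_subjects = 2,
#'                          seed = 3, missing_rate = 0.2)
#' sum(imputedFlags(imputeMissingCounts(cc)))
#' @export
imputeMissingCounts <- function(x) {
  stopifnot(is(x, "CellCounts"))
  df <- cellCounts(x)
  cls <- wbcClasses()
  flags <- imputedFlags(x)
  for (s in unique(df$subject_id)) {
    rows <- which(df$subject_id == s)
    rows <- rows[order(df$sampling_index[rows])]
    for (cc in cls) {
      v <- df[rows, cc]
      nas <- which(is.na(v))
      if (!length(nas)) next
      bad <- nas[nas == 1L | nas == length(v) |
                   c(diff(nas) == 1L, FALSE) | c(FALSE, diff(nas) == 1L)]
      if (length(bad))
        stop("cannot impute ", cc, " for subject ", s,
             " at sampling index ",
             paste(df$sampling_index[rows][bad], collapse = ", "),
             ": boundary or consecutive missing values")
      v[nas] <- (v[nas - 1L] + v[nas + 1L]) / 2
      df[rows, cc] <- v
      flags[rows[nas], cc] <- TRUE
    }
  }
  if (any(df[, cls] <= 0))
    stop("non-positive cell counts after imputation")
  CellCounts(df, flags)
}

#' Normalize methylation by white-blood-cell counts
#'
#' Divides each probe's value at each sample by the subject's count for the
#' requested WBC class at the same timepoint, producing one normalized
#' matrix per class ("all" runs all 13). Counts must be complete (run
#' [imputeMissingCounts()] first) and strictly positive, and must cover all
#' subjects in the matrix.
#'
#' @param x a [MethylExperiment].
#' @param counts a [CellCounts].
#' @param cell_class one of [wbcClasses()], or `"all"`.
#' @return a single [MethylExperiment] (scale tag `"M"`, since values leave
#'   the beta range), or a named list of them for `"all"`.
#' @export
normalizeByCellCount <- function(x, counts, cell_class = "all") {
  stopifnot(is(x, "MethylExperiment"), is(counts, "CellCounts"))
  classes <- if (identical(cell_class, "all")) wbcClasses()
  else match.arg(cell_class, wbcClasses())
  cd <- sampleSheet(x)
  df <- cellCounts(counts)
  key_m <- paste(cd$subject_id, cd$sampling_index)
  key_c <- paste(df$subject_id, df$sampling_index)
  idx <- match(key_m, key_c)
  if (anyNA(idx))
    stop("cell counts missing for sample(s): ",
         paste(utils::head(rownames(cd)[is.na(idx)], 5), collapse = ", "))
  one <- function(cl) {
    cnt <- df[[cl]][idx]
    if (anyNA(cnt)) stop("NA counts for class ", cl,
                         "; run imputeMissingCounts() first")
    if (any(cnt <= 0)) stop("non-positive counts for class ", cl)
    m <- sweep(methValues(x), 2L, cnt, "/")
    out <- MethylExperiment(m, as.data.frame(cd), scale = "M")
    metadata(out)$normalized_by <- cl
    out
  }
  if (length(classes) == 1L) one(classes)
  else stats::setNames(lapply(classes, one), classes)
}

#' Configuration for the methylation-vs-composition correlation null
#'
#' @param alpha per-test error rate used for the observed/expected count.
#' @param n_probes number of probes entering the analysis.
#' @param n_cell_classes number of WBC classes (13).
#' @param method correlation method.
#' @param fdr_alpha BH level for the adjusted significant count.
#' @return list of class `"CorrelationNullConfig"`.
#' @export
correlationNullConfig <- function(alpha = 0.05, n_probes = 1000L,
                                  n_cell_classes = 13L,
                                  method = c("pearson", "spearman"),
                                  fdr_alpha = 0.05) {
  .stopIfNot(alpha > 0 && alpha < 1 || alpha == 0, "alpha must lie in [0,1)")
  structure(list(alpha = alpha, n_probes = as.integer(n_probes),
                 n_cell_classes = as.integer(n_cell_classes),
                 method = match.arg(method), fdr_alpha = fdr_alpha),
            class = "CorrelationNullConfig")
}

#' Expected count of significant correlations under the null
#'
#' With independent tests at level `alpha` over `n_probes` probes and
#' `n_cell_classes` WBC classes, chance alone yields
#' `alpha * n_probes * n_cell_classes` significant correlations (the
#' non-exclusive classes make the tests dependent, which inflates the
#' variance but not this mean).
#'
#' @param config a [correlationNullConfig()].
#' @return expected count (numeric).
#' @examples
#' expectedNullCorrelations(correlationNullConfig()) # 650
#' @export
expectedNullCorrelations <- function(config = correlationNullConfig()) {
  config$alpha * config$n_probes * config$n_cell_classes
}

#' Correlate final-timepoint methylation with WBC composition
#'
#' At the last sampling index, computes for every (probe, WBC class) pair
#' the correlation across subjects between methylation and the class's
#' relative proportion (class count / total WBC count). Reports the observed
#' number of p-values below `alpha`, the expected count under the null, and
#' the BH-adjusted significant count. The total-WBC class's proportion is
#' identically 1 and is skipped with a flag, as is any other constant
#' vector.
#'
#' @param x a [MethylExperiment] (all timepoints; the final one is selected
#'   by maximum sampling index).
#' @param counts a [CellCounts] covering that timepoint.
#' @param config a [correlationNullConfig()].
#' @return list with `pairs` (`data.frame`: probe_id, cell_class, r, p, q,
#'   skipped), `n_observed` (p < alpha), `n_expected`, `n_bh_significant`,
#'   `n_tested`, `config`.
#' @export
compositionCorrelation <- function(x, counts,
                                   config = correlationNullConfig()) {
  stopifnot(is(x, "MethylExperiment"), is(counts, "CellCounts"))
  cd <- sampleSheet(x)
  final_idx <- max(cd$sampling_index)
  sel <- cd$sampling_index == final_idx
  m <- methValues(x)[, sel, drop = FALSE]
  subj <- cd$subject_id[sel]
  df <- cellCounts(counts)
  dff <- df[df$sampling_index == final_idx, , drop = FALSE]
  row <- match(subj, dff$subject_id)
  keep <- !is.na(row)
  if (sum(keep) < 3L)
    stop("need at least 3 subjects with methylation and counts at the final timepoint")
  m <- m[, keep, drop = FALSE]
  dff <- dff[row[keep], , drop = FALSE]
  n <- ncol(m)
  classes <- wbcClasses()
  prop <- as.matrix(dff[, classes]) / dff$wbc_total

  res <- lapply(classes, function(cl) {
    p_vec <- prop[, cl]
    if (stats::sd(p_vec) < .Machine$double.eps^0.5)
      return(data.frame(probe_id = rownames(m), cell_class = cl,
                        r = NA_real_, p = NA_real_, skipped = TRUE))
    if (config$method == "spearman") {
      yv <- t(apply(m, 1L, rank))
      xv <- rank(p_vec)
    } else {
      yv <- m; xv <- p_vec
    }
    r <- as.numeric(stats::cor(t(yv), xv))
    # guard exact +-1 from degenerate probes
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    data.frame(probe_id = rownames(m), cell_class = cl, r = r, p = p,
               skipped = FALSE)
  })
  pairs <- do.call(rbind, res)
  tested <- !pairs$skipped & !is.na(pairs$p)
  pairs$q <- NA_real_
  pairs$q[tested] <- bhAdjust(pairs$p[tested])
  list(pairs = pairs,
       n_observed = sum(pairs$p[tested] < config$alpha),
       n_expected = expectedNullCorrelations(config),
       n_bh_significant = sum(pairs$q[tested] <= config$fdr_alpha),
       n_tested = sum(tested), config = config)
}
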