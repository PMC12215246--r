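#' Apply a probe mask and report filtering bookkeeping
#'
#' Removes masked probes from the matrix (unknown mask IDs are ignored with
#' a warning) and reports per-reason counts plus the removal percentage,
#' both as the raw ratio and rounded to two decimals as such figures are
#' customarily printed. Array-wide context: EPIC-style QC typically drops a
#' few percent of probes for failed detection, SNP overlap/cross-reactivity
#' and sex chromosomes.
#'
#' @param x a [MethylExperiment].
#' @param mask `data.frame` with `probe_id` and `reason` columns (see
#'   [readProbeMask()]).
#' @return list with elements `methyl` (filtered [MethylExperiment]) and
#'   `report` (list: `n_input`, `n_removed`, `n_survivors`,
#'   `per_reason` named counts, `pct_removed` raw percentage,
#'   `pct_removed_printed` two-decimal rounding).
#' @examples
#' sim <- simulateMethylation(10, studyDesign(n_subjects = 2), seed = 1)
#' mask <- data.frame(probe_id = probeIDs(sim$methyl)[1:3],
#'                    reason = "detection")
#' applyProbeFilters(sim$methyl, mask)$report$per_reason
#' @export
applyProbeFilters <- function(x, mask) {
  stopifnot(is(x, "MethylExperiment"))
  if (nrow(mask) > 0 && (is.null(mask$probe_id) || is.null(mask$reason)))
    stop("mask must have probe_id and reason columns")
  unknown <- setdiff(mask$probe_id, probeIDs(x))
  if (length(unknown)) {
    warning(length(unknown), " mask probe ID(s) not present in the matrix; ",
            "ignored")
    mask <- mask[!mask$probe_id %in% unknown, , drop = FALSE]
  }
  drop_ids <- unique(mask$probe_id)
  n_input <- nrow(x)
  survivors <- setdiff(probeIDs(x), drop_ids)
  if (length(survivors) == 0L)
    stop("probe filtering removed every probe")
  per_reason <- if (nrow(mask)) {
    tab <- tapply(mask$probe_id, mask$reason,
                  function(p) length(unique(p)))
    as.integer(tab) |> stats::setNames(names(tab))
  } else integer(0)
  report <- filterReport(n_removed = length(drop_ids), n_total = n_input,
                         per_reason = per_reason)
  list(methyl = x[survivors, ], report = report)
}

#' Probe-filter bookkeeping from counts
#'
#' Pure arithmetic used by [applyProbeFilters()] and directly when only the
#' counts are known (e.g. recomputing a printed removal percentage).
#'
#' @param n_removed unique probes removed.
#' @param n_total probes on the input array.
#' @param per_reason optional named integer vector of per-reason counts.
#' @return list with `n_input`, `n_removed`, `n_survivors`, `per_reason`,
#'   `pct_removed` (raw), `pct_removed_printed` (2 dp).
#' @examples
#' filterReport(48064, 864935)$pct_removed
#' @export
filterReport <- function(n_removed, n_total, per_reason = integer(0)) {
  pct <- 100 * n_removed / n_total
  list(n_input = n_total, n_removed = n_removed,
       n_survivors = n_total - n_removed, per_reason = per_reason,
       pct_removed = pct, pct_removed_printed = round(pct, 2))
}

#' Split a 45-h series into two overlapping 24-h condition windows
#'
#' The first `window` samples per subject form the baseline window and the
#' last `window` the sleep-deprivation window. With the default 16-sample,
#' 3-h design and `window = 9` each window spans a full 24 h inclusive and
#' the two windows share sampling indices 8 and 9 — the compromise that
#' yields equal-length complete day cycles in both conditions. The
#' `condition` column of each returned window's sample sheet is set to the
#' window label (overlap samples appear in both, relabelled accordingly).
#'
#' @param x a [MethylExperiment] whose sample sheet has `subject_id` and
#'   `sampling_index`.
#' @param window samples per condition window.
#' @param labels length-2 condition labels (baseline first).
#' @return named list of two [MethylExperiment]s (`baseline`,
#'   `sleep_deprivation` by default labels).
#' @examples
#' sim <- simulateMethylation(5, studyDesign(n_subjects = 2), seed = 1)
#' sw <- splitConditions(sim$methyl)
#' ncol(sw$baseline); ncol(sw$sleep_deprivation)
#' @export
splitConditions <- function(x, window = 9L,
                            labels = c("baseline", "sleep_deprivation")) {
  stopifnot(is(x, "MethylExperiment"))
  cd <- sampleSheet(x)
  .stopIfNot(all(c("subject_id", "sampling_index") %in% colnames(cd)),
             "sample sheet needs subject_id and sampling_index")
  n_idx <- max(cd$sampling_index)
  .stopIfNot(window <= n_idx, "window longer than the series")
  counts <- table(cd$subject_id)
  short <- names(counts)[counts < n_idx]
  if (length(short))
    stop("subject(s) with incomplete series: ",
         paste(short, collapse = ", "))
  take <- function(idx_set, label) {
    keep <- cd$sampling_index %in% idx_set
    sub <- x[, keep]
    cdd <- colData(sub)
    cdd$condition <- label
    colData(sub) <- cdd
    sub
  }
  out <- list(take(seq_len(window), labels[1L]),
              take(seq(n_idx - window + 1L, n_idx), labels[2L]))
  names(out) <- labels
  out
}

#' Z-score each probe across all samples of a window
#'
#' Centers and scales every probe row to mean 0, sample SD 1 across all
#' subject x timepoint entries (subjects pooled), the standardization
#' applied per condition window before rhythm classification. Zero-variance
#' probes are left as all zeros and flagged.
#'
#' @param x a [MethylExperiment] or numeric matrix.
#' @return same type as the input with standardized rows; flagged probe IDs
#'   in `attr(, "zero_variance")` (on the matrix, or in
#'   `metadata(x)$zero_variance` for a `MethylExperiment`, which is returned
#'   with scale tag `"M"` since standardized values leave the beta range).
#' @examples
#' zscoreProbes(matrix(1:6, 2, dimnames = list(c("a", "b"), NULL)))
#' @export
zscoreProbes <- function(x) {
  m <- if (is(x, "MethylExperiment")) methValues(x) else x
  mu <- rowMeans(m)
  sdev <- .rowSds(m)
  zero <- sdev < .Machine$double.eps^0.5
  sdev[zero] <- 1
  z <- (m - mu) / sdev
  z[zero, ] <- 0
  flagged <- rownames(m)[zero]
  if (is(x, "MethylExperiment")) {
    out <- MethylExperiment(z, as.data.frame(sampleSheet(x)), scale = "M")
    metadata(out)$zero_variance <- flagged
    metadata(out)$standardized <- TRUE
    out
  } else {
    attr(z, "zero_variance") <- flagged
    z
  }
}

#' Remove batch/covariate structure by per-probe least squares
#'
#' Fits, per probe, an ordinary least-squares model on the requested sample
#' covariates (categorical covariates expanded to indicators) and returns
#' residuals plus the probe's grand mean, so the output stays on the input
#' scale. This is an optional stage, off by default in [runPipeline()]: with
#' a fully randomized plate layout batch structure is ignorable, and the
#' per-probe fixed-effects fit is the reproducible counterpart of a
#' mixed-model adjustment.
#'
#' @param x a [MethylExperiment].
#' @param covariates character vector of sample-sheet column names.
#' @return a [MethylExperiment] with adjusted values.
#' @export
residualizeCovariates <- function(x, covariates = c("batch",
                                                    "batch_position",
                                                    "age")) {
  stopifnot(is(x, "MethylExperiment"))
  cd <- as.data.frame(sampleSheet(x))
  miss <- setdiff(covariates, colnames(cd))
  if (length(miss))
    stop("covariate(s) not in sample sheet: ", paste(miss, collapse = ", "))
  df <- cd[, covariates, drop = FALSE]
  for (cc in covariates)
    if (is.character(df[[cc]])) df[[cc]] <- factor(df[[cc]])
  # drop constant covariates (single level): nothing to adjust
  keep <- vapply(df, function(v) length(unique(v)) > 1L, logical(1L))
  if (!any(keep)) return(x)
  X <- stats::model.matrix(~ ., data = df[, keep, drop = FALSE])
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1L, ncol(X))]]
    stop("rank-deficient covariate design; aliased: ",
         paste(aliased, collapse = ", "))
  }
  m <- methValues(x)
  res <- t(qr.resid(qr_x, t(m))) + rowMeans(m)
  out <- x
  SummarizedExperiment::assay(out, "meth") <- res
  # adjusted beta values can stray outside [0,1]; retag as M-like values
  if (methScale(x) == "beta" && (min(res) < 0 || max(res) > 1))
    metadata(out)$scale <- "M"
  validObject(out)
  out
}
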