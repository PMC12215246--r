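#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<-
NULL

#' MethylExperiment: probe x sample methylation values with sample metadata
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single methylation assay (beta values in \[0,1\] or M-values) together with
#' the sample sheet in `colData`. The measurement scale is carried as a tag in
#' `metadata(x)$scale` and enforced by the validity method, so downstream
#' stages can refuse to, e.g., logit-transform an already-M-scale matrix.
#'
#' @slot . inherits all slots from `SummarizedExperiment`.
#' @export
setClass("MethylExperiment", contains = "SummarizedExperiment")

setValidity("MethylExperiment", function(object) {
  msg <- character()
  sc <- metadata(object)$scale
  if (is.null(sc) || !sc %in% c("beta", "M"))
    msg <- c(msg, "metadata(object)$scale must be \"beta\" or \"M\"")
  if (length(assays(object)) < 1L) {
    msg <- c(msg, "exactly one methylation assay is required")
  } else {
    v <- assay(object)
    if (!is.numeric(v)) msg <- c(msg, "assay must be numeric")
    if (identical(sc, "beta") && length(v) &&
        (min(v, na.rm = TRUE) < 0 || max(v, na.rm = TRUE) > 1))
      msg <- c(msg, "beta-scale values must lie in [0,1]")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate probe IDs")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample IDs")
  if (length(msg)) msg else TRUE
})

#' Construct a MethylExperiment
#'
#' @param values numeric probe x sample matrix with probe IDs as rownames and
#'   sample IDs as colnames.
#' @param sampleSheet a `data.frame`/`DataFrame` of per-sample metadata, one
#'   row per column of `values` (see [readSampleSheet()] for required
#'   columns). Row order must match the column order of `values`; if it has a
#'   `sample_id` column it is matched against `colnames(values)`.
#' @param scale `"beta"` or `"M"` — scale of the stored values.
#'
#' @return A `MethylExperiment`.
#' @examples
#' sheet <- simulateSampleSheet(studyDesign(n_subjects = 2))
#' m <- matrix(runif(5 * nrow(sheet)), nrow = 5,
#'             dimnames = list(paste0("cg", 1:5), sheet$sample_id))
#' MethylExperiment(m, sheet)
#' @export
MethylExperiment <- function(values, sampleSheet, scale = c("beta", "M")) {
  scale <- match.arg(scale)
  if (is.null(rownames(values)))
    stop("'values' must carry probe IDs as rownames")
  if (is.null(colnames(values)))
    stop("'values' must carry sample IDs as colnames")
  sampleSheet <- as(sampleSheet, "DataFrame")
  if (!is.null(sampleSheet$sample_id)) {
    idx <- match(colnames(values), sampleSheet$sample_id)
    if (anyNA(idx))
      stop("sample sheet is missing samples: ",
           paste(utils::head(colnames(values)[is.na(idx)], 5), collapse = ", "))
    sampleSheet <- sampleSheet[idx, , drop = FALSE]
    rownames(sampleSheet) <- sampleSheet$sample_id
  }
  se <- SummarizedExperiment(assays = list(meth = values),
                             colData = sampleSheet,
                             metadata = list(scale = scale))
  new("MethylExperiment", se)
}

#' @describeIn MethylExperiment the methylation value matrix.
#' @param x,object a `MethylExperiment`.
#' @export
methValues <- function(x) assay(x, "meth")

#' @describeIn MethylExperiment the scale tag (`"beta"` or `"M"`).
#' @export
methScale <- function(x) metadata(x)$scale

#' @describeIn MethylExperiment the sample sheet as a `DataFrame`.
#' @export
sampleSheet <- function(x) colData(x)

#' @describeIn MethylExperiment probe identifiers.
#' @export
probeIDs <- function(x) rownames(x)

setMethod("show", "MethylExperiment", function(object) {
  cat("MethylExperiment:", nrow(object), "probes x", ncol(object),
      "samples (", metadata(object)$scale, "scale )\n")
  cd <- colData(object)
  if (!is.null(cd$subject_id))
    cat("  subjects:", length(unique(cd$subject_id)), "")
  if (!is.null(cd$condition))
    cat(" conditions:", paste(unique(cd$condition), collapse = ", "))
  cat("\n")
})

# ---- CellCounts ------------------------------------------------------------

#' Canonical white-blood-cell class column names
#'
#' The 13 (non-exclusive) WBC count categories used for normalization:
#' total WBC, granulocytes, lymphocytes, total T, total B, monocytes,
#' total/memory/naive CD4, total/memory/naive CD8, NK/dendritic.
#' Totals are sums of their parts by construction:
#' `cd8_total = cd8_memory + cd8_naive`, `cd4_total = cd4_memory + cd4_naive`,
#' `t_total = cd4_total + cd8_total`,
#' `lymphocytes = t_total + b_total + nk_dendritic`,
#' `wbc_total = granulocytes + lymphocytes + monocytes`.
#'
#' @return character vector of the 13 class column names.
#' @export
wbcClasses <- function() {
  c("wbc_total", "granulocytes", "lymphocytes", "t_total", "b_total",
    "monocytes", "cd4_total", "cd4_memory", "cd4_naive",
    "cd8_total", "cd8_memory", "cd8_naive", "nk_dendritic")
}

#' CellCounts: subject x timepoint white-blood-cell counts
#'
#' Holds per-subject, per-sampling-index counts (cells per microlitre) for the
#' 13 WBC classes of [wbcClasses()], plus a logical matrix flagging entries
#' that are (or were, post-imputation) missing.
#'
#' @slot counts `data.frame` with columns `subject_id`, `sampling_index`,
#'   `clock_time` and the 13 class columns. Missing entries are `NA` until
#'   [imputeMissingCounts()] fills them.
#' @slot missing logical matrix, rows matching `counts`, columns the 13
#'   classes; `TRUE` where the original measurement was absent.
#' @export
setClass("CellCounts",
         representation(counts = "data.frame", missing = "matrix"))

setValidity("CellCounts", function(object) {
  msg <- character()
  need <- c("subject_id", "sampling_index", "clock_time", wbcClasses())
  miss <- setdiff(need, colnames(object@counts))
  if (length(miss))
    msg <- c(msg, paste("counts is missing columns:",
                        paste(miss, collapse = ", ")))
  if (!is.logical(object@missing) ||
      nrow(object@missing) != nrow(object@counts) ||
      ncol(object@missing) != 13L)
    msg <- c(msg, "missing must be a logical matrix with 13 class columns")
  if (length(msg)) msg else TRUE
})

#' Construct a CellCounts object
#'
#' @param counts `data.frame` with `subject_id`, `sampling_index`,
#'   `clock_time` and the 13 columns of [wbcClasses()]; `NA` marks a missing
#'   measurement.
#' @param missing optional logical flag matrix; defaults to `is.na()` of the
#'   class columns.
#' @return A `CellCounts` object.
#' @export
CellCounts <- function(counts, missing = NULL) {
  counts <- as.data.frame(counts)
  cls <- wbcClasses()
  if (is.null(missing)) {
    missing <- as.matrix(is.na(counts[, intersect(cls, colnames(counts)),
                                      drop = FALSE]))
    if (ncol(missing) == 13L) colnames(missing) <- cls
  }
  obj <- new("CellCounts", counts = counts, missing = missing)
  validObject(obj)
  obj
}

#' @describeIn CellCounts the count table (`data.frame`).
#' @param x,object a `CellCounts` object.
#' @export
cellCounts <- function(x) x@counts

#' @describeIn CellCounts logical flags marking originally-missing entries.
#' @export
imputedFlags <- function(x) x@missing

setMethod("show", "CellCounts", function(object) {
  cat("CellCounts:", length(unique(object@counts$subject_id)), "subjects x",
      length(unique(object@counts$sampling_index)), "timepoints, 13 classes\n")
  nmiss <- sum(object@missing)
  if (nmiss) cat("  flagged (missing/imputed) entries:", nmiss, "\n")
})
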