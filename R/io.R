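#' Read and write probe x sample methylation matrices
#'
#' `readMethylMatrix` reads a delimited text matrix (first column = probe ID,
#' header row = sample IDs; tab or comma, auto-detected) into a
#' [MethylExperiment], optionally in chunks of rows so array-scale files
#' (hundreds of thousands of probes) stream without a single large parse.
#' `writeMethylMatrix` writes the matrix back in the same layout; the round
#' trip is lossless to the written precision.
#'
#' @param path file path.
#' @param sampleSheet optional sample sheet `data.frame` to attach (else a
#'   minimal one with `sample_id` only is built).
#' @param scale `"beta"` or `"M"`, tag for the stored values.
#' @param sep field separator; `"auto"` sniffs tab vs comma from the header.
#' @param chunk_size rows per read chunk; `Inf` reads in one pass.
#' @return `readMethylMatrix`: a [MethylExperiment].
#'   `writeMethylMatrix`: the path, invisibly.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' sim <- simulateMethylation(5, studyDesign(n_subjects = 2), seed = 1)
#' writeMethylMatrix(sim$methyl, tf)
#' readMethylMatrix(tf, sampleSheet = as.data.frame(sampleSheet(sim$methyl)))
#' @export
readMethylMatrix <- function(path, sampleSheet = NULL,
                             scale = c("beta", "M"), sep = "auto",
                             chunk_size = Inf) {
  scale <- match.arg(scale)
  .stopIfNot(file.exists(path), "file not found: ", path)
  if (identical(sep, "auto")) {
    hdr <- readLines(path, n = 1L)
    sep <- if (lengths(regmatches(hdr, gregexpr("\t", hdr))) > 0) "\t" else ","
  }
  if (is.finite(chunk_size)) {
    hdr <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
    chunks <- list()
    skip <- 1L
    repeat {
      dt <- data.table::fread(path, sep = sep, skip = skip,
                              nrows = chunk_size, header = FALSE,
                              data.table = FALSE, showProgress = FALSE)
      if (nrow(dt) == 0L) break
      chunks[[length(chunks) + 1L]] <- dt
      skip <- skip + nrow(dt)
      if (nrow(dt) < chunk_size) break
    }
    dt <- do.call(rbind, chunks)
    colnames(dt) <- hdr[seq_len(ncol(dt))]
  } else {
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            data.table = FALSE, showProgress = FALSE)
  }
  if (ncol(dt) < 2L) stop("matrix file needs a probe ID column plus samples")
  ids <- as.character(dt[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated probe ID(s): ", paste(unique(utils::head(dup, 5)),
                                           collapse = ", "))
  body <- dt[, -1L, drop = FALSE]
  bad <- !vapply(body, is.numeric, logical(1L))
  if (any(bad))
    stop("non-numeric values in column(s): ",
         paste(colnames(body)[bad], collapse = ", "))
  m <- as.matrix(body)
  rownames(m) <- ids
  if (is.null(sampleSheet))
    sampleSheet <- data.frame(sample_id = colnames(m))
  MethylExperiment(m, sampleSheet, scale = scale)
}

#' @rdname readMethylMatrix
#' @param x a [MethylExperiment] or a plain matrix with dimnames.
#' @export
writeMethylMatrix <- function(x, path, sep = "\t") {
  m <- if (is(x, "MethylExperiment")) methValues(x) else x
  out <- data.table::data.table(probe_id = rownames(m))
  out <- cbind(out, data.table::as.data.table(m))
  data.table::fwrite(out, path, sep = sep)
  invisible(path)
}

#' Read a sample sheet
#'
#' Required columns: `sample_id`, `subject_id`, `condition`,
#' `sampling_index`, `clock_time`. Optional: `time_awake`, `batch`,
#' `batch_position`, `age`, `elapsed_time`. `(subject_id, sampling_index)`
#' must be unique and clock times must lie in \[0, 24).
#'
#' @param path delimited text file (separator auto-detected by `fread`).
#' @return `data.frame`.
#' @export
readSampleSheet <- function(path) {
  df <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  need <- c("sample_id", "subject_id", "condition", "sampling_index",
            "clock_time")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df[, c("subject_id", "sampling_index")]))
    stop("(subject_id, sampling_index) pairs must be unique")
  if (any(df$clock_time < 0 | df$clock_time >= 24))
    stop("clock_time must lie in [0,24)")
  rownames(df) <- df$sample_id
  df
}

#' Read a probe mask (probes to drop, with reasons)
#'
#' One probe ID per line, optionally followed by a separator and a reason
#' label (`detection`, `snp_crossreactive`, `sex_chromosome`, ...). A missing
#' reason column is filled with `"unspecified"`.
#'
#' @param path text file.
#' @return `data.frame` with columns `probe_id`, `reason`.
#' @export
readProbeMask <- function(path) {
  df <- data.table::fread(path, data.table = FALSE, header = FALSE,
                          showProgress = FALSE)
  colnames(df)[1L] <- "probe_id"
  if (ncol(df) >= 2L) colnames(df)[2L] <- "reason"
  else df$reason <- "unspecified"
  df[, c("probe_id", "reason")]
}

#' Read a white-blood-cell count table
#'
#' Delimited text with `subject_id`, `sampling_index`, `clock_time` and the
#' 13 class columns of [wbcClasses()]; empty cells become `NA` and are
#' flagged as missing.
#'
#' @param path delimited text file.
#' @return a [CellCounts] object.
#' @export
readCellCounts <- function(path) {
  df <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  CellCounts(df)
}

#' Read a probe-to-gene manifest
#'
#' Two-column delimited text: probe ID, gene symbol. Probes may map to
#' multiple genes (one row each).
#'
#' @param path delimited text file with or without a header line.
#' @return `data.frame` with columns `probe_id`, `gene`.
#' @export
readGeneManifest <- function(path) {
  df <- data.table::fread(path, data.table = FALSE, showProgress = FALSE,
                          header = "auto")
  if (ncol(df) < 2L) stop("manifest needs two columns: probe_id, gene")
  colnames(df)[1:2] <- c("probe_id", "gene")
  df[, c("probe_id", "gene")]
}

#' Read gene sets in GMT format
#'
#' Standard tab-delimited GMT: set name, description, then member genes.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) fgsea::gmtPathways(path)
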