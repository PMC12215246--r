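#' Run the full diurnal-methylation analysis pipeline
#'
#' Orchestrates simulate/ingest -> probe filtering -> condition split ->
#' per-window z-scoring -> cosinor -> five-model rhythm classification ->
#' paired differential methylation with the threshold grid -> optional
#' WBC normalization re-classification and the composition-correlation
#' null. All randomness flows from the single `seed`; rerunning with the
#' same configuration yields byte-identical outputs.
#'
#' @param config nested list (or path to a YAML file with the same keys):
#' \describe{
#'   \item{`simulate`}{list(`n_probes`, optional [planTruth()] arguments) to
#'     generate data, or `NULL` when `input` is given.}
#'   \item{`input`}{list(`matrix`, `sample_sheet`, optional `cell_counts`,
#'     `probe_mask`, `scale`) of file paths.}
#'   \item{`classifier`}{arguments for [classifierConfig()].}
#'   \item{`dmp`}{list(`headline` threshold, `top_n`).}
#'   \item{`wbc`}{list(`enabled`, optional `n_subjects`, `missing_rate`);
#'     requires cell counts.}
#'   \item{`enrich`}{list(`gmt`, `manifest`) paths, optional.}
#'   \item{`out_dir`}{output directory for tables (optional; no files
#'     written when `NULL`).}
#'   \item{`seed`}{integer.}
#' }
#' @param quiet suppress stage messages.
#' @return list of class `"RunReport"`: per-stage dimensions, the filter
#'   report, class summary, DMP grid, correlation summary, seed, and the
#'   in-memory stage results under `$results`.
#' @examples
#' rep <- runPipeline(list(simulate = list(n_probes = 60),
#'                         seed = 4), quiet = TRUE)
#' rep$class_summary$table
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  say <- function(...) if (!quiet) message("[methRhythm] ", ...)
  report <- list(seed = seed, stages = list())
  note <- function(stage, ...) {
    report$stages[[stage]] <<- list(...)
    say(stage, ": ", paste(names(list(...)), unlist(list(...)),
                           sep = "=", collapse = ", "))
  }

  # ---- validate paths up front: fail before any compute
  for (p in unlist(config$input)) if (is.character(p) && !file.exists(p))
    stop("input path does not exist: ", p)
  if (isTRUE(config$wbc$enabled) && !is.null(config$input) &&
      is.null(config$input$cell_counts) && is.null(config$simulate))
    stop("WBC stage enabled but no cell-count source configured")
  if (!is.null(config$enrich))
    for (p in unlist(config$enrich)) if (!file.exists(p))
      stop("enrichment input does not exist: ", p)

  # ---- ingest or simulate
  cc <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    n_probes <- sim_args$n_probes %||% 1000L
    design <- do.call(studyDesign, sim_args$design %||% list())
    truth_args <- sim_args[setdiff(names(sim_args), c("n_probes", "design",
                                                      "cell_subjects",
                                                      "missing_rate"))]
    truth <- do.call(planTruth, truth_args)
    sim <- simulateMethylation(n_probes, design, truth, seed = seed)
    me <- sim$methyl
    cc <- simulateCellCounts(design,
                             n_subjects = sim_args$cell_subjects %||%
                               min(10L, design$n_subjects),
                             seed = seed,
                             missing_rate = sim_args$missing_rate %||% 0.02)
    report$truth <- sim$truth
    note("simulate", probes = nrow(me), samples = ncol(me))
  } else {
    inp <- config$input
    .stopIfNot(!is.null(inp$matrix) && !is.null(inp$sample_sheet),
               "config$input needs matrix and sample_sheet paths")
    sheet <- readSampleSheet(inp$sample_sheet)
    me <- readMethylMatrix(inp$matrix, sampleSheet = sheet,
                           scale = inp$scale %||% "beta")
    if (!is.null(inp$cell_counts)) cc <- readCellCounts(inp$cell_counts)
    note("ingest", probes = nrow(me), samples = ncol(me))
  }

  # ---- probe filtering
  if (!is.null(config$input$probe_mask)) {
    mask <- readProbeMask(config$input$probe_mask)
    fr <- applyProbeFilters(me, mask)
    me <- fr$methyl
    report$filter <- fr$report
    note("filter", removed = fr$report$n_removed,
         survivors = fr$report$n_survivors)
  } else report$filter <- filterReport(0L, nrow(me))

  # ---- split into overlapping 24-h windows and z-score
  windows <- splitConditions(me)
  zwin <- lapply(windows, zscoreProbes)
  note("split", baseline = ncol(windows[[1L]]),
       sleep_deprivation = ncol(windows[[2L]]))

  # ---- cosinor per condition: acrophase on z-scored, amplitude on raw
  ccfg <- do.call(classifierConfig, config$classifier %||% list())
  cos_z <- lapply(zwin, function(wx)
    cosinorTest(cosinorFit(wx, period = ccfg$period)))
  cos_raw <- lapply(windows, function(wx)
    cosinorFit(wx, period = ccfg$period))
  note("cosinor", period = ccfg$period)

  # ---- classification
  classification <- classifyRhythms(zwin, ccfg)
  class_summary <- summarizeClasses(classification)
  note("classify", classified = class_summary$n_classifiable,
       rhythmic = class_summary$n_rhythmic)

  # ---- paired differential methylation on the unstandardized series
  pd <- pairedDifferences(me)
  dmp_records <- lapply(seq_along(pd), function(i)
    moderatedT(pd[[i]]$delta, pair = pd[[i]]))
  names(dmp_records) <- names(pd)
  headline <- config$dmp$headline %||% 5e-4
  grid <- countDmps(dmp_records, headline = headline)
  fstat <- moderatedF(pd)
  note("dmp", pairs = length(pd), probes = grid$n_probes)

  # ---- WBC normalization + composition correlation
  corr <- NULL
  wbc_class_counts <- NULL
  if (!is.null(cc) && !identical(config$wbc$enabled, FALSE)) {
    cc <- imputeMissingCounts(cc)
    have <- unique(cellCounts(cc)$subject_id)
    keep <- sampleSheet(me)$subject_id %in% have
    me_sub <- me[, keep]
    ncfg <- do.call(correlationNullConfig,
                    c(list(n_probes = nrow(me_sub)),
                      config$wbc$null %||% list()))
    corr <- compositionCorrelation(me_sub, cc, ncfg)
    note("corr-null", observed = corr$n_observed,
         expected = corr$n_expected)
    if (isTRUE(config$wbc$reclassify)) {
      norm <- normalizeByCellCount(me_sub, cc, "all")
      wbc_class_counts <- vapply(norm, function(nm) {
        zz <- lapply(splitConditions(nm), zscoreProbes)
        summarizeClasses(classifyRhythms(zz, ccfg))$n_rhythmic
      }, numeric(1L))
      note("normalize-wbc", classes = length(norm))
    }
  }

  # ---- enrichment
  enrich <- NULL
  if (!is.null(config$enrich)) {
    manifest <- readGeneManifest(config$enrich$manifest)
    sets <- readGmt(config$enrich$gmt)
    top_n <- config$dmp$top_n %||% 1000L
    last <- dmp_records[[length(dmp_records)]]
    top <- selectTopDmps(last, min(top_n, nrow(last)))
    mapped <- mapToGenes(top, manifest)
    universe <- unique(manifest$gene[manifest$probe_id %in% probeIDs(me)])
    enrich <- overrepresentationTest(mapped$genes, sets, universe)
    note("enrich", sets = nrow(enrich), genes = length(mapped$genes))
  }

  # ---- probe-count conservation
  stopifnot(report$filter$n_survivors == nrow(me),
            nrow(classification) == nrow(me),
            grid$n_probes == nrow(me))

  report$class_summary <- class_summary
  report$dmp_grid <- grid
  report$correlation <- if (is.null(corr)) NULL else
    corr[c("n_observed", "n_expected", "n_bh_significant", "n_tested")]
  report$wbc_rhythmic_counts <- wbc_class_counts
  report$results <- list(methyl = me, windows = windows, zwindows = zwin,
                         cosinor_z = cos_z, cosinor_raw = cos_raw,
                         classification = classification,
                         dmp_records = dmp_records, moderated_f = fstat,
                         correlation = corr, enrichment = enrich,
                         cell_counts = cc)
  class(report) <- "RunReport"

  if (!is.null(config$out_dir)) writeRunReport(report, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write pipeline outputs as delimited text plus a key-value report
#'
#' @param report a `"RunReport"` from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeRunReport <- function(report, dir) {
  stopifnot(inherits(report, "RunReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- report$results
  fw <- function(x, f, ...) data.table::fwrite(as.data.frame(x),
                                               file.path(dir, f), sep = "\t",
                                               ...)
  fw(res$classification, "classification.tsv")
  fw(report$class_summary$table, "class_summary.tsv")
  for (nm in names(res$dmp_records))
    fw(res$dmp_records[[nm]], paste0("dmp_", nm, ".tsv"))
  grid_df <- data.frame(pair = rownames(report$dmp_grid$counts),
                        time_awake = report$dmp_grid$direction$time_awake,
                        report$dmp_grid$counts, check.names = FALSE)
  fw(grid_df, "dmp_grid.tsv")
  fw(report$dmp_grid$direction, "dmp_direction.tsv")
  for (i in 1:2)
    fw(res$cosinor_z[[i]], paste0("cosinor_", names(res$cosinor_z)[i],
                                  ".tsv"))
  if (!is.null(res$correlation)) fw(res$correlation$pairs,
                                    "composition_correlation.tsv")
  if (!is.null(res$enrichment)) fw(res$enrichment, "enrichment.tsv")
  summary_kv <- c(seed = report$seed,
                  n_probes = report$filter$n_survivors,
                  n_classifiable = report$class_summary$n_classifiable,
                  n_rhythmic = report$class_summary$n_rhythmic,
                  n_rhythmic_both = report$class_summary$n_rhythmic_both)
  yaml::write_yaml(as.list(summary_kv), file.path(dir, "run_report.yaml"))
  invisible(dir)
}

#' @export
print.RunReport <- function(x, ...) {
  cat("methRhythm run (seed ", x$seed, ")\n", sep = "")
  cat("  probes analysed:", x$filter$n_survivors, "\n")
  cat("  classifiable:", x$class_summary$n_classifiable,
      " rhythmic:", x$class_summary$n_rhythmic, "\n")
  if (!is.null(x$correlation))
    cat("  composition correlations: observed", x$correlation$n_observed,
        "expected", x$correlation$n_expected, "\n")
  invisible(x)
}
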