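#' Describe the sampling design of a sleep-deprivation methylation study
#'
#' Defaults reproduce the study layout the package targets: 15 healthy
#' subjects sampled every 3 h for 45 h starting at 15:00, i.e. 16 samples per
#' subject spanning a baseline day/night (indices 1–8, 15:00 day 2 to 12:00
#' day 3) followed by a night of total sleep deprivation (indices 9–16,
#' 15:00 day 3 to 12:00 day 4). Lights out/on times are metadata used to
#' compute time awake.
#'
#' @param n_subjects number of subjects.
#' @param sampling_interval hours between consecutive samples.
#' @param n_samples_per_subject samples per subject.
#' @param start_clock_time clock time (hours-of-day) of the first sample.
#' @param condition_labels length-2 character: baseline label, then the
#'   sleep-deprivation label.
#' @param lights_out,lights_on habitual sleep episode bounds, hours-of-day.
#' @return A list of class `"StudyDesign"`.
#' @examples
#' studyDesign()
#' @export
studyDesign <- function(n_subjects = 15L,
                        sampling_interval = 3,
                        n_samples_per_subject = 16L,
                        start_clock_time = 15,
                        condition_labels = c("baseline", "sleep_deprivation"),
                        lights_out = 23, lights_on = 7) {
  .stopIfNot(n_subjects >= 1, "n_subjects must be >= 1")
  .stopIfNot(sampling_interval > 0, "sampling_interval must be positive")
  .stopIfNot(n_samples_per_subject >= 2,
             "n_samples_per_subject must be >= 2")
  .stopIfNot(length(condition_labels) == 2L,
             "condition_labels must have exactly two labels")
  structure(list(n_subjects = as.integer(n_subjects),
                 sampling_interval = sampling_interval,
                 n_samples_per_subject = as.integer(n_samples_per_subject),
                 start_clock_time = wrapClock(start_clock_time),
                 condition_labels = condition_labels,
                 lights_out = lights_out, lights_on = lights_on),
            class = "StudyDesign")
}

#' Expand a StudyDesign into a per-sample sheet
#'
#' One row per subject x sampling index with elapsed time, wrapped clock
#' time, the physical condition (first half baseline, second half sleep
#' deprivation), time awake, and batch/age placeholders. Time awake counts
#' from lights-on (07:00 by default) of the current day for baseline samples
#' and accumulates continuously through the sleep-deprivation night; samples
#' drawn while subjects are asleep carry `NA`.
#'
#' @param design a [studyDesign()].
#' @param batch_size samples per array batch, used to assign `batch` and
#'   `batch_position` in sample order (plate layout surrogate).
#' @param ages optional numeric vector of subject ages (recycled); default
#'   draws nothing and uses a fixed 24.
#' @return `data.frame` with columns `sample_id`, `subject_id`, `condition`,
#'   `sampling_index`, `clock_time`, `elapsed_time`, `time_awake`, `batch`,
#'   `batch_position`, `age`.
#' @export
simulateSampleSheet <- function(design = studyDesign(), batch_size = 96L,
                                ages = NULL) {
  ns <- design$n_subjects
  np <- design$n_samples_per_subject
  subj <- sprintf("S%02d", seq_len(ns))
  idx <- seq_len(np)
  elapsed <- (idx - 1) * design$sampling_interval
  clock <- wrapClock(design$start_clock_time + elapsed)
  half <- np %/% 2L
  cond <- rep(design$condition_labels[2L], np)
  cond[idx <= half] <- design$condition_labels[1L]

  # time awake: wake at lights_on each morning; asleep between lights_out and
  # lights_on during the baseline night; wakefulness is continuous through
  # the sleep-deprivation night
  asleep <- clock >= design$lights_out | clock < design$lights_on
  ta <- wrapClock(clock - design$lights_on)
  ta[cond == design$condition_labels[1L] & asleep] <- NA_real_
  sd_idx <- which(cond == design$condition_labels[2L])
  if (length(sd_idx))
    ta[sd_idx] <- wrapClock(clock[sd_idx[1L]] - design$lights_on) +
      (elapsed[sd_idx] - elapsed[sd_idx[1L]])

  df <- expand.grid(sampling_index = idx, subject_id = subj,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[order(df$subject_id, df$sampling_index), , drop = FALSE]
  df$sample_id <- sprintf("%s_T%02d", df$subject_id, df$sampling_index)
  df$condition <- cond[df$sampling_index]
  df$clock_time <- clock[df$sampling_index]
  df$elapsed_time <- elapsed[df$sampling_index]
  df$time_awake <- ta[df$sampling_index]
  n <- nrow(df)
  df$batch <- sprintf("B%d", ((seq_len(n) - 1L) %/% batch_size) + 1L)
  df$batch_position <- ((seq_len(n) - 1L) %% batch_size) + 1L
  df$age <- if (is.null(ages)) 24 else rep_len(ages, ns)[match(df$subject_id, subj)]
  rownames(df) <- df$sample_id
  df[, c("sample_id", "subject_id", "condition", "sampling_index",
         "clock_time", "elapsed_time", "time_awake", "batch",
         "batch_position", "age")]
}

#' Configuration of the planted ground truth for simulated methylation
#'
#' Class proportions default to the mix observed among classifiable sites in
#' the study the package emulates (48.1% arrhythmic, 35.4% same, 7.2% loss,
#' 7.0% gain, 2.3% change). Signal is built on the M-value (logit-beta)
#' scale; `amplitude`/`noise_sd` are on that scale, so their ratio is the
#' per-observation signal-to-noise of the rhythm.
#'
#' @param class_proportions named numeric over
#'   `c("arrhy","same","loss","gain","change")`, summing to 1.
#' @param mesor_mean,mesor_sd distribution of per-probe mesors (M scale).
#' @param amplitude rhythm amplitude (M scale) for rhythmic probes; scalar or
#'   one value per probe.
#' @param phase_shift acrophase shift (hours) applied to "change" probes in
#'   the sleep-deprivation condition; sign randomized per probe.
#' @param subject_intercept_sd SD of the per-subject random intercept.
#' @param noise_sd SD of the Gaussian observation noise (M scale); a scalar,
#'   or one value per probe for heterogeneous probe variances. Zero gives
#'   noiseless series for deterministic checks.
#' @param dmp_fraction fraction of probes receiving a late-wakefulness drift.
#' @param drift_magnitude absolute drift effect (M scale) at the final
#'   sample; ramps linearly over samples with >= `drift_onset` h awake.
#' @param drift_onset hours of continual wakefulness after which the drift
#'   engages.
#' @param hypo_fraction probability a drifting probe drifts negative
#'   (hypomethylation); the study observed 70% hypomethylated sites.
#' @return list of class `"PlantedTruthConfig"`.
#' @export
planTruth <- function(class_proportions = c(arrhy = 0.481, same = 0.354,
                                            loss = 0.072, gain = 0.070,
                                            change = 0.023),
                      mesor_mean = 0, mesor_sd = 1.5,
                      amplitude = 1, phase_shift = 6,
                      subject_intercept_sd = 0.25,
                      noise_sd = 0.25,
                      dmp_fraction = 0.05, drift_magnitude = 0.5,
                      drift_onset = 23, hypo_fraction = 0.70) {
  need <- c("arrhy", "same", "loss", "gain", "change")
  if (!setequal(names(class_proportions), need))
    stop("class_proportions must be named over: ", paste(need, collapse = ", "))
  class_proportions <- class_proportions[need]
  if (any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-8)
    stop("class_proportions must be non-negative and sum to 1")
  if (!is.numeric(noise_sd) || any(noise_sd < 0))
    stop("noise_sd must be non-negative")
  if (hypo_fraction < 0 || hypo_fraction > 1)
    stop("hypo_fraction must lie in [0,1]")
  if (dmp_fraction < 0 || dmp_fraction > 1)
    stop("dmp_fraction must lie in [0,1]")
  structure(list(class_proportions = class_proportions,
                 mesor_mean = mesor_mean, mesor_sd = mesor_sd,
                 amplitude = amplitude, phase_shift = phase_shift,
                 subject_intercept_sd = subject_intercept_sd,
                 noise_sd = noise_sd, dmp_fraction = dmp_fraction,
                 drift_magnitude = drift_magnitude,
                 drift_onset = drift_onset,
                 hypo_fraction = hypo_fraction),
            class = "PlantedTruthConfig")
}

#' Simulate a methylation time-series dataset with known ground truth
#'
#' Builds, per probe and sample, an M-scale signal
#' `mesor + subject intercept + A * cos(2*pi*(clock - acrophase)/24) * mask +
#' drift + noise` and maps it through the logistic function to beta scale.
#' The rhythm mask depends on the planted class and the sample's physical
#' condition: "same" probes oscillate throughout, "loss" only during
#' baseline, "gain" only during sleep deprivation, and "change" probes
#' oscillate throughout with a shifted acrophase under sleep deprivation.
#' A signed drift (hypomethylating with probability `hypo_fraction`) ramps in
#' at samples with >= `drift_onset` hours of continual wakefulness,
#' emulating the late-wakefulness methylation change.
#'
#' @param n_probes number of probes to simulate.
#' @param design a [studyDesign()].
#' @param truth a [planTruth()] configuration.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return list of class `"SyntheticDataset"` with elements
#'   \describe{
#'     \item{`methyl`}{[MethylExperiment] on beta scale,}
#'     \item{`mvalues`}{the underlying M-scale matrix (same dimensions),}
#'     \item{`truth`}{`DataFrame` of per-probe planted parameters
#'       (`class`, `mesor`, `amplitude`, `acrophase_baseline`,
#'       `acrophase_sd`, `drift`),}
#'     \item{`design`, `seed`}{the inputs.}
#'   }
#' @examples
#' sim <- simulateMethylation(50, studyDesign(n_subjects = 3), seed = 1)
#' sim$methyl
#' @export
simulateMethylation <- function(n_probes, design = studyDesign(),
                                truth = planTruth(), seed = 1L) {
  .stopIfNot(n_probes >= 1, "n_probes must be >= 1")
  stopifnot(inherits(design, "StudyDesign"),
            inherits(truth, "PlantedTruthConfig"))
  set.seed(as.integer(seed))
  sheet <- simulateSampleSheet(design)
  n_samp <- nrow(sheet)

  cls <- sample(names(truth$class_proportions), n_probes, replace = TRUE,
                prob = truth$class_proportions)
  mesor <- stats::rnorm(n_probes, truth$mesor_mean, truth$mesor_sd)
  amp <- rep_len(truth$amplitude, n_probes)
  amp[cls == "arrhy"] <- 0
  acro <- stats::runif(n_probes, 0, 24)
  shift_sign <- sample(c(-1, 1), n_probes, replace = TRUE)
  acro_sd <- ifelse(cls == "change",
                    wrapClock(acro + shift_sign * truth$phase_shift), acro)
  drifting <- stats::runif(n_probes) < truth$dmp_fraction
  drift_sign <- ifelse(stats::runif(n_probes) < truth$hypo_fraction, -1, 1)
  drift <- ifelse(drifting, drift_sign * truth$drift_magnitude, 0)

  probe_id <- sprintf("cg%07d", seq_len(n_probes))
  subj_int <- stats::rnorm(design$n_subjects, 0, truth$subject_intercept_sd)
  names(subj_int) <- sprintf("S%02d", seq_len(design$n_subjects))

  is_sd <- sheet$condition == design$condition_labels[2L]
  w <- 2 * pi / 24
  # per-sample drift ramp: 0 before onset, linear up to 1 at the final sample
  ta <- sheet$time_awake
  ta[is.na(ta) | !is_sd] <- -Inf
  ta_max <- max(ta[is.finite(ta)], -Inf)
  onset <- truth$drift_onset
  ramp <- numeric(n_samp)
  if (is.finite(ta_max) && ta_max >= onset) {
    span <- ta_max - (onset - design$sampling_interval)
    sel <- ta >= onset
    ramp[sel] <- (ta[sel] - (onset - design$sampling_interval)) / span
  }

  # rhythm phase matrix: probes x samples. Planted classes are defined at
  # the level of the two overlapping 24-h analysis windows, so for loss and
  # gain probes the rhythm is silent in the samples shared by both windows
  # (otherwise "no rhythm in one window" would be unsatisfiable); change
  # probes switch phase at the physical condition boundary.
  win <- design$n_samples_per_subject %/% 2L + 1L
  n_idx <- design$n_samples_per_subject
  base_only <- sheet$sampling_index <= n_idx - win          # idx 1..7
  sd_only <- sheet$sampling_index > win                     # idx 10..16
  cos_base <- cos(w * outer(-acro, sheet$clock_time, "+"))  # cos(w(t - acro))
  cos_sd <- cos(w * outer(-acro_sd, sheet$clock_time, "+"))
  mask_base <- matrix(FALSE, n_probes, n_samp)
  mask_sd <- matrix(FALSE, n_probes, n_samp)
  mask_base[cls %in% c("same", "change"), ] <-
    rep(!is_sd, each = sum(cls %in% c("same", "change")))
  mask_sd[cls %in% c("same", "change"), ] <-
    rep(is_sd, each = sum(cls %in% c("same", "change")))
  mask_base[cls == "loss", ] <- rep(base_only, each = sum(cls == "loss"))
  mask_sd[cls == "gain", ] <- rep(sd_only, each = sum(cls == "gain"))
  rhythm <- amp * (cos_base * mask_base + cos_sd * mask_sd)

  m <- mesor + rhythm + outer(drift, ramp)
  m <- m + matrix(subj_int[sheet$subject_id], n_probes, n_samp, byrow = TRUE)
  if (any(truth$noise_sd > 0)) {
    # a vector noise_sd gives per-probe variances (recycled along rows)
    sd_vec <- rep_len(truth$noise_sd, n_probes)
    m <- m + matrix(stats::rnorm(n_probes * n_samp, 0, sd_vec),
                    n_probes, n_samp)
  }
  dimnames(m) <- list(probe_id, sheet$sample_id)
  beta <- mToBeta(m)

  truth_df <- DataFrame(probe_id = probe_id, class = cls, mesor = mesor,
                        amplitude = amp, acrophase_baseline = acro,
                        acrophase_sd = acro_sd, drift = drift,
                        row.names = probe_id)
  truth_df$acrophase_baseline[cls %in% c("arrhy", "gain")] <- NA_real_
  truth_df$acrophase_sd[cls %in% c("arrhy", "loss")] <- NA_real_

  structure(list(methyl = MethylExperiment(beta, sheet, scale = "beta"),
                 mvalues = m, truth = truth_df, design = design,
                 seed = as.integer(seed)),
            class = "SyntheticDataset")
}

#' Simulate diurnal white-blood-cell counts
#'
#' Generates counts (cells per microlitre) for the 8 leaf WBC populations
#' with log-scale sinusoidal diurnal rhythms plus lognormal noise, then sums
#' them into the 5 aggregate classes so the non-exclusive structure holds by
#' construction (`cd8_total = cd8_memory + cd8_naive`, etc.; see
#' [wbcClasses()]). Granulocytes peak in the evening and lymphocyte subsets
#' at night, the canonical human pattern. Optionally plants missing
#' timepoints (whole rows, all 13 classes) at interior sampling indices only,
#' never two consecutive, mirroring a study in which occasional timepoints
#' lacked a differential count.
#'
#' @param design a [studyDesign()].
#' @param n_subjects number of subjects with counts (may be fewer than the
#'   methylation cohort; the emulated study had counts for 10 of 15).
#' @param seed integer seed.
#' @param missing_rate probability in \[0,1) that a subject x interior
#'   timepoint row is missing.
#' @param noise_sd lognormal noise SD on the log-count scale.
#' @return a [CellCounts] object; missing rows hold `NA` with flags set.
#' @examples
#' cc <- simulateCellCounts(studyDesign(n_subjects = 3), n_subjects = 3,
#'                          seed = 1, missing_rate = 0)
#' head(cellCounts(cc))
#' @export
simulateCellCounts <- function(design = studyDesign(), n_subjects = 10L,
                               seed = 1L, missing_rate = 0.02,
                               noise_sd = 0.08) {
  .stopIfNot(missing_rate >= 0 && missing_rate < 1,
             "missing_rate must lie in [0,1)")
  set.seed(as.integer(seed) + 7L)
  np <- design$n_samples_per_subject
  subj <- sprintf("S%02d", seq_len(n_subjects))
  idx <- seq_len(np)
  clock <- wrapClock(design$start_clock_time + (idx - 1) * design$sampling_interval)

  # leaf populations: mesor (cells/ul), relative log-amplitude, acrophase (h)
  leaves <- data.frame(
    class = c("granulocytes", "monocytes", "b_total", "nk_dendritic",
              "cd4_memory", "cd4_naive", "cd8_memory", "cd8_naive"),
    mesor = c(3800, 450, 250, 350, 500, 450, 220, 180),
    relamp = c(0.15, 0.12, 0.20, 0.18, 0.22, 0.22, 0.20, 0.20),
    acro = c(19, 21, 2, 1, 1.5, 2, 1, 1.5))

  w <- 2 * pi / 24
  grid <- expand.grid(sampling_index = idx, subject_id = subj,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$subject_id, grid$sampling_index), , drop = FALSE]
  grid$clock_time <- clock[grid$sampling_index]
  n <- nrow(grid)
  leafmat <- sapply(seq_len(nrow(leaves)), function(k) {
    lf <- leaves[k, ]
    lf$mesor * exp(lf$relamp * cos(w * (grid$clock_time - lf$acro)) +
                     stats::rnorm(n, 0, noise_sd))
  })
  colnames(leafmat) <- leaves$class
  out <- data.frame(grid, leafmat, check.names = FALSE)
  out$cd4_total <- out$cd4_memory + out$cd4_naive
  out$cd8_total <- out$cd8_memory + out$cd8_naive
  out$t_total <- out$cd4_total + out$cd8_total
  out$lymphocytes <- out$t_total + out$b_total + out$nk_dendritic
  out$wbc_total <- out$granulocytes + out$lymphocytes + out$monocytes
  out <- out[, c("subject_id", "sampling_index", "clock_time", wbcClasses())]

  if (missing_rate > 0 && np > 2) {
    for (s in subj) {
      rows <- which(out$subject_id == s)
      interior <- rows[-c(1L, length(rows))]
      cand <- interior[stats::runif(length(interior)) < missing_rate]
      # drop any candidate adjacent to an already-chosen one
      keep <- c()
      for (r in cand)
        if (!any(abs(keep - r) == 1L)) keep <- c(keep, r)
      if (length(keep)) out[keep, wbcClasses()] <- NA_real_
    }
  }
  rownames(out) <- NULL
  CellCounts(out)
}

#' Write a synthetic dataset to delimited text files
#'
#' @param sim a `"SyntheticDataset"` from [simulateMethylation()].
#' @param dir output directory (created if needed).
#' @param cellcounts optional [CellCounts] to write alongside.
#' @return invisibly, the named vector of file paths written.
#' @export
writeSyntheticDataset <- function(sim, dir, cellcounts = NULL) {
  stopifnot(inherits(sim, "SyntheticDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "beta_matrix.tsv"),
             sheet = file.path(dir, "sample_sheet.csv"),
             truth = file.path(dir, "truth.tsv"))
  writeMethylMatrix(sim$methyl, paths[["matrix"]])
  data.table::fwrite(as.data.frame(sampleSheet(sim$methyl)), paths[["sheet"]])
  data.table::fwrite(as.data.frame(sim$truth), paths[["truth"]], sep = "\t")
  if (!is.null(cellcounts)) {
    paths <- c(paths, cellcounts = file.path(dir, "cell_counts.csv"))
    data.table::fwrite(cellCounts(cellcounts), paths[["cellcounts"]])
  }
  invisible(paths)
}
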