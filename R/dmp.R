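#' Matched-clock-time paired differences
#'
#' Pairs each sleep-deprivation sample with the baseline sample taken at the
#' same clock time 24 h earlier, per subject, and returns one probes x
#' subjects difference matrix per clock-time pair
#' (`delta = sleep deprivation - baseline`). With the default 16-sample,
#' 3-h design this yields eight pairs with cumulative time awake 8, 11, ...,
#' 29 h. Subjects missing either member of a pair are dropped from that pair
#' with a warning.
#'
#' @param x a [MethylExperiment] holding the full series (values on the
#'   scale differences should be computed on — normally unstandardized).
#' @param conditions length-2 condition labels, baseline first.
#' @return list of class `"PairedDifferences"`: per pair a list with
#'   `delta` (matrix), `clock_time`, `baseline_index`, `sd_index`,
#'   `time_awake`.
#' @examples
#' sim <- simulateMethylation(10, studyDesign(n_subjects = 3), seed = 1)
#' pd <- pairedDifferences(sim$methyl)
#' vapply(pd, `[[`, 0, "time_awake")
#' @export
pairedDifferences <- function(x, conditions = c("baseline",
                                                "sleep_deprivation")) {
  stopifnot(is(x, "MethylExperiment"))
  cd <- as.data.frame(sampleSheet(x))
  .stopIfNot(all(conditions %in% cd$condition),
             "both condition labels must appear in the sample sheet")
  m <- methValues(x)
  base <- cd[cd$condition == conditions[1L], ]
  sdep <- cd[cd$condition == conditions[2L], ]
  pairs <- list()
  for (bi in sort(unique(base$sampling_index))) {
    clock <- base$clock_time[base$sampling_index == bi][1L]
    si_all <- unique(sdep$sampling_index[abs(clockDiff(sdep$clock_time,
                                                       clock)) < 1e-8])
    if (!length(si_all)) next
    si <- min(si_all)
    b_rows <- base[base$sampling_index == bi, ]
    s_rows <- sdep[sdep$sampling_index == si, ]
    subj <- intersect(b_rows$subject_id, s_rows$subject_id)
    dropped <- setdiff(union(b_rows$subject_id, s_rows$subject_id), subj)
    if (length(dropped))
      warning("pair ", bi, "/", si, ": dropping subject(s) ",
              paste(dropped, collapse = ", "), " missing one member")
    if (!length(subj)) next
    bcol <- b_rows$sample_id[match(subj, b_rows$subject_id)]
    scol <- s_rows$sample_id[match(subj, s_rows$subject_id)]
    delta <- m[, scol, drop = FALSE] - m[, bcol, drop = FALSE]
    colnames(delta) <- subj
    ta <- s_rows$time_awake[match(subj, s_rows$subject_id)][1L]
    pairs[[sprintf("pair_%02d_%02d", bi, si)]] <-
      list(delta = delta, clock_time = clock, baseline_index = bi,
           sd_index = si, time_awake = ta)
  }
  if (!length(pairs)) stop("no matched clock-time pairs found")
  structure(pairs, class = "PairedDifferences")
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Method-of-moments fit of the scaled-F model for probe-level sample
#' variances (`s^2 ~ s0^2 * F(df, d0)`) on the log scale, the closed-form
#' route to the prior degrees of freedom `d0` and prior variance `s0^2`
#' that a moderated t-test shrinks toward. If the moment estimate of the
#' excess log-variance spread is non-positive, the variances are consistent
#' with a common value and `d0 = Inf` (complete pooling) is returned with a
#' warning.
#'
#' @param variances per-probe sample variances (length >= 10).
#' @param df residual degrees of freedom of each variance (scalar).
#' @return list of class `"EBayesHyperparams"`: `d0`, `s0sq`, `df`.
#' @export
fitEBayes <- function(variances, df) {
  v <- variances[is.finite(variances) & variances > 0]
  .stopIfNot(length(v) >= 10, "need >= 10 positive variances")
  if (length(v) < length(variances) &&
      all(variances[is.finite(variances)] == 0))
    stop("all variances are zero")
  z <- log(v)
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- stats::var(z)
  excess <- ev - trigamma(df / 2)
  if (excess <= 0) {
    warning("log-variances no more dispersed than chi-square sampling noise; ",
            "using d0 = Inf (complete pooling)")
    d0 <- Inf
    s0sq <- exp(mean(e))
  } else {
    d0 <- 2 * .trigammaInverse(excess)
    s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0sq = s0sq, df = df),
            class = "EBayesHyperparams")
}

# Newton solve of trigamma(x) = y, y > 0
.trigammaInverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Moderated one-sample t-test on paired differences
#'
#' For each probe, shrinks the sample variance of the paired differences
#' toward the ensemble prior, `s_tilde^2 = (d0*s0^2 + d*s^2)/(d0 + d)`, and
#' tests the mean difference with `t = mean / (s_tilde/sqrt(n))` on
#' `d0 + d` degrees of freedom (two-sided p). Direction is `hypo` when the
#' mean difference is negative (less methylated after sleep deprivation),
#' `hyper` otherwise.
#'
#' @param delta probes x subjects matrix of paired differences.
#' @param hyper an `"EBayesHyperparams"` from [fitEBayes()], or `NULL` to
#'   estimate it from `delta` itself. Pass `d0 = 0` via
#'   `list(d0 = 0, s0sq = NA)` for the ordinary (unmoderated) paired t.
#' @param pair optional metadata (list with `baseline_index`, `sd_index`,
#'   `time_awake`) copied into the output.
#' @return `DataFrame`: `probe_id`, `delta_mean`, `s2`, `s2_post`, `t`,
#'   `df_total`, `p`, `q` (BH across probes), `direction`.
#' @export
moderatedT <- function(delta, hyper = NULL, pair = NULL) {
  delta <- as.matrix(delta)
  n <- ncol(delta)
  .stopIfNot(n >= 2, "need >= 2 subjects per pair")
  d <- n - 1
  mu <- rowMeans(delta)
  s2 <- rowSums((delta - mu)^2) / d
  if (is.null(hyper)) hyper <- fitEBayes(s2, d)
  d0 <- hyper$d0
  s2_post <- if (is.infinite(d0)) rep(hyper$s0sq, length(s2))
  else if (d0 == 0) s2
  else (d0 * hyper$s0sq + d * s2) / (d0 + d)
  tt <- mu / sqrt(s2_post / n)
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tt), df = df_total)
  DataFrame(probe_id = rownames(delta), delta_mean = unname(mu),
            s2 = unname(s2), s2_post = unname(s2_post), t = unname(tt),
            df_total = df_total, p = unname(p), q = unname(bhAdjust(p)),
            direction = unname(ifelse(mu < 0, "hypo", "hyper")),
            baseline_index = if (is.null(pair)) NA_integer_ else pair$baseline_index,
            sd_index = if (is.null(pair)) NA_integer_ else pair$sd_index,
            time_awake = if (is.null(pair)) NA_real_ else pair$time_awake,
            row.names = rownames(delta))
}

#' Joint moderated F test across all clock-time pairs
#'
#' Pools the residual variance per probe across the pairs, shrinks it with
#' empirical-Bayes hyperparameters estimated on the pooled variances, and
#' tests all pair mean differences jointly:
#' `F = mean_p(n_p * delta_bar_p^2) / s_tilde^2` referred to
#' `F(n_pairs, d0 + d)` with `d` the pooled residual degrees of freedom.
#' With a single pair this reduces to the squared moderated t.
#'
#' @param pd a `"PairedDifferences"` from [pairedDifferences()].
#' @param hyper optional `"EBayesHyperparams"` (estimated from the pooled
#'   variances when `NULL`).
#' @return `DataFrame`: `probe_id`, `f`, `df1`, `df2`, `p`, `q`.
#' @export
moderatedF <- function(pd, hyper = NULL) {
  stopifnot(inherits(pd, "PairedDifferences"))
  k <- length(pd)
  probes <- rownames(pd[[1L]]$delta)
  ssq <- numeric(length(probes))
  msq <- numeric(length(probes))
  dtot <- 0
  for (p in pd) {
    n <- ncol(p$delta)
    mu <- rowMeans(p$delta)
    ssq <- ssq + rowSums((p$delta - mu)^2)
    msq <- msq + n * mu^2
    dtot <- dtot + (n - 1)
  }
  s2 <- ssq / dtot
  if (is.null(hyper)) hyper <- fitEBayes(s2, dtot)
  d0 <- hyper$d0
  s2_post <- if (is.infinite(d0)) rep(hyper$s0sq, length(s2))
  else if (d0 == 0) s2
  else (d0 * hyper$s0sq + dtot * s2) / (d0 + dtot)
  f <- (msq / k) / s2_post
  df2 <- d0 + dtot
  pv <- stats::pf(f, k, df2, lower.tail = FALSE)
  DataFrame(probe_id = probes, f = unname(f), df1 = k, df2 = df2,
            p = unname(pv), q = unname(bhAdjust(pv)), row.names = probes)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values), monotone in p and invariant to
#' input order.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return q-values, same length and order as `p`.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.04, 0.05))
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Default DMP p-value threshold grid
#'
#' `5e-8` (genome-wide) through `5e-2` by decades, the grid used for
#' accumulating differentially-methylated-position counts per timepoint.
#' @return numeric vector of 7 thresholds.
#' @export
dmpThresholds <- function() 5 * 10^(-(8:2))

#' Count DMPs over a p-value threshold grid
#'
#' For each clock-time pair, counts records with `p` below each threshold
#' (unadjusted p, as in the accumulating-count presentation), splits
#' hypo/hypermethylated calls at the headline threshold, and reports the
#' expected count under the null (`threshold x probes tested`).
#'
#' @param records list of [moderatedT()] results, one per pair.
#' @param thresholds p-value grid, ascending.
#' @param headline threshold at which the hypo/hyper split is reported.
#' @return list with `counts` (pairs x thresholds matrix), `expected`
#'   (named numeric), `direction` (`data.frame`: pair, time_awake, n_hypo,
#'   n_hyper, hypo_share), `n_probes`.
#' @export
countDmps <- function(records, thresholds = dmpThresholds(),
                      headline = 5e-4) {
  .stopIfNot(length(records) >= 1, "no records")
  thresholds <- sort(thresholds)
  n_probes <- nrow(records[[1L]])
  cnt <- t(vapply(records, function(r)
    vapply(thresholds, function(th) sum(r$p < th), 0), numeric(length(thresholds))))
  colnames(cnt) <- formatC(thresholds, format = "e", digits = 0)
  rownames(cnt) <- names(records)
  dir <- do.call(rbind, lapply(seq_along(records), function(i) {
    r <- records[[i]]
    sig <- r$p < headline
    nh <- sum(sig & r$direction == "hypo")
    ny <- sum(sig & r$direction == "hyper")
    data.frame(pair = names(records)[i],
               time_awake = r$time_awake[1L],
               n_hypo = nh, n_hyper = ny,
               hypo_share = if (nh + ny > 0) nh / (nh + ny) else NA_real_)
  }))
  list(counts = cnt,
       expected = stats::setNames(thresholds * n_probes, colnames(cnt)),
       direction = dir, n_probes = n_probes, headline = headline)
}

#' Select the top-N DMPs of a pair and map them to genes
#'
#' `selectTopDmps` ranks by ascending p, breaking ties by larger absolute
#' mean difference and then probe ID. `mapToGenes` resolves probes through
#' a probe-to-gene manifest, reporting unmapped probes and gene
#' multiplicities.
#'
#' @param records a [moderatedT()] result.
#' @param n number of probes to select.
#' @return `selectTopDmps`: character vector of probe IDs.
#' @export
selectTopDmps <- function(records, n = 1000L) {
  if (n == 0L) return(character(0))
  if (n > nrow(records)) {
    warning("requested ", n, " DMPs but only ", nrow(records),
            " records; returning all")
    n <- nrow(records)
  }
  ord <- order(records$p, -abs(records$delta_mean), records$probe_id)
  records$probe_id[ord][seq_len(n)]
}

#' @rdname selectTopDmps
#' @param probes character vector of probe IDs.
#' @param manifest `data.frame` with `probe_id`, `gene` (see
#'   [readGeneManifest()]).
#' @return `mapToGenes`: list with `genes` (unique gene symbols),
#'   `unmapped` (probes absent from the manifest), `multiplicity` (table of
#'   probes per gene).
#' @export
mapToGenes <- function(probes, manifest) {
  hit <- manifest[manifest$probe_id %in% probes, , drop = FALSE]
  unmapped <- setdiff(probes, manifest$probe_id)
  if (length(unmapped))
    message(length(unmapped), " probe(s) not covered by the manifest")
  list(genes = sort(unique(hit$gene)), unmapped = unmapped,
       multiplicity = sort(table(hit$gene), decreasing = TRUE))
}

#' Gene-set over-representation by one-sided Fisher's exact test
#'
#' For each gene set, builds the 2x2 membership table of the query list
#' against the universe and computes the hypergeometric upper-tail p-value
#' (equivalently one-sided Fisher) and the sample odds ratio, BH-adjusted
#' across sets.
#'
#' @param genes query gene list (character).
#' @param gene_sets named list of character vectors (see [readGmt()]).
#' @param universe background gene universe; must contain `genes`.
#' @return `data.frame`: set, n_set, n_overlap, odds_ratio, p, q, ordered by
#'   ascending p.
#' @examples
#' sets <- list(a = c("G1", "G2"), b = c("G3", "G4", "G5"))
#' overrepresentationTest(c("G1", "G2", "G9"), sets, paste0("G", 1:20))
#' @export
overrepresentationTest <- function(genes, gene_sets, universe) {
  .stopIfNot(length(universe) > 0, "empty universe")
  .stopIfNot(length(gene_sets) > 0, "no gene sets")
  universe <- unique(universe)
  genes <- unique(genes)
  if (!all(genes %in% universe))
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(genes, universe), 5), collapse = ", "))
  N <- length(universe)
  klist <- length(genes)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    mset <- length(set)
    q <- length(intersect(genes, set))
    p <- stats::phyper(q - 1, mset, N - mset, klist, lower.tail = FALSE)
    a <- q; b <- klist - q; cc <- mset - q; dd <- N - mset - klist + q
    orat <- (a * dd) / max(b * cc, .Machine$double.eps)
    data.frame(set = nm, n_set = mset, n_overlap = q, odds_ratio = orat,
               p = p)
  })
  out <- do.call(rbind, res)
  out$q <- bhAdjust(out$p)
  out[order(out$p, out$set), , drop = FALSE]
}
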