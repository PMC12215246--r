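test_that("imputation takes the midpoint of adjacent timepoints", {
  des <- studyDesign(n_subjects = 2)
  cc <- simulateCellCounts(des, n_subjects = 2, seed = 1, missing_rate = 0)
  df <- cellCounts(cc)
  # plant one gap and check the midpoint rule on every class
  row <- which(df$subject_id == "S01" & df$sampling_index == 5)
  before <- df
  df[row, wbcClasses()] <- NA_real_
  imp <- imputeMissingCounts(CellCounts(df))
  dfi <- cellCounts(imp)
  up <- which(df$subject_id == "S01" & df$sampling_index == 4)
  dn <- which(df$subject_id == "S01" & df$sampling_index == 6)
  for (cl in wbcClasses())
    expect_equal(dfi[row, cl], (df[up, cl] + df[dn, cl]) / 2)
  expect_true(all(imputedFlags(imp)[row, ]))
  # all non-missing entries preserved bit-exactly
  keep <- setdiff(seq_len(nrow(df)), row)
  expect_identical(dfi[keep, wbcClasses()], before[keep, wbcClasses()])
})

test_that("imputation with no gaps is the identity", {
  cc <- simulateCellCounts(studyDesign(n_subjects = 2), n_subjects = 2,
                           seed = 2, missing_rate = 0)
  imp <- imputeMissingCounts(cc)
  expect_identical(cellCounts(imp), cellCounts(cc))
  expect_equal(sum(imputedFlags(imp)), 0L)
})

test_that("random interior gaps match a brute-force neighbor-mean oracle", {
  set.seed(3)
  for (rep_i in 1:5) {
    cc <- simulateCellCounts(studyDesign(n_subjects = 4), n_subjects = 4,
                             seed = rep_i + 10, missing_rate = 0.15)
    df <- cellCounts(cc)
    imp <- cellCounts(imputeMissingCounts(cc))
    for (s in unique(df$subject_id)) {
      rows <- which(df$subject_id == s)
      rows <- rows[order(df$sampling_index[rows])]
      for (cl in wbcClasses()) {
        v <- df[rows, cl]
        nas <- which(is.na(v))
        for (j in nas)
          expect_equal(imp[rows[j], cl], (v[j - 1] + v[j + 1]) / 2)
      }
    }
  }
})

test_that("boundary or consecutive gaps are rejected with positions listed", {
  cc <- simulateCellCounts(studyDesign(n_subjects = 1), n_subjects = 1,
                           seed = 4, missing_rate = 0)
  df <- cellCounts(cc)
  df[df$sampling_index == 1, wbcClasses()] <- NA_real_
  expect_error(imputeMissingCounts(CellCounts(df)), "sampling index 1")
  df2 <- cellCounts(cc)
  df2[df2$sampling_index %in% c(5, 6), wbcClasses()] <- NA_real_
  expect_error(imputeMissingCounts(CellCounts(df2)), "consecutive")
})

test_that("cell-count normalization divides by the matched count", {
  des <- studyDesign(n_subjects = 3)
  sim <- simulateMethylation(8, des, seed = 5)
  cc <- simulateCellCounts(des, n_subjects = 3, seed = 5, missing_rate = 0)
  df <- cellCounts(cc)
  # all-ones counts: identity
  df1 <- df
  df1[, wbcClasses()] <- 1
  norm1 <- normalizeByCellCount(sim$methyl, CellCounts(df1), "granulocytes")
  expect_equal(methValues(norm1), methValues(sim$methyl))

  # doubling one timepoint's count halves the normalized values there
  dfx <- df
  sel <- dfx$subject_id == "S02" & dfx$sampling_index == 7
  na <- normalizeByCellCount(sim$methyl, CellCounts(dfx), "monocytes")
  dfx$monocytes[sel] <- 2 * dfx$monocytes[sel]
  nb <- normalizeByCellCount(sim$methyl, CellCounts(dfx), "monocytes")
  col <- sampleSheet(sim$methyl)$subject_id == "S02" &
    sampleSheet(sim$methyl)$sampling_index == 7
  expect_equal(methValues(nb)[, col], methValues(na)[, col] / 2)
  expect_equal(methValues(nb)[, !col], methValues(na)[, !col])

  # normalization commutes with probe subsetting
  all13 <- normalizeByCellCount(sim$methyl, cc, "all")
  expect_length(all13, 13L)
  sub <- normalizeByCellCount(sim$methyl[1:3, ], cc, "b_total")
  expect_equal(methValues(sub), methValues(all13$b_total)[1:3, ])
})

test_that("the analytic null count follows alpha x probes x classes", {
  expect_equal(expectedNullCorrelations(correlationNullConfig()), 650)
  expect_equal(expectedNullCorrelations(correlationNullConfig(alpha = 0)), 0)
})

test_that("independent methylation and counts reject at the nominal rate", {
  des <- studyDesign(n_subjects = 10)
  rates <- sapply(1:25, function(s) {
    sim <- simulateMethylation(120, des, seed = s + 300)
    cc <- imputeMissingCounts(simulateCellCounts(des, n_subjects = 10,
                                                 seed = s + 700,
                                                 missing_rate = 0.02))
    r <- compositionCorrelation(sim$methyl, cc)
    c(rate = r$n_observed / r$n_tested, bh = r$n_bh_significant)
  })
  # mean rejection rate near alpha (class dependence inflates only variance)
  expect_lt(abs(mean(rates["rate", ]) - 0.05), 0.012)
  expect_lt(mean(rates["bh", ]), 1)
  # the total-WBC proportion is constant 1 and must be skipped
  sim <- simulateMethylation(50, des, seed = 999)
  cc <- imputeMissingCounts(simulateCellCounts(des, n_subjects = 10,
                                               seed = 999))
  r <- compositionCorrelation(sim$methyl, cc)
  expect_true(all(r$pairs$skipped[r$pairs$cell_class == "wbc_total"]))
  expect_equal(r$n_tested, 12 * 50)
})
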