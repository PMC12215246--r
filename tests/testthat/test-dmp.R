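test_that("paired differences match the matched-clock-time layout", {
  des <- studyDesign(n_subjects = 4)
  sim <- simulateMethylation(12, des, seed = 1)
  pd <- pairedDifferences(sim$methyl)
  expect_length(pd, 8L)
  expect_equal(unname(vapply(pd, `[[`, 0, "time_awake")), seq(8, 29, by = 3))
  # direct-subtraction oracle for one pair
  m <- methValues(sim$methyl)
  sh <- as.data.frame(sampleSheet(sim$methyl))
  p3 <- pd[[3]]
  for (s in colnames(p3$delta)) {
    b <- sh$sample_id[sh$subject_id == s & sh$sampling_index == p3$baseline_index]
    d <- sh$sample_id[sh$subject_id == s & sh$sampling_index == p3$sd_index]
    expect_equal(p3$delta[, s], m[, d] - m[, b])
  }
  # a dropped sample drops only that subject from that pair
  sub <- sim$methyl[, -which(colnames(sim$methyl) == "S02_T11")]
  expect_warning(pd2 <- pairedDifferences(sub), "S02")
  expect_equal(ncol(pd2[[3]]$delta), 3L)
  expect_equal(ncol(pd2[[4]]$delta), 4L)
})

test_that("identical windows give all-zero differences", {
  des <- studyDesign(n_subjects = 3)
  sheet <- simulateSampleSheet(des)
  m <- matrix(runif(5 * 8), 5, 8)
  vals <- cbind(m, m)[, order(rep(1:16, times = 1))]
  # build a matrix whose SD half repeats the baseline half per subject
  vals <- matrix(0, 5, nrow(sheet), dimnames = list(sprintf("cg%d", 1:5),
                                                    sheet$sample_id))
  for (s in unique(sheet$subject_id)) {
    block <- matrix(runif(5 * 8), 5, 8)
    vals[, sheet$subject_id == s] <- cbind(block, block)
  }
  me <- MethylExperiment(vals, sheet, scale = "beta")
  pd <- pairedDifferences(me)
  expect_true(all(vapply(pd, function(p) max(abs(p$delta)), 0) == 0))
})

test_that("moderated t reduces to the ordinary paired t when d0 = 0", {
  set.seed(2)
  delta <- matrix(rnorm(200 * 15, 0, 0.2), 200,
                  dimnames = list(sprintf("p%03d", 1:200), NULL))
  mt <- moderatedT(delta, hyper = list(d0 = 0, s0sq = NA))
  for (i in c(1, 57, 200)) {
    tt <- t.test(delta[i, ])
    expect_equal(mt$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(mt$p[i], tt$p.value, tolerance = 1e-10)
  }
  # full-shrinkage limit: every probe uses the pooled prior variance
  mtInf <- moderatedT(delta, hyper = list(d0 = Inf, s0sq = 0.04))
  expect_equal(unique(mtInf$s2_post), 0.04)
})

test_that("hyperparameter estimation matches the scaled-F moment solution", {
  skip_if_not_installed("limma")
  set.seed(3)
  d <- 14
  s2 <- 0.04 * rf(4000, d, 8)
  h <- fitEBayes(s2, d)
  sq <- limma::squeezeVar(s2, d)
  expect_equal(h$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(h$s0sq, sq$var.prior, tolerance = 1e-6)
  post <- (h$d0 * h$s0sq + d * s2) / (h$d0 + d)
  expect_equal(post, sq$var.post, tolerance = 1e-8)
  # equal variances collapse to complete pooling
  expect_warning(hInf <- fitEBayes(rep(0.1, 50) * rchisq(50, 1e6) / 1e6, 99),
                 "pooling")
  expect_true(is.infinite(hInf$d0))
})

test_that("the moderated t is calibrated on null data", {
  set.seed(4)
  sds <- sqrt(0.02 * rf(5000, 30, 12))   # heterogeneous probe variances
  delta <- matrix(rnorm(5000 * 15, 0, sds), 5000,
                  dimnames = list(sprintf("p%04d", 1:5000), NULL))
  mt <- moderatedT(delta)
  expect_gt(mean(mt$p < 0.05), 0.040)
  expect_lt(mean(mt$p < 0.05), 0.060)
  expect_gt(stats::ks.test(mt$p, "punif")$p.value, 0.01)
  expect_true(all(mt$q >= mt$p - 1e-12))
  expect_equal(mt$direction, ifelse(mt$delta_mean < 0, "hypo", "hyper"))
})

test_that("the moderated F equals t^2 for one pair and detects late effects", {
  set.seed(5)
  n <- 15; P <- 600; sig <- 0.2
  mk <- function(effect) {
    pd <- lapply(1:8, function(i) {
      d <- matrix(rnorm(P * n, 0, sig), P,
                  dimnames = list(sprintf("p%03d", 1:P), NULL))
      if (i >= 7) d <- d + effect
      list(delta = d, baseline_index = i, sd_index = i + 8,
           time_awake = 5 + 3 * i, clock_time = 0)
    })
    names(pd) <- sprintf("pair_%02d_%02d", 1:8, 9:16)
    structure(pd, class = "PairedDifferences")
  }
  one <- mk(0)[1]
  class(one) <- "PairedDifferences"
  suppressWarnings({
    f1 <- moderatedF(one)
    t1 <- moderatedT(one[[1]]$delta, fitEBayes(
      rowSums((one[[1]]$delta - rowMeans(one[[1]]$delta))^2) / (n - 1),
      n - 1))
  })
  expect_equal(f1$f, t1$t^2, tolerance = 1e-9)

  suppressWarnings(f0 <- moderatedF(mk(0)))
  expect_gt(stats::ks.test(f0$p, "punif")$p.value, 0.01)

  suppressWarnings({
    fa <- moderatedF(mk(0.12))
    single <- sapply(1:8, function(i) {
      p <- mk(0.12)[[i]]
      mean(moderatedT(p$delta)$p < 0.05)
    })
  })
  # the joint F beats the average per-pair power when the effect is late
  expect_gt(mean(fa$p < 0.05), mean(single))
})

test_that("BH adjustment matches a direct step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(rep(0.2, 6)), rep(0.2, 6))
  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(3:200, 1))
    q <- bhAdjust(p)
    expect_equal(q, bhOracle(p), tolerance = 1e-12)
    # order invariance and monotonicity
    o <- sample(length(p))
    expect_equal(bhAdjust(p[o]), q[o])
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bhAdjust(c(0.2, 1.4)), "0,1")
})

test_that("DMP counting over the threshold grid is monotone and splits direction", {
  rec <- S4Vectors::DataFrame(probe_id = sprintf("p%02d", 1:10),
                              p = c(1e-9, 4e-7, 2e-6, 3e-5, 2e-3, 1e-3,
                                    2e-2, 0.2, 0.6, 0.9),
                              delta_mean = c(-1, -1, -1, 1, -1, 1, -1, 1,
                                             -1, 1),
                              time_awake = 29)
  rec$direction <- ifelse(rec$delta_mean < 0, "hypo", "hyper")
  grid <- countDmps(list(pair_08 = rec))
  expect_equal(unname(grid$counts[1, ]), c(1, 2, 3, 4, 4, 6, 7))
  expect_true(all(diff(grid$counts[1, ]) >= 0))
  expect_equal(grid$expected[["5e-04"]], 5e-4 * 10)
  # direction split at the headline threshold 5e-4: p < 5e-4 keeps 4 records
  expect_equal(grid$direction$n_hypo, 3)
  expect_equal(grid$direction$n_hyper, 1)
  expect_equal(grid$direction$hypo_share, 0.75)
  empty <- countDmps(list(pair_08 = rec[rec$p > 2, ]))
  expect_true(all(empty$counts == 0))
})

test_that("top-DMP selection and gene mapping follow the tie rules", {
  rec <- S4Vectors::DataFrame(probe_id = c("a", "b", "c", "d"),
                              p = c(0.01, 0.005, 0.01, 0.5),
                              delta_mean = c(0.5, 0.1, -0.9, 0))
  expect_equal(selectTopDmps(rec, 0), character(0))
  expect_equal(selectTopDmps(rec, 3), c("b", "c", "a"))
  expect_warning(all4 <- selectTopDmps(rec, 9), "only 4")
  expect_length(all4, 4L)

  manifest <- data.frame(probe_id = c("a", "b", "c", "x", "y"),
                         gene = c("G1", "G1", "G2", "G3", "G3"))
  mp <- mapToGenes(c("a", "b", "c", "d"), manifest)
  expect_equal(mp$genes, c("G1", "G2"))
  expect_equal(mp$unmapped, "d")
  expect_equal(unname(mp$multiplicity["G1"]), 2L)
})

test_that("over-representation matches the hypergeometric tail", {
  universe <- sprintf("G%03d", 1:500)
  sets <- list(hit = universe[1:30], other = universe[101:160])
  genes <- c(universe[1:6], universe[201:215])
  res <- overrepresentationTest(genes, sets, universe)
  hit <- res[res$set == "hit", ]
  expect_equal(hit$p,
               phyper(5, 30, 470, length(genes), lower.tail = FALSE),
               tolerance = 1e-12)
  ft <- fisher.test(matrix(c(6, 15, 24, 455), 2), alternative = "greater")
  expect_equal(hit$p, ft$p.value, tolerance = 1e-9)
  # perfect overlap is the most significant possible
  res2 <- overrepresentationTest(universe[1:30], sets, universe)
  expect_equal(res2$set[1], "hit")
  expect_lt(res2$p[1], 1e-20)
  # null simulation: p uniform-ish for random draws
  set.seed(7)
  ps <- replicate(300, {
    g <- sample(universe, 20)
    overrepresentationTest(g, sets["hit"], universe)$p
  })
  # hypergeometric p is discrete, hence conservative: valid, never inflated
  for (thr in c(0.05, 0.25))
    expect_lte(mean(ps < thr), thr + 3 * sqrt(thr * (1 - thr) / 300))
  expect_error(overrepresentationTest("G001", sets, character(0)), "universe")
})
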