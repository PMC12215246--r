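test_that("candidate-model RSS values respect nesting and match an OLS oracle", {
  set.seed(20)
  t9 <- seq(15, 39, by = 3) %% 24
  times <- rep(t9, times = 2 * 5)          # 5 replicates per window
  cond <- rep(c(FALSE, TRUE), each = 45)
  y <- matrix(rnorm(30 * 90), 30, dimnames = list(sprintf("p%02d", 1:30),
                                                  NULL))
  f <- fitCandidateModels(y, times, cond)
  # the full model is nested above every other
  expect_true(all(f$rss[, "change"] <= f$rss + 1e-10))
  expect_equal(f$k, c(arrhy = 2L, same = 4L, loss = 4L, gain = 4L,
                      change = 6L))

  # independent lm() oracle on explicit design matrices
  w <- 2 * pi / 24
  d <- data.frame(g = factor(cond), c = cos(w * times), s = sin(w * times))
  for (i in c(1, 17)) {
    yy <- y[i, ]
    oracle <- c(
      arrhy = sum(resid(lm(yy ~ 0 + g, d))^2),
      same = sum(resid(lm(yy ~ 0 + g + c + s, d))^2),
      loss = sum(resid(lm(yy ~ 0 + g + I(c * (g == FALSE)) +
                            I(s * (g == FALSE)), d))^2),
      gain = sum(resid(lm(yy ~ 0 + g + I(c * (g == TRUE)) +
                            I(s * (g == TRUE)), d))^2),
      change = sum(resid(lm(yy ~ 0 + g + g:c + g:s, d))^2))
    expect_equal(unname(f$rss[i, ]), unname(oracle), tolerance = 1e-8)
  }

  # noiseless shared rhythm: same and change fit exactly, arrhy does not
  ye <- rbind(p = 0.7 * cos(w * (times - 5)))
  fe <- fitCandidateModels(ye, times, cond)
  expect_lt(fe$rss[, "same"], 1e-18)
  expect_lt(fe$rss[, "change"], 1e-18)
  expect_gt(fe$rss[, "arrhy"], 1)
})

test_that("Akaike weights follow the softmax formula and sum to one", {
  expect_equal(unname(akaikeWeights(rep(10, 5))), rep(0.2, 5))
  w <- akaikeWeights(c(0, 2))
  expect_equal(unname(w), c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_equal(unname(akaikeWeights(c(5, Inf, Inf))), c(1, 0, 0))
  # exact fits take all weight; parsimony breaks exact-fit ties
  expect_equal(unname(akaikeWeights(c(-Inf, 3, -Inf), k = c(6, 2, 4))),
               c(0, 0, 1))
  set.seed(21)
  for (i in 1:25) {
    ic <- rnorm(5, sd = 10^runif(1, 0, 3))
    expect_equal(sum(akaikeWeights(ic)), 1, tolerance = 1e-9)
  }
})

test_that("identical strong rhythms in both windows classify as same", {
  des <- studyDesign(n_subjects = 15)
  sim <- simulateMethylation(30, des,
                             onlyClass("same", amplitude = 1.25,
                                       noise_sd = 0.25, dmp_fraction = 0),
                             seed = 22)
  cl <- classifyRhythms(simWindows(sim))
  expect_true(mean(cl$class == "same") > 0.75)
  expect_false(any(cl$class %in% c("loss", "gain", "arrhy")))
  ok <- cl$class == "same"
  d <- ((cl$acrophase_baseline - cl$acrophase_sd + 12) %% 24) - 12
  expect_lt(max(abs(d[ok])), 1.5)
})

test_that("pure noise probes are not called rhythmic", {
  sim <- simulateMethylation(400, studyDesign(n_subjects = 15),
                             onlyClass("arrhy", dmp_fraction = 0),
                             seed = 23)
  cl <- classifyRhythms(simWindows(sim))
  expect_gt(mean(cl$class %in% c("arrhy", "unclassified")), 0.95)
  expect_gt(mean(cl$best_model == "arrhy"), 0.6)
})

test_that("zero-variance probes are flagged and assigned arrhy", {
  des <- studyDesign(n_subjects = 3)
  m <- matrix(0.5, 2, 48)
  m[2, ] <- runif(48)
  me <- toyMethyl(m, des)
  sw <- lapply(splitConditions(me), zscoreProbes)
  cl <- classifyRhythms(sw, classifierConfig(prefilter = FALSE))
  expect_true(cl$zero_variance[1])
  expect_equal(cl$class[1], "arrhy")
})

test_that("planted classes are recovered at high signal-to-noise", {
  des <- studyDesign(n_subjects = 15)
  recall <- sapply(c("same", "loss", "gain", "change"), function(k) {
    sim <- simulateMethylation(300, des,
                               onlyClass(k, amplitude = 1.25,
                                         noise_sd = 0.25,
                                         dmp_fraction = 0),
                               seed = 24)
    cl <- classifyRhythms(simWindows(sim))
    mean(cl$class == k)
  })
  # operating characteristics of AIC selection with the 0.6 weight cutoff:
  # the nesting "change" model absorbs ~chi2(2) of noise at a fixed penalty,
  # capping loss/gain recovery well below 1 at any signal strength
  expect_gt(recall[["same"]], 0.80)
  expect_gt(recall[["loss"]], 0.70)
  expect_gt(recall[["gain"]], 0.70)
  expect_gt(recall[["change"]], 0.90)
})

test_that("swapping condition labels exchanges loss and gain only", {
  sim <- simulateMethylation(300, studyDesign(n_subjects = 8), seed = 25)
  zw <- simWindows(sim)
  cl_fwd <- classifyRhythms(zw)
  cl_rev <- classifyRhythms(rev(zw))
  map <- c(arrhy = "arrhy", same = "same", loss = "gain", gain = "loss",
           change = "change", unclassified = "unclassified")
  expect_equal(unname(map[cl_fwd$class]), cl_rev$class)
})

test_that("raising the weight cutoff never classifies an unclassified probe", {
  sim <- simulateMethylation(250, studyDesign(n_subjects = 6), seed = 26)
  zw <- simWindows(sim)
  lo <- classifyRhythms(zw, classifierConfig(weight_cutoff = 0.5,
                                             prefilter = FALSE))
  hi <- classifyRhythms(zw, classifierConfig(weight_cutoff = 0.8,
                                             prefilter = FALSE))
  moved <- lo$class == "unclassified" & hi$class != "unclassified"
  expect_equal(sum(moved), 0L)
  # and the classified set at the high cutoff is a subset
  expect_true(all(hi$class[hi$class != "unclassified"] ==
                    lo$class[hi$class != "unclassified"]))
})

test_that("class summaries reproduce count bookkeeping", {
  s <- summarizeClasses(c(same = 79163, loss = 16077, gain = 15735,
                          change = 5144, arrhy = 107476,
                          unclassified = 594432))
  expect_equal(s$n_rhythmic, 116119)
  expect_equal(s$n_classifiable, 223595)
  expect_equal(s$n_rhythmic_both, 84307)
  tab <- s$table
  # percentages recomputed from counts agree to 0.1
  expect_equal(tab$pct_classifiable[tab$class == "same"], 35.4,
               tolerance = 0.1)
  expect_equal(tab$pct_all[tab$class == "not_classifiable"], 72.7,
               tolerance = 0.1)
  empty <- summarizeClasses(character(0))
  expect_equal(sum(empty$table$n), 0)
})
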