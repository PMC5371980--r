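test_that("AUC is 1 for separated scores, 0 for reversed, 0.5 for constant", {
  classes <- rep(c("d", "h"), each = 4)
  expect_equal(roc_curve(c(5, 6, 7, 8, 1, 2, 3, 4), classes, "d")$auc, 1)
  expect_equal(roc_curve(c(1, 2, 3, 4, 5, 6, 7, 8), classes, "d")$auc, 0)
  expect_equal(roc_curve(rep(2, 8), classes, "d")$auc, 0.5)
})

test_that("the tiny fixture reproduces its enumerated concordance and Youden point", {
  ds <- tiny_dataset()
  scores <- as.numeric(ds$values[, 1])
  r <- roc_curve(scores, ds$classes, "disease")
  expect_equal(r$auc, oracle_auc(scores, ds$classes, "disease"),
               tolerance = 1e-15)
  expect_equal(r$auc, 2 / 3, tolerance = 1e-15)

  best <- oracle_optimal_cutoff(scores, ds$classes, "disease")
  opt <- optimal_cutoff(r)
  expect_equal(unname(opt["cutoff"]), best$cutoff)  # 6: J ties, SP = 1 wins
  expect_equal(unname(opt["se"]), best$se)
  expect_equal(unname(opt["sp"]), best$sp)
  expect_equal(best$cutoff, 6)
})

test_that("trapezoidal AUC equals tie-corrected pairwise concordance on random data", {
  for (seed in 1:8) {
    n1 <- 5 + seed; n0 <- 20 - seed
    classes <- c(rep("case", n1), rep("ctrl", n0))
    scores <- withr::with_seed(seed, {
      s <- c(rnorm(n1, 1), rnorm(n0))
      if (seed %% 2 == 0) s <- round(s, 1)  # induce ties
      s
    })
    r <- roc_curve(scores, classes, "case")
    expect_equal(r$auc, oracle_auc(scores, classes, "case"),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC and is invariant under monotone score transforms", {
  skip_if_not_installed("pROC")
  ds <- random_dataset(seed = 61)
  scores <- combo_score(ds, c("m1", "m2"), method = "glm")
  r <- roc_curve(scores, ds$classes, "case")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = ds$classes, predictor = scores, levels = c("ctrl", "case"),
    direction = "<", quiet = TRUE)))
  expect_equal(r$auc, ref, tolerance = 1e-12)

  for (f in list(function(x) 3 * x + 2, exp, function(x) x^3))
    expect_equal(roc_curve(f(scores), ds$classes, "case")$auc, r$auc,
                 tolerance = 1e-12)
})

test_that("ROC curves run from (0,0) to (1,1) with monotone coordinates", {
  for (seed in c(3, 14)) {
    ds <- random_dataset(seed = seed)
    # the full 6-marker GLM may hit separation; the linear-predictor
    # fallback warning is the documented behaviour and ordering still holds
    r <- roc_curve(suppressWarnings(combo_score(ds, ds$marker_names, "glm")),
                   ds$classes, "case")
    expect_equal(r$curve$fpr[1], 0)
    expect_equal(r$curve$tpr[1], 0)
    expect_equal(r$curve$fpr[nrow(r$curve)], 1)
    expect_equal(r$curve$tpr[nrow(r$curve)], 1)
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
    expect_true(r$auc >= 0 && r$auc <= 1)
  }
})

test_that("the optimal cutoff matches an exhaustive Youden scan on random data", {
  for (seed in 1:5) {
    classes <- c(rep("case", 10), rep("ctrl", 12))
    scores <- withr::with_seed(seed, round(c(rnorm(10, 0.8), rnorm(12)), 1))
    r <- roc_curve(scores, classes, "case")
    best <- oracle_optimal_cutoff(scores, classes, "case")
    expect_equal(r$optimal$cutoff, best$cutoff)
    expect_equal(r$optimal$se + r$optimal$sp, best$se + best$sp,
                 tolerance = 1e-12)
  }
})

test_that("glm and count combination scores behave as documented", {
  vals <- rbind(s1 = c(500, 100), s2 = c(400, 100), s3 = c(500, 500))
  colnames(vals) <- c("m1", "m2")
  ds <- marker_dataset(vals, classes = c("d", "h", "d"), positive_label = "d")
  cnt <- combo_score(ds, c("m1", "m2"), method = "count", thr = 450)
  expect_equal(unname(cnt), c(1, 0, 2))
  expect_error(combo_score(ds, c("m1", "m2"), method = "count"), "thr")

  # single-marker glm score is a monotone transform of the marker: same AUC
  big <- random_dataset(seed = 71)
  raw_auc <- roc_curve(big$values[, "m1"], big$classes, "case")$auc
  glm_auc <- roc_curve(combo_score(big, "m1", "glm"), big$classes, "case")$auc
  expect_equal(glm_auc, raw_auc, tolerance = 1e-12)
})

test_that("prediction summaries tally the 2x2 table and conserve class totals", {
  p <- predictions(scores = c(0.9, 0.2, 0.1, 0.8),
                   classes = c("d", "d", "h", "h"),
                   cutoff = 0.5, positive_label = "d")
  expect_equal(c(p$tp, p$fn, p$tn, p$fp), c(1, 1, 1, 1))

  ds <- random_dataset(seed = 81)
  sc <- combo_score(ds, c("m1", "m2"), "glm")
  r <- roc_curve(sc, ds$classes, "case")
  for (cut in quantile(sc, c(0.1, 0.5, 0.9))) {
    p <- predictions(sc, ds$classes, cut, "case")
    expect_equal(p$tp + p$fn, sum(ds$classes == "case"))
    expect_equal(p$tn + p$fp, sum(ds$classes == "ctrl"))
  }
  # perfect separation at the optimal cutoff leaves no false calls
  sep <- c(rep(1, 5), rep(0, 5))
  ps <- predictions(sep, rep(c("d", "h"), each = 5), cutoff = 0.5,
                    positive_label = "d")
  expect_equal(ps$fp + ps$fn, 0)
})

test_that("count-score ROC at threshold minf-1 reproduces the combinatorial SE/SP", {
  ds <- random_dataset(seed = 91)
  thr <- unname(median(ds$values))
  combos <- combinatorial_analysis(ds, stringency(thr, 1))
  multi <- combos[combos$size >= 2, ]
  for (i in c(1, 5, 9, 13, nrow(multi))) {
    members <- multi$members[[i]]
    sc <- combo_score(ds, members, method = "count", thr = thr)
    r <- roc_curve(sc, ds$classes, "case")
    at0 <- r$curve[which(r$curve$threshold == 0), ]  # score > 0 <=> minf = 1
    expect_equal(100 * at0$se, multi$se[i], tolerance = 1e-12)
    expect_equal(100 * at0$sp, multi$sp[i], tolerance = 1e-12)
  }
})

test_that("the ROC report has one consistent row per requested combo", {
  ds <- random_dataset(seed = 101)
  combos <- combinatorial_analysis(ds, stringency(unname(median(ds$values)), 1))
  gold <- select_gold(combos, 40, 40)
  rep <- roc_report(ds, gold, method = "glm")
  expect_equal(nrow(rep), nrow(gold))
  expect_true(all(rep$auc >= 0 & rep$auc <= 1))
  # the first row reproduces a direct single-combo computation
  sc <- combo_score(ds, gold$members[[1]], "glm")
  r <- roc_curve(sc, ds$classes, "case")
  expect_equal(rep$auc[1], r$auc, tolerance = 1e-12)
  expect_equal(rep$cutoff[1], r$optimal$cutoff)
})

test_that("adding a pure-noise marker barely moves the glm AUC on a large fixture", {
  ds <- simulate_marker_data(n_cases = 300, n_controls = 300, n_markers = 3,
                             case_location = log(700), control_location = log(300),
                             correlation = 0, seed = 424)
  noise <- withr::with_seed(99, rlnorm(600, log(400), 0.5))
  vals <- cbind(ds$values, noise = noise)
  ds2 <- marker_dataset(vals, ds$classes, positive_label = "case",
                        sample_ids = ds$sample_ids)
  auc_base <- roc_curve(combo_score(ds, c("marker1", "marker2"), "glm"),
                        ds$classes, "case")$auc
  auc_noise <- roc_curve(combo_score(ds2, c("marker1", "marker2", "noise"), "glm"),
                         ds2$classes, "case")$auc
  expect_lt(abs(auc_noise - auc_base), 0.05)
})
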