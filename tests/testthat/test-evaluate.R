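test_that("confusion counts match a position-by-position recount", {
  pred <- c(rep(1L, 7), rep(0L, 93))
  expect_identical(confusion_counts(pred, pred),
                   structure(list(TP = 7L, FP = 0L, TN = 93L, FN = 0L),
                             class = "confusion"))

  truth <- c(rep(1L, 10), rep(0L, 90))
  allb <- confusion_counts(rep(1L, 100), truth)
  expect_identical(c(allb$TP, allb$FP, allb$TN, allb$FN), c(10L, 90L, 0L, 0L))

  set.seed(61)
  p <- sample(0:1, 500, replace = TRUE)
  t <- sample(0:1, 500, replace = TRUE)
  cc <- confusion_counts(p, t)
  manual <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (i in seq_along(p)) {
    key <- if (p[i] == 1L && t[i] == 1L) "TP" else if (p[i] == 1L) "FP"
      else if (t[i] == 1L) "FN" else "TN"
    manual[key] <- manual[key] + 1L
  }
  expect_identical(c(cc$TP, cc$FP, cc$TN, cc$FN), unname(manual))

  expect_error(confusion_counts(c(0L, 2L), c(0L, 1L)), "two-state")
})

test_that("scalar metrics reproduce the hand-worked confusion", {
  m <- scalar_metrics(structure(list(TP = 8, FN = 2, TN = 85, FP = 5),
                                class = "confusion"))
  expect_equal(m$Sn, 0.800, tolerance = 1e-12)
  expect_equal(m$Sp, 0.94444, tolerance = 1e-4)
  expect_equal(m$Ac, 0.93, tolerance = 1e-12)
  expect_equal(m$MCC, 0.664, tolerance = 1e-3)
  expect_equal(m$Sw, m$Sn + m$Sp - 1, tolerance = 1e-12)
  expect_length(m$undefined, 0)

  perfect <- scalar_metrics(structure(list(TP = 10, FN = 0, TN = 90, FP = 0),
                                      class = "confusion"))
  expect_equal(unlist(perfect[c("Sn", "Sp", "Ac", "MCC", "Sw")]),
               c(Sn = 1, Sp = 1, Ac = 1, MCC = 1, Sw = 1))

  # weighted-score identity from the hinge-size analysis: Sn 0.81 + Sp 0.87
  expect_equal(0.81 + 0.87 - 1, 0.68, tolerance = 1e-12)
})

test_that("zero denominators surface as undefined rather than zero", {
  m <- scalar_metrics(structure(list(TP = 0, FN = 0, TN = 9, FP = 1),
                                class = "confusion"))
  expect_true(is.na(m$Sn))
  expect_true(all(c("Sn", "Sw") %in% m$undefined))
  expect_false("Sp" %in% m$undefined)
})

test_that("MCC is invariant under class swap and Sw equals 2*balanced accuracy - 1", {
  set.seed(62)
  for (i in 1:20) {
    cnt <- as.list(sample(1:50, 4))
    names(cnt) <- c("TP", "FP", "TN", "FN")
    m <- scalar_metrics(structure(cnt, class = "confusion"))
    swapped <- scalar_metrics(structure(
      list(TP = cnt$TN, FP = cnt$FN, TN = cnt$TP, FN = cnt$FP),
      class = "confusion"))
    expect_equal(m$MCC, swapped$MCC, tolerance = 1e-12)
    expect_equal(m$Sw, 2 * (m$Sn + m$Sp) / 2 - 1, tolerance = 1e-12)
  }
})

test_that("rank-based AUC equals the brute-force pairwise oracle", {
  set.seed(63)
  truth <- sample(0:1, 200, replace = TRUE)
  scores <- runif(200)
  scores[sample(200, 40)] <- round(scores[sample(200, 40)], 1)  # force ties
  expect_equal(roc_auc(scores, truth), auc_oracle(scores, truth),
               tolerance = 1e-12)

  # cross-check against an independent library implementation
  expect_equal(roc_auc(scores, truth),
               as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-9)

  # perfect separation and all-ties conventions
  expect_equal(roc_auc(c(rep(1, 5), rep(0, 5)), c(rep(1L, 5), rep(0L, 5))), 1)
  expect_equal(roc_auc(rep(0.5, 10), sample(0:1, 10, replace = TRUE,
                                            prob = c(.5, .5))), 0.5)
  # complement symmetry
  expect_equal(roc_auc(-scores, truth), 1 - roc_auc(scores, truth),
               tolerance = 1e-12)
  # single-class truth is undefined
  expect_true(is.na(roc_auc(runif(5), rep(1L, 5))))
})

test_that("bootstrap SE of a Bernoulli predictor tracks binomial sampling theory", {
  set.seed(64)
  p <- 0.9; m <- 40; k <- 50
  targets <- replicate(m, rbinom(k, 1, p), simplify = FALSE)
  acc <- function(tg) mean(unlist(tg))
  se <- bootstrap_se(targets, acc, frac = 0.8, reps = 1000, seed = 9)
  analytic <- sqrt(p * (1 - p) / (0.8 * m * k))
  expect_lt(abs(se - analytic) / analytic, 0.25)

  # determinism under a fixed seed
  expect_identical(se, bootstrap_se(targets, acc, frac = 0.8, reps = 1000,
                                    seed = 9))
  # a metric constant across targets has zero SE
  expect_equal(bootstrap_se(replicate(10, 1, simplify = FALSE),
                            function(tg) mean(unlist(tg)), seed = 1), 0)
})

test_that("metric reports pool confusions and attach bootstrap SEs", {
  set.seed(65)
  targets <- lapply(1:12, function(i) {
    truth <- sample(0:1, 80, replace = TRUE, prob = c(0.9, 0.1))
    scores <- runif(80) * 0.3 + truth * 0.5
    list(calls2 = as.integer(scores > 0.5), truth2 = truth, scores = scores)
  })
  rep <- metric_report(targets, se = TRUE, reps = 100, seed = 2)
  pooled <- confusion_counts(unlist(lapply(targets, `[[`, "calls2")),
                             unlist(lapply(targets, `[[`, "truth2")))
  expect_equal(rep$Sn, scalar_metrics(pooled)$Sn)
  expect_equal(rep$AUC, roc_auc(unlist(lapply(targets, `[[`, "scores")),
                                unlist(lapply(targets, `[[`, "truth2"))))
  expect_true(all(is.finite(rep$SE)))
  path <- withr::local_tempfile(fileext = ".json")
  txt <- withr::local_tempfile(fileext = ".txt")
  write_metric_report(rep, path, txt)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$Sn, rep$Sn, tolerance = 1e-12)
  expect_match(readLines(txt)[1], "^Sn")
})
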