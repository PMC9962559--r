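test_that("confusion matrices tally truth against prediction", {
  truth <- rep(oxidation_levels, c(126, 77, 187))
  cm <- confusion(truth, truth)
  expect_equal(unname(diag(unclass(cm))), c(126, 77, 187))
  expect_equal(sum(cm) - sum(diag(unclass(cm))), 0)
  cm2 <- suppressWarnings(confusion(truth, rep("Bad", 390)))
  expect_equal(unname(unclass(cm2)[, "Bad"]), c(126, 77, 187))
  expect_true(all(unclass(cm2)[, c("Good", "Fair")] == 0))
  set.seed(3)
  a <- sample(oxidation_levels, 300, TRUE)
  b <- sample(oxidation_levels, 300, TRUE)
  expect_equal(sum(confusion(a, b)), 300)
  # brute-force tally agreement
  expect_equal(unclass(confusion(a, b))["Fair", "Bad"],
               sum(a == "Fair" & b == "Bad"), ignore_attr = TRUE)
  expect_oxi_error(confusion(a, b[-1]))
  expect_oxi_error(confusion("Good", "Excellent"))
})

test_that("precision, recall and F1 follow their defining formulas", {
  # one class with TP=8, FP=2, FN=0
  cm <- confusion(rep(c("Good", "Fair"), c(8, 12)),
                  rep(c("Good", "Fair"), c(10, 10)))
  m <- suppressWarnings(class_metrics(cm))
  good <- m[m$class == "Good", ]
  expect_equal(good$precision, 0.8)
  expect_equal(good$recall, 1.0)
  expect_equal(good$f1, 2 * 0.8 / 1.8)
  # perfect predictions
  mp <- class_metrics(confusion(rep(oxidation_levels, 5),
                                rep(oxidation_levels, 5)))
  expect_true(all(mp$precision == 1 & mp$recall == 1 & mp$f1 == 1))
})

test_that("F1 equals p when precision == recall and lies between them otherwise", {
  set.seed(9)
  for (i in 1:20) {
    truth <- sample(oxidation_levels, 120, TRUE)
    pred <- ifelse(runif(120) < 0.6, truth,
                   sample(oxidation_levels, 120, TRUE))
    m <- suppressWarnings(class_metrics(confusion(truth, pred)))
    expect_true(all(m$f1 >= pmin(m$precision, m$recall) - 1e-12))
    expect_true(all(m$f1 <= pmax(m$precision, m$recall) + 1e-12))
    eq <- m$precision == m$recall
    expect_equal(m$f1[eq], m$precision[eq])
  }
})

test_that("degenerate confusion matrices warn and zero the affected metrics", {
  cm <- confusion(rep(c("Good", "Bad"), 5), rep("Good", 10))
  expect_warning(m <- class_metrics(cm), "never predicted")
  expect_equal(m$precision[m$class == "Bad"], 0)
  expect_equal(m$f1[m$class == "Bad"], 0)
})

test_that("weighted F1 is the support-weighted mean of per-class F1", {
  m <- data.frame(class = oxidation_levels, precision = 1, recall = 1,
                  f1 = c(0.96, 0.81, 0.96), support = c(126, 77, 187))
  expect_equal(weighted_f1(m),
               (126 * 0.96 + 77 * 0.81 + 187 * 0.96) / 390)
  m$support <- c(10, 10, 10)
  expect_equal(weighted_f1(m), mean(c(0.96, 0.81, 0.96)))
  m$support <- c(0, 10, 10)
  expect_equal(weighted_f1(m), mean(c(0.81, 0.96)))
  m$support <- c(0, 0, 0)
  expect_oxi_error(weighted_f1(m))
})

test_that("micro accuracy equals the trace ratio and permuting labels consistently leaves metrics unchanged", {
  set.seed(4)
  truth <- sample(oxidation_levels, 200, TRUE)
  pred <- sample(oxidation_levels, 200, TRUE)
  rep1 <- suppressWarnings(eval_report(truth, pred))
  cm <- unclass(rep1$confusion)
  expect_equal(rep1$accuracy, sum(diag(cm)) / sum(cm))
  # relabel Good<->Bad everywhere: the multiset of per-class metrics persists
  swap <- function(x) c(Good = "Bad", Fair = "Fair", Bad = "Good")[x]
  rep2 <- suppressWarnings(eval_report(swap(truth), swap(pred)))
  m1 <- rep1$per_class[order(rep1$per_class$class), ]
  m2 <- rep2$per_class
  m2$class <- swap(m2$class)
  m2 <- m2[order(m2$class), ]
  expect_equal(m1[c("precision", "recall", "f1", "support")],
               m2[c("precision", "recall", "f1", "support")],
               ignore_attr = TRUE)
  expect_equal(rep1$accuracy, rep2$accuracy)
})

test_that("aggregation produces medians, IQRs and the repetition-test arithmetic", {
  mk <- function(flip) {
    truth <- rep(oxidation_levels, c(4, 3, 5))
    pred <- truth
    if (flip > 0) pred[seq_len(flip)] <- "Bad"
    suppressWarnings(eval_report(truth, pred))
  }
  reps <- lapply(c(0, 1, 2), mk)
  agg <- aggregate_repetitions(reps)
  expect_equal(agg$total_tests, 3 * 12)
  good_rec <- agg$per_class[agg$per_class$class == "Good" &
                              agg$per_class$metric == "recall", ]
  expect_equal(good_rec$median, median(c(4, 3, 2) / 4))
  # single report: median equals the value, IQR collapses onto it
  agg1 <- aggregate_repetitions(reps[1])
  expect_equal(agg1$per_class$median, agg1$per_class$q25)
  expect_equal(agg1$per_class$median, agg1$per_class$q75)
  # identical reports aggregate to their common values
  agg3 <- aggregate_repetitions(reps[c(1, 1, 1)])
  f1s <- agg3$per_class[agg3$per_class$metric == "f1", ]
  expect_equal(f1s$median, reps[[1]]$per_class$f1)
  expect_equal(f1s$q25, reps[[1]]$per_class$f1)
  # odd-count median of three spread values
  spread <- lapply(c(6, 5, 4), mk)  # distinct metric values
  aggs <- aggregate_repetitions(spread)
  gr <- aggs$per_class[aggs$per_class$class == "Good" &
                         aggs$per_class$metric == "recall", "median"]
  expect_equal(gr, median(c(0, 0, 0)))
  # inconsistent supports are rejected
  other <- suppressWarnings(eval_report(rep(oxidation_levels, c(5, 3, 4)),
                                        rep(oxidation_levels, c(5, 3, 4))))
  expect_oxi_error(aggregate_repetitions(list(reps[[1]], other)))
})

test_that("the benchmark table has the Bad/Fair/Good/Overall shape", {
  truth <- rep(oxidation_levels, c(126, 77, 187))
  reps <- lapply(1:3, function(i) eval_report(truth, truth))
  tab <- report_table(aggregate_repetitions(reps))
  expect_equal(names(tab), c("quantity", "Bad", "Fair", "Good", "Overall"))
  expect_equal(tab$Overall[tab$quantity == "total_tests"], "1170")
  expect_equal(tab$Bad[tab$quantity == "support"], "187")
})
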