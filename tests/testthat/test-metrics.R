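# The three published 4 x 2949 confusion tables ship as CSV fixtures; every
# derived statistic below is recomputed from the counts.

test_that("published confusion tables reload with their structure intact", {
  for (mdl in c("resnet", "alexnet", "squeezenet")) {
    ct <- paper_confusion(mdl)
    expect_s3_class(ct, "confusion_table")
    expect_equal(unname(rowSums(ct)), rep(2949, 4))
    expect_equal(sum(ct), 4 * 2949)
  }
})

test_that("accuracy, macro aggregates and kappa match the published values", {
  res <- metrics_report(paper_confusion("resnet"))
  expect_equal(res$accuracy, 0.97008, tolerance = 1e-5)
  expect_equal(res$macro_recall, 0.97008, tolerance = 1e-5)
  expect_equal(res$macro_precision, 0.97011, tolerance = 1e-5)
  expect_equal(res$macro_f1, 0.97009, tolerance = 1e-5)
  expect_equal(res$kappa, 0.96010, tolerance = 1e-5)

  alex <- metrics_report(paper_confusion("alexnet"))
  expect_equal(alex$accuracy, 0.95897, tolerance = 1e-5)
  expect_equal(alex$macro_precision, 0.95907, tolerance = 1e-5)
  expect_equal(alex$macro_f1, 0.95902, tolerance = 1e-5)
  expect_equal(alex$kappa, 0.94529, tolerance = 1e-5)

  sq <- metrics_report(paper_confusion("squeezenet"))
  expect_equal(sq$accuracy, 0.75398, tolerance = 1e-5)
  expect_equal(sq$kappa, 0.67198, tolerance = 1e-5)
})

test_that("per-class recall/precision/F1 match the published 3 d.p. values", {
  # absolute tolerance at the tables' print precision
  near <- function(actual, printed) expect_lt(max(abs(actual - printed)),
                                              5e-4 + 1e-12)
  pc <- per_class_metrics(paper_confusion("resnet"))
  near(pc$recall,    c(0.950, 0.985, 0.959, 0.986))
  near(pc$precision, c(0.958, 0.968, 0.981, 0.974))
  near(pc$f1,        c(0.954, 0.976, 0.970, 0.980))

  pc <- per_class_metrics(paper_confusion("alexnet"))
  near(pc$recall,    c(0.934, 0.968, 0.969, 0.965))
  near(pc$precision, c(0.938, 0.964, 0.953, 0.982))
  near(pc$f1,        c(0.936, 0.966, 0.961, 0.973))

  pc <- per_class_metrics(paper_confusion("squeezenet"))
  near(pc$recall,    c(0.742, 0.720, 0.690, 0.865))
  near(pc$precision, c(0.659, 0.846, 0.807, 0.740))
  near(pc$f1,        c(0.698, 0.778, 0.744, 0.798))
})

test_that("degenerate tables hit their documented edge behaviour", {
  perfect <- confusion_table(diag(4) * 10)
  expect_equal(accuracy(perfect), 1)
  expect_equal(cohens_kappa(perfect), 1)
  expect_true(all(per_class_metrics(perfect)$f1 == 1))

  flat <- confusion_table(matrix(5, 4, 4))
  expect_equal(cohens_kappa(flat), 0)     # observed = chance agreement

  # constant classifier: undefined precision is NA-flagged, macro errors
  constant <- confusion_table(matrix(c(rep(c(0, 10, 0, 0), 4)), 4, 4,
                                     byrow = TRUE))
  pc <- per_class_metrics(constant)
  expect_true(is.na(pc$precision[1]))
  expect_false(is.na(pc$precision[2]))
  expect_error(macro_metrics(constant), "undefined")
  rep_partial <- metrics_report(constant, partial = TRUE)
  expect_true(is.na(rep_partial$macro_f1))

  empty <- confusion_table(matrix(0, 4, 4))
  expect_error(accuracy(empty), "undefined")
  single <- confusion_table(matrix(c(7, rep(0, 15)), 4, 4))
  expect_error(cohens_kappa(single), "degenerate")
})

test_that("F1 conventions differ as documented", {
  # harmonic of macro precision/recall vs mean of per-class F1s
  alex <- paper_confusion("alexnet")
  harm <- macro_metrics(alex, "macro_harmonic")$macro_f1
  avg <- macro_metrics(alex, "mean_per_class")$macro_f1
  expect_equal(harm, 0.95902, tolerance = 1e-5)
  expect_false(isTRUE(all.equal(harm, avg, tolerance = 1e-5)))
})

test_that("metric identities hold for balanced tables", {
  # equal row sums: accuracy == macro recall, kappa == (acc - 1/4)/(3/4)
  set.seed(8)
  for (i in 1:5) {
    m <- matrix(sample(0:50, 16, replace = TRUE), 4, 4)
    m <- t(apply(m, 1, function(r) { r[1] <- r[1] + 200 - sum(r); r }))
    ct <- confusion_table(m)
    expect_equal(accuracy(ct), macro_metrics(ct)$macro_recall)
    expect_equal(cohens_kappa(ct), (accuracy(ct) - 0.25) / 0.75)
  }
})

test_that("class permutation permutes per-class metrics, fixes aggregates", {
  ct <- paper_confusion("resnet")
  perm <- c(3, 1, 4, 2)
  ctp <- confusion_table(unclass(ct)[perm, perm],
                         classes = beat_classes()[perm])
  expect_equal(accuracy(ctp), accuracy(ct))
  expect_equal(cohens_kappa(ctp), cohens_kappa(ct))
  expect_equal(per_class_metrics(ctp)$f1, per_class_metrics(ct)$f1[perm])
})

test_that("aggregated tables equal a brute-force recount of label pairs", {
  set.seed(12)
  true <- sample(beat_classes(), 300, replace = TRUE)
  pred <- ifelse(runif(300) < 0.8, true,
                 sample(beat_classes(), 300, replace = TRUE))
  ct <- confusion_from_labels(true, pred)
  # independent recount: loop over pairs
  recount <- matrix(0L, 4, 4, dimnames = list(beat_classes(), beat_classes()))
  for (i in seq_along(true)) {
    recount[true[i], pred[i]] <- recount[true[i], pred[i]] + 1L
  }
  expect_equal(unclass(ct), recount, ignore_attr = TRUE)
  expect_equal(accuracy(ct), mean(true == pred))
})

test_that("confusion tables round-trip through CSV", {
  ct <- paper_confusion("resnet")
  f <- tempfile(fileext = ".csv")
  write_confusion_csv(ct, f)
  expect_equal(unclass(read_confusion_csv(f)), unclass(ct),
               ignore_attr = TRUE)
})
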