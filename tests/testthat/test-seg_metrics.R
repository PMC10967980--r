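test_that("confusion_counts tallies the four cells", {
  ones <- matrix(1L, 10, 10); zeros <- matrix(0L, 10, 10)
  expect_equal(confusion_counts(ones, ones),
               tibble::tibble(tp = 100L, fp = 0L, fn = 0L, tn = 0L))
  expect_equal(confusion_counts(ones, zeros)$fp, 100L)

  pred <- matrix(c(1L, 0L, 0L, 0L), 2, 2, byrow = TRUE)
  truth <- matrix(c(1L, 1L, 0L, 0L), 2, 2, byrow = TRUE)
  cc <- confusion_counts(pred, truth)
  expect_equal(unlist(cc), c(tp = 1L, fp = 0L, fn = 1L, tn = 2L))
  expect_error(confusion_counts(pred, matrix(0L, 3, 3)), "identical dimensions")
})

test_that("metrics_row reproduces enumerable cases", {
  row <- metrics_row(tibble::tibble(tp = 1, fp = 0, fn = 1, tn = 2), "c1")
  expect_equal(row$iou, 0.5)
  expect_equal(row$dice, 2 / 3)
  expect_equal(row$accuracy, 0.75)
  expect_equal(row$precision, 1)
  expect_equal(row$recall, 0.5)
  expect_equal(row$specificity, 1)

  perfect <- mask_metrics(matrix(1L, 4, 4), matrix(1L, 4, 4))
  expect_true(all(unlist(perfect[ctenhance:::METRIC_NAMES]) == 1))

  pred <- matrix(c(1L, 0L), 1, 2); truth <- matrix(c(0L, 1L), 1, 2)
  disj <- mask_metrics(pred, truth)
  expect_true(all(unlist(disj[c("iou", "dice", "precision", "recall", "f1")]) == 0))
})

test_that("degenerate empty-mask cases follow the agreed conventions", {
  e <- matrix(0L, 3, 3); f <- matrix(c(1L, rep(0L, 8)), 3, 3)
  both <- mask_metrics(e, e)
  expect_true(all(unlist(both[ctenhance:::METRIC_NAMES]) == 1))
  one <- mask_metrics(e, f)   # empty prediction, non-empty truth
  expect_equal(one$precision, 0)
  expect_equal(one$recall, 0)
  expect_equal(one$iou, 0)
  expect_equal(mask_metrics(f, e)$precision, 0)
})

test_that("metric identities hold and match the pixel-loop oracle on random masks", {
  set.seed(50)
  for (i in 1:60) {
    pred <- random_mask(16, 16, runif(1, 0.1, 0.9))
    truth <- random_mask(16, 16, runif(1, 0.1, 0.9))
    row <- mask_metrics(pred, truth)
    o <- oracle_metrics(pred, truth)
    for (m in c("iou", "dice", "accuracy", "precision", "recall", "f1", "specificity"))
      expect_identical(row[[m]], o[[m]])
    # exact identities
    expect_equal(row$f1, row$dice, tolerance = 1e-12)
    expect_identical(row$recall, row$sensitivity)
    expect_equal(row$dice, 2 * row$iou / (1 + row$iou), tolerance = 1e-12)
    # symmetry: swapping pred/truth preserves iou/dice/accuracy, swaps P/R
    sw <- mask_metrics(truth, pred)
    expect_identical(sw$iou, row$iou)
    expect_identical(sw$dice, row$dice)
    expect_identical(sw$accuracy, row$accuracy)
    expect_identical(sw$precision, row$recall)
    expect_identical(sw$recall, row$precision)
    # label-complement duality: complementing both masks swaps sens/spec
    comp <- mask_metrics(1L - pred, 1L - truth)
    expect_identical(comp$sensitivity, row$specificity)
    expect_identical(comp$specificity, row$sensitivity)
  }
})

test_that("dice_from_iou implements the Dice-Jaccard identity", {
  expect_equal(dice_from_iou(0), 0)
  expect_equal(dice_from_iou(1), 1)
  expect_equal(round(dice_from_iou(0.6667), 4), 0.8000)
  expect_equal(round(dice_from_iou(0.9635), 4), 0.9814)
  expect_error(dice_from_iou(1.2), "\\[0, 1\\]")
})

test_that("metrics_report aggregates by full-precision column means", {
  one <- mask_metrics(matrix(1L, 2, 2), matrix(1L, 2, 2), "a")
  rep1 <- metrics_report(one)
  expect_equal(unlist(rep1$mean_row[ctenhance:::METRIC_NAMES]),
               unlist(one[ctenhance:::METRIC_NAMES]))

  ten <- dplyr::bind_rows(replicate(10, one, simplify = FALSE))
  rep10 <- metrics_report(ten)
  expect_equal(unlist(rep10$mean_row[ctenhance:::METRIC_NAMES]),
               unlist(one[ctenhance:::METRIC_NAMES]))
  expect_error(metrics_report(one[0, ]), "empty")

  scores <- example_scores()
  rp <- metrics_report(scores[scores$variant == "proposed", ])
  expect_equal(round(rp$mean_row$iou, 4), 0.9002)
  expect_true(all(rp$mean_row$iou >= min(rp$rows$iou),
                  rp$mean_row$iou <= max(rp$rows$iou)))
})

test_that("tidy/glance expose rows and mean row; compare_reports uses rounded means", {
  scores <- example_scores()
  rp <- metrics_report(scores[scores$variant == "proposed", ])
  rn <- metrics_report(scores[scores$variant == "normalization", ])
  expect_identical(tidy(rp), rp$rows)
  expect_identical(glance(rp), rp$mean_row)

  cmp <- compare_reports(rn, rp)
  expect_equal(cmp$delta[cmp$metric == "iou"], -0.0810)
  expect_equal(cmp$delta[cmp$metric == "accuracy"], -0.0082)

  p <- autoplot(rp)
  expect_s3_class(p, "ggplot")
})

test_that("reports round-trip through CSV and JSON and evaluate_masks pairs files", {
  td <- withr::local_tempdir()
  set.seed(51)
  rows <- dplyr::bind_rows(lapply(1:3, function(i)
    mask_metrics(random_mask(8, 8), random_mask(8, 8), paste0("case", i))))
  rep0 <- metrics_report(rows)
  for (ext in c("report.csv", "report.json")) {
    p <- file.path(td, ext)
    write_report(rep0, p)
    back <- read_report(p)
    expect_equal(back$rows[ctenhance:::METRIC_NAMES],
                 rep0$rows[ctenhance:::METRIC_NAMES])
  }

  pd <- file.path(td, "pred"); tdir <- file.path(td, "truth")
  dir.create(pd); dir.create(tdir)
  for (i in 1:2) {
    write_mask(random_mask(8, 8), file.path(pd, sprintf("c%d.png", i)))
    write_mask(random_mask(8, 8), file.path(tdir, sprintf("c%d.png", i)))
  }
  ev <- evaluate_masks(pd, tdir)
  expect_s3_class(ev, "metrics_report")
  expect_equal(nrow(ev$rows), 2)
  expect_error(evaluate_masks(pd, file.path(td, "pred", "c1.png")), "differ in size")
})
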