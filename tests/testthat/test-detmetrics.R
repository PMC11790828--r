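test_that("greedy matching assigns TPs, FPs and FNs per the single-match rule", {
  gt <- ground_truth_records("a", "c1", 10, 10, 4, 4)
  d1 <- detection_records("a", "c1", 0.9, 10, 10, 4, 4)
  m <- match_detections(d1, gt, 0.5)
  expect_true(m$dets$tp)
  expect_true(m$gts$matched)

  # two detections on one gt: only the higher score matches
  d2 <- detection_records("a", "c1", c(0.6, 0.9), 10, 10, 4, 4)
  m2 <- match_detections(d2, gt, 0.5)
  expect_equal(m2$dets$tp[order(m2$dets$score)], c(FALSE, TRUE))

  # no detections: gt stays unmatched
  d0 <- detection_records(character(0), character(0), numeric(0),
                          numeric(0), numeric(0), numeric(0), numeric(0))
  m0 <- match_detections(d0, gt, 0.5)
  expect_false(m0$gts$matched)

  # matching respects image and class boundaries
  d3 <- detection_records("b", "c1", 0.9, 10, 10, 4, 4)
  expect_false(match_detections(d3, gt, 0.5)$dets$tp)
  d4 <- detection_records("a", "c2", 0.9, 10, 10, 4, 4)
  expect_false(match_detections(d4, gt, 0.5)$dets$tp)
})

test_that("precision/recall/F1 formulas and 0/0 conventions", {
  r <- precision_recall_f1(8, 2, 2)
  expect_equal(c(r$precision, r$recall, r$f1), c(0.8, 0.8, 0.8))
  r0 <- precision_recall_f1(0, 0, 0)
  expect_equal(c(r0$precision, r0$recall, r0$f1), c(0, 0, 0))
  # harmonic mean: P=0.5, R=1 -> F1 = 2/3
  r2 <- precision_recall_f1(1, 1, 0)
  expect_equal(r2$f1, 2 / 3)
})

test_that("AP is 1 for a perfect detector, 0 for a hopeless one, NA without ground truth", {
  gt <- ground_truth_records(c("a", "a", "b"), "c1",
                             c(10, 30, 20), c(10, 30, 20), 6, 6)
  perfect <- detection_records(gt$image_id, gt$class_id, c(0.9, 0.8, 0.7),
                               gt$cx, gt$cy, gt$w, gt$h)
  expect_equal(average_precision(perfect, gt, "c1", 0.5), 1)
  off <- detection_records("a", "c1", 0.9, 100, 100, 2, 2)
  expect_equal(average_precision(off, gt, "c1", 0.5), 0)
  expect_true(is.na(average_precision(perfect, gt, "c2", 0.5)))
})

test_that("AP agrees with the exhaustive threshold-enumeration oracle", {
  set.seed(41)
  for (i in 1:30) {
    g <- ground_truth_records(sample(c("im1", "im2"), 6, TRUE),
                              sample(c("c1", "c2"), 6, TRUE),
                              runif(6, 5, 55), runif(6, 5, 55),
                              runif(6, 4, 14), runif(6, 4, 14))
    base <- g[sample.int(6, 10, TRUE), ]
    d <- detection_records(base$image_id, sample(c("c1", "c2"), 10, TRUE),
                           runif(10),
                           base$cx + rnorm(10, 0, 3), base$cy + rnorm(10, 0, 3),
                           base$w * exp(rnorm(10, 0, 0.2)),
                           base$h * exp(rnorm(10, 0, 0.2)))
    for (cl in c("c1", "c2")) {
      expect_equal(average_precision(d, g, cl, 0.5), ap_oracle(d, g, cl, 0.5),
                   tolerance = 1e-9)
    }
  }
})

test_that("mAP is the arithmetic mean over classes and thresholds", {
  # class A perfect (AP 1), class B: top-score FP then a TP (AP 0.5)
  gt <- ground_truth_records(c("a", "a"), c("A", "B"),
                             c(10, 30), c(10, 30), 6, 6)
  dets <- detection_records(c("a", "a", "a"), c("A", "B", "B"),
                            c(0.9, 0.8, 0.7),
                            c(10, 50, 30), c(10, 50, 30), 6, 6)
  m <- mean_ap(dets, gt, 0.5)
  expect_equal(sort(m$per_class$ap), c(0.5, 1))
  expect_equal(m$map, 0.75)
  # a single-threshold list reproduces mAP0.5
  expect_equal(mean_ap(dets, gt, c(0.5))$map, m$map)
})

test_that("stricter IoU thresholds never help: mAP0.5-0.95 <= mAP0.5", {
  set.seed(42)
  for (i in 1:10) {
    g <- ground_truth_records(sample(c("im1", "im2"), 5, TRUE), "c1",
                              runif(5, 10, 50), runif(5, 10, 50),
                              runif(5, 6, 14), runif(5, 6, 14))
    base <- g[sample.int(5, 8, TRUE), ]
    d <- detection_records(base$image_id, "c1", runif(8),
                           base$cx + rnorm(8, 0, 2), base$cy + rnorm(8, 0, 2),
                           base$w * exp(rnorm(8, 0, 0.15)),
                           base$h * exp(rnorm(8, 0, 0.15)))
    expect_lte(mean_ap(d, g, seq(0.5, 0.95, 0.05))$map,
               mean_ap(d, g, 0.5)$map + 1e-12)
  }
})

test_that("duplicating a detection at lower score only adds false positives", {
  set.seed(43)
  g <- ground_truth_records(c("a", "a"), "c1", c(10, 30), c(10, 30), 6, 6)
  d <- detection_records(c("a", "a"), "c1", c(0.9, 0.6),
                         c(10.5, 30.5), c(10, 30), 6, 6)
  ap0 <- average_precision(d, g, "c1", 0.5)
  dup <- rbind(d, transform(d[1, ], score = 0.3))
  ap1 <- average_precision(dup, g, "c1", 0.5)
  expect_lte(ap1, ap0 + 1e-12)
  m <- match_detections(dup, g, 0.5)
  expect_equal(sum(m$dets$tp), 2)
})

test_that("metrics are invariant under record order permutation", {
  set.seed(44)
  g <- ground_truth_records(sample(c("im1", "im2"), 6, TRUE),
                            sample(c("c1", "c2"), 6, TRUE),
                            runif(6, 10, 50), runif(6, 10, 50),
                            runif(6, 6, 14), runif(6, 6, 14))
  base <- g[sample.int(6, 12, TRUE), ]
  d <- detection_records(base$image_id, base$class_id, runif(12),
                         base$cx + rnorm(12, 0, 2), base$cy + rnorm(12, 0, 2),
                         base$w, base$h)
  ref <- evaluate_detections(d, g)
  for (i in 1:5) {
    dp <- d[sample.int(nrow(d)), ]
    got <- evaluate_detections(dp, g)
    expect_equal(got$map50, ref$map50)
    expect_equal(got$map5095, ref$map5095)
    expect_equal(got$f1, ref$f1)
  }
})

test_that("record files round-trip through the delimited schemas", {
  g <- ground_truth_records(c("a", "b"), c("c1", "c2"),
                            c(10, 20), c(10, 20), c(4, 6), c(4, 6))
  d <- detection_records("a", "c1", 0.9, 10, 10, 4, 4)
  gp <- withr::local_tempfile(fileext = ".txt")
  dp <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(g, gp, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(d, dp, row.names = FALSE, col.names = FALSE, quote = FALSE)
  expect_equal(read_ground_truth(gp), g)
  expect_equal(read_detections(dp), d)
})
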