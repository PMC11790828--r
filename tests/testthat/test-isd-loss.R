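test_that("hyperparameter ranges are enforced at construction", {
  expect_s3_class(isd_config(), "isd_config")
  expect_silent(isd_config(ratio = 0.5))
  expect_silent(isd_config(ratio = 1.5))
  expect_silent(isd_config(theta = 2))
  expect_silent(isd_config(theta = 6))
  expect_silent(isd_config(k = 1))
  expect_error(isd_config(ratio = 0.4), class = "isdiou_config_error")
  expect_error(isd_config(ratio = 1.6), "1.5", class = "isdiou_config_error")
  expect_error(isd_config(k = 0), class = "isdiou_config_error")
  expect_error(isd_config(k = 1.01), class = "isdiou_config_error")
  expect_error(isd_config(theta = 1.9), class = "isdiou_config_error")
  expect_error(isd_config(theta = 6.1), class = "isdiou_config_error")
  expect_error(isd_config(s = -0.1), class = "isdiou_config_error")
  expect_error(inner_iou(boxes(0, 0, 1, 1), boxes(0, 0, 1, 1), ratio = 2),
               class = "isdiou_config_error")
})

test_that("inner IoU matches hand geometry and reduces to IoU at ratio 1", {
  p <- boxes(1, 0, 4, 4); g <- boxes(0, 0, 4, 4)
  expect_equal(inner_iou(g, g, 1.2), 1)
  expect_equal(inner_iou(p, g, 1.0), 0.6)
  expect_equal(inner_iou(p, g, 0.5), 1 / 3)

  set.seed(21)
  rp <- random_boxes(500); rg <- random_boxes(500)
  expect_equal(inner_iou(rp, rg, 1.0), box_iou(rp, rg), tolerance = 1e-14)
  # symmetric in (pred, gt)
  expect_equal(inner_iou(rp, rg, 0.7), inner_iou(rg, rp, 0.7))
  for (r in c(0.5, 0.75, 1.25, 1.5)) {
    v <- inner_iou(rp, rg, r)
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("shape weights follow the gt-shape formula and sum to 2", {
  expect_equal(shape_weights(boxes(0, 0, 4, 4), s = 3), data.frame(w1 = 1, h1 = 1))
  expect_equal(shape_weights(boxes(0, 0, 7, 2), s = 0), data.frame(w1 = 1, h1 = 1))
  sw <- shape_weights(boxes(0, 0, 4, 2), s = 1)
  expect_equal(sw$w1, 8 / 6)
  expect_equal(sw$h1, 4 / 6)
  set.seed(22)
  g <- random_boxes(100)
  for (s in c(0, 0.5, 1, 2)) {
    sw <- shape_weights(g, s)
    expect_equal(sw$w1 + sw$h1, rep(2, 100))
    expect_true(all(sw$w1 > 0 & sw$h1 > 0))
  }
})

test_that("distance term matches the worked value, vanishes when concentric, and is scale-free", {
  cfg <- isd_config(ratio = 1, k = 0.5, theta = 4, s = 1)
  expect_equal(distance_term(boxes(0, 0, 2, 7), boxes(0, 0, 4, 4), cfg), 0)
  p <- boxes(1, 0, 4, 4); g <- boxes(0, 0, 4, 4)
  expect_equal(distance_term(p, g, cfg), 0.5 * (1 - exp(-0.04)), tolerance = 1e-12)

  set.seed(23)
  rp <- random_boxes(100); rg <- random_boxes(100)
  d1 <- distance_term(rp, rg, cfg)
  d2 <- distance_term(boxes(rp$cx * 2, rp$cy * 2, rp$w * 2, rp$h * 2),
                      boxes(rg$cx * 2, rg$cy * 2, rg$w * 2, rg$h * 2), cfg)
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_true(all(d1 >= 0 & d1 <= 2 * cfg$k))
})

test_that("distance term is strictly increasing in horizontal center offset", {
  cfg <- isd_config()
  g <- boxes(0, 0, 4, 4)
  d <- seq(0, 6, by = 0.25)
  vals <- distance_term(boxes(d, 0, 4, 4), g, cfg)
  expect_true(all(diff(vals) > 0))
})

test_that("shape term matches the worked value and grows with height mismatch", {
  cfg <- isd_config(ratio = 1, k = 0.5, theta = 4, s = 1)
  # identical shapes at different positions
  expect_equal(shape_term(boxes(9, -3, 4, 2), boxes(0, 0, 4, 2), cfg), 0)
  expect_equal(shape_term(boxes(0, 0, 4, 2), boxes(0, 0, 4, 4), cfg),
               0.5 * (1 - exp(-0.5))^4, tolerance = 1e-12)
  # monotone sweep in |h - h^gt|
  h <- c(4, 3.5, 3, 2.5, 2, 1.5, 1)
  vals <- shape_term(boxes(0, 0, 4, h), boxes(0, 0, 4, 4), cfg)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("crossed vs direct weight pairing differ exactly by swapping the weights", {
  g <- boxes(0, 0, 6, 2)  # non-square gt so w1 != h1
  p <- boxes(0, 0, 3, 2)
  crossed <- shape_term(p, g, isd_config(shape_weight_pairing = "crossed"))
  direct <- shape_term(p, g, isd_config(shape_weight_pairing = "direct"))
  sw <- shape_weights(g, 1)
  th <- 4
  expect_equal(crossed, 0.5 * ((1 - exp(-sw$h1 * 0.5))^th + 0))
  expect_equal(direct, 0.5 * ((1 - exp(-sw$w1 * 0.5))^th + 0))
  expect_false(isTRUE(all.equal(crossed, direct)))
})

test_that("iSD-IoU total is the exact component sum with the worked value", {
  cfg <- isd_config(ratio = 1, k = 0.5, theta = 4, s = 1)
  p <- boxes(1, 0, 4, 4); g <- boxes(0, 0, 4, 4)
  lb <- isd_loss(p, g, cfg)
  expect_equal(lb$total, (1 - 0.6) + 0.5 * (1 - exp(-0.04)), tolerance = 1e-12)
  expect_equal(lb$omega, 0)

  set.seed(24)
  rp <- random_boxes(300); rg <- random_boxes(300)
  lb <- isd_loss(rp, rg, cfg)
  expect_identical(lb$total,
                   (1 - inner_iou(rp, rg, cfg$ratio)) +
                     distance_term(rp, rg, cfg) + shape_term(rp, rg, cfg))
  expect_true(all(lb$total >= 0 & lb$total <= 2 + 2 * cfg$k))
})

test_that("the full loss is invariant under joint translation and positive scaling", {
  cfg <- isd_config(ratio = 0.8, k = 0.7, theta = 3, s = 1.5)
  set.seed(25)
  rp <- random_boxes(200); rg <- random_boxes(200)
  dx <- runif(200, -50, 50); dy <- runif(200, -50, 50); sc <- runif(200, 0.05, 20)
  t1 <- isd_loss(rp, rg, cfg)$total
  t2 <- isd_loss(boxes((rp$cx + dx) * sc, (rp$cy + dy) * sc, rp$w * sc, rp$h * sc),
                 boxes((rg$cx + dx) * sc, (rg$cy + dy) * sc, rg$w * sc, rg$h * sc),
                 cfg)$total
  expect_equal(t1, t2, tolerance = 1e-9)
})

test_that("distance and shape terms are asymmetric in (pred, gt), as the weights follow gt", {
  cfg <- isd_config()
  p <- boxes(2, 1, 6, 2); g <- boxes(0, 0, 2, 5)
  expect_false(isTRUE(all.equal(distance_term(p, g, cfg), distance_term(g, p, cfg))))
  expect_false(isTRUE(all.equal(shape_term(p, g, cfg), shape_term(g, p, cfg))))
})

test_that("reference losses obey their standard orderings", {
  a <- boxes(0, 0, 4, 4)
  for (w in c("iou", "diou", "ciou")) expect_equal(reference_loss(a, a, w), 0)
  far_p <- boxes(100, 100, 2, 2)
  expect_gt(reference_loss(far_p, a, "diou"), reference_loss(far_p, a, "iou"))
  set.seed(26)
  rp <- random_boxes(300); rg <- random_boxes(300)
  expect_true(all(reference_loss(rp, rg, "ciou") >= reference_loss(rp, rg, "diou") - 1e-12))
  expect_error(reference_loss(a, a, "giou"), class = "isdiou_usage_error")
})
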