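# Confusion-matrix areas, perimeter scores, overlap matching and per-fire
# statistics.

test_that("identical polygons give a perfect confusion matrix", {
  sq <- square_geom(0, 0, 1000)
  region <- square_geom(-5000, -5000, 20000)
  cm <- area_confusion(sq, sq, region)
  expect_equal(cm$TP, 1e6, tolerance = 1e-9)
  expect_equal(cm$FP, 0, tolerance = 1e-3)
  expect_equal(cm$FN, 0, tolerance = 1e-3)
  s <- perimeter_scores(cm)
  expect_equal(s$precision, 1, tolerance = 1e-9)
  expect_equal(s$recall, 1, tolerance = 1e-9)
  expect_equal(s$iou, 1, tolerance = 1e-9)
  expect_equal(s$f1, 1, tolerance = 1e-9)
  expect_equal(s$ratio, 1, tolerance = 1e-9)
})

test_that("disjoint unit squares in a 100-unit region split cleanly", {
  # work in unit-sized geometry: 1 m squares in a 10 x 10 m region
  a <- square_geom(0, 0, 1)
  b <- square_geom(5, 5, 1)
  region <- square_geom(0, 0, 10)
  cm <- area_confusion(a, b, region)
  expect_equal(cm$TP, 0)
  expect_equal(cm$FP, 1)
  expect_equal(cm$FN, 1)
  expect_equal(cm$TN, 98)
})

test_that("half-overlapping squares recover the analytic overlap area", {
  a <- square_geom(0, 0, 1000)
  b <- square_geom(500, 0, 1000)
  region <- square_geom(-2000, -2000, 6000)
  cm <- area_confusion(a, b, region)
  expect_equal(cm$TP, 500 * 1000, tolerance = 1e-9)
  expect_equal(cm$FP, 500 * 1000, tolerance = 1e-9)
  expect_equal(cm$FN, 500 * 1000, tolerance = 1e-9)
  # conservation: cells sum exactly to the region area
  expect_equal(cm$TN + cm$FP + cm$FN + cm$TP, fg_area(region),
               tolerance = 1e-6)
})

test_that("region not covering the polygons is rejected", {
  expect_error(area_confusion(square_geom(0, 0, 1000),
                              square_geom(0, 0, 1000),
                              square_geom(0, 0, 500)),
               "does not cover")
})

test_that("swapping pred and ref swaps precision and recall only", {
  set.seed(31)
  for (rep in 1:5) {
    pts1 <- cbind(runif(12, 0, 3000), runif(12, 0, 3000))
    pts2 <- cbind(runif(12, 1000, 4000), runif(12, 1000, 4000))
    g1 <- fire_hull(pts1)$geom
    g2 <- fire_hull(pts2)$geom
    region <- square_geom(-3000, -3000, 12000)
    s12 <- perimeter_scores(area_confusion(g1, g2, region))
    s21 <- perimeter_scores(area_confusion(g2, g1, region))
    expect_equal(s12$precision, s21$recall, tolerance = 1e-9)
    expect_equal(s12$recall, s21$precision, tolerance = 1e-9)
    expect_equal(s12$iou, s21$iou, tolerance = 1e-9)
    expect_equal(s12$f1, s21$f1, tolerance = 1e-9)
    expect_equal(s12$accuracy, s21$accuracy, tolerance = 1e-9)
    # f1 is the harmonic mean of precision and recall
    if (!is.na(s12$f1) && s12$precision > 0 && s12$recall > 0)
      expect_equal(s12$f1, 2 / (1 / s12$precision + 1 / s12$recall),
                   tolerance = 1e-12)
  }
})

test_that("zero denominators give missing scores", {
  cm <- confusion_matrix(100, 0, 0, 0)
  s <- perimeter_scores(cm)
  expect_true(is.na(s$ratio))
  expect_true(is.na(s$precision))
  expect_true(is.na(s$recall))
  expect_true(is.na(s$f1))
})

test_that("overlap matching maps reference fires to all overlapping predictions", {
  ref <- list(R1 = square_geom(0, 0, 2000))
  pred <- list(P1 = square_geom(100, 100, 500),
               P2 = square_geom(1200, 1200, 500),
               P3 = square_geom(50000, 0, 500))
  m <- match_by_overlap(pred, ref)
  expect_length(m$mapping, 1)
  expect_setequal(m$mapping$R1, c("P1", "P2"))
  expect_equal(m$unmatched_pred, "P3")
  # no overlaps: empty mapping, everything unmatched
  m2 <- match_by_overlap(list(A = square_geom(0, 0, 10)),
                         list(B = square_geom(100, 100, 10)))
  expect_length(m2$mapping, 0)
  expect_equal(m2$unmatched_pred, "A")
  expect_equal(m2$unmatched_ref, "B")
  # identical sets: a bijection
  same <- list(X = square_geom(0, 0, 100), Y = square_geom(500, 500, 100))
  m3 <- match_by_overlap(same, same)
  expect_equal(m3$mapping, list(X = "X", Y = "Y"))
})

test_that("per-fire scores report the mean and population sd over reference fires", {
  ref <- list(R1 = square_geom(0, 0, 1000),
              R2 = square_geom(10000, 0, 1000))
  pred <- list(P1 = square_geom(0, 0, 1000),        # perfect match of R1
               P2 = square_geom(10000, 0, 1000 / 2))  # half of R2 (iou 0.5)
  pred$P2 <- fgeom(list(rbind(c(10000, 0), c(11000, 0), c(11000, 500),
                              c(10000, 500))))      # exactly half area
  m <- match_by_overlap(pred, ref)
  out <- per_fire_scores(m, pred, ref)
  expect_equal(nrow(out$per_fire), 2)
  expect_equal(unname(out$mean["iou"]), 0.75, tolerance = 1e-9)
  expect_equal(unname(out$sd["iou"]), 0.25, tolerance = 1e-9)
  # single reference fire: sd 0
  m1 <- match_by_overlap(pred["P1"], ref["R1"])
  out1 <- per_fire_scores(m1, pred["P1"], ref["R1"])
  expect_equal(unname(out1$sd["iou"]), 0)
  # an unmatched reference fire is excluded but counted
  ref3 <- c(ref, list(R3 = square_geom(50000, 0, 1000)))
  m3 <- match_by_overlap(pred, ref3)
  out3 <- per_fire_scores(m3, pred, ref3)
  expect_equal(nrow(out3$per_fire), 2)
  expect_equal(out3$n_unmatched_ref, 1)
})

test_that("a reference covering two predictions scores their union", {
  ref <- list(R = square_geom(0, 0, 1000))
  pred <- list(A = fgeom(list(rbind(c(0, 0), c(500, 0), c(500, 1000),
                                    c(0, 1000)))),
               B = fgeom(list(rbind(c(500, 0), c(1000, 0), c(1000, 1000),
                                    c(500, 1000)))))
  m <- match_by_overlap(pred, ref)
  out <- per_fire_scores(m, pred, ref)
  expect_equal(unname(out$mean["iou"]), 1, tolerance = 1e-9)
  expect_equal(unname(out$mean["ratio"]), 1, tolerance = 1e-9)
})
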