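test_that("iou matches brute-force set counting and is total", {
  expect_equal(iou(matrix(TRUE, 4, 4), matrix(TRUE, 4, 4)), 1)
  a <- matrix(FALSE, 4, 4); a[1:2, ] <- TRUE
  b <- matrix(FALSE, 4, 4); b[3:4, ] <- TRUE
  expect_equal(iou(a, b), 0)
  # equal-area masks overlapping on half their area: |I| = A/2, |U| = 3A/2
  a <- matrix(FALSE, 4, 4); a[, 1:2] <- TRUE
  b <- matrix(FALSE, 4, 4); b[, 2:3] <- TRUE
  expect_equal(iou(a, b), 1 / 3)
  expect_equal(iou(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), 1)
  expect_equal(iou(matrix(FALSE, 3, 3), matrix(TRUE, 3, 3)), 0)
  expect_error(iou(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shape")
  # brute force over random masks: count matching index sets
  set.seed(7)
  for (k in 1:50) {
    a <- matrix(runif(256) < 0.4, 16, 16)
    b <- matrix(runif(256) < 0.4, 16, 16)
    ia <- which(a); ib <- which(b)
    u <- length(union(ia, ib))
    expected <- if (u == 0) 1 else length(intersect(ia, ib)) / u
    expect_identical(iou(a, b), expected)
    expect_identical(iou(a, b), iou(b, a))
  }
})

test_that("detection loss reproduces the cross-entropy values", {
  expect_equal(detection_loss(c(0.5, 0.5), c(0, 1)), log(2))
  expect_equal(detection_loss(c(0.25, 0.75), c(1, 0)), -log(0.25))
  expect_lt(detection_loss(c(1e-12, 1 - 1e-12), c(0, 1)), 1e-9)
  expect_gt(detection_loss(c(1, 0), c(0, 1)), 20)  # clamped, finite
})

test_that("segmentation loss applies the class weight and matches a direct sum", {
  s <- matrix(0.5, 20, 20)
  lab <- matrix(0, 20, 20); lab[1:5, ] <- 1    # 100 skin / 300 non-skin
  expect_equal(segmentation_loss(s, lab), 600 * log(2))  # lambda = 3
  # perfect prediction: loss ~ 0
  perfect <- matrix(0, 20, 20); perfect[lab == 1] <- 1
  expect_lt(segmentation_loss(perfect, lab), 1e-6)
  expect_error(segmentation_loss(s, matrix(1, 20, 20)), "skin")
  # lambda forced to 1 equals unweighted cross-entropy by explicit loops
  set.seed(3)
  for (k in 1:5) {
    s4 <- matrix(runif(16, 0.05, 0.95), 4, 4)
    l4 <- matrix(rbinom(16, 1, 0.5), 4, 4)
    direct <- 0
    for (i in 1:4) for (j in 1:4) {
      direct <- direct - (1 - l4[i, j]) * log(1 - s4[i, j]) -
        l4[i, j] * log(s4[i, j])
    }
    expect_equal(segmentation_loss(s4, l4, lambda = 1), direct,
                 tolerance = 1e-9)
  }
})

test_that("unified loss combines task losses by their weights", {
  expect_equal(unified_loss(0.5, 2.0, 1, 1), 2.5)
  expect_equal(unified_loss(0.7, 2.0, 0, 1), 2.0)  # stage-1 regime
  expect_equal(unified_loss(0, 0), 0)
  expect_error(unified_loss(1, 1, -1, 1), "non-negative")
})

test_that("colour models separate skin from background and are monotone in threshold", {
  set.seed(2)
  skin <- cbind(rnorm(400, 220, 12), rnorm(400, 170, 12), rnorm(400, 148, 12))
  bg <- cbind(rnorm(400, 60, 12), rnorm(400, 68, 12), rnorm(400, 80, 12))
  px <- rbind(skin, bg)
  labels <- rep(c(1, 0), each = 400)
  frame <- array(0, c(20, 20, 3))
  fresh_s <- cbind(rnorm(200, 220, 12), rnorm(200, 170, 12), rnorm(200, 148, 12))
  fresh_b <- cbind(rnorm(200, 60, 12), rnorm(200, 68, 12), rnorm(200, 80, 12))
  for (ch in 1:3)
    frame[, , ch] <- matrix(c(fresh_s[, ch], fresh_b[, ch]), 20)
  truth <- matrix(rep(c(TRUE, FALSE), each = 200), 20)
  for (kind in c("gmm", "naive_bayes")) {
    model <- train_colour_model(px, labels, kind, seed = 4)
    cl <- classify_skin(frame, model)
    expect_gt(mean(cl$mask == truth), 0.99)
    expect_true(all(cl$probability >= 0 & cl$probability <= 1))
    # monotone thresholding: mask(t2) subset of mask(t1) for t1 < t2
    m1 <- classify_skin(frame, model, 0.3)$mask
    m2 <- classify_skin(frame, model, 0.7)$mask
    expect_true(all(m1[m2]))
    expect_equal(classify_skin(frame, model, 0)$n_skin, 400)
  }
  expect_error(train_colour_model(skin, rep(1, 400)), "non-skin")
  # tiny balanced input still fits
  small <- train_colour_model(px[c(1:10, 401:410), ],
                              labels[c(1:10, 401:410)], "naive_bayes")
  expect_equal(small$priors, c(0.5, 0.5))
})

test_that("classifier masks overlap the scene ground truth", {
  sc <- quiet_scene(duration = 5, noise_sd = 2, flicker_sd = 0.003)
  frame_ids <- c(10, 40, 70)
  px <- NULL; labels <- NULL
  for (i in frame_ids) {
    fr <- sc$frames$get_frame(i)
    m <- sc$truth$get_mask(i)
    sel <- seq(1, length(m), by = 7)
    px <- rbind(px, cbind(as.vector(fr[, , 1])[sel], as.vector(fr[, , 2])[sel],
                          as.vector(fr[, , 3])[sel]))
    labels <- c(labels, as.vector(m)[sel])
  }
  model <- train_colour_model(px, labels, "gmm", seed = 9)
  cl <- classify_skin(sc$frames$get_frame(55), model)
  expect_gt(iou(cl$mask, sc$truth$get_mask(55)), 0.8)
})

test_that("augmentation transforms have the stated identities", {
  sc <- quiet_scene(duration = 2, noise_sd = 0)
  fr <- sc$frames$get_frame(5)
  expect_equal(augment_image(fr, "rotate", 360), fr)
  expect_equal(augment_image(augment_image(fr, "mirror_x"), "mirror_x"), fr)
  expect_equal(augment_image(augment_image(fr, "mirror_y"), "mirror_y"), fr)
  expect_lt(max(abs(augment_image(fr, "lighting", 1.0) - fr)), 1)
  expect_error(augment_image(fr, "rotate", 30), "45")
  expect_error(augment_image(fr, "lighting", -1), "positive")
  # rotation + inverse rotation recovers the mask area within 2%
  mask3 <- array(0, c(64, 64, 3))
  mask3[20:45, 25:40, ] <- 255
  back <- augment_image(augment_image(mask3, "rotate", 45), "rotate", 315)
  a0 <- sum(mask3[, , 1] > 127)
  a1 <- sum(back[, , 1] > 127)
  expect_lt(abs(a1 - a0) / a0, 0.02)
})
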