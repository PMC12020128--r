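test_that("iou matches direct evaluations", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 2, 2), c(5, 5, 7, 7)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_equal(iou(c(0, 0, 0, 2), c(0, 0, 2, 2)), 0)  # degenerate box
})

test_that("greedy matching handles the edge cases and agrees with optimal", {
  b <- rbind(c(0, 0, 10, 10), c(20, 20, 30, 30))
  mt <- match_boxes(b, b)
  expect_equal(nrow(mt$pairs), 2L)
  expect_equal(mt$pairs[, "iou"], c(1, 1), ignore_attr = TRUE)
  mt0 <- match_boxes(matrix(numeric(0), 0, 4), b)
  expect_equal(mt0$unmatched_truth, c(1L, 2L))
  # brute-force assignment oracle maximizing total IoU (no ties): each
  # prediction is a jittered truth
  withr::with_seed(81, {
    for (rep in 1:20) {
      truths <- cbind(runif(3, 0, 30), runif(3, 0, 30), 0, 0)
      truths[, 3] <- truths[, 1] + runif(3, 8, 14)
      truths[, 4] <- truths[, 2] + runif(3, 8, 14)
      preds <- truths + matrix(runif(12, -2, 2), 3, 4)
      perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                    c(3, 1, 2), c(3, 2, 1))
      scores <- vapply(perms, function(pm) {
        sum(vapply(1:3, function(i) iou(preds[i, ], truths[pm[i], ]),
                   numeric(1)))
      }, numeric(1))
      best <- perms[[which.max(scores)]]
      mt <- match_boxes(preds, truths, iou_threshold = 0.1)
      got <- mt$pairs[order(mt$pairs[, 1]), 2]
      expect_equal(as.integer(got), best)
    }
  })
})

test_that("detection_train_loss matches direct evaluation and the oracle", {
  target <- random_target(1L, seed = 90L)
  perfect <- detections(target$boxes,
                        matrix(as.numeric(1:3 == target$class_ids[1] + 1L),
                               1, 3), 1)
  expect_equal(detection_train_loss(perfect, target), 0, tolerance = 1e-5)
  # half-confident true class, perfect box and objectness
  half <- perfect
  half$class_probs[1, target$class_ids[1] + 1L] <- 0.5
  expect_equal(detection_train_loss(half, target), -log(0.5),
               tolerance = 1e-5)
  withr::with_seed(91, {
    for (rep in 1:20) {
      target <- random_target(3L, seed = 900 + rep)
      pred <- detections(
        target$boxes + matrix(runif(12, -2, 2), 3, 4),
        matrix(runif(9), 3, 3), runif(3))
      expect_equal(detection_train_loss(pred, target),
                   oracle_det_loss(pred, target), tolerance = 1e-6)
    }
  })
})

test_that("dice loss matches its definition", {
  t <- matrix(rbinom(16 * 16, 1, 0.3), 16, 16)
  expect_equal(dice_loss(t, t), 0)
  expect_equal(dice_loss(matrix(0, 16, 16), t), 1)
  expect_equal(dice_loss(matrix(0, 4, 4), matrix(0, 4, 4)), 0)
  withr::with_seed(92, {
    for (rep in 1:20) {
      p <- matrix(runif(256), 16, 16)
      t <- matrix(rbinom(256, 1, 0.4), 16, 16)
      num <- 0; dp <- 0; dt <- 0
      for (i in 1:16) for (j in 1:16) {
        num <- num + p[i, j] * t[i, j]
        dp <- dp + p[i, j]^2; dt <- dt + t[i, j]^2
      }
      expect_equal(dice_loss(p, t), 1 - 2 * num / (dp + dt),
                   tolerance = 1e-6)
    }
  })
  expect_error(dice_loss(matrix(0, 4, 4), matrix(0, 5, 5)), "shape")
})

test_that("total loss is the weighted sum and linear in lambda", {
  expect_equal(total_train_loss(0.5, 0.25, 0), 0.5)
  expect_equal(total_train_loss(0.5, 0.25, 1), 0.75)
  l_aux <- 0.37
  slope <- (total_train_loss(0.2, l_aux, 0.8) -
              total_train_loss(0.2, l_aux, 0.3)) / 0.5
  expect_equal(slope, l_aux, tolerance = 1e-12)
})

test_that("zeroed fusion makes the dual forward equal independent forwards", {
  m <- zero_fusion(toy_model())
  sc <- toy_scenes(1L)[[1]]
  fused <- forward_fused(m, sc$image, fused = TRUE, nms = FALSE)
  indep <- forward_fused(m, sc$image, fused = FALSE, nms = FALSE)
  expect_identical(fused$raw, indep$raw)
  expect_identical(fused$mask, indep$mask)
})

test_that("forward output respects the head contracts and is deterministic", {
  m <- toy_model()
  sc <- toy_scenes(1L)[[1]]
  a <- forward_fused(m, sc$image, nms = FALSE)
  b <- forward_fused(m, sc$image, nms = FALSE)
  expect_identical(a$raw, b$raw)
  expect_equal(dim(a$mask), dim(sc$image)[1:2])
  expect_true(all(a$mask >= 0 & a$mask <= 1))
  expect_true(all(a$detections$confidence >= 0 & a$detections$confidence <= 1))
  expect_equal(dim(a$raw), c(m$grid, m$grid, 5L + m$num_classes))
})

test_that("toy backbone stages have the declared shapes and finite grads", {
  bb <- make_toy_backbone(3L, c(4L, 6L, 8L), seed = 9L)
  expect_identical(bb, make_toy_backbone(3L, c(4L, 6L, 8L), seed = 9L))
  x <- as_node(random_image(64, 64, seed = 3L))
  wrapped <- pestshift:::ag_wrap(bb)
  sizes <- c(32L, 16L, 8L)
  for (k in 1:3) {
    x <- pestshift:::backbone_stage_forward(x, wrapped[[k]])
    expect_equal(dim(ag_value(x)), c(sizes[k], sizes[k], c(4L, 6L, 8L)[k]))
  }
  ag_backward(ag_mean(x))
  g <- pestshift:::ag_grads(wrapped)
  expect_true(pestshift:::params_finite(g))
})

test_that("a zero learning rate leaves all parameters unchanged", {
  m <- toy_model()
  cfg <- toy_train_config()
  res <- train_step(m, toy_scenes(2L), cfg, lr = 0, freeze_gates = TRUE)
  # gate lr is separate; with freeze_gates the whole model must be unchanged
  expect_identical(res$model, m)
})

test_that("one small-lr step descends the batch loss", {
  m <- toy_model()
  cfg <- toy_train_config(momentum = 0)
  batch <- toy_scenes(4L)
  before <- train_step(m, batch, cfg, lr = 0, freeze_gates = TRUE)$loss
  small <- train_config(image_size = 48L, batch_size = 4L, dag_lr = 1e-4,
                        momentum = 0, seed = 3L)
  stepped <- train_step(m, batch, small, lr = 1e-3)
  after <- train_step(stepped$model, batch, small, lr = 0,
                      freeze_gates = TRUE)$loss
  expect_lt(after, before)
})

test_that("freezing the gate group leaves gate parameters bitwise unchanged", {
  m <- toy_model()
  res <- train_step(m, toy_scenes(2L), toy_train_config(), lr = 0.01,
                    freeze_gates = TRUE)
  expect_identical(res$model$gates, m$gates)
  res2 <- train_step(m, toy_scenes(2L), toy_train_config(), lr = 0.01,
                     freeze_gates = FALSE)
  expect_false(identical(res2$model$gates, m$gates))
})

test_that("training with zeroed frozen fusion reproduces independent trajectories", {
  scenes <- toy_scenes(4L)
  cfg <- toy_train_config()
  m <- zero_fusion(toy_model())
  two_steps <- function(fused) {
    mm <- m; opt <- NULL
    for (i in 1:2) {
      r <- train_step(mm, scenes, cfg, lr = 0.01, freeze_gates = TRUE,
                      fused = fused, opt = opt)
      mm <- r$model; opt <- r$opt
    }
    mm
  }
  m_fused <- two_steps(TRUE)
  m_indep <- two_steps(FALSE)
  expect_identical(m_fused$main_backbone, m_indep$main_backbone)
  expect_identical(m_fused$aux_backbone, m_indep$aux_backbone)
  expect_identical(m_fused$main_head, m_indep$main_head)
  expect_identical(m_fused$aux_head, m_indep$aux_head)
})

test_that("checkpoints round-trip through JSON", {
  m <- toy_model()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  sc <- toy_scenes(1L)[[1]]
  a <- forward_fused(m, sc$image, nms = FALSE)
  b <- forward_fused(m2, sc$image, nms = FALSE)
  expect_equal(a$raw, b$raw, tolerance = 1e-12)
  expect_equal(a$mask, b$mask, tolerance = 1e-12)
})
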