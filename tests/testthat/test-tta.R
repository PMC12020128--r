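test_that("the variant generator emits the configured count, seeded", {
  img <- random_image(16, 16, seed = 1L)
  cfg <- tta_config(seed = 5L)
  vs <- generate_variants(img, cfg)
  expect_length(vs, 16L)
  for (v in vs) {
    expect_equal(dim(v), dim(img))
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_identical(generate_variants(img, cfg), vs)
  expect_false(identical(generate_variants(img, tta_config(seed = 6L)), vs))
})

test_that("identity settings reproduce the input in every variant", {
  img <- random_image(16, 16, seed = 2L)
  cfg <- tta_config(noise_alpha = 0, brightness_factor_range = c(1, 1),
                    offset_range = c(0, 0), seed = 7L)
  for (v in generate_variants(img, cfg)) expect_equal(v, img)
})

test_that("image confidence is the mean post-NMS box confidence", {
  det <- detections(rbind(c(0, 0, 5, 5), c(10, 10, 15, 15)),
                    matrix(0.5, 2, 3), c(0.9, 0.7))
  expect_equal(image_confidence(det), 0.8)
  expect_equal(image_confidence(pestshift:::detections_empty(3L)), 0)
  perm <- pestshift:::detections_subset(det, c(2L, 1L))
  expect_equal(image_confidence(perm), 0.8)
})

make_result <- function(conf, mask_val = 0.5, H = 8L) {
  det <- if (length(conf)) {
    detections(cbind(0, 0, 4, 4)[rep(1, length(conf)), , drop = FALSE],
               matrix(1 / 3, length(conf), 3), conf)
  } else {
    pestshift:::detections_empty(3L)
  }
  list(detections = det, mask = matrix(mask_val, H, H))
}

test_that("pseudo-label selection is an argmax with documented tie-breaks", {
  results <- c(list(make_result(0.1)), list(make_result(0.9)),
               replicate(3, make_result(0.1), simplify = FALSE))
  pl <- select_pseudo_label(results)
  expect_equal(pl$source_variant, 1L)  # 0-based: second entry wins
  expect_equal(pl$conf, 0.9)
  # all equal -> variant 0, main model
  same <- replicate(4, make_result(0.6), simplify = FALSE)
  pl0 <- select_pseudo_label(same)
  expect_equal(pl0$source_variant, 0L)
  expect_equal(pl0$source_model, "main")
  # linear-scan oracle on random scores (aux margin 0: mask at 0.5)
  withr::with_seed(55, {
    for (rep in 1:10) {
      confs <- runif(6, 0.01, 0.99)
      results <- lapply(confs, make_result)
      pl <- select_pseudo_label(results)
      expect_equal(pl$source_variant, which.max(confs) - 1L)
    }
  })
  expect_error(select_pseudo_label(list()), "no variant")
})

test_that("pseudo-label masks are binarized and boxes keep the original frame", {
  res <- list(list(detections = detections(cbind(1, 2, 7, 9),
                                           matrix(c(0.9, 0.05, 0.05), 1, 3),
                                           0.8),
                   mask = matrix(c(0.8, 0.2), 4, 4)))
  pl <- select_pseudo_label(res)
  expect_true(all(pl$mask %in% c(0, 1)))
  expect_equal(pl$boxes, cbind(1, 2, 7, 9), ignore_attr = TRUE)
  expect_equal(pl$class_ids, 0L)
})

test_that("tta_main_loss matches direct evaluation and the loop oracle", {
  boxes <- rbind(c(0.1, 0.1, 0.4, 0.4))
  pl <- pseudo_label(boxes, 0L, matrix(c(1, 0, 0), 1, 3), 1,
                     matrix(0, 4, 4))
  pred <- detections(boxes, matrix(c(1, 0, 0), 1, 3), 1)
  expect_equal(tta_main_loss(pred, pl), 0, tolerance = 1e-5)
  # single box offset by delta in every coordinate -> loc = 4 delta^2
  delta <- 0.05
  pred2 <- detections(boxes + delta, matrix(c(1, 0, 0), 1, 3), 1)
  expect_equal(tta_main_loss(pred2, pl), 4 * delta^2, tolerance = 1e-4)
  withr::with_seed(56, {
    for (rep in 1:20) {
      tb <- cbind(runif(3, 0, 20), runif(3, 0, 20), 0, 0)
      tb[, 3] <- tb[, 1] + runif(3, 8, 12)
      tb[, 4] <- tb[, 2] + runif(3, 8, 12)
      pl <- pseudo_label(tb, sample(0:2, 3, TRUE),
                         matrix(runif(9), 3, 3), runif(3),
                         matrix(0, 4, 4))
      pred <- detections(tb + matrix(runif(12, -1, 1), 3, 4),
                         matrix(runif(9), 3, 3), runif(3))
      expect_equal(tta_main_loss(pred, pl, image_size = 32),
                   oracle_tta_main(pred, pl, 32), tolerance = 1e-6)
    }
  })
})

test_that("tta_aux_loss matches the normalized double-loop oracle", {
  g <- matrix(rbinom(64, 1, 0.5), 8, 8)
  expect_equal(tta_aux_loss(g, g), 0)
  expect_equal(tta_aux_loss(matrix(0, 8, 8), matrix(1, 8, 8)), 1)
  withr::with_seed(57, {
    for (rep in 1:10) {
      s <- matrix(runif(256), 16, 16)
      g <- matrix(rbinom(256, 1, 0.5), 16, 16)
      acc <- 0
      for (i in 1:16) for (j in 1:16) acc <- acc + (s[i, j] - g[i, j])^2
      expect_equal(tta_aux_loss(s, g), acc / 256, tolerance = 1e-6)
    }
  })
  expect_error(tta_aux_loss(matrix(0, 4, 4), matrix(0, 5, 5)), "shape")
})

test_that("eta = 0 leaves the model and its prediction unchanged", {
  m <- trained_toy_model()
  sc <- toy_scenes(1L, seed = 200L)[[1]]
  cfg <- tta_config(eta = 0, seed = 9L)
  before <- predict_scene(m, sc$image)
  res <- tta_step(m, sc$image, cfg)
  expect_identical(res$model$main_backbone, m$main_backbone)
  expect_identical(res$model$aux_head, m$aux_head)
  expect_equal(res$detections$boxes, before$detections$boxes)
  expect_equal(res$mask, before$mask)
})

test_that("gates stay frozen during adaptation unless adapt_dag is set", {
  m <- trained_toy_model()
  sc <- toy_scenes(1L, seed = 201L)[[1]]
  res <- tta_step(m, sc$image, tta_config(eta = 1e-3, seed = 10L))
  expect_identical(res$model$gates, m$gates)
  res2 <- tta_step(m, sc$image,
                   tta_config(eta = 1e-3, adapt_dag = TRUE, seed = 10L))
  expect_false(identical(res2$model$gates, m$gates))
})

test_that("one adaptation step descends the loss against its pseudo-label", {
  m <- trained_toy_model()
  scenes <- toy_scenes(4L, seed = 202L)
  shifted <- lapply(scenes, apply_corruption,
                    spec = corruption_spec("BR", 0.5, seed = 3L))
  cfg <- tta_config(eta = 1e-4, seed = 11L)
  for (sc in shifted) {
    res <- tta_step(m, sc$image, cfg)
    after <- tta_total_loss(res$model, sc$image, res$pseudo_label, cfg)
    expect_lt(after, res$loss)
  }
})

test_that("a self-consistent prediction yields zero loss and gradient", {
  # construct a pseudo-label exactly equal to a one-hot prediction
  pl <- pseudo_label(rbind(c(2, 2, 10, 10)), 1L, matrix(c(0, 1, 0), 1, 3),
                     1, matrix(0, 16, 16))
  pred <- detections(rbind(c(2, 2, 10, 10)), matrix(c(0, 1, 0), 1, 3), 1)
  expect_equal(tta_main_loss(pred, pl, image_size = 16), 0, tolerance = 1e-5)
  expect_equal(tta_aux_loss(matrix(0, 16, 16), pl$mask), 0)
})

test_that("repeated adaptation on pure noise keeps parameters finite", {
  m <- trained_toy_model()
  cfg <- tta_config(eta = 1e-3, seed = 12L)
  withr::with_seed(58, {
    for (i in 1:25) {
      img <- array(runif(48 * 48 * 3), c(48, 48, 3))
      res <- tta_step(m, img, cfg)
      m <- res$model
    }
  })
  expect_true(pestshift:::params_finite(m$main_backbone))
  expect_true(pestshift:::params_finite(m$aux_backbone))
  expect_true(pestshift:::params_finite(m$main_head))
  expect_true(pestshift:::params_finite(m$aux_head))
})

test_that("continual adaptation reduces to plain evaluation when eta = 0", {
  m <- trained_toy_model()
  scenes <- toy_scenes(4L, seed = 203L)
  stream <- list(list(domain = "clean", scenes = scenes))
  cfg <- tta_config(eta = 0, seed = 13L)
  res <- continual_adapt(m, stream, cfg)
  preds <- lapply(scenes, function(sc) predict_scene(m, sc$image)$detections)
  direct <- metric_set(preds, scenes)
  expect_equal(res$per_domain$map50, direct$map50)
  expect_equal(res$per_domain$precision, direct$precision)
  # determinism across reruns
  res2 <- continual_adapt(m, stream, cfg)
  expect_equal(res$per_domain, res2$per_domain)
})

test_that("adaptation state carries across domains (order matters)", {
  m <- trained_toy_model()
  scenes <- toy_scenes(3L, seed = 204L)
  blocks <- list(
    list(domain = "BR", scenes = lapply(scenes, apply_corruption,
                                        spec = corruption_spec("BR", 0.8, 1L))),
    list(domain = "DA", scenes = lapply(scenes, apply_corruption,
                                        spec = corruption_spec("DA", 0.8, 2L))))
  cfg <- tta_config(eta = 5e-3, seed = 14L)
  fwd <- continual_adapt(m, blocks, cfg)
  rev <- continual_adapt(m, blocks[c(2, 1)], cfg)
  # the DA block is seen with different incoming weights in the two orders,
  # so the final model states differ
  expect_false(isTRUE(all.equal(fwd$model$main_backbone,
                                rev$model$main_backbone)))
})
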