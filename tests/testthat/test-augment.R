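test_that("bce_loss matches direct evaluations and the loop oracle", {
  expect_equal(bce_loss(matrix(c(1, 0), 1), matrix(c(1, 0), 1)), 0,
               tolerance = 1e-6)
  expect_equal(bce_loss(matrix(0.5), matrix(1)), -log(0.5),
               tolerance = 1e-9)
  withr::with_seed(31, {
    for (rep in 1:20) {
      probs <- matrix(runif(12, 0.01, 0.99), 3, 4)
      labels <- matrix(rbinom(12, 1, 0.5), 3, 4)
      expect_equal(bce_loss(probs, labels), oracle_bce(probs, labels),
                   tolerance = 1e-6)
    }
  })
})

test_that("dif_loss matches direct evaluation and the loop oracle", {
  a <- list(array(0.3, c(2, 2, 3)))
  expect_equal(dif_loss(a, a), 0)
  expect_equal(dif_loss(list(array(0, c(1, 1, 1))),
                        list(array(0.5, c(1, 1, 1)))), 0.25)
  withr::with_seed(32, {
    for (rep in 1:10) {
      oris <- lapply(1:4, function(i) array(runif(8 * 8 * 3), c(8, 8, 3)))
      augs <- lapply(1:4, function(i) array(runif(8 * 8 * 3), c(8, 8, 3)))
      expect_equal(dif_loss(oris, augs), oracle_dif(oris, augs),
                   tolerance = 1e-6)
    }
  })
  expect_error(dif_loss(list(a[[1]]), list()))
})

test_that("bdf_loss matches the pairwise oracle and is permutation-invariant", {
  one <- list(array(0.2, c(2, 2, 3)))
  expect_equal(bdf_loss(one), 0)
  expect_equal(bdf_loss(c(one, one)), 0)
  withr::with_seed(33, {
    for (rep in 1:10) {
      augs <- lapply(1:4, function(i) array(runif(8 * 8 * 3), c(8, 8, 3)))
      expect_equal(bdf_loss(augs), oracle_bdf(augs), tolerance = 1e-6)
      perm <- sample(4)
      expect_equal(bdf_loss(augs[perm]), bdf_loss(augs), tolerance = 1e-12)
    }
  })
})

test_that("weak noise augmentation has the mapped standard deviation", {
  img <- array(0.5, c(640, 540, 3))
  expect_identical(weak_augment_noise(img, 0, seed = 1L), img)
  out <- weak_augment_noise(img, 8, seed = 2L)
  expect_equal(stats::sd(out - img), 8 / 255, tolerance = 0.05)
  ones <- array(1, c(8, 8, 3))
  expect_true(all(weak_augment_noise(ones, 16, seed = 3L) <= 1))
  expect_error(weak_augment_noise(img, -1))
})

test_that("weak brightness adjustment is the clipped affine map", {
  img <- array(0.5, c(4, 4, 3))
  expect_identical(weak_augment_brightness(img, 1, 0), img)
  expect_equal(weak_augment_brightness(array(0.5, c(1, 1, 3)), 1.3, 0.3),
               array(0.95, c(1, 1, 3)))
  withr::with_seed(34, {
    for (rep in 1:20) {
      img <- array(runif(4 * 4 * 3), c(4, 4, 3))
      beta <- runif(1, 0.7, 1.3); B <- runif(1, -0.3, 0.3)
      oracle <- img
      for (i in seq_along(img)) {
        oracle[i] <- min(max(beta * img[i] + B, 0), 1)
      }
      expect_equal(weak_augment_brightness(img, beta, B), oracle,
                   tolerance = 1e-6)
    }
  })
})

test_that("the untrained generator is identity-dominant", {
  state <- strong_augmenter_state(3L, seed = 40L)
  imgs <- lapply(1:2, function(i) random_image(16, 16, seed = i))
  outs <- strong_augment(imgs, state)
  expect_length(outs, 2L)
  for (i in 1:2) {
    expect_equal(dim(outs[[i]]), dim(imgs[[i]]))
    expect_lt(max(abs(outs[[i]] - imgs[[i]])), 0.1)
    expect_true(all(outs[[i]] >= 0 & outs[[i]] <= 1))
  }
  expect_error(strong_augment(list(random_image(16, 16), random_image(8, 8)),
                              state))
})

test_that("strong augmenter gradients are finite and not all zero", {
  state <- strong_augmenter_state(3L, seed = 41L)
  # perturb the final layer so the generator is off identity
  state$generator$w4 <- state$generator$w4 + 0.01
  img <- random_image(16, 16, seed = 9L)
  gp <- ag_wrap(state$generator)
  out <- pestshift:::generator_forward(img, gp)
  ag_backward(ag_mean(out))
  g <- pestshift:::ag_grads(gp)
  expect_true(pestshift:::params_finite(g))
  expect_gt(sum(abs(unlist(g))), 0)
})

test_that("zero learning rate leaves the generator unchanged", {
  state <- strong_augmenter_state(3L, alpha = 0, seed = 42L)
  scenes <- toy_scenes(3L, seed = 50L)
  batch <- lapply(scenes, `[[`, "image")
  labels <- scene_class_labels(scenes, 3L)
  out <- update_strong_augmenter(state, batch, labels)
  expect_identical(out$generator, state$generator)
  expect_identical(out$classifier, state$classifier)
  expect_equal(out$rounds_done, 1L)
})

test_that("one generator step descends its combined objective", {
  scenes <- toy_scenes(4L, seed = 51L)
  batch <- lapply(scenes, `[[`, "image")
  labels <- scene_class_labels(scenes, 3L)
  objective <- function(state) {
    augs <- strong_augment(batch, state)
    probs <- t(vapply(augs, function(a) {
      ag_value(pestshift:::classifier_forward(a, ag_wrap(state$classifier)))
    }, numeric(3)))
    state$lambda_bce * bce_loss(probs, labels) -
      state$lambda_d * (state$lambda_dif * dif_loss(batch, augs) +
                          state$lambda_bdf * bdf_loss(augs))
  }
  state <- strong_augmenter_state(3L, alpha = 1e-3, seed = 43L)
  state$generator$w4 <- state$generator$w4 + 0.01
  before <- objective(state)
  stepped <- update_strong_augmenter(state, batch, labels)
  # evaluate the generator objective with the OLD classifier (the quantity
  # the generator step descended)
  stepped_gen_only <- state
  stepped_gen_only$generator <- stepped$generator
  expect_lt(objective(stepped_gen_only), before)
})

test_that("a classifier step with frozen generator decreases its BCE", {
  scenes <- toy_scenes(4L, seed = 52L)
  batch <- lapply(scenes, `[[`, "image")
  labels <- scene_class_labels(scenes, 3L)
  state <- strong_augmenter_state(3L, alpha = 1e-3, seed = 44L)
  cls_bce <- function(state) {
    augs <- strong_augment(batch, state)
    inputs <- c(augs, batch)
    probs <- t(vapply(inputs, function(a) {
      ag_value(pestshift:::classifier_forward(a, ag_wrap(state$classifier)))
    }, numeric(3)))
    bce_loss(probs, rbind(labels, labels))
  }
  before <- cls_bce(state)
  stepped <- update_strong_augmenter(state, batch, labels)
  after_state <- state
  after_state$classifier <- stepped$classifier
  expect_lt(cls_bce(after_state), before)
})

test_that("with lambda_d = 0 repeated updates keep BCE non-increasing", {
  scenes <- toy_scenes(4L, seed = 53L)
  batch <- lapply(scenes, `[[`, "image")
  labels <- scene_class_labels(scenes, 3L)
  state <- strong_augmenter_state(3L, alpha = 5e-3, lambda_d = 0, seed = 45L)
  gen_bce <- function(state) {
    augs <- strong_augment(batch, state)
    probs <- t(vapply(augs, function(a) {
      ag_value(pestshift:::classifier_forward(a, ag_wrap(state$classifier)))
    }, numeric(3)))
    bce_loss(probs, labels)
  }
  first <- gen_bce(state)
  for (i in 1:10) state <- update_strong_augmenter(state, batch, labels)
  expect_lte(gen_bce(state), first)
})

test_that("build_augmented_datasets assembles the 7x combined set", {
  scenes <- toy_scenes(10L, seed = 54L)
  state <- strong_augmenter_state(3L, seed = 46L)
  state <- train_strong_augmenter(state, scenes, rounds = 4L)
  cfg <- weak_augmenter_config(seed = 60L)
  ds <- build_augmented_datasets(scenes, state, cfg)
  expect_length(ds$strong, 30L)
  expect_length(ds$weak, 30L)
  expect_length(combined_scenes(ds), 70L)
  # label invariance: every augmented scene keeps its source labels
  for (i in seq_along(ds$strong)) {
    src <- scenes[[(i - 1L) %% 10L + 1L]]
    expect_identical(ds$strong[[i]]$boxes, src$boxes)
    expect_identical(ds$weak[[i]]$boxes, src$boxes)
    expect_identical(ds$weak[[i]]$mask, src$mask)
  }
  # weak augmentation is deterministic in the config seed
  ds2 <- build_augmented_datasets(scenes, state, cfg)
  expect_identical(lapply(ds2$weak, `[[`, "image"),
                   lapply(ds$weak, `[[`, "image"))
  # too few completed rounds is an error
  fresh <- strong_augmenter_state(3L, seed = 47L)
  fresh <- train_strong_augmenter(fresh, scenes, rounds = 2L)
  expect_error(build_augmented_datasets(scenes, fresh, cfg), "rounds")
})

test_that("augmented images stay in range", {
  scenes <- toy_scenes(4L, seed = 55L)
  state <- strong_augmenter_state(3L, seed = 48L)
  state <- train_strong_augmenter(state, scenes, rounds = 3L)
  ds <- build_augmented_datasets(scenes, state, weak_augmenter_config(seed = 61L))
  for (sc in combined_scenes(ds)) {
    expect_true(all(sc$image >= 0 & sc$image <= 1))
  }
})
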