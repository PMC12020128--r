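zeroed_gate <- function(C, seed = 1L) gate_zero_transform(gate_params(C, seed = seed))

test_that("gate weight is the sigmoid of the pooled affine descriptor", {
  f <- array(runif(8 * 8 * 4), c(8, 8, 4))
  p <- gate_params(4L, seed = 2L)
  p$W[] <- 0; p$b[] <- 0
  expect_equal(gate_weight(f, p), rep(0.5, 4))
  p$b[] <- 20
  expect_equal(gate_weight(f, p), rep(1, 4), tolerance = 1e-6)
  # loop oracle on random parameters
  withr::with_seed(71, {
    for (rep in 1:20) {
      p <- gate_params(4L, seed = rep)
      p$W <- matrix(rnorm(16), 4, 4); p$b <- rnorm(4)
      f <- array(runif(8 * 8 * 4, -1, 1), c(8, 8, 4))
      desc <- vapply(1:4, function(c) mean(f[, , c]), numeric(1))
      oracle <- vapply(1:4, function(r) {
        1 / (1 + exp(-(sum(p$W[r, ] * desc) + p$b[r])))
      }, numeric(1))
      g <- gate_weight(f, p)
      expect_equal(g, oracle, tolerance = 1e-6)
      expect_true(all(g > 0 & g < 1))
    }
  })
})

test_that("gate transform is the elementwise GeLU of the 1x1 affine", {
  f <- array(runif(6 * 6 * 3), c(6, 6, 3))
  p <- gate_params(3L, seed = 3L)
  p$U[] <- 0; p$e[] <- 0
  expect_equal(gate_transform(f, p), array(0, c(6, 6, 3)))
  p$e[] <- 3
  expect_equal(gate_transform(f, p), array(3 * pnorm(3), c(6, 6, 3)),
               tolerance = 1e-4)
  withr::with_seed(72, {
    for (rep in 1:10) {
      p <- gate_params(3L, seed = 100 + rep)
      f <- array(runif(4 * 4 * 3, -1, 1), c(4, 4, 3))
      oracle <- array(0, c(4, 4, 3))
      for (i in 1:4) for (j in 1:4) for (co in 1:3) {
        z <- sum(f[i, j, ] * p$U[, co]) + p$e[co]
        oracle[i, j, co] <- z * pnorm(z)
      }
      expect_equal(gate_transform(f, p), oracle, tolerance = 1e-6)
    }
  })
})

test_that("fusion adds the gated message onto the destination", {
  f_src <- array(runif(8 * 8 * 4), c(8, 8, 4))
  f_dst <- array(runif(8 * 8 * 4), c(8, 8, 4))
  # zeroed transform: identity fusion
  expect_identical(gate_fuse(f_src, f_dst, zeroed_gate(4L)), f_dst)
  # open gate (b -> +inf): output = dst + transform
  p <- gate_params(4L, seed = 5L)
  p$W[] <- 0; p$b[] <- 50
  o <- gate_transform(f_src, p)
  expect_equal(gate_fuse(f_src, f_dst, p), f_dst + o, tolerance = 1e-6)
  # loop oracle
  withr::with_seed(73, {
    for (rep in 1:10) {
      p <- gate_params(4L, seed = 200 + rep)
      f_src <- array(runif(4 * 4 * 4, -1, 1), c(4, 4, 4))
      f_dst <- array(runif(4 * 4 * 4, -1, 1), c(4, 4, 4))
      x <- gate_weight(f_src, p)
      o <- gate_transform(f_src, p)
      oracle <- f_dst
      for (i in 1:4) for (j in 1:4) for (c in 1:4) {
        oracle[i, j, c] <- x[c] * o[i, j, c] + f_dst[i, j, c]
      }
      expect_equal(gate_fuse(f_src, f_dst, p), oracle, tolerance = 1e-6)
    }
  })
  expect_error(gate_fuse(array(0, c(4, 4, 2)), f_dst, p), "channel")
})

test_that("bidirectional fusion is simultaneous and matches two fuse calls", {
  f_main <- array(runif(8 * 8 * 4), c(8, 8, 4))
  f_aux <- array(runif(8 * 8 * 4), c(8, 8, 4))
  p_ma <- gate_params(4L, seed = 6L)
  p_am <- gate_params(4L, seed = 7L)
  out <- bidirectional_fuse(f_main, f_aux, p_ma, p_am)
  expect_equal(out$main, gate_fuse(f_aux, f_main, p_am))
  expect_equal(out$aux, gate_fuse(f_main, f_aux, p_ma))
  # zeroed transforms leave both unchanged
  out0 <- bidirectional_fuse(f_main, f_aux, zeroed_gate(4L), zeroed_gate(4L))
  expect_identical(out0$main, f_main)
  expect_identical(out0$aux, f_aux)
  expect_error(bidirectional_fuse(f_main, f_aux, p_ma, p_am,
                                  stage_main = 1L, stage_aux = 2L), "stage")
})

test_that("fusion output is differentiable in the gate parameters", {
  withr::with_seed(74, {
    f_src <- array(runif(6 * 6 * 3), c(6, 6, 3))
    f_dst <- array(runif(6 * 6 * 3), c(6, 6, 3))
    p <- gate_params(3L, seed = 8L)
    wp <- ag_wrap(unclass(p))
    out <- ag_mean(pestshift:::gate_fuse_graph(ag_leaf(f_src),
                                               ag_leaf(f_dst), wp))
    ag_backward(out)
    # finite-difference spot check on W
    f_of_W <- function(W) {
      p2 <- p; p2$W <- W
      mean(gate_fuse(f_src, f_dst, p2))
    }
    eps <- 1e-6
    for (i in c(1L, 5L)) {
      W2 <- p$W; W2[i] <- W2[i] + eps
      fd <- (f_of_W(W2) - f_of_W(p$W)) / eps
      expect_equal(wp$W$grad[i], fd, tolerance = 1e-4)
      expect_true(abs(wp$W$grad[i]) > 0)
    }
  })
})

test_that("gates learn to shut a pure-noise source branch", {
  # branch a carries pure noise; branch b's target ignores a entirely, so
  # training should shrink the gated message magnitude (multi-seed version
  # in the acceptance suite)
  for (seed in 1L) {
    withr::with_seed(1000 + seed, {
      C <- 4L
      p <- gate_params(C, init_scale = 0.3, seed = 300 + seed)
      dsts <- lapply(1:4, function(i) array(runif(6 * 6 * C), c(6, 6, C)))
      targets <- dsts  # the destination branch is already right: ignore a
      msg_norm <- function(p) {
        mean(vapply(1:4, function(i) {
          src <- array(rnorm(6 * 6 * C), c(6, 6, C))
          sqrt(mean((gate_fuse(src, dsts[[i]], p) - dsts[[i]])^2))
        }, numeric(1)))
      }
      init_norm <- msg_norm(p)
      params <- unclass(p)
      for (step in 1:200) {
        src <- array(rnorm(6 * 6 * C), c(6, 6, C))
        i <- sample(4, 1)
        wp <- ag_wrap(params)
        fused <- pestshift:::gate_fuse_graph(ag_leaf(src),
                                             ag_leaf(dsts[[i]]), wp)
        loss <- ag_mean(ag_mul(ag_sub(fused, targets[[i]]),
                               ag_sub(fused, targets[[i]])))
        ag_backward(loss)
        params <- pestshift:::sgd_step(params, pestshift:::ag_grads(wp), 0.05)
      }
      final_norm <- msg_norm(structure(params, class = "gate_params"))
      expect_lt(final_norm, init_norm)
    })
  }
})
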