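# Shared fixtures. Toy experiments run on 48x48 scenes with a small
# dual-branch model so the whole suite stays within a CPU-minutes budget;
# expensive artifacts (the trained toy checkpoint) are built once per session
# and memoized.

.fixtures <- new.env(parent = emptyenv())

toy_spec <- function(seed = 11L, ...) {
  scene_spec(image_height = 48L, image_width = 48L, num_classes = 3L,
             seed = seed, ...)
}

toy_scenes <- function(n = 8L, seed = 11L, ...) {
  generate_scenes(toy_spec(seed = seed, ...), n)
}

toy_model <- function(seed = 2L) {
  dual_branch_model(3L, image_size = 48L, stages = 2L,
                    channels = c(8L, 12L), head_hidden = 12L, seed = seed)
}

toy_train_config <- function(seed = 3L, ...) {
  train_config(image_size = 48L, batch_size = 8L, seed = seed, ...)
}

# a toy checkpoint trained on clean scenes; memoized across tests
trained_toy_model <- function() {
  if (!is.null(.fixtures$trained)) return(.fixtures$trained)
  scenes <- toy_scenes(24L, seed = 101L)
  cfg <- toy_train_config(lr_init = 0.05, lr_final = 0.005,
                          schedule = "cosine")
  fit <- train_dual_branch(toy_model(seed = 5L), scenes, cfg, steps = 250L)
  .fixtures$trained <- fit$model
  fit$model
}

# connected components of a binary matrix (4-connectivity flood fill);
# independent oracle for mask/object counts
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (start in which(mask > 0 & lab == 0L)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    H <- nrow(mask)
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      i <- (cur - 1L) %% H + 1L
      j <- (cur - 1L) %/% H + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] >= 1 && nb[1] <= H && nb[2] >= 1 && nb[2] <= ncol(mask)) {
          k <- nb[1] + (nb[2] - 1L) * H
          if (mask[k] > 0 && lab[k] == 0L) {
            lab[k] <- comp
            queue <- c(queue, k)
          }
        }
      }
    }
  }
  comp
}

random_image <- function(H = 8L, W = 8L, seed = 1L) {
  withr::with_seed(seed, array(stats::runif(H * W * 3), c(H, W, 3)))
}
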