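# Learnable dynamic augmentation. A small residual encoder-decoder generator
# ("strong augmenter") is trained adversarially against a class-consistency
# classifier: the generator minimizes the classifier's binary cross-entropy
# (so augmented images keep their classes) while maximizing (i) the mean
# squared difference to the originals and (ii) the pairwise difference within
# each augmented batch. A fixed stochastic "weak augmenter" adds Gaussian
# noise and affine brightness changes. Outputs from the final retained rounds
# of the strong augmenter, three weak rounds, and the originals together form
# a 7x training set.

BCE_EPS <- 1e-7

# ---- weak augmenter --------------------------------------------------------

#' Weak augmenter configuration
#'
#' @param sigma_levels Gaussian noise standard deviations on the 0-255
#'   intensity scale (divided by 255 when applied to `[0,1]` images)
#' @param beta_range brightness scaling factor range
#' @param offset_range brightness offset range
#' @param rounds number of weak rounds (each multiplies the dataset once)
#' @param seed integer seed
#' @return an object of class `weak_augmenter_config`
#' @export
weak_augmenter_config <- function(sigma_levels = c(4, 8, 12, 16),
                                  beta_range = c(0.7, 1.3),
                                  offset_range = c(-0.3, 0.3),
                                  rounds = 3L, seed = 1L) {
  stopifnot(all(sigma_levels >= 0), beta_range[1] <= beta_range[2],
            offset_range[1] <= offset_range[2], rounds >= 1)
  structure(list(sigma_levels = sigma_levels, beta_range = beta_range,
                 offset_range = offset_range, rounds = as.integer(rounds),
                 seed = as.integer(seed)),
            class = "weak_augmenter_config")
}

#' Add Gaussian pixel noise (weak augmentation)
#'
#' @param image H x W x 3 array in `[0,1]`
#' @param sigma noise standard deviation on the 0-255 scale
#' @param seed integer seed
#' @return noisy image, clipped to `[0,1]`
#' @export
weak_augment_noise <- function(image, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  d <- dim(image)
  out <- with_seed(derive_seed(seed, "weak-noise"), {
    image + array(stats::rnorm(length(image), 0, sigma / 255), d)
  })
  out <- pmin(pmax(out, 0), 1)
  dim(out) <- d
  out
}

#' Affine brightness adjustment (weak augmentation)
#'
#' Computes `beta * image + offset`, clipped to `[0,1]`.
#' @param image H x W x 3 array in `[0,1]`
#' @param beta scaling factor
#' @param offset additive offset
#' @return adjusted image
#' @export
weak_augment_brightness <- function(image, beta, offset) {
  out <- pmin(pmax(beta * image + offset, 0), 1)
  dim(out) <- dim(image)
  out
}

# ---- losses (plain-numeric surface) ----------------------------------------

#' Class-consistency binary cross-entropy
#'
#' Mean over images and classes of the multi-label binary cross-entropy
#' between predicted class probabilities and binary presence labels.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` before logs.
#'
#' @param probs n x K matrix (or K-vector) of predicted probabilities
#' @param labels matching binary matrix/vector
#' @return scalar loss
#' @export
bce_loss <- function(probs, labels) {
  probs <- as.matrix(probs); labels <- as.matrix(labels)
  stopifnot(all(dim(probs) == dim(labels)))
  p <- pmin(pmax(probs, BCE_EPS), 1 - BCE_EPS)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Original-vs-augmented difference loss
#'
#' Sum over image pairs of the per-pixel mean squared difference between each
#' original and its augmented version.
#' @param originals,augments equal-length lists of equal-shape arrays
#' @return scalar loss
#' @export
dif_loss <- function(originals, augments) {
  if (length(originals) != length(augments)) stop("paired lists required")
  sum(vapply(seq_along(originals), function(i) {
    mean((originals[[i]] - augments[[i]])^2)
  }, numeric(1)))
}

#' Within-batch augmentation diversity loss
#'
#' Mean over unordered pairs of augmented images of the per-pixel mean squared
#' difference; 0 for fewer than two images.
#' @param augments list of equal-shape arrays
#' @return scalar loss
#' @export
bdf_loss <- function(augments) {
  n <- length(augments)
  if (n < 2) return(0)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (!all(dim(augments[[i]]) == dim(augments[[j]]))) {
      stop("augmented batch images must share a shape")
    }
    tot <- tot + mean((augments[[i]] - augments[[j]])^2)
  }
  tot * 2 / (n * (n - 1))
}

# ---- strong augmenter ------------------------------------------------------

init_generator_params <- function(seed) {
  with_seed(derive_seed(seed, "generator-init"), list(
    w1 = matrix(stats::rnorm(9 * 3 * 8, 0, 0.08), 9 * 3, 8), b1 = numeric(8),
    w2 = matrix(stats::rnorm(9 * 8 * 8, 0, 0.08), 9 * 8, 8), b2 = numeric(8),
    w3 = matrix(stats::rnorm(9 * 8 * 8, 0, 0.08), 9 * 8, 8), b3 = numeric(8),
    # final layer zero-initialized: the untrained generator is the identity
    w4 = matrix(0, 9 * 8, 3), b4 = numeric(3)
  ))
}

init_classifier_params <- function(num_classes, seed) {
  with_seed(derive_seed(seed, "classifier-init"), list(
    w1 = matrix(stats::rnorm(9 * 3 * 8, 0, 0.15), 9 * 3, 8), b1 = numeric(8),
    w2 = matrix(stats::rnorm(9 * 8 * 8, 0, 0.15), 9 * 8, 8), b2 = numeric(8),
    wf = matrix(stats::rnorm(8 * num_classes, 0, 0.3), num_classes, 8),
    bf = numeric(num_classes)
  ))
}

#' Strong augmenter state
#'
#' Holds the generator (residual encoder-decoder image-to-image network), the
#' class-consistency classifier, the loss weights, and the retained per-round
#' outputs. Defaults follow the training recipe: learning rate `alpha = 0.01`,
#' loss weights `lambda_bce = 0.4`, `lambda_d = 0.6`, `lambda_dif = 0.5`,
#' `lambda_bdf = 0.5`, and the final 3 rounds retained.
#'
#' @param num_classes number of classes K the classifier scores
#' @param alpha generator/classifier learning rate
#' @param lambda_bce,lambda_d,lambda_dif,lambda_bdf loss weights (all >= 0)
#' @param retained_rounds number of final rounds kept as the strong dataset
#' @param seed integer seed for parameter initialization
#' @return an object of class `strong_augmenter_state`
#' @export
strong_augmenter_state <- function(num_classes, alpha = 0.01,
                                   lambda_bce = 0.4, lambda_d = 0.6,
                                   lambda_dif = 0.5, lambda_bdf = 0.5,
                                   retained_rounds = 3L, seed = 1L) {
  stopifnot(num_classes >= 2, lambda_bce >= 0, lambda_d >= 0,
            lambda_dif >= 0, lambda_bdf >= 0, retained_rounds >= 1)
  structure(list(
    generator = init_generator_params(seed),
    classifier = init_classifier_params(num_classes, seed),
    num_classes = as.integer(num_classes),
    alpha = alpha, lambda_bce = lambda_bce, lambda_d = lambda_d,
    lambda_dif = lambda_dif, lambda_bdf = lambda_bdf,
    retained_rounds = as.integer(retained_rounds),
    rounds_done = 0L, history = list()
  ), class = "strong_augmenter_state")
}

# graph forward of the generator on one image node/array
generator_forward <- function(img, gp) {
  x <- as_node(img)
  h <- ag_avgpool2(ag_relu(ag_conv3x3(x, gp$w1, gp$b1)))
  r <- ag_relu(ag_conv3x3(h, gp$w2, gp$b2))
  h <- ag_add(h, ag_conv3x3(r, gp$w3, gp$b3))
  delta <- ag_conv3x3(ag_upsample2(h), gp$w4, gp$b4)
  ag_clamp(ag_add(x, delta), 0, 1)
}

# graph forward of the classifier -> K-vector of probabilities
classifier_forward <- function(img, cp) {
  x <- as_node(img)
  h <- ag_avgpool2(ag_relu(ag_conv3x3(x, cp$w1, cp$b1)))
  h <- ag_relu(ag_conv3x3(h, cp$w2, cp$b2))
  ag_sigmoid(ag_affine(ag_gap(h), cp$wf, cp$bf))
}

#' Run the strong augmenter on a batch of images
#'
#' @param batch list of equal-shape H x W x 3 arrays in `[0,1]`
#' @param state a [strong_augmenter_state()]
#' @return list of augmented images (same shapes, values in `[0,1]`)
#' @export
strong_augment <- function(batch, state) {
  stopifnot(inherits(state, "strong_augmenter_state"), length(batch) >= 1)
  d0 <- dim(batch[[1]])
  for (im in batch) {
    if (!all(dim(im) == d0)) stop("batch images must share a shape")
  }
  gp <- ag_wrap(state$generator)
  lapply(batch, function(im) ag_value(generator_forward(im, gp)))
}

# graph BCE mean over a list of prob nodes vs label matrix rows
bce_graph <- function(prob_nodes, labels) {
  n <- length(prob_nodes); K <- ncol(labels)
  total <- NULL
  for (i in seq_len(n)) {
    p <- ag_clamp(prob_nodes[[i]], BCE_EPS, 1 - BCE_EPS)
    y <- labels[i, ]
    term <- ag_add(ag_mul(y, ag_log(p)),
                   ag_mul(1 - y, ag_log(ag_sub(1, p))))
    s <- ag_sum(term)
    total <- if (is.null(total)) s else ag_add(total, s)
  }
  ag_mul(ag_neg(total), 1 / (n * K))
}

#' Binary presence labels of a batch of scenes
#'
#' @param scenes list of [labeled_scene()]
#' @param num_classes number of classes K
#' @return n x K binary matrix
#' @export
scene_class_labels <- function(scenes, num_classes) {
  t(vapply(scenes, function(sc) {
    as.numeric((seq_len(num_classes) - 1L) %in% sc$class_ids)
  }, numeric(num_classes)))
}

#' One adversarial update of the strong augmenter
#'
#' The generator takes a gradient step on
#' `lambda_bce * L_bce - lambda_d * (lambda_dif * L_dif + lambda_bdf * L_bdf)`
#' (keep classes, diverge from the originals and within the batch); the
#' classifier is then updated separately by minimizing the binary
#' cross-entropy on both augmented and original images. The round's augmented
#' images are appended to the retained history.
#'
#' @param state a [strong_augmenter_state()]
#' @param batch list of H x W x 3 arrays in `[0,1]`
#' @param labels n x K binary class-presence matrix
#' @return the updated state
#' @export
update_strong_augmenter <- function(state, batch, labels) {
  stopifnot(length(batch) >= 1)
  labels <- as.matrix(labels)
  # -- generator step
  gp <- ag_wrap(state$generator)
  cp_frozen <- state$classifier  # plain constants: no classifier grads here
  augs <- lapply(batch, function(im) generator_forward(im, gp))
  probs <- lapply(augs, function(a) {
    classifier_forward(a, lapply(cp_frozen, new_ag_node))
  })
  l_bce <- bce_graph(probs, labels)
  # L_dif: sum over pairs of per-pixel MSE to the original
  l_dif <- NULL
  for (i in seq_along(batch)) {
    m <- ag_mean(ag_mul(ag_sub(augs[[i]], batch[[i]]),
                        ag_sub(augs[[i]], batch[[i]])))
    l_dif <- if (is.null(l_dif)) m else ag_add(l_dif, m)
  }
  # L_bdf: mean over unordered augmented pairs
  n <- length(batch)
  l_bdf <- new_ag_node(0)
  if (n >= 2) {
    acc <- NULL
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      m <- ag_mean(ag_mul(ag_sub(augs[[i]], augs[[j]]),
                          ag_sub(augs[[i]], augs[[j]])))
      acc <- if (is.null(acc)) m else ag_add(acc, m)
    }
    l_bdf <- ag_mul(acc, 2 / (n * (n - 1)))
  }
  objective <- ag_sub(ag_mul(l_bce, state$lambda_bce),
                      ag_mul(ag_add(ag_mul(l_dif, state$lambda_dif),
                                    ag_mul(l_bdf, state$lambda_bdf)),
                             state$lambda_d))
  ag_backward(objective)
  g_grads <- ag_grads(gp)
  if (!params_finite(g_grads)) {
    warning("non-finite generator gradients; step skipped")
  } else {
    state$generator <- sgd_step(state$generator, g_grads, state$alpha)
  }
  aug_values <- lapply(augs, ag_value)

  # -- classifier step (frozen generator): minimize BCE on augmented + original
  cp <- ag_wrap(state$classifier)
  cls_inputs <- c(aug_values, batch)
  cls_labels <- rbind(labels, labels)
  probs2 <- lapply(cls_inputs, function(im) classifier_forward(im, cp))
  l_cls <- bce_graph(probs2, cls_labels)
  ag_backward(l_cls)
  c_grads <- ag_grads(cp)
  if (!params_finite(c_grads)) {
    warning("non-finite classifier gradients; step skipped")
  } else {
    state$classifier <- sgd_step(state$classifier, c_grads, state$alpha)
  }

  state$rounds_done <- state$rounds_done + 1L
  state$history <- c(state$history, list(aug_values))
  keep <- max(1L, length(state$history) - state$retained_rounds + 1L)
  state$history <- state$history[keep:length(state$history)]
  state
}

#' Train the strong augmenter for several rounds
#'
#' @param state a [strong_augmenter_state()]
#' @param scenes list of [labeled_scene()] forming the (small) training set
#' @param rounds number of adversarial rounds (default 10); the final
#'   `retained_rounds` rounds' outputs form the strong-augmented dataset
#' @return the trained state
#' @export
train_strong_augmenter <- function(state, scenes, rounds = 10L) {
  batch <- lapply(scenes, `[[`, "image")
  labels <- scene_class_labels(scenes, state$num_classes)
  for (r in seq_len(rounds)) {
    state <- update_strong_augmenter(state, batch, labels)
  }
  state
}

# ---- combined dataset ------------------------------------------------------

#' Assemble the 7x combined training dataset
#'
#' Strong part: the retained final rounds' generator outputs (3 per original
#' by default). Weak part: `cfg$rounds` independent weak rounds, each drawing
#' one noise level sigma and one `(beta, offset)` pair and applying brightness
#' then noise to every image. Labels are copied from the source scenes
#' unchanged (all augmentations are photometric).
#'
#' @param originals list of [labeled_scene()]
#' @param state a trained [strong_augmenter_state()] (at least
#'   `retained_rounds` rounds completed)
#' @param cfg a [weak_augmenter_config()]
#' @return an object of class `augmented_dataset` with elements `original`,
#'   `strong`, `weak`
#' @export
build_augmented_datasets <- function(originals, state, cfg) {
  stopifnot(inherits(state, "strong_augmenter_state"),
            inherits(cfg, "weak_augmenter_config"))
  if (state$rounds_done < state$retained_rounds ||
      length(state$history) < state$retained_rounds) {
    stop("strong augmenter has fewer than retained_rounds completed rounds")
  }
  relabel <- function(img, src) {
    structure(list(image = img, boxes = src$boxes,
                   class_ids = src$class_ids, mask = src$mask),
              class = "labeled_scene")
  }
  strong <- list()
  for (round_imgs in state$history) {
    stopifnot(length(round_imgs) == length(originals))
    for (i in seq_along(originals)) {
      strong[[length(strong) + 1L]] <- relabel(round_imgs[[i]], originals[[i]])
    }
  }
  weak <- list()
  for (r in seq_len(cfg$rounds)) {
    draws <- with_seed(derive_seed(cfg$seed, "weak-round", r), {
      list(sigma = sample(cfg$sigma_levels, 1L),
           beta = stats::runif(1, cfg$beta_range[1], cfg$beta_range[2]),
           offset = stats::runif(1, cfg$offset_range[1], cfg$offset_range[2]))
    })
    for (i in seq_along(originals)) {
      img <- weak_augment_brightness(originals[[i]]$image,
                                     draws$beta, draws$offset)
      img <- weak_augment_noise(img, draws$sigma,
                                derive_seed(cfg$seed, "weak", r, i))
      weak[[length(weak) + 1L]] <- relabel(img, originals[[i]])
    }
  }
  structure(list(original = originals, strong = strong, weak = weak),
            class = "augmented_dataset")
}

#' Flatten an augmented dataset into one training list
#'
#' @param dataset an `augmented_dataset`
#' @return list of [labeled_scene()] (original + strong + weak)
#' @export
combined_scenes <- function(dataset) {
  stopifnot(inherits(dataset, "augmented_dataset"))
  c(dataset$original, dataset$strong, dataset$weak)
}
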