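# Parameterized photometric corruptions emulating weather/lighting domain
# shifts: brightness (BR), darkness (DA), Gaussian noise (GN), fog (FO),
# rain (RA), snow (SN), salt-and-pepper (SP). All corruptions are
# intensity-only: boxes, class ids and masks pass through unchanged.
#
# Severity maps (fixed constants; severity s in [0,1], s = 0 is the identity):
#   BR  multiplicative brighten, factor 1 + 0.8 s
#   DA  multiplicative darken,   factor 1 - 0.8 s
#   GN  additive Gaussian noise, sd = 32 s on the 0-255 scale (32 s / 255 here)
#   FO  alpha-blend with a smooth white haze field, mean alpha ~ 0.65 s
#   RA  ceil(40 s) slanted bright streaks, opacity 0.2 + 0.5 s
#   SN  ceil(30 s) white blobs, opacity 0.3 + 0.6 s
#   SP  per-pixel flips to 0 or 1 with probability 0.1 s (half salt, half pepper)

corruption_kinds <- c("BR", "DA", "GN", "FO", "RA", "SN", "SP")

#' Specification of a domain corruption
#'
#' @param kind one of `"BR"`, `"DA"`, `"GN"`, `"FO"`, `"RA"`, `"SN"`, `"SP"`
#'   (brightness, darkness, Gaussian noise, fog, rain, snow, salt-and-pepper)
#' @param severity numeric in `[0, 1]`; 0 is the identity for every kind
#' @param seed integer seed for the stochastic kinds
#' @return an object of class `corruption_spec`
#' @export
corruption_spec <- function(kind, severity = 0.5, seed = 1L) {
  kind <- match.arg(kind, corruption_kinds)
  stopifnot(severity >= 0, severity <= 1)
  structure(list(kind = kind, severity = as.numeric(severity),
                 seed = as.integer(seed)),
            class = "corruption_spec")
}

# smooth [0,1] field from a low-resolution uniform grid, bilinearly upsampled
smooth_field <- function(H, W, cells = 6L) {
  g <- matrix(stats::runif((cells + 1L)^2), cells + 1L, cells + 1L)
  yi <- (seq_len(H) - 0.5) / H * cells
  xi <- (seq_len(W) - 0.5) / W * cells
  y0 <- pmin(floor(yi), cells - 1L); x0 <- pmin(floor(xi), cells - 1L)
  fy <- yi - y0; fx <- xi - x0
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    r0 <- g[y0[i] + 1L, ]; r1 <- g[y0[i] + 2L, ]
    row0 <- r0[x0 + 1L] * (1 - fx) + r0[x0 + 2L] * fx
    row1 <- r1[x0 + 1L] * (1 - fx) + r1[x0 + 2L] * fx
    out[i, ] <- row0 * (1 - fy[i]) + row1 * fy[i]
  }
  out
}

#' Apply a photometric domain corruption to a scene
#'
#' The image is transformed according to the corruption kind and severity and
#' clipped to `[0,1]`; boxes, class ids and mask are returned unchanged.
#' Deterministic in `(scene, spec)`.
#'
#' @param scene a [labeled_scene()]
#' @param spec a [corruption_spec()]
#' @return a corrupted [labeled_scene()]
#' @export
apply_corruption <- function(scene, spec) {
  stopifnot(inherits(scene, "labeled_scene"), inherits(spec, "corruption_spec"))
  img <- scene$image
  d <- dim(img); H <- d[1]; W <- d[2]
  s <- spec$severity
  out <- with_seed(derive_seed(spec$seed, "corrupt", spec$kind), {
    switch(spec$kind,
      BR = img * (1 + 0.8 * s),
      DA = img * (1 - 0.8 * s),
      GN = img + array(stats::rnorm(length(img), 0, 32 * s / 255), d),
      FO = {
        a <- s * (0.4 + 0.5 * smooth_field(H, W))
        ab <- array(rep(a, 3L), d)
        (1 - ab) * img + ab
      },
      RA = {
        n <- ceiling(40 * s)
        opac <- if (s > 0) 0.2 + 0.5 * s else 0
        over <- matrix(0, H, W)
        if (n > 0) {
          for (k in seq_len(n)) {
            x0 <- stats::runif(1, -0.3 * W, W)
            slope <- stats::runif(1, 0.1, 0.3)
            rows <- seq_len(H)
            cols <- round(x0 + slope * rows)
            okv <- cols >= 1 & cols <= W
            over[cbind(rows[okv], cols[okv])] <- 1
          }
        }
        ob <- array(rep(over * opac, 3L), d)
        (1 - ob) * img + ob * 0.9
      },
      SN = {
        n <- ceiling(30 * s)
        opac <- if (s > 0) 0.3 + 0.6 * s else 0
        over <- matrix(0, H, W)
        if (n > 0) {
          py <- matrix(rep(seq_len(H) - 0.5, W), H, W)
          px <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
          for (k in seq_len(n)) {
            xc <- stats::runif(1, 0, W); yc <- stats::runif(1, 0, H)
            r <- stats::runif(1, 0.8, 2.2)
            over[(px - xc)^2 + (py - yc)^2 <= r^2] <- 1
          }
        }
        ob <- array(rep(over * opac, 3L), d)
        (1 - ob) * img + ob
      },
      SP = {
        p <- 0.1 * s
        u <- array(stats::runif(length(img)), d)
        outv <- img
        outv[u < p / 2] <- 0
        outv[u >= p / 2 & u < p] <- 1
        outv
      },
      stop("unknown corruption kind: ", spec$kind))
  })
  out <- pmin(pmax(out, 0), 1)
  dim(out) <- d
  structure(list(image = out, boxes = scene$boxes,
                 class_ids = scene$class_ids, mask = scene$mask),
            class = "labeled_scene")
}

#' The seven-domain corruption sequence used for continual-adaptation runs
#'
#' @param severity severity shared by all domains
#' @param seed integer seed
#' @return list of [corruption_spec()] in order BR, DA, GN, FO, RA, SN, SP
#' @export
domain_sequence <- function(severity = 0.5, seed = 1L) {
  lapply(corruption_kinds, function(k) {
    corruption_spec(k, severity, derive_seed(seed, "domain", k))
  })
}
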