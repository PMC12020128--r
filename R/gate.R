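# Gated cross-task feature fusion. At each backbone stage, each branch sends
# the other a message: a per-channel sigmoid gate computed from the source
# feature's global-average-pooled channel descriptor (fully connected layer),
# multiplied by a GeLU-activated 1x1 channel-mixing transform of the source
# feature map, added onto the destination feature. Zeroed transform
# parameters make every fusion point an exact no-op, so a dual-branch forward
# then equals two independent single-branch forwards.

#' Learnable gate parameters for one fusion direction
#'
#' `W, b` form the fully connected gate acting on the source branch's
#' channel descriptor; `U, e` form the 1x1 channel-mixing transform. When the
#' destination branch has a different channel count, a learnable 1x1
#' projection `P` maps the message onto it (identity when counts match).
#'
#' @param channels_src source-branch channel count
#' @param channels_dst destination-branch channel count
#' @param init_scale standard deviation of the random init for `W` and `U`
#'   (biases start at zero)
#' @param seed integer seed
#' @return an object of class `gate_params`
#' @export
gate_params <- function(channels_src, channels_dst = channels_src,
                        init_scale = 0.1, seed = 1L) {
  p <- with_seed(derive_seed(seed, "gate-init"), {
    list(
      W = matrix(stats::rnorm(channels_src^2, 0, init_scale),
                 channels_src, channels_src),
      b = numeric(channels_src),
      U = matrix(stats::rnorm(channels_src^2, 0, init_scale),
                 channels_src, channels_src),
      e = numeric(channels_src),
      P = if (channels_dst != channels_src) {
        matrix(stats::rnorm(channels_src * channels_dst, 0, init_scale),
               channels_src, channels_dst)
      }
    )
  })
  structure(p, class = "gate_params")
}

#' Zero the transform of a gate (identity fusion)
#'
#' @param p a [gate_params()]
#' @return the gate with `U` and `e` set to zero, making [gate_fuse()] a no-op
#' @export
gate_zero_transform <- function(p) {
  p$U[] <- 0
  p$e[] <- 0
  p
}

# ---- graph versions (used inside model forwards) ---------------------------

gate_weight_graph <- function(f_src, wp) {
  ag_sigmoid(ag_affine(ag_gap(f_src), wp$W, wp$b))
}

gate_transform_graph <- function(f_src, wp) {
  ag_gelu(ag_conv1x1(f_src, wp$U, wp$e))
}

gate_message_graph <- function(f_src, wp) {
  x <- gate_weight_graph(f_src, wp)
  o <- gate_transform_graph(f_src, wp)
  msg <- ag_chan_scale(o, x)
  if (!is.null(wp$P) && !is.null(ag_value(wp$P))) {
    msg <- ag_conv1x1(msg, wp$P, numeric(ncol(ag_value(wp$P))))
  }
  msg
}

gate_fuse_graph <- function(f_src, f_dst, wp) {
  ag_add(gate_message_graph(f_src, wp), f_dst)
}

# ---- plain-numeric surface -------------------------------------------------

#' Per-channel gate weight of a fusion direction
#'
#' Sigmoid of the fully connected layer applied to the source feature map's
#' global-average-pooled channel descriptor; each component lies strictly in
#' (0, 1) and is broadcast over the spatial grid during fusion.
#'
#' @param f_src source feature map, H x W x C array
#' @param p a [gate_params()]
#' @return numeric gate vector of length C, components in (0, 1)
#' @export
gate_weight <- function(f_src, p) {
  stopifnot(dim(f_src)[3] == ncol(p$W))
  ag_value(gate_weight_graph(as_node(f_src), ag_wrap(unclass(p))))
}

#' GeLU-activated transform of the source feature map
#'
#' @param f_src source feature map, H x W x C array
#' @param p a [gate_params()]
#' @return transformed map, same shape as `f_src`
#' @export
gate_transform <- function(f_src, p) {
  stopifnot(dim(f_src)[3] == ncol(p$U))
  ag_value(gate_transform_graph(as_node(f_src), ag_wrap(unclass(p))))
}

#' Fuse a gated message from a source branch into a destination feature
#'
#' Computes `gate (x) transform (+) f_dst`: the per-channel gate scales the
#' transformed source map, and the result is added to the destination map.
#'
#' @param f_src source feature map, H x W x C_src
#' @param f_dst destination feature map, H x W x C_dst
#' @param p a [gate_params()]
#' @return fused feature map, same shape as `f_dst`
#' @export
gate_fuse <- function(f_src, f_dst, p) {
  if (dim(f_src)[3] != ncol(p$W)) stop("source channel count mismatch")
  cd <- if (is.null(p$P)) ncol(p$U) else ncol(p$P)
  if (dim(f_dst)[3] != cd) stop("destination channel count mismatch")
  if (!all(dim(f_src)[1:2] == dim(f_dst)[1:2])) {
    stop("spatial dimensions must match")
  }
  ag_value(gate_fuse_graph(as_node(f_src), as_node(f_dst),
                           ag_wrap(unclass(p))))
}

#' Simultaneous bidirectional fusion between two branches
#'
#' Both directions are computed from the pre-fusion features, so the update is
#' order-independent: the returned pair equals two independent [gate_fuse()]
#' calls on the original inputs.
#'
#' @param f_main,f_aux same-stage feature maps of the two branches
#' @param p_ma gate for the main-to-aux direction
#' @param p_am gate for the aux-to-main direction
#' @param stage_main,stage_aux optional stage indices; an error is raised if
#'   both are given and differ
#' @return list with fused `main` and `aux` feature maps
#' @export
bidirectional_fuse <- function(f_main, f_aux, p_ma, p_am,
                               stage_main = NULL, stage_aux = NULL) {
  if (!is.null(stage_main) && !is.null(stage_aux) &&
      stage_main != stage_aux) {
    stop("features come from different stages")
  }
  list(main = gate_fuse(f_aux, f_main, p_am),
       aux = gate_fuse(f_main, f_aux, p_ma))
}
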