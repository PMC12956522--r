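# Network construction and the time-stepped forward engine. A network is a
# list of blocks; each weighted block is a linear or conv transform, optional
# batch normalization, and a LIF activation. The output block is a plain
# linear + LIF readout with no normalization; decisions accumulate the output
# spike train as an average over the T-step window.

#' Describe an SNN architecture
#'
#' Two families are supported. `"mlp"`: a chain of fully connected
#' linear -> batch-norm -> LIF blocks (default hidden sizes 512, 256, 64)
#' ending in a linear -> LIF output layer without normalization. `"conv"`:
#' two conv(3x3, stride 1, pad 1) -> batch-norm -> LIF -> maxpool(2x2)
#' blocks with 64 and 128 channels, global average pooling, a 128 -> 64
#' fully connected block and a linear -> LIF output.
#'
#' @param kind `"mlp"` or `"conv"`.
#' @param input_shape For `"mlp"`, the flattened input size (e.g. 784). For
#'   `"conv"`, `c(channels, height, width)`; height and width must be
#'   divisible by 4 (two 2x2 pooling stages).
#' @param n_classes Number of output classes.
#' @param hidden Hidden layer sizes for the MLP family.
#' @param conv_channels Channel counts of the two conv blocks.
#' @param classifier_hidden Size of the fully connected block after global
#'   average pooling in the conv family.
#' @param recurrent_last_hidden If `TRUE`, the last hidden spiking layer
#'   receives recurrent input from its own previous-step spikes (see
#'   [add_recurrence()]).
#' @return A classed list describing the layer chain.
#' @examples
#' architecture_spec("mlp", input_shape = 784, n_classes = 10)
#' @export
architecture_spec <- function(kind = c("mlp", "conv"), input_shape,
                              n_classes = 10, hidden = c(512, 256, 64),
                              conv_channels = c(64, 128),
                              classifier_hidden = 64,
                              recurrent_last_hidden = FALSE) {
  kind <- match.arg(kind)
  stopifnot(n_classes >= 1)
  if (kind == "mlp") {
    stopifnot(length(input_shape) == 1L, input_shape >= 1, length(hidden) >= 1)
  } else {
    stopifnot(length(input_shape) == 3L, length(conv_channels) == 2L)
    if (input_shape[2] %% 4 != 0 || input_shape[3] %% 4 != 0) {
      rlang::abort("Conv input height and width must be divisible by 4.")
    }
  }
  structure(
    list(kind = kind, input_shape = as.integer(input_shape),
         n_classes = as.integer(n_classes), hidden = as.integer(hidden),
         conv_channels = as.integer(conv_channels),
         classifier_hidden = as.integer(classifier_hidden),
         recurrent_last_hidden = isTRUE(recurrent_last_hidden)),
    class = "architecture_spec"
  )
}

new_bn <- function(n) {
  # rvar starts at 1 - eps so the inference transform is exactly the
  # identity at initialization (1/sqrt(rvar + eps) == 1)
  list(gamma = rep(1, n), beta = rep(0, n), rmean = rep(0, n),
       rvar = rep(1 - 1e-5, n), momentum = 0.1, eps = 1e-5)
}

init_weight <- function(n_out, n_in_fan, n_elems) {
  lim <- 1 / sqrt(n_in_fan)
  stats::runif(n_elems, -lim, lim)
}

#' Build a spiking network
#'
#' Instantiates the layer chain of an [architecture_spec()]. Every spiking
#' layer shares the single [neuron_config()] supplied here; normalization sits
#' between the linear/conv transform and the spiking nonlinearity and is the
#' identity transform at initialization (running mean 0, variance 1, unit
#' affine), so untrained-network behaviour is analytic. Weight initialization
#' is deterministic under `seed`.
#'
#' @param spec An [architecture_spec()].
#' @param config A [neuron_config()] shared by all spiking layers.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `snn_network`.
#' @examples
#' net <- build_network(architecture_spec("mlp", 16, 2, hidden = 4), neuron_config(), seed = 1)
#' @export
build_network <- function(spec, config, seed = 1) {
  stopifnot(inherits(spec, "architecture_spec"), inherits(config, "neuron_config"))
  layers <- withr::with_seed(as.integer(seed), {
    out <- list()
    if (spec$kind == "mlp") {
      sizes <- c(spec$input_shape, spec$hidden)
      for (i in seq_along(spec$hidden)) {
        n_in <- sizes[i]; n_out <- sizes[i + 1]
        out[[length(out) + 1L]] <- list(
          type = "dense", n_in = n_in, n_out = n_out,
          W = matrix(init_weight(n_out, n_in, n_out * n_in), n_out, n_in),
          b = rep(0, n_out), bn = new_bn(n_out), spiking = TRUE,
          pool = FALSE, gap = FALSE, recurrent = FALSE, W_rec = NULL,
          n_neurons = n_out, fanout = NA_integer_
        )
      }
      n_in <- spec$hidden[length(spec$hidden)]
    } else {
      C <- spec$input_shape[1]; H <- spec$input_shape[2]; Wd <- spec$input_shape[3]
      chans <- c(C, spec$conv_channels)
      for (i in 1:2) {
        O <- chans[i + 1]
        out[[length(out) + 1L]] <- list(
          type = "conv", n_in = chans[i], n_out = O,
          W = array(init_weight(O, chans[i] * 9, O * chans[i] * 9),
                    c(O, chans[i], 3, 3)),
          b = rep(0, O), bn = new_bn(O), spiking = TRUE,
          pool = TRUE, gap = (i == 2), recurrent = FALSE, W_rec = NULL,
          in_hw = c(H, Wd), n_neurons = O * H * Wd, out_shape = c(O, H, Wd)
        )
        H <- H %/% 2L; Wd <- Wd %/% 2L
      }
      n_in <- spec$conv_channels[2]
      n_out <- spec$classifier_hidden
      out[[length(out) + 1L]] <- list(
        type = "dense", n_in = n_in, n_out = n_out,
        W = matrix(init_weight(n_out, n_in, n_out * n_in), n_out, n_in),
        b = rep(0, n_out), bn = new_bn(n_out), spiking = TRUE,
        pool = FALSE, gap = FALSE, recurrent = FALSE, W_rec = NULL,
        n_neurons = n_out, fanout = NA_integer_
      )
      n_in <- n_out
    }
    out[[length(out) + 1L]] <- list(
      type = "dense", n_in = n_in, n_out = spec$n_classes,
      W = matrix(init_weight(spec$n_classes, n_in, spec$n_classes * n_in),
                 spec$n_classes, n_in),
      b = rep(0, spec$n_classes), bn = NULL, spiking = TRUE,
      pool = FALSE, gap = FALSE, recurrent = FALSE, W_rec = NULL,
      n_neurons = spec$n_classes, fanout = NA_integer_
    )
    out
  })
  net <- structure(
    list(spec = spec, config = config, layers = layers, seed = as.integer(seed)),
    class = "snn_network"
  )
  if (spec$recurrent_last_hidden) net <- add_recurrence(net, seed = seed + 1L)
  net
}

#' @export
print.snn_network <- function(x, ...) {
  cat(sprintf("<snn_network> %s, %d blocks, %d classes\n",
              x$spec$kind, length(x$layers), x$spec$n_classes))
  for (l in x$layers) {
    cat(sprintf(
      "  %s %d -> %d%s%s%s\n", l$type, l$n_in, l$n_out,
      if (!is.null(l$bn)) " +BN" else "",
      if (l$pool) " +pool" else "", if (l$recurrent) " +rec" else ""
    ))
  }
  invisible(x)
}

#' Add recurrent connections to the last hidden spiking layer
#'
#' The last hidden spiking layer receives an extra input term
#' `W_rec %*% S[t-1]` from its own previous-step spikes. `W_rec` is
#' initialized near zero so the recurrent network starts as a small
#' perturbation of the feedforward one.
#'
#' @param network An `snn_network`.
#' @param seed Seed for the recurrent weight initialization.
#' @param sd Standard deviation of the near-zero Gaussian initialization.
#' @return The network with recurrence enabled.
#' @export
add_recurrence <- function(network, seed = 1, sd = 0.01) {
  stopifnot(inherits(network, "snn_network"))
  idx <- length(network$layers) - 1L # last hidden spiking layer
  if (idx < 1L) rlang::abort("Network has no hidden spiking layer.")
  n <- network$layers[[idx]]$n_neurons
  network$layers[[idx]]$recurrent <- TRUE
  network$layers[[idx]]$W_rec <- withr::with_seed(
    as.integer(seed), matrix(stats::rnorm(n * n, sd = sd), n, n)
  )
  network$spec$recurrent_last_hidden <- TRUE
  network
}

# fresh (or boundary-applied) engine states for a batch
engine_states <- function(net, n_batch) {
  lapply(net$layers, function(l) {
    if (l$type == "conv") {
      # conv states kept as [B, C, H, W] arrays
      shp <- c(n_batch, l$out_shape)
      list(v = array(net$config$v_reset, shp), refr = array(0, shp),
           last_spikes = array(0, shp))
    } else {
      st <- init_state(l$n_out, net$config, n_batch = n_batch)
      if (n_batch == 1L) {
        st$v <- matrix(st$v, 1L); st$refr <- matrix(st$refr, 1L)
        st$last_spikes <- matrix(st$last_spikes, 1L)
      }
      unclass(st)[c("v", "refr", "last_spikes")]
    }
  })
}

apply_policy_states <- function(net, states, policy) {
  if (policy == "carry" || is.null(states)) {
    return(states)
  }
  lapply(states, function(s) {
    s$v[] <- net$config$v_reset; s$refr[] <- 0; s$last_spikes[] <- 0
    s
  })
}

# one LIF update on arbitrary-shaped arrays; returns spikes, new v/refr and
# the tape entries needed for BPTT
engine_lif <- function(v, refr, y, cfg, smooth, slope) {
  active <- (refr <= 0) * 1
  u <- (1 - cfg$alpha) * v + y
  if (smooth) {
    S <- surrogate_spike(u - cfg$v_th, slope) * active
  } else {
    S <- (u >= cfg$v_th) * active
  }
  if (cfg$reset_mode == "hard") {
    v_post <- u * (1 - S) + cfg$v_reset * S
  } else {
    v_post <- u - cfg$v_th * S
  }
  v_new <- active * v_post + (1 - active) * v
  refr_new <- active * S * cfg$t_ref + (1 - active) * (refr - 1)
  list(S = S, v = v_new, refr = refr_new, u = u, active = active)
}

# The time-stepped forward pass. x is [B, T, features] (mlp) or
# [B, T, C, H, W] (conv). Returns per-class mean output spikes, optional
# per-layer spike records, per-weighted-layer incoming spike counts per step,
# final states and (in train mode) the tape for BPTT.
snn_forward <- function(net, x, n_steps = NULL, states = NULL,
                        train_mode = FALSE, record = FALSE,
                        smooth = FALSE, slope = 2.0) {
  cfg <- net$config
  d <- dim(x)
  B <- d[1]
  T_in <- d[2]
  if (is.null(n_steps)) n_steps <- T_in
  if (n_steps != T_in) rlang::abort("Input horizon does not match `n_steps`.")
  if (is.null(states)) states <- engine_states(net, B)
  L <- length(net$layers)
  counts <- matrix(0, B, net$spec$n_classes)
  tape <- if (train_mode) vector("list", n_steps) else NULL
  recs <- if (record) {
    lapply(net$layers, function(l) array(0, c(B, n_steps, l$n_neurons)))
  } else NULL
  incoming <- matrix(0, L, n_steps) # total spikes entering each weighted layer
  rec_prev <- lapply(net$layers, function(l) {
    if (l$recurrent) matrix(0, B, l$n_neurons) else NULL
  })

  for (t in seq_len(n_steps)) {
    if (length(d) == 3L) {
      a <- matrix(x[, t, ], B, d[3])
    } else {
      a <- array(x[, t, , , ], c(B, d[3], d[4], d[5]))
    }
    step_tape <- if (train_mode) vector("list", L) else NULL
    a_count <- sum(a) # spikes feeding the next weighted layer
    for (l in seq_len(L)) {
      blk <- net$layers[[l]]
      st <- states[[l]]
      incoming[l, t] <- a_count
      if (blk$type == "dense") {
        z <- a %*% t(blk$W) + rep(blk$b, each = B)
        if (blk$recurrent) z <- z + rec_prev[[l]] %*% t(blk$W_rec)
        if (!is.null(blk$bn)) {
          bnc <- bn_forward(z, blk$bn, train_mode)
          y <- bnc$y
        } else {
          bnc <- NULL
          y <- z
        }
        lr <- engine_lif(st$v, st$refr, y, cfg, smooth, slope)
        states[[l]]$v <- lr$v
        states[[l]]$refr <- lr$refr
        states[[l]]$last_spikes <- lr$S
        if (train_mode) {
          step_tape[[l]] <- list(x = a, bnc = bnc, u = lr$u, S = lr$S,
                                 active = lr$active,
                                 S_rec_prev = if (blk$recurrent) rec_prev[[l]])
          if (!is.null(blk$bn)) {
            net$layers[[l]]$bn$rmean <- (1 - blk$bn$momentum) * blk$bn$rmean +
              blk$bn$momentum * bnc$mean
            net$layers[[l]]$bn$rvar <- (1 - blk$bn$momentum) * blk$bn$rvar +
              blk$bn$momentum * bnc$var
          }
        }
        if (blk$recurrent) rec_prev[[l]] <- lr$S
        if (record) recs[[l]][, t, ] <- lr$S
        a <- lr$S
        a_count <- sum(a)
        if (l == L) counts <- counts + lr$S
      } else { # conv block
        z <- conv3_forward(a, blk$W, blk$b)
        zm <- conv_to_bnmat(z)
        bnc <- bn_forward(zm, blk$bn, train_mode)
        y <- bnmat_to_conv(bnc$y, dim(z))
        lr <- engine_lif(st$v, st$refr, y, cfg, smooth, slope)
        states[[l]]$v <- lr$v
        states[[l]]$refr <- lr$refr
        states[[l]]$last_spikes <- lr$S
        if (train_mode) {
          step_tape[[l]] <- list(x = a, bnc = bnc, u = lr$u, S = lr$S,
                                 active = lr$active, z_dim = dim(z))
          net$layers[[l]]$bn$rmean <- (1 - blk$bn$momentum) * blk$bn$rmean +
            blk$bn$momentum * bnc$mean
          net$layers[[l]]$bn$rvar <- (1 - blk$bn$momentum) * blk$bn$rvar +
            blk$bn$momentum * bnc$var
        }
        if (record) recs[[l]][, t, ] <- matrix(lr$S, B)
        pooled <- pool2_forward(lr$S)
        if (train_mode) {
          step_tape[[l]]$pool_arg <- pooled$arg
          step_tape[[l]]$pre_pool_dim <- dim(lr$S)
        }
        a <- pooled$out
        a_count <- sum(a) # pooled spikes feed the next layer's synapses
        if (blk$gap) {
          dpool <- dim(a)
          if (train_mode) step_tape[[l]]$gap_dim <- dpool
          a <- matrix(apply(a, c(1, 2), mean), B, dpool[2])
        }
      }
    }
    if (train_mode) tape[[t]] <- step_tape
  }
  list(counts = counts / n_steps, record = recs, incoming = incoming,
       states = states, tape = tape, net = net)
}

#' Run a spiking network on one input sample
#'
#' Unrolls the network over the sample's T timesteps and accumulates the
#' output spike train as an average over the window. The between-sample
#' membrane policy is applied to `state` before the run: `"reset"`
#' reinitializes every membrane to `v_reset`, `"carry"` keeps the provided
#' state (a fresh state is used when `state` is `NULL`).
#'
#' @param network An `snn_network` from [build_network()].
#' @param input A spike tensor: `[T x features]` matrix for MLP networks or
#'   `[T x channels x height x width]` array for conv networks.
#' @param n_steps Expected horizon T; defaults to the input's first dimension
#'   and must match it.
#' @param policy `"reset"` or `"carry"`.
#' @param record If `TRUE`, return binary spike traces for every spiking
#'   layer as `[T x n_neurons]` matrices.
#' @param state Carried engine state from a previous call (for the carry
#'   policy); `NULL` starts fresh.
#' @return A list with `counts` (per-class mean output spikes over T),
#'   `record` (list of per-layer spike matrices or `NULL`), `incoming`
#'   (per-weighted-layer incoming spike counts per step) and `state` (final
#'   engine state, for streaming).
#' @export
forward <- function(network, input, n_steps = NULL, policy = "reset",
                    record = FALSE, state = NULL) {
  stopifnot(inherits(network, "snn_network"))
  d <- dim(input)
  xb <- array(input, c(1L, d))
  policy <- as.character(state_policy(unclass(policy)))
  state <- apply_policy_states(network, state, policy)
  out <- snn_forward(network, xb, n_steps = n_steps, states = state,
                     record = record)
  rec <- if (record) {
    lapply(out$record, function(r) matrix(r[1, , ], dim(r)[2], dim(r)[3]))
  } else NULL
  list(counts = drop(out$counts), record = rec,
       incoming = out$incoming, state = out$states)
}

#' Decode a class label from accumulated output spikes
#'
#' Argmax over per-class accumulated output spike counts, with ties broken by
#' the lowest class index. An all-zero count vector is still decoded (label
#' 0) but flagged via the `"degenerate"` attribute.
#'
#' @param counts Numeric vector of per-class accumulated spike counts.
#' @return The 0-based predicted label (integer), with attribute
#'   `degenerate = TRUE` when no output spike was emitted.
#' @examples
#' predict_label(c(0.1, 0.9, 0.3))
#' @export
predict_label <- function(counts) {
  if (length(counts) < 1L) rlang::abort("`counts` must have at least one class.")
  lab <- which.max(counts) - 1L # which.max already breaks ties low
  if (all(counts == 0)) attr(lab, "degenerate") <- TRUE
  lab
}

#' Synaptic fan-out of each weighted layer
#'
#' Fan-out counts the synapses touched by one incoming spike: the number of
#' output units for a dense layer, and `kernel_h * kernel_w * out_channels`
#' for a conv layer (interior approximation that ignores image-boundary
#' truncation).
#'
#' @param network An `snn_network`.
#' @return A tibble with columns `layer`, `type`, `fanout`.
#' @export
fanout_table <- function(network) {
  stopifnot(inherits(network, "snn_network"))
  tibble::tibble(
    layer = seq_along(network$layers),
    type = purrr::map_chr(network$layers, "type"),
    fanout = purrr::map_int(network$layers, function(l) {
      if (l$type == "conv") as.integer(9L * l$n_out) else as.integer(l$n_out)
    })
  )
}
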