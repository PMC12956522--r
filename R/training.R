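# Surrogate-gradient training: backpropagation through time over the T-step
# unrolled LIF dynamics. The spike indicator's derivative is replaced by the
# arctangent pseudo-derivative g(u) = s / (1 + (pi*s*u)^2) with u = v_pre -
# v_th; gradients also flow through the reset term, so the BPTT gradient is
# exactly the gradient of the smooth relaxation in which every Heaviside is
# replaced by surrogate_spike(). That makes the implementation verifiable
# against central finite differences of the smooth-forward loss.

#' Training configuration
#'
#' @param n_steps Timesteps per sample T (default 10).
#' @param epochs Number of passes over the training set.
#' @param lr Adam learning rate (> 0), default 1e-3.
#' @param batch_size Minibatch size (>= 2; batch normalization needs batch
#'   statistics).
#' @param surrogate_slope Arctangent surrogate slope s (dimensionless),
#'   default 2.
#' @param policy Membrane-state policy applied between samples during
#'   training: `"reset"` (default) or `"carry"`.
#' @param seed Integer seed; training is fully reproducible under it.
#' @return A classed list of settings.
#' @export
training_config <- function(n_steps = 10, epochs = 10, lr = 1e-3,
                            batch_size = 32, surrogate_slope = 2.0,
                            policy = "reset", seed = 1) {
  stopifnot(n_steps >= 1, epochs >= 0, lr > 0, batch_size >= 2,
            surrogate_slope > 0)
  policy <- as.character(state_policy(policy))
  structure(
    list(n_steps = as.integer(n_steps), epochs = as.integer(epochs),
         lr = lr, batch_size = as.integer(batch_size),
         surrogate_slope = surrogate_slope, policy = policy,
         seed = as.integer(seed)),
    class = "training_config"
  )
}

zero_grads <- function(net) {
  lapply(net$layers, function(l) {
    g <- list(dW = l$W * 0, db = l$b * 0)
    if (!is.null(l$bn)) {
      g$dgamma <- l$bn$gamma * 0
      g$dbeta <- l$bn$beta * 0
    }
    if (l$recurrent) g$dW_rec <- l$W_rec * 0
    g
  })
}

# BPTT over a recorded tape. dcounts is [B x K], the loss gradient wrt the
# per-class mean output spikes. Returns per-layer parameter gradients.
snn_backward <- function(net, fw, dcounts, slope) {
  cfg <- net$config
  layers <- net$layers
  L <- length(layers)
  n_steps <- length(fw$tape)
  B <- nrow(dcounts)
  grads <- zero_grads(net)
  # dL/dv_t carried backward per layer, and recurrent dL/du_{t+1} %*% W_rec
  dv_next <- lapply(layers, function(l) NULL)
  rec_carry <- lapply(layers, function(l) NULL)

  lif_back <- function(blk, tp, dS, dv) {
    g <- surrogate_deriv(tp$u - cfg$v_th, slope)
    if (is.null(dv)) dv <- tp$u * 0
    if (cfg$reset_mode == "hard") {
      dvdu <- (1 - tp$S) + (cfg$v_reset - tp$u) * g
    } else {
      dvdu <- 1 - cfg$v_th * g
    }
    du <- (dv * dvdu + dS * g) * tp$active
    dv_prev <- (1 - cfg$alpha) * du + dv * (1 - tp$active)
    list(du = du, dv_prev = dv_prev)
  }

  for (t in rev(seq_len(n_steps))) {
    tape_t <- fw$tape[[t]]
    dS_above <- dcounts / n_steps # gradient wrt output-layer spikes at step t
    for (l in rev(seq_len(L))) {
      blk <- layers[[l]]
      tp <- tape_t[[l]]
      if (blk$type == "dense") {
        dS <- dS_above
        if (!is.null(rec_carry[[l]])) {
          dS <- dS + rec_carry[[l]]
          rec_carry[l] <- list(NULL)
        }
        lb <- lif_back(blk, tp, dS, dv_next[[l]])
        dv_next[[l]] <- lb$dv_prev
        dy <- lb$du
        if (!is.null(blk$bn)) {
          bb <- bn_backward(dy, tp$bnc, blk$bn)
          grads[[l]]$dgamma <- grads[[l]]$dgamma + bb$dgamma
          grads[[l]]$dbeta <- grads[[l]]$dbeta + bb$dbeta
          dz <- bb$dz
        } else {
          dz <- dy
        }
        if (blk$recurrent) { # recurrent input enters pre-normalization
          grads[[l]]$dW_rec <- grads[[l]]$dW_rec + t(dz) %*% tp$S_rec_prev
          if (t > 1L) rec_carry[l] <- list(dz %*% blk$W_rec)
        }
        grads[[l]]$dW <- grads[[l]]$dW + t(dz) %*% tp$x
        grads[[l]]$db <- grads[[l]]$db + colSums(dz)
        dS_above <- dz %*% blk$W
      } else { # conv block
        dpost <- dS_above
        if (blk$gap) {
          gd <- tp$gap_dim
          # undo global average pooling: spread gradient over spatial cells
          dpost <- array(0, gd)
          for (ch in seq_len(gd[2])) {
            dpost[, ch, , ] <- dS_above[, ch] / (gd[3] * gd[4])
          }
        }
        dS <- pool2_backward(dpost, tp$pool_arg, tp$pre_pool_dim)
        lb <- lif_back(blk, tp, dS, dv_next[[l]])
        dv_next[[l]] <- lb$dv_prev
        dy <- lb$du
        bb <- bn_backward(conv_to_bnmat(dy), tp$bnc, blk$bn)
        grads[[l]]$dgamma <- grads[[l]]$dgamma + bb$dgamma
        grads[[l]]$dbeta <- grads[[l]]$dbeta + bb$dbeta
        dz <- bnmat_to_conv(bb$dz, tp$z_dim)
        cb <- conv3_backward(tp$x, blk$W, dz)
        grads[[l]]$dW <- grads[[l]]$dW + cb$dW
        grads[[l]]$db <- grads[[l]]$db + cb$db
        dS_above <- cb$dx
      }
    }
  }
  grads
}

# cross-entropy on softmax of the per-class mean output spike counts;
# returns loss and gradient wrt counts
ce_loss <- function(counts, labels) {
  B <- nrow(counts)
  m <- apply(counts, 1, max)
  e <- exp(counts - m)
  p <- e / rowSums(e)
  idx <- cbind(seq_len(B), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dcounts <- p
  dcounts[idx] <- dcounts[idx] - 1
  list(loss = loss, dcounts = dcounts / B)
}

adam_init <- function(net) {
  lapply(net$layers, function(l) {
    slot <- function(x) list(m = x * 0, v = x * 0)
    g <- list(W = slot(l$W), b = slot(l$b))
    if (!is.null(l$bn)) {
      g$gamma <- slot(l$bn$gamma)
      g$beta <- slot(l$bn$beta)
    }
    if (l$recurrent) g$W_rec <- slot(l$W_rec)
    g
  })
}

adam_update <- function(net, grads, opt, lr, step,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  upd <- function(param, grad, slot) {
    slot$m <- beta1 * slot$m + (1 - beta1) * grad
    slot$v <- beta2 * slot$v + (1 - beta2) * grad^2
    param <- param - lr * (slot$m / bc1) / (sqrt(slot$v / bc2) + eps)
    list(param = param, slot = slot)
  }
  for (l in seq_along(net$layers)) {
    u <- upd(net$layers[[l]]$W, grads[[l]]$dW, opt[[l]]$W)
    net$layers[[l]]$W <- u$param; opt[[l]]$W <- u$slot
    u <- upd(net$layers[[l]]$b, grads[[l]]$db, opt[[l]]$b)
    net$layers[[l]]$b <- u$param; opt[[l]]$b <- u$slot
    if (!is.null(net$layers[[l]]$bn)) {
      u <- upd(net$layers[[l]]$bn$gamma, grads[[l]]$dgamma, opt[[l]]$gamma)
      net$layers[[l]]$bn$gamma <- u$param; opt[[l]]$gamma <- u$slot
      u <- upd(net$layers[[l]]$bn$beta, grads[[l]]$dbeta, opt[[l]]$beta)
      net$layers[[l]]$bn$beta <- u$param; opt[[l]]$beta <- u$slot
    }
    if (net$layers[[l]]$recurrent) {
      u <- upd(net$layers[[l]]$W_rec, grads[[l]]$dW_rec, opt[[l]]$W_rec)
      net$layers[[l]]$W_rec <- u$param; opt[[l]]$W_rec <- u$slot
    }
  }
  list(net = net, opt = opt)
}

#' Encode a synthetic task split into batched spike tensors
#'
#' Static images are Poisson encoded over `n_steps` timesteps (per-sample
#' seeds derived from `seed`); event streams are binned into `n_steps` bins
#' with polarity channels.
#'
#' @param split A `train` or `test` split from [make_static_task()] or
#'   [make_event_task()].
#' @param n_steps Encoding horizon T.
#' @param seed Integer seed (static encoding only).
#' @param height,width,duration Frame geometry for event splits.
#' @return A list `x` (array `[N, T, features]` or `[N, T, 2, H, W]`) and
#'   `labels` (0-based integer vector).
#' @export
encode_dataset <- function(split, n_steps, seed = 1, height = NULL,
                           width = NULL, duration = NULL) {
  if (!is.null(split$images)) {
    n <- length(split$images)
    f <- length(split$images[[1]])
    x <- array(0, c(n, n_steps, f))
    for (i in seq_len(n)) {
      x[i, , ] <- poisson_encode(split$images[[i]], n_steps,
                                 seed = as.integer(seed) * 7919L + i)
    }
  } else {
    n <- length(split$streams)
    x <- array(0, c(n, n_steps, 2L, height, width))
    for (i in seq_len(n)) {
      x[i, , , , ] <- bin_events(split$streams[[i]], n_steps, height, width,
                                 duration = duration)
    }
  }
  list(x = x, labels = as.integer(split$labels))
}

#' Train a spiking network with surrogate-gradient BPTT
#'
#' Minimizes cross-entropy on the softmax of the per-class mean output spike
#' counts with Adam, backpropagating through the T-step unrolled dynamics and
#' substituting the arctangent pseudo-derivative for the spike indicator's
#' derivative. The membrane-state policy of `config` is applied between
#' batches: `reset` starts every batch from fresh membranes, `carry`
#' propagates final states across consecutive batches. Fully reproducible
#' under `config$seed`; `epochs = 0` returns the network unchanged.
#'
#' @param network An `snn_network`.
#' @param data An encoded dataset from [encode_dataset()] (fields `x`,
#'   `labels`).
#' @param config A [training_config()]. Training requires `t_ref = 0` in the
#'   neuron configuration (refractory gating is not differentiable).
#' @return A list with class `snn_fit`: `network` (trained), `history`
#'   (tibble: epoch, loss, accuracy) and `config`.
#' @export
train_network <- function(network, data, config = training_config()) {
  stopifnot(inherits(network, "snn_network"), inherits(config, "training_config"))
  if (network$config$t_ref > 0) {
    rlang::abort("Training requires t_ref = 0 in the neuron configuration.")
  }
  n <- dim(data$x)[1]
  if (dim(data$x)[2] != config$n_steps) {
    rlang::abort("Encoded horizon does not match `config$n_steps`.")
  }
  history <- tibble::tibble(epoch = integer(), loss = numeric(),
                            accuracy = numeric())
  if (config$epochs == 0L) {
    return(structure(list(network = network, history = history,
                          config = config), class = "snn_fit"))
  }
  net <- network
  opt <- adam_init(net)
  step <- 0L
  withr::with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      carried <- NULL
      ep_loss <- 0
      ep_hits <- 0
      nb <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        if (length(idx) < 2L) next # BN needs at least two rows
        xb <- index_batch(data$x, idx)
        yb <- data$labels[idx]
        states <- NULL
        if (config$policy == "carry" && !is.null(carried) &&
            dim(carried[[1]]$v)[1] == length(idx)) {
          states <- carried
        }
        fw <- snn_forward(net, xb, states = states, train_mode = TRUE,
                          slope = config$surrogate_slope)
        net <- fw$net # pick up batch-norm running statistics
        ls <- ce_loss(fw$counts, yb)
        if (!is.finite(ls$loss)) {
          rlang::abort(sprintf("Non-finite loss at epoch %d.", ep))
        }
        grads <- snn_backward(net, fw, ls$dcounts, config$surrogate_slope)
        step <- step + 1L
        au <- adam_update(net, grads, opt, config$lr, step)
        net <- au$net
        opt <- au$opt
        if (config$policy == "carry") carried <- fw$states
        ep_loss <- ep_loss + ls$loss
        ep_hits <- ep_hits + sum(apply(fw$counts, 1, which.max) - 1L == yb)
        nb <- nb + 1L
      }
      history <- dplyr::bind_rows(history, tibble::tibble(
        epoch = ep, loss = ep_loss / nb, accuracy = ep_hits / n
      ))
    }
  })
  structure(list(network = net, history = history, config = config),
            class = "snn_fit")
}

index_batch <- function(x, idx) {
  d <- dim(x)
  if (length(d) == 3L) {
    x[idx, , , drop = FALSE]
  } else {
    x[idx, , , , , drop = FALSE]
  }
}

#' Evaluate a network on an encoded dataset
#'
#' Streams the dataset through the network under the given between-sample
#' membrane policy. Under `reset`, samples are independent and are evaluated
#' as one batch; under `carry`, samples are processed sequentially in the
#' given order, propagating the final membrane state of each sample to the
#' next.
#'
#' @param network An `snn_network` (or `snn_fit`).
#' @param data An encoded dataset from [encode_dataset()].
#' @param policy `"reset"` or `"carry"`.
#' @param record If `TRUE`, keep per-layer spike records for every sample.
#' @param order Evaluation order (indices); default is dataset order.
#' @return A list: `accuracy`, `predictions` (0-based), `counts`
#'   (`[N x n_classes]`), `mean_rate` (spikes/neuron/timestep across all
#'   spiking layers), `total_spikes`, `sop`, `incoming` (per-layer per-step
#'   spike counts summed over samples) and optionally `records`.
#' @export
evaluate_network <- function(network, data, policy = "reset", record = FALSE,
                             order = NULL) {
  if (inherits(network, "snn_fit")) network <- network$network
  stopifnot(inherits(network, "snn_network"))
  policy <- as.character(state_policy(policy))
  n <- dim(data$x)[1]
  if (is.null(order)) order <- seq_len(n)
  n_neurons <- sum(purrr::map_int(network$layers, ~ as.integer(.x$n_neurons)))
  n_steps <- dim(data$x)[2]
  if (policy == "reset") {
    fw <- snn_forward(network, index_batch(data$x, order), record = TRUE)
    counts <- fw$counts
    incoming <- fw$incoming
    total_spikes <- sum(purrr::map_dbl(fw$record, sum))
    records <- if (record) fw$record else NULL
  } else {
    counts <- matrix(0, n, network$spec$n_classes)
    incoming <- NULL
    total_spikes <- 0
    records <- if (record) {
      lapply(network$layers, function(l) array(0, c(n, n_steps, l$n_neurons)))
    } else NULL
    state <- NULL
    for (j in seq_len(n)) {
      i <- order[j]
      fw <- snn_forward(network, index_batch(data$x, i), states = state,
                        record = TRUE)
      state <- fw$states # carry V^T to the next sample
      counts[j, ] <- fw$counts
      incoming <- if (is.null(incoming)) fw$incoming else incoming + fw$incoming
      total_spikes <- total_spikes + sum(purrr::map_dbl(fw$record, sum))
      if (record) {
        for (l in seq_along(records)) records[[l]][j, , ] <- fw$record[[l]]
      }
    }
  }
  preds <- apply(counts, 1, which.max) - 1L
  labels <- data$labels[order]
  fo <- fanout_table(network)$fanout
  sop <- sum(rowSums(incoming) * fo)
  list(
    accuracy = mean(preds == labels), predictions = preds, labels = labels,
    counts = counts,
    mean_rate = total_spikes / (n * n_neurons * n_steps),
    total_spikes = total_spikes, sop = sop, incoming = incoming,
    records = records, order = order
  )
}
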