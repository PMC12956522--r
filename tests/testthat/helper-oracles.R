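# Independent reference implementations (oracles) and shared fixtures.
# Oracles are deliberately written as plain per-element loops, independent of
# the package's vectorized code paths.

# scalar per-neuron LIF simulation: v0 length n, currents [T x n]
scalar_lif_trace <- function(v0, currents, cfg) {
  t_steps <- nrow(currents)
  n <- length(v0)
  v_out <- matrix(0, t_steps, n)
  s_out <- matrix(0, t_steps, n)
  for (j in seq_len(n)) {
    v <- v0[j]
    refr <- 0
    for (t in seq_len(t_steps)) {
      if (refr > 0) {
        refr <- refr - 1
        s_out[t, j] <- 0
      } else {
        u <- (1 - cfg$alpha) * v + currents[t, j]
        if (u >= cfg$v_th) {
          s_out[t, j] <- 1
          v <- if (cfg$reset_mode == "hard") cfg$v_reset else u - cfg$v_th
          refr <- cfg$t_ref
        } else {
          v <- u
        }
      }
      v_out[t, j] <- v
    }
  }
  list(v = v_out, spikes = s_out)
}

# run the package's lif_step over a trace for comparison with the oracle
vector_lif_trace <- function(v0, currents, cfg) {
  st <- init_state(length(v0), cfg)
  st$v <- v0
  t_steps <- nrow(currents)
  v_out <- matrix(0, t_steps, length(v0))
  s_out <- matrix(0, t_steps, length(v0))
  for (t in seq_len(t_steps)) {
    r <- lif_step(st, currents[t, ], cfg)
    st <- r$state
    v_out[t, ] <- st$v
    s_out[t, ] <- r$spikes
  }
  list(v = v_out, spikes = s_out)
}

# brute-force SOP: accumulate one operation per incoming spike per synapse
brute_sop <- function(incoming, fanout) {
  total <- 0
  for (l in seq_len(nrow(incoming))) {
    for (t in seq_len(ncol(incoming))) {
      n_spikes <- incoming[l, t]
      for (s in seq_len(fanout[l])) {
        total <- total + n_spikes
      }
    }
  }
  total
}

# exhaustive 4-neighbour boundary enumeration on a logical mask; axes of
# length 1 are collapsed dimensions with no neighbours
brute_boundary <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      nb <- list()
      if (nr > 1) nb <- c(nb, list(c(i - 1, j), c(i + 1, j)))
      if (nc > 1) nb <- c(nb, list(c(i, j - 1), c(i, j + 1)))
      for (q in nb) {
        outside <- q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc ||
          !mask[q[1], q[2]]
        if (outside) {
          out[i, j] <- TRUE
          break
        }
      }
    }
  }
  out
}

# exhaustive pairwise-domination Pareto front (maximize a, maximize 1 - e)
brute_pareto <- function(a, e) {
  n <- length(a)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (a[j] >= a[i] && (1 - e[j]) >= (1 - e[i]) &&
          (a[j] > a[i] || (1 - e[j]) > (1 - e[i]))) {
        keep[i] <- FALSE
      }
    }
  }
  keep
}

# reference forward pass for a small MLP with identity normalization:
# plain scalar loops over time, layers and neurons
reference_mlp_forward <- function(net, x) {
  cfg <- net$config
  t_steps <- nrow(x)
  layers <- net$layers
  vs <- lapply(layers, function(l) rep(cfg$v_reset, l$n_out))
  out_spikes <- matrix(0, t_steps, layers[[length(layers)]]$n_out)
  layer_spikes <- lapply(layers, function(l) matrix(0, t_steps, l$n_out))
  for (t in seq_len(t_steps)) {
    a <- x[t, ]
    for (l in seq_along(layers)) {
      blk <- layers[[l]]
      s_new <- numeric(blk$n_out)
      for (j in seq_len(blk$n_out)) {
        z <- sum(blk$W[j, ] * a) + blk$b[j]
        u <- (1 - cfg$alpha) * vs[[l]][j] + z
        if (u >= cfg$v_th) {
          s_new[j] <- 1
          vs[[l]][j] <- if (cfg$reset_mode == "hard") cfg$v_reset else u - cfg$v_th
        } else {
          vs[[l]][j] <- u
        }
      }
      layer_spikes[[l]][t, ] <- s_new
      a <- s_new
    }
    out_spikes[t, ] <- a
  }
  list(counts = colMeans(out_spikes), layer_spikes = layer_spikes)
}

# ---- shared expensive fixtures, computed once per test run -----------------

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

fixture_task <- function() {
  memo("task", make_static_task(synthetic_task_config(seed = 42)))
}

fixture_arch <- function() {
  architecture_spec("mlp", input_shape = 144, n_classes = 4,
                    hidden = c(32, 16))
}

fixture_train_data <- function() {
  memo("train_data", encode_dataset(fixture_task()$train, 10, seed = 5))
}

fixture_test_data <- function() {
  memo("test_data", encode_dataset(fixture_task()$test, 10, seed = 6))
}

# the balanced-point trained model shared by the policy/diagnostic tests
fixture_fit <- function() {
  memo("fit", {
    net <- build_network(fixture_arch(), neuron_config(tau_m = 2, v_th = 1),
                         seed = 1)
    train_network(net, fixture_train_data(),
                  training_config(epochs = 20, seed = 1))
  })
}
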