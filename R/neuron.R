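# Discrete-time leaky integrate-and-fire dynamics. A layer's state can hold a
# plain numeric vector (one membrane per neuron) or a [batch x neuron] matrix;
# every update below is elementwise, so both shapes share one code path.

#' Neuron hyperparameter configuration
#'
#' Bundles the leaky integrate-and-fire (LIF) hyperparameters used throughout
#' the package: the membrane time constant `tau_m`, firing threshold `v_th`,
#' reset potential `v_reset`, integration step `dt`, absolute refractory
#' period `t_ref` and the reset mode. The per-step leak factor
#' `alpha = dt / tau_m` is derived and stored; forward-Euler integration
#' requires `tau_m > dt` so that `alpha` lies in (0, 1).
#'
#' @param tau_m Membrane time constant in ms. Must exceed `dt`.
#' @param v_th Firing threshold in V. Must exceed `v_reset`.
#' @param v_reset Reset potential in V. Default 0.
#' @param dt Integration step in ms. Default 1.
#' @param t_ref Absolute refractory period, in integer steps. Default 0.
#' @param reset_mode `"hard"` (clamp to `v_reset`, the default) or `"soft"`
#'   (subtract `v_th`).
#'
#' @return An object of class `neuron_config`: a named list with the fields
#'   above plus the derived leak factor `alpha`.
#' @examples
#' cfg <- neuron_config(tau_m = 2, v_th = 1)
#' cfg$alpha # 0.5
#' @export
neuron_config <- function(tau_m = 2, v_th = 1, v_reset = 0, dt = 1,
                          t_ref = 0L, reset_mode = c("hard", "soft")) {
  reset_mode <- match.arg(reset_mode)
  stopifnot(is.numeric(tau_m), length(tau_m) == 1L, is.finite(tau_m))
  stopifnot(is.numeric(v_th), length(v_th) == 1L, is.finite(v_th))
  stopifnot(is.numeric(v_reset), length(v_reset) == 1L, is.finite(v_reset))
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0)
  if (tau_m <= dt) {
    rlang::abort("`tau_m` must exceed `dt` so that alpha = dt/tau_m < 1.")
  }
  if (v_th <= v_reset) {
    rlang::abort("`v_th` must exceed `v_reset`.")
  }
  if (length(t_ref) != 1L || t_ref < 0 || t_ref != as.integer(t_ref)) {
    rlang::abort("`t_ref` must be a single non-negative integer.")
  }
  structure(
    list(
      tau_m = as.numeric(tau_m), v_th = as.numeric(v_th),
      v_reset = as.numeric(v_reset), dt = as.numeric(dt),
      t_ref = as.integer(t_ref), reset_mode = reset_mode,
      alpha = as.numeric(dt / tau_m)
    ),
    class = "neuron_config"
  )
}

#' @export
print.neuron_config <- function(x, ...) {
  cat(sprintf(
    "<neuron_config> tau_m=%g ms, v_th=%g V, v_reset=%g V, dt=%g ms, t_ref=%d, %s reset (alpha=%g)\n",
    x$tau_m, x$v_th, x$v_reset, x$dt, x$t_ref, x$reset_mode, x$alpha
  ))
  invisible(x)
}

#' Initialize a LIF layer state
#'
#' Membranes start exactly at `v_reset`, with no refractory carry-over and no
#' previous spikes. With `n_batch > 1` the state holds `[n_batch x n_neurons]`
#' matrices so a whole batch of independent samples shares one state object.
#'
#' @param n_neurons Number of neurons in the layer (>= 1).
#' @param config A [neuron_config()].
#' @param n_batch Number of independent batch rows. Default 1 (plain vectors).
#'
#' @return An object of class `layer_state`: list with fields `v` (membrane
#'   potentials), `refr` (remaining refractory steps) and `last_spikes`
#'   (binary spike indicator from the most recent step).
#' @examples
#' st <- init_state(3, neuron_config())
#' st$v
#' @export
init_state <- function(n_neurons, config, n_batch = 1L) {
  stopifnot(inherits(config, "neuron_config"))
  if (length(n_neurons) != 1L || n_neurons < 1) {
    rlang::abort("`n_neurons` must be a single count >= 1.")
  }
  shape <- function(fill) {
    if (n_batch > 1L) matrix(fill, n_batch, n_neurons) else rep(fill, n_neurons)
  }
  structure(
    list(v = shape(config$v_reset), refr = shape(0), last_spikes = shape(0)),
    class = "layer_state"
  )
}

#' Advance a LIF layer by one timestep
#'
#' Forward-Euler update of the membrane potential with threshold crossing and
#' per-mode reset. For non-refractory neurons the pre-reset potential is
#' `v_pre = (1 - alpha) * v + I`; a spike is emitted wherever
#' `v_pre >= v_th`. The reset is applied exactly once, according to
#' `config$reset_mode`: hard reset clamps spiking membranes to `v_reset`,
#' soft reset subtracts `v_th`. Spiking neurons enter the refractory period
#' (`refr = t_ref`); refractory neurons do not integrate, emit no spike, and
#' their counter decrements by one.
#'
#' @param state A `layer_state` (see [init_state()]).
#' @param input_current Synaptic input current, same shape as `state$v`.
#' @param config A [neuron_config()].
#'
#' @return A list with elements `state` (the updated `layer_state`) and
#'   `spikes` (binary array of the same shape as `state$v`).
#' @examples
#' cfg <- neuron_config(tau_m = 2, v_th = 10)
#' st <- init_state(1, cfg)
#' st$v <- 1
#' lif_step(st, 0, cfg)$state$v # decays to 0.5
#' @export
lif_step <- function(state, input_current, config) {
  stopifnot(inherits(state, "layer_state"), inherits(config, "neuron_config"))
  if (length(input_current) != length(state$v)) {
    rlang::abort("`input_current` size does not match the layer state.")
  }
  if (!all(is.finite(input_current))) {
    rlang::abort("`input_current` contains non-finite values.")
  }
  active <- state$refr <= 0
  v_pre <- (1 - config$alpha) * state$v + input_current
  spikes <- as.numeric(v_pre >= config$v_th) * active
  if (config$reset_mode == "hard") {
    v_post <- v_pre * (1 - spikes) + config$v_reset * spikes
  } else {
    v_post <- v_pre - config$v_th * spikes
  }
  v_new <- ifelse(active, v_post, state$v)
  refr_new <- ifelse(active, spikes * config$t_ref, state$refr - 1)
  dim(spikes) <- dim(state$v)
  dim(v_new) <- dim(state$v)
  dim(refr_new) <- dim(state$v)
  state$v <- v_new
  state$refr <- refr_new
  state$last_spikes <- spikes
  list(state = state, spikes = spikes)
}

#' Membrane-state policy between input samples
#'
#' @param policy `"reset"` or `"carry"`.
#' @return The validated policy string, classed `state_policy`.
#' @examples
#' state_policy("carry")
#' @export
state_policy <- function(policy = c("reset", "carry")) {
  if (length(policy) > 2L || !all(policy %in% c("reset", "carry"))) {
    rlang::abort("`policy` must be \"reset\" or \"carry\".")
  }
  structure(match.arg(policy), class = "state_policy")
}

#' Apply the between-sample state policy
#'
#' Under the `reset` policy all membranes are reinitialized to `v_reset`,
#' refractory counters cleared and previous spikes forgotten — equivalent to a
#' fresh [init_state()]. Under `carry` the final state of the previous sample
#' is propagated unchanged to the next input.
#'
#' @param state A `layer_state`.
#' @param policy `"reset"` or `"carry"` (or a [state_policy()]).
#' @param config The layer's [neuron_config()].
#' @return The (possibly reinitialized) `layer_state`.
#' @examples
#' cfg <- neuron_config()
#' st <- init_state(2, cfg)
#' st$v <- c(0.3, 0.7)
#' apply_sample_boundary(st, "carry", cfg)$v
#' apply_sample_boundary(st, "reset", cfg)$v
#' @export
apply_sample_boundary <- function(state, policy, config) {
  stopifnot(inherits(state, "layer_state"))
  policy <- state_policy(unclass(policy))
  if (policy == "carry") {
    return(state)
  }
  zero <- state$v * 0
  state$v <- zero + config$v_reset
  state$refr <- zero
  state$last_spikes <- zero
  state
}
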