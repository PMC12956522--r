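# SOP energy proxy and the composite accuracy-energy scores over a sweep.

#' Count synaptic operations
#'
#' The SOP energy proxy: every spike entering a layer touches that layer's
#' fan-out synapses, so `SOP = sum over layers and steps of
#' N_in(l, t) * fanout(l)`.
#'
#' @param incoming Incoming spikes per layer per step: a `[layers x steps]`
#'   matrix or a list of per-step count vectors, as produced by
#'   [evaluate_network()].
#' @param fanout Per-layer fan-out (synapses per incoming spike): positive
#'   numbers, one per layer (see [fanout_table()]).
#' @return The total SOP count.
#' @examples
#' count_sop(matrix(c(3, 5), 1), fanout = 10) # 80
#' @export
count_sop <- function(incoming, fanout) {
  if (is.list(incoming)) {
    incoming <- do.call(rbind, lapply(incoming, as.numeric))
  }
  incoming <- rbind(incoming)
  if (length(fanout) != nrow(incoming)) {
    rlang::abort("One fan-out value per layer is required.")
  }
  if (any(!is.finite(fanout)) || any(fanout <= 0)) {
    rlang::abort("Fan-out values must be positive.")
  }
  if (any(incoming < 0)) rlang::abort("Spike counts must be non-negative.")
  sum(rowSums(incoming) * fanout)
}

#' Min-max normalize values over a sweep
#'
#' `(x - min) / (max - min)`, using the observed extrema. A degenerate
#' (constant) dimension maps to all zeros: a flat axis carries no cost
#' signal.
#'
#' @param x Numeric vector (length >= 1).
#' @return Values in `[0, 1]`.
#' @examples
#' min_max_normalize(c(2, 4, 6))
#' @export
min_max_normalize <- function(x) {
  stopifnot(length(x) >= 1)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Balanced efficiency score
#'
#' `BES = A_norm - lambda * E_norm`: a weighted difference of normalized
#' accuracy and normalized energy. Higher `lambda` penalizes energy more
#' strongly.
#'
#' @param a_norm,e_norm Normalized accuracy and energy in `[0, 1]`.
#' @param lambda Trade-off weight in `[0, 1]`.
#' @return Scores in `[-lambda, 1]`.
#' @examples
#' bes(0.8, 0.4, lambda = 0.5) # 0.6
#' @export
bes <- function(a_norm, e_norm, lambda) {
  if (length(lambda) != 1L || lambda < 0 || lambda > 1) {
    rlang::abort("`lambda` must lie in [0, 1].")
  }
  a_norm - lambda * e_norm
}

#' Efficiency-accuracy score
#'
#' The F-beta-style harmonic composite
#' `EAS = (1 + beta^2) * A_norm * (1 - E_norm) /
#' (beta^2 * (1 - E_norm) + A_norm)`, defined as 0 when the denominator
#' vanishes. Exactly as in the F-beta score, the argument outside the
#' `beta^2` weight is the emphasized one: `beta > 1` stresses accuracy
#' (the ranking converges to the accuracy ranking as `beta` grows),
#' `beta < 1` stresses energy.
#'
#' @param a_norm,e_norm Normalized accuracy and energy in `[0, 1]`.
#' @param beta Emphasis parameter (> 0).
#' @return Scores in `[0, 1]`.
#' @examples
#' eas(0.5, 0.5, beta = 5) # 0.5
#' @export
eas <- function(a_norm, e_norm, beta) {
  if (length(beta) != 1L || beta <= 0) rlang::abort("`beta` must be > 0.")
  inv_e <- 1 - e_norm
  den <- beta^2 * inv_e + a_norm
  ifelse(den == 0, 0, (1 + beta^2) * a_norm * inv_e / den)
}

#' Pareto front of the accuracy-energy trade-off
#'
#' Non-dominated points when jointly maximizing `a_norm` and `1 - e_norm`.
#' A point is dominated if another point is at least as good on both axes
#' and strictly better on one.
#'
#' @param a_norm,e_norm Normalized accuracy and energy vectors.
#' @return Logical vector marking Pareto-optimal points.
#' @export
pareto_front <- function(a_norm, e_norm) {
  n <- length(a_norm)
  inv_e <- 1 - e_norm
  vapply(seq_len(n), function(i) {
    !any(a_norm >= a_norm[i] & inv_e >= inv_e[i] &
           (a_norm > a_norm[i] | inv_e > inv_e[i]))
  }, logical(1))
}

#' Score a sweep with the composite efficiency metrics
#'
#' Normalizes accuracy and SOP over the sweep with the observed extrema,
#' evaluates BES and EAS at every grid point, and reports the best operating
#' point per score together with the Pareto front of `(A_norm, 1 - E_norm)`.
#'
#' @param sweep An `snn_sweep` tibble from [run_sweep()].
#' @param lambda BES trade-off weight (default 0.5).
#' @param beta EAS emphasis (default 5).
#' @return A tibble of class `snn_efficiency`: the sweep columns plus
#'   `a_norm`, `e_norm`, `bes`, `eas`, `pareto`, with attributes `best_bes`
#'   and `best_eas` (one-row tibbles) and the parameters used.
#' @export
score_sweep <- function(sweep, lambda = 0.5, beta = 5) {
  if (nrow(sweep) == 0L) rlang::abort("Empty sweep.")
  out <- dplyr::mutate(
    tibble::as_tibble(sweep),
    a_norm = min_max_normalize(.data$accuracy),
    e_norm = min_max_normalize(.data$sop),
    bes = bes(.data$a_norm, .data$e_norm, lambda),
    eas = eas(.data$a_norm, .data$e_norm, beta),
    pareto = pareto_front(.data$a_norm, .data$e_norm)
  )
  class(out) <- c("snn_efficiency", class(out))
  attr(out, "lambda") <- lambda
  attr(out, "beta") <- beta
  attr(out, "best_bes") <- out[which.max(out$bes), ]
  attr(out, "best_eas") <- out[which.max(out$eas), ]
  out
}
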