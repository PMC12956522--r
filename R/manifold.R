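# Operational-manifold machinery: mean-rate computation, the (tau_m, v_th)
# grid sweep, and membership/boundary extraction.
#
# The manifold M is the set of hyperparameter points whose mean firing rate
# lies between the silent and saturated bounds while accuracy stays above a
# floor; its boundary is the subset of M with at least one axis-adjacent
# neighbour outside M.

#' Mean network firing rate
#'
#' The mean spike rate per neuron per timestep, averaged over every spiking
#' layer (including the output layer) and over the evaluation set:
#' `r = (1/N) * sum over layers/neurons of (1/T) * sum over t of S`.
#'
#' @param records Layer-wise spike records: a list with one element per
#'   spiking layer, each either an `[N x T x n]` array over the evaluation
#'   set or a `[T x n]` matrix for a single sample.
#' @return The scalar mean rate in spikes/neuron/timestep, in `[0, 1]`.
#' @examples
#' # two neurons, T = 4, trains (1,0,1,0) and (0,0,0,1): rate 0.375
#' mean_firing_rate(list(cbind(c(1, 0, 1, 0), c(0, 0, 0, 1))))
#' @export
mean_firing_rate <- function(records) {
  if (length(records) == 0L) rlang::abort("Empty record set.")
  per_layer <- purrr::map_dbl(records, mean)
  n_per_layer <- purrr::map_dbl(records, function(r) {
    d <- dim(r)
    d[length(d)] # neurons are the trailing dimension
  })
  # Eq-style average: every neuron weighted equally across layers
  sum(per_layer * n_per_layer) / sum(n_per_layer)
}

#' Define a (tau_m, v_th) sweep grid
#'
#' Defaults follow the uniform sweep protocol: 10 uniformly spaced points
#' with `tau_m` in `[1.001, 5]` ms and `v_th` in `[0.01, 3]` V.
#'
#' @param tau_values Strictly increasing membrane time constants (ms); all
#'   must exceed `dt`.
#' @param vth_values Strictly increasing thresholds (V).
#' @param dt Integration step used to validate `tau_values`.
#' @return A classed list with the two axes.
#' @export
sweep_grid <- function(tau_values = seq(1.001, 5, length.out = 10),
                       vth_values = seq(0.01, 3, length.out = 10),
                       dt = 1) {
  stopifnot(length(tau_values) >= 1, length(vth_values) >= 1)
  if (is.unsorted(tau_values, strictly = TRUE) ||
      is.unsorted(vth_values, strictly = TRUE)) {
    rlang::abort("Grid axes must be strictly increasing.")
  }
  if (any(tau_values <= dt)) {
    rlang::abort("All tau_m values must exceed dt (alpha < 1).")
  }
  structure(list(tau_values = tau_values, vth_values = vth_values, dt = dt),
            class = "sweep_grid")
}

#' Bundle an encoded task for sweeping
#'
#' @param train,test Encoded datasets from [encode_dataset()].
#' @param spec The [architecture_spec()] to instantiate at every grid point.
#' @return A classed list.
#' @export
sweep_task <- function(train, test, spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  structure(list(train = train, test = test, spec = spec),
            class = "sweep_task")
}

#' Sweep the (tau_m, v_th) grid
#'
#' For every grid point, either trains a fresh network at that configuration
#' (`train_then_eval`, the default; the same `base_seed` is used at every
#' point for comparability) or re-evaluates a provided trained network under
#' the new neuron configuration (`eval_only`), then measures test accuracy,
#' mean firing rate, total spike count and the SOP energy proxy.
#'
#' @param task A [sweep_task()].
#' @param grid A [sweep_grid()].
#' @param mode `"train_then_eval"` or `"eval_only"`.
#' @param base_seed Seed for network initialization and training at every
#'   grid point.
#' @param train_config A [training_config()] (ignored in `eval_only` mode).
#' @param network A trained `snn_network`/`snn_fit` (required for
#'   `eval_only`).
#' @param v_reset,dt,t_ref,reset_mode Remaining neuron hyperparameters held
#'   constant across the sweep.
#' @return A tibble of class `snn_sweep` with one row per grid point:
#'   `tau_m`, `v_th`, `accuracy`, `mean_rate`, `total_spikes`, `sop`.
#' @export
run_sweep <- function(task, grid, mode = c("train_then_eval", "eval_only"),
                      base_seed = 1, train_config = training_config(),
                      network = NULL, v_reset = 0, dt = 1, t_ref = 0L,
                      reset_mode = "hard") {
  mode <- match.arg(mode)
  stopifnot(inherits(task, "sweep_task"), inherits(grid, "sweep_grid"))
  if (any(grid$tau_values <= dt)) {
    rlang::abort("Grid contains tau_m <= dt; rejected before running.")
  }
  if (mode == "eval_only" && is.null(network)) {
    rlang::abort("`eval_only` mode needs a trained `network`.")
  }
  if (inherits(network, "snn_fit")) network <- network$network
  pts <- tidyr::expand_grid(tau_m = grid$tau_values, v_th = grid$vth_values)
  rows <- purrr::pmap(pts, function(tau_m, v_th) {
    cfg <- neuron_config(tau_m = tau_m, v_th = v_th, v_reset = v_reset,
                         dt = dt, t_ref = t_ref, reset_mode = reset_mode)
    if (mode == "train_then_eval") {
      net <- build_network(task$spec, cfg, seed = base_seed)
      fit <- train_network(net, task$train, train_config)
      net <- fit$network
    } else {
      net <- network
      net$config <- cfg
    }
    ev <- evaluate_network(net, task$test, policy = "reset")
    tibble::tibble(tau_m = tau_m, v_th = v_th, accuracy = ev$accuracy,
                   mean_rate = ev$mean_rate, total_spikes = ev$total_spikes,
                   sop = ev$sop)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("snn_sweep", class(out))
  attr(out, "grid") <- grid
  out
}

#' Manifold membership criteria
#'
#' @param r_min,r_max Rate bounds in spikes/neuron/timestep delimiting the
#'   silent and saturated regimes (defaults 0.01 and 0.5).
#' @param a_thr Accuracy floor. With `a_thr_mode = "relative"` (default) the
#'   floor is `a_thr * max(accuracy)` observed over the sweep; with
#'   `"absolute"` it is used as-is.
#' @param a_thr_mode `"relative"` or `"absolute"`.
#' @return A classed list.
#' @export
manifold_spec <- function(r_min = 0.01, r_max = 0.5, a_thr = 0.9,
                          a_thr_mode = c("relative", "absolute")) {
  a_thr_mode <- match.arg(a_thr_mode)
  stopifnot(r_min >= 0, r_max <= 1, r_min < r_max, a_thr >= 0)
  structure(list(r_min = r_min, r_max = r_max, a_thr = a_thr,
                 a_thr_mode = a_thr_mode), class = "manifold_spec")
}

sweep_matrix <- function(sweep, col) {
  taus <- sort(unique(sweep$tau_m))
  vths <- sort(unique(sweep$v_th))
  m <- matrix(NA_real_, length(taus), length(vths),
              dimnames = list(tau_m = signif(taus, 6), v_th = signif(vths, 6)))
  m[cbind(match(sweep$tau_m, taus), match(sweep$v_th, vths))] <- sweep[[col]]
  m
}

#' Manifold membership over a sweep
#'
#' A grid point belongs to the operational manifold when
#' `r_min <= mean_rate <= r_max` and `accuracy >= A_thr` (the floor resolved
#' against the sweep's maximum accuracy in relative mode).
#'
#' @param sweep An `snn_sweep` tibble from [run_sweep()].
#' @param spec A [manifold_spec()].
#' @return A logical `[n_tau x n_vth]` membership matrix with the resolved
#'   accuracy floor in attribute `"a_floor"`.
#' @export
manifold_membership <- function(sweep, spec = manifold_spec()) {
  stopifnot(inherits(spec, "manifold_spec"))
  a_floor <- if (spec$a_thr_mode == "relative") {
    spec$a_thr * max(sweep$accuracy)
  } else {
    spec$a_thr
  }
  rates <- sweep_matrix(sweep, "mean_rate")
  accs <- sweep_matrix(sweep, "accuracy")
  m <- rates >= spec$r_min & rates <= spec$r_max & accs >= a_floor
  attr(m, "a_floor") <- a_floor
  m
}

#' Manifold boundary of a membership mask
#'
#' A cell lies on the boundary iff it is in the manifold and at least one of
#' its 4-neighbours (axis-adjacent cells) is outside. Cells on the grid edge
#' have out-of-grid neighbours, which count as outside: off-grid behaviour is
#' unknown, so the edge is never certified interior. An axis of length 1 is a
#' collapsed (unswept) dimension and contributes no neighbours, so a single
#' row or column behaves as a one-dimensional sweep.
#'
#' @param membership A logical membership matrix.
#' @return A logical matrix of the same shape; always a subset of
#'   `membership`.
#' @examples
#' manifold_boundary(matrix(c(FALSE, TRUE, TRUE, TRUE, FALSE), 1))
#' @export
manifold_boundary <- function(membership) {
  m <- membership
  m[is.na(m)] <- FALSE
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  core <- function(di, dj) pad[2:(nr + 1L) + di, 2:(nc + 1L) + dj, drop = FALSE]
  any_out <- matrix(FALSE, nr, nc)
  if (nr > 1L) any_out <- any_out | !core(-1, 0) | !core(1, 0)
  if (nc > 1L) any_out <- any_out | !core(0, -1) | !core(0, 1)
  out <- m & any_out
  dimnames(out) <- dimnames(membership)
  out
}

#' Extract the operational manifold from a sweep
#'
#' @param sweep An `snn_sweep` tibble.
#' @param spec A [manifold_spec()].
#' @return An object of class `manifold_result`: list with the logical
#'   `membership` and `boundary` matrices, the resolved accuracy floor and
#'   the annotated sweep tibble (columns `in_manifold`, `on_boundary`).
#' @export
manifold <- function(sweep, spec = manifold_spec()) {
  m <- manifold_membership(sweep, spec)
  b <- manifold_boundary(m)
  taus <- sort(unique(sweep$tau_m))
  vths <- sort(unique(sweep$v_th))
  idx <- cbind(match(sweep$tau_m, taus), match(sweep$v_th, vths))
  annotated <- dplyr::mutate(tibble::as_tibble(sweep),
                             in_manifold = m[idx], on_boundary = b[idx])
  structure(
    list(membership = m, boundary = b, a_floor = attr(m, "a_floor"),
         spec = spec, sweep = annotated),
    class = "manifold_result"
  )
}

#' @export
print.manifold_result <- function(x, ...) {
  cat(sprintf(
    "<manifold_result> %d/%d grid points in M (%d on boundary), accuracy floor %.3f\n",
    sum(x$membership, na.rm = TRUE), length(x$membership),
    sum(x$boundary, na.rm = TRUE), x$a_floor
  ))
  invisible(x)
}

#' Count 4-connected components of a logical mask
#'
#' Used to check the contiguity of the operational manifold on a grid.
#'
#' @param mask A logical matrix.
#' @return The number of 4-connected components of `TRUE` cells.
#' @export
n_components_4 <- function(mask) {
  mask[is.na(mask)] <- FALSE
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (mask[i, j] && !seen[i, j]) {
        comps <- comps + 1L
        queue <- list(c(i, j))
        seen[i, j] <- TRUE
        while (length(queue)) {
          p <- queue[[1]]; queue <- queue[-1]
          for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
            q <- p + d
            if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
                mask[q[1], q[2]] && !seen[q[1], q[2]]) {
              seen[q[1], q[2]] <- TRUE
              queue[[length(queue) + 1L]] <- q
            }
          }
        }
      }
    }
  }
  comps
}
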