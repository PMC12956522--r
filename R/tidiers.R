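# broom-style tidiers for the package's fitted/derived objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained network
#'
#' @param x An `snn_fit` from [train_network()].
#' @param ... Unused.
#' @return The per-epoch training history: `epoch`, `loss`, `accuracy`.
#' @export
tidy.snn_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a trained network
#'
#' @param x An `snn_fit`.
#' @param ... Unused.
#' @return A one-row tibble: final loss/accuracy and key settings.
#' @export
glance.snn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    final_loss = if (nrow(h)) h$loss[nrow(h)] else NA_real_,
    final_accuracy = if (nrow(h)) h$accuracy[nrow(h)] else NA_real_,
    tau_m = x$network$config$tau_m,
    v_th = x$network$config$v_th,
    policy = x$config$policy,
    n_steps = x$config$n_steps
  )
}

#' Tidy a manifold result
#'
#' @param x A `manifold_result` from [manifold()].
#' @param ... Unused.
#' @return The sweep tibble annotated with `in_manifold` and `on_boundary`.
#' @export
tidy.manifold_result <- function(x, ...) {
  x$sweep
}

#' One-row summary of a manifold result
#'
#' @param x A `manifold_result`.
#' @param ... Unused.
#' @return A one-row tibble: grid size, membership/boundary counts, the
#'   resolved accuracy floor and the number of 4-connected components.
#' @export
glance.manifold_result <- function(x, ...) {
  tibble::tibble(
    n_points = length(x$membership),
    n_in_manifold = sum(x$membership, na.rm = TRUE),
    n_boundary = sum(x$boundary, na.rm = TRUE),
    a_floor = x$a_floor,
    n_components = n_components_4(x$membership)
  )
}

#' Tidy collected perturbation pairs
#'
#' @param x A `perturbation_pairs` object from [collect_pairs()].
#' @param ... Unused.
#' @return A tibble with one row per pair: `label`, `flip_level`.
#' @export
tidy.perturbation_pairs <- function(x, ...) {
  tibble::tibble(
    label = purrr::map_int(x$pairs, ~ as.integer(.x$label)),
    flip_level = purrr::map_int(x$pairs, ~ as.integer(.x$flip_level))
  )
}

#' Tidy a condition classifier
#'
#' @param x A `condition_classifier` from [condition_classifier()].
#' @param ... Unused.
#' @return The normalized feature-importance tibble (`feature`, `gain`).
#' @export
tidy.condition_classifier <- function(x, ...) {
  x$importance
}

#' One-row summary of a condition classifier
#'
#' @param x A `condition_classifier`.
#' @param ... Unused.
#' @return A one-row tibble with held-out `accuracy` and split sizes.
#' @export
glance.condition_classifier <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n_train = x$n_train,
                 n_test = x$n_test)
}
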