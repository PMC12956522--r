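# Reset-vs-carry inference comparison: accuracy as a function of the
# inference horizon T, and class-conditional output-spike histograms.

#' Accuracy versus inference horizon under reset and carry policies
#'
#' For each policy and horizon T, streams the test split through the trained
#' network and records accuracy. Poisson encodings are regenerated at each T
#' with the evaluation seed, so shorter horizons are genuine re-encodings and
#' not truncations. Under `carry` the test set is streamed in a single fixed
#' seeded shuffle (derived from `seed`), propagating the final membrane state
#' of each sample to the next; under `reset` membranes are reinitialized
#' before every sample and the order is irrelevant.
#'
#' @param network A trained `snn_network` or `snn_fit`. An untrained network
#'   (no history) triggers a warning, not an error.
#' @param task A `static_task` (its `test` split is used).
#' @param policies Character vector from `c("reset", "carry")`.
#' @param t_values Integer horizons (all >= 1).
#' @param seed Evaluation seed driving encodings and the carry stream order.
#' @return A tibble of class `policy_curve`: columns `policy`, `t_steps`,
#'   `accuracy`; the carry evaluation order is stored in attribute
#'   `"carry_order"`.
#' @export
evaluate_policy_curve <- function(network, task, policies = c("reset", "carry"),
                                  t_values = c(1, 2, 3, 5, 10), seed = 1) {
  if (inherits(network, "snn_fit")) {
    if (nrow(network$history) == 0L) {
      rlang::warn("Evaluating an untrained network (empty training history).")
    }
    network <- network$network
  }
  stopifnot(all(t_values >= 1), all(policies %in% c("reset", "carry")))
  n_test <- length(task$test$labels)
  carry_order <- withr::with_seed(as.integer(seed) + 211L, sample(n_test))
  rows <- purrr::map(t_values, function(tt) {
    data_t <- encode_dataset(task$test, n_steps = tt, seed = seed)
    purrr::map(policies, function(pol) {
      ev <- evaluate_network(network, data_t, policy = pol,
                             order = if (pol == "carry") carry_order else NULL)
      tibble::tibble(policy = pol, t_steps = as.integer(tt),
                     accuracy = ev$accuracy)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  class(out) <- c("policy_curve", class(out))
  attr(out, "carry_order") <- carry_order
  out
}

#' Class-conditional output-spike histogram
#'
#' Averages the output-layer spike counts at each timestep `1..T` over all
#' test samples of the requested class, under the given membrane policy
#' (`carry` streams the full test set in dataset order and then selects the
#' class samples, so residual state from preceding samples is retained).
#'
#' @param network A trained `snn_network` or `snn_fit`.
#' @param task A `static_task`.
#' @param class_label 0-based class to condition on; must be present.
#' @param policy `"reset"` or `"carry"`.
#' @param t_steps Inference horizon T.
#' @param seed Encoding seed.
#' @return A tibble of class `output_histogram`: columns `t`, `neuron`
#'   (0-based output index), `mean_count`.
#' @export
class_output_histogram <- function(network, task, class_label,
                                   policy = "reset", t_steps = 10, seed = 1) {
  if (inherits(network, "snn_fit")) network <- network$network
  labels <- task$test$labels
  if (!class_label %in% labels) {
    rlang::abort(sprintf("Class %d absent from the test split.", class_label))
  }
  data_t <- encode_dataset(task$test, n_steps = t_steps, seed = seed)
  ev <- evaluate_network(network, data_t, policy = policy, record = TRUE)
  out_layer <- length(network$layers)
  rec <- ev$records[[out_layer]] # [N x T x n_classes]
  sel <- which(labels[ev$order] == class_label)
  mean_counts <- apply(rec[sel, , , drop = FALSE], c(2, 3), mean)
  out <- tidyr::expand_grid(t = seq_len(t_steps),
                            neuron = seq_len(dim(rec)[3]) - 1L)
  out$mean_count <- as.numeric(t(mean_counts)) # row-major: t outer, neuron inner
  class(out) <- c("output_histogram", class(out))
  out
}
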