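# Pipeline commands and report writing. Every command is a pure function of
# its RunConfig: one global seed expands deterministically into per-stage
# seeds, artifacts embed the resolved configuration, and reruns with the same
# config produce byte-identical CSV/JSON outputs.

STAGE_OFFSETS <- c(synth = 1L, encode = 2L, train = 3L, sweep = 4L,
                   score = 5L, policy = 6L, diagnose = 7L)

#' Derive a per-stage seed from the global seed
#'
#' `stage_seed = (seed * 101 + offset) mod (2^31 - 1)`, with a fixed offset
#' per pipeline stage, so every stage is independently reproducible from the
#' single global seed.
#'
#' @param seed Global integer seed.
#' @param stage One of `"synth"`, `"encode"`, `"train"`, `"sweep"`,
#'   `"score"`, `"policy"`, `"diagnose"`.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  off <- STAGE_OFFSETS[[stage]]
  as.integer((as.double(seed) * 101 + off) %% (2^31 - 1))
}

#' Default pipeline configuration
#'
#' A nested list of per-stage parameter sections with documented defaults:
#' the desk-scale synthetic study (4 classes, 12x12 images, a small MLP with
#' hidden sizes 32 and 16, T = 10), the default sweep grid and manifold
#' bounds, the efficiency parameters `lambda = 0.5` and `beta = 5`, the
#' policy horizons and the perturbation/diagnostics settings.
#'
#' @param seed Global seed; every random procedure derives its seed from it
#'   via [stage_seed()].
#' @param out_dir Output directory for command artifacts.
#' @return A classed nested list; unspecified fields keep these defaults.
#' @export
default_run_config <- function(seed = 1, out_dir = "snn-artifacts") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    synthetic = list(n_classes = 4, height = 12, width = 12,
                     train_per_class = 40, test_per_class = 20,
                     contrast = 0.4, noise_sd = 0.35),
    neuron = list(tau_m = 2, v_th = 1, v_reset = 0, dt = 1, t_ref = 0,
                  reset_mode = "hard"),
    architecture = list(kind = "mlp", hidden = c(32, 16)),
    training = list(n_steps = 10, epochs = 20, lr = 1e-3, batch_size = 32,
                    surrogate_slope = 2, policy = "reset"),
    sweep = list(tau_min = 1.001, tau_max = 5, n_tau = 5,
                 vth_min = 0.01, vth_max = 3, n_vth = 5,
                 mode = "train_then_eval"),
    manifold = list(r_min = 0.01, r_max = 0.5, a_thr = 0.9,
                    a_thr_mode = "relative"),
    efficiency = list(lambda = 0.5, beta = 5),
    policy = list(t_values = c(1, 2, 3, 5, 10),
                  policies = c("reset", "carry")),
    perturbation = list(max_pairs = 2000, swap_increment = 1,
                        max_level = NULL, eval_per_class = 100),
    diagnostics = list(n_neurons = 16, t_steps = 10, rate = 0.2,
                       c_clean = 0, c_noisy = 0.5, n_samples = 1000)
  ), class = "run_config")
}

# merge user overrides (possibly from YAML) into the defaults
resolve_run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  base <- default_run_config(
    seed = config$seed %||% 1,
    out_dir = config$out_dir %||% "snn-artifacts"
  )
  for (sec in setdiff(names(base), c("seed", "out_dir"))) {
    if (!is.null(config[[sec]])) {
      base[[sec]][names(config[[sec]])] <- config[[sec]]
    }
  }
  base
}

cfg_task <- function(cfg) {
  s <- cfg$synthetic
  make_static_task(synthetic_task_config(
    n_classes = s$n_classes, height = s$height, width = s$width,
    train_per_class = s$train_per_class, test_per_class = s$test_per_class,
    contrast = s$contrast, noise_sd = s$noise_sd,
    seed = stage_seed(cfg$seed, "synth")
  ))
}

cfg_neuron <- function(cfg) {
  n <- cfg$neuron
  neuron_config(tau_m = n$tau_m, v_th = n$v_th, v_reset = n$v_reset,
                dt = n$dt, t_ref = n$t_ref, reset_mode = n$reset_mode)
}

cfg_arch <- function(cfg, task) {
  a <- cfg$architecture
  if (a$kind == "mlp") {
    architecture_spec("mlp",
                      input_shape = task$config$height * task$config$width,
                      n_classes = task$config$n_classes, hidden = a$hidden)
  } else {
    architecture_spec("conv", input_shape = a$input_shape,
                      n_classes = a$n_classes %||% task$config$n_classes,
                      conv_channels = a$conv_channels %||% c(64, 128),
                      classifier_hidden = a$classifier_hidden %||% 64)
  }
}

cfg_training <- function(cfg) {
  t <- cfg$training
  training_config(n_steps = t$n_steps, epochs = t$epochs, lr = t$lr,
                  batch_size = t$batch_size,
                  surrogate_slope = t$surrogate_slope, policy = t$policy,
                  seed = stage_seed(cfg$seed, "train"))
}

cfg_trained_fit <- function(cfg) {
  task <- cfg_task(cfg)
  tc <- cfg_training(cfg)
  enc_seed <- stage_seed(cfg$seed, "encode")
  train_data <- encode_dataset(task$train, tc$n_steps, seed = enc_seed)
  net <- build_network(cfg_arch(cfg, task), cfg_neuron(cfg),
                       seed = stage_seed(cfg$seed, "train"))
  fit <- train_network(net, train_data, tc)
  list(task = task, fit = fit, train_data = train_data,
       test_data = encode_dataset(task$test, tc$n_steps,
                                  seed = enc_seed + 1L))
}

#' Write a results table or report
#'
#' CSV output has a stable column order and numeric values rounded to 10
#' significant digits; JSON output uses stable key order and the same
#' precision, so reruns of a deterministic pipeline diff cleanly.
#'
#' @param results A data frame (csv) or list (json).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (format == "csv") {
    df <- dplyr::mutate(tibble::as_tibble(results),
                        dplyr::across(dplyr::where(is.numeric),
                                      ~ signif(.x, 10)))
    readr::write_csv(df, path, progress = FALSE)
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}

log_stage <- function(...) {
  message(sprintf(...))
}

#' Run a pipeline command
#'
#' Executes one stage of the study pipeline on a resolved configuration and
#' writes its artifacts (CSV/JSON with the embedded resolved config) under
#' `config$out_dir`. Commands are pure functions of the configuration:
#' rerunning any command with the same config reproduces byte-identical
#' outputs.
#'
#' * `synth`: writes the synthetic train/test image datasets.
#' * `train`: trains the configured network; writes history and checkpoint.
#' * `sweep`: grid sweep plus manifold membership/boundary; writes the sweep
#'   CSV.
#' * `score`: reads the sweep CSV, appends efficiency columns and writes the
#'   operating-point report.
#' * `policy`: reset-vs-carry accuracy curve over the configured horizons.
#' * `diagnose`: perturbation pairs, correlation feature table, mutual
#'   information and classifier report.
#'
#' @param name Command name: `"synth"`, `"train"`, `"sweep"`, `"score"`,
#'   `"policy"` or `"diagnose"`.
#' @param config A [default_run_config()]-style list (partial overrides
#'   allowed) or the path to a YAML file of overrides.
#' @return Invisibly, a character vector of the artifact paths written.
#' @export
run_command <- function(name, config = list()) {
  if (!name %in% c("synth", "train", "sweep", "score", "policy", "diagnose")) {
    rlang::abort(sprintf("Unknown command \"%s\".", name))
  }
  cfg <- resolve_run_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(p) {
    paths <<- c(paths, p)
    p
  }
  cfg_json <- unclass(cfg)
  cfg_json$out_dir <- NULL # artifacts are location-independent
  cfg_json$perturbation$max_level <- cfg$perturbation$max_level %||% "3T"
  write_report(list(command = name, config = cfg_json),
               put(file.path(out, paste0(name, "_config.json"))), "json")

  if (name == "synth") {
    task <- cfg_task(cfg)
    log_stage("synth: %d train / %d test samples",
              length(task$train$labels), length(task$test$labels))
    flatten_split <- function(split) {
      mat <- do.call(rbind, lapply(split$images, as.numeric))
      colnames(mat) <- paste0("px", seq_len(ncol(mat)))
      dplyr::bind_cols(tibble::tibble(label = split$labels),
                       tibble::as_tibble(mat))
    }
    write_report(flatten_split(task$train),
                 put(file.path(out, "synth_train.csv")))
    write_report(flatten_split(task$test),
                 put(file.path(out, "synth_test.csv")))
  } else if (name == "train") {
    tr <- cfg_trained_fit(cfg)
    ev <- evaluate_network(tr$fit, tr$test_data)
    log_stage("train: final loss %.4f, test accuracy %.3f",
              tr$fit$history$loss[nrow(tr$fit$history)], ev$accuracy)
    write_report(tr$fit$history, put(file.path(out, "train_history.csv")))
    write_report(network_checkpoint(tr$fit$network),
                 put(file.path(out, "train_checkpoint.json")), "json")
  } else if (name == "sweep") {
    task <- cfg_task(cfg)
    tc <- cfg_training(cfg)
    enc_seed <- stage_seed(cfg$seed, "encode")
    st <- sweep_task(
      encode_dataset(task$train, tc$n_steps, seed = enc_seed),
      encode_dataset(task$test, tc$n_steps, seed = enc_seed + 1L),
      cfg_arch(cfg, task)
    )
    g <- sweep_grid(
      seq(cfg$sweep$tau_min, cfg$sweep$tau_max, length.out = cfg$sweep$n_tau),
      seq(cfg$sweep$vth_min, cfg$sweep$vth_max, length.out = cfg$sweep$n_vth),
      dt = cfg$neuron$dt
    )
    sw <- run_sweep(st, g, mode = cfg$sweep$mode,
                    base_seed = stage_seed(cfg$seed, "sweep"),
                    train_config = tc, v_reset = cfg$neuron$v_reset,
                    dt = cfg$neuron$dt, reset_mode = cfg$neuron$reset_mode)
    mf <- manifold(sw, manifold_spec(cfg$manifold$r_min, cfg$manifold$r_max,
                                     cfg$manifold$a_thr,
                                     cfg$manifold$a_thr_mode))
    log_stage("sweep: %d points, %d in manifold", nrow(sw),
              sum(mf$sweep$in_manifold))
    write_report(mf$sweep, put(file.path(out, "sweep.csv")))
  } else if (name == "score") {
    sweep_path <- file.path(out, "sweep.csv")
    if (!file.exists(sweep_path)) {
      rlang::abort("score: missing input artifact sweep.csv (run `sweep` first).")
    }
    sw <- readr::read_csv(sweep_path, show_col_types = FALSE, progress = FALSE)
    sc <- score_sweep(sw, lambda = cfg$efficiency$lambda,
                      beta = cfg$efficiency$beta)
    log_stage("score: best BES %.3f, best EAS %.3f",
              max(sc$bes), max(sc$eas))
    write_report(sc, put(file.path(out, "score.csv")))
    report <- list(
      lambda = cfg$efficiency$lambda, beta = cfg$efficiency$beta,
      best_bes = as.list(attr(sc, "best_bes")),
      best_eas = as.list(attr(sc, "best_eas")),
      n_pareto = sum(sc$pareto)
    )
    write_report(report, put(file.path(out, "score_report.json")), "json")
  } else if (name == "policy") {
    tr <- cfg_trained_fit(cfg)
    pc <- evaluate_policy_curve(tr$fit, tr$task,
                                policies = cfg$policy$policies,
                                t_values = cfg$policy$t_values,
                                seed = stage_seed(cfg$seed, "policy"))
    log_stage("policy: %d (policy, T) points", nrow(pc))
    write_report(pc, put(file.path(out, "policy_curve.csv")))
  } else if (name == "diagnose") {
    tr <- cfg_trained_fit(cfg)
    dseed <- stage_seed(cfg$seed, "diagnose")
    # dedicated, larger evaluation draw: the perturbation protocol streams a
    # full test set and keeps only samples that flip
    s <- cfg$synthetic
    ev_task <- make_static_task(synthetic_task_config(
      n_classes = s$n_classes, height = s$height, width = s$width,
      train_per_class = 1,
      test_per_class = cfg$perturbation$eval_per_class %||% 100,
      contrast = s$contrast, noise_sd = s$noise_sd, seed = dseed + 13L
    ))
    ev_data <- encode_dataset(ev_task$test, cfg$training$n_steps,
                              seed = dseed + 17L)
    pp <- collect_pairs(tr$fit, ev_data, perturbation_config(
      max_pairs = cfg$perturbation$max_pairs,
      swap_increment = cfg$perturbation$swap_increment,
      max_level = cfg$perturbation$max_level, seed = dseed
    ))
    log_stage("diagnose: %d perturbation pairs", length(pp$pairs))
    d <- cfg$diagnostics
    clean <- lapply(seq_len(d$n_samples), function(i) {
      make_correlated_spike_trains(d$n_neurons, d$t_steps, d$rate, d$c_clean,
                                   seed = dseed + 2L * i)
    })
    noisy <- lapply(seq_len(d$n_samples), function(i) {
      make_correlated_spike_trains(d$n_neurons, d$t_steps, d$rate, d$c_noisy,
                                   seed = dseed + 2L * i + 1L)
    })
    feats <- correlation_feature_table(clean, noisy)
    write_report(feats, put(file.path(out, "diagnose_features.csv")))
    mi <- mutual_information_scores(feats[corr_feature_names],
                                    feats$condition)
    clf <- condition_classifier(feats[corr_feature_names], feats$condition,
                                seed = dseed)
    pair_report <- if (length(pp$pairs) >= 1L) {
      cs <- summarize_correlations(
        lapply(pp$pairs, function(p) correlation_matrix(p$clean_activity))
      )
      ns <- summarize_correlations(
        lapply(pp$pairs, function(p) correlation_matrix(p$perturbed_activity))
      )
      list(n_pairs = length(pp$pairs), clean = as.list(cs),
           noisy = as.list(ns))
    } else {
      list(n_pairs = 0L)
    }
    write_report(list(
      mutual_information = as.list(stats::setNames(mi$mi_bits, mi$feature)),
      classifier_accuracy = clf$accuracy,
      importances = as.list(stats::setNames(clf$importance$gain,
                                            clf$importance$feature)),
      perturbation_pairs = pair_report
    ), put(file.path(out, "diagnose_report.json")), "json")
    write_report(tidy(pp), put(file.path(out, "diagnose_pairs.csv")))
  }
  invisible(paths)
}

# flat JSON-serializable network checkpoint (text only)
network_checkpoint <- function(net) {
  list(
    kind = net$spec$kind,
    n_classes = net$spec$n_classes,
    neuron = unclass(net$config),
    layers = lapply(net$layers, function(l) {
      list(type = l$type, n_in = l$n_in, n_out = l$n_out,
           W = as.numeric(l$W), b = as.numeric(l$b),
           bn = if (!is.null(l$bn)) {
             l$bn[c("gamma", "beta", "rmean", "rvar")]
           },
           W_rec = if (l$recurrent) as.numeric(l$W_rec))
    })
  )
}
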