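#' Validate an experiment configuration
#'
#' Reads a YAML experiment configuration (or takes an equivalent named
#' list) and performs full structural and semantic validation: task
#' parameters, network shape consistency, divisibility of T by every
#' working-memory length, and training hyperparameters. All problems are
#' collected and reported together.
#'
#' @param config Path to a YAML file, or a named list with elements
#'   `task`, `network`, `training`, and optionally `split`, `seeds`,
#'   `sweep`, `output_dir`.
#' @return A validated object of class `snn_experiment_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_snn("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_snn("config must be a YAML file path or a list")
  errs <- character(0)
  note <- function(...) errs <<- c(errs, paste0(...))

  task <- config$task
  if (is.null(task)) note("task: missing section")
  net <- config$network
  if (is.null(net)) note("network: missing section")
  tr <- config$training
  if (is.null(tr)) note("training: missing section")
  if (length(errs)) stop_snn("invalid config:\n  ", paste(errs, collapse = "\n  "))

  spec <- tryCatch(
    task_spec(kind = task$kind %||% "order",
              n_samples = task$n_samples %||% 2000L,
              T = task$T %||% 32L, n_in = task$n_in %||% 16L,
              motif_len = task$motif_len %||% 8L,
              jitter = task$jitter %||% 2L,
              noise_rate = task$noise_rate %||% 0.02,
              motif_density = task$motif_density %||% 0.3,
              seed = 1L),
    error = function(e) { note("task: ", conditionMessage(e)); NULL }
  )

  mode <- net$mode %||% "segment"
  if (!mode %in% c("classic", "overlap", "segment")) {
    note("network: unknown mode '", mode, "'")
  }
  hidden <- as.integer(net$hidden %||% 64L)
  if (any(hidden < 1)) note("network: hidden widths must be >= 1")
  readout <- net$readout %||% "fusion"
  if (!readout %in% c("fusion", "count")) {
    note("network: unknown readout '", readout, "'")
  }
  mem_len <- as.integer(net$mem_len %||% 8L)
  sweep <- if (!is.null(config$sweep)) as.integer(unlist(config$sweep)) else NULL
  if (!is.null(spec) && mode == "segment") {
    for (L in c(if (is.null(sweep)) mem_len, sweep)) {
      if (L < 1 || spec$T %% L != 0L) {
        note("network: mem_len ", L, " must divide T = ", spec$T,
             " in segment mode")
      }
    }
  }
  tau <- net$tau %||% 2
  if (tau <= 0) note("network: tau must be > 0")

  lr <- tr$learning_rate %||% 1e-3
  if (lr <= 0) note("training: learning_rate must be > 0")
  epochs <- as.integer(tr$epochs %||% 30L)
  if (epochs < 1) note("training: epochs must be >= 1")
  batch <- as.integer(tr$batch_size %||% 32L)
  if (batch < 1) note("training: batch_size must be >= 1")
  optimizer <- tr$optimizer %||% "adam"
  if (!optimizer %in% c("adam", "sgd_momentum")) {
    note("training: unknown optimizer '", optimizer, "'")
  }
  loss <- tr$loss %||% "cross_entropy"
  if (!loss %in% c("cross_entropy", "mse")) {
    note("training: unknown loss '", loss, "'")
  }

  split <- as.numeric(unlist(config$split %||% c(0.8, 0.2)))
  if (length(split) != 2L || any(split <= 0) || abs(sum(split) - 1) > 1e-8) {
    note("split: must be two positive fractions summing to 1")
  }
  seeds <- as.integer(unlist(config$seeds %||% 1:5))
  if (length(seeds) < 1L) note("seeds: need at least one seed")

  if (length(errs)) stop_snn("invalid config:\n  ", paste(errs, collapse = "\n  "))
  structure(list(
    task = spec,
    network = list(hidden = hidden, mode = mode, mem_len = mem_len,
                   readout = readout, tau = tau, theta = net$theta %||% 1,
                   v_rest = net$v_rest %||% 0),
    training = list(epochs = epochs, batch_size = batch, learning_rate = lr,
                    optimizer = optimizer, loss = loss),
    split = split, seeds = seeds, sweep = sweep,
    output_dir = config$output_dir
  ), class = "snn_experiment_config")
}

run_single <- function(cfg, seed, mem_len) {
  spec <- cfg$task
  spec$seed <- as.integer(seed)
  data <- make_task(spec)
  parts <- split_dataset(data, cfg$split, seed = seed)
  net <- snn_network(spec$n_in, cfg$network$hidden, n_out = 2L, T = spec$T,
                     mode = cfg$network$mode, mem_len = mem_len,
                     readout = cfg$network$readout, tau = cfg$network$tau,
                     theta = cfg$network$theta, v_rest = cfg$network$v_rest,
                     seed = seed)
  t0 <- proc.time()[["elapsed"]]
  fit <- snn_fit(parts$train, net, epochs = cfg$training$epochs,
                 batch_size = cfg$training$batch_size,
                 learning_rate = cfg$training$learning_rate,
                 optimizer = cfg$training$optimizer, loss = cfg$training$loss,
                 seed = seed)
  train_seconds <- proc.time()[["elapsed"]] - t0
  ev <- snn_evaluate(fit, parts$test)
  # single-sample inference time (hardware-dependent; reported, never asserted)
  one <- parts$test$spikes[1, , , drop = FALSE]
  t1 <- proc.time()[["elapsed"]]
  reps <- 10L
  for (r in seq_len(reps)) snn_forward(fit$network, one)
  infer_seconds <- (proc.time()[["elapsed"]] - t1) / reps
  list(fit = fit,
       row = data.frame(mem_len = mem_len, seed = seed,
                        test_accuracy = ev$accuracy,
                        train_accuracy = fit$history$train_accuracy[cfg$training$epochs],
                        final_loss = fit$history$loss[cfg$training$epochs],
                        mean_firing_rate = ev$mean_firing_rate,
                        train_seconds = train_seconds,
                        infer_seconds_per_sample = infer_seconds))
}

#' Run an experiment (optionally a memory-length sweep)
#'
#' For each working-memory length in `sweep` (or the single configured
#' `mem_len`) and each seed: generates the task data, splits it, builds
#' and trains a network, and evaluates it on the held-out split.
#' Metrics are aggregated as mean and standard deviation over seeds.
#' Wall-clock timings (training, single-sample inference) are recorded
#' but are hardware-dependent and never part of the deterministic output.
#'
#' If `output_dir` is set, writes `metrics.json` (deterministic metrics
#' only) and `timing.json` there.
#'
#' @param config A path, list, or validated `snn_experiment_config`.
#' @return An object of class `snn_experiment` with `runs` (one row per
#'   seed x sweep value) and `aggregate` (per sweep value) data frames.
#' @export
run_experiment <- function(config) {
  cfg <- if (inherits(config, "snn_experiment_config")) config
         else validate_config(config)
  mem_lens <- cfg$sweep %||% cfg$network$mem_len
  runs <- list()
  for (L in mem_lens) {
    for (seed in cfg$seeds) {
      runs[[length(runs) + 1L]] <- run_single(cfg, seed, L)$row
    }
  }
  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(split(runs, runs$mem_len), function(g) {
    data.frame(mem_len = g$mem_len[1],
               mean_test_accuracy = mean(g$test_accuracy),
               sd_test_accuracy = stats::sd(g$test_accuracy),
               mean_infer_seconds = mean(g$infer_seconds_per_sample),
               n_seeds = nrow(g))
  }))
  rownames(agg) <- NULL
  res <- structure(list(runs = runs, aggregate = agg, config = cfg),
                   class = "snn_experiment")
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    det_cols <- setdiff(names(runs), c("train_seconds",
                                       "infer_seconds_per_sample"))
    jsonlite::write_json(
      list(runs = runs[det_cols],
           aggregate = agg[setdiff(names(agg), "mean_infer_seconds")]),
      file.path(cfg$output_dir, "metrics.json"), digits = NA)
    jsonlite::write_json(
      runs[c("mem_len", "seed", "train_seconds", "infer_seconds_per_sample")],
      file.path(cfg$output_dir, "timing.json"), digits = NA)
  }
  res
}

#' @export
print.snn_experiment <- function(x, ...) {
  cat(sprintf("Experiment: %s task, %s mode, %d seed(s)\n",
              x$config$task$kind, x$config$network$mode,
              length(x$config$seeds)))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  mem_len %2d: accuracy %.3f +/- %.3f (inference %.2g s/sample)\n",
                agg$mem_len[i], agg$mean_test_accuracy[i],
                ifelse(is.na(agg$sd_test_accuracy[i]), 0, agg$sd_test_accuracy[i]),
                agg$mean_infer_seconds[i]))
  }
  invisible(x)
}
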