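#' Synthetic task specification
#'
#' Parameters of the synthetic spike-train classification tasks. Two task
#' families are provided:
#' \describe{
#'   \item{order}{two spike motifs A and B appear in both classes, in
#'     opposite temporal order — only global order is informative;}
#'   \item{density}{a class-specific motif appears in one randomly chosen
#'     window — all spikes are concentrated in a small part of the train.}
#' }
#'
#' @param kind `"order"` or `"density"`.
#' @param n_samples Number of samples (classes are balanced).
#' @param T Timesteps per train.
#' @param n_in Input neurons.
#' @param motif_len Motif length in timesteps.
#' @param jitter Maximum absolute displacement (timesteps) of each motif
#'   from its nominal position (order task only).
#' @param noise_rate Background Bernoulli spike probability per (t, neuron).
#' @param motif_density Within-motif Bernoulli spike probability.
#' @param seed RNG seed; generation is a pure function of (spec, seed).
#' @return An object of class `snn_task_spec`.
#' @export
task_spec <- function(kind = c("order", "density"), n_samples = 2000L,
                      T = 32L, n_in = 16L, motif_len = 8L, jitter = 2L,
                      noise_rate = 0.02, motif_density = 0.3, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_samples >= 2, T >= 1, n_in >= 1, motif_len >= 1, jitter >= 0)
  if (noise_rate < 0 || noise_rate > 1 || motif_density < 0 || motif_density > 1) {
    stop_snn("noise_rate and motif_density must be probabilities in [0, 1]")
  }
  if (2 * motif_len + 2 * jitter > T) {
    stop_snn("need 2*motif_len + 2*jitter <= T")
  }
  structure(list(kind = kind, n_samples = as.integer(n_samples),
                 T = as.integer(T), n_in = as.integer(n_in),
                 motif_len = as.integer(motif_len), jitter = as.integer(jitter),
                 noise_rate = noise_rate, motif_density = motif_density,
                 seed = as.integer(seed)),
            class = "snn_task_spec")
}

new_dataset <- function(spikes, labels, spec) {
  structure(list(spikes = spikes, labels = as.integer(labels), spec = spec),
            class = "snn_dataset")
}

#' @export
print.snn_dataset <- function(x, ...) {
  d <- dim(x$spikes)
  cat(sprintf("Spike-train dataset: %d samples x %d timesteps x %d neurons\n",
              d[1], d[2], d[3]))
  cat("Labels:", paste(sprintf("%d x class %d", tabulate(x$labels + 1L),
                               sort(unique(x$labels))), collapse = ", "), "\n")
  invisible(x)
}

draw_motif <- function(motif_len, n_in, density) {
  (matrix(stats::runif(motif_len * n_in), motif_len, n_in) < density) + 0
}

#' Temporal-order discrimination task
#'
#' Generates balanced two-class spike trains in which the only informative
#' feature is global temporal order. Two motifs A and B are drawn once per
#' seed; class 0 samples contain A in the first half of the train and B in
#' the second half, class 1 the reverse. Each motif is displaced by a
#' uniform jitter, and background spikes are added at `noise_rate`. Both
#' classes contain both motifs exactly once, so per-neuron spike counts
#' over the whole train are identically distributed across classes and a
#' time-blind readout cannot beat chance systematically.
#'
#' @param spec A [task_spec()] with `kind = "order"`. Placement requires
#'   `motif_len + 2*jitter <= T/2` so the jittered motifs stay inside
#'   their halves.
#' @return An object of class `snn_dataset` (fields `spikes`
#'   n x T x n_in, `labels`, `spec`).
#' @export
make_order_task <- function(spec) {
  stopifnot(inherits(spec, "snn_task_spec"))
  if (spec$kind != "order") stop_snn("spec$kind must be 'order'")
  half <- spec$T %/% 2L
  base <- (half - spec$motif_len) %/% 2L
  if (spec$motif_len + 2L * spec$jitter > half) {
    stop_snn("jittered motifs would collide across halves: need ",
             "motif_len + 2*jitter <= T/2")
  }
  with_seed(spec$seed, {
    A <- draw_motif(spec$motif_len, spec$n_in, spec$motif_density)
    B <- draw_motif(spec$motif_len, spec$n_in, spec$motif_density)
    labels <- sample(rep(0:1, length.out = spec$n_samples))
    spikes <- array(0, c(spec$n_samples, spec$T, spec$n_in))
    for (s in seq_len(spec$n_samples)) {
      first <- if (labels[s] == 0L) A else B
      second <- if (labels[s] == 0L) B else A
      o1 <- base + sample.int(2L * spec$jitter + 1L, 1L) - spec$jitter - 1L
      o2 <- base + sample.int(2L * spec$jitter + 1L, 1L) - spec$jitter - 1L
      x <- matrix(0, spec$T, spec$n_in)
      x[o1 + seq_len(spec$motif_len), ] <- first
      x[half + o2 + seq_len(spec$motif_len), ] <- second
      if (spec$noise_rate > 0) {
        noise <- matrix(stats::runif(spec$T * spec$n_in), spec$T, spec$n_in) <
          spec$noise_rate
        x <- pmin(x + noise, 1)
      }
      spikes[s, , ] <- x
    }
    new_dataset(spikes, labels, spec)
  })
}

#' Uneven-spike-density task
#'
#' Generates balanced two-class spike trains whose informative motif (A for
#' class 0, B for class 1, drawn once per seed) occupies exactly one
#' window of length `motif_len`, chosen uniformly among the aligned
#' windows; the rest of the train carries only background noise. Classes
#' differ in which motif appears, never in when it appears.
#'
#' @param spec A [task_spec()] with `kind = "density"`; `motif_len` must
#'   divide `T`.
#' @return An object of class `snn_dataset`.
#' @export
make_density_task <- function(spec) {
  stopifnot(inherits(spec, "snn_task_spec"))
  if (spec$kind != "density") stop_snn("spec$kind must be 'density'")
  if (spec$T %% spec$motif_len != 0L) {
    stop_snn("density task requires motif_len to divide T")
  }
  n_win <- spec$T %/% spec$motif_len
  with_seed(spec$seed, {
    A <- draw_motif(spec$motif_len, spec$n_in, spec$motif_density)
    B <- draw_motif(spec$motif_len, spec$n_in, spec$motif_density)
    labels <- sample(rep(0:1, length.out = spec$n_samples))
    spikes <- array(0, c(spec$n_samples, spec$T, spec$n_in))
    for (s in seq_len(spec$n_samples)) {
      motif <- if (labels[s] == 0L) A else B
      w <- sample.int(n_win, 1L) - 1L
      x <- matrix(0, spec$T, spec$n_in)
      x[w * spec$motif_len + seq_len(spec$motif_len), ] <- motif
      if (spec$noise_rate > 0) {
        noise <- matrix(stats::runif(spec$T * spec$n_in), spec$T, spec$n_in) <
          spec$noise_rate
        x <- pmin(x + noise, 1)
      }
      spikes[s, , ] <- x
    }
    new_dataset(spikes, labels, spec)
  })
}

#' Generate a synthetic dataset from a task spec
#'
#' Dispatches to [make_order_task()] or [make_density_task()].
#'
#' @param spec A [task_spec()].
#' @return An `snn_dataset`.
#' @export
make_task <- function(spec) {
  switch(spec$kind,
         order = make_order_task(spec),
         density = make_density_task(spec),
         stop_snn("unknown task kind: ", spec$kind))
}

#' Stratified train/test split
#'
#' Splits a dataset into disjoint subsets, stratified by label, with the
#' first fraction of each class's shuffled indices going to the first
#' subset. Reproducible for a given seed.
#'
#' @param data An `snn_dataset`.
#' @param fractions Two positive fractions summing to 1, e.g. `c(0.8, 0.2)`.
#' @param seed RNG seed for the shuffle.
#' @return List of two `snn_dataset`s (`train`, `test`).
#' @export
split_dataset <- function(data, fractions = c(0.8, 0.2), seed = 1L) {
  stopifnot(inherits(data, "snn_dataset"))
  if (length(fractions) != 2L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop_snn("fractions must be two positive numbers summing to 1")
  }
  idx_train <- integer(0)
  with_seed(seed, {
    for (cls in sort(unique(data$labels))) {
      cls_idx <- sample(which(data$labels == cls))
      n1 <- round(fractions[1] * length(cls_idx))
      idx_train <- c(idx_train, cls_idx[seq_len(n1)])
    }
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_along(data$labels), idx_train)
  if (length(idx_train) == 0L || length(idx_test) == 0L) {
    stop_snn("split fractions produce an empty subset")
  }
  subset_ds <- function(idx) {
    new_dataset(data$spikes[idx, , , drop = FALSE], data$labels[idx], data$spec)
  }
  list(train = subset_ds(idx_train), test = subset_ds(idx_test))
}

#' Save a dataset as plain text
#'
#' Writes `spec.json`, `labels.csv` (sample,label) and `events.csv`
#' (sample,t,neuron; all 0-based) into `dir`. Restored losslessly by
#' [load_dataset()].
#'
#' @param data An `snn_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_dataset <- function(data, dir) {
  stopifnot(inherits(data, "snn_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(data$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(sample = seq_along(data$labels) - 1L, label = data$labels),
    file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  idx <- which(data$spikes == 1, arr.ind = TRUE)
  ev <- data.frame(sample = idx[, 1] - 1L, t = idx[, 2] - 1L,
                   neuron = idx[, 3] - 1L)
  ev <- ev[order(ev$sample, ev$t, ev$neuron), ]
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' Load a dataset saved by [save_dataset()]
#'
#' @param dir Directory containing `spec.json`, `labels.csv`, `events.csv`.
#' @return An `snn_dataset`.
#' @export
load_dataset <- function(dir) {
  spec_raw <- jsonlite::read_json(file.path(dir, "spec.json"),
                                  simplifyVector = TRUE)
  spec <- do.call(task_spec, spec_raw)
  labels <- utils::read.csv(file.path(dir, "labels.csv"))
  ev <- utils::read.csv(file.path(dir, "events.csv"))
  spikes <- array(0, c(nrow(labels), spec$T, spec$n_in))
  if (nrow(ev) > 0) {
    spikes[cbind(ev$sample + 1L, ev$t + 1L, ev$neuron + 1L)] <- 1
  }
  new_dataset(spikes, labels$label[order(labels$sample)], spec)
}
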