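#' Construct a spiking network with working memory
#'
#' Builds a feedforward spiking network: one or more LIF layers whose
#' synaptic drive is computed under a shared working-memory mode, followed
#' by a readout over the last layer's spike train. Weights are initialized
#' reproducibly from `seed`: spatial matrices by width-scaled uniform
#' (Glorot) draws, temporal taps `w2` at the window average `1/Nk`.
#'
#' Modes:
#' \describe{
#'   \item{classic}{single zero-delay synapse per connection — the baseline
#'     LIF network;}
#'   \item{overlap}{`mem_len` overlapping dendrite groups with arithmetic
#'     delays `0:(mem_len-1)` and trainable temporal taps;}
#'   \item{segment}{non-overlapping working-memory windows of length
#'     `mem_len` with trainable within-window taps.}
#' }
#' Readouts: `"fusion"` — the temporal fusion head with trainable per-step
#' taps (initialized to `1/T`); `"count"` — spike-count readout, i.e. the
#' same static head with all temporal taps fixed at 1 (untrainable), so
#' logits depend only on total spike counts.
#'
#' @param n_in Input neurons.
#' @param n_hidden Integer vector of hidden-layer widths.
#' @param n_out Output classes.
#' @param T Timesteps per sample.
#' @param mode Working-memory mode of the hidden layers.
#' @param mem_len Window length L (overlap/segment modes); must divide T in
#'   segment mode.
#' @param readout `"fusion"` or `"count"`.
#' @param tau,theta,v_rest LIF parameters shared by all hidden layers.
#' @param seed RNG seed for weight initialization.
#' @return An object of class `snn_network`.
#' @export
snn_network <- function(n_in, n_hidden = 64L, n_out = 2L, T = 32L,
                        mode = c("segment", "overlap", "classic"),
                        mem_len = 8L, readout = c("fusion", "count"),
                        tau = 2, theta = 1, v_rest = 0, seed = 1L) {
  mode <- match.arg(mode)
  readout <- match.arg(readout)
  stopifnot(n_in >= 1, all(n_hidden >= 1), n_out >= 1, T >= 1)
  if (mode == "segment") {
    if (mem_len < 1 || T %% mem_len != 0L) {
      stop_snn("segment mode requires mem_len >= 1 dividing T")
    }
  }
  if (mode == "overlap" && mem_len < 1) stop_snn("mem_len must be >= 1")
  nk <- switch(mode, classic = 1L, as.integer(mem_len))
  widths <- c(n_in, n_hidden)
  glorot <- function(ni, no) {
    a <- sqrt(6 / (ni + no))
    matrix(stats::runif(ni * no, -a, a), ni, no)
  }
  with_seed(seed, {
    layers <- vector("list", length(n_hidden))
    for (l in seq_along(n_hidden)) {
      layers[[l]] <- list(
        W1 = glorot(widths[l], widths[l + 1]),
        w2 = rep(1 / nk, nk)
      )
    }
    head <- list(
      W = glorot(widths[length(widths)], n_out),
      w_time = if (readout == "fusion") rep(1 / T, T) else rep(1, T)
    )
    structure(list(
      n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
      n_out = as.integer(n_out), T = as.integer(T),
      mode = mode, mem_len = as.integer(mem_len), readout = readout,
      lif = lif_params(tau, theta, v_rest),
      layers = layers, head = head, seed = as.integer(seed)
    ), class = "snn_network")
  })
}

#' @export
print.snn_network <- function(x, ...) {
  cat("Spiking network with working memory\n")
  cat(sprintf("  architecture: %s -> %s -> %d (T = %d)\n", x$n_in,
              paste(x$n_hidden, collapse = " -> "), x$n_out, x$T))
  cat(sprintf("  mode: %s%s, readout: %s\n", x$mode,
              if (x$mode != "classic") sprintf(" (mem_len = %d)", x$mem_len) else "",
              x$readout))
  cat(sprintf("  LIF: tau = %g, theta = %g, v_rest = %g\n",
              x$lif$tau, x$lif$theta, x$lif$v_rest))
  cat(sprintf("  parameters: %d\n", n_params(x)))
  invisible(x)
}

n_params <- function(net) {
  n <- length(net$head$W) +
    if (net$readout == "fusion") length(net$head$w_time) else 0L
  for (l in net$layers) {
    n <- n + length(l$W1) + if (net$mode == "classic") 0L else length(l$w2)
  }
  n
}

layer_delays <- function(net) {
  if (net$mode == "classic") 0L else seq_len(net$mem_len) - 1L
}

#' Extract a hidden layer as a layer_spec
#'
#' Views layer `l` of a network as a standalone [layer_spec()], so the
#' drive/LIF operations can be applied to it directly.
#'
#' @param net An `snn_network`.
#' @param l Layer index.
#' @return A [layer_spec()].
#' @export
network_layer_spec <- function(net, l = 1L) {
  stopifnot(inherits(net, "snn_network"), l >= 1, l <= length(net$layers))
  kern <- delay_kernel(net$layers[[l]]$W1, net$layers[[l]]$w2,
                       delays = layer_delays(net))
  wm <- switch(net$mode,
    classic = wm_config("classic"),
    overlap = wm_config("overlap"),
    segment = wm_config("segment", mem_len = net$mem_len))
  layer_spec(kern, net$lif, wm)
}

#' Save network weights to JSON
#'
#' Plain-text checkpoint: architecture fields plus all weights, written
#' with full double precision. Restored by [load_network()].
#'
#' @param net An `snn_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "snn_network"))
  obj <- list(
    n_in = net$n_in, n_hidden = net$n_hidden, n_out = net$n_out, T = net$T,
    mode = net$mode, mem_len = net$mem_len, readout = net$readout,
    tau = net$lif$tau, theta = net$lif$theta, v_rest = net$lif$v_rest,
    seed = net$seed,
    layers = lapply(net$layers, function(l) {
      list(W1 = as.vector(l$W1), dim_W1 = dim(l$W1), w2 = l$w2)
    }),
    head = list(W = as.vector(net$head$W), dim_W = dim(net$head$W),
                w_time = net$head$w_time)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load network weights from JSON
#'
#' @param path A checkpoint written by [save_network()].
#' @return An `snn_network`.
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  net <- snn_network(obj$n_in, obj$n_hidden, obj$n_out, obj$T, obj$mode,
                     obj$mem_len, obj$readout, obj$tau, obj$theta,
                     obj$v_rest, obj$seed)
  for (l in seq_along(net$layers)) {
    lay <- obj$layers[[l]]
    net$layers[[l]]$W1 <- matrix(lay$W1, lay$dim_W1[1], lay$dim_W1[2])
    net$layers[[l]]$w2 <- lay$w2
  }
  net$head$W <- matrix(obj$head$W, obj$head$dim_W[1], obj$head$dim_W[2])
  net$head$w_time <- obj$head$w_time
  net
}
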