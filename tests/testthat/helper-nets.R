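# Shared fixture builders (all generated in code, seeded).

random_spikes <- function(B, T, N, seed, p = 0.3) {
  set.seed(seed)
  array((runif(B * T * N) < p) + 0, c(B, T, N))
}

random_spike_matrix <- function(T, N, seed, p = 0.3) {
  set.seed(seed)
  matrix((runif(T * N) < p) + 0, T, N)
}

# small random network covering all modes/readouts
random_small_net <- function(seed) {
  set.seed(seed)
  mode <- sample(c("classic", "overlap", "segment"), 1)
  Tn <- sample(c(4L, 6L, 8L), 1)
  mem_len <- if (mode == "segment") sample(c(1L, 2L), 1) * (Tn %/% 4L) else
    sample(2:3, 1)
  if (mode == "segment" && mem_len < 1L) mem_len <- 1L
  n_in <- sample(2:4, 1)
  n_hidden <- if (runif(1) < 0.5) sample(2:4, 1) else sample(2:3, 2)
  readout <- sample(c("fusion", "count"), 1)
  snn_network(n_in, n_hidden, n_out = 2L, T = Tn, mode = mode,
              mem_len = mem_len, readout = readout,
              tau = runif(1, 1.2, 4), theta = runif(1, 0.5, 1.2),
              seed = seed)
}

flatten_grads <- function(net, grads) {
  g <- list()
  for (l in seq_along(grads$layers)) {
    g[[paste0("L", l, ".W1")]] <- grads$layers[[l]]$W1
    if (net$mode != "classic") {
      g[[paste0("L", l, ".w2")]] <- as.numeric(grads$layers[[l]]$w2)
    }
  }
  g[["head.W"]] <- grads$head$W
  if (net$readout == "fusion") g[["head.w_time"]] <- grads$head$w_time
  g
}

max_grad_diff <- function(net, spikes3, labels, loss = "cross_entropy",
                          detach_reset = FALSE) {
  mine <- snn_gradients(net, spikes3, labels, loss = loss,
                        detach_reset = detach_reset)
  oracle <- ad_net_gradients(net, spikes3, labels, loss = loss,
                             detach_reset = detach_reset)
  gm <- flatten_grads(net, mine$gradients)
  stopifnot(identical(sort(names(gm)), sort(names(oracle$gradients))))
  diffs <- vapply(names(gm), function(nm) {
    max(abs(gm[[nm]] - oracle$gradients[[nm]]))
  }, 0)
  c(max(diffs), abs(mine$loss - oracle$loss))
}

# expected trainable-parameter list of an untrained network
trainable_params_of <- function(net) {
  p <- list()
  for (l in seq_along(net$layers)) {
    p[[paste0("L", l, ".W1")]] <- net$layers[[l]]$W1
    if (net$mode != "classic") p[[paste0("L", l, ".w2")]] <- net$layers[[l]]$w2
  }
  p[["head.W"]] <- net$head$W
  if (net$readout == "fusion") p[["head.w_time"]] <- net$head$w_time
  p
}

new_empty_dataset <- function() {
  structure(list(spikes = array(0, c(0, 4, 2)), labels = integer(0),
                 spec = NULL), class = "snn_dataset")
}
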