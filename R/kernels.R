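#' Dense multi-dendrite delay kernel
#'
#' Full weight tensor `W[i, j, k]` connecting presynaptic neuron i to
#' postsynaptic neuron j through dendrite group k, where group k transmits
#' with integer delay `delays[k]`. This is the unfactorized form and serves
#' as the brute-force reference for the factorized kernel.
#'
#' @param W Real array of dimension `c(Ni, Nj, Nk)`.
#' @param delays Integer vector of length Nk; nonnegative, strictly
#'   ascending.
#' @return An object of class `dense_delay_kernel`.
#' @export
dense_delay_kernel <- function(W, delays) {
  if (!is.array(W) || length(dim(W)) != 3L) {
    stop_snn("W must be a 3-d array (Ni x Nj x Nk)")
  }
  delays <- check_delays(delays, dim(W)[3])
  structure(list(W = W, delays = delays), class = "dense_delay_kernel")
}

#' Factorized delay kernel
#'
#' Decomposition of the dense Ni x Nj x Nk delay-weight tensor into a
#' spatial matrix `W1` (Ni x Nj) shared by all dendrite groups and a
#' temporal weight vector `w2` (length Nk) shared by all synapses, so that
#' `W[i, j, k] = w2[k] * W1[i, j]`. Parameter count drops from
#' `Ni*Nj*Nk` to `Ni*Nj + Nk`.
#'
#' @param W1 Real Ni x Nj spatial weight matrix.
#' @param w2 Real temporal weight vector, one entry per dendrite group.
#' @param delays Integer delays, one per dendrite group; defaults to the
#'   arithmetic set `0:(length(w2) - 1)`.
#' @return An object of class `delay_kernel`.
#' @export
delay_kernel <- function(W1, w2, delays = seq_along(w2) - 1L) {
  if (!is.matrix(W1) || !all(is.finite(W1))) {
    stop_snn("W1 must be a finite numeric matrix")
  }
  if (!is.numeric(w2) || length(w2) < 1L || !all(is.finite(w2))) {
    stop_snn("w2 must be a finite numeric vector")
  }
  delays <- check_delays(delays, length(w2))
  structure(list(W1 = W1, w2 = as.numeric(w2), delays = delays),
            class = "delay_kernel")
}

check_delays <- function(delays, nk) {
  if (length(delays) != nk) {
    stop_snn("need exactly one delay per dendrite group")
  }
  if (anyNA(delays) || any(delays < 0) || any(delays != as.integer(delays))) {
    stop_snn("delays must be nonnegative integers")
  }
  delays <- as.integer(delays)
  if (is.unsorted(delays, strictly = TRUE)) {
    stop_snn("delays must be strictly ascending")
  }
  delays
}

#' Expand a factorized kernel to its dense equivalent
#'
#' @param kernel A [delay_kernel()].
#' @return The rank-1 [dense_delay_kernel()] with
#'   `W[i, j, k] = w2[k] * W1[i, j]`.
#' @export
as_dense_kernel <- function(kernel) {
  stopifnot(inherits(kernel, "delay_kernel"))
  Ni <- nrow(kernel$W1); Nj <- ncol(kernel$W1); Nk <- length(kernel$w2)
  W <- array(0, c(Ni, Nj, Nk))
  for (k in seq_len(Nk)) W[, , k] <- kernel$w2[k] * kernel$W1
  dense_delay_kernel(W, kernel$delays)
}

#' Working-memory configuration
#'
#' Selects how a layer turns input spikes into membrane drive:
#' \describe{
#'   \item{classic}{single zero-delay synapse, the baseline LIF drive;}
#'   \item{overlap}{overlapping multi-delay dendrites realized as a causal
#'     1-d temporal convolution;}
#'   \item{segment}{non-overlapping working-memory windows of length
#'     `mem_len`: all spikes inside a window are aggregated and fed to the
#'     neuron as a constant drive throughout that window;}
#'   \item{fusion}{the temporal fusion readout (head only, see
#'     [fusion_head()]).}
#' }
#'
#' @param mode One of `"classic"`, `"overlap"`, `"segment"`, `"fusion"`.
#' @param mem_len Working-memory window length L (segment mode; >= 1).
#' @param pad How to handle T not divisible by `mem_len` in segment mode:
#'   `"strict"` (error, default) or `"zero"` (zero-pad the final window).
#' @return An object of class `wm_config`.
#' @export
wm_config <- function(mode = c("classic", "overlap", "segment", "fusion"),
                      mem_len = NULL, pad = c("strict", "zero")) {
  mode <- match.arg(mode)
  pad <- match.arg(pad)
  if (mode == "segment") {
    if (is.null(mem_len) || mem_len < 1 || mem_len != as.integer(mem_len)) {
      stop_snn("segment mode requires integer mem_len >= 1")
    }
    mem_len <- as.integer(mem_len)
  }
  structure(list(mode = mode, mem_len = mem_len, pad = pad),
            class = "wm_config")
}

#' Temporal fusion readout head
#'
#' Static decoding layer that weights the spikes of every timestep of a
#' length-T input train: `o[j] = sum_t w_time[t] * sum_i W1[i, j] * s_i(t)`.
#' It is evaluated once per sample, at the final step, with no leak and no
#' threshold, and its outputs are used as logits.
#'
#' @param W1 Real Ni x Nj spatial weight matrix.
#' @param w_time Real temporal weight vector of length T (one tap per
#'   timestep of the input window).
#' @return An object of class `fusion_head`.
#' @export
fusion_head <- function(W1, w_time) {
  if (!is.matrix(W1) || !all(is.finite(W1))) {
    stop_snn("W1 must be a finite numeric matrix")
  }
  if (!is.numeric(w_time) || length(w_time) < 1L || !all(is.finite(w_time))) {
    stop_snn("w_time must be a finite numeric vector")
  }
  structure(list(W1 = W1, w_time = as.numeric(w_time), T = length(w_time)),
            class = "fusion_head")
}

#' Layer specification
#'
#' A hidden spiking layer: a factorized delay kernel, LIF parameters, and a
#' working-memory configuration choosing the drive computation.
#'
#' @param kernel A [delay_kernel()].
#' @param lif A [lif_params()] object.
#' @param wm A [wm_config()]; fusion mode is reserved for the head.
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(kernel, lif = lif_params(), wm = wm_config("classic")) {
  stopifnot(inherits(kernel, "delay_kernel"), inherits(lif, "lif_params"),
            inherits(wm, "wm_config"))
  if (wm$mode == "fusion") {
    stop_snn("fusion mode is a readout head, not a hidden layer; use fusion_head()")
  }
  if (wm$mode == "classic") {
    if (!identical(kernel$delays, 0L) || !identical(kernel$w2, 1)) {
      stop_snn("classic mode requires delays == {0} and w2 == {1}")
    }
  }
  if (wm$mode == "segment" && length(kernel$w2) != wm$mem_len) {
    stop_snn("segment mode requires length(w2) == mem_len")
  }
  structure(list(kernel = kernel, lif = lif, wm = wm), class = "layer_spec")
}
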