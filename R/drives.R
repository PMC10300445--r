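#' Dense multi-dendrite drive (brute force)
#'
#' Synaptic drive of a layer of multi-delay dendrites computed from the full
#' weight tensor: `I[t, j] = sum_k sum_i W[i, j, k] * s_i(t - delays[k])`,
#' with spikes at negative times taken as zero (causal zero-padding).
#' Quadratic in the dendrite count; kept as the reference implementation
#' against which the factorized path is checked.
#'
#' @param S Binary T x Ni spike matrix (time-major).
#' @param kernel A [dense_delay_kernel()].
#' @return Real T x Nj drive matrix.
#' @export
dense_delay_drive <- function(S, kernel) {
  stopifnot(inherits(kernel, "dense_delay_kernel"))
  check_binary_matrix(S)
  Tn <- nrow(S)
  Ni <- dim(kernel$W)[1]; Nj <- dim(kernel$W)[2]
  if (ncol(S) != Ni) stop_snn("spike train width does not match kernel Ni")
  I <- matrix(0, Tn, Nj)
  for (k in seq_along(kernel$delays)) {
    d <- kernel$delays[k]
    if (d >= Tn) next
    contrib <- S[seq_len(Tn - d), , drop = FALSE] %*% kernel$W[, , k]
    I[(d + 1):Tn, ] <- I[(d + 1):Tn, ] + contrib
  }
  I
}

#' Factorized multi-dendrite drive
#'
#' Same drive as [dense_delay_drive()] for a rank-1 kernel, computed as a
#' spatial projection followed by a causal 1-d temporal convolution:
#' `I[t, j] = sum_k w2[k] * sum_i W1[i, j] * s_i(t - delays[k])`.
#'
#' @param S Binary T x Ni spike matrix.
#' @param kernel A [delay_kernel()].
#' @return Real T x Nj drive matrix.
#' @export
factorized_delay_drive <- function(S, kernel) {
  stopifnot(inherits(kernel, "delay_kernel"))
  check_binary_matrix(S)
  if (ncol(S) != nrow(kernel$W1)) {
    stop_snn("spike train width does not match kernel Ni")
  }
  Tn <- nrow(S)
  P <- S %*% kernel$W1
  I <- matrix(0, Tn, ncol(P))
  for (k in seq_along(kernel$delays)) {
    d <- kernel$delays[k]
    if (d >= Tn) next
    I[(d + 1):Tn, ] <- I[(d + 1):Tn, ] +
      kernel$w2[k] * P[seq_len(Tn - d), , drop = FALSE]
  }
  I
}

#' Working-memory segment drive
#'
#' Non-overlapping working memory: the spike train is cut into windows of
#' length `mem_len`; within window m the drive is the weighted aggregate of
#' all window spikes, `drive_m[j] = sum_p w2[p] * sum_i W1[i, j] *
#' s_i(m*L + p)`, delivered unchanged at every timestep of the window. The
#' temporal weights `w2` are indexed by within-window position (ascending
#' time) and must have length `mem_len`.
#'
#' @param S Binary T x Ni spike matrix.
#' @param kernel A [delay_kernel()] whose `w2` has length `mem_len`.
#' @param mem_len Window length L >= 1.
#' @param pad `"strict"` errors when `mem_len` does not divide T;
#'   `"zero"` zero-pads the final window.
#' @return Real T x Nj drive matrix, constant within each window.
#' @export
segment_drive <- function(S, kernel, mem_len, pad = c("strict", "zero")) {
  stopifnot(inherits(kernel, "delay_kernel"))
  pad <- match.arg(pad)
  check_binary_matrix(S)
  if (ncol(S) != nrow(kernel$W1)) {
    stop_snn("spike train width does not match kernel Ni")
  }
  if (mem_len < 1 || mem_len != as.integer(mem_len)) {
    stop_snn("mem_len must be a positive integer")
  }
  mem_len <- as.integer(mem_len)
  if (length(kernel$w2) != mem_len) {
    stop_snn("segment drive requires length(w2) == mem_len")
  }
  Tn <- nrow(S)
  if (Tn %% mem_len != 0L) {
    if (pad == "strict") {
      stop_snn("T (", Tn, ") is not divisible by mem_len (", mem_len,
               "); set pad = \"zero\" to zero-pad the final window")
    }
    Tpad <- as.integer(ceiling(Tn / mem_len) * mem_len)
    S <- rbind(S, matrix(0, Tpad - Tn, ncol(S)))
  }
  P <- S %*% kernel$W1
  n_win <- nrow(S) %/% mem_len
  I <- matrix(0, nrow(S), ncol(P))
  for (m in seq_len(n_win) - 1L) {
    rows <- m * mem_len + seq_len(mem_len)
    drive_m <- as.vector(kernel$w2 %*% P[rows, , drop = FALSE])
    I[rows, ] <- matrix(drive_m, mem_len, ncol(P), byrow = TRUE)
  }
  I[seq_len(Tn), , drop = FALSE]
}

#' Temporal fusion readout
#'
#' Applies a [fusion_head()] to a spike train:
#' `o[j] = sum_t w_time[t] * sum_i W1[i, j] * s_i(t)`. A single static
#' readout over the whole train — no leak, no threshold — emitted once per
#' sample as the network output (logits).
#'
#' @param S Binary T x Ni spike matrix with `T == head$T`.
#' @param head A [fusion_head()].
#' @return Numeric output vector of length Nj.
#' @export
temporal_fusion <- function(S, head) {
  stopifnot(inherits(head, "fusion_head"))
  check_binary_matrix(S)
  if (nrow(S) != head$T) {
    stop_snn("spike train length ", nrow(S), " does not match head T ", head$T)
  }
  if (ncol(S) != nrow(head$W1)) {
    stop_snn("spike train width does not match head Ni")
  }
  as.vector(head$w_time %*% (S %*% head$W1))
}

#' Forward pass of one spiking layer
#'
#' Computes the layer drive according to the working-memory mode (classic,
#' overlap, or segment) and runs LIF dynamics over it.
#'
#' @param S Binary T x Ni input spike matrix.
#' @param spec A [layer_spec()].
#' @param V0 Initial membrane potentials (defaults to `v_rest`).
#' @return A `membrane_trace` (see [lif_run()]).
#' @export
layer_forward <- function(S, spec, V0 = NULL) {
  stopifnot(inherits(spec, "layer_spec"))
  drive <- switch(spec$wm$mode,
    classic = factorized_delay_drive(S, spec$kernel),
    overlap = factorized_delay_drive(S, spec$kernel),
    segment = segment_drive(S, spec$kernel, spec$wm$mem_len, spec$wm$pad),
    stop_snn("unknown working-memory mode: ", spec$wm$mode)
  )
  lif_run(drive, spec$lif, V0)
}
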