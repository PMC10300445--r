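#' Membrane leak factor
#'
#' Decay coefficient of the discrete-time leaky integrate-and-fire (LIF)
#' membrane, `exp(-1/tau)`. Between two timesteps with no input the membrane
#' potential is multiplied by this factor. `tau = Inf` gives a leak of 1,
#' i.e. the pure integrate-and-fire (I&F) limit.
#'
#' @param tau Membrane time constant in timesteps; must be positive
#'   (`Inf` allowed).
#' @return The decay coefficient in (0, 1].
#' @examples
#' leak_factor(2)          # exp(-0.5)
#' leak_factor(1 / log(2)) # 0.5
#' @export
leak_factor <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0) {
    stop_snn("tau must be a single positive number")
  }
  exp(-1 / tau)
}

#' LIF neuron parameters
#'
#' Bundle of the membrane time constant `tau`, firing threshold `theta` and
#' resting potential `v_rest`, together with the derived leak `exp(-1/tau)`.
#' The spike response kernel is fixed at the identity, so a presynaptic
#' spike contributes its synaptic weight directly to the membrane drive.
#'
#' @param tau Membrane time constant (timesteps, > 0; `Inf` for I&F).
#' @param theta Firing threshold (potential units).
#' @param v_rest Resting potential the membrane is reset to after a spike.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(tau = 2, theta = 1, v_rest = 0) {
  leak <- leak_factor(tau)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta)) {
    stop_snn("theta must be a single finite number")
  }
  if (!is.numeric(v_rest) || length(v_rest) != 1L || !is.finite(v_rest)) {
    stop_snn("v_rest must be a single finite number")
  }
  structure(
    list(tau = tau, theta = theta, v_rest = v_rest, leak = leak),
    class = "lif_params"
  )
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf(
    "LIF parameters: tau = %g, theta = %g, v_rest = %g (leak = %.6g)\n",
    x$tau, x$theta, x$v_rest, x$leak
  ))
  invisible(x)
}

#' One LIF timestep
#'
#' Advances a vector of LIF membranes by one timestep: leak, integrate the
#' synaptic drive, threshold, hard-reset. The threshold test is
#' `V >= theta` (a membrane exactly at threshold fires), and firing neurons
#' are reset to `v_rest` at the same timestep.
#'
#' @param V_prev Membrane potentials at the previous step (numeric vector).
#' @param I_t Synaptic drive entering at this step (same length as `V_prev`).
#' @param params A [lif_params()] object.
#' @return A list with `V` (post-reset potentials) and `spikes` (0/1 vector).
#' @export
lif_step <- function(V_prev, I_t, params) {
  stopifnot(inherits(params, "lif_params"))
  if (length(V_prev) != length(I_t)) {
    stop_snn("V_prev and I_t must have the same length")
  }
  V_mid <- params$leak * V_prev + I_t
  spikes <- as.numeric(V_mid >= params$theta)
  V_new <- V_mid * (1 - spikes) + params$v_rest * spikes
  list(V = V_new, spikes = spikes)
}

#' Run LIF dynamics over a drive trace
#'
#' Iterates [lif_step()] over every row of a T x N drive matrix and records
#' the full membrane and spike history.
#'
#' @param drive Real T x N matrix of synaptic drive (one row per timestep).
#' @param params A [lif_params()] object.
#' @param V0 Initial membrane potentials; defaults to `v_rest` everywhere.
#' @return An object of class `membrane_trace`: a list with `V` (T x N
#'   post-reset potentials) and `spikes` (T x N binary matrix).
#' @export
lif_run <- function(drive, params, V0 = NULL) {
  stopifnot(inherits(params, "lif_params"))
  check_finite_matrix(drive, "drive")
  Tn <- nrow(drive); N <- ncol(drive)
  if (is.null(V0)) V0 <- rep(params$v_rest, N)
  if (length(V0) != N) stop_snn("V0 must have one entry per neuron")
  V <- matrix(0, Tn, N)
  S <- matrix(0, Tn, N)
  v <- V0
  for (t in seq_len(Tn)) {
    st <- lif_step(v, drive[t, ], params)
    v <- st$V
    V[t, ] <- v
    S[t, ] <- st$spikes
  }
  structure(list(V = V, spikes = S), class = "membrane_trace")
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat(sprintf(
    "Membrane trace: %d timesteps x %d neurons, %d spikes (rate %.3f)\n",
    nrow(x$V), ncol(x$V), sum(x$spikes), mean(x$spikes)
  ))
  invisible(x)
}
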