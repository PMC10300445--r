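#' Parameter count of a multi-dendrite layer
#'
#' Number of synaptic weights of one layer with Ni inputs, Nj outputs and
#' Nk dendrite groups: `Ni*Nj*Nk` for the dense tensor, `Ni*Nj + Nk` after
#' factorization into a spatial matrix and a shared temporal vector (only
#' Nk more than a classic single-synapse layer).
#'
#' @param Ni,Nj,Nk Positive layer dimensions.
#' @param factorized Count the factorized form?
#' @return Integer parameter count.
#' @export
parameter_count <- function(Ni, Nj, Nk, factorized = TRUE) {
  for (d in c(Ni, Nj, Nk)) {
    if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 1 ||
        d != as.integer(d)) {
      stop_snn("dimensions must be positive integers")
    }
  }
  if (factorized) as.integer(Ni * Nj + Nk) else as.integer(Ni * Nj * Nk)
}

#' Membrane-state memory accesses
#'
#' Closed-form count of membrane-state (V_BRAM) accesses per neuron group
#' per sample of length T. A classic LIF schedule fetches and stores the
#' membrane potential at every timestep (`2*T`); under working-memory
#' scheduling the fetch happens only at the start of each window of
#' length `mem_len` and the store only at its end (`2*ceiling(T/mem_len)`).
#' Input/output spike traffic is identical in both schemes and excluded.
#'
#' @param T Timesteps (>= 1).
#' @param mem_len Window length, `1 <= mem_len <= T`.
#' @param scheme `"classic"` or `"wm"`.
#' @return Integer access count.
#' @export
state_memory_accesses <- function(T, mem_len, scheme = c("classic", "wm")) {
  scheme <- match.arg(scheme)
  if (T < 1 || T != as.integer(T)) stop_snn("T must be a positive integer")
  if (mem_len < 1 || mem_len > T || mem_len != as.integer(mem_len)) {
    stop_snn("mem_len must be an integer in [1, T]")
  }
  if (scheme == "classic") 2L * as.integer(T)
  else 2L * as.integer(ceiling(T / mem_len))
}

#' Instrumented LIF run counting state-memory accesses
#'
#' Runs the same LIF dynamics as [lif_run()] while emulating the
#' state-memory schedule: the membrane vector lives in a backing store and
#' is fetched into working registers at each window start and stored back
#' at each window end (classic scheduling is the `mem_len = 1` case).
#' Serves as the simulation cross-check of [state_memory_accesses()].
#'
#' @param drive Real T x N drive matrix.
#' @param params A [lif_params()].
#' @param mem_len Window length of the schedule.
#' @param V0 Initial membrane potentials.
#' @return List with `trace` (a `membrane_trace`, identical to
#'   [lif_run()]'s), `fetches`, `stores` and `accesses`.
#' @export
lif_run_instrumented <- function(drive, params, mem_len = 1L, V0 = NULL) {
  stopifnot(inherits(params, "lif_params"))
  check_finite_matrix(drive, "drive")
  Tn <- nrow(drive); N <- ncol(drive)
  if (mem_len < 1 || mem_len > Tn) stop_snn("mem_len must be in [1, T]")
  if (is.null(V0)) V0 <- rep(params$v_rest, N)
  bram <- V0                      # backing state store
  fetches <- 0L; stores <- 0L
  V <- matrix(0, Tn, N); S <- matrix(0, Tn, N)
  t <- 1L
  while (t <= Tn) {
    v <- bram; fetches <- fetches + 1L      # window-start fetch
    t_end <- min(t + mem_len - 1L, Tn)
    for (tt in t:t_end) {                   # in-register updates
      st <- lif_step(v, drive[tt, ], params)
      v <- st$V
      V[tt, ] <- v
      S[tt, ] <- st$spikes
    }
    bram <- v; stores <- stores + 1L        # window-end store
    t <- t_end + 1L
  }
  list(trace = structure(list(V = V, spikes = S), class = "membrane_trace"),
       fetches = fetches, stores = stores, accesses = fetches + stores)
}

#' Efficiency report for a working-memory layer
#'
#' Collects the closed-form parameter and state-access counts for one
#' layer configuration.
#'
#' @param Ni,Nj,Nk Layer dimensions (dendrite groups Nk).
#' @param T Timesteps per sample.
#' @param mem_len Working-memory window length.
#' @return An object of class `cost_report`.
#' @export
cost_report <- function(Ni, Nj, Nk, T, mem_len) {
  dense <- parameter_count(Ni, Nj, Nk, factorized = FALSE)
  fact <- parameter_count(Ni, Nj, Nk, factorized = TRUE)
  classic <- state_memory_accesses(T, mem_len, "classic")
  wm <- state_memory_accesses(T, mem_len, "wm")
  structure(list(
    Ni = Ni, Nj = Nj, Nk = Nk, T = T, mem_len = mem_len,
    dense_params = dense, factorized_params = fact,
    classic_state_accesses = classic, wm_state_accesses = wm,
    param_reduction_factor = dense / fact,
    access_reduction_factor = classic / wm
  ), class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat("Working-memory layer cost report\n")
  cat(sprintf("  layer: Ni=%d Nj=%d Nk=%d, T=%d, mem_len=%d\n",
              x$Ni, x$Nj, x$Nk, x$T, x$mem_len))
  cat(sprintf("  parameters: dense %d, factorized %d (x%.3g reduction)\n",
              x$dense_params, x$factorized_params, x$param_reduction_factor))
  cat(sprintf("  state accesses/sample: classic %d, working memory %d (x%.3g reduction)\n",
              x$classic_state_accesses, x$wm_state_accesses,
              x$access_reduction_factor))
  invisible(x)
}

#' @export
as.list.cost_report <- function(x, ...) unclass(x)
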