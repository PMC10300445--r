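#' Direct (current) coding
#'
#' Injects normalized feature values directly as input current: every
#' timestep receives the same real-valued row. The result is a current
#' trace, not a binary spike train.
#'
#' @param values Numeric vector in \[0, 1\] (one entry per input neuron).
#' @param T Number of timesteps.
#' @return Real T x N matrix with each row equal to `values`.
#' @export
direct_encode <- function(values, T) {
  check_unit_values(values)
  check_T(T, 1L)
  matrix(values, nrow = T, ncol = length(values), byrow = TRUE)
}

#' Rate (Poisson) coding
#'
#' Encodes each value as a stochastic spike train whose per-step firing
#' probability equals the value — the standard discrete-time Bernoulli
#' realization of Poisson rate coding. Reproducible for a given seed.
#'
#' @param values Numeric vector in \[0, 1\].
#' @param T Number of timesteps.
#' @param seed RNG seed.
#' @return Binary T x N spike matrix.
#' @export
rate_encode <- function(values, T, seed) {
  check_unit_values(values)
  check_T(T, 1L)
  N <- length(values)
  with_seed(seed, {
    u <- matrix(stats::runif(T * N), T, N)
    (u < matrix(values, T, N, byrow = TRUE)) + 0
  })
}

#' Latency (time-to-first-spike) coding
#'
#' Maps each value to a single spike whose timing encodes intensity:
#' stronger inputs fire earlier. A value v > 0 spikes once at
#' `t = round((1 - v) * (T - 1))` (0-based); v = 0 emits no spike.
#'
#' @param values Numeric vector in \[0, 1\].
#' @param T Number of timesteps (>= 2).
#' @return Binary T x N spike matrix with at most one spike per column.
#' @export
latency_encode <- function(values, T) {
  check_unit_values(values)
  check_T(T, 2L)
  N <- length(values)
  S <- matrix(0, T, N)
  for (n in seq_len(N)) {
    v <- values[n]
    if (v > 0) S[round((1 - v) * (T - 1)) + 1L, n] <- 1
  }
  S
}

check_unit_values <- function(values) {
  if (!is.numeric(values) || length(values) < 1L || anyNA(values) ||
      any(values < 0 | values > 1)) {
    stop_snn("values must be numeric in [0, 1]")
  }
  invisible(values)
}

check_T <- function(T, min_T) {
  if (!is.numeric(T) || length(T) != 1L || is.na(T) ||
      T != as.integer(T) || T < min_T) {
    stop_snn("T must be an integer >= ", min_T)
  }
  invisible(T)
}

#' Parse a bit-string spike train
#'
#' Reads the compact 0/1 notation for a single-neuron spike train, e.g.
#' `"010110"` is a 6-step train with spikes at (0-based) timesteps 1, 3
#' and 4.
#'
#' @param bits Nonempty string of `0`/`1` characters.
#' @return Binary T x 1 spike matrix, T = `nchar(bits)`.
#' @seealso [format_bitstring()] for the inverse.
#' @export
parse_bitstring <- function(bits) {
  if (!is.character(bits) || length(bits) != 1L || nchar(bits) < 1L) {
    stop_snn("bits must be a single nonempty string")
  }
  chars <- strsplit(bits, "")[[1]]
  if (!all(chars %in% c("0", "1"))) {
    stop_snn("bit-string may contain only '0' and '1'")
  }
  matrix(as.numeric(chars), ncol = 1)
}

#' Format a single-neuron spike train as a bit-string
#'
#' @param S Binary T x 1 spike matrix.
#' @return String of `0`/`1` characters of length T.
#' @export
format_bitstring <- function(S) {
  check_binary_matrix(S)
  if (ncol(S) != 1L) stop_snn("bit-string notation is for single-neuron trains")
  paste(as.integer(S[, 1]), collapse = "")
}

#' Read a spike train from an event-list CSV
#'
#' The file format is a comment line `# T=<int> N=<int>` declaring the
#' train dimensions, a header `t,neuron` (optionally `t,neuron,polarity`),
#' and one 0-based `(t, neuron)` record per spike. Polarity is carried
#' through by [write_events()] but ignored when reconstructing the train.
#'
#' @param path Path to the CSV file.
#' @return Binary T x N spike matrix.
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop_snn("event file too short: ", path)
  hdr <- regmatches(lines[1], regexec("^#\\s*T=(\\d+)\\s+N=(\\d+)\\s*$", lines[1]))[[1]]
  if (length(hdr) != 3L) {
    stop_snn("line 1: expected dimension comment '# T=<int> N=<int>'")
  }
  Tn <- as.integer(hdr[2]); N <- as.integer(hdr[3])
  if (Tn < 1L || N < 1L) stop_snn("line 1: T and N must be >= 1")
  cols <- strsplit(lines[2], ",")[[1]]
  if (!identical(cols[1:2], c("t", "neuron"))) {
    stop_snn("line 2: expected header 't,neuron[,polarity]'")
  }
  S <- matrix(0, Tn, N)
  if (length(lines) > 2L) {
    for (ln in 3:length(lines)) {
      if (!nzchar(lines[ln])) next
      fields <- suppressWarnings(as.integer(strsplit(lines[ln], ",")[[1]]))
      if (length(fields) < 2L || anyNA(fields[1:2])) {
        stop_snn("line ", ln, ": malformed event row '", lines[ln], "'")
      }
      t <- fields[1]; nn <- fields[2]
      if (t < 0L || t >= Tn || nn < 0L || nn >= N) {
        stop_snn("line ", ln, ": event (t=", t, ", neuron=", nn,
                 ") outside declared bounds T=", Tn, ", N=", N)
      }
      S[t + 1L, nn + 1L] <- 1
    }
  }
  S
}

#' Write a spike train as an event-list CSV
#'
#' Events are written 0-based in canonical time-major order; see
#' [read_events()] for the format. Round-trips losslessly.
#'
#' @param S Binary T x N spike matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(S, path) {
  check_binary_matrix(S)
  idx <- which(S == 1, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  rows <- sprintf("%d,%d", idx[ord, 1] - 1L, idx[ord, 2] - 1L)
  writeLines(c(sprintf("# T=%d N=%d", nrow(S), ncol(S)), "t,neuron", rows),
             path)
  invisible(path)
}
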