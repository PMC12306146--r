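#' Configuration for the binaural IPD classification task
#'
#' The task: a pure tone of frequency `f` reaches the two ears with an
#' interaural phase difference (IPD) `alpha` drawn uniformly from
#' `[ipd_min, ipd_max]`. Each ear is represented by `n_psi` input neurons with
#' uniformly spaced phase delays `psi_j = j*pi/(2*(n_psi-1))`, firing Poisson
#' spikes with rate `rate_max * ((1 + sin(theta_ij(t)))/2)^2` where
#' `theta_ij(t) = 2*pi*f*t + i*alpha + psi_j` and `i = 0` (left) or `1`
#' (right). The network must report which of `n_classes` equal-width IPD
#' intervals contains `alpha`.
#'
#' Defaults follow the base study conditions: 50 Hz tone, 100 neurons per ear,
#' 12 classes, 600 sp/s peak rate, 100 ms stimuli simulated at 1 ms
#' resolution.
#'
#' @param f tone frequency (Hz).
#' @param n_psi input neurons per ear.
#' @param n_classes number of IPD classes.
#' @param rate_max maximum firing rate (sp/s); `rate_max * dt` must be <= 1
#'   for the per-bin Bernoulli encoding to be a valid probability.
#' @param duration stimulus length (s).
#' @param dt simulation time step (s).
#' @param ipd_min,ipd_max IPD range (radians).
#' @return an object of class `ipd_task` (a validated list).
#' @export
task_config <- function(f = 50, n_psi = 100, n_classes = 12, rate_max = 600,
                        duration = 0.1, dt = 0.001,
                        ipd_min = -pi / 2, ipd_max = pi / 2) {
  if (f <= 0) stop("f must be > 0")
  if (n_psi < 2) stop("n_psi must be >= 2")
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (rate_max * dt > 1 + 1e-12)
    stop("rate_max * dt must be <= 1 (Bernoulli validity): got ",
         rate_max * dt)
  n_bins <- duration / dt
  if (abs(n_bins - round(n_bins)) > 1e-9 || n_bins < 1)
    stop("duration/dt must be a positive integer")
  if (ipd_min >= ipd_max) stop("ipd_min must be < ipd_max")
  structure(list(f = f, n_psi = as.integer(n_psi),
                 n_classes = as.integer(n_classes), rate_max = rate_max,
                 duration = duration, dt = dt, n_bins = as.integer(round(n_bins)),
                 ipd_min = ipd_min, ipd_max = ipd_max),
            class = "ipd_task")
}

#' @export
print.ipd_task <- function(x, ...) {
  cat(sprintf(
    "IPD task: f = %g Hz, %d neurons/ear, %d classes, Rmax = %g sp/s, %g ms @ %g ms\n",
    x$f, x$n_psi, x$n_classes, x$rate_max, 1e3 * x$duration, 1e3 * x$dt))
  invisible(x)
}

#' Per-neuron phase delays
#'
#' `psi_j = j * pi / (2 * (n_psi - 1))` for `j = 0, ..., n_psi - 1`: uniformly
#' spaced and including both endpoints 0 and pi/2, so that comparing a left
#' and a right neuron can realize any phase difference in `(-pi/2, pi/2)`.
#'
#' @param n_psi number of input neurons per ear.
#' @return numeric vector of length `n_psi` (radians).
#' @export
phase_delays <- function(n_psi) {
  stopifnot(n_psi >= 2)
  (seq_len(n_psi) - 1) * pi / (2 * (n_psi - 1))
}

#' Sample IPDs uniformly
#'
#' @param n number of trials.
#' @param cfg an [task_config()] object (supplies the IPD range).
#' @param seed optional integer seed; when given, draws come from the
#'   package's own counter-based stream and do not touch R's RNG state.
#' @return numeric vector of IPDs (radians).
#' @export
sample_ipds <- function(n, cfg = task_config(), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive integer")
  n <- as.integer(n)
  u <- if (is.null(seed)) runif(n) else
    as.numeric(cpp_runif_stream(n, derive_seed(seed, "ipd")))
  cfg$ipd_min + u * (cfg$ipd_max - cfg$ipd_min)
}

#' Instantaneous input firing rates for one IPD
#'
#' `R_ij(t) = rate_max * ((1 + sin(2*pi*f*t + i*alpha + psi_j))/2)^2`, with
#' ear index `i = 0` (left, no IPD) and `i = 1` (right, + alpha). Rates are
#' evaluated at bin start times `t = 0, dt, ..., duration - dt`.
#'
#' @param ipd IPD alpha (radians), must lie in the task's IPD range.
#' @param cfg an [task_config()] object.
#' @param psi phase-delay vector (defaults to [phase_delays()]).
#' @return matrix (time bins x `2 * n_psi`) of rates in sp/s; channels are
#'   ordered `[ear0 neurons, ear1 neurons]`.
#' @export
input_rates <- function(ipd, cfg = task_config(), psi = phase_delays(cfg$n_psi)) {
  if (ipd < cfg$ipd_min - 1e-12 || ipd > cfg$ipd_max + 1e-12)
    stop("ipd outside task range")
  cpp_input_rates(ipd, cfg$f, psi, cfg$rate_max, cfg$dt, cfg$n_bins)
}

#' Generate Poisson spikes from a rate tensor
#'
#' Each bin is an independent Bernoulli draw with `p = rate * dt` (exact
#' thinning is unnecessary at the rates used here; `rate_max * dt = 0.6` by
#' default).
#'
#' @param rates nonnegative rate matrix (time bins x channels), sp/s.
#' @param dt time step (s).
#' @param seed integer seed.
#' @return binary matrix of the same shape.
#' @export
generate_spikes <- function(rates, dt, seed = 1L) {
  if (any(rates < 0)) stop("rates must be nonnegative")
  p <- rates * dt
  bad <- which(apply(p > 1 + 1e-12, 2, any))
  if (length(bad))
    stop("rate * dt exceeds 1 for channel(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  u <- matrix(cpp_runif_stream(length(p), derive_seed(seed, "spk")),
              nrow(p), ncol(p))
  (u < p) * 1
}

#' Generate a batch of task trials as a spike tensor
#'
#' Draws IPDs (unless supplied), builds the phase-delayed sinusoidal rates
#' and emits Poisson spikes, all from a single integer seed. This is the
#' universal exchange object of the package.
#'
#' @param n number of trials (ignored when `ipds` is given).
#' @param cfg an [task_config()] object.
#' @param seed integer seed.
#' @param ipds optional vector of IPDs (radians) to use instead of sampling.
#' @param psi optional phase-delay vector (defaults to [phase_delays()];
#'   pass zeros to disable the delay bank, as the delay-learning models do).
#' @return an object of class `spike_batch`: list with `spikes` (array
#'   trials x bins x channels), `dt`, `ipd_true`, `class_true`, and the task
#'   config.
#' @export
spike_batch <- function(n, cfg = task_config(), seed = 1L, ipds = NULL,
                        psi = phase_delays(cfg$n_psi)) {
  if (is.null(ipds)) ipds <- sample_ipds(n, cfg, seed = seed)
  spikes <- cpp_spike_batch(ipds, cfg$f, psi, cfg$rate_max, cfg$dt,
                            cfg$n_bins, derive_seed(seed, "batch"))
  structure(list(spikes = spikes, dt = cfg$dt, ipd_true = ipds,
                 class_true = ipd_to_class(ipds, cfg$n_classes), cfg = cfg),
            class = "spike_batch")
}

#' @export
print.spike_batch <- function(x, ...) {
  d <- dim(x$spikes)
  cat(sprintf("spike_batch: %d trials x %d bins x %d channels (dt = %g ms)\n",
              d[1], d[2], d[3], 1e3 * x$dt))
  invisible(x)
}

#' Map IPD angles to class indices
#'
#' Class `k` (0-based) covers `[-pi/2 + k*pi/n_classes,
#' -pi/2 + (k+1)*pi/n_classes)`; the upper boundary `+pi/2` is assigned to
#' the top class so the bins partition the IPD range.
#'
#' @param ipd IPD(s) in radians, in `[-pi/2, pi/2]`.
#' @param n_classes number of classes.
#' @return integer class indices in `0:(n_classes - 1)`.
#' @export
ipd_to_class <- function(ipd, n_classes) {
  if (any(ipd < -pi / 2 - 1e-9 | ipd > pi / 2 + 1e-9))
    stop("ipd outside [-pi/2, pi/2]")
  k <- floor((ipd + pi / 2) / (pi / n_classes))
  as.integer(pmin(pmax(k, 0), n_classes - 1))
}

#' Class index to IPD interval midpoint
#'
#' @param k class index (0-based), in `0:(n_classes - 1)`.
#' @param n_classes number of classes.
#' @return midpoint IPD `-pi/2 + (k + 0.5) * pi / n_classes` (radians).
#' @export
class_to_midpoint <- function(k, n_classes) {
  if (any(k < 0 | k > n_classes - 1)) stop("class index out of range")
  -pi / 2 + (k + 0.5) * pi / n_classes
}
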