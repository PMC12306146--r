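#' Network parameters for the LIF classifier
#'
#' Holds the dense input-to-hidden and hidden-to-output weight matrices,
#' membrane time constants, and (optionally) per-unit sign constraints for
#' Dale's-law training. The spike threshold is fixed at 1 and the reset at 0
#' (dimensionless membrane units).
#'
#' @param w_ih input-to-hidden weights (`2*n_psi` x `n_h`).
#' @param w_ho hidden-to-output weights (`n_h` x `n_classes`).
#' @param tau_h,tau_o membrane time constants (s) of the hidden LIF layer and
#'   the non-spiking readout layer.
#' @param beta slope of the fast-sigmoid surrogate derivative.
#' @param sign_ih,sign_ho optional per-row sign vectors (+1 excitatory, -1
#'   inhibitory, 0 unconstrained).
#' @return an object of class `network_params`.
#' @export
network_params <- function(w_ih, w_ho, tau_h = 0.002, tau_o = 0.002,
                           beta = 10, sign_ih = NULL, sign_ho = NULL) {
  w_ih <- as.matrix(w_ih); w_ho <- as.matrix(w_ho)
  if (ncol(w_ih) != nrow(w_ho)) stop("w_ih and w_ho shapes are inconsistent")
  if (tau_h <= 0 || tau_o <= 0) stop("membrane time constants must be > 0")
  if (!all(is.finite(w_ih))) stop("non-finite weights in layer w_ih")
  if (!all(is.finite(w_ho))) stop("non-finite weights in layer w_ho")
  chk_sign <- function(w, s, nm) {
    if (is.null(s)) return(invisible())
    if (length(s) != nrow(w)) stop("sign mask length mismatch for ", nm)
    viol <- w * s < 0
    if (any(viol[s != 0, ])) stop("weights violate sign mask in ", nm)
  }
  chk_sign(w_ih, sign_ih, "w_ih"); chk_sign(w_ho, sign_ho, "w_ho")
  structure(list(w_ih = w_ih, w_ho = w_ho, tau_h = tau_h, tau_o = tau_o,
                 v_th = 1, v_reset = 0, beta = beta,
                 sign_ih = sign_ih, sign_ho = sign_ho),
            class = "network_params")
}

#' Initialize network weights
#'
#' Uniform in `+/- sqrt(1/fan_in)` per layer. Under a Dale mode, each
#' presynaptic unit gets a fixed sign and the initial weights take that sign
#' (magnitudes from the same uniform law).
#'
#' @param cfg an [task_config()] object.
#' @param n_h number of hidden neurons.
#' @param seed integer seed.
#' @param dale_mode one of `"none"`, `"balanced"`, `"excitatory_only"`,
#'   `"inhibitory_only"`, or a list with per-layer inhibitory fractions
#'   `list(ih = ..., ho = ...)`.
#' @param tau_h,tau_o,beta passed to [network_params()].
#' @return a `network_params` object.
#' @export
init_network <- function(cfg, n_h = 8, seed = 1L, dale_mode = "none",
                         tau_h = 0.002, tau_o = 0.002, beta = 10) {
  n_in <- 2L * cfg$n_psi
  u <- cpp_runif_stream(n_in * n_h + n_h * cfg$n_classes,
                        derive_seed(seed, "init"))
  w_ih <- matrix((u[seq_len(n_in * n_h)] * 2 - 1) / sqrt(n_in), n_in, n_h)
  w_ho <- matrix((u[-seq_len(n_in * n_h)] * 2 - 1) / sqrt(n_h),
                 n_h, cfg$n_classes)
  masks <- dale_sign_masks(n_in, n_h, dale_mode, seed = seed)
  if (!is.null(masks$ih)) w_ih <- abs(w_ih) * masks$ih
  if (!is.null(masks$ho)) w_ho <- abs(w_ho) * masks$ho
  network_params(w_ih, w_ho, tau_h = tau_h, tau_o = tau_o, beta = beta,
                 sign_ih = masks$ih, sign_ho = masks$ho)
}

#' Leaky integrate-and-fire layer, reference implementation
#'
#' Discrete-time LIF dynamics with an exponential-integrator update (exact
#' for the linear membrane ODE): per step, `v <- v*exp(-dt/tau)`, then input
#' spikes are integrated (`v <- v + s %*% W`), then any neuron with `v >= 1`
#' emits a spike and resets to 0 in the same step.
#'
#' This plain-R version is the readable reference (and the independent oracle
#' the tests compare the fused C++ training path against); it is fine for
#' analysis-scale inputs.
#'
#' @param spikes binary input array (trials x bins x channels) or a
#'   [spike_batch()] object.
#' @param w weight matrix (channels x neurons).
#' @param tau membrane time constant (s).
#' @param dt time step (s).
#' @return list with `spikes` (trials x bins x neurons) and `v` (membrane
#'   traces after reset, same shape).
#' @export
lif_forward <- function(spikes, w, tau, dt) {
  if (inherits(spikes, "spike_batch")) spikes <- spikes$spikes
  if (!all(is.finite(w))) stop("non-finite weights in LIF layer")
  if (tau <= 0 || dt <= 0) stop("tau and dt must be > 0")
  d <- dim(spikes); B <- d[1]; T <- d[2]
  n <- ncol(w)
  a <- exp(-dt / tau)
  v <- matrix(0, B, n)
  out_s <- array(0, c(B, T, n)); out_v <- array(0, c(B, T, n))
  for (t in seq_len(T)) {
    v <- a * v + matrix(spikes[, t, ], B) %*% w
    s <- (v >= 1) * 1
    v <- v * (1 - s)
    out_s[, t, ] <- s
    out_v[, t, ] <- v
  }
  list(spikes = out_s, v = out_v)
}

#' Leaky non-spiking readout layer, reference implementation
#'
#' Identical leaky integration to [lif_forward()] but with no threshold or
#' reset; also returns the time-mean membrane potential `v_bar` over the full
#' stimulus duration, from which the class decision is read out.
#'
#' @param hidden_spikes array (trials x bins x hidden neurons); values may be
#'   fractional (linearity holds exactly).
#' @param w_ho weight matrix (hidden x classes).
#' @param tau membrane time constant (s).
#' @param dt time step (s).
#' @return list with `v` (trials x bins x classes) and `v_bar`
#'   (trials x classes).
#' @export
readout_forward <- function(hidden_spikes, w_ho, tau, dt) {
  if (!all(is.finite(w_ho))) stop("non-finite weights in readout layer")
  if (tau <= 0 || dt <= 0) stop("tau and dt must be > 0")
  d <- dim(hidden_spikes); B <- d[1]; T <- d[2]
  a <- exp(-dt / tau)
  u <- matrix(0, B, ncol(w_ho))
  out <- array(0, c(B, T, ncol(w_ho)))
  for (t in seq_len(T)) {
    u <- a * u + matrix(hidden_spikes[, t, ], B) %*% w_ho
    out[, t, ] <- u
  }
  list(v = out, v_bar = apply(out, c(1, 3), mean))
}

#' Numerically stable log-softmax
#'
#' @param v_bar matrix (trials x classes) or vector of mean membrane
#'   potentials.
#' @return same shape; rows satisfy `sum(exp(x)) == 1`.
#' @export
log_softmax <- function(v_bar) {
  vec <- is.null(dim(v_bar))
  if (vec) v_bar <- matrix(v_bar, 1)
  if (!all(is.finite(v_bar))) stop("non-finite inputs to log_softmax")
  m <- apply(v_bar, 1, max)
  z <- v_bar - m
  x <- z - log(rowSums(exp(z)))
  if (vec) drop(x) else x
}

#' Classify from readout potentials
#'
#' The decision is the most active output neuron (ties broken toward the
#' lowest class index); the IPD estimate is that class's interval midpoint.
#' Because log-softmax is monotone, classifying from `v_bar` or from
#' `log_softmax(v_bar)` gives identical answers.
#'
#' @param x matrix (trials x classes) or vector of `v_bar` or log-softmax
#'   values.
#' @param n_classes number of classes (defaults to `ncol(x)`).
#' @return list with `k_hat` (0-based class indices) and `ipd_hat` (radians).
#' @export
classify <- function(x, n_classes = NULL) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  n_classes <- n_classes %||% ncol(x)
  k <- max.col(x, ties.method = "first") - 1L
  list(k_hat = k, ipd_hat = class_to_midpoint(k, n_classes))
}

#' Spike nonlinearity with surrogate derivative
#'
#' Forward value is the hard step `1[v >= 1]`; the backward pass uses the
#' fast-sigmoid pseudo-derivative `beta / (beta*|v - 1| + 1)^2`, which is
#' finite everywhere and peaks at `beta` on the threshold.
#'
#' @param v membrane potential(s).
#' @param beta surrogate slope.
#' @return list with `spike` (0/1) and `grad` (pseudo-derivative).
#' @export
surrogate_spike <- function(v, beta = 10) {
  list(spike = (v >= 1) * 1, grad = beta / (beta * abs(v - 1) + 1)^2)
}

# Fused forward pass over a spike tensor: hidden currents by matrix product,
# then the C++ LIF + readout. Internal workhorse for training/eval/analysis.
snn_pass <- function(spikes, params, y = NULL, r_minus = 100, r_plus = 200,
                     c_reg = 0, want_grad = FALSE, want_spikes = FALSE,
                     dt, soft = FALSE) {
  d <- dim(spikes); B <- d[1]; T <- d[2]
  xmat <- matrix(spikes, B * T, d[3])
  imat <- xmat %*% params$w_ih
  res <- cpp_snn_pass(imat, B, T, params$w_ho, params$tau_h, params$tau_o,
                      dt, params$beta,
                      if (is.null(y)) integer(0) else as.integer(y),
                      r_minus, r_plus, c_reg, want_grad, want_spikes, soft)
  if (want_grad && !is.null(y)) res$dW_ih <- crossprod(xmat, res$dI)
  res
}
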