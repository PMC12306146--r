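# Post-training analysis: IPD tuning curves and their Gaussian-dip fits, the
# Ricker-wavelet summary of the hidden-to-output weights, a rate-based closed
# form for LIF firing, the six-parameter reduced model, and nonnegative
# tensor component analysis of hidden-layer spiking.

#' IPD tuning curves of the hidden and output layers
#'
#' Mean response per IPD grid point over repeated Poisson draws: firing rate
#' for hidden neurons, mean readout potential for output neurons. Curves are
#' normalized per neuron to a maximum of 1; all-zero (silent) neurons are
#' flagged and left unnormalized.
#'
#' @param params a [network_params()] object.
#' @param task an [task_config()] object.
#' @param ipd_grid IPD grid (radians).
#' @param trials_per_point Poisson repeats per grid point (>= 10).
#' @param seed integer seed.
#' @return list of class `tuning_curves` with `ipd_grid`, `hidden` (grid x
#'   neurons, normalized rates), `hidden_raw` (sp/s), `output` (grid x
#'   classes, normalized v_bar), `output_raw`, `silent` (logical).
#' @export
tuning_curves <- function(params, task,
                          ipd_grid = seq(task$ipd_min, task$ipd_max,
                                         length.out = 37),
                          trials_per_point = 50, seed = 1L) {
  stopifnot(trials_per_point >= 10)
  psi <- phase_delays(task$n_psi)
  n_h <- ncol(params$w_ih)
  hid <- matrix(0, length(ipd_grid), n_h)
  out <- matrix(0, length(ipd_grid), task$n_classes)
  for (i in seq_along(ipd_grid)) {
    X <- cpp_spike_batch(rep(ipd_grid[i], trials_per_point), task$f, psi,
                         task$rate_max, task$dt, task$n_bins,
                         derive_seed(seed, sprintf("tc-%d", i)))
    res <- snn_pass(X, params, dt = task$dt)
    hid[i, ] <- colMeans(res$counts) / task$duration
    out[i, ] <- colMeans(res$vbar)
  }
  silent <- apply(hid, 2, function(z) all(z == 0))
  norm1 <- function(m, dead) {
    for (j in seq_len(ncol(m)))
      if (!dead[j]) m[, j] <- m[, j] / max(m[, j])
    m
  }
  structure(list(ipd_grid = ipd_grid, hidden = norm1(hid, silent),
                 hidden_raw = hid,
                 output = norm1(out, apply(out, 2, function(z) all(z <= 0))),
                 output_raw = out, silent = silent),
            class = "tuning_curves")
}

#' Fit a Gaussian-dip tuning curve
#'
#' Nonlinear least squares of `a + b * exp(-(alpha - alpha_i)^2 /
#' (2*sigma_alpha^2))`: a high baseline `a` with a (for trained hidden units,
#' negative-`b`) localized dip at the least-preferred IPD `alpha_i`. The
#' center is initialized at the curve's argmin and the width at three grid
#' spacings.
#'
#' @param ipd IPD grid (radians).
#' @param rate responses (same length).
#' @return object of class `gaussian_dip_fit`: `a`, `b`, `alpha_i`,
#'   `sigma_alpha`, `r_squared`, `degenerate` (flat-curve flag),
#'   `fitted`.
#' @export
fit_gaussian_dip <- function(ipd, rate) {
  stopifnot(length(ipd) == length(rate), all(is.finite(rate)))
  if (diff(range(rate)) < 1e-10) {
    return(structure(list(a = mean(rate), b = 0, alpha_i = ipd[1],
                          sigma_alpha = NA_real_, r_squared = 0,
                          degenerate = TRUE, fitted = rep(mean(rate),
                                                          length(ipd))),
                     class = "gaussian_dip_fit"))
  }
  start <- list(a = as.numeric(quantile(rate, 0.9)),
                b = min(rate) - as.numeric(quantile(rate, 0.9)),
                alpha_i = ipd[which.min(rate)],
                sigma_alpha = 3 * mean(diff(ipd)))
  df <- data.frame(ipd = ipd, rate = rate)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rate ~ a + b * exp(-(ipd - alpha_i)^2 / (2 * sigma_alpha^2)),
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("gaussian dip fit failed to converge (start: a=",
           signif(start$a, 3), ", alpha_i=", signif(start$alpha_i, 3),
           "): ", conditionMessage(e)))
  cf <- coef(fit)
  fitted <- cf[["a"]] + cf[["b"]] *
    exp(-(ipd - cf[["alpha_i"]])^2 / (2 * cf[["sigma_alpha"]]^2))
  r2 <- 1 - sum((rate - fitted)^2) / sum((rate - mean(rate))^2)
  structure(list(a = cf[["a"]], b = cf[["b"]], alpha_i = cf[["alpha_i"]],
                 sigma_alpha = abs(cf[["sigma_alpha"]]), r_squared = r2,
                 degenerate = abs(cf[["b"]]) < 1e-6 * max(abs(rate)),
                 fitted = fitted),
            class = "gaussian_dip_fit")
}

#' Rate-based closed form for LIF firing
#'
#' The firing rate of a LIF neuron `tau * v' = r_in - v` with refractory
#' period `t_refrac` under constant drive `r_in` (in threshold units):
#' zero for `r_in <= 1`, else `1 / (t_refrac + tau * log(r_in/(r_in - 1)))`.
#' In the discrete-time simulation the refractory period equals `dt`. The
#' form remains a good approximation when `r_in` varies in time.
#'
#' @param r_in drive trace in threshold units (vector ok).
#' @param tau membrane time constant (s).
#' @param t_refrac refractory period (s), > 0.
#' @return firing rate(s), sp/s.
#' @export
rate_approximation <- function(r_in, tau, t_refrac) {
  stopifnot(t_refrac > 0, tau > 0)
  out <- numeric(length(r_in))
  sup <- which(r_in > 1)
  out[sup] <- 1 / (t_refrac + tau * log(r_in[sup] / (r_in[sup] - 1)))
  out
}

#' Rate-based approximation of the trained network's tuning curves
#'
#' Ignores spike timing entirely: the hidden drive is the input rate passed
#' through `w_ih`, converted to threshold units (a per-step jump `c` and
#' leak `exp(-dt/tau)` correspond to the constant continuous drive
#' `c / (1 - exp(-dt/tau))`), then through [rate_approximation()]; output
#' activity is `r_o(t) = sum_h w_ho * r_h(t)`, time-averaged.
#'
#' @param params a [network_params()] object.
#' @param task an [task_config()] object.
#' @param ipd_grid IPD grid (radians).
#' @return list with `hidden` (grid x neurons, sp/s) and `output` (grid x
#'   classes, arbitrary units).
#' @export
rate_based_curves <- function(params, task,
                              ipd_grid = seq(task$ipd_min, task$ipd_max,
                                             length.out = 37)) {
  psi <- phase_delays(task$n_psi)
  n_h <- ncol(params$w_ih)
  scale <- task$dt / (1 - exp(-task$dt / params$tau_h))
  hid <- matrix(0, length(ipd_grid), n_h)
  out <- matrix(0, length(ipd_grid), task$n_classes)
  for (i in seq_along(ipd_grid)) {
    R <- input_rates(ipd_grid[i], task, psi)   # bins x channels
    drive <- (R %*% params$w_ih) * scale       # threshold units
    rh <- matrix(rate_approximation(drive, params$tau_h, task$dt),
                 nrow(drive), n_h)
    hid[i, ] <- colMeans(rh)
    out[i, ] <- colMeans(rh %*% params$w_ho)
  }
  list(hidden = hid, output = out)
}

#' Fit the hidden-to-output weights with a Ricker wavelet
#'
#' `W_ho[h, o] ~ a * (1 - (delta/sigma_delta)^2) * exp(-delta^2 /
#' (2*sigma_delta^2)) + b` with `delta = o - n_classes * h / n_h` (0-based
#' indices): broad excitation with narrowly tuned inhibition along the
#' diagonal. Fit over all (h, o) pairs by least squares. The hidden units
#' should first be reordered by least-preferred IPD
#' ([reorder_hidden_by_worst_delay()]).
#'
#' @param w_ho weight matrix (hidden x classes), already reordered.
#' @return object of class `ricker_fit`: `a`, `b`, `sigma_delta`,
#'   `r_squared`, `fitted` (same shape as `w_ho`).
#' @export
fit_ricker <- function(w_ho) {
  n_h <- nrow(w_ho); n_c <- ncol(w_ho)
  h <- rep(0:(n_h - 1), n_c)
  o <- rep(0:(n_c - 1), each = n_h)
  delta <- o - n_c * h / n_h
  wv <- as.vector(w_ho)
  df <- data.frame(delta = delta, w = wv)
  start <- list(a = max(wv) - min(wv), b = min(wv), sigma_delta = 1.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      w ~ a * (1 - (delta / sigma_delta)^2) *
        exp(-delta^2 / (2 * sigma_delta^2)) + b,
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("ricker fit failed to converge (start a=", signif(start$a, 3),
           "): ", conditionMessage(e)))
  cf <- coef(fit)
  pred <- ricker_eval(delta, cf[["a"]], cf[["b"]], abs(cf[["sigma_delta"]]))
  r2 <- 1 - sum((wv - pred)^2) / sum((wv - mean(wv))^2)
  structure(list(a = cf[["a"]], b = cf[["b"]],
                 sigma_delta = abs(cf[["sigma_delta"]]), r_squared = r2,
                 fitted = matrix(pred, n_h, n_c)),
            class = "ricker_fit")
}

ricker_eval <- function(delta, a, b, sigma)
  a * (1 - (delta / sigma)^2) * exp(-delta^2 / (2 * sigma^2)) + b

#' Reorder hidden units by their least-preferred IPD
#'
#' Fits a Gaussian dip to each hidden tuning curve and returns the
#' permutation sorting neurons by fitted dip center `alpha_i` ascending
#' (ties broken by neuron index). Apply the permutation consistently to
#' `w_ih` columns and `w_ho` rows.
#'
#' @param curves a `tuning_curves` object, or a matrix (grid x neurons) with
#'   attribute-free rates plus `ipd_grid`.
#' @param ipd_grid grid (radians), taken from `curves` when it is a
#'   `tuning_curves` object.
#' @return integer permutation of hidden indices.
#' @export
reorder_hidden_by_worst_delay <- function(curves, ipd_grid = NULL) {
  if (inherits(curves, "tuning_curves")) {
    ipd_grid <- curves$ipd_grid
    m <- curves$hidden
  } else m <- as.matrix(curves)
  centers <- vapply(seq_len(ncol(m)), function(j)
    fit_gaussian_dip(ipd_grid, m[, j])$alpha_i, numeric(1))
  order(centers, seq_len(ncol(m)))
}

#' Build the six-parameter reduced model
#'
#' Combines the idealized hidden tuning (Gaussian dip `a, b, sigma_alpha`
#' with dip centers fixed at `alpha_i = -pi/2 + i*pi/n_h`) with the Ricker
#' weight model (`a, b, sigma_delta`): six free parameters in place of the
#' full model's `n_psi*n_h + n_h*n_classes`.
#'
#' @param dip a `gaussian_dip_fit` (shared across hidden units).
#' @param ricker a `ricker_fit`.
#' @param n_h,n_classes layer sizes.
#' @return object of class `reduced_model`.
#' @export
reduced_model <- function(dip, ricker, n_h = 8, n_classes = 12) {
  structure(list(a_dip = dip$a, b_dip = dip$b,
                 sigma_alpha = dip$sigma_alpha, a_rick = ricker$a,
                 b_rick = ricker$b, sigma_delta = ricker$sigma_delta,
                 n_h = n_h, n_classes = n_classes),
            class = "reduced_model")
}

#' Build the reduced model from a trained network
#'
#' Runs the whole summary pipeline: tuning curves, reordering by
#' least-preferred IPD, Gaussian-dip fits on the raw (sp/s) hidden curves
#' with the shared parameters taken as the mean over non-degenerate units,
#' and the Ricker fit of the reordered hidden-to-output weights.
#'
#' @param params a [network_params()] object.
#' @param task an [task_config()] object.
#' @param trials_per_point,seed passed to [tuning_curves()].
#' @return a [reduced_model()] with attributes `order` (the hidden
#'   permutation), `dips` (per-unit fits), and `ricker`.
#' @export
build_reduced_model <- function(params, task, trials_per_point = 40,
                                seed = 1L) {
  tc <- tuning_curves(params, task, trials_per_point = trials_per_point,
                      seed = seed)
  ord <- reorder_hidden_by_worst_delay(tc)
  dips <- lapply(ord, function(j)
    fit_gaussian_dip(tc$ipd_grid, tc$hidden_raw[, j]))
  ok <- !vapply(dips, `[[`, logical(1), "degenerate")
  if (!any(ok)) stop("all hidden units degenerate; cannot reduce")
  dip <- structure(list(
    a = mean(vapply(dips[ok], `[[`, numeric(1), "a")),
    b = mean(vapply(dips[ok], `[[`, numeric(1), "b")),
    alpha_i = 0,
    sigma_alpha = mean(vapply(dips[ok], `[[`, numeric(1), "sigma_alpha"))),
    class = "gaussian_dip_fit")
  rick <- fit_ricker(params$w_ho[ord, , drop = FALSE])
  out <- reduced_model(dip, rick, n_h = ncol(params$w_ih),
                       n_classes = task$n_classes)
  attr(out, "order") <- ord
  attr(out, "dips") <- dips
  attr(out, "ricker") <- rick
  attr(out, "curves") <- tc
  out
}

#' Predict output tuning and classifications from the reduced model
#'
#' Idealized hidden curves (Gaussian dip at `alpha_i = -pi/2 + i*pi/n_h`)
#' are passed through the Ricker weight model; classification is the argmax
#' output. No trained weights are consulted.
#'
#' @param rm a [reduced_model()] object.
#' @param ipds IPDs (radians).
#' @return list with `hidden` (length(ipds) x n_h), `output`
#'   (length(ipds) x n_classes), `k_hat` (0-based classes).
#' @export
reduced_model_predict <- function(rm, ipds) {
  alpha_i <- -pi / 2 + (0:(rm$n_h - 1)) * pi / rm$n_h
  hid <- vapply(alpha_i, function(ai)
    rm$a_dip + rm$b_dip * exp(-(ipds - ai)^2 / (2 * rm$sigma_alpha^2)),
    numeric(length(ipds)))
  hid <- matrix(hid, length(ipds), rm$n_h)
  h <- rep(0:(rm$n_h - 1), rm$n_classes)
  o <- rep(0:(rm$n_classes - 1), each = rm$n_h)
  W <- matrix(ricker_eval(o - rm$n_classes * h / rm$n_h, rm$a_rick,
                          rm$b_rick, rm$sigma_delta),
              rm$n_h, rm$n_classes)
  out <- hid %*% W
  list(hidden = hid, output = out,
       k_hat = max.col(out, ties.method = "first") - 1L)
}

# ---- Tensor component analysis --------------------------------------------

#' Smooth spike trains with a Gaussian kernel
#'
#' Temporal convolution of each unit's spike train with a normalized
#' Gaussian (truncated at four standard deviations, zero-padded edges):
#' total spike mass is preserved up to edge truncation, and the operation is
#' linear.
#'
#' @param x spike array with time along `time_dim` (default 2, the
#'   trials x time x units layout), a matrix (time x units), or a vector.
#' @param kernel_sigma kernel width (bins), > 0.
#' @param time_dim which dimension of a 3D array is time.
#' @return smoothed array of the same shape.
#' @export
smooth_spikes <- function(x, kernel_sigma, time_dim = 2) {
  stopifnot(kernel_sigma > 0)
  rad <- max(1L, ceiling(4 * kernel_sigma))
  kern <- exp(-0.5 * ((-rad):rad / kernel_sigma)^2)
  kern <- kern / sum(kern)
  smooth_vec_mat <- function(m) {  # time along rows
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(kern)) {
      off <- j - rad - 1L
      src <- seq_len(n) - off
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + kern[j] * m[src[ok], , drop = FALSE]
    }
    out
  }
  if (is.null(dim(x))) return(drop(smooth_vec_mat(matrix(x, ncol = 1))))
  if (length(dim(x)) == 2) return(smooth_vec_mat(x))
  stopifnot(length(dim(x)) == 3)
  ap <- aperm(x, c(time_dim, setdiff(1:3, time_dim)))
  d <- dim(ap)
  sm <- smooth_vec_mat(matrix(ap, d[1], d[2] * d[3]))
  dim(sm) <- d
  aperm(sm, order(c(time_dim, setdiff(1:3, time_dim))))
}

#' Nonnegative tensor component analysis (CP decomposition)
#'
#' Rank-`rank` nonnegative canonical polyadic decomposition of a
#' neurons x time x trials activity tensor by hierarchical alternating least
#' squares (HALS): each component is the outer product of a neuron factor
#' (which units participate), a time factor (within-trial dynamics), and a
#' trial factor (per-trial activation). Best of `restarts` seeded random
#' initializations by reconstruction error; neuron and time columns are
#' returned unit-norm with the scale absorbed into the trial factors.
#'
#' @param x nonnegative 3D array (neurons x time x trials).
#' @param rank number of components (>= 1, at most the smallest dimension).
#' @param seed integer seed.
#' @param restarts random restarts.
#' @param max_sweeps maximum alternating sweeps.
#' @param tol stop when the relative reconstruction-error change drops
#'   below this.
#' @return object of class `tca_factors`: `neuron`, `time`, `trial` factor
#'   matrices (all entries >= 0), `rank`, `rel_error`
#'   (`||x - rec||_F / ||x||_F`), `error_trace` of the winning restart.
#' @export
tca_decompose <- function(x, rank, seed = 1L, restarts = 5,
                          max_sweeps = 500, tol = 1e-6) {
  stopifnot(length(dim(x)) == 3)
  if (any(x < 0)) stop("tensor must be nonnegative")
  d <- dim(x)
  if (rank < 1 || rank > min(d))
    stop("rank must be between 1 and the smallest tensor dimension (",
         min(d), ")")
  X1 <- matrix(x, d[1], d[2] * d[3])                     # mode-1 unfolding
  X2 <- matrix(aperm(x, c(2, 1, 3)), d[2], d[1] * d[3])  # mode-2
  X3 <- matrix(aperm(x, c(3, 1, 2)), d[3], d[1] * d[2])  # mode-3
  nrmx <- sqrt(sum(x^2))
  khatri_rao <- function(B, C) {  # columnwise Kronecker, (nB*nC) x R
    sapply(seq_len(ncol(B)), function(r) kronecker(C[, r], B[, r]))
  }
  best <- NULL
  for (rs in seq_len(restarts)) {
    u <- cpp_runif_stream((d[1] + d[2] + d[3]) * rank,
                          derive_seed(seed, sprintf("tca-%d", rs)))
    A <- matrix(u[seq_len(d[1] * rank)], d[1], rank) + 0.1
    B <- matrix(u[d[1] * rank + seq_len(d[2] * rank)], d[2], rank) + 0.1
    C <- matrix(utils::tail(u, d[3] * rank), d[3], rank) + 0.1
    trace <- numeric(0)
    prev <- Inf
    for (sw in seq_len(max_sweeps)) {
      upd <- function(X, F1, F2, F) {
        # HALS columnwise update of factor F for unfolding X = F (F2 kr F1)^T
        P <- X %*% khatri_rao(F1, F2)          # n x R  (MTTKRP)
        G <- crossprod(F1) * crossprod(F2)     # R x R
        for (r in seq_len(rank)) {
          num <- P[, r] - F %*% G[, r] + F[, r] * G[r, r]
          F[, r] <- pmax(num / max(G[r, r], 1e-12), 0)
        }
        F
      }
      A <- upd(X1, B, C, A)
      B <- upd(X2, A, C, B)
      C <- upd(X3, A, B, C)
      # ||X - rec||^2 = ||X||^2 - 2<X3 kr, C> + <G C, C>
      P3 <- X3 %*% khatri_rao(A, B)
      G3 <- crossprod(A) * crossprod(B)
      err2 <- max(nrmx^2 - 2 * sum(P3 * C) + sum((C %*% G3) * C), 0)
      rel <- sqrt(err2) / nrmx
      trace <- c(trace, rel)
      if (is.finite(prev) && abs(prev - rel) < tol) break
      prev <- rel
    }
    if (is.null(best) || rel < best$rel_error)
      best <- list(A = A, B = B, C = C, rel_error = rel, trace = trace)
  }
  # normalize neuron/time columns, absorb scale into trial factors
  A <- best$A; B <- best$B; C <- best$C
  for (r in seq_len(rank)) {
    na <- sqrt(sum(A[, r]^2)); nb <- sqrt(sum(B[, r]^2))
    if (na > 0) A[, r] <- A[, r] / na
    if (nb > 0) B[, r] <- B[, r] / nb
    C[, r] <- C[, r] * na * nb
  }
  structure(list(neuron = A, time = B, trial = C, rank = rank,
                 rel_error = best$rel_error, error_trace = best$trace),
            class = "tca_factors")
}

#' Reconstruct a tensor from TCA factors
#'
#' @param f a `tca_factors` object.
#' @return array (neurons x time x trials).
#' @export
tca_reconstruct <- function(f) {
  d <- c(nrow(f$neuron), nrow(f$time), nrow(f$trial))
  out <- array(0, d)
  for (r in seq_len(f$rank))
    out <- out + outer(outer(f$neuron[, r], f$time[, r]), f$trial[, r])
  out
}

#' Hidden-layer activity tensor for TCA
#'
#' Runs the network on a batch, smooths hidden spikes with a Gaussian
#' kernel, and arranges them as neurons x time x trials.
#'
#' @param params a [network_params()] object.
#' @param batch a [spike_batch()].
#' @param kernel_sigma smoothing width (bins).
#' @return array (neurons x time x trials), with `ipd` attribute carrying
#'   the per-trial IPDs.
#' @export
hidden_activity_tensor <- function(params, batch, kernel_sigma = 3) {
  res <- snn_pass(batch$spikes, params, dt = batch$dt, want_spikes = TRUE)
  S <- res$spikes                       # (trials, neurons, time)
  sm <- smooth_spikes(aperm(S, c(1, 3, 2)), kernel_sigma, time_dim = 2)
  out <- aperm(sm, c(3, 2, 1))          # neurons x time x trials
  attr(out, "ipd") <- batch$ipd_true
  out
}
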