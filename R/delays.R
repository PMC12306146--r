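# Trainable input delays: (1) the differentiable delay layer (DDL), a 1D
# translation + linear interpolation that makes discrete-time spike delays
# differentiable, with a multiplicative-synapse (squared-difference) readout
# trained on delays only; (2) delay learning through a temporal convolution
# whose per-synapse kernel has a single, continuously positioned non-zero
# element, co-trained with the weights.

#' Shift spike trains by (possibly fractional) delays
#'
#' Translation along time with linear interpolation: integer multiples of the
#' time step reproduce exact index shifting (the interpolation picks the
#' coincident source bin with weight one); fractional delays split each
#' spike's mass linearly between the two adjacent bins, making the operation
#' differentiable with respect to the delay. Inputs are zero-padded by `pad`
#' bins so no spike mass is lost.
#'
#' @param x spike matrix (time bins x channels) or a vector (one channel).
#' @param delays per-channel delays in units of the time step (bins);
#'   recycled if scalar. Must satisfy `0 <= delay <= pad`.
#' @param pad number of zero bins appended (default: enough for the largest
#'   delay).
#' @return matrix ((bins + pad) x channels) of shifted, possibly fractional,
#'   spike trains.
#' @export
ddl_shift <- function(x, delays, pad = ceiling(max(delays))) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  nc <- ncol(x)
  delays <- rep_len(delays, nc)
  if (any(delays < 0)) stop("delays must be nonnegative")
  bad <- which(delays > pad + 1e-12)
  if (length(bad))
    stop("delay exceeds pad for channel(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  Tp <- nrow(x) + pad
  xp <- rbind(x, matrix(0, pad, nc))
  out <- matrix(0, Tp, nc)
  for (ch in seq_len(nc)) {
    k <- floor(delays[ch]); w <- delays[ch] - k
    a <- shift_rows(xp[, ch], k)
    b <- if (w > 0) shift_rows(xp[, ch], k + 1) else 0
    out[, ch] <- (1 - w) * a + w * b
  }
  out
}

shift_rows <- function(v, k) {
  n <- length(v)
  if (k == 0) return(v)
  if (k >= n) return(numeric(n))
  c(numeric(k), v[seq_len(n - k)])
}

# shift the columns of a (trials x time) matrix right by integer k
shift_cols <- function(m, k) {
  n <- ncol(m)
  out <- matrix(0, nrow(m), n)
  if (k < n) out[, (k + 1):n] <- m[, seq_len(n - k), drop = FALSE]
  out
}

#' Leaky (exponential) filtering of a spike train
#'
#' Discrete form of `tau * du/dt = -u + S(t)` with unit jumps per spike:
#' `u_t = u_{t-1} * exp(-dt/tau) + s_t`.
#'
#' @param x matrix (time x channels) or vector.
#' @param tau time constant (s).
#' @param dt time step (s).
#' @return filtered trace, same shape.
#' @export
leaky_filter <- function(x, tau, dt) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  a <- exp(-dt / tau)
  out <- x
  if (nrow(x) > 1)
    for (t in 2:nrow(x)) out[t, ] <- a * out[t - 1, ] + x[t, ]
  if (vec) drop(out) else out
}

#' Multiplicative-synapse coincidence readout
#'
#' Each output node `i` filters a (fixed-)delayed copy of the left train and
#' a (learnable-)delayed copy of the right train into dendritic potentials
#' `u_1i, u_2i` and scores their coincidence as
#' `v_i = -sum_t (u_1i(t) - u_2i(t))^2`: always `<= 0`, with equality iff the
#' filtered trains coincide. Expanding the square shows this is a
#' multi-synaptic multiplicative-additive interaction
#' (`u1^2 - 2*u1*u2 + u2^2`).
#'
#' @param left,right binary spike trains (equal-length vectors).
#' @param delays_left,delays_right per-class delays in bins.
#' @param tau_m dendritic time constant (s).
#' @param dt time step (s).
#' @param pad zero-padding (bins).
#' @return numeric vector of per-class output potentials `v_i`.
#' @export
multiplicative_readout <- function(left, right, delays_left, delays_right,
                                   tau_m = 0.002, dt = 0.001,
                                   pad = ceiling(max(delays_left,
                                                     delays_right))) {
  stopifnot(length(left) == length(right))
  n <- max(length(delays_left), length(delays_right))
  dl <- rep_len(delays_left, n); dr <- rep_len(delays_right, n)
  u1 <- leaky_filter(ddl_shift(matrix(left, length(left), n), dl, pad = pad),
                     tau_m, dt)
  u2 <- leaky_filter(ddl_shift(matrix(right, length(right), n), dr,
                               pad = pad), tau_m, dt)
  -colSums((u1 - u2)^2)
}

#' Configuration for the differentiable-delay-layer model
#'
#' The 36-class setup: output classes are IPD angles spanning
#' `[-90, +85]` degrees in 5-degree steps. Delays from one ear are fixed (a
#' constant quarter-period lag so that every class's compensating delay is
#' nonnegative); delays from the other ear are learnable, one per class.
#' Weights are set to one and biases to zero; only delays train.
#'
#' @param n_classes number of IPD classes.
#' @param angle_min smallest class angle (degrees).
#' @param angle_step class spacing (degrees).
#' @param f tone frequency (Hz).
#' @param rate_max peak Poisson rate (sp/s).
#' @param duration,dt stimulus length and time step (s).
#' @param tau_m dendritic time constant (s).
#' @param pad zero-padding (bins).
#' @param epochs,n_train,batch_size,learning_rate Adam-on-delays training
#'   parameters.
#' @param logit_scale scale applied to the (per-bin mean) squared-difference
#'   scores before the softmax.
#' @param discrete_ipds if `TRUE`, trial IPDs sit exactly at class angles
#'   (used for delay-recovery checks); default draws continuous IPDs.
#' @param seed master seed.
#' @return an object of class `ddl_config`.
#' @export
ddl_config <- function(n_classes = 36, angle_min = -90, angle_step = 5,
                       f = 50, rate_max = 600, duration = 0.1, dt = 0.001,
                       tau_m = 0.002, pad = NULL, epochs = 40,
                       n_train = 4608, batch_size = 128,
                       learning_rate = 0.1, logit_scale = 5,
                       discrete_ipds = FALSE, seed = 1L) {
  period_bins <- 1 / (f * dt)
  fixed_delay <- round(period_bins / 4)  # quarter period, in bins
  max_target <- fixed_delay + period_bins / 2
  if (is.null(pad)) pad <- ceiling(max_target) + 2
  structure(list(n_classes = as.integer(n_classes), angle_min = angle_min,
                 angle_step = angle_step, f = f, rate_max = rate_max,
                 duration = duration, dt = dt,
                 n_bins = as.integer(round(duration / dt)), tau_m = tau_m,
                 pad = as.integer(pad), fixed_delay = fixed_delay,
                 epochs = as.integer(epochs), n_train = as.integer(n_train),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, logit_scale = logit_scale,
                 discrete_ipds = isTRUE(discrete_ipds),
                 seed = as.integer(seed)),
            class = "ddl_config")
}

#' @export
print.ddl_config <- function(x, ...) {
  cat(sprintf("DDL task: %d classes [%g, %g] deg, f = %g Hz\n", x$n_classes,
              x$angle_min, x$angle_min + (x$n_classes - 1) * x$angle_step,
              x$f))
  invisible(x)
}

ddl_class_angles <- function(cfg)
  cfg$angle_min + cfg$angle_step * (seq_len(cfg$n_classes) - 1)

# Draw one batch of DDL trials: per-ear single-channel Poisson trains.
ddl_batch <- function(cfg, n, seed) {
  ang <- ddl_class_angles(cfg)
  u <- cpp_runif_stream(n, derive_seed(seed, "ddl-ipd"))
  deg <- if (cfg$discrete_ipds) ang[floor(u * cfg$n_classes) + 1] else
    cfg$angle_min + u * cfg$n_classes * cfg$angle_step
  y <- pmin(floor((deg - cfg$angle_min) / cfg$angle_step), cfg$n_classes - 1)
  ipd <- deg * pi / 180
  X <- cpp_spike_batch(ipd, cfg$f, 0, cfg$rate_max, cfg$dt, cfg$n_bins,
                       derive_seed(seed, "ddl-spk"))
  # psi = 0 => one channel per ear: [,,1] left, [,,2] right
  list(left = matrix(X[, , 1], n), right = matrix(X[, , 2], n), y = y,
       ipd_deg = deg)
}

# Forward/backward through the DDL + multiplicative readout for a batch.
# Returns logits and (optionally) the gradient wrt the learnable delays.
ddl_pass <- function(left, right, d_fixed, d_learn, cfg, want_grad = FALSE) {
  B <- nrow(left); Tp <- ncol(left) + cfg$pad
  ncl <- length(d_learn)
  a <- exp(-cfg$dt / cfg$tau_m)
  Lp <- cbind(left, matrix(0, B, cfg$pad))
  Rp <- cbind(right, matrix(0, B, cfg$pad))
  u1m <- matrix(0, B, Tp)  # shared across classes (fixed delay is constant)
  L1 <- shift_cols(Lp, d_fixed)
  for (t in seq_len(Tp))
    u1m[, t] <- (if (t > 1) a * u1m[, t - 1] else 0) + L1[, t]
  k <- floor(d_learn); wf <- d_learn - k
  SA <- lapply(seq_len(ncl), function(i) shift_cols(Rp, k[i]))
  SB <- lapply(seq_len(ncl), function(i) shift_cols(Rp, k[i] + 1))
  u2 <- matrix(0, B, ncl); w2 <- matrix(0, B, ncl)
  vsum <- matrix(0, B, ncl); gsum <- matrix(0, B, ncl)
  for (t in seq_len(Tp)) {
    s2 <- vapply(seq_len(ncl),
                 function(i) (1 - wf[i]) * SA[[i]][, t] + wf[i] * SB[[i]][, t],
                 numeric(B))
    u2 <- a * u2 + s2
    dd <- u2 - u1m[, t]
    vsum <- vsum + dd * dd
    if (want_grad) {
      ds2 <- vapply(seq_len(ncl),
                    function(i) SB[[i]][, t] - SA[[i]][, t], numeric(B))
      w2 <- a * w2 + ds2
      gsum <- gsum + dd * w2
    }
  }
  logits <- -cfg$logit_scale * vsum / Tp
  out <- list(logits = logits)
  if (want_grad) out$dlogit_dd <- -2 * cfg$logit_scale * gsum / Tp
  out
}

#' Train the differentiable delay layer on the IPD task
#'
#' Gradient descent (Adam) on the learnable per-class delays only, with
#' cross-entropy loss on the softmax of the squared-difference output
#' potentials. The fixed-ear delays never change. At evaluation, learned
#' delays are snapped to integer multiples of the time step.
#'
#' @param cfg a [ddl_config()] object.
#' @param n_test test-set size.
#' @param verbose print per-epoch loss.
#' @return an object of class `ddl_result`: learned `delays` (bins),
#'   `fixed_delay`, `loss_history`, `metrics` (accuracy, `mae_deg`,
#'   confusion, error histogram), `target_delays` (the coincidence-
#'   compensating delays implied by each class angle), and the config.
#' @export
train_ddl <- function(cfg = ddl_config(), n_test = 4096, verbose = FALSE) {
  ncl <- cfg$n_classes
  d_learn <- rep(cfg$fixed_delay, ncl)  # vertical band before training
  st <- adam_init(list(d = ncl))$d
  n_batches <- cfg$n_train %/% cfg$batch_size
  loss_history <- numeric(cfg$epochs)
  for (e in seq_len(cfg$epochs)) {
    eseed <- derive_seed(cfg$seed, sprintf("ddl-epoch-%d", e))
    eloss <- 0
    for (bi in seq_len(n_batches)) {
      bt <- ddl_batch(cfg, cfg$batch_size,
                      derive_seed(eseed, sprintf("b-%d", bi)))
      fp <- ddl_pass(bt$left, bt$right, cfg$fixed_delay, d_learn, cfg,
                     want_grad = TRUE)
      x <- log_softmax(fp$logits)
      loss <- cross_entropy_loss(x, bt$y)
      if (!is.finite(loss))
        stop(sprintf("DDL training diverged at epoch %d, lr = %g",
                     e, cfg$learning_rate))
      p <- exp(x)
      g <- p / nrow(p)
      g[cbind(seq_len(nrow(p)), bt$y + 1L)] <-
        g[cbind(seq_len(nrow(p)), bt$y + 1L)] - 1 / nrow(p)
      grad_d <- colSums(g * fp$dlogit_dd)
      st <- adam_step(st, grad_d, cfg$learning_rate)
      d_learn <- pmin(pmax(d_learn - st$delta, 0), cfg$pad - 1)
      eloss <- eloss + loss
    }
    loss_history[e] <- eloss / n_batches
    if (verbose) message(sprintf("DDL epoch %3d  loss %.4f", e,
                                 loss_history[e]))
  }
  metrics <- evaluate_ddl(d_learn, cfg, n_test = n_test,
                          seed = derive_seed(cfg$seed, "ddl-test"))
  ang <- ddl_class_angles(cfg)
  target <- cfg$fixed_delay +
    (ang * pi / 180) / (2 * pi * cfg$f) / cfg$dt
  structure(list(delays = d_learn, fixed_delay = cfg$fixed_delay,
                 loss_history = loss_history, metrics = metrics,
                 target_delays = target, config = cfg),
            class = "ddl_result")
}

#' Evaluate a set of DDL delays
#'
#' Delays are snapped to integer bins (multiples of the minimum delay), the
#' batch is scored by the multiplicative readout, and the predicted class's
#' angle is the IPD estimate.
#'
#' @param delays learnable delays (bins).
#' @param cfg a [ddl_config()] object.
#' @param n_test number of trials.
#' @param seed integer seed.
#' @return list with `accuracy`, `mae_deg`, `chance`, `confusion`,
#'   `abs_errors_deg`.
#' @export
evaluate_ddl <- function(delays, cfg, n_test = 4096, seed = 1L) {
  d_snap <- round(delays)
  k_hat <- integer(0); y_all <- integer(0); err <- numeric(0)
  done <- 0L; ci <- 0L
  while (done < n_test) {
    take <- min(512L, n_test - done)
    ci <- ci + 1L
    bt <- ddl_batch(cfg, take, derive_seed(seed, sprintf("ev-%d", ci)))
    fp <- ddl_pass(bt$left, bt$right, cfg$fixed_delay, d_snap, cfg)
    kh <- max.col(fp$logits, ties.method = "first") - 1L
    est <- cfg$angle_min + cfg$angle_step * kh
    k_hat <- c(k_hat, kh); y_all <- c(y_all, bt$y)
    err <- c(err, abs(est - bt$ipd_deg))
    done <- done + take
  }
  list(accuracy = mean(k_hat == y_all), mae_deg = mean(err),
       chance = 1 / cfg$n_classes,
       confusion = unclass(table(factor(y_all, levels = 0:(cfg$n_classes - 1)),
                                 factor(k_hat, levels = 0:(cfg$n_classes - 1)))),
       abs_errors_deg = err)
}

# ---- DCLS: single-nonzero-kernel temporal convolution ----------------------

#' Delayed, weighted synaptic currents via temporal convolution
#'
#' Each synapse is a 1D convolution through time whose kernel has a single
#' non-zero element at a continuously positioned delay. In training mode the
#' kernel is a normalized Gaussian bump of width `sigma` centered on the
#' position (differentiable in the position; the taps always sum to the
#' weight). In inference mode it collapses to one tap at the rounded
#' position. Positions outside `[0, kernel_len - 1]` are clamped with a
#' warning.
#'
#' @param spikes binary array (trials x bins x channels) or a
#'   [spike_batch()].
#' @param weights,positions matrices (channels x postsynaptic neurons);
#'   positions in bins.
#' @param sigma interpolation width (bins).
#' @param kernel_len maximum delay + 1 (bins).
#' @param mode `"train"` or `"inference"`.
#' @return current array (trials x bins x postsynaptic neurons).
#' @export
dcls_forward <- function(spikes, weights, positions, sigma = 1,
                         kernel_len = 25, mode = c("train", "inference")) {
  mode <- match.arg(mode)
  if (inherits(spikes, "spike_batch")) spikes <- spikes$spikes
  stopifnot(kernel_len >= 1)
  if (any(positions < 0 | positions > kernel_len - 1)) {
    warning("positions outside [0, kernel_len - 1] clamped")
    positions <- pmin(pmax(positions, 0), kernel_len - 1)
  }
  d <- dim(spikes); B <- d[1]; T <- d[2]
  xmat <- matrix(spikes, B * T, d[3])
  imat <- cpp_dcls_conv(xmat, B, T, weights, positions, sigma, kernel_len,
                        mode == "inference")
  array(imat, c(B, T, ncol(weights)))
}

#' Configuration for the co-trained weights-plus-delays model
#'
#' A 12-class IPD network whose input channels carry no preassigned phase
#' delays (the delay bank of the base model is removed); instead every
#' input-to-hidden synapse has a learnable weight and a learnable delay
#' realized as a single-nonzero-element temporal convolution. The
#' interpolation width `sigma` is annealed linearly across epochs so the
#' kernel ends close to its single-tap inference form.
#'
#' @param task an [task_config()]; `n_psi` here is channels per ear (the
#'   channels are interchangeable since all phase delays are zero).
#' @param n_h hidden LIF neurons.
#' @param kernel_len maximum delay + 1 (bins).
#' @param sigma0,sigma_end interpolation width schedule (bins).
#' @param epochs,n_train,batch_size training sizes.
#' @param lr_w,lr_pos Adam learning rates for weights (both layers) and
#'   delay positions.
#' @param r_minus,r_plus,c_reg firing-rate regularizer (see
#'   [train_config()]); `c_reg = NULL` means `log(n_classes)`.
#' @param seed master seed.
#' @return an object of class `dcls_config`.
#' @export
dcls_config <- function(task = task_config(n_psi = 50), n_h = 8,
                        kernel_len = 25, sigma0 = 2, sigma_end = 0.25,
                        epochs = 25, n_train = 5120, batch_size = 128,
                        lr_w = 0.002, lr_pos = 0.1, r_minus = 100,
                        r_plus = 200, c_reg = NULL, seed = 1L) {
  if (kernel_len > task$n_bins) stop("kernel_len cannot exceed the bin count")
  structure(list(task = task, n_h = as.integer(n_h),
                 kernel_len = as.integer(kernel_len), sigma0 = sigma0,
                 sigma_end = sigma_end, epochs = as.integer(epochs),
                 n_train = as.integer(n_train),
                 batch_size = as.integer(batch_size), lr_w = lr_w,
                 lr_pos = lr_pos, r_minus = r_minus, r_plus = r_plus,
                 c_reg = c_reg, seed = as.integer(seed)),
            class = "dcls_config")
}

#' Train the single-nonzero-kernel delay model (weights + delays)
#'
#' Surrogate gradient descent jointly on input-to-hidden weights, their
#' delay positions, and the hidden-to-output weights, with the same
#' cross-entropy + firing-rate loss as the base model. `sigma` anneals
#' linearly from `sigma0` to `sigma_end`; evaluation uses the collapsed
#' single-tap kernels.
#'
#' @param cfg a [dcls_config()] object.
#' @param n_test test-set size.
#' @param verbose print per-epoch loss.
#' @return an object of class `dcls_result`: `weights`, `positions`,
#'   `w_ho`, `loss_history`, `metrics` (an `eval_report`-like list), the
#'   per-synapse receptive fields ([dcls_receptive_fields()]), and the
#'   config.
#' @export
train_dcls <- function(cfg = dcls_config(), n_test = 4096, verbose = FALSE) {
  task <- cfg$task
  n_in <- 2L * task$n_psi
  c_reg <- cfg$c_reg %||% log(task$n_classes)
  D <- cfg$kernel_len
  u <- cpp_runif_stream(n_in * cfg$n_h * 2 + cfg$n_h * task$n_classes,
                        derive_seed(cfg$seed, "dcls-init"))
  w <- matrix((u[seq_len(n_in * cfg$n_h)] * 2 - 1) / sqrt(n_in),
              n_in, cfg$n_h)
  pos <- matrix(u[n_in * cfg$n_h + seq_len(n_in * cfg$n_h)] * (D - 1),
                n_in, cfg$n_h)
  w_ho <- matrix((utils::tail(u, cfg$n_h * task$n_classes) * 2 - 1) /
                   sqrt(cfg$n_h), cfg$n_h, task$n_classes)
  st <- adam_init(list(w = dim(w), pos = dim(pos), who = dim(w_ho)))
  psi0 <- rep(0, task$n_psi)
  n_batches <- cfg$n_train %/% cfg$batch_size
  loss_history <- numeric(cfg$epochs)
  for (e in seq_len(cfg$epochs)) {
    sigma <- cfg$sigma0 +
      (cfg$sigma_end - cfg$sigma0) * (e - 1) / max(cfg$epochs - 1, 1)
    eseed <- derive_seed(cfg$seed, sprintf("dcls-epoch-%d", e))
    ipds_all <- sample_ipds(cfg$n_train, task, seed = eseed)
    eloss <- 0
    for (bi in seq_len(n_batches)) {
      idx <- ((bi - 1) * cfg$batch_size + 1):(bi * cfg$batch_size)
      ipds <- ipds_all[idx]
      X <- cpp_spike_batch(ipds, task$f, psi0, task$rate_max, task$dt,
                           task$n_bins,
                           derive_seed(eseed, sprintf("b-%d", bi)))
      B <- length(ipds); T <- task$n_bins
      xmat <- matrix(X, B * T, n_in)
      imat <- cpp_dcls_conv(xmat, B, T, w, pos, sigma, D, FALSE)
      res <- cpp_snn_pass(imat, B, T, w_ho, task_tau(cfg), task_tau(cfg),
                          task$dt, 10,
                          ipd_to_class(ipds, task$n_classes),
                          cfg$r_minus, cfg$r_plus, c_reg, TRUE, FALSE, FALSE)
      loss <- res$loss_ce + res$loss_reg
      if (!is.finite(loss))
        stop(sprintf("DCLS training diverged at epoch %d", e))
      cg <- cpp_dcls_conv_grad(xmat, B, T, res$dI, w, pos, sigma, D)
      st$w <- adam_step(st$w, cg$dw, cfg$lr_w)
      st$pos <- adam_step(st$pos, cg$dpos, cfg$lr_pos)
      st$who <- adam_step(st$who, res$dWho, cfg$lr_w)
      w <- w - st$w$delta
      pos <- pmin(pmax(pos - st$pos$delta, 0), D - 1)
      w_ho <- w_ho - st$who$delta
      eloss <- eloss + loss
    }
    loss_history[e] <- eloss / n_batches
    if (verbose) message(sprintf("DCLS epoch %3d  sigma %.2f  loss %.4f",
                                 e, sigma, loss_history[e]))
  }
  metrics <- evaluate_dcls(w, pos, w_ho, cfg, n_test = n_test,
                           seed = derive_seed(cfg$seed, "dcls-test"))
  structure(list(weights = w, positions = pos, w_ho = w_ho,
                 loss_history = loss_history, metrics = metrics,
                 config = cfg),
            class = "dcls_result")
}

task_tau <- function(cfg) cfg$tau %||% 0.002

#' Evaluate a DCLS model with collapsed (single-tap) kernels
#'
#' @param w,pos,w_ho trained parameters.
#' @param cfg a [dcls_config()] object.
#' @param n_test,seed test draw.
#' @return list with `accuracy`, `mae_deg`, `confusion`, `hidden_rates`.
#' @export
evaluate_dcls <- function(w, pos, w_ho, cfg, n_test = 4096, seed = 1L) {
  task <- cfg$task
  psi0 <- rep(0, task$n_psi)
  ipds <- sample_ipds(n_test, task, seed = seed)
  y <- ipd_to_class(ipds, task$n_classes)
  k_hat <- integer(n_test)
  counts <- numeric(cfg$n_h)
  done <- 0L; ci <- 0L
  while (done < n_test) {
    take <- min(512L, n_test - done)
    idx <- done + seq_len(take)
    ci <- ci + 1L
    X <- cpp_spike_batch(ipds[idx], task$f, psi0, task$rate_max, task$dt,
                         task$n_bins, derive_seed(seed, sprintf("ev-%d", ci)))
    B <- take; T <- task$n_bins
    xmat <- matrix(X, B * T, 2L * task$n_psi)
    imat <- cpp_dcls_conv(xmat, B, T, w, pos, cfg$sigma_end, cfg$kernel_len,
                          TRUE)
    res <- cpp_snn_pass(imat, B, T, w_ho, task_tau(cfg), task_tau(cfg),
                        task$dt, 10, integer(0), cfg$r_minus, cfg$r_plus, 0,
                        FALSE, FALSE, FALSE)
    k_hat[idx] <- classify(res$vbar, task$n_classes)$k_hat
    counts <- counts + colSums(res$counts)
    done <- done + take
  }
  mae_deg <- mean(abs(class_to_midpoint(k_hat, task$n_classes) - ipds)) *
    180 / pi
  list(accuracy = mean(k_hat == y), mae_deg = mae_deg,
       confusion = unclass(table(factor(y, levels = 0:(task$n_classes - 1)),
                                 factor(k_hat,
                                        levels = 0:(task$n_classes - 1)))),
       hidden_rates = counts / n_test / task$duration)
}

#' Per-synapse receptive fields of a DCLS model
#'
#' One `(weight, delay)` pair per synapse: the spatiotemporal receptive
#' field of each hidden neuron over (presynaptic index, learned delay).
#'
#' @param fit a `dcls_result` from [train_dcls()].
#' @return data frame with columns `hidden`, `input`, `delay_bins`,
#'   `delay_ms`, `weight`.
#' @export
dcls_receptive_fields <- function(fit) {
  w <- fit$weights; pos <- fit$positions
  dt_ms <- 1e3 * fit$config$task$dt
  data.frame(hidden = rep(seq_len(ncol(w)), each = nrow(w)),
             input = rep(seq_len(nrow(w)), ncol(w)),
             delay_bins = round(as.vector(pos)),
             delay_ms = round(as.vector(pos)) * dt_ms,
             weight = as.vector(w))
}
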