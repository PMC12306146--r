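#' Training configuration
#'
#' Defaults are the base study conditions: 16,384 fresh samples per epoch in
#' batches of 128, 100 epochs, Adam with learning rate 0.001, and a
#' firing-rate regularizer with thresholds `r_minus = 100` and
#' `r_plus = 200` sp/s whose scale `c` defaults to `log(n_classes)` (the
#' expected initial cross-entropy of a uniform predictor).
#'
#' @param n_train samples per epoch.
#' @param batch_size batch size; must divide `n_train`.
#' @param epochs number of epochs.
#' @param learning_rate Adam learning rate.
#' @param r_minus,r_plus regularizer thresholds (sp/s); `r_plus > r_minus`.
#' @param c_reg regularizer scale; `NULL` means `log(n_classes)`.
#' @param n_h hidden layer size.
#' @param tau_h,tau_o membrane time constants (s).
#' @param beta surrogate slope.
#' @param seed master seed for init + stimulus draws.
#' @param dale_mode see [init_network()].
#' @param fresh_samples if `TRUE` (default) a fresh stimulus set is drawn
#'   every epoch; if `FALSE` one fixed set is reused (ablation mode).
#' @return an object of class `train_config`.
#' @export
train_config <- function(n_train = 16384, batch_size = 128, epochs = 100,
                         learning_rate = 0.001, r_minus = 100, r_plus = 200,
                         c_reg = NULL, n_h = 8, tau_h = 0.002, tau_o = 0.002,
                         beta = 10, seed = 1L, dale_mode = "none",
                         fresh_samples = TRUE) {
  if (r_minus < 0 || r_plus <= r_minus)
    stop("constraint violated: r_plus > r_minus >= 0")
  if (n_train %% batch_size != 0) stop("batch_size must divide n_train")
  structure(list(n_train = as.integer(n_train),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 r_minus = r_minus, r_plus = r_plus, c_reg = c_reg,
                 n_h = as.integer(n_h), tau_h = tau_h, tau_o = tau_o,
                 beta = beta, seed = as.integer(seed), dale_mode = dale_mode,
                 fresh_samples = isTRUE(fresh_samples)),
            class = "train_config")
}

#' Cross-entropy (negative log-likelihood) loss
#'
#' @param x log-softmax outputs (trials x classes).
#' @param k_true 0-based true class indices.
#' @return mean over the batch of `-x[k_true]`.
#' @export
cross_entropy_loss <- function(x, k_true) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  stopifnot(length(k_true) == nrow(x))
  -mean(x[cbind(seq_len(nrow(x)), as.integer(k_true) + 1L)])
}

#' Firing-rate regularizer
#'
#' Each hidden neuron's batch-averaged firing rate `r_m` contributes nothing
#' below `r_minus`, and `L_m = ((r_m - r_minus)/(r_plus - r_minus))^2` above
#' it (so `L_m = 1` exactly at `r_m = r_plus`). The total is
#' `c * sum(L_m) / n_h`. Continuous at `r_minus` and monotone in `r_m`.
#'
#' @param rates per-neuron batch-averaged firing rates (sp/s), or a hidden
#'   spike array (trials x bins x neurons) from which rates are computed.
#' @param duration stimulus duration (s); needed when `rates` is an array.
#' @param r_minus,r_plus thresholds (sp/s).
#' @param c_reg scale constant.
#' @return scalar penalty.
#' @export
rate_regularizer <- function(rates, duration = NULL, r_minus = 100,
                             r_plus = 200, c_reg = log(12)) {
  if (is.array(rates) && length(dim(rates)) == 3) {
    if (is.null(duration) || duration <= 0) stop("duration must be > 0")
    rates <- apply(rates, 3, sum) / dim(rates)[1] / duration
  }
  z <- pmax(rates - r_minus, 0) / (r_plus - r_minus)
  c_reg * sum(z^2) / length(rates)
}

# ---- Dale's-law sign constraints ------------------------------------------

# Per-unit sign vectors for a Dale mode. "balanced" assigns half of the
# presynaptic units in each layer to be inhibitory (a seeded permutation).
dale_sign_masks <- function(n_in, n_h, mode, seed = 1L) {
  frac <- function(n, p, tag) {
    s <- rep(1, n)
    n_inh <- round(p * n)
    if (n_inh > 0) {
      u <- cpp_runif_stream(n, derive_seed(seed, paste0("dale-", tag)))
      s[order(u)[seq_len(n_inh)]] <- -1
    }
    s
  }
  if (is.character(mode)) {
    switch(mode,
      none = list(ih = NULL, ho = NULL),
      balanced = list(ih = frac(n_in, 0.5, "ih"), ho = frac(n_h, 0.5, "ho")),
      excitatory_only = list(ih = rep(1, n_in), ho = rep(1, n_h)),
      inhibitory_only = list(ih = rep(-1, n_in), ho = rep(-1, n_h)),
      stop("unknown dale_mode: ", mode))
  } else if (is.list(mode)) {
    list(ih = frac(n_in, mode$ih %||% 0, "ih"),
         ho = frac(n_h, mode$ho %||% 0, "ho"))
  } else stop("dale_mode must be a string or a list of fractions")
}

#' Apply a Dale's-law sign constraint to network parameters
#'
#' Each presynaptic unit is assigned a fixed sign and the weights are
#' reparameterized as `sign * |magnitude|`, so the constraint holds exactly
#' after every optimizer step (projection-free). The returned object carries
#' the sign masks; [train_ipd_net()] trains the magnitudes.
#'
#' @param params a [network_params()] object.
#' @param mode see [init_network()].
#' @param seed seed for the (balanced/fractional) sign assignment.
#' @return a `network_params` object with sign masks set and weights
#'   conforming.
#' @export
apply_dale_constraint <- function(params, mode, seed = 1L) {
  masks <- dale_sign_masks(nrow(params$w_ih), nrow(params$w_ho), mode, seed)
  w_ih <- params$w_ih; w_ho <- params$w_ho
  if (!is.null(masks$ih)) w_ih <- abs(w_ih) * masks$ih
  if (!is.null(masks$ho)) w_ho <- abs(w_ho) * masks$ho
  network_params(w_ih, w_ho, params$tau_h, params$tau_o, params$beta,
                 sign_ih = masks$ih, sign_ho = masks$ho)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, s), v = array(0, s), t = 0))
}

adam_step <- function(st, g, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mhat <- st$m / (1 - b1^st$t)
  vhat <- st$v / (1 - b2^st$t)
  st$delta <- lr * mhat / (sqrt(vhat) + eps)
  st
}

# ---- Training loop ---------------------------------------------------------

#' Train the LIF network on the IPD task
#'
#' Surrogate gradient descent (backpropagation through time with a
#' fast-sigmoid pseudo-derivative) on cross-entropy plus the firing-rate
#' regularizer, using Adam. By default a fresh stimulus set is drawn every
#' epoch. Under a Dale mode the sign-magnitude reparameterization guarantees
#' that no weight ever changes sign. Deterministic given `cfg$seed`.
#'
#' @param task an [task_config()] object.
#' @param cfg a [train_config()] object.
#' @param init optional `network_params` to continue training from (its sign
#'   masks, if any, are kept).
#' @param n_test test-set size for the final evaluation (0 to skip).
#' @param verbose print per-epoch loss.
#' @return an object of class `train_result`: `params`, `loss_history`
#'   (per-epoch mean training loss), `metrics` (an `eval_report` or `NULL`),
#'   and the configs.
#' @export
train_ipd_net <- function(task, cfg = train_config(), init = NULL,
                          n_test = 4096, verbose = FALSE) {
  c_reg <- cfg$c_reg %||% log(task$n_classes)
  params <- init %||% init_network(task, n_h = cfg$n_h, seed = cfg$seed,
                                   dale_mode = cfg$dale_mode,
                                   tau_h = cfg$tau_h, tau_o = cfg$tau_o,
                                   beta = cfg$beta)
  dale <- !is.null(params$sign_ih) || !is.null(params$sign_ho)
  # magnitude parameters for the sign-magnitude reparameterization
  m_ih <- if (is.null(params$sign_ih)) params$w_ih else abs(params$w_ih)
  m_ho <- if (is.null(params$sign_ho)) params$w_ho else abs(params$w_ho)
  eff <- function() {
    w_ih <- if (is.null(params$sign_ih)) m_ih else abs(m_ih) * params$sign_ih
    w_ho <- if (is.null(params$sign_ho)) m_ho else abs(m_ho) * params$sign_ho
    list(w_ih = w_ih, w_ho = w_ho)
  }
  st <- adam_init(list(ih = dim(m_ih), ho = dim(m_ho)))
  n_batches <- cfg$n_train %/% cfg$batch_size
  psi <- phase_delays(task$n_psi)
  loss_history <- numeric(cfg$epochs)
  for (e in seq_len(cfg$epochs)) {
    eseed <- derive_seed(cfg$seed, sprintf("epoch-%d", e))
    if (!cfg$fresh_samples) eseed <- derive_seed(cfg$seed, "epoch-fixed")
    ipds_all <- sample_ipds(cfg$n_train, task, seed = eseed)
    eloss <- 0
    for (bi in seq_len(n_batches)) {
      idx <- ((bi - 1) * cfg$batch_size + 1):(bi * cfg$batch_size)
      ipds <- ipds_all[idx]
      y <- ipd_to_class(ipds, task$n_classes)
      w <- eff()
      res <- cpp_train_batch(ipds, task$f, psi, task$rate_max, task$dt,
                             task$n_bins,
                             derive_seed(eseed, sprintf("b-%d", bi)),
                             w$w_ih, w$w_ho, cfg$tau_h, cfg$tau_o, cfg$beta,
                             y, cfg$r_minus, cfg$r_plus, c_reg, TRUE)
      loss <- res$loss_ce + res$loss_reg
      if (!is.finite(loss))
        stop(sprintf(
          "training diverged (non-finite loss) at epoch %d, lr = %g",
          e, cfg$learning_rate))
      g_ih <- res$dWih; g_ho <- res$dWho
      if (!is.null(params$sign_ih))
        g_ih <- g_ih * params$sign_ih * sign(m_ih)
      if (!is.null(params$sign_ho))
        g_ho <- g_ho * params$sign_ho * sign(m_ho)
      st$ih <- adam_step(st$ih, g_ih, cfg$learning_rate)
      st$ho <- adam_step(st$ho, g_ho, cfg$learning_rate)
      m_ih <- m_ih - st$ih$delta
      m_ho <- m_ho - st$ho$delta
      eloss <- eloss + loss
    }
    loss_history[e] <- eloss / n_batches
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f", e, loss_history[e]))
  }
  w <- eff()
  params$w_ih <- w$w_ih; params$w_ho <- w$w_ho
  metrics <- if (n_test > 0)
    evaluate_network(params, task, n_test = n_test,
                     seed = derive_seed(cfg$seed, "test"))
  structure(list(params = params, loss_history = loss_history,
                 metrics = metrics, task = task, config = cfg),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("train_result: %d epochs, final loss %.4f\n",
              length(x$loss_history), utils::tail(x$loss_history, 1)))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Evaluate a trained network on fresh stimuli
#'
#' @param params a [network_params()] object.
#' @param task an [task_config()] object.
#' @param n_test number of fresh test trials.
#' @param seed integer seed for the test draw.
#' @param chunk trials per forward chunk (memory control).
#' @return an object of class `eval_report`: `accuracy` (fraction),
#'   `mae_deg` (mean `|ipd_hat - ipd_true|` via class midpoints, degrees),
#'   `confusion` (true x estimated count matrix), `hidden_rates` (per-neuron
#'   mean firing rate over the test set, sp/s), `n_test`.
#' @export
evaluate_network <- function(params, task, n_test = 4096, seed = 1L,
                             chunk = 512L) {
  stopifnot(n_test >= 1)
  psi <- phase_delays(task$n_psi)
  ipds <- sample_ipds(n_test, task, seed = seed)
  y <- ipd_to_class(ipds, task$n_classes)
  k_hat <- integer(n_test)
  counts <- numeric(ncol(params$w_ih))
  done <- 0L
  ci <- 0L
  while (done < n_test) {
    take <- min(chunk, n_test - done)
    idx <- done + seq_len(take)
    ci <- ci + 1L
    res <- cpp_train_batch(ipds[idx], task$f, psi, task$rate_max, task$dt,
                           task$n_bins,
                           derive_seed(seed, sprintf("eval-%d", ci)),
                           params$w_ih, params$w_ho, params$tau_h,
                           params$tau_o, params$beta, integer(0),
                           100, 200, 0, FALSE)
    k_hat[idx] <- classify(res$vbar, task$n_classes)$k_hat
    counts <- counts + colSums(res$counts)
    done <- done + take
  }
  mae_deg <- mean(abs(class_to_midpoint(k_hat, task$n_classes) - ipds)) *
    180 / pi
  confusion <- table(factor(y, levels = 0:(task$n_classes - 1)),
                     factor(k_hat, levels = 0:(task$n_classes - 1)))
  structure(list(accuracy = mean(k_hat == y), mae_deg = mae_deg,
                 confusion = unclass(confusion),
                 hidden_rates = counts / n_test / task$duration,
                 n_test = n_test),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: accuracy %.1f%%, MAE %.2f deg (n = %d)\n",
              100 * x$accuracy, x$mae_deg, x$n_test))
  cat(sprintf("hidden rates (sp/s): %s\n",
              paste(sprintf("%.0f", x$hidden_rates), collapse = " ")))
  invisible(x)
}

#' Parameter count of the full model, printed formula
#'
#' `n_psi * n_h + n_h * n_classes` (= 896 at the base configuration
#' 100/8/12), the count the six-parameter reduced model is compared against.
#'
#' @param n_psi,n_h,n_classes layer sizes.
#' @return integer.
#' @export
count_full_model_params <- function(n_psi = 100, n_h = 8, n_classes = 12) {
  as.integer(n_psi * n_h + n_h * n_classes)
}
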