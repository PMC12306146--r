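# Tuning curves and their fits, the rate-based closed form, the reduced
# model, spike smoothing, and nonnegative tensor component analysis.

test_that("rate approximation matches its closed-form anchors", {
  tau <- 0.002; dt <- 0.001
  expect_equal(rate_approximation(0.5, tau, dt), 0)   # subthreshold drive
  expect_equal(rate_approximation(1, tau, dt), 0)
  r_unit <- exp(1) / (exp(1) - 1)  # chosen so log(r/(r-1)) = 1
  expect_equal(rate_approximation(r_unit, tau, dt), 1 / (dt + tau))
})

test_that("rate approximation agrees with brute-force LIF simulation", {
  # LIF with constant drive r_in (threshold units) and an explicit
  # refractory hold of t_refrac after each spike, integrated at a fine step
  # so the comparison probes the formula rather than integration error
  sim_rate <- function(r_in, tau, t_refrac, h = tau / 400, T_s = 10) {
    n <- round(T_s / h); a <- exp(-h / tau)
    refr_steps <- round(t_refrac / h)
    v <- 0; spikes <- 0; hold <- 0
    for (t in seq_len(n)) {
      if (hold > 0) { hold <- hold - 1; next }
      v <- v * a + r_in * (1 - a)
      if (v >= 1) { spikes <- spikes + 1; v <- 0; hold <- refr_steps }
    }
    spikes / T_s
  }
  tau <- 0.002; t_refrac <- tau / 20
  for (r_in in c(1.1, 1.5, 2, 5, 10)) {
    sim <- sim_rate(r_in, tau, t_refrac)
    expect_lt(abs(rate_approximation(r_in, tau, t_refrac) - sim) / sim, 0.05)
  }
})

test_that("gaussian dip fit recovers known parameters from noisy data", {
  grid <- seq(-pi / 2, pi / 2, length.out = 37)
  truth <- c(a = 1, b = -0.6, alpha_i = 0.3, sigma_alpha = 0.25)
  curve <- truth["a"] + truth["b"] *
    exp(-(grid - truth["alpha_i"])^2 / (2 * truth["sigma_alpha"]^2))
  noise <- (cpp_runif_stream(37, 12345) - 0.5) * 0.01 * sqrt(12)  # sd 0.01
  fit <- fit_gaussian_dip(grid, curve + noise)
  expect_lt(abs(fit$a - 1) / 1, 0.05)
  expect_lt(abs(fit$b - (-0.6)) / 0.6, 0.05)
  expect_lt(abs(fit$alpha_i - 0.3) / 0.3, 0.05)
  expect_lt(abs(fit$sigma_alpha - 0.25) / 0.25, 0.05)
  expect_gt(fit$r_squared, 0.99)
  # value of the fitted model at the dip center is a + b
  at_center <- fit$a + fit$b *
    exp(-(fit$alpha_i - fit$alpha_i)^2 / (2 * fit$sigma_alpha^2))
  expect_equal(at_center, fit$a + fit$b)
  expect_lt(abs(min(fit$fitted) - (fit$a + fit$b)), 0.02)
  # self-consistency: refit on the noise-free fitted curve
  refit <- fit_gaussian_dip(grid, fit$fitted)
  expect_lt(abs(refit$a - fit$a) / abs(fit$a), 0.01)
  expect_lt(abs(refit$sigma_alpha - fit$sigma_alpha) / fit$sigma_alpha, 0.01)
  # a flat curve is flagged degenerate
  flat <- fit_gaussian_dip(grid, rep(0.8, 37))
  expect_true(flat$degenerate)
  expect_equal(flat$b, 0)
})

test_that("ricker fit recovers known parameters and its anchors", {
  n_h <- 8; n_c <- 12
  truth <- list(a = 2, b = -0.1, sigma_delta = 1.5)
  h <- rep(0:(n_h - 1), n_c); o <- rep(0:(n_c - 1), each = n_h)
  delta <- o - n_c * h / n_h
  W <- matrix(ipdnet:::ricker_eval(delta, truth$a, truth$b,
                                   truth$sigma_delta), n_h, n_c)
  noise <- matrix((cpp_runif_stream(n_h * n_c, 777) - 0.5) * 0.02, n_h, n_c)
  fit <- fit_ricker(W + noise)
  expect_lt(abs(fit$a - truth$a) / truth$a, 0.05)
  expect_lt(abs(fit$b - truth$b) / abs(truth$b), 0.05)
  expect_lt(abs(fit$sigma_delta - truth$sigma_delta) / truth$sigma_delta, 0.05)
  # anchors: value a+b at delta = 0, exactly b at delta = +/- sigma
  expect_equal(ipdnet:::ricker_eval(0, 2, -0.1, 1.5), 1.9)
  expect_equal(ipdnet:::ricker_eval(1.5, 2, -0.1, 1.5), -0.1)
  expect_equal(ipdnet:::ricker_eval(-1.5, 2, -0.1, 1.5), -0.1)
  # self-consistency on the noise-free surface
  refit <- fit_ricker(fit$fitted)
  expect_lt(abs(refit$sigma_delta - fit$sigma_delta) / fit$sigma_delta, 0.01)
})

test_that("hidden reordering sorts by fitted dip center", {
  grid <- seq(-pi / 2, pi / 2, length.out = 37)
  centers <- c(-1.2, -0.5, 0.1, 0.9)
  curves <- sapply(centers, function(ai)
    1 - 0.7 * exp(-(grid - ai)^2 / (2 * 0.2^2)))
  expect_identical(reorder_hidden_by_worst_delay(curves, grid), 1:4)
  expect_identical(reorder_hidden_by_worst_delay(curves[, 4:1], grid), 4:1)
  perm <- reorder_hidden_by_worst_delay(curves[, c(3, 1, 4, 2)], grid)
  expect_identical(perm, c(2L, 4L, 1L, 3L))
})

test_that("the reduced model needs exactly six parameters and degrades to chance", {
  dip <- structure(list(a = 1, b = -0.7, alpha_i = 0, sigma_alpha = 0.3),
                   class = "gaussian_dip_fit")
  rick <- structure(list(a = 1.5, b = -0.2, sigma_delta = 1.4),
                    class = "ricker_fit")
  rm6 <- reduced_model(dip, rick, n_h = 8, n_classes = 12)
  free <- c("a_dip", "b_dip", "sigma_alpha", "a_rick", "b_rick",
            "sigma_delta")
  expect_length(free, 6)
  expect_true(all(free %in% names(rm6)))
  ipds <- seq(-pi / 2, pi / 2, length.out = 101)
  pred <- reduced_model_predict(rm6, ipds)
  expect_equal(dim(pred$output), c(101, 12))
  # with no dip (b = 0) the hidden response is IPD-independent: one constant
  # prediction for every input
  rm_flat <- rm6; rm_flat$b_dip <- 0
  pf <- reduced_model_predict(rm_flat, ipds)
  expect_length(unique(pf$k_hat), 1)
})

test_that("gaussian smoothing preserves mass, linearity, and the delta limit", {
  x <- numeric(50); x[25] <- 1
  sm <- smooth_spikes(x, 3)
  expect_equal(sum(sm), 1, tolerance = 1e-9)   # interior spike keeps mass
  expect_equal(which.max(sm), 25)
  a <- stats::rbinom(50, 1, 0.3); b <- stats::rbinom(50, 1, 0.3)
  expect_equal(smooth_spikes(a + b, 2), smooth_spikes(a, 2) + smooth_spikes(b, 2),
               tolerance = 1e-12)
  expect_equal(smooth_spikes(x, 1e-4), x, tolerance = 1e-8)  # sigma -> 0
  arr <- array(stats::rbinom(4 * 30 * 2, 1, 0.2), c(4, 30, 2))
  smarr <- smooth_spikes(arr, 2)
  expect_equal(dim(smarr), dim(arr))
  expect_equal(smarr[2, , 1], smooth_spikes(arr[2, , 1], 2), tolerance = 1e-12)
})

test_that("nonnegative TCA recovers a planted rank-1 tensor", {
  u <- cpp_runif_stream(8 + 30 + 20, 31) + 0.2
  a <- u[1:8]; b <- u[9:38]; c3 <- u[39:58]
  x <- outer(outer(a, b), c3)
  f <- tca_decompose(x, rank = 1, seed = 2, restarts = 3)
  expect_true(all(f$neuron >= 0) && all(f$time >= 0) && all(f$trial >= 0))
  expect_lt(f$rel_error, 1e-4)
  expect_gt(abs(cor(f$neuron[, 1], a)), 0.99)
  expect_gt(abs(cor(f$time[, 1], b)), 0.99)
  expect_gt(abs(cor(f$trial[, 1], c3)), 0.99)
  # unit-norm neuron/time columns, scale absorbed in the trial factor
  expect_equal(sum(f$neuron[, 1]^2), 1, tolerance = 1e-9)
  expect_equal(sum(f$time[, 1]^2), 1, tolerance = 1e-9)
  expect_equal(tca_reconstruct(f), x, tolerance = 1e-3)
})

test_that("TCA error is monotone in sweeps and non-increasing in rank", {
  u <- cpp_runif_stream(6 * 25 * 15, 99)
  x <- array(u, c(6, 25, 15))  # noisy nonnegative tensor
  f1 <- tca_decompose(x, rank = 1, seed = 5, restarts = 2)
  f3 <- tca_decompose(x, rank = 3, seed = 5, restarts = 2)
  expect_true(all(diff(f1$error_trace) <= 1e-8))
  expect_true(all(diff(f3$error_trace) <= 1e-8))
  expect_lte(f3$rel_error, f1$rel_error + 1e-9)
  expect_error(tca_decompose(x, rank = 10), "rank")
  expect_error(tca_decompose(x - 10, rank = 2), "nonnegative")
})

test_that("tuning curves have the right shape contracts on a tiny network", {
  task <- tiny_task()
  p <- tiny_params(task, n_h = 3, seed = 21)
  tc <- tuning_curves(p, task, ipd_grid = seq(-pi / 2, pi / 2, length.out = 9),
                      trials_per_point = 15, seed = 3)
  expect_equal(dim(tc$hidden), c(9, 3))
  live <- which(!tc$silent)
  for (j in live) expect_equal(max(tc$hidden[, j]), 1)
  expect_true(all(tc$hidden_raw >= 0))
  # a network with all-zero input weights is silent and flagged
  p0 <- network_params(matrix(0, 2 * task$n_psi, 2), matrix(1, 2, 4))
  tc0 <- tuning_curves(p0, task, trials_per_point = 10, seed = 1)
  expect_true(all(tc0$silent))
})
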