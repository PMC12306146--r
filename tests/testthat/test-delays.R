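# Differentiable delay layer (translation + interpolation), the
# multiplicative-synapse readout, and the single-nonzero-kernel temporal
# convolution.

test_that("integer delays reproduce exact index shifting, bitwise", {
  set.seed(1)
  for (rep in 1:500) {
    T <- sample(20:60, 1)
    x <- matrix(rbinom(T, 1, 0.3), T, 1)
    d <- sample(0:10, 1)
    out <- ddl_shift(x, d, pad = 12)
    ref <- c(rep(0, d), x[, 1], rep(0, 12 - d))
    expect_identical(out[, 1], ref)
  }
})

test_that("zero delay is the identity and fractional delays interpolate", {
  x <- matrix(0, 30, 1); x[10, 1] <- 1
  expect_equal(ddl_shift(x, 0, pad = 5)[1:30, 1], x[, 1])
  out <- ddl_shift(x, 2.5, pad = 5)
  expect_equal(out[12, 1], 0.5)  # mass split between bins 12 and 13
  expect_equal(out[13, 1], 0.5)
  expect_equal(sum(out), 1)
  out2 <- ddl_shift(x, 3.25, pad = 5)
  expect_equal(out2[13, 1], 0.75)
  expect_equal(out2[14, 1], 0.25)
  expect_error(ddl_shift(x, 9, pad = 5), "channel")
})

test_that("spike mass is conserved under shifting within the pad", {
  set.seed(7)
  x <- matrix(rbinom(200, 1, 0.4), 40, 5)
  d <- runif(5, 0, 9.5)
  out <- ddl_shift(x, d, pad = 10)
  expect_equal(colSums(out), colSums(x), tolerance = 1e-12)
})

test_that("multiplicative readout is a negated coincidence score", {
  set.seed(3)
  s <- rbinom(50, 1, 0.3)
  # identical trains, zero delays: perfect coincidence
  expect_equal(multiplicative_readout(s, s, 0, 0), 0)
  # any inputs: v <= 0
  s2 <- rbinom(50, 1, 0.3)
  v <- multiplicative_readout(s, s2, c(0, 2), c(1, 2), pad = 4)
  expect_true(all(v <= 0))
  # right train arrives 3 bins late: compensating with delay 3 on the left
  # side restores coincidence exactly (trailing zeros so no mass is cut off)
  s[48:50] <- 0
  sh <- c(rep(0, 3), s[1:47])
  v2 <- multiplicative_readout(s, sh, 1:5, rep(0, 5), pad = 6)
  expect_equal(which.max(v2), 3)
  expect_equal(v2[3], 0)
  # expansion identity (u1-u2)^2 = u1^2 - 2 u1 u2 + u2^2
  u1 <- leaky_filter(ddl_shift(s, 0, pad = 6)[, 1], 0.002, 0.001)
  u2 <- leaky_filter(ddl_shift(s2, 1.5, pad = 6)[, 1], 0.002, 0.001)
  direct <- -sum((u1 - u2)^2)
  expanded <- -sum(u1^2 - 2 * u1 * u2 + u2^2)
  expect_equal(direct, expanded, tolerance = 1e-10)
})

test_that("the delay gradient points toward coincidence", {
  # left train: one spike; right train: same spike shifted by Delta bins.
  # The gradient of -v wrt the learnable delay must point toward Delta.
  cfg <- ddl_config(n_classes = 1, pad = 12, logit_scale = 1)
  for (delta in c(-3, -1, 1, 3)) {
    T <- 40
    left <- matrix(0, 1, T); left[1, 20] <- 1
    right <- matrix(0, 1, T); right[1, 20 - delta] <- 1  # arrives earlier/later
    # learnable delay d acts on the right train; coincidence at d = d_fixed + delta
    d0 <- cfg$fixed_delay
    fp <- ipdnet:::ddl_pass(left, right, d_fixed = cfg$fixed_delay,
                            d_learn = d0 + 0.5 * sign(delta), cfg,
                            want_grad = TRUE)
    # coincidence is at d = d0 + delta; the logit gradient must point there
    grad <- fp$dlogit_dd[1, 1]
    expect_gt(abs(grad), 0)
    expect_identical(sign(grad), sign(delta))
    # numerical cross-check of the interpolation gradient
    eps <- 1e-4
    lp <- ipdnet:::ddl_pass(left, right, cfg$fixed_delay,
                            d0 + 0.5 * sign(delta) + eps, cfg)$logits[1, 1]
    lm <- ipdnet:::ddl_pass(left, right, cfg$fixed_delay,
                            d0 + 0.5 * sign(delta) - eps, cfg)$logits[1, 1]
    expect_equal(grad, (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("DDL training recovers integer-bin delays on a synthetic task", {
  # classes at exact one-bin ITD spacing: at 50 Hz with 1 ms bins, one bin of
  # delay is 18 degrees of phase
  cfg <- ddl_config(n_classes = 8, angle_min = -72, angle_step = 18,
                    epochs = 16, n_train = 1152, batch_size = 128,
                    discrete_ipds = TRUE, seed = 5)
  fit <- train_ddl(cfg, n_test = 512)
  expect_true(all(round(fit$target_delays, 6) == round(fit$target_delays)))
  hits <- abs(fit$delays - fit$target_delays) <= 1
  expect_gte(mean(hits), 0.8)
  # the fixed-ear delay never trained
  expect_identical(fit$fixed_delay, cfg$fixed_delay)
  # and accuracy is well above chance
  expect_gt(fit$metrics$accuracy, 2 * fit$metrics$chance)
})

test_that("DCLS kernels preserve mass and collapse to shifts", {
  task <- tiny_task()
  x <- array(0, c(1, 20, 1)); x[1, 5, 1] <- 1
  # sigma -> 0 at an integer position: pure weighted shift
  out <- dcls_forward(x, matrix(0.7), matrix(3), sigma = 1e-4, kernel_len = 10)
  expect_equal(out[1, 8, 1], 0.7, tolerance = 1e-9)
  expect_equal(sum(out), 0.7, tolerance = 1e-9)
  # kernel taps sum to the weight for any position/sigma (incl. boundary)
  for (p in c(0, 1.3, 4.5, 8.9, 9)) {
    out <- dcls_forward(x, matrix(-1.4), matrix(p), sigma = 2, kernel_len = 10)
    expect_equal(sum(out), -1.4, tolerance = 1e-9)
  }
  # inference mode: single tap at round(position)
  outi <- dcls_forward(x, matrix(2), matrix(3.4), sigma = 2, kernel_len = 10,
                       mode = "inference")
  expect_equal(outi[1, 8, 1], 2)
  expect_equal(sum(outi != 0), 1)
  # superposition across synapses
  set.seed(2)
  xs <- array(rbinom(2 * 30 * 2, 1, 0.3), c(2, 30, 2))
  w <- matrix(runif(2), 2, 1); pos <- matrix(c(1.2, 4.7), 2, 1)
  both <- dcls_forward(xs, w, pos, sigma = 1, kernel_len = 8)
  only1 <- dcls_forward(xs, w * c(1, 0), pos, sigma = 1, kernel_len = 8)
  only2 <- dcls_forward(xs, w * c(0, 1), pos, sigma = 1, kernel_len = 8)
  expect_equal(both, only1 + only2, tolerance = 1e-12)
  expect_warning(dcls_forward(x, matrix(1), matrix(20), kernel_len = 10),
                 "clamped")
})

test_that("training-mode DCLS output approaches inference mode as sigma shrinks", {
  set.seed(4)
  x <- array(rbinom(4 * 40 * 3, 1, 0.3), c(4, 40, 3))
  w <- matrix(rnorm(3 * 2), 3, 2)
  pos <- matrix(round(runif(6, 0, 9)), 3, 2)  # integer positions
  tr <- dcls_forward(x, w, pos, sigma = 0.25, kernel_len = 12)
  inf <- dcls_forward(x, w, pos, sigma = 0.25, kernel_len = 12,
                      mode = "inference")
  expect_equal(tr, inf, tolerance = 0.05)
})

test_that("receptive-field export has one weight/delay pair per synapse", {
  fit <- list(weights = matrix(1:6 / 10, 3, 2),
              positions = matrix(c(1.2, 3.8, 2, 0, 5.5, 4), 3, 2),
              config = list(task = task_config(n_psi = 2)))
  rf <- dcls_receptive_fields(fit)
  expect_equal(nrow(rf), 6)
  expect_equal(rf$delay_bins, round(as.vector(fit$positions)))
  expect_equal(rf$weight, as.vector(fit$weights))
  expect_equal(rf$delay_ms, rf$delay_bins * 1)
})
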