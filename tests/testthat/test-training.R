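# Loss construction, gradient correctness, Dale's-law constraints, seeded
# determinism, and evaluation reports.

test_that("cross-entropy loss has the textbook anchors", {
  n <- 12
  x_unif <- matrix(-log(n), 4, n)
  expect_equal(cross_entropy_loss(x_unif, c(0, 3, 7, 11)), log(n))
  x_perfect <- log_softmax(matrix(c(50, rep(0, n - 1)), 1))
  expect_lt(cross_entropy_loss(x_perfect, 0), 1e-10)
  x <- log_softmax(matrix(rnorm(6 * n), 6))
  y <- c(0, 1, 2, 3, 4, 5)
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(cross_entropy_loss(x[perm, ], y[perm]),
               cross_entropy_loss(x, y))
})

test_that("rate regularizer hits its anchor values and is continuous", {
  expect_equal(rate_regularizer(200, r_minus = 100, r_plus = 200,
                                c_reg = 1), 1)   # L_m = 1 at r_plus
  expect_equal(rate_regularizer(100, r_minus = 100, r_plus = 200,
                                c_reg = 1), 0)   # nothing at r_minus
  expect_equal(rate_regularizer(150, r_minus = 100, r_plus = 200,
                                c_reg = 1), 0.25)
  expect_equal(rate_regularizer(50, r_minus = 100, r_plus = 200, c_reg = 1), 0)
  # continuity at r_minus and monotonicity
  r <- seq(90, 110, by = 0.1)
  L <- vapply(r, rate_regularizer, numeric(1), r_minus = 100, r_plus = 200,
              c_reg = 1)
  expect_lt(max(abs(diff(L))), 0.001)
  r2 <- seq(0, 300, by = 0.5)
  L2 <- vapply(r2, rate_regularizer, numeric(1), r_minus = 100,
               r_plus = 200, c_reg = 1)
  expect_true(all(diff(L2) >= 0))
  # array form: counts / trials / duration
  s <- array(0, c(10, 30, 2)); s[, 1:15, 1] <- 1  # neuron 1 at 500 sp/s
  expect_equal(rate_regularizer(s, duration = 0.03, r_minus = 100,
                                r_plus = 200, c_reg = 2),
               2 * ((500 - 100) / 100)^2 / 2)
  expect_error(train_config(r_minus = 200, r_plus = 100), "r_plus")
})

test_that("backprop gradients match finite differences on a toy network", {
  # smooth (surrogate-in-place-of-step) pass: exactly differentiable
  task <- tiny_task()
  b <- spike_batch(8, task, seed = 3)
  X <- b$spikes
  B <- dim(X)[1]; T <- dim(X)[2]; C <- dim(X)[3]
  n_h <- 5
  u <- cpp_runif_stream(C * n_h + n_h * 4, 99)
  Wih <- matrix(u[seq_len(C * n_h)] - 0.5, C, n_h) * 0.8
  Who <- matrix(utils::tail(u, n_h * 4) - 0.5, n_h, 4)
  y <- b$class_true
  lossfn <- function(Wih, Who, grad = FALSE) {
    xm <- matrix(X, B * T, C)
    r <- ipdnet:::cpp_snn_pass(xm %*% Wih, B, T, Who, 0.002, 0.002, 0.001,
                               10, y, 100, 200, log(4), grad, FALSE, TRUE)
    out <- list(loss = r$loss_ce + r$loss_reg)
    if (grad) { out$gih <- crossprod(xm, r$dI); out$gho <- r$dWho }
    out
  }
  an <- lossfn(Wih, Who, grad = TRUE)
  eps <- 1e-6
  check <- function(i, layer) {
    if (layer == "ih") {
      Wp <- Wih; Wp[i] <- Wp[i] + eps; Wm <- Wih; Wm[i] <- Wm[i] - eps
      fd <- (lossfn(Wp, Who)$loss - lossfn(Wm, Who)$loss) / (2 * eps)
      abs(fd - an$gih[i]) / max(abs(fd), 1e-8)
    } else {
      Wp <- Who; Wp[i] <- Wp[i] + eps; Wm <- Who; Wm[i] <- Wm[i] - eps
      fd <- (lossfn(Wih, Wp)$loss - lossfn(Wih, Wm)$loss) / (2 * eps)
      abs(fd - an$gho[i]) / max(abs(fd), 1e-8)
    }
  }
  idx_ih <- round(seq(1, length(Wih), length.out = 6))
  idx_ho <- round(seq(1, length(Who), length.out = 4))
  errs <- c(vapply(idx_ih, check, numeric(1), layer = "ih"),
            vapply(idx_ho, check, numeric(1), layer = "ho"))
  expect_lt(max(errs), 1e-3)
})

test_that("DCLS convolution gradients match finite differences", {
  task <- tiny_task()
  b <- spike_batch(6, task, seed = 17)
  X <- b$spikes
  B <- dim(X)[1]; T <- dim(X)[2]; C <- dim(X)[3]
  xm <- matrix(X, B * T, C)
  n_h <- 3; D <- 8; sigma <- 1.2
  u <- cpp_runif_stream(C * n_h * 2 + n_h * 4, 55)
  w <- matrix(u[seq_len(C * n_h)] - 0.5, C, n_h)
  pos <- matrix(u[C * n_h + seq_len(C * n_h)] * (D - 2) + 0.5, C, n_h)
  Who <- matrix(utils::tail(u, n_h * 4) - 0.5, n_h, 4)
  y <- b$class_true
  lossfn <- function(w, pos, grad = FALSE) {
    I <- ipdnet:::cpp_dcls_conv(xm, B, T, w, pos, sigma, D, FALSE)
    r <- ipdnet:::cpp_snn_pass(I, B, T, Who, 0.002, 0.002, 0.001, 10, y,
                               100, 200, log(4), grad, FALSE, TRUE)
    out <- list(loss = r$loss_ce + r$loss_reg)
    if (grad)
      out$g <- ipdnet:::cpp_dcls_conv_grad(xm, B, T, r$dI, w, pos, sigma, D)
    out
  }
  an <- lossfn(w, pos, grad = TRUE)
  eps <- 1e-5
  errs <- c()
  for (i in round(seq(1, length(w), length.out = 5))) {
    wp <- w; wp[i] <- wp[i] + eps; wm <- w; wm[i] <- wm[i] - eps
    fd <- (lossfn(wp, pos)$loss - lossfn(wm, pos)$loss) / (2 * eps)
    errs <- c(errs, abs(fd - an$g$dw[i]) / max(abs(fd), 1e-7))
    pp <- pos; pp[i] <- pp[i] + eps; pm <- pos; pm[i] <- pm[i] - eps
    fd2 <- (lossfn(w, pp)$loss - lossfn(w, pm)$loss) / (2 * eps)
    errs <- c(errs, abs(fd2 - an$g$dpos[i]) / max(abs(fd2), 1e-7))
  }
  expect_lt(max(errs), 1e-3)
})

test_that("Dale constraint holds across the whole optimization trace", {
  task <- tiny_task()
  cfg <- train_config(n_train = 256, batch_size = 64, epochs = 3, n_h = 4,
                      seed = 5, dale_mode = "balanced")
  res <- train_ipd_net(task, cfg, n_test = 0)
  p <- res$params
  expect_true(all(sign(p$w_ih[p$sign_ih == 1, ]) >= 0))
  expect_true(all(sign(p$w_ih[p$sign_ih == -1, ]) <= 0))
  expect_true(all(sign(p$w_ho[p$sign_ho == 1, ]) >= 0))
  expect_true(all(sign(p$w_ho[p$sign_ho == -1, ]) <= 0))
  # balanced assignment really is half/half
  expect_equal(sum(p$sign_ih == -1), task$n_psi)
  # inhibitory-only inputs: no spikes propagate -> chance accuracy
  cfg_inh <- train_config(n_train = 128, batch_size = 64, epochs = 1, n_h = 4,
                          seed = 5, dale_mode = "inhibitory_only")
  res_inh <- train_ipd_net(task, cfg_inh, n_test = 1000)
  expect_equal(sum(res_inh$metrics$hidden_rates), 0)
  p0 <- 1 / task$n_classes
  expect_lt(abs(res_inh$metrics$accuracy - p0),
            3 * sqrt(p0 * (1 - p0) / 1000))
})

test_that("apply_dale_constraint conforms existing weights", {
  p <- tiny_params()
  pd <- apply_dale_constraint(p, "balanced", seed = 3)
  expect_true(all(pd$w_ih * pd$sign_ih >= 0))
  expect_equal(abs(pd$w_ih), abs(p$w_ih))
})

test_that("training is deterministic given a seed and reduces the loss", {
  task <- tiny_task()
  cfg <- train_config(n_train = 512, batch_size = 64, epochs = 4, n_h = 4,
                      seed = 42)
  r1 <- train_ipd_net(task, cfg, n_test = 500)
  r2 <- train_ipd_net(task, cfg, n_test = 500)
  expect_identical(r1$loss_history, r2$loss_history)
  expect_equal(r1$params$w_ih, r2$params$w_ih, tolerance = 1e-12)
  expect_identical(r1$metrics$confusion, r2$metrics$confusion)
  expect_lt(utils::tail(r1$loss_history, 1), r1$loss_history[1])
  expect_length(r1$loss_history, 4)
})

test_that("evaluation reports are self-consistent", {
  task <- tiny_task()
  p <- tiny_params(task, seed = 2)
  rep <- evaluate_network(p, task, n_test = 600, seed = 9)
  expect_equal(sum(rep$confusion), 600)
  expect_true(all(rowSums(rep$confusion) ==
                    table(factor(ipd_to_class(sample_ipds(600, task, seed = 9),
                                              task$n_classes),
                                 levels = 0:(task$n_classes - 1)))))
  expect_gte(rep$accuracy, 0); expect_lte(rep$accuracy, 1)
  # a perfect oracle classifier's MAE is the mean within-bin distance to the
  # midpoint: width/4 (brute-force expectation over the uniform draw)
  alpha <- sample_ipds(20000, task, seed = 77)
  oracle_mae <- mean(abs(class_to_midpoint(ipd_to_class(alpha, 12), 12) -
                           alpha)) * 180 / pi
  expect_equal(oracle_mae, (180 / 12) / 4, tolerance = 0.02)
  # the trained-model MAE can never beat the oracle floor
  expect_gte(rep$mae_deg, 0)
})

test_that("the printed parameter-count formula is reproduced", {
  expect_identical(count_full_model_params(100, 8, 12), 896L)
  expect_identical(count_full_model_params(10, 4, 4), 56L)
})
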