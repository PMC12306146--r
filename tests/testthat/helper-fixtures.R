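# Shared fixtures: small task/network configurations built in code, and a
# lazily trained base model reused by the heavier analysis checks.

tiny_task <- function(...) {
  task_config(n_psi = 10, n_classes = 4, duration = 0.03, ...)
}

tiny_params <- function(task = tiny_task(), n_h = 3, seed = 11) {
  init_network(task, n_h = n_h, seed = seed)
}

# Train-once cache for the base model (study conditions); heavier tests that
# need a trained network share it. The 100-epoch model is optimized in two
# stages (30 epochs, then 70 more from that checkpoint) so the reduced-run
# behaviour and the fully trained behaviour come from one optimization trace.
.fixture_env <- new.env(parent = emptyenv())

base_model_30ep <- function() {
  if (is.null(.fixture_env$base30)) {
    task <- task_config()
    cfg <- train_config(epochs = 30, seed = 20240703)
    .fixture_env$base30 <- train_ipd_net(task, cfg, n_test = 4096)
  }
  .fixture_env$base30
}

base_model <- function() {
  if (is.null(.fixture_env$base)) {
    m30 <- base_model_30ep()
    cfg <- train_config(epochs = 70, seed = 20240704)
    full <- train_ipd_net(m30$task, cfg, init = m30$params, n_test = 4096)
    full$loss_history <- c(m30$loss_history, full$loss_history)
    .fixture_env$base <- full
  }
  .fixture_env$base
}
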