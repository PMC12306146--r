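# Configuration files, run serialization with checksums, and report
# generation. Runs are stored as plain JSON (full double precision) with an
# md5 manifest, so artifacts are text, diffable, and verifiable.

config_schema <- list(
  task = c("f", "n_psi", "n_classes", "rate_max", "duration", "dt",
           "ipd_min", "ipd_max"),
  train = c("n_train", "batch_size", "epochs", "learning_rate", "r_minus",
            "r_plus", "c_reg", "n_h", "tau_h", "tau_o", "beta", "seed",
            "dale_mode", "fresh_samples"),
  ddl = c("n_classes", "angle_min", "angle_step", "f", "rate_max",
          "duration", "dt", "tau_m", "pad", "epochs", "n_train",
          "batch_size", "learning_rate", "logit_scale", "discrete_ipds",
          "seed"),
  dcls = c("n_h", "kernel_len", "sigma0", "sigma_end", "epochs", "n_train",
           "batch_size", "lr_w", "lr_pos", "r_minus", "r_plus", "c_reg",
           "seed"))

#' Load and validate a YAML configuration file
#'
#' Sections `task`, `train`, `ddl`, `dcls` are recognized; unknown sections
#' or keys are rejected, defaults are filled by the corresponding
#' constructors, and constraint violations surface with the offending key.
#'
#' @param path YAML file.
#' @param quiet suppress the echo of filled defaults.
#' @return list with validated `task`, `train`, `ddl`, `dcls` entries (only
#'   those whose constructors apply).
#' @export
load_config <- function(path, quiet = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(config_schema))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), config_schema[[sec]])
    if (length(bad))
      stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "))
  }
  out <- list()
  out$task <- do.call(task_config, raw$task %||% list())
  if (!is.null(raw$train)) out$train <- do.call(train_config, raw$train)
  if (!is.null(raw$ddl)) out$ddl <- do.call(ddl_config, raw$ddl)
  if (!is.null(raw$dcls)) {
    args <- raw$dcls
    args$task <- out$task
    out$dcls <- do.call(dcls_config, args)
  }
  if (!quiet)
    message("config loaded from ", path, "; sections: ",
            paste(names(out), collapse = ", "))
  out
}

#' Write a configuration back to YAML
#'
#' Inverse of [load_config()]: `load -> dump -> load` is idempotent.
#'
#' @param cfg list as returned by [load_config()].
#' @param path output YAML file.
#' @export
dump_config <- function(cfg, path) {
  strip <- function(x, keep)
    x[intersect(keep, names(x))]
  out <- list()
  if (!is.null(cfg$task)) out$task <- strip(cfg$task, config_schema$task)
  if (!is.null(cfg$train)) out$train <- strip(cfg$train, config_schema$train)
  if (!is.null(cfg$ddl)) out$ddl <- strip(cfg$ddl, config_schema$ddl)
  if (!is.null(cfg$dcls)) out$dcls <- strip(cfg$dcls, config_schema$dcls)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

run_payload <- function(result) {
  p <- result$params
  list(
    format = "ipdnet-run-1",
    version = as.character(utils::packageVersion("ipdnet")),
    task = unclass(result$task),
    config = unclass(result$config),
    params = list(w_ih = p$w_ih, w_ho = p$w_ho, tau_h = p$tau_h,
                  tau_o = p$tau_o, beta = p$beta,
                  sign_ih = p$sign_ih, sign_ho = p$sign_ho),
    loss_history = result$loss_history,
    metrics = if (is.null(result$metrics)) NULL else
      unclass(result$metrics))
}

#' Save / load a training run
#'
#' The run (trained parameters, loss history, metrics, configs) is written
#' as JSON at full double precision, together with a `<path>.manifest.json`
#' carrying the file's md5 checksum and a timestamp. [load_run()] verifies
#' the checksum and refuses corrupted files unless `force = TRUE`; the
#' round trip preserves all tensors bitwise.
#'
#' @param result a `train_result` from [train_ipd_net()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
save_run <- function(result, path) {
  stopifnot(inherits(result, "train_result"))
  # 17 significant digits: doubles survive the round trip bitwise
  jsonlite::write_json(run_payload(result), path, digits = I(17),
                       auto_unbox = TRUE, null = "null", pretty = FALSE)
  manifest <- list(file = basename(path),
                   md5 = unname(tools::md5sum(path)),
                   created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_run
#' @param path JSON file written by [save_run()].
#' @param force skip the checksum verification.
#' @return a `train_result`.
#' @export
load_run <- function(path, force = FALSE) {
  if (!file.exists(path)) stop("run file not found: ", path)
  mpath <- paste0(path, ".manifest.json")
  if (file.exists(mpath) && !force) {
    manifest <- jsonlite::read_json(mpath)
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, manifest$md5))
      stop("checksum mismatch for ", path,
           " (file corrupt or edited); use force = TRUE to load anyway")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$format, "ipdnet-run-1"))
    stop("not an ipdnet run file: ", path)
  for (k in c("task", "params", "loss_history"))
    if (is.null(raw[[k]])) stop("run file is missing dataset '", k, "'")
  task <- do.call(task_config, raw$task[c("f", "n_psi", "n_classes",
                                          "rate_max", "duration", "dt",
                                          "ipd_min", "ipd_max")])
  pr <- raw$params
  params <- network_params(pr$w_ih, pr$w_ho, tau_h = pr$tau_h,
                           tau_o = pr$tau_o, beta = pr$beta,
                           sign_ih = pr$sign_ih, sign_ho = pr$sign_ho)
  metrics <- raw$metrics
  if (!is.null(metrics)) {
    metrics$confusion <- as.matrix(metrics$confusion)
    class(metrics) <- "eval_report"
  }
  structure(list(params = params, loss_history = raw$loss_history,
                 metrics = metrics, task = task, config = raw$config),
            class = "train_result")
}

#' Write a metrics report for a run
#'
#' Emits `report.json` (accuracy, MAE in degrees, hidden firing rates, loss
#' history summary), `confusion.csv`, and optionally simple figures (input
#' raster, tuning curves, weight matrices) as PNG. Regenerating the report
#' from the same run is byte-identical.
#'
#' @param run a `train_result`.
#' @param dir output directory (created if needed).
#' @param analysis optional `tuning_curves` object to include fit summaries.
#' @param figures also draw PNG figures.
#' @return path of `report.json`, invisibly.
#' @export
make_report <- function(run, dir, analysis = NULL, figures = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- run$metrics
  if (is.null(m)) stop("run has no evaluation metrics; run evaluate first")
  rep <- list(accuracy = m$accuracy, mae_deg = m$mae_deg,
              hidden_rates = m$hidden_rates, n_test = m$n_test,
              first_epoch_loss = run$loss_history[1],
              final_epoch_loss = utils::tail(run$loss_history, 1))
  if (!is.null(analysis)) {
    ord <- reorder_hidden_by_worst_delay(analysis)
    rep$hidden_order <- ord
    rep$silent_hidden <- which(analysis$silent)
  }
  jpath <- file.path(dir, "report.json")
  jsonlite::write_json(rep, jpath, digits = NA, auto_unbox = TRUE)
  write.csv(m$confusion, file.path(dir, "confusion.csv"))
  if (figures) {
    grDevices::png(file.path(dir, "loss.png"), 600, 400)
    graphics::plot(run$loss_history, type = "l", xlab = "epoch",
                   ylab = "training loss")
    grDevices::dev.off()
    if (!is.null(analysis)) {
      grDevices::png(file.path(dir, "tuning_hidden.png"), 800, 500)
      graphics::matplot(analysis$ipd_grid, analysis$hidden, type = "l",
                        lty = 1, xlab = "IPD (rad)",
                        ylab = "normalized rate")
      grDevices::dev.off()
    }
  }
  invisible(jpath)
}
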