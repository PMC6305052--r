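#' End-to-end run configuration
#'
#' Parameters for [run_end_to_end()]: simulate (or load) a dataset, run
#' the preprocessing pipeline, rasterize (or extract sequences), train a
#' neural classifier on a 60/20/20 stratified split, and run the
#' feature-table baselines under 5-fold cross-validation.
#'
#' The neural defaults are a scale-rehearsal setting: MKNet-A with
#' reduced filter widths (4, 8, 16) trained on images mean-pooled by
#' (4, 16) to 30 x 150, which preserves the curve's vertical position and
#' shape cues while keeping a desk-scale run in seconds. At native
#' geometry set `downscale = c(1, 1)` and the full filter complement.
#'
#' @param n number of simulated records.
#' @param class_balance fraction of abnormal records.
#' @param seed master seed; every stochastic stage derives from it.
#' @param arch `"mknet-a"`, `"mknet-b"`, `"mknet-c"` or `"mkrnn"`.
#' @param filters MKNet filters per block.
#' @param epochs,batch_size,learning_rate,optimizer training parameters.
#' @param augmentation random horizontal-shift augmentation during
#'   training.
#' @param downscale image mean-pooling factors (rows, cols).
#' @param subsample sequence decimation factor for MKRNN.
#' @param qc a [qc_config()].
#' @param params0,params1 per-class [sim_params()].
#' @return list of class `"run_config"`.
#' @export
run_config <- function(n = 400, class_balance = 0.5, seed = 1L,
                       arch = c("mknet-a", "mknet-b", "mknet-c", "mkrnn"),
                       filters = c(4L, 8L, 16L), epochs = 8,
                       batch_size = 16, learning_rate = 2e-3,
                       optimizer = "rmsprop", augmentation = FALSE,
                       downscale = c(4L, 16L), subsample = 8L,
                       qc = qc_config(),
                       params0 = sim_params(0), params1 = sim_params(1)) {
  structure(list(n = n, class_balance = class_balance, seed = as.integer(seed),
                 arch = match.arg(arch), filters = filters,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, optimizer = optimizer,
                 augmentation = augmentation,
                 downscale = as.integer(rep_len(downscale, 2)),
                 subsample = as.integer(subsample), qc = qc,
                 params0 = params0, params1 = params1),
            class = "run_config")
}

#' Run the full pipeline: simulate, preprocess, train, evaluate
#'
#' Stages: (1) simulate `cfg$n` labeled records plus their feature table;
#' (2) preprocess every record, separating rejected records (QC reports
#' kept); (3) split the survivors 60/20/20 (stratified), rasterize to
#' clipped chart images (MKNet) or keep cleaned sequences (MKRNN), and
#' train with per-epoch validation; (4) score the held-out test split
#' (metrics + ROC); (5) run the SVM and random-forest baselines on the
#' feature table under stratified 5-fold cross-validation. Fully
#' reproducible from `cfg` (all stages derive their seeds from
#' `cfg$seed`).
#'
#' @param cfg a [run_config()].
#' @param dataset optional pre-built `fhr_dataset` (skips simulation).
#' @param verbose print per-stage summaries.
#' @return list of class `"ctg_run"`: `counts` (generated, rejected,
#'   clean, train/val/test sizes), `model` (the fitted `ctg_model`),
#'   `test_metrics`, `test_roc`, `svm_report`, `rf_report`, `qc_reports`,
#'   and the resolved `cfg`.
#' @export
run_end_to_end <- function(cfg = run_config(), dataset = NULL,
                           verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  ds <- dataset %||% simulate_dataset(cfg$n, cfg$class_balance,
                                      cfg$params0, cfg$params1,
                                      seed = cfg$seed)
  say("simulated %d records (%d abnormal)", length(ds$records),
      sum(ds$labels == 1))

  cleaned <- list(); clean_labels <- integer(); qc_reports <- list()
  rejected <- 0L
  for (r in ds$records) {
    out <- run_pipeline(r, cfg$qc)
    if (inherits(out, "qc_rejection")) {
      rejected <- rejected + 1L
      qc_reports[[length(qc_reports) + 1L]] <- out$report
    } else {
      cleaned[[length(cleaned) + 1L]] <- out
      clean_labels <- c(clean_labels, r$label)
      qc_reports[[length(qc_reports) + 1L]] <-
        scan_missing(r, cfg$qc)
    }
  }
  say("preprocessing: %d clean, %d rejected", length(cleaned), rejected)
  if (length(cleaned) < 10 || length(unique(clean_labels)) < 2) {
    stop("too few clean records survive QC to train on")
  }

  sp <- split_dataset(clean_labels, seed = cfg$seed)
  is_seq <- cfg$arch == "mkrnn"
  if (is_seq) {
    inputs <- lapply(cleaned, `[[`, "values")
    spec <- build_mkrnn(units = 32L,
                        timesteps = length(inputs[[1]]) %/% cfg$subsample +
                          as.integer(length(inputs[[1]]) %% cfg$subsample > 0))
  } else {
    inputs <- lapply(cleaned, function(cs) {
      render_image(clip_range(cs$values), source_id = cs$source_id)
    })
    variant <- toupper(sub("mknet-", "", cfg$arch))
    spec <- build_mknet(variant, filters = cfg$filters)
  }
  tcfg <- train_config(epochs = cfg$epochs, batch_size = cfg$batch_size,
                       optimizer = cfg$optimizer,
                       learning_rate = cfg$learning_rate,
                       augmentation = cfg$augmentation,
                       downscale = cfg$downscale, subsample = cfg$subsample,
                       seed = cfg$seed)
  model <- train(spec, inputs[sp$train], clean_labels[sp$train], tcfg,
                 validation = list(x = inputs[sp$validation],
                                   y = clean_labels[sp$validation]))
  say("trained %s: final val acc %.3f", spec$name,
      utils::tail(model$history$val_acc, 1))

  probs <- predict_proba(model, inputs[sp$test])[, "1"]
  test_metrics <- compute_metrics(clean_labels[sp$test],
                                  as.integer(probs > 0.5))
  test_roc <- roc_curve_auc(clean_labels[sp$test], probs)
  say("test accuracy %.3f, AUC %.3f", test_metrics$accuracy, test_roc$auc)

  feats <- ds$features
  labels <- ds$labels
  svm_report <- evaluate_model(
    function(xx, yy) suppressWarnings(fit_svm(xx, yy)),
    function(m, xx) predict(m, xx, type = "score"),
    feats, labels, protocol = "kfold", k = 5, seed = cfg$seed)
  rf_report <- evaluate_model(
    function(xx, yy) fit_rf(xx, yy, seed = cfg$seed),
    function(m, xx) predict(m, xx, type = "score"),
    feats, labels, protocol = "kfold", k = 5, seed = cfg$seed)
  say("baselines: SVM acc %.3f (AUC %.3f), RF acc %.3f (AUC %.3f)",
      svm_report$accuracy, svm_report$mean_auc,
      rf_report$accuracy, rf_report$mean_auc)

  structure(list(
    counts = list(generated = length(ds$records), rejected = rejected,
                  clean = length(cleaned), train = length(sp$train),
                  validation = length(sp$validation),
                  test = length(sp$test)),
    model = model, test_metrics = test_metrics, test_roc = test_roc,
    svm_report = svm_report, rf_report = rf_report,
    qc_reports = qc_reports, cfg = cfg, dataset = ds
  ), class = "ctg_run")
}

#' @export
print.ctg_run <- function(x, ...) {
  co <- x$counts
  cat(sprintf("End-to-end run (%s): %d generated, %d rejected, %d clean (%d/%d/%d train/val/test)\n",
              x$cfg$arch, co$generated, co$rejected, co$clean,
              co$train, co$validation, co$test))
  cat(sprintf("  %s test accuracy %.4f, AUC %.4f\n", x$model$spec$name,
              x$test_metrics$accuracy, x$test_roc$auc))
  cat(sprintf("  SVM 5-fold accuracy %.4f, mean AUC %.4f\n",
              x$svm_report$accuracy, x$svm_report$mean_auc))
  cat(sprintf("  RF  5-fold accuracy %.4f, mean AUC %.4f\n",
              x$rf_report$accuracy, x$rf_report$mean_auc))
  invisible(x)
}
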