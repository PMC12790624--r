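# Stratified k-fold cross-validation. Fold assignment is stratified by class
# (required for small positive sets) and seeded from the training config, so
# identical seeds give identical folds, fits and metrics.

#' Stratified fold assignment
#'
#' @param labels a `label_set`.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector over universe indices: fold id for labeled genes,
#'   NA for unlabeled.
#' @export
stratified_folds <- function(labels, k, seed) {
  npos <- length(labels$positives); nneg <- length(labels$negatives)
  if (npos < k || nneg < k) {
    stop(sprintf(paste0("class with fewer members (%d positives, %d ",
                        "negatives) than folds (%d); use a smaller k"),
                 npos, nneg, k), call. = FALSE)
  }
  set.seed(make_seed(seed, 2L))
  n <- npos + nneg + length(labels$unlabeled)
  fold <- rep(NA_integer_, n)
  fold[labels$positives] <- sample(rep_len(seq_len(k), npos))
  fold[labels$negatives] <- sample(rep_len(seq_len(k), nneg))
  fold
}

#' Cross-validated evaluation
#'
#' Stratified k-fold cross-validation (reference protocol: k = 10). Per fold,
#' the model is trained on the other k-1 parts of the labeled genes (all
#' genes always participate in message passing — transductive), the held-out
#' labeled genes are scored, and AUROC / AUPRC / F1 at the configured
#' threshold are computed. Every labeled gene is scored exactly once
#' out-of-fold. Optionally a final model is refit on all labeled genes for
#' downstream ranking of unlabeled genes.
#'
#' @param dataset a `driver_dataset`.
#' @param model a [model_config()].
#' @param training a [train_config()].
#' @param k number of folds (>= 2).
#' @param ablation an [ablation_spec()] or NULL.
#' @param final_model also refit on all labeled genes (default TRUE).
#' @param verbose print per-fold progress.
#' @return an object of class `cv_driver_fusion`: per-fold metrics
#'   (`$folds`), aggregate mean/sd (`$summary`), out-of-fold scores
#'   (`$oof_scores`), fold assignment, and optionally `$final` (the
#'   full-data `driver_fusion` fit).
#' @export
cross_validate <- function(dataset, model = model_config(),
                           training = train_config(), k = 10L,
                           ablation = NULL, final_model = TRUE,
                           verbose = FALSE) {
  stopifnot(k >= 2L)
  prep <- prepare_inputs(dataset, model, ablation)
  fold <- stratified_folds(dataset$labels, k, training$seed)
  labeled <- which(!is.na(fold))
  oof <- rep(NA_real_, prep$n)
  folds <- data.frame(fold = seq_len(k), auroc = NA_real_,
                      auprc = NA_real_, f1 = NA_real_)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- setdiff(labeled, test_idx)
    tcfg <- training
    tcfg$seed <- make_seed(training$seed, 100L + f)
    fit <- driver_fusion(dataset, model, tcfg, ablation,
                         train_idx = train_idx, prep = prep)
    oof[test_idx] <- fit$scores[test_idx]
    met <- compute_metrics(fit$scores[test_idx], prep$y[test_idx],
                           training$threshold)
    folds[f, c("auroc", "auprc", "f1")] <- met
    if (verbose) {
      message(sprintf("fold %2d/%d  AUROC %.3f  AUPRC %.3f  F1 %.3f",
                      f, k, met["auroc"], met["auprc"], met["f1"]))
    }
  }
  summary_tab <- data.frame(
    metric = c("auroc", "auprc", "f1"),
    mean = colMeans(folds[, c("auroc", "auprc", "f1")]),
    sd = apply(folds[, c("auroc", "auprc", "f1")], 2L, stats::sd))
  rownames(summary_tab) <- NULL
  final <- NULL
  if (final_model) {
    tcfg <- training
    tcfg$seed <- make_seed(training$seed, 99L)
    final <- driver_fusion(dataset, model, tcfg, ablation, prep = prep)
  }
  names(oof) <- prep$symbols
  structure(list(folds = folds, summary = summary_tab, oof_scores = oof,
                 fold_assignment = fold, final = final, k = k,
                 model = model, training = training, ablation = ablation),
            class = "cv_driver_fusion")
}

#' @export
print.cv_driver_fusion <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$k))
  for (r in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-6s %.3f +/- %.3f\n", toupper(x$summary$metric[r]),
                x$summary$mean[r], x$summary$sd[r]))
  }
  invisible(x)
}

#' @export
summary.cv_driver_fusion <- function(object, ...) {
  print(object)
  cat("per-fold metrics:\n")
  print(object$folds, row.names = FALSE, digits = 3L)
  invisible(object)
}
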