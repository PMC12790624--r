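# Model assembly and training.
#
# driver_fusion() is the fitting function: it wires the per-view GCN
# encoders, attention fusion, gene-set attention, frozen structural
# encodings and the edge-biased transformer into one computation graph on
# the autodiff tape, and trains all learnable parameters end-to-end with
# AdamW under focal loss, masked to the labeled training genes (unlabeled
# genes participate in message passing and attention but not the loss —
# standard transductive practice).

#' Training configuration
#'
#' Reference settings: AdamW with weight decay 1e-4; focal loss alpha = 1.0,
#' gamma = 1.5; pan-cancer preset 30 epochs at learning rate 1e-3,
#' cancer-specific preset 50 epochs at 1e-4. One full-batch gradient step per
#' epoch (transductive full-graph training).
#'
#' @param learning_rate AdamW learning rate (> 0).
#' @param weight_decay decoupled weight decay.
#' @param epochs full-batch training epochs.
#' @param focal_alpha,focal_gamma focal-loss parameters.
#' @param seed master seed for initialization, dropout and fold assignment.
#' @param threshold classification cutoff for F1 reporting.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-4,
                         epochs = 30L, focal_alpha = 1.0, focal_gamma = 1.5,
                         seed = 1L, threshold = 0.5) {
  stopifnot(learning_rate > 0, focal_gamma >= 0, threshold > 0, threshold < 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), focal_alpha = focal_alpha,
                 focal_gamma = focal_gamma, seed = as.integer(seed),
                 threshold = threshold),
            class = "train_config")
}

#' Hyperparameter presets
#'
#' `"pan_cancer"`: L = 3, H = 4, dropout 0.1, learning rate 1e-3, 30 epochs.
#' `"cancer_specific"`: L = 2, H = 2, dropout 0.2, learning rate 1e-4,
#' 50 epochs. Both use embedding width `d` (reference 128; pass a smaller
#' value for small graphs).
#'
#' @param preset preset name.
#' @param d embedding width override.
#' @param seed training seed.
#' @return list with `model` ([model_config()]) and `training`
#'   ([train_config()]).
#' @export
df_preset <- function(preset = c("pan_cancer", "cancer_specific"),
                      d = 128L, seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "pan_cancer") {
    list(model = model_config(d = d, n_layers = 3L, n_heads = 4L,
                              dropout = 0.1),
         training = train_config(learning_rate = 1e-3, epochs = 30L,
                                 seed = seed))
  } else {
    list(model = model_config(d = d, n_layers = 2L, n_heads = 2L,
                              dropout = 0.2),
         training = train_config(learning_rate = 1e-4, epochs = 50L,
                                 seed = seed))
  }
}

#' Ablation switches
#'
#' Subsets of the six component switches: `PE` (random-walk positional
#' encoding), `CE` (PageRank centrality), `GSA` (gene-set attention), `EAA`
#' (edge-attention bias), `NFE` (multi-view network feature encoder / fused
#' embedding), `IF` (raw multi-omics input features). Disabling a switch
#' zeroes the corresponding input block or bias and removes its parameters.
#'
#' @param disable character vector of switches to disable.
#' @return an `ablation_spec`.
#' @export
ablation_spec <- function(disable = character()) {
  valid <- c("PE", "CE", "GSA", "EAA", "NFE", "IF")
  disable <- unique(toupper(disable))
  bad <- setdiff(disable, valid)
  if (length(bad) > 0L) {
    stop("unknown ablation switch(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(disable, class = "ablation_spec")
}

ablated <- function(ablation, switch) {
  !is.null(ablation) && switch %in% unclass(ablation)
}

make_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 65537) %% 2147483647)
}

## ---- parameters ------------------------------------------------------------

fan_in_uniform <- function(nr, nc, fan_in = nr) {
  lim <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Nested parameter list. Dimensions: F raw features, S gene sets, k_in
# assembled input width, from the model config and ablation switches.
init_parameters <- function(mcfg, n_features, n_sets, k_in, ablation) {
  d <- mcfg$d
  p <- list()
  if (!ablated(ablation, "NFE")) {
    p$views <- lapply(stats::setNames(MODALITIES, MODALITIES), function(m) {
      list(W1 = fan_in_uniform(n_features, d),
           W2 = fan_in_uniform(d, d))
    })
    p$a <- fan_in_uniform(d, 1L)
  }
  if (!ablated(ablation, "GSA") && n_sets > 0L) {
    p$W_attn <- fan_in_uniform(n_sets, n_sets)
    p$E_set <- fan_in_uniform(n_sets, d)
  }
  p$W_proj <- fan_in_uniform(d, k_in, fan_in = k_in)
  p$b_proj <- matrix(0, d, 1L)
  if (!ablated(ablation, "EAA")) {
    p$W_edge <- fan_in_uniform(mcfg$n_heads, 2L, fan_in = 2L)
    p$b_edge <- matrix(0, mcfg$n_heads, 1L)
  }
  p$layers <- lapply(seq_len(mcfg$n_layers), function(l) {
    list(Wq = fan_in_uniform(d, d), bq = matrix(0, d, 1L),
         Wk = fan_in_uniform(d, d), bk = matrix(0, d, 1L),
         Wv = fan_in_uniform(d, d), bv = matrix(0, d, 1L),
         Wo = fan_in_uniform(d, d), bo = matrix(0, d, 1L),
         Wf1 = fan_in_uniform(d, 4L * d), bf1 = matrix(0, 4L * d, 1L),
         Wf2 = fan_in_uniform(4L * d, d), bf2 = matrix(0, d, 1L),
         g1 = matrix(1, d, 1L), b1 = matrix(0, d, 1L),
         g2 = matrix(1, d, 1L), b2 = matrix(0, d, 1L))
  })
  names(p$layers) <- paste0("L", seq_len(mcfg$n_layers))
  p$w <- fan_in_uniform(d, 1L)
  p$b <- matrix(0, 1L, 1L)
  p
}

# mirror a nested parameter list into tape parameter nodes
params_to_nodes <- function(tape, params) {
  rec <- function(x) {
    if (is.matrix(x)) tp_param(tape, x) else lapply(x, rec)
  }
  rec(params)
}

# pull gradients out of the node mirror (zeros where untouched)
collect_grads <- function(nodes) {
  rec <- function(x) {
    if (is.environment(x)) {
      if (is.null(x$grad)) matrix(0, nrow(x$value), ncol(x$value)) else x$grad
    } else lapply(x, rec)
  }
  rec(nodes)
}

zeros_like <- function(params) {
  rec <- function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else lapply(x, rec)
  }
  rec(params)
}

# one decoupled-weight-decay Adam step over the whole nested structure
adamw_update <- function(p, g, m, v, lr, wd, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.matrix(p)) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- p - lr * mhat / (sqrt(vhat) + eps) - lr * wd * p
    return(list(p = p, m = m, v = v))
  }
  for (nm in names(p)) {
    res <- adamw_update(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, wd, t,
                        beta1, beta2, eps)
    p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
  }
  list(p = p, m = m, v = v)
}

## ---- forward graph ---------------------------------------------------------

# precomputations shared by every epoch and every CV fold (transductive:
# the graph, features, gene sets and frozen encodings never change)
prepare_inputs <- function(dataset, mcfg, ablation = NULL) {
  n <- length(dataset$graph$universe)
  if (n > mcfg$attention_cap) {
    stop(sprintf(paste0("full-graph attention over %d nodes exceeds the cap ",
                        "(%d); raise attention_cap in model_config() if you ",
                        "have the memory for an N x N attention matrix"),
                 n, mcfg$attention_cap), call. = FALSE)
  }
  d_rw <- if (is.null(mcfg$d_rw)) min(mcfg$d, n - 1L) else
    min(mcfg$d_rw, n - 1L)
  Ahat <- lapply(dataset$graph$views, function(v) {
    normalized_adjacency(v, n, weighted = mcfg$weighted_messages,
                         normalization = mcfg$normalization)
  })
  enc <- structural_encoding(dataset, d_rw)
  M <- if (is.null(dataset$gene_sets)) NULL else dataset$gene_sets$membership
  y <- rep(NA_real_, n)
  y[dataset$labels$positives] <- 1
  y[dataset$labels$negatives] <- 0
  list(n = n, d_rw = d_rw, X = dataset$features, Ahat = Ahat, M = M,
       e_rw = enc$e_rw, e_pr = enc$e_pr,
       edge_data = edge_descriptor_data(dataset$graph), y = y,
       symbols = as.character(dataset$graph$universe))
}

# build the full forward graph; returns nodes of interest
df_forward <- function(tape, prep, pn, mcfg, ablation, training) {
  n <- prep$n; d <- mcfg$d
  zero_block <- function(w) tp_const(tape, matrix(0, n, w))

  x_node <- if (ablated(ablation, "IF")) zero_block(ncol(prep$X)) else
    tp_const(tape, prep$X)

  alpha <- NULL
  if (ablated(ablation, "NFE")) {
    zf <- zero_block(d)
  } else {
    Xc <- tp_const(tape, prep$X)
    z_nodes <- lapply(MODALITIES, function(m) {
      tape_gcn(tape, prep$Ahat[[m]], Xc, pn$views[[m]]$W1, pn$views[[m]]$W2)
    })
    fus <- tape_fusion(tape, z_nodes, pn$a)
    zf <- fus$z_fusion
    alpha <- fus$alpha
  }

  if (ablated(ablation, "GSA") || is.null(prep$M)) {
    eg <- zero_block(d)
  } else {
    gs <- tape_geneset(tape, tp_const(tape, prep$M), pn$W_attn, pn$E_set)
    eg <- gs$E_gene
  }

  e_rw <- if (ablated(ablation, "PE")) matrix(0, n, prep$d_rw) else prep$e_rw
  e_pr <- if (ablated(ablation, "CE")) matrix(0, n, 1L) else prep$e_pr
  struct_node <- tp_const(tape, structural_concat(e_rw, e_pr))

  h_in <- tp_cbind(tape, list(x_node, zf, eg, struct_node))
  H0 <- tp_add_rowvec(tape,
                      tp_matmul(tape, h_in, tp_transpose(tape, pn$W_proj)),
                      pn$b_proj)

  B_heads <- if (ablated(ablation, "EAA")) NULL else
    lapply(seq_len(mcfg$n_heads), function(h) {
      tp_edge_bias_head(tape, pn$W_edge, pn$b_edge, h, prep$edge_data, n)
    })

  node <- H0
  for (l in seq_len(mcfg$n_layers)) {
    node <- tape_transformer_layer(tape, node, pn$layers[[l]], B_heads,
                                   mcfg, training)$H
  }
  logits <- tp_add_rowvec(tape, tp_matmul(tape, node, pn$w), pn$b)
  list(logits = logits, alpha = alpha, HL = node)
}

## ---- fitting ---------------------------------------------------------------

#' Fit the multi-view graph transformer
#'
#' Trains all learnable parameters (per-view GCN weights, fusion attention
#' vector, gene-set attention and embedding table, input projection,
#' edge-bias projection, transformer stack, output head) end-to-end with
#' AdamW under focal loss over the labeled training genes. Training is
#' full-graph and transductive; one gradient step per epoch. Fully seeded:
#' the same dataset, configuration and seed reproduce the fit bit-for-bit.
#'
#' @param dataset a `driver_dataset`.
#' @param model a [model_config()].
#' @param training a [train_config()].
#' @param ablation an [ablation_spec()] or NULL.
#' @param train_idx universe indices of labeled genes to train on (defaults
#'   to all labeled genes; cross-validation passes fold complements).
#' @param prep precomputed [prepare_inputs()] result, reused across CV folds.
#' @param verbose print the loss each epoch.
#' @return an object of class `driver_fusion` with components `scores`
#'   (named per-gene probabilities), `alpha` (per-gene view-attention
#'   weights), `params`, `history`, and the configurations.
#' @seealso [predict.driver_fusion()], [cross_validate()],
#'   [attention_report()], [stratify_scores()]
#' @export
driver_fusion <- function(dataset, model = model_config(),
                          training = train_config(), ablation = NULL,
                          train_idx = NULL, prep = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "driver_dataset"),
            inherits(model, "model_config"),
            inherits(training, "train_config"))
  if (!is.null(ablation)) ablation <- ablation_spec(unclass(ablation))
  if (is.null(prep)) prep <- prepare_inputs(dataset, model, ablation)
  labeled <- which(!is.na(prep$y))
  if (is.null(train_idx)) train_idx <- labeled
  train_idx <- sort(intersect(train_idx, labeled))
  yt <- prep$y[train_idx]
  if (length(unique(yt)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }

  set.seed(make_seed(training$seed, 1L))
  n_sets <- if (is.null(prep$M)) 0L else ncol(prep$M)
  k_in <- ncol(prep$X) + 2L * model$d + prep$d_rw + 1L
  params <- init_parameters(model, ncol(prep$X), n_sets, k_in, ablation)
  mstate <- zeros_like(params)
  vstate <- zeros_like(params)

  history <- data.frame(epoch = seq_len(training$epochs),
                        loss = NA_real_)
  for (epoch in seq_len(training$epochs)) {
    tape <- new_tape()
    pn <- params_to_nodes(tape, params)
    fw <- df_forward(tape, prep, pn, model, ablation, training = TRUE)
    loss <- tp_focal_loss(tape, fw$logits, prep$y, train_idx,
                          training$focal_alpha, training$focal_gamma)
    tp_backward(tape, loss)
    grads <- collect_grads(pn)
    upd <- adamw_update(params, grads, mstate, vstate,
                        training$learning_rate, training$weight_decay, epoch)
    params <- upd$p; mstate <- upd$m; vstate <- upd$v
    history$loss[epoch] <- tp_value(loss)
    if (verbose) {
      message(sprintf("epoch %3d  focal loss %.6f", epoch, tp_value(loss)))
    }
  }

  # final deterministic (eval-mode) pass
  tape <- new_tape()
  pn <- params_to_nodes(tape, params)
  fw <- df_forward(tape, prep, pn, model, ablation, training = FALSE)
  scores <- as.vector(1 / (1 + exp(-tp_value(fw$logits))))
  names(scores) <- prep$symbols
  alpha <- if (is.null(fw$alpha)) NULL else {
    a <- tp_value(fw$alpha); dimnames(a) <- list(prep$symbols, MODALITIES); a
  }

  structure(list(scores = scores, alpha = alpha, params = params,
                 history = history, model = model, training = training,
                 ablation = ablation, train_idx = train_idx,
                 labels = dataset$labels, prep = prep,
                 universe = dataset$graph$universe,
                 n_parameters = sum(unlist(lapply(
                   flatten_params(params), length)))),
            class = "driver_fusion")
}

flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
    if (is.matrix(x[[nm]])) out[[key]] <- x[[nm]]
    else out <- c(out, flatten_params(x[[nm]], key))
  }
  out
}

#' Edge-attention bias of a fitted model
#'
#' Materializes the per-head bias matrices under the fitted parameters; under
#' the `EAA` ablation this is identically zero.
#'
#' @param object a fitted `driver_fusion`.
#' @return list of H N x N matrices.
#' @export
edge_bias <- function(object) {
  stopifnot(inherits(object, "driver_fusion"))
  n <- object$prep$n
  if (ablated(object$ablation, "EAA")) {
    return(replicate(object$model$n_heads, matrix(0, n, n),
                     simplify = FALSE))
  }
  g <- structure(list(universe = object$universe,
                      views = lapply(MODALITIES, function(m) {
                        list(edges = data.frame(
                          i = object$prep$edge_data[[m]]$i,
                          j = object$prep$edge_data[[m]]$j,
                          score = object$prep$edge_data[[m]]$score))
                      })),
                 class = "multiview_graph")
  names(g$views) <- MODALITIES
  build_edge_bias(g, object$params$W_edge,
                  as.vector(object$params$b_edge))
}

## ---- S3 methods ------------------------------------------------------------

#' @export
print.driver_fusion <- function(x, ...) {
  cat(sprintf("driver_fusion fit: %d genes, d = %d, L = %d, H = %d\n",
              x$prep$n, x$model$d, x$model$n_layers, x$model$n_heads))
  if (!is.null(x$ablation) && length(x$ablation) > 0L) {
    cat("  ablated:", paste(unclass(x$ablation), collapse = ", "), "\n")
  }
  cat(sprintf("  %d parameters; %d epochs; final focal loss %.5f\n",
              x$n_parameters, nrow(x$history),
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.driver_fusion <- function(object, ...) {
  lab <- c(object$labels$positives, object$labels$negatives)
  y <- object$prep$y[lab]
  met <- compute_metrics(object$scores[lab], y, object$training$threshold)
  out <- list(fit = object, train_metrics = met,
              alpha_means = if (is.null(object$alpha)) NULL else
                colMeans(object$alpha))
  class(out) <- "summary.driver_fusion"
  out
}

#' @export
print.summary.driver_fusion <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  labeled-gene (training) metrics: AUROC %.3f, AUPRC %.3f, F1 %.3f\n",
              x$train_metrics["auroc"], x$train_metrics["auprc"],
              x$train_metrics["f1"]))
  if (!is.null(x$alpha_means)) {
    cat("  mean view attention:",
        paste(sprintf("%s %.3f", names(x$alpha_means), x$alpha_means),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predicted driver probabilities
#'
#' The model is transductive: predictions exist for every gene of the fitted
#' graph (labeled or not). `type = "link"` returns logits, `"table"` the
#' ranked prediction table with fusion attention weights.
#'
#' @param object a fitted `driver_fusion`.
#' @param type `"response"`, `"link"` or `"table"`.
#' @param ... unused.
#' @return named numeric vector, or a data.frame for `type = "table"`.
#' @export
predict.driver_fusion <- function(object,
                                  type = c("response", "link", "table"),
                                  ...) {
  type <- match.arg(type)
  s <- object$scores
  if (type == "response") return(s)
  if (type == "link") return(stats::qlogis(s))
  tab <- predict_scores(matrix(stats::qlogis(s), ncol = 1L), w = 1, b = 0,
                        symbols = names(s))
  if (!is.null(object$alpha)) {
    tab <- cbind(tab, as.data.frame(object$alpha[tab$gene, , drop = FALSE]))
  }
  rownames(tab) <- NULL
  tab
}

#' @export
fitted.driver_fusion <- function(object, ...) object$scores

#' Residuals of a fitted driver-gene model
#'
#' Defined over labeled genes only. `"response"`: `y - p`; `"deviance"`:
#' signed square-root binomial deviance.
#'
#' @param object a fitted `driver_fusion`.
#' @param type `"response"` or `"deviance"`.
#' @param ... unused.
#' @return named numeric vector over labeled genes.
#' @export
residuals.driver_fusion <- function(object,
                                    type = c("response", "deviance"), ...) {
  type <- match.arg(type)
  lab <- c(object$labels$positives, object$labels$negatives)
  y <- object$prep$y[lab]
  p <- pmin(pmax(object$scores[lab], 1e-12), 1 - 1e-12)
  if (type == "response") return(stats::setNames(y - p, names(p)))
  d <- sqrt(-2 * (y * log(p) + (1 - y) * log(1 - p)))
  stats::setNames(sign(y - p) * d, names(p))
}

#' @export
coef.driver_fusion <- function(object, ...) flatten_params(object$params)

#' Simulate labels from a fitted model
#'
#' Draws Bernoulli labels for every gene from the fitted probabilities
#' (the model's generative reading of its scores).
#'
#' @param object a fitted `driver_fusion`.
#' @param nsim number of replicate draws.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return N x nsim integer matrix.
#' @export
simulate.driver_fusion <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$scores)
  out <- matrix(stats::rbinom(n * nsim, 1L, rep(object$scores, nsim)),
                n, nsim, dimnames = list(names(object$scores), NULL))
  out
}

#' Diagnostic plots for a fitted model
#'
#' Left: score distributions for positive, negative and unlabeled genes.
#' Right: mean fusion attention per network view (omitted under the NFE
#' ablation).
#'
#' @param x a fitted `driver_fusion`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.driver_fusion <- function(x, ...) {
  op <- graphics::par(mfrow = c(1L, if (is.null(x$alpha)) 1L else 2L))
  on.exit(graphics::par(op))
  groups <- list(positive = x$labels$positives,
                 negative = x$labels$negatives,
                 unlabeled = x$labels$unlabeled)
  cols <- c("#D55E00", "#0072B2", "grey60")
  keep <- lengths(groups) > 1L
  dens <- lapply(which(keep), function(k) {
    stats::density(x$scores[groups[[k]]], from = 0, to = 1)
  })
  ylim <- c(0, max(vapply(dens, function(d) max(d$y), numeric(1L))))
  graphics::plot(dens[[1L]], col = cols[keep][1L], ylim = ylim,
                 main = "Predicted driver probability", xlab = "score", ...)
  for (k in seq_along(dens)[-1L]) {
    graphics::lines(dens[[k]], col = cols[keep][k])
  }
  graphics::legend("topright", legend = names(groups)[keep],
                   col = cols[keep], lty = 1L, bty = "n")
  if (!is.null(x$alpha)) {
    graphics::barplot(colMeans(x$alpha), col = "grey40",
                      main = "Mean view attention", ylab = "alpha")
  }
  invisible(x)
}

## ---- checkpoints -----------------------------------------------------------

universe_hash <- function(universe) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(universe), f)
  unname(tools::md5sum(f))
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the configuration, parameter blobs and a content hash of
#' the gene universe; loading against a dataset with a different universe is
#' refused.
#'
#' @param object a fitted `driver_fusion`.
#' @param path file path.
#' @return `load_checkpoint` returns the fitted object.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "driver_fusion"))
  obj <- object
  obj$checkpoint_hash <- universe_hash(object$universe)
  saveRDS(obj, path, version = 2L)
  invisible(path)
}

#' @param dataset optional `driver_dataset` to validate the universe against.
#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, dataset = NULL) {
  if (!file.exists(path)) {
    stop("checkpoint file not found: ", path, call. = FALSE)
  }
  obj <- readRDS(path)
  stopifnot(inherits(obj, "driver_fusion"))
  if (!is.null(dataset)) {
    if (!identical(obj$checkpoint_hash,
                   universe_hash(dataset$graph$universe))) {
      stop("checkpoint universe does not match the supplied dataset",
           call. = FALSE)
    }
  }
  obj
}
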