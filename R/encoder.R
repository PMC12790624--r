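# Per-view two-layer graph convolution and learnable attention fusion across
# the three views.
#
# Convolution uses symmetric normalization with added self-loops,
# c_ij = sqrt((deg_i + 1)(deg_j + 1)) — the standard GCN convention for the
# unspecified "degree-based scaling" — so isolated-in-view nodes still emit a
# self-loop-only message (required: the GO/Pathway views do not cover all
# genes). Message passing is unweighted by default; edge scores gate
# existence and feed the edge-attention bias. No activation after the second
# layer.

#' Two-layer graph convolution for one view
#'
#' `Z = Ahat ReLU(Ahat X W1) W2` with `Ahat = D^-1/2 (A + I) D^-1/2`
#' (`normalization = "sym"`) or `D^-1 (A + I)` (`"row"`).
#'
#' @param features N x F (normalized) feature matrix.
#' @param view an aligned `network_view` with integer edges.
#' @param params list with `W1` (F x d) and `W2` (d x d).
#' @param normalization `"sym"` (default) or `"row"`.
#' @param weighted use edge scores as message weights (default FALSE).
#' @return N x d embedding matrix.
#' @export
gcn_two_layer <- function(features, view, params,
                          normalization = "sym", weighted = FALSE) {
  stopifnot(is.matrix(features), ncol(features) == nrow(params$W1),
            ncol(params$W1) == nrow(params$W2))
  n <- nrow(features)
  Ahat <- normalized_adjacency(view, n, weighted = weighted,
                               normalization = normalization)
  H1 <- pmax(as.matrix(Ahat %*% (features %*% params$W1)), 0)
  as.matrix(Ahat %*% (H1 %*% params$W2))
}

#' Attention fusion of per-view embeddings
#'
#' Per node, the three view logits are `Z_i a`; `alpha_i = softmax` over them
#' and `z_fusion_i = sum_m alpha_im z_i^(m)`. The alphas are the per-gene
#' modality weights used for interpretability.
#'
#' @param z_list list of three N x d matrices, in PPI/GO/Pathway order.
#' @param a length-d attention vector.
#' @return list with `z_fusion` (N x d) and `alpha` (N x 3, rows sum to 1).
#' @export
fuse_views <- function(z_list, a) {
  stopifnot(length(z_list) == 3L)
  a <- matrix(as.vector(a), ncol = 1L)
  logits <- do.call(cbind, lapply(z_list, function(z) z %*% a))
  if (any(!is.finite(logits))) {
    stop("non-finite fusion logits", call. = FALSE)
  }
  logits <- logits - apply(logits, 1L, max)
  e <- exp(logits)
  alpha <- e / rowSums(e)
  zf <- alpha[, 1L] * z_list[[1L]] + alpha[, 2L] * z_list[[2L]] +
    alpha[, 3L] * z_list[[3L]]
  colnames(alpha) <- MODALITIES
  list(z_fusion = zf, alpha = alpha)
}

## ---- tape versions (training path) ----------------------------------------

tape_gcn <- function(tape, Ahat, X, W1, W2) {
  h1 <- tp_relu(tape, tp_spmm(tape, Ahat, tp_matmul(tape, X, W1)))
  tp_spmm(tape, Ahat, tp_matmul(tape, h1, W2))
}

tape_fusion <- function(tape, z_nodes, a) {
  logit_cols <- lapply(z_nodes, function(z) tp_matmul(tape, z, a))
  logits <- tp_cbind(tape, logit_cols)
  alpha <- tp_row_softmax(tape, logits)
  parts <- lapply(seq_along(z_nodes), function(m) {
    tp_rowscale(tape, z_nodes[[m]], tp_cols(tape, alpha, m))
  })
  zf <- tp_add(tape, tp_add(tape, parts[[1L]], parts[[2L]]), parts[[3L]])
  list(z_fusion = zf, alpha = alpha)
}

tape_geneset <- function(tape, M, W_attn, E_set) {
  A <- tp_row_softmax(tape, tp_matmul(tape, M, W_attn))
  list(E_gene = tp_matmul(tape, A, E_set), A = A)
}
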