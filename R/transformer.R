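# Transformer backbone with edge-attention bias.
#
# Input assembly (raw attributes | fused multi-view embedding | gene-set
# functional embedding | structural encoding) -> single linear projection to
# width d -> L post-norm transformer layers whose per-head pre-softmax
# attention logits carry an additive edge bias derived from the biological
# views -> linear + sigmoid head. The bias tensor is built once and shared
# across layers. Feed-forward width is 4d with GELU (unstated in the source;
# adopted as the field convention). Dropout acts on sublayer outputs during
# training only.

#' Assemble the transformer input block
#'
#' Column-concatenates raw features, fused embedding, functional embedding
#' and structural encoding; width `F + d + d + (d_rw + 1)` (in the reference
#' configuration with `d_rw = d`, `F + 3d + 1`).
#'
#' @param x N x F raw (normalized) features.
#' @param z_fusion N x d fused multi-view embedding.
#' @param e_gene N x d functional embedding.
#' @param e_struct N x (d_rw + 1) structural encoding.
#' @return N x (F + 2d + d_rw + 1) matrix.
#' @export
assemble_input <- function(x, z_fusion, e_gene, e_struct) {
  nr <- c(nrow(x), nrow(z_fusion), nrow(e_gene), nrow(e_struct))
  if (length(unique(nr)) != 1L) {
    stop("assemble_input: blocks disagree on row count", call. = FALSE)
  }
  cbind(x, z_fusion, e_gene, e_struct)
}

#' Project the assembled input into model space
#'
#' `H0 = h_input W_proj^T + b_proj` (single linear transformation).
#'
#' @param h_input N x k assembled input.
#' @param W_proj d x k projection matrix.
#' @param b_proj length-d bias.
#' @return N x d matrix.
#' @export
project_input <- function(h_input, W_proj, b_proj) {
  stopifnot(ncol(h_input) == ncol(W_proj))
  sweep(h_input %*% t(W_proj), 2L, as.vector(b_proj), "+")
}

# per-view edge arrays consumed by the edge-bias op
edge_descriptor_data <- function(graph) {
  lapply(graph$views, function(v) {
    list(i = v$edges$i, j = v$edges$j, score = v$edges$score)
  })
}

#' Build the edge-attention bias
#'
#' For each gene pair connected in at least one view,
#' `b_ij = sum_m sigma(W_edge s_ij^(m) + b_edge)` with the compact pairwise
#' descriptor `s_ij^(m) = [score_ij^(m), 1]` (k = 2). Pairs without an edge in
#' any view contribute exactly 0 ("no evidence, no modulation"), keeping the
#' tensor sparse in spirit; it is materialized densely per head for the
#' full-graph attention.
#'
#' @param graph an aligned `multiview_graph`.
#' @param W_edge H x 2 shared projection.
#' @param b_edge length-H bias.
#' @return list of H symmetric N x N matrices, each per-view contribution in
#'   (0, 1).
#' @export
build_edge_bias <- function(graph, W_edge, b_edge) {
  n <- length(graph$universe)
  H <- nrow(W_edge)
  ed <- edge_descriptor_data(graph)
  lapply(seq_len(H), function(h) {
    B <- matrix(0, n, n)
    for (m in seq_along(ed)) {
      e <- ed[[m]]
      if (length(e$i) == 0L) next
      s <- 1 / (1 + exp(-(W_edge[h, 1L] * e$score + W_edge[h, 2L] +
                            b_edge[h])))
      up <- cbind(e$i, e$j); lo <- cbind(e$j, e$i)
      B[up] <- B[up] + s
      B[lo] <- B[lo] + s
    }
    B
  })
}

#' Model configuration
#'
#' @param d embedding width (divisible by `n_heads`). Reference value 128;
#'   the synthetic world uses 32.
#' @param n_layers transformer depth L.
#' @param n_heads attention head count H.
#' @param dropout dropout rate on sublayer outputs, training only.
#' @param d_rw positional-encoding width; `NULL` means `min(d, N - 1)`.
#' @param normalization GCN normalization, `"sym"` or `"row"`.
#' @param weighted_messages score-weighted GCN aggregation (default FALSE).
#' @param attention_cap refuse full-graph attention above this node count.
#' @return a `model_config` list.
#' @export
model_config <- function(d = 128L, n_layers = 3L, n_heads = 4L,
                         dropout = 0.1, d_rw = NULL,
                         normalization = "sym", weighted_messages = FALSE,
                         attention_cap = 20000L) {
  stopifnot(d %% n_heads == 0L, dropout >= 0, dropout < 1,
            n_layers >= 1L, n_heads >= 1L)
  structure(list(d = as.integer(d), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), dropout = dropout,
                 d_rw = d_rw, normalization = normalization,
                 weighted_messages = weighted_messages,
                 attention_cap = as.integer(attention_cap)),
            class = "model_config")
}

# one post-norm transformer layer on the tape; B_heads: list of H bias nodes
# (or NULL for no bias). Returns the updated representation node.
tape_transformer_layer <- function(tape, Hin, lp, B_heads, config, training) {
  d <- config$d; H <- config$n_heads; dh <- d %/% H
  scale <- 1 / sqrt(dh)
  Q <- tp_add_rowvec(tape, tp_matmul(tape, Hin, lp$Wq), lp$bq)
  K <- tp_add_rowvec(tape, tp_matmul(tape, Hin, lp$Wk), lp$bk)
  V <- tp_add_rowvec(tape, tp_matmul(tape, Hin, lp$Wv), lp$bv)
  heads <- vector("list", H)
  attn <- vector("list", H)
  for (h in seq_len(H)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    Qh <- tp_cols(tape, Q, cols)
    Kh <- tp_cols(tape, K, cols)
    Vh <- tp_cols(tape, V, cols)
    Bh <- if (is.null(B_heads)) NULL else B_heads[[h]]
    heads[[h]] <- tp_attention(tape, Qh, Kh, Vh, Bh, scale)
    attn[[h]] <- heads[[h]]
  }
  O <- tp_add_rowvec(tape, tp_matmul(tape, tp_cbind(tape, heads), lp$Wo),
                     lp$bo)
  O <- tp_dropout(tape, O, config$dropout, training)
  H1 <- tp_layernorm(tape, tp_add(tape, Hin, O), lp$g1, lp$b1)
  FF <- tp_add_rowvec(tape,
                      tp_matmul(tape,
                                tp_gelu(tape,
                                        tp_add_rowvec(tape,
                                                      tp_matmul(tape, H1, lp$Wf1),
                                                      lp$bf1)),
                                lp$Wf2),
                      lp$bf2)
  FF <- tp_dropout(tape, FF, config$dropout, training)
  out <- tp_layernorm(tape, tp_add(tape, H1, FF), lp$g2, lp$b2)
  list(H = out, attn = attn)
}

tp_transpose <- function(tape, a) {
  tp_node(tape, t(a$value), list(a), function(g) list(t(g)))
}

#' Transformer encoder forward pass
#'
#' Runs `L` post-norm transformer layers with per-head additive attention
#' bias on the pre-softmax logits. Deterministic in eval mode
#' (`training = FALSE`); with `B = NULL` (all-zero bias) it is exactly a
#' vanilla transformer encoder — the edge-attention ablation reuses this same
#' code path with the bias removed.
#'
#' @param H0 N x d projected input.
#' @param B list of H N x N bias matrices from [build_edge_bias()], or NULL.
#' @param config a [model_config()].
#' @param params model parameters (list with `layers`), e.g. from a fitted
#'   model's `$params`.
#' @param training apply dropout.
#' @param return_attention also return per-layer per-head attention matrices.
#' @return N x d matrix `HL` (with attribute `attention` if requested).
#' @export
transformer_forward <- function(H0, B, config, params, training = FALSE,
                                return_attention = FALSE) {
  tape <- new_tape()
  node <- tp_const(tape, H0)
  B_heads <- if (is.null(B)) NULL else lapply(B, function(b) tp_const(tape, b))
  pl <- params_to_nodes(tape, params)
  attn <- list()
  for (l in seq_len(config$n_layers)) {
    res <- tape_transformer_layer(tape, node, pl$layers[[l]], B_heads,
                                  config, training)
    node <- res$H
    if (return_attention) {
      attn[[l]] <- lapply(res$attn, function(nd) nd$attn)
    }
  }
  out <- tp_value(node)
  if (any(!is.finite(out))) {
    stop("non-finite activations in transformer forward", call. = FALSE)
  }
  if (return_attention) attr(out, "attention") <- attn
  out
}

#' Prediction head
#'
#' `y_i = sigmoid(w . h_i + b)`; genes ranked by descending score, ties broken
#' by gene symbol.
#'
#' @param HL N x d final representations.
#' @param w length-d weight vector.
#' @param b scalar bias.
#' @param symbols optional gene symbols for the rank tie-break.
#' @return data.frame with `gene` (if symbols given), `score`, `rank`.
#' @export
predict_scores <- function(HL, w, b, symbols = NULL) {
  logit <- as.vector(HL %*% matrix(as.vector(w), ncol = 1L)) + b
  score <- 1 / (1 + exp(-logit))
  if (is.null(symbols)) symbols <- sprintf("g%06d", seq_along(score))
  o <- order(-score, symbols, method = "radix")
  rank <- integer(length(score)); rank[o] <- seq_along(score)
  data.frame(gene = symbols, score = score, rank = rank,
             stringsAsFactors = FALSE)
}
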