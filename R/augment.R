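# Feature augmentation: gene-set-guided functional embedding, random-walk
# positional encoding (PCA of the row-stochastic transition matrix of the PPI
# view) and PageRank centrality. The structural pieces are computed once per
# dataset and frozen (they are inputs, not trained); the gene-set attention
# parameters ARE trainable and live in the model graph — geneset_embed() here
# is the deterministic forward used both standalone and (via the tape) in
# training.

#' Gene-set-guided functional embedding
#'
#' `A = softmax_rows(M W_attn)`, `E_gene = A E_set`. Rows of `A` are a
#' per-gene attention distribution over gene sets; an all-zero membership row
#' yields the uniform distribution.
#'
#' @param M N x S binary membership matrix (or a `gene_set_matrix`).
#' @param W_attn S x S attention parameter matrix.
#' @param E_set S x d gene-set embedding table.
#' @return list with `E_gene` (N x d) and `A` (N x S, rows sum to 1).
#' @export
geneset_embed <- function(M, W_attn, E_set) {
  if (inherits(M, "gene_set_matrix")) M <- M$membership
  stopifnot(ncol(M) > 0L, ncol(M) == nrow(W_attn),
            ncol(W_attn) == nrow(E_set))
  Z <- M %*% W_attn
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  A <- E / rowSums(E)
  list(E_gene = A %*% E_set, A = A)
}

# row-stochastic random-walk transition matrix of a view (dense);
# isolated nodes get a self-transition of 1
transition_matrix <- function(view, n) {
  A <- as.matrix(view_adjacency(view, n, weighted = FALSE,
                                self_loops = FALSE))
  deg <- rowSums(A)
  iso <- deg == 0
  Tm <- A / ifelse(deg == 0, 1, deg)
  if (any(iso)) Tm[cbind(which(iso), which(iso))] <- 1
  Tm
}

#' Random-walk positional encoding
#'
#' Builds the row-stochastic transition matrix `T = D^-1 A` of the PPI view
#' (isolated nodes get a self-transition of 1), applies PCA (columns
#' centered), and returns the first `d_rw` principal-component score columns
#' scaled by their singular values ("variance-scaled"). Component signs are
#' fixed so each component's largest-magnitude loading is positive, making
#' the encoding deterministic. Columns beyond the available rank are
#' zero-padded.
#'
#' @param view the PPI `network_view` (aligned, integer edges).
#' @param n universe size.
#' @param d_rw number of positional dimensions (capped at `n - 1`).
#' @return N x d_rw matrix.
#' @export
random_walk_positional <- function(view, n, d_rw) {
  d_rw <- min(d_rw, n - 1L)
  if (d_rw < 1L) return(matrix(0, n, max(d_rw, 0L)))
  Tm <- transition_matrix(view, n)
  Tc <- sweep(Tm, 2L, colMeans(Tm))
  sv <- svd(Tc, nu = min(n, d_rw), nv = min(n, d_rw))
  k <- sum(sv$d > 1e-10 * sv$d[1L])
  k <- min(k, d_rw)
  out <- matrix(0, n, d_rw)
  if (k > 0L) {
    U <- sv$u[, seq_len(k), drop = FALSE]
    V <- sv$v[, seq_len(k), drop = FALSE]
    # sign convention: largest-|loading| entry of each right singular vector
    # is positive
    flip <- vapply(seq_len(k), function(c_) {
      v <- V[, c_]
      sign(v[which.max(abs(v))])
    }, numeric(1L))
    out[, seq_len(k)] <- U %*% diag(sv$d[seq_len(k)] * flip, k)
  }
  out
}

#' PageRank centrality
#'
#' Standard PageRank with uniform teleportation; dangling-node mass is
#' redistributed uniformly. Power iteration to an L1 tolerance of 1e-10
#' (default cap 200 iterations).
#'
#' @param view an aligned `network_view` (the PPI view in the full pipeline).
#' @param n universe size.
#' @param damping damping factor, default 0.85.
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return numeric vector of length `n`, entries in `(0, 1]`, summing to 1.
#' @export
pagerank <- function(view, n, damping = 0.85, tol = 1e-10, max_iter = 200L) {
  stopifnot(damping > 0, damping < 1)
  A <- view_adjacency(view, n, weighted = FALSE, self_loops = FALSE)
  deg <- Matrix::rowSums(A)
  dangling <- deg == 0
  # column-stochastic transition from the row perspective: p' = t(T) p
  Dinv <- Matrix::Diagonal(n, 1 / ifelse(deg == 0, 1, deg))
  Tt <- Matrix::t(Dinv %*% A)
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    p_new <- damping * as.vector(Tt %*% p) +
      damping * sum(p[dangling]) / n + (1 - damping) / n
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) return(p)
  }
  stop(sprintf("PageRank did not converge in %d iterations (L1 residual %.3g)",
               max_iter, delta), call. = FALSE)
}

#' Concatenate structural encodings
#'
#' `e_struct = [e_rw | e_pr]`, width `d_rw + 1`.
#'
#' @param e_rw N x d_rw positional block.
#' @param e_pr length-N PageRank vector (or N x 1 matrix).
#' @return N x (d_rw + 1) matrix.
#' @export
structural_concat <- function(e_rw, e_pr) {
  e_pr <- matrix(as.vector(e_pr), ncol = 1L)
  if (nrow(e_rw) != nrow(e_pr)) {
    stop("structural_concat: row counts differ", call. = FALSE)
  }
  cbind(e_rw, e_pr)
}

# one-shot precomputation of frozen encodings for a dataset
structural_encoding <- function(dataset, d_rw) {
  n <- length(dataset$graph$universe)
  ppi <- dataset$graph$views$PPI
  e_rw <- random_walk_positional(ppi, n, d_rw)
  e_pr <- pagerank(ppi, n)
  list(e_rw = e_rw, e_pr = matrix(e_pr, ncol = 1L),
       e_struct = structural_concat(e_rw, e_pr))
}
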