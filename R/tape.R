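# Minimal reverse-mode autodifferentiation tape.
#
# No deep-learning framework is available to R in this environment, so the
# model's gradients are computed by this small tape: each forward op records
# its parents and a backward closure; backward() sweeps the tape in reverse
# topological (creation) order. Values are base-R numeric matrices; sparse
# adjacency constants stay as Matrix::dgCMatrix outside the tape.
#
# Every op here is exercised by finite-difference gradient checks in the
# test suite.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  class(tp) <- "df_tape"
  tp
}

tp_node <- function(tape, value, parents = list(), backward = NULL,
                    param = FALSE, name = NULL) {
  # force arguments BEFORE claiming an id: nested op calls create their
  # parent nodes while the promises are evaluated, and reverse-sweep
  # correctness needs parent ids strictly below child ids
  force(parents); force(value); force(backward)
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  node <- new.env(parent = emptyenv())
  node$id <- tape$n
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$param <- param
  node$name <- name
  node$grad <- NULL
  tape$nodes[[tape$n]] <- node
  node
}

tp_const <- function(tape, value) tp_node(tape, value)

tp_param <- function(tape, value, name = NULL) {
  tp_node(tape, value, param = TRUE, name = name)
}

tp_value <- function(node) node$value

# Accumulate gradient g into node (no-op for constants without parents that
# are not parameters, but accumulation is cheap and keeps the sweep simple).
tp_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Reverse sweep from scalar root. Returns invisibly; gradients sit in
# node$grad for parameter nodes.
tp_backward <- function(tape, root) {
  stopifnot(length(root$value) == 1L)
  root$grad <- 1
  for (k in seq(tape$n, 1L)) {
    node <- tape$nodes[[k]]
    if (is.null(node) || is.null(node$grad) || is.null(node$backward)) next
    grads <- node$backward(node$grad)
    for (p in seq_along(node$parents)) {
      if (!is.null(grads[[p]])) tp_accum(node$parents[[p]], grads[[p]])
    }
  }
  invisible(NULL)
}

tp_zero_grads <- function(tape) {
  for (k in seq_len(tape$n)) tape$nodes[[k]]$grad <- NULL
  invisible(NULL)
}

## ---- elementary ops --------------------------------------------------------

tp_matmul <- function(tape, a, b) {
  tp_node(tape, a$value %*% b$value, list(a, b), function(g) {
    list(tcrossprod(g, b$value), crossprod(a$value, g))
  })
}

# sparse (constant) %*% dense(node); A is a Matrix object, assumed fixed.
tp_spmm <- function(tape, A, x) {
  tp_node(tape, as.matrix(A %*% x$value), list(x), function(g) {
    list(as.matrix(Matrix::crossprod(A, g)))
  })
}

tp_add <- function(tape, a, b) {
  tp_node(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

# add a length-ncol bias vector to every row
tp_add_rowvec <- function(tape, a, v) {
  n <- nrow(a$value)
  tp_node(tape, a$value + rep(as.vector(v$value), each = n), list(a, v),
          function(g) list(g, matrix(colSums(g), ncol = 1L)))
}

tp_scale <- function(tape, a, s) {
  tp_node(tape, a$value * s, list(a), function(g) list(g * s))
}

tp_mul <- function(tape, a, b) {
  tp_node(tape, a$value * b$value, list(a, b), function(g) {
    list(g * b$value, g * a$value)
  })
}

# scale row i of matrix a (N x d) by scalar w[i] (N x 1 node)
tp_rowscale <- function(tape, a, w) {
  wv <- as.vector(w$value)
  tp_node(tape, a$value * wv, list(a, w), function(g) {
    list(g * wv, matrix(rowSums(g * a$value), ncol = 1L))
  })
}

tp_relu <- function(tape, a) {
  tp_node(tape, pmax(a$value, 0), list(a), function(g) {
    list(g * (a$value > 0))
  })
}

tp_gelu <- function(tape, a) {
  x <- a$value
  tp_node(tape, x * stats::pnorm(x), list(a), function(g) {
    list(g * (stats::pnorm(x) + x * stats::dnorm(x)))
  })
}

tp_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  tp_node(tape, s, list(a), function(g) list(g * s * (1 - s)))
}

tp_row_softmax <- function(tape, a) {
  x <- a$value
  x <- x - x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x)
  p <- e / rowSums(e)
  tp_node(tape, p, list(a), function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

# row-wise layer normalization with learnable gain/offset (length-d vectors)
tp_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$value
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowSums(xc * xc) / d
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gv <- as.vector(gamma$value)
  bv <- as.vector(beta$value)
  nr <- nrow(x)
  y <- xhat * rep(gv, each = nr) + rep(bv, each = nr)
  tp_node(tape, y, list(a, gamma, beta), function(g) {
    dxhat <- g * rep(gv, each = nr)
    dgamma <- matrix(colSums(g * xhat), ncol = 1L)
    dbeta <- matrix(colSums(g), ncol = 1L)
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dx <- inv * (dxhat - m1 - xhat * m2)
    list(dx, dgamma, dbeta)
  })
}

tp_cbind <- function(tape, nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1L))
  tp_node(tape, do.call(cbind, lapply(nodes, tp_value)), nodes, function(g) {
    out <- vector("list", length(nodes))
    at <- 0L
    for (k in seq_along(nodes)) {
      out[[k]] <- g[, at + seq_len(widths[k]), drop = FALSE]
      at <- at + widths[k]
    }
    out
  })
}

tp_cols <- function(tape, a, idx) {
  nc <- ncol(a$value)
  tp_node(tape, a$value[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$value), nc)
    out[, idx] <- g
    list(out)
  })
}

# inverted dropout; identity when training = FALSE. Draws from the session RNG
# so training remains reproducible under set.seed().
tp_dropout <- function(tape, a, rate, training) {
  if (!training || rate <= 0) return(a)
  keep <- (matrix(stats::runif(length(a$value)), nrow(a$value)) >= rate) /
    (1 - rate)
  tp_node(tape, a$value * keep, list(a), function(g) list(g * keep))
}

## ---- composite ops ---------------------------------------------------------

# Focal loss over labeled rows of a logit column vector.
# loss = mean_i over mask of -alpha * (1 - p_t)^gamma * log(p_t),
# p_t = p for y = 1, 1 - p for y = 0, with p = sigmoid(logit) clamped to
# [eps, 1 - eps]. Gradient flows through the clamp interior only.
tp_focal_loss <- function(tape, logits, y, mask, alpha, gamma, eps = 1e-7) {
  if (length(mask) == 0L) stop("focal loss: empty labeled set", call. = FALSE)
  l <- as.vector(logits$value)[mask]
  yv <- y[mask]
  p <- 1 / (1 + exp(-l))
  inside <- p > eps & p < 1 - eps
  pc <- pmin(pmax(p, eps), 1 - eps)
  pt <- ifelse(yv == 1, pc, 1 - pc)
  n <- length(mask)
  loss <- mean(-alpha * (1 - pt)^gamma * log(pt))
  tp_node(tape, loss, list(logits), function(g) {
    # d loss_i / d pt
    if (gamma == 0) {
      dpt <- -alpha / pt
    } else {
      dpt <- -alpha * (-gamma * (1 - pt)^(gamma - 1) * log(pt) +
                         (1 - pt)^gamma / pt)
    }
    dp <- dpt * ifelse(yv == 1, 1, -1)
    dl <- dp * pc * (1 - pc) * inside
    out <- matrix(0, nrow(logits$value), 1L)
    out[mask, 1L] <- g * dl / n
    list(out)
  })
}

# One attention head fused into a single op (keeps the number of N x N
# intermediates — the memory/GC hot spot of full-graph attention — minimal):
#   P = row_softmax(Q K^T * scale + B),  out = P V
# B may be NULL (vanilla attention) or an N x N bias node.
tp_attention <- function(tape, Q, K, V, B, scale) {
  logits <- tcrossprod(Q$value, K$value) * scale
  if (!is.null(B)) logits <- logits + B$value
  logits <- logits - logits[cbind(seq_len(nrow(logits)),
                                  max.col(logits, ties.method = "first"))]
  P <- exp(logits)
  P <- P / rowSums(P)
  parents <- if (is.null(B)) list(Q, K, V) else list(Q, K, V, B)
  node <- tp_node(tape, P %*% V$value, parents, function(g) {
    dP <- tcrossprod(g, V$value)
    dlogits <- P * (dP - rowSums(dP * P))
    out <- list(dlogits %*% K$value * scale,
                crossprod(dlogits, Q$value) * scale,
                crossprod(P, g))
    if (!is.null(B)) out$dB <- dlogits
    out
  })
  node$attn <- P
  node
}

# Edge-attention bias for one head: dense N x N matrix
#   B_h[i, j] = sum over views with an edge (i, j) of
#               sigmoid(W_edge[h, ] . s_ij^(m) + b_edge[h]),
# descriptor s_ij^(m) = [score_ij^(m), 1]. Pairs with no edge in any view get
# exactly 0. edge_data is a list per view of list(i, j, score) with i < j.
tp_edge_bias_head <- function(tape, W_edge, b_edge, h, edge_data, n) {
  w <- W_edge$value[h, ]
  b <- b_edge$value[h]
  B <- matrix(0, n, n)
  sig <- vector("list", length(edge_data))
  for (m in seq_along(edge_data)) {
    ed <- edge_data[[m]]
    if (length(ed$i) == 0L) { sig[[m]] <- numeric(0L); next }
    s <- 1 / (1 + exp(-(w[1L] * ed$score + w[2L] + b)))
    sig[[m]] <- s
    up <- cbind(ed$i, ed$j)
    lo <- cbind(ed$j, ed$i)
    B[up] <- B[up] + s
    B[lo] <- B[lo] + s
  }
  tp_node(tape, B, list(W_edge, b_edge), function(g) {
    gW <- matrix(0, nrow(W_edge$value), ncol(W_edge$value))
    gb <- matrix(0, length(b_edge$value), 1L)
    for (m in seq_along(edge_data)) {
      ed <- edge_data[[m]]
      if (length(ed$i) == 0L) next
      s <- sig[[m]]
      ge <- g[cbind(ed$i, ed$j)] + g[cbind(ed$j, ed$i)]
      core <- ge * s * (1 - s)
      gW[h, 1L] <- gW[h, 1L] + sum(core * ed$score)
      gW[h, 2L] <- gW[h, 2L] + sum(core)
      gb[h, 1L] <- gb[h, 1L] + sum(core)
    }
    list(gW, gb)
  })
}
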