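# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive (explicit loops, dense algebra) and never
# call the implementation paths they check.

# aligned view directly from integer edges
make_view <- function(n, i, j, score, modality = "PPI", threshold = 0) {
  stopifnot(all(i < j))
  o <- order(i, j)
  structure(list(modality = modality,
                 edges = data.frame(i = i[o], j = j[o], score = score[o]),
                 n_nodes = length(unique(c(i, j))), threshold = threshold),
            class = "network_view")
}

# Erdos-Renyi aligned view with uniform scores above a threshold
random_view <- function(n, p, modality = "PPI", threshold = 0.5) {
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(ij)) < p
  i <- ij[keep, 1L]; j <- ij[keep, 2L]
  make_view(n, i, j, threshold + stats::runif(length(i)) * (1 - threshold),
            modality, threshold)
}

tiny_dataset <- function(n = 60L, seed = 1L, ...) {
  generate_dataset(synthetic_config(
    n_genes = n, n_drivers = max(6L, n %/% 10L),
    n_negatives = max(12L, n %/% 4L), n_sets = 12L, seed = seed, ...))
}

# dense two-layer GCN by explicit double loop over neighborhoods
# (self-loops added, c_ij = sqrt((deg_i + 1)(deg_j + 1)))
oracle_gcn <- function(X, view, W1, W2, n) {
  nb <- rep(list(integer()), n)
  for (r in seq_len(nrow(view$edges))) {
    i <- view$edges$i[r]; j <- view$edges$j[r]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  deg <- lengths(nb)
  H1 <- matrix(0, n, ncol(W1))
  for (i in seq_len(n)) {
    acc <- numeric(ncol(W1))
    for (j in c(i, nb[[i]])) {
      cij <- sqrt((deg[i] + 1) * (deg[j] + 1))
      acc <- acc + as.vector(X[j, , drop = FALSE] %*% W1) / cij
    }
    H1[i, ] <- pmax(acc, 0)
  }
  Z <- matrix(0, n, ncol(W2))
  for (i in seq_len(n)) {
    acc <- numeric(ncol(W2))
    for (j in c(i, nb[[i]])) {
      cij <- sqrt((deg[i] + 1) * (deg[j] + 1))
      acc <- acc + as.vector(H1[j, , drop = FALSE] %*% W2) / cij
    }
    Z[i, ] <- acc
  }
  Z
}

# exhaustive pairwise AUROC (ties counted half)
oracle_auroc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (scores[p] > scores[q]) 1 else
      if (scores[p] == scores[q]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# dense PageRank by long power iteration on the explicit Google matrix
oracle_pagerank <- function(view, n, damping = 0.85, iters = 1000L) {
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(view$edges))) {
    i <- view$edges$i[r]; j <- view$edges$j[r]
    A[i, j] <- 1; A[j, i] <- 1
  }
  deg <- rowSums(A)
  Tm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Tm[i, ] <- if (deg[i] == 0) rep(1 / n, n) else A[i, ] / deg[i]
  }
  G <- damping * Tm + (1 - damping) / n
  p <- rep(1 / n, n)
  for (it in seq_len(iters)) p <- as.vector(t(G) %*% p)
  p / sum(p)
}

# from-scratch single transformer layer (one head at a time), mirroring the
# documented architecture: post-norm, GELU feed-forward of width 4d
oracle_transformer_layer <- function(H, lp, B, n_heads, eps = 1e-5) {
  n <- nrow(H); d <- ncol(H); dh <- d / n_heads
  addrow <- function(M, v) M + matrix(as.vector(v), n, length(v), byrow = TRUE)
  layernorm <- function(M, gvec, bvec) {
    out <- M
    for (i in seq_len(n)) {
      x <- M[i, ]
      mu <- mean(x); va <- mean((x - mu)^2)
      out[i, ] <- (x - mu) / sqrt(va + eps) * as.vector(gvec) + as.vector(bvec)
    }
    out
  }
  Q <- addrow(H %*% lp$Wq, lp$bq)
  K <- addrow(H %*% lp$Wk, lp$bk)
  V <- addrow(H %*% lp$Wv, lp$bv)
  O <- matrix(0, n, d)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1) * dh + seq_len(dh)
    logits <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
    if (!is.null(B)) logits <- logits + B[[h]]
    P <- matrix(0, n, n)
    for (i in seq_len(n)) {
      e <- exp(logits[i, ] - max(logits[i, ]))
      P[i, ] <- e / sum(e)
    }
    O[, cols] <- P %*% V[, cols, drop = FALSE]
  }
  O <- addrow(O %*% lp$Wo, lp$bo)
  H1 <- layernorm(H + O, lp$g1, lp$b1)
  ffin <- addrow(H1 %*% lp$Wf1, lp$bf1)
  gelu <- ffin * pnorm(ffin)
  FF <- addrow(gelu %*% lp$Wf2, lp$bf2)
  layernorm(H1 + FF, lp$g2, lp$b2)
}

# labeled-gene label vector of a dataset
dataset_y <- function(ds) {
  n <- length(ds$graph$universe)
  y <- rep(NA_real_, n)
  y[ds$labels$positives] <- 1
  y[ds$labels$negatives] <- 0
  y
}
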