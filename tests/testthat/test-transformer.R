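# Input assembly, projection, edge bias, biased attention, prediction head.

random_layer_params <- function(d) {
  list(Wq = matrix(rnorm(d * d), d, d) / sqrt(d), bq = matrix(0, d, 1),
       Wk = matrix(rnorm(d * d), d, d) / sqrt(d), bk = matrix(0, d, 1),
       Wv = matrix(rnorm(d * d), d, d) / sqrt(d), bv = matrix(rnorm(d) / 10, d, 1),
       Wo = matrix(rnorm(d * d), d, d) / sqrt(d), bo = matrix(0, d, 1),
       Wf1 = matrix(rnorm(d * 4 * d), d, 4 * d) / sqrt(d),
       bf1 = matrix(0, 4 * d, 1),
       Wf2 = matrix(rnorm(4 * d * d), 4 * d, d) / sqrt(4 * d),
       bf2 = matrix(0, d, 1),
       g1 = matrix(1, d, 1), b1 = matrix(0, d, 1),
       g2 = matrix(1, d, 1), b2 = matrix(0, d, 1))
}

test_that("assembled input has the documented width and slices back exactly", {
  set.seed(20)
  n <- 6L
  x <- matrix(rnorm(n * 2), n, 2)
  zf <- matrix(rnorm(n * 3), n, 3)
  eg <- matrix(rnorm(n * 3), n, 3)
  es <- matrix(rnorm(n * 4), n, 4) # d_rw = 3 plus PageRank column
  h <- assemble_input(x, zf, eg, es)
  expect_equal(ncol(h), 2L + 3L + 3L + 4L) # F + d + d + (d_rw + 1) = 12
  expect_equal(h[, 1:2], x)
  expect_equal(h[, 3:5], zf)
  expect_equal(h[, 6:8], eg)
  expect_equal(h[, 9:12], es)
  expect_equal(assemble_input(x * 0, zf * 0, eg * 0, es * 0),
               matrix(0, n, 12L))
  expect_error(assemble_input(x[1:3, ], zf, eg, es), "row count")
})

test_that("projection matches explicit per-row dot products", {
  set.seed(21)
  h <- matrix(rnorm(40), 8, 5)
  W <- matrix(rnorm(15), 3, 5)
  b <- rnorm(3)
  H0 <- project_input(h, W, b)
  expect_equal(dim(H0), c(8L, 3L))
  for (i in 1:8) {
    expect_equal(H0[i, ], as.vector(W %*% h[i, ]) + b, tolerance = 1e-7)
  }
  expect_equal(project_input(h, matrix(0, 3, 5), c(2, 2, 2)),
               matrix(2, 8, 3))
})

test_that("edge bias follows the sigmoid-sum definition", {
  # one pair connected in all three views, zero parameters: 3 * sigmoid(0)
  g <- structure(list(universe = gene_universe(c("A", "B")),
                      views = stats::setNames(lapply(c("PPI", "GO", "Pathway"),
                                                     function(m) {
                        make_view(2L, 1L, 2L, 0.9, m)
                      }), c("PPI", "GO", "Pathway"))),
                 class = "multiview_graph")
  B <- build_edge_bias(g, matrix(0, 2, 2), c(0, 0))
  expect_length(B, 2L)
  expect_equal(B[[1]][1, 2], 1.5)
  expect_equal(B[[1]][2, 1], 1.5)
  expect_equal(B[[1]][1, 1], 0)
  # single-view pair: sigma(0) = 0.5
  g$views$GO$edges <- g$views$GO$edges[0, ]
  g$views$Pathway$edges <- g$views$Pathway$edges[0, ]
  expect_equal(build_edge_bias(g, matrix(0, 2, 2), c(0, 0))[[1]][1, 2], 0.5)
})

test_that("edge bias matches a per-pair per-view per-head loop oracle", {
  set.seed(22)
  n <- 6L
  views <- stats::setNames(lapply(c("PPI", "GO", "Pathway"), function(m) {
    random_view(n, 0.5, m)
  }), c("PPI", "GO", "Pathway"))
  g <- structure(list(universe = gene_universe(sprintf("g%d", 1:n)),
                      views = views), class = "multiview_graph")
  H <- 3L
  W <- matrix(rnorm(H * 2), H, 2)
  b <- rnorm(H)
  B <- build_edge_bias(g, W, b)
  for (h in seq_len(H)) {
    ref <- matrix(0, n, n)
    for (v in views) {
      for (r in seq_len(nrow(v$edges))) {
        i <- v$edges$i[r]; j <- v$edges$j[r]; s <- v$edges$score[r]
        val <- 1 / (1 + exp(-(W[h, 1] * s + W[h, 2] + b[h])))
        ref[i, j] <- ref[i, j] + val
        ref[j, i] <- ref[j, i] + val
      }
    }
    expect_equal(B[[h]], ref, tolerance = 1e-7)
    expect_equal(B[[h]], t(B[[h]]))
    # per-view contributions lie in the sigmoid range
    expect_true(all(B[[h]][B[[h]] != 0] > 0 & B[[h]][B[[h]] != 0] < 3))
  }
})

test_that("a single token passes through attention as a pure feed-forward path", {
  set.seed(23)
  d <- 4L
  lp <- random_layer_params(d)
  H0 <- matrix(rnorm(d), 1, d)
  cfg <- model_config(d = d, n_layers = 1L, n_heads = 1L, dropout = 0)
  out <- transformer_forward(H0, NULL, cfg, list(layers = list(L1 = lp)))
  ref <- oracle_transformer_layer(H0, lp, NULL, 1L)
  expect_equal(out, ref, tolerance = 1e-8)
})

test_that("identical tokens with symmetric bias stay identical", {
  set.seed(24)
  d <- 4L
  lp <- random_layer_params(d)
  H0 <- matrix(rep(rnorm(d), each = 3), 3, d)
  B <- list(matrix(1, 3, 3))
  cfg <- model_config(d = d, n_layers = 1L, n_heads = 1L, dropout = 0)
  out <- transformer_forward(H0, B, cfg, list(layers = list(L1 = lp)))
  expect_equal(out[1, ], out[2, ])
  expect_equal(out[1, ], out[3, ])
})

test_that("biased multi-head attention matches the explicit per-head oracle", {
  set.seed(25)
  n <- 5L; d <- 8L; H <- 2L
  lp1 <- random_layer_params(d)
  lp2 <- random_layer_params(d)
  H0 <- matrix(rnorm(n * d), n, d)
  B <- lapply(1:H, function(h) {
    M <- matrix(rnorm(n * n), n, n); (M + t(M)) / 2
  })
  cfg <- model_config(d = d, n_layers = 2L, n_heads = H, dropout = 0)
  out <- transformer_forward(H0, B, cfg,
                             list(layers = list(L1 = lp1, L2 = lp2)))
  ref <- oracle_transformer_layer(
    oracle_transformer_layer(H0, lp1, B, H), lp2, B, H)
  expect_equal(out, ref, tolerance = 1e-5)
})

test_that("attention rows sum to one and eval forward is reproducible", {
  set.seed(26)
  n <- 7L; d <- 6L
  lp <- random_layer_params(d)
  H0 <- matrix(rnorm(n * d), n, d)
  B <- list(matrix(0.3, n, n), matrix(0, n, n))
  cfg <- model_config(d = d, n_layers = 1L, n_heads = 2L, dropout = 0)
  out <- transformer_forward(H0, B, cfg, list(layers = list(L1 = lp)),
                             return_attention = TRUE)
  for (P in attr(out, "attention")[[1]]) {
    expect_equal(unname(rowSums(P)), rep(1, n), tolerance = 1e-6)
  }
  out2 <- transformer_forward(H0, B, cfg, list(layers = list(L1 = lp)))
  expect_identical(as.vector(out), as.vector(out2))
})

test_that("zero bias reduces exactly to the vanilla transformer path", {
  set.seed(27)
  n <- 6L; d <- 4L
  lp <- random_layer_params(d)
  H0 <- matrix(rnorm(n * d), n, d)
  cfg <- model_config(d = d, n_layers = 1L, n_heads = 2L, dropout = 0)
  Bzero <- list(matrix(0, n, n), matrix(0, n, n))
  expect_equal(transformer_forward(H0, Bzero, cfg,
                                   list(layers = list(L1 = lp))),
               transformer_forward(H0, NULL, cfg,
                                   list(layers = list(L1 = lp))),
               tolerance = 1e-12)
})

test_that("the prediction head is a per-gene sigmoid with ranked output", {
  set.seed(28)
  HL <- matrix(rnorm(20), 5, 4)
  tab0 <- predict_scores(HL, rep(0, 4), 0)
  expect_equal(tab0$score, rep(0.5, 5))
  expect_equal(sort(tab0$rank), 1:5) # ranks a permutation even under ties
  tab_sat <- predict_scores(HL, rep(0, 4), 30)
  expect_true(all(tab_sat$score >= 1 - 1e-13))
  w <- rnorm(4); b <- rnorm(1)
  tab <- predict_scores(HL, w, b, symbols = sprintf("s%d", 1:5))
  for (i in 1:5) {
    expect_equal(tab$score[tab$gene == sprintf("s%d", i)],
                 1 / (1 + exp(-(sum(HL[i, ] * w) + b))), tolerance = 1e-9)
  }
  # monotonicity: increasing the linear score increases the sigmoid output
  expect_true(all(diff(tab$score[order(-tab$rank)]) >= 0))
})
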