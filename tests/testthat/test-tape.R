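# Finite-difference verification of the reverse-mode tape. Each op is
# checked through a scalar read-out; the full model gradient is checked in
# one pass over every parameter group.

fd_check <- function(build, params, eps = 1e-6, tol = 1e-5) {
  # build(tape, param_nodes) -> scalar node
  tape <- driverfusion:::new_tape()
  pn <- lapply(params, function(p) driverfusion:::tp_param(tape, p))
  root <- build(tape, pn)
  driverfusion:::tp_backward(tape, root)
  for (nm in names(params)) {
    ana <- pn[[nm]]$grad
    if (is.null(ana)) ana <- matrix(0, nrow(params[[nm]]), ncol(params[[nm]]))
    for (k in sample(length(params[[nm]]), min(4L, length(params[[nm]])))) {
      f <- function(delta) {
        p2 <- params
        p2[[nm]][k] <- p2[[nm]][k] + delta
        tape2 <- driverfusion:::new_tape()
        pn2 <- lapply(p2, function(p) driverfusion:::tp_param(tape2, p))
        driverfusion:::tp_value(build(tape2, pn2))
      }
      num <- (f(eps) - f(-eps)) / (2 * eps)
      expect_equal(ana[k], num, tolerance = tol,
                   info = sprintf("%s[%d]", nm, k))
    }
  }
}

test_that("elementary op gradients match finite differences", {
  set.seed(31)
  A <- matrix(rnorm(12), 4, 3)
  # read-out: weighted sum with fixed coefficients
  ro <- function(tape, node, w) {
    driverfusion:::tp_focal_loss(
      tape,
      driverfusion:::tp_node(tape, matrix(rowSums(node$value * w), ncol = 1),
                             list(node), function(g) list(
                               matrix(g, nrow(w), ncol(w)) * w)),
      y = rep(1, nrow(w)), mask = seq_len(nrow(w)), alpha = 1, gamma = 0)
  }
  w4 <- matrix(rnorm(12), 4, 3)
  C33 <- matrix(rnorm(9), 3, 3)
  c41 <- matrix(rnorm(4), 4, 1)
  cases <- list(
    matmul = function(tape, pn) ro(tape, driverfusion:::tp_matmul(
      tape, pn$X, driverfusion:::tp_const(tape, C33)), w4),
    relu = function(tape, pn) ro(tape, driverfusion:::tp_relu(tape, pn$X), w4),
    gelu = function(tape, pn) ro(tape, driverfusion:::tp_gelu(tape, pn$X), w4),
    sigmoid = function(tape, pn) ro(tape,
                                    driverfusion:::tp_sigmoid(tape, pn$X), w4),
    softmax = function(tape, pn) ro(tape,
                                    driverfusion:::tp_row_softmax(tape, pn$X),
                                    w4),
    rowscale = function(tape, pn) ro(tape, driverfusion:::tp_rowscale(
      tape, pn$X, driverfusion:::tp_const(tape, c41)), w4))
  set.seed(100)
  for (nm in names(cases)) fd_check(cases[[nm]], list(X = A))
})

test_that("layernorm and attention gradients match finite differences", {
  set.seed(32)
  H <- matrix(rnorm(20), 5, 4)
  gmm <- matrix(runif(4, 0.5, 1.5), 4, 1)
  bta <- matrix(rnorm(4, sd = 0.1), 4, 1)
  w5 <- matrix(rnorm(20), 5, 4)
  ro <- function(tape, node, w) {
    driverfusion:::tp_focal_loss(
      tape,
      driverfusion:::tp_node(tape, matrix(rowSums(node$value * w), ncol = 1),
                             list(node), function(g) list(
                               matrix(g, nrow(w), ncol(w)) * w)),
      y = rep(1, nrow(w)), mask = seq_len(nrow(w)), alpha = 1, gamma = 0)
  }
  fd_check(function(tape, pn) {
    ro(tape, driverfusion:::tp_layernorm(tape, pn$H, pn$g, pn$b), w5)
  }, list(H = H, g = gmm, b = bta))
  B <- matrix(rnorm(25), 5, 5); B <- B + t(B)
  fd_check(function(tape, pn) {
    ro(tape, driverfusion:::tp_attention(
      tape, pn$Q, pn$K, pn$V, driverfusion:::tp_const(tape, B), 0.5), w5)
  }, list(Q = H, K = H + 0.1, V = H - 0.2))
})

test_that("focal loss value and gradient match a closed-form check", {
  # gamma = 2, y = 1, p = 0.9: loss = 0.01 * (-log 0.9)
  tape <- driverfusion:::new_tape()
  lg <- driverfusion:::tp_param(tape, matrix(stats::qlogis(0.9), 1, 1))
  l <- driverfusion:::tp_focal_loss(tape, lg, y = 1, mask = 1L,
                                    alpha = 1, gamma = 2)
  expect_equal(driverfusion:::tp_value(l), 0.1^2 * -log(0.9),
               tolerance = 1e-12)
  driverfusion:::tp_backward(tape, l)
  eps <- 1e-6
  f <- function(d) {
    p <- stats::plogis(stats::qlogis(0.9) + d)
    (1 - p)^2 * -log(p)
  }
  expect_equal(lg$grad[1, 1], (f(eps) - f(-eps)) / (2 * eps),
               tolerance = 1e-5)
})

test_that("the full model gradient matches finite differences everywhere", {
  set.seed(42)
  ds <- generate_dataset(synthetic_config(n_genes = 25L, n_drivers = 5L,
                                          n_negatives = 10L, n_sets = 6L,
                                          n_features = 4L, seed = 9L))
  mcfg <- model_config(d = 8L, n_layers = 2L, n_heads = 2L, dropout = 0,
                       d_rw = 4L)
  prep <- driverfusion:::prepare_inputs(ds, mcfg)
  set.seed(123)
  params <- driverfusion:::init_parameters(
    mcfg, ncol(prep$X), ncol(prep$M),
    ncol(prep$X) + 2L * mcfg$d + prep$d_rw + 1L, NULL)
  mask <- which(!is.na(prep$y))
  loss_at <- function(p) {
    tape <- driverfusion:::new_tape()
    pn <- driverfusion:::params_to_nodes(tape, p)
    fw <- driverfusion:::df_forward(tape, prep, pn, mcfg, NULL,
                                    training = FALSE)
    driverfusion:::tp_value(driverfusion:::tp_focal_loss(
      tape, fw$logits, prep$y, mask, 1.0, 1.5))
  }
  tape <- driverfusion:::new_tape()
  pn <- driverfusion:::params_to_nodes(tape, params)
  fw <- driverfusion:::df_forward(tape, prep, pn, mcfg, NULL,
                                  training = FALSE)
  l <- driverfusion:::tp_focal_loss(tape, fw$logits, prep$y, mask, 1.0, 1.5)
  driverfusion:::tp_backward(tape, l)
  flatg <- driverfusion:::flatten_params(driverfusion:::collect_grads(pn))
  eps <- 1e-6
  set.seed(99)
  for (nm in names(flatg)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    k <- sample(length(flatg[[nm]]), 1L)
    bump <- function(delta) {
      q <- params
      ref <- paste0("[[\"", path, "\"]]", collapse = "")
      eval(parse(text = paste0("q", ref, "[k] <- q", ref, "[k] + delta")))
      q
    }
    num <- (loss_at(bump(eps)) - loss_at(bump(-eps))) / (2 * eps)
    expect_equal(flatg[[nm]][k], num, tolerance = 1e-4, info = nm)
  }
})
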