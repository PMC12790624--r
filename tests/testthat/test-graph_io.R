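# Edge-list loading, view alignment, GMT parsing, normalization and labels.

write_edges <- function(rows, header = FALSE) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  lines <- vapply(rows, function(r) paste(r, collapse = "\t"), "")
  if (header) lines <- c("gene_a\tgene_b\tscore", lines)
  writeLines(lines, f)
  f
}

test_that("edge loading thresholds, dedups, canonicalizes and drops self-loops", {
  f <- write_edges(list(c("A", "B", "0.90"), c("A", "C", "0.30"),
                        c("B", "A", "0.88")))
  v <- load_edge_list(f, "PPI", 0.85)
  expect_equal(nrow(v$edges), 1L)
  expect_equal(v$edges$a, "A")
  expect_equal(v$edges$b, "B")
  expect_equal(v$edges$score, 0.90) # duplicate keeps the maximum score

  f2 <- write_edges(list(c("A", "A", "0.99")))
  expect_equal(nrow(load_edge_list(f2, "PPI", 0)$edges), 0L)

  # header auto-detection yields the same view
  f3 <- write_edges(list(c("A", "B", "0.9")), header = TRUE)
  expect_equal(load_edge_list(f3, "GO", 0.8)$edges,
               load_edge_list(write_edges(list(c("A", "B", "0.9"))),
                              "GO", 0.8)$edges)
})

test_that("edge count matches a brute-force line scan on random input", {
  set.seed(11)
  for (rep in 1:3) {
    genes <- sprintf("g%d", 1:6)
    rows <- lapply(1:10, function(k) {
      c(sample(genes, 2L), sprintf("%.4f", stats::runif(1)))
    })
    f <- write_edges(rows)
    v <- load_edge_list(f, "Pathway", 0.6)
    # independent rescan: keep score >= 0.6, no self-loops, unique unordered
    keys <- character(); best <- numeric()
    for (r in rows) {
      s <- as.numeric(r[3])
      if (s < 0.6 || r[1] == r[2]) next
      key <- paste(sort(r[1:2]), collapse = "|")
      if (is.na(best[key]) || s > best[key]) best[key] <- s
      keys <- union(keys, key)
    }
    expect_equal(nrow(v$edges), length(keys))
    got <- stats::setNames(v$edges$score,
                           paste(v$edges$a, v$edges$b, sep = "|"))
    expect_equal(got[sort(names(got))], best[sort(names(best))])
    expect_true(all(v$edges$score >= 0.6))
  }
})

test_that("malformed rows and out-of-range scores are rejected with line numbers", {
  f <- write_edges(list(c("A", "B", "0.9"), c("C", "D")))
  expect_error(load_edge_list(f, "PPI", 0.5), "line 2")
  # row 1 with a non-numeric score is a header by the auto-detection rule,
  # so the malformed row sits at line 2
  f2 <- write_edges(list(c("A", "B", "0.4"), c("A", "C", "xyz")))
  expect_error(load_edge_list(f2, "PPI", 0.5), "non-numeric")
  f3 <- write_edges(list(c("A", "B", "1.7")))
  expect_error(load_edge_list(f3, "PPI", 0.5), "outside")
})

test_that("alignment restricts GO/Pathway to the PPI universe", {
  ppi <- load_edge_list(write_edges(list(c("A", "B", "0.9"),
                                         c("B", "C", "0.95"))), "PPI", 0.85)
  go <- load_edge_list(write_edges(list(c("C", "D", "0.9"),
                                        c("A", "B", "0.85"))), "GO", 0.8)
  pw <- load_edge_list(write_edges(list(c("A", "C", "0.7"))), "Pathway", 0.6)
  g <- align_views(ppi, go, pw, "ppi_nodes")
  expect_equal(as.character(g$universe), c("A", "B", "C"))
  expect_equal(nrow(g$views$GO$edges), 1L) # (C,D) dropped
  expect_equal(nrow(g$views$Pathway$edges), 1L)
  # every retained endpoint lies in the PPI node set
  for (v in g$views) {
    expect_true(all(c(v$edges$i, v$edges$j) %in%
                      seq_along(g$universe)))
    expect_true(all(v$edges$i < v$edges$j))
  }
  expect_error(align_views(load_edge_list(write_edges(list()), "PPI", 0.5),
                           go, pw), "empty PPI")
})

test_that("alignment keeps all GO/Pathway endpoints inside the PPI set on random views", {
  set.seed(7)
  syms <- sprintf("s%02d", 1:50)
  mk <- function(modality, thr) {
    rows <- lapply(1:60, function(k) {
      c(sample(syms, 2L), sprintf("%.3f", stats::runif(1, thr, 1)))
    })
    load_edge_list(write_edges(rows), modality, thr)
  }
  g <- align_views(mk("PPI", 0.85), mk("GO", 0.8), mk("Pathway", 0.6))
  ppi_nodes <- as.character(g$universe)
  for (m in c("GO", "Pathway")) {
    v <- g$views[[m]]
    expect_true(all(as.character(g$universe)[c(v$edges$i, v$edges$j)] %in%
                      ppi_nodes))
  }
})

test_that("GMT parsing restricts to the universe and excludes keyword sets", {
  u <- gene_universe(c("A", "B"))
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB", "CANCER_UP\tdesc\tA", "EMPTY\tdesc\tZ"), f)
  gs <- load_gene_sets(f, u, exclusion_keywords = "cancer")
  expect_equal(colnames(gs$membership), "S1")
  expect_equal(unname(gs$membership[, 1L]), c(1, 1))
  expect_error(load_gene_sets(f, u, exclusion_keywords = c("cancer", "S1",
                                                           "empty")),
               "no gene sets survive")
})

test_that("GMT membership matches a direct re-parse on random sets", {
  set.seed(5)
  genes <- sprintf("G%02d", 1:30)
  u <- gene_universe(genes)
  sets <- lapply(1:20, function(s) sample(genes, sample(2:8, 1L)))
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(vapply(seq_along(sets), function(s) {
    paste(c(sprintf("SET%02d", s), "d", sets[[s]]), collapse = "\t")
  }, ""), f)
  gs <- load_gene_sets(f, u)
  for (s in seq_along(sets)) {
    expect_equal(unname(gs$membership[, sprintf("SET%02d", s)]),
                 as.numeric(as.character(u) %in% sets[[s]]), info = s)
  }
})

test_that("z-score normalization uses population SD, guards constants, idempotent", {
  X <- cbind(a = c(1, 3), b = c(5, 5))
  Z <- zscore_normalize(X)
  expect_equal(unname(Z[, "a"]), c(-1, 1)) # population SD convention
  expect_equal(unname(Z[, "b"]), c(0, 0))
  set.seed(3)
  R <- matrix(stats::rnorm(120), 30, 4)
  ZR <- zscore_normalize(R)
  expect_true(all(abs(colMeans(ZR)) < 1e-9))
  expect_true(all(abs(sqrt(colMeans(ZR^2)) - 1) < 1e-9))
  expect_equal(unclass(zscore_normalize(ZR)), unclass(ZR), tolerance = 1e-9)
})

test_that("label building partitions the universe and flags conflicts", {
  u <- gene_universe(c("A", "B", "C"))
  ls <- label_set("A", "B", u)
  expect_equal(ls$unlabeled, match("C", u))
  expect_error(label_set("A", "A", u), "both positive and negative")
  set.seed(2)
  genes <- sprintf("x%03d", 1:200)
  u2 <- gene_universe(genes)
  pick <- sample(genes, 100L)
  ls2 <- label_set(pick[1:40], pick[41:100], u2)
  expect_equal(length(ls2$positives) + length(ls2$negatives) +
                 length(ls2$unlabeled), 200L)
  expect_length(intersect(ls2$positives, ls2$negatives), 0L)
})

test_that("re-reading the same files yields identical datasets", {
  ds <- tiny_dataset(n = 40L, seed = 8L)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  rd <- function() read_dataset(
    ppi = file.path(dir, "ppi_edges.tsv"),
    go = file.path(dir, "go_edges.tsv"),
    pathway = file.path(dir, "pathway_edges.tsv"),
    features = file.path(dir, "features.tsv"),
    genesets = file.path(dir, "gene_sets.gmt"),
    positives = file.path(dir, "positives.txt"),
    negatives = file.path(dir, "negatives.txt"),
    gene_list = file.path(dir, "genes.txt"))
  expect_identical(rd(), rd())
})
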