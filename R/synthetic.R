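# Seeded synthetic datasets with the statistical structure the model assumes:
# three partially overlapping degree-heterogeneous views, a dense feature
# matrix with a planted driver class (shifted means, elevated centrality), a
# sparse binary gene-set matrix with driver-enriched sets, and a ~1:2.7
# imbalanced label set echoing the 796:2187 pan-cancer corpus at reduced
# scale.

#' Synthetic dataset configuration
#'
#' Defaults are the package's stated synthetic world: 500 genes with 60
#' planted drivers and 160 sampled negatives (1:2.7 class imbalance), 48
#' feature columns, 50 gene sets, driver feature shift 1.5 standard
#' deviations in a random half of the columns, drivers' expected degree
#' multiplied by 3 (hubs), set enrichment probability 0.4 against a 0.05
#' baseline, half of PPI edges copied into each other view, edge density 0.03.
#'
#' @param n_genes,n_drivers,n_negatives,n_features,n_sets sizes.
#' @param feature_shift mean shift (in SD units) added to driver rows in a
#'   random half of the feature columns.
#' @param hub_bias expected-degree multiplier for drivers (>= 1).
#' @param set_enrichment probability a driver belongs to each gene set.
#' @param baseline_membership probability a non-driver belongs to each set.
#' @param view_overlap fraction of PPI edges copied into the GO and Pathway
#'   views; the remainder of each view is drawn independently.
#' @param edge_density expected edge density of each view.
#' @param thresholds per-view minimum edge score; synthetic scores are drawn
#'   uniformly in `[threshold, 1]`.
#' @param seed master seed; one derived RNG stream per component.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 500L, n_drivers = 60L,
                             n_negatives = 160L, n_features = 48L,
                             n_sets = 50L, feature_shift = 1.5,
                             hub_bias = 3, set_enrichment = 0.4,
                             baseline_membership = 0.05,
                             view_overlap = 0.5, edge_density = 0.03,
                             thresholds = c(PPI = 0.85, GO = 0.8,
                                            Pathway = 0.6),
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_drivers = as.integer(n_drivers),
              n_negatives = as.integer(n_negatives),
              n_features = as.integer(n_features), n_sets = as.integer(n_sets),
              feature_shift = feature_shift, hub_bias = hub_bias,
              set_enrichment = set_enrichment,
              baseline_membership = baseline_membership,
              view_overlap = view_overlap, edge_density = edge_density,
              thresholds = thresholds, seed = as.integer(seed))
  stopifnot(cfg$n_drivers + cfg$n_negatives <= cfg$n_genes,
            cfg$hub_bias >= 1, cfg$edge_density > 0, cfg$edge_density < 1,
            cfg$view_overlap >= 0, cfg$view_overlap <= 1,
            cfg$set_enrichment > 0, cfg$set_enrichment <= 1,
            cfg$baseline_membership > 0, cfg$baseline_membership <= 1)
  if (cfg$edge_density * cfg$hub_bias * (cfg$n_genes - 1) >= cfg$n_genes) {
    stop("infeasible density/hub_bias combination: expected driver degree ",
         "exceeds n_genes", call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# derived sub-seed, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 10007) %% 2147483647)
}

# Chung-Lu expected-degree draw: P(i ~ j) = min(1, w_i w_j / sum(w)).
# Returns canonical i < j integer edges.
chung_lu_edges <- function(w) {
  n <- length(w)
  W <- sum(w)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- pmin(1, w[ij[, 1L]] * w[ij[, 2L]] / W)
  keep <- stats::runif(nrow(ij)) < p
  list(i = ij[keep, 1L], j = ij[keep, 2L])
}

#' Generate a synthetic driver-gene dataset
#'
#' See [synthetic_config()] for the generative model. Regeneration with the
#' same config (including seed) is bit-identical.
#'
#' @param config a [synthetic_config()].
#' @return a `driver_dataset` whose `truth` field holds the planted class
#'   (1 = driver) and with attribute `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_genes
  symbols <- sprintf("G%05d", seq_len(n))
  universe <- gene_universe(symbols)
  drivers <- seq_len(config$n_drivers) # lexicographic order preserved: G00001..
  is_driver <- seq_len(n) %in% drivers

  # -- graphs: one RNG stream per view ---------------------------------------
  base_deg <- config$edge_density * (n - 1)
  w <- rep(base_deg, n)
  w[drivers] <- w[drivers] * config$hub_bias
  views <- vector("list", 3L)
  names(views) <- MODALITIES
  ppi_e <- NULL
  for (m in seq_along(MODALITIES)) {
    set.seed(derive_seed(config$seed, m))
    mod <- MODALITIES[m]
    e <- chung_lu_edges(w)
    if (mod != "PPI") {
      # copy a fraction of PPI edges, keep an independent remainder
      keep_own <- stats::runif(length(e$i)) >= config$view_overlap
      ncopy <- round(config$view_overlap * length(ppi_e$i))
      copy <- if (ncopy > 0L)
        sample(length(ppi_e$i), ncopy) else integer()
      i <- c(e$i[keep_own], ppi_e$i[copy])
      j <- c(e$j[keep_own], ppi_e$j[copy])
      key <- i * (n + 1) + j
      dup <- duplicated(key)
      e <- list(i = i[!dup], j = j[!dup])
    } else {
      ppi_e <- e
    }
    thr <- config$thresholds[[mod]]
    score <- thr + stats::runif(length(e$i)) * (1 - thr)
    o <- order(e$i, e$j)
    views[[mod]] <- structure(
      list(modality = mod,
           edges = data.frame(i = e$i[o], j = e$j[o], score = score[o]),
           n_nodes = length(unique(c(e$i, e$j))), threshold = thr),
      class = "network_view")
  }
  graph <- structure(list(universe = universe, views = views),
                     class = "multiview_graph")

  # -- features --------------------------------------------------------------
  set.seed(derive_seed(config$seed, 11L))
  X <- matrix(stats::rnorm(n * config$n_features), n, config$n_features)
  shifted_cols <- sample(config$n_features, max(1L, config$n_features %/% 2L))
  X[drivers, shifted_cols] <- X[drivers, shifted_cols] + config$feature_shift
  colnames(X) <- sprintf("f%02d", seq_len(config$n_features))
  rownames(X) <- symbols
  X <- zscore_normalize(X)

  # -- gene sets -------------------------------------------------------------
  set.seed(derive_seed(config$seed, 12L))
  p <- matrix(config$baseline_membership, n, config$n_sets)
  p[drivers, ] <- config$set_enrichment
  M <- (matrix(stats::runif(n * config$n_sets), n, config$n_sets) < p) * 1
  dimnames(M) <- list(symbols, sprintf("SET_%03d", seq_len(config$n_sets)))
  M <- M[, colSums(M) > 0, drop = FALSE]
  gene_sets <- structure(list(membership = M, set_names = colnames(M)),
                         class = "gene_set_matrix")

  # -- labels ----------------------------------------------------------------
  set.seed(derive_seed(config$seed, 13L))
  nondrivers <- which(!is_driver)
  negs <- sort(sample(nondrivers, config$n_negatives))
  labels <- structure(list(positives = drivers, negatives = negs,
                           unlabeled = setdiff(seq_len(n), c(drivers, negs))),
                      class = "label_set")

  ds <- driver_dataset(graph, X, gene_sets, labels,
                       truth = as.integer(is_driver))
  attr(ds, "config") <- config
  ds
}

#' Summarize a dataset
#'
#' Node/edge counts per view, density, label counts — the synthetic analogue
#' of a corpus summary table.
#'
#' @param dataset a `driver_dataset`.
#' @return a list with `n_genes`, a per-view data.frame `views`
#'   (`edges`, `nodes`, `density`), and `labels` counts.
#' @export
describe_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "driver_dataset"))
  n <- length(dataset$graph$universe)
  vs <- do.call(rbind, lapply(dataset$graph$views, function(v) {
    data.frame(modality = v$modality, edges = nrow(v$edges),
               nodes = v$n_nodes,
               density = nrow(v$edges) / (n * (n - 1) / 2))
  }))
  rownames(vs) <- NULL
  list(n_genes = n, views = vs,
       labels = c(positives = length(dataset$labels$positives),
                  negatives = length(dataset$labels$negatives),
                  unlabeled = length(dataset$labels$unlabeled)))
}

#' Write a dataset in the package's file formats
#'
#' Emits exactly the formats [read_dataset()] consumes (edge-list TSVs, a
#' feature TSV, a GMT file, label lists), so synthetic runs exercise the real
#' I/O path.
#'
#' @param dataset a `driver_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  u <- as.character(dataset$graph$universe)
  paths <- list()
  f <- file.path(dir, "genes.txt")
  writeLines(u, f)
  paths$genes <- f
  for (m in MODALITIES) {
    v <- dataset$graph$views[[m]]
    f <- file.path(dir, paste0(tolower(m), "_edges.tsv"))
    df <- data.frame(gene_a = u[v$edges$i], gene_b = u[v$edges$j],
                     score = sprintf("%.6f", v$edges$score))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[m]] <- f
  }
  f <- file.path(dir, "features.tsv")
  df <- data.frame(gene = u, dataset$features, check.names = FALSE)
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$features <- f
  if (!is.null(dataset$gene_sets)) {
    f <- file.path(dir, "gene_sets.gmt")
    M <- dataset$gene_sets$membership
    lines <- vapply(seq_len(ncol(M)), function(s) {
      paste(c(colnames(M)[s], "synthetic", u[M[, s] > 0]), collapse = "\t")
    }, "")
    writeLines(lines, f)
    paths$genesets <- f
  }
  f <- file.path(dir, "positives.txt")
  writeLines(u[dataset$labels$positives], f); paths$positives <- f
  f <- file.path(dir, "negatives.txt")
  writeLines(u[dataset$labels$negatives], f); paths$negatives <- f
  if (!is.null(dataset$truth)) {
    f <- file.path(dir, "truth.tsv")
    utils::write.table(data.frame(gene = u, driver = dataset$truth), f,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths$truth <- f
  }
  invisible(paths)
}
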