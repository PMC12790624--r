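# Reading, filtering and node-aligning the three network views, the per-gene
# omics feature table, GMT gene sets and label lists into one dataset object.
#
# Gene identifiers are opaque case-sensitive strings after whitespace
# stripping; no alias resolution. Universe ordering is lexicographic
# (C collation) so fold assignment and every downstream computation are
# reproducible for a given symbol set.

MODALITIES <- c("PPI", "GO", "Pathway")

#' Construct a gene universe
#'
#' An ordered set of unique gene symbols. Ordering is deterministic
#' (lexicographic under C collation) for a given symbol set, so positions are
#' stable across runs and platforms.
#'
#' @param symbols character vector of gene symbols (duplicates collapsed).
#' @return character vector of class `gene_universe`, sorted, no duplicates.
#' @export
gene_universe <- function(symbols) {
  s <- unique(trimws(as.character(symbols)))
  s <- s[nzchar(s)]
  s <- sort(s, method = "radix")
  structure(s, class = "gene_universe")
}

universe_index <- function(universe, symbols) match(symbols, universe)

#' Load a weighted edge list for one network view
#'
#' Reads a three-column TSV (`gene_a`, `gene_b`, `score`; header auto-detected
#' from a non-numeric third field in row 1), drops self-loops and rows with
#' score below `threshold`, collapses duplicate pairs keeping the maximum
#' score, and canonicalizes pairs so `gene_a < gene_b` lexicographically.
#'
#' Reference-corpus thresholds: 0.85 for the STRING PPI view (0.5 for CPDB),
#' 0.8 for GO semantic similarity, 0.6 for pathway co-occurrence.
#'
#' @param path TSV file path.
#' @param modality one of `"PPI"`, `"GO"`, `"Pathway"`.
#' @param threshold minimum retained edge score, in `[0, 1]`.
#' @return a `network_view`: list with `modality`, `edges` (data.frame
#'   `a`, `b`, `score` over symbols), `n_nodes`.
#' @export
load_edge_list <- function(path, modality = c("PPI", "GO", "Pathway"),
                           threshold) {
  modality <- match.arg(modality)
  stopifnot(is.numeric(threshold), threshold >= 0, threshold <= 1)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(new_network_view(modality,
                            data.frame(a = character(), b = character(),
                                       score = numeric()), threshold))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  f1 <- fields[[1L]]
  if (length(f1) >= 3L && is.na(suppressWarnings(as.numeric(f1[[3L]])))) {
    start <- 2L # header row
  }
  a <- character(); b <- character(); score <- numeric()
  if (start <= length(fields)) {
    rows <- fields[seq(start, length(fields))]
    nf <- lengths(rows)
    bad <- which(nf < 3L)
    if (length(bad) > 0L) {
      stop(sprintf("malformed edge list row at line %d of %s: fewer than 3 fields",
                   bad[1L] + start - 1L, path), call. = FALSE)
    }
    a <- trimws(vapply(rows, `[[`, "", 1L))
    b <- trimws(vapply(rows, `[[`, "", 2L))
    score <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 3L)))
    if (anyNA(score)) {
      stop(sprintf("malformed edge list row at line %d of %s: non-numeric score",
                   which(is.na(score))[1L] + start - 1L, path), call. = FALSE)
    }
    if (any(score < 0 | score > 1)) {
      stop(sprintf("edge score outside [0, 1] at line %d of %s",
                   which(score < 0 | score > 1)[1L] + start - 1L, path),
           call. = FALSE)
    }
  }
  keep <- score >= threshold & a != b & nzchar(a) & nzchar(b)
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  # canonicalize pair order, then collapse duplicates keeping max score
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  if (length(a) > 0L) {
    key <- paste(a, b, sep = "\r")
    score <- vapply(split(score, key), max, numeric(1L))
    ab <- strsplit(names(score), "\r", fixed = TRUE)
    a <- vapply(ab, `[[`, "", 1L)
    b <- vapply(ab, `[[`, "", 2L)
    o <- order(a, b, method = "radix")
    a <- a[o]; b <- b[o]; score <- unname(score[o])
  }
  new_network_view(modality, data.frame(a = a, b = b, score = score,
                                        stringsAsFactors = FALSE), threshold)
}

new_network_view <- function(modality, edges, threshold) {
  structure(list(modality = modality, edges = edges,
                 n_nodes = length(unique(c(edges$a, edges$b))),
                 threshold = threshold),
            class = "network_view")
}

view_symbols <- function(view) unique(c(view$edges$a, view$edges$b))

#' Node-align the three network views over a shared gene universe
#'
#' Under the `"ppi_nodes"` policy (the reference convention) the universe is the
#' PPI node set and GO/Pathway edges with either endpoint outside it are
#' dropped; `"union"` keeps every node seen in any view.
#'
#' @param ppi,go,pathway `network_view` objects from [load_edge_list()].
#' @param universe_policy `"ppi_nodes"` or `"union"`.
#' @param gene_list optional character vector of symbols that overrides the
#'   policy (an explicit universe, e.g. from a synthetic dataset's
#'   `genes.txt`); edges with endpoints outside it are dropped.
#' @return a `multiview_graph`: list with `universe` (a [gene_universe()]) and
#'   `views`, each view's edges re-indexed to integer universe positions
#'   (`i < j`).
#' @export
align_views <- function(ppi, go, pathway,
                        universe_policy = c("ppi_nodes", "union"),
                        gene_list = NULL) {
  universe_policy <- match.arg(universe_policy)
  stopifnot(inherits(ppi, "network_view"), ppi$modality == "PPI",
            inherits(go, "network_view"), inherits(pathway, "network_view"))
  if (!is.null(gene_list)) {
    syms <- gene_list
  } else if (universe_policy == "ppi_nodes") {
    syms <- view_symbols(ppi)
    if (length(syms) == 0L) stop("empty PPI view: no universe", call. = FALSE)
  } else {
    syms <- c(view_symbols(ppi), view_symbols(go), view_symbols(pathway))
  }
  universe <- gene_universe(syms)
  views <- lapply(list(PPI = ppi, GO = go, Pathway = pathway), function(v) {
    i <- universe_index(universe, v$edges$a)
    j <- universe_index(universe, v$edges$b)
    keep <- !is.na(i) & !is.na(j)
    i <- i[keep]; j <- j[keep]; score <- v$edges$score[keep]
    swap <- i > j
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
    o <- order(i, j)
    structure(list(modality = v$modality,
                   edges = data.frame(i = i[o], j = j[o], score = score[o]),
                   n_nodes = length(unique(c(i, j))),
                   threshold = v$threshold),
              class = "network_view")
  })
  structure(list(universe = universe, views = views),
            class = "multiview_graph")
}

#' Per-view neighbor lists
#'
#' @param graph a `multiview_graph`.
#' @return for each view, a list of integer neighbor vectors per node.
#' @export
neighbor_lists <- function(graph) {
  n <- length(graph$universe)
  lapply(graph$views, function(v) {
    nb <- rep(list(integer()), n)
    if (nrow(v$edges) > 0L) {
      half <- split(c(v$edges$j, v$edges$i), c(v$edges$i, v$edges$j))
      nb[as.integer(names(half))] <- lapply(half, function(x) sort(unique(x)))
    }
    nb
  })
}

# sparse symmetric adjacency of one aligned view; optionally score-weighted,
# optionally with unit self-loops
view_adjacency <- function(view, n, weighted = FALSE, self_loops = FALSE) {
  e <- view$edges
  w <- if (weighted) e$score else rep(1, nrow(e))
  A <- Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i), x = c(w, w),
                            dims = c(n, n))
  if (self_loops) A <- A + Matrix::Diagonal(n)
  A
}

# symmetric GCN normalization D^-1/2 (A + I) D^-1/2 (deg + 1 through the
# self-loop), or row normalization D^-1 (A + I)
normalized_adjacency <- function(view, n, weighted = FALSE,
                                 normalization = c("sym", "row")) {
  normalization <- match.arg(normalization)
  A <- view_adjacency(view, n, weighted = weighted, self_loops = TRUE)
  deg <- Matrix::rowSums(A)
  if (normalization == "sym") {
    Dhalf <- Matrix::Diagonal(n, 1 / sqrt(deg))
    Dhalf %*% A %*% Dhalf
  } else {
    Matrix::Diagonal(n, 1 / deg) %*% A
  }
}

#' Load gene sets from a GMT file
#'
#' GMT dialect: `set_name TAB description TAB gene TAB gene ...`. Membership is
#' restricted to universe genes; sets whose name contains any exclusion
#' keyword (case-insensitive) are removed, as are columns left empty after
#' restriction.
#'
#' @param path GMT file path.
#' @param universe a [gene_universe()].
#' @param exclusion_keywords character vector (e.g. `"cancer"`); sets whose
#'   names match are excluded to avoid label leakage.
#' @return a `gene_set_matrix`: list with `membership` (N x S binary matrix,
#'   rownames = universe, colnames = set names) and `set_names`.
#' @export
load_gene_sets <- function(path, universe, exclusion_keywords = character()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(fields, `[[`, "", 1L)
  genes <- lapply(fields, function(f) {
    if (length(f) < 3L) character() else trimws(f[-c(1L, 2L)])
  })
  if (length(exclusion_keywords) > 0L) {
    drop <- Reduce(`|`, lapply(exclusion_keywords, function(k) {
      grepl(k, names_, ignore.case = TRUE, fixed = FALSE)
    }), accumulate = FALSE)
    names_ <- names_[!drop]; genes <- genes[!drop]
  }
  n <- length(universe)
  M <- matrix(0, n, length(names_),
              dimnames = list(as.character(universe), names_))
  for (s in seq_along(genes)) {
    idx <- universe_index(universe, genes[[s]])
    idx <- idx[!is.na(idx)]
    M[idx, s] <- 1
  }
  keep <- colSums(M) > 0
  M <- M[, keep, drop = FALSE]
  if (ncol(M) == 0L) {
    stop("no gene sets survive keyword exclusion and universe restriction; ",
         "relax exclusion_keywords or check the universe", call. = FALSE)
  }
  structure(list(membership = M, set_names = colnames(M)),
            class = "gene_set_matrix")
}

#' Z-score normalize a feature matrix
#'
#' Each column is transformed to `(x - mean) / sd` using the population
#' standard deviation; constant columns map to all-zeros. Normalization is
#' global (the whole matrix at once, before any train/test splitting), exactly
#' as the source protocol specifies; the train/test leakage this implies is a
#' documented property, not corrected.
#'
#' @param features numeric matrix (genes x features).
#' @return matrix of the same shape with attribute `normalized = TRUE`.
#'   Idempotent up to floating-point tolerance.
#' @export
zscore_normalize <- function(features) {
  stopifnot(is.matrix(features), nrow(features) >= 2L)
  mu <- colMeans(features)
  sd_pop <- sqrt(colMeans(sweep(features, 2L, mu)^2))
  sd_pop[sd_pop < 1e-12] <- Inf # constant columns -> 0
  out <- sweep(sweep(features, 2L, mu), 2L, sd_pop, "/")
  attr(out, "normalized") <- TRUE
  out
}

#' Load a per-gene feature table
#'
#' TSV/CSV with a gene-symbol first column and named numeric columns
#' (the reference layout is 48 columns: 16 cancer types x mutation rate,
#' differential methylation, differential expression). Universe genes absent
#' from the table receive all-zero rows (post-normalization equivalent), with
#' a warning.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.csv` = comma, otherwise tab).
#' @param universe a [gene_universe()].
#' @param normalize z-score the columns (default TRUE).
#' @return numeric matrix, rows = universe order.
#' @export
load_features <- function(path, universe, normalize = TRUE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  syms <- trimws(as.character(df[[1L]]))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  if (normalize) vals <- zscore_normalize(vals)
  n <- length(universe)
  out <- matrix(0, n, ncol(vals),
                dimnames = list(as.character(universe), colnames(vals)))
  idx <- universe_index(universe, syms)
  hit <- !is.na(idx)
  out[idx[hit], ] <- vals[hit, , drop = FALSE]
  missing <- n - length(unique(idx[hit]))
  if (missing > 0L) {
    warning(sprintf("%d universe genes absent from the feature table; given all-zero rows",
                    missing), call. = FALSE)
  }
  attr(out, "normalized") <- normalize
  out
}

#' Build a label set from positive/negative gene lists
#'
#' Plain-text files, one symbol per line, `#` comment lines ignored. Symbols
#' outside the universe are dropped with a message; a gene in both lists is an
#' error.
#'
#' @param positive_path,negative_path file paths (or character vectors of
#'   symbols via [label_set()]).
#' @param universe a [gene_universe()].
#' @return a `label_set`: list with integer index vectors `positives`,
#'   `negatives`, `unlabeled`.
#' @export
build_labels <- function(positive_path, negative_path, universe) {
  read_syms <- function(p) {
    x <- trimws(readLines(p))
    x[nzchar(x) & !startsWith(x, "#")]
  }
  label_set(read_syms(positive_path), read_syms(negative_path), universe)
}

#' @param positives,negatives character vectors of gene symbols.
#' @rdname build_labels
#' @export
label_set <- function(positives, negatives, universe) {
  both <- intersect(positives, negatives)
  if (length(both) > 0L) {
    stop("gene(s) listed as both positive and negative: ",
         paste(utils::head(both, 5L), collapse = ", "), call. = FALSE)
  }
  pos <- universe_index(universe, unique(positives))
  neg <- universe_index(universe, unique(negatives))
  dropped <- sum(is.na(pos)) + sum(is.na(neg))
  if (dropped > 0L) {
    message(sprintf("%d labeled gene(s) not in the universe were dropped", dropped))
  }
  pos <- sort(pos[!is.na(pos)])
  neg <- sort(neg[!is.na(neg)])
  structure(list(positives = pos, negatives = neg,
                 unlabeled = setdiff(seq_along(universe), c(pos, neg))),
            class = "label_set")
}

#' Assemble a driver-gene dataset
#'
#' Bundles the aligned multi-view graph, the normalized feature matrix, the
#' gene-set membership matrix and the labels into one index-consistent object,
#' the input to [driver_fusion()].
#'
#' @param graph a `multiview_graph` from [align_views()].
#' @param features numeric N x F matrix in universe order.
#' @param gene_sets a `gene_set_matrix`, or NULL for a dataset without the
#'   gene-set channel.
#' @param labels a `label_set`.
#' @param truth optional integer/logical vector of planted classes (synthetic
#'   data only).
#' @return object of class `driver_dataset`.
#' @export
driver_dataset <- function(graph, features, gene_sets, labels, truth = NULL) {
  n <- length(graph$universe)
  stopifnot(inherits(graph, "multiview_graph"),
            is.matrix(features), nrow(features) == n,
            inherits(labels, "label_set"))
  if (!is.null(gene_sets)) {
    stopifnot(inherits(gene_sets, "gene_set_matrix"),
              nrow(gene_sets$membership) == n)
  }
  for (v in graph$views) {
    if (nrow(v$edges) > 0L) {
      stopifnot(all(v$edges$i >= 1L), all(v$edges$j <= n),
                all(v$edges$i < v$edges$j))
    }
  }
  structure(list(graph = graph, features = features, gene_sets = gene_sets,
                 labels = labels, truth = truth),
            class = "driver_dataset")
}

#' Read a full dataset from files
#'
#' Convenience wrapper chaining [load_edge_list()], [align_views()],
#' [load_features()], [load_gene_sets()] and [build_labels()].
#'
#' @param ppi,go,pathway edge-list TSV paths.
#' @param features feature-table path.
#' @param genesets GMT path (optional).
#' @param positives,negatives label-list paths.
#' @param thresholds named numeric vector of per-view score thresholds.
#' @param exclusion_keywords passed to [load_gene_sets()].
#' @param universe_policy passed to [align_views()].
#' @param gene_list optional path of an explicit gene-universe file (one
#'   symbol per line), overriding `universe_policy`.
#' @return a `driver_dataset`.
#' @export
read_dataset <- function(ppi, go, pathway, features, genesets = NULL,
                         positives, negatives,
                         thresholds = c(PPI = 0.85, GO = 0.8, Pathway = 0.6),
                         exclusion_keywords = c("cancer", "tumor", "tumour",
                                                "carcinoma", "oncogen",
                                                "leukemia", "melanoma",
                                                "glioma", "sarcoma"),
                         universe_policy = "ppi_nodes", gene_list = NULL) {
  syms <- if (is.null(gene_list)) NULL else {
    x <- trimws(readLines(gene_list))
    x[nzchar(x) & !startsWith(x, "#")]
  }
  g <- align_views(load_edge_list(ppi, "PPI", thresholds[["PPI"]]),
                   load_edge_list(go, "GO", thresholds[["GO"]]),
                   load_edge_list(pathway, "Pathway", thresholds[["Pathway"]]),
                   universe_policy = universe_policy, gene_list = syms)
  X <- load_features(features, g$universe)
  M <- if (is.null(genesets)) NULL else
    load_gene_sets(genesets, g$universe, exclusion_keywords)
  lab <- build_labels(positives, negatives, g$universe)
  driver_dataset(g, X, M, lab)
}

#' @export
print.driver_dataset <- function(x, ...) {
  n <- length(x$graph$universe)
  cat(sprintf("driver_dataset: %d genes\n", n))
  for (m in MODALITIES) {
    v <- x$graph$views[[m]]
    cat(sprintf("  %-8s %6d edges over %d nodes (threshold %.2f)\n",
                m, nrow(v$edges), v$n_nodes, v$threshold))
  }
  cat(sprintf("  features: %d columns; gene sets: %s\n", ncol(x$features),
              if (is.null(x$gene_sets)) "none"
              else ncol(x$gene_sets$membership)))
  cat(sprintf("  labels: %d positive / %d negative / %d unlabeled\n",
              length(x$labels$positives), length(x$labels$negatives),
              length(x$labels$unlabeled)))
  invisible(x)
}
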