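# Downstream reports: score stratification by gene category, novel-candidate
# extraction, and the attention interpretability report.

#' Stratify prediction scores by gene category
#'
#' Categories (typically known driver / potential driver / non-driver /
#' other) must partition the universe. Reports per-category quartiles and the
#' expected ordering checks
#' known > potential > other > non-driver (on medians) as booleans.
#'
#' @param scores named per-gene score vector (e.g. `fitted(fit)` or
#'   out-of-fold scores).
#' @param categories named list of integer index vectors (or symbol vectors
#'   matched against `names(scores)`) partitioning the genes.
#' @return a `stratification_report`: data.frame of per-category summaries
#'   with attribute `ordering` (named logical vector).
#' @export
stratify_scores <- function(scores, categories) {
  idx <- lapply(categories, function(g) {
    if (is.character(g)) match(g, names(scores)) else as.integer(g)
  })
  all_idx <- sort(unlist(idx, use.names = FALSE))
  if (anyNA(all_idx) || anyDuplicated(all_idx) ||
      length(all_idx) != length(scores) ||
      !identical(all_idx, seq_along(scores))) {
    stop("categories must partition the gene universe (no overlap, no gaps)",
         call. = FALSE)
  }
  tab <- do.call(rbind, lapply(names(idx), function(nm) {
    q <- stats::quantile(scores[idx[[nm]]], c(0.25, 0.5, 0.75))
    data.frame(category = nm, n = length(idx[[nm]]),
               q25 = q[[1L]], median = q[[2L]], q75 = q[[3L]])
  }))
  rownames(tab) <- NULL
  med <- stats::setNames(tab$median, tab$category)
  ord <- c(known_gt_potential = NA, potential_gt_other = NA,
           other_gt_nondriver = NA)
  if (all(c("known_driver", "potential_driver") %in% names(med))) {
    ord["known_gt_potential"] <- med["known_driver"] > med["potential_driver"]
  }
  if (all(c("potential_driver", "other") %in% names(med))) {
    ord["potential_gt_other"] <- med["potential_driver"] > med["other"]
  }
  if (all(c("other", "non_driver") %in% names(med))) {
    ord["other_gt_nondriver"] <- med["other"] > med["non_driver"]
  }
  structure(tab, ordering = ord, class = c("stratification_report",
                                           class(tab)))
}

#' Novel candidate drivers
#'
#' Takes the `top_k` genes by score, removes known drivers, and returns the
#' remainder with their ranks; with 122 known drivers inside a top-300 set
#' this leaves 178 novel candidates (the reference arithmetic).
#'
#' @param scores named per-gene score vector.
#' @param known_drivers character vector of known driver symbols (or integer
#'   indices).
#' @param top_k size of the top set.
#' @return data.frame `gene`, `score`, `rank` (rank within the full ranking),
#'   known drivers removed.
#' @export
novel_candidates <- function(scores, known_drivers, top_k) {
  stopifnot(top_k <= length(scores))
  if (is.numeric(known_drivers)) known_drivers <- names(scores)[known_drivers]
  o <- order(-scores, names(scores), method = "radix")
  top <- o[seq_len(top_k)]
  tab <- data.frame(gene = names(scores)[top], score = unname(scores[top]),
                    rank = seq_len(top_k), stringsAsFactors = FALSE)
  tab[!(tab$gene %in% known_drivers), , drop = FALSE]
}

#' Attention interpretability report
#'
#' Extracts per-gene fusion attention weights (alpha over the PPI / GO /
#' Pathway views), their per-view means, and an average-linkage hierarchical
#' clustering of genes by attention profile (the attention-archetype
#' analysis).
#'
#' @param model a fitted `driver_fusion` (must not have the NFE ablation), or
#'   directly an N x 3 alpha matrix.
#' @param n_clusters number of clusters to cut the tree into.
#' @return an `attention_report`: list with `alpha`, `view_means`, `cluster`
#'   (integer assignment) and `hclust` (the tree).
#' @export
attention_report <- function(model, n_clusters = 4L) {
  alpha <- if (is.matrix(model)) model else model$alpha
  if (is.null(alpha)) {
    stop("no fusion attention available (NFE ablated?)", call. = FALSE)
  }
  stopifnot(ncol(alpha) == 3L)
  hc <- stats::hclust(stats::dist(alpha), method = "average")
  cl <- stats::cutree(hc, k = min(n_clusters, nrow(alpha)))
  structure(list(alpha = alpha, view_means = colMeans(alpha),
                 cluster = cl, hclust = hc),
            class = "attention_report")
}

#' @export
print.attention_report <- function(x, ...) {
  cat("attention report over", nrow(x$alpha), "genes\n")
  cat("  mean view attention:",
      paste(sprintf("%s %.3f", names(x$view_means), x$view_means),
            collapse = ", "), "\n")
  cat("  cluster sizes:", paste(table(x$cluster), collapse = ", "), "\n")
  invisible(x)
}

#' Write cross-validation artifacts
#'
#' Per-fold metrics CSV, per-gene out-of-fold score TSV, ranked
#' novel-candidate TSV and attention-report TSV, plus a JSON run manifest
#' capturing config, seed and package version.
#'
#' @param cv a `cv_driver_fusion`.
#' @param dir output directory.
#' @param top_k novel-candidate list size.
#' @param known_drivers symbols treated as known (defaults to the positives).
#' @return invisibly, the manifest list.
#' @export
write_cv_results <- function(cv, dir, top_k = 300L, known_drivers = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cv$folds, file.path(dir, "fold_metrics.csv"),
                   row.names = FALSE)
  oof <- data.frame(gene = names(cv$oof_scores), score = cv$oof_scores,
                    fold = cv$fold_assignment)
  utils::write.table(oof[!is.na(oof$score), ],
                     file.path(dir, "oof_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(k = cv$k, model = unclass(cv$model),
                   training = unclass(cv$training),
                   ablation = if (is.null(cv$ablation)) character() else
                     unclass(cv$ablation),
                   summary = cv$summary,
                   package_version = as.character(utils::packageVersion(
                     "driverfusion")))
  if (!is.null(cv$final)) {
    scores <- cv$final$scores
    if (is.null(known_drivers)) {
      known_drivers <- names(scores)[cv$final$labels$positives]
    }
    nc <- novel_candidates(scores, known_drivers, min(top_k, length(scores)))
    utils::write.table(nc, file.path(dir, "novel_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cv$final$alpha)) {
      rep_ <- attention_report(cv$final)
      utils::write.table(
        data.frame(gene = rownames(rep_$alpha), rep_$alpha,
                   cluster = rep_$cluster),
        file.path(dir, "attention_report.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Paired Wilcoxon comparison of fold metrics
#'
#' Helper for comparing two cross-validation runs fold-by-fold (signed-rank
#' test on a chosen metric).
#'
#' @param cv_a,cv_b `cv_driver_fusion` objects with the same k.
#' @param metric `"auroc"`, `"auprc"` or `"f1"`.
#' @return the [stats::wilcox.test()] result.
#' @export
compare_folds <- function(cv_a, cv_b, metric = c("auprc", "auroc", "f1")) {
  metric <- match.arg(metric)
  stopifnot(cv_a$k == cv_b$k)
  stats::wilcox.test(cv_a$folds[[metric]], cv_b$folds[[metric]],
                     paired = TRUE, exact = FALSE)
}
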