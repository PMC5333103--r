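#' Leave-one-out cross validation for one disease
#'
#' Each known disease gene is held out in turn and re-scored from the
#' remaining `K - 1` genes, so its score contains no self-information; its
#' genome-wide rank and rank ratio under that fold's training set are
#' recorded. Background (non-disease) genes are scored once with the full
#' `K`-gene set: rescoring every negative in every fold would cost `K`
#' complete reruns for scores that barely move, and the held-out gene's
#' assessment is what the protocol is about.
#'
#' @param D distance matrix (adjusted or raw) covering the component.
#' @param ds a [disease_gene_set()] or character vector with `K >= 2` genes,
#'   all present in `D`.
#' @param weight_mode passed to [disease_weights()].
#' @return object of class `loocv_result`: list with
#'   \describe{
#'     \item{folds}{data frame `gene`, `weight`, `rank`, `rank_ratio` for
#'       the `K` held-out genes}
#'     \item{scores}{named numeric over every gene of `D`: held-out weight
#'       for disease genes, full-set weight for the rest}
#'     \item{labels}{named 0/1 vector, 1 = known disease gene}
#'     \item{disease_id, n_genes, n_disease}{bookkeeping}
#'   }
#' @export
loocv <- function(D, ds, weight_mode = "difference") {
  disease_id <- if (inherits(ds, "disease_gene_set")) ds$disease_id else NA_character_
  dg <- if (inherits(ds, "disease_gene_set")) ds$genes else unique(as.character(ds))
  missing <- setdiff(dg, rownames(D))
  if (length(missing) > 0L) {
    stop("disease gene(s) not in the distance matrix: ",
         paste(missing, collapse = ", "))
  }
  K <- length(dg)
  if (K < 2L) stop("leave-one-out needs at least 2 disease genes")
  genes <- rownames(D)
  N <- length(genes)

  wv_full <- disease_weights(D, dg, weight_mode = weight_mode)
  scores <- wv_full$weight
  names(scores) <- wv_full$gene

  folds <- data.frame(gene = dg, weight = NA_real_, rank = NA_integer_,
                      rank_ratio = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(K)) {
    g <- dg[i]
    wv <- disease_weights(D, setdiff(dg, g), weight_mode = weight_mode)
    ranked <- rank_genes(wv)
    folds$weight[i] <- wv$weight[match(g, wv$gene)]
    folds$rank[i] <- ranked$rank[match(g, ranked$gene)]
    folds$rank_ratio[i] <- folds$rank[i] / N
    scores[g] <- folds$weight[i]
  }
  labels <- as.integer(genes %in% dg)
  names(labels) <- genes
  structure(list(folds = folds, scores = scores, labels = labels,
                 disease_id = disease_id, n_genes = N, n_disease = K),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("loocv_result '%s': %d disease genes over %d genes\n",
              x$disease_id, x$n_disease, x$n_genes))
  cat(sprintf("  median held-out rank ratio: %.3f\n",
              stats::median(x$folds$rank_ratio)))
  invisible(x)
}

#' Precision-recall curve, AUC and F-max
#'
#' Sweeps the distinct score values in descending order; at each threshold
#' `precision = TP/(TP+FP)` and `recall = TP/K` over the items scoring at or
#' above it (tied items enter together). The area under the curve is the
#' trapezoid over recall on the stepwise points, with the segment from
#' recall 0 to the first point taken at the first point's precision; no
#' precision interpolation. F-max is the maximum, over all thresholds, of
#' the F1 score `2PR/(P+R)`.
#'
#' @param scores numeric scores, larger = more disease-like.
#' @param labels 0/1 (or logical) labels, same length; both classes must be
#'   present.
#' @return object of class `pr_curve`: list with `points` (data frame
#'   `threshold`, `tp`, `fp`, `precision`, `recall`, `f1`), `auc`, `fmax`,
#'   `n_pos`, `n_neg`.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  if (any(is.na(scores)) || any(is.na(labels))) stop("NA in scores or labels")
  K <- sum(labels)
  if (K == 0L || K == length(labels)) {
    stop("need at least one positive and one negative label")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  cum_tp <- cumsum(l)
  cum_fp <- cumsum(1L - l)
  last <- c(which(diff(s) != 0), length(s))
  tp <- cum_tp[last]
  fp <- cum_fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / K
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall /
                 (precision + recall), 0)
  auc <- sum(diff(c(0, recall)) *
               (precision + c(precision[1], utils::head(precision, -1))) / 2)
  structure(list(points = data.frame(threshold = s[last], tp = tp, fp = fp,
                                     precision = precision, recall = recall,
                                     f1 = f1),
                 auc = auc, fmax = max(f1), n_pos = K,
                 n_neg = length(labels) - K),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("pr_curve: %d pos / %d neg, %d thresholds | AUC %.4f, F-max %.4f\n",
              x$n_pos, x$n_neg, nrow(x$points), x$auc, x$fmax))
  invisible(x)
}

#' True-positive rate among the top-k predictions
#'
#' Orders the LOOCV-scored genome-wide list (held-out scores for disease
#' genes, full-set scores for the rest; ties broken by gene id) and reports,
#' for each `k`, the number of known disease genes among the top `k`. The
#' default `"precision"` reading divides by `k` — the fraction of the top-k
#' shortlist that is a true disease gene, i.e. the hit rate an experimental
#' follow-up of `k` candidates would see. `"recall"` divides by `K` instead.
#'
#' @param lr a [loocv()] result.
#' @param ks integer thresholds, e.g. `c(50, 100, 150, 200)`.
#' @param mode `"precision"` (default) or `"recall"`.
#' @return data frame `k`, `hits`, `tpr`.
#' @export
tpr_at_k <- function(lr, ks = c(50L, 100L, 150L, 200L),
                     mode = c("precision", "recall")) {
  mode <- match.arg(mode)
  stopifnot(inherits(lr, "loocv_result"))
  ks <- as.integer(ks)
  if (any(ks < 1L) || any(ks > lr$n_genes)) {
    stop("each k must lie in [1, number of genes]")
  }
  o <- order(-lr$scores, names(lr$scores), method = "radix")
  l <- as.numeric(lr$labels[o])
  hits <- as.integer(vapply(ks, function(k) sum(l[seq_len(k)]), 1))
  denom <- if (mode == "precision") ks else rep(lr$n_disease, length(ks))
  data.frame(k = ks, hits = hits, tpr = hits / denom)
}

#' Rank ratio of a gene within a ranking
#'
#' The gene's 1-based rank divided by the number of ranked genes; lower is
#' better (0.01 = top percentile). Genes flagged `unranked` have no ratio.
#'
#' @param ranking data frame from [rank_genes()] or [prioritize_disease()].
#' @param gene single gene identifier.
#' @return numeric in `(0, 1]`, or `NA` for an unranked gene.
#' @export
rank_ratio <- function(ranking, gene) {
  i <- match(gene, ranking$gene)
  if (is.na(i)) stop("gene '", gene, "' not present in the ranking")
  if (isTRUE(ranking$unranked[i])) return(NA_real_)
  n_ranked <- sum(!ranking$unranked)
  ranking$rank[i] / n_ranked
}

#' Pool predictions across diseases into one precision-recall curve
#'
#' Raw weights are not comparable across diseases, so each disease's LOOCV
#' scores are first converted to precision scores (the same conversion as
#' [convert_scores()], with the held-out labels as the positives) and the
#' converted (score, label) pairs from all diseases are concatenated into a
#' single curve.
#'
#' @param results list of [loocv()] results (at least 2), or a list of
#'   `list(scores=, labels=)` pairs.
#' @param convert logical; set `FALSE` if the supplied scores are already
#'   cross-disease comparable.
#' @return a [pr_curve()] over the pooled pairs, with attribute `n_pooled`.
#' @export
pooled_pr <- function(results, convert = TRUE) {
  if (length(results) < 2L) stop("pooling needs at least 2 diseases")
  pooled_scores <- numeric()
  pooled_labels <- integer()
  for (r in results) {
    s <- r$scores
    l <- as.integer(r$labels)
    if (convert) {
      s <- precision_convert(s, l == 1L)$score
    }
    pooled_scores <- c(pooled_scores, s)
    pooled_labels <- c(pooled_labels, l)
  }
  out <- pr_curve(pooled_scores, pooled_labels)
  attr(out, "n_pooled") <- length(pooled_scores)
  out
}

#' Adjusted-versus-raw distance benefit, per disease
#'
#' Runs the whole LOOCV pipeline twice per disease — once on raw
#' shortest-path distances, once on centrality-adjusted distances — and
#' reports the F-max under each, together with the mean pairwise raw
#' distance among the disease genes (compactness of the disease module; the
#' adjustment tends to help compact modules and not scattered ones) and the
#' disease-size stratum.
#'
#' @param net a [gene_network()] or a [build_distance_cache()] cache.
#' @param gene_sets list of [disease_gene_set()] (as from
#'   [load_gene_sets()]).
#' @param mode normalization mode for the adjusted run.
#' @return data frame with one row per disease: `disease_id`, `n_genes`
#'   (`K`), `stratum`, `mean_disease_distance`, `fmax_raw`, `fmax_adjusted`,
#'   `auc_raw`, `auc_adjusted`.
#' @export
compare_raw_vs_adjusted <- function(net, gene_sets, mode = "geometric") {
  if (inherits(net, "gene_network")) {
    D <- raw_distances(net)
    Dadj <- adjust_distances(D, mode = mode)
  } else {
    D <- net$raw
    Dadj <- net$adjusted
  }
  rows <- lapply(gene_sets, function(ds) {
    dg <- intersect(ds$genes, rownames(D))
    lr_raw <- loocv(D, disease_gene_set(ds$disease_id, dg))
    lr_adj <- loocv(Dadj, disease_gene_set(ds$disease_id, dg))
    pr_raw <- pr_curve(lr_raw$scores, lr_raw$labels)
    pr_adj <- pr_curve(lr_adj$scores, lr_adj$labels)
    K <- length(dg)
    pairs <- D[dg, dg, drop = FALSE]
    mean_dd <- if (K > 1L) mean(pairs[upper.tri(pairs)]) else NA_real_
    data.frame(disease_id = ds$disease_id, n_genes = K,
               stratum = size_stratum(K), mean_disease_distance = mean_dd,
               fmax_raw = pr_raw$fmax, fmax_adjusted = pr_adj$fmax,
               auc_raw = pr_raw$auc, auc_adjusted = pr_adj$auc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

size_stratum <- function(K) {
  cut(K, breaks = c(0, 10, 50, 100, Inf),
      labels = c("<=10", "11-50", "51-100", ">100"))
}
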