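#' Disease-specific gene weights
#'
#' For every gene `i` of the component, the weight contrasts its mean
#' adjusted distance to *all* `N` genes with its mean adjusted distance to
#' the `K` known disease genes:
#'
#' `w_i = (1/N) sum_j Dadj[i, j]  -  (1/K) sum_{j in disease} Dadj[i, j]`
#'
#' A gene that sits relatively closer to the disease genes than to a random
#' gene gets a large positive weight; guilt by association, with the
#' all-gene mean as the per-gene baseline. A ratio variant
#' (`mean_all / mean_disease`) is available for sensitivity analysis.
#'
#' @param D adjusted (or raw, for comparison runs) distance matrix.
#' @param disease_genes character vector of known disease genes; must all be
#'   rows of `D`. May have length 1 (leave-one-out folds train on `K - 1`).
#' @param weight_mode `"difference"` (default) or `"ratio"`.
#' @return data frame with one row per gene of `D`: columns `gene`,
#'   `mean_all`, `mean_disease`, `weight`; attribute `weight_mode`.
#' @export
disease_weights <- function(D, disease_genes,
                            weight_mode = c("difference", "ratio")) {
  weight_mode <- match.arg(weight_mode)
  disease_genes <- unique(as.character(disease_genes))
  if (length(disease_genes) == 0L) stop("empty disease gene set")
  missing <- setdiff(disease_genes, rownames(D))
  if (length(missing) > 0L) {
    stop("disease gene(s) not in the distance matrix: ",
         paste(missing, collapse = ", "))
  }
  mean_all <- rowMeans(D)
  mean_disease <- rowMeans(D[, disease_genes, drop = FALSE])
  weight <- switch(weight_mode,
                   difference = mean_all - mean_disease,
                   ratio = mean_all / mean_disease)
  out <- data.frame(gene = rownames(D), mean_all = mean_all,
                    mean_disease = mean_disease, weight = weight,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "weight_mode") <- weight_mode
  out
}

#' Rank genes by weight
#'
#' Sorts genes by weight in descending order; ties are broken by ascending
#' gene identifier so the ranking is deterministic. Genes outside the
#' network's largest component carry no weight and are appended at the
#' bottom, flagged `unranked`.
#'
#' @param wv weight table from [disease_weights()].
#' @param off_component genes with no defined weight to append last.
#' @return data frame `rank`, `gene`, `weight`, `unranked`, ordered by rank.
#' @export
rank_genes <- function(wv, off_component = character()) {
  ord <- order(-wv$weight, wv$gene, method = "radix")
  ranked <- data.frame(rank = seq_along(ord), gene = wv$gene[ord],
                       weight = wv$weight[ord], unranked = FALSE,
                       stringsAsFactors = FALSE)
  if (length(off_component) > 0L) {
    extra <- data.frame(rank = nrow(ranked) + seq_along(sort(off_component)),
                        gene = sort(off_component), weight = NA_real_,
                        unranked = TRUE, stringsAsFactors = FALSE)
    ranked <- rbind(ranked, extra)
  }
  rownames(ranked) <- NULL
  ranked
}

# Core of the score conversion, shared by convert_scores() and the pooled
# cross-disease evaluation: precision TP/P at each distinct score threshold
# (inclusive: "at or above"), mapped back onto each item.
precision_convert <- function(scores, is_positive, inclusive = TRUE,
                              monotone = FALSE) {
  stopifnot(length(scores) == length(is_positive))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  cum_tp <- cumsum(as.numeric(is_positive[o]))
  # last index of each tie group = the inclusive ">= threshold" counts
  last <- c(which(diff(s) != 0), length(s))
  u <- s[last]
  P <- last
  TP <- cum_tp[last]
  if (!inclusive) {
    P <- c(0, P[-length(P)])
    TP <- c(0, TP[-length(TP)])
  }
  precision <- ifelse(P > 0, TP / P, NA_real_)
  if (monotone) precision <- cummax(ifelse(is.na(precision), 0, precision))
  thresholds <- data.frame(weight = u, P = P, TP = TP,
                           precision = precision)
  list(score = precision[match(scores, u)], thresholds = thresholds)
}

#' Convert weights to cross-disease-comparable precision scores
#'
#' Disease-specific weights order genes within one disease but are not
#' comparable across diseases. Each weight is therefore converted to the
#' precision `TP/P` among genes scoring at or above it, where `P` counts all
#' genes with weight `>= w` and `TP` counts the known disease genes among
#' them — the probability that a gene at that threshold is a disease gene.
#' At the weakest threshold every gene is admitted and the score equals the
#' prevalence `K/N`.
#'
#' The threshold is inclusive (`>=`) so that a gene's own threshold contains
#' itself and its ties; an exclusive reading would leave the top gene with a
#' 0/0 precision. Precision is reported as computed, not monotonized; set
#' `monotone = TRUE` for a running-max (isotonic) variant.
#'
#' @param wv weight table from [disease_weights()].
#' @param disease_genes the known disease genes (`TP` numerator).
#' @param inclusive logical; threshold includes the gene's own weight.
#' @param monotone logical; running-max precision down the ranking.
#' @return list with `scores` (named numeric per gene, in `[0, 1]`) and
#'   `thresholds` (data frame `weight`, `P`, `TP`, `precision`).
#' @export
convert_scores <- function(wv, disease_genes, inclusive = TRUE,
                           monotone = FALSE) {
  disease_genes <- unique(as.character(disease_genes))
  conv <- precision_convert(wv$weight, wv$gene %in% disease_genes,
                            inclusive = inclusive, monotone = monotone)
  scores <- conv$score
  names(scores) <- wv$gene
  list(scores = scores, thresholds = conv$thresholds)
}

#' Genome-wide prioritization for one disease
#'
#' Composes the three scoring steps — disease-specific weights over the
#' adjusted (or raw) distances, deterministic ranking, precision score
#' conversion — into the final ranked table. Known disease genes stay in the
#' ranking (the candidate list is genome-wide); they are marked by
#' `is_known` instead.
#'
#' @param x a [gene_network()], a distance matrix from [raw_distances()] /
#'   [adjust_distances()], or a cache from [build_distance_cache()].
#' @param ds a [disease_gene_set()] or a character vector of disease genes.
#'   Genes absent from the network are dropped (with a warning).
#' @param distance `"adjusted"` (default) or `"raw"`; only consulted when
#'   `x` is a network or cache.
#' @param mode normalization mode for [adjust_distances()] when `x` is a
#'   network.
#' @param weight_mode,inclusive,monotone passed to [disease_weights()] and
#'   [convert_scores()].
#' @return data frame `rank`, `gene`, `weight`, `score`, `is_known`,
#'   `unranked`; attribute `disease_id`.
#' @export
prioritize_disease <- function(x, ds, distance = c("adjusted", "raw"),
                               mode = "geometric",
                               weight_mode = "difference",
                               inclusive = TRUE, monotone = FALSE) {
  distance <- match.arg(distance)
  D <- resolve_distances(x, distance, mode)
  disease_id <- if (inherits(ds, "disease_gene_set")) ds$disease_id else NA_character_
  genes <- if (inherits(ds, "disease_gene_set")) ds$genes else as.character(ds)
  keep <- genes %in% rownames(D)
  if (any(!keep)) {
    warning(sprintf("%d disease gene(s) outside the ranked component dropped",
                    sum(!keep)))
    genes <- genes[keep]
  }
  if (length(genes) == 0L) stop("no disease gene lies in the ranked component")
  wv <- disease_weights(D, genes, weight_mode = weight_mode)
  ranked <- rank_genes(wv, off_component = attr(D, "off_component"))
  conv <- convert_scores(wv, genes, inclusive = inclusive,
                         monotone = monotone)
  ranked$score <- unname(conv$scores[ranked$gene])
  ranked$is_known <- ranked$gene %in% genes
  out <- ranked[, c("rank", "gene", "weight", "score", "is_known", "unranked")]
  attr(out, "disease_id") <- disease_id
  attr(out, "thresholds") <- conv$thresholds
  out
}

# Accept a network, a cache list, or a ready distance matrix.
resolve_distances <- function(x, distance = "adjusted", mode = "geometric") {
  if (inherits(x, "gene_network")) {
    D <- raw_distances(x)
    if (distance == "adjusted") D <- adjust_distances(D, mode = mode)
    return(D)
  }
  if (is.list(x) && all(c("raw", "adjusted") %in% names(x))) {
    D <- if (distance == "adjusted") x$adjusted else x$raw
    if (is.null(attr(D, "off_component"))) {
      attr(D, "off_component") <- x$off_component
    }
    return(D)
  }
  if (is.matrix(x)) return(x)
  stop("cannot interpret `x` as a network, distance cache, or matrix")
}
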