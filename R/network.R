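#' Construct a gene functional-association network
#'
#' A `gene_network` is an undirected weighted graph over gene identifiers.
#' Each edge carries an integer confidence score `S` in `(0, 1000]` (the
#' STRING convention: higher score, higher confidence that the two genes act
#' together). The constructor canonicalizes the edge list: self-loops are
#' dropped, each pair is stored with the lexicographically smaller identifier
#' first, and duplicate rows are merged keeping the maximum score.
#'
#' @param edges a data frame with columns `from`, `to`, `score` (extra
#'   columns are ignored). Scores must be integers in `(0, 1000]`.
#' @param genes optional character vector fixing the gene order; must contain
#'   every edge endpoint. Defaults to first-appearance order in `edges`.
#' @return An object of class `gene_network`: a list with elements `genes`
#'   (character vector, the node order) and `edges` (data frame with columns
#'   `from`, `to`, `score`, canonicalized as above).
#' @examples
#' net <- gene_network(data.frame(from = c("g1", "g2"),
#'                                to   = c("g2", "g3"),
#'                                score = c(800L, 150L)))
#' net
#' @seealso [load_network()] to read a STRING-style edge list from disk.
#' @export
gene_network <- function(edges, genes = NULL) {
  edges <- as.data.frame(edges)[, c("from", "to", "score")]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  check_scores(edges$score)
  edges$score <- as.integer(edges$score)

  appearance <- unique(c(rbind(edges$from, edges$to)))
  if (is.null(genes)) {
    genes <- appearance
  } else {
    genes <- as.character(genes)
    missing <- setdiff(appearance, genes)
    if (length(missing) > 0L) {
      stop("edge endpoints not in `genes`: ", paste(missing, collapse = ", "))
    }
  }
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")

  edges <- edges[edges$from != edges$to, , drop = FALSE]
  if (nrow(edges) > 0L) {
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    edges$from <- a
    edges$to <- b
    # duplicate pairs merge to the maximum confidence
    key <- paste(a, b, sep = "\r")
    if (anyDuplicated(key)) {
      score <- tapply(edges$score, key, max)
      first <- !duplicated(key)
      edges <- edges[first, , drop = FALSE]
      edges$score <- as.integer(score[paste(edges$from, edges$to, sep = "\r")])
    }
  }
  rownames(edges) <- NULL
  structure(list(genes = genes, edges = edges), class = "gene_network")
}

check_scores <- function(score) {
  if (length(score) == 0L) return(invisible(TRUE))
  bad <- !is.finite(score) | score <= 0 | score > 1000 | score != round(score)
  if (any(bad)) {
    stop("confidence scores must be integers in (0, 1000]; offending values: ",
         paste(utils::head(score[bad], 5L), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d edges\n",
              length(x$genes), nrow(x$edges)))
  if (nrow(x$edges) > 0L) {
    cat(sprintf("  confidence range: %d-%d\n",
                min(x$edges$score), max(x$edges$score)))
  }
  invisible(x)
}

#' @export
format.gene_network <- function(x, ...) {
  sprintf("gene_network(%d genes, %d edges)", length(x$genes), nrow(x$edges))
}

#' Number of genes and edges
#'
#' @param net a [gene_network()]
#' @return integer count.
#' @export
n_genes <- function(net) length(net$genes)

#' @rdname n_genes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Convert a gene network to an igraph graph
#'
#' Edge weights on the returned graph are raw network distances `1000/S`,
#' ready for shortest-path computation.
#'
#' @param net a [gene_network()]
#' @return an undirected `igraph` graph whose `weight` edge attribute holds
#'   `1000/S` and whose `score` attribute holds the original confidence.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  d <- net$edges
  d$weight <- edge_distance(d$score)
  igraph::graph_from_data_frame(
    d, directed = FALSE,
    vertices = data.frame(name = net$genes, stringsAsFactors = FALSE)
  )
}

#' Construct a disease gene set
#'
#' @param disease_id single string naming the disease.
#' @param genes character vector of gene identifiers; duplicates are removed.
#' @return An object of class `disease_gene_set` with elements `disease_id`
#'   and `genes`.
#' @export
disease_gene_set <- function(disease_id, genes) {
  stopifnot(is.character(disease_id), length(disease_id) == 1L)
  structure(list(disease_id = disease_id,
                 genes = unique(as.character(genes))),
            class = "disease_gene_set")
}

#' @export
print.disease_gene_set <- function(x, ...) {
  cat(sprintf("disease_gene_set '%s': %d genes\n",
              x$disease_id, length(x$genes)))
  invisible(x)
}

#' Restrict a disease gene set to the genes of a network
#'
#' Genes absent from the network are dropped with a warning giving the count.
#'
#' @param ds a [disease_gene_set()]
#' @param network a [gene_network()], or a character vector of gene ids.
#' @return the restricted `disease_gene_set`.
#' @export
intersect_with_network <- function(ds, network) {
  genes <- if (inherits(network, "gene_network")) network$genes else network
  keep <- ds$genes %in% genes
  if (any(!keep)) {
    warning(sprintf("disease '%s': %d gene(s) not in the network dropped",
                    ds$disease_id, sum(!keep)))
  }
  ds$genes <- ds$genes[keep]
  ds
}
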