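#' Raw edge distance from a confidence score
#'
#' An edge with confidence `S` has raw distance `1000/S`, so the highest
#' confidence (`S = 1000`) gives distance 1 and lower confidence gives
#' proportionally longer distances.
#'
#' @param score integer confidence score(s) in `(0, 1000]`.
#' @return numeric vector of distances `1000/score`.
#' @examples
#' edge_distance(c(1000, 400, 150))  # 1.0, 2.5, 6.667
#' @export
edge_distance <- function(score) {
  if (any(!is.finite(score) | score <= 0 | score > 1000)) {
    stop("confidence score must lie in (0, 1000]")
  }
  1000 / score
}

#' All-pairs raw shortest-path distances
#'
#' Runs Dijkstra's algorithm from every node of the network over edge
#' weights `1000/S`. `D[a, b]` is the length of the cheapest path between
#' `a` and `b`; `D[a, a] = 0`. Computation is restricted to the largest
#' connected component: infinite distances to unreachable genes would poison
#' every downstream mean, so genes outside the component are excluded from
#' the matrix and recorded in the `off_component` attribute (downstream
#' ranking appends them, flagged unranked).
#'
#' @param net a [gene_network()] with at least 2 genes.
#' @return symmetric numeric matrix with `dimnames` set to the component's
#'   genes (network order preserved) and attribute `off_component`, the
#'   character vector of excluded genes.
#' @export
raw_distances <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  if (length(net$genes) < 2L) stop("network must contain at least 2 genes")
  g <- as_igraph(net)
  comp <- igraph::components(g)
  keep_comp <- which.max(comp$csize)
  member <- names(comp$membership)[comp$membership == keep_comp]
  keep <- net$genes[net$genes %in% member]
  off <- setdiff(net$genes, keep)
  sub <- igraph::induced_subgraph(g, keep)
  D <- igraph::distances(sub, v = keep, to = keep,
                         weights = igraph::E(sub)$weight,
                         algorithm = "dijkstra")
  D <- D[keep, keep, drop = FALSE]
  attr(D, "off_component") <- off
  attr(D, "distance_kind") <- "raw"
  D
}

#' Per-gene mean raw distance (centrality profile)
#'
#' The mean raw network distance of gene `a` is
#' `mu_a = (1/N) * sum_j D[a, j]` over all `N` genes of the component,
#' including the zero self term. A small `mu` marks a central (hub-like)
#' gene that is close to everything.
#'
#' @param D distance matrix from [raw_distances()].
#' @param divisor `"N"` (default) divides by the number of genes including
#'   the self term; `"N-1"` excludes it. Both are exposed because the mean's
#'   exact denominator is a modelling choice; rankings are insensitive to it
#'   (the two differ by the constant factor `N/(N-1)`).
#' @return named numeric vector `mu` over the matrix's genes.
#' @export
mean_raw_distance <- function(D, divisor = c("N", "N-1")) {
  divisor <- match.arg(divisor)
  n <- ncol(D)
  mu <- rowSums(D) / if (divisor == "N") n else n - 1L
  mu
}

#' Centrality-adjusted network distances
#'
#' Normalizes each raw distance by the endpoint centralities so that a short
#' raw distance to a hub (which is close to *everything*) counts for less
#' than an equally short distance to a peripheral gene. Three symmetric
#' normalization forms are provided; all leave the diagonal at zero.
#'
#' \describe{
#'   \item{geometric (default)}{`Dadj[a,b] = D[a,b] / sqrt(mu_a * mu_b)`}
#'   \item{arithmetic}{`Dadj[a,b] = 2 * D[a,b] / (mu_a + mu_b)`}
#'   \item{product}{`Dadj[a,b] = D[a,b]^2 / (mu_a * mu_b)`}
#' }
#'
#' The geometric and arithmetic forms are dimensionless and invariant under
#' a uniform rescaling of all raw distances; the product form rescales
#' quadratically in the numerator and so shares the invariance.
#'
#' @param D raw distance matrix from [raw_distances()].
#' @param mu optional centrality profile; computed from `D` by default.
#' @param mode normalization variant, see above.
#' @return adjusted distance matrix with the same `dimnames` and
#'   `off_component` attribute as `D`.
#' @export
adjust_distances <- function(D, mu = NULL,
                             mode = c("geometric", "arithmetic", "product")) {
  mode <- match.arg(mode)
  if (is.null(mu)) mu <- mean_raw_distance(D)
  if (any(mu <= 0)) {
    stop("mean raw distance must be positive for every gene ",
         "(isolated gene in a >= 2 gene component?)")
  }
  Dadj <- switch(mode,
    geometric  = D / sqrt(outer(mu, mu)),
    arithmetic = 2 * D / outer(mu, mu, `+`),
    product    = D^2 / outer(mu, mu)
  )
  dimnames(Dadj) <- dimnames(D)
  attr(Dadj, "off_component") <- attr(D, "off_component")
  attr(Dadj, "distance_kind") <- "adjusted"
  attr(Dadj, "mode") <- mode
  Dadj
}

#' Build (or load) a distance cache for a network
#'
#' Computing the all-pairs matrix is the expensive step and is reused across
#' diseases, so it is computed once and serialized. The cache stores the raw
#' matrix, the adjusted matrix under the requested mode, the gene order, the
#' off-component genes, and an edge-list digest used to detect stale caches.
#'
#' @param net a [gene_network()].
#' @param mode normalization mode passed to [adjust_distances()].
#' @param path optional path; when given, the cache list is `saveRDS()`ed
#'   there.
#' @return invisibly, the cache: a list with elements `genes`, `raw`,
#'   `adjusted`, `mode`, `off_component`, `edge_digest`.
#' @export
build_distance_cache <- function(net, mode = "geometric", path = NULL) {
  D <- raw_distances(net)
  Dadj <- adjust_distances(D, mode = mode)
  cache <- list(
    genes = rownames(D),
    raw = D,
    adjusted = Dadj,
    mode = mode,
    off_component = attr(D, "off_component"),
    edge_digest = edge_digest(net)
  )
  if (!is.null(path)) saveRDS(cache, path)
  invisible(cache)
}

#' @rdname build_distance_cache
#' @param path path of a cache written by `build_distance_cache`.
#' @export
load_distance_cache <- function(path) {
  if (!file.exists(path)) stop_data("distance cache not found: ", path)
  cache <- readRDS(path)
  need <- c("genes", "raw", "adjusted", "mode")
  if (!is.list(cache) || !all(need %in% names(cache))) {
    stop_data("not a netprio distance cache: ", path)
  }
  cache
}

edge_digest <- function(net) {
  e <- net$edges
  lines <- paste(e$from, e$to, e$score, sep = "\t")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(lines, f)
  unname(tools::md5sum(f))
}
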