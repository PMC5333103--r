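#' Describe a synthetic-network scenario
#'
#' Bundles the parameters of the generator into a validated object that can
#' be serialized to JSON ([write_scenario()]) and reproduced exactly from
#' its seed. The generated networks emulate the structure the prioritization
#' method exploits: a sparse background of mostly low-confidence functional
#' associations with one or more planted disease modules — small gene sets
#' that are densely interconnected at high confidence. Setting the module
#' edge probability and confidence equal to the background values ("zero
#' cohesion") turns the module genes into an exchangeable random gene set,
#' the null condition.
#'
#' Defaults describe the standard planted-module test bed used throughout
#' the package: 300 genes, one module of 15, within-module confidence around
#' 900 (distance ~1.1) at edge probability 0.8, background confidence around
#' 200 (distance 5) at edge probability 0.02 (mean background degree ~6).
#'
#' @param n_genes number of genes.
#' @param background_p background (Erdos-Renyi) edge probability.
#' @param background_score_mean,background_score_sd normal parameters of
#'   background confidence scores, rounded to integers and clamped to
#'   `[1, 1000]`.
#' @param module_sizes integer vector, one planted module per entry.
#' @param module_p within-module edge probability.
#' @param module_score_mean,module_score_sd confidence distribution of
#'   within-module edges.
#' @param n_hubs number of designated hub genes connected to every other
#'   gene.
#' @param hub_score confidence of hub edges.
#' @param backbone_score confidence of the low-confidence spanning edges
#'   added only if the draw is disconnected.
#' @param topology `"er"` (Erdos-Renyi background) or `"pa"` (preferential
#'   attachment, for hub-heavy backgrounds).
#' @param seed integer RNG seed; part of the scenario.
#' @return object of class `synthetic_scenario` (a validated list).
#' @export
synthetic_scenario <- function(n_genes = 300L,
                               background_p = 0.02,
                               background_score_mean = 200,
                               background_score_sd = 50,
                               module_sizes = 15L,
                               module_p = 0.8,
                               module_score_mean = 900,
                               module_score_sd = 50,
                               n_hubs = 0L,
                               hub_score = 800L,
                               backbone_score = 100L,
                               topology = c("er", "pa"),
                               seed = 1L) {
  topology <- match.arg(topology)
  sc <- list(n_genes = as.integer(n_genes),
             background_p = as.numeric(background_p),
             background_score_mean = as.numeric(background_score_mean),
             background_score_sd = as.numeric(background_score_sd),
             module_sizes = as.integer(module_sizes),
             module_p = as.numeric(module_p),
             module_score_mean = as.numeric(module_score_mean),
             module_score_sd = as.numeric(module_score_sd),
             n_hubs = as.integer(n_hubs),
             hub_score = as.integer(hub_score),
             backbone_score = as.integer(backbone_score),
             topology = topology, seed = as.integer(seed))
  validate_scenario(sc)
  structure(sc, class = "synthetic_scenario")
}

validate_scenario <- function(sc) {
  if (sc$n_genes < 3L) stop("scenario needs at least 3 genes")
  if (sum(sc$module_sizes) + sc$n_hubs > sc$n_genes) {
    stop("modules plus hubs exceed the number of genes")
  }
  if (any(sc$module_sizes < 2L)) stop("each module needs at least 2 genes")
  if (sc$background_p < 0 || sc$background_p > 1 ||
      sc$module_p < 0 || sc$module_p > 1) {
    stop("edge probabilities must lie in [0, 1]")
  }
  for (s in c(sc$hub_score, sc$backbone_score)) {
    if (s < 1L || s > 1000L) stop("scores must lie in [1, 1000]")
  }
  invisible(sc)
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "synthetic_scenario: %d genes, modules {%s}, bg p=%.3g S~N(%g,%g), module p=%.3g S~N(%g,%g), %d hub(s), seed %d\n",
    x$n_genes, paste(x$module_sizes, collapse = ","), x$background_p,
    x$background_score_mean, x$background_score_sd, x$module_p,
    x$module_score_mean, x$module_score_sd, x$n_hubs, x$seed))
  invisible(x)
}

#' Serialize / restore a scenario as JSON
#'
#' @param sc a [synthetic_scenario()].
#' @param path file path.
#' @return `write_scenario` invisibly returns `path`; `read_scenario`
#'   returns the scenario.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  jsonlite::write_json(unclass(sc), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop_data("scenario file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(synthetic_scenario))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop_data("unknown scenario key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(synthetic_scenario, raw)
}

# draw integer confidence scores from a truncated, rounded normal
draw_scores <- function(n, mean, sd) {
  pmin(pmax(round(stats::rnorm(n, mean, sd)), 1), 1000)
}

#' Generate a synthetic network with planted disease modules
#'
#' Reproducible given the scenario's seed (the caller's RNG state is left
#' untouched). Gene ids are zero-padded (`g001`, ...) so lexicographic and
#' numeric order agree. Module genes are the first ids, hubs the last. If
#' the drawn graph is disconnected, a low-confidence backbone edge joins
#' each extra component to the largest one, keeping every gene reachable
#' without materially shortening within-module paths.
#'
#' @param sc a [synthetic_scenario()].
#' @return list with `network` (a [gene_network()]), `gene_sets` (named list
#'   of [disease_gene_set()], the planted ground truth, ids `module1`, ...),
#'   `hubs` (character vector), and `scenario`.
#' @export
generate_scenario <- function(sc) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(sc$seed)

  width <- max(3L, nchar(as.character(sc$n_genes)))
  genes <- sprintf(paste0("g%0", width, "d"), seq_len(sc$n_genes))
  hubs <- if (sc$n_hubs > 0L) utils::tail(genes, sc$n_hubs) else character()

  # planted modules take the leading ids, disjointly
  offsets <- cumsum(c(0L, sc$module_sizes))
  modules <- lapply(seq_along(sc$module_sizes), function(m) {
    genes[(offsets[m] + 1L):offsets[m + 1L]]
  })

  # background topology
  g_bg <- if (sc$topology == "er") {
    igraph::sample_gnp(sc$n_genes, sc$background_p, directed = FALSE)
  } else {
    igraph::sample_pa(sc$n_genes, m = max(1L, round(sc$background_p * sc$n_genes / 2)),
                      directed = FALSE)
  }
  bg <- igraph::as_edgelist(g_bg, names = FALSE)
  edges <- data.frame(from = genes[bg[, 1L]], to = genes[bg[, 2L]],
                      score = draw_scores(nrow(bg), sc$background_score_mean,
                                          sc$background_score_sd),
                      stringsAsFactors = FALSE)

  # within-module edges
  for (mod in modules) {
    pairs <- utils::combn(mod, 2L)
    keep <- stats::runif(ncol(pairs)) < sc$module_p
    if (any(keep)) {
      edges <- rbind(edges, data.frame(
        from = pairs[1L, keep], to = pairs[2L, keep],
        score = draw_scores(sum(keep), sc$module_score_mean,
                            sc$module_score_sd),
        stringsAsFactors = FALSE))
    }
  }

  # hub spokes
  for (h in hubs) {
    others <- setdiff(genes, h)
    edges <- rbind(edges, data.frame(from = h, to = others,
                                     score = sc$hub_score,
                                     stringsAsFactors = FALSE))
  }

  net <- gene_network(edges, genes = genes)
  net <- connect_backbone(net, sc$backbone_score)

  gene_sets <- lapply(seq_along(modules), function(m) {
    disease_gene_set(paste0("module", m), modules[[m]])
  })
  names(gene_sets) <- vapply(gene_sets, function(s) s$disease_id, "")
  list(network = net, gene_sets = gene_sets, hubs = hubs, scenario = sc)
}

# join any extra components to the largest one with low-confidence edges
connect_backbone <- function(net, backbone_score) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  if (comp$no <= 1L) return(net)
  main <- which.max(comp$csize)
  membership <- comp$membership[net$genes]
  anchor <- net$genes[membership == main][1L]
  extra <- lapply(setdiff(seq_len(comp$no), main), function(cid) {
    rep_gene <- net$genes[membership == cid][1L]
    data.frame(from = anchor, to = rep_gene,
               score = as.integer(backbone_score), stringsAsFactors = FALSE)
  })
  gene_network(rbind(net$edges, do.call(rbind, extra)), genes = net$genes)
}

#' Hub-distortion fixture
#'
#' A designed network that isolates the centrality problem the distance
#' adjustment addresses: one hub gene connected to every other gene at
#' uniform confidence, a module of higher mutual confidence among a subset
#' of the leaves, and (unless `pure_star`) a moderate-confidence background
#' among the leaves. The hub's raw shortest-path distance to the module is
#' as short as to anything else, so under raw distances it ranks directly
#' after the module genes; its mean raw distance is the smallest in the
#' network, and the centrality adjustment discounts that indiscriminate
#' closeness. The defaults place the background's confidence close enough
#' to the hub's that genuine multi-edge background paths compete with the
#' hub shortcut — the regime in which hub centrality misleads the raw
#' distance and the adjustment demotes the hub.
#'
#' @param n_leaves number of non-hub genes (>= 3).
#' @param n_module size of the planted module among the leaves (>= 3).
#' @param seed RNG seed for the background edges.
#' @param pure_star drop the background so that removing the hub
#'   disconnects the graph (exercises the largest-component policy).
#' @param hub_score,module_score,background_score,background_p edge
#'   parameters.
#' @return list with `network`, `hub` (gene id), `module` (a
#'   [disease_gene_set()] with id `"module"`), and the parameters.
#' @export
hub_fixture <- function(n_leaves = 60L, n_module = 5L, seed = 1L,
                        pure_star = FALSE, hub_score = 700L,
                        module_score = 600L, background_score = 400L,
                        background_p = 0.12) {
  if (n_leaves < 3L || n_module < 3L) {
    stop("need n_leaves >= 3 and n_module >= 3")
  }
  if (n_module > n_leaves) stop("module cannot exceed the number of leaves")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  width <- max(2L, nchar(as.character(n_leaves)))
  leaves <- sprintf(paste0("L%0", width, "d"), seq_len(n_leaves))
  hub <- "hub"
  module <- leaves[seq_len(n_module)]

  edges <- data.frame(from = hub, to = leaves,
                      score = as.integer(hub_score),
                      stringsAsFactors = FALSE)
  pairs <- utils::combn(module, 2L)
  edges <- rbind(edges, data.frame(from = pairs[1L, ], to = pairs[2L, ],
                                   score = as.integer(module_score),
                                   stringsAsFactors = FALSE))
  if (!pure_star) {
    all_pairs <- utils::combn(leaves, 2L)
    in_module <- all_pairs[1L, ] %in% module & all_pairs[2L, ] %in% module
    cand <- all_pairs[, !in_module, drop = FALSE]
    keep <- stats::runif(ncol(cand)) < background_p
    if (any(keep)) {
      edges <- rbind(edges, data.frame(
        from = cand[1L, keep], to = cand[2L, keep],
        score = as.integer(background_score), stringsAsFactors = FALSE))
    }
  }
  net <- gene_network(edges, genes = c(hub, leaves))
  list(network = net, hub = hub,
       module = disease_gene_set("module", module),
       n_leaves = n_leaves, n_module = n_module, seed = seed,
       pure_star = pure_star)
}
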