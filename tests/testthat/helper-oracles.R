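# Independent oracles used by the unit and acceptance tests. These never
# call the package's own distance/weighting code paths: shortest paths come
# from a vectorized Floyd-Warshall recursion, and the formula oracles are
# literal direct summations.

# Confidence scores whose 1000/S distance is an exact multiple of 0.25, so
# path sums are exactly representable and two correct shortest-path
# implementations must agree bit for bit.
dyadic_scores <- c(1000L, 800L, 500L, 400L, 250L, 200L, 125L, 100L,
                   50L, 40L, 25L, 20L, 10L, 8L, 5L, 4L)

# Floyd-Warshall all-pairs shortest paths over 1000/S edge weights,
# straight from the edge list.
fw_distances <- function(net) {
  genes <- net$genes
  n <- length(genes)
  D <- matrix(Inf, n, n, dimnames = list(genes, genes))
  diag(D) <- 0
  for (r in seq_len(nrow(net$edges))) {
    i <- match(net$edges$from[r], genes)
    j <- match(net$edges$to[r], genes)
    d <- 1000 / net$edges$score[r]
    if (d < D[i, j]) D[i, j] <- D[j, i] <- d
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# Random connected graph on n nodes: a random recursive spanning tree plus
# extra random edges, with scores from `pool`.
random_connected_net <- function(n, seed, pool = dyadic_scores) {
  set.seed(seed)
  genes <- sprintf("n%02d", seq_len(n))
  from <- integer(0)
  to <- integer(0)
  for (i in 2:n) {
    from <- c(from, sample.int(i - 1L, 1L))
    to <- c(to, i)
  }
  n_extra <- sample.int(2L * n, 1L)
  a <- sample.int(n, n_extra, replace = TRUE)
  b <- sample.int(n, n_extra, replace = TRUE)
  keep <- a != b
  from <- c(from, a[keep])
  to <- c(to, b[keep])
  gene_network(data.frame(from = genes[from], to = genes[to],
                          score = sample(pool, length(from), replace = TRUE),
                          stringsAsFactors = FALSE),
               genes = genes)
}

# mu by explicit summation
oracle_mu <- function(D) {
  n <- ncol(D)
  mu <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) s <- s + D[i, j]
    mu[i] <- s / n
  }
  names(mu) <- rownames(D)
  mu
}

# adjusted distance by explicit per-entry evaluation
oracle_adjust <- function(D, mode) {
  mu <- oracle_mu(D)
  n <- ncol(D)
  A <- matrix(0, n, n, dimnames = dimnames(D))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      A[i, j] <- switch(mode,
        geometric  = D[i, j] / sqrt(mu[i] * mu[j]),
        arithmetic = 2 * D[i, j] / (mu[i] + mu[j]),
        product    = D[i, j]^2 / (mu[i] * mu[j]))
    }
  }
  A
}

# disease weight by explicit summation
oracle_weights <- function(Dadj, disease_genes) {
  genes <- rownames(Dadj)
  N <- length(genes)
  K <- length(disease_genes)
  w <- numeric(N)
  for (i in seq_len(N)) {
    all_sum <- 0
    for (j in seq_len(N)) all_sum <- all_sum + Dadj[i, j]
    dis_sum <- 0
    for (g in disease_genes) dis_sum <- dis_sum + Dadj[i, g]
    w[i] <- all_sum / N - dis_sum / K
  }
  names(w) <- genes
  w
}

# precision conversion by explicit counting at each gene's own weight
oracle_precision <- function(weights, disease_genes) {
  genes <- names(weights)
  vapply(genes, function(g) {
    at_or_above <- weights >= weights[g]
    sum(at_or_above & genes %in% disease_genes) / sum(at_or_above)
  }, 1)
}

# trapezoidal area under the (recall, precision) points of a pr_curve
# object, recomputed from its points (used for sanity checks)
oracle_trapezoid <- function(recall, precision) {
  r0 <- c(0, recall[-length(recall)])
  p0 <- c(precision[1], precision[-length(precision)])
  sum((recall - r0) * (precision + p0) / 2)
}

# small planted-module scenario for unit tests (cheaper than the full
# 300-gene test bed)
small_planted <- function(seed) {
  generate_scenario(synthetic_scenario(
    n_genes = 120L, module_sizes = 8L, background_p = 0.04, seed = seed))
}
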