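toy_adjusted <- function(seed = 1, n = 20) {
  net <- random_connected_net(n, seed = seed)
  adjust_distances(raw_distances(net))
}

test_that("taking the whole network as the disease set zeroes all weights", {
  Dadj <- toy_adjusted()
  wv <- disease_weights(Dadj, rownames(Dadj))
  expect_equal(wv$weight, rep(0, nrow(wv)))
})

test_that("weights match the direct-summation oracle", {
  for (s in 1:5) {
    Dadj <- toy_adjusted(seed = s)
    dg <- sample(rownames(Dadj), 4)
    wv <- disease_weights(Dadj, dg)
    w_oracle <- oracle_weights(Dadj, dg)
    expect_equal(wv$weight, unname(w_oracle[wv$gene]), tolerance = 1e-12)
    # enlarging the disease set re-derives cleanly too
    dg2 <- c(dg, sample(setdiff(rownames(Dadj), dg), 1))
    wv2 <- disease_weights(Dadj, dg2)
    expect_equal(wv2$weight, unname(oracle_weights(Dadj, dg2)[wv2$gene]),
                 tolerance = 1e-12)
  }
})

test_that("N * mean_all equals the adjusted-matrix row sums", {
  Dadj <- toy_adjusted(seed = 9)
  wv <- disease_weights(Dadj, rownames(Dadj)[1:3])
  expect_equal(nrow(wv) * wv$mean_all,
               unname(rowSums(Dadj)[wv$gene]), tolerance = 1e-6)
})

test_that("module genes out-weigh background genes on a planted module", {
  sim <- small_planted(seed = 4)
  Dadj <- adjust_distances(raw_distances(sim$network))
  dg <- sim$gene_sets$module1$genes
  wv <- disease_weights(Dadj, dg)
  in_mod <- wv$gene %in% dg
  expect_gt(mean(wv$weight[in_mod]), mean(wv$weight[!in_mod]))
})

test_that("the ratio weight mode is available and differs", {
  Dadj <- toy_adjusted(seed = 2)
  dg <- rownames(Dadj)[1:3]
  w_diff <- disease_weights(Dadj, dg)
  w_ratio <- disease_weights(Dadj, dg, weight_mode = "ratio")
  expect_equal(w_ratio$weight, w_ratio$mean_all / w_ratio$mean_disease)
  expect_false(isTRUE(all.equal(w_diff$weight, w_ratio$weight)))
})

test_that("ranking is descending with lexicographic tie-break", {
  wv <- data.frame(gene = c("g1", "g2", "g3"),
                   weight = c(0.2, 0.5, 0.2))
  rk <- rank_genes(wv)
  expect_equal(rk$gene, c("g2", "g1", "g3"))
  expect_equal(rk$rank, 1:3)
  # all-equal weights fall back to pure id order
  wv$weight <- 1
  expect_equal(rank_genes(wv)$gene, c("g1", "g2", "g3"))
})

test_that("ranking ignores the input row order", {
  wv <- data.frame(gene = c("b", "a", "d", "c"),
                   weight = c(1, 3, 1, 2))
  perm <- wv[c(3, 1, 4, 2), ]
  expect_equal(rank_genes(wv), rank_genes(perm))
})

test_that("off-component genes are appended unranked in id order", {
  wv <- data.frame(gene = c("a", "b"), weight = c(1, 2))
  rk <- rank_genes(wv, off_component = c("z", "y"))
  expect_equal(rk$gene, c("b", "a", "y", "z"))
  expect_equal(rk$unranked, c(FALSE, FALSE, TRUE, TRUE))
  expect_true(all(is.na(rk$weight[3:4])))
})

test_that("precision conversion counts TP/P at inclusive thresholds", {
  wv <- data.frame(gene = paste0("g", 1:4), weight = c(4, 3, 2, 1))
  conv <- convert_scores(wv, disease_genes = "g1")
  expect_equal(unname(conv$scores), c(1, 1 / 2, 1 / 3, 1 / 4))
  expect_equal(conv$thresholds$P, 1:4)
  expect_equal(conv$thresholds$TP, rep(1, 4))
})

test_that("perfect separation gives the top genes score 1", {
  wv <- data.frame(gene = paste0("g", 1:6), weight = 6:1)
  conv <- convert_scores(wv, disease_genes = c("g1", "g2"))
  expect_equal(unname(conv$scores[1:2]), c(1, 1))
})

test_that("the weakest threshold score equals prevalence K/N", {
  for (s in 1:5) {
    Dadj <- toy_adjusted(seed = 20 + s)
    dg <- sample(rownames(Dadj), 3)
    wv <- disease_weights(Dadj, dg)
    conv <- convert_scores(wv, dg)
    expect_equal(min(conv$thresholds$precision[nrow(conv$thresholds)]),
                 length(dg) / nrow(wv))
  }
})

test_that("tied weights share one converted score", {
  wv <- data.frame(gene = paste0("g", 1:5), weight = c(3, 2, 2, 2, 1))
  conv <- convert_scores(wv, disease_genes = c("g2", "g5"))
  expect_equal(conv$scores[["g2"]], conv$scores[["g3"]])
  expect_equal(conv$scores[["g3"]], conv$scores[["g4"]])
})

test_that("converted scores match the per-gene counting oracle", {
  for (s in 1:5) {
    Dadj <- toy_adjusted(seed = 30 + s)
    dg <- sample(rownames(Dadj), 4)
    wv <- disease_weights(Dadj, dg)
    conv <- convert_scores(wv, dg)
    w <- stats::setNames(wv$weight, wv$gene)
    expect_equal(conv$scores[names(w)], oracle_precision(w, dg),
                 tolerance = 1e-12)
  }
})

test_that("monotone mode yields a running-max precision profile", {
  wv <- data.frame(gene = paste0("g", 1:6), weight = 6:1)
  plain <- convert_scores(wv, disease_genes = c("g2", "g3"))
  mono <- convert_scores(wv, disease_genes = c("g2", "g3"),
                         monotone = TRUE)
  expect_equal(mono$thresholds$precision,
               cummax(plain$thresholds$precision))
  expect_false(isTRUE(all.equal(mono$scores, plain$scores)))
})

test_that("full prioritization is deterministic and complete", {
  sim <- small_planted(seed = 6)
  ds <- sim$gene_sets$module1
  t1 <- prioritize_disease(sim$network, ds)
  t2 <- prioritize_disease(sim$network, ds)
  expect_identical(t1, t2)
  expect_setequal(t1$gene, sim$network$genes)
  expect_equal(t1$rank, seq_len(nrow(t1)))
  expect_equal(sum(t1$is_known), length(ds$genes))
})

test_that("a minimum-size disease set of two genes runs end to end", {
  net <- random_connected_net(15, seed = 8)
  tab <- prioritize_disease(net, rownames(raw_distances(net))[1:2])
  expect_equal(nrow(tab), 15L)
})

test_that("off-network disease genes are dropped with a warning", {
  net <- random_connected_net(10, seed = 8)
  expect_warning(
    tab <- prioritize_disease(net, c(net$genes[1:2], "ghost")),
    "dropped")
  expect_false("ghost" %in% tab$gene)
  expect_equal(sum(tab$is_known), 2L)
})
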