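test_that("leave-one-out runs K folds and scores every gene once", {
  sim <- small_planted(seed = 1)
  Dadj <- adjust_distances(raw_distances(sim$network))
  ds <- sim$gene_sets$module1
  lr <- loocv(Dadj, ds)
  expect_equal(nrow(lr$folds), length(ds$genes))
  expect_setequal(names(lr$scores), rownames(Dadj))
  expect_equal(sum(lr$labels), length(ds$genes))
  expect_equal(anyDuplicated(names(lr$scores)), 0L)
  # held-out scores come from the K-1 training set, not the full set
  full <- disease_weights(Dadj, ds$genes)
  g <- ds$genes[1]
  expect_false(isTRUE(all.equal(lr$scores[[g]],
                                full$weight[match(g, full$gene)])))
})

test_that("the smallest legal disease set (K = 2) yields two folds", {
  net <- random_connected_net(12, seed = 2)
  D <- adjust_distances(raw_distances(net))
  lr <- loocv(D, rownames(D)[1:2])
  expect_equal(nrow(lr$folds), 2L)
  expect_error(loocv(D, rownames(D)[1]), "at least 2")
})

test_that("removing then re-adding a gene reproduces the full-set weights", {
  net <- random_connected_net(15, seed = 3)
  D <- adjust_distances(raw_distances(net))
  dg <- rownames(D)[1:4]
  w1 <- disease_weights(D, dg)
  w2 <- disease_weights(D, c(setdiff(dg, dg[2]), dg[2]))
  expect_equal(w1$weight, w2$weight)
})

test_that("a planted module is recovered with low held-out rank ratios", {
  sim <- small_planted(seed = 5)
  Dadj <- adjust_distances(raw_distances(sim$network))
  lr <- loocv(Dadj, sim$gene_sets$module1)
  expect_lt(median(lr$folds$rank_ratio), 0.5)
  # and far better than under permuted gene labels
  set.seed(99)
  random_set <- sample(rownames(Dadj), lr$n_disease)
  lr_perm <- loocv(Dadj, random_set)
  expect_lt(median(lr$folds$rank_ratio),
            median(lr_perm$folds$rank_ratio))
})

test_that("the PR curve reproduces a hand-enumerated example", {
  # scores: pos 0.9, neg 0.8, pos 0.7, neg 0.1
  pc <- pr_curve(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
  expect_equal(pc$points$recall, c(0.5, 0.5, 1, 1))
  expect_equal(pc$points$precision, c(1, 0.5, 2 / 3, 0.5))
  expect_equal(pc$fmax, 0.8)
  expect_equal(pc$auc, oracle_trapezoid(pc$points$recall,
                                        pc$points$precision))
})

test_that("perfect separation gives AUC and F-max of one", {
  pc <- pr_curve(c(5, 4, 3, 2, 1), c(1, 1, 0, 0, 0))
  expect_equal(pc$auc, 1)
  expect_equal(pc$fmax, 1)
})

test_that("tied scores enter the PR curve together", {
  pc <- pr_curve(c(1, 1, 1, 0), c(1, 0, 1, 0))
  expect_equal(nrow(pc$points), 2L)
  expect_equal(pc$points$precision[1], 2 / 3)
})

test_that("a single-class input is rejected", {
  expect_error(pr_curve(c(1, 2), c(1, 1)), "positive and one negative")
  expect_error(pr_curve(c(1, 2), c(0, 0)), "positive and one negative")
})

test_that("F-max dominates the F1 of every threshold", {
  sim <- small_planted(seed = 8)
  Dadj <- adjust_distances(raw_distances(sim$network))
  lr <- loocv(Dadj, sim$gene_sets$module1)
  pc <- pr_curve(lr$scores, lr$labels)
  expect_equal(pc$fmax, max(pc$points$f1))
  expect_true(all(pc$points$f1 <= pc$fmax))
  expect_true(all(diff(pc$points$recall) >= 0))
  expect_gte(pc$auc, 0); expect_lte(pc$auc, 1)
})

test_that("TPR@k counts positives in the top k of the scored list", {
  sim <- small_planted(seed = 9)
  Dadj <- adjust_distances(raw_distances(sim$network))
  ds <- sim$gene_sets$module1
  lr <- loocv(Dadj, ds)
  K <- lr$n_disease
  tk <- tpr_at_k(lr, ks = c(K, lr$n_genes))
  # whole list: hit count is exactly K, so TPR@N = K/N
  expect_equal(tk$hits[2], K)
  expect_equal(tk$tpr[2], K / lr$n_genes)
  # recall-like reading divides by K instead
  tr <- tpr_at_k(lr, ks = lr$n_genes, mode = "recall")
  expect_equal(tr$tpr, 1)
  expect_error(tpr_at_k(lr, ks = 0), "k must lie")
})

test_that("a perfectly recovered module gives TPR@K of one", {
  scores <- c(a = 9, b = 8, c = 7, d = 1, e = 0.5, f = 0.2)
  lr <- structure(list(scores = scores,
                       labels = c(a = 1, b = 1, c = 1, d = 0, e = 0, f = 0),
                       n_genes = 6L, n_disease = 3L,
                       folds = NULL, disease_id = "toy"),
                  class = "loocv_result")
  expect_equal(tpr_at_k(lr, ks = 3)$tpr, 1)
  expect_equal(tpr_at_k(lr, ks = 3, mode = "recall")$tpr, 1)
})

test_that("rank ratio is rank over ranked-list size", {
  rk <- data.frame(rank = 1:100, gene = sprintf("g%03d", 1:100),
                   weight = 100:1, unranked = FALSE)
  expect_equal(rank_ratio(rk, "g001"), 0.01)
  expect_equal(rank_ratio(rk, "g100"), 1)
  expect_error(rank_ratio(rk, "nope"), "not present")
  rk$unranked[100] <- TRUE
  expect_true(is.na(rank_ratio(rk, "g100")))
  expect_equal(rank_ratio(rk, "g099"), 99 / 99)
})

test_that("median rank ratio of random placements concentrates near 0.5", {
  set.seed(123)
  ratios <- replicate(400, {
    n <- 50
    rk <- data.frame(rank = 1:n, gene = sample(sprintf("g%02d", 1:n)),
                     weight = n:1, unranked = FALSE)
    rank_ratio(rk, "g01")
  })
  expect_lt(abs(median(ratios) - 0.5), 0.1)
})

test_that("pooling two identical diseases preserves the AUC", {
  sim <- small_planted(seed = 10)
  Dadj <- adjust_distances(raw_distances(sim$network))
  lr <- loocv(Dadj, sim$gene_sets$module1)
  single <- pr_curve(netprio:::precision_convert(lr$scores, lr$labels == 1L)$score, lr$labels)
  pooled <- pooled_pr(list(lr, lr))
  expect_equal(pooled$auc, single$auc, tolerance = 1e-12)
  expect_equal(pooled$n_pos, 2L * single$n_pos)
})

test_that("pooling a strong and a null disease lands strictly between", {
  sim <- small_planted(seed = 11)
  Dadj <- adjust_distances(raw_distances(sim$network))
  lr_good <- loocv(Dadj, sim$gene_sets$module1)
  set.seed(7)
  lr_null <- loocv(Dadj, sample(setdiff(rownames(Dadj),
                                        sim$gene_sets$module1$genes), 8))
  auc_good <- pr_curve(lr_good$scores, lr_good$labels)$auc
  auc_null <- pr_curve(lr_null$scores, lr_null$labels)$auc
  pooled <- pooled_pr(list(lr_good, lr_null))
  expect_lt(pooled$auc, auc_good)
  expect_gt(pooled$auc, auc_null)
  expect_error(pooled_pr(list(lr_good)), "at least 2")
})

test_that("raw-vs-adjusted comparison reports per-disease diagnostics", {
  fx <- hub_fixture()
  sets <- list(module = fx$module)
  tab <- compare_raw_vs_adjusted(fx$network, sets)
  expect_equal(nrow(tab), 1L)
  expect_equal(as.character(tab$stratum), "<=10")
  # mean pairwise disease distance equals the brute-force average
  D <- raw_distances(fx$network)
  dg <- fx$module$genes
  acc <- 0; npair <- 0
  for (i in seq_along(dg)) {
    for (j in seq_along(dg)) {
      if (i < j) { acc <- acc + D[dg[i], dg[j]]; npair <- npair + 1 }
    }
  }
  expect_equal(tab$mean_disease_distance, acc / npair)
  expect_gte(tab$fmax_adjusted, tab$fmax_raw)
})

test_that("size strata cut at 10, 50 and 100 genes", {
  expect_equal(as.character(netprio:::size_stratum(c(2, 10, 11, 50, 51, 100, 101))),
               c("<=10", "<=10", "11-50", "11-50", "51-100", "51-100", ">100"))
})
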