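test_that("AUC follows Mann-Whitney pair counting with half-credit ties", {
  expect_equal(roc_auc(c(2, 3), c(0, 1))$auc, 1)
  expect_equal(roc_auc(rep(1, 5), rep(1, 7))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.7), c(0.8, 0.6))$auc, 0.75)
  expect_error(roc_auc(numeric(0), 1), "non-empty")

  set.seed(47)
  for (k in 1:200) {
    pos <- sample(0:10, sample(50, 1), replace = TRUE) / 10
    neg <- sample(0:10, sample(50, 1), replace = TRUE) / 10
    expect_equal(roc_auc(pos, neg)$auc, brute_force_auc(pos, neg),
                 tolerance = 1e-12)
  }
})

test_that("ROC points run monotonically from (0,0) to (1,1)", {
  set.seed(53)
  for (k in 1:20) {
    r <- roc_auc(runif(20), runif(30))$roc_points
    expect_equal(unlist(r[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r[nrow(r), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(59)
  pos <- runif(25); neg <- runif(40)
  base <- roc_auc(pos, neg)$auc
  for (f in list(function(x) 3 * x + 2, exp, function(x) x^3,
                 function(x) log(x + 1)))
    expect_equal(roc_auc(f(pos), f(neg))$auc, base, tolerance = 1e-12)
})

test_that("global LOOCV separates a planted strong-similarity toy perfectly", {
  # each held-out positive reconnects through a high lncRNA similarity to
  # an lncRNA sharing the disease; negatives have no such path
  data <- association_dataset(c("l1", "l2", "l3"), c("d1", "d2"),
                              matrix(c(1, 0, 1, 0, 0, 1), 3, byrow = TRUE))
  LS <- sim_from(matrix(c(1, 0.9, 0, 0.9, 1, 0, 0, 0, 1), 3),
                 c("l1", "l2", "l3"))
  DS <- sim_from(diag(2), c("d1", "d2"))
  cfg <- network_config(T = 0.2, tau = 3)
  # bypass similarity recomputation: score folds on similarity-frozen nets
  net <- build_network(data, DS, LS, cfg)
  pos <- c(score_pair(remove_association(net, "l1", "d1"), "l1", "d1", cfg)$score,
           score_pair(remove_association(net, "l2", "d1"), "l2", "d1", cfg)$score)
  neg <- score_all(net, data, cfg)[data$LD == 0]
  expect_gt(min(pos), max(neg))
  expect_equal(roc_auc(pos, neg)$auc, 1)
})

test_that("global LOOCV pools one positive per association and holds its edge out", {
  set.seed(61)
  syn <- generate_synthetic(synth_config(n_lncrnas = 10, n_diseases = 10,
                                         n_blocks = 2, seed = 9))
  res <- global_loocv(syn$data, syn$SS)
  expect_s3_class(res, "loocv_result")
  expect_equal(length(res$positive_scores), sum(syn$data$LD))
  expect_equal(length(res$negative_scores), sum(syn$data$LD == 0))
  expect_equal(nrow(res$per_fold), sum(syn$data$LD))
  expect_equal(res$auc, brute_force_auc(res$positive_scores,
                                        res$negative_scores),
               tolerance = 1e-12)
  expect_error(global_loocv(association_dataset("l1", "d1", matrix(1, 1, 1)),
                            sim_from(diag(1), "d1")),
               "at least 2")
})

test_that("local LOOCV has one fold per associated entity and labels candidates", {
  syn <- generate_synthetic(synth_config(n_lncrnas = 8, n_diseases = 8,
                                         n_blocks = 2, seed = 17))
  for (mode in c("novel_lncrna", "novel_disease")) {
    res <- local_loocv(syn$data, syn$SS, mode = mode)
    n_entities <- if (mode == "novel_lncrna") sum(rowSums(syn$data$LD) > 0)
                  else sum(colSums(syn$data$LD) > 0)
    expect_equal(length(unique(res$per_fold$entity)), n_entities)
    expect_equal(length(res$positive_scores), sum(syn$data$LD))
    expect_equal(res$auc,
                 brute_force_auc(res$positive_scores, res$negative_scores),
                 tolerance = 1e-12)
  }
})

test_that("a fully isolated held-out entity scores zero everywhere", {
  # one lncRNA whose only connection is its single association; holding the
  # row out leaves it with kernel similarity below any usable path
  data <- association_dataset(c("l1", "l2"), c("d1", "d2"),
                              matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  SS <- sim_from(diag(2), c("d1", "d2"))
  res <- local_loocv(data, SS, network_config(T = 0.9, tau = 3),
                     mode = "novel_lncrna")
  expect_true(all(res$per_fold$score == 0))
  expect_equal(res$auc, 0.5)
})

test_that("held-out positives outrank negatives in a hand-traced local fold", {
  # l1 and l2 share d1; when l1's row is held out, its kernel similarity to
  # l2 survives and reconnects l1 to d1, while d2 stays unreachable
  data <- association_dataset(c("l1", "l2", "l3"), c("d1", "d2", "d3"),
                              matrix(c(1, 0, 0,
                                       1, 0, 0,
                                       0, 0, 1), 3, byrow = TRUE))
  SS <- sim_from(diag(3), c("d1", "d2", "d3"))
  res <- local_loocv(data, SS, network_config(T = 0.1, tau = 3),
                     mode = "novel_lncrna")
  fold1 <- res$per_fold[res$per_fold$entity == "l1", ]
  expect_gt(fold1$score[fold1$candidate == "d1"],
            max(fold1$score[fold1$candidate == "d2"]))
})

test_that("precision bins count true associations per score interval", {
  res <- structure(list(positive_scores = c(0.9, 0.6),
                        negative_scores = c(0.55, 0.1),
                        mode = "global"), class = "loocv_result")
  pb <- precision_bins(res, c(0, 0.5, 1))
  expect_equal(pb$n_predictions, c(1L, 3L))
  expect_equal(pb$n_true, c(0L, 2L))
  expect_equal(pb$precision, c(0, 2 / 3))

  only_pos <- structure(list(positive_scores = c(0.8, 0.9),
                             negative_scores = 0.1, mode = "global"),
                        class = "loocv_result")
  pb2 <- precision_bins(only_pos, c(0.5, 1))
  expect_equal(pb2$precision, 1)
  pb3 <- precision_bins(only_pos, c(0.05, 0.15, 0.5))
  expect_true(is.na(pb3$precision[2]))   # empty interval flagged as NA
  expect_error(precision_bins(res, c(1, 0.5)), "increasing")
})

test_that("a single-cell parameter sweep reproduces the direct LOOCV AUC", {
  syn <- generate_synthetic(synth_config(n_lncrnas = 10, n_diseases = 10,
                                         n_blocks = 2, seed = 21))
  sw <- parameter_sweep(syn$data, syn$SS, T_values = 0.2, L_values = 3)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$auc, global_loocv(syn$data, syn$SS)$auc)

  # the L = 1 column matches the closed-form direct-edge-only limit
  sw1 <- parameter_sweep(syn$data, syn$SS, T_values = 0.2, L_values = 1)
  cfg1 <- network_config(T = 0.2, tau = 1)
  expect_equal(sw1$auc, global_loocv(syn$data, syn$SS, cfg1)$auc)
})

test_that("kernel ablation settings coincide when no entity needs a fallback", {
  # strictly positive SS and overlapping disease sets: NS and NF are empty
  set.seed(67)
  nd <- 6; nl <- 6
  m <- matrix(runif(nd * nd, 0.3, 0.9), nd); m <- (m + t(m)) / 2; diag(m) <- 1
  SS <- sim_from(m, paste0("d", 1:nd))
  LD <- matrix(rbinom(nl * nd, 1, 0.5), nl, nd)
  LD[rowSums(LD) == 0, 1] <- 1
  data <- association_dataset(paste0("l", 1:nl), paste0("d", 1:nd), LD)
  sims <- compute_similarities(data, SS)
  expect_length(sims$NS, 0)
  expect_length(sims$NF, 0)
  aucs <- kernel_ablation(data, SS)
  expect_equal(unname(aucs), rep(aucs[["both"]], 4))
})
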