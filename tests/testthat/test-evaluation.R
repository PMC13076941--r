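# Evaluation metrics against independent oracles, and the fine-tuning heads.

test_that("ARI matches exhaustive pair counting on all small partitions", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               ari_oracle(c(1, 1, 2, 2), c(1, 2, 1, 2)))
  parts <- all_partitions(4)
  for (x in parts) for (y in parts) {
    expect_equal(adjusted_rand_index(x, y), ari_oracle(x, y),
                 tolerance = 1e-12)
  }
  set.seed(5)
  for (i in 1:20) {
    x <- sample(1:3, 6, replace = TRUE)
    y <- sample(1:3, 6, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), ari_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})

test_that("NMI matches the entropy oracle and its conventions", {
  expect_equal(normalized_mutual_information(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(normalized_mutual_information(c(1, 1, 2, 2), c(7, 7, 3, 3)), 1)
  parts <- all_partitions(4)
  for (x in parts[2:15]) for (y in parts[2:15]) {
    expect_equal(normalized_mutual_information(x, y), nmi_oracle(x, y),
                 tolerance = 1e-12)
  }
  set.seed(6)
  x <- sample(1:4, 1e4, replace = TRUE)
  y <- sample(1:4, 1e4, replace = TRUE)
  expect_lt(normalized_mutual_information(x, y), 0.01)
  expect_warning(z <- normalized_mutual_information(rep(1, 5), rep(2, 5)),
                 "single-class")
  expect_equal(z, 0)
})

test_that("silhouette matches brute force and handles singletons", {
  # two tight, well-separated clusters
  set.seed(7)
  X <- rbind(matrix(rnorm(20, 0, 0.01), 10, 2),
             matrix(rnorm(20, 10, 0.01), 10, 2))
  lab <- rep(c("a", "b"), each = 10)
  expect_gt(silhouette_score(X, lab), 0.9)

  # singleton convention a = 0: {0} vs {10} plus a far companion point
  X2 <- matrix(c(0, 10, 10.5), ncol = 1)
  expect_equal(silhouette_score(X2, c("a", "b", "b")),
               silhouette_oracle(X2, c("a", "b", "b")), tolerance = 1e-12)
  # all-singleton clusters: a = 0 everywhere, so every point scores 1
  expect_equal(silhouette_score(matrix(c(0, 10, 20), ncol = 1),
                                c("a", "b", "c")), 1)

  set.seed(8)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    lab <- sample(letters[1:3], n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(silhouette_score(X, lab), silhouette_oracle(X, lab),
                 tolerance = 1e-9)
  }
  # random labels on structureless geometry score near zero
  set.seed(9)
  Xr <- matrix(rnorm(400), 200, 2)
  labr <- sample(c("a", "b"), 200, replace = TRUE)
  expect_lt(abs(silhouette_score(Xr, labr)), 0.1)
  expect_error(silhouette_score(Xr, rep("a", 200)), "single cluster")
})

test_that("silhouette agrees with cluster::silhouette on multi-member clusters", {
  skip_if_not_installed("cluster")
  set.seed(10)
  X <- matrix(rnorm(60), 20, 3)
  lab <- rep(1:2, each = 10)
  sil <- cluster::silhouette(lab, dist(X))
  expect_equal(silhouette_score(X, lab), mean(sil[, "sil_width"]),
               tolerance = 1e-9)
})

test_that("classification report: perfect case, closed-form MCC, invariances", {
  r <- classification_report(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(r$accuracy, 1)
  expect_equal(r$precision, 1)
  expect_equal(r$f1, 1)
  expect_equal(r$mcc, 1)
  expect_true(all(r$confusion == diag(3)))

  # binary table TP=8 FP=2 FN=1 TN=9 against the closed binary formula
  pred <- c(rep("pos", 8), rep("pos", 2), rep("neg", 1), rep("neg", 9))
  tru <- c(rep("pos", 8), rep("neg", 2), rep("pos", 1), rep("neg", 9))
  r2 <- classification_report(pred, tru)
  mcc_hand <- (8 * 9 - 2 * 1) / sqrt((8 + 2) * (8 + 1) * (9 + 2) * (9 + 1))
  expect_equal(r2$mcc, mcc_hand, tolerance = 1e-12)

  relab <- c(a = "z", b = "y", c = "x")
  p3 <- sample(c("a", "b", "c"), 30, replace = TRUE)
  t3 <- sample(c("a", "b", "c"), 30, replace = TRUE)
  r3 <- classification_report(p3, t3)
  r4 <- classification_report(unname(relab[p3]), unname(relab[t3]))
  expect_equal(r3$f1, r4$f1, tolerance = 1e-12)
  expect_equal(r3$mcc, r4$mcc, tolerance = 1e-12)
  expect_error(classification_report(character(0), character(0)),
               "non-empty")
})

test_that("AUROC equals the Mann-Whitney statistic and is rank-invariant", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(average_precision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(11)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    y <- c(rep(1, sample(3:(n - 3), 1)))
    y <- c(y, rep(0, n - length(y)))
    s <- rnorm(n) + y
    u <- suppressWarnings(wilcox.test(s[y == 1], s[y == 0])$statistic)
    expect_equal(auroc(s, y), unname(u) / (sum(y == 1) * sum(y == 0)),
                 tolerance = 1e-12)
    expect_equal(auroc(exp(3 * s), y), auroc(s, y), tolerance = 1e-12)
  }
  set.seed(12)
  s <- rnorm(1e4); y <- rep(c(0, 1), 5e3)
  expect_lt(abs(auroc(s, y) - 0.5), 3 * sqrt(1 / 12 * (1e4) / (5e3 * 5e3)))
  expect_error(auroc(s, rep(1, 1e4)), "one class")
})

test_that("AUROC and APR agree with pROC cross-checks", {
  skip_if_not_installed("pROC")
  set.seed(13)
  y <- rep(c(0, 1), each = 50)
  s <- rnorm(100) + y * 1.5
  expect_equal(auroc(s, y),
               as.numeric(suppressMessages(pROC::auc(y, s))),
               tolerance = 1e-9)
})

test_that("paratope metrics combine thresholded and threshold-free views", {
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.1)
  labels <- c(1, 1, 0, 1, 0, 0)
  pm <- paratope_metrics(scores, labels, threshold = 0.5)
  expect_equal(pm$precision, 2 / 3)
  expect_equal(pm$recall, 2 / 3)
  expect_equal(pm$f1, 2 / 3)
  expect_equal(pm$auroc, auroc(scores, labels))
  expect_equal(pm$apr, average_precision(scores, labels))
  expect_error(paratope_metrics(1:3, c(1, 1)), "length mismatch")
})

test_that("subtype fine-tuning learns the planted signal", {
  pre <- fx_pretrained()
  clf <- fx_classifier()
  te_df <- pre$curated$split$test
  te <- encode_batch(te_df, fx_vocab(), mode = "hcdr3", max_len = 32)
  pred <- predict(clf, te)
  expect_gt(mean(pred$label == te_df$subtype), 0.9)
  expect_true(all(pred$label %in% clf$classes))
  expect_equal(dim(pred$prob), c(nrow(te_df), 3))
  expect_equal(rowSums(pred$prob), rep(1, nrow(te_df)), tolerance = 1e-9)
  # fine-tuned backbone variant runs and reports through the same API
  clf_ft <- fine_tune_classifier(pre$model, pre$train_enc$batch,
                                 pre$curated$split$train$subtype,
                                 epochs = 1, finetune_backbone = TRUE,
                                 seed = 5)
  pred_ft <- predict(clf_ft, te)
  expect_true(all(pred_ft$label %in% clf_ft$classes))
})

test_that("paratope head recovers a deterministic motif", {
  ps <- simulate_paratope_set(60, motif = "YYGMD", seed = 21,
                              seq_length = c(60, 80),
                              n_random_contacts = 0)
  tr <- ps[1:40, ]; te <- ps[41:60, ]
  m <- init_model(fx_tiny_config(max_len = 96, seed = 3))
  sc <- fine_tune_paratope(m, tr, fx_vocab(), max_len = 96, epochs = 250,
                           lr = 3e-2, seed = 3)
  out <- predict(sc, te)
  expect_gt(auroc(out$score, out$label), 0.9)
  # one score per residue position, none for special/metadata positions
  expect_equal(nrow(out), sum(nchar(te$sequence)))
  expect_identical(out$record[1], te$id[1])
})

test_that("paratope head validates label alignment", {
  ps <- simulate_paratope_set(3, motif = "YYGMD", seed = 22)
  ps$labels[2] <- paste0(ps$labels[2], "0")
  m <- init_model(fx_tiny_config(max_len = 64, seed = 3))
  expect_error(fine_tune_paratope(m, ps, fx_vocab(), max_len = 64),
               "ab_0002")
})

test_that("embedding_eval scores separable embeddings highly", {
  set.seed(23)
  emb <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
               matrix(rnorm(40, 5, 0.2), 20, 2))
  lab <- rep(c("x", "y"), each = 20)
  ev <- embedding_eval(emb, lab, seed = 1)
  expect_gt(ev$ari, 0.99)
  expect_gt(ev$nmi, 0.99)
  expect_gt(ev$silhouette, 0.9)
})
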