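# Training machinery: masking statistics, loss oracles, balanced sampling,
# LR schedule, and the joint training loop.

make_residue_batch <- function(n, len, vocab, seed = 1) {
  set.seed(seed)
  aa <- vocab$blocks$amino_acid
  ids <- matrix(sample(aa, n * len, replace = TRUE), n, len)
  ids[, 1] <- vocab$ids[["[CLS]"]]
  list(ids = ids, pad_mask = matrix(TRUE, n, len),
       category = matrix(c(rep("special", n),
                           rep("residue", n * (len - 1))), n, len),
       source_id = as.character(seq_len(n)), max_len = len)
}

test_that("masking hits 15% of maskable positions with the 80/10/10 rule", {
  vocab <- fx_vocab()
  b <- make_residue_batch(2000, 51, vocab, seed = 2)
  n_maskable <- 2000 * 50
  mk <- apply_masking(b, vocab, rate = 0.15, seed = 3)
  n_sel <- sum(mk$masked)
  se <- sqrt(0.15 * 0.85 * n_maskable)
  expect_lt(abs(n_sel - 0.15 * n_maskable), 3 * se)

  sel_orig <- b$ids[mk$masked]
  sel_new <- mk$corrupted_ids[mk$masked]
  frac_mask <- mean(sel_new == vocab$ids[["[MASK]"]])
  frac_same <- mean(sel_new == sel_orig)
  changed_random <- mean(sel_new != vocab$ids[["[MASK]"]] &
                           sel_new != sel_orig)
  se_sel <- function(p) 3 * sqrt(p * (1 - p) / n_sel)
  expect_lt(abs(frac_mask - 0.8), se_sel(0.8))
  # a "random amino acid" replacement can coincide with the original
  # (p = 1/20), so the unchanged fraction is 0.1 + 0.1/20
  expect_lt(abs(frac_same - 0.105), se_sel(0.105))
  expect_lt(abs(changed_random - 0.095), se_sel(0.095))

  # special and pad positions are never selected
  expect_true(all(!mk$masked[, 1]))
  real_b <- encode_batch(fx_repertoire()[1:50, ], vocab, mode = "hcdr3",
                         max_len = 32)
  mk2 <- apply_masking(real_b, vocab, rate = 0.5, seed = 4)
  expect_true(all(!mk2$masked[real_b$category == "special"]))
  expect_true(all(!mk2$masked[!real_b$pad_mask]))
  expect_identical(which(mk2$targets >= 0), which(mk2$masked))
  expect_error(apply_masking(real_b, vocab, rate = 1.2), "rate")
})

test_that("MLM loss follows the per-batch normalization exactly", {
  V <- 260
  uniform <- array(0, dim = c(1, 4, V))
  targets <- matrix(c(-1L, 5L, -1L, -1L), 1, 4)
  expect_equal(mlm_loss(uniform, targets), log(260), tolerance = 1e-10)

  # two masked positions in one sequence double the loss
  targets2 <- matrix(c(-1L, 5L, 9L, -1L), 1, 4)
  expect_equal(mlm_loss(uniform, targets2), 2 * log(260), tolerance = 1e-10)

  conc <- array(0, dim = c(1, 4, V))
  conc[1, 2, 6] <- 50
  expect_lt(mlm_loss(conc, matrix(c(-1L, 5L, -1L, -1L), 1, 4)), 1e-8)

  expect_warning(z <- mlm_loss(uniform, matrix(-1L, 1, 4)), "no masked")
  expect_equal(z, 0)

  # independent per-position log-softmax oracle on random logits
  set.seed(7)
  B <- 3; T_ <- 6; V2 <- 15
  logits <- array(rnorm(B * T_ * V2), dim = c(B, T_, V2))
  targets3 <- matrix(-1L, B, T_)
  targets3[cbind(c(1, 1, 2, 3), c(2, 5, 3, 6))] <- c(4L, 0L, 9L, 14L)
  oracle <- 0
  for (bb in 1:B) for (tt in 1:T_) {
    if (targets3[bb, tt] >= 0) {
      l <- logits[bb, tt, ]
      oracle <- oracle - (l[targets3[bb, tt] + 1] - log(sum(exp(l))))
    }
  }
  expect_equal(mlm_loss(logits, targets3), oracle / B, tolerance = 1e-5)
})

test_that("cosine similarity obeys its closed form", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2),
               tolerance = 1e-5)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero")
})

test_that("contrastive loss matches a hand-evaluated softmax oracle", {
  # unit vectors at angles 0, 0, 180; labels A, A, B; tau = 1
  E <- rbind(c(1, 0), c(1, 0), c(-1, 0))
  lab <- c("A", "A", "B")
  # anchors 1 and 2 (one positive each); anchor 3 has none
  # sim: (1,2)=1, (1,3)=-1, (2,3)=-1
  l1 <- -(1 - log(exp(1) + exp(-1)))
  oracle <- mean(c(l1, l1))
  expect_equal(contrastive_loss(E, lab, tau = 1), oracle, tolerance = 1e-10)

  # all-identical embeddings: every similarity equal -> uniform softmax
  E2 <- matrix(rep(c(2, 1, 2), 5), nrow = 5, byrow = TRUE)
  lab2 <- c("A", "A", "A", "B", "B")
  n <- 5
  l_a <- -log(1 / (n - 1))          # each positive term: 1/(n-1) softmax
  expect_equal(contrastive_loss(E2, lab2, tau = 0.5), l_a,
               tolerance = 1e-10)

  # raising a positive similarity with negatives fixed lowers the loss
  base <- rbind(c(1, 0), c(0.6, 0.8), c(-1, 0.2))
  lab3 <- c("A", "A", "B")
  closer <- base
  closer[2, ] <- c(0.95, sqrt(1 - 0.95^2))
  expect_lt(contrastive_loss(closer, lab3, tau = 0.1),
            contrastive_loss(base, lab3, tau = 0.1))

  expect_error(contrastive_loss(base, lab3, tau = -1), "tau")
  expect_warning(z <- contrastive_loss(base, c("A", "B", "C"), tau = 1),
                 "no anchor")
  expect_equal(z, 0)
})

test_that("contrastive loss is invariant to batch order and rotation", {
  set.seed(11)
  E <- matrix(rnorm(12 * 4), 12, 4)
  lab <- rep(c("a", "b", "c"), each = 4)
  l0 <- contrastive_loss(E, lab, tau = 0.07)
  perm <- sample(12)
  expect_equal(contrastive_loss(E[perm, ], lab[perm], tau = 0.07), l0,
               tolerance = 1e-10)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))   # orthogonal rotation
  expect_equal(contrastive_loss(E %*% Q, lab, tau = 0.07), l0,
               tolerance = 1e-8)
})

test_that("total loss is the exact convex combination", {
  expect_equal(total_loss(3.2, 9.9, 0), 3.2)
  expect_equal(total_loss(3.2, 9.9, 1), 9.9)
  expect_equal(total_loss(2.0, 4.0, 0.25), 2.5)
  for (w in c(0.1, 0.5, 0.9)) {
    v <- total_loss(1, 5, w)
    expect_true(v >= 1 && v <= 5)
  }
  expect_error(total_loss(1, 2, 1.5), "w_cl")
})

test_that("balanced sampler equalizes class draws", {
  labels <- c(rep("big", 900), rep("small", 100))
  s <- balanced_sampler(labels, batch_size = 100, seed = 3)
  draws <- unlist(lapply(1:100, function(i) s()))
  frac_small <- mean(labels[draws] == "small")
  se <- sqrt(0.25 / length(draws))
  expect_lt(abs(frac_small - 0.5), 3 * se)

  s1 <- balanced_sampler(labels, 10, seed = 4)
  s2 <- balanced_sampler(labels, 10, seed = 4)
  expect_identical(c(s1(), s1()), c(s2(), s2()))

  sing <- balanced_sampler(rep("only", 5), 8, seed = 1)
  expect_true(all(sing() %in% 1:5))
  expect_error(balanced_sampler(character(0), 4), "empty")
})

test_that("learning-rate schedule: warmup, peak, plateau decay", {
  tc <- training_config(peak_lr = 1e-4, warmup_fraction = 0.05,
                        plateau_patience = 3, plateau_factor = 0.3,
                        total_steps = 1000)
  expect_equal(lr_schedule(0, 1000, tc), 0)
  expect_equal(lr_schedule(50, 1000, tc), 1e-4)
  expect_equal(lr_schedule(25, 1000, tc), 5e-5)
  expect_equal(lr_schedule(500, 1000, tc, c(3, 2.5, 2.4)), 1e-4)
  # three consecutive non-improving evaluations -> one decay
  expect_equal(lr_schedule(500, 1000, tc, c(2, 2.3, 2.2, 2.1)), 3e-5)
  # improvement resets the counter
  expect_equal(lr_schedule(500, 1000, tc, c(2, 2.3, 2.2, 1.9, 2.0)), 1e-4)
  # two plateaus -> two decays
  expect_equal(lr_schedule(900, 1000, tc, c(2, rep(2.5, 6))), 1e-4 * 0.09,
               tolerance = 1e-12)
})

test_that("training reduces validation MLM loss and is seed-reproducible", {
  vocab <- fx_vocab()
  cur <- fx_curated()
  enc <- function(df) list(batch = encode_batch(df, vocab, mode = "hcdr3",
                                                max_len = 32),
                           labels = df$subtype)
  tr <- enc(cur$split$train[1:120, ])
  va <- enc(cur$split$validation)
  cfg <- model_config(n_layers = 1, n_heads = 2, hidden_dim = 16,
                      ffn_dim = 32, vocab_size = vocab$size, max_len = 32,
                      dropout = 0.1, seed = 2)
  tc <- training_config(w_cl = 0, peak_lr = 1e-3, total_steps = 120,
                        batch_size = 8, eval_interval = 30, seed = 6)
  out1 <- train(init_model(cfg), tr, va, tc, vocab)
  expect_lt(tail(out1$val_history$val_mlm_loss, 1),
            out1$val_history$val_mlm_loss[1])
  out2 <- train(init_model(cfg), tr, va, tc, vocab)
  expect_identical(out1$model$params$tok_emb, out2$model$params$tok_emb)
  expect_identical(out1$history$loss_total, out2$history$loss_total)
  expect_true(all(is.na(out1$history$loss_cl)))   # w_cl = 0: pure MLM path
})

test_that("joint training separates subtypes in embedding space", {
  pre <- fx_pretrained()
  cur <- pre$curated
  te <- encode_batch(cur$split$test, fx_vocab(), mode = "hcdr3",
                     max_len = 32)
  emb <- cls_embedding(pre$model, te)
  lab <- cur$split$test$subtype
  Z <- emb / sqrt(rowSums(emb^2))
  S <- Z %*% t(Z)
  same <- outer(lab, lab, "==") & !diag(nrow(S))
  within <- mean(S[same & upper.tri(S)])
  between <- mean(S[!same & upper.tri(S)])
  expect_gt(within, between)
})
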