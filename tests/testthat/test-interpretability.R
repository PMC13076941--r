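# Attention attribution, integrated gradients, and saturation mutagenesis.

# hand-built forward output: 1 record, 2 layers x 1 head, T = 6 with
# positions: [CLS] r r r [SEP] [PAD]  (3 residues at offsets 2:4)
fake_attention_fixture <- function(A1, A2) {
  batch <- list(ids = matrix(0L, 1, 6),
                pad_mask = matrix(c(rep(TRUE, 5), FALSE), 1),
                category = matrix(c("special", "residue", "residue",
                                    "residue", "special", "special"), 1),
                source_id = "x", max_len = 6)
  wrap <- function(A) {
    arr <- array(0, dim = c(1, 1, 6, 6))
    arr[1, 1, , ] <- A
    arr
  }
  list(fw = list(attention = list(wrap(A1), wrap(A2)), B = 1, T = 6),
       batch = batch)
}

test_that("attention scores aggregate received attention correctly", {
  U <- matrix(1 / 5, 6, 6)          # uniform over the 5 real keys
  U[, 6] <- 0
  fx <- fake_attention_fixture(U, U)
  pr <- residue_attention_scores(fx$fw, fx$batch)
  expect_equal(pr$scores, rep(1 / 5, 3))
  expect_identical(pr$positions, 1:3)

  # one head attending only to encoding position 3 (residue offset 2)
  P <- matrix(0, 6, 6); P[, 3] <- 1
  fx2 <- fake_attention_fixture(U, P)
  pr_max <- residue_attention_scores(fx2$fw, fx2$batch, head_agg = "max")
  expect_equal(which.max(pr_max$scores), 2)

  # brute-force oracle on random attention tensors
  set.seed(3)
  R1 <- matrix(runif(36), 6, 6); R1 <- R1 / rowSums(R1)
  R2 <- matrix(runif(36), 6, 6); R2 <- R2 / rowSums(R2)
  fx3 <- fake_attention_fixture(R1, R2)
  pr3 <- residue_attention_scores(fx3$fw, fx3$batch)
  oracle <- numeric(3)
  for (jj in 1:3) {
    acc <- 0
    for (A in list(R1, R2)) {
      s <- 0
      for (q in 1:5) s <- s + A[q, jj + 1]
      acc <- acc + s / 5
    }
    oracle[jj] <- acc / 2
  }
  expect_equal(pr3$scores, oracle, tolerance = 1e-9)
  expect_error(residue_attention_scores(fx3$fw, fx3$batch,
                                        layer_set = integer(0)), "empty")
})

test_that("paratope enrichment: perfect scores, permutation null, oracle", {
  labs <- list(c(1, 0, 0), c(0, 1, 0))
  perfect <- list(c(5, 0, 0), c(0, 5, 0))
  en <- attention_paratope_enrichment(perfect, labs, top_frac = 1 / 3)
  expect_equal(en$top_paratope_fraction, 1.0)

  set.seed(4)
  n <- 10000
  scores <- runif(n)
  labels <- rbinom(n, 1, 0.2)
  en2 <- attention_paratope_enrichment(list(scores), list(labels),
                                       top_frac = 0.05)
  se <- 3 * sqrt(0.2 * 0.8 / en2$n_top)
  expect_lt(abs(en2$top_paratope_fraction - 0.2), se)
  expect_lt(abs(en2$background_paratope_fraction - 0.2), se)

  # sort-and-count oracle
  k <- ceiling(0.05 * n)
  top_idx <- order(scores, decreasing = TRUE)[1:k]
  expect_equal(en2$top_paratope_fraction, mean(labels[top_idx]))
  expect_equal(en2$n_top, k)
})

test_that("layer trajectory has one row per layer and a null under shuffling", {
  pre <- fx_pretrained()
  reps <- pre$curated$split$train[1:12, ]
  b <- encode_batch(reps, fx_vocab(), mode = "hcdr3", max_len = 32)
  fw <- forward(pre$model, b)
  # binding labels = planted motif positions within the HCDR3
  motifs <- subtype_motifs(c("naive", "memory", "plasma"))
  labs <- lapply(seq_len(nrow(reps)), function(i) {
    n_res <- sum(b$category[i, ] == "residue")
    lab <- integer(n_res)
    at <- regexpr(motifs[[reps$subtype[i]]], reps$hcdr3[i], fixed = TRUE)
    if (at > 0) lab[at:(at + 4)] <- 1L
    lab
  })
  tj <- layer_trajectory(fw, b, labs)
  expect_equal(nrow(tj), 2)
  expect_identical(names(tj), c("layer", "binding", "non_binding"))
  expect_true(all(is.finite(unlist(tj))))
  # label shuffling should erase any binding/non-binding gap on average
  set.seed(5)
  gaps <- replicate(20, {
    sl <- lapply(labs, sample)
    tjs <- layer_trajectory(fw, b, sl)
    mean(tjs$binding - tjs$non_binding)
  })
  obs_gap <- mean(abs(gaps))
  expect_lt(abs(mean(gaps)), 3 * sd(gaps))
})

test_that("midpoint IG is exact for linear scorers at any step count", {
  set.seed(6)
  w <- matrix(rnorm(12), 3, 4)
  x <- matrix(rnorm(12), 3, 4)
  grad_fn <- function(z) w
  for (steps in c(1, 7, 200)) {
    ig <- ig_midpoint(grad_fn, x, steps = steps)
    expect_equal(ig, x * w, tolerance = 1e-12)
    expect_equal(sum(ig), sum(w * x), tolerance = 1e-12)
  }
  expect_error(ig_midpoint(grad_fn, x, steps = 0), "steps")
})

test_that("midpoint IG error shrinks with step count on a nonlinear scorer", {
  set.seed(7)
  w <- rnorm(6)
  x <- rnorm(6)
  f <- function(z) sum(tanh(z * w)^3)
  grad_fn <- function(z) 3 * tanh(z * w)^2 * (1 - tanh(z * w)^2) * w
  ref <- ig_midpoint(grad_fn, x, steps = 1e4)
  err10 <- sum(abs(ig_midpoint(grad_fn, x, steps = 10) - ref))
  err200 <- sum(abs(ig_midpoint(grad_fn, x, steps = 200) - ref))
  expect_lt(err200, err10)
  # completeness of the high-resolution reference
  expect_equal(sum(ref), f(x) - f(0 * x), tolerance = 1e-6)
})

test_that("IG on the trained encoder satisfies completeness", {
  pre <- fx_pretrained()
  clf <- fx_classifier()
  rec <- pre$curated$split$test[1, ]
  enc <- encode(rec, fx_vocab(), mode = "hcdr3", max_len = 32)
  prof <- integrated_gradients(pre$model, enc,
                               target = list(type = "class",
                                             classifier = clf),
                               steps = 200)
  expect_lt(prof$completeness$relative_gap, 0.01)
  expect_length(prof$scores, nchar(rec$hcdr3))
  expect_true(all(is.finite(prof$all_scores)))
})

test_that("top-decile selection respects ties and the ceiling rule", {
  expect_length(top_decile_positions(1:10), 1)
  expect_identical(top_decile_positions(1:10), 10L)
  expect_length(top_decile_positions(rep(2, 25)), 25)
  set.seed(8)
  for (i in 1:10) {
    s <- rnorm(sample(10:80, 1))
    got <- top_decile_positions(s)
    k <- ceiling(0.1 * length(s))
    thr <- sort(s, decreasing = TRUE)[k]
    expect_identical(got, which(s >= thr))
    expect_gte(length(got), k)
  }
})

test_that("saturation mutagenesis probes 19 substitutions per position", {
  pre <- fx_pretrained()
  clf <- fx_classifier()
  rec <- pre$curated$split$test[2, ]
  res <- saturation_mutagenesis(clf, rec, positions = c(2, 4),
                                vocab = fx_vocab(), mode = "hcdr3",
                                max_len = 32, seed = 9)
  expect_equal(nrow(res), 19 * 4)
  expect_true(all(table(res$position) == 19))
  expect_true(all(res$substituted != res$original))
  expect_true(all(res$delta >= -1 & res$delta <= 1))
  expect_setequal(unique(res$group), c("top_ig", "random_control"))
  expect_error(saturation_mutagenesis(clf, rec, positions = 999,
                                      vocab = fx_vocab(), mode = "hcdr3",
                                      max_len = 32), "out of range")
})

test_that("fold-change statistic matches a count oracle and flags zeros", {
  mk <- function(top, ctl) {
    data.frame(position = 0, group = rep(c("top_ig", "random_control"),
                                         c(length(top), length(ctl))),
               original = "A", substituted = "C", delta = c(top, ctl))
  }
  set.seed(10)
  d <- rnorm(200, 0, 0.05)
  same <- mk(d, d)
  fc <- mutagenesis_fold_change(same, eps = 0.01)
  expect_equal(fc$fold, 1)
  fc2 <- mutagenesis_fold_change(mk(c(-0.5, -0.5, 0.2), c(0.1, 0.2)))
  expect_true(fc2$infinite)
  top <- rnorm(100, -0.05, 0.1); ctl <- rnorm(100, 0, 0.02)
  fc3 <- mutagenesis_fold_change(mk(top, ctl), eps = 0.01)
  expect_equal(fc3$fold,
               mean(top < -0.01) / mean(ctl < -0.01), tolerance = 1e-12)
})

test_that("IG concentrates on planted motif positions", {
  pre <- fx_pretrained()
  clf <- fx_classifier()
  te <- pre$curated$split$test
  motifs <- subtype_motifs(c("naive", "memory", "plasma"))
  n_rec <- min(15, nrow(te))
  per_rec <- list()
  set.seed(11)
  for (i in seq_len(n_rec)) {
    rec <- te[i, ]
    at <- regexpr(motifs[[rec$subtype]], rec$hcdr3, fixed = TRUE)
    if (at <= 0) next
    motif_pos <- (at - 1):(at + 3)        # 0-based residue offsets
    enc <- encode(rec, fx_vocab(), mode = "hcdr3", max_len = 32)
    prof <- integrated_gradients(pre$model, enc,
                                 target = list(type = "class",
                                               classifier = clf),
                                 steps = 25)
    mag <- abs(prof$scores)
    top <- top_decile_positions(mag) - 1L  # to 0-based residue offsets
    per_rec[[length(per_rec) + 1L]] <-
      list(n = length(mag), k = length(top), motif = motif_pos,
           overlap = mean(top %in% motif_pos))
  }
  observed <- mean(vapply(per_rec, `[[`, numeric(1), "overlap"))
  # permutation null: equally sized random position sets per record
  null_means <- replicate(199, {
    mean(vapply(per_rec, function(r) {
      mean((sample(r$n, r$k) - 1L) %in% r$motif)
    }, numeric(1)))
  })
  p_value <- (1 + sum(null_means >= observed)) / (1 + length(null_means))
  expect_lt(p_value, 0.05)
})
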