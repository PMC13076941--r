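# Shared fixtures, built in code and memoized for the test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fx_pools <- function() fixture("pools", function() build_germline_pools(seed = 1))

fx_vocab <- function() fixture("vocab", function() {
  build_vocabulary(pool_gene_symbols(fx_pools()))
})

# small 3-subtype planted-motif repertoire (heavy chains only, strong signal)
fx_repertoire <- function() fixture("repertoire", function() {
  cfg <- sim_config(n_records = 400,
                    subtype_labels = c("naive", "memory", "plasma"),
                    motif_strength = 1, fraction_heavy = 1, seed = 7)
  simulate_repertoire(cfg, fx_pools())
})

fx_curated <- function() fixture("curated", function() {
  curate(fx_repertoire(), seed = 7)
})

fx_tiny_config <- function(max_len = 32L, dropout = 0.1, seed = 5L) {
  model_config(n_layers = 2, n_heads = 2, hidden_dim = 32, ffn_dim = 64,
               vocab_size = fx_vocab()$size, max_len = max_len,
               dropout = dropout, seed = seed)
}

# a small encoder pretrained with the joint objective on the fixture
# repertoire; reused by evaluation and interpretability tests
fx_pretrained <- function() fixture("pretrained", function() {
  cur <- fx_curated()
  vocab <- fx_vocab()
  enc <- function(df) list(batch = encode_batch(df, vocab, mode = "hcdr3",
                                                max_len = 32),
                           labels = df$subtype)
  tr <- enc(cur$split$train)
  va <- enc(cur$split$validation)
  model <- init_model(fx_tiny_config())
  tc <- training_config(w_cl = 0.5, tau = 0.07, peak_lr = 1e-3,
                        total_steps = 300, batch_size = 16,
                        eval_interval = 100, seed = 5)
  out <- train(model, tr, va, tc, vocab)
  list(model = out$model, curated = cur, train_enc = tr,
       history = out$history)
})

fx_classifier <- function() fixture("classifier", function() {
  pre <- fx_pretrained()
  fine_tune_classifier(pre$model, pre$train_enc$batch,
                       pre$curated$split$train$subtype, epochs = 40,
                       seed = 5)
})

# random BCR-like records without simulator structure
random_records <- function(n, len = c(90, 120), seed = 1) {
  set.seed(seed)
  data.frame(
    id = sprintf("r%04d", seq_len(n)), chain = "heavy", locus = "IGH",
    sequence = vapply(seq_len(n), function(i) {
      L <- len[1] + sample.int(len[2] - len[1] + 1, 1) - 1
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                   L, replace = TRUE), collapse = "")
    }, character(1)),
    hcdr3 = NA_character_, hcdr3_start = NA_integer_, hcdr3_end = NA_integer_,
    v_call = "IGHV1-1", d_call = "IGHD1-1", j_call = "IGHJ1",
    isotype = "IgM", subtype = NA_character_, n_mutations = 0L,
    stringsAsFactors = FALSE
  )
}

# exhaustive global-alignment oracle: enumerates every alignment of two
# short strings, picks max score (match +1, mismatch 0, gap -1), breaking
# ties toward fewer gaps, and returns matches / alignment length.
identity_oracle <- function(a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  best <- list(score = -Inf, gaps = Inf, id = NA_real_)
  rec <- function(i, j, score, gaps, matches, len) {
    if (i > length(ac) && j > length(bc)) {
      if (score > best$score ||
          (score == best$score && gaps < best$gaps)) {
        best <<- list(score = score, gaps = gaps, id = matches / len)
      }
      return(invisible())
    }
    if (i <= length(ac) && j <= length(bc)) {
      rec(i + 1, j + 1, score + (ac[i] == bc[j]), gaps,
          matches + (ac[i] == bc[j]), len + 1)
    }
    if (i <= length(ac)) rec(i + 1, j, score - 1, gaps + 1, matches, len + 1)
    if (j <= length(bc)) rec(i, j + 1, score - 1, gaps + 1, matches, len + 1)
  }
  rec(1, 1, 0, 0, 0, 0)
  best$id
}

# all set partitions of 1..n as label vectors
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    k <- max(p)
    for (g in seq_len(k + 1)) out[[length(out) + 1L]] <- c(p, g)
  }
  out
}

# pair-counting ARI oracle: loops over all element pairs
ari_oracle <- function(x, y) {
  n <- length(x)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sx <- x[i] == x[j]; sy <- y[i] == y[j]
    if (sx && sy) a <- a + 1
    else if (sx && !sy) b <- b + 1
    else if (!sx && sy) cc <- cc + 1
    else d <- d + 1
  }
  denom <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (denom == 0) return(1)
  2 * (a * d - b * cc) / denom
}

# entropy/MI oracle with explicit loops (arithmetic-mean normalization)
nmi_oracle <- function(x, y) {
  n <- length(x)
  ux <- unique(x); uy <- unique(y)
  hx <- 0; hy <- 0; mi <- 0
  for (u in ux) { p <- mean(x == u); hx <- hx - p * log(p) }
  for (v in uy) { p <- mean(y == v); hy <- hy - p * log(p) }
  for (u in ux) for (v in uy) {
    pj <- mean(x == u & y == v)
    if (pj > 0) mi <- mi + pj * log(pj / (mean(x == u) * mean(y == v)))
  }
  if (hx == 0 && hy == 0) return(0)
  mi / ((hx + hy) / 2)
}

# brute-force silhouette oracle (singleton convention a = 0)
silhouette_oracle <- function(X, labels) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    a <- if (length(own)) mean(vapply(own, function(j) d(i, j), 1)) else 0
    b <- Inf
    for (l in setdiff(unique(labels), labels[i])) {
      mem <- which(labels == l)
      b <- min(b, mean(vapply(mem, function(j) d(i, j), 1)))
    }
    s[i] <- if (a == 0 && b == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}
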