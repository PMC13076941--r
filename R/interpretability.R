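# Interpretability: attention-derived residue scores and their enrichment on
# paratope labels, per-layer attention trajectories, integrated-gradients
# attribution in embedding space (midpoint Riemann rule, zero baseline) with
# a completeness audit, and in-silico saturation mutagenesis with the
# decrease-frequency fold statistic.

#' Attention-derived residue scores
#'
#' Score of residue j = attention received by j: mean attention weight from
#' all non-pad query positions to j, aggregated over heads (`mean` or `max`)
#' and averaged over the selected layers. Scores are reported for residue
#' positions only (pad/special/metadata columns excluded). Set
#' `direction = "emitted"` to aggregate rows instead of columns.
#'
#' @param fw [forward()] output (with `attention`).
#' @param batch The encoded batch that produced `fw`.
#' @param record Record index within the batch.
#' @param layer_set Integer layer indices (default all).
#' @param head_agg `"mean"` or `"max"`.
#' @param direction `"received"` (default) or `"emitted"`.
#' @return Object of class `attribution_profile`: list with `scores` (one
#'   per residue position), `positions` (0-based offsets within the
#'   encoding), `method = "attention"`, provenance fields.
#' @export
residue_attention_scores <- function(fw, batch, record = 1L,
                                     layer_set = NULL,
                                     head_agg = c("mean", "max"),
                                     direction = c("received", "emitted")) {
  head_agg <- match.arg(head_agg)
  direction <- match.arg(direction)
  n_layers <- length(fw$attention)
  layer_set <- layer_set %||% seq_len(n_layers)
  assert_that(length(layer_set) > 0, "layer_set must be non-empty")
  assert_that(all(layer_set >= 1 & layer_set <= n_layers),
              "layer index out of range")
  real <- batch$pad_mask[record, ]
  res_pos <- which(batch$category[record, ] == "residue")
  nh <- dim(fw$attention[[1]])[2]
  per_layer <- vapply(layer_set, function(l) {
    per_head <- vapply(seq_len(nh), function(h) {
      A <- fw$attention[[l]][record, h, , ]
      if (direction == "received") {
        colMeans(A[real, res_pos, drop = FALSE])
      } else {
        rowMeans(A[res_pos, real, drop = FALSE])
      }
    }, numeric(length(res_pos)))
    if (head_agg == "mean") rowMeans(per_head) else apply(per_head, 1, max)
  }, numeric(length(res_pos)))
  scores <- rowMeans(matrix(per_layer, nrow = length(res_pos)))
  structure(list(scores = scores, positions = res_pos - 1L,
                 method = "attention", layer_set = layer_set,
                 head_agg = head_agg, direction = direction,
                 source_id = batch$source_id[record]),
            class = "attribution_profile")
}

#' Paratope enrichment of top-ranked residue scores
#'
#' Pools residue scores and their binary paratope labels across records,
#' takes the `ceiling(top_frac * N)` highest-scoring residues, and reports
#' the paratope-labelled fraction of that top set, of the remaining
#' (background) residues, and their ratio.
#'
#' @param profiles List of `attribution_profile` (or numeric score vectors).
#' @param label_vectors List of matching binary 0/1 label vectors.
#' @param top_frac Top fraction, default 0.01.
#' @return list: `top_paratope_fraction`, `background_paratope_fraction`,
#'   `ratio`, `n_top`, `n_total`.
#' @export
attention_paratope_enrichment <- function(profiles, label_vectors,
                                          top_frac = 0.01) {
  scores <- unlist(lapply(profiles, function(p) {
    if (inherits(p, "attribution_profile")) p$scores else p
  }))
  labels <- as.integer(unlist(label_vectors))
  assert_that(length(scores) == length(labels),
              "pooled scores and labels differ in length")
  N <- length(scores)
  n_top <- ceiling(top_frac * N)
  assert_that(n_top >= 1, "top set is empty")
  ord <- order(scores, decreasing = TRUE)
  top <- ord[seq_len(n_top)]
  rest <- ord[-seq_len(n_top)]
  tf <- mean(labels[top])
  bf <- mean(labels[rest])
  list(top_paratope_fraction = tf, background_paratope_fraction = bf,
       ratio = if (bf > 0) tf / bf else Inf, n_top = n_top, n_total = N)
}

#' Per-layer attention trajectory on binding vs non-binding residues
#'
#' For every layer, the mean attention-received score over residues labelled
#' as binding and over residues labelled as non-binding, pooled across
#' records.
#'
#' @param fw [forward()] output over the record set.
#' @param batch Encoded batch.
#' @param label_vectors List of binary label vectors (one per record,
#'   aligned to residue positions of the encoding).
#' @return data.frame: layer, binding, non_binding.
#' @export
layer_trajectory <- function(fw, batch, label_vectors) {
  n_layers <- length(fw$attention)
  B <- nrow(batch$ids)
  out <- lapply(seq_len(n_layers), function(l) {
    sb <- c(); snb <- c()
    for (b in seq_len(B)) {
      pr <- residue_attention_scores(fw, batch, record = b, layer_set = l)
      lab <- as.integer(label_vectors[[b]])[seq_along(pr$scores)]
      sb <- c(sb, pr$scores[lab == 1])
      snb <- c(snb, pr$scores[lab == 0])
    }
    data.frame(layer = l, binding = mean(sb), non_binding = mean(snb))
  })
  do.call(rbind, out)
}

#' Midpoint-rule path integral (integrated gradients core)
#'
#' Approximates the straight-line path integral of gradients from `baseline`
#' to `x` with an m-step midpoint Riemann sum:
#' `(x - baseline) * mean_k grad(baseline + (k - 0.5)/m * (x - baseline))`.
#' Exact for linear scorers at any step count.
#'
#' @param grad_fn function(x_like) -> gradient array of the scalar target.
#' @param x Input array.
#' @param baseline Baseline array (default zero).
#' @param steps Number of interpolation steps (>= 1).
#' @return Attribution array, same shape as `x`.
#' @export
ig_midpoint <- function(grad_fn, x, baseline = NULL, steps = 200L) {
  assert_that(steps >= 1, "steps must be >= 1")
  baseline <- baseline %||% (x * 0)
  diff <- x - baseline
  acc <- x * 0
  for (k in seq_len(steps)) {
    alpha <- (k - 0.5) / steps
    acc <- acc + grad_fn(baseline + alpha * diff)
  }
  diff * acc / steps
}

#' Integrated-gradients attribution for an encoded sequence
#'
#' Straight-line path in embedding space from a zero baseline to the input's
#' embedding activation, midpoint Riemann rule. The attributed quantity is
#' the output of the embedding stage (token + position lookup followed by
#' the embedding layer norm): the layer norm is scale-invariant, so a path
#' defined before it would leave the model output constant everywhere except
#' an infinitesimal neighborhood of the baseline; attributing the embedding
#' block's output (as layer-wise integrated gradients on BERT-style encoders
#' do) keeps the completeness axiom numerically meaningful. Per-dimension
#' attributions are summed per token position. The target scalar is either
#' the classifier probability of a subtype class (fixed at the input's
#' predicted class when `class` is omitted) or an MLM logit at a position.
#'
#' @param model `bcr_model`.
#' @param encoded `encoded_seq` (single sequence).
#' @param target Either `list(type = "class", classifier = <subtype_classifier>,
#'   class = <label or NULL for predicted>)` or
#'   `list(type = "token", position = <1-based>, token_id = <0-based>)`.
#' @param steps Interpolation steps (default 200).
#' @return `attribution_profile` with residue-position `scores`, plus
#'   `all_scores` (every position, metadata included), `completeness`
#'   (f(input), f(baseline), attribution sum and relative gap).
#' @export
integrated_gradients <- function(model, encoded, target, steps = 200L) {
  assert_that(steps >= 1, "steps must be >= 1")
  batch <- as_batch(encoded)
  ids <- batch$ids; pad <- batch$pad_mask
  T_ <- ncol(ids); H <- model$config$hidden_dim
  x <- embedding_output(model, ids)
  eval_point <- function(emb, want_grad = TRUE) {
    fw <- transformer_forward(model, ids, pad, inputs_embeds = emb,
                              want_cache = want_grad,
                              want_mlm = (target$type == "token"),
                              want_attention = FALSE)
    if (target$type == "token") {
      f <- fw$mlm_logits[target$position, target$token_id + 1L]
      if (!want_grad) return(list(f = f))
      dlog <- matrix(0, T_, model$config$vocab_size)
      dlog[target$position, target$token_id + 1L] <- 1
      bk <- transformer_backward(model, fw, d_logits = dlog)
    } else {
      clf <- target$classifier
      cls <- fw$hidden[1, , drop = FALSE]
      logits <- cls %*% clf$Wc + bcast(clf$bc, 1)
      p <- exp(log_softmax_rows(logits))[1, ]
      ci <- if (is.null(target[["class"]])) which.max(p) else
        match(target[["class"]], clf$classes)
      f <- p[ci]
      if (!want_grad) return(list(f = f))
      dp <- -p[ci] * p
      dp[ci] <- dp[ci] + p[ci]
      d_cls <- as.vector(clf$Wc %*% dp)
      d_hidden <- matrix(0, T_, H)
      d_hidden[1, ] <- d_cls
      bk <- transformer_backward(model, fw, d_hidden = d_hidden)
    }
    list(f = f, grad = bk$d_inputs_embeds)
  }
  if (target$type == "class" && is.null(target[["class"]])) {
    # fix the target at the input's predicted class for the whole path
    clf <- target$classifier
    fw0 <- transformer_forward(model, ids, pad, inputs_embeds = x,
                               want_mlm = FALSE, want_attention = FALSE)
    p0 <- exp(log_softmax_rows(fw0$hidden[1, , drop = FALSE] %*% clf$Wc +
                                 bcast(clf$bc, 1)))[1, ]
    target[["class"]] <- clf$classes[which.max(p0)]
  }
  acc <- x * 0
  for (k in seq_len(steps)) {
    alpha <- (k - 0.5) / steps
    acc <- acc + eval_point(alpha * x)$grad
  }
  attr_mat <- x * acc / steps
  all_scores <- rowSums(attr_mat)
  f_in <- eval_point(x, want_grad = FALSE)$f
  f_base <- eval_point(x * 0, want_grad = FALSE)$f
  res_pos <- which(batch$category[1, ] == "residue")
  structure(list(scores = all_scores[res_pos], positions = res_pos - 1L,
                 all_scores = all_scores, method = "integrated_gradients",
                 steps = steps, target = target$type,
                 completeness = list(
                   f_input = f_in, f_baseline = f_base,
                   attribution_sum = sum(all_scores),
                   relative_gap = abs(sum(all_scores) - (f_in - f_base)) /
                     max(abs(f_in - f_base), 1e-12)),
                 source_id = batch$source_id[1]),
            class = "attribution_profile")
}

#' Embedding-stage output for a batch of token ids
#'
#' Token + position embedding lookup followed by the embedding layer norm;
#' the activation that [integrated_gradients()] attributes.
#'
#' @param model `bcr_model`.
#' @param ids B x T (or length-T) matrix of 0-based token ids.
#' @return (B*T) x hidden matrix.
#' @export
embedding_output <- function(model, ids) {
  if (!is.matrix(ids)) ids <- matrix(ids, nrow = 1)
  T_ <- ncol(ids)
  p <- model$params
  Xe <- p$tok_emb[as.vector(t(ids)) + 1L, , drop = FALSE] +
    p$pos_emb[rep(seq_len(T_), nrow(ids)), , drop = FALSE]
  ln_forward(Xe, p$emb_ln_g, p$emb_ln_b)$y
}

#' Top-decile positions of an attribution profile
#'
#' Positions whose score is >= the 90th percentile score (the
#' `ceiling(0.1 * n)`-th largest value); ties are included, so the set has
#' at least `ceiling(0.1 * n)` members.
#'
#' @param profile `attribution_profile` or numeric score vector.
#' @return Integer indices into the score vector (1-based).
#' @export
top_decile_positions <- function(profile) {
  scores <- if (inherits(profile, "attribution_profile")) profile$scores else profile
  n <- length(scores)
  assert_that(n >= 1, "empty profile")
  thr <- sort(scores, decreasing = TRUE)[ceiling(0.1 * n)]
  which(scores >= thr)
}

#' In-silico saturation mutagenesis
#'
#' Each given residue position (plus an equal number of random control
#' positions drawn from the remaining residue positions) is mutated to all
#' 19 alternative amino acids; each mutant is re-scored with the classifier
#' and the change in probability of the original predicted class recorded.
#'
#' @param classifier `subtype_classifier`.
#' @param record One-row BCR record data.frame.
#' @param positions 0-based residue indices (within the sequence of the
#'   encoding mode used) to probe (the "top" group).
#' @param vocab `bcr_vocab`.
#' @param mode,max_len Encoding settings (must match the classifier's
#'   training encoding).
#' @param seed Seed for control-position sampling.
#' @return data.frame of class rows: position, group (`top_ig` /
#'   `random_control`), original, substituted, delta (P_mutant - P_original
#'   of the original predicted class).
#' @export
saturation_mutagenesis <- function(classifier, record, positions, vocab,
                                   mode = "full_length", max_len = NULL,
                                   seed = 1L) {
  max_len <- max_len %||% classifier$model$config$max_len
  seq_str <- if (mode == "hcdr3") record$hcdr3 else record$sequence
  L <- nchar(seq_str)
  assert_that(all(positions >= 0 & positions < L), "position out of range")
  set.seed(seed)
  pool <- setdiff(seq_len(L) - 1L, positions)
  control <- if (length(pool) >= length(positions)) {
    sample(pool, length(positions))
  } else pool
  enc0 <- encode(record, vocab, mode = mode, max_len = max_len)
  pr0 <- predict(classifier, enc0)
  c0 <- max.col(pr0$prob, ties.method = "first")[1]
  p0 <- pr0$prob[1, c0]
  probe <- function(pos_set, group) {
    rows <- list()
    for (pos in pos_set) {
      orig <- substr(seq_str, pos + 1L, pos + 1L)
      for (aa in setdiff(AA_ALPHABET, orig)) {
        mut <- seq_str
        substr(mut, pos + 1L, pos + 1L) <- aa
        rec2 <- record
        if (mode == "hcdr3") rec2$hcdr3 <- mut else rec2$sequence <- mut
        pm <- predict(classifier, encode(rec2, vocab, mode = mode,
                                         max_len = max_len))$prob[1, c0]
        rows[[length(rows) + 1L]] <-
          data.frame(position = pos, group = group, original = orig,
                     substituted = aa, delta = pm - p0,
                     stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  rbind(probe(positions, "top_ig"), probe(control, "random_control"))
}

#' Fold change of probability-decrease frequency
#'
#' Fraction of top-group substitutions that decrease the original-class
#' probability by more than `eps`, divided by the same fraction in the
#' random-control group.
#'
#' @param results [saturation_mutagenesis()] output.
#' @param eps Decrease threshold (default 0.01).
#' @return list: `fold` (Inf with `infinite = TRUE` when the control group
#'   has no decreases), `top_fraction`, `control_fraction`.
#' @export
mutagenesis_fold_change <- function(results, eps = 0.01) {
  top <- results$delta[results$group == "top_ig"]
  ctl <- results$delta[results$group == "random_control"]
  assert_that(length(top) > 0 && length(ctl) > 0,
              "both mutagenesis groups must be non-empty")
  tf <- mean(top < -eps)
  cf <- mean(ctl < -eps)
  if (cf == 0) {
    list(fold = Inf, infinite = TRUE, top_fraction = tf, control_fraction = 0)
  } else {
    list(fold = tf / cf, infinite = FALSE, top_fraction = tf,
         control_fraction = cf)
  }
}
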