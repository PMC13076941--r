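# Joint pretraining: masked-language-model corruption, the MLM loss
# (per-batch normalization: mean over sequences of summed masked-position
# negative log-probabilities), phenotype-aware supervised contrastive loss on
# CLS embeddings (temperature-scaled cosine InfoNCE with same-subtype
# positives), their convex combination, class-balanced sampling, the
# warmup + plateau-decay learning-rate schedule, and an AdamW optimizer.

#' Training configuration
#'
#' @param w_cl Contrastive-loss weight in \[0, 1\] (0 = pure MLM).
#' @param tau Contrastive temperature (> 0).
#' @param peak_lr Peak learning rate reached at the end of warmup.
#' @param warmup_fraction Fraction of total steps spent in linear warmup.
#' @param plateau_patience Consecutive non-improving evaluations before a
#'   learning-rate decay.
#' @param plateau_factor Multiplicative decay factor.
#' @param batch_size,total_steps,eval_interval Loop sizes.
#' @param mask_rate MLM corruption rate.
#' @param weight_decay Decoupled weight decay (matrices only; biases and
#'   layer-norm parameters are exempt).
#' @param seed Seed for the whole run.
#' @return Validated `training_config` list.
#' @export
training_config <- function(w_cl = 0.1, tau = 0.07, peak_lr = 1e-4,
                            warmup_fraction = 0.05, plateau_patience = 3L,
                            plateau_factor = 0.3, batch_size = 16L,
                            total_steps = 500L, eval_interval = 50L,
                            mask_rate = 0.15, weight_decay = 0.01,
                            seed = 1L) {
  assert_that(w_cl >= 0 && w_cl <= 1, "w_cl must lie in [0, 1]")
  assert_that(tau > 0, "tau must be positive")
  assert_that(peak_lr > 0 && warmup_fraction > 0 && plateau_patience > 0 &&
              plateau_factor > 0 && batch_size > 0 && total_steps > 0 &&
              eval_interval > 0, "all training sizes must be positive")
  structure(list(w_cl = w_cl, tau = tau, peak_lr = peak_lr,
                 warmup_fraction = warmup_fraction,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor,
                 batch_size = as.integer(batch_size),
                 total_steps = as.integer(total_steps),
                 eval_interval = as.integer(eval_interval),
                 mask_rate = mask_rate, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Apply MLM masking to an encoded batch
#'
#' Each maskable position (real, non-special token: residues and metadata)
#' is independently selected with probability `rate`; a selected position is
#' replaced by \[MASK\] with probability 0.8, by a uniformly random
#' amino-acid token with probability 0.1, and left unchanged with
#' probability 0.1. Targets hold the original ids at selected positions and
#' -1 elsewhere.
#'
#' @param batch [encode_batch()] result.
#' @param vocab `bcr_vocab`.
#' @param rate Selection probability in (0, 1).
#' @param seed Optional seed.
#' @return list: `corrupted_ids`, `targets` (both B x T), `pad_mask`,
#'   `category`, `masked` (logical B x T).
#' @export
apply_masking <- function(batch, vocab, rate = 0.15, seed = NULL) {
  assert_that(rate > 0 && rate < 1, "rate must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  ids <- batch$ids
  maskable <- batch$pad_mask & batch$category != "special"
  sel <- maskable & matrix(runif(length(ids)) < rate, nrow(ids))
  targets <- matrix(-1L, nrow(ids), ncol(ids))
  targets[sel] <- ids[sel]
  corrupted <- ids
  n_sel <- sum(sel)
  if (n_sel > 0) {
    u <- runif(n_sel)
    aa_ids <- vocab$blocks$amino_acid
    repl <- ids[sel]
    repl[u < 0.8] <- vocab$ids[["[MASK]"]]
    n_rand <- sum(u >= 0.8 & u < 0.9)
    repl[u >= 0.8 & u < 0.9] <- sample(aa_ids, n_rand, replace = TRUE)
    corrupted[sel] <- repl
  }
  list(corrupted_ids = corrupted, targets = targets,
       pad_mask = batch$pad_mask, category = batch$category,
       masked = sel, max_len = batch$max_len)
}

#' @noRd
log_softmax_rows <- function(logits) {
  m <- apply(logits, 1, max)
  logits - m - log(rowSums(exp(logits - m)))
}

#' Masked-language-model loss
#'
#' Mean over sequences of the summed negative log-probabilities of the true
#' tokens at masked positions (normalized by the batch size, not by the
#' number of masked positions).
#'
#' @param mlm_logits B x T x vocab array (as returned by [forward()]) or a
#'   (B*T) x vocab matrix.
#' @param targets B x T integer matrix, -1 at unmasked positions, original
#'   0-based token ids at masked positions.
#' @return Scalar loss.
#' @export
mlm_loss <- function(mlm_logits, targets) {
  g <- mlm_loss_grad(mlm_logits, targets, want_grad = FALSE)
  g$loss
}

#' @noRd
mlm_loss_grad <- function(mlm_logits, targets, want_grad = TRUE) {
  B <- nrow(targets); T_ <- ncol(targets)
  if (length(dim(mlm_logits)) == 3) {
    V <- dim(mlm_logits)[3]
    flat <- matrix(aperm(mlm_logits, c(3, 2, 1)), ncol = V, byrow = TRUE)
  } else {
    flat <- mlm_logits
    V <- ncol(flat)
  }
  tflat <- as.vector(t(targets))           # row (b-1)*T + t ordering
  mask <- tflat >= 0
  if (!any(mask)) {
    warning("no masked positions in batch; MLM loss defined as 0")
    return(list(loss = 0,
                d_logits = if (want_grad) matrix(0, B * T_, V) else NULL))
  }
  lp <- log_softmax_rows(flat[mask, , drop = FALSE])
  picked <- lp[cbind(seq_len(sum(mask)), tflat[mask] + 1L)]
  loss <- -sum(picked) / B
  d <- NULL
  if (want_grad) {
    probs <- exp(lp)
    probs[cbind(seq_len(sum(mask)), tflat[mask] + 1L)] <-
      probs[cbind(seq_len(sum(mask)), tflat[mask] + 1L)] - 1
    d <- matrix(0, B * T_, V)
    d[mask, ] <- probs / B
  }
  list(loss = loss, d_logits = d)
}

#' Cosine similarity
#'
#' @param h_i,h_j Non-zero numeric vectors of equal length.
#' @return Scalar in \[-1, 1\].
#' @export
cosine_similarity <- function(h_i, h_j) {
  ni <- sqrt(sum(h_i^2)); nj <- sqrt(sum(h_j^2))
  assert_that(ni > 0 && nj > 0, "cosine similarity undefined for zero vectors")
  sum(h_i * h_j) / (ni * nj)
}

#' Supervised contrastive loss
#'
#' Supervised InfoNCE on cosine similarities: for each anchor i with
#' positive set P(i) (same subtype, excluding i),
#' `loss_i = -(1/|P(i)|) * sum_p log( exp(sim(i,p)/tau) /
#' sum_{a != i} exp(sim(i,a)/tau) )`; the batch loss is the mean over
#' anchors with at least one positive. Anchors without positives are
#' skipped; if no anchor has a positive the loss is 0 with a warning.
#'
#' @param embeddings n x d matrix of sequence embeddings.
#' @param subtype_labels Length-n label vector.
#' @param tau Temperature > 0.
#' @return Scalar loss.
#' @export
contrastive_loss <- function(embeddings, subtype_labels, tau) {
  contrastive_loss_grad(embeddings, subtype_labels, tau,
                        want_grad = FALSE)$loss
}

#' @noRd
contrastive_loss_grad <- function(embeddings, subtype_labels, tau,
                                  want_grad = TRUE) {
  assert_that(tau > 0, "tau must be positive")
  n <- nrow(embeddings)
  assert_that(n == length(subtype_labels), "embeddings/labels length mismatch")
  norms <- sqrt(rowSums(embeddings^2))
  assert_that(all(norms > 0), "zero embedding vector")
  Z <- embeddings / norms
  S <- (Z %*% t(Z)) / tau
  same <- outer(subtype_labels, subtype_labels, "==")
  diag(same) <- FALSE
  n_pos <- rowSums(same)
  anchors <- which(n_pos > 0)
  if (length(anchors) == 0) {
    warning("no anchor has a positive; contrastive loss defined as 0")
    return(list(loss = 0,
                d_embeddings = if (want_grad) matrix(0, n, ncol(embeddings)) else NULL))
  }
  # log-sum-exp over a != i, row-wise
  Sx <- S; diag(Sx) <- -Inf
  mx <- apply(Sx, 1, max)
  lse <- mx + log(rowSums(exp(Sx - mx)))
  loss_i <- vapply(anchors, function(i) {
    -(sum(S[i, same[i, ]]) / n_pos[i] - lse[i])
  }, numeric(1))
  loss <- mean(loss_i)
  if (!want_grad) return(list(loss = loss))
  # dL/dS[i,j] for anchor i: softmax_ij - 1{j in P(i)}/|P(i)|, / n_anchors
  G <- matrix(0, n, n)
  for (i in anchors) {
    soft <- exp(Sx[i, ] - lse[i])
    gi <- soft
    gi[same[i, ]] <- gi[same[i, ]] - 1 / n_pos[i]
    G[i, ] <- gi / length(anchors)
  }
  dZ <- ((G + t(G)) %*% Z) / tau
  # through z = h / ||h||
  dH <- (dZ - Z * rowSums(dZ * Z)) / norms
  list(loss = loss, d_embeddings = dH)
}

#' Total loss
#'
#' Convex combination `(1 - w_cl) * l_mlm + w_cl * l_cl`.
#'
#' @param l_mlm,l_cl Scalar losses.
#' @param w_cl Weight in \[0, 1\].
#' @return Scalar.
#' @export
total_loss <- function(l_mlm, l_cl, w_cl) {
  assert_that(w_cl >= 0 && w_cl <= 1, "w_cl must lie in [0, 1]")
  (1 - w_cl) * l_mlm + w_cl * l_cl
}

#' Class-balanced sampler
#'
#' Sampling with replacement with per-record probability proportional to
#' 1 / frequency(class), so expected per-class counts in a batch are equal.
#' Returns a closure producing successive index batches; deterministic per
#' seed and independent of other RNG use between calls.
#'
#' @param subtype_labels Label vector (NA allowed; NA forms its own class).
#' @param batch_size Batch size.
#' @param seed Integer seed.
#' @return function() -> integer vector of `batch_size` indices.
#' @export
balanced_sampler <- function(subtype_labels, batch_size, seed = 1L) {
  assert_that(length(subtype_labels) > 0, "empty label vector")
  lab <- ifelse(is.na(subtype_labels), "<NA>", as.character(subtype_labels))
  freq <- table(lab)
  w <- 1 / as.numeric(freq[lab])
  w <- w / sum(w)
  state <- local({ set.seed(seed); .Random.seed })
  function() {
    old <- .GlobalEnv$.Random.seed
    assign(".Random.seed", state, envir = .GlobalEnv)
    idx <- sample.int(length(lab), batch_size, replace = TRUE, prob = w)
    state <<- .GlobalEnv$.Random.seed
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    idx
  }
}

#' Learning-rate schedule
#'
#' Linear warmup from 0 to `config$peak_lr` over the first
#' `warmup_fraction * total_steps` steps, then constant at the peak until
#' the plateau rule fires: after `plateau_patience` consecutive evaluations
#' without validation-loss improvement the rate is multiplied by
#' `plateau_factor` (the counter resets on improvement or on decay).
#'
#' @param step Current step (0-based).
#' @param total_steps Total planned steps.
#' @param config `training_config`.
#' @param val_loss_history Numeric vector of validation losses observed so
#'   far (in evaluation order).
#' @return Learning rate.
#' @export
lr_schedule <- function(step, total_steps, config,
                        val_loss_history = numeric(0)) {
  warmup_steps <- max(1, round(config$warmup_fraction * total_steps))
  if (step <= warmup_steps) {
    return(config$peak_lr * step / warmup_steps)
  }
  decays <- 0L
  best <- Inf
  streak <- 0L
  for (v in val_loss_history) {
    if (v < best) {
      best <- v
      streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak >= config$plateau_patience) {
        decays <- decays + 1L
        streak <- 0L
      }
    }
  }
  config$peak_lr * config$plateau_factor^decays
}

# ---- AdamW -----------------------------------------------------------------

#' @noRd
adamw_init <- function(params) {
  list(m = zero_like_params(params), v = zero_like_params(params), t = 0L)
}

#' @noRd
adamw_update <- function(params, grads, state, lr, weight_decay,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(rec, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    upd <- lr * mhat / (sqrt(vhat) + eps)
    if (is.matrix(p) && weight_decay > 0) upd <- upd + lr * weight_decay * p
    list(p = p - upd, m = m, v = v)
  }
  out <- rec(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

#' @noRd
scale_params <- function(a, s) rapply(a, function(x) x * s, how = "replace")

#' @noRd
add_params <- function(a, b) {
  rec <- function(x, y) {
    if (is.list(x)) Map(rec, x, y) else x + y
  }
  rec(a, b)
}

# ---- training loop ---------------------------------------------------------

#' Pretrain a model with joint MLM + contrastive objectives
#'
#' Per step: draw a class-balanced batch, apply MLM masking, forward the
#' corrupted batch and compute the MLM loss on all records; when
#' `config$w_cl > 0`, run a second (unmasked, dropout-free) forward pass on
#' the labelled records of the batch, compute the contrastive loss on their
#' CLS embeddings, and combine the two gradients as the convex combination
#' of the total loss. Parameters are updated with AdamW at the scheduled
#' rate. Validation MLM loss is evaluated every `eval_interval` steps on a
#' fixed pre-masked validation batch and drives the plateau decay. Fully
#' seeded; aborts on non-finite loss.
#'
#' @param model `bcr_model`.
#' @param train_data list with `batch` ([encode_batch()] result) and
#'   `labels` (subtype per record; NA = unlabeled, contributes MLM only).
#' @param val_data Same shape as `train_data` (labels optional).
#' @param config `training_config`.
#' @param vocab `bcr_vocab`.
#' @return list: `model` (trained), `history` (data.frame of per-step
#'   losses/rates), `val_history` (data.frame of evaluation losses).
#' @export
train <- function(model, train_data, val_data, config, vocab) {
  set.seed(config$seed)
  labels <- train_data$labels
  sampler <- balanced_sampler(labels, config$batch_size, seed = config$seed)
  val_masked <- apply_masking(val_data$batch, vocab, rate = config$mask_rate)
  state <- adamw_init(model$params)
  val_losses <- numeric(0)
  hist <- vector("list", config$total_steps)
  val_hist <- list()
  for (step in seq_len(config$total_steps)) {
    idx <- sampler()
    sub <- subset_batch(train_data$batch, idx)
    masked <- apply_masking(sub, vocab, rate = config$mask_rate)
    fw <- transformer_forward(model, masked$corrupted_ids, masked$pad_mask,
                              training = TRUE, want_cache = TRUE,
                              want_attention = FALSE)
    ml <- mlm_loss_grad(fw$mlm_logits, masked$targets)
    bk <- transformer_backward(model, fw, d_logits = ml$d_logits)
    grads <- scale_params(bk$grads, 1 - config$w_cl)
    l_cl <- NA_real_
    if (config$w_cl > 0) {
      lab_b <- labels[idx]
      ok <- !is.na(lab_b)
      if (sum(ok) >= 2 && length(unique(lab_b[ok])) >= 1) {
        sub_l <- subset_batch(sub, which(ok))
        fw2 <- transformer_forward(model, sub_l$ids, sub_l$pad_mask,
                                   want_cache = TRUE, want_mlm = FALSE,
                                   want_attention = FALSE)
        T_ <- fw2$T
        cls_rows <- (seq_len(fw2$B) - 1L) * T_ + 1L
        cls <- fw2$hidden[cls_rows, , drop = FALSE]
        cg <- contrastive_loss_grad(cls, lab_b[ok], config$tau)
        l_cl <- cg$loss
        d_hidden <- matrix(0, fw2$B * T_, model$config$hidden_dim)
        d_hidden[cls_rows, ] <- cg$d_embeddings
        bk2 <- transformer_backward(model, fw2, d_hidden = d_hidden)
        grads <- add_params(grads, scale_params(bk2$grads, config$w_cl))
      }
    }
    l_total <- total_loss(ml$loss, if (is.na(l_cl)) 0 else l_cl, config$w_cl)
    if (!is.finite(l_total)) {
      stop(sprintf("training diverged at step %d (loss = %g)", step, l_total),
           call. = FALSE)
    }
    lr <- lr_schedule(step, config$total_steps, config, val_losses)
    upd <- adamw_update(model$params, grads, state, lr, config$weight_decay)
    model$params <- upd$params
    state <- upd$state
    hist[[step]] <- data.frame(step = step, lr = lr, loss_mlm = ml$loss,
                               loss_cl = l_cl, loss_total = l_total)
    if (step %% config$eval_interval == 0) {
      vfw <- transformer_forward(model, val_masked$corrupted_ids,
                                 val_masked$pad_mask, want_cache = FALSE,
                                 want_attention = FALSE)
      vl <- mlm_loss_grad(vfw$mlm_logits, val_masked$targets,
                          want_grad = FALSE)$loss
      val_losses <- c(val_losses, vl)
      val_hist[[length(val_hist) + 1L]] <-
        data.frame(step = step, val_mlm_loss = vl)
    }
  }
  list(model = model,
       history = do.call(rbind, hist),
       val_history = if (length(val_hist)) do.call(rbind, val_hist) else
         data.frame(step = integer(0), val_mlm_loss = numeric(0)))
}

#' Subset an encoded batch by row indices
#' @param batch [encode_batch()] result.
#' @param idx Integer row indices.
#' @return Encoded batch restricted to `idx`.
#' @export
subset_batch <- function(batch, idx) {
  list(ids = batch$ids[idx, , drop = FALSE],
       pad_mask = batch$pad_mask[idx, , drop = FALSE],
       category = batch$category[idx, , drop = FALSE],
       source_id = batch$source_id[idx],
       max_len = batch$max_len)
}
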