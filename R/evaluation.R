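# Evaluation: external clustering indices for embedding quality (ARI, NMI,
# silhouette), subtype classification with macro-averaged report and
# multiclass (Gorodkin) MCC, and per-residue paratope scoring with the six
# benchmark metrics (precision, recall, F1, MCC, AUROC, APR).

#' Adjusted Rand index
#'
#' Permutation-model-adjusted Rand index from the contingency table of two
#' partitions (wraps the standard mclust implementation).
#'
#' @param labels_a,labels_b Equal-length label vectors (n >= 2).
#' @return Scalar <= 1.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  assert_that(length(labels_a) == length(labels_b),
              "partitions must have equal length")
  assert_that(length(labels_a) >= 2, "need at least 2 elements")
  r <- mclust::adjustedRandIndex(labels_a, labels_b)
  if (!is.finite(r)) {
    # degenerate partitions (expected index = maximum index): 0/0; the two
    # partitions then make identical pair judgments iff their co-membership
    # relations coincide
    same <- identical(outer(labels_a, labels_a, "=="),
                      outer(labels_b, labels_b, "=="))
    r <- if (same) 1 else 0
  }
  r
}

#' Normalized mutual information
#'
#' Mutual information of the two partitions normalized by the arithmetic
#' mean of their entropies (natural log). Degenerate single-class input on
#' both sides yields 0 with a warning.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Scalar in \[0, 1\].
#' @export
normalized_mutual_information <- function(labels_a, labels_b) {
  assert_that(length(labels_a) == length(labels_b),
              "partitions must have equal length")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  pij <- tab / n
  pi_ <- rowSums(pij); pj <- colSums(pij)
  entropy <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- entropy(pi_); hb <- entropy(pj)
  if (ha == 0 && hb == 0) {
    warning("both partitions are single-class; NMI defined as 0")
    return(0)
  }
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj)[nz]))
  mi / ((ha + hb) / 2)
}

#' Silhouette score
#'
#' Mean over points of (b - a) / max(a, b) with Euclidean distances, where a
#' is the mean distance to the point's own cluster (excluding itself) and b
#' the smallest mean distance to another cluster. For singleton clusters the
#' convention a = 0 is used (so an isolated, well-separated point scores 1).
#'
#' @param embeddings n x d numeric matrix.
#' @param labels Length-n cluster labels (>= 2 distinct, n >= 3).
#' @return Scalar in \[-1, 1\].
#' @export
silhouette_score <- function(embeddings, labels) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  assert_that(n == length(labels), "embeddings/labels length mismatch")
  assert_that(length(unique(labels)) >= 2,
              "silhouette undefined for a single cluster")
  assert_that(n >= 3, "need at least 3 points")
  D <- as.matrix(dist(embeddings))
  labs <- unique(labels)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(D[i, own]) else 0
    b <- min(vapply(labs[labs != labels[i]], function(l) {
      mean(D[i, labels == l])
    }, numeric(1)))
    if (a == 0 && b == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Score embeddings against a labelling
#'
#' Clusters the embeddings with k-means (k = number of distinct labels,
#' seeded) and reports ARI and NMI of the clustering against the labels,
#' plus the silhouette of the labels themselves in the embedding space.
#'
#' @param embeddings n x d matrix (e.g. CLS embeddings).
#' @param labels True grouping (subtype, isotype, V family, mutation bin...).
#' @param seed k-means seed.
#' @return list: `ari`, `nmi`, `silhouette`.
#' @export
embedding_eval <- function(embeddings, labels, seed = 1L) {
  k <- length(unique(labels))
  set.seed(seed)
  km <- kmeans(embeddings, centers = k, nstart = 5)
  list(ari = adjusted_rand_index(km$cluster, labels),
       nmi = normalized_mutual_information(km$cluster, labels),
       silhouette = silhouette_score(embeddings, labels))
}

#' Multiclass classification report
#'
#' Macro-averaged precision/recall/F1 (classes absent from predictions score
#' 0 precision), multiclass MCC in the Gorodkin form computed from the full
#' confusion matrix, and the confusion matrix itself (rows = truth).
#'
#' @param predictions,truth Equal-length label vectors.
#' @param averaging `"macro"` (default) or `"micro"` for P/R/F1.
#' @return list of class `metrics_report`: `accuracy`, `precision`,
#'   `recall`, `f1`, `mcc`, `per_class` (data.frame), `confusion` (matrix),
#'   `averaging`.
#' @export
classification_report <- function(predictions, truth, averaging = "macro") {
  assert_that(length(predictions) == length(truth) && length(truth) > 0,
              "predictions/truth must be non-empty and equal length")
  averaging <- match.arg(averaging, c("macro", "micro"))
  classes <- sort(unique(c(as.character(predictions), as.character(truth))))
  pred <- factor(as.character(predictions), levels = classes)
  tru <- factor(as.character(truth), levels = classes)
  cm <- table(truth = tru, prediction = pred)
  tp <- diag(cm)
  support <- rowSums(cm)
  pred_n <- colSums(cm)
  prec <- ifelse(pred_n > 0, tp / pred_n, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- support > 0
  if (averaging == "macro") {
    P <- mean(prec[present]); R <- mean(rec[present]); F1 <- mean(f1[present])
  } else {
    P <- R <- F1 <- sum(tp) / length(truth)
  }
  # Gorodkin multiclass MCC from the confusion matrix
  n <- sum(cm)
  cmn <- as.matrix(cm)
  cov_xy <- n * sum(tp) - sum(pred_n * support)
  cov_xx <- n^2 - sum(pred_n^2)
  cov_yy <- n^2 - sum(support^2)
  mcc <- if (cov_xx == 0 || cov_yy == 0) 0 else
    cov_xy / sqrt(cov_xx) / sqrt(cov_yy)
  structure(list(accuracy = sum(tp) / length(truth),
                 precision = P, recall = R, f1 = F1, mcc = mcc,
                 per_class = data.frame(class = classes, precision = as.numeric(prec),
                                        recall = as.numeric(rec), f1 = as.numeric(f1),
                                        support = as.numeric(support)),
                 confusion = cmn, averaging = averaging),
            class = "metrics_report")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with midrank tie handling.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1), both classes present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  assert_that(n1 > 0 && n0 > 0, "AUROC undefined: only one class present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step interpolation: AP = sum over descending-score positives of
#' (R_k - R_{k-1}) * P_k.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1) with at least one positive.
#' @return AP in \[0, 1\].
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  assert_that(sum(labels == 1) > 0, "AP undefined without positives")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / sum(y)
  drec <- diff(c(0, rec))
  sum(drec * prec)
}

#' Per-residue paratope metrics
#'
#' Residue scores pooled across sequences (micro): thresholded precision,
#' recall, F1 and binary MCC at `threshold`, plus threshold-free AUROC and
#' average precision.
#'
#' @param scores Numeric vector of per-residue scores (pooled).
#' @param labels Binary 0/1 vector, same length.
#' @param threshold Operating threshold for the thresholded metrics.
#' @return list of class `metrics_report` fields: `precision`, `recall`,
#'   `f1`, `mcc`, `auroc`, `apr`, `threshold`.
#' @export
paratope_metrics <- function(scores, labels, threshold = 0.5) {
  assert_that(length(scores) == length(labels), "scores/labels length mismatch")
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  structure(list(precision = prec, recall = rec, f1 = f1, mcc = mcc,
                 auroc = auroc(scores, labels),
                 apr = average_precision(scores, labels),
                 threshold = threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  num <- vapply(x, function(v) is.numeric(v) && length(v) == 1, logical(1))
  cat("<metrics_report>",
      paste(sprintf("%s=%.4f", names(x)[num], unlist(x[num])),
            collapse = "  "), "\n")
  invisible(x)
}

# ---- fine-tuning heads -----------------------------------------------------

#' Fine-tune a subtype classifier
#'
#' Linear softmax head on the CLS embedding trained by cross-entropy with
#' AdamW. With `finetune_backbone = FALSE` (default) the encoder is frozen
#' and embeddings are computed once; with `TRUE`, gradients flow into the
#' encoder.
#'
#' @param model Pretrained `bcr_model`.
#' @param batch Encoded batch of labelled records.
#' @param labels Subtype label per record (no NA).
#' @param epochs Passes over the data.
#' @param lr Head learning rate.
#' @param batch_size Mini-batch size.
#' @param finetune_backbone Update encoder weights too.
#' @param seed Seed.
#' @return Object of class `subtype_classifier` with `predict` support.
#' @export
fine_tune_classifier <- function(model, batch, labels, epochs = 30L,
                                 lr = 5e-3, batch_size = 32L,
                                 finetune_backbone = FALSE, seed = 1L) {
  assert_that(!anyNA(labels), "labels must be complete")
  set.seed(seed)
  classes <- sort(unique(as.character(labels)))
  y <- match(as.character(labels), classes)
  H <- model$config$hidden_dim; K <- length(classes)
  Wc <- matrix(rnorm(H * K, sd = 0.02), H, K); bc <- numeric(K)
  n <- nrow(batch$ids)
  if (!finetune_backbone) {
    emb <- cls_embedding(model, batch)
  }
  head_state <- adamw_init(list(Wc = Wc, bc = bc))
  back_state <- if (finetune_backbone) adamw_init(model$params) else NULL
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      if (finetune_backbone) {
        sb <- subset_batch(batch, idx)
        fw <- transformer_forward(model, sb$ids, sb$pad_mask,
                                  want_cache = TRUE, want_mlm = FALSE,
                                  want_attention = FALSE)
        cls_rows <- (seq_len(fw$B) - 1L) * fw$T + 1L
        E <- fw$hidden[cls_rows, , drop = FALSE]
      } else {
        E <- emb[idx, , drop = FALSE]
      }
      logits <- E %*% Wc + bcast(bc, length(idx))
      lp <- log_softmax_rows(logits)
      probs <- exp(lp)
      d <- probs
      d[cbind(seq_along(idx), y[idx])] <- d[cbind(seq_along(idx), y[idx])] - 1
      d <- d / length(idx)
      gW <- t(E) %*% d
      gb <- colSums(d)
      upd <- adamw_update(list(Wc = Wc, bc = bc), list(Wc = gW, bc = gb),
                          head_state, lr, weight_decay = 0)
      Wc <- upd$params$Wc; bc <- upd$params$bc
      head_state <- upd$state
      if (finetune_backbone) {
        dE <- d %*% t(Wc)
        d_hidden <- matrix(0, fw$B * fw$T, H)
        d_hidden[cls_rows, ] <- dE
        bk <- transformer_backward(model, fw, d_hidden = d_hidden)
        updb <- adamw_update(model$params, bk$grads, back_state, lr * 0.1,
                             weight_decay = 0.01)
        model$params <- updb$params
        back_state <- updb$state
      }
    }
  }
  structure(list(model = model, Wc = Wc, bc = bc, classes = classes,
                 finetuned_backbone = finetune_backbone),
            class = "subtype_classifier")
}

#' Predict subtypes (and class probabilities)
#'
#' @param object `subtype_classifier`.
#' @param batch Encoded batch.
#' @param ... Unused.
#' @return list: `label` (predicted class per record), `prob` (n x K matrix).
#' @export
predict.subtype_classifier <- function(object, batch, ...) {
  E <- cls_embedding(object$model, batch)
  logits <- E %*% object$Wc + bcast(object$bc, nrow(E))
  probs <- exp(log_softmax_rows(logits))
  colnames(probs) <- object$classes
  list(label = object$classes[max.col(probs, ties.method = "first")],
       prob = probs)
}

#' Fine-tune a per-residue paratope head
#'
#' Binary logistic head over final hidden states at residue positions,
#' trained with class-weighted cross-entropy (weights inversely proportional
#' to class frequency) to counter paratope sparsity. Loss and gradients are
#' restricted to residue positions: \[CLS\]/\[SEP\]/metadata/\[PAD\]
#' positions are excluded. The encoder is frozen.
#'
#' @param model Pretrained `bcr_model`.
#' @param paratope_records data.frame with `id`, `sequence`, `labels`
#'   columns (label string per residue).
#' @param vocab `bcr_vocab`.
#' @param max_len Encoding length.
#' @param epochs,lr Optimization settings.
#' @param seed Seed.
#' @return Object of class `paratope_scorer`.
#' @export
fine_tune_paratope <- function(model, paratope_records, vocab,
                               max_len = NULL, epochs = 50L, lr = 5e-3,
                               seed = 1L) {
  max_len <- max_len %||% model$config$max_len
  set.seed(seed)
  prep <- paratope_design(model, paratope_records, vocab, max_len)
  X <- prep$X; y <- prep$y
  wpos <- length(y) / (2 * sum(y == 1))
  wneg <- length(y) / (2 * sum(y == 0))
  w <- ifelse(y == 1, wpos, wneg)
  H <- ncol(X)
  wv <- numeric(H); b0 <- 0
  st <- adamw_init(list(w = wv, b = b0))
  for (ep in seq_len(epochs)) {
    z <- as.vector(X %*% wv) + b0
    p <- 1 / (1 + exp(-z))
    gz <- w * (p - y) / length(y)
    gW <- as.vector(t(X) %*% gz)
    gb <- sum(gz)
    upd <- adamw_update(list(w = wv, b = b0), list(w = gW, b = gb), st, lr,
                        weight_decay = 0)
    wv <- upd$params$w; b0 <- upd$params$b
    st <- upd$state
  }
  structure(list(model = model, w = wv, b = b0, vocab = vocab,
                 max_len = max_len), class = "paratope_scorer")
}

#' @noRd
paratope_design <- function(model, paratope_records, vocab, max_len) {
  lab_len <- nchar(paratope_records$labels)
  seq_len_ <- nchar(paratope_records$sequence)
  bad <- lab_len != seq_len_
  if (any(bad)) {
    stop("label/sequence length mismatch for record(s): ",
         paste(head(paratope_records$id[bad]), collapse = ", "),
         call. = FALSE)
  }
  batch <- encode_batch(as_paratope_bcr(paratope_records), vocab,
                        mode = "full_length", max_len = max_len)
  fw <- transformer_forward(model, batch$ids, batch$pad_mask,
                            want_mlm = FALSE, want_attention = FALSE)
  T_ <- fw$T
  rows <- list(); ys <- list(); recs <- list(); poss <- list()
  for (i in seq_len(nrow(paratope_records))) {
    res_pos <- which(batch$category[i, ] == "residue")
    lab <- as.integer(strsplit(paratope_records$labels[i], "")[[1]])
    lab <- lab[seq_along(res_pos)]         # truncation drops tail labels
    rows[[i]] <- fw$hidden[(i - 1L) * T_ + res_pos, , drop = FALSE]
    ys[[i]] <- lab
    recs[[i]] <- rep(paratope_records$id[i], length(res_pos))
    poss[[i]] <- seq_along(res_pos) - 1L
  }
  list(X = do.call(rbind, rows), y = unlist(ys), record = unlist(recs),
       position = unlist(poss), batch = batch)
}

#' @noRd
as_paratope_bcr <- function(pr) {
  data.frame(id = pr$id, chain = pr$chain %||% "heavy",
             locus = "IGH", sequence = pr$sequence, hcdr3 = NA_character_,
             hcdr3_start = NA_integer_, hcdr3_end = NA_integer_,
             v_call = NA_character_, d_call = NA_character_,
             j_call = NA_character_, isotype = NA_character_,
             subtype = NA_character_, n_mutations = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Score residues with a paratope head
#'
#' @param object `paratope_scorer`.
#' @param paratope_records data.frame with `id`, `sequence` (and `labels`
#'   if available, passed through).
#' @param ... Unused.
#' @return data.frame: record, position (0-based residue index), score, and
#'   label when available.
#' @export
predict.paratope_scorer <- function(object, paratope_records, ...) {
  if (is.null(paratope_records$labels)) paratope_records$labels <-
      vapply(nchar(paratope_records$sequence),
             function(L) paste(rep("0", L), collapse = ""), character(1))
  prep <- paratope_design(object$model, paratope_records, object$vocab,
                          object$max_len)
  z <- as.vector(prep$X %*% object$w) + object$b
  data.frame(record = prep$record, position = prep$position,
             score = 1 / (1 + exp(-z)), label = prep$y,
             stringsAsFactors = FALSE)
}
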