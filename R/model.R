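# User-facing model API: configuration, initialization, parameter counting,
# forward pass and CLS embeddings. The encoder is a post-layer-norm
# bidirectional transformer (BERT-style): learned token and position
# embeddings, multi-head self-attention with padding exclusion, GELU
# feed-forward blocks, and an MLM head (dense + GELU + layer norm) whose
# output weights are tied to the token embeddings with a free bias. No
# pooler and no token-type embeddings.

#' Model configuration
#'
#' The reference preset (12 layers, 12 heads, hidden 768, feed-forward 3072,
#' vocabulary 260, maximum length 148) totals ~86 million trainable
#' parameters.
#'
#' @param n_layers,n_heads,hidden_dim,ffn_dim Encoder shape.
#' @param vocab_size Vocabulary size.
#' @param max_len Maximum sequence length (positional table size).
#' @param dropout Dropout probability (training mode only).
#' @param seed Initialization seed.
#' @return Validated `model_config` list.
#' @export
model_config <- function(n_layers = 12L, n_heads = 12L, hidden_dim = 768L,
                         ffn_dim = 3072L, vocab_size = 260L, max_len = 148L,
                         dropout = 0.1, seed = 1L) {
  if (hidden_dim %% n_heads != 0) {
    stop("hidden_dim must be divisible by n_heads", call. = FALSE)
  }
  assert_that(n_layers >= 0 && n_heads >= 1 && hidden_dim >= 1 &&
              ffn_dim >= 1 && vocab_size >= 1 && max_len >= 1,
              "config dimensions must be positive")
  assert_that(dropout >= 0 && dropout < 1, "dropout must lie in [0, 1)")
  structure(list(n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 hidden_dim = as.integer(hidden_dim),
                 ffn_dim = as.integer(ffn_dim),
                 vocab_size = as.integer(vocab_size),
                 max_len = as.integer(max_len),
                 dropout = dropout, seed = as.integer(seed)),
            class = "model_config")
}

#' Initialize a model
#'
#' Weights drawn N(0, 0.02^2) (BERT convention), layer-norm gains 1, all
#' biases 0; deterministic per seed.
#'
#' @param config `model_config`.
#' @param seed Overrides `config$seed` when given.
#' @return An object of class `bcr_model`: list with `config` and `params`.
#' @export
init_model <- function(config, seed = NULL) {
  set.seed(seed %||% config$seed)
  H <- config$hidden_dim; Fd <- config$ffn_dim; V <- config$vocab_size
  W <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.02), nr, nc)
  layer <- function() {
    list(Wq = W(H, H), bq = numeric(H), Wk = W(H, H), bk = numeric(H),
         Wv = W(H, H), bv = numeric(H), Wo = W(H, H), bo = numeric(H),
         ln1_g = rep(1, H), ln1_b = numeric(H),
         W1 = W(H, Fd), b1 = numeric(Fd), W2 = W(Fd, H), b2 = numeric(H),
         ln2_g = rep(1, H), ln2_b = numeric(H))
  }
  params <- list(
    tok_emb = W(V, H),
    pos_emb = W(config$max_len, H),
    emb_ln_g = rep(1, H), emb_ln_b = numeric(H),
    layers = lapply(seq_len(config$n_layers), function(i) layer()),
    mlm_W = W(H, H), mlm_b = numeric(H),
    mlm_ln_g = rep(1, H), mlm_ln_b = numeric(H),
    mlm_out_b = numeric(V)
  )
  structure(list(config = config, params = params), class = "bcr_model")
}

#' @export
print.bcr_model <- function(x, ...) {
  cat(sprintf("<bcr_model> %d layers x %d heads, hidden %d, ffn %d, vocab %d, max_len %d (%.2fM params)\n",
              x$config$n_layers, x$config$n_heads, x$config$hidden_dim,
              x$config$ffn_dim, x$config$vocab_size, x$config$max_len,
              count_parameters(x) / 1e6))
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact count over token and position embeddings, all encoder layers and
#' the MLM head; the tied MLM output matrix is the token embedding and is
#' counted once.
#'
#' @param model `bcr_model`.
#' @param scope Currently only `"encoder_with_mlm_head"`.
#' @return Integer-valued count (as double to avoid 32-bit overflow).
#' @export
count_parameters <- function(model, scope = "encoder_with_mlm_head") {
  scope <- match.arg(scope, "encoder_with_mlm_head")
  sum(rapply(model$params, function(x) as.numeric(length(x)), how = "unlist"))
}

#' Forward pass over an encoded batch
#'
#' @param model `bcr_model`.
#' @param batch An [encode_batch()] result, or a single `encoded_seq`.
#' @param training Enables dropout (non-deterministic); default FALSE.
#' @param want_hidden_states Also return per-layer hidden states.
#' @return list: `mlm_logits` (B x T x vocab array), `cls_embedding`
#'   (B x hidden matrix), `hidden` ((B*T) x hidden matrix), `attention`
#'   (list over layers of B x heads x T x T arrays), optionally
#'   `hidden_states`.
#' @export
forward <- function(model, batch, training = FALSE,
                    want_hidden_states = FALSE) {
  batch <- as_batch(batch)
  ids <- batch$ids; pad <- batch$pad_mask
  assert_that(ncol(ids) == model$config$max_len,
              "batch length does not match model max_len")
  assert_that(all(ids >= 0 & ids < model$config$vocab_size),
              "token id outside model vocabulary")
  fw <- transformer_forward(model, ids, pad, training = training,
                            want_hidden_states = want_hidden_states)
  B <- fw$B; T_ <- fw$T; V <- model$config$vocab_size
  H <- model$config$hidden_dim
  logits <- aperm(array(t(fw$mlm_logits), dim = c(V, T_, B)), c(3, 2, 1))
  cls <- fw$hidden[(seq_len(B) - 1L) * T_ + 1L, , drop = FALSE]
  out <- list(mlm_logits = logits, cls_embedding = cls, hidden = fw$hidden,
              attention = fw$attention, B = B, T = T_)
  if (want_hidden_states) out$hidden_states <- fw$hidden_states
  out
}

#' @noRd
as_batch <- function(batch) {
  if (inherits(batch, "encoded_seq")) {
    list(ids = matrix(batch$ids, nrow = 1),
         pad_mask = matrix(batch$pad_mask, nrow = 1),
         category = matrix(batch$category, nrow = 1),
         source_id = batch$source_id, max_len = length(batch$ids))
  } else batch
}

#' Sequence-level embedding via the \[CLS\] token
#'
#' Final-layer hidden state at position 0, with no projection.
#'
#' @param model `bcr_model`.
#' @param batch Encoded batch or single `encoded_seq`.
#' @return B x hidden matrix.
#' @export
cls_embedding <- function(model, batch) {
  batch <- as_batch(batch)
  fw <- transformer_forward(model, batch$ids, batch$pad_mask,
                            want_mlm = FALSE, want_attention = FALSE)
  fw$hidden[(seq_len(fw$B) - 1L) * fw$T + 1L, , drop = FALSE]
}

#' Save / load a model checkpoint
#'
#' Checkpoints store config, weights and a vocabulary hash; loading refuses
#' a checkpoint whose vocabulary hash does not match the supplied
#' vocabulary.
#'
#' @param model `bcr_model`.
#' @param path Checkpoint file.
#' @param vocab `bcr_vocab` the model was trained with.
#' @return `path` invisibly; `load_checkpoint` returns the model.
#' @export
save_checkpoint <- function(model, path, vocab) {
  saveRDS(list(config = model$config, params = model$params,
               vocab_hash = vocab_hash(vocab)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, vocab) {
  obj <- readRDS(path)
  if (!identical(obj$vocab_hash, vocab_hash(vocab))) {
    stop("checkpoint vocabulary hash does not match the supplied vocabulary",
         call. = FALSE)
  }
  structure(list(config = obj$config, params = obj$params),
            class = "bcr_model")
}
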