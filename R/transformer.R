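# Transformer encoder internals: forward pass with caching and the matching
# analytic backward pass. Implemented directly on base R matrices (BLAS
# matmuls); hidden states for a batch are stored as a (B*T) x H matrix with
# row (b-1)*T + t holding position t of sequence b. Gradients are verified
# against central finite differences in the test suite.

LN_EPS <- 1e-12
ATTN_NEG <- -1e9

#' @noRd
gelu <- function(x) x * stats::pnorm(x)

#' @noRd
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

#' @noRd
bcast <- function(v, n) matrix(v, nrow = n, ncol = length(v), byrow = TRUE)

#' @noRd
ln_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + LN_EPS)
  xhat <- xc * inv
  list(y = xhat * bcast(g, nrow(x)) + bcast(b, nrow(x)),
       xhat = xhat, inv = inv)
}

#' @noRd
ln_backward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- dy * bcast(g, nrow(dy))
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

#' @noRd
softmax_rows <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

#' @noRd
dropout_mask <- function(dim, p) {
  if (p <= 0) return(NULL)
  matrix((runif(prod(dim)) >= p) / (1 - p), nrow = dim[1], ncol = dim[2])
}

#' @noRd
apply_drop <- function(x, mask) if (is.null(mask)) x else x * mask

# Full forward pass. `ids` is B x T (0-based), `pad_mask` B x T logical.
# When `inputs_embeds` (BT x H) is given it replaces the output of the whole
# embedding stage (token + position lookup AND the embedding layer norm).
# This is the attribution entry point for integrated gradients: the layer
# norm is scale-invariant, so interpolating before it would make the path
# from a zero baseline degenerate.
# Returns hidden states, per-layer attention, MLM logits, and (if
# want_cache) everything the backward pass needs.
#' @noRd
transformer_forward <- function(model, ids, pad_mask, inputs_embeds = NULL,
                                training = FALSE, want_cache = FALSE,
                                want_mlm = TRUE, want_attention = TRUE,
                                want_hidden_states = FALSE) {
  p <- model$params
  cfg <- model$config
  B <- nrow(ids); T_ <- ncol(ids); H <- cfg$hidden_dim
  nh <- cfg$n_heads; dh <- H %/% nh
  drop_p <- if (training) cfg$dropout else 0
  flat_ids <- as.vector(t(ids)) + 1L
  pos_idx <- rep(seq_len(T_), B)
  if (is.null(inputs_embeds)) {
    Xe <- p$tok_emb[flat_ids, , drop = FALSE] +
      p$pos_emb[pos_idx, , drop = FALSE]
    ln0 <- ln_forward(Xe, p$emb_ln_g, p$emb_ln_b)
    emb_out <- ln0$y
  } else {
    ln0 <- NULL
    emb_out <- inputs_embeds
  }
  m0 <- dropout_mask(dim(emb_out), drop_p)
  X <- apply_drop(emb_out, m0)

  rows_of <- function(b) ((b - 1L) * T_ + 1L):(b * T_)
  head_cols <- function(h) ((h - 1L) * dh + 1L):(h * dh)
  caches <- vector("list", cfg$n_layers)
  attn_out <- if (want_attention) vector("list", cfg$n_layers) else NULL
  hs <- if (want_hidden_states) vector("list", cfg$n_layers) else NULL

  for (l in seq_len(cfg$n_layers)) {
    lp <- p$layers[[l]]
    X_in <- X
    Q <- X %*% lp$Wq + bcast(lp$bq, B * T_)
    K <- X %*% lp$Wk + bcast(lp$bk, B * T_)
    V <- X %*% lp$Wv + bcast(lp$bv, B * T_)
    Ctx <- matrix(0, B * T_, H)
    A_list <- vector("list", B)
    if (want_attention) attn_out[[l]] <- array(0, dim = c(B, nh, T_, T_))
    Adrop_list <- vector("list", B)
    for (b in seq_len(B)) {
      rb <- rows_of(b)
      keymask <- pad_mask[b, ]
      A_list[[b]] <- vector("list", nh)
      Adrop_list[[b]] <- vector("list", nh)
      for (h in seq_len(nh)) {
        hc <- head_cols(h)
        S <- (Q[rb, hc, drop = FALSE] %*% t(K[rb, hc, drop = FALSE])) / sqrt(dh)
        if (!all(keymask)) S[, !keymask] <- ATTN_NEG
        A <- softmax_rows(S)
        if (want_attention) attn_out[[l]][b, h, , ] <- A
        Am <- dropout_mask(dim(A), drop_p)
        Ad <- apply_drop(A, Am)
        Ctx[rb, hc] <- Ad %*% V[rb, hc, drop = FALSE]
        A_list[[b]][[h]] <- A
        Adrop_list[[b]][h] <- list(Am)   # may be NULL (no dropout)
      }
    }
    O <- Ctx %*% lp$Wo + bcast(lp$bo, B * T_)
    mo <- dropout_mask(dim(O), drop_p)
    O <- apply_drop(O, mo)
    R1 <- X_in + O
    ln1 <- ln_forward(R1, lp$ln1_g, lp$ln1_b)
    X1 <- ln1$y
    Hpre <- X1 %*% lp$W1 + bcast(lp$b1, B * T_)
    Hact <- gelu(Hpre)
    F2 <- Hact %*% lp$W2 + bcast(lp$b2, B * T_)
    mf <- dropout_mask(dim(F2), drop_p)
    F2 <- apply_drop(F2, mf)
    R2 <- X1 + F2
    ln2 <- ln_forward(R2, lp$ln2_g, lp$ln2_b)
    X <- ln2$y
    if (want_hidden_states) hs[[l]] <- X
    if (want_cache) {
      caches[[l]] <- list(X_in = X_in, Q = Q, K = K, V = V, Ctx = Ctx,
                          A = A_list, Am = Adrop_list, mo = mo, mf = mf,
                          ln1 = ln1, X1 = X1, Hpre = Hpre, Hact = Hact,
                          ln2 = ln2)
    }
  }

  out <- list(hidden = X, attention = attn_out, hidden_states = hs,
              B = B, T = T_)
  if (want_mlm) {
    Mpre <- X %*% p$mlm_W + bcast(p$mlm_b, B * T_)
    Mact <- gelu(Mpre)
    lnm <- ln_forward(Mact, p$mlm_ln_g, p$mlm_ln_b)
    out$mlm_logits <- lnm$y %*% t(p$tok_emb) + bcast(p$mlm_out_b, B * T_)
    if (want_cache) out$mlm_cache <- list(Mpre = Mpre, lnm = lnm, Hml = lnm$y)
  }
  if (want_cache) {
    out$cache <- list(layers = caches, ln0 = ln0, m0 = m0,
                      flat_ids = flat_ids, pos_idx = pos_idx,
                      pad_mask = pad_mask, ids = ids,
                      inputs_embeds_used = !is.null(inputs_embeds))
  }
  out
}

#' @noRd
zero_like_params <- function(p) {
  rapply(p, function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  }, how = "replace")
}

# Backward pass. `fw` must come from transformer_forward(want_cache = TRUE).
# d_logits: gradient w.r.t. MLM logits (BT x V) or NULL; d_hidden: gradient
# w.r.t. final hidden states (BT x H) or NULL. Returns list(grads,
# d_inputs_embeds) where grads mirrors model$params (tied MLM output
# gradients accumulate into tok_emb).
#' @noRd
transformer_backward <- function(model, fw, d_logits = NULL, d_hidden = NULL) {
  p <- model$params
  cfg <- model$config
  B <- fw$B; T_ <- fw$T; H <- cfg$hidden_dim
  nh <- cfg$n_heads; dh <- H %/% nh
  cache <- fw$cache
  g <- zero_like_params(p)
  dX <- matrix(0, B * T_, H)
  if (!is.null(d_hidden)) dX <- dX + d_hidden

  if (!is.null(d_logits)) {
    mc <- fw$mlm_cache
    # logits = Hml %*% t(tok_emb) + out_b
    g$mlm_out_b <- g$mlm_out_b + colSums(d_logits)
    g$tok_emb <- g$tok_emb + t(d_logits) %*% mc$Hml
    dHml <- d_logits %*% p$tok_emb
    lb <- ln_backward(dHml, mc$lnm, p$mlm_ln_g)
    g$mlm_ln_g <- g$mlm_ln_g + lb$dg
    g$mlm_ln_b <- g$mlm_ln_b + lb$db
    dMpre <- lb$dx * gelu_grad(mc$Mpre)
    g$mlm_W <- g$mlm_W + t(fw$hidden) %*% dMpre
    g$mlm_b <- g$mlm_b + colSums(dMpre)
    dX <- dX + dMpre %*% t(p$mlm_W)
  }

  rows_of <- function(b) ((b - 1L) * T_ + 1L):(b * T_)
  head_cols <- function(h) ((h - 1L) * dh + 1L):(h * dh)

  for (l in rev(seq_len(cfg$n_layers))) {
    lp <- p$layers[[l]]
    cl <- cache$layers[[l]]
    lb2 <- ln_backward(dX, cl$ln2, lp$ln2_g)
    g$layers[[l]]$ln2_g <- g$layers[[l]]$ln2_g + lb2$dg
    g$layers[[l]]$ln2_b <- g$layers[[l]]$ln2_b + lb2$db
    dR2 <- lb2$dx
    dF2 <- apply_drop(dR2, cl$mf)
    g$layers[[l]]$W2 <- g$layers[[l]]$W2 + t(cl$Hact) %*% dF2
    g$layers[[l]]$b2 <- g$layers[[l]]$b2 + colSums(dF2)
    dHact <- dF2 %*% t(lp$W2)
    dHpre <- dHact * gelu_grad(cl$Hpre)
    g$layers[[l]]$W1 <- g$layers[[l]]$W1 + t(cl$X1) %*% dHpre
    g$layers[[l]]$b1 <- g$layers[[l]]$b1 + colSums(dHpre)
    dX1 <- dR2 + dHpre %*% t(lp$W1)
    lb1 <- ln_backward(dX1, cl$ln1, lp$ln1_g)
    g$layers[[l]]$ln1_g <- g$layers[[l]]$ln1_g + lb1$dg
    g$layers[[l]]$ln1_b <- g$layers[[l]]$ln1_b + lb1$db
    dR1 <- lb1$dx
    dO <- apply_drop(dR1, cl$mo)
    g$layers[[l]]$Wo <- g$layers[[l]]$Wo + t(cl$Ctx) %*% dO
    g$layers[[l]]$bo <- g$layers[[l]]$bo + colSums(dO)
    dCtx <- dO %*% t(lp$Wo)
    dQ <- matrix(0, B * T_, H); dK <- matrix(0, B * T_, H)
    dV <- matrix(0, B * T_, H)
    for (b in seq_len(B)) {
      rb <- rows_of(b)
      for (h in seq_len(nh)) {
        hc <- head_cols(h)
        A <- cl$A[[b]][[h]]
        Am <- cl$Am[[b]][[h]]
        Ad <- apply_drop(A, Am)
        dCh <- dCtx[rb, hc, drop = FALSE]
        dAd <- dCh %*% t(cl$V[rb, hc, drop = FALSE])
        dV[rb, hc] <- dV[rb, hc] + t(Ad) %*% dCh
        dA <- apply_drop(dAd, Am)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rb, hc] <- dQ[rb, hc] +
          (dS %*% cl$K[rb, hc, drop = FALSE]) / sqrt(dh)
        dK[rb, hc] <- dK[rb, hc] +
          (t(dS) %*% cl$Q[rb, hc, drop = FALSE]) / sqrt(dh)
      }
    }
    g$layers[[l]]$Wq <- g$layers[[l]]$Wq + t(cl$X_in) %*% dQ
    g$layers[[l]]$bq <- g$layers[[l]]$bq + colSums(dQ)
    g$layers[[l]]$Wk <- g$layers[[l]]$Wk + t(cl$X_in) %*% dK
    g$layers[[l]]$bk <- g$layers[[l]]$bk + colSums(dK)
    g$layers[[l]]$Wv <- g$layers[[l]]$Wv + t(cl$X_in) %*% dV
    g$layers[[l]]$bv <- g$layers[[l]]$bv + colSums(dV)
    dX <- dR1 + dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)
  }

  dX <- apply_drop(dX, cache$m0)
  if (cache$inputs_embeds_used) {
    # gradient w.r.t. the injected embedding-stage output
    return(list(grads = g, d_inputs_embeds = dX))
  }
  lb0 <- ln_backward(dX, cache$ln0, p$emb_ln_g)
  g$emb_ln_g <- g$emb_ln_g + lb0$dg
  g$emb_ln_b <- g$emb_ln_b + lb0$db
  dXe <- lb0$dx
  g$tok_emb <- g$tok_emb +
    unrowsum(dXe, cache$flat_ids, nrow(p$tok_emb))
  g$pos_emb <- g$pos_emb +
    unrowsum(dXe, cache$pos_idx, nrow(p$pos_emb))
  list(grads = g, d_inputs_embeds = dXe)
}

# scatter-add rows of x into an n_out-row matrix by 1-based group index
#' @noRd
unrowsum <- function(x, group, n_out) {
  rs <- rowsum(x, group = group, reorder = FALSE)
  out <- matrix(0, n_out, ncol(x))
  out[as.integer(rownames(rs)), ] <- rs
  out
}
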