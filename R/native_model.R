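#' Configuration for the sequence-structure attention model
#'
#' @param d Per-head query/key dimension (the `d` in the attention scaling).
#' @param heads Number of attention heads.
#' @param layers Number of cross-attention layers.
#' @param max_relative_distance Relative sequence offsets are clipped to
#'   `[-max_relative_distance, +max_relative_distance]`, each with a learned
#'   embedding (no bucketing).
#' @param structure_vocab Size of the structure-token codebook the model
#'   accepts (default 2048).
#' @param scale Attention-score scaling: `"sqrt"` divides by `sqrt(5 d)`
#'   (default), `"linear"` by `5 d`.
#' @param seed Seed for parameter initialization.
#' @return List of class `model_config`.
#' @export
model_config <- function(d = 16L, heads = 2L, layers = 2L,
                         max_relative_distance = 128L,
                         structure_vocab = 2048L,
                         scale = c("sqrt", "linear"), seed = 1L) {
  scale <- match.arg(scale)
  stopifnot(d >= 1L, heads >= 1L, layers >= 1L, max_relative_distance >= 1L,
            structure_vocab >= 1L)
  structure(list(d = as.integer(d), heads = as.integer(heads),
                 layers = as.integer(layers),
                 max_relative_distance = as.integer(max_relative_distance),
                 structure_vocab = as.integer(structure_vocab),
                 scale = scale, seed = as.integer(seed)),
            class = "model_config")
}

attn_scale_factor <- function(config) {
  if (config$scale == "sqrt") 1 / sqrt(5 * config$d) else 1 / (5 * config$d)
}

#' Initialize model parameters
#'
#' Separate embedding tables are kept for the sequence stream, the structure
#' stream, and the two relative-position streams (query-side and key-side
#' position embeddings are not shared).
#'
#' @param config A [model_config()].
#' @return Nested list of parameter matrices (class `native_params`).
#' @export
init_native_model <- function(config) {
  set.seed(config$seed)
  D <- config$d * config$heads
  m <- config$max_relative_distance
  V <- vocab_size()
  rmat <- function(nr, nc, sd = 0.1) {
    matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  }
  layers <- lapply(seq_len(config$layers), function(l) {
    heads <- lapply(seq_len(config$heads), function(h) {
      list(W_qr = rmat(D, config$d), W_kr = rmat(D, config$d),
           W_qs = rmat(D, config$d), W_ks = rmat(D, config$d),
           W_qp = rmat(D, config$d), W_kp = rmat(D, config$d),
           W_v  = rmat(D, config$d))
    })
    names(heads) <- paste0("h", seq_along(heads))
    list(heads = heads, W_o = rmat(D, D))
  })
  names(layers) <- paste0("l", seq_along(layers))
  structure(list(
    E_R = rmat(V, D), E_S = rmat(config$structure_vocab, D),
    E_Pq = rmat(2L * m + 1L, D), E_Pk = rmat(2L * m + 1L, D),
    layers = layers, W_out = rmat(D, V), b_out = rep(0, V),
    config = config), class = "native_params")
}

# clipped relative-offset index matrices; offset(i, j) = clip(i - j)
rel_index_matrices <- function(L, m) {
  i <- matrix(seq_len(L), L, L)
  o <- pmin(pmax(i - t(i), -m), m)  # o[i, j] = clip(i - j)
  list(ij = o + m + 1L,             # index of P_ij (offset i - j)
       ji = -o + m + 1L)            # index of P_ji (offset j - i)
}

# Single forward pass on an autodiff tape. `pn` are tape-wrapped parameters
# mirroring init_native_model()'s structure. Returns the logits node and,
# when record_state = TRUE, the per-layer/per-head attention pieces (values).
forward_native <- function(tape, pn, ids, sids, config, record_state = FALSE) {
  L <- length(ids)
  stopifnot(length(sids) == L)
  if (any(sids < 1L | sids > config$structure_vocab)) {
    stop("structure token id out of range [1, ", config$structure_vocab, "]")
  }
  idx <- rel_index_matrices(L, config$max_relative_distance)
  sf <- attn_scale_factor(config)
  H <- ad_rows(tape, pn$E_R, ids)
  S <- ad_rows(tape, pn$E_S, sids)
  states <- list()
  for (l in seq_len(config$layers)) {
    lp <- pn$layers[[l]]
    head_outs <- list()
    head_states <- list()
    for (h in seq_len(config$heads)) {
      hp <- lp$heads[[h]]
      QR <- ad_matmul(tape, H, hp$W_qr)
      KR <- ad_matmul(tape, H, hp$W_kr)
      QS <- ad_matmul(tape, S, hp$W_qs)
      KS <- ad_matmul(tape, S, hp$W_ks)
      Uq <- ad_matmul(tape, pn$E_Pq, hp$W_qp)  # (2m+1) x d, query-side P
      Uk <- ad_matmul(tape, pn$E_Pk, hp$W_kp)  # (2m+1) x d, key-side P
      T1 <- ad_matmul_t(tape, QR, KR)                      # R_i . R_j
      T2 <- ad_matmul_t(tape, QR, KS)                      # R_i . S_j
      T3 <- ad_gather_cols(tape, ad_matmul_t(tape, QR, Uk), idx$ji)  # R_i . P_ji
      T4 <- ad_matmul_t(tape, QS, KR)                      # S_i . R_j
      T5 <- ad_gather_rows_mat(tape, ad_matmul_t(tape, Uq, KR), idx$ij)
      # T5[i, j] = Q^P_{ij} . K^R_j: gather row idx$ij[i, j] of Uq KR^T
      Hattn <- ad_add(tape, ad_add(tape, T1, T2),
                      ad_add(tape, T3, ad_add(tape, T4, T5)))
      A <- ad_row_softmax(tape, ad_scale(tape, Hattn, sf))
      VR <- ad_matmul(tape, H, hp$W_v)
      out <- ad_matmul(tape, A, VR)
      head_outs[[h]] <- out
      if (record_state) {
        head_states[[h]] <- list(
          terms = list(T1 = T1$value, T2 = T2$value, T3 = T3$value,
                       T4 = T4$value, T5 = T5$value),
          H_attn = Hattn$value, weights = A$value, V_R = VR$value,
          Q_R = QR$value, K_R = KR$value, R_o = out$value)
      }
    }
    concat <- if (length(head_outs) > 1L) ad_cbind(tape, head_outs)
              else head_outs[[1L]]
    H_new <- ad_add(tape, H, ad_matmul(tape, concat, lp$W_o))
    if (record_state) {
      states[[l]] <- list(heads = head_states, H_in = H$value,
                          H_out = H_new$value)
    }
    H <- H_new
  }
  logits <- ad_add_bias(tape, ad_matmul(tape, H, pn$W_out), pn$b_out)
  list(logits = logits, states = states, H = H)
}

wrap_params <- function(tape, params) {
  wrap <- function(x) {
    if (is.list(x)) lapply(x, wrap) else ad_param(tape, x)
  }
  w <- wrap(params[setdiff(names(params), "config")])
  w$b_out <- ad_param(tape, matrix(params$b_out, nrow = 1L))
  w
}

#' Disentangled cross-attention scores
#'
#' Computes, per head, the five amino-acid-relevant bilinear attention terms
#' between the sequence stream (R), structure stream (S) and clipped
#' relative-position stream (P):
#' `Attn(i,j) = Q^R_i K^R_j + Q^R_i K^S_j + Q^R_i K^P_ji + Q^S_i K^R_j +
#' Q^P_ij K^R_j`. Products not involving the sequence stream (S-S, S-P, P-P)
#' are discarded by construction.
#'
#' @param R_tokens Integer sequence-token ids (1..25) or an amino-acid string.
#' @param S_tokens Integer structure-token ids in `[1, structure_vocab]`.
#' @param config A [model_config()].
#' @param params Parameters from [init_native_model()] or [train_masked_lm()].
#' @param layer Which layer's attention state to return (default 1).
#' @return List of class `attention_state`: per-head five term matrices,
#'   unnormalized scores `H_attn`, softmax `weights`, value matrices `V_R`,
#'   updated representation `R_o`, plus the layer input `H_in`.
#' @export
disentangled_attention <- function(R_tokens, S_tokens, config, params,
                                   layer = 1L) {
  if (is.character(R_tokens)) R_tokens <- tokenize_sequence(R_tokens)$ids
  stopifnot(length(R_tokens) == length(S_tokens), layer <= config$layers)
  tape <- ad_tape()
  pn <- wrap_params(tape, params)
  fw <- forward_native(tape, pn, as.integer(R_tokens), as.integer(S_tokens),
                       config, record_state = TRUE)
  st <- fw$states[[layer]]
  structure(list(heads = st$heads, H_in = st$H_in, H_out = st$H_out,
                 config = config), class = "attention_state")
}

#' Attention-weighted update of the sequence representation
#'
#' Applies the softmax normalization `softmax(H_attn / sqrt(5 d))` (over the
#' last dimension) and multiplies by the sequence value matrix, per head.
#'
#' @param state An `attention_state` from [disentangled_attention()].
#' @param config A [model_config()].
#' @return List with per-head `weights` (rows sum to 1) and `R_o` matrices.
#' @export
attention_update <- function(state, config = state$config) {
  sf <- attn_scale_factor(config)
  lapply(state$heads, function(hs) {
    x <- hs$H_attn * sf
    p <- exp(x - apply(x, 1L, max))
    p <- p / rowSums(p)
    list(weights = p, R_o = p %*% hs$V_R)
  })
}

#' Train the toy masked language model
#'
#' BERT-style masked-token recovery: at each step one (sequence, structure)
#' pair is drawn, a fraction `mask_rate` of positions is corrupted (80%
#' replaced by `<mask>`, 10% by a random amino acid, 10% left unchanged) and
#' the cross-entropy of the model's logits at the corrupted positions against
#' the original tokens is minimized with Adam. Deterministic under `seed`.
#'
#' @param corpus List of training pairs; each element is a list with `seq`
#'   (amino-acid string or token ids) and optional `struct` (structure-token
#'   ids, default all 1).
#' @param config A [model_config()].
#' @param mask_rate Fraction of positions corrupted per step, in (0, 1).
#' @param steps Number of optimization steps.
#' @param lr Adam learning rate.
#' @param seed Seed for masking and data order (default `config$seed`).
#' @param params Optional warm-start parameters.
#' @return List with trained `params`, per-step `loss_trace`, and `config`.
#' @export
train_masked_lm <- function(corpus, config, mask_rate = 0.15, steps = 300L,
                            lr = 1e-2, seed = config$seed, params = NULL) {
  if (length(corpus) == 0L) stop("empty training corpus")
  if (!(mask_rate > 0 && mask_rate < 1)) {
    stop("mask_rate must be strictly inside (0, 1)")
  }
  items <- lapply(corpus, function(it) {
    ids <- if (is.character(it$seq)) tokenize_sequence(it$seq)$ids
           else as.integer(it$seq)
    sids <- if (is.null(it$struct)) rep(1L, length(ids))
            else as.integer(it$struct)
    stopifnot(length(sids) == length(ids))
    list(ids = ids, sids = sids)
  })
  params <- params %||% init_native_model(config)
  flat <- flatten_params(params[setdiff(names(params), "config")])
  flat$b_out <- matrix(params$b_out, nrow = 1L)
  opt <- adam_state(flat)
  mask_id <- vocab_size()  # <mask> is the last vocabulary entry
  set.seed(seed)
  trace <- numeric(steps)
  for (step in seq_len(steps)) {
    it <- items[[(step - 1L) %% length(items) + 1L]]
    L <- length(it$ids)
    n_mask <- max(1L, round(mask_rate * L))
    pos <- sample.int(L, n_mask)
    corrupted <- it$ids
    u <- stats::runif(n_mask)
    corrupted[pos[u < 0.8]] <- mask_id
    rnd <- u >= 0.8 & u < 0.9
    corrupted[pos[rnd]] <- sample.int(20L, sum(rnd), replace = TRUE)
    p <- unflatten_params(flat, params)
    p$b_out <- as.vector(flat$b_out)
    tape <- ad_tape()
    pn <- wrap_params(tape, p)
    fw <- forward_native(tape, pn, corrupted, it$sids, config)
    loss <- ad_masked_ce(tape, fw$logits, pos, it$ids[pos])
    ad_backward(tape, loss)
    trace[step] <- loss$value
    gn <- flatten_params(pn)
    grads <- lapply(gn, function(nd) nd$grad)
    upd <- adam_step(flat, grads, opt, lr = lr)
    flat <- upd$params
    opt <- upd$state
  }
  out <- unflatten_params(flat, params)
  out$b_out <- as.vector(flat$b_out)
  out$config <- config
  class(out) <- "native_params"
  list(params = out, loss_trace = trace, config = config)
}

#' Native logits from the sequence-structure model
#'
#' Full-sequence unmasked forward pass; no per-position masking is applied
#' during input preparation.
#'
#' @param seq Amino-acid string (or integer token ids).
#' @param structure_tokens Integer structure-token ids, same length.
#' @param params Parameters (with `$config`) from [init_native_model()] or
#'   [train_masked_lm()].
#' @return A [logit_matrix()] with role "native", L x 25.
#' @export
native_logits <- function(seq, structure_tokens, params) {
  config <- params$config
  ids <- if (is.character(seq)) tokenize_sequence(seq)$ids else as.integer(seq)
  if (length(ids) != length(structure_tokens)) {
    stop("sequence and structure token lengths differ (",
         length(ids), " vs ", length(structure_tokens), ")")
  }
  tape <- ad_tape()
  pn <- wrap_params(tape, params)
  fw <- forward_native(tape, pn, ids, as.integer(structure_tokens), config)
  logit_matrix(fw$logits$value, role = "native")
}
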