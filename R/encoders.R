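# Forward passes of the text and video branches. Batches are processed as a
# single stacked token matrix with a block-diagonal attention mask, so
# samples never attend across the batch and batched encoding is exactly
# equivalent to encoding each sample alone.

# Pre-LN transformer encoder block. `mask` is a logical N x N matrix
# (TRUE = query row may attend key column); attention softmax support is
# restricted to it.
transformer_block <- function(tape, P, prefix, X, mask, n_heads) {
  d <- ncol(X$value)
  dh <- d %/% n_heads
  g <- function(s) P(paste0(prefix, "_", s))
  Xn <- ag_layernorm(tape, X, g("ln1_g"), g("ln1_b"))
  Q <- ag_affine(tape, Xn, g("Wq"), g("bq"))
  K <- ag_affine(tape, Xn, g("Wk"), g("bk"))
  Vv <- ag_affine(tape, Xn, g("Wv"), g("bv"))
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- ag_cols(tape, Q, cols)
    Kh <- ag_cols(tape, K, cols)
    Vh <- ag_cols(tape, Vv, cols)
    A <- ag_softmax_rows(tape, ag_mm(tape, Qh, ag_t(tape, Kh)), mask,
                         scale = 1 / sqrt(dh))
    heads[[h]] <- ag_mm(tape, A, Vh)
  }
  O <- ag_affine(tape, ag_cbind(tape, heads), g("Wo"), g("bo"))
  X <- ag_add(tape, X, O)
  Xn <- ag_layernorm(tape, X, g("ln2_g"), g("ln2_b"))
  H <- ag_relu(tape, ag_affine(tape, Xn, g("Wm1"), g("bm1")))
  M <- ag_affine(tape, H, g("Wm2"), g("bm2"))
  ag_add(tape, X, M)
}

# Block-diagonal attention mask: query row i may attend key j iff
# allowed[j] and both belong to the same sample.
block_mask <- function(sample_of, allowed) {
  outer(sample_of, sample_of, "==") & matrix(allowed, length(sample_of),
                                             length(sample_of), byrow = TRUE)
}

# Text branch: token ids (B x L, padded) -> B x d_s unit-norm embeddings.
text_forward <- function(tape, P, cfg, ids_mat, lens) {
  # trailing all-pad columns carry no information (pads are masked out of
  # attention and never pooled), so the batch is trimmed to its longest
  # real sequence
  L <- max(lens)
  ids_mat <- ids_mat[, seq_len(L), drop = FALSE]
  B <- nrow(ids_mat)
  flat <- as.integer(t(ids_mat))  # sample-major
  if (any(flat < 1L | flat > vocab_size(cfg$vocab)))
    stop("token id out of vocabulary range")
  X <- ag_rows(tape, P("tok_emb"), flat)
  X <- ag_add(tape, X, ag_rows(tape, P("txt_pos"), rep(seq_len(L), B)))
  sample_of <- rep(seq_len(B), each = L)
  pos_in <- rep(seq_len(L), B)
  allowed <- pos_in <= lens[sample_of]  # pads (beyond the end marker) masked out
  mask <- block_mask(sample_of, allowed)
  for (i in seq_len(cfg$n_layers_text))
    X <- transformer_block(tape, P, paste0("t", i), X, mask, cfg$n_heads)
  X <- ag_layernorm(tape, X, P("txt_lnf_g"), P("txt_lnf_b"))
  pooled <- ag_rows(tape, X, (seq_len(B) - 1L) * L + lens)  # end-marker rows
  ag_l2norm_rows(tape, ag_mm(tape, pooled, P("txt_proj")))
}

# Video branch: list of B patch matrices (T*P x patch^2, frame-major) ->
# B x d_s unit-norm embeddings.
video_forward <- function(tape, P_, cfg, patch_mats) {
  B <- length(patch_mats)
  Pn <- prod(cfg$input_size %/% cfg$patch_size)
  Tn <- nrow(patch_mats[[1]]) %/% Pn
  if (Tn > cfg$max_frames) stop("frame count exceeds the TPE table capacity")
  Xraw <- ag_const(tape, do.call(rbind, patch_mats))
  X <- ag_affine(tape, Xraw, P_("patch_proj"), P_("patch_b"))
  X <- ag_add(tape, X, ag_rows(tape, P_("spa_pos"), rep(rep(seq_len(Pn), Tn), B)))
  X <- ag_add(tape, X, ag_rows(tape, P_("tpe"), rep(rep(seq_len(Tn), each = Pn), B)))
  sample_of <- rep(seq_len(B), each = Tn * Pn)
  mask <- if (B > 1L) block_mask(sample_of, rep(TRUE, length(sample_of))) else NULL
  for (i in seq_len(cfg$n_layers_video))
    X <- transformer_block(tape, P_, paste0("v", i), X, mask, cfg$n_heads)
  X <- ag_layernorm(tape, X, P_("vid_lnf_g"), P_("vid_lnf_b"))
  # mean over each frame's tokens -> (B*T) x d in (sample, frame) order
  N <- B * Tn * Pn
  pool <- matrix(0, B * Tn, N)
  fr <- rep(seq_len(B * Tn), each = Pn)
  pool[cbind(fr, seq_len(N))] <- 1 / Pn
  pooled <- ag_mm(tape, ag_const(tape, pool), X)
  if (cfg$temporal == "lstm") {
    hdim <- cfg$d
    h <- ag_const(tape, matrix(0, B, hdim))
    cc <- ag_const(tape, matrix(0, B, hdim))
    for (t in seq_len(Tn)) {
      xt <- ag_rows(tape, pooled, (seq_len(B) - 1L) * Tn + t)
      gates <- ag_add(tape, ag_affine(tape, xt, P_("lstm_Wx"), P_("lstm_b")),
                            ag_mm(tape, h, P_("lstm_Wh")))
      ig <- ag_sigmoid(tape, ag_cols(tape, gates, 1:hdim))
      fg <- ag_sigmoid(tape, ag_cols(tape, gates, (hdim + 1):(2 * hdim)))
      gg <- ag_tanh(tape, ag_cols(tape, gates, (2 * hdim + 1):(3 * hdim)))
      og <- ag_sigmoid(tape, ag_cols(tape, gates, (3 * hdim + 1):(4 * hdim)))
      cc <- ag_add(tape, ag_mul(tape, fg, cc), ag_mul(tape, ig, gg))
      h <- ag_mul(tape, og, ag_tanh(tape, cc))
    }
    top <- h
  } else {
    # order-invariant ablation: mean over frames
    fpool <- matrix(0, B, B * Tn)
    fpool[cbind(rep(seq_len(B), each = Tn), seq_len(B * Tn))] <- 1 / Tn
    top <- ag_mm(tape, ag_const(tape, fpool), pooled)
  }
  ag_l2norm_rows(tape, ag_mm(tape, top, P_("vid_proj")))
}

# Residual adapter applied to a stack of embeddings (rows), then
# re-normalised to the unit sphere.
adapter_forward <- function(tape, P, branch, X) {
  pre <- paste0("ad_", substr(branch, 1, 1))
  Fnew <- ag_affine(tape,
                    ag_relu(tape, ag_affine(tape, X, P(paste0(pre, "_W1")),
                                            P(paste0(pre, "_b1")))),
                    P(paste0(pre, "_W2")), P(paste0(pre, "_b2")))
  alpha <- ag_sigmoid(tape, P(paste0(pre, "_alpha_logit")))
  one_minus <- ag_add(tape, ag_neg(tape, alpha), ag_const(tape, matrix(1, 1, 1)))
  ag_l2norm_rows(tape, ag_add(tape, ag_mul(tape, Fnew, alpha),
                              ag_mul(tape, X, one_minus)))
}

## ---- user-facing encoding helpers -----------------------------------------

#' Encode prompt strings into shared-space embeddings
#'
#' Tokenizes and runs the text branch (plus the text adapter when attached).
#' Each row of the result is a unit-norm `d_s`-vector; batching is exactly
#' equivalent to encoding each string alone.
#'
#' @param model A `ceus_model`.
#' @param texts Character vector of prompts.
#' @return Numeric matrix, `length(texts)` x `d_s`.
#' @export
encode_text <- function(model, texts) {
  cfg <- model$config
  toks <- lapply(texts, tokenize, vocab = cfg$vocab,
                 context_length = cfg$context_length)
  ids <- do.call(rbind, lapply(toks, `[[`, "ids"))
  lens <- vapply(toks, `[[`, integer(1), "len")
  tape <- ag_tape()
  P <- ag_param_cache(tape, model$params)
  E <- text_forward(tape, P, cfg, ids, lens)
  if (cfg$afto_where %in% c("text", "both")) E <- adapter_forward(tape, P, "text", E)
  E$value
}

#' Encode videos (lists of frames) into shared-space embeddings
#'
#' Each video is a list of frames (matrices in `[0, 1]`, already cropped and
#' resized to the model input size). Runs patch tokenization with spatial and
#' temporal position embeddings, the spatial transformer, the temporal head,
#' the shared-space projection (plus the video adapter when attached).
#'
#' @param model A `ceus_model`.
#' @param videos List of videos; each a list of `T` frame matrices.
#' @return Numeric matrix, `length(videos)` x `d_s`.
#' @export
encode_video <- function(model, videos) {
  cfg <- model$config
  mats <- lapply(videos, function(fr) patchify_frames(fr, cfg$patch_size))
  tape <- ag_tape()
  P <- ag_param_cache(tape, model$params)
  E <- video_forward(tape, P, cfg, mats)
  if (cfg$afto_where %in% c("video", "both")) E <- adapter_forward(tape, P, "video", E)
  E$value
}

#' Convert frames into a frame-major patch-pixel matrix
#'
#' Frames are split into non-overlapping square patches (row-major within
#' each frame); each patch is flattened (column-major) into a row. Rows are
#' ordered frame-major: all patches of frame 1, then frame 2, and so on.
#'
#' @param frames List of `T` matrices, all `H x W` with `H`, `W` divisible by
#'   `patch_size`.
#' @param patch_size Patch edge length.
#' @return Matrix of size `(T * P) x patch_size^2` with `P = (H/patch) *
#'   (W/patch)` patches per frame.
#' @export
patchify_frames <- function(frames, patch_size) {
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  if (H %% patch_size != 0 || W %% patch_size != 0)
    stop("frame dimensions must be divisible by `patch_size`")
  py <- H %/% patch_size; px <- W %/% patch_size
  out <- matrix(0, length(frames) * py * px, patch_size^2)
  r <- 0L
  for (f in frames) {
    for (i in seq_len(py)) {
      for (j in seq_len(px)) {
        r <- r + 1L
        out[r, ] <- as.vector(f[((i - 1L) * patch_size + 1L):(i * patch_size),
                                ((j - 1L) * patch_size + 1L):(j * patch_size)])
      }
    }
  }
  out
}

#' Patch token embeddings of one video (before the transformer)
#'
#' Returns the token matrix actually fed to the spatial transformer: linear
#' patch projection plus spatial position embedding plus the frame's
#' temporal position embedding (TPE), frame-major. Useful for inspecting the
#' tokenization contract: `T` frames with `P` patches each yield `T * P`
#' rows, and all tokens of frame `i` share the same TPE vector.
#'
#' @param model A `ceus_model`.
#' @param frames List of `T` frame matrices in `[0, 1]`.
#' @param with_tpe Set `FALSE` to omit the temporal position embedding.
#' @return `(T * P) x d` matrix with attribute `frame_index` (1-based, per
#'   row).
#' @export
video_token_embeddings <- function(model, frames, with_tpe = TRUE) {
  cfg <- model$config
  Pn <- prod(cfg$input_size %/% cfg$patch_size)
  Tn <- length(frames)
  if (Tn > cfg$max_frames) stop("frame count exceeds the TPE table capacity")
  Xr <- patchify_frames(frames, cfg$patch_size)
  X <- sweep(Xr %*% model$params$patch_proj, 2L, as.numeric(model$params$patch_b), "+")
  X <- X + model$params$spa_pos[rep(seq_len(Pn), Tn), , drop = FALSE]
  if (with_tpe)
    X <- X + model$params$tpe[rep(seq_len(Tn), each = Pn), , drop = FALSE]
  attr(X, "frame_index") <- rep(seq_len(Tn), each = Pn)
  X
}
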