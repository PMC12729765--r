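# Contrastive core: scaled cosine similarities between the two branches,
# label-derived soft target distributions, the bidirectional KL objective,
# and prompt-ensemble classification.

#' Scaled similarity matrix with directional softmax distributions
#'
#' `S[i, j] = tau * <V_i, T_j>` for unit-norm rows; `p_x2y` is the row-wise
#' softmax (video-to-text) and `p_y2x` the row-wise softmax of `t(S)`
#' (text-to-video).
#'
#' @param V `B x d_s` video embeddings, rows unit-norm.
#' @param Tm `B x d_s` text embeddings, rows unit-norm.
#' @param tau Positive similarity scale.
#' @return A `batch_similarity` list with `S`, `p_x2y`, `p_y2x`, `tau`.
#' @export
similarity_matrix <- function(V, Tm, tau) {
  if (tau <= 0) stop("`tau` must be positive")
  if (max(abs(sqrt(rowSums(V^2)) - 1)) > 1e-3 ||
      max(abs(sqrt(rowSums(Tm^2)) - 1)) > 1e-3)
    stop("embedding rows must be L2-normalized")
  S <- tau * tcrossprod(V, Tm)
  softmax_rows <- function(M) {
    E <- exp(M - apply(M, 1L, max))
    E / rowSums(E)
  }
  structure(list(S = S, p_x2y = softmax_rows(S), p_y2x = softmax_rows(t(S)),
                 tau = tau), class = "batch_similarity")
}

#' Label-derived soft target distributions
#'
#' Row `i` of `q_x2y` is uniform over the columns `j` whose label matches
#' label `i` (and likewise `q_y2x`); with all labels distinct this reduces
#' to the identity. With small batches and two classes, duplicate labels per
#' batch are the rule, which is why the targets are soft rather than
#' strictly diagonal.
#'
#' @param labels Vector of `B >= 2` class ids.
#' @return A `target_distribution` list with `q_x2y`, `q_y2x`.
#' @export
target_distribution <- function(labels) {
  B <- length(labels)
  if (B < 2) stop("need at least two samples")
  M <- outer(labels, labels, "==") * 1
  q <- M / rowSums(M)
  structure(list(q_x2y = q, q_y2x = q), class = "target_distribution")
}

#' Bidirectional KL contrastive loss
#'
#' One half of the mean row-wise `KL(q || p)` over both directions:
#' `L = 1/2 [ mean_i KL(q_x2y[i,] || p_x2y[i,]) + mean_j KL(q_y2x[j,] ||
#' p_y2x[j,]) ]`. The `KL(q || p)` orientation keeps the loss finite for
#' one-hot targets (it reduces to cross-entropy up to the entropy of `q`);
#' an epsilon floor of 1e-8 guards the logarithm. The loss is zero exactly
#' when both predicted distributions equal their targets.
#'
#' @param batch A [similarity_matrix()] result.
#' @param targets A [target_distribution()] result.
#' @return Non-negative scalar loss.
#' @export
kl_contrastive_loss <- function(batch, targets) {
  stopifnot(inherits(batch, "batch_similarity"),
            inherits(targets, "target_distribution"))
  kl_rows <- function(q, p) {
    p <- pmax(p, 1e-8)
    terms <- ifelse(q > 0, q * (log(q) - log(p)), 0)
    mean(rowSums(terms))
  }
  0.5 * (kl_rows(targets$q_x2y, batch$p_x2y) +
         kl_rows(targets$q_y2x, batch$p_y2x))
}

# Tape version of the objective used in training: builds the similarity
# logits from embedding nodes and a log-temperature node, and returns the
# scalar loss node. Gradients flow to both branches and to the temperature.
contrastive_loss_node <- function(tape, Vn, Tn, log_tau_node, labels) {
  B <- nrow(Vn$value)
  tau <- ag_exp(tape, log_tau_node)
  S <- ag_mul(tape, ag_mm(tape, Vn, ag_t(tape, Tn)), tau)
  q <- target_distribution(labels)$q_x2y
  qlogq <- sum(ifelse(q > 0, q * log(q), 0)) / B
  lp_x2y <- ag_logsoftmax_rows(tape, S)
  lp_y2x <- ag_logsoftmax_rows(tape, ag_t(tape, S))
  ce_x <- ag_scale(tape, ag_sum(tape, ag_mul(tape, lp_x2y, ag_const(tape, q))), -1 / B)
  ce_y <- ag_scale(tape, ag_sum(tape, ag_mul(tape, lp_y2x, ag_const(tape, q))), -1 / B)
  # 0.5 * (KL + KL) = 0.5 * (CE_x + H(q) + CE_y + H(q))
  ag_add(tape, ag_scale(tape, ag_add(tape, ce_x, ce_y), 0.5),
         ag_const(tape, matrix(qlogq, 1, 1)))
}

#' Prompt-ensemble classification of a video embedding
#'
#' Scores each class by aggregating the cosine similarity between the video
#' embedding and the class's rendered prompt embeddings (`mean` by default,
#' `max` optionally), and converts scores to probabilities with a softmax at
#' scale `tau`. The predicted class is the argmax; exact ties resolve to the
#' lowest class id.
#'
#' @param video_emb Unit-norm numeric vector of length `d_s`.
#' @param class_prompt_embs List (one element per class, in class-id order)
#'   of matrices whose rows are unit-norm prompt embeddings.
#' @param tau Positive softmax scale.
#' @param ensemble `"mean"` or `"max"` similarity aggregation.
#' @return List with `probs` (numeric vector over classes) and `class`
#'   (0-based predicted class id).
#' @export
classify <- function(video_emb, class_prompt_embs, tau = 1,
                     ensemble = c("mean", "max")) {
  ensemble <- match.arg(ensemble)
  if (length(class_prompt_embs) < 2) stop("need at least two classes")
  if (any(vapply(class_prompt_embs, nrow, integer(1)) < 1))
    stop("each class needs at least one prompt embedding")
  sims <- vapply(class_prompt_embs, function(E) {
    s <- as.numeric(E %*% video_emb)
    if (ensemble == "mean") mean(s) else max(s)
  }, numeric(1))
  z <- tau * sims
  p <- exp(z - max(z)) / sum(exp(z - max(z)))
  list(probs = p, class = which.max(p) - 1L)
}
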