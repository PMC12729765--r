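# Adaptive fine-tuning: a lightweight residual adapter per branch. The
# adapter passes the raw shared-space feature through a bottleneck MLP
# (down-projection, ReLU, up-projection) and blends the result with the raw
# feature, F_mix = alpha * F_new + (1 - alpha) * F_raw, where the mixing
# coefficient alpha is the logistic transform of an unconstrained scalar
# learned by backpropagation alongside the other parameters.

#' Create an adapter state
#'
#' @param d_s Shared-space dimension the adapter operates in.
#' @param bottleneck Bottleneck width; must be smaller than `d_s`.
#' @param alpha_init Initial mixing coefficient in (0, 1); stored as a
#'   logit so the learned coefficient always stays in the open interval.
#' @param branch Branch tag, `"video"` or `"text"`.
#' @param seed Seed for the weight initialisation. The up-projection starts
#'   at small variance so the adapter begins near the identity.
#' @return An `adapter_state` with fields `W1` (`d_s x b`), `b1`, `W2`
#'   (`b x d_s`), `b2`, `alpha_logit`, `branch`.
#' @export
adapter_state <- function(d_s, bottleneck = max(1L, d_s %/% 4L),
                          alpha_init = 0.5, branch = c("video", "text"),
                          seed = NULL) {
  branch <- match.arg(branch)
  if (bottleneck >= d_s) stop("`bottleneck` must be smaller than `d_s`")
  if (alpha_init <= 0 || alpha_init >= 1) stop("`alpha_init` must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  structure(list(
    W1 = init_weight(d_s, bottleneck, 1 / sqrt(d_s)),
    b1 = matrix(0, 1, bottleneck),
    W2 = init_weight(bottleneck, d_s, 0.01),
    b2 = matrix(0, 1, d_s),
    alpha_logit = matrix(stats::qlogis(alpha_init), 1, 1),
    branch = branch
  ), class = "adapter_state")
}

#' Apply a residual adapter to a shared-space embedding
#'
#' Computes `F_new = W2 relu(W1 F_raw + b1) + b2` and blends
#' `alpha * F_new + (1 - alpha) * F_raw` with
#' `alpha = plogis(alpha_logit)`, optionally re-normalising the result to
#' the unit sphere (the training-time behaviour, so downstream cosine
#' similarities stay on scale).
#'
#' @param F_raw Numeric vector of length `d_s`, or a matrix with `d_s`
#'   columns (one embedding per row).
#' @param state An [adapter_state()].
#' @param renormalize L2-normalise rows after mixing (default `TRUE`).
#' @return Adapted embedding, same shape as `F_raw`.
#' @export
adapt <- function(F_raw, state, renormalize = TRUE) {
  stopifnot(inherits(state, "adapter_state"))
  vec <- !is.matrix(F_raw)
  X <- if (vec) matrix(F_raw, 1) else F_raw
  if (ncol(X) != nrow(state$W1)) stop("embedding dimension mismatch")
  H <- pmax(sweep(X %*% state$W1, 2L, as.numeric(state$b1), "+"), 0)
  Fnew <- sweep(H %*% state$W2, 2L, as.numeric(state$b2), "+")
  alpha <- stats::plogis(state$alpha_logit[1, 1])
  M <- alpha * Fnew + (1 - alpha) * X
  if (renormalize) M <- M / sqrt(rowSums(M^2) + 1e-12)
  if (vec) as.numeric(M) else M
}

#' Attach residual adapters to a model
#'
#' Inserts adapters after the designated branch projections. Adapter
#' parameters enter the model's parameter list (names prefixed `ad_v_` /
#' `ad_t_`) and hence the trainable set; `where = "none"` returns the model
#' unchanged. With `freeze_backbone = TRUE` in the model config only the
#' adapters and the temperature remain trainable.
#'
#' @param model A `ceus_model`.
#' @param where `"video"`, `"text"`, `"both"`, or `"none"`.
#' @return The model with adapters attached and `config$afto_where` updated.
#' @export
attach_adapters <- function(model, where = c("none", "video", "text", "both")) {
  where <- match.arg(where)
  if (where == "none") {
    model$config$afto_where <- "none"
    return(model)
  }
  cfg <- model$config
  add_branch <- function(params, tag) {
    st <- adapter_state(cfg$d_s, cfg$afto_bottleneck, cfg$afto_alpha_init,
                        branch = if (tag == "v") "video" else "text")
    params[[paste0("ad_", tag, "_W1")]] <- st$W1
    params[[paste0("ad_", tag, "_b1")]] <- st$b1
    params[[paste0("ad_", tag, "_W2")]] <- st$W2
    params[[paste0("ad_", tag, "_b2")]] <- st$b2
    params[[paste0("ad_", tag, "_alpha_logit")]] <- st$alpha_logit
    params
  }
  if (where %in% c("video", "both")) model$params <- add_branch(model$params, "v")
  if (where %in% c("text", "both")) model$params <- add_branch(model$params, "t")
  model$config$afto_where <- where
  model
}

#' Current mixing coefficients of an adapted model
#'
#' @param model A `ceus_model` with adapters attached.
#' @return Named numeric vector of `alpha = plogis(alpha_logit)` per branch.
#' @export
adapter_alphas <- function(model) {
  out <- c()
  if (!is.null(model$params$ad_v_alpha_logit))
    out <- c(out, video = stats::plogis(model$params$ad_v_alpha_logit[1, 1]))
  if (!is.null(model$params$ad_t_alpha_logit))
    out <- c(out, text = stats::plogis(model$params$ad_t_alpha_logit[1, 1]))
  out
}
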