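# Model configuration and parameter initialisation for the dual-branch
# text-video contrastive model. Both branches project into a shared
# d_s-dimensional embedding space on the unit sphere.

#' Model configuration
#'
#' The default is a desk-scale configuration (32-dimensional embeddings, two
#' transformer layers per branch, 32 x 32 inputs) that trains in minutes on a
#' CPU; the full-scale configuration matching the published architecture uses
#' six layers per branch (`n_layers_text = 6`, `n_layers_video = 6`) and
#' 224 x 224 inputs.
#'
#' @param d Transformer width of both encoders.
#' @param d_s Shared embedding space dimension.
#' @param n_heads Attention heads; must divide `d`.
#' @param n_layers_text,n_layers_video Transformer depth per branch.
#' @param context_length Maximum token sequence length (with markers).
#' @param input_size Model input frame size `c(height, width)`; must be
#'   divisible by `patch_size`.
#' @param patch_size Square patch edge in pixels.
#' @param max_frames Capacity of the temporal position embedding table.
#' @param mlp_ratio Feed-forward hidden width as a multiple of `d`.
#' @param temporal `"lstm"` for the recurrent temporal head, `"meanpool"`
#'   for the order-invariant ablation.
#' @param tau_init Initial similarity scale (temperature inverse); learned in
#'   log space.
#' @param afto_where Which branches carry residual adapters:
#'   `"none"`, `"video"`, `"text"`, or `"both"`.
#' @param afto_bottleneck Adapter bottleneck width (default `d_s / 4`).
#' @param afto_alpha_init Initial mixing coefficient in (0, 1).
#' @param freeze_backbone When adapters are attached, freeze everything but
#'   the adapters (and temperature). Only meaningful with imported
#'   pretrained weights; when training from random initialisation leave
#'   `FALSE`.
#' @param use_clinical_text Append clinical attribute phrases to training
#'   texts.
#' @param ensemble `"mean"` or `"max"` aggregation of the prompt ensemble at
#'   inference.
#' @param pool A [prompt_pool()]; default [default_prompt_pool()].
#' @param vocab A `ceus_vocab`; by default built from the pool's templates,
#'   class labels and the clinical attribute vocabulary.
#' @return A `ceus_model_config` object.
#' @export
ceus_model_config <- function(d = 32, d_s = 32, n_heads = 2,
                              n_layers_text = 2, n_layers_video = 2,
                              context_length = 32,
                              input_size = c(32, 32), patch_size = 16,
                              max_frames = 40, mlp_ratio = 4,
                              temporal = c("lstm", "meanpool"),
                              tau_init = 14,
                              afto_where = c("none", "video", "text", "both"),
                              afto_bottleneck = max(1L, d_s %/% 4L),
                              afto_alpha_init = 0.5,
                              freeze_backbone = FALSE,
                              use_clinical_text = TRUE,
                              ensemble = c("mean", "max"),
                              pool = default_prompt_pool(),
                              vocab = NULL) {
  temporal <- match.arg(temporal)
  afto_where <- match.arg(afto_where)
  ensemble <- match.arg(ensemble)
  if (d %% n_heads != 0) stop("`d` must be divisible by `n_heads`")
  if (any(input_size %% patch_size != 0))
    stop("`input_size` must be divisible by `patch_size`")
  if (n_layers_text < 1 || n_layers_video < 1) stop("at least one layer per branch")
  if (afto_alpha_init <= 0 || afto_alpha_init >= 1)
    stop("`afto_alpha_init` must lie in (0, 1)")
  if (afto_bottleneck >= d_s) stop("adapter bottleneck must be smaller than `d_s`")
  if (is.null(vocab)) {
    attr_texts <- unlist(lapply(clinical_attribute_tables(), `[[`, "values"))
    tpl_texts <- vapply(pool$templates, `[[`, character(1), "text")
    vocab <- build_vocab(c(tpl_texts, pool$class_labels, attr_texts))
  }
  structure(list(
    d = as.integer(d), d_s = as.integer(d_s), n_heads = as.integer(n_heads),
    n_layers_text = as.integer(n_layers_text),
    n_layers_video = as.integer(n_layers_video),
    context_length = as.integer(context_length),
    input_size = as.integer(input_size), patch_size = as.integer(patch_size),
    max_frames = as.integer(max_frames), mlp_ratio = mlp_ratio,
    temporal = temporal, tau_init = tau_init,
    afto_where = afto_where, afto_bottleneck = as.integer(afto_bottleneck),
    afto_alpha_init = afto_alpha_init, freeze_backbone = freeze_backbone,
    use_clinical_text = use_clinical_text, ensemble = ensemble,
    pool = pool, vocab = vocab
  ), class = "ceus_model_config")
}

init_weight <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

init_transformer_layer <- function(params, prefix, d, mlp_ratio) {
  sd <- 1 / sqrt(d)
  dm <- as.integer(mlp_ratio * d)
  params[[paste0(prefix, "_ln1_g")]] <- matrix(1, 1, d)
  params[[paste0(prefix, "_ln1_b")]] <- matrix(0, 1, d)
  for (w in c("Wq", "Wk", "Wv", "Wo"))
    params[[paste0(prefix, "_", w)]] <- init_weight(d, d, sd)
  for (b in c("bq", "bk", "bv", "bo"))
    params[[paste0(prefix, "_", b)]] <- matrix(0, 1, d)
  params[[paste0(prefix, "_ln2_g")]] <- matrix(1, 1, d)
  params[[paste0(prefix, "_ln2_b")]] <- matrix(0, 1, d)
  params[[paste0(prefix, "_Wm1")]] <- init_weight(d, dm, sd)
  params[[paste0(prefix, "_bm1")]] <- matrix(0, 1, dm)
  params[[paste0(prefix, "_Wm2")]] <- init_weight(dm, d, 1 / sqrt(dm))
  params[[paste0(prefix, "_bm2")]] <- matrix(0, 1, d)
  params
}

#' Build a dual-branch contrastive model
#'
#' Initialises all parameters from the given seed: token and positional
#' embeddings, the per-branch transformer stacks, the video patch projection
#' with spatial and temporal position embeddings, the LSTM temporal head,
#' the shared-space projections, the learnable log-temperature, and (when
#' `afto_where != "none"`) the residual adapters.
#'
#' @param config A [ceus_model_config()].
#' @param seed Integer seed for the initialisation.
#' @return A `ceus_model` list with `config` and named `params`.
#' @export
build_ceus_model <- function(config, seed = 0L) {
  stopifnot(inherits(config, "ceus_model_config"))
  set.seed(seed)
  d <- config$d; d_s <- config$d_s
  V <- vocab_size(config$vocab)
  L <- config$context_length
  P <- prod(config$input_size %/% config$patch_size)
  p2 <- config$patch_size^2
  params <- list()
  params$tok_emb <- init_weight(V, d, 0.02)
  params$txt_pos <- init_weight(L, d, 0.01)
  for (i in seq_len(config$n_layers_text))
    params <- init_transformer_layer(params, paste0("t", i), d, config$mlp_ratio)
  params$txt_lnf_g <- matrix(1, 1, d)
  params$txt_lnf_b <- matrix(0, 1, d)
  params$txt_proj <- init_weight(d, d_s, 1 / sqrt(d))
  params$patch_proj <- init_weight(p2, d, 1 / sqrt(p2))
  params$patch_b <- matrix(0, 1, d)
  params$spa_pos <- init_weight(P, d, 0.01)
  params$tpe <- init_weight(config$max_frames, d, 0.01)
  for (i in seq_len(config$n_layers_video))
    params <- init_transformer_layer(params, paste0("v", i), d, config$mlp_ratio)
  params$vid_lnf_g <- matrix(1, 1, d)
  params$vid_lnf_b <- matrix(0, 1, d)
  h <- d  # recurrent hidden size pinned to the transformer width
  params$lstm_Wx <- init_weight(d, 4 * h, 1 / sqrt(d))
  params$lstm_Wh <- init_weight(h, 4 * h, 1 / sqrt(h))
  b <- matrix(0, 1, 4 * h)
  b[1, (h + 1):(2 * h)] <- 1  # forget-gate bias
  params$lstm_b <- b
  params$vid_proj <- init_weight(h, d_s, 1 / sqrt(h))
  params$log_tau <- matrix(log(config$tau_init), 1, 1)
  model <- structure(list(config = config, params = params), class = "ceus_model")
  if (config$afto_where != "none") {
    model <- attach_adapters(model, config$afto_where)
  }
  model
}

#' Number of parameters of a model
#' @param model A `ceus_model`.
#' @return Integer count of scalar parameters.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# Names of parameters updated by the optimizer under the freezing policy.
trainable_param_names <- function(model) {
  nm <- names(model$params)
  cfg <- model$config
  if (cfg$freeze_backbone && cfg$afto_where != "none") {
    nm[grepl("^ad_", nm) | nm == "log_tau"]
  } else {
    nm
  }
}
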