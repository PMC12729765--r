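# Training: AdamW with decoupled weight decay and cosine learning-rate
# decay, minibatch contrastive updates with per-instance random prompts,
# clip-level augmentation, and validation-loss early stopping after a
# minimum number of epochs.

#' Training configuration
#'
#' Defaults follow the published protocol: AdamW, batch size 4, a minimum of
#' 50 epochs with early stopping, 10 input frames from the +/-5 keyframe
#' window. The learning rate decays on a cosine schedule; weight decay is
#' not applied to biases, layer-norm gains, the mixing logits, or the
#' temperature.
#'
#' @param batch_size Minibatch size (>= 2; the contrastive loss needs pairs).
#' @param min_epochs Minimum epochs before early stopping may trigger.
#' @param max_epochs Hard epoch cap.
#' @param patience Epochs without validation-loss improvement (after
#'   `min_epochs`) before stopping.
#' @param lr Peak learning rate.
#' @param weight_decay Decoupled weight decay for weight matrices.
#' @param augment Apply clip-level augmentation (horizontal flip, intensity
#'   jitter) to training videos.
#' @param random_prompt Sample one template per instance per step; `FALSE`
#'   fixes the first template (the fixed-prompt baseline).
#' @param n_frames Frames sampled per video.
#' @param half_window Keyframe window half width.
#' @param seed Seed for shuffling, prompt sampling and augmentation.
#' @return A `ceus_train_config`.
#' @export
ceus_train_config <- function(batch_size = 4, min_epochs = 50, max_epochs = 100,
                              patience = 10, lr = 1e-4, weight_decay = 1e-2,
                              augment = TRUE, random_prompt = TRUE,
                              n_frames = 10, half_window = 5, seed = 0L) {
  if (batch_size < 2) stop("`batch_size` must be at least 2")
  if (min_epochs < 1) stop("`min_epochs` must be at least 1")
  structure(list(batch_size = as.integer(batch_size),
                 min_epochs = as.integer(min_epochs),
                 max_epochs = as.integer(max_epochs),
                 patience = patience, lr = lr, weight_decay = weight_decay,
                 augment = augment, random_prompt = random_prompt,
                 n_frames = as.integer(n_frames),
                 half_window = as.integer(half_window),
                 seed = as.integer(seed)),
            class = "ceus_train_config")
}

#' Prepare CEUS samples for training
#'
#' Runs [preprocess_sample()] on each sample and precomputes the frame-major
#' patch-pixel matrix (and its horizontally flipped counterpart, used by
#' augmentation) so the per-step cost is just the network forward/backward.
#'
#' @param samples List of `ceus_sample` objects.
#' @param config A `ceus_model_config` (for input size and patch size).
#' @param n_frames,half_window,threshold Preprocessing parameters.
#' @return List of prepared samples with fields `patches`, `patches_flip`,
#'   `class_label`, `patient_id`, `clinical_attributes`.
#' @export
prepare_samples <- function(samples, config, n_frames = 10, half_window = 5,
                            threshold = 50) {
  lapply(samples, function(s) {
    pp <- preprocess_sample(s, out_size = config$input_size,
                            threshold = threshold,
                            half_window = half_window, n_out = n_frames)
    flip <- lapply(pp$frames, function(f) f[, rev(seq_len(ncol(f))), drop = FALSE])
    list(patches = patchify_frames(pp$frames, config$patch_size),
         patches_flip = patchify_frames(flip, config$patch_size),
         class_label = s$class_label,
         patient_id = s$patient_id,
         clinical_attributes = s$clinical_attributes)
  })
}

# Training text for one instance: a rendered prompt, optionally suffixed
# with the imaging-related clinical attribute phrases.
instance_text <- function(prep, cfg, random_prompt = TRUE) {
  pool <- cfg$pool
  tpl <- if (random_prompt) sample_prompt(pool) else pool$templates[[1L]]
  txt <- render_prompt(tpl, pool$class_labels[prep$class_label + 1L])
  if (cfg$use_clinical_text && length(prep$clinical_attributes)) {
    ca <- prep$clinical_attributes
    keep <- intersect(c("Contrast-enhanced ultrasound parameters",
                        "Conventional ultrasound parameters"), names(ca))
    if (length(keep)) txt <- paste0(txt, ", ", paste(ca[keep], collapse = ", "))
  }
  txt
}

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# Decoupled weight decay is applied only to 2-D weight matrices (not to
# biases/gains, which are 1-row, nor to the scalar logits).
adamw_step <- function(params, grads, state, lr, weight_decay,
                       trainable, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    if (!(nm %in% trainable)) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && nrow(params[[nm]]) > 1L)
      upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

# One forward pass to the loss node over a batch of prepared samples.
batch_loss_node <- function(tape, P, model, batch, texts) {
  cfg <- model$config
  toks <- lapply(texts, tokenize, vocab = cfg$vocab,
                 context_length = cfg$context_length)
  ids <- do.call(rbind, lapply(toks, `[[`, "ids"))
  lens <- vapply(toks, `[[`, integer(1), "len")
  Tn <- text_forward(tape, P, cfg, ids, lens)
  Vn <- video_forward(tape, P, cfg, lapply(batch, `[[`, "patches"))
  if (cfg$afto_where %in% c("text", "both")) Tn <- adapter_forward(tape, P, "text", Tn)
  if (cfg$afto_where %in% c("video", "both")) Vn <- adapter_forward(tape, P, "video", Vn)
  labels <- vapply(batch, `[[`, integer(1), "class_label")
  contrastive_loss_node(tape, Vn, Tn, P("log_tau"), labels)
}

# Mean contrastive loss over a prepared set, no parameter updates, fixed
# first template (deterministic).
dataset_loss <- function(model, prep, batch_size = 8L) {
  cfg <- model$config
  n <- length(prep)
  if (n == 1L) prep <- c(prep, prep)  # pairwise loss needs B >= 2; monitor on a duplicate
  n <- length(prep)
  starts <- seq(1L, n, by = batch_size)
  groups <- lapply(seq_along(starts), function(k)
    starts[k]:(if (k < length(starts)) starts[k + 1L] - 1L else n))
  if (length(groups) > 1L && length(groups[[length(groups)]]) == 1L) {
    # merge a trailing singleton into its neighbour: the loss needs pairs
    k <- length(groups)
    groups[[k - 1L]] <- c(groups[[k - 1L]], groups[[k]])
    groups[[k]] <- NULL
  }
  tot <- 0; cnt <- 0
  for (gi in groups) {
    batch <- prep[gi]
    texts <- vapply(batch, instance_text, character(1), cfg = cfg,
                    random_prompt = FALSE)
    tape <- ag_tape()
    P <- ag_param_cache(tape, model$params)
    loss <- batch_loss_node(tape, P, model, batch, texts)
    tot <- tot + as.numeric(loss$value) * length(batch)
    cnt <- cnt + length(batch)
  }
  tot / cnt
}

augment_batch <- function(batch) {
  lapply(batch, function(s) {
    if (stats::runif(1) < 0.5) s$patches <- s$patches_flip
    s$patches <- s$patches * stats::runif(1, 0.9, 1.1) + stats::runif(1, -0.05, 0.05)
    s
  })
}

#' Train a model on one fold
#'
#' Minibatch AdamW updates of the bidirectional KL contrastive objective.
#' Runs at least `min_epochs` epochs and stops when the validation loss has
#' not improved for `patience` consecutive epochs; the parameters from the
#' best validation epoch are restored. Fully reproducible given the seeds.
#'
#' @param model A `ceus_model` (freshly built).
#' @param train_prep,val_prep Prepared sample lists from
#'   [prepare_samples()]; patient sets must be disjoint.
#' @param tc A [ceus_train_config()].
#' @param verbose Print per-epoch losses.
#' @return List with the trained `model` and a `history` data frame
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
train_fold <- function(model, train_prep, val_prep, tc = ceus_train_config(),
                       verbose = FALSE) {
  if (length(train_prep) < 2L) stop("training split needs at least 2 samples")
  if (length(val_prep) < 1L) stop("validation split is empty")
  if (length(intersect(vapply(train_prep, `[[`, character(1), "patient_id"),
                       vapply(val_prep, `[[`, character(1), "patient_id"))))
    stop("train and validation patient sets overlap")
  cfg <- model$config
  trainable <- trainable_param_names(model)
  opt <- adamw_init(model$params)
  set.seed(tc$seed)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  n <- length(train_prep)
  for (epoch in seq_len(tc$max_epochs)) {
    lr_t <- tc$lr * 0.5 * (1 + cos(pi * (epoch - 1) / tc$max_epochs))
    ord <- sample.int(n)
    ep_loss <- 0; ep_n <- 0
    i <- 1L
    while (i <= n) {
      j <- min(n, i + tc$batch_size - 1L)
      idx <- ord[i:j]
      i <- j + 1L
      if (length(idx) < 2L) next  # contrastive loss needs pairs
      batch <- train_prep[idx]
      if (tc$augment) batch <- augment_batch(batch)
      texts <- vapply(batch, instance_text, character(1), cfg = cfg,
                      random_prompt = tc$random_prompt)
      tape <- ag_tape()
      P <- ag_param_cache(tape, model$params)
      loss <- batch_loss_node(tape, P, model, batch, texts)
      ag_backward(tape, loss)
      grads <- ag_collect_grads(P)
      res <- adamw_step(model$params, grads, opt, lr_t, tc$weight_decay, trainable)
      model$params <- res$params
      opt <- res$state
      ep_loss <- ep_loss + as.numeric(loss$value) * length(idx)
      ep_n <- ep_n + length(idx)
    }
    vl <- dataset_loss(model, val_prep)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / ep_n,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      ep_loss / ep_n, vl))
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, params = model$params, epoch = epoch)
    }
    if (epoch >= tc$min_epochs && epoch - best$epoch >= tc$patience) break
  }
  model$params <- best$params
  list(model = model, history = hist)
}

#' Classify prepared samples with a trained model
#'
#' Encodes the full prompt ensemble for every class once, then scores each
#' video by [classify()] with the model's learned temperature.
#'
#' @param model A trained `ceus_model`.
#' @param prep Prepared samples from [prepare_samples()].
#' @return Data frame with `patient_id`, `label`, `score` (probability of
#'   class 1, metastatic) and `pred`.
#' @export
predict_samples <- function(model, prep) {
  cfg <- model$config
  n_class <- length(cfg$pool$class_labels)
  embs <- lapply(seq_len(n_class) - 1L, function(cid)
    encode_text(model, class_prompt_texts(cfg$pool, cid, "all")))
  tau <- exp(model$params$log_tau[1, 1])
  out <- lapply(seq(1, length(prep), by = 8L), function(i) {
    idx <- i:min(length(prep), i + 7L)
    Vm <- {
      tape <- ag_tape()
      P <- ag_param_cache(tape, model$params)
      E <- video_forward(tape, P, cfg, lapply(prep[idx], `[[`, "patches"))
      if (cfg$afto_where %in% c("video", "both"))
        E <- adapter_forward(tape, P, "video", E)
      E$value
    }
    do.call(rbind, lapply(seq_along(idx), function(k) {
      cl <- classify(Vm[k, ], embs, tau = tau, ensemble = cfg$ensemble)
      data.frame(patient_id = prep[[idx[k]]]$patient_id,
                 label = prep[[idx[k]]]$class_label,
                 score = cl$probs[2], pred = cl$class,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, out)
}
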