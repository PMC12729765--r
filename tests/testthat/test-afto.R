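test_that("adapt reproduces the hand-worked 2-D mixing example", {
  st <- adapter_state(d_s = 2, bottleneck = 1, alpha_init = 0.5, branch = "video")
  st$W1 <- matrix(c(1, 0), 2, 1)
  st$W2 <- matrix(c(0, 1), 1, 2)
  st$b1 <- matrix(0, 1, 1); st$b2 <- matrix(0, 1, 2)
  st$alpha_logit <- matrix(0, 1, 1)  # alpha = 0.5
  # F_new = W2 relu(W1 (2,0)) = (0,2); mix = 0.5*(0,2) + 0.5*(2,0) = (1,1)
  expect_equal(adapt(c(2, 0), st, renormalize = FALSE), c(1, 1), tolerance = 1e-6)
  expect_equal(adapt(c(2, 0), st), c(1, 1) / sqrt(2), tolerance = 1e-6)
})

test_that("alpha limits recover the raw and the new features", {
  set.seed(10)
  st <- adapter_state(d_s = 8, bottleneck = 2, branch = "text", seed = 1)
  F_raw <- rnorm(8); F_raw <- F_raw / sqrt(sum(F_raw^2))
  st$alpha_logit <- matrix(stats::qlogis(1e-6), 1, 1)
  expect_equal(adapt(F_raw, st, renormalize = FALSE), F_raw, tolerance = 1e-4)
  st$alpha_logit <- matrix(stats::qlogis(1 - 1e-9), 1, 1)
  H <- pmax(F_raw %*% st$W1 + as.numeric(st$b1), 0)
  F_new <- as.numeric(H %*% st$W2) + as.numeric(st$b2)
  expect_equal(adapt(F_raw, st, renormalize = FALSE), F_new, tolerance = 1e-4)
})

test_that("adapter starts near the identity (residual safety)", {
  set.seed(2)
  st <- adapter_state(d_s = 32, bottleneck = 8, alpha_init = 0.5, branch = "video")
  for (i in 1:10) {
    F_raw <- rnorm(32); F_raw <- F_raw / sqrt(sum(F_raw^2))
    expect_lt(sqrt(sum((adapt(F_raw, st) - F_raw)^2)), 0.1)
  }
  expect_error(adapt(rnorm(16), st), "dimension mismatch")
})

test_that("attach inserts adapters per branch without cross-interference", {
  cfg <- tiny_config()
  base <- build_ceus_model(cfg, seed = 1)
  n0 <- count_params(base)
  expect_equal(count_params(attach_adapters(base, "none")), n0)
  b <- cfg$afto_bottleneck; ds <- cfg$d_s
  per_adapter <- ds * b + b * ds + b + ds + 1
  both <- attach_adapters(base, "both")
  expect_equal(count_params(both), n0 + 2 * per_adapter)
  expect_setequal(grep("^ad_", names(both$params), value = TRUE),
                  c(paste0("ad_v_", c("W1", "b1", "W2", "b2", "alpha_logit")),
                    paste0("ad_t_", c("W1", "b1", "W2", "b2", "alpha_logit"))))
  # video-only adapters leave the text branch bit-identical
  vid <- attach_adapters(base, "video")
  txt <- "a video of action metastatic"
  expect_identical(encode_text(vid, txt), encode_text(base, txt))
  expect_error(attach_adapters(base, "sideways"))
})

test_that("alpha is in (0,1), learnable, and moves under optimization", {
  cfg <- tiny_config(afto_where = "both")
  model <- build_ceus_model(cfg, seed = 3)
  a0 <- adapter_alphas(model)
  expect_true(all(a0 > 0 & a0 < 1))
  expect_equal(unname(a0), c(0.5, 0.5))
  ds <- tiny_dataset(n = 4, n_frames = 20, seed = 21)
  prep <- prepare_samples(ds, cfg, n_frames = 4)
  tc <- ceus_train_config(min_epochs = 1, max_epochs = 2, patience = 10,
                          lr = 1e-2, n_frames = 4, seed = 0)
  fit <- train_fold(model, prep[1:3], prep[4], tc)
  a1 <- adapter_alphas(fit$model)
  expect_gt(max(abs(a1 - a0)), 1e-6)  # gradient reached the mixing logits
})

test_that("freezing the backbone trains only adapters and temperature", {
  cfg <- tiny_config(afto_where = "both", freeze_backbone = TRUE)
  model <- build_ceus_model(cfg, seed = 4)
  trainable <- ceusalnm:::trainable_param_names(model)
  expect_setequal(trainable, c(grep("^ad_", names(model$params), value = TRUE),
                               "log_tau"))
  ds <- tiny_dataset(n = 4, n_frames = 20, seed = 22)
  prep <- prepare_samples(ds, cfg, n_frames = 4)
  tc <- ceus_train_config(min_epochs = 1, max_epochs = 1, patience = 1,
                          lr = 1e-2, n_frames = 4, seed = 0)
  fit <- train_fold(model, prep[1:3], prep[4], tc)
  frozen <- setdiff(names(model$params), trainable)
  for (nm in frozen) expect_identical(fit$model$params[[nm]], model$params[[nm]])
  expect_false(identical(fit$model$params$ad_v_W2, model$params$ad_v_W2))
})
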