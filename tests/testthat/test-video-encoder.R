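test_that("patch tokenization yields T*P tokens with shared per-frame TPE", {
  cfg <- ceus_model_config(input_size = c(64, 64), patch_size = 16)
  model <- build_ceus_model(cfg, seed = 1)
  frames <- random_frames(10, 64, 64, seed = 2)
  X <- video_token_embeddings(model, frames)
  expect_equal(nrow(X), 160)  # 10 frames x 16 patches
  expect_equal(attr(X, "frame_index"), rep(1:10, each = 16))
  # two pixel-identical frames differ exactly by TPE_2 - TPE_1 on every token
  same <- video_token_embeddings(model, list(frames[[1]], frames[[1]]))
  diff <- same[17:32, ] - same[1:16, ]
  tpe_delta <- model$params$tpe[2, ] - model$params$tpe[1, ]
  expect_equal(diff, matrix(tpe_delta, 16, ncol(same), byrow = TRUE),
               tolerance = 1e-12)
  # removing TPE shifts all of frame 1's tokens by the same vector
  noT <- video_token_embeddings(model, frames[1], with_tpe = FALSE)
  shift <- X[1:16, ] - noT
  expect_equal(shift, matrix(shift[1, ], 16, ncol(X), byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(patchify_frames(random_frames(2, 30, 30), 16), "divisible")
})

test_that("video embeddings are unit-norm, batch-consistent and temporally sensitive", {
  cfg <- tiny_config()
  model <- build_ceus_model(cfg, seed = 4)
  vids <- lapply(1:3, function(i) random_frames(6, 16, 16, seed = i))
  E <- encode_video(model, vids)
  expect_equal(sqrt(rowSums(E^2)), rep(1, 3), tolerance = 1e-5)
  for (i in 1:3)
    expect_equal(encode_video(model, vids[i])[1, ], E[i, ], tolerance = 1e-5)
  # reversing frame order must change the embedding through the LSTM
  rev1 <- encode_video(model, list(rev(vids[[1]])))
  cossim <- sum(rev1[1, ] * E[1, ])
  expect_lt(cossim, 1 - 1e-4)
  # frame count beyond the TPE table errors
  expect_error(encode_video(model, list(random_frames(13, 16, 16))), "TPE")
})

test_that("shuffling patches within a frame changes the embedding (spatial PE active)", {
  cfg <- tiny_config()
  model <- build_ceus_model(cfg, seed = 5)
  fr <- random_frames(4, 16, 16, seed = 9)
  base <- encode_video(model, list(fr))
  # swap the two left patches with the two right patches in every frame
  swapped <- lapply(fr, function(f) f[, c(9:16, 1:8)])
  other <- encode_video(model, list(swapped))
  expect_gt(max(abs(base - other)), 1e-4)
})

test_that("mean-pool temporal head is frame-order invariant under identical TPE", {
  cfg <- tiny_config(temporal = "meanpool")
  model <- build_ceus_model(cfg, seed = 6)
  # give every frame the same temporal embedding so order cannot leak in
  model$params$tpe <- matrix(rep(model$params$tpe[1, ], each = nrow(model$params$tpe)),
                             nrow(model$params$tpe))
  fr <- random_frames(5, 16, 16, seed = 3)
  a <- encode_video(model, list(fr))
  b <- encode_video(model, list(rev(fr)))
  expect_equal(a, b, tolerance = 1e-10)
  # whereas the LSTM head with the same flattened TPE still distinguishes order
  cfg2 <- tiny_config(temporal = "lstm")
  model2 <- build_ceus_model(cfg2, seed = 6)
  model2$params$tpe <- model$params$tpe
  a2 <- encode_video(model2, list(fr))
  b2 <- encode_video(model2, list(rev(fr)))
  expect_gt(max(abs(a2 - b2)), 1e-6)
})

test_that("one contrastive step reaches every video-branch parameter", {
  cfg <- tiny_config()
  model <- build_ceus_model(cfg, seed = 7)
  ds <- tiny_dataset(n = 4, n_frames = 20, seed = 13)
  prep <- prepare_samples(ds, cfg, n_frames = 4)
  texts <- vapply(prep, ceusalnm:::instance_text, character(1), cfg = cfg)
  tape <- ceusalnm:::ag_tape()
  P <- ceusalnm:::ag_param_cache(tape, model$params)
  loss <- ceusalnm:::batch_loss_node(tape, P, model, prep, texts)
  ceusalnm:::ag_backward(tape, loss)
  g <- ceusalnm:::ag_collect_grads(P)
  vid_params <- grep("^(v[0-9]+_|patch_|spa_pos|tpe|vid_|lstm_)",
                     names(model$params), value = TRUE)
  for (nm in vid_params) {
    expect_true(nm %in% names(g), info = nm)
    expect_gt(max(abs(g[[nm]])), 0, label = paste("grad", nm))
  }
  expect_gt(max(abs(g$log_tau)), 0)
})
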