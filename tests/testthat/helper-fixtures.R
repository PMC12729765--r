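# Shared fixtures: tiny deterministic datasets, pools and models built in
# code at test time.

tiny_pool <- function() {
  prompt_pool(list(
    prompt_template("pre", "{}, an action"),
    prompt_template("mid", "the disease is {}, look here"),
    prompt_template("post", "a video of action {}")
  ), c("non-metastatic", "metastatic"))
}

tiny_config <- function(...) {
  ceus_model_config(d = 8, d_s = 8, n_heads = 2, n_layers_text = 1,
                    n_layers_video = 1, context_length = 24,
                    input_size = c(16, 16), patch_size = 8, max_frames = 12,
                    mlp_ratio = 2, pool = tiny_pool(), ...)
}

tiny_dataset <- function(n = 6, n_frames = 40, seed = 42, noise = 0.05) {
  generate_dataset(synthetic_config(n_patients = n, n_frames = n_frames,
                                    noise_sigma = noise, seed = seed))
}

random_frames <- function(n, h, w, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix(runif(h * w), h, w))
}

# Brute-force BFS flood-fill labelling (8-connectivity): the independent
# oracle for largest_component_bbox.
bfs_largest_bbox <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  best <- NULL
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || seen[i, j]) next
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    cells <- matrix(0L, 0, 2)
    while (length(queue)) {
      c0 <- queue[[1]]; queue <- queue[-1]
      cells <- rbind(cells, c0)
      for (di in -1:1) for (dj in -1:1) {
        ni <- c0[1] + di; nj <- c0[2] + dj
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            mask[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
    cand <- list(count = nrow(cells),
                 y0 = min(cells[, 1]) - 1L, y1 = max(cells[, 1]),
                 x0 = min(cells[, 2]) - 1L, x1 = max(cells[, 2]))
    if (is.null(best) || cand$count > best$count ||
        (cand$count == best$count &&
         (cand$y0 < best$y0 || (cand$y0 == best$y0 && cand$x0 < best$x0))))
      best <- cand
  }
  best[c("x0", "y0", "x1", "y1")]
}
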