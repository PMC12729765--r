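test_that("stratified folds partition patients with balanced class counts", {
  ids <- sprintf("P%02d", 1:10)
  labs <- rep(c(0, 1), each = 5)
  f <- make_folds(ids, labs, k = 5, seed = 1)
  expect_setequal(names(f), ids)
  expect_equal(as.integer(table(f)), rep(2L, 5))
  for (k in 1:5) expect_equal(sum(labs[f == k] == 1), 1)
  # 6/4 split: one class-1 patient per fold... class-0 counts {2,1,1,1,1}
  labs2 <- c(rep(1, 6), rep(0, 4))
  f2 <- suppressWarnings(make_folds(ids, labs2, k = 5, seed = 2))
  c1 <- vapply(1:5, function(k) sum(labs2[f2 == k] == 1), numeric(1))
  c0 <- vapply(1:5, function(k) sum(labs2[f2 == k] == 0), numeric(1))
  expect_equal(sort(c1), c(1, 1, 1, 1, 2))
  expect_equal(sort(c0), c(0, 1, 1, 1, 1))
  expect_error(make_folds(c("a", "a", "b"), c(0, 1, 1)), "unique")
  expect_error(make_folds(ids, rep(0, 10)), "both classes")
  expect_warning(make_folds(ids, c(1, rep(0, 9)), k = 5, seed = 0), "best-effort")
})

test_that("fold assignment is deterministic and always a stratified partition", {
  set.seed(17)
  for (rep in 1:1000) {
    n <- sample(6:40, 1)
    k <- sample(2:min(5, n %/% 2), 1)
    labs <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    ids <- sprintf("X%03d", seq_len(n))
    seed <- sample.int(10000, 1)
    f <- suppressWarnings(make_folds(ids, labs, k = k, seed = seed))
    f2 <- suppressWarnings(make_folds(ids, labs, k = k, seed = seed))
    expect_identical(f, f2)
    expect_setequal(names(f), ids)         # partition: all patients, once
    expect_true(all(f >= 1 & f <= k))
    for (cl in 0:1) {                      # class counts within 1 of ideal
      cnt <- vapply(1:k, function(j) sum(labs[f == j] == cl), numeric(1))
      expect_lte(max(cnt) - min(cnt), 1)
    }
  }
})

test_that("confusion metrics reproduce hand-computed values and symmetries", {
  # TP=3, FN=1, TN=4, FP=2
  y <- c(rep(1, 4), rep(0, 6))
  s <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.55, 0.1, 0.2, 0.3, 0.4)
  m <- compute_metrics(y, s)
  expect_equal(m$tp, 3); expect_equal(m$fn, 1)
  expect_equal(m$tn, 4); expect_equal(m$fp, 2)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 2 / 3, tolerance = 1e-4)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.6)
  expect_equal(m$f1, 2 / 3, tolerance = 1e-4)
  expect_false(m$zero_division)
  # perfect scores
  mp <- compute_metrics(c(0, 1, 0, 1), c(0.1, 0.9, 0.2, 0.8))
  expect_equal(unlist(mp[c("sensitivity", "specificity", "accuracy",
                           "precision", "f1")]), rep(1, 5), ignore_attr = TRUE)
  # flipping predictions swaps sensitivity and specificity roles
  mf <- compute_metrics(y, 1 - s)
  expect_equal(mf$sensitivity, 1 - m$sensitivity + 0)  # 3 of 4 now missed
  expect_equal(mf$tp, m$fn); expect_equal(mf$tn, m$fp)
  # all-negative predictions trip the zero-division flag
  mz <- compute_metrics(c(0, 1), c(0.1, 0.2))
  expect_equal(mz$precision, 0)
  expect_true(mz$zero_division)
  expect_error(compute_metrics(c(1, 1), c(0.4, 0.6)), "both classes")
})

test_that("trapezoidal AUC matches the brute-force pair-counting oracle", {
  pair_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc, 0.75)
  expect_equal(roc_auc(c(0, 1, 0, 1), c(0.1, 0.9, 0.2, 0.8))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)
  set.seed(31)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 2)  # coarse scores force ties
    expect_equal(roc_auc(y, s)$auc, pair_auc(y, s), tolerance = 1e-10)
  }
})

test_that("net benefit follows the decision-analytic formula with its references", {
  # TP=8, FP=2, N=20 at p_t = 0.2: NB = 0.4 - 0.1 * 0.25 = 0.375
  y <- c(rep(1, 9), rep(0, 11))
  s <- c(rep(0.9, 8), 0.05, rep(0.8, 2), rep(0.05, 9))
  dc <- decision_curve(y, s, thresholds = c(0.2, 0.5, 0.9))
  expect_equal(dc$net_benefit[dc$threshold == 0.2], 8 / 20 - (2 / 20) * 0.25)
  expect_equal(dc$treat_none, rep(0, 3))
  prev <- mean(y)
  expect_equal(dc$treat_all, prev - (1 - prev) * dc$threshold / (1 - dc$threshold))
  # treat-all net benefit crosses zero exactly at the prevalence threshold
  dc2 <- decision_curve(y, s, thresholds = prev)
  expect_equal(dc2$treat_all, 0, tolerance = 1e-12)
  # p_t outside (0,1) is dropped
  expect_equal(nrow(decision_curve(y, s, thresholds = c(0.3, 1))), 1)
  expect_error(decision_curve(y, s, thresholds = 1), "no valid")
})

test_that("the module ablation table enumerates the six configurations", {
  cfgs <- ceusalnm:::module_ablation_configs()
  expect_equal(names(cfgs),
               c("Baseline", "Baseline + RP", "Baseline + AFTO (video)",
                 "Baseline + AFTO (text)", "Baseline + AFTO (both)",
                 "Baseline + RP + AFTO"))
  expect_false(cfgs[["Baseline"]]$random_prompt)
  expect_equal(cfgs[["Baseline + AFTO (both)"]]$afto_where, "both")
  expect_true(cfgs[["Baseline + RP + AFTO"]]$random_prompt)
})

test_that("the frames ablation records per-run errors without aborting the suite", {
  ds <- tiny_dataset(n = 4, n_frames = 14, seed = 33)
  cfg <- tiny_config()
  tc <- ceus_train_config(min_epochs = 1, max_epochs = 1, patience = 1,
                          lr = 1e-2, n_frames = 10, half_window = 5, seed = 0)
  # 14-frame videos cannot supply 32 frames: that run must fail, others not
  tab <- run_ablation(ds, cfg, tc, suite = "frames", k = 2, seeds = 0)
  expect_equal(nrow(tab), 7)
  expect_equal(tab$configuration,
               paste0(c(2, 4, 8, 10, 12, 16, 32), " frames"))
  expect_true(nzchar(tab$error[tab$configuration == "32 frames"]))
  expect_false(any(nzchar(tab$error[tab$configuration %in%
                                    c("2 frames", "4 frames", "8 frames")])))
})
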