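test_that("similarity matrix scales cosine similarities and normalises per direction", {
  V <- diag(2)
  sm <- similarity_matrix(V, V, tau = 1)
  expect_equal(sm$S, diag(2))
  # softmax([1,0]) = (e/(e+1), 1/(e+1))
  p <- exp(1) / (exp(1) + 1)
  expect_equal(sm$p_x2y, matrix(c(p, 1 - p, 1 - p, p), 2, byrow = TRUE),
               tolerance = 1e-6)
  expect_equal(rowSums(sm$p_x2y), c(1, 1), tolerance = 1e-9)
  expect_equal(rowSums(sm$p_y2x), c(1, 1), tolerance = 1e-9)
  # large tau drives the match distribution to the identity
  sharp <- similarity_matrix(V, V, tau = 200)
  expect_equal(sharp$p_x2y, diag(2), tolerance = 1e-12)
  # permutation equivariance: permuting text rows permutes similarity columns
  set.seed(1)
  A <- matrix(rnorm(12), 3); A <- A / sqrt(rowSums(A^2))
  B <- matrix(rnorm(12), 3); B <- B / sqrt(rowSums(B^2))
  pi <- c(3, 1, 2)
  expect_equal(similarity_matrix(A, B[pi, ], 2)$S,
               similarity_matrix(A, B, 2)$S[, pi])
  expect_error(similarity_matrix(2 * V, V, 1), "normalized")
  expect_error(similarity_matrix(V, V, 0), "positive")
})

test_that("target distributions are uniform over label matches", {
  expect_equal(target_distribution(c(0, 1))$q_x2y, diag(2))
  expect_equal(target_distribution(c(0, 0))$q_x2y, matrix(0.5, 2, 2))
  q <- target_distribution(c(0, 0, 1, 1))$q_x2y
  blk <- matrix(0.5, 2, 2)
  expect_equal(q, rbind(cbind(blk, 0 * blk), cbind(0 * blk, blk)))
  expect_equal(rowSums(q), rep(1, 4))
  expect_error(target_distribution(1), "at least two")
})

test_that("KL loss has the exact zero point and matches the hand-derived B=2 value", {
  V <- diag(2)
  sm <- similarity_matrix(V, V, 1)
  tg <- target_distribution(c(0, 1))
  # p = q exactly: plug the softmax outputs in as targets
  tg_eq <- tg; tg_eq$q_x2y <- sm$p_x2y; tg_eq$q_y2x <- sm$p_y2x
  expect_equal(kl_contrastive_loss(sm, tg_eq), 0, tolerance = 1e-12)
  # hand value: each row contributes -log softmax(1 vs 0) = 0.3133
  expect_equal(kl_contrastive_loss(sm, tg), -log(exp(1) / (1 + exp(1))),
               tolerance = 1e-3)
  expect_gte(kl_contrastive_loss(sm, tg), 0)
  # symmetry under transposing S and swapping the two target matrices
  set.seed(4)
  A <- matrix(rnorm(16), 4); A <- A / sqrt(rowSums(A^2))
  B <- matrix(rnorm(16), 4); B <- B / sqrt(rowSums(B^2))
  labs <- c(0, 1, 1, 0)
  l1 <- kl_contrastive_loss(similarity_matrix(A, B, 3), target_distribution(labs))
  l2 <- kl_contrastive_loss(similarity_matrix(B, A, 3), target_distribution(labs))
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("the tape loss agrees with the numeric loss and is driven to zero by optimization", {
  set.seed(11)
  B <- 4; d <- 8
  V <- matrix(rnorm(B * d), B); V <- V / sqrt(rowSums(V^2))
  Tm <- matrix(rnorm(B * d), B); Tm <- Tm / sqrt(rowSums(Tm^2))
  labs <- c(0, 0, 1, 1)
  tau <- 5
  num <- kl_contrastive_loss(similarity_matrix(V, Tm, tau), target_distribution(labs))
  tape <- ceusalnm:::ag_tape()
  Vn <- ceusalnm:::ag_leaf(tape, V)
  Tn <- ceusalnm:::ag_leaf(tape, Tm)
  lt <- ceusalnm:::ag_leaf(tape, matrix(log(tau), 1, 1))
  ln <- ceusalnm:::contrastive_loss_node(tape, Vn, Tn, lt, labs)
  expect_equal(as.numeric(ln$value), num, tolerance = 1e-10)
  # 200 plain gradient steps on a separable embedding task cut the loss >= 50%
  params <- list(V = matrix(rnorm(B * d), B), T = matrix(rnorm(B * d), B),
                 log_tau = matrix(log(5), 1, 1))
  loss_at <- function(params) {
    tape <- ceusalnm:::ag_tape()
    P <- ceusalnm:::ag_param_cache(tape, params)
    Vn <- ceusalnm:::ag_l2norm_rows(tape, P("V"))
    Tn <- ceusalnm:::ag_l2norm_rows(tape, P("T"))
    node <- ceusalnm:::contrastive_loss_node(tape, Vn, Tn, P("log_tau"), labs)
    list(tape = tape, node = node, P = P)
  }
  l0 <- as.numeric(loss_at(params)$node$value)
  for (i in 1:200) {
    r <- loss_at(params)
    ceusalnm:::ag_backward(r$tape, r$node)
    g <- ceusalnm:::ag_collect_grads(r$P)
    for (nm in names(g)) params[[nm]] <- params[[nm]] - 0.05 * g[[nm]]
  }
  l1 <- as.numeric(loss_at(params)$node$value)
  expect_lt(l1, 0.5 * l0)
})

test_that("classification aggregates prompt ensembles by mean similarity", {
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  # video embedding equals the class-1 prompt: class 1 wins
  r <- classify(e2, list(matrix(e1, 1), matrix(e2, 1)), tau = 4)
  expect_gt(r$probs[2], 0.5)
  expect_equal(r$class, 1L)
  # identical ensembles: exact tie resolved to class 0
  r2 <- classify(e1, list(matrix(e1, 1), matrix(e1, 1)), tau = 4)
  expect_equal(r2$probs, c(0.5, 0.5))
  expect_equal(r2$class, 0L)
  # hand-computed 2 classes x 3 prompts under mean aggregation
  set.seed(2)
  E0 <- matrix(rnorm(9), 3); E0 <- E0 / sqrt(rowSums(E0^2))
  E1 <- matrix(rnorm(9), 3); E1 <- E1 / sqrt(rowSums(E1^2))
  v <- rnorm(3); v <- v / sqrt(sum(v^2))
  tau <- 3
  s0 <- mean(E0 %*% v); s1 <- mean(E1 %*% v)
  pref <- exp(tau * c(s0, s1)); pref <- pref / sum(pref)
  rr <- classify(v, list(E0, E1), tau = tau)
  expect_equal(rr$probs, pref, tolerance = 1e-12)
  # duplicating a prompt shifts the mean (mean semantics, not max)
  rdup <- classify(v, list(rbind(E0, E0[1, ]), E1), tau = tau)
  s0d <- mean(rbind(E0, E0[1, ]) %*% v)
  expect_equal(rdup$probs[1] / rdup$probs[2],
               exp(tau * s0d) / exp(tau * s1), tolerance = 1e-12)
  if (abs(E0[1, ] %*% v - s0) > 1e-8) expect_false(isTRUE(all.equal(rdup$probs, rr$probs)))
  # under max aggregation duplication is a no-op
  rmax1 <- classify(v, list(E0, E1), tau = tau, ensemble = "max")
  rmax2 <- classify(v, list(rbind(E0, E0[1, ]), E1), tau = tau, ensemble = "max")
  expect_equal(rmax1$probs, rmax2$probs)
  expect_error(classify(v, list(E0)), "two classes")
})
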