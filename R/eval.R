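# Evaluation harness: patient-level stratified k-fold cross-validation,
# confusion metrics, ROC/AUC, decision-curve analysis, and the ablation
# drivers.

#' Patient-level stratified fold assignment
#'
#' Shuffles the patients of each class (seeded) and deals them to folds
#' round-robin, continuing the fold counter across classes so both per-fold
#' class counts and total fold sizes stay within one patient of the
#' stratified ideal. Every patient lands in exactly one fold.
#'
#' @param patient_ids Character vector of unique patient ids.
#' @param labels Class labels aligned with `patient_ids`.
#' @param k Number of folds.
#' @param seed Seed for the shuffles.
#' @return A `fold_assignment`: named integer vector (patient -> fold in
#'   `1..k`) with attribute `k`.
#' @export
make_folds <- function(patient_ids, labels, k = 5, seed = 0L) {
  stopifnot(length(patient_ids) == length(labels))
  if (anyDuplicated(patient_ids)) stop("`patient_ids` must be unique")
  if (length(patient_ids) < k) stop("fewer patients than folds")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  tab <- table(labels)
  if (any(tab < k))
    warning("a class has fewer than `k` patients; stratification is best-effort")
  set.seed(seed)
  fold <- integer(length(patient_ids))
  names(fold) <- patient_ids
  nxt <- 0L
  for (cl in sample(names(tab))) {
    members <- sample(patient_ids[labels == cl])
    for (p in members) {
      fold[p] <- (nxt %% k) + 1L
      nxt <- nxt + 1L
    }
  }
  structure(fold, k = as.integer(k), class = "fold_assignment")
}

#' Confusion metrics at a score threshold
#'
#' Predicts class 1 when `score >= threshold` and reports sensitivity,
#' specificity, accuracy, precision and F1 together with the confusion
#' counts. Undefined ratios (zero denominators) are reported as 0 and
#' flagged.
#'
#' @param y_true 0/1 labels (both classes present).
#' @param y_score Scores in `[0, 1]` (probability of class 1).
#' @param threshold Decision threshold (default 0.5).
#' @return A `metrics_report` list: `sensitivity`, `specificity`,
#'   `accuracy`, `precision`, `f1`, `tp`, `fp`, `tn`, `fn`,
#'   `zero_division`.
#' @export
compute_metrics <- function(y_true, y_score, threshold = 0.5) {
  stopifnot(length(y_true) == length(y_score))
  if (length(unique(y_true)) < 2) stop("both classes must be present in `y_true`")
  pred <- as.integer(y_score >= threshold)
  tp <- sum(pred == 1 & y_true == 1)
  fp <- sum(pred == 1 & y_true == 0)
  tn <- sum(pred == 0 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  zero_division <- FALSE
  div <- function(a, b) {
    if (b == 0) { zero_division <<- TRUE; return(0) }
    a / b
  }
  sen <- div(tp, tp + fn)
  spe <- div(tn, tn + fp)
  acc <- (tp + tn) / length(y_true)
  pre <- div(tp, tp + fp)
  f1 <- if (pre + sen == 0) { zero_division <- TRUE; 0 } else 2 * pre * sen / (pre + sen)
  structure(list(sensitivity = sen, specificity = spe, accuracy = acc,
                 precision = pre, f1 = f1, tp = tp, fp = fp, tn = tn, fn = fn,
                 zero_division = zero_division),
            class = "metrics_report")
}

#' ROC curve and AUC
#'
#' Trapezoidal AUC over all score thresholds, equivalent to the Mann-Whitney
#' statistic with tied scores counted half. Constant scores yield 0.5, the
#' chance diagonal.
#'
#' @param y_true 0/1 labels (both classes present).
#' @param y_score Numeric scores, larger meaning more class-1.
#' @return List with `auc` and a `curve` data frame (`fpr`, `tpr`).
#' @export
roc_auc <- function(y_true, y_score) {
  if (length(unique(y_true)) < 2) stop("both classes must be present in `y_true`")
  r <- pROC::roc(response = y_true, predictor = y_score,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  list(auc = as.numeric(pROC::auc(r)),
       curve = data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities))
}

#' Decision-curve analysis
#'
#' Net benefit of treating when `score >= p_t`:
#' `NB(p_t) = TP/N - (FP/N) * p_t / (1 - p_t)`, against the treat-all
#' reference `prevalence - (1 - prevalence) * p_t / (1 - p_t)` and the
#' treat-none reference, which is identically 0.
#'
#' @param y_true 0/1 labels.
#' @param y_score Scores in `[0, 1]`.
#' @param thresholds Grid of threshold probabilities in (0, 1); values
#'   outside the open interval are dropped.
#' @return A `net_benefit_curve` data frame with `threshold`, `net_benefit`,
#'   `treat_all`, `treat_none`.
#' @export
decision_curve <- function(y_true, y_score,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  if (!length(thresholds)) stop("no valid thresholds in (0, 1)")
  N <- length(y_true)
  prev <- mean(y_true == 1)
  odds <- thresholds / (1 - thresholds)
  nb <- vapply(seq_along(thresholds), function(i) {
    pred <- y_score >= thresholds[i]
    tp <- sum(pred & y_true == 1)
    fp <- sum(pred & y_true == 0)
    tp / N - (fp / N) * odds[i]
  }, numeric(1))
  structure(data.frame(threshold = thresholds, net_benefit = nb,
                       treat_all = prev - (1 - prev) * odds,
                       treat_none = 0),
            class = c("net_benefit_curve", "data.frame"))
}

#' Patient-level stratified cross-validation of the full pipeline
#'
#' Splits patients into `k` stratified folds, trains a freshly initialised
#' model on each training split and scores the held-out fold. Fold
#' disjointness is asserted on every fold.
#'
#' @param samples List of `ceus_sample` objects.
#' @param config A [ceus_model_config()].
#' @param tc A [ceus_train_config()].
#' @param k Number of folds.
#' @param seed Seed controlling folds and per-fold model initialisation.
#' @param verbose Print fold progress.
#' @return A `ceus_cv_result`: `per_fold` data frame (fold metrics + AUC),
#'   `summary` (mean and sd per metric), `scores` (pooled out-of-fold
#'   predictions), `histories` (per-fold training histories), `folds`.
#' @export
cross_validate <- function(samples, config, tc = ceus_train_config(), k = 5,
                           seed = 0L, verbose = FALSE) {
  ids <- vapply(samples, `[[`, character(1), "patient_id")
  labels <- vapply(samples, `[[`, integer(1), "class_label")
  folds <- make_folds(ids, labels, k = k, seed = seed)
  prep <- prepare_samples(samples, config, n_frames = tc$n_frames,
                          half_window = tc$half_window)
  per_fold <- list(); scores <- list(); histories <- list()
  for (f in seq_len(k)) {
    tr <- prep[folds[ids] != f]
    va <- prep[folds[ids] == f]
    stopifnot(!length(intersect(vapply(tr, `[[`, character(1), "patient_id"),
                                vapply(va, `[[`, character(1), "patient_id"))))
    model <- build_ceus_model(config, seed = seed * 131L + f)
    tcf <- tc; tcf$seed <- tc$seed * 131L + f
    fit <- train_fold(model, tr, va, tcf)
    pr <- predict_samples(fit$model, va)
    pr$fold <- f
    m <- compute_metrics(pr$label, pr$score)
    auc_f <- if (length(unique(pr$label)) == 2) roc_auc(pr$label, pr$score)$auc else NA_real_
    per_fold[[f]] <- data.frame(fold = f, sensitivity = m$sensitivity,
                                specificity = m$specificity, accuracy = m$accuracy,
                                precision = m$precision, f1 = m$f1, auc = auc_f)
    scores[[f]] <- pr
    histories[[f]] <- fit$history
    if (verbose) message(sprintf("fold %d: acc %.3f auc %.3f", f, m$accuracy, auc_f))
  }
  per_fold <- do.call(rbind, per_fold)
  scores <- do.call(rbind, scores)
  metric_cols <- setdiff(names(per_fold), "fold")
  summary <- data.frame(metric = metric_cols,
                        mean = vapply(metric_cols, function(c) mean(per_fold[[c]], na.rm = TRUE), numeric(1)),
                        sd = vapply(metric_cols, function(c) stats::sd(per_fold[[c]], na.rm = TRUE), numeric(1)))
  structure(list(per_fold = per_fold, summary = summary, scores = scores,
                 histories = histories, folds = folds),
            class = "ceus_cv_result")
}

#' @export
print.ceus_cv_result <- function(x, ...) {
  cat("Patient-level stratified cross-validation (", max(x$per_fold$fold),
      " folds, ", nrow(x$scores), " samples)\n\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  pooled <- roc_auc(x$scores$label, x$scores$score)$auc
  cat(sprintf("\n  pooled out-of-fold AUC: %.4f\n", pooled))
  invisible(x)
}

module_ablation_configs <- function() {
  list(
    "Baseline" = list(random_prompt = FALSE, afto_where = "none"),
    "Baseline + RP" = list(random_prompt = TRUE, afto_where = "none"),
    "Baseline + AFTO (video)" = list(random_prompt = FALSE, afto_where = "video"),
    "Baseline + AFTO (text)" = list(random_prompt = FALSE, afto_where = "text"),
    "Baseline + AFTO (both)" = list(random_prompt = FALSE, afto_where = "both"),
    "Baseline + RP + AFTO" = list(random_prompt = TRUE, afto_where = "both")
  )
}

#' Ablation drivers
#'
#' `suite = "modules"` runs the six module configurations (baseline, random
#' prompts, adapters on either or both branches, and the full method);
#' `suite = "frames"` sweeps the input frame count over
#' `c(2, 4, 8, 10, 12, 16, 32)`, widening the keyframe sampling window to
#' `ceiling(n/2)` when the requested count exceeds the +/-5 window's 11
#' frames. All runs share folds and seeds. A run that errors is recorded in
#' its row and the suite continues.
#'
#' @param samples List of `ceus_sample` objects.
#' @param config A [ceus_model_config()] used as the base.
#' @param tc A [ceus_train_config()] used as the base.
#' @param suite `"modules"` or `"frames"`.
#' @param k Folds per run.
#' @param seeds Integer vector; each configuration is run once per seed and
#'   metrics are averaged across seeds.
#' @param configs For `suite = "modules"`, optional subset of configuration
#'   names to run.
#' @return Data frame with one row per configuration (averaged over seeds):
#'   metric means, or an `error` message for failed runs.
#' @export
run_ablation <- function(samples, config, tc = ceus_train_config(),
                         suite = c("modules", "frames"), k = 5, seeds = 0L,
                         configs = NULL) {
  suite <- match.arg(suite)
  runs <- if (suite == "modules") {
    cl <- module_ablation_configs()
    if (!is.null(configs)) cl <- cl[configs]
    cl
  } else {
    counts <- c(2, 4, 8, 10, 12, 16, 32)
    stats::setNames(lapply(counts, function(n) list(n_frames = n)),
                    paste0(counts, " frames"))
  }
  rows <- lapply(names(runs), function(nm) {
    r <- runs[[nm]]
    res <- tryCatch({
      per_seed <- lapply(seeds, function(s) {
        cfgi <- config
        tci <- tc
        if (!is.null(r$afto_where)) cfgi$afto_where <- r$afto_where
        if (!is.null(r$random_prompt)) tci$random_prompt <- r$random_prompt
        if (!is.null(r$n_frames)) {
          tci$n_frames <- r$n_frames
          if (2 * tci$half_window + 1 < r$n_frames)
            tci$half_window <- ceiling(r$n_frames / 2)
        }
        cv <- cross_validate(samples, cfgi, tci, k = k, seed = s)
        colMeans(cv$per_fold[, c("sensitivity", "specificity", "accuracy",
                                 "precision", "f1", "auc")], na.rm = TRUE)
      })
      m <- as.data.frame(t(Reduce(`+`, per_seed) / length(per_seed)))
      m$error <- ""
      m
    }, error = function(e) {
      data.frame(sensitivity = NA_real_, specificity = NA_real_,
                 accuracy = NA_real_, precision = NA_real_, f1 = NA_real_,
                 auc = NA_real_, error = conditionMessage(e))
    })
    cbind(data.frame(configuration = nm, stringsAsFactors = FALSE), res)
  })
  do.call(rbind, rows)
}
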