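# Evaluation metrics: RMSE / R-squared for regression, row-normalized
# confusion matrices, trapezoidal ROC AUC and step-wise average precision
# for declared binary contrasts.

#' Area under the ROC curve (trapezoidal)
#'
#' Thresholds sweep the score; tied scores are handled as a single threshold
#' step, which makes the trapezoidal area equal to the Mann-Whitney
#' probability with half credit for ties.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels 0/1 (or logical) true labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  P <- sum(labels == 1L)
  Ng <- sum(labels == 0L)
  if (P == 0L || Ng == 0L) stop_tsgcn("roc_auc: need both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- c(0, cumsum(tapply(l, grp, sum)))
  fp <- c(0, cumsum(tapply(1L - l, grp, sum)))
  tpr <- tp / P
  fpr <- fp / Ng
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Average precision (step-wise)
#'
#' `AP = sum_k (R_k - R_{k-1}) P_k` over descending score thresholds (tied
#' scores grouped); the non-interpolated rule, equal to the area under the
#' precision-recall curve by step-wise summation.
#'
#' @inheritParams roc_auc
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  P <- sum(labels == 1L)
  if (P == 0L || P == length(labels)) stop_tsgcn("average_precision: need both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(tapply(l, grp, sum))
  npred <- cumsum(tapply(rep(1L, length(l)), grp, sum))
  prec <- tp / npred
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Row-normalized confusion matrix
#'
#' @param true,predicted 0-based class indices.
#' @param M class count.
#' @return `M x M` matrix; entry (r, c) is the fraction of true class `r`
#'   assigned to class `c`; each row with any examples sums to 1.
#' @export
confusion_matrix <- function(true, predicted, M) {
  cm <- matrix(0, M, M)
  for (i in seq_along(true)) {
    cm[true[i] + 1L, predicted[i] + 1L] <- cm[true[i] + 1L, predicted[i] + 1L] + 1
  }
  rs <- rowSums(cm)
  cm / ifelse(rs == 0, 1, rs)
}

rmse <- function(pred, true) sqrt(mean((pred - true)^2))
r_squared <- function(pred, true) 1 - sum((true - pred)^2) / sum((true - mean(true))^2)

#' Task description for evaluation
#'
#' @param kind `"classification"` or `"regression"`.
#' @param M class count or target dimension.
#' @param contrasts for classification, a named list of binary contrasts,
#'   each `list(positive = <class indices>, negative = <class indices>)`
#'   (0-based); the contrast score is the summed posterior probability of
#'   the positive classes, restricted to examples belonging to either side.
#' @param target_stats for regression, the [fit_target_stats()] used to
#'   invert predictions back to the (log) scale on which accuracies are
#'   reported.
#' @param target_names optional names of regression targets.
#' @return an `eval_task` list.
#' @export
eval_task <- function(kind = c("classification", "regression"), M,
                      contrasts = list(), target_stats = NULL,
                      target_names = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, M = as.integer(M), contrasts = contrasts,
                 target_stats = target_stats, target_names = target_names),
            class = "eval_task")
}

# The standard binary contrasts of the two classification benchmarks.
# Sweeps: classes (0 hard, 1 hard-linked, 2 soft, 3 soft-linked, 4 neutral);
# the combined "sweep" score is the summed hard + soft probability.
# Introgression: classes (0 A->B, 1 B->A, 2 none).
sweep_contrasts <- function() {
  list(
    "sweep_vs_unselected" = list(positive = c(0L, 2L), negative = c(1L, 3L, 4L)),
    "hard_vs_soft" = list(positive = 0L, negative = 2L)
  )
}
introgression_contrasts <- function() {
  list(
    "introgressed_vs_none" = list(positive = c(0L, 1L), negative = 2L),
    "direction" = list(positive = 0L, negative = 1L)
  )
}

#' Evaluate a trained model on a held-out test split
#'
#' Regression: RMSE and R-squared per target on the scale on which targets
#' were standardized (natural log for log-scaled targets), plus the same on
#' the standardized z scale. Classification: row-normalized argmax confusion
#' matrix and, per declared contrast, trapezoidal ROC AUC and step-wise
#' average precision computed from summed class posterior probabilities.
#'
#' @param model a trained [gcn_model()].
#' @param features featurized test records with labels.
#' @param task an [eval_task()].
#' @return an `eval_report` list with per-example scores attached.
#' @export
gcn_evaluate <- function(model, features, task) {
  spec <- if (task$kind == "classification") {
    loss_spec("categorical_cross_entropy", M = task$M)
  } else loss_spec("smooth_l1", M = task$M)
  out <- eval_pass(model, features, spec)
  targets <- batch_targets(features, spec)
  rep_out <- list(kind = task$kind)
  if (task$kind == "regression") {
    st <- task$target_stats
    pred_log <- sweep(sweep(out, 2, st$sd, "*"), 2, st$mean, "+")
    true_log <- sweep(sweep(as.matrix(targets), 2, st$sd, "*"), 2, st$mean, "+")
    nm <- task$target_names %||% paste0("target", seq_len(ncol(out)))
    rep_out$regression <- data.frame(
      target = nm,
      rmse = vapply(seq_len(ncol(out)), function(j) rmse(pred_log[, j], true_log[, j]), 0),
      r2 = vapply(seq_len(ncol(out)), function(j) r_squared(pred_log[, j], true_log[, j]), 0),
      rmse_z = vapply(seq_len(ncol(out)), function(j) rmse(out[, j], targets[, j]), 0),
      r2_z = vapply(seq_len(ncol(out)), function(j) r_squared(out[, j], targets[, j]), 0),
      stringsAsFactors = FALSE)
    rep_out$scores <- data.frame(pred = pred_log, true = true_log)
  } else {
    probs <- softmax_rows(out)
    pred_class <- max.col(probs) - 1L
    rep_out$confusion <- confusion_matrix(targets, pred_class, task$M)
    rep_out$accuracy <- mean(pred_class == targets)
    if (length(task$contrasts)) {
      rep_out$contrasts <- do.call(rbind, lapply(names(task$contrasts), function(nm) {
        ct <- task$contrasts[[nm]]
        sel <- targets %in% c(ct$positive, ct$negative)
        if (!any(targets[sel] %in% ct$positive) || !any(targets[sel] %in% ct$negative)) {
          stop_tsgcn("gcn_evaluate: contrast '%s' has a single class in the test set", nm)
        }
        sc <- rowSums(probs[sel, ct$positive + 1L, drop = FALSE])
        lab <- as.integer(targets[sel] %in% ct$positive)
        data.frame(contrast = nm, auc = roc_auc(sc, lab),
                   ap = average_precision(sc, lab), n = sum(sel),
                   stringsAsFactors = FALSE)
      }))
    }
    rep_out$scores <- data.frame(true = targets, pred = pred_class, probs)
  }
  structure(rep_out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s\n", x$kind))
  if (x$kind == "regression") {
    print(x$regression[, c("target", "rmse", "r2")], row.names = FALSE)
  } else {
    cat(sprintf("accuracy: %.4f\n", x$accuracy))
    if (!is.null(x$contrasts)) print(x$contrasts, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' Per-example scores are included so reports are self-contained; writing is
#' canonical (sorted keys, full precision) so re-running an evaluation with
#' the same checkpoint and seed reproduces the file byte for byte.
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @export
write_eval_report <- function(report, path) {
  writeLines(as.character(canonical_json(unclass(report))), path)
  invisible(path)
}
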