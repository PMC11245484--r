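# Evaluation layer: confusion matrices, classification and error metrics,
# rank-based AUC, per-subject majority voting, subject-wise CV runner,
# configuration sweeps, metric gating, and cohort descriptive statistics.

.classes <- c("fatigue", "non_fatigue")

#' Two-class confusion matrix
#'
#' Counts with fatigue as the positive class: rows are the true label,
#' columns the prediction, so the matrix is `[TP, FN; FP, TN]`.
#'
#' @param truth,predicted Character vectors over
#'   `c("fatigue", "non_fatigue")`, equal length.
#' @return A 2x2 integer matrix with dimnames `truth` x `predicted`.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  bad <- setdiff(unique(c(truth, predicted)), .classes)
  if (length(bad)) stop("labels outside the class set: ",
                        paste(bad, collapse = ", "))
  m <- matrix(0L, 2, 2, dimnames = list(truth = .classes,
                                        predicted = .classes))
  for (i in seq_along(truth)) {
    m[truth[i], predicted[i]] <- m[truth[i], predicted[i]] + 1L
  }
  m
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2 Pr Re / (Pr + Re), accuracy = (TP+TN)/total, fatigue positive.
#' Undefined ratios (zero denominators) are reported as 0 with a warning.
#'
#' @param confusion A matrix from [confusion_matrix()].
#' @return A one-row tibble: `accuracy`, `precision`, `recall`, `f1`.
#' @export
class_metrics <- function(confusion) {
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  tp <- confusion["fatigue", "fatigue"]
  fn <- confusion["fatigue", "non_fatigue"]
  fp <- confusion["non_fatigue", "fatigue"]
  tn <- confusion["non_fatigue", "non_fatigue"]
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting 0")
      0
    } else num / den
  }
  pr <- safe_div(tp, tp + fp, "precision")
  re <- safe_div(tp, tp + fn, "recall")
  f1 <- if (pr + re == 0) 0 else 2 * pr * re / (pr + re)
  tibble::tibble(accuracy = (tp + tn) / total, precision = pr,
                 recall = re, f1 = f1)
}

#' Prediction error metrics
#'
#' @param predicted,actual Equal-length numeric vectors.
#' @return A one-row tibble: `mae`, `mse`, `rmse` (`mse = rmse^2`).
#' @export
error_metrics <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(predicted) == 0) {
    stop("predicted and actual must be nonempty vectors of equal length")
  }
  mse <- mean((predicted - actual)^2)
  tibble::tibble(mae = mean(abs(predicted - actual)), mse = mse,
                 rmse = sqrt(mse))
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with midrank tie correction: the
#' probability that a random fatigue window scores above a random
#' non-fatigue window, counting ties as 1/2.
#'
#' @param scores Numeric scores (higher = more fatigue-like).
#' @param truth True labels over `c("fatigue", "non_fatigue")`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  pos <- truth == "fatigue"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Majority vote over a subject's window labels
#'
#' Returns the modal label; an exact tie resolves to fatigue (the
#' conservative choice for a screening task).
#'
#' @param labels Nonempty character vector of window labels.
#' @return A single label.
#' @export
majority_vote <- function(labels) {
  if (length(labels) == 0) stop("empty label vector")
  n_fat <- sum(labels == "fatigue")
  if (n_fat >= length(labels) / 2) "fatigue" else "non_fatigue"
}

#' Metric gate
#'
#' Passes iff AUC, F1, precision and accuracy all strictly exceed the
#' threshold.
#'
#' @param report A `cv_report` or anything with `auc`, `f1`, `precision`,
#'   `accuracy` fields (e.g. one row of [glance.cv_report()]).
#' @param tau Threshold (default 0.825).
#' @return Logical.
#' @export
gate <- function(report, tau = 0.825) {
  if (inherits(report, "cv_report")) report <- glance(report)
  need <- c("auc", "f1", "precision", "accuracy")
  missing <- setdiff(need, names(report))
  if (length(missing)) stop("missing metrics: ", paste(missing, collapse = ", "))
  all(vapply(need, function(m) report[[m]] > tau, logical(1)))
}

#' Per-condition cohort statistics
#'
#' Mean and population standard deviation of KSS and PVT latency per
#' condition, as printed in cohort summary tables.
#'
#' @param cohort Data frame with `condition`, `kss` and `pvt_ms` columns
#'   (e.g. a simulated cohort or an assessment table).
#' @return A tibble with one row per condition: `n`, `kss_mean`, `kss_sd`,
#'   `pvt_mean`, `pvt_sd`.
#' @export
cohort_stats <- function(cohort) {
  stopifnot(all(c("condition", "kss", "pvt_ms") %in% names(cohort)))
  if (any(table(cohort$condition) == 0) || nrow(cohort) == 0) {
    stop("empty condition group")
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  cohort |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n = dplyr::n(),
                     kss_mean = mean(.data$kss), kss_sd = pop_sd(.data$kss),
                     pvt_mean = mean(.data$pvt_ms),
                     pvt_sd = pop_sd(.data$pvt_ms), .groups = "drop")
}

#' Subject-wise cross-validated training and evaluation
#'
#' For each fold of the plan, trains a fresh model (seeded per fold from the
#' config seed) on the training subjects' windows and predicts the test
#' subjects' windows.  Window-level predictions are pooled across folds for
#' the aggregate metrics (micro-averaging); per-fold metrics and per-record
#' majority votes are also reported.
#'
#' @param windows Windows tibble ([segment_cohort()]) with `subject_id`,
#'   `label`, `samples`.
#' @param config A [model_config()].
#' @param plan A [make_folds()] plan over the windows' subjects.
#' @return A `cv_report`: list with `window_predictions`, `fold_metrics`,
#'   `pooled` (one-row tibble of aggregate metrics), `confusion` (pooled),
#'   `subject_votes`, `config` and `plan`.
#' @export
run_cv <- function(windows, config = model_config(), plan) {
  stopifnot(inherits(plan, "fold_plan"))
  preds <- vector("list", nrow(plan))
  fold_rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    tr <- windows[windows$subject_id %in% plan$train_subjects[[i]], ]
    te <- windows[windows$subject_id %in% plan$test_subjects[[i]], ]
    if (nrow(te) == 0 || nrow(tr) == 0) {
      stop("fold ", i, " has an empty train or test window set")
    }
    stopifnot(length(intersect(tr$subject_id, te$subject_id)) == 0)
    cfg_i <- config
    cfg_i$seed <- config$seed + 131L * i
    fit <- train_model(tr, cfg_i)
    p <- predict(fit, te)
    p$fold <- i
    preds[[i]] <- p
    cm <- confusion_matrix(p$label, p$.pred)
    fold_rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(fold = i, n_train = nrow(tr), n_test = nrow(te)),
      class_metrics(cm),
      tibble::tibble(final_loss = fit$history$loss[nrow(fit$history)]))
  }
  all_pred <- dplyr::bind_rows(preds)
  cm <- confusion_matrix(all_pred$label, all_pred$.pred)
  err <- error_metrics(all_pred$p_fatigue,
                       as.numeric(all_pred$label == "fatigue"))
  pooled <- dplyr::bind_cols(
    class_metrics(cm),
    tibble::tibble(auc = roc_auc(all_pred$p_fatigue, all_pred$label)),
    err)
  votes <- all_pred |>
    dplyr::group_by(.data$subject_id, .data$label) |>
    dplyr::summarise(n_windows = dplyr::n(),
                     vote = majority_vote(.data$.pred), .groups = "drop") |>
    dplyr::mutate(correct = .data$vote == .data$label)
  structure(list(window_predictions = all_pred,
                 fold_metrics = dplyr::bind_rows(fold_rows),
                 pooled = pooled, confusion = cm, subject_votes = votes,
                 config = config, plan = plan),
            class = "cv_report")
}

#' Sweep architecture settings over a common fold plan
#'
#' Re-runs [run_cv()] for each row of a settings grid (any
#' [model_config()] fields), holding folds and seeds fixed, and annotates
#' the best row by pooled accuracy.
#'
#' @param windows Windows tibble.
#' @param base_config Base [model_config()]; grid columns override it.
#' @param grid Data frame of configuration overrides, one row per setting.
#' @param plan A [make_folds()] plan.
#' @return The grid with pooled `accuracy`, `precision`, `recall`, `f1`,
#'   `auc` columns and a logical `best` marker.
#' @export
grid_sweep <- function(windows, base_config = model_config(), grid, plan) {
  stopifnot(nrow(grid) >= 1)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    cfg <- utils::modifyList(unclass(base_config),
                             as.list(grid[i, , drop = FALSE]))
    cfg <- do.call(model_config, cfg[names(cfg) %in% names(formals(model_config))])
    rep <- run_cv(windows, cfg, plan)
    dplyr::bind_cols(tibble::as_tibble(grid[i, , drop = FALSE]),
                     rep$pooled[, c("accuracy", "precision", "recall",
                                    "f1", "auc")])
  })
  out <- dplyr::bind_rows(rows)
  out$best <- out$accuracy == max(out$accuracy)
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", nrow(x$fold_metrics), " folds, ",
      nrow(x$window_predictions), " test windows\n", sep = "")
  cat("pooled: accuracy ", round(x$pooled$accuracy, 3),
      ", precision ", round(x$pooled$precision, 3),
      ", recall ", round(x$pooled$recall, 3),
      ", F1 ", round(x$pooled$f1, 3),
      ", AUC ", round(x$pooled$auc, 3), "\n", sep = "")
  cat("subject votes correct: ", sum(x$subject_votes$correct), "/",
      nrow(x$subject_votes), "\n", sep = "")
  invisible(x)
}

#' @describeIn run_cv Per-fold metrics as a tibble.
#' @param x A `cv_report`.
#' @param ... Unused.
#' @export
tidy.cv_report <- function(x, ...) x$fold_metrics

#' @describeIn run_cv One-row tibble of pooled metrics plus the majority-vote
#'   subject accuracy.
#' @export
glance.cv_report <- function(x, ...) {
  dplyr::bind_cols(x$pooled,
                   tibble::tibble(
                     vote_accuracy = mean(x$subject_votes$correct),
                     n_folds = nrow(x$fold_metrics),
                     n_windows = nrow(x$window_predictions)))
}

#' @describeIn run_cv Pooled ROC curve.
#' @param object A `cv_report`.
#' @export
autoplot.cv_report <- function(object, ...) {
  p <- object$window_predictions
  ths <- sort(unique(c(-Inf, p$p_fatigue, Inf)), decreasing = TRUE)
  pos <- p$label == "fatigue"
  roc <- purrr::map_dfr(ths, function(th) {
    tibble::tibble(tpr = mean(p$p_fatigue[pos] >= th),
                   fpr = mean(p$p_fatigue[!pos] >= th))
  })
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, colour = "grey") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("Pooled ROC (AUC = %.3f)",
                                  object$pooled$auc)) +
    ggplot2::theme_minimal()
}

#' Write a cv_report to disk
#'
#' Writes pooled and per-fold metrics (CSV + JSON), the pooled confusion
#' matrix (CSV) and per-window predictions (CSV).
#'
#' @param report A `cv_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    pooled_csv = file.path(dir, "metrics_pooled.csv"),
    folds_csv = file.path(dir, "metrics_folds.csv"),
    json = file.path(dir, "metrics.json"),
    confusion = file.path(dir, "confusion.csv"),
    predictions = file.path(dir, "window_predictions.csv"))
  utils::write.csv(glance(report), paths["pooled_csv"], row.names = FALSE)
  utils::write.csv(report$fold_metrics, paths["folds_csv"], row.names = FALSE)
  jsonlite::write_json(list(pooled = as.list(glance(report)),
                            folds = report$fold_metrics,
                            subject_votes = report$subject_votes),
                       paths["json"], auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(report$confusion), paths["confusion"],
                   row.names = FALSE)
  utils::write.csv(report$window_predictions, paths["predictions"],
                   row.names = FALSE)
  invisible(paths)
}
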