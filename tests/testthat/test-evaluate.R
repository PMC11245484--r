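test_that("confusion matrix counts with fatigue as the positive class", {
  tr <- c("fatigue", "fatigue", "fatigue", "non_fatigue", "non_fatigue")
  pr <- c("fatigue", "fatigue", "non_fatigue", "non_fatigue", "fatigue")
  cm <- confusion_matrix(tr, pr)
  expect_equal(cm["fatigue", "fatigue"], 2L)          # TP
  expect_equal(cm["fatigue", "non_fatigue"], 1L)      # FN
  expect_equal(cm["non_fatigue", "fatigue"], 1L)      # FP
  expect_equal(cm["non_fatigue", "non_fatigue"], 1L)  # TN
  expect_equal(sum(cm), 5)

  perfect <- confusion_matrix(tr, tr)
  expect_equal(perfect["fatigue", "non_fatigue"] +
                 perfect["non_fatigue", "fatigue"], 0L)
  expect_error(confusion_matrix(tr, pr[-1]), "equal length")
  expect_error(confusion_matrix(c("fatigue", "tired"), c("fatigue", "fatigue")),
               "outside the class set")
})

test_that("classification metrics follow their defining formulas", {
  cm <- confusion_matrix(
    c("fatigue", "fatigue", "fatigue", "non_fatigue", "non_fatigue"),
    c("fatigue", "fatigue", "non_fatigue", "non_fatigue", "fatigue"))
  m <- class_metrics(cm)
  expect_equal(m$accuracy, 0.6)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)

  # harmonic mean of equal precision/recall is that value
  cm2 <- matrix(c(8L, 2L, 2L, 8L), 2, 2,
                dimnames = list(truth = c("fatigue", "non_fatigue"),
                                predicted = c("fatigue", "non_fatigue")))
  expect_equal(class_metrics(cm2)$f1, 0.8)

  # degenerate case: no positive predictions
  cm3 <- matrix(c(0L, 0L, 2L, 3L), 2, 2, byrow = TRUE,
                dimnames = dimnames(cm2))
  expect_warning(m3 <- class_metrics(cm3), "undefined")
  expect_equal(m3$f1, 0)
})

test_that("F1 sits between min and arithmetic mean of precision and recall", {
  set.seed(9)
  for (i in 1:20) {
    cm <- matrix(as.integer(rmultinom(1, 40, rep(0.25, 4))), 2, 2,
                 dimnames = list(truth = c("fatigue", "non_fatigue"),
                                 predicted = c("fatigue", "non_fatigue")))
    m <- suppressWarnings(class_metrics(cm))
    if (m$precision > 0 && m$recall > 0) {
      expect_lte(min(m$precision, m$recall) - 1e-12, m$f1)
      expect_lte(m$f1, sqrt(m$precision * m$recall) + 1e-12)
      expect_lte(sqrt(m$precision * m$recall),
                 (m$precision + m$recall) / 2 + 1e-12)
    }
  }
})

test_that("error metrics satisfy the MSE = RMSE^2 identity", {
  m <- error_metrics(c(1, -1, 1, -1), c(0, 0, 0, 0))
  expect_equal(c(m$mae, m$mse, m$rmse), c(1, 1, 1))
  m2 <- error_metrics(c(3, -1), c(0, 0))
  expect_equal(c(m2$mae, m2$mse, m2$rmse), c(2, 5, sqrt(5)))
  m3 <- error_metrics(c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(c(m3$mae, m3$mse, m3$rmse), c(0, 0, 0))
  expect_equal(m2$mse, m2$rmse^2, tolerance = 1e-12)
  expect_error(error_metrics(1:3, 1:2), "equal length")
})

test_that("rank AUC matches the threshold-sweep oracle and handles ties", {
  lab <- c(rep("fatigue", 4), rep("non_fatigue", 4))
  expect_equal(roc_auc(c(4, 3.5, 3, 2.9, 2, 1, 0.5, 0), lab), 1)
  expect_equal(roc_auc(rep(1, 8), lab), 0.5)
  expect_error(roc_auc(1:3, rep("fatigue", 3)), "both classes")

  set.seed(10)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    truth <- sample(c("fatigue", "non_fatigue"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("fatigue", "non_fatigue")
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
    expect_equal(roc_auc(scores, truth), trapezoid_auc(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  truth <- sample(c("fatigue", "non_fatigue"), 60, replace = TRUE)
  scores <- rnorm(60) + (truth == "fatigue")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(truth, levels = c("non_fatigue", "fatigue")),
    predictor = scores, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(scores, truth), ref, tolerance = 1e-12)
})

test_that("majority voting is modal with the fatigue tie-break", {
  expect_equal(majority_vote(rep(c("fatigue", "non_fatigue"), c(21, 19))),
               "fatigue")
  expect_equal(majority_vote(rep(c("fatigue", "non_fatigue"), c(19, 21))),
               "non_fatigue")
  expect_equal(majority_vote(rep("non_fatigue", 7)), "non_fatigue")
  expect_equal(majority_vote(rep(c("fatigue", "non_fatigue"), c(20, 20))),
               "fatigue")
  expect_error(majority_vote(character(0)), "empty")
})

test_that("the metric gate requires all four metrics strictly above tau", {
  ok <- list(auc = 0.9, f1 = 0.9, precision = 0.9, accuracy = 0.9)
  expect_true(gate(ok))
  expect_false(gate(list(auc = 0.825, f1 = 0.9, precision = 0.9,
                         accuracy = 0.9)))
  expect_false(gate(list(auc = 0.9, f1 = 0.9, precision = 0.9,
                         accuracy = 0.5)))
  expect_true(gate(list(auc = 0.83, f1 = 0.9, precision = 0.9,
                        accuracy = 0.9), tau = 0.8))
  expect_error(gate(list(auc = 0.9, f1 = 0.9)), "missing metrics")
})

test_that("cohort statistics reproduce the reference assessment table", {
  tab <- read.csv(system.file("extdata", "cohort_kss_pvt.csv",
                              package = "ppgfatigue"))
  st <- cohort_stats(tab)
  fat <- st[st$condition == "fatigue", ]
  nf <- st[st$condition == "non_fatigue", ]
  expect_equal(round(fat$kss_mean, 1), 7.4)
  expect_equal(round(fat$pvt_mean, 1), 469.4)
  expect_equal(round(nf$kss_mean, 1), 2.8)
  expect_equal(round(nf$pvt_mean), 356)
  expect_equal(round(fat$kss_sd, 2), 0.64)   # population convention

  single <- cohort_stats(data.frame(condition = c("fatigue", "non_fatigue"),
                                    kss = c(7, 2), pvt_ms = c(500, 300)))
  expect_equal(single$kss_sd, c(0, 0))
  expect_error(cohort_stats(tab[0, ]), "empty")
})

small_cv_setup <- function(seed = 11) {
  co <- tiny_cohort(n_subjects = 4, duration_s = 60, seed = seed)
  w <- segment_cohort(co, window_s = 8)
  plan <- make_folds(unique(w$subject_id), "kfold_by_subject", k = 2,
                     seed = seed)
  list(windows = w, plan = plan,
       config = model_config(layers = 4, kernels = 6, kernel_size = 5,
                             bilstm_hidden = 8, epochs = 6, seed = seed))
}

test_that("cross-validation keeps folds subject-disjoint and is reproducible", {
  s <- small_cv_setup()
  rep1 <- run_cv(s$windows, s$config, s$plan)
  expect_equal(sum(rep1$confusion), nrow(s$windows))
  expect_equal(nrow(rep1$fold_metrics), 2)
  expect_equal(rep1$pooled$mse, rep1$pooled$rmse^2, tolerance = 1e-12)
  recomputed <- (rep1$confusion["fatigue", "fatigue"] +
                   rep1$confusion["non_fatigue", "non_fatigue"]) /
    sum(rep1$confusion)
  expect_equal(rep1$pooled$accuracy, recomputed, tolerance = 1e-12)
  # every window of every subject appears exactly once as test data
  counts <- table(rep1$window_predictions$subject_id)
  expect_equal(sum(counts), nrow(s$windows))

  rep2 <- run_cv(s$windows, s$config, s$plan)
  expect_identical(rep1$pooled, rep2$pooled)

  g <- glance(rep1)
  expect_true(all(c("accuracy", "auc", "vote_accuracy") %in% names(g)))
  expect_equal(nrow(tidy(rep1)), 2)
})

test_that("coin-flip labels give chance-level pooled accuracy", {
  s <- small_cv_setup(seed = 23)
  w <- s$windows
  w$label <- ppgfatigue:::with_seed(99,
    sample(c("fatigue", "non_fatigue"), nrow(w), replace = TRUE))
  rep <- suppressWarnings(run_cv(w, s$config, s$plan))
  se <- 0.5 / sqrt(nrow(w))
  expect_lt(abs(rep$pooled$accuracy - 0.5), 3 * se)
})

test_that("grid sweeps report one reproducible row per setting", {
  s <- small_cv_setup(seed = 31)
  grid <- data.frame(layers = c(4L, 5L), kernels = c(4L, 6L))
  out <- suppressWarnings(grid_sweep(s$windows, s$config, grid, s$plan))
  expect_equal(nrow(out), 2)
  expect_true(any(out$best))
  expect_equal(max(out$accuracy), out$accuracy[which(out$best)[1]])
  out2 <- suppressWarnings(grid_sweep(s$windows, s$config, grid, s$plan))
  expect_equal(out$accuracy, out2$accuracy)
})
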