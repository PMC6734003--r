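# toy window table where the label is a deterministic function of mis_0
# (values kept away from the 0.5 boundary so the classes are separable
# with a margin)
toy_windows <- function(n = 200, seed = 1, noise = 0) {
  set.seed(seed)
  mis <- ifelse(runif(n) < 0.5, runif(n, 0, 0.4), runif(n, 0.6, 1))
  data.frame(ref = "ref", center = seq_len(n) + 2L, kmer = "GGACT",
             q_m2 = rnorm(n, 12), q_m1 = rnorm(n, 12),
             q_0 = rnorm(n, 12) - 3 * (mis > 0.5) * (1 - noise),
             q_p1 = rnorm(n, 12), q_p2 = rnorm(n, 12),
             mis_m2 = runif(n, 0, 0.1), mis_m1 = runif(n, 0, 0.1),
             mis_0 = mis, mis_p1 = runif(n, 0, 0.1),
             mis_p2 = runif(n, 0, 0.1),
             del_m2 = runif(n, 0, 0.1), del_m1 = runif(n, 0, 0.1),
             del_0 = runif(n, 0, 0.1), del_p1 = runif(n, 0, 0.1),
             del_p2 = runif(n, 0, 0.1),
             curr_mean = rnorm(n, 100), curr_sd = abs(rnorm(n, 2)),
             cov_min = 50L, complete = TRUE,
             label = ifelse(mis > 0.5, "modified", "unmodified"),
             stringsAsFactors = FALSE)
}

test_that("a separable toy problem is learned perfectly by every kernel", {
  wf <- toy_windows(200, seed = 2)
  for (kn in c("linear", "polynomial", "radial")) {
    fit <- train_svm(wf, feature_set = "mis0", kernels = kn, seed = 3)
    expect_equal(fit$heldout_accuracy, 1.0)
  }
  fit <- train_svm(wf, seed = 3)
  expect_true(fit$selected_kernel %in% c("linear", "polynomial", "radial"))
  expect_equal(fit$selected_kernel,
               names(fit$kernel_accuracy)[which.max(fit$kernel_accuracy)])
  # a window resembling a confidently modified exemplar scores > 0.5
  probe <- wf[wf$mis_0 > 0.9, ][1, ]
  expect_gt(predict(fit, probe), 0.5)
  # duplicated rows get identical probabilities; empty input -> empty output
  two <- predict(fit, rbind(probe, probe))
  expect_equal(two[1], two[2])
  expect_length(predict(fit, wf[0, ]), 0)
})

test_that("shuffled labels give chance-level held-out accuracy", {
  wf <- toy_windows(400, seed = 4)
  set.seed(5)
  wf$label <- sample(wf$label)
  fit <- train_svm(wf, feature_set = "mis0", kernels = "linear", seed = 6)
  expect_gt(fit$heldout_accuracy, 0.35)
  expect_lt(fit$heldout_accuracy, 0.65)
})

test_that("training guards its inputs and records metadata", {
  wf <- toy_windows(100, seed = 7)
  wf1 <- wf[wf$label == "modified", ]
  expect_error(train_svm(wf1), "both")
  small <- rbind(wf[wf$label == "modified", ][1:5, ],
                 wf[wf$label == "unmodified", ][1:30, ])
  fit <- train_svm(small, kernels = "linear", seed = 1)
  expect_match(fit$warnings, "fewer than 10")
  expect_error(predict(fit, wf[, setdiff(names(wf), "mis_0")]), "mis_0")
  # standardization leakage guard: scaling parameters recompute from the
  # training split alone
  fit2 <- train_svm(wf, feature_set = "combined3", kernels = "linear",
                    seed = 11)
  set.seed(11)
  lab <- factor(wf$label, levels = c("unmodified", "modified"))
  idx <- sort(unlist(lapply(levels(lab), function(lv) {
    ii <- which(lab == lv)
    sample(ii, max(1L, round(length(ii) * 0.75)))
  })))
  x <- as.matrix(wf[idx, c("q_0", "mis_0", "del_0")])
  expect_equal(unname(fit2$center), unname(colMeans(x)))
  expect_equal(unname(fit2$scale), unname(apply(x, 2, sd)))
})

test_that("evaluate counts the confusion matrix correctly", {
  r <- evaluate(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$accuracy, 1.0)
  expect_equal(c(r$TP, r$TN, r$FP, r$FN), c(2, 2, 0, 0))
  expect_error(evaluate(numeric(0), numeric(0)), "empty")
  # threshold uses >=
  r2 <- evaluate(c(0.5, 0.4), c(1, 0))
  expect_equal(c(r2$TP, r2$TN), c(1, 1))
  # random instances vs brute-force confusion counting
  set.seed(8)
  for (i in 1:20) {
    p <- runif(30); y <- runif(30) > 0.5
    r3 <- evaluate(p, y)
    pred <- p >= 0.5
    expect_equal(c(r3$TP, r3$TN, r3$FP, r3$FN),
                 c(sum(pred & y), sum(!pred & !y),
                   sum(pred & !y), sum(!pred & y)))
  }
})

test_that("AUC equals pairwise concordance and behaves at the extremes", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
  # 6-point mixed example against the O(n^2) oracle
  p6 <- c(0.1, 0.4, 0.35, 0.8, 0.35, 0.9); y6 <- c(0, 0, 1, 1, 0, 1)
  expect_equal(roc_auc(p6, y6)$auc, oracle_auc(p6, y6))
  set.seed(9)
  for (i in 1:100) {
    n <- sample(6:25, 1)
    p <- round(runif(n), 2)  # rounding forces ties
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_auc(p, y)$auc, oracle_auc(p, y), info = paste("case", i))
  }
  # invariance under strictly monotone transforms
  p <- runif(40); y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  expect_equal(roc_auc(plogis(3 * p - 1), y)$auc, roc_auc(p, y)$auc)
})

test_that("AUC and curve agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  p <- runif(200); y <- rbinom(200, 1, 0.4)
  ours <- roc_auc(p, y)
  theirs <- pROC::roc(y, p, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(theirs)), tolerance = 1e-12)
})

test_that("accuracy at the Youden-optimal threshold dominates threshold 0.5", {
  set.seed(12)
  p <- runif(300); y <- rbinom(300, 1, plogis(4 * (p - 0.3)))
  rc <- roc_auc(p, y)
  j <- which.max(rc$curve$tpr - rc$curve$fpr)
  thr <- rc$curve$threshold[j]
  acc_j <- evaluate(p, y, threshold = thr)$accuracy
  acc_5 <- evaluate(p, y, threshold = 0.5)$accuracy
  expect_gte(acc_j, acc_5 - 1e-9)
})
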