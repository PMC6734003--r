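#' Confusion-matrix performance report
#'
#' Thresholds probabilities at `threshold` (`>=` means "modified") and counts
#' true/false positives and negatives. Accuracy is the sum of correct
#' modified and unmodified predictions over all windows tested; recovery
#' (sensitivity) is TP over all truly modified; specificity is TN over all
#' truly unmodified; ppv is TP over predicted positives.
#'
#' @param probabilities Numeric vector of modification probabilities.
#' @param labels Logical/0-1 vector (TRUE = modified), same length.
#' @param threshold Decision threshold (default 0.5).
#' @param auc If `TRUE`, also compute the AUC (requires both classes).
#' @return Object of class `"performance_report"`: list with TP, TN, FP, FN,
#'   accuracy, sensitivity (= recovery), specificity, ppv, and optionally auc.
#' @export
evaluate <- function(probabilities, labels, threshold = 0.5, auc = FALSE) {
  if (length(probabilities) == 0) stop("empty input")
  stopifnot(length(probabilities) == length(labels))
  lab <- as.logical(labels)
  pred <- probabilities >= threshold
  TP <- sum(pred & lab); TN <- sum(!pred & !lab)
  FP <- sum(pred & !lab); FN <- sum(!pred & lab)
  rep_ <- list(TP = TP, TN = TN, FP = FP, FN = FN,
               accuracy = (TP + TN) / (TP + TN + FP + FN),
               sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
               specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
               ppv = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
               threshold = threshold)
  rep_$recovery <- rep_$sensitivity
  if (auc) rep_$auc <- roc_auc(probabilities, lab)$auc
  class(rep_) <- "performance_report"
  rep_
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("performance: TP %d  TN %d  FP %d  FN %d\n",
              x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("  accuracy %.3f  recovery %.3f  specificity %.3f  ppv %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$ppv))
  if (!is.null(x$auc)) cat(sprintf("  AUC %.3f\n", x$auc))
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC is computed as the Mann-Whitney concordance probability (rank-based;
#' ties count one half). The curve reports (FPR, TPR) at every distinct score
#' threshold, from (0, 0) to (1, 1).
#'
#' @param probabilities Numeric scores (higher = more likely modified).
#' @param labels Logical/0-1 truth vector; both classes must be present.
#' @return List with `curve` (data frame: threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(probabilities, labels) {
  lab <- as.logical(labels)
  stopifnot(length(probabilities) == length(lab))
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(probabilities)  # midranks handle ties
  auc <- (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(probabilities), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(lab & probabilities >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!lab & probabilities >= t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr),
                      fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  list(curve = curve, auc = auc)
}

#' AUC as a function of methylation ratio
#'
#' For each requested methylation ratio, mixes modified and unmodified read
#' sets with [mix_read_sets()], recomputes per-site and window features, and
#' scores the candidate windows with the trained model. Every candidate site
#' of the mixture is partially modified, so the ROC contrasts the mixture
#' sample (positives) against an independent unmodified control sample of
#' the same depth (negatives), window by window. At ratio 0 the two samples
#' are exchangeable and AUC is expected near 0.5.
#'
#' @param model A fitted [train_svm()] model.
#' @param modified,unmodified [simulate_reads()] results for the fully
#'   modified and unmodified read pools (per-base and event tables); the
#'   unmodified pool must hold at least `2 * n_reads` reads so the control
#'   sample shares no read with the mixture.
#' @param reference Named character vector of length 1 (the reference used).
#' @param candidate_centers Window centers to score (e.g. all single-A
#'   A-centered windows).
#' @param ratios Methylation ratios (default the nine standard ratios 0, 5,
#'   10, 25, 50, 75, 90, 95 and 100%).
#' @param n_reads Reads per mixture (and per control sample).
#' @param seed Integer RNG seed.
#' @return Data frame with columns `ratio`, `auc`, `n_sites`.
#' @export
mixture_curve <- function(model, modified, unmodified, reference,
                          candidate_centers,
                          ratios = c(0, 0.05, 0.10, 0.25, 0.50,
                                     0.75, 0.90, 0.95, 1),
                          n_reads = 100L, seed = 1L) {
  stopifnot(length(reference) == 1, !is.null(names(reference)))
  if (length(unique(unmodified$per_base$read_id)) < 2 * n_reads)
    stop("unmodified pool must hold at least 2 * n_reads reads ",
         "(mixture plus disjoint control)")
  score_sample <- function(per_base, ids, sim_pool) {
    ev <- NULL
    for (i in seq_along(sim_pool))
      ev <- rbind(ev, sim_pool[[i]]$events[
        sim_pool[[i]]$events$read_id %in% ids, , drop = FALSE])
    sites <- per_site_features(per_base, reference)
    wf <- window_features(sites, current_window_stats(ev))
    wf <- wf[wf$center %in% candidate_centers, , drop = FALSE]
    predict(model, wf)
  }
  out <- data.frame(ratio = ratios, auc = NA_real_, n_sites = NA_integer_)
  for (i in seq_along(ratios)) {
    mix <- mix_read_sets(modified$per_base, unmodified$per_base,
                         fraction = ratios[i], n_reads = n_reads,
                         seed = seed + i)
    ids <- attr(mix, "read_ids")
    used <- unlist(ids)
    pool <- setdiff(unique(unmodified$per_base$read_id), used)
    set.seed(seed + 1000L + i)
    ctrl_ids <- sample(pool, n_reads)
    ctrl <- unmodified$per_base[unmodified$per_base$read_id %in% ctrl_ids, ,
                                drop = FALSE]
    pr_mix <- score_sample(mix, used, list(modified, unmodified))
    pr_ctl <- score_sample(ctrl, ctrl_ids, list(unmodified))
    pr <- c(pr_mix, pr_ctl)
    truth <- rep(c(TRUE, FALSE), c(length(pr_mix), length(pr_ctl)))
    ok <- !is.na(pr)
    out$auc[i] <- roc_auc(pr[ok], truth[ok])$auc
    out$n_sites[i] <- sum(ok)
  }
  out
}
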