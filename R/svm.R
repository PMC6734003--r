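#' Train an SVM classifier of modified versus unmodified 5-mer windows
#'
#' Fits support vector machines over window feature vectors with a stratified
#' train/test split, per-feature standardization estimated on the training
#' split only, and Platt-style probability outputs. Every requested kernel is
#' fitted and the one with the highest held-out accuracy is retained (ties go
#' to the earlier kernel in `kernels`).
#'
#' Windows whose 5-mer contains more than one A are expected to have been
#' excluded upstream (a fully modified construct methylates every A, so
#' multi-A k-mers carry several modifications at once and are not biological).
#'
#' @param windows Window feature table from [window_features()] with a
#'   two-level `label` column (`"modified"` / `"unmodified"`).
#' @param feature_set One of `"combined3"` (quality, mismatch, deletion at
#'   position 0; the default working model), `"extended15"` (all three at
#'   -2..+2), `"q0"`, `"mis0"`, `"del0"`, `"curr_mean"`, `"curr_sd"`,
#'   `"curr2"`.
#' @param kernels Kernels to compare, subset of
#'   `c("linear", "polynomial", "radial")`.
#' @param train_fraction Fraction of windows used for training (default 0.75).
#' @param seed Integer RNG seed for the split.
#' @param cost SVM cost parameter passed to [e1071::svm()] (library default).
#' @return Object of class `"epierr_svm"`: the selected fit, standardization
#'   parameters, per-kernel held-out accuracies, and split metadata.
#' @export
train_svm <- function(windows, feature_set = "combined3",
                      kernels = c("linear", "polynomial", "radial"),
                      train_fraction = 0.75, seed = 1L, cost = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  kernels <- match.arg(kernels, c("linear", "polynomial", "radial"),
                       several.ok = TRUE)
  cols <- feature_columns(feature_set)
  missing_cols <- setdiff(cols, names(windows))
  if (length(missing_cols))
    stop("windows lack feature columns: ", paste(missing_cols, collapse = ", "))
  lab <- windows$label
  keep <- !is.na(lab) & stats::complete.cases(windows[, cols, drop = FALSE])
  windows <- windows[keep, , drop = FALSE]
  lab <- factor(windows$label, levels = c("unmodified", "modified"))
  if (nlevels(droplevels(lab)) < 2)
    stop("training requires both modified and unmodified windows")
  warnings_meta <- character(0)
  if (any(table(lab) < 10))
    warnings_meta <- c(warnings_meta,
                       "fewer than 10 windows in at least one class")
  set.seed(seed)
  idx_train <- unlist(lapply(levels(lab), function(lv) {
    ii <- which(lab == lv)
    sample(ii, max(1L, round(length(ii) * train_fraction)))
  }))
  idx_train <- sort(idx_train)
  x <- as.matrix(windows[, cols, drop = FALSE])
  center <- colMeans(x[idx_train, , drop = FALSE])
  scale_ <- apply(x[idx_train, , drop = FALSE], 2, stats::sd)
  scale_[scale_ == 0 | is.na(scale_)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  xtr <- xs[idx_train, , drop = FALSE]
  xte <- xs[-idx_train, , drop = FALSE]
  ytr <- lab[idx_train]; yte <- lab[-idx_train]

  fits <- list(); acc <- stats::setNames(numeric(length(kernels)), kernels)
  for (kn in kernels) {
    set.seed(seed)  # probability calibration uses internal CV
    fit <- e1071::svm(xtr, ytr, kernel = kn, cost = cost, scale = FALSE,
                      probability = TRUE)
    pr <- attr(stats::predict(fit, xte, probability = TRUE),
               "probabilities")[, "modified"]
    acc[kn] <- mean((pr >= 0.5) == (yte == "modified"))
    fits[[kn]] <- fit
  }
  selected <- kernels[which.max(acc)]
  obj <- structure(list(
    feature_set = feature_set, features = cols,
    selected_kernel = selected, fit = fits[[selected]],
    center = center, scale = scale_,
    kernel_accuracy = acc, heldout_accuracy = acc[[selected]],
    n_train = length(idx_train), n_test = nrow(xs) - length(idx_train),
    train_fraction = train_fraction, cost = cost, seed = seed,
    warnings = warnings_meta,
    heldout = list(prob = attr(stats::predict(fits[[selected]], xte,
                                              probability = TRUE),
                               "probabilities")[, "modified"],
                   label = yte)),
    class = "epierr_svm")
  obj
}

#' @export
print.epierr_svm <- function(x, ...) {
  cat("SVM window classifier (", x$feature_set, ": ",
      paste(x$features, collapse = ", "), ")\n", sep = "")
  cat("  kernel:", x$selected_kernel,
      sprintf("(held-out accuracy %.3f on %d windows)\n",
              x$heldout_accuracy, x$n_test))
  invisible(x)
}

#' @export
summary.epierr_svm <- function(object, ...) {
  cat("SVM window classifier\n")
  cat("  feature set :", object$feature_set, "\n")
  cat("  features    :", paste(object$features, collapse = ", "), "\n")
  cat("  n train/test:", object$n_train, "/", object$n_test,
      sprintf("(train fraction %.2f, seed %d)\n", object$train_fraction,
              object$seed))
  cat("  kernel accuracies (held out):\n")
  for (kn in names(object$kernel_accuracy))
    cat(sprintf("    %-10s %.3f%s\n", kn, object$kernel_accuracy[[kn]],
                if (kn == object$selected_kernel) "  <- selected" else ""))
  if (length(object$warnings))
    cat("  warnings:", paste(object$warnings, collapse = "; "), "\n")
  invisible(object)
}

#' Predict modification probabilities for windows
#'
#' @param object A fitted [train_svm()] model.
#' @param newdata Window feature table exposing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities of "modified", one per row of
#'   `newdata`; rows with missing features get `NA` and are listed in the
#'   `"skipped"` attribute with the reason.
#' @export
predict.epierr_svm <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols))
    stop("newdata lacks feature columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(newdata) == 0) return(numeric(0))
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  ok <- stats::complete.cases(x)
  out <- rep(NA_real_, nrow(x))
  if (any(ok)) {
    xs <- sweep(sweep(x[ok, , drop = FALSE], 2, object$center), 2,
                object$scale, "/")
    pr <- attr(stats::predict(object$fit, xs, probability = TRUE),
               "probabilities")[, "modified"]
    out[ok] <- pr
  }
  if (any(!ok))
    attr(out, "skipped") <- data.frame(row = which(!ok),
                                       reason = "missing feature value")
  out
}

#' Alias for [predict.epierr_svm()]
#' @param model A fitted [train_svm()] model.
#' @param windows Window feature table.
#' @return Probability vector, as for the predict method.
#' @export
predict_proba <- function(model, windows) predict(model, windows)

#' @export
coef.epierr_svm <- function(object, ...) {
  if (object$selected_kernel != "linear") {
    message("coefficients are only available for the linear kernel")
    return(NULL)
  }
  w <- drop(crossprod(object$fit$coefs, object$fit$SV))
  c(w, `(intercept)` = -object$fit$rho)
}

#' @export
plot.epierr_svm <- function(x, ...) {
  rc <- roc_auc(x$heldout$prob, x$heldout$label == "modified")
  plot(rc$curve$fpr, rc$curve$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("Held-out ROC (%s, AUC = %.3f)", x$feature_set,
                      rc$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(rc)
}
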