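#' Equal-prior linear discriminant classification with LOOCV
#'
#' Linear discriminant analysis written out from the Gaussian
#' equal-covariance model: group mean vectors and a pooled within-group
#' covariance are estimated, and with equal prior probabilities a case
#' is assigned to the group with the highest linear discriminant score
#' `x' W mu_k - mu_k' W mu_k / 2`, `W` the inverse pooled covariance --
#' equivalently, the smallest Mahalanobis distance to a group centroid.
#' Ties are broken toward the earlier group label, deterministically.
#'
#' Classification success measured on the training data (resubstitution)
#' is optimistic when the predictor suite is large relative to the number
#' of cases, so leave-one-out cross-validation is run as well: each case
#' is serially excluded, the means and pooled covariance are refit
#' without it (no downdating shortcut -- slower but unambiguous), and the
#' case is predicted by the discriminant in which it had no influence.
#'
#' @param x numeric feature matrix (cases x features).
#' @param grouping factor or character vector of class labels.
#' @param shrink shrinkage weight in `[0, 1]` pulling the pooled
#'   covariance toward its diagonal (default 0, i.e. none); a warning is
#'   emitted whenever the feature count reaches the smallest group size,
#'   the regime where shrinkage may be needed.
#' @param loocv run leave-one-out cross-validation (default `TRUE`).
#' @return Object of class `lda_loocv`: `means`, `pooled_cov`, `priors`,
#'   `levels`, `resub` (predicted labels), `confusion_resub`,
#'   `pct_correct_resub`, and when `loocv` the `cv`, `confusion_cv`,
#'   `pct_correct_cv` counterparts.
#' @export
lda_loocv <- function(x, grouping, shrink = 0, loocv = TRUE) {
  x <- as.matrix(x)
  g <- factor(grouping)
  if (nlevels(g) < 2) stop("need at least 2 classes")
  if (anyNA(x)) stop("features contain NA")
  n_g <- table(g)
  if (loocv && any(n_g < 2)) {
    stop("leave-one-out cross-validation requires every group to have ",
         "at least 2 members")
  }
  if (ncol(x) >= min(n_g)) {
    warning(sprintf(
      "feature count (%d) >= smallest group size (%d); pooled covariance may be unstable (see 'shrink')",
      ncol(x), min(n_g)))
  }
  fit <- .lda_train(x, g, shrink)
  resub <- .lda_classify(x, fit)
  out <- list(means = fit$means, pooled_cov = fit$S,
              priors = stats::setNames(rep(1 / nlevels(g), nlevels(g)),
                                       levels(g)),
              levels = levels(g), shrink = shrink,
              resub = resub,
              confusion_resub = table(actual = g, predicted = resub),
              pct_correct_resub = 100 * mean(resub == g))
  if (loocv) {
    cv <- factor(rep(NA_character_, nrow(x)), levels = levels(g))
    for (i in seq_len(nrow(x))) {
      fit_i <- .lda_train(x[-i, , drop = FALSE], g[-i], shrink,
                          levels_all = levels(g))
      cv[i] <- .lda_classify(x[i, , drop = FALSE], fit_i)
    }
    out$cv <- cv
    out$confusion_cv <- table(actual = g, predicted = cv)
    out$pct_correct_cv <- 100 * mean(cv == g)
  }
  class(out) <- "lda_loocv"
  out
}

.lda_train <- function(x, g, shrink, levels_all = levels(g)) {
  g <- factor(g, levels = levels_all)
  k <- nlevels(g)
  p <- ncol(x)
  means <- matrix(0, k, p, dimnames = list(levels(g), colnames(x)))
  Sp <- matrix(0, p, p)
  for (lev in levels(g)) {
    xi <- x[g == lev, , drop = FALSE]
    means[lev, ] <- colMeans(xi)
    if (nrow(xi) > 1) {
      Sp <- Sp + crossprod(sweep(xi, 2, means[lev, ]))
    }
  }
  Sp <- Sp / (nrow(x) - k)
  if (shrink > 0) Sp <- (1 - shrink) * Sp + shrink * diag(diag(Sp), p)
  W <- tryCatch(solve(Sp), error = function(e)
    stop("singular pooled covariance; set 'shrink' > 0"))
  list(means = means, S = Sp, W = W, levels = levels(g))
}

.lda_classify <- function(x, fit) {
  # equal priors: maximize x'W mu_k - mu_k'W mu_k / 2; ties -> earlier level
  D <- x %*% fit$W %*% t(fit$means) -
    matrix(rep(0.5 * rowSums((fit$means %*% fit$W) * fit$means),
               each = nrow(x)), nrow(x))
  factor(fit$levels[max.col(D, ties.method = "first")],
         levels = fit$levels)
}

#' @export
print.lda_loocv <- function(x, ...) {
  cat(sprintf("LDA (equal priors): %d classes, %d features\n",
              length(x$levels), ncol(x$means)))
  cat(sprintf("  resubstitution: %.1f%% correct\n", x$pct_correct_resub))
  if (!is.null(x$pct_correct_cv)) {
    cat(sprintf("  leave-one-out:  %.1f%% correct\n", x$pct_correct_cv))
  }
  invisible(x)
}

#' @export
predict.lda_loocv <- function(object, newdata, ...) {
  fit <- list(means = object$means,
              S = object$pooled_cov,
              W = solve(object$pooled_cov),
              levels = object$levels)
  .lda_classify(as.matrix(newdata), fit)
}
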