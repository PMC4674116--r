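#' Nested effects design
#'
#' Effects-coded columns for an inner factor nested within an outer
#' factor: within each outer level, the inner levels occurring there are
#' effects-coded (k-1 columns), zero for specimens outside that outer
#' level.  With two species inside each feeding orientation this yields
#' one column per orientation, two model degrees of freedom in total.
#'
#' @param outer,inner factor or character vectors of equal length.
#' @return Numeric design matrix with `sum(k_i - 1)` columns.
#' @export
nested_effects <- function(outer, inner) {
  outer <- as.character(outer); inner <- as.character(inner)
  X <- NULL
  for (lev in unique(outer)) {
    idx <- outer == lev
    inner_here <- inner[idx]
    if (length(unique(inner_here)) < 2) next
    Xi <- matrix(0, length(outer), length(unique(inner_here)) - 1)
    Xi[idx, ] <- effects_design(inner_here)
    colnames(Xi) <- paste0(lev, ":", colnames(effects_design(inner_here)))
    X <- cbind(X, Xi)
  }
  if (is.null(X)) stop("no nested structure: inner factor constant within outer levels")
  X
}

rao_F <- function(lambda, p, q, v) {
  # Rao's approximate (sometimes exact) F for Wilks' lambda.
  # p: number of responses, q: hypothesis df, v: error df.
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1 <- p * q
  df2 <- s * (v - (p - q + 1) / 2) - (p * q - 2) / 2
  lam_s <- lambda^(1 / s)
  Fval <- ((1 - lam_s) / lam_s) * (df2 / df1)
  list(F = Fval, df1 = df1, df2 = df2, s = s,
       p_value = stats::pf(Fval, df1, df2, lower.tail = FALSE),
       eta_sq = 1 - lam_s,
       exact = s %in% c(1, 2) || p <= 2 || q <= 2)
}

#' Wilks' lambda MANOVA with sequential sums of squares
#'
#' Multivariate analysis of variance computed from first principles.
#' Effects enter in the order given (sequential, type I, sums of squares
#' and cross-products): each effect's hypothesis SSCP `H` is the drop in
#' residual SSCP when its columns join the design; the error SSCP `E`
#' comes from the full model.  Per effect the statistic is Wilks'
#' `Lambda = det(E) / det(E + H)`, converted to Rao's F:
#' `s = sqrt((p^2 q^2 - 4)/(p^2 + q^2 - 5))` (1 when undefined),
#' `F = ((1 - Lambda^(1/s)) / Lambda^(1/s)) * (df2 / df1)` with
#' `df1 = p q`, `df2 = s (v - (p - q + 1)/2) - (p q - 2)/2`, exact when
#' `s` is 1 or 2.  Effect strength is partial eta squared,
#' `1 - Lambda^(1/s)`.
#'
#' When `prune` is `TRUE`, effects whose names are listed in `prunable`
#' (typically covariate-by-factor interactions) are removed
#' hierarchically: while any prunable effect has `P >= threshold` the
#' least significant one is dropped and the model refit, mirroring the
#' usual treatment of non-significant allometry interactions.
#'
#' @param Y numeric response matrix (specimens x responses), complete.
#' @param effects named, ordered list of design-matrix blocks (each a
#'   numeric matrix or column vector; no intercept -- one is added).
#' @param prune logical; hierarchically remove non-significant prunable
#'   effects.
#' @param prunable character vector of effect names eligible for
#'   removal (default: none).
#' @param threshold p-value at or above which a prunable effect is
#'   removed (default 0.05).
#' @return Object of class `wilks_manova`: `table` (data frame with one
#'   row per effect: `lambda`, `F`, `df1`, `df2`, `s`, `p_value`,
#'   `eta_sq`, `exact`), `E`, `H` (named list), `error_df`, `n`,
#'   `pruned` (character vector of removed effects), `canonical`
#'   (per-effect eigenvectors of `solve(E) %*% H`).
#' @export
wilks_manova <- function(Y, effects, prune = FALSE,
                         prunable = character(0), threshold = 0.05) {
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("responses contain NA; impute first")
  effects <- lapply(effects, function(b) {
    b <- as.matrix(b); storage.mode(b) <- "double"; b
  })
  if (is.null(names(effects)) || any(!nzchar(names(effects)))) {
    stop("effects must be a named list")
  }
  pruned <- character(0)
  repeat {
    fit <- .manova_core(Y, effects)
    if (!prune) break
    cand <- intersect(prunable, rownames(fit$table))
    ps <- fit$table[cand, "p_value"]
    drop_idx <- cand[ps >= threshold]
    if (length(drop_idx) == 0) break
    worst <- drop_idx[which.max(fit$table[drop_idx, "p_value"])]
    pruned <- c(pruned, worst)
    effects <- effects[setdiff(names(effects), worst)]
  }
  fit$pruned <- pruned
  fit$call <- match.call()
  class(fit) <- "wilks_manova"
  fit
}

.manova_core <- function(Y, effects) {
  n <- nrow(Y); p <- ncol(Y)
  X <- matrix(1, n, 1)
  Xfull <- cbind(X, do.call(cbind, effects))
  rk_full <- qr(Xfull)$rank
  v <- n - rk_full
  if (v <= 0) stop("no error degrees of freedom: model saturated")
  res_full <- stats::lm.fit(Xfull, Y)$residuals
  E <- crossprod(res_full)
  if (p > 1) {
    dE <- determinant(E, logarithm = TRUE)
    if (dE$sign <= 0 || !is.finite(dE$modulus)) {
      stop("singular error SSCP: fewer responses or more specimens needed")
    }
  } else if (E[1, 1] <= 0) {
    E[1, 1] <- 0
  }
  tab <- NULL
  Hs <- list(); canon <- list()
  res_prev <- stats::lm.fit(X, Y)$residuals
  rk_prev <- 1L
  for (nm in names(effects)) {
    X <- cbind(X, effects[[nm]])
    rk_now <- qr(X)$rank
    q <- rk_now - rk_prev
    if (q == 0) stop("effect '", nm, "' adds no degrees of freedom")
    res_now <- stats::lm.fit(X, Y)$residuals
    H <- crossprod(res_prev) - crossprod(res_now)
    H <- (H + t(H)) / 2
    Hs[[nm]] <- H
    lambda <- .wilks_lambda(E, H)
    rf <- rao_F(lambda, p, q, v)
    tab <- rbind(tab, data.frame(
      effect = nm, lambda = lambda, F = rf$F, df1 = rf$df1, df2 = rf$df2,
      s = rf$s, p_value = rf$p_value, eta_sq = rf$eta_sq,
      exact = rf$exact, stringsAsFactors = FALSE))
    canon[[nm]] <- tryCatch(canonical_vectors(E, H),
                            error = function(e) NULL)
    res_prev <- res_now; rk_prev <- rk_now
  }
  rownames(tab) <- tab$effect
  list(table = tab, E = E, H = Hs, error_df = v, n = n, p = p,
       canonical = canon)
}

.wilks_lambda <- function(E, H) {
  p <- ncol(E)
  if (p == 1) return(E[1, 1] / (E[1, 1] + H[1, 1]))
  dE <- determinant(E, logarithm = TRUE)
  dEH <- determinant(E + H, logarithm = TRUE)
  exp(as.numeric(dE$modulus - dEH$modulus))
}

#' @export
print.wilks_manova <- function(x, digits = 4, ...) {
  cat(sprintf("Wilks' lambda MANOVA: %d specimens, %d responses, error df %d\n",
              x$n, x$p, x$error_df))
  tab <- x$table
  tab$lambda <- signif(tab$lambda, digits)
  tab$F <- signif(tab$F, digits)
  tab$p_value <- signif(tab$p_value, 3)
  tab$eta_sq <- signif(tab$eta_sq, 3)
  print(tab[, c("effect", "lambda", "F", "df1", "df2", "p_value",
                "eta_sq", "exact")], row.names = FALSE)
  if (length(x$pruned)) {
    cat("pruned (P >= 0.05):", paste(x$pruned, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.wilks_manova <- function(object, ...) object$table

#' Canonical axes of a MANOVA effect
#'
#' Eigenvectors of `solve(E) %*% H`, ordered by descending (real)
#' eigenvalue, with the sign convention that the largest-magnitude
#' loading of each axis is positive.  For a one-degree-of-freedom effect
#' there is exactly one nonzero eigenvalue.
#'
#' @param E error SSCP matrix (invertible).
#' @param H hypothesis SSCP matrix for the effect.
#' @param tol relative tolerance on imaginary parts before erroring.
#' @return List: `vectors` (p x p, columns ordered), `eigenvalues`.
#' @export
canonical_vectors <- function(E, H, tol = 1e-8) {
  M <- solve(E, H)
  ev <- eigen(M)
  scale_ref <- max(abs(ev$values), 1e-300)
  if (max(abs(Im(ev$values))) > tol * scale_ref) {
    stop("complex eigenvalues beyond tolerance in canonical decomposition")
  }
  vals <- Re(ev$values)
  vecs <- Re(ev$vectors)
  ord <- order(vals, decreasing = TRUE)
  vals <- vals[ord]; vecs <- vecs[, ord, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- rownames(H)
  list(vectors = vecs, eigenvalues = vals)
}

#' Multivariate regression ordination scores
#'
#' Projects centred responses onto the multivariate regression vector
#' `Y ~ x`: with `beta` the per-response partial regression coefficients
#' of a single effect column, scores are `center(Y) %*% beta / ||beta||`.
#' Unlike canonical axes these are not distorted by patterns in the error
#' covariance, which is why they are preferred for display when a
#' loading flips direction between the canonical space and the least
#' squares means.
#'
#' @param Y response matrix.
#' @param x numeric effect column (or one-column matrix); full rank
#'   after centring.
#' @param other optional matrix of columns to partial out first (e.g.
#'   other model effects), so `beta` is a partial coefficient vector.
#' @return List: `scores` (length n), `coefficients` (per response),
#'   used for vector plots.
#' @export
regression_scores <- function(Y, x, other = NULL) {
  Y <- as.matrix(Y)
  x <- as.matrix(x)
  if (ncol(x) != 1) stop("x must be a single effect column")
  Yc <- sweep(Y, 2, colMeans(Y))
  xc <- x - mean(x)
  if (!is.null(other)) {
    oc <- sweep(as.matrix(other), 2, colMeans(as.matrix(other)))
    xc <- stats::lm.fit(cbind(1, oc), xc)$residuals
    Yc <- stats::lm.fit(cbind(1, oc), Yc)$residuals
  }
  if (sum(xc^2) < 1e-12) stop("effect column is constant (rank deficient)")
  beta <- drop(crossprod(Yc, xc) / sum(xc^2))
  nb <- sqrt(sum(beta^2))
  if (nb == 0) stop("zero regression vector")
  list(scores = drop(Yc %*% beta) / nb, coefficients = beta)
}
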