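#' One-way analysis of variance with least-squares means
#'
#' Standard one-way decomposition fitted through `stats::lm`, reported
#' with the quantities the craniometric analyses use: the F ratio with
#' its degrees of freedom, the p-value, adjusted R-squared, and the
#' per-group least-squares means (for a one-way design, the group
#' means).  If the within-group variance is exactly zero while groups
#' differ, F is reported as `Inf` and flagged.
#'
#' @param y numeric response vector.
#' @param groups factor or character vector of group labels.
#' @return Object of class `cm_anova`: `F`, `df1`, `df2`, `p_value`,
#'   `r2_adj`, `ls_means` (named vector), `n_by_group`, `ms_within`,
#'   `infinite_F` flag, plus the underlying `lm` fit.
#' @export
anova_fit <- function(y, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  fit <- stats::lm(y ~ g)
  an <- stats::anova(fit)
  ssb <- an[1, "Sum Sq"]; ssw <- an[2, "Sum Sq"]
  df1 <- an[1, "Df"]; df2 <- an[2, "Df"]
  null_between <- ssb <= .Machine$double.eps * max(ssw, 1)
  infinite <- !null_between && ssw <= .Machine$double.eps * max(ssb, 1)
  Fval <- if (null_between) 0 else if (infinite) Inf else an[1, "F value"]
  pval <- if (null_between) 1 else if (infinite) 0 else an[1, "Pr(>F)"]
  res <- list(F = Fval, df1 = df1, df2 = df2, p_value = pval,
              r2_adj = summary(fit)$adj.r.squared,
              ls_means = c(tapply(y, g, mean)),
              n_by_group = as.vector(table(g)),
              groups = levels(g),
              ms_within = ssw / df2,
              infinite_F = infinite,
              fit = fit)
  class(res) <- "cm_anova"
  res
}

#' @export
print.cm_anova <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d,%d) = %.4g, P = %.3g, adj. R^2 = %.3f\n",
              x$df1, x$df2, x$F, x$p_value, x$r2_adj))
  cat("LS means:\n"); print(round(x$ls_means, 4))
  invisible(x)
}

#' Tukey's HSD pairwise contrasts
#'
#' Studentized-range post hoc contrasts after a one-way ANOVA, with the
#' Tukey-Kramer denominator for unequal group sizes:
#' `q_ij = |m_i - m_j| / sqrt(MSW (1/n_i + 1/n_j) / 2)`, adjusted
#' p-values from the studentized range distribution with `k` groups and
#' the ANOVA's error df.
#'
#' @param y numeric response vector.
#' @param groups group labels.
#' @param alpha significance level for the `significant` flag.
#' @return Data frame of class `tukey_hsd`, one row per pair:
#'   `group_1`, `group_2`, `diff`, `q`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(y, groups, alpha = 0.05) {
  a <- anova_fit(y, groups)
  k <- length(a$groups)
  if (k < 2) stop("need at least 2 groups")
  out <- NULL
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      d <- a$ls_means[i] - a$ls_means[j]
      se <- sqrt(a$ms_within * (1 / a$n_by_group[i] + 1 / a$n_by_group[j]) / 2)
      q <- abs(d) / se
      p <- stats::ptukey(q, nmeans = k, df = a$df2, lower.tail = FALSE)
      out <- rbind(out, data.frame(
        group_1 = a$groups[i], group_2 = a$groups[j],
        diff = unname(d), q = unname(q), p_adj = unname(p),
        significant = unname(p < alpha), stringsAsFactors = FALSE))
    }
  }
  class(out) <- c("tukey_hsd", "data.frame")
  attr(out, "alpha") <- alpha
  out
}
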