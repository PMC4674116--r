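#' Default shape-variable set for the published analyses
#'
#' The form and shape MANOVAs use 24 shape inputs, which after the
#' one-dimension PCA reduction leave 23 shape components (and 24 form
#' responses once log GMS joins them).  The set is all registry traits
#' except zygoma height (`ZH`), the smallest measure and nearly
#' collinear with zygoma width; OSA enters as its square root.
#'
#' @return Character vector of 24 trait codes.
#' @export
analysis_shape_traits <- function() setdiff(shape_traits(), "ZH")

#' Species-level craniometric analysis
#'
#' End-to-end pipeline over a four-species measurement table:
#' imputation of missing cells (EM, species design) when needed; log
#' transform and size/shape decomposition; one-way ANOVA of log GMS by
#' species with Tukey contrasts; form MANOVA (23 shape components plus
#' log GMS as responses) and shape MANOVA (shape components only, log
#' GMS covariate with hierarchically pruned covariate-by-factor
#' interactions), both with feeding orientation and species nested in
#' feeding orientation as effects; equal-prior LDA with LOOCV for
#' feeding orientation and species on form and shape data; and the
#' functional jaw indices with their ANOVAs and Tukey tables.
#'
#' @param table a `measurement_table` with 4 species.
#' @param shape_subset trait codes entering the shape variables
#'   (default [analysis_shape_traits()]).
#' @param osa_scale scale for the OSA size adjustment, see
#'   [residual_osa()].
#' @return A list of class `craniomorph_report`; see Details.
#' @export
run_species_analysis <- function(table, shape_subset = analysis_shape_traits(),
                                 osa_scale = "raw") {
  lb <- specimen_labels(table)
  if (length(unique(lb$species)) < 2) stop("need multiple species")
  if (anyNA(lb$feeding_mode)) stop("missing feeding-mode labels")
  validation <- validate_measurements(table)
  imput <- NULL
  if (any(is.na(table))) {
    imp <- impute_measurements(table, group = "species")
    table <- imp$table
    imput <- imp$fit
  }
  decomp <- size_shape(table, shape_subset = shape_subset)
  lb <- decomp$labels
  feeding <- factor(lb$feeding_mode, levels = c("mouth", "hand"))
  species <- lb$species

  size_anova <- anova_fit(decomp$log_gms, species)
  size_tukey <- tukey_hsd(decomp$log_gms, species)

  X_feed <- effects_design(feeding)
  X_nest <- nested_effects(feeding, species)
  shape_Y <- decomp$pca$scores
  form_Y <- cbind(shape_Y, log_gms = decomp$log_gms)

  form_manova <- wilks_manova(form_Y, list(
    feeding_orientation = X_feed,
    `species(feeding)` = X_nest))

  size_c <- decomp$log_gms - mean(decomp$log_gms)
  shape_manova <- wilks_manova(shape_Y, list(
    feeding_orientation = X_feed,
    `species(feeding)` = X_nest,
    size = size_c,
    `size:feeding` = X_feed * size_c,
    `size:species(feeding)` = X_nest * size_c),
    prune = TRUE,
    prunable = c("size:feeding", "size:species(feeding)"))

  ld <- list(
    feeding_form = lda_loocv(form_Y, feeding),
    feeding_shape = lda_loocv(shape_Y, feeding),
    species_form = lda_loocv(form_Y, species),
    species_shape = lda_loocv(shape_Y, species))

  fx <- functional_indices(table, osa_scale = osa_scale)
  functional <- list(
    indices = fx,
    mbi_anova = anova_fit(fx$mbi, species),
    mbi_tukey = tukey_hsd(fx$mbi, species),
    ma_masseter_anova = anova_fit(fx$asin_ma_masseter, species),
    ma_masseter_anova_raw = anova_fit(fx$ma_masseter, species),
    ma_masseter_tukey = tukey_hsd(fx$asin_ma_masseter, species),
    ma_temporalis_anova = anova_fit(fx$asin_ma_temporalis, species),
    ma_temporalis_anova_raw = anova_fit(fx$ma_temporalis, species),
    ma_temporalis_tukey = tukey_hsd(fx$asin_ma_temporalis, species),
    osa_anova = anova_fit(fx$residual_osa, species),
    osa_tukey = tukey_hsd(fx$residual_osa, species),
    means = .group_index_means(fx, species))

  ord <- regression_scores(shape_Y, X_feed, other = X_nest)

  structure(list(
    level = "species",
    n = nrow(table), validation = validation, imputation = imput,
    decomposition = decomp,
    size_anova = size_anova, size_tukey = size_tukey,
    form_manova = form_manova, shape_manova = shape_manova,
    lda = ld, functional = functional, ordination = ord),
    class = "craniomorph_report")
}

.group_index_means <- function(fx, groups) {
  agg <- stats::aggregate(
    fx[, c("mbi", "ma_masseter", "ma_temporalis", "residual_osa")],
    by = list(group = groups), FUN = mean, na.rm = TRUE)
  agg
}

#' Sea otter subspecies analysis
#'
#' The same pipeline restricted to the sea otter sample, with subspecies
#' as the grouping factor: size ANOVA, form and shape MANOVA (size
#' covariate with pruned interactions), subspecies LDA with LOOCV on
#' form and shape, canonical ordination of form, and the functional
#' indices, including the size-adjusted occlusal-surface-area contrast
#' of the southern subspecies against the other two.
#'
#' @param table a `measurement_table`; non-sea-otter specimens are
#'   dropped.
#' @param shape_subset,osa_scale as in [run_species_analysis()].
#' @return A list of class `craniomorph_report`.
#' @export
run_subspecies_analysis <- function(table,
                                    shape_subset = analysis_shape_traits(),
                                    osa_scale = "raw") {
  lb <- specimen_labels(table)
  if (any(lb$species == "sea")) table <- subset_specimens(table, lb$species == "sea")
  lb <- specimen_labels(table)
  sub <- lb$subspecies
  if (anyNA(sub)) stop("sea otter specimens lack subspecies labels")
  if (length(unique(sub)) < 2) stop("need at least 2 subspecies")
  validation <- validate_measurements(table)
  imput <- NULL
  if (any(is.na(table))) {
    imp <- impute_measurements(table, group = "subspecies")
    table <- imp$table
    imput <- imp$fit
  }
  decomp <- size_shape(table, shape_subset = shape_subset)
  sub <- factor(decomp$labels$subspecies, levels = sea_otter_subspecies())
  sub <- droplevels(sub)

  size_anova <- anova_fit(decomp$log_gms, sub)
  size_tukey <- tukey_hsd(decomp$log_gms, sub)

  X_sub <- effects_design(sub)
  shape_Y <- decomp$pca$scores
  form_Y <- cbind(shape_Y, log_gms = decomp$log_gms)

  form_manova <- wilks_manova(form_Y, list(subspecies = X_sub))
  size_c <- decomp$log_gms - mean(decomp$log_gms)
  shape_manova <- wilks_manova(shape_Y, list(
    subspecies = X_sub, size = size_c,
    `size:subspecies` = X_sub * size_c),
    prune = TRUE, prunable = "size:subspecies")

  ld <- list(
    subspecies_form = lda_loocv(form_Y, sub),
    subspecies_shape = lda_loocv(shape_Y, sub))

  fx <- functional_indices(table, osa_scale = osa_scale)
  functional <- list(
    indices = fx,
    mbi_anova = anova_fit(fx$mbi, sub),
    mbi_tukey = tukey_hsd(fx$mbi, sub),
    ma_masseter_anova = anova_fit(fx$asin_ma_masseter, sub),
    ma_masseter_anova_raw = anova_fit(fx$ma_masseter, sub),
    ma_masseter_tukey = tukey_hsd(fx$asin_ma_masseter, sub),
    ma_temporalis_anova = anova_fit(fx$asin_ma_temporalis, sub),
    ma_temporalis_anova_raw = anova_fit(fx$ma_temporalis, sub),
    osa_anova = anova_fit(fx$residual_osa, sub),
    osa_tukey = tukey_hsd(fx$residual_osa, sub),
    osa_southern_excess_pct = osa_excess_pct(fx, sub),
    means = .group_index_means(fx, sub))

  canon <- form_manova$canonical$subspecies
  scores <- NULL
  if (!is.null(canon)) {
    scores <- sweep(form_Y, 2, colMeans(form_Y)) %*%
      canon$vectors[, 1:2, drop = FALSE]
  }

  structure(list(
    level = "subspecies",
    n = nrow(table), validation = validation, imputation = imput,
    decomposition = decomp,
    size_anova = size_anova, size_tukey = size_tukey,
    form_manova = form_manova, shape_manova = shape_manova,
    lda = ld, functional = functional,
    canonical_scores = scores),
    class = "craniomorph_report")
}

#' Size-adjusted OSA excess of one group over the others
#'
#' Expresses the difference between a focal group's mean size-adjusted
#' OSA residual and the unweighted mean of the remaining groups'
#' residuals, as a percentage of the predicted OSA at the sample mean
#' condylobasal length.
#'
#' @param fx a `functional_indices` table.
#' @param groups grouping labels aligned with `fx`.
#' @param focal focal group label (default `"southern"`).
#' @return Percentage (single number).
#' @export
osa_excess_pct <- function(fx, groups, focal = "southern") {
  groups <- as.character(groups)
  if (!focal %in% groups) stop("focal group not present")
  res <- fx$residual_osa
  m <- tapply(res, groups, mean, na.rm = TRUE)
  others <- setdiff(names(m), focal)
  fit <- attr(fx, "osa_fit")
  base <- mean(fit$fitted, na.rm = TRUE)
  if (fit$scale == "sqrt") base <- base^2
  100 * (m[[focal]] - mean(m[others])) / base
}

#' @export
print.craniomorph_report <- function(x, ...) {
  cat(sprintf("craniometric analysis report (%s level), %d specimens\n",
              x$level, x$n))
  cat(sprintf("  missing on input: %.2f%%%s\n",
              100 * x$validation$missing_fraction,
              if (is.null(x$imputation)) "" else
                sprintf(" (EM-imputed, %d iterations)",
                        x$imputation$iterations)))
  cat(sprintf("\nsize: ANOVA F(%d,%d) = %.1f, adj. R^2 = %.2f\n",
              x$size_anova$df1, x$size_anova$df2, x$size_anova$F,
              x$size_anova$r2_adj))
  cat("  LS mean log GMS:",
      paste(sprintf("%s %.2f", names(x$size_anova$ls_means),
                    x$size_anova$ls_means), collapse = ", "), "\n")
  cat("\nform MANOVA:\n"); print(x$form_manova)
  cat("\nshape MANOVA:\n"); print(x$shape_manova)
  cat("\nLDA percent correct (resubstitution / LOOCV):\n")
  for (nm in names(x$lda)) {
    cat(sprintf("  %-16s %.1f / %.1f\n", nm,
                x$lda[[nm]]$pct_correct_resub, x$lda[[nm]]$pct_correct_cv))
  }
  f <- x$functional
  cat(sprintf("\nMBI ANOVA: F(%d,%d) = %.1f\n", f$mbi_anova$df1,
              f$mbi_anova$df2, f$mbi_anova$F))
  cat(sprintf("MA masseter ANOVA (arcsine): F(%d,%d) = %.1f\n",
              f$ma_masseter_anova$df1, f$ma_masseter_anova$df2,
              f$ma_masseter_anova$F))
  cat(sprintf("MA temporalis ANOVA (arcsine): F(%d,%d) = %.1f\n",
              f$ma_temporalis_anova$df1, f$ma_temporalis_anova$df2,
              f$ma_temporalis_anova$F))
  print(f$means, digits = 3)
  if (!is.null(f$osa_southern_excess_pct)) {
    cat(sprintf("size-adjusted OSA, southern excess: %.1f%%\n",
                f$osa_southern_excess_pct))
  }
  invisible(x)
}

#' Serialize a report to JSON
#'
#' Flattens the numeric content of a report (test statistics, LS means,
#' confusion matrices, functional-index summaries, pruning trace) into a
#' JSON file that round-trips losslessly.
#'
#' @param report a `craniomorph_report`.
#' @param path output file; `NULL` returns the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
report_to_json <- function(report, path = NULL) {
  an <- function(a) list(F = a$F, df1 = a$df1, df2 = a$df2,
                         p_value = a$p_value, r2_adj = a$r2_adj,
                         ls_means = as.list(a$ls_means))
  mv <- function(m) {
    lapply(seq_len(nrow(m$table)), function(i) as.list(m$table[i, ]))
  }
  ld <- function(l) list(pct_correct_resub = l$pct_correct_resub,
                         pct_correct_cv = l$pct_correct_cv,
                         confusion_cv = as.data.frame(l$confusion_cv))
  f <- report$functional
  obj <- list(
    level = report$level, n = report$n,
    missing_fraction = report$validation$missing_fraction,
    size_anova = an(report$size_anova),
    form_manova = mv(report$form_manova),
    shape_manova = mv(report$shape_manova),
    shape_pruned = report$shape_manova$pruned,
    lda = lapply(report$lda, ld),
    mbi_anova = an(f$mbi_anova),
    ma_masseter_anova = an(f$ma_masseter_anova),
    ma_temporalis_anova = an(f$ma_temporalis_anova),
    osa_anova = an(f$osa_anova),
    index_means = f$means)
  if (!is.null(f$osa_southern_excess_pct)) {
    obj$osa_southern_excess_pct <- unname(f$osa_southern_excess_pct)
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Ordination plot of a report
#'
#' Species-level reports plot the multivariate regression scores for
#' feeding orientation against log GMS; subspecies reports plot the
#' first two canonical axes of the form MANOVA.
#'
#' @param x a `craniomorph_report`.
#' @param ... passed to `plot`.
#' @export
plot.craniomorph_report <- function(x, ...) {
  lb <- x$decomposition$labels
  if (x$level == "species") {
    grp <- factor(lb$species)
    plot(x$decomposition$log_gms, x$ordination$scores,
         col = as.integer(grp), pch = 16,
         xlab = "log GMS", ylab = "feeding-orientation regression score",
         ...)
    graphics::legend("topleft", legend = levels(grp), col = seq_along(levels(grp)),
                     pch = 16, cex = 0.8)
  } else {
    grp <- factor(lb$subspecies)
    plot(x$canonical_scores[, 1], x$canonical_scores[, 2],
         col = as.integer(grp), pch = 16,
         xlab = "canonical axis 1", ylab = "canonical axis 2", ...)
    graphics::legend("topleft", legend = levels(grp), col = seq_along(levels(grp)),
                     pch = 16, cex = 0.8)
  }
  invisible(x)
}
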