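#' Natural-log transform of a measurement table
#'
#' Converts measurements to natural logs for all downstream analysis.
#' The areal trait OSA (mm^2) is first replaced by its square root so a
#' single linear (mm) scale applies to every column; the missingness
#' pattern is preserved.
#'
#' @param table a `measurement_table`, or a plain positive matrix.
#' @return Numeric matrix of log measurements (same dimnames); for OSA
#'   the value is `log(sqrt(OSA))`.
#' @export
log_transform <- function(table) {
  vals <- as.matrix(unclass(table))
  attr(vals, "labels") <- NULL; attr(vals, "registry") <- NULL
  if (any(!is.na(vals) & vals <= 0)) {
    bad <- which(!is.na(vals) & vals <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("nonpositive value at specimen %s, trait %s",
                 rownames(vals)[bad[1]] %||% bad[1],
                 colnames(vals)[bad[2]] %||% bad[2]))
  }
  reg <- attr(table, "registry")
  if (!is.null(reg)) {
    areal <- intersect(reg$code[reg$areal], colnames(vals))
    vals[, areal] <- sqrt(vals[, areal])
  }
  log(vals)
}

#' Log geometric mean size
#'
#' The geometric mean of k major linear dimensions is the linearised
#' volume of the skull: the k-th root of their product.  On the log scale
#' this is just the row mean of the log measures over the size subset,
#' which by default excludes the two minor zygoma measures (ZH, ZW) and
#' the areal OSA, leaving 22 major dimensions.  GMS is homogeneous of
#' degree one: uniformly rescaling a specimen by c rescales GMS by c.
#'
#' @param log_table matrix of log measurements (from [log_transform()]),
#'   complete (impute first).
#' @param traits character vector of trait codes to include.
#' @return Numeric vector of per-specimen log GMS.
#' @export
compute_gms <- function(log_table, traits = gms_traits()) {
  if (length(traits) == 0) stop("empty GMS trait subset")
  missing_tr <- setdiff(traits, colnames(log_table))
  if (length(missing_tr)) {
    stop("traits absent from table: ", paste(missing_tr, collapse = ", "))
  }
  sub <- log_table[, traits, drop = FALSE]
  if (anyNA(sub)) stop("GMS requires complete data; impute first")
  rowMeans(sub)
}

#' Log-shape ratios
#'
#' Size-standardised shape variables.  The default Mosimann convention is
#' `log(trait) - log(GMS) = log(trait / GMS)`: invariant to uniform
#' scaling of a specimen, and summing to zero across the GMS subset by
#' construction.  A literal ratio-of-logs convention
#' `log(trait) / log(GMS)` is selectable; it is not scale-invariant and
#' is undefined when GMS is exactly 1 mm (log GMS = 0), which is guarded.
#'
#' @param log_table matrix of log measurements.
#' @param log_gms per-specimen log GMS (from [compute_gms()]).
#' @param traits trait codes forming the shape-variable set (default all
#'   registry traits present in the table).
#' @param convention `"mosimann"` (default) or `"ratio-of-logs"`.
#' @return Specimens x traits matrix of shape values.
#' @export
shape_ratios <- function(log_table, log_gms,
                         traits = intersect(shape_traits(),
                                            colnames(log_table)),
                         convention = c("mosimann", "ratio-of-logs")) {
  convention <- match.arg(convention)
  sub <- log_table[, traits, drop = FALSE]
  if (anyNA(sub)) stop("shape ratios require complete data; impute first")
  if (convention == "mosimann") {
    sweep(sub, 1, log_gms, `-`)
  } else {
    if (any(abs(log_gms) < 1e-12)) {
      stop("log GMS is zero (GMS = 1 mm): the ratio-of-logs convention ",
           "is undefined; use the mosimann convention")
    }
    sweep(sub, 1, log_gms, `/`)
  }
}

#' Covariance principal components of shape
#'
#' Eigen-decomposition of the covariance matrix of the shape variables,
#' retaining p-1 components: size standardisation removes one dimension
#' from the shape space (for Mosimann ratios over the GMS subset the
#' smallest eigenvalue is numerically zero), so the last component is
#' dropped, exactly as in geometric morphometrics.  Eigenvector signs
#' follow the convention that each component's largest-magnitude loading
#' is positive, so ordinations are reproducible.
#'
#' @param shape numeric matrix (specimens x shape traits).
#' @param n_keep number of components to keep; default `ncol(shape) - 1`.
#' @return A list of class `shape_pca`: `scores` (n x n_keep), `loadings`
#'   (p x n_keep), `eigenvalues` (all p, non-increasing), `center`,
#'   `dropped_variance`.
#' @export
pca_reduce <- function(shape, n_keep = ncol(shape) - 1L) {
  shape <- as.matrix(shape)
  if (nrow(shape) < 3) stop("need at least 3 specimens for PCA")
  ctr <- colMeans(shape)
  xc <- sweep(shape, 2, ctr)
  ev <- eigen(stats::cov(shape), symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  vecs <- ev$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  n_keep <- min(n_keep, ncol(shape))
  keep <- seq_len(n_keep)
  scores <- xc %*% vecs[, keep, drop = FALSE]
  colnames(scores) <- paste0("PC", keep)
  rownames(vecs) <- colnames(shape)
  colnames(vecs) <- paste0("PC", seq_len(ncol(vecs)))
  structure(list(scores = scores,
                 loadings = vecs[, keep, drop = FALSE],
                 eigenvalues = vals, center = ctr,
                 dropped_variance = sum(vals[-keep])),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("shape PCA: %d components retained of %d; %.4g%% variance dropped\n",
              ncol(x$scores), length(x$eigenvalues),
              100 * x$dropped_variance / sum(x$eigenvalues)))
  invisible(x)
}

#' Decompose a measurement table into size and shape
#'
#' One-stop wrapper: log-transform (OSA to its square root), log GMS over
#' the size subset, Mosimann log-shape ratios over the shape subset, and
#' covariance PCA reduced by one dimension.  The table must be complete;
#' run [impute_measurements()] first if it has missing cells.
#'
#' @param table a complete `measurement_table`.
#' @param gms_subset trait codes for size (default the 22 major
#'   dimensions).
#' @param shape_subset trait codes for shape (default all 25, with OSA as
#'   its square root).
#' @param convention shape convention, see [shape_ratios()].
#' @return A list of class `size_shape`: `log_gms`, `shape` (ratio
#'   matrix), `pca` (a `shape_pca`), `labels`.
#' @export
size_shape <- function(table, gms_subset = gms_traits(),
                       shape_subset = intersect(shape_traits(),
                                                colnames(table)),
                       convention = "mosimann") {
  lg <- log_transform(table)
  if (anyNA(lg)) stop("table has missing cells; impute first")
  g <- compute_gms(lg, gms_subset)
  sh <- shape_ratios(lg, g, traits = shape_subset, convention = convention)
  structure(list(log_gms = g, shape = sh, pca = pca_reduce(sh),
                 labels = specimen_labels(table)),
            class = "size_shape")
}

#' @export
print.size_shape <- function(x, ...) {
  cat(sprintf("size/shape decomposition: %d specimens, %d shape traits -> %d PCs\n",
              length(x$log_gms), ncol(x$shape), ncol(x$pca$scores)))
  cat(sprintf("  log GMS range: [%.3f, %.3f]\n", min(x$log_gms),
              max(x$log_gms)))
  invisible(x)
}
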