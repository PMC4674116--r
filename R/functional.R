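#' Mandibular bluntness index
#'
#' Ratio of jaw width (condyle to condyle) to jaw length (symphysis tip
#' to condyle).  Values above 1 mean the mandible is wider than long --
#' the blunt, force-favouring architecture of durophagous feeders.
#' Dimensionless, hence invariant to uniform scaling of the specimen.
#'
#' @param jw jaw width, mm (> 0).
#' @param jl jaw length, mm (> 0).
#' @return Numeric vector of MBI values.
#' @export
mbi <- function(jw, jl) {
  if (any(jw <= 0, na.rm = TRUE) || any(jl <= 0, na.rm = TRUE)) {
    stop("jaw measures must be positive")
  }
  jw / jl
}

#' Jaw-lever mechanical advantage
#'
#' In-lever over out-lever of the jaw lever system.  Applied twice per
#' specimen: the masseter moment arm (MAM) over the out-lever at the
#' carnassial (OLC), and the temporalis moment arm (MAT) over OLC.  High
#' values favour bite force, low values jaw-closing velocity.
#'
#' @param in_lever muscle moment arm, mm (> 0).
#' @param out_lever joint-to-bite-point distance, mm (> 0).
#' @return Numeric vector of dimensionless ratios.
#' @export
mechanical_advantage <- function(in_lever, out_lever) {
  if (any(in_lever <= 0, na.rm = TRUE) || any(out_lever <= 0, na.rm = TRUE)) {
    stop("lever arms must be positive")
  }
  in_lever / out_lever
}

#' Arcsine transform of a ratio
#'
#' Variance-stabilising transform for ratio data ahead of ANOVA.  The
#' default is `asin(sqrt(x))`; values above 1 (which occur for the
#' temporalis mechanical advantage in long-jawed species) are clamped to
#' 1 with a per-value warning.  The literal `asin(x)` is selectable;
#' it is clamped the same way.
#'
#' @param x nonnegative ratios.
#' @param method `"sqrt"` (default, `asin(sqrt(x))`) or `"literal"`
#'   (`asin(x)`).
#' @return Numeric vector in radians.
#' @export
arcsine_transform <- function(x, method = c("sqrt", "literal")) {
  method <- match.arg(method)
  if (any(x < 0, na.rm = TRUE)) stop("ratios must be nonnegative")
  over <- !is.na(x) & x > 1
  if (any(over)) {
    warning(sprintf("%d ratio(s) exceed 1 and were clamped to 1 before arcsine",
                    sum(over)))
    x[over] <- 1
  }
  if (method == "sqrt") asin(sqrt(x)) else asin(x)
}

#' Size-adjusted occlusal surface area
#'
#' Removes skull size from OSA by ordinary least squares: OSA is
#' regressed on condylobasal length over the pooled sample and the
#' residuals are returned for use as a size-adjusted response.  By
#' construction the residuals sum to zero and are uncorrelated with CBL.
#'
#' @param osa occlusal surface area per specimen, mm^2 (or its square
#'   root when `scale = "sqrt"`).
#' @param cbl condylobasal length per specimen, mm.
#' @param scale `"raw"` (default) regresses OSA in mm^2; `"sqrt"`
#'   regresses `sqrt(OSA)`, the linearised form used in the morphometric
#'   decomposition.
#' @return List of class `residual_osa`: `residuals`, `fitted`,
#'   `coefficients` (intercept, slope), `scale`.
#' @export
residual_osa <- function(osa, cbl, scale = c("raw", "sqrt")) {
  scale <- match.arg(scale)
  ok <- !is.na(osa) & !is.na(cbl)
  if (stats::sd(cbl[ok]) == 0) stop("condylobasal length is constant")
  y <- if (scale == "sqrt") sqrt(osa) else osa
  fit <- stats::lm(y ~ cbl)
  res <- rep(NA_real_, length(osa))
  res[ok] <- stats::residuals(fit)
  fitted <- rep(NA_real_, length(osa))
  fitted[ok] <- stats::fitted(fit)
  structure(list(residuals = res, fitted = fitted,
                 coefficients = stats::coef(fit), scale = scale),
            class = "residual_osa")
}

#' Functional jaw indices for a measurement table
#'
#' Per-specimen functional characters: mandibular bluntness (JW/JL),
#' masseter and temporalis mechanical advantage (MAM/OLC, MAT/OLC) with
#' their arcsine transforms, and size-adjusted occlusal surface area
#' (residual of OSA on CBL over the whole table).
#'
#' @param table a `measurement_table` containing JW, JL, MAM, MAT, OLC,
#'   OSA, CBL.
#' @param osa_scale passed to [residual_osa()].
#' @return Data frame of class `functional_indices`, one row per
#'   specimen: labels plus `mbi`, `ma_masseter`, `ma_temporalis`,
#'   `asin_ma_masseter`, `asin_ma_temporalis`, `residual_osa`.
#' @export
functional_indices <- function(table, osa_scale = "raw") {
  need <- c("JW", "JL", "MAM", "MAT", "OLC", "OSA", "CBL")
  absent <- setdiff(need, colnames(table))
  if (length(absent)) {
    stop("table lacks trait(s): ", paste(absent, collapse = ", "))
  }
  lb <- specimen_labels(table)
  v <- unclass(table)
  ros <- residual_osa(v[, "OSA"], v[, "CBL"], scale = osa_scale)
  out <- data.frame(
    lb[, c("specimen_id", "species", "subspecies", "feeding_mode")],
    mbi = mbi(v[, "JW"], v[, "JL"]),
    ma_masseter = mechanical_advantage(v[, "MAM"], v[, "OLC"]),
    ma_temporalis = mechanical_advantage(v[, "MAT"], v[, "OLC"]),
    stringsAsFactors = FALSE
  )
  out$asin_ma_masseter <- suppressWarnings(arcsine_transform(out$ma_masseter))
  out$asin_ma_temporalis <- suppressWarnings(arcsine_transform(out$ma_temporalis))
  out$residual_osa <- ros$residuals
  attr(out, "osa_fit") <- ros
  class(out) <- c("functional_indices", "data.frame")
  out
}
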