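test_that("effects coding produces k-1 sum-to-zero columns with -1 reference", {
  X2 <- effects_design(c("A", "B"))
  expect_equal(unname(X2), matrix(c(1, -1), 2))
  X3 <- effects_design(c("A", "B", "C"))
  expect_equal(unname(X3), rbind(c(1, 0), c(0, 1), c(-1, -1)))
  # balanced groups -> columns sum to zero
  X <- effects_design(rep(c("A", "B", "C", "D"), each = 5))
  expect_equal(ncol(X), 3)
  expect_equal(colSums(X), c(eff_A = 0, eff_B = 0, eff_C = 0))
  expect_error(effects_design(rep("A", 4)), "at least 2")
})

test_that("a complete table is returned untouched after one iteration", {
  y <- toy_log_matrix(n = 12)
  g <- rep(c("u", "v"), 6)
  fit <- em_impute(y, effects_design(g))
  expect_identical(fit$completed, y)
  expect_equal(fit$iterations, 1)
  expect_true(fit$converged)
  expect_equal(fit$n_missing, 0)
})

test_that("EM conditional mean matches the bivariate closed form", {
  set.seed(20)
  n <- 4000
  rho <- 0.5
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  dat <- cbind(x = c(x, 2.0), y = c(y, NA))
  fit <- em_impute(dat, design = NULL, tol = 1e-12)
  # self-consistency: imputed value equals the fitted model's conditional
  # mean mu_y + (sigma_xy / sigma_xx) (x - mu_x), to 1e-8
  mu <- fit$coefficients[1, ]
  S <- fit$sigma
  expected <- mu["y"] + S["x", "y"] / S["x", "x"] * (2.0 - mu["x"])
  expect_equal(unname(fit$completed[n + 1, "y"]), unname(expected),
               tolerance = 1e-8)
  # convergence to the population value rho * x = 1.0 at large n
  se <- sqrt(1 - rho^2) / sqrt(n)
  expect_lt(abs(fit$completed[n + 1, "y"] - 1.0), 5 * se + 0.05)
})

test_that("observed-data log-likelihood never decreases across EM iterations", {
  tab <- inject_missing(tiny_table(n_per = 8), rate = 0.05, seed = 9)
  # 48 specimens support a moderate trait set, not all 25
  lg <- log_transform(tab)[, 1:8]
  fit <- em_impute(lg, effects_design(specimen_labels(tab)$species),
                   tol = 1e-10)
  expect_gt(fit$iterations, 1)
  expect_true(all(diff(fit$loglik) >= -1e-8 * abs(fit$loglik[-1])))
  # observed cells untouched
  obs <- !is.na(lg)
  expect_identical(fit$completed[obs], lg[obs])
})

test_that("imputation beats the per-trait marginal spread and is permutation invariant", {
  cfg <- otter_sim_config(missing_rate = 0, bilateral_sd = 0)
  truth_tab <- simulate_otters(cfg, seed = 31)$table
  lg_true <- log_transform(truth_tab)
  masked <- inject_missing(truth_tab, rate = 0.03, seed = 32)
  lg <- log_transform(masked)
  des <- effects_design(specimen_labels(masked)$species)
  fit <- em_impute(lg, des)
  holes <- is.na(lg)
  rmse <- sqrt(mean((fit$completed[holes] - lg_true[holes])^2))
  marg_sd <- mean(apply(lg_true, 2, sd))
  expect_lt(rmse, marg_sd)
  # mean imputation would be bounded below by the within-column spread;
  # the model-based fill must do better than the pooled marginal SD and
  # also better than group-blind column means
  col_means <- matrix(colMeans(lg, na.rm = TRUE), nrow(lg), ncol(lg),
                      byrow = TRUE)
  rmse_mean <- sqrt(mean((col_means[holes] - lg_true[holes])^2))
  expect_lt(rmse, rmse_mean)

  perm <- sample(nrow(lg))
  fit_p <- em_impute(lg[perm, ], des[perm, , drop = FALSE])
  expect_equal(fit_p$completed, fit$completed[perm, ], tolerance = 1e-7)
})

test_that("degenerate inputs are rejected with useful errors", {
  y <- toy_log_matrix(n = 5)
  y[1, ] <- NA
  expect_error(em_impute(y), "observed")
  # singular residual covariance -> ridge advice
  y2 <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4) * 2, c = c(1, 2, NA, 4))
  expect_error(suppressWarnings(em_impute(y2)), "ridge")
  set.seed(4)
  y3 <- matrix(rnorm(40, 5, 1), 10, dimnames = list(NULL, c("a", "b", "c", "d")))
  y3[1, 1] <- NA; y3[5, 3] <- NA
  expect_warning(em_impute(y3, max_iter = 1, tol = 1e-15), "converge")
})

test_that("impute_measurements completes a table on the mm scale", {
  tab <- inject_missing(study_table(seed = 11), rate = 0.01, seed = 12)
  out <- impute_measurements(tab)
  expect_false(anyNA(out$table))
  obs <- !is.na(unclass(tab)[, colnames(tab)])
  expect_equal(unclass(out$table)[, colnames(tab)][obs],
               unclass(tab)[, colnames(tab)][obs], tolerance = 1e-12)
  expect_s3_class(out$fit, "em_impute")
})
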