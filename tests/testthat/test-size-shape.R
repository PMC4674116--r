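test_that("log transform uses natural logs and the square root of OSA", {
  tab <- tiny_table(n_per = 2)
  vals <- unclass(tab)[, colnames(tab)]
  vals[, "TL"] <- 10
  vals[, "OSA"] <- 144
  lb <- specimen_labels(tab)
  t2 <- measurement_table(vals, species = lb$species, subspecies = lb$subspecies)
  lg <- log_transform(t2)
  expect_equal(unname(lg[1, "TL"]), log(10), tolerance = 1e-12)
  expect_equal(unname(lg[1, "OSA"]), log(12), tolerance = 1e-12)
  vals[1, "TL"] <- 0
  expect_error(measurement_table(vals, species = lb$species,
                                 subspecies = lb$subspecies), "TL")
  m <- matrix(c(1, 0), 1, dimnames = list(NULL, c("a", "b")))
  expect_error(log_transform(m), "nonpositive")
})

test_that("geometric mean size matches the product-root oracle and is homogeneous", {
  m <- matrix(log(c(2, 4, 8)), 1, dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(unname(compute_gms(m, traits = c("A", "B", "C"))),
               log((2 * 4 * 8)^(1 / 3)), tolerance = 1e-12)
  m10 <- matrix(log(10), 2, 3, dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(unname(compute_gms(m10, traits = c("A", "B", "C"))),
               rep(log(10), 2))
  expect_error(compute_gms(m, traits = character(0)), "empty")
  # GMS(c x) = c GMS(x) on 100 random specimens
  set.seed(51)
  for (i in 1:100) {
    x <- exp(rnorm(5, 2, 0.5))
    cc <- exp(rnorm(1))
    lm1 <- matrix(log(x), 1, dimnames = list(NULL, letters[1:5]))
    lm2 <- matrix(log(cc * x), 1, dimnames = list(NULL, letters[1:5]))
    expect_equal(compute_gms(lm2, traits = letters[1:5]),
                 compute_gms(lm1, traits = letters[1:5]) + log(cc),
                 tolerance = 1e-10)
  }
})

test_that("Mosimann shape ratios are scale invariant and sum to zero over the GMS subset", {
  lg <- toy_log_matrix(n = 20, traits = letters[1:6], seed = 8)
  g <- compute_gms(lg, traits = letters[1:6])
  sh <- shape_ratios(lg, g, traits = letters[1:6])
  expect_equal(max(abs(rowSums(sh))), 0, tolerance = 1e-10)
  # trait equal to GMS -> shape value 0
  lg0 <- matrix(2, 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  sh0 <- shape_ratios(lg0, compute_gms(lg0, c("a", "b", "c")),
                      traits = c("a", "b", "c"))
  expect_equal(unname(sh0[1, ]), c(0, 0, 0))
  # uniform scaling x2 leaves the shape row unchanged
  lg2 <- lg + log(2)
  sh2 <- shape_ratios(lg2, compute_gms(lg2, traits = letters[1:6]),
                      traits = letters[1:6])
  expect_equal(sh2, sh, tolerance = 1e-10)
  # literal ratio-of-logs convention differs and is guarded at GMS = 1
  shr <- shape_ratios(lg, g, traits = letters[1:6],
                      convention = "ratio-of-logs")
  expect_equal(shr, sweep(lg, 1, g, `/`))
  lg1 <- matrix(c(log(2), -log(2)), 1,
                dimnames = list(NULL, c("a", "b")))
  expect_error(
    shape_ratios(lg1, compute_gms(lg1, c("a", "b")), traits = c("a", "b"),
                 convention = "ratio-of-logs"),
    "mosimann")
})

test_that("covariance PCA conserves variance, centres scores, and drops one rank", {
  set.seed(60)
  lg <- toy_log_matrix(n = 40, traits = letters[1:5], seed = 61)
  g <- compute_gms(lg, traits = letters[1:5])
  sh <- shape_ratios(lg, g, traits = letters[1:5])
  pc <- pca_reduce(sh)
  # sum-to-zero constraint makes the smallest eigenvalue numerically zero
  expect_lt(min(pc$eigenvalues), 1e-12 * max(pc$eigenvalues))
  # conservation: retained + dropped = total trace
  expect_equal(sum(pc$eigenvalues), sum(diag(cov(sh))), tolerance = 1e-10)
  expect_equal(sum(pc$eigenvalues[seq_len(ncol(pc$scores))]) +
                 pc$dropped_variance,
               sum(pc$eigenvalues), tolerance = 1e-10)
  # scores are centred with diagonal covariance equal to the eigenvalues
  expect_equal(unname(colMeans(pc$scores)), rep(0, ncol(pc$scores)),
               tolerance = 1e-10)
  cs <- cov(pc$scores)
  expect_equal(unname(diag(cs)),
               pc$eigenvalues[seq_len(ncol(pc$scores))], tolerance = 1e-9)
  expect_equal(max(abs(cs[upper.tri(cs)])), 0, tolerance = 1e-9)
  # eigenvalues non-increasing, non-negative
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  expect_true(all(pc$eigenvalues >= 0))
})

test_that("full-rank PCA reconstructs the centred data (5 x 4 toy)", {
  set.seed(62)
  x <- matrix(rnorm(20), 5, dimnames = list(NULL, c("w", "x", "y", "z")))
  pc <- pca_reduce(x, n_keep = 4)
  recon <- pc$scores %*% t(pc$loadings)
  expect_equal(recon, sweep(x, 2, colMeans(x)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("size_shape wrapper ties the pieces together on a study table", {
  tab <- tiny_table(n_per = 5)
  d <- size_shape(tab)
  expect_equal(length(d$log_gms), nrow(tab))
  expect_equal(ncol(d$shape), 25)          # full trait set by default
  expect_equal(ncol(d$pca$scores), 24)
  d2 <- size_shape(tab, shape_subset = analysis_shape_traits())
  expect_equal(ncol(d2$shape), 24)         # published analyses drop ZH
  expect_equal(ncol(d2$pca$scores), 23)
  tab_m <- inject_missing(tab, 0.02, seed = 3)
  expect_error(size_shape(tab_m), "impute")
})
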