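test_that("equal group mean vectors give a null MANOVA", {
  Y <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20), 10))
  Y2 <- rbind(Y, Y)  # identical group blocks -> identical means
  g <- rep(c("a", "b"), each = nrow(Y))
  fit <- wilks_manova(Y2, list(group = effects_design(g)))
  expect_equal(fit$table["group", "lambda"], 1, tolerance = 1e-9)
  expect_equal(fit$table["group", "F"], 0, tolerance = 1e-9)
  expect_equal(fit$table["group", "eta_sq"], 0, tolerance = 1e-9)
})

test_that("Wilks' lambda matches the direct SSCP oracle on a small integer example", {
  Y <- rbind(c(1, 2), c(2, 4), c(3, 3), c(6, 7), c(7, 9), c(8, 8))
  g <- rep(c("a", "b"), each = 3)
  fit <- wilks_manova(Y, list(group = effects_design(g)))
  orc <- oracle_wilks_oneway(Y, g)
  expect_equal(fit$table["group", "lambda"], orc$lambda, tolerance = 1e-12)
  # q = 1 exact F: ((1 - L)/L) ((v - p + 1)/p)
  v <- nrow(Y) - 2; p <- 2
  expect_equal(fit$table["group", "F"],
               (1 - orc$lambda) / orc$lambda * (v - p + 1) / p,
               tolerance = 1e-12)
  expect_equal(fit$E, orc$E, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(fit$H$group, orc$H, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("lambda and Rao's F agree with oracles over random small instances", {
  set.seed(90)
  for (rep_i in 1:50) {
    p <- sample(2:4, 1)
    k <- sample(2:3, 1)
    n_per <- sample(5:9, 1)
    g <- rep(letters[1:k], each = n_per)
    Y <- matrix(rnorm(length(g) * p, sd = 1 + rep_i %% 3), length(g), p)
    Y <- Y + outer(as.integer(factor(g)), seq_len(p) / 2)
    fit <- wilks_manova(Y, list(group = effects_design(g)))
    orc <- oracle_wilks_oneway(Y, g)
    expect_equal(fit$table["group", "lambda"], orc$lambda, tolerance = 1e-9)
    # independent library oracle for the whole statistic
    sm <- summary(stats::manova(Y ~ factor(g)), test = "Wilks")$stats
    expect_equal(fit$table["group", "lambda"], unname(sm[1, "Wilks"]),
                 tolerance = 1e-8)
    expect_equal(fit$table["group", "F"], unname(sm[1, "approx F"]),
                 tolerance = 1e-6)
    expect_equal(as.numeric(fit$table["group", c("df1", "df2")]),
                 as.numeric(sm[1, c("num Df", "den Df")]),
                 tolerance = 1e-9)
  }
})

test_that("single-response MANOVA reduces exactly to the ANOVA F", {
  set.seed(91)
  for (i in 1:10) {
    g <- rep(letters[1:3], times = c(7, 9, 11))
    y <- rnorm(length(g)) + as.integer(factor(g)) * 0.5
    fitm <- wilks_manova(matrix(y), list(group = effects_design(g)))
    fita <- anova_fit(y, g)
    expect_equal(fitm$table["group", "F"], fita$F, tolerance = 1e-9)
    expect_equal(fitm$table["group", "p_value"], fita$p_value,
                 tolerance = 1e-9)
  }
})

test_that("lambda is invariant under joint nonsingular linear maps of the responses", {
  set.seed(92)
  g <- rep(letters[1:3], each = 8)
  Y <- matrix(rnorm(24 * 4), 24, 4) + as.integer(factor(g))
  fit0 <- wilks_manova(Y, list(group = effects_design(g)))
  for (i in 1:5) {
    A <- matrix(rnorm(16), 4, 4)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(16), 4, 4)
    fitA <- wilks_manova(Y %*% A, list(group = effects_design(g)))
    expect_equal(fitA$table["group", "lambda"],
                 fit0$table["group", "lambda"], tolerance = 1e-8)
  }
})

test_that("partial eta squared equals 1 - lambda when s = 1", {
  set.seed(93)
  g <- rep(c("a", "b"), each = 10)           # q = 1 -> s = 1
  Y <- matrix(rnorm(20 * 5), 20, 5) + as.integer(factor(g))
  fit <- wilks_manova(Y, list(group = effects_design(g)))
  expect_equal(fit$table["group", "s"], 1)
  expect_equal(fit$table["group", "eta_sq"],
               1 - fit$table["group", "lambda"], tolerance = 1e-12)
})

test_that("sequential fitting with nesting reproduces the published df structure", {
  tab <- study_table(seed = 17)
  tab <- impute_measurements(tab)$table
  d <- size_shape(tab, shape_subset = analysis_shape_traits())
  lb <- d$labels
  feeding <- factor(lb$feeding_mode, levels = c("mouth", "hand"))
  Xf <- effects_design(feeding)
  Xn <- nested_effects(feeding, lb$species)
  expect_equal(ncol(Xn), 2)   # one contrast per feeding mode
  form_Y <- cbind(d$pca$scores, log_gms = d$log_gms)
  fit <- wilks_manova(form_Y, list(feeding = Xf, `species(feeding)` = Xn))
  n <- nrow(tab)
  expect_equal(fit$error_df, n - 4)
  expect_equal(as.numeric(fit$table["feeding", c("df1", "df2")]),
               c(24, (n - 4) - 23))
  expect_equal(fit$table["species(feeding)", "df1"], 48)
  expect_equal(fit$table["species(feeding)", "s"], 2)
  expect_equal(fit$table["species(feeding)", "df2"],
               2 * ((n - 4) - 11.5) - 23)
})

test_that("hierarchical pruning removes non-significant covariate interactions", {
  set.seed(94)
  n <- 60
  g <- rep(c("a", "b"), each = n / 2)
  X <- effects_design(g)
  size <- rnorm(n)
  # common allometry, no group-specific slope
  Y <- cbind(size + rnorm(n, sd = 0.3) + (g == "a"),
             0.5 * size + rnorm(n, sd = 0.3))
  fit <- wilks_manova(Y, list(group = X, size = size,
                              `size:group` = X * size),
                      prune = TRUE, prunable = "size:group")
  expect_true("size:group" %in% fit$pruned)
  expect_false("size:group" %in% rownames(fit$table))
  # a real interaction survives pruning
  Y2 <- Y + cbind(as.numeric(g == "a") * size * 2, 0)
  fit2 <- wilks_manova(Y2, list(group = X, size = size,
                                `size:group` = X * size),
                       prune = TRUE, prunable = "size:group")
  expect_equal(fit2$pruned, character(0))
  expect_true("size:group" %in% rownames(fit2$table))
})

test_that("canonical axes follow the E^-1 H eigenstructure", {
  set.seed(95)
  g <- rep(c("a", "b"), each = 12)
  Y <- matrix(rnorm(24 * 3), 24, 3)
  Y[g == "b", ] <- Y[g == "b", ] + c(1, 2, -1)[col(Y[g == "b", ])]
  fit <- wilks_manova(Y, list(group = effects_design(g)))
  cv <- fit$canonical$group
  # q = 1: exactly one nonzero eigenvalue
  expect_gt(cv$eigenvalues[1], 0.1)
  expect_lt(max(abs(cv$eigenvalues[-1])), 1e-10 * cv$eigenvalues[1])
  # two-group closed form: axis parallel to E^-1 (mean difference)
  dmean <- colMeans(Y[g == "a", ]) - colMeans(Y[g == "b", ])
  dir_expected <- solve(fit$E, dmean)
  v1 <- cv$vectors[, 1]
  cosang <- abs(sum(v1 * dir_expected)) /
    sqrt(sum(v1^2) * sum(dir_expected^2))
  expect_equal(cosang, 1, tolerance = 1e-8)
})

test_that("regression scores behave as a projection on the regression vector", {
  set.seed(96)
  n <- 30
  x <- rep(c(-1, 1), each = n / 2)
  beta <- c(2, -1, 0.5)
  Y <- outer(x, beta)
  rs <- regression_scores(Y, x)
  expect_equal(abs(cor(rs$scores, x)), 1, tolerance = 1e-10)
  # invariant to adding a constant to any response column
  Y2 <- sweep(Y, 2, c(10, -5, 3), `+`)
  rs2 <- regression_scores(Y2, x)
  expect_equal(rs2$scores, rs$scores, tolerance = 1e-10)
  # noisy two-mode data: score ordering recovers the generating labels
  Yn <- Y + matrix(rnorm(n * 3, sd = 0.1), n)
  rsn <- regression_scores(Yn, x)
  expect_true(all(rsn$scores[x == 1] > max(rsn$scores[x == -1])) ||
                all(rsn$scores[x == 1] < min(rsn$scores[x == -1])))
  expect_error(regression_scores(Y, rep(1, n)), "constant")
})
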