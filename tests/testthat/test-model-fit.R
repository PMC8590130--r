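test_that("design columns follow the factor-by-rhythm crossing", {
  # one binary factor, random mesor: {1, C, x, z, C:x, C:z}
  d <- make_exact_data()
  fml <- build_cosinor_formula("y", factors = "C", random = "mesor")
  X <- model.matrix(fml$fixed, as.data.frame(d))
  expect_equal(ncol(X), 6)
  expect_setequal(colnames(X),
                  c("(Intercept)", "CL1", "x", "z", "CL1:x", "CL1:z"))

  # no factors: pure cosinor limit {1, x, z}
  fml0 <- build_cosinor_formula("y", random = "mesor")
  expect_equal(ncol(model.matrix(fml0$fixed, as.data.frame(d))), 3)

  # 2 x 3 interaction crossed with {1, x, z}: 18 columns
  set.seed(5)
  df <- data.frame(id = rep(1:30, each = 4), time = runif(120, 0, 24),
                   y = rnorm(120),
                   sex = rep(sample(c("F", "M"), 30, TRUE), each = 4),
                   bmi = rep(sample(c("normal", "over", "obese"), 30, TRUE),
                             each = 4))
  dd <- cosinor_data(df, covariates = c("sex", "bmi"))
  fml2 <- build_cosinor_formula("y", interactions = c("sex", "bmi"),
                                random = "rhythm")
  expect_equal(ncol(model.matrix(fml2$fixed, as.data.frame(dd))), 18)
  expect_match(deparse(fml2$full), "1 + x + z | id", fixed = TRUE)
})

test_that("noise-free data reproduce the generating coefficients", {
  coefs <- c(int = 10, C = 2, x = 3, z = 1, Cx = -1, Cz = 0)
  d <- make_exact_data(coefs, residual_sd = 1e-9)
  f <- fit_cosinor_mixed(d, factors = "C")
  co <- coef(f)
  expect_equal(unname(co[c("(Intercept)", "CL1", "x", "z", "CL1:x", "CL1:z")]),
               unname(coefs), tolerance = 1e-7)
  expect_true(f$converged)
})

test_that("boundary mixed fits agree with the closed-form OLS oracle", {
  for (seed in 1:3) {
    d <- make_boundary_data(seed = seed)
    f <- fit_cosinor_mixed(d, factors = "g")
    expect_true(f$singular)
    X <- model.matrix(f$fixed_formula, as.data.frame(d))
    beta_ols <- ols_oracle(X, d$y)
    expect_equal(unname(coef(f)), unname(beta_ols), tolerance = 1e-6)
  }
})

test_that("parameter recovery on a known mixed-model generator", {
  truth <- data.frame(group = c("A", "B"),
                      mesor = c(60, 60),
                      amplitude = c(sqrt(8^2 + 4^2), sqrt(8^2 + 4^2)),
                      acrophase = rep(atan2(4, 8) - 2 * pi, 2))
  # that acrophase corresponds to beta = 8, gamma = -4
  lin <- cosinor_to_linear(truth$mesor[1], truth$amplitude[1],
                           truth$acrophase[1])
  expect_equal(lin$beta, 8, tolerance = 1e-9)
  expect_equal(lin$gamma, -4, tolerance = 1e-9)

  d <- simulate_cosinor_data(n_subjects = 100, obs_per_subject = 10,
                             factors = list(group = c("A", "B")),
                             truth = truth,
                             re_sd = c(mesor = 8, beta = 0, gamma = 0),
                             residual_sd = 5, seed = 101)
  f <- fit_cosinor_mixed(d, factors = "group")
  co <- coef(f)
  se <- sqrt(diag(vcov(f)))
  expect_lt(abs(co[["(Intercept)"]] - 60), 3 * se[["(Intercept)"]])
  expect_lt(abs(co[["x"]] - 8), 3 * se[["x"]])
  expect_lt(abs(co[["z"]] + 4), 3 * se[["z"]])
})

test_that("degenerate designs are rejected or flagged appropriately", {
  d <- make_exact_data()
  df <- as.data.frame(d)
  # aliased factor: duplicate of C under another name
  df$C2 <- df$C
  dd <- cosinor_data(df, covariates = c("C", "C2"))
  expect_error(fit_cosinor_mixed(dd, factors = c("C", "C2")),
               "rank deficient.*C2", perl = TRUE)

  # single-level factor
  df$only <- "one"
  d1 <- cosinor_data(df, covariates = "only")
  expect_error(fit_cosinor_mixed(d1, factors = "only"), "fewer than 2")

  # single-subject dataset: boundary fit allowed
  solo <- simulate_cosinor_data(n_subjects = 1, obs_per_subject = 12,
                                factors = list(), re_sd = c(0, 0, 0),
                                residual_sd = 1, seed = 9)
  fs <- fit_cosinor_mixed(solo)
  expect_true(fs$converged)
  expect_true(all(is.finite(coef(fs))))

  # single-observation subjects are reported
  df2 <- as.data.frame(make_boundary_data())[-(2:8), ]
  d2 <- cosinor_data(df2, covariates = "g")
  expect_message(fit_cosinor_mixed(d2, factors = "g"),
                 "single observation")
})

test_that("reference-level choice does not move fitted values or EMMs", {
  d <- simulate_cosinor_data(n_subjects = 30, obs_per_subject = 6,
                             factors = list(g = c("A", "B", "C")), seed = 17)
  f1 <- fit_cosinor_mixed(d, factors = "g")
  d2 <- d
  d2$g <- stats::relevel(d2$g, ref = "C")
  f2 <- fit_cosinor_mixed(d2, factors = "g")
  expect_equal(unname(stats::fitted(f1$model)),
               unname(stats::fitted(f2$model)), tolerance = 1e-8)
  g1 <- marginal_linear_params(f1, ~g)
  g2 <- marginal_linear_params(f2, ~g)
  # same cells, different row order; align by level
  g2 <- g2[match(g1$g, g2$g), ]
  expect_equal(g1$mesor, g2$mesor, tolerance = 1e-8)
  expect_equal(g1$beta, g2$beta, tolerance = 1e-8)
  expect_equal(g1$gamma, g2$gamma, tolerance = 1e-8)
})

test_that("Wald tests match the coefficient table and quadratic form", {
  d <- simulate_cosinor_data(n_subjects = 40, obs_per_subject = 8, seed = 23)
  f <- fit_cosinor_mixed(d, factors = "group")
  s <- summary(f)$coefficients

  w <- wald_test(f, c(x = 1))
  expect_equal(w$estimate, s["x", "estimate"])
  expect_equal(w$z, s["x", "z"])
  expect_equal(w$p, s["x", "p"])

  # multi-coefficient combination: se from the explicit double sum
  wt <- c("(Intercept)" = 1, "groupB" = 0.5, "x" = -2)
  res <- wald_test(f, wt)
  V <- vcov(f)
  co <- coef(f)
  full <- setNames(numeric(length(co)), names(co))
  full[names(wt)] <- wt
  se2 <- 0
  for (i in names(co)) for (j in names(co))
    se2 <- se2 + full[[i]] * full[[j]] * V[i, j]
  expect_equal(res$se, sqrt(se2), tolerance = 1e-12)
  expect_equal(res$estimate, sum(full * co), tolerance = 1e-12)

  expect_error(wald_test(f, c(bogus = 1)), "unknown")
  expect_error(wald_test(f, c(x = 0)), "zero")
})

test_that("null Wald z-statistics are close to standard normal", {
  # under a generator with gamma = 0, the z for `z` should be ~ N(0,1)
  set.seed(31)
  zs <- replicate(400, {
    id <- rep(1:20, each = 5)
    tt <- runif(100, 0, 24)
    y <- 50 + 5 * cos(2 * pi * tt / 24) + rnorm(20, 0, 4)[id] + rnorm(100, 0, 3)
    d <- cosinor_data(data.frame(id = id, time = tt, y = y))
    f <- fit_cosinor_mixed(d)
    wald_test(f, c(z = 1))$z
  })
  expect_gt(stats::ks.test(zs, "pnorm")$p.value, 0.01)
})
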