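test_that("EMM formulas parse like emmeans specifications", {
  expect_equal(parse_emm_spec("~COVID"),
               list(means_over = "COVID", conditioned_on = character()))
  expect_equal(parse_emm_spec(~bmi_cat | sex),
               list(means_over = "bmi_cat", conditioned_on = "sex"))
  expect_equal(parse_emm_spec("~a+b|c")$means_over, c("a", "b"))
  expect_error(parse_emm_spec("~a|a"), "both sides")
  expect_error(parse_emm_spec("~"), "parse|factors")
})

test_that("grid cells are direct coefficient sums under treatment coding", {
  coefs <- c(int = 10, C = 2, x = 3, z = 1, Cx = -1, Cz = 0)
  d <- make_exact_data(coefs, residual_sd = 1e-9)
  f <- fit_cosinor_mixed(d, factors = "C")
  g <- marginal_linear_params(f, ~C)
  expect_equal(nrow(g), 2)
  expect_equal(g$mesor, c(10, 12), tolerance = 1e-6)
  expect_equal(g$beta, c(3, 2), tolerance = 1e-6)
  expect_equal(g$gamma, c(1, 1), tolerance = 1e-6)
  # weights in the averaging matrix: each row's intercept weight is 1
  L <- attr(g, "L")
  expect_equal(unname(L[, "mesor", "(Intercept)"]), c(1, 1))
  expect_true(all(vapply(attr(g, "vcov_blocks"),
                         function(B) isSymmetric(B) && all(eigen(B)$values > -1e-10),
                         logical(1))))
})

test_that("non-grid factors are averaged with equal weights", {
  d <- simulate_cosinor_data(n_subjects = 40, obs_per_subject = 8,
                             factors = list(sex = c("F", "M"),
                                            covid = c("neg", "pos")),
                             seed = 19)
  f <- fit_cosinor_mixed(d, factors = c("sex", "covid"))
  g <- marginal_linear_params(f, ~covid)
  co <- coef(f)
  # hand-computed L for the additive 2x2 model, averaging sex at 1/2
  expect_equal(g$mesor[1], co[["(Intercept)"]] + 0.5 * co[["sexM"]],
               tolerance = 1e-10)
  expect_equal(g$mesor[2],
               co[["(Intercept)"]] + 0.5 * co[["sexM"]] + co[["covidpos"]],
               tolerance = 1e-10)
  expect_equal(g$beta[1], co[["x"]] + 0.5 * co[["sexM:x"]], tolerance = 1e-10)
  expect_equal(g$gamma[2], co[["z"]] + 0.5 * co[["sexM:z"]] + co[["covidpos:z"]],
               tolerance = 1e-10)

  # three-level grids give three rows
  d3 <- simulate_cosinor_data(n_subjects = 30, obs_per_subject = 6,
                              factors = list(bmi = c("normal", "over", "obese")),
                              seed = 20)
  f3 <- fit_cosinor_mixed(d3, factors = "bmi")
  expect_equal(nrow(marginal_linear_params(f3, ~bmi)), 3)
})

test_that("marginal linear parameters agree with emmeans", {
  skip_if_not_installed("emmeans")
  d <- simulate_cosinor_data(n_subjects = 40, obs_per_subject = 8,
                             factors = list(sex = c("F", "M"),
                                            covid = c("neg", "pos")),
                             seed = 29)
  f <- fit_cosinor_mixed(d, factors = c("sex", "covid"))
  g <- marginal_linear_params(f, ~covid)

  em_m <- as.data.frame(emmeans::emmeans(f$model, ~covid,
                                         at = list(x = 0, z = 0),
                                         lmer.df = "asymptotic"))
  expect_equal(g$mesor, em_m$emmean, tolerance = 1e-8)
  em_b <- as.data.frame(emmeans::emtrends(f$model, ~covid, var = "x",
                                          at = list(x = 0, z = 0),
                                          lmer.df = "asymptotic"))
  expect_equal(g$beta, em_b$x.trend, tolerance = 1e-8)
  em_g <- as.data.frame(emmeans::emtrends(f$model, ~covid, var = "z",
                                          at = list(x = 0, z = 0),
                                          lmer.df = "asymptotic"))
  expect_equal(g$gamma, em_g$z.trend, tolerance = 1e-8)
})

test_that("a factor with no effect collapses out of the grid", {
  # noise-free generator in which `d2` has identical parameters in both
  # levels: the grid over `g` must match the model without `d2`
  set.seed(33)
  df <- data.frame(id = rep(1:20, each = 6), time = runif(120, 0, 24),
                   g = rep(sample(c("A", "B"), 20, TRUE), each = 6),
                   d2 = rep(sample(c("u", "v"), 20, TRUE), each = 6))
  xz <- recode_time(df$time)
  df$y <- 50 + 4 * (df$g == "B") + 6 * xz$x - 2 * xz$z +
    3 * (df$g == "B") * xz$x + rnorm(120, 0, 1e-8)
  d_full <- cosinor_data(df, covariates = c("g", "d2"))
  f_with <- fit_cosinor_mixed(d_full, factors = c("g", "d2"))
  f_without <- fit_cosinor_mixed(d_full, factors = "g")
  g_with <- marginal_linear_params(f_with, ~g)
  g_without <- marginal_linear_params(f_without, ~g)
  expect_equal(g_with$mesor, g_without$mesor, tolerance = 1e-6)
  expect_equal(g_with$beta, g_without$beta, tolerance = 1e-6)
  expect_equal(g_with$gamma, g_without$gamma, tolerance = 1e-6)
})

test_that("proportional weights use observed frequencies", {
  set.seed(37)
  n_sub <- 60
  sex <- rep(sample(c("F", "M"), n_sub, TRUE, prob = c(0.75, 0.25)), each = 5)
  df <- data.frame(id = rep(1:n_sub, each = 5), time = runif(n_sub * 5, 0, 24),
                   sex = sex,
                   covid = rep(sample(c("neg", "pos"), n_sub, TRUE), each = 5))
  xz <- recode_time(df$time)
  df$y <- 50 + 3 * (df$sex == "M") + 5 * xz$x + rnorm(nrow(df), 0, 2)
  d <- cosinor_data(df, covariates = c("sex", "covid"))
  f <- fit_cosinor_mixed(d, factors = c("sex", "covid"))
  g <- marginal_linear_params(f, ~covid, weights = "proportional")
  co <- coef(f)
  w_m <- mean(d$sex == "M")
  expect_equal(g$mesor[1], co[["(Intercept)"]] + w_m * co[["sexM"]],
               tolerance = 1e-10)
})

test_that("unobserved grid cells are computed but flagged extrapolated", {
  set.seed(41)
  n_sub <- 30
  sex <- sample(c("F", "M"), n_sub, TRUE)
  covid <- ifelse(sex == "M", "neg",
                  sample(c("neg", "pos"), n_sub, TRUE))  # no M:pos cell
  df <- data.frame(id = rep(1:n_sub, each = 5),
                   time = runif(n_sub * 5, 0, 24),
                   sex = rep(sex, each = 5), covid = rep(covid, each = 5))
  df$y <- 50 + 5 * cos(2 * pi * df$time / 24) + rnorm(nrow(df), 0, 3)
  d <- cosinor_data(df, covariates = c("sex", "covid"))
  f <- fit_cosinor_mixed(d, factors = c("sex", "covid"))
  expect_warning(g <- marginal_linear_params(f, ~covid | sex),
                 "extrapolated")
  expect_equal(sum(g$extrapolated), 1)
  expect_equal(nrow(g), 4)
})

test_that("nonlinear grid parameters come from the inverse relationship", {
  coefs <- c(int = 10, C = 0, x = 3, z = 4, Cx = 0, Cz = 0)
  d <- make_exact_data(coefs, residual_sd = 1e-9)
  f <- fit_cosinor_mixed(d, factors = "C")
  nl <- cosinor_emm(f, ~C)
  expect_equal(nl$amplitude, c(5, 5), tolerance = 1e-6)
  expect_equal(nl$acrophase, rep(-0.927295218, 2), tolerance = 1e-6)
  expect_equal(nl$mesor, c(10, 10), tolerance = 1e-6)

  # rotation invariance of the amplitude: (beta, gamma) -> (gamma, -beta)
  coefs2 <- c(int = 10, C = 0, x = 4, z = -3, Cx = 0, Cz = 0)
  d2 <- make_exact_data(coefs2, residual_sd = 1e-9)
  f2 <- fit_cosinor_mixed(d2, factors = "C")
  nl2 <- cosinor_emm(f2, ~C)
  expect_equal(nl2$amplitude, nl$amplitude, tolerance = 1e-6)
})
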