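# Independent oracles and small fixture builders used across test files.

# Closed-form OLS oracle: (X'X)^{-1} X'Y, no lme4 involvement.
ols_oracle <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# Textbook type-7 quantile: h = (n-1)p + 1, linear interpolation between
# order statistics (independent of stats::quantile).
quantile7_oracle <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# Brute-force circular wrap: try all branches d + 2*pi*k and keep the one
# in (-pi, pi].
wrap_oracle <- function(phi1, phi2) {
  cands <- (phi1 - phi2) + 2 * pi * (-3:3)
  cands[cands > -pi & cands <= pi][1]
}

# Dataset whose residuals are centred within subject, forcing the REML
# random-intercept variance to the zero boundary so the mixed fit must
# coincide with OLS.
make_boundary_data <- function(n_subjects = 12, n_obs = 8, seed = 1) {
  set.seed(seed)
  id <- rep(seq_len(n_subjects), each = n_obs)
  tt <- runif(n_subjects * n_obs, 0, 24)
  g <- rep(sample(c("a", "b"), n_subjects, replace = TRUE), each = n_obs)
  x <- cos(2 * pi * tt / 24)
  z <- sin(2 * pi * tt / 24)
  e <- rnorm(length(tt), 0, 4)
  e <- e - ave(e, id)                      # within-subject centring
  y <- 50 + 3 * (g == "b") + 8 * x - 4 * z + 2 * (g == "b") * x + e
  cosinor_data(data.frame(id = id, time = tt, y = y, g = g),
               time = "time", response = "y", subject = "id",
               covariates = "g")
}

# Noise-free-ish dataset generated directly from given linear coefficients
# for a single binary factor model (used to check exact EMM arithmetic).
make_exact_data <- function(coefs = c(int = 10, C = 2, x = 3, z = 1,
                                      Cx = -1, Cz = 0),
                            residual_sd = 1e-8, seed = 2) {
  set.seed(seed)
  n_sub <- 8
  id <- rep(seq_len(n_sub), each = 6)
  tt <- runif(length(id), 0, 24)
  C <- rep(rep(c("L0", "L1"), each = n_sub / 2), each = 6)
  x <- cos(2 * pi * tt / 24)
  z <- sin(2 * pi * tt / 24)
  c1 <- as.numeric(C == "L1")
  y <- coefs["int"] + coefs["C"] * c1 + coefs["x"] * x + coefs["z"] * z +
    coefs["Cx"] * c1 * x + coefs["Cz"] * c1 * z +
    rnorm(length(id), 0, residual_sd)
  cosinor_data(data.frame(id = id, time = tt, y = y, C = C),
               time = "time", response = "y", subject = "id",
               covariates = "C")
}
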