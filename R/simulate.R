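#' Simulate a longitudinal circadian dataset with known rhythm parameters
#'
#' Generates sparse, non-uniformly sampled repeated daily measurements from
#' the same mixed-effects cosinor model the fitter assumes: each subject is
#' assigned to a covariate cell with its own true \eqn{(M, A, \phi)}, the
#' triple is mapped to linear coefficients via [cosinor_to_linear()],
#' subject-level random deviations are drawn on the linear
#' \eqn{(M, \beta, \gamma)} scale from a multivariate normal, and Gaussian
#' residual noise is added. Generating random effects on the linear scale
#' matches the fitted model exactly; subject-level amplitude and acrophase
#' then follow a derived, non-Gaussian distribution.
#'
#' Sampling times emulate wearable data: `"daytime"` (default) draws most
#' times from waking hours (a normal centred early afternoon, truncated to
#' 6--23 h) with a small uniform background over the full day; `"uniform"`
#' draws uniformly over \eqn{[0, period)}. Missingness is applied by
#' dropping each planned observation independently with probability
#' `missing_rate` (a missing-completely-at-random mechanism, the simplest
#' case of MAR).
#'
#' @param n_subjects number of subjects.
#' @param obs_per_subject planned observations per subject: a single count
#'   or a length-2 range sampled uniformly per subject.
#' @param period rhythm period in hours.
#' @param sampling `"daytime"` or `"uniform"` time-of-day scheme.
#' @param factors named list of level vectors for the categorical
#'   covariates, e.g. `list(sex = c("F", "M"), bmi = c("normal", "high"))`.
#' @param proportions optional named list of level probabilities per factor
#'   (default equal). Factors are assigned independently per subject.
#' @param truth data.frame giving the true cell parameters: one row per
#'   combination of all factor levels, with the factor columns plus
#'   `mesor`, `amplitude`, `acrophase`. `NULL` uses an HRV-like default.
#' @param re_sd length-3 named numeric: standard deviations of the
#'   subject-level deviations of `mesor`, `beta`, `gamma` (response units).
#' @param re_cor optional 3x3 correlation matrix for the random effects
#'   (default identity).
#' @param residual_sd residual standard deviation (must be > 0).
#' @param missing_rate probability in \eqn{[0, 1)} that a planned
#'   observation is dropped.
#' @param seed optional integer seed for reproducibility.
#' @return a [cosinor_data()] object with columns `id`, `time`, `y` and the
#'   factor columns; the generating parameters are attached as attributes
#'   `truth` (cell-level, with linear coefficients appended) and `design`.
#' @examples
#' d <- simulate_cosinor_data(n_subjects = 30, obs_per_subject = 8, seed = 42)
#' attr(d, "truth")
#' @export
simulate_cosinor_data <- function(n_subjects = 100,
                                  obs_per_subject = 10,
                                  period = 24,
                                  sampling = c("daytime", "uniform"),
                                  factors = list(group = c("A", "B")),
                                  proportions = NULL,
                                  truth = NULL,
                                  re_sd = c(mesor = 8, beta = 2, gamma = 2),
                                  re_cor = NULL,
                                  residual_sd = 10,
                                  missing_rate = 0,
                                  seed = NULL) {
  check_period(period)
  sampling <- match.arg(sampling)
  if (!is.null(seed)) set.seed(seed)
  if (length(re_sd) != 3L || any(re_sd < 0))
    stop("`re_sd` must be 3 nonnegative sds (mesor, beta, gamma)", call. = FALSE)
  if (residual_sd <= 0) stop("`residual_sd` must be > 0", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  if (is.null(re_cor)) re_cor <- diag(3)

  factors <- factors %||% list()
  fnames <- names(factors)
  if (length(factors) && (is.null(fnames) || any(fnames == "")))
    stop("`factors` must be a named list of level vectors", call. = FALSE)

  if (is.null(truth)) truth <- default_truth(factors)
  key <- function(df) {
    if (!length(fnames)) return(rep("", nrow(df)))
    do.call(paste, c(lapply(df[fnames], as.character), sep = "\r"))
  }
  cells <- if (length(factors)) {
    expand.grid(factors, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else data.frame(row.names = 1)
  truth_key <- key(truth)
  missing_cells <- setdiff(key(cells), truth_key)
  if (length(missing_cells))
    stop("`truth` does not cover every factor cell (",
         length(missing_cells), " missing)", call. = FALSE)
  lin <- cosinor_to_linear(truth$mesor, truth$amplitude, truth$acrophase)
  truth$beta <- lin$beta
  truth$gamma <- lin$gamma

  # subject-level factor assignment
  subj <- data.frame(id = sprintf("s%03d", seq_len(n_subjects)))
  for (f in fnames) {
    p <- proportions[[f]] %||% rep(1 / length(factors[[f]]), length(factors[[f]]))
    if (length(p) != length(factors[[f]]) || abs(sum(p) - 1) > 1e-8)
      stop("proportions for `", f, "` must match its levels and sum to 1",
           call. = FALSE)
    subj[[f]] <- sample(factors[[f]], n_subjects, replace = TRUE, prob = p)
  }
  idx <- match(key(subj), truth_key)

  # random effects on the linear scale: b = D * chol(R)' * z
  Lr <- t(chol(re_cor))
  b <- t(diag(re_sd, 3) %*% Lr %*% matrix(stats::rnorm(3 * n_subjects), 3))

  n_i <- if (length(obs_per_subject) == 2L) {
    sample(seq(obs_per_subject[1], obs_per_subject[2]), n_subjects,
           replace = TRUE)
  } else rep_len(obs_per_subject, n_subjects)

  row_id <- rep(seq_len(n_subjects), n_i)
  n_tot <- length(row_id)
  tt <- draw_times(n_tot, period, sampling)
  xz <- recode_time(tt, period)
  mu <- (truth$mesor[idx][row_id] + b[row_id, 1]) +
    (truth$beta[idx][row_id] + b[row_id, 2]) * xz$x +
    (truth$gamma[idx][row_id] + b[row_id, 3]) * xz$z
  y <- mu + stats::rnorm(n_tot, 0, residual_sd)

  out <- data.frame(id = subj$id[row_id], time = tt, y = y)
  for (f in fnames) out[[f]] <- subj[[f]][row_id]
  if (missing_rate > 0)
    out <- out[stats::runif(n_tot) >= missing_rate, , drop = FALSE]

  cd <- cosinor_data(out, time = "time", response = "y", subject = "id",
                     covariates = fnames, period = period)
  attr(cd, "truth") <- truth
  attr(cd, "design") <- list(n_subjects = n_subjects,
                             obs_per_subject = obs_per_subject,
                             period = period, sampling = sampling,
                             re_sd = re_sd, re_cor = re_cor,
                             residual_sd = residual_sd,
                             missing_rate = missing_rate, seed = seed)
  cd
}

# HRV-like default truth: mesor ~50 ms, amplitude 6-10 ms, overnight peak
default_truth <- function(factors) {
  if (!length(factors))
    return(data.frame(mesor = 50, amplitude = 10, acrophase = -1.0))
  cells <- expand.grid(factors, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  k <- nrow(cells)
  cells$mesor <- 50 - 4 * (seq_len(k) - 1)
  cells$amplitude <- 10 - 2 * ((seq_len(k) - 1) %% 3)
  cells$acrophase <- -1.0 - 0.4 * (seq_len(k) - 1)
  cells
}

draw_times <- function(n, period, sampling) {
  if (sampling == "uniform") return(stats::runif(n, 0, period))
  # daytime: 85% truncated normal over waking hours, 15% uniform background
  waking <- stats::runif(n) < 0.85
  t <- numeric(n)
  nw <- sum(waking)
  if (nw) {
    lo <- stats::pnorm(6, 13, 4)
    hi <- stats::pnorm(23, 13, 4)
    t[waking] <- stats::qnorm(stats::runif(nw, lo, hi), 13, 4)
  }
  t[!waking] <- stats::runif(n - nw, 0, 24)
  (t / 24 * period) %% period
}

#' Write a simulated (or any) cosinor dataset to delimited text
#'
#' Writes the observation table as CSV and, when the dataset carries
#' generating truth (from [simulate_cosinor_data()]), the true cell
#' parameters as a YAML sidecar next to it.
#'
#' @param data a `cosinor_data` object.
#' @param path output CSV path.
#' @param truth_path optional path for the truth sidecar; default
#'   `<path>.truth.yaml` when truth is present.
#' @return `path`, invisibly.
#' @export
write_cosinor_data <- function(data, path, truth_path = NULL) {
  df <- as.data.frame(data)
  df$x <- NULL
  df$z <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  truth <- attr(data, "truth")
  if (!is.null(truth)) {
    truth_path <- truth_path %||% paste0(path, ".truth.yaml")
    yaml::write_yaml(lapply(as.list(truth), as.vector), truth_path)
  }
  invisible(path)
}
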