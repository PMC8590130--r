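#' Bootstrap the nonlinear cosinor parameters and their group contrasts
#'
#' Amplitude and acrophase are nonlinear functions of the fixed-effect
#' coefficients, so their sampling distributions are obtained by
#' bootstrapping. Each replicate repeats the full estimation pipeline:
#' \enumerate{
#'   \item resample or regenerate the data (see `scheme`) and refit the
#'     linear mixed model;
#'   \item compute the estimated marginal means of the linear parameters
#'     \eqn{(M_g, \beta_g, \gamma_g)} for each grid cell;
#'   \item apply the inverse relationship to obtain \eqn{(M_g, A_g, \phi_g)};
#'   \item form all pairwise differences between cells within each
#'     conditioning stratum (acrophase differences wrapped to the minimal
#'     circular branch).
#' }
#' The default `"parametric"` scheme simulates responses from the fitted
#' model (fixed effects, estimated random-effect covariance, residual
#' variance) and refits; `"cluster"` resamples whole subjects with
#' replacement. Replicates whose refit fails are skipped and counted; if
#' more than 10\% fail the result is flagged unreliable, and if all fail an
#' error is raised. The EMM averaging matrix depends only on the design, so
#' it is computed once and reused across replicates.
#'
#' @param fit a `cosinor_fit`.
#' @param specs EMM/contrast specification, e.g. `~COVID` or
#'   `~bmi_cat | sex`.
#' @param nsim number of bootstrap replicates (default 500).
#' @param seed optional integer seed; fixed seed gives identical draws.
#' @param scheme `"parametric"` (default) or `"cluster"`.
#' @param level confidence level for downstream intervals.
#' @param weights EMM averaging weights, see [marginal_linear_params()].
#' @return a `cosinor_boot` object holding per-replicate cell draws and
#'   contrast draws, the full-data point estimates, and bookkeeping
#'   (`n_requested`, `n_failed`, `seed`, `scheme`, `level`). Summarise with
#'   [means_ci()] and [contrasts_ci()].
#' @examples
#' d <- simulate_cosinor_data(n_subjects = 25, obs_per_subject = 6, seed = 7)
#' f <- fit_cosinor_mixed(d, factors = "group")
#' b <- bootstrap_cosinor(f, ~group, nsim = 50, seed = 1)
#' contrasts_ci(b)
#' @export
bootstrap_cosinor <- function(fit, specs, nsim = 500, seed = NULL,
                              scheme = c("parametric", "cluster"),
                              level = 0.95,
                              weights = c("equal", "proportional")) {
  scheme <- match.arg(scheme)
  weights <- match.arg(weights)
  if (!inherits(fit, "cosinor_fit"))
    stop("`fit` must be a cosinor_fit", call. = FALSE)
  if (nsim < 1) stop("`nsim` must be >= 1", call. = FALSE)
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  grid <- marginal_linear_params(fit, specs, weights)
  L <- attr(grid, "L")                # cells x 3 x p
  n_cells <- nrow(grid)
  period <- fit$period
  means_over <- attr(grid, "means_over")
  conditioned_on <- attr(grid, "conditioned_on")
  # flatten to p x (3*cells) for one matrix product per replicate
  p <- dim(L)[3]
  Lmat <- matrix(aperm(L, c(3, 2, 1)), nrow = p)  # columns: (param, cell)

  cell_labels <- if (length(means_over))
    apply(as.data.frame(grid)[, means_over, drop = FALSE], 1, paste,
          collapse = ":")
  else rep("overall", n_cells)
  n_per_stratum <- prod(vapply(fit$xlev[means_over], length, integer(1)))
  n_strata <- n_cells / n_per_stratum
  pairs <- make_pairs(n_per_stratum, n_strata)

  est0 <- linear_to_cosinor(grid$mesor, grid$beta, grid$gamma, period)
  contrast_est <- pair_contrasts(as.matrix(est0[c("mesor", "amplitude",
                                                  "acrophase")]), pairs)

  cell_draws <- array(NA_real_, dim = c(nsim, n_cells, 3),
                      dimnames = list(NULL, NULL,
                                      c("mesor", "amplitude", "acrophase")))
  contrast_draws <- array(NA_real_, dim = c(nsim, nrow(pairs), 3),
                          dimnames = list(NULL, NULL,
                                          c("mesor", "amplitude", "acrophase")))

  one_replicate <- switch(scheme,
    parametric = {
      ysim <- stats::simulate(fit$model, nsim = nsim)
      function(b) {
        m <- lme4::refit(fit$model, ysim[[b]], control = fit$control)
        lme4::fixef(m)
      }
    },
    cluster = {
      df <- as.data.frame(fit$data)
      sp <- split(seq_len(nrow(df)), df[[fit$subject]], drop = TRUE)
      function(b) {
        take <- sample(length(sp), length(sp), replace = TRUE)
        idx <- unlist(sp[take], use.names = FALSE)
        nd <- df[idx, , drop = FALSE]
        nd[[fit$subject]] <- factor(rep(seq_along(take),
                                        lengths(sp[take])))
        m <- suppressMessages(
          lme4::lmer(stats::formula(fit$model), data = nd, REML = fit$reml,
                     control = fit$control))
        co <- lme4::fixef(m)
        if (length(co) != p) stop("rank change in resample")
        co
      }
    })

  n_failed <- 0L
  for (b in seq_len(nsim)) {
    co <- tryCatch(one_replicate(b), error = function(e) NULL)
    if (is.null(co) || anyNA(co) || any(!is.finite(co))) {
      n_failed <- n_failed + 1L
      next
    }
    lin <- matrix(drop(co %*% Lmat), nrow = 3)  # 3 x cells
    nl <- linear_to_cosinor(lin[1, ], lin[2, ], lin[3, ], period)
    cell_draws[b, , ] <- as.matrix(nl[c("mesor", "amplitude", "acrophase")])
    contrast_draws[b, , ] <-
      pair_contrasts(as.matrix(nl[c("mesor", "amplitude", "acrophase")]),
                     pairs)
  }
  if (n_failed == nsim)
    stop("all ", nsim, " bootstrap refits failed", call. = FALSE)
  unreliable <- n_failed / nsim > 0.1
  if (unreliable)
    warning(n_failed, " of ", nsim,
            " bootstrap refits failed (> 10%); result flagged unreliable",
            call. = FALSE)

  structure(list(
    cell_draws = cell_draws,
    contrast_draws = contrast_draws,
    grid = grid,
    est = est0,
    contrast_est = contrast_est,
    pairs = pairs,
    cell_labels = cell_labels,
    means_over = means_over,
    conditioned_on = conditioned_on,
    period = period,
    n_requested = as.integer(nsim),
    n_failed = n_failed,
    unreliable = unreliable,
    ci_level = level,
    seed = seed,
    scheme = scheme
  ), class = "cosinor_boot")
}

# all i<j pairs within each stratum of consecutive cells
make_pairs <- function(n_per_stratum, n_strata) {
  if (n_per_stratum < 2)
    stop("need at least 2 cells to contrast", call. = FALSE)
  base <- t(utils::combn(n_per_stratum, 2))
  out <- do.call(rbind, lapply(seq_len(n_strata), function(s) {
    off <- (s - 1L) * n_per_stratum
    cbind(i = base[, 1] + off, j = base[, 2] + off, stratum = s)
  }))
  as.data.frame(out)
}

# params: cells x 3 matrix (mesor, amplitude, acrophase) -> pairs x 3
pair_contrasts <- function(params, pairs) {
  cbind(
    mesor = params[pairs$i, 1] - params[pairs$j, 1],
    amplitude = params[pairs$i, 2] - params[pairs$j, 2],
    acrophase = wrap_phase_difference(params[pairs$i, 3], params[pairs$j, 3])
  )
}

#' @export
print.cosinor_boot <- function(x, ...) {
  cat("<cosinor_boot> ", x$scheme, " bootstrap, ",
      x$n_requested - x$n_failed, "/", x$n_requested, " successful replicates",
      if (x$unreliable) " [UNRELIABLE: >10% failures]", "\n", sep = "")
  print(contrasts_ci(x), ...)
  invisible(x)
}

#' Percentile bootstrap confidence interval
#'
#' Empirical quantiles of the draws at \eqn{(1 - level)/2} and
#' \eqn{1 - (1 - level)/2}, with the standard type-7 interpolation.
#' Identical draws give a valid zero-width interval.
#'
#' @param draws numeric vector of bootstrap draws (NAs dropped).
#' @param level confidence level in (0, 1).
#' @return named numeric `c(lower, upper)`.
#' @export
percentile_ci <- function(draws, level = 0.95) {
  draws <- draws[!is.na(draws)]
  if (length(draws) < 2L)
    stop("need at least 2 successful draws for a percentile interval",
         call. = FALSE)
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  a <- (1 - level) / 2
  q <- stats::quantile(draws, c(a, 1 - a), type = 7, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Two-sided bootstrap p-value from contrast draws
#'
#' Add-one sign-count construction: with \eqn{B} successful draws,
#' \deqn{p = \min\left(1, \frac{2\min(\#\{d \le 0\} + 1, \#\{d \ge 0\} + 1)}{B + 1}\right).}
#' It never returns exactly 0 (the smallest attainable value is
#' \eqn{2/(B+1)}) and is monotone in the imbalance of signs.
#'
#' @param draws numeric vector of bootstrap contrast draws (NAs dropped).
#' @return a p-value in (0, 1].
#' @export
boot_pvalue <- function(draws) {
  draws <- draws[!is.na(draws)]
  if (length(draws) < 1L) stop("no successful draws", call. = FALSE)
  B <- length(draws)
  min(1, 2 * min(sum(draws <= 0) + 1, sum(draws >= 0) + 1) / (B + 1))
}

#' Significance star labels
#'
#' Maps a p-value to the conventional star labels: `***` for p < 0.001,
#' `**` for p < 0.01, `*` for p < 0.05, `+` for p < 0.1 and `""` otherwise
#' (all strict inequalities).
#'
#' @param p numeric vector of p-values in \eqn{[0, 1]}.
#' @return character vector of labels.
#' @export
significance_stars <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*",
                       ifelse(p < 0.1, "+", ""))))
}

# unwrap draws onto the branch nearest the point estimate; returns list
# with adjusted draws and a wide-dispersion flag
unwrap_about <- function(draws, est) {
  dev <- wrap_phase_difference(draws, est)
  list(draws = est + dev,
       wide = (max(dev, na.rm = TRUE) - min(dev, na.rm = TRUE)) > pi)
}

#' Bootstrap confidence intervals for cell-level cosinor parameters
#'
#' Summarises a [bootstrap_cosinor()] result at the cell level: for every
#' grid cell and each of MESOR, amplitude, acrophase and peak time, the
#' full-data point estimate with percentile bootstrap bounds. Acrophase
#' draws are first unwrapped to the circular branch nearest the point
#' estimate (quantiles of raw angles are meaningless across the branch
#' cut); cells whose acrophase dispersion exceeds half a cycle are flagged
#' `wide_phase`. Cells with zero amplitude have undefined acrophase: their
#' phase bounds are `NA`.
#'
#' @param boot a `cosinor_boot` object.
#' @param level confidence level; defaults to the one stored in `boot`.
#' @return a data.frame: grid factor columns, `parameter`, `estimate`,
#'   `lower`, `upper`, `wide_phase`.
#' @export
means_ci <- function(boot, level = NULL) {
  level <- level %||% boot$ci_level
  grid <- as.data.frame(boot$grid)
  fac <- setdiff(names(grid), c("mesor", "beta", "gamma", "extrapolated"))
  period <- boot$period
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    est <- boot$est[i, ]
    m_ci <- percentile_ci(boot$cell_draws[, i, "mesor"], level)
    a_ci <- percentile_ci(boot$cell_draws[, i, "amplitude"], level)
    wide <- FALSE
    if (est$degenerate) {
      p_ci <- c(lower = NA_real_, upper = NA_real_)
      t_ci <- c(lower = NA_real_, upper = NA_real_)
    } else {
      uw <- unwrap_about(boot$cell_draws[, i, "acrophase"], est$acrophase)
      wide <- uw$wide
      p_ci <- percentile_ci(uw$draws, level)
      # peak time is a decreasing linear map of acrophase on the branch
      t_ci <- c(lower = -p_ci[["upper"]] * period / (2 * pi),
                upper = -p_ci[["lower"]] * period / (2 * pi))
    }
    blk <- data.frame(
      parameter = c("mesor", "amplitude", "acrophase", "peak_time"),
      estimate = c(est$mesor, est$amplitude, est$acrophase, est$peak_time),
      lower = c(m_ci[["lower"]], a_ci[["lower"]], p_ci[["lower"]],
                t_ci[["lower"]]),
      upper = c(m_ci[["upper"]], a_ci[["upper"]], p_ci[["upper"]],
                t_ci[["upper"]]),
      wide_phase = c(FALSE, FALSE, wide, wide)
    )
    out[[i]] <- cbind(grid[rep(i, 4), fac, drop = FALSE], blk)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bootstrap confidence intervals and p-values for pairwise contrasts
#'
#' Summarises a [bootstrap_cosinor()] result at the contrast level: all
#' pairwise differences between cells of the means grid within each
#' conditioning stratum, for MESOR, amplitude, and acrophase (the latter
#' reported both in radians, wrapped to \eqn{(-\pi, \pi]}, and in hours,
#' wrapped to half a period). Intervals are percentile bootstrap intervals;
#' p-values come from [boot_pvalue()]; stars from [significance_stars()].
#' No multiplicity adjustment is applied across pairs.
#'
#' @inheritParams means_ci
#' @return a data.frame: conditioning factor columns (if any), `contrast`,
#'   `parameter`, `estimate`, `lower`, `upper`, `p`, `stars`.
#' @export
contrasts_ci <- function(boot, level = NULL) {
  level <- level %||% boot$ci_level
  grid <- as.data.frame(boot$grid)
  period <- boot$period
  cond <- boot$conditioned_on
  out <- vector("list", nrow(boot$pairs))
  for (k in seq_len(nrow(boot$pairs))) {
    i <- boot$pairs$i[k]; j <- boot$pairs$j[k]
    lab <- paste(boot$cell_labels[i], "-", boot$cell_labels[j])
    rows <- list()
    for (par in c("mesor", "amplitude")) {
      d <- boot$contrast_draws[, k, par]
      ci <- percentile_ci(d, level)
      pv <- boot_pvalue(d)
      rows[[par]] <- data.frame(contrast = lab, parameter = par,
                                estimate = boot$contrast_est[k, par],
                                lower = ci[["lower"]], upper = ci[["upper"]],
                                p = pv, stars = significance_stars(pv))
    }
    est_phi <- boot$contrast_est[k, "acrophase"]
    uw <- unwrap_about(boot$contrast_draws[, k, "acrophase"], est_phi)
    ci <- percentile_ci(uw$draws, level)
    pv <- boot_pvalue(uw$draws)
    rows$acrophase <- data.frame(contrast = lab, parameter = "acrophase",
                                 estimate = est_phi,
                                 lower = ci[["lower"]], upper = ci[["upper"]],
                                 p = pv, stars = significance_stars(pv))
    # hours scale: decreasing linear map h = -phi * period / (2*pi)
    rows$acrophase_hours <- data.frame(
      contrast = lab, parameter = "acrophase_hours",
      estimate = -est_phi * period / (2 * pi),
      lower = -ci[["upper"]] * period / (2 * pi),
      upper = -ci[["lower"]] * period / (2 * pi),
      p = pv, stars = significance_stars(pv))
    blk <- do.call(rbind, rows)
    if (length(cond)) {
      blk <- cbind(grid[rep(i, nrow(blk)), cond, drop = FALSE], blk)
    }
    out[[k]] <- blk
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
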