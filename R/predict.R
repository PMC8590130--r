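#' Fitted population-level circadian curves per grid cell
#'
#' Evaluates the marginal fitted curve
#' \eqn{M_g + \beta_g \cos(2\pi t/\tau) + \gamma_g \sin(2\pi t/\tau)} for
#' every cell of an EMM grid on a grid of clock times. The maximum of each
#' curve equals \eqn{M_g + A_g} and occurs at the cell's peak time, up to
#' the time-grid resolution.
#'
#' @param fit a `cosinor_fit`.
#' @param specs EMM specification (see [marginal_linear_params()]); `NULL`
#'   for a model without factors gives the single overall curve.
#' @param times numeric vector of clock times in hours (default: one full
#'   period at 0.1 h resolution).
#' @param weights EMM averaging weights.
#' @return a data.frame with the grid factor columns, `time` and `fitted`.
#' @export
predict_curve <- function(fit, specs = NULL, times = NULL,
                          weights = c("equal", "proportional")) {
  if (!inherits(fit, "cosinor_fit"))
    stop("`fit` must be a cosinor_fit", call. = FALSE)
  times <- times %||% seq(0, fit$period, by = 0.1)
  if (!length(times)) stop("`times` must be non-empty", call. = FALSE)
  if (is.null(specs)) {
    if (length(fit$all_factors))
      stop("model has factors; supply `specs` (e.g. ~", fit$all_factors[1],
           ")", call. = FALSE)
    co <- coef(fit)
    cells <- data.frame(mesor = co[["(Intercept)"]], beta = co[["x"]],
                        gamma = co[["z"]])
    fac <- character()
  } else {
    grid <- marginal_linear_params(fit, specs, match.arg(weights))
    cells <- as.data.frame(grid)
    fac <- setdiff(names(cells), c("mesor", "beta", "gamma", "extrapolated"))
  }
  xz <- recode_time(times, fit$period)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    blk <- data.frame(time = times,
                      fitted = cells$mesor[i] + cells$beta[i] * xz$x +
                        cells$gamma[i] * xz$z)
    if (length(fac)) blk <- cbind(cells[rep(i, length(times)), fac,
                                        drop = FALSE], blk)
    blk
  }))
  rownames(out) <- NULL
  out
}

#' Plot fitted circadian curves
#'
#' Basic ggplot2 rendering of [predict_curve()] output, one colour per grid
#' cell, optionally overlaying the observations. Returned as a ggplot
#' object so further layers can be added.
#'
#' @inheritParams predict_curve
#' @param data optional `cosinor_data` to overlay as points.
#' @return a ggplot object.
#' @export
plot_cosinor_curves <- function(fit, specs = NULL, times = NULL,
                                data = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("package ggplot2 is required for plotting", call. = FALSE)
  cv <- predict_curve(fit, specs, times)
  fac <- setdiff(names(cv), c("time", "fitted"))
  if (length(fac)) {
    cv$cell <- interaction(cv[fac], sep = ":")
    p <- ggplot2::ggplot(cv, ggplot2::aes(x = .data$time, y = .data$fitted,
                                          colour = .data$cell))
  } else {
    p <- ggplot2::ggplot(cv, ggplot2::aes(x = .data$time, y = .data$fitted))
  }
  if (!is.null(data)) {
    roles <- attr(data, "roles")
    pts <- data.frame(time = data[[roles$time]] %% attr(data, "period"),
                      y = data[[roles$response]])
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(x = .data$time, y = .data$y),
                                 inherit.aes = FALSE, alpha = 0.2)
  }
  p + ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time of day (h)", y = fit$response)
}
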