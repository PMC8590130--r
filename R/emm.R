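#' Parse an estimated-marginal-means specification
#'
#' Specifications follow the `emmeans` formula idiom: `~F` requests means
#' over the levels of factor `F`, `~F1 | F2` requests means over `F1`
#' separately within each level of `F2` (conditioning). Several factors may
#' be combined with `+` on either side.
#'
#' @param specs a one-sided formula or a string such as `"~bmi_cat|sex"`.
#' @return a list with character vectors `means_over` and `conditioned_on`.
#' @export
parse_emm_spec <- function(specs) {
  if (inherits(specs, "formula")) specs <- deparse(specs)
  specs <- paste(specs, collapse = "")
  s <- gsub("\\s+", "", specs)
  s <- sub("^~", "", s)
  if (s == "" || grepl("~", s))
    stop("cannot parse EMM specification: ", specs, call. = FALSE)
  parts <- strsplit(s, "|", fixed = TRUE)[[1]]
  if (length(parts) > 2L)
    stop("at most one `|` allowed in an EMM specification", call. = FALSE)
  split_terms <- function(p) {
    if (is.na(p) || p == "") return(character())
    strsplit(p, "[+*:]")[[1]]
  }
  means_over <- split_terms(parts[1])
  conditioned_on <- if (length(parts) == 2L) split_terms(parts[2]) else character()
  if (!length(means_over))
    stop("EMM specification names no factors", call. = FALSE)
  overlap <- intersect(means_over, conditioned_on)
  if (length(overlap))
    stop("factor(s) on both sides of `|`: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  list(means_over = means_over, conditioned_on = conditioned_on)
}

#' Marginal linear cosinor parameters over a factor grid
#'
#' For each combination of the requested factor levels, computes the
#' model-implied linear cosinor triple \eqn{(M_g, \beta_g, \gamma_g)}: the
#' intercept-scale, `x`-scale and `z`-scale components of the linear
#' predictor with the grid factors fixed at their levels and every other
#' model factor averaged over its levels (equal weights by default, as in
#' `emmeans`; `"proportional"` uses the observed joint frequencies).
#'
#' Each grid value is an exact linear combination \eqn{L\hat c} of the
#' fixed-effect coefficients; the averaging matrix \eqn{L} and the
#' per-cell covariance blocks \eqn{L\hat V L^\top} are attached as
#' attributes and reused by the bootstrap (they depend only on the design,
#' not on the coefficients). Grid cells whose factor combination never
#' occurs in the data are still computed (the model defines them) but
#' flagged `extrapolated`.
#'
#' @param fit a `cosinor_fit`.
#' @param specs EMM specification, e.g. `~COVID` or `~bmi_cat | sex`
#'   (formula or string); see [parse_emm_spec()].
#' @param weights `"equal"` (default) or `"proportional"` averaging over
#'   non-grid factors.
#' @return a `cosinor_emm` data.frame: grid factor columns, `mesor`,
#'   `beta`, `gamma`, `extrapolated`; attributes `L` (cells x 3 x p array),
#'   `vcov_blocks`, `period`, `means_over`, `conditioned_on`.
#' @export
marginal_linear_params <- function(fit, specs, weights = c("equal", "proportional")) {
  weights <- match.arg(weights)
  if (!inherits(fit, "cosinor_fit"))
    stop("`fit` must be a cosinor_fit", call. = FALSE)
  sp <- parse_emm_spec(specs)
  grid_factors <- c(sp$means_over, sp$conditioned_on)
  bad <- setdiff(grid_factors, fit$all_factors)
  if (length(bad))
    stop("factor(s) not in the fitted model: ", paste(bad, collapse = ", "),
         call. = FALSE)
  avg_factors <- setdiff(fit$all_factors, grid_factors)

  # grid rows: means_over varies fastest, conditioning strata are blocks
  grid <- expand.grid(lapply(fit$xlev[grid_factors], identity),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = TRUE)
  names(grid) <- grid_factors
  n_cells <- nrow(grid)

  avg <- if (length(avg_factors)) {
    expand.grid(lapply(fit$xlev[avg_factors], identity),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = TRUE)
  } else data.frame(row.names = 1)
  if (length(avg_factors)) names(avg) <- avg_factors
  w <- if (weights == "equal" || !length(avg_factors)) {
    rep(1 / nrow(avg), nrow(avg))
  } else {
    obs <- interaction(as.data.frame(fit$data)[avg_factors], drop = FALSE)
    tab <- table(obs)
    key <- interaction(avg, drop = FALSE)
    freq <- as.numeric(tab[as.character(key)])
    freq[is.na(freq)] <- 0
    if (sum(freq) == 0)
      stop("no observations to form proportional weights", call. = FALSE)
    freq / sum(freq)
  }

  trms <- stats::delete.response(stats::terms(fit$fixed_formula))
  co <- coef(fit)
  p <- length(co)
  mm_at <- function(newdata, xval, zval) {
    newdata$x <- xval
    newdata$z <- zval
    M <- stats::model.matrix(trms, newdata, xlev = fit$xlev)
    if (!identical(colnames(M), names(co)))
      stop("internal error: design columns do not match coefficients")
    M
  }

  obs_cells <- if (n_cells > 0 && length(grid_factors)) {
    unique(interaction(as.data.frame(fit$data)[grid_factors], drop = FALSE))
  } else NULL

  L <- array(0, dim = c(n_cells, 3L, p),
             dimnames = list(NULL, c("mesor", "beta", "gamma"), names(co)))
  extrapolated <- logical(n_cells)
  for (i in seq_len(n_cells)) {
    nd <- avg
    for (f in grid_factors)
      nd[[f]] <- factor(rep(as.character(grid[i, f]), nrow(avg)),
                        levels = fit$xlev[[f]])
    M0 <- mm_at(nd, 0, 0)
    Mx <- mm_at(nd, 1, 0)
    Mz <- mm_at(nd, 0, 1)
    L[i, "mesor", ] <- drop(w %*% M0)
    L[i, "beta", ] <- drop(w %*% (Mx - M0))
    L[i, "gamma", ] <- drop(w %*% (Mz - M0))
    if (!is.null(obs_cells))
      extrapolated[i] <- !(as.character(interaction(grid[i, , drop = FALSE],
                                                    drop = FALSE)) %in%
                             as.character(obs_cells))
  }
  if (any(extrapolated))
    warning("EMM grid contains cell(s) with no observed data (extrapolated): ",
            paste(apply(grid[extrapolated, , drop = FALSE], 1, paste,
                        collapse = ":"), collapse = ", "), call. = FALSE)

  V <- vcov(fit)
  est <- t(apply(L, 1L, function(Li) Li %*% co))
  vcov_blocks <- lapply(seq_len(n_cells), function(i) {
    Li <- matrix(L[i, , ], nrow = 3L)
    B <- Li %*% V %*% t(Li)
    dimnames(B) <- list(c("mesor", "beta", "gamma"), c("mesor", "beta", "gamma"))
    B
  })

  out <- cbind(grid,
               data.frame(mesor = est[, 1], beta = est[, 2], gamma = est[, 3],
                          extrapolated = extrapolated))
  structure(out,
            L = L, vcov_blocks = vcov_blocks,
            period = fit$period,
            means_over = sp$means_over, conditioned_on = sp$conditioned_on,
            class = c("cosinor_emm", "data.frame"))
}

#' Nonlinear cosinor parameters on an EMM grid
#'
#' Applies the inverse relationship [linear_to_cosinor()] row-wise to an
#' EMM grid, yielding per-cell MESOR, amplitude, acrophase and peak time.
#' These are point estimates only; their sampling uncertainty is obtained
#' by [bootstrap_cosinor()], not by a delta-method approximation, because
#' amplitude and acrophase are nonlinear in the coefficients.
#'
#' @param grid a `cosinor_emm` grid from [marginal_linear_params()].
#' @param period rhythm period in hours; defaults to the grid's.
#' @return a data.frame: grid factor columns plus `mesor`, `amplitude`,
#'   `acrophase` (radians in \eqn{(-2\pi, 0]}), `peak_time` (hours),
#'   `degenerate`.
#' @export
marginal_cosinor_params <- function(grid, period = NULL) {
  if (!inherits(grid, "cosinor_emm"))
    stop("`grid` must come from marginal_linear_params()", call. = FALSE)
  period <- period %||% attr(grid, "period")
  nl <- linear_to_cosinor(grid$mesor, grid$beta, grid$gamma, period)
  fac <- setdiff(names(grid), c("mesor", "beta", "gamma", "extrapolated"))
  out <- cbind(as.data.frame(grid)[fac], nl,
               extrapolated = grid$extrapolated)
  attr(out, "period") <- period
  attr(out, "means_over") <- attr(grid, "means_over")
  attr(out, "conditioned_on") <- attr(grid, "conditioned_on")
  out
}

#' @rdname marginal_cosinor_params
#' @inheritParams marginal_linear_params
#' @details `cosinor_emm()` is the one-call convenience wrapper:
#'   `marginal_cosinor_params(marginal_linear_params(fit, specs))`.
#' @export
cosinor_emm <- function(fit, specs, weights = c("equal", "proportional"),
                        period = NULL) {
  marginal_cosinor_params(marginal_linear_params(fit, specs, weights), period)
}

#' @export
print.cosinor_emm <- function(x, ...) {
  cat("<cosinor_emm> marginal linear cosinor parameters (",
      nrow(x), " cell", if (nrow(x) != 1) "s", ")\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}
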