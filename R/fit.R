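#' Build the mixed-effects cosinor model formula
#'
#' Constructs the formula for the linearized cosinor mixed model. Every
#' categorical covariate enters as a treatment-coded main effect and in
#' interaction with both rhythm regressors `x` and `z`, so each factor level
#' has its own MESOR shift and its own rotation of the \eqn{(\beta, \gamma)}
#' pair. An interaction pair contributes the full cell structure of the two
#' factors, again crossed with `x` and `z`. Two random-effect structures are
#' supported: a random MESOR per subject (`(1 | subject)`) or random MESOR
#' plus random rhythm coefficients (`(1 + x + z | subject)`, with an
#' unstructured covariance).
#'
#' @param response response column name.
#' @param factors character vector of additive categorical covariates.
#' @param interactions character vector of length 2 (or list of such pairs)
#'   naming factor pairs whose full interaction enters the model.
#' @param random `"mesor"` or `"rhythm"`.
#' @param subject subject-identifier column name.
#' @return a list with elements `fixed` (one-sided fixed-effects formula),
#'   `full` (two-sided formula including the random-effect term) and
#'   `random` (the structure name).
#' @export
build_cosinor_formula <- function(response, factors = character(),
                                  interactions = NULL,
                                  random = c("mesor", "rhythm"),
                                  subject = "id") {
  random <- match.arg(random)
  if (!is.null(interactions) && !is.list(interactions))
    interactions <- list(interactions)
  for (p in interactions %||% list())
    if (length(p) != 2L)
      stop("each interaction must name exactly two factors", call. = FALSE)
  terms_c <- c(factors,
               vapply(interactions %||% list(),
                      function(p) paste(p, collapse = " * "), character(1)))
  fixed_rhs <- if (length(terms_c))
    sprintf("(%s) * (x + z)", paste(terms_c, collapse = " + "))
  else
    "x + z"
  re <- switch(random,
               mesor = sprintf("(1 | %s)", subject),
               rhythm = sprintf("(1 + x + z | %s)", subject))
  list(
    fixed = stats::as.formula(paste("~", fixed_rhs)),
    full = stats::as.formula(paste(response, "~", fixed_rhs, "+", re)),
    random = random
  )
}

#' Fit a mixed-effects cosinor model
#'
#' Fits the linearized cosinor model with subject-level random effects by
#' (RE)ML using \pkg{lme4}. Fixed effects comprise the grand MESOR and
#' rhythm coefficients \eqn{(\beta, \gamma)} plus, for every factor (or
#' interaction cell) beyond the reference, a MESOR offset and offsets to
#' \eqn{\beta} and \eqn{\gamma}. Random effects model the within-subject
#' correlation of repeated daily measurements; their covariance is
#' unstructured.
#'
#' The design matrix is checked for full column rank before fitting;
#' aliased columns are reported by name. Subjects contributing a single
#' observation are allowed (they inform the fixed effects) but are counted
#' in a message. A fit whose random-effect covariance lands on the zero
#' boundary is returned with `singular = TRUE`; its fixed effects then
#' coincide with ordinary least squares.
#'
#' @param data a [cosinor_data()] object.
#' @param response response column; defaults to the role declared in `data`.
#' @param factors character vector of categorical covariates entering
#'   additively (each crossed with the rhythm terms).
#' @param interactions a factor pair (or list of pairs) entering as a full
#'   interaction, crossed with the rhythm terms.
#' @param random random-effect structure: `"mesor"` (random intercept) or
#'   `"rhythm"` (random intercept + random `x` and `z` coefficients).
#' @param reml logical; REML (default) or ML estimation.
#' @param control an [lme4::lmerControl()] object. The default disables the
#'   finite-difference derivative check (the optimizer's own convergence
#'   code is retained) to keep repeated bootstrap refits fast.
#' @return a `cosinor_fit` object wrapping the \pkg{lme4} fit together with
#'   the dataset, formulas, factor levels and convergence flags.
#' @examples
#' d <- simulate_cosinor_data(n_subjects = 20, obs_per_subject = 6, seed = 1)
#' f <- fit_cosinor_mixed(d, factors = "group")
#' coef(f)
#' @export
fit_cosinor_mixed <- function(data, response = NULL, factors = character(),
                              interactions = NULL,
                              random = c("mesor", "rhythm"), reml = TRUE,
                              control = cosinor_lmer_control()) {
  if (!inherits(data, "cosinor_data"))
    stop("`data` must be a cosinor_data object", call. = FALSE)
  random <- match.arg(random)
  roles <- attr(data, "roles")
  response <- response %||% roles$response
  subject <- roles$subject
  all_factors <- unique(c(factors, unlist(interactions)))
  missing_f <- setdiff(c(response, all_factors), names(data))
  if (length(missing_f))
    stop("column(s) not in dataset: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  for (f in all_factors) {
    if (!is.factor(data[[f]])) data[[f]] <- factor(data[[f]])
    if (nlevels(droplevels(data[[f]])) < 2L)
      stop("factor `", f, "` has fewer than 2 observed levels", call. = FALSE)
    data[[f]] <- droplevels(data[[f]])
  }

  fml <- build_cosinor_formula(response, factors, interactions, random,
                               subject)

  X <- stats::model.matrix(fml$fixed, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fixed-effects design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  n_single <- sum(table(droplevels(data[[subject]])) == 1L)
  if (n_single > 0)
    message("fit_cosinor_mixed: ", n_single,
            " subject(s) contribute a single observation")

  model <- lme4::lmer(fml$full, data = as.data.frame(data), REML = reml,
                      control = control)
  opt_ok <- isTRUE(model@optinfo$conv$opt == 0)
  singular <- lme4::isSingular(model)
  if (!opt_ok)
    warning("mixed-model optimizer did not report convergence", call. = FALSE)

  xlev <- lapply(all_factors, function(f) levels(data[[f]]))
  names(xlev) <- all_factors

  structure(list(
    model = model,
    data = data,
    response = response,
    factors = factors,
    interactions = if (is.null(interactions) || is.list(interactions))
      interactions else list(interactions),
    all_factors = all_factors,
    random = random,
    fixed_formula = fml$fixed,
    period = attr(data, "period"),
    subject = subject,
    xlev = xlev,
    reml = reml,
    control = control,
    converged = opt_ok,
    singular = singular,
    n_obs = nrow(data),
    n_subjects = nlevels(droplevels(data[[subject]]))
  ), class = "cosinor_fit")
}

#' Default optimizer control for cosinor mixed fits
#'
#' \code{lmerControl} preset used by [fit_cosinor_mixed()]: the
#' finite-difference derivative check after optimization is disabled (it
#' dominates runtime for small models and is redundant with the optimizer's
#' own convergence code), and singular-fit messages are suppressed because
#' boundary fits are an expected, flagged outcome here.
#'
#' @param ... passed on to [lme4::lmerControl()].
#' @return an `lmerControl` object.
#' @export
cosinor_lmer_control <- function(...) {
  lme4::lmerControl(calc.derivs = FALSE,
                    check.conv.singular = "ignore",
                    check.conv.grad = "ignore",
                    check.conv.hess = "ignore",
                    check.nlev.gtr.1 = "ignore",
                    ...)
}

#' @export
coef.cosinor_fit <- function(object, ...) lme4::fixef(object$model)

#' @export
vcov.cosinor_fit <- function(object, ...) {
  V <- as.matrix(stats::vcov(object$model))
  dimnames(V) <- list(names(lme4::fixef(object$model)),
                      names(lme4::fixef(object$model)))
  V
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat("<cosinor_fit> ", x$response, " on ", x$n_obs, " obs / ",
      x$n_subjects, " subjects, period ", x$period, " h\n", sep = "")
  cat("  random structure:",
      if (x$random == "mesor") "(1 | subject)" else "(1 + x + z | subject)",
      if (x$singular) "[boundary]" else "", "\n")
  print(round(lme4::fixef(x$model), 4))
  invisible(x)
}

#' @export
summary.cosinor_fit <- function(object, ...) {
  co <- lme4::fixef(object$model)
  se <- sqrt(diag(vcov(object)))
  zval <- co / se
  vc <- as.data.frame(lme4::VarCorr(object$model))
  out <- list(
    coefficients = data.frame(estimate = co, se = se, z = zval,
                              p = 2 * stats::pnorm(-abs(zval))),
    varcorr = vc,
    sigma = stats::sigma(object$model),
    converged = object$converged,
    singular = object$singular,
    n_obs = object$n_obs,
    n_subjects = object$n_subjects
  )
  class(out) <- "summary.cosinor_fit"
  out
}

#' @export
print.summary.cosinor_fit <- function(x, ...) {
  cat("Fixed effects:\n")
  print(round(x$coefficients, 5))
  cat("\nRandom effects / residual:\n")
  print(x$varcorr)
  cat("\nconverged:", x$converged, " boundary:", x$singular,
      " n_obs:", x$n_obs, " n_subjects:", x$n_subjects, "\n")
  invisible(x)
}

#' Wald test of a linear combination of fixed effects
#'
#' Any hypothesis expressible as a linear function of the fixed-effect
#' coefficients (MESOR offsets and the \eqn{\beta}/\eqn{\gamma} terms) can
#' be tested directly from the estimated coefficients and their covariance:
#' the statistic is \eqn{w^\top\hat c / \sqrt{w^\top \hat V w}}, referred to
#' a standard normal. No degrees-of-freedom correction is applied. The
#' nonlinear parameters (amplitude, acrophase) are not linear in the
#' coefficients; use [bootstrap_cosinor()] for those.
#'
#' @param fit a `cosinor_fit`.
#' @param weights numeric vector of contrast weights, either of the full
#'   coefficient length (in coefficient order) or named by coefficient.
#' @return a one-row data.frame: `estimate`, `se`, `z`, `p`.
#' @export
wald_test <- function(fit, weights) {
  co <- coef(fit)
  if (!is.null(names(weights))) {
    bad <- setdiff(names(weights), names(co))
    if (length(bad))
      stop("unknown coefficient(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    w <- stats::setNames(numeric(length(co)), names(co))
    w[names(weights)] <- weights
  } else {
    if (length(weights) != length(co))
      stop("`weights` must have length ", length(co),
           " (or be named)", call. = FALSE)
    w <- as.numeric(weights)
  }
  if (all(w == 0)) stop("`weights` must not be all zero", call. = FALSE)
  est <- sum(w * co)
  se <- sqrt(drop(t(w) %*% vcov(fit) %*% w))
  zval <- est / se
  data.frame(estimate = est, se = se, z = zval,
             p = 2 * stats::pnorm(-abs(zval)))
}
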