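#' Build a validated cosinor dataset from long-format observations
#'
#' Takes one row per observation (subject identifier, clock time in hours,
#' a continuous response, and optional categorical covariates), appends the
#' rhythm regressors `x` and `z` via [recode_time()], and validates the
#' result. Rows with missing response or missing values in any declared
#' covariate are dropped; the drop count is recorded in the `n_dropped`
#' attribute and reported with a message. Rows with missing subject or time
#' are an error: they cannot be analysed under any model.
#'
#' Times are used modulo the period; no date arithmetic is performed.
#'
#' @param data a data.frame in long format.
#' @param time,response,subject names of the columns holding time-of-day
#'   (hours), the response, and the subject identifier.
#' @param covariates character vector of categorical covariate column names
#'   (may be empty). Each is converted to a factor.
#' @param period rhythm period in hours (default 24).
#' @return a `cosinor_data` object: the input data.frame restricted to
#'   complete cases, with numeric `x` and `z` columns appended and
#'   attributes `period`, `roles` (column-role map), `n_dropped`.
#' @examples
#' d <- data.frame(id = c("a", "a", "b"), hour = c(0, 6, 12),
#'                 hrv = c(55, 62, 48))
#' cd <- cosinor_data(d, time = "hour", response = "hrv", subject = "id")
#' cd$x  # 1, 0, -1
#' @export
cosinor_data <- function(data, time = "time", response = "y", subject = "id",
                         covariates = character(), period = 24) {
  check_period(period)
  if (!is.data.frame(data)) stop("`data` must be a data.frame", call. = FALSE)
  covariates <- as.character(covariates %||% character())
  needed <- c(time, response, subject, covariates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  data <- as.data.frame(data)

  if (anyNA(data[[subject]]) || anyNA(data[[time]]))
    stop("missing subject id or time in rows: ",
         paste(utils::head(which(is.na(data[[subject]]) | is.na(data[[time]])), 5),
               collapse = ", "), call. = FALSE)
  if (!is.numeric(data[[time]]))
    stop("time column `", time, "` must be numeric (hours)", call. = FALSE)
  if (!is.numeric(data[[response]]))
    stop("response column `", response, "` must be numeric", call. = FALSE)

  keep <- !is.na(data[[response]])
  for (cv in covariates) keep <- keep & !is.na(data[[cv]])
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("cosinor_data: dropped ", n_dropped,
            " row(s) with missing response or covariate values")
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL

  out[[subject]] <- factor(out[[subject]])
  for (cv in covariates) out[[cv]] <- factor(out[[cv]])

  xz <- recode_time(out[[time]], period)
  out$x <- xz$x
  out$z <- xz$z

  structure(out,
            period = period,
            roles = list(time = time, response = response, subject = subject,
                         covariates = covariates),
            n_dropped = n_dropped,
            class = c("cosinor_data", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a delimited long-format file into a cosinor dataset
#'
#' Reads a comma- or tab-delimited text file (header row required; the
#' delimiter is sniffed from the header unless given) and passes it to
#' [cosinor_data()].
#'
#' @inheritParams cosinor_data
#' @param path path to the delimited file.
#' @param sep field delimiter; `NULL` (default) sniffs "," vs tab from the
#'   header line.
#' @return a `cosinor_data` object.
#' @export
read_cosinor_data <- function(path, time = "time", response = "y",
                              subject = "id", covariates = character(),
                              period = 24, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  cosinor_data(raw, time = time, response = response, subject = subject,
               covariates = covariates, period = period)
}

#' @export
print.cosinor_data <- function(x, ...) {
  roles <- attr(x, "roles")
  cat("<cosinor_data> ", nrow(x), " observations, ",
      nlevels(x[[roles$subject]]), " subjects, period ",
      attr(x, "period"), " h\n", sep = "")
  if (attr(x, "n_dropped") > 0)
    cat("  (", attr(x, "n_dropped"), " incomplete row(s) dropped)\n", sep = "")
  print(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Per-subject sampling summary of a cosinor dataset
#'
#' One row per subject: number of observations, earliest and latest time of
#' day, and the within-day spread of sampling times. Subjects whose
#' observations all fall at a single clock time are flagged: they carry no
#' information about the rhythm shape.
#'
#' @param object a `cosinor_data` object.
#' @param ... unused.
#' @return a data.frame with columns `subject`, `n_obs`, `t_min`, `t_max`,
#'   `t_spread` and logical `no_spread`.
#' @export
summary.cosinor_data <- function(object, ...) {
  roles <- attr(object, "roles")
  period <- attr(object, "period")
  if (nrow(object) == 0L)
    return(data.frame(subject = character(), n_obs = integer(),
                      t_min = numeric(), t_max = numeric(),
                      t_spread = numeric(), no_spread = logical()))
  tt <- object[[roles$time]] %% period
  sp <- split(tt, object[[roles$subject]], drop = TRUE)
  out <- data.frame(
    subject = names(sp),
    n_obs = vapply(sp, length, integer(1)),
    t_min = vapply(sp, min, numeric(1)),
    t_max = vapply(sp, max, numeric(1)),
    row.names = NULL
  )
  out$t_spread <- out$t_max - out$t_min
  out$no_spread <- out$n_obs > 1L & out$t_spread == 0
  if (any(out$no_spread))
    warning("subject(s) with no within-day spread of sampling times: ",
            paste(out$subject[out$no_spread], collapse = ", "), call. = FALSE)
  out
}
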