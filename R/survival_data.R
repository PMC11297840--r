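#' Construct a right-censored survival dataset
#'
#' Bundles observed survival times, event indicators and baseline covariates
#' into the container used throughout the package.  Rows with missing values
#' in any of the supplied columns are dropped (with a message reporting the
#' count), covariates keep their measurement scale (numeric columns are
#' treated as continuous, `factor` columns as unordered factors, `ordered`
#' columns as ordered factors).
#'
#' @param time numeric vector of observed survival times (nonnegative).
#' @param event integer/logical vector; 1 (or `TRUE`) if the event was
#'   observed, 0 if the individual was right-censored.
#' @param covariates data frame with one row per individual, or `NULL` for a
#'   covariate-free dataset.
#' @param id optional identifiers; defaults to `1:n`.
#' @return An object of class `survival_data` with components `id`, `time`,
#'   `event` and `x` (a data frame, possibly with zero columns).
#' @examples
#' d <- survival_data(time = c(1, 2, 3), event = c(1, 0, 1),
#'                    covariates = data.frame(age = c(50, 61, 47)))
#' d$event
#' @export
survival_data <- function(time, event, covariates = NULL, id = NULL) {
  if (is.logical(event)) event <- as.integer(event)
  n <- length(time)
  if (length(event) != n)
    stop("'time' and 'event' must have the same length", call. = FALSE)
  if (is.null(covariates)) {
    covariates <- as.data.frame(matrix(nrow = n, ncol = 0))
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n)
    stop("'covariates' must have one row per individual", call. = FALSE)
  if (is.null(id)) id <- seq_len(n)
  if (length(id) != n)
    stop("'id' must have one entry per individual", call. = FALSE)

  keep <- !is.na(time) & !is.na(event)
  if (ncol(covariates) > 0L)
    keep <- keep & stats::complete.cases(covariates)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("survival_data: dropped %d row(s) with missing values", dropped))
    time <- time[keep]; event <- event[keep]
    covariates <- covariates[keep, , drop = FALSE]
    id <- id[keep]
    n <- length(time)
  }
  if (n < 2L) stop("at least two individuals are required", call. = FALSE)
  if (any(time < 0)) stop("'time' must be nonnegative", call. = FALSE)
  if (!all(event %in% c(0L, 1L)))
    stop("'event' must be binary (0 = censored, 1 = event)", call. = FALSE)

  for (j in seq_along(covariates)) {
    if (is.character(covariates[[j]]))
      covariates[[j]] <- factor(covariates[[j]])
  }
  rownames(covariates) <- NULL
  structure(list(id = id, time = as.numeric(time), event = as.integer(event),
                 x = covariates),
            class = "survival_data")
}

#' @export
print.survival_data <- function(x, ...) {
  cat(sprintf("Right-censored survival data: n = %d, events = %d (%.1f%%), p = %d covariate(s)\n",
              length(x$time), sum(x$event), 100 * mean(x$event), ncol(x$x)))
  invisible(x)
}

#' Number of individuals in a survival dataset
#' @param x a `survival_data` object.
#' @return integer count.
#' @export
n_individuals <- function(x) {
  stopifnot(inherits(x, "survival_data"))
  length(x$time)
}

#' Read right-censored survival data from a delimited text file
#'
#' Expects columns `id`, `time` and `status` (0/1); all remaining columns are
#' taken as covariates.  An optional sidecar configuration can declare
#' covariate measurement scales.
#'
#' @param file path to a CSV file.
#' @param scales optional named character vector mapping covariate names to
#'   `"continuous"`, `"ordered"` or `"unordered"`; unlisted columns keep the
#'   type inferred by [utils::read.csv()].
#' @param ... passed on to [utils::read.csv()].
#' @return A `survival_data` object.
#' @export
read_survival_csv <- function(file, scales = NULL, ...) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, ...)
  required <- c("id", "time", "status")
  if (!all(required %in% names(df)))
    stop("CSV must contain columns 'id', 'time' and 'status'", call. = FALSE)
  covs <- df[, setdiff(names(df), required), drop = FALSE]
  if (!is.null(scales)) {
    for (nm in names(scales)) {
      if (!nm %in% names(covs)) next
      covs[[nm]] <- switch(match.arg(scales[[nm]],
                                     c("continuous", "ordered", "unordered")),
                           continuous = as.numeric(covs[[nm]]),
                           ordered    = factor(covs[[nm]], ordered = TRUE),
                           unordered  = factor(covs[[nm]]))
    }
  }
  survival_data(time = df$time, event = df$status, covariates = covs, id = df$id)
}

#' Construct a time grid
#'
#' A strictly increasing vector of evaluation times \eqn{t_1 < \ldots < t_K}
#' on which pseudo-values and survival probabilities are computed.
#'
#' @param points numeric vector of positive, strictly increasing time points.
#' @return An object of class `time_grid`.
#' @export
time_grid <- function(points) {
  points <- as.numeric(points)
  if (length(points) < 1L) stop("a time grid needs at least one point", call. = FALSE)
  if (any(points <= 0)) stop("time grid points must be positive", call. = FALSE)
  if (any(diff(points) <= 0))
    stop("time grid points must be strictly increasing", call. = FALSE)
  structure(points, class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat("Time grid (K =", length(x), "):", format(unclass(x), digits = 4), "\n")
  invisible(x)
}

#' Select a time grid from empirical quantiles of observed times
#'
#' The grid points are empirical quantiles (linear-interpolation convention,
#' `type = 7`) of a pilot sample of observed survival times, the standard
#' choice being the 10/30/50/70/90 percent quantiles.
#'
#' @param pilot_times numeric vector of observed times from a pilot sample.
#' @param quantile_levels quantile levels in (0, 1).
#' @return A `time_grid` of at most `length(quantile_levels)` strictly
#'   increasing points (exact duplicates are removed).
#' @export
choose_time_grid <- function(pilot_times, quantile_levels = c(.1, .3, .5, .7, .9)) {
  if (length(pilot_times) == 0L) stop("pilot sample is empty", call. = FALSE)
  if (any(quantile_levels <= 0 | quantile_levels >= 1))
    stop("'quantile_levels' must lie in (0, 1)", call. = FALSE)
  if (length(quantile_levels) > length(unique(pilot_times)))
    stop("degenerate time grid: more grid points requested than distinct pilot values",
         call. = FALSE)
  q <- unique(unname(stats::quantile(pilot_times, probs = quantile_levels,
                                     type = 7, names = FALSE)))
  q <- q[q > 0]
  if (length(q) < 1L)
    stop("degenerate time grid: pilot sample has too few distinct values",
         call. = FALSE)
  time_grid(sort(q))
}
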