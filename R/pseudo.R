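## Kaplan-Meier machinery and jackknife pseudo-values.
##
## The product-limit estimator is implemented in-package because the
## leave-one-out recomputation underlying the pseudo-values needs access to
## the sorted risk-set counts; tests cross-check every curve against
## survival::survfit.

## distinct event times with event counts d_j and at-risk counts n_j
## (individuals with T >= t_j; tied censorings remain at risk for tied events)
km_counts <- function(time, event) {
  et <- sort(unique(time[event == 1L]))
  if (length(et) == 0L)
    return(list(times = numeric(0), d = integer(0), n_risk = integer(0)))
  d <- vapply(et, function(t) sum(time == t & event == 1L), integer(1))
  n_risk <- vapply(et, function(t) sum(time >= t), integer(1))
  list(times = et, d = d, n_risk = n_risk)
}

## evaluate a right-continuous product-limit curve at arbitrary times
km_eval <- function(counts, at) {
  if (length(counts$times) == 0L) return(rep(1, length(at)))
  surv <- cumprod(1 - counts$d / counts$n_risk)
  idx <- findInterval(at, counts$times)
  out <- rep(1, length(at))
  out[idx > 0L] <- surv[idx[idx > 0L]]
  out
}

#' Kaplan-Meier survival estimates on a time grid
#'
#' Product-limit estimates \eqn{\hat S_{KM}(t_k)} with the right-continuous
#' step convention; at tied times, events precede censorings (tied censored
#' individuals remain in the risk set of the tied event).
#'
#' @param dataset a [survival_data()] object.
#' @param grid a [time_grid()] (or numeric vector of evaluation times).
#' @return Numeric vector of survival estimates, one per grid point.
#' @examples
#' d <- survival_data(time = c(1, 2, 3), event = c(1, 1, 1))
#' kaplan_meier(d, time_grid(2))  # (2/3) * (1/2) = 1/3
#' @export
kaplan_meier <- function(dataset, grid) {
  stopifnot(inherits(dataset, "survival_data"))
  km_eval(km_counts(dataset$time, dataset$event), as.numeric(grid))
}

#' Jackknife pseudo-values of the Kaplan-Meier estimator
#'
#' Computes \eqn{\hat\theta_i(t_k) = n \hat S_{KM}(t_k) - (n-1)
#' \hat S_{KM}(t_k)^{-i}} for every individual and grid point, where
#' \eqn{\hat S^{-i}} is the Kaplan-Meier estimate with individual \eqn{i}
#' removed.  Without censoring the pseudo-values reduce exactly to the binary
#' survival indicators \eqn{1\{\tilde T_i > t_k\}}; under censoring they may
#' fall outside \eqn{[0,1]}.  The column means always reproduce the
#' full-sample Kaplan-Meier curve (jackknife identity).
#'
#' @param dataset a [survival_data()] object (n >= 2).
#' @param grid a [time_grid()].
#' @param method `"fast"` (closed-form update of the leave-one-out risk-set
#'   counts, O(n log n)) or `"naive"` (n explicit leave-one-out fits sharing
#'   one sort order).  Both give identical results; the naive path is kept as
#'   an internal oracle.
#' @return An object of class `pseudo_values`: list with `values` (n x K
#'   matrix) and `grid`.
#' @export
jackknife_pseudo_values <- function(dataset, grid,
                                    method = c("fast", "naive")) {
  stopifnot(inherits(dataset, "survival_data"))
  method <- match.arg(method)
  n <- length(dataset$time)
  if (n < 2L) stop("pseudo-values require n >= 2", call. = FALSE)
  grid <- as.numeric(grid)
  s_full <- kaplan_meier(dataset, grid)
  loo <- switch(method,
                fast  = loo_km_fast(dataset$time, dataset$event, grid),
                naive = loo_km_naive(dataset$time, dataset$event, grid))
  values <- n * matrix(s_full, nrow = n, ncol = length(grid), byrow = TRUE) -
    (n - 1) * loo
  colnames(values) <- paste0("t", seq_along(grid))
  structure(list(values = values, grid = time_grid(grid)),
            class = "pseudo_values")
}

#' @export
print.pseudo_values <- function(x, ...) {
  cat(sprintf("Pseudo-value matrix: n = %d, K = %d, range [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

## n x K matrix of leave-one-out KM estimates, one explicit refit per
## individual (shared counts recomputed from the reduced sample)
loo_km_naive <- function(time, event, grid) {
  n <- length(time)
  out <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    out[i, ] <- km_eval(km_counts(time[-i], event[-i]), grid)
  }
  out
}

## Closed-form leave-one-out curves.  Removing individual i changes the
## product-limit factor at event time e_j <= T_i from (1 - d_j/n_j) to
## (1 - d_j/(n_j - 1)); if i's own event occurs at e_j the numerator drops by
## one as well.  Factors at event times beyond T_i are unchanged.  Cumulative
## log-factor sums make this O(n log n) over all individuals.
loo_km_fast <- function(time, event, grid) {
  n <- length(time)
  K <- length(grid)
  cnt <- km_counts(time, event)
  m <- length(cnt$times)
  if (m == 0L) return(matrix(1, n, K))

  logf0 <- log1p(-cnt$d / cnt$n_risk)                 # subject not at risk
  denom1 <- cnt$n_risk - 1
  f1 <- ifelse(denom1 > 0, 1 - cnt$d / denom1, 1)     # at risk, not own event
  fe <- ifelse(denom1 > 0, 1 - (cnt$d - 1) / denom1, 1)  # own event removed
  logf1 <- rep(-Inf, m); logf1[f1 > 0] <- log(f1[f1 > 0])
  logfe <- rep(-Inf, m); logfe[fe > 0] <- log(fe[fe > 0])
  logf1[denom1 == 0] <- 0   # removed subject was the whole risk set
  logfe[denom1 == 0] <- 0

  L0 <- c(0, cumsum(logf0))
  L1 <- c(0, cumsum(logf1))

  ## B_i: number of event times <= T_i (subject at risk for all of them)
  B <- findInterval(time, cnt$times)
  ## own-event position (0 if censored or time not an event time)
  own <- ifelse(event == 1L, B, 0L)
  own_corr <- rep(0, n)
  has_own <- own > 0L & event == 1L
  own_corr[has_own] <- logfe[own[has_own]] - logf1[own[has_own]]

  gidx <- findInterval(grid, cnt$times)  # events contributing at each t_k
  out <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    mk <- gidx[k]
    if (mk == 0L) { out[, k] <- 1; next }
    cut <- pmin(B, mk)
    ls <- L1[cut + 1L] + (L0[mk + 1L] - L0[cut + 1L])
    ls <- ls + ifelse(has_own & own <= mk, own_corr, 0)
    out[, k] <- exp(ls)
  }
  ## heavy ties can make the log-factor replacement indeterminate (Inf - Inf);
  ## recompute those rows explicitly
  bad <- which(!is.finite(rowSums(out)))
  for (i in bad) {
    out[i, ] <- km_eval(km_counts(time[-i], event[-i]), grid)
  }
  out
}

#' Long-format augmentation of pseudo-value data
#'
#' Reshapes an n x K pseudo-value matrix into the nK-row table used as input
#' to the node-wise gradient-boosting models: each individual contributes one
#' row per time point, carrying its id, the time value, the pseudo-value, a
#' constant column `x0 = 1` and the (dummy-expanded) covariates replicated K
#' times.  Unordered factors are expanded to full-rank treatment coding with
#' the first sorted level as reference; ordered factors enter as integer
#' scores.
#'
#' @param dataset a [survival_data()] object.
#' @param pv a `pseudo_values` object from [jackknife_pseudo_values()] with
#'   one row per individual of `dataset`.
#' @return An object of class `augmented_table`: list with `table` (data
#'   frame with columns `id`, `time`, `pseudo`, `x0`, covariate columns),
#'   `grid`, `k_index` (time-grid index per row) and `design` (covariate
#'   expansion metadata).
#' @export
augment_long_format <- function(dataset, pv) {
  stopifnot(inherits(dataset, "survival_data"), inherits(pv, "pseudo_values"))
  n <- length(dataset$time)
  if (nrow(pv$values) != n)
    stop("pseudo-value matrix and dataset dimensions do not match", call. = FALSE)
  K <- length(pv$grid)
  X <- expand_design(dataset$x)
  rows_id <- rep(seq_len(n), each = K)
  tab <- data.frame(
    id = dataset$id[rows_id],
    time = rep(as.numeric(pv$grid), times = n),
    pseudo = as.vector(t(pv$values)),
    x0 = 1
  )
  if (ncol(X$matrix) > 0L) {
    tab <- cbind(tab, as.data.frame(X$matrix[rows_id, , drop = FALSE]))
  }
  rownames(tab) <- NULL
  structure(list(table = tab, grid = pv$grid,
                 k_index = rep(seq_len(K), times = n),
                 row_individual = rows_id,
                 design = X$design),
            class = "augmented_table")
}

#' @export
print.augmented_table <- function(x, ...) {
  cat(sprintf("Augmented table: %d rows (%d individuals x K = %d), %d design column(s)\n",
              nrow(x$table), nrow(x$table) / length(x$grid), length(x$grid),
              ncol(x$table) - 4L))
  invisible(x)
}

## Expand a covariate data frame into the numeric design used by boosting.
## Continuous -> as is; ordered factor -> integer scores; unordered factor ->
## full-rank treatment dummies (reference = first sorted level).
expand_design <- function(x) {
  cols <- list()
  design <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.ordered(v)) {
      cols[[nm]] <- as.numeric(v)
      design[[nm]] <- list(type = "ordered", levels = levels(v), columns = nm)
    } else if (is.factor(v)) {
      lev <- levels(v)
      dn <- paste0(nm, lev[-1L])
      for (l in seq_along(lev[-1L]))
        cols[[dn[l]]] <- as.numeric(v == lev[-1L][l])
      design[[nm]] <- list(type = "unordered", levels = lev, columns = dn)
    } else {
      cols[[nm]] <- as.numeric(v)
      design[[nm]] <- list(type = "continuous", columns = nm)
    }
  }
  mat <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = nrow(x), ncol = 0)
  if (length(cols)) colnames(mat) <- names(cols)
  list(matrix = mat, design = design)
}
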