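## Evaluation metrics for survival probability estimates (MSE/RMSE, bias,
## IPCW Brier score, IPCW truncated concordance index) and the standard GEE
## pseudo-value regression baseline.

#' Mean squared error of survival probability estimates
#'
#' Mean squared deviation over all nK (individual, time point) entries,
#' together with its square root.
#'
#' @param estimates,truths numeric matrices (or vectors) of equal shape.
#' @return List with `mse` and `rmse`.
#' @export
mse_survival <- function(estimates, truths) {
  if (!identical(dim(as.matrix(estimates)), dim(as.matrix(truths))))
    stop("'estimates' and 'truths' must have the same shape", call. = FALSE)
  mse <- mean((estimates - truths)^2)
  list(mse = mse, rmse = sqrt(mse))
}

#' Bias of survival probability estimates
#'
#' Mean deviation (estimate minus truth) per time point, and its average
#' across time points.
#'
#' @param estimates,truths numeric matrices, individuals x time points.
#' @return List with `per_time` and `overall`.
#' @export
bias_survival <- function(estimates, truths) {
  estimates <- as.matrix(estimates); truths <- as.matrix(truths)
  if (!identical(dim(estimates), dim(truths)))
    stop("'estimates' and 'truths' must have the same shape", call. = FALSE)
  per_time <- colMeans(estimates - truths)
  list(per_time = per_time, overall = mean(per_time))
}

## Kaplan-Meier estimate of the censoring survival function G(t) = P(C > t)
## (reversed roles: censorings are the events).  Evaluated right-continuous;
## use `left = TRUE` for G(t-).
censoring_km <- function(dataset, at, left = FALSE) {
  cnt <- km_counts(dataset$time, 1L - dataset$event)
  if (left) {
    km_eval(cnt, at - 1e-12 * pmax(1, abs(at)))
  } else {
    km_eval(cnt, at)
  }
}

#' Censoring-weighted (IPCW) Brier score
#'
#' At each grid time t the score is the mean over individuals of
#' \deqn{\hat S(t|X_i)^2 1\{\tilde T_i \le t, \Delta_i = 1\} / \hat G(\tilde T_i^-)
#'   + (1-\hat S(t|X_i))^2 1\{\tilde T_i > t\} / \hat G(t),}
#' with \eqn{\hat G} the Kaplan-Meier estimator of the censoring
#' distribution.  Individuals censored before t contribute nothing.  Terms
#' whose weight denominator is zero are dropped with a message.
#'
#' @param dataset a [survival_data()] object.
#' @param predicted matrix of predicted survival probabilities, individuals
#'   x grid times.
#' @param grid evaluation times.
#' @return List with `per_time` and `overall` (time-averaged).
#' @export
brier_score <- function(dataset, predicted, grid) {
  predicted <- as.matrix(predicted)
  grid <- as.numeric(grid)
  n <- length(dataset$time)
  stopifnot(nrow(predicted) == n, ncol(predicted) == length(grid))
  g_event <- censoring_km(dataset, dataset$time, left = TRUE)
  g_grid <- censoring_km(dataset, grid)
  dropped <- 0L
  per_time <- vapply(seq_along(grid), function(k) {
    t <- grid[k]
    s <- predicted[, k]
    w_ev <- as.numeric(dataset$time <= t & dataset$event == 1L)
    w_at <- as.numeric(dataset$time > t)
    term_ev <- s^2 * w_ev / g_event
    term_at <- (1 - s)^2 * w_at / g_grid[k]
    bad <- (w_ev > 0 & g_event <= 0) | (w_at > 0 & g_grid[k] <= 0)
    dropped <<- dropped + sum(bad)
    term_ev[!is.finite(term_ev)] <- 0
    term_at[!is.finite(term_at)] <- 0
    sum(term_ev + term_at) / n
  }, numeric(1))
  if (dropped > 0L)
    message(sprintf("brier_score: dropped %d term(s) with zero censoring weight", dropped))
  list(per_time = per_time, overall = mean(per_time))
}

#' IPCW truncated concordance index
#'
#' Probability-of-concordance estimate over comparable pairs \eqn{(i,j)}
#' with \eqn{\Delta_i = 1}, \eqn{\tilde T_i < \tilde T_j} and
#' \eqn{\tilde T_i < \tau}, weighted by \eqn{\hat G(\tilde T_i^-)^{-2}}; a
#' pair is concordant when the earlier-event individual has the higher
#' predicted risk, ties in risk count one half.
#'
#' @param dataset a [survival_data()] object.
#' @param risk numeric risk scores at the horizon (e.g. `1 - S(tau | X)`).
#' @param tau truncation horizon.
#' @return Concordance in `[0, 1]`, or `NA` when no admissible pair exists.
#' @export
c_index <- function(dataset, risk, tau) {
  n <- length(dataset$time)
  stopifnot(length(risk) == n)
  g_left <- censoring_km(dataset, dataset$time, left = TRUE)
  num <- 0; den <- 0
  for (i in which(dataset$event == 1L & dataset$time < tau)) {
    js <- which(dataset$time > dataset$time[i])
    if (length(js) == 0L) next
    w <- if (g_left[i] > 0) 1 / g_left[i]^2 else next
    conc <- (risk[i] > risk[js]) + 0.5 * (risk[i] == risk[js])
    num <- num + w * sum(conc)
    den <- den + w * length(js)
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' GEE pseudo-value regression (independence working covariance)
#'
#' Fits the marginal model \eqn{g(S(t_k|X_i)) = \alpha_k + \gamma^\top X_i}
#' with the complementary log-log link by solving the estimating equation
#' \eqn{\sum_i D_i^\top (\hat\theta_i - h(\beta^\top X_{i,\cdot})) = 0}
#' (identity working covariance) via damped Gauss-Newton: this is
#' stationarity of the squared pseudo-value loss over the linear predictor
#' class.
#'
#' @param aug an [augment_long_format()] table.
#' @param max_iter maximum Gauss-Newton iterations.
#' @param tol convergence tolerance on the estimating-equation sup-norm.
#' @return An object of class `gee_fit` with `alpha` (K time intercepts),
#'   `gamma` (covariate coefficients), `converged`, `iterations` and
#'   `grad_norm`.
#' @export
fit_gee <- function(aug, max_iter = 200L, tol = 1e-8) {
  stopifnot(inherits(aug, "augmented_table"))
  K <- length(aug$grid)
  Z <- stats::model.matrix(~ 0 + factor(aug$k_index))
  colnames(Z) <- paste0("alpha", seq_len(K))
  Xcov <- as.matrix(aug$table[, setdiff(names(aug$table),
                                        c("id", "time", "pseudo", "x0")),
                              drop = FALSE])
  X <- cbind(Z, Xcov)
  theta <- aug$table$pseudo
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("augmented design is rank deficient", call. = FALSE)

  ## start from the link-transformed per-time means, zero covariate effects
  beta <- c(cloglog_link(as.numeric(rowsum(theta, aug$k_index)) /
                           tabulate(aug$k_index, nbins = K)),
            rep(0, ncol(Xcov)))
  obj <- function(b) sum((theta - cloglog_response(as.numeric(X %*% b)))^2)
  ee <- function(b) {
    f <- as.numeric(X %*% b)
    hp <- -exp(-exp(pmin(pmax(-f, -EXP_CLAMP), EXP_CLAMP))) *
      exp(pmin(pmax(-f, -EXP_CLAMP), EXP_CLAMP))
    r <- theta - cloglog_response(f)
    crossprod(X, hp * r)
  }
  cur <- obj(beta)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    f <- as.numeric(X %*% beta)
    mf <- pmin(pmax(-f, -EXP_CLAMP), EXP_CLAMP)
    hp <- -exp(-exp(mf)) * exp(mf)              # dh/df < 0
    r <- theta - cloglog_response(f)
    J <- X * hp                                  # Jacobian of h(X beta)
    step <- tryCatch(solve(crossprod(J), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    improved <- FALSE
    for (half in 1:30) {
      cand <- beta + lam * as.numeric(step)
      val <- obj(cand)
      if (val <= cur + 1e-12) { beta <- cand; cur <- val; improved <- TRUE; break }
      lam <- lam / 2
    }
    gn <- max(abs(ee(beta)))
    if (gn < tol) { converged <- TRUE; break }
    if (!improved) break
  }
  gn <- max(abs(ee(beta)))
  if (!converged && gn >= tol)
    warning(sprintf("GEE solver did not reach tolerance (sup-norm %.3g after %d iterations)",
                    gn, it))
  structure(list(alpha = beta[seq_len(K)],
                 gamma = stats::setNames(beta[-seq_len(K)], colnames(Xcov)),
                 converged = converged || gn < tol,
                 iterations = it, grad_norm = gn),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("GEE pseudo-value fit (cloglog link, independence working covariance)\n"))
  cat(sprintf("  converged: %s (estimating-equation sup-norm %.3g, %d iteration(s))\n",
              x$converged, x$grad_norm, x$iterations))
  cat("  alpha:", format(x$alpha, digits = 4), "\n")
  if (length(x$gamma)) cat("  gamma:", format(x$gamma, digits = 4), "\n")
  invisible(x)
}

#' Write a metrics report
#'
#' Writes per-time and averaged metric values as delimited text or JSON.
#'
#' @param metrics named list as produced by the metric functions.
#' @param path output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA)
  } else {
    flat <- unlist(metrics)
    utils::write.csv(data.frame(metric = names(flat), value = as.numeric(flat)),
                     path, row.names = FALSE)
  }
  invisible(path)
}
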