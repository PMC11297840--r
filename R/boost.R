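## Component-wise gradient boosting on an augmented pseudo-value table.
##
## Loss: squared deviation between the pseudo-value and the complementary
## log-log response h(f) = 1 - exp(-exp(-f)).  Base-learners: an intercept
## learner, one no-intercept simple linear learner per (centered) design
## column, and a monotone (nondecreasing) time learner defined on the K grid
## levels.  At each iteration all usable learners are fitted to the negative
## gradient and the one with the smallest residual sum of squares is added
## with step length nu.

EXP_CLAMP <- 700  # |arguments| of exp() are clamped to avoid overflow

#' Complementary log-log response function
#'
#' \eqn{h(f) = 1 - \exp(-\exp(-f))}, the inverse of the link
#' \eqn{g(S) = -\log(-\log(1-S))}; strictly decreasing in `f` and mapping the
#' linear predictor to a survival probability in (0, 1).
#'
#' @param f numeric vector on the linear-predictor scale.
#' @return Survival probabilities.
#' @examples cloglog_response(0)  # 1 - exp(-1)
#' @export
cloglog_response <- function(f) {
  1 - exp(-exp(pmin(pmax(-f, -EXP_CLAMP), EXP_CLAMP)))
}

#' Complementary log-log link
#'
#' @param s survival probabilities in (0, 1); values are clipped to
#'   `[1e-6, 1 - 1e-6]` to guard the double logarithm.
#' @return Linear-predictor values with `cloglog_response(cloglog_link(s)) = s`.
#' @export
cloglog_link <- function(s) {
  s <- pmin(pmax(s, 1e-6), 1 - 1e-6)
  -log(-log(1 - s))
}

#' Squared-error pseudo-value loss on the response scale
#'
#' \eqn{\rho(\theta, f) = (\theta - h(f))^2} with `h` the complementary
#' log-log response; the loss underlying the GEE estimating equation with an
#' independence working covariance.
#'
#' @param theta pseudo-values.
#' @param f linear-predictor values.
#' @return Elementwise loss values.
#' @export
pseudo_loss <- function(theta, f) {
  (theta - cloglog_response(f))^2
}

#' Negative gradient of the pseudo-value loss
#'
#' \eqn{-\partial\rho/\partial f = -2\,\exp(-\exp(-f))\exp(-f)\,(\theta -
#' h(f))}; exponentials are clamped so that extreme linear predictors return
#' 0 instead of overflowing.
#'
#' @inheritParams pseudo_loss
#' @return Elementwise negative gradient.
#' @export
negative_gradient <- function(theta, f) {
  mf <- pmin(pmax(-f, -EXP_CLAMP), EXP_CLAMP)
  w <- exp(-exp(mf)) * exp(mf)
  w[mf < -40] <- 0   # h saturates; gradient vanishes below double precision
  -2 * w * (theta - (1 - exp(-exp(mf))))
}

#' Control parameters for node-wise gradient boosting
#'
#' @param nu step length (shrinkage) in (0, 1].
#' @param mstop number of boosting iterations (overridden node-wise by the
#'   tree orchestration).
#' @param time_df target effective degrees of freedom of the monotone time
#'   base-learner (second-order difference penalty on the K grid levels).
#' @param center center design columns within each node before fitting the
#'   no-intercept linear learners (the induced constants are absorbed into
#'   the intercept on reconstruction).
#' @return A list of class `boost_control`.
#' @export
boost_control <- function(nu = 0.01, mstop = 100L, time_df = 4, center = TRUE) {
  stopifnot(nu > 0, nu <= 1, mstop >= 0, time_df >= 1)
  structure(list(nu = nu, mstop = as.integer(mstop), time_df = time_df,
                 center = isTRUE(center)),
            class = "boost_control")
}

#' Simple no-intercept linear base-learner
#'
#' Least-squares fit of a working response on a single (centered) covariate
#' column without intercept: slope \eqn{\sum x u / \sum x^2}.
#'
#' @param x covariate column (should be centered).
#' @param u working response (negative gradient).
#' @return List with `slope`, `fitted` and `rss`.
#' @export
fit_linear_baselearner <- function(x, u) {
  sxx <- sum(x^2)
  if (sxx <= 0) stop("constant covariate: linear base-learner unusable", call. = FALSE)
  slope <- sum(x * u) / sxx
  fitted <- slope * x
  list(slope = slope, fitted = fitted, rss = sum(u^2) - slope^2 * sxx)
}

## ---- monotone time base-learner -------------------------------------------

## Precompute the equality-constrained solvers for every active set of the
## K-1 order constraints; W and the penalty are fixed within a node, so only
## the right-hand side changes across boosting iterations.
monotone_solver <- function(w, lambda) {
  K <- length(w)
  if (K > 12L)
    stop("monotone time base-learner supports at most 12 grid points", call. = FALSE)
  D <- diff_matrix(K, 2L)
  P <- lambda * crossprod(D)
  WP <- diag(w, K) + P
  n_con <- K - 1L
  sets <- lapply(0:(2^n_con - 1L), function(code) {
    act <- as.logical(bitwAnd(code, 2^(seq_len(n_con) - 1L)))
    blk <- cumsum(c(1L, as.integer(!act)))          # merged equality blocks
    M <- outer(blk, seq_len(max(blk)), "==") * 1
    list(M = M, Ainv = solve(crossprod(M, WP %*% M)))
  })
  list(w = w, lambda = lambda, D = D, sets = sets, K = K)
}

## Exact solution of
##   min_a  sum_k w_k (ybar_k - a_k)^2 + lambda ||D2 a||^2
##   s.t.   a_1 <= a_2 <= ... <= a_K
## by enumerating the active sets (strictly convex QP; the optimum is the
## best feasible equality-constrained solution).
monotone_penalized_fit <- function(ybar, w, lambda, solver = NULL) {
  K <- length(ybar)
  if (K == 1L) return(ybar)
  if (is.null(solver)) solver <- monotone_solver(w, lambda)
  wy <- w * ybar
  ## the unconstrained ridge solution, when already nondecreasing, is the
  ## optimum of the constrained problem
  s0 <- solver$sets[[1L]]
  a0 <- as.numeric(s0$M %*% (s0$Ainv %*% crossprod(s0$M, wy)))
  if (all(diff(a0) >= -1e-10)) return(a0)
  best <- NULL; best_obj <- Inf
  for (s in solver$sets) {
    a <- as.numeric(s$M %*% (s$Ainv %*% crossprod(s$M, wy)))
    if (any(diff(a) < -1e-10)) next
    obj <- sum(w * (ybar - a)^2) + solver$lambda * sum((solver$D %*% a)^2)
    if (obj < best_obj - 1e-12) { best_obj <- obj; best <- a }
  }
  best
}

diff_matrix <- function(K, order = 2L) {
  D <- diag(K)
  for (i in seq_len(order)) D <- diff(D)
  D
}

## penalty strength matching a target effective df of the *unconstrained*
## smoother: df(lambda) = tr((W + lambda D'D)^{-1} W)
time_lambda_for_df <- function(w, df_target) {
  K <- length(w)
  if (df_target >= K) return(0)
  D <- diff_matrix(K, 2L)
  DtD <- crossprod(D)
  df_of <- function(lam) sum(diag(solve(diag(w, K) + lam * DtD) %*% diag(w, K)))
  lo <- 1e-8; hi <- 1
  while (df_of(hi) > df_target && hi < 1e12) hi <- hi * 10
  if (df_of(hi) > df_target) return(hi)
  stats::uniroot(function(l) df_of(l) - df_target, c(lo, hi), tol = 1e-8)$root
}

#' Monotone time base-learner on the grid levels
#'
#' Penalized least-squares fit of the working response on the time variable,
#' constrained to be nondecreasing in time.  Training and prediction only
#' ever use the K grid values, so the smoother is parameterized directly by
#' its K fitted levels with a second-order difference roughness penalty; the
#' fit depends on an observation only through its grid point.
#'
#' @param k_index integer vector mapping each observation to its grid point
#'   (1..K).
#' @param u working response.
#' @param K number of grid points.
#' @param lambda penalty strength (see [boost_control()]'s `time_df`).
#' @return List with `levels` (K fitted values, nondecreasing), `fitted`
#'   (per observation) and `rss`.
#' @export
fit_monotone_time_baselearner <- function(k_index, u, K, lambda, solver = NULL) {
  w <- tabulate(k_index, nbins = K)
  ybar <- rep(0, K)
  sums <- rowsum(u, k_index, reorder = TRUE)
  ybar[as.integer(rownames(sums))] <- sums / pmax(w[as.integer(rownames(sums))], 1)
  a <- monotone_penalized_fit(ybar, w, lambda, solver)
  fitted <- a[k_index]
  list(levels = a, fitted = fitted, rss = sum((u - fitted)^2))
}

## ---- node-wise boosting ----------------------------------------------------

#' Component-wise gradient boosting in one node
#'
#' Iterates `mstop` times: the negative gradient of the pseudo-value loss at
#' the current fit is computed, all usable base-learners (intercept, linear
#' per design column, monotone time) are fitted to it, and the learner with
#' the smallest residual sum of squares updates the fit by `nu` times its
#' fitted values.  Zero-variance design columns (e.g. dummies of ancestor
#' split variables) are excluded.  The aggregated fit decomposes as
#' \eqn{\hat f = \hat f^{[0]} + \gamma_0 + \sum_j \gamma_j x_j + \alpha(t)}.
#'
#' @param theta pseudo-values of the node's observations (length nK).
#' @param X numeric design matrix (nK x p, dummy-expanded covariates).
#' @param k_index grid index (1..K) per observation.
#' @param offset length-K vector of link-scale offsets per grid point.
#' @param control a [boost_control()] object.
#' @param mstop optional override of `control$mstop`.
#' @param trace_risk record the training risk after every iteration (off by
#'   default; the path is diagnostic only).
#' @return An object of class `boost_fit` with components `offset`,
#'   `gamma0`, `gamma` (named slopes on the raw covariate scale), `alpha`
#'   (K monotone time-curve values), `selected` (per-iteration learner log:
#'   0 intercept, j covariate column, p+1 time), `fitted` (final
#'   per-observation linear predictor) and `risk` (training risk path when
#'   traced).
#' @export
boost_node <- function(theta, X, k_index, offset, control = boost_control(),
                       mstop = NULL, trace_risk = FALSE) {
  K <- length(offset)
  nK <- length(theta)
  stopifnot(length(k_index) == nK, is.null(X) || nrow(X) == nK)
  if (is.null(mstop)) mstop <- control$mstop
  p <- if (is.null(X)) 0L else ncol(X)

  xmeans <- rep(0, p)
  usable <- logical(p)
  Xu <- NULL
  sxx <- numeric(0)
  if (p > 0L) {
    xmeans <- colMeans(X)
    Xc <- if (control$center) sweep(X, 2, xmeans) else X
    centered_ss <- colSums(sweep(X, 2, xmeans)^2)
    usable <- centered_ss > 1e-12   # zero-variance columns are never learners
    Xu <- Xc[, usable, drop = FALSE]
    sxx <- colSums(Xu^2)
  }
  time_usable <- K > 1L
  counts_k <- tabulate(k_index, nbins = K)
  lambda <- 0
  tsolver <- NULL
  if (time_usable) {
    lambda <- time_lambda_for_df(counts_k, control$time_df)
    tsolver <- monotone_solver(counts_k, lambda)
  }

  f <- offset[k_index]
  gamma0 <- 0
  gamma_c <- rep(0, p)       # slopes on the centered scale
  alpha <- rep(0, K)
  selected <- integer(mstop)
  risk <- if (trace_risk) numeric(mstop) else numeric(0)
  usable_idx <- which(usable)

  if (mstop > 0L && !any(usable) && !time_usable) {
    warning("no usable base-learners in node; returning offset-only fit")
    mstop <- 0L
    selected <- integer(0)
  }

  for (m in seq_len(mstop)) {
    u <- negative_gradient(theta, f)
    su2 <- sum(u^2)
    ubar <- mean(u)
    best_rss <- su2 - nK * ubar^2          # intercept learner
    best_id <- 0L
    slopes <- NULL
    if (length(usable_idx)) {
      slopes <- as.numeric(crossprod(Xu, u)) / sxx
      rss_j <- su2 - slopes^2 * sxx
      jb <- which.min(rss_j)
      if (rss_j[jb] < best_rss - 1e-12) {
        best_rss <- rss_j[jb]; best_id <- usable_idx[jb]
      }
    }
    tl <- NULL
    if (time_usable) {
      tl <- fit_monotone_time_baselearner(k_index, u, K, lambda, tsolver)
      if (tl$rss < best_rss - 1e-12) { best_rss <- tl$rss; best_id <- p + 1L }
    }
    if (best_id == 0L) {
      gamma0 <- gamma0 + control$nu * ubar
      f <- f + control$nu * ubar
    } else if (best_id <= p) {
      jb <- match(best_id, usable_idx)
      sl <- slopes[jb]
      gamma_c[best_id] <- gamma_c[best_id] + control$nu * sl
      f <- f + control$nu * sl * Xu[, jb]
    } else {
      alpha <- alpha + control$nu * tl$levels
      f <- f + control$nu * tl$fitted
    }
    selected[m] <- best_id
    if (trace_risk) risk[m] <- sum(pseudo_loss(theta, f))
  }

  ## raw-scale reconstruction: gamma_c * (x - xbar) = gamma_c * x - gamma_c * xbar
  gamma <- gamma_c
  g0 <- gamma0 - if (control$center && p > 0L) sum(gamma_c * xmeans) else 0
  names(gamma) <- if (p > 0L) colnames(X) else character(0)
  structure(list(offset = offset, gamma0 = g0, gamma = gamma, alpha = alpha,
                 selected = selected, fitted = f, risk = risk,
                 nu = control$nu, mstop = mstop),
            class = "boost_fit")
}

#' @export
print.boost_fit <- function(x, ...) {
  sel <- sum(x$gamma != 0)
  cat(sprintf("Boosting fit: mstop = %d, %d covariate(s) selected, time learner used %d time(s)\n",
              x$mstop, sel, sum(x$selected == length(x$gamma) + 1L)))
  invisible(x)
}

## evaluate a boost_fit for arbitrary covariate rows / grid indices
boost_fit_predict <- function(fit, X, k_index) {
  f <- fit$offset[k_index] + fit$gamma0 + fit$alpha[k_index]
  if (length(fit$gamma) > 0L && !is.null(X))
    f <- f + as.numeric(X %*% fit$gamma)
  f
}

#' Time-dependent offset of a daughter node
#'
#' The offset at grid point \eqn{t_k} is the average, over the node's
#' observations at \eqn{t_k}, of the parent node's fitted values (on the
#' link scale).  For the root node the offset is the link-transformed mean
#' pseudo-value per time point, which by the jackknife identity equals the
#' link-transformed Kaplan-Meier curve.
#'
#' @param parent_fitted per-observation fitted values of the parent node (in
#'   the parent's row order), or `NULL` for the root.
#' @param member_rows indices of the node's observations within the parent's
#'   rows (ignored for the root).
#' @param k_index grid index of the node's observations.
#' @param K number of grid points.
#' @param root_pseudo pseudo-values of all root observations (root only).
#' @return Length-K offset vector on the link scale.
#' @export
compute_offset <- function(parent_fitted, member_rows, k_index, K,
                           root_pseudo = NULL) {
  if (is.null(parent_fitted)) {
    means <- as.numeric(rowsum(root_pseudo, k_index) / tabulate(k_index, nbins = K))
    return(cloglog_link(means))
  }
  vals <- parent_fitted[member_rows]
  as.numeric(rowsum(vals, k_index) / tabulate(k_index, nbins = K))
}
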