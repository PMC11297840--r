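## Generators for the two lognormal simulation designs, with exact
## ground-truth survival functions and independent censoring drawn from an
## identical pipeline (yielding a 50% censoring rate for these symmetric
## processes).

#' Random correlation matrix with bounded off-diagonals
#'
#' A diffuse Wishart draw (`df = d + 2`) rescaled to unit diagonal yields
#' substantial correlations; off-diagonals exceeding the bound are clipped
#' and the result repaired to the nearest positive-definite correlation
#' matrix (eigenvalue flooring), so the restriction on the pairwise
#' correlations genuinely binds.
#'
#' @param d dimension.
#' @param max_abs bound on the absolute off-diagonal correlations.
#' @return A d x d correlation matrix.
#' @export
random_correlation_matrix <- function(d, max_abs = 0.5) {
  df <- d + 2L
  W <- crossprod(matrix(stats::rnorm(df * d), df, d))
  R <- stats::cov2cor(W)
  for (rep in 1:50) {
    off <- R[upper.tri(R)]
    if (all(abs(off) <= max_abs + 1e-10)) break
    R[upper.tri(R)] <- pmin(pmax(off, -max_abs), max_abs)
    R[lower.tri(R)] <- t(R)[lower.tri(R)]
    e <- eigen(R, symmetric = TRUE)
    if (min(e$values) < 1e-6) {
      vals <- pmax(e$values, 1e-6)
      R <- e$vectors %*% diag(vals) %*% t(e$vectors)
      R <- stats::cov2cor(R)
    }
  }
  R
}

#' Sample correlated standard-uniform covariates
#'
#' Normal-copula construction with the intermediate-correlation adjustment
#' \eqn{r_{normal} = 2 \sin(\pi r_{target} / 6)}, which makes the Pearson
#' correlations of the uniform marginals match the target.  If the adjusted
#' matrix is not positive definite it is repaired by eigenvalue flooring
#' (with a message reporting the perturbation).
#'
#' @param n number of individuals.
#' @param R target correlation matrix (|off-diagonals| <= 0.5).
#' @param copula_root optional precomputed square root of the adjusted
#'   copula matrix (avoids refactorization across repeated draws).
#' @return n x d matrix with standard-uniform marginals.
#' @export
sample_correlated_uniforms <- function(n, R, copula_root = NULL) {
  if (is.null(copula_root)) copula_root <- uniform_copula_root(R)
  Z <- matrix(stats::rnorm(n * ncol(copula_root)), n) %*% t(copula_root)
  stats::pnorm(Z)
}

## square root of the normal-copula correlation matrix matching uniform
## Pearson correlations R (intermediate-correlation adjustment); repairs a
## non-PD adjusted matrix by eigenvalue flooring
uniform_copula_root <- function(R, quiet = FALSE) {
  stopifnot(isSymmetric(unname(R)), all(abs(R[upper.tri(R)]) <= 0.5 + 1e-8))
  Rn <- 2 * sin(pi * R / 6)
  diag(Rn) <- 1
  e <- eigen(Rn, symmetric = TRUE)
  if (min(e$values) < 1e-8) {
    vals <- pmax(e$values, 1e-8)
    Rn2 <- stats::cov2cor(e$vectors %*% diag(vals) %*% t(e$vectors))
    if (!quiet)
      message(sprintf("uniform_copula_root: repaired non-PD copula matrix (max perturbation %.3g)",
                      max(abs(Rn2 - Rn))))
    Rn <- Rn2
    e <- eigen(Rn, symmetric = TRUE)
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)))
}

#' Specification of the tree-structured lognormal simulation design (study 1)
#'
#' Ten correlated standard-uniform covariates; individuals are partitioned by
#' median rules on x1, then x2 (left branch) and x3 (right branch); in each
#' of the four terminal subgroups the log survival time is a linear
#' combination of the covariates plus standard-normal noise.  Each subgroup
#' uses its fixed coefficient vector with exactly five zero entries; the
#' coefficients and the covariate correlation matrix are fixed across
#' replications.
#'
#' @param master_seed seed fixing the correlation matrix (shared by all
#'   replications).
#' @return A list of class `study1_spec` with `correlation` and `coef`
#'   (4 x 10 matrix, rows for terminal subgroups 3, 4, 6, 7).
#' @export
study1_spec <- function(master_seed = 1001) {
  coef <- rbind(
    `3` = c(0, -1.19, -0.94, -0.82, -0.94, 0, -0.95, 0, 0, 0),
    `4` = c(-0.63, -0.47, -0.43, 0.67, 0, -0.54, 0, 0, 0, 0),
    `6` = c(0, -0.47, -0.39, 0, -0.64, 0, 0, -0.09, 0, 0.01),
    `7` = c(0.50, 0.48, 0, 0.24, 0, 0, 0.68, 0.77, 0, 0))
  colnames(coef) <- paste0("x", 1:10)
  stopifnot(all(rowSums(coef == 0) == 5L))
  R <- withr_seed(master_seed, random_correlation_matrix(10, max_abs = 0.5))
  structure(list(correlation = R, coef = coef, master_seed = master_seed,
                 copula_root = uniform_copula_root(R, quiet = TRUE)),
            class = "study1_spec")
}

## evaluate an expression under a temporary RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

## one draw of (covariates, eta, log-time) from the study-1 pipeline
study1_draw <- function(n, spec) {
  X <- sample_correlated_uniforms(n, spec$correlation, spec$copula_root)
  colnames(X) <- paste0("x", 1:10)
  xi1 <- stats::median(X[, 1])
  left <- X[, 1] <= xi1
  xi2 <- stats::median(X[left, 2])
  xi3 <- stats::median(X[!left, 3])
  node <- ifelse(left,
                 ifelse(X[, 2] <= xi2, 3L, 4L),
                 ifelse(X[, 3] <= xi3, 6L, 7L))
  eta <- rowSums(X * spec$coef[as.character(node), , drop = FALSE])
  logT <- eta + stats::rnorm(n)
  list(X = X, eta = eta, node = node, logT = logT,
       thresholds = c(xi1 = xi1, xi2 = xi2, xi3 = xi3))
}

#' Simulate right-censored data from the study-1 design
#'
#' Event times are lognormal with subgroup-specific linear predictors
#' (median-rule tree on x1/x2/x3); censoring times are drawn from an
#' independent, identically specified pipeline (fresh covariates and noise),
#' giving a 50 percent censoring rate.  The exact true survival function
#' \eqn{S(t|X_i) = 1 - \Phi(\log t - \eta_i)} is recorded.
#'
#' @param n number of individuals.
#' @param spec a [study1_spec()].
#' @return A list of class `sim_truth`: `data` (a [survival_data()]),
#'   `eta` (true linear predictors), `node` (true subgroup), `thresholds`
#'   and `true_survival(times)` (function returning the n x K truth matrix).
#' @export
simulate_study1 <- function(n, spec = study1_spec()) {
  ev <- study1_draw(n, spec)
  cs <- study1_draw(n, spec)       # independent censoring pipeline
  T_ev <- exp(ev$logT)
  C <- exp(cs$logT)
  time <- pmin(T_ev, C)
  status <- as.integer(T_ev <= C)
  data <- survival_data(time, status, as.data.frame(ev$X))
  sim_truth(data, ev$eta, node = ev$node, thresholds = ev$thresholds)
}

sim_truth <- function(data, eta, ...) {
  structure(list(data = data, eta = eta,
                 true_survival = function(times) {
                   outer(eta, as.numeric(times),
                         function(e, t) 1 - stats::pnorm(log(t) - e))
                 }, ...),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulated survival data with exact ground truth\n")
  print(x$data)
  invisible(x)
}

#' Specification of the additive main/interaction design (study 2)
#'
#' Thirty unit-variance multivariate-normal covariates with a random (fixed)
#' correlation structure; five covariates are informative with main-effect
#' coefficients drawn once from U[-1,1], and the ten pairwise interactions
#' among the informative covariates carry U[-1,1] coefficients as well.
#'
#' @param master_seed seed fixing the covariance, the informative subset and
#'   the coefficients across replications.
#' @return A list of class `study2_spec`.
#' @export
study2_spec <- function(master_seed = 2002) {
  withr_seed(master_seed, {
    R <- random_correlation_matrix(30, max_abs = 0.9)
    informative <- sort(sample.int(30, 5))
    gamma <- numeric(30)
    gamma[informative] <- stats::runif(5, -1, 1)
    pairs <- utils::combn(informative, 2)
    gamma_int <- stats::runif(ncol(pairs), -1, 1)
    e <- eigen(R, symmetric = TRUE)
    root <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
    structure(list(correlation = R, informative = informative,
                   gamma = gamma, pairs = pairs, gamma_int = gamma_int,
                   root = root, master_seed = master_seed),
              class = "study2_spec")
  })
}

#' Simulate right-censored data from the study-2 design
#'
#' The main-effect predictor and the interaction-only predictor are
#' empirically standardized and mixed with weight `lambda` (1 = main
#' effects only, 0 = interactions only); the combined predictor is
#' standardized again and log survival times are this predictor plus
#' standard-normal noise.  Censoring comes from an independent identical
#' pipeline (50 percent censoring).
#'
#' @param n number of individuals.
#' @param lambda mixing weight in `[0, 1]`.
#' @param spec a [study2_spec()].
#' @return A `sim_truth` object (see [simulate_study1()]).
#' @export
simulate_study2 <- function(n, lambda = 0.5, spec = study2_spec()) {
  stopifnot(lambda >= 0, lambda <= 1)
  ev <- study2_draw(n, lambda, spec)
  cs <- study2_draw(n, lambda, spec)
  T_ev <- exp(ev$logT)
  C <- exp(cs$logT)
  time <- pmin(T_ev, C)
  status <- as.integer(T_ev <= C)
  data <- survival_data(time, status, as.data.frame(ev$X))
  sim_truth(data, ev$eta, lambda = lambda)
}

study2_draw <- function(n, lambda, spec) {
  d <- ncol(spec$correlation)
  X <- matrix(stats::rnorm(n * d), n) %*% t(spec$root)
  colnames(X) <- paste0("x", seq_len(d))
  eta1 <- as.numeric(X %*% spec$gamma)
  inter <- X[, spec$pairs[1, ], drop = FALSE] * X[, spec$pairs[2, ], drop = FALSE]
  eta2 <- as.numeric(inter %*% spec$gamma_int)
  sd1 <- stats::sd(eta1); sd2 <- stats::sd(eta2)
  if (sd1 <= 0 || sd2 <= 0)
    stop("degenerate predictor component (zero empirical standard deviation)",
         call. = FALSE)
  eta <- lambda * (eta1 - mean(eta1)) / sd1 + (1 - lambda) * (eta2 - mean(eta2)) / sd2
  sde <- stats::sd(eta)
  if (sde <= 0)
    stop("degenerate combined predictor (zero empirical standard deviation)",
         call. = FALSE)
  eta <- (eta - mean(eta)) / sde
  logT <- eta + stats::rnorm(n)
  list(X = X, eta = eta, logT = logT)
}

#' Default time grid for a simulation design
#'
#' Simulates a pilot sample of independent individuals from the design and
#' takes the empirical 10/30/50/70/90 percent quantiles of the observed
#' (censored) times.
#'
#' @param study `"study1"` or `"study2"`.
#' @param n_pilot pilot sample size.
#' @param lambda mixing weight (study 2 only).
#' @param spec optional design specification.
#' @return A [time_grid()] of (at most) five points.
#' @export
build_default_time_grid <- function(study = c("study1", "study2"),
                                    n_pilot = 1000L, lambda = 0.5,
                                    spec = NULL) {
  study <- match.arg(study)
  sim <- if (study == "study1") {
    simulate_study1(n_pilot, spec %||% study1_spec())
  } else {
    simulate_study2(n_pilot, lambda, spec %||% study2_spec())
  }
  choose_time_grid(sim$data$time, c(.1, .3, .5, .7, .9))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
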