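test_that("the complementary log-log response and link are mutual inverses with the right limits", {
  expect_equal(cloglog_response(0), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(cloglog_response(1e6), 0, tolerance = 1e-12)
  expect_equal(cloglog_response(-1e6), 1, tolerance = 1e-12)
  for (s in c(0.1, 0.5, 0.9))
    expect_equal(cloglog_response(cloglog_link(s)), s, tolerance = 1e-12)
  f <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(cloglog_response(f)) < 0))
})

test_that("the pseudo-value loss and its gradient agree with finite differences", {
  expect_equal(pseudo_loss(cloglog_response(0.7), 0.7), 0)
  expect_equal(pseudo_loss(1, 0), (1 - (1 - exp(-1)))^2, tolerance = 1e-12)
  expect_true(all(pseudo_loss(runif(20, -0.5, 1.5), rnorm(20)) >= 0))

  grid <- expand.grid(theta = c(-0.4, 0, 0.3, 1, 1.6),
                      f = seq(-6, 6, by = 0.25))
  eps <- 1e-6
  num <- -(pseudo_loss(grid$theta, grid$f + eps) -
             pseudo_loss(grid$theta, grid$f - eps)) / (2 * eps)
  expect_lt(max(abs(num - negative_gradient(grid$theta, grid$f))), 1e-6)

  expect_equal(negative_gradient(cloglog_response(1.2), 1.2), 0)
  # guarded exponentials: no overflow, exact zero in the saturated regime
  expect_identical(negative_gradient(0.5, 800), 0)
  expect_identical(negative_gradient(0.5, -800), 0)
})

test_that("the linear base-learner is the closed-form no-intercept regression", {
  x <- c(-1, 0.5, 2, -0.5, 1)
  fit <- fit_linear_baselearner(x, 2 * x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$rss, 0, tolerance = 1e-12)

  u <- c(1, 2, -1, 0, 1)
  u_perp <- u - sum(u * x) / sum(x^2) * x
  fit2 <- fit_linear_baselearner(x, u_perp)
  expect_equal(fit2$slope, 0, tolerance = 1e-12)
  expect_equal(fit2$rss, sum(u_perp^2), tolerance = 1e-12)

  set.seed(51)
  x3 <- rnorm(10); u3 <- rnorm(10)
  expect_equal(fit_linear_baselearner(x3, u3)$slope, sum(x3 * u3) / sum(x3^2))
  expect_error(fit_linear_baselearner(rep(0, 5), u), "constant")
})

test_that("the monotone time base-learner solves the constrained penalized problem", {
  # interpolation limit: already nondecreasing group means are matched
  kidx <- rep(1:5, each = 4)
  u <- rep(c(-2, -1, 0.5, 1, 3), each = 4)
  fit <- fit_monotone_time_baselearner(kidx, u, K = 5, lambda = 1e-10)
  expect_equal(fit$levels, c(-2, -1, 0.5, 1, 3), tolerance = 1e-6)

  # decreasing response: the constraint binds, the fit never decreases
  ud <- rep(c(3, 2, 1, 0, -1), each = 4)
  fd <- fit_monotone_time_baselearner(kidx, ud, K = 5, lambda = 0.5)
  expect_true(all(diff(fd$levels) >= -1e-10))

  # identical fitted value for identical time
  expect_equal(fd$fitted, fd$levels[kidx])

  # exact QP solution: never beaten by a reparametrised numerical optimizer
  set.seed(52)
  for (r in 1:15) {
    ybar <- rnorm(5)
    w <- rep(sample(2:6, 1), 5)
    lam <- runif(1, 0.01, 5)
    a <- prtrees:::monotone_penalized_fit(ybar, w, lam)
    expect_true(all(diff(a) >= -1e-8))
    D <- diff(diff(diag(5)))
    objective <- function(b) {
      av <- b[1] + c(0, cumsum(b[-1]^2))
      sum(w * (ybar - av)^2) + lam * sum((D %*% av)^2)
    }
    o <- optim(c(ybar[1], rep(0.1, 4)), objective, method = "BFGS",
               control = list(maxit = 3000, reltol = 1e-14))
    expect_lte(sum(w * (ybar - a)^2) + lam * sum((D %*% a)^2), o$value + 1e-6)
  }
})

test_that("node-wise boosting selects the signal, descends the risk and decomposes additively", {
  set.seed(53)
  n <- 120; K <- 5
  kidx <- rep(1:K, n)
  x1 <- rep(runif(n), each = K)
  x2 <- rep(runif(n), each = K)
  S <- cloglog_response(-1 + 2 * x1 + 0.3 * kidx)
  theta <- S + rnorm(n * K, sd = 0.05)
  offset <- as.numeric(cloglog_link(rowsum(theta, kidx) / n))
  X <- cbind(x1 = x1, x2 = x2)

  f0 <- boost_node(theta, X, kidx, offset, boost_control(mstop = 0))
  expect_equal(f0$fitted, offset[kidx])
  expect_equal(unname(f0$gamma), c(0, 0))
  expect_equal(f0$alpha, rep(0, K))

  fit <- boost_node(theta, X, kidx, offset,
                    boost_control(nu = 0.01, mstop = 400), trace_risk = TRUE)
  cov_iters <- fit$selected[fit$selected %in% 1:2]
  expect_gte(mean(cov_iters == 1), 0.9)
  expect_gt(fit$gamma[["x1"]], 0)

  # training risk is nonincreasing for small nu
  expect_true(all(diff(fit$risk) <= 1e-9))

  # bookkeeping identity: aggregated coefficients reproduce the fit
  recon <- fit$offset[kidx] + fit$gamma0 + as.numeric(X %*% fit$gamma) +
    fit$alpha[kidx]
  expect_equal(recon, fit$fitted, tolerance = 1e-10)

  # monotone baseline => nonincreasing survival over the grid
  expect_true(all(diff(fit$offset + fit$gamma0 + fit$alpha) >= -1e-10))

  # zero-variance columns are excluded, their slopes exactly zero
  X3 <- cbind(X, z = rep(1, n * K))
  fit3 <- boost_node(theta, X3, kidx, offset, boost_control(mstop = 50))
  expect_identical(fit3$gamma[["z"]], 0)
  expect_false(any(fit3$selected == 3))
})

test_that("early stopping shrinks noise coefficients below signal coefficients", {
  set.seed(54)
  n <- 150; K <- 3
  kidx <- rep(1:K, n)
  xs <- matrix(runif(n * 5), n, 5)
  X <- xs[rep(1:n, each = K), ]
  colnames(X) <- paste0("x", 1:5)
  S <- cloglog_response(-0.5 + 1.5 * X[, 1] + 0.2 * kidx)
  theta <- S + rnorm(n * K, sd = 0.1)
  offset <- as.numeric(cloglog_link(rowsum(theta, kidx) / n))
  fit <- boost_node(theta, X, kidx, offset, boost_control(nu = 0.01, mstop = 150))
  expect_gt(abs(fit$gamma[["x1"]]), max(abs(fit$gamma[2:5])))
})

test_that("offsets average parent fitted values per time point; the root offset is the link-KM curve", {
  set.seed(55)
  d <- random_dataset(80)
  grid <- time_grid(quantile(d$time, c(.25, .5, .75)))
  pv <- jackknife_pseudo_values(d, grid)
  K <- 3
  kidx <- rep(1:K, 80)
  theta <- as.vector(t(pv$values))

  off_root <- compute_offset(NULL, NULL, kidx, K, root_pseudo = theta)
  expect_equal(cloglog_response(off_root), kaplan_meier(d, grid),
               tolerance = 1e-10)

  # node = parent: offset is the per-time mean of the parent fit
  parent_fitted <- rnorm(80 * K)
  off <- compute_offset(parent_fitted, seq_len(80 * K), kidx, K)
  expect_equal(off, as.numeric(rowsum(parent_fitted, kidx) / 80))

  # monotone parent fits give monotone offsets
  mono <- off_root[kidx] + rep(rnorm(80), each = K)
  off2 <- compute_offset(mono, seq_len(80 * K), kidx, K)
  expect_true(all(diff(off2) >= -1e-12))
})
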