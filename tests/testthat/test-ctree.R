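test_that("the standardized statistic matches hand-computed permutation moments (K = 1)", {
  theta <- matrix(c(0.2, 1.4, -0.5, 0.9, 0.1), ncol = 1)
  g <- matrix(c(1.1, 2.3, 0.4, 1.8, 0.9), ncol = 1)
  m <- 5
  T_obs <- sum(g * theta)
  mu <- sum(g) * mean(theta)
  vh <- mean((theta - mean(theta))^2)
  varT <- vh * (m / (m - 1) * sum(g^2) - sum(g)^2 / (m - 1))
  st <- correlation_statistic(theta, g)
  expect_equal(st$statistic[1, 1], (T_obs - mu) / sqrt(varT), tolerance = 1e-12)
  expect_equal(st$max_abs, abs(st$statistic[1, 1]))
})

test_that("a covariate equal to one pseudo-value column dominates the statistic matrix", {
  set.seed(41)
  theta <- matrix(rnorm(60 * 4), 60, 4)
  g <- matrix(theta[, 1], ncol = 1)
  st <- correlation_statistic(theta, g)
  expect_equal(which.max(abs(st$statistic)), 1L)
})

test_that("permutation p-values are uniform under the null and minimal under strong signal", {
  set.seed(42)
  pvals <- replicate(400, {
    theta <- matrix(rnorm(30 * 3), 30, 3)
    g <- matrix(rnorm(30), ncol = 1)
    permutation_pvalue(theta, g, n_perm = 199)$p_value
  })
  # ties among discrete permutation p-values are expected; the KS test is
  # used only as a coarse uniformity check
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)

  # perfectly informative covariate: p at the lower bound 1/(1+B)
  hits <- replicate(30, {
    theta <- matrix(rnorm(200 * 3), 200, 3)
    g <- matrix(theta[, 2] + rnorm(200, sd = 0.05), ncol = 1)
    permutation_pvalue(theta, g, n_perm = 199)$p_value == 1 / 200
  })
  expect_gte(mean(hits), 0.99)
})

test_that("split-variable selection stops on pure noise and finds the informative covariate", {
  set.seed(43)
  stops <- replicate(60, {
    theta <- matrix(rnorm(40 * 3), 40, 3)
    x <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
    is.null(select_split_variable(theta, x, tree_control(n_perm = 99)))
  })
  # raw minimum of two p-values compared with alpha = 0.05: the stop rate
  # stays close to 1 - alpha * p-ish
  expect_gt(mean(stops), 0.8)

  theta <- matrix(rnorm(120 * 3), 120, 3)
  x <- data.frame(s = theta[, 1] + rnorm(120, sd = 0.1), n1 = rnorm(120))
  sel <- select_split_variable(theta, x, tree_control(n_perm = 199))
  expect_equal(sel$name, "s")
  expect_equal(sel$p_value, 1 / 200)

  # constant covariates are unusable, not errors
  x2 <- data.frame(c1 = rep(1, 120), s = theta[, 1])
  sel2 <- select_split_variable(theta, x2, tree_control(n_perm = 199))
  expect_equal(sel2$name, "s")
})

test_that("the split maximizer agrees with brute-force enumeration on small nodes", {
  set.seed(44)
  for (r in 1:25) {
    m <- sample(8:20, 1)
    theta <- matrix(rnorm(m * 2), m, 2)
    xv <- rnorm(m)
    sp <- find_best_split(theta, xv, min_size = 2)
    expect_equal(sp$score, split_oracle(theta, xv, 2), tolerance = 1e-10)
  }

  # noiseless step outcome: threshold lies in the midpoint interval at 0.5
  x <- seq(0.05, 0.95, length.out = 30)
  th <- matrix(rep(ifelse(x > 0.5, 2, 0), 3), ncol = 3)
  sp <- find_best_split(th, x, min_size = 3)
  lo <- max(x[x <= 0.5]); hi <- min(x[x > 0.5])
  expect_gte(sp$threshold, lo)
  expect_lte(sp$threshold, hi)

  # binary covariate: the single admissible partition
  v <- factor(rep(c("a", "b"), each = 10))
  spb <- find_best_split(matrix(rnorm(20), ncol = 1), v, min_size = 2)
  expect_equal(spb$kind, "subset")
  expect_equal(spb$left_levels, "a")

  # factor split agrees with enumerating partitions through the oracle on
  # the induced binary memberships
  set.seed(45)
  v3 <- factor(sample(letters[1:3], 15, replace = TRUE))
  th3 <- matrix(rnorm(15 * 2), 15, 2)
  sp3 <- find_best_split(th3, v3, min_size = 1)
  scores <- sapply(list("a", "b", "c", c("a", "b"), c("a", "c"), c("b", "c")),
                   function(ls) {
    right <- !(as.character(v3) %in% ls)
    if (!sum(right) || !sum(!right)) return(-Inf)
    m <- 15; hbar <- colMeans(th3); vh <- colMeans(sweep(th3, 2, hbar)^2)
    nr <- sum(right); s2 <- nr * (m - nr) / (m - 1) * vh
    max(abs(colSums(th3[right, , drop = FALSE]) - nr * hbar) / sqrt(s2))
  })
  expect_equal(sp3$score, max(scores), tolerance = 1e-10)
})

test_that("tree growing respects depth, significance and node-size constraints", {
  set.seed(46)
  d <- random_dataset(200, p = 3)
  grid <- time_grid(quantile(d$time, c(.2, .5, .8)))
  pv <- jackknife_pseudo_values(d, grid)

  t0 <- grow_tree(d, pv, tree_control(maxdepth = 0, seed = 1))
  expect_length(t0$nodes, 1L)
  expect_true(t0$nodes[["1"]]$terminal)

  # pure-noise covariates mostly stop immediately
  tn <- grow_tree(d, pv, tree_control(maxdepth = 3, n_perm = 199, seed = 2))
  expect_lte(length(tn$nodes), 3L)

  # informative structure: pseudo-values shift with x1 via survival times
  set.seed(47)
  x1 <- runif(300)
  tm <- exp(rnorm(300, mean = 2 * (x1 > 0.5)))
  cs <- exp(rnorm(300, mean = 1))
  d2 <- survival_data(pmin(tm, cs), as.integer(tm <= cs),
                      data.frame(x1 = x1, x2 = runif(300)))
  pv2 <- jackknife_pseudo_values(d2, time_grid(quantile(d2$time, c(.2, .5, .8))))
  tr <- grow_tree(d2, pv2, tree_control(maxdepth = 2, n_perm = 199,
                                        min_node_size = 20, seed = 3))
  expect_equal(tr$nodes[["1"]]$split$name, "x1")
  expect_gt(tr$nodes[["1"]]$split$threshold, 0.3)
  expect_lt(tr$nodes[["1"]]$split$threshold, 0.7)

  # children partition the parent exactly; terminal nodes respect min size
  for (nd in tr$nodes) {
    if (!nd$terminal) {
      kids <- c(tr$nodes[[as.character(nd$children[1])]]$members,
                tr$nodes[[as.character(nd$children[2])]]$members)
      expect_setequal(kids, nd$members)
    } else {
      expect_gte(nd$size, 20)
    }
  }
})

test_that("tree growing is deterministic given the seed and ignores id relabeling", {
  set.seed(48)
  d <- random_dataset(150, p = 3)
  grid <- time_grid(quantile(d$time, c(.25, .5, .75)))
  pv <- jackknife_pseudo_values(d, grid)
  t1 <- grow_tree(d, pv, tree_control(maxdepth = 2, n_perm = 99, seed = 7))
  t2 <- grow_tree(d, pv, tree_control(maxdepth = 2, n_perm = 99, seed = 7))
  expect_identical(t1$nodes, t2$nodes)

  d3 <- d
  d3$id <- rev(d3$id)
  t3 <- grow_tree(d3, pv, tree_control(maxdepth = 2, n_perm = 99, seed = 7))
  expect_identical(lapply(t1$nodes, `[`, c("split", "members")),
                   lapply(t3$nodes, `[`, c("split", "members")))
})
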