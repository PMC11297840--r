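# Shared fixtures and independent oracles, all built in code.

# random right-censored dataset with lognormal times
random_dataset <- function(n, p = 0, censor = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tm <- exp(rnorm(n))
  cn <- if (censor > 0) exp(rnorm(n) + qnorm(1 - censor) * sqrt(2)) else rep(Inf, n)
  covs <- if (p > 0) as.data.frame(matrix(runif(n * p), n, p,
                                          dimnames = list(NULL, paste0("x", 1:p))))
          else NULL
  survival_data(pmin(tm, cn), as.integer(tm <= cn), covs)
}

# leave-one-out pseudo-values via the survival package (independent oracle)
pseudo_oracle_survfit <- function(d, grid) {
  n <- length(d$time)
  full <- summary(survival::survfit(survival::Surv(d$time, d$event) ~ 1),
                  times = grid, extend = TRUE)$surv
  loo <- t(vapply(seq_len(n), function(i) {
    s <- survival::survfit(survival::Surv(d$time[-i], d$event[-i]) ~ 1)
    summary(s, times = grid, extend = TRUE)$surv
  }, numeric(length(grid))))
  n * matrix(full, n, length(grid), byrow = TRUE) - (n - 1) * loo
}

# brute-force maximizer of the standardized two-sample split statistic
split_oracle <- function(theta, xv, min_size) {
  m <- nrow(theta)
  hbar <- colMeans(theta)
  vh <- colMeans(sweep(theta, 2, hbar)^2)
  xs <- sort(unique(xv))
  best <- -Inf
  for (t in (head(xs, -1) + diff(xs) / 2)) {
    right <- xv > t
    nr <- sum(right)
    if (nr < min_size || m - nr < min_size) next
    s2 <- nr * (m - nr) / (m - 1) * vh
    z <- abs(colSums(theta[right, , drop = FALSE]) - nr * hbar) / sqrt(s2)
    z <- z[s2 > 0]
    if (length(z)) best <- max(best, max(z))
  }
  best
}

# brute-force IPCW truncated concordance (explicit pair enumeration)
cindex_oracle <- function(d, risk, tau) {
  n <- length(d$time)
  gs <- survival::survfit(survival::Surv(d$time, 1 - d$event) ~ 1)
  G <- function(t) summary(gs, times = t - 1e-10, extend = TRUE)$surv
  num <- 0; den <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (d$event[i] != 1L || d$time[i] >= d$time[j] || d$time[i] >= tau) next
    g <- G(d$time[i])
    if (g <= 0) next
    w <- 1 / g^2
    num <- num + w * ((risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j]))
    den <- den + w
  }
  if (den == 0) NA_real_ else num / den
}
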