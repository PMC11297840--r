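## Multivariate conditional-inference tree on the n x K pseudo-value outcome.
##
## Split variables are selected by permutation tests of a linear association
## statistic between each covariate and the K-dimensional pseudo-value
## vectors (whole individuals are permuted, never single entries), and split
## points maximize the standardized two-sample statistic over all admissible
## binary partitions.  Standardization uses the exact conditional
## (Strasser-Weber) permutation moments.

#' Control parameters for tree growing
#'
#' @param maxdepth maximum tree depth D (D = 0 gives a single root node).
#' @param alpha significance threshold for the permutation tests; a node is
#'   not split if all covariate p-values exceed `alpha`.
#' @param min_node_size minimum number of individuals per daughter node;
#'   defaults to `5 * K` at fit time when `NULL`.
#' @param n_perm number of permutations for the split-variable tests.
#' @param multiplicity_adjust if `TRUE`, Bonferroni-adjust the minimum
#'   p-value across covariates before comparing with `alpha` (off by
#'   default: the raw minimum is compared).
#' @param max_factor_levels unordered factors with more observed levels than
#'   this are rejected (split search enumerates all binary partitions).
#' @param seed optional integer seed for the permutation stream.
#' @return A list of class `tree_control`.
#' @export
tree_control <- function(maxdepth = 2L, alpha = 0.05, min_node_size = NULL,
                         n_perm = 9999L, multiplicity_adjust = FALSE,
                         max_factor_levels = 10L, seed = NULL) {
  stopifnot(maxdepth >= 0, alpha > 0, alpha <= 1, n_perm >= 1)
  if (!is.null(min_node_size)) stopifnot(min_node_size >= 1)
  structure(list(maxdepth = as.integer(maxdepth), alpha = alpha,
                 min_node_size = min_node_size, n_perm = as.integer(n_perm),
                 multiplicity_adjust = isTRUE(multiplicity_adjust),
                 max_factor_levels = as.integer(max_factor_levels),
                 seed = seed),
            class = "tree_control")
}

## transformation g_j for the linear statistic: matrix with one row per node
## member (continuous -> value, ordered -> scores, unordered -> level
## indicators)
tree_transform <- function(v) {
  if (is.ordered(v)) {
    matrix(as.numeric(v), ncol = 1)
  } else if (is.factor(v)) {
    lev <- levels(v)[tabulate(v, nbins = nlevels(v)) > 0]
    sapply(lev, function(l) as.numeric(v == l))
  } else {
    matrix(as.numeric(v), ncol = 1)
  }
}

#' Standardized linear association statistic for one covariate
#'
#' Computes the linear statistic \eqn{T_j = \sum_i \tilde g_j(X_{ij})
#' (\hat\theta_i(t_1),\ldots,\hat\theta_i(t_K))^\top}, centers and scales each
#' element by its exact conditional permutation mean and standard deviation,
#' and summarizes by the maximum absolute standardized element.
#'
#' @param theta numeric matrix (node members x K) of pseudo-values.
#' @param g numeric transformation matrix (node members x p-tilde) of the
#'   covariate, e.g. from a continuous covariate (one column) or factor
#'   dummies.
#' @return List with `statistic` (standardized p-tilde x K matrix, `NA` for
#'   degenerate elements) and `max_abs`.
#' @export
correlation_statistic <- function(theta, g) {
  g <- as.matrix(g)
  m <- nrow(theta)
  stopifnot(nrow(g) == m, m >= 2)
  mom <- sw_moments(theta, g)
  T_obs <- crossprod(g, theta)
  std <- (T_obs - mom$mean) / mom$sd
  std[mom$sd <= 0] <- NA_real_
  if (all(is.na(std))) stop("covariate is constant within the node", call. = FALSE)
  list(statistic = std, max_abs = max(abs(std), na.rm = TRUE))
}

## Strasser-Weber conditional moments of T = crossprod(g, theta) under
## permutation of the rows of theta:
##   E[T_ak]   = colSums(g)_a * mean(theta_k)
##   Var[T_ak] = V_k * ( m/(m-1) sum g_a^2 - 1/(m-1) (sum g_a)^2 )
## with V_k = mean((theta_k - mean)^2).
sw_moments <- function(theta, g) {
  m <- nrow(theta)
  hbar <- colMeans(theta)
  vh <- colMeans(sweep(theta, 2, hbar)^2)
  gs <- colSums(g)
  gss <- colSums(g^2)
  gvar <- m / (m - 1) * gss - gs^2 / (m - 1)
  mean_mat <- outer(gs, hbar)
  var_mat <- outer(gvar, vh)
  list(mean = mean_mat, sd = sqrt(pmax(var_mat, 0)))
}

#' Permutation p-value for the association of one covariate
#'
#' The null distribution of the maximum absolute standardized statistic is
#' obtained by permuting whole individuals (rows of the pseudo-value matrix);
#' the p-value uses the add-one convention
#' \eqn{p = (1 + \#\{T^{perm} \ge T^{obs}\}) / (1 + B)}.
#'
#' @inheritParams correlation_statistic
#' @param n_perm number of permutations.
#' @param perms optional precomputed permutation index matrix (node size x
#'   `n_perm`); drawn from the current RNG stream when `NULL`.
#' @return List with `p_value`, `max_abs` (observed) and `statistic`.
#' @export
permutation_pvalue <- function(theta, g, n_perm = 9999L, perms = NULL) {
  g <- as.matrix(g)
  m <- nrow(theta)
  obs <- correlation_statistic(theta, g)
  if (is.null(perms))
    perms <- replicate(n_perm, sample.int(m))
  n_perm <- ncol(perms)
  mom <- sw_moments(theta, g)
  ok <- mom$sd > 0
  if (ncol(g) == 1L) {
    ## scalar transformation: all permutations in one BLAS call
    gp <- matrix(g[perms], m, n_perm)
    Tall <- crossprod(gp, theta)                     # n_perm x K
    std <- abs(sweep(sweep(Tall, 2, mom$mean[1, ]), 2, mom$sd[1, ], "/"))
    std[, !ok[1, ]] <- NA_real_
    tmax <- apply(std, 1, max, na.rm = TRUE)
  } else {
    tmax <- vapply(seq_len(n_perm), function(r) {
      Tp <- crossprod(g[perms[, r], , drop = FALSE], theta)
      max(abs((Tp - mom$mean) / mom$sd)[ok])
    }, numeric(1))
  }
  p <- (1 + sum(tmax >= obs$max_abs - 1e-12)) / (1 + n_perm)
  list(p_value = p, max_abs = obs$max_abs, statistic = obs$statistic)
}

## usable covariate: non-constant within the node (and factor level count
## within bounds)
covariate_usable <- function(v, max_factor_levels) {
  if (is.factor(v) && !is.ordered(v)) {
    nl <- sum(tabulate(v, nbins = nlevels(v)) > 0)
    if (nl > max_factor_levels)
      stop(sprintf("unordered factor with %d observed levels exceeds the limit of %d",
                   nl, max_factor_levels), call. = FALSE)
    nl >= 2
  } else {
    length(unique(as.numeric(v))) >= 2
  }
}

#' Select the split variable of a node
#'
#' Runs the permutation test for every usable (non-constant) covariate and
#' returns the covariate with the smallest p-value, or `NULL` when all
#' p-values exceed the significance threshold.  P-value ties are broken by
#' the larger observed maximum-absolute statistic, then by the smaller
#' covariate index.
#'
#' @param theta pseudo-value matrix restricted to the node members.
#' @param x covariate data frame restricted to the node members.
#' @param control a [tree_control()] object.
#' @return `NULL`, or a list with `variable` (column index), `name`,
#'   `p_value` and per-covariate test results.
#' @export
select_split_variable <- function(theta, x, control = tree_control()) {
  m <- nrow(theta)
  usable <- vapply(x, covariate_usable, logical(1),
                   max_factor_levels = control$max_factor_levels)
  if (!any(usable)) return(NULL)
  perms <- replicate(control$n_perm, sample.int(m))
  res <- lapply(which(usable), function(j) {
    permutation_pvalue(theta, tree_transform(x[[j]]), perms = perms)
  })
  p <- vapply(res, `[[`, numeric(1), "p_value")
  stat <- vapply(res, `[[`, numeric(1), "max_abs")
  pmin_raw <- min(p)
  p_sel <- if (control$multiplicity_adjust) min(1, pmin_raw * sum(usable)) else pmin_raw
  if (p_sel > control$alpha) return(NULL)
  cand <- which(p == pmin_raw)
  if (length(cand) > 1L) cand <- cand[order(-stat[cand])]
  j_star <- which(usable)[cand[1L]]
  list(variable = j_star, name = names(x)[j_star], p_value = p_sel,
       p_values = p, statistics = stat)
}

#' Find the best binary split for a selected covariate
#'
#' Maximizes the standardized two-sample statistic
#' \eqn{\max_k |(\sum_{i \in right} \hat\theta_i(t_k) - \mu_{k,s}) /
#' \sigma_{k,s}|} over all admissible partitions: threshold rules at
#' midpoints between consecutive distinct values for continuous and ordered
#' covariates, and all proper binary groupings of the observed categories for
#' unordered factors.  Partitions leaving fewer than `min_size` individuals
#' in either daughter are not admissible.
#'
#' @param theta pseudo-value matrix restricted to the node members.
#' @param v covariate vector (node members).
#' @param min_size minimum daughter-node size (individuals).
#' @return `NULL` when no admissible partition exists, otherwise a list with
#'   `kind` (`"threshold"` or `"subset"`), `threshold` or `left_levels`,
#'   `score` and `right` (logical membership of the right daughter).
#' @export
find_best_split <- function(theta, v, min_size = 1L) {
  m <- nrow(theta)
  hbar <- colMeans(theta)
  vh <- colMeans(sweep(theta, 2, hbar)^2)
  score_of <- function(right) {
    nr <- sum(right)
    sr <- colSums(theta[right, , drop = FALSE])
    sigma2 <- nr * (m - nr) / (m - 1) * vh
    z <- abs(sr - nr * hbar) / sqrt(sigma2)
    z[sigma2 <= 0] <- NA_real_
    if (all(is.na(z))) -Inf else max(z, na.rm = TRUE)
  }
  if (is.factor(v) && !is.ordered(v)) {
    lev <- levels(v)[tabulate(v, nbins = nlevels(v)) > 0]
    c_lev <- length(lev)
    if (c_lev < 2L) return(NULL)
    best <- NULL
    ## enumerate the 2^(c-1) - 1 proper binary partitions: the first level is
    ## pinned to the left; the code selects which of the remaining levels
    ## join it (at least one must stay on the right)
    for (code in 0:(2^(c_lev - 1L) - 2L)) {
      left_set <- lev[c(TRUE, bitwAnd(code, 2^(seq_len(c_lev - 1L) - 1L)) > 0)]
      right <- !(as.character(v) %in% left_set)
      if (sum(right) < min_size || sum(!right) < min_size) next
      sc <- score_of(right)
      if (is.null(best) || sc > best$score)
        best <- list(kind = "subset", left_levels = left_set,
                     right_levels = setdiff(lev, left_set),
                     score = sc, right = right)
    }
    return(best)
  }
  xv <- as.numeric(v)
  ord <- order(xv)
  xs <- xv[ord]
  cums <- apply(theta[ord, , drop = FALSE], 2, cumsum)
  cums <- rbind(matrix(cums, ncol = ncol(theta)))
  ## candidate cuts after position i where the value changes
  cut_pos <- which(diff(xs) > 0)
  cut_pos <- cut_pos[cut_pos >= min_size & (m - cut_pos) >= min_size]
  if (length(cut_pos) == 0L) return(NULL)
  nr <- m - cut_pos
  sr <- matrix(colSums(theta), nrow = length(cut_pos), ncol = ncol(theta),
               byrow = TRUE) - cums[cut_pos, , drop = FALSE]
  sigma2 <- outer(nr * (m - nr) / (m - 1), vh)
  z <- abs(sr - outer(nr, hbar)) / sqrt(sigma2)
  z[sigma2 <= 0] <- NA_real_
  sc <- apply(z, 1, function(r) if (all(is.na(r))) -Inf else max(r, na.rm = TRUE))
  if (all(!is.finite(sc))) return(NULL)
  b <- which.max(sc)
  thr <- (xs[cut_pos[b]] + xs[cut_pos[b] + 1L]) / 2
  list(kind = "threshold", threshold = thr, score = sc[b], right = xv > thr)
}

#' Grow a multivariate conditional-inference tree on pseudo-values
#'
#' Recursively applies [select_split_variable()] and [find_best_split()],
#' stopping at depth `maxdepth`, when no covariate reaches significance, or
#' when no partition respects the minimum node size.  All K observations of
#' one individual stay together: splitting acts on individuals.
#'
#' @param dataset a [survival_data()] object.
#' @param pv the matching `pseudo_values` object.
#' @param control a [tree_control()] object; a `NULL` `min_node_size`
#'   defaults to `5 * K`.
#' @return An object of class `pv_tree`: list with `nodes` (each carrying
#'   id, depth, member indices, size, split rule, p-value, children) and
#'   metadata.
#' @export
grow_tree <- function(dataset, pv, control = tree_control()) {
  stopifnot(inherits(dataset, "survival_data"), inherits(pv, "pseudo_values"))
  if (!is.null(control$seed)) set.seed(control$seed)
  K <- length(pv$grid)
  min_size <- if (is.null(control$min_node_size)) 5L * K else control$min_node_size
  n <- nrow(pv$values)
  nodes <- list()

  build <- function(id, members, depth) {
    node <- list(id = id, depth = depth, members = members,
                 size = length(members), split = NULL, p_value = NA_real_,
                 children = NULL, terminal = TRUE)
    if (depth < control$maxdepth && length(members) >= 2L * min_size) {
      theta <- pv$values[members, , drop = FALSE]
      xm <- dataset$x[members, , drop = FALSE]
      sel <- if (ncol(xm) > 0L) select_split_variable(theta, xm, control) else NULL
      if (!is.null(sel)) {
        sp <- find_best_split(theta, xm[[sel$variable]], min_size = min_size)
        if (!is.null(sp)) {
          node$split <- list(variable = sel$variable, name = sel$name,
                             kind = sp$kind,
                             threshold = sp$threshold,
                             left_levels = sp$left_levels,
                             right_levels = sp$right_levels)
          node$p_value <- sel$p_value
          node$terminal <- FALSE
          node$children <- c(2L * id, 2L * id + 1L)
          nodes[[as.character(id)]] <<- node
          build(2L * id, members[!sp$right], depth + 1L)
          build(2L * id + 1L, members[sp$right], depth + 1L)
          return(invisible(NULL))
        }
      }
    }
    nodes[[as.character(id)]] <<- node
    invisible(NULL)
  }
  build(1L, seq_len(n), 0L)
  structure(list(nodes = nodes, n = n, min_node_size = min_size,
                 control = control, var_names = names(dataset$x)),
            class = "pv_tree")
}

#' @export
print.pv_tree <- function(x, ...) {
  ids <- sort(as.integer(names(x$nodes)))
  cat(sprintf("Multivariate conditional-inference tree: %d node(s), %d terminal\n",
              length(ids), sum(vapply(x$nodes, `[[`, logical(1), "terminal"))))
  for (id in ids) {
    nd <- x$nodes[[as.character(id)]]
    ind <- paste(rep("  ", nd$depth), collapse = "")
    if (nd$terminal) {
      cat(sprintf("%s[%d] terminal, n = %d\n", ind, nd$id, nd$size))
    } else {
      rule <- if (nd$split$kind == "threshold")
        sprintf("%s <= %.4g", nd$split$name, nd$split$threshold)
      else
        sprintf("%s in {%s}", nd$split$name,
                paste(nd$split$left_levels, collapse = ","))
      cat(sprintf("%s[%d] n = %d, split: %s (p = %.4g)\n",
                  ind, nd$id, nd$size, rule, nd$p_value))
    }
  }
  invisible(x)
}

## route covariate rows down the tree; returns terminal node id per row
route_tree <- function(tree, x) {
  n <- nrow(x)
  out <- integer(n)
  for (i in seq_len(n)) {
    id <- 1L
    repeat {
      nd <- tree$nodes[[as.character(id)]]
      if (nd$terminal) { out[i] <- id; break }
      sp <- nd$split
      v <- x[[sp$name]]
      if (is.null(v)) stop(sprintf("covariate '%s' missing from new data", sp$name),
                           call. = FALSE)
      if (sp$kind == "threshold") {
        go_right <- as.numeric(v[i]) > sp$threshold
      } else {
        val <- as.character(v[i])
        if (!val %in% c(sp$left_levels, sp$right_levels))
          stop(sprintf("cannot route individual %d: level '%s' of '%s' was not observed during training",
                       i, val, sp$name), call. = FALSE)
        go_right <- val %in% sp$right_levels
      }
      id <- if (go_right) nd$children[2L] else nd$children[1L]
    }
  }
  out
}
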