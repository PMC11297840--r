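## Pseudo-value regression trees: orchestration of pseudo-value computation,
## tree growing, cascaded node-wise boosting, cross-validated tuning of the
## root iteration number, and survival prediction.

#' Node-wise boosting iteration budget
#'
#' Allocates boosting iterations proportionally to node size:
#' \eqn{m_{stop}(N) = round(\tilde n_N / n \cdot m_{stop}(1))} (nearest
#' integer, half away from zero), so the root receives `m_stop1` exactly and
#' smaller (deeper) nodes receive fewer iterations, possibly zero.
#'
#' @param m_stop1 root iteration number.
#' @param n_node number of individuals in the node.
#' @param n total number of individuals.
#' @return Integer iteration count for the node.
#' @examples node_mstop(400, 250, 1000)  # 100
#' @export
node_mstop <- function(m_stop1, n_node, n) {
  stopifnot(n_node <= n, n > 0, m_stop1 >= 0)
  as.integer(floor(n_node / n * m_stop1 + 0.5))
}

#' Fit a pseudo-value regression tree
#'
#' Runs the full pipeline: jackknife pseudo-values on the time grid, a
#' multivariate conditional-inference tree on the pseudo-value vectors, and
#' breadth-first cascaded gradient boosting in every node, where each node's
#' offset is the per-time-point average of its parent's fitted values (root:
#' link-transformed mean pseudo-values, i.e. the link-transformed
#' Kaplan-Meier curve) and its iteration budget follows [node_mstop()].
#'
#' @param dataset a [survival_data()] object.
#' @param grid a [time_grid()]; when `NULL`, chosen from the observed times
#'   via [choose_time_grid()].
#' @param m_stop1 root boosting iteration number (tune with
#'   [cross_validate_mstop()]).
#' @param tree_control a [tree_control()] object.
#' @param boost_control a [boost_control()] object.
#' @return An object of class `prt` containing the time grid, the fitted
#'   tree, the per-node boosting fits, and training metadata.
#' @export
fit_prt <- function(dataset, grid = NULL, m_stop1 = 100L,
                    tree_control = NULL, boost_control = NULL) {
  stopifnot(inherits(dataset, "survival_data"))
  if (is.null(tree_control)) tree_control <- tree_control()
  if (is.null(boost_control)) boost_control <- boost_control()
  if (is.null(grid)) grid <- choose_time_grid(dataset$time)
  pv <- jackknife_pseudo_values(dataset, grid)
  tree <- grow_tree(dataset, pv, tree_control)
  aug <- augment_long_format(dataset, pv)
  model <- fit_prt_nodes(tree, aug, m_stop1, boost_control)
  model$dataset_n <- length(dataset$time)
  model$grid <- grid
  model$m_stop1 <- m_stop1
  model$tree_control <- tree_control
  model$boost_control <- boost_control
  class(model) <- "prt"
  model
}

## cascade of node-wise boosting fits over an already grown tree
fit_prt_nodes <- function(tree, aug, m_stop1, boost_control) {
  K <- length(aug$grid)
  n <- tree$n
  Xall <- as.matrix(aug$table[, setdiff(names(aug$table),
                                        c("id", "time", "pseudo", "x0")),
                              drop = FALSE])
  theta_all <- aug$table$pseudo
  kidx_all <- aug$k_index

  ids <- sort(as.integer(names(tree$nodes)))
  fits <- list()
  rowsets <- list()   # augmented-table rows per node
  for (id in ids) {
    nd <- tree$nodes[[as.character(id)]]
    rows <- which(aug$row_individual %in% nd$members)
    rowsets[[as.character(id)]] <- rows
    if (id == 1L) {
      offset <- compute_offset(NULL, NULL, kidx_all, K, root_pseudo = theta_all)
    } else {
      parent <- id %/% 2L
      pf <- fits[[as.character(parent)]]
      prows <- rowsets[[as.character(parent)]]
      member_rows <- match(rows, prows)
      offset <- compute_offset(pf$fitted, member_rows, kidx_all[rows], K)
    }
    ms <- node_mstop(m_stop1, nd$size, n)
    fits[[as.character(id)]] <- boost_node(
      theta_all[rows],
      if (ncol(Xall) > 0L) Xall[rows, , drop = FALSE] else NULL,
      kidx_all[rows], offset, boost_control, mstop = ms)
  }
  list(tree = tree, node_fits = fits, design = aug$design,
       design_columns = colnames(Xall))
}

#' @export
print.prt <- function(x, ...) {
  cat("Pseudo-value regression tree\n")
  cat(sprintf("  n = %d individuals, K = %d time points, m_stop(1) = %d\n",
              x$dataset_n, length(x$grid), x$m_stop1))
  print(x$tree)
  invisible(x)
}

## expand new covariates with the training design (factor levels checked)
expand_newdata <- function(model, newdata) {
  newdata <- as.data.frame(newdata)
  cols <- list()
  for (nm in names(model$design)) {
    d <- model$design[[nm]]
    v <- newdata[[nm]]
    if (is.null(v))
      stop(sprintf("covariate '%s' missing from new data", nm), call. = FALSE)
    if (d$type == "continuous") {
      cols[[nm]] <- as.numeric(v)
    } else {
      vv <- as.character(v)
      if (!all(vv %in% d$levels))
        stop(sprintf("unseen level(s) of '%s': %s", nm,
                     paste(setdiff(unique(vv), d$levels), collapse = ", ")),
             call. = FALSE)
      if (d$type == "ordered") {
        cols[[nm]] <- as.numeric(factor(vv, levels = d$levels, ordered = TRUE))
      } else {
        for (l in d$levels[-1L])
          cols[[paste0(nm, l)]] <- as.numeric(vv == l)
      }
    }
  }
  mat <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = nrow(newdata), ncol = 0)
  if (length(cols)) colnames(mat) <- names(cols)
  mat[, model$design_columns, drop = FALSE]
}

#' Predict survival probabilities from a fitted PRT model
#'
#' Each individual is routed to a terminal node by the tree's split rules,
#' and the terminal node's boosting fit (offset + intercept + linear
#' covariate effects + monotone time curve) is evaluated on the link scale
#' and transformed with the complementary log-log response.  Predictions are
#' only defined on the training time grid and are nonincreasing in time.
#'
#' @param object a fitted `prt` model.
#' @param newdata data frame of covariates (training schema).
#' @param times evaluation times; must be a subset of the training grid
#'   (default: the full grid).
#' @param ... unused.
#' @return Matrix of survival probabilities, individuals x times.
#' @export
predict.prt <- function(object, newdata, times = NULL, ...) {
  grid <- as.numeric(object$grid)
  if (is.null(times)) times <- grid
  kpos <- match(times, grid)
  if (anyNA(kpos)) {
    ## tolerate floating-point representation differences
    kpos <- vapply(times, function(t) {
      j <- which(abs(grid - t) <= 1e-8 * pmax(1, abs(t)))
      if (length(j) != 1L) NA_integer_ else j
    }, integer(1))
  }
  if (anyNA(kpos))
    stop("all prediction times must lie on the training time grid", call. = FALSE)
  newdata <- as.data.frame(newdata)
  X <- expand_newdata(object, newdata)
  term <- route_tree(object$tree, newdata)
  n_new <- nrow(newdata)
  out <- matrix(NA_real_, n_new, length(kpos))
  for (id in unique(term)) {
    fit <- object$node_fits[[as.character(id)]]
    rows <- which(term == id)
    for (jj in seq_along(kpos)) {
      f <- boost_fit_predict(fit, X[rows, , drop = FALSE],
                             rep(kpos[jj], length(rows)))
      out[rows, jj] <- cloglog_response(f)
    }
  }
  colnames(out) <- paste0("t", seq_along(kpos))
  out
}

#' Cross-validated tuning of the root iteration number
#'
#' K-fold cross-validation over candidate values of `m_stop1`.  Folds are
#' formed by individual (all K pseudo-value rows travel together) and
#' stratified by the event indicator.  Within each training fold the
#' pseudo-values are recomputed and the tree is regrown; test-fold
#' pseudo-values are computed within the test fold, and the pseudo-value
#' loss of the predictions is pooled over all test observations.  The
#' candidate with minimal mean loss is selected (ties: smallest candidate).
#'
#' @param dataset a [survival_data()] object.
#' @param grid a [time_grid()].
#' @param candidates candidate `m_stop1` values.
#' @param folds number of folds (>= 2).
#' @param tree_control,boost_control control objects as in [fit_prt()].
#' @param seed integer seed for the fold assignment and permutation streams.
#' @return An object of class `prt_cv`: list with `candidates`, `loss`
#'   (mean pooled loss per candidate) and `m_stop1` (selected value).
#' @export
cross_validate_mstop <- function(dataset, grid,
                                 candidates = c(0, 50, 100, 250, 500, 1000, 2500),
                                 folds = 5L,
                                 tree_control = NULL, boost_control = NULL,
                                 seed = NULL) {
  if (is.null(tree_control)) tree_control <- tree_control()
  if (is.null(boost_control)) boost_control <- boost_control()
  stopifnot(inherits(dataset, "survival_data"), folds >= 2L,
            length(candidates) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- length(dataset$time)
  fold_id <- integer(n)
  for (ev in unique(dataset$event)) {
    idx <- which(dataset$event == ev)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  candidates <- sort(unique(as.integer(candidates)))
  loss_sum <- numeric(length(candidates))
  loss_n <- 0
  for (fo in seq_len(folds)) {
    tr <- which(fold_id != fo)
    te <- which(fold_id == fo)
    dtr <- survival_data(dataset$time[tr], dataset$event[tr],
                         dataset$x[tr, , drop = FALSE], id = dataset$id[tr])
    dte <- survival_data(dataset$time[te], dataset$event[te],
                         dataset$x[te, , drop = FALSE], id = dataset$id[te])
    pv_tr <- jackknife_pseudo_values(dtr, grid)
    ## small folds may not support the requested depth; grow_tree stops on
    ## its own via the node-size constraint
    tree <- grow_tree(dtr, pv_tr, tree_control)
    aug <- augment_long_format(dtr, pv_tr)
    pv_te <- jackknife_pseudo_values(dte, grid)
    theta_te <- as.vector(t(pv_te$values))
    for (ci in seq_along(candidates)) {
      m <- fit_prt_nodes(tree, aug, candidates[ci], boost_control)
      m$grid <- grid
      m$dataset_n <- length(tr)
      class(m) <- "prt"
      pred <- predict.prt(m, dte$x)
      loss_sum[ci] <- loss_sum[ci] + sum((theta_te - as.vector(t(pred)))^2)
    }
    loss_n <- loss_n + length(theta_te)
  }
  loss <- loss_sum / loss_n
  best <- candidates[which.min(loss)]
  structure(list(candidates = candidates, loss = loss, m_stop1 = best,
                 folds = folds),
            class = "prt_cv")
}

#' @export
print.prt_cv <- function(x, ...) {
  cat("Cross-validated m_stop(1) tuning\n")
  print(data.frame(m_stop1 = x$candidates, mean_loss = x$loss))
  cat("selected:", x$m_stop1, "\n")
  invisible(x)
}

## ---- serialization ---------------------------------------------------------

#' Serialize a fitted PRT model to JSON
#'
#' Writes a versioned structured-text representation of the tree (split
#' rules, p-values, node sizes) and the per-node boosting fits (offsets,
#' coefficients, time curve, selection log), sufficient to re-apply the
#' model to new data bit-identically.
#'
#' @param model a fitted `prt` model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_prt <- function(model, path) {
  nodes <- lapply(model$tree$nodes, function(nd) {
    list(id = nd$id, depth = nd$depth, size = nd$size,
         terminal = nd$terminal, p_value = nd$p_value,
         split = nd$split, children = nd$children)
  })
  fits <- lapply(model$node_fits, function(f) {
    list(offset = f$offset, gamma0 = f$gamma0, gamma = as.list(f$gamma),
         alpha = f$alpha, selected = f$selected, nu = f$nu, mstop = f$mstop)
  })
  obj <- list(schema_version = 1L,
              grid = as.numeric(model$grid),
              n = model$dataset_n,
              m_stop1 = model$m_stop1,
              design = model$design,
              design_columns = as.list(model$design_columns),
              min_node_size = model$tree$min_node_size,
              nodes = nodes, fits = fits)
  ## 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Deserialize a PRT model written by [write_prt()]
#'
#' @param path path to the JSON model file.
#' @return A `prt` model usable with [predict.prt()].
#' @export
read_prt <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(as.integer(obj$schema_version), 1L))
    stop("unsupported model schema version", call. = FALSE)
  nodes <- lapply(obj$nodes, function(nd) {
    nd$children <- if (length(nd$children)) as.integer(unlist(nd$children)) else NULL
    if (!is.null(nd$split)) {
      nd$split$left_levels <- unlist(nd$split$left_levels)
      nd$split$right_levels <- unlist(nd$split$right_levels)
    }
    nd
  })
  names(nodes) <- vapply(nodes, function(nd) as.character(nd$id), character(1))
  fits <- lapply(obj$fits, function(f) {
    gamma <- unlist(f$gamma)
    if (is.null(gamma)) gamma <- numeric(0)
    structure(list(offset = as.numeric(f$offset), gamma0 = f$gamma0,
                   gamma = gamma, alpha = as.numeric(f$alpha),
                   selected = as.integer(unlist(f$selected)),
                   nu = f$nu, mstop = f$mstop),
              class = "boost_fit")
  })
  names(fits) <- names(obj$fits)
  design <- lapply(obj$design, function(d) {
    d$columns <- unlist(d$columns); d$levels <- unlist(d$levels); d
  })
  model <- list(tree = structure(list(nodes = nodes, n = obj$n,
                                      min_node_size = obj$min_node_size),
                                 class = "pv_tree"),
                node_fits = fits,
                design = design,
                design_columns = unlist(obj$design_columns),
                dataset_n = obj$n,
                grid = time_grid(obj$grid),
                m_stop1 = obj$m_stop1)
  class(model) <- "prt"
  model
}
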