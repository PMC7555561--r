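# Unique-parameter counting under fusion, information criteria, lambda-grid
# searches with warm starts, and regularization-path extraction.

# connected components of an undirected graph on 1..n given an edge list
# (2-column matrix); simple union-find
.n_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (length(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1]); b <- find(edges[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}

# number of distinct parameter groups in one item's K x C logit matrix,
# linking the pairs the strategy penalizes when |difference| < tol
# (transitive closure, so a chain a ~ b ~ c counts once)
.item_groups <- function(g, strategy, tol) {
  K <- nrow(g); C <- ncol(g)
  id <- function(k, c) (c - 1L) * K + k
  edges <- NULL
  add <- function(e, k1, c1, k2, c2, ok) {
    if (any(ok)) rbind(e, cbind(id(k1, c1), id(k2, c2))[ok, , drop = FALSE]) else e
  }
  if (strategy %in% c("fused_classes", "fused_both", "group_classes") && C >= 2) {
    for (c1 in 1:(C - 1)) for (c2 in (c1 + 1):C) {
      d <- abs(g[, c1] - g[, c2])
      ok <- if (strategy == "group_classes") rep(max(d) < tol, K) else d < tol
      edges <- add(edges, seq_len(K), c1, seq_len(K), c2, ok)
    }
  }
  if (strategy %in% c("fused_categories", "fused_both", "group_categories") && K >= 2) {
    for (k1 in 1:(K - 1)) for (k2 in (k1 + 1):K) {
      d <- abs(g[k1, ] - g[k2, ])
      ok <- if (strategy == "group_categories") rep(max(d) < tol, C) else d < tol
      edges <- add(edges, k1, seq_len(C), k2, seq_len(C), ok)
    }
  }
  .n_components(K * C, edges)
}

#' Count unique free parameters under fusion
#'
#' For each item, parameters are grouped by the transitive closure of
#' "absolute logit difference below `fuse_tol`" along the pairs the penalty
#' strategy fuses (classes within category, categories within class, both,
#' or whole blocks for the group strategies); a group of parameters
#' estimated equal counts as a single free parameter. The total is
#' `sum_i #groups_i + (C - 1)` class-probability parameters; the number of
#' regularized item parameters is the raw item-parameter count minus the
#' group count.
#'
#' @param params a [model_params()] or `rlca_fit`.
#' @param spec a [penalty_spec()]; with `NULL` no pairs are fused and the
#'   saturated count `sum_i K_i C + C - 1` results.
#' @param fuse_tol positive logit tolerance for declaring two parameters
#'   equal.
#' @return list with `n_params` and `n_regularized`
#'   (`n_params + n_regularized` always equals the saturated count).
#' @export
count_unique_params <- function(params, spec = NULL, fuse_tol = 0.01) {
  if (inherits(params, "rlca_fit")) params <- params$params
  C <- params$C
  raw_item <- sum(vapply(params$gamma, function(g) nrow(g) * ncol(g), 0L))
  if (is.null(spec)) {
    groups <- raw_item
  } else {
    if (!inherits(spec, "penalty_spec")) stop("`spec` must be a penalty_spec")
    groups <- sum(vapply(params$gamma, .item_groups, 0L,
                         strategy = spec$strategy, tol = fuse_tol))
  }
  list(n_params = as.integer(groups + C - 1L),
       n_regularized = as.integer(raw_item - groups))
}

#' Information criteria
#'
#' `AIC = -2 loglik + 2 k` and `BIC = -2 loglik + k log N`, with `k` the
#' number of unique free parameters.
#'
#' @param loglik log-likelihood.
#' @param n_params number of free parameters (>= 1).
#' @param N sample size.
#' @return list with `aic` and `bic`.
#' @export
information_criteria <- function(loglik, n_params, N) {
  if (n_params < 1) stop("`n_params` must be >= 1", call. = FALSE)
  list(aic = -2 * loglik + 2 * n_params,
       bic = -2 * loglik + n_params * log(N))
}

#' Grid search over regularization parameters
#'
#' Fits a regularized latent class model at every point of a grid of
#' regularization parameters, warm-starting each fit from the previous
#' solution (path following from small to large penalties). The first grid
#' point additionally uses `n_starts` random starts plus a warm start from
#' an unpenalized multi-start fit. Each point's criteria use the
#' fused-parameter count of [count_unique_params()]. Strategies fusing only
#' classes take `grid1` (lambda1), strategies fusing only categories take
#' `grid2` (lambda2), and `fused_both` takes the Cartesian product of both.
#'
#' @param data a [response_matrix()] or integer matrix.
#' @param C number of classes.
#' @param spec_template a [penalty_spec()] supplying family, strategy and
#'   constants; its lambdas are overwritten per grid point (build it with
#'   placeholder lambdas, e.g. 0).
#' @param grid1 increasing vector of lambda1 values (class fusion).
#' @param grid2 increasing vector of lambda2 values (category fusion).
#' @param criterion `"bic"` (default) or `"aic"` for `best_index()`.
#' @param seed integer seed.
#' @param n_starts random starts at the first grid point.
#' @param base_fit optional unpenalized `rlca_fit` reused as the warm start
#'   (computed internally when `NULL`).
#' @param fuse_tol tolerance of the unique-parameter count.
#' @param max_iter,tol EM control per grid point.
#' @param verbose print one line per grid point.
#' @return an object of class `rlca_selection`: `grid` (a data frame with
#'   lambda1, lambda2, loglik, n_params, n_regularized, aic, bic,
#'   converged, n_iter), per-point `params` and `item_probs`,
#'   `best_bic_index`, `best_aic_index`, and bookkeeping fields.
#' @export
rlca_grid_search <- function(data, C, spec_template, grid1 = NULL, grid2 = NULL,
                             criterion = c("bic", "aic"), seed = 1,
                             n_starts = 3, base_fit = NULL, fuse_tol = 0.01,
                             max_iter = 500, tol = 1e-6, verbose = FALSE) {
  criterion <- match.arg(criterion)
  data <- as_response_matrix(data)
  if (!inherits(spec_template, "penalty_spec"))
    stop("`spec_template` must be a penalty_spec", call. = FALSE)
  st <- spec_template$strategy
  needs1 <- st %in% c("fused_classes", "fused_both", "group_classes")
  needs2 <- st %in% c("fused_categories", "fused_both", "group_categories")
  if (needs1 && is.null(grid1))
    stop("strategy '", st, "' requires `grid1`", call. = FALSE)
  if (needs2 && is.null(grid2))
    stop("strategy '", st, "' requires `grid2`", call. = FALSE)
  g1 <- if (needs1) sort(unique(grid1)) else 0
  g2 <- if (needs2) sort(unique(grid2)) else 0
  grid <- expand.grid(lambda2 = g2, lambda1 = g1)[, c("lambda1", "lambda2")]
  if (any(grid$lambda1 < 0) || any(grid$lambda2 < 0))
    stop("grid values must be nonnegative", call. = FALSE)

  if (is.null(base_fit))
    base_fit <- rlca_fit(data, C, spec = NULL, n_starts = 10, seed = seed,
                         max_iter = max_iter, tol = tol)
  prev <- base_fit$params

  n_grid <- nrow(grid)
  fits <- vector("list", n_grid)
  rows <- vector("list", n_grid)
  for (j in seq_len(n_grid)) {
    spec_j <- spec_template
    spec_j$lambda1 <- grid$lambda1[j]
    spec_j$lambda2 <- grid$lambda2[j]
    # later grid points start close to their solution, so the smoothing
    # anneal can start tighter and decay faster than in a cold fit
    f <- rlca_fit(data, C, spec_j,
                  n_starts = if (j == 1) n_starts else 1,
                  seed = seed + j, init = prev, fuse_tol = fuse_tol,
                  max_iter = max_iter, tol = tol,
                  eps_start = if (j == 1) 1e-3 else 1e-4,
                  eps_decay = if (j == 1) 0.85 else 0.6)
    if (j > 1) {
      # the penalized likelihood is multimodal: the warm path start can
      # carry over-fused solutions along, so also try a start from the
      # unpenalized fit and keep the better stationary point
      f2 <- rlca_fit(data, C, spec_j, n_starts = 1, seed = seed + j,
                     init = base_fit$params, fuse_tol = fuse_tol,
                     max_iter = max_iter, tol = tol,
                     eps_start = 1e-4, eps_decay = 0.6)
      if (f2$penalized_objective > f$penalized_objective) f <- f2
    }
    prev <- f$params
    fits[[j]] <- list(params = f$params, item_probs = f$item_probs)
    rows[[j]] <- data.frame(
      lambda1 = grid$lambda1[j], lambda2 = grid$lambda2[j],
      loglik = f$loglik, n_params = f$n_params,
      n_regularized = f$n_regularized, aic = f$aic, bic = f$bic,
      converged = f$converged, n_iter = f$n_iter)
    if (verbose)
      message(sprintf("lambda1 = %.3f lambda2 = %.3f  BIC = %.1f  #nreg = %d",
                      grid$lambda1[j], grid$lambda2[j], f$bic, f$n_regularized))
  }
  tab <- do.call(rbind, rows)
  ok <- which(tab$converged)
  if (!length(ok)) {
    warning("no grid point converged; best indices are NA")
    bb <- ba <- NA_integer_
  } else {
    bb <- ok[which.min(tab$bic[ok])]
    ba <- ok[which.min(tab$aic[ok])]
  }
  structure(list(grid = tab, fits = fits,
                 best_bic_index = bb, best_aic_index = ba,
                 criterion = criterion, C = C, N = data$N,
                 items = data$items, K = data$K,
                 spec_template = spec_template, fuse_tol = fuse_tol,
                 seed = seed, base_fit = base_fit),
            class = "rlca_selection")
}

#' @export
print.rlca_selection <- function(x, ...) {
  cat("Regularization grid search: ", nrow(x$grid), " points, C = ", x$C,
      ", strategy = ", x$spec_template$strategy, "\n", sep = "")
  b <- best_index(x)
  if (!is.na(b))
    cat(sprintf("  best %s at lambda1 = %.3g, lambda2 = %.3g: %s = %.1f, #np = %d, #nreg = %d\n",
                x$criterion, x$grid$lambda1[b], x$grid$lambda2[b],
                toupper(x$criterion), x$grid[[x$criterion]][b],
                x$grid$n_params[b], x$grid$n_regularized[b]))
  invisible(x)
}

#' Index of the criterion-optimal grid point
#'
#' @param selection an `rlca_selection`.
#' @param criterion `"bic"` or `"aic"`; defaults to the criterion chosen at
#'   search time.
#' @export
best_index <- function(selection, criterion = NULL) {
  if (is.null(criterion)) criterion <- selection$criterion
  switch(match.arg(criterion, c("bic", "aic")),
         bic = selection$best_bic_index,
         aic = selection$best_aic_index)
}

#' Extract a full fit for one grid point
#'
#' Re-runs the EM (one warm start from the stored solution) so the full
#' `rlca_fit` object, including the posterior, is available for a selected
#' grid point.
#'
#' @param selection an `rlca_selection`.
#' @param data the response data the search was run on.
#' @param index grid-point index; defaults to the criterion-optimal point.
#' @param ... passed to [rlca_fit()].
#' @export
extract_fit <- function(selection, data, index = NULL, ...) {
  if (is.null(index)) index <- best_index(selection)
  if (is.na(index) || index < 1 || index > nrow(selection$grid))
    stop("invalid grid index", call. = FALSE)
  spec <- selection$spec_template
  spec$lambda1 <- selection$grid$lambda1[index]
  spec$lambda2 <- selection$grid$lambda2[index]
  rlca_fit(data, selection$C, spec, n_starts = 1,
           init = selection$fits[[index]]$params,
           seed = selection$seed, fuse_tol = selection$fuse_tol, ...)
}

#' Regularization path of an item's fitted probabilities
#'
#' Fitted response probabilities of one item as a function of the (single)
#' regularization parameter along a 1D grid search; merge events show up as
#' coinciding columns.
#'
#' @param selection an `rlca_selection` over a one-dimensional grid.
#' @param item item index or label.
#' @param classes class indices (default all).
#' @param category response category whose probability is traced; defaults
#'   to the correct-response convention (category 1 for dichotomous items,
#'   category 0 for polytomous items).
#' @return data frame with a `lambda` column and one column per class.
#' @export
regularization_path <- function(selection, item, classes = NULL,
                                category = NULL) {
  tab <- selection$grid
  v1 <- length(unique(tab$lambda1)) > 1
  v2 <- length(unique(tab$lambda2)) > 1
  if (v1 && v2)
    stop("regularization paths require a one-dimensional grid", call. = FALSE)
  lambda <- if (v2) tab$lambda2 else tab$lambda1
  if (is.character(item)) item <- match(item, selection$items)
  if (is.na(item) || item < 1 || item > length(selection$items))
    stop("item out of range", call. = FALSE)
  K <- selection$K[item]
  if (is.null(category)) category <- if (K == 1L) 1L else 0L
  if (category < 0 || category > K) stop("category out of range", call. = FALSE)
  if (is.null(classes)) classes <- seq_len(selection$C)
  if (any(classes < 1 | classes > selection$C))
    stop("class out of range", call. = FALSE)
  probs <- t(vapply(selection$fits, function(f)
    f$item_probs[[item]][category + 1L, classes], numeric(length(classes))))
  out <- data.frame(lambda = lambda, probs)
  colnames(out)[-1] <- paste0("class", classes)
  out[order(out$lambda), , drop = FALSE]
}

#' Write a selection summary / path CSV
#'
#' `write_selection_csv()` writes one row per grid point with columns
#' `C, lambda1, lambda2, np, nreg, loglik, aic, bic, converged`.
#' `write_path_csv()` writes the long path table
#' `lambda1, lambda2, item, category, class, prob`.
#'
#' @param selection an `rlca_selection`.
#' @param path output file.
#' @export
write_selection_csv <- function(selection, path) {
  tab <- selection$grid
  out <- data.frame(C = selection$C,
                    lambda1 = tab$lambda1, lambda2 = tab$lambda2,
                    np = tab$n_params, nreg = tab$n_regularized,
                    loglik = signif(tab$loglik, 6),
                    aic = signif(tab$aic, 6), bic = signif(tab$bic, 6),
                    converged = tab$converged)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_selection_csv
#' @export
write_path_csv <- function(selection, path) {
  tab <- selection$grid
  rows <- do.call(rbind, lapply(seq_len(nrow(tab)), function(j) {
    do.call(rbind, lapply(seq_along(selection$items), function(i) {
      p <- selection$fits[[j]]$item_probs[[i]]
      data.frame(lambda1 = tab$lambda1[j], lambda2 = tab$lambda2[j],
                 item = selection$items[i],
                 category = rep(seq_len(nrow(p)) - 1L, ncol(p)),
                 class = rep(seq_len(ncol(p)), each = nrow(p)),
                 prob = signif(as.vector(p), 6))
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
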