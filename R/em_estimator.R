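# Penalized EM estimation: E-step posteriors, closed-form class-probability
# M-step, per-item penalized M-steps via quasi-Newton optimization of the
# smoothed objective, and the multi-start fitting driver.

#' E-step posterior class probabilities
#'
#' Conditional probability of each latent class given a person's responses,
#' `u*_nc = p_c prod_i p_{i,x_ni,c} / sum_d p_d prod_i p_{i,x_ni,d}`.
#'
#' @param data a [response_matrix()] (or coercible matrix).
#' @param params a [model_params()].
#' @return `N x C` matrix with rows summing to one.
#' @export
e_step <- function(data, params) {
  data <- as_response_matrix(data)
  .posterior_loglik(data, params)$posterior
}

#' M-step for the class logits
#'
#' The maximizer of the class part of the expected complete-data
#' log-likelihood is the posterior mean, `p_c = mean_n u*_nc`; it is
#' returned as class logits with `delta_1 = 0`. Classes whose posterior
#' mass falls below `floor` are floored (with a warning) to keep the next
#' E-step well defined.
#'
#' @param posterior `N x C` posterior matrix.
#' @param floor lower bound on class probabilities.
#' @return class logit vector `delta`.
#' @export
m_step_class_probs <- function(posterior, floor = 1e-6) {
  p <- colMeans(posterior)
  if (any(p < floor)) {
    warning("degenerate class with vanishing posterior mass; probability floored")
    p <- pmax(p, floor)
    p <- p / sum(p)
  }
  delta_from_class_probs(p)
}

# posterior-weighted category counts for one item: (K+1) x C
.item_counts <- function(x_i, posterior, K) {
  counts <- matrix(0, K + 1L, ncol(posterior))
  tmp <- rowsum(posterior, x_i)
  counts[as.integer(rownames(tmp)) + 1L, ] <- tmp
  counts
}

# per-item 0/1 indicator matrices (N x (K_i+1)), built once per fit so the
# M-step counts reduce to a crossprod
.onehot_list <- function(data) {
  lapply(seq_len(data$I), function(i) {
    M <- matrix(0, data$N, data$K[i] + 1L)
    M[cbind(seq_len(data$N), data$data[, i] + 1L)] <- 1
    M
  })
}

# Penalized weighted multinomial-logit maximization for one item, given the
# posterior-weighted counts. Maximizes sum_kc n_kc log p_kc(gamma) minus
# n_total * Pen_smooth(gamma). Guarded so the returned point is never worse
# than the initial one (generalized-EM ascent).
.optimize_item <- function(counts, n_total, spec, gamma_init, eps,
                           maxit = 100, reltol = 1e-10, restarts = 0,
                           grad_tol = 1e-4) {
  K <- nrow(gamma_init); C <- ncol(gamma_init)
  penalized <- .is_penalized(spec)
  n_c <- colSums(counts)
  fn <- function(par) {
    g <- matrix(par, K, C)
    q <- sum(counts * log(.clamp_prob(.probs_fast(g))))
    if (penalized) q <- q - n_total * .fused_value(g, spec, eps)
    -q
  }
  gr <- function(par) {
    g <- matrix(par, K, C)
    p <- .probs_fast(g)
    G <- counts[-1, , drop = FALSE] -
      p[-1, , drop = FALSE] * rep(n_c, each = K)
    if (penalized) G <- G - n_total * .fused_grad(g, spec, eps)
    -as.vector(G)
  }
  res <- stats::optim(as.vector(gamma_init), fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  # BFGS can stop on a flat function change while the gradient is still
  # appreciable; a restart resets its curvature estimate
  for (r in seq_len(restarts)) {
    if (max(abs(gr(res$par))) <= grad_tol) break
    res <- stats::optim(res$par, fn, gr, method = "BFGS",
                        control = list(maxit = maxit, reltol = reltol))
  }
  out <- if (res$value <= fn(as.vector(gamma_init))) res$par
         else as.vector(gamma_init)
  g <- matrix(out, K, C)
  structure(g,
            objective = -fn(out),
            grad_norm = max(abs(gr(out))),
            converged = res$convergence == 0L)
}

#' Penalized M-step for a single item
#'
#' Maximizes the item part of the expected complete-data log-likelihood
#' minus `N` times the smoothed fused penalty,
#' `sum_n sum_k sum_c x_nik u*_nc log p_ic(k; gamma_i) - N Pen(gamma_i)`,
#' by quasi-Newton (BFGS) iteration from `gamma_init`. The objective value
#' at the returned point is never below the value at `gamma_init`.
#'
#' @param item_data integer vector of the item's categories (one per person).
#' @param posterior `N x C` posterior matrix.
#' @param spec a [penalty_spec()] or `NULL` for the unpenalized M-step.
#' @param gamma_init `K x C` starting logits.
#' @param eps smoothing constant (defaults to `spec$smooth_eps`).
#' @param maxit maximum BFGS iterations.
#' @return `K x C` logit matrix with attributes `objective`, `grad_norm`
#'   and `converged`.
#' @export
m_step_item <- function(item_data, posterior, spec, gamma_init,
                        eps = NULL, maxit = 500) {
  gamma_init <- as.matrix(gamma_init)
  K <- nrow(gamma_init)
  counts <- .item_counts(item_data, posterior, K)
  if (is.null(eps)) eps <- if (inherits(spec, "penalty_spec")) spec$smooth_eps else 1e-6
  .optimize_item(counts, nrow(posterior), spec, gamma_init, eps,
                 maxit = maxit, restarts = 3)
}

# one full EM run from a given starting point
.em_run <- function(data, params, spec, max_iter, tol, gamma_tol,
                    eps_start, eps_final, eps_decay, class_floor,
                    optim_maxit, onehots = NULL) {
  penalized <- .is_penalized(spec)
  N <- data$N; I <- data$I; K <- data$K; X <- data$data
  if (is.null(onehots)) onehots <- .onehot_list(data)
  pl <- .posterior_loglik(data, params)
  trace <- numeric(0)
  obj_prev <- -Inf
  converged <- FALSE
  for (t in seq_len(max_iter)) {
    eps_t <- if (penalized) max(eps_final, eps_start * eps_decay^(t - 1)) else eps_final
    post <- pl$posterior
    delta <- m_step_class_probs(post, floor = class_floor)
    gamma <- params$gamma
    pen <- 0
    for (i in seq_len(I)) {
      counts <- crossprod(onehots[[i]], post)
      if (penalized) {
        g <- .optimize_item(counts, N, spec, gamma[[i]], eps_t,
                            maxit = optim_maxit)
        pen <- pen + .fused_value(g, spec, eps_t)
      } else {
        p <- .clamp_prob(counts / rep(pmax(colSums(counts), 1e-12),
                                      each = nrow(counts)))
        g <- log(p[-1, , drop = FALSE]) - rep(log(p[1, ]), each = K[i])
      }
      gamma[[i]] <- matrix(as.numeric(g), K[i], length(delta))
    }
    max_dg <- max(abs(unlist(gamma) - unlist(params$gamma)))
    params <- structure(list(gamma = gamma, delta = delta, C = length(delta)),
                        class = "model_params")
    pl <- .posterior_loglik(data, params)
    obj <- pl$loglik - N * pen
    trace[t] <- obj
    eps_done <- !penalized || eps_t <= eps_final * (1 + 1e-12)
    if (is.finite(obj_prev) && abs(obj - obj_prev) < tol &&
        max_dg < gamma_tol && eps_done) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  list(params = params, loglik = pl$loglik, posterior = pl$posterior,
       n_iter = length(trace), converged = converged, trace = trace)
}

.random_start <- function(data, C) {
  gamma <- lapply(data$K, function(k)
    matrix(stats::qlogis(stats::runif(k * C, 0.2, 0.8)), k, C))
  structure(list(gamma = gamma, delta = rep(0, C), C = C),
            class = "model_params")
}

.extract_params <- function(x) {
  if (inherits(x, "rlca_fit")) x$params
  else if (inherits(x, "model_params")) x
  else stop("`init` must be a model_params or rlca_fit object", call. = FALSE)
}

#' Fit a (regularized) latent class model
#'
#' Penalized EM estimation. The E-step computes posterior class
#' probabilities; the M-step updates the class probabilities in closed form
#' and each item's logits by quasi-Newton maximization of the expected
#' complete-data log-likelihood minus `N` times the fused penalty. The
#' penalty's absolute values are smoothed by `sqrt(x^2 + eps)` with `eps`
#' annealed geometrically from `eps_start` down to `eps_final` over the EM
#' iterations, so late iterations optimize an essentially exact objective.
#' Multiple random starts guard against local maxima; the best run by the
#' exact penalized objective is returned. With `spec = NULL` (or all
#' regularization parameters zero) the fit is the ordinary exploratory LCM
#' with closed-form M-steps.
#'
#' @param data a [response_matrix()] or integer matrix.
#' @param C number of latent classes.
#' @param spec a [penalty_spec()], or `NULL` for an unpenalized fit.
#' @param n_starts number of EM starts (a supplied `init` counts as the
#'   first start).
#' @param seed integer seed for the random starts.
#' @param max_iter maximum EM iterations per start.
#' @param tol absolute convergence tolerance on the penalized objective.
#' @param gamma_tol convergence tolerance on `max |change in gamma|`.
#' @param init optional warm start ([model_params()] or `rlca_fit`).
#' @param fuse_tol logit tolerance under which fitted parameters count as
#'   fused for the unique-parameter count.
#' @param class_floor lower bound for class probabilities in the M-step.
#' @param eps_start,eps_final,eps_decay smoothing-anneal schedule.
#' @param optim_maxit BFGS iteration cap per item M-step.
#' @return an object of class `rlca_fit`: converged parameters, `loglik`,
#'   exact `penalized_objective`, `posterior`, unique/regularized parameter
#'   counts, `aic`/`bic`, fitted `class_probs` and per-item `item_probs`,
#'   the objective trace of the best run, and bookkeeping fields.
#' @export
#' @examples
#' sim <- simulate_lcm(fixture_design("table1_dichotomous"), N = 200, seed = 1)
#' fit <- rlca_fit(sim$data, C = 4, n_starts = 2, seed = 1, max_iter = 50)
#' fit
rlca_fit <- function(data, C, spec = NULL, n_starts = 10, seed = 1,
                     max_iter = 500, tol = 1e-6, gamma_tol = 1e-4,
                     init = NULL, fuse_tol = 0.01, class_floor = 1e-6,
                     eps_start = 1e-3, eps_final = 1e-6, eps_decay = 0.85,
                     optim_maxit = 100) {
  data <- as_response_matrix(data)
  if (C < 1) stop("`C` must be >= 1", call. = FALSE)
  if (!is.null(spec) && !inherits(spec, "penalty_spec"))
    stop("`spec` must be a penalty_spec or NULL", call. = FALSE)
  n_pat <- nrow(unique(data$data))
  if (C > n_pat)
    warning("more classes than distinct response patterns")
  set.seed(seed)
  starts <- list()
  if (!is.null(init)) starts[[1]] <- .extract_params(init)
  while (length(starts) < max(n_starts, length(starts)))
    starts[[length(starts) + 1L]] <- .random_start(data, C)

  penalized <- .is_penalized(spec)
  onehots <- .onehot_list(data)
  runs <- lapply(starts, function(s)
    .em_run(data, s, spec, max_iter, tol, gamma_tol,
            eps_start, eps_final, eps_decay, class_floor, optim_maxit,
            onehots = onehots))
  exact_obj <- vapply(runs, function(r) {
    pen <- if (penalized)
      sum(vapply(r$params$gamma, .fused_value, 0, spec = spec, eps = 0))
    else 0
    r$loglik - data$N * pen
  }, 0)
  best <- which.max(exact_obj)
  run <- runs[[best]]

  counts <- count_unique_params(run$params, spec, fuse_tol = fuse_tol)
  ic <- information_criteria(run$loglik, counts$n_params, data$N)
  structure(list(
    params = run$params,
    loglik = run$loglik,
    penalized_objective = exact_obj[best],
    posterior = run$posterior,
    n_iter = run$n_iter,
    converged = run$converged,
    n_params = counts$n_params,
    n_regularized = counts$n_regularized,
    aic = ic$aic, bic = ic$bic,
    class_probs = class_probs(run$params$delta),
    item_probs = lapply(run$params$gamma, logits_to_probs),
    items = data$items,
    spec = spec, C = C, N = data$N, seed = seed,
    n_starts = length(starts), start_index = best,
    start_objectives = exact_obj,
    objective_trace = run$trace,
    fuse_tol = fuse_tol), class = "rlca_fit")
}

#' @export
print.rlca_fit <- function(x, digits = 4, ...) {
  cat("Latent class model fit (", x$C, " classes, N = ", x$N, ")\n", sep = "")
  if (.is_penalized(x$spec))
    cat("  penalty: ", x$spec$family, " / ", x$spec$strategy,
        "  lambda1 = ", format(x$spec$lambda1),
        ", lambda2 = ", format(x$spec$lambda2), "\n", sep = "")
  else cat("  unpenalized exploratory LCM\n")
  cat("  logLik = ", format(x$loglik, digits = 8),
      "  AIC = ", format(x$aic, digits = 8),
      "  BIC = ", format(x$bic, digits = 8), "\n", sep = "")
  cat("  free parameters = ", x$n_params,
      "  regularized item parameters = ", x$n_regularized, "\n", sep = "")
  cat("  class probabilities: ",
      paste(format(round(x$class_probs, digits)), collapse = " "), "\n", sep = "")
  cat("  converged: ", x$converged, " (", x$n_iter, " EM iterations)\n", sep = "")
  invisible(x)
}

# all permutations of 1..n (n! x n matrix); n is small (<= 8)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# permutation perm such that est_probs[, perm] best matches true_probs
.match_perm <- function(est_probs, true_probs) {
  C <- ncol(est_probs[[1]])
  if (C > 8) stop("exhaustive label matching supported for C <= 8", call. = FALSE)
  perms <- .permutations(C)
  cost <- apply(perms, 1, function(pp)
    sum(vapply(seq_along(est_probs), function(i)
      sum(abs(est_probs[[i]][, pp, drop = FALSE] - true_probs[[i]])), 0)))
  perms[which.min(cost), ]
}

#' Relabel fitted classes to match a generating design
#'
#' Mixture likelihoods are invariant under permutation of class labels
#' (label switching), so fitted classes must be aligned before comparing a
#' fit to the generating truth. The permutation minimizing the total
#' absolute difference between fitted and true item probability tables is
#' found exhaustively (C <= 8) and applied to all class-indexed components
#' of the fit.
#'
#' @param fit an `rlca_fit`.
#' @param design the generating [true_design()] (or a list of true item
#'   probability tables).
#' @return the fit with classes relabeled; the permutation used is stored
#'   in `$label_permutation` (entry `c` gives the fitted class matched to
#'   design class `c`).
#' @export
align_to_design <- function(fit, design) {
  true_probs <- if (inherits(design, "true_design")) design$item_probs else design
  perm <- .match_perm(fit$item_probs, true_probs)
  fit$params$gamma <- lapply(fit$params$gamma,
                             function(g) g[, perm, drop = FALSE])
  p <- fit$class_probs[perm]
  fit$params$delta <- delta_from_class_probs(p)
  fit$class_probs <- p
  fit$item_probs <- lapply(fit$item_probs, function(tab) tab[, perm, drop = FALSE])
  fit$posterior <- fit$posterior[, perm, drop = FALSE]
  fit$label_permutation <- perm
  fit
}
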