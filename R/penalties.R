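# Fused penalty families (LASSO, SCAD, MCP), their differentiable
# approximations, and the assembled fused / fused-group penalties applied to
# the item logits of a latent class model.

.penalty_families <- c("lasso", "scad", "mcp")
.penalty_strategies <- c("fused_classes", "fused_categories", "fused_both",
                         "group_categories", "group_classes")

.default_concavity <- function(family) {
  switch(family, mcp = 3, scad = 3.7, lasso = NA_real_)
}

.check_concavity <- function(family, concavity) {
  if (family == "scad" && (!is.finite(concavity) || concavity <= 2))
    stop("SCAD requires concavity > 2", call. = FALSE)
  if (family == "mcp" && (!is.finite(concavity) || concavity <= 1))
    stop("MCP requires concavity > 1", call. = FALSE)
  invisible(TRUE)
}

# Penalty evaluated at a nonnegative magnitude u (|x| or a smoothed |x|).
# MCP: lam*u - u^2/(2a) below the plateau a*lam, constant a*lam^2/2 beyond.
# SCAD: lam*u on [0, lam], quadratic blend on (lam, a*lam], then (a+1)lam^2/2.
.h_value <- function(u, lam, family, a) {
  if (family == "lasso") return(lam * u)
  if (family == "mcp") {
    v <- lam * u - u * u / (2 * a)
    v[u > a * lam] <- a * lam * lam / 2
    return(v)
  }
  v <- lam * u
  mid <- u > lam & u <= a * lam
  if (any(mid))
    v[mid] <- (2 * a * lam * u[mid] - u[mid]^2 - lam^2) / (2 * (a - 1))
  v[u > a * lam] <- (a + 1) * lam^2 / 2
  v
}

# dH/du; continuous for all three families (0 beyond the MCP/SCAD plateau).
.h_deriv <- function(u, lam, family, a) {
  if (family == "lasso") return(rep(lam, length(u)))
  if (family == "mcp") {
    v <- lam - u / a
    v[u > a * lam] <- 0
    return(v)
  }
  v <- rep(lam, length(u))
  mid <- u > lam & u <= a * lam
  if (any(mid)) v[mid] <- (a * lam - u[mid]) / (a - 1)
  v[u > a * lam] <- 0
  v
}

#' Scalar penalty function
#'
#' Evaluates the LASSO, SCAD or MCP penalty at `x` for regularization
#' strength `lam`. The LASSO penalty is `lam * |x|`; SCAD and MCP agree with
#' the LASSO near zero but flatten to a constant plateau for large `|x|`,
#' which reduces the shrinkage bias of strongly separated parameters.
#'
#' @param x numeric vector of (signed) arguments.
#' @param lam nonnegative regularization parameter.
#' @param family one of `"lasso"`, `"scad"`, `"mcp"`.
#' @param concavity shape constant `a` of SCAD/MCP (default 3.7 for SCAD,
#'   3 for MCP; must exceed 2 resp. 1). Ignored for LASSO.
#' @return numeric vector of nonnegative penalty values.
#' @export
#' @examples
#' penalty_value(0.5, 0.25, "lasso")     # 0.125
#' penalty_value(c(10, 20), 0.25, "mcp") # equal: both on the plateau
penalty_value <- function(x, lam, family = c("lasso", "scad", "mcp"),
                          concavity = NULL) {
  family <- match.arg(family)
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0)
    stop("`lam` must be a single nonnegative number", call. = FALSE)
  if (is.null(concavity)) concavity <- .default_concavity(family)
  .check_concavity(family, concavity)
  .h_value(abs(x), lam, family, concavity)
}

#' Differentiable approximation of a penalty function
#'
#' Replaces `|x|` by `sqrt(x^2 + eps)` inside [penalty_value()], giving an
#' everywhere-differentiable surrogate used by the penalized M-step. The
#' approximation error is bounded by a monotone function of `eps` and
#' vanishes as `eps -> 0`.
#'
#' @inheritParams penalty_value
#' @param eps small positive smoothing constant.
#' @return numeric vector of nonnegative values.
#' @export
smooth_penalty_value <- function(x, lam, family = c("lasso", "scad", "mcp"),
                                 concavity = NULL, eps = 1e-4) {
  family <- match.arg(family)
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("`eps` must be a single positive number", call. = FALSE)
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0)
    stop("`lam` must be a single nonnegative number", call. = FALSE)
  if (is.null(concavity)) concavity <- .default_concavity(family)
  .check_concavity(family, concavity)
  .h_value(sqrt(x^2 + eps), lam, family, concavity)
}

#' Penalty specification
#'
#' Bundles the penalty family, the fusion strategy and its regularization
#' parameters. `lambda1` is the class-fusion strength (the single `lambda`
#' of the dichotomous model), `lambda2` the category-fusion strength.
#' The five strategies are:
#' \describe{
#'   \item{fused_classes}{pairwise differences between classes within each
#'     response category (dichotomous items are the one-category case);
#'     uses `lambda1`.}
#'   \item{fused_categories}{pairwise differences between categories within
#'     each class; uses `lambda2`.}
#'   \item{fused_both}{the sum of the two penalties above; uses both.}
#'   \item{group_categories}{the Euclidean norm of the whole class-profile
#'     difference of two categories, so categories merge or stay distinct as
#'     a block; uses `lambda2`.}
#'   \item{group_classes}{the Euclidean norm of the whole category-profile
#'     difference of two classes; uses `lambda1`.}
#' }
#'
#' @param family penalty family, `"mcp"`, `"scad"` or `"lasso"`.
#' @param strategy fusion strategy, see Details.
#' @param lambda1 nonnegative class-fusion strength.
#' @param lambda2 nonnegative category-fusion strength.
#' @param concavity SCAD/MCP shape constant (defaults 3.7 / 3).
#' @param smooth_eps smoothing constant of the differentiable approximation.
#' @return an object of class `penalty_spec`.
#' @export
#' @examples
#' penalty_spec("mcp", "fused_classes", lambda1 = 0.2)
penalty_spec <- function(family = c("mcp", "scad", "lasso"),
                         strategy = c("fused_classes", "fused_categories",
                                      "fused_both", "group_categories",
                                      "group_classes"),
                         lambda1 = NULL, lambda2 = NULL,
                         concavity = NULL, smooth_eps = 1e-4) {
  family <- match.arg(family)
  strategy <- match.arg(strategy)
  if (is.null(concavity)) concavity <- .default_concavity(family)
  .check_concavity(family, concavity)
  needs1 <- strategy %in% c("fused_classes", "fused_both", "group_classes")
  needs2 <- strategy %in% c("fused_categories", "fused_both", "group_categories")
  if (needs1 && is.null(lambda1))
    stop("strategy '", strategy, "' requires `lambda1`", call. = FALSE)
  if (needs2 && is.null(lambda2))
    stop("strategy '", strategy, "' requires `lambda2`", call. = FALSE)
  if (is.null(lambda1)) lambda1 <- 0
  if (is.null(lambda2)) lambda2 <- 0
  if (lambda1 < 0 || lambda2 < 0)
    stop("regularization parameters must be nonnegative", call. = FALSE)
  if (!is.numeric(smooth_eps) || smooth_eps <= 0)
    stop("`smooth_eps` must be positive", call. = FALSE)
  structure(list(family = family, strategy = strategy,
                 lambda1 = lambda1, lambda2 = lambda2,
                 concavity = concavity, smooth_eps = smooth_eps),
            class = "penalty_spec")
}

#' @export
print.penalty_spec <- function(x, ...) {
  cat("Penalty spec: ", x$family, " / ", x$strategy, "\n", sep = "")
  cat("  lambda1 = ", format(x$lambda1), ", lambda2 = ", format(x$lambda2),
      if (x$family != "lasso") paste0(", a = ", format(x$concavity)),
      ", eps = ", format(x$smooth_eps), "\n", sep = "")
  invisible(x)
}

.is_penalized <- function(spec) {
  inherits(spec, "penalty_spec") && (spec$lambda1 > 0 || spec$lambda2 > 0)
}

# Value of the assembled fused penalty for one item's logit matrix (K x C).
# eps = 0 gives the exact (non-smooth) penalty; eps > 0 the differentiable
# approximation used during optimization.
.fused_value <- function(g, spec, eps = 0) {
  K <- nrow(g); C <- ncol(g)
  a <- spec$concavity; fam <- spec$family; st <- spec$strategy
  sab <- if (eps > 0) function(d) sqrt(d * d + eps) else abs
  val <- 0
  if (st %in% c("fused_classes", "fused_both") && spec$lambda1 > 0 && C >= 2) {
    for (c1 in 1:(C - 1)) for (c2 in (c1 + 1):C)
      val <- val + sum(.h_value(sab(g[, c1] - g[, c2]), spec$lambda1, fam, a))
  }
  if (st %in% c("fused_categories", "fused_both") && spec$lambda2 > 0 && K >= 2) {
    for (k1 in 1:(K - 1)) for (k2 in (k1 + 1):K)
      val <- val + sum(.h_value(sab(g[k1, ] - g[k2, ]), spec$lambda2, fam, a))
  }
  if (st == "group_categories" && spec$lambda2 > 0 && K >= 2) {
    for (k1 in 1:(K - 1)) for (k2 in (k1 + 1):K) {
      d <- g[k1, ] - g[k2, ]
      val <- val + .h_value(sqrt(sum(d * d) + eps), spec$lambda2, fam, a)
    }
  }
  if (st == "group_classes" && spec$lambda1 > 0 && C >= 2) {
    for (c1 in 1:(C - 1)) for (c2 in (c1 + 1):C) {
      d <- g[, c1] - g[, c2]
      val <- val + .h_value(sqrt(sum(d * d) + eps), spec$lambda1, fam, a)
    }
  }
  val
}

# Gradient of the smoothed fused penalty w.r.t. the K x C logit matrix.
.fused_grad <- function(g, spec, eps) {
  K <- nrow(g); C <- ncol(g)
  a <- spec$concavity; fam <- spec$family; st <- spec$strategy
  G <- matrix(0, K, C)
  if (st %in% c("fused_classes", "fused_both") && spec$lambda1 > 0 && C >= 2) {
    for (c1 in 1:(C - 1)) for (c2 in (c1 + 1):C) {
      d <- g[, c1] - g[, c2]
      u <- sqrt(d * d + eps)
      w <- .h_deriv(u, spec$lambda1, fam, a) * d / u
      G[, c1] <- G[, c1] + w
      G[, c2] <- G[, c2] - w
    }
  }
  if (st %in% c("fused_categories", "fused_both") && spec$lambda2 > 0 && K >= 2) {
    for (k1 in 1:(K - 1)) for (k2 in (k1 + 1):K) {
      d <- g[k1, ] - g[k2, ]
      u <- sqrt(d * d + eps)
      w <- .h_deriv(u, spec$lambda2, fam, a) * d / u
      G[k1, ] <- G[k1, ] + w
      G[k2, ] <- G[k2, ] - w
    }
  }
  if (st == "group_categories" && spec$lambda2 > 0 && K >= 2) {
    for (k1 in 1:(K - 1)) for (k2 in (k1 + 1):K) {
      d <- g[k1, ] - g[k2, ]
      u <- sqrt(sum(d * d) + eps)
      w <- .h_deriv(u, spec$lambda2, fam, a) * d / u
      G[k1, ] <- G[k1, ] + w
      G[k2, ] <- G[k2, ] - w
    }
  }
  if (st == "group_classes" && spec$lambda1 > 0 && C >= 2) {
    for (c1 in 1:(C - 1)) for (c2 in (c1 + 1):C) {
      d <- g[, c1] - g[, c2]
      u <- sqrt(sum(d * d) + eps)
      w <- .h_deriv(u, spec$lambda1, fam, a) * d / u
      G[, c1] <- G[, c1] + w
      G[, c2] <- G[, c2] - w
    }
  }
  G
}

#' Fused penalty of an item's logit matrix
#'
#' Evaluates the exact (non-smoothed) fused or fused-group penalty of one
#' item's logit matrix under a [penalty_spec()]. Rows index response
#' categories `1..K` (the reference category 0 carries logit 0 and is not
#' penalized), columns index latent classes. The penalty is applied on the
#' logit scale, which is also the scale used during estimation.
#'
#' @param gamma_item numeric `K x C` matrix of item logits.
#' @param spec a [penalty_spec()].
#' @param smooth if `TRUE`, evaluate the differentiable approximation at
#'   `spec$smooth_eps` instead of the exact penalty.
#' @return a single nonnegative number; 0 when all entries relevant to the
#'   strategy are equal.
#' @export
fused_penalty <- function(gamma_item, spec, smooth = FALSE) {
  if (!inherits(spec, "penalty_spec")) stop("`spec` must be a penalty_spec")
  g <- as.matrix(gamma_item)
  if (!is.numeric(g) || anyNA(g) || any(!is.finite(g)))
    stop("`gamma_item` must be a finite numeric matrix", call. = FALSE)
  .fused_value(g, spec, eps = if (smooth) spec$smooth_eps else 0)
}
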