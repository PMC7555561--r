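# Exploratory latent class models for dichotomous / polytomous items:
# multinomial-logit parameterization, likelihood, simulation, and the two
# built-in simulation designs used throughout the package documentation.

.clamp_prob <- function(p, lo = 1e-12) pmin(pmax(p, lo), 1 - lo)

#' Response matrix
#'
#' Validates and wraps a persons-by-items matrix of integer response
#' categories. Item `i` takes categories `0..K_i` (0-based coding; for
#' multiple-choice data category 0 is conventionally the correct response
#' in polytomous scorings, category 1 the correct response in dichotomous
#' scorings). Missing values are rejected.
#'
#' @param data integer matrix or data frame, persons in rows, items in
#'   columns.
#' @param n_categories optional integer vector of per-item category counts
#'   (`K_i + 1`); inferred from the data when omitted.
#' @return an object of class `response_matrix` with fields `data`
#'   (integer matrix), `K` (per-item maximum category), `N`, `I`, `items`.
#' @export
response_matrix <- function(data, n_categories = NULL) {
  x <- as.matrix(data)
  if (!is.numeric(x)) stop("responses must be numeric integer codes", call. = FALSE)
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop(sprintf("missing response at row %d, column %d", idx[1], idx[2]),
         call. = FALSE)
  }
  if (any(x != round(x))) {
    idx <- which(x != round(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer response at row %d, column %d", idx[1], idx[2]),
         call. = FALSE)
  }
  if (any(x < 0)) stop("response categories must be >= 0", call. = FALSE)
  storage.mode(x) <- "integer"
  N <- nrow(x); I <- ncol(x)
  if (N < 1L || I < 1L) stop("need at least one person and one item", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("item", seq_len(I))
  K <- pmax(apply(x, 2, max), 1L)
  if (!is.null(n_categories)) {
    if (length(n_categories) == 1L) n_categories <- rep(n_categories, I)
    if (length(n_categories) != I)
      stop("`n_categories` must have one entry per item", call. = FALSE)
    if (any(n_categories - 1L < K))
      stop("observed categories exceed `n_categories`", call. = FALSE)
    K <- as.integer(n_categories) - 1L
  }
  structure(list(data = x, K = as.integer(K), N = N, I = I,
                 items = colnames(x)),
            class = "response_matrix")
}

as_response_matrix <- function(data, n_categories = NULL) {
  if (inherits(data, "response_matrix")) data else response_matrix(data, n_categories)
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("Response matrix: ", x$N, " persons x ", x$I, " items\n", sep = "")
  cat("  categories per item: ", paste(x$K + 1L, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Convert item logits to response probabilities
#'
#' Maps a `K x C` matrix of item logits (reference category 0 fixed at logit
#' 0) to the `(K+1) x C` table of response-category probabilities via the
#' multinomial-logit transform `P(X = x | U = c) = exp(g_xc) / (1 + sum_k
#' exp(g_kc))`. Computation is stabilized against overflow.
#'
#' @param gamma_item numeric `K x C` matrix (a `1 x C` matrix or a length-C
#'   vector for dichotomous items).
#' @return `(K+1) x C` matrix with columns summing to one; row 1 is the
#'   reference category 0.
#' @export
logits_to_probs <- function(gamma_item) {
  g <- rbind(0, as.matrix(gamma_item))
  m <- apply(g, 2, max)
  e <- exp(sweep(g, 2, m, "-"))
  p <- sweep(e, 2, colSums(e), "/")
  rownames(p) <- paste0("cat", seq_len(nrow(p)) - 1L)
  p
}

#' Convert response probabilities to item logits
#'
#' Inverse of [logits_to_probs()]: `g_kc = log(p_kc / p_0c)`. Probabilities
#' must be strictly inside (0, 1) unless a clamping bound is supplied.
#'
#' @param prob_table `(K+1) x C` matrix of probabilities, columns summing to
#'   one; row 1 is the reference category.
#' @param clamp optional lower probability bound; when given, entries are
#'   clamped into `[clamp, 1 - clamp]` before taking logs instead of
#'   raising an error at 0/1.
#' @return `K x C` matrix of logits.
#' @export
probs_to_logits <- function(prob_table, clamp = NULL) {
  p <- as.matrix(prob_table)
  if (nrow(p) < 2L) stop("need at least two categories", call. = FALSE)
  cs <- colSums(p)
  if (any(abs(cs - 1) > 1e-6))
    stop("probability columns must sum to one", call. = FALSE)
  if (is.null(clamp)) {
    if (any(p <= 0) || any(p >= 1))
      stop("probabilities must lie strictly in (0, 1); use `clamp`",
           call. = FALSE)
  } else {
    p <- .clamp_prob(p, clamp)
  }
  g <- sweep(log(p[-1, , drop = FALSE]), 2, log(p[1, ]), "-")
  dimnames(g) <- NULL
  g
}

#' Class probabilities from class logits
#'
#' `p_c = exp(delta_c) / sum_j exp(delta_j)` with the identification
#' constraint `delta_1 = 0`.
#'
#' @param delta numeric vector of class logits, first entry 0.
#' @return probability vector summing to one.
#' @export
class_probs <- function(delta) {
  if (delta[1] != 0) stop("`delta[1]` must be fixed at 0", call. = FALSE)
  e <- exp(delta - max(delta))
  e / sum(e)
}

#' @rdname class_probs
#' @param p probability vector (strictly positive, sums to one).
#' @export
delta_from_class_probs <- function(p) {
  if (any(p <= 0)) stop("class probabilities must be positive", call. = FALSE)
  log(p / p[1])
}

#' Model parameters of a latent class model
#'
#' @param gamma list with one `K_i x C` logit matrix per item (reference
#'   category 0 implicit at logit 0).
#' @param delta class logits, `delta[1] == 0`.
#' @return object of class `model_params` with fields `gamma`, `delta`, `C`.
#' @export
model_params <- function(gamma, delta) {
  if (!is.list(gamma)) stop("`gamma` must be a list of matrices", call. = FALSE)
  C <- length(delta)
  gamma <- lapply(gamma, function(g) {
    g <- as.matrix(g)
    if (ncol(g) != C) stop("each gamma matrix needs C columns", call. = FALSE)
    if (anyNA(g) || any(!is.finite(g))) stop("logits must be finite", call. = FALSE)
    g
  })
  if (delta[1] != 0) stop("`delta[1]` must be fixed at 0", call. = FALSE)
  structure(list(gamma = gamma, delta = as.numeric(delta), C = C),
            class = "model_params")
}

#' True generating design of a latent class simulation
#'
#' @param class_probs length-`C` probability vector.
#' @param item_probs list with one `(K_i+1) x C` probability table per item
#'   (rows = categories `0..K_i`, columns = classes; columns sum to one).
#' @param items optional item labels.
#' @return object of class `true_design`.
#' @export
true_design <- function(class_probs, item_probs, items = NULL) {
  p <- as.numeric(class_probs)
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8)
    stop("`class_probs` must be a probability vector", call. = FALSE)
  item_probs <- lapply(item_probs, function(tab) {
    tab <- as.matrix(tab)
    if (any(tab < 0) || any(tab > 1))
      stop("item probabilities must lie in [0, 1]", call. = FALSE)
    if (any(abs(colSums(tab) - 1) > 1e-6))
      stop("item probability columns must sum to one", call. = FALSE)
    if (ncol(tab) != length(p))
      stop("item tables must have one column per class", call. = FALSE)
    rownames(tab) <- paste0("cat", seq_len(nrow(tab)) - 1L)
    tab
  })
  I <- length(item_probs)
  if (is.null(items)) items <- paste0("item", seq_len(I))
  structure(list(class_probs = p, item_probs = item_probs,
                 C = length(p), I = I,
                 K = vapply(item_probs, nrow, 1L) - 1L, items = items),
            class = "true_design")
}

#' @export
print.true_design <- function(x, ...) {
  cat("Latent class design: ", x$I, " items, ", x$C, " classes\n", sep = "")
  cat("  class probabilities: ", paste(format(x$class_probs), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Model parameters encoding a generating design
#'
#' @param design a [true_design()].
#' @param clamp probability bound used before the log-odds transform
#'   (designs may contain structural zeros).
#' @return a [model_params()] object.
#' @export
params_from_design <- function(design, clamp = 1e-12) {
  gamma <- lapply(design$item_probs, probs_to_logits, clamp = clamp)
  model_params(gamma, delta_from_class_probs(design$class_probs))
}

# fast multinomial-logit transform for the EM hot path; falls back to the
# overflow-stable exported version for extreme logits
.probs_fast <- function(g) {
  if (max(g) > 300) return(logits_to_probs(g))
  e <- rbind(1, exp(g))
  e / rep(colSums(e), each = nrow(e))
}

# N x C matrix of per-person log densities log prod_i p_{i, x_ni, c}
.log_density_matrix <- function(data, params) {
  X <- data$data
  L <- matrix(0, data$N, params$C)
  for (i in seq_len(data$I)) {
    lp <- log(.clamp_prob(.probs_fast(params$gamma[[i]])))
    L <- L + lp[X[, i] + 1L, , drop = FALSE]
  }
  L
}

# posterior matrix and observed-data log-likelihood in one pass
.posterior_loglik <- function(data, params) {
  A <- .log_density_matrix(data, params)
  A <- A + rep(log(.clamp_prob(class_probs(params$delta))), each = nrow(A))
  m <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  W <- exp(A - m)
  s <- rowSums(W)
  list(posterior = W / s, loglik = sum(m + log(s)))
}

#' Log-likelihood of a latent class model
#'
#' Observed-data log-likelihood `sum_n log sum_c p_c prod_i p_{i, x_ni, c}`
#' under conditional independence of items given class.
#'
#' @param data a [response_matrix()] (or coercible matrix).
#' @param params a [model_params()].
#' @return a single finite number.
#' @export
lcm_log_likelihood <- function(data, params) {
  data <- as_response_matrix(data)
  if (length(params$gamma) != data$I)
    stop("parameter and data dimensions disagree", call. = FALSE)
  for (i in seq_len(data$I))
    if (max(data$data[, i]) > nrow(params$gamma[[i]]))
      stop(sprintf("item %d has categories outside the model range", i),
           call. = FALSE)
  .posterior_loglik(data, params)$loglik
}

#' Simulate item responses from a latent class design
#'
#' Draws class memberships from the design's class probabilities and item
#' responses from the class-specific category tables. A single integer seed
#' governs both draws, so runs are exactly reproducible.
#'
#' @param design a [true_design()].
#' @param N number of persons.
#' @param seed integer seed.
#' @return list with components `data` (a [response_matrix()]), `class`
#'   (true memberships), `design`.
#' @export
simulate_lcm <- function(design, N, seed = 1) {
  if (!inherits(design, "true_design")) stop("`design` must be a true_design")
  if (N < 1) stop("`N` must be >= 1", call. = FALSE)
  set.seed(seed)
  u <- sample.int(design$C, N, replace = TRUE, prob = design$class_probs)
  X <- matrix(0L, N, design$I, dimnames = list(NULL, design$items))
  for (i in seq_len(design$I)) {
    tab <- design$item_probs[[i]]
    for (c in seq_len(design$C)) {
      idx <- which(u == c)
      if (length(idx))
        X[idx, i] <- sample.int(nrow(tab), length(idx), replace = TRUE,
                                prob = tab[, c]) - 1L
    }
  }
  list(data = response_matrix(X, n_categories = design$K + 1L),
       class = u, design = design)
}

#' Built-in simulation designs
#'
#' Two strongly structured generating designs with 12 items and 4 latent
#' classes (class probabilities 0.30, 0.20, 0.10, 0.40). Parameters are
#' specified for six items and duplicated for items 7-12. The dichotomous
#' design carries extensive within-item equality of correct-response
#' probabilities across classes; in the four-category polytomous design
#' many distractor categories additionally share probabilities within and
#' across classes. The classes are partially ordered: class 1 is weakest on
#' every item, class 4 strongest.
#'
#' @param name `"table1_dichotomous"` or `"table5_polytomous"`.
#' @return a [true_design()].
#' @export
fixture_design <- function(name = c("table1_dichotomous", "table5_polytomous")) {
  name <- match.arg(name)
  class_p <- c(0.30, 0.20, 0.10, 0.40)
  if (name == "table1_dichotomous") {
    correct <- matrix(c(
      0.10, 0.82, 0.82, 0.82,
      0.22, 0.88, 0.88, 0.88,
      0.16, 0.79, 0.16, 0.79,
      0.25, 0.85, 0.25, 0.85,
      0.10, 0.10, 0.46, 0.91,
      0.22, 0.22, 0.22, 0.79), nrow = 6, byrow = TRUE)
    item_probs <- lapply(rep(seq_len(6), 2), function(r)
      rbind(1 - correct[r, ], correct[r, ]))
  } else {
    blocks <- list(
      matrix(c(0.10, 0.82, 0.82, 0.82,
               0.30, 0.06, 0.06, 0.06,
               0.30, 0.06, 0.06, 0.06,
               0.30, 0.06, 0.06, 0.06), 4, 4, byrow = TRUE),
      matrix(c(0.22, 0.88, 0.88, 0.88,
               0.26, 0.05, 0.04, 0.06,
               0.26, 0.05, 0.04, 0.06,
               0.26, 0.02, 0.04, 0.00), 4, 4, byrow = TRUE),
      matrix(c(0.16, 0.79, 0.16, 0.79,
               0.28, 0.11, 0.28, 0.11,
               0.33, 0.05, 0.33, 0.05,
               0.23, 0.05, 0.23, 0.05), 4, 4, byrow = TRUE),
      matrix(c(0.25, 0.85, 0.25, 0.85,
               0.35, 0.03, 0.35, 0.03,
               0.20, 0.03, 0.20, 0.03,
               0.20, 0.09, 0.20, 0.09), 4, 4, byrow = TRUE),
      matrix(c(0.10, 0.10, 0.46, 0.91,
               0.30, 0.30, 0.18, 0.03,
               0.30, 0.30, 0.18, 0.03,
               0.30, 0.30, 0.18, 0.03), 4, 4, byrow = TRUE),
      matrix(c(0.22, 0.22, 0.22, 0.79,
               0.24, 0.23, 0.22, 0.06,
               0.20, 0.17, 0.12, 0.04,
               0.34, 0.38, 0.44, 0.11), 4, 4, byrow = TRUE))
    item_probs <- blocks[rep(seq_len(6), 2)]
  }
  true_design(class_p, item_probs)
}

#' Write / read a design's probability tables as CSV
#'
#' Long layout with one row per item and category and one column per class
#' (`item, category, class1..classC`), mirroring the usual presentation of
#' latent class probability tables.
#'
#' @param design a [true_design()].
#' @param path output file.
#' @export
write_design_csv <- function(design, path) {
  rows <- do.call(rbind, lapply(seq_len(design$I), function(i) {
    tab <- design$item_probs[[i]]
    data.frame(item = design$items[i],
               category = seq_len(nrow(tab)) - 1L,
               tab, check.names = FALSE, row.names = NULL)
  }))
  colnames(rows)[-(1:2)] <- paste0("class", seq_len(design$C))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @param class_probs class probabilities to attach on reading (the CSV
#'   layout stores only the item tables).
#' @export
read_design_csv <- function(path, class_probs) {
  df <- utils::read.csv(path, check.names = FALSE)
  items <- unique(df$item)
  item_probs <- lapply(items, function(it) {
    sub <- df[df$item == it, , drop = FALSE]
    sub <- sub[order(sub$category), , drop = FALSE]
    as.matrix(sub[, -(1:2), drop = FALSE])
  })
  true_design(class_probs, item_probs, items = items)
}

#' Number of free parameters of a saturated exploratory LCM
#'
#' `sum_i K_i * C + C - 1`; for `I` dichotomous items this is
#' `I * C + C - 1`.
#'
#' @param K per-item number of non-reference categories (`K_i`).
#' @param C number of classes.
#' @export
lcm_param_count <- function(K, C) {
  as.integer(sum(K) * C + C - 1L)
}
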