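# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can act as a second opinion on the implementation.

# mixture log-likelihood by direct summation
brute_loglik <- function(X, class_p, item_tabs) {
  ll <- 0
  for (n in seq_len(nrow(X))) {
    s <- 0
    for (c in seq_along(class_p)) {
      f <- class_p[c]
      for (i in seq_len(ncol(X))) f <- f * item_tabs[[i]][X[n, i] + 1, c]
      s <- s + f
    }
    ll <- ll + log(s)
  }
  ll
}

# posterior class membership by direct Bayes rule
brute_posterior <- function(X, class_p, item_tabs) {
  P <- matrix(0, nrow(X), length(class_p))
  for (n in seq_len(nrow(X))) {
    for (c in seq_along(class_p)) {
      f <- class_p[c]
      for (i in seq_len(ncol(X))) f <- f * item_tabs[[i]][X[n, i] + 1, c]
      P[n, c] <- f
    }
    P[n, ] <- P[n, ] / sum(P[n, ])
  }
  P
}

# double-loop evaluation of the fused penalties, mirroring their definitions
# term by term
brute_fused_penalty <- function(g, spec) {
  h <- function(x) penalty_value(x, switch(spec$strategy,
        fused_classes = , group_classes = spec$lambda1,
        fused_categories = , group_categories = spec$lambda2, NA),
        spec$family, spec$concavity)
  K <- nrow(g); C <- ncol(g)
  val <- 0
  if (spec$strategy %in% c("fused_classes", "fused_both")) {
    hv <- function(x) penalty_value(x, spec$lambda1, spec$family, spec$concavity)
    for (k in seq_len(K)) for (c in seq_len(C)) for (d in seq_len(C))
      if (c < d) val <- val + hv(g[k, c] - g[k, d])
  }
  if (spec$strategy %in% c("fused_categories", "fused_both")) {
    hv <- function(x) penalty_value(x, spec$lambda2, spec$family, spec$concavity)
    for (c in seq_len(C)) for (k in seq_len(K)) for (h2 in seq_len(K))
      if (k < h2) val <- val + hv(g[k, c] - g[h2, c])
  }
  if (spec$strategy == "group_categories") {
    for (k in seq_len(K)) for (h2 in seq_len(K))
      if (k < h2) val <- val + h(sqrt(sum((g[k, ] - g[h2, ])^2)))
  }
  if (spec$strategy == "group_classes") {
    for (c in seq_len(C)) for (d in seq_len(C))
      if (c < d) val <- val + h(sqrt(sum((g[, c] - g[, d])^2)))
  }
  val
}

# a minimal, textbook EM for the unpenalized latent class model, written
# independently of the package internals
plain_em <- function(X, K, class_p, item_tabs, n_iter = 200) {
  N <- nrow(X); I <- ncol(X); C <- length(class_p)
  for (it in seq_len(n_iter)) {
    post <- brute_posterior(X, class_p, item_tabs)
    class_p <- colMeans(post)
    for (i in seq_len(I)) {
      tab <- matrix(0, K[i] + 1, C)
      for (k in 0:K[i]) {
        idx <- which(X[, i] == k)
        for (c in seq_len(C))
          tab[k + 1, c] <- sum(post[idx, c]) / sum(post[, c])
      }
      item_tabs[[i]] <- pmin(pmax(tab, 1e-12), 1 - 1e-12)
    }
  }
  list(class_p = class_p, item_tabs = item_tabs,
       loglik = brute_loglik(X, class_p, item_tabs))
}

# small random ingredients under the caller's seed
random_prob_table <- function(K, C) {
  p <- matrix(stats::rgamma((K + 1) * C, 2, 1), K + 1, C)
  sweep(p, 2, colSums(p), "/")
}

random_toy_model <- function(N = 12, I = 3, K = c(1, 2, 3), C = 2) {
  item_tabs <- lapply(K, random_prob_table, C = C)
  class_p <- as.numeric(random_prob_table(C - 1, 1))
  X <- sapply(seq_len(I), function(i)
    sample(0:K[i], N, replace = TRUE))
  list(X = X, class_p = class_p, item_tabs = item_tabs, K = K, C = C)
}

# raw multiple-choice columns realized exactly at the bundled SPM-LS
# percentage frequencies (N = 1000 keeps the per-mille counts integral; the
# items whose printed percentages sum to 99.9 get the remainder added to the
# correct option)
spmls_synthetic_raw <- function() {
  freq <- spmls_option_frequencies()
  items <- unique(freq$item)
  N <- 1000L
  X <- matrix(0L, N, length(items), dimnames = list(NULL, items))
  key <- integer(length(items))
  for (j in seq_along(items)) {
    sub <- freq[freq$item == items[j], ]
    counts <- round(sub$percent * 10)
    counts[1] <- counts[1] + (N - sum(counts))
    X[, j] <- rep(sub$original_code, counts)
    key[j] <- sub$original_code[sub$category == 0]
  }
  raw_choice_data(X, key)
}
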