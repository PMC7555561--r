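test_that("E-step posteriors match the direct Bayes computation", {
  # one class: posterior is identically 1
  set.seed(21)
  toy <- random_toy_model(N = 10, C = 1)
  params <- model_params(lapply(toy$item_tabs, probs_to_logits), delta = 0)
  expect_equal(unname(e_step(toy$X, params)), matrix(1, 10, 1))

  # identical item probabilities across classes: posterior equals the prior
  tab <- random_prob_table(2, 1)
  params <- model_params(list(probs_to_logits(cbind(tab, tab, tab))),
                         delta_from_class_probs(c(0.5, 0.3, 0.2)))
  post <- e_step(matrix(sample(0:2, 8, TRUE), 8, 1), params)
  for (n in 1:8) expect_equal(unname(post[n, ]), c(0.5, 0.3, 0.2))

  # random two-class toys against the Bayes oracle
  for (r in 1:5) {
    toy <- random_toy_model(N = 15, I = 2, K = c(1, 2), C = 2)
    params <- model_params(lapply(toy$item_tabs, probs_to_logits),
                           delta_from_class_probs(toy$class_p))
    expect_equal(unname(e_step(toy$X, params)),
                 brute_posterior(toy$X, toy$class_p, toy$item_tabs),
                 tolerance = 1e-12)
  }
  # rows always sum to one
  expect_equal(rowSums(e_step(toy$X, params)), rep(1, 15))
})

test_that("class-probability M-step is the posterior mean", {
  post <- rbind(diag(2)[c(1, 1, 1), ], c(0, 1))
  expect_equal(class_probs(m_step_class_probs(post)), c(0.75, 0.25))
  expect_equal(class_probs(m_step_class_probs(matrix(1 / 3, 9, 3))),
               rep(1 / 3, 3))
  # agrees with direct numerical maximization of the Q-term over delta
  set.seed(4)
  for (r in 1:3) {
    u <- matrix(rgamma(30, 1), 10, 3)
    u <- u / rowSums(u)
    qfun <- function(d2) -sum(u %*% diag(log(class_probs(c(0, d2)))))
    opt <- optim(c(0, 0), qfun, method = "BFGS")
    expect_equal(class_probs(m_step_class_probs(u)),
                 class_probs(c(0, opt$par)), tolerance = 1e-4)
  }
  # degenerate class mass is floored with a warning
  expect_warning(m_step_class_probs(matrix(c(1, 1, 0, 0), 2, 2)), "floored")
})

test_that("unpenalized item M-step equals posterior-weighted frequencies", {
  set.seed(31)
  for (r in 1:3) {
    x <- sample(0:2, 40, TRUE)
    u <- matrix(rgamma(120, 1), 40, 3)
    u <- u / rowSums(u)
    g <- m_step_item(x, u, spec = NULL, gamma_init = matrix(0, 2, 3))
    fitted <- logits_to_probs(g)
    expected <- sapply(1:3, function(c)
      sapply(0:2, function(k) sum(u[x == k, c]) / sum(u[, c])))
    expect_equal(unname(fitted), expected, tolerance = 1e-5)
  }
})

test_that("a very large class-fusion penalty pools the classes", {
  set.seed(32)
  x <- sample(0:2, 200, TRUE, prob = c(0.5, 0.3, 0.2))
  u <- matrix(rgamma(600, 1), 200, 3)
  u <- u / rowSums(u)
  spec <- penalty_spec("lasso", "fused_classes", lambda1 = 10)
  g <- m_step_item(x, u, spec, gamma_init = matrix(0, 2, 3), eps = 1e-8)
  fitted <- logits_to_probs(g)
  pooled <- as.numeric(table(factor(x, 0:2)) / 200)
  for (c in 1:3) expect_equal(unname(fitted[, c]), pooled, tolerance = 1e-3)
})

test_that("item M-step never decreases its objective from the start", {
  set.seed(33)
  x <- sample(0:1, 60, TRUE)
  u <- matrix(rgamma(120, 1), 60, 2)
  u <- u / rowSums(u)
  spec <- penalty_spec("mcp", "fused_classes", lambda1 = 0.3)
  obj <- function(g, eps = 1e-6) {
    p <- logits_to_probs(g)
    sum(sapply(1:2, function(c) sum(log(p[x + 1, c]) * u[, c]))) -
      60 * rlca:::.fused_value(g, spec, eps)
  }
  for (r in 1:20) {
    init <- matrix(rnorm(2, sd = 2), 1, 2)
    g <- m_step_item(x, u, spec, gamma_init = init, eps = 1e-6)
    expect_gte(obj(g) - obj(init), -1e-8)
    expect_lt(attr(g, "grad_norm"), 1e-3)
  }
})

test_that("the penalized objective is monotone over EM iterations", {
  sim <- simulate_lcm(fixture_design("table1_dichotomous"), 300, seed = 2)
  spec <- penalty_spec("mcp", "fused_classes", lambda1 = 0.15)
  fit <- rlca_fit(sim$data, 3, spec, n_starts = 2, seed = 1, max_iter = 120)
  expect_true(all(diff(fit$objective_trace) >= -1e-6))
  expect_equal(rowSums(fit$posterior), rep(1, 300), tolerance = 1e-12)
  expect_lte(fit$penalized_objective, fit$loglik)

  # unpenalized EM is monotone in the log-likelihood itself
  fit0 <- rlca_fit(sim$data, 3, n_starts = 2, seed = 1)
  expect_true(all(diff(fit0$objective_trace) >= -1e-6))
})

test_that("single-class unpenalized fit has the closed-form solution", {
  set.seed(41)
  X <- cbind(sample(0:1, 80, TRUE), sample(0:3, 80, TRUE))
  fit <- rlca_fit(X, 1, n_starts = 1, seed = 1)
  marg1 <- as.numeric(table(factor(X[, 1], 0:1)) / 80)
  expect_equal(unname(fit$item_probs[[1]]), matrix(marg1, 2, 1),
               tolerance = 1e-8)
  direct <- sum(log(marg1[X[, 1] + 1])) +
    sum(log((table(factor(X[, 2], 0:3)) / 80)[X[, 2] + 1]))
  expect_equal(fit$loglik, as.numeric(direct), tolerance = 1e-8)
  expect_equal(fit$n_params, 4L + 1L - 1L + 0L)  # K1 + K2 + C - 1 = 4
})

test_that("lambda = 0 fits agree with an independent plain EM", {
  set.seed(51)
  des <- true_design(c(0.6, 0.4),
                     list(rbind(c(0.8, 0.3), c(0.2, 0.7)),
                          rbind(c(0.7, 0.2), c(0.3, 0.8)),
                          rbind(c(0.6, 0.1), c(0.2, 0.3), c(0.2, 0.6))))
  sim <- simulate_lcm(des, 150, seed = 3)
  start <- rlca:::.random_start(sim$data, 2)
  oracle <- plain_em(sim$data$data, sim$data$K,
                     class_probs(start$delta),
                     lapply(start$gamma, logits_to_probs), n_iter = 300)
  fit <- rlca_fit(sim$data, 2, n_starts = 1, init = start, seed = 1,
                  max_iter = 300)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-4)
  expect_equal(unname(fit$class_probs), oracle$class_p, tolerance = 1e-3)

  # zero-lambda penalty spec gives the same fit as spec = NULL
  spec0 <- penalty_spec("mcp", "fused_classes", lambda1 = 0)
  fitp <- rlca_fit(sim$data, 2, spec0, n_starts = 1, init = start, seed = 1,
                   max_iter = 300)
  expect_equal(fitp$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("label permutation leaves the likelihood unchanged", {
  sim <- simulate_lcm(fixture_design("table1_dichotomous"), 200, seed = 4)
  fit <- rlca_fit(sim$data, 3, n_starts = 3, seed = 2)
  perm <- c(2, 3, 1)
  permuted <- model_params(
    lapply(fit$params$gamma, function(g) g[, perm, drop = FALSE]),
    delta_from_class_probs(fit$class_probs[perm]))
  expect_equal(lcm_log_likelihood(sim$data, permuted), fit$loglik,
               tolerance = 1e-9)
})

test_that("fitted probabilities recover the generating design at N = 1000", {
  des <- fixture_design("table1_dichotomous")
  sim <- simulate_lcm(des, 1000, seed = 101)
  fit <- align_to_design(rlca_fit(sim$data, 4, n_starts = 10, seed = 101), des)
  expect_lt(max(abs(fit$class_probs - des$class_probs)), 0.05)
  # elementwise recovery; the binomial sampling error of the smallest class
  # (expected 100 members) dominates the worst case
  for (i in seq_len(12)) {
    expect_lt(max(abs(fit$item_probs[[i]] - des$item_probs[[i]])), 0.08)
  }
  mad <- mean(sapply(seq_len(12), function(i)
    mean(abs(fit$item_probs[[i]] - des$item_probs[[i]]))))
  expect_lt(mad, 0.03)
})

test_that("fit warns when classes outnumber distinct response patterns", {
  X <- matrix(rep(c(0L, 1L), each = 4), 4, 2)  # two distinct patterns
  expect_warning(rlca_fit(X, 3, n_starts = 1, seed = 1, max_iter = 20),
                 "patterns")
})
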