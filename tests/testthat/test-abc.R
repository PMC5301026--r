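test_that("summary vector agrees with the diversity/structure modules", {
  set.seed(61)
  spec <- scenario_founder(600, 200, 680, 50, 11000, 90, 1e-3, n_msat = 5L)
  ds <- simulate_coalescent(spec, c(bar = 8L, tpe = 6L), seed = 62L)
  s <- compute_summaries(ds)
  div <- msat_diversity(ds$genotypes)
  f <- global_f_statistics(ds$genotypes)
  expect_equal(unname(s["na_bar"]), div["bar", "na_mean"])
  expect_equal(unname(s["he_tpe"]), div["tpe", "he_mean"])
  expect_equal(unname(s["f_is"]), unname(f["f_is"]))
  expect_equal(unname(s["f_st"]), unname(f["f_st"]))
  expect_equal(unname(s["mean_pairwise_fst"]),
               mean(unfold_upper(pairwise_fst_nei(ds$genotypes))))
})

test_that("monomorphic tables are null-coded, and lengths are stable", {
  gt <- make_gt(c("A", "A", "B", "B"), list(matrix(5L, 4L, 2L)))
  s <- compute_summaries(gt)
  expect_true(attr(s, "degenerate"))
  expect_equal(unname(s[c("he_A", "he_B", "f_is", "f_st", "f_it")]),
               rep(0, 5L))
  set.seed(63)
  spec <- scenario_founder(300, 100, 300, 40, 5000, 50, 1e-3, n_msat = 4L)
  l1 <- length(compute_summaries(simulate_coalescent(spec, c(bar = 6L, tpe = 5L))))
  l2 <- length(compute_summaries(simulate_coalescent(spec, c(bar = 9L, tpe = 3L))))
  expect_equal(l1, l2)
})

test_that("rejection retains nearest simulations deterministically", {
  set.seed(64)
  n <- 300L
  sims <- list(params = matrix(rnorm(n), ncol = 1L,
                               dimnames = list(NULL, "theta")),
               summaries = matrix(rnorm(2L * n), ncol = 2L,
                                  dimnames = list(NULL, c("s1", "s2"))))
  obs <- c(s1 = 0.2, s2 = -0.1)
  all_kept <- abc_reject(obs, sims, retain_k = n)
  expect_setequal(all_kept$index, seq_len(n))
  expect_equal(sort(all_kept$params), sort(sims$params))
  # an exactly matching simulation ranks first
  sims$summaries[57L, ] <- obs
  r <- abc_reject(obs, sims, retain_k = 10L)
  expect_equal(r$index[1L], 57L)
  expect_equal(r$distances[1L], 0)
  expect_error(abc_reject(obs, sims, retain_k = n + 1L), "exceeds")
})

test_that("rejection posterior approaches the conjugate-normal posterior", {
  # theta ~ N(0, 1); data mean of m draws ~ N(theta, 1/m); analytic posterior
  # mean = xbar * 1 / (1 + 1/m)
  set.seed(65)
  m <- 25L
  n_sims <- 20000L
  theta <- rnorm(n_sims)
  xbar <- rnorm(n_sims, theta, sqrt(1 / m))
  sims <- list(params = matrix(theta, ncol = 1L,
                               dimnames = list(NULL, "theta")),
               summaries = matrix(xbar, ncol = 1L,
                                  dimnames = list(NULL, "xbar")))
  obs <- c(xbar = 0.8)
  post_mean_true <- 0.8 / (1 + 1 / m)
  r <- abc_reject(obs, sims, retain_k = 400L)
  expect_lt(abs(mean(r$params) - post_mean_true), 0.05)
})

test_that("GLM marginal density matches a closed-form Gaussian evidence", {
  # theta ~ N(0,1), s | theta ~ N(theta, 0.25): marginal s ~ N(0, 1.25)
  set.seed(66)
  n <- 4000L
  theta <- rnorm(n)
  s <- rnorm(n, theta, 0.5)
  sims <- list(params = matrix(theta, ncol = 1L,
                               dimnames = list(NULL, "theta")),
               summaries = matrix(s, ncol = 1L, dimnames = list(NULL, "s")))
  obs <- c(s = 0.4)
  ret <- abc_reject(obs, sims, retain_k = n)   # keep all: global evidence
  dens <- glm_marginal_density(ret, obs)
  expect_lt(abs(dens - stats::dnorm(0.4, 0, sqrt(1.25))) /
              stats::dnorm(0.4, 0, sqrt(1.25)), 0.10)
  # identical retained sets give identical densities; far-out observations ~ 0
  expect_equal(glm_marginal_density(ret, obs), dens)
  expect_lt(glm_marginal_density(ret, c(s = 50)), 1e-12)
})

test_that("model posteriors normalize and Bayes factors chain transitively", {
  mc <- model_posterior(c(a = 2, b = 2))
  expect_equal(unname(mc$posterior), c(0.5, 0.5))
  mc3 <- model_posterior(c(a = 1e-10, b = 3e-10, c = 6e-10))
  expect_equal(sum(mc3$posterior), 1, tolerance = 1e-9)
  bf <- mc3$bayes_factors
  expect_equal(bf["a", "c"], bf["a", "b"] * bf["b", "c"], tolerance = 1e-12)
  expect_error(model_posterior(c(a = 0, b = 0)), "zero")
})

test_that("posterior parameter summaries behave on known samples", {
  expect_warning(r <- posterior_param_estimates(
    matrix(5, 100L, 1L, dimnames = list(NULL, "k"))), "constant")
  expect_equal(r$mode, 5)
  expect_equal(r$hi95 - r$lo95, 0)
  set.seed(67)
  u <- matrix(runif(20000L), ncol = 1L, dimnames = list(NULL, "u"))
  ru <- posterior_param_estimates(u)
  expect_lt(abs(ru$lo95 - 0.025), 0.01)
  expect_lt(abs(ru$hi95 - 0.975), 0.01)
})

test_that("PLS components maximize covariance with parameters", {
  set.seed(68)
  n <- 500L
  X <- matrix(rnorm(n * 6L), n, 6L,
              dimnames = list(NULL, paste0("s", 1:6)))
  Y <- X[, 1L] * 2 + X[, 2L] + rnorm(n, 0, 0.3)
  Y <- matrix(Y, ncol = 1L, dimnames = list(NULL, "p"))
  fit <- pls_transform(X, Y, k = 2L)
  # oracle: first weight vector is the leading left singular vector of X0'Y0
  X0 <- scale(X); Y0 <- scale(Y)
  w_oracle <- svd(crossprod(X0, Y0))$u[, 1L]
  t1 <- X0 %*% w_oracle
  expect_gt(abs(cor(fit$scores[, 1L], t1)), 1 - 1e-8)
  # scores live in the span of the standardized summaries
  expect_equal(qr(cbind(X0, fit$scores))$rank, qr(X0)$rank)
  # duplicate columns do not crash
  fit2 <- pls_transform(cbind(X, X[, 1L, drop = FALSE]), Y, k = 2L)
  expect_equal(fit2$k, 2L)
  # params independent of summaries: component barely explains them
  Yind <- matrix(rnorm(n), ncol = 1L, dimnames = list(NULL, "p"))
  fit3 <- pls_transform(X, Yind, k = 1L)
  expect_lt(summary(lm(Yind ~ fit3$scores))$r.squared, 0.05)
  expect_error(pls_transform(X, Y, k = 0L), "positive")
  # rotation applies consistently to new data
  expect_equal(pls_apply(fit, X[3L, ]), fit$scores[3L, , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("the ABC pipeline is reproducible under a master seed", {
  ss <- c(bar = 6L, tpe1 = 4L, tpe2 = 4L, tpe3 = 4L)
  run <- function() {
    set.seed(70)
    refs <- list(abc_reference("multiple_origins", ss, n_sims = 150L,
                               n_msat = 5L),
                 abc_reference("single_origin", ss, n_sims = 150L,
                               n_msat = 5L))
    obs_spec <- scenario_multiple_origins(600, 50, 60, 40, 80, 2000, 30000,
                                          1e-4, mu_msat = 5e-4, n_msat = 5L)
    obs <- compute_summaries(simulate_coalescent(obs_spec, ss))
    abc_model_choice(obs, refs, retain_k = 120L)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$comparison$posterior, r2$comparison$posterior)
  expect_equal(sum(r1$comparison$posterior), 1, tolerance = 1e-9)
})
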