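test_that("indicator conditional probability matches the mixture formula", {
  # beta = 0: psi1(0)/psi0(0) = tau1/tau0 = 1/10, so at p = 0.5 the
  # probability is (1/10) / (1/10 + 1) = 1/11
  expect_equal(gamma_conditional_probability(0, 0.5), 1 / 11, tolerance = 1e-12)
  expect_equal(gamma_conditional_probability(3.7, 1), 1)
  expect_equal(gamma_conditional_probability(0.2, 0), 0)
  # monotone increasing in |beta|
  b <- seq(0, 1, by = 0.05)
  pr <- gamma_conditional_probability(b, 0.5)
  expect_true(all(diff(pr) > 0))
  expect_equal(gamma_conditional_probability(-b, 0.5), pr)
  # direct evaluation of the mixture for a non-default prior
  ssl <- ssl_prior(1, 5)
  psi1 <- 0.5 * exp(-1 * 0.3); psi0 <- 2.5 * exp(-5 * 0.3)
  expect_equal(gamma_conditional_probability(0.3, 0.4, ssl),
               0.4 * psi1 / (0.4 * psi1 + 0.6 * psi0), tolerance = 1e-12)
})

test_that("the chain is reproducible and the two beta kernels agree", {
  td <- toy_fit_data()
  f1 <- bmrf(td$x, n_iter = 800, burn_in = 300, seed = 5)
  f2 <- bmrf(td$x, n_iter = 800, burn_in = 300, seed = 5)
  expect_identical(f1$samples$beta_draws, f2$samples$beta_draws)
  expect_identical(f1$samples$gamma_draws, f2$samples$gamma_draws)
  expect_true(all(f1$samples$gamma_draws %in% 0:1))
  expect_equal(nrow(f1$samples$beta_draws), nrow(f1$samples$p_draws))

  fm <- bmrf(td$x, n_iter = 12000, burn_in = 2000, seed = 6,
             beta_update = "metropolis", mh_sd = 0.15)
  fg <- bmrf(td$x, n_iter = 12000, burn_in = 2000, seed = 6)
  expect_lt(max(abs(fm$edges$existence_probability -
                    fg$edges$existence_probability)), 0.08)
})

test_that("single-pair chain matches the quadrature oracle", {
  om <- matrix(c(1, 0.35, 0.35, 1), 2, 2)
  x <- standardize_expression(sample_mvn(om, 30, seed = 17))
  fit <- bmrf(x, n_iter = 24000, burn_in = 4000, seed = 2)
  est <- mean(fit$samples$gamma_draws[, 1])
  se <- batch_mcse(fit$samples$gamma_draws[, 1])
  expect_lt(abs(est - edge_prob_oracle_p2(x)), 3 * se)
})

test_that("edge summaries and network selection honor the threshold", {
  td <- toy_fit_data()
  fit <- bmrf(td$x, n_iter = 2000, burn_in = 500, seed = 11)
  e <- fit$edges
  expect_true(all(e$existence_probability >= 0 & e$existence_probability <= 1))
  expect_true(all(e$beta_q025 <= e$beta_median & e$beta_median <= e$beta_q975))
  expect_equal(e$selected, e$existence_probability > 0.5)

  # raising the threshold never adds an edge
  e9 <- summarize_edges(fit$samples, threshold = 0.9)
  expect_true(all(e9$selected <= e$selected))

  # hand-built draws: all-one indicators give probability one
  fake <- structure(list(
    beta_draws = matrix(rnorm(200), 100, 2),
    gamma_draws = cbind(rep(1L, 100), rep(0L, 100)),
    p_draws = matrix(0.5, 100, 2), sigma2_draws = matrix(1, 100, 3),
    pairs = cbind(c(1L, 1L), c(2L, 3L)), gene_ids = c("a", "b", "c"),
    config = list()), class = "bmrf_samples")
  es <- summarize_edges(fake, 0.5)
  expect_equal(es$existence_probability, c(1, 0))
  expect_equal(es$selected, c(TRUE, FALSE))
  net <- select_network(es, gene_ids = c("a", "b", "c"))
  expect_equal(net["a", "b"], 1L)
  expect_equal(sum(net), 2L)
  expect_equal(net, t(net))

  # probabilities (0.6, 0.4) at threshold 0.5: only the first selected
  fake$gamma_draws <- cbind(rep(c(1L, 0L), c(60, 40)),
                            rep(c(1L, 0L), c(40, 60)))
  es2 <- summarize_edges(fake, 0.5)
  expect_equal(es2$selected, c(TRUE, FALSE))

  expect_error(summarize_edges(structure(list(gamma_draws = matrix(0, 10, 1)),
                                         class = "bmrf_samples")),
               "at least 100")
})

test_that("fit object methods expose coefficients, fits, and residuals", {
  td <- toy_fit_data()
  fit <- bmrf(td$x, n_iter = 1500, burn_in = 500, seed = 13)
  expect_s3_class(fit, "bmrf")
  expect_output(print(fit), "candidate pairs: 10")
  expect_output(print(summary(fit)), "Top edges")

  B <- coef(fit)
  expect_equal(B, t(B))
  expect_equal(diag(B), rep(0, 5), ignore_attr = TRUE)
  expect_equal(unname(B[1, 2]), fit$edges$beta_mean[1])

  expect_equal(fitted(fit), td$x %*% t(B))
  expect_equal(residuals(fit), td$x - fitted(fit), ignore_attr = TRUE)
  expect_equal(predict(fit, td$x), fitted(fit))

  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("strengths recover sign and nulls stay improbable on the two-hub network", {
  fx <- m3_fixture()
  x <- standardize_expression(sample_mvn(fx$omega, 250, seed = 23))
  pri <- edge_priors(g_star = screen_correlation(x, 0.10))
  fit <- bmrf(x, priors = pri, n_iter = 6000, burn_in = 2000, seed = 23,
              keep_draws = FALSE)
  e <- fit$edges
  idx <- cbind(match(e$gene_i, fit$gene_ids), match(e$gene_j, fit$gene_ids))
  is_true_edge <- fx$graph[idx] == 1
  # omega = +0.216 on edges, so beta = -omega/omega_jj must be negative
  covered <- is_true_edge & e$existence_probability > 0.5
  expect_gte(mean(e$beta_mean[covered] < 0), 0.95)
  # non-edges: average existence probability below 0.1
  nontrue <- e$existence_probability[!is_true_edge]
  n_pairs <- choose(fit$p, 2)
  expect_lt(sum(nontrue) / (n_pairs - sum(is_true_edge)), 0.1)
})
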