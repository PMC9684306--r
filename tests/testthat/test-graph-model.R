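test_that("precision_to_car reproduces the Gaussian conditional parameters", {
  # independence case
  car <- precision_to_car(diag(4))
  expect_equal(car$beta, matrix(0, 4, 4))
  expect_equal(car$sigma2, rep(1, 4))

  # bivariate case checked against the conditional distribution of the MVN:
  # X1 | X2 = x ~ N(sigma12/sigma22 * x, sigma11 - sigma12^2/sigma22)
  om <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  car <- precision_to_car(om)
  sigma <- solve(om)
  slope <- sigma[1, 2] / sigma[2, 2]
  cond_var <- sigma[1, 1] - sigma[1, 2]^2 / sigma[2, 2]
  expect_equal(car$beta[1, 2], slope, tolerance = 1e-12)
  expect_equal(car$beta[1, 2], -0.3, tolerance = 1e-12)
  expect_equal(car$sigma2[1], cond_var, tolerance = 1e-12)
  expect_equal(car$sigma2, c(1, 1), tolerance = 1e-12)

  # equal diagonal implies a symmetric strength matrix
  g <- random_network(8, 0.3, seed = 4)
  om <- random_precision(g, seed = 4)        # unit diagonal by construction
  car <- precision_to_car(om)
  expect_lt(max(abs(car$beta - t(car$beta))), 1e-12)
  expect_equal(diag(car$beta), rep(0, 8), ignore_attr = TRUE)

  # round trip: omega_jk = -beta_jk * omega_jj recovers omega
  rec <- -car$beta * diag(om)
  diag(rec) <- diag(om)
  expect_equal(rec, om, tolerance = 1e-12)
})

test_that("precision matrix validation rejects bad inputs", {
  asym <- diag(3); asym[1, 2] <- 0.5
  expect_error(precision_to_car(asym), "symmetric")
  npd <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(precision_to_car(npd), "positive definite")
  expect_error(precision_to_partial_corr(npd), "positive definite")
})

test_that("partial correlations match conditioning-based brute force", {
  expect_equal(precision_to_partial_corr(diag(3)), diag(3))

  om <- diag(4); om[1, 2] <- om[2, 1] <- 0.216
  rho <- precision_to_partial_corr(om)
  expect_equal(rho[1, 2], -0.216, tolerance = 1e-12)

  for (seed in 1:5) {
    set.seed(seed)
    p <- sample(3:6, 1)
    a <- matrix(rnorm(p * p), p)
    om <- crossprod(a) + diag(p)          # random PD, unequal diagonal
    rho <- precision_to_partial_corr(om)
    expect_equal(rho, t(rho))
    expect_equal(diag(rho), rep(1, p), ignore_attr = TRUE)
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      expect_equal(rho[i, j], partial_corr_by_conditioning(om, i, j),
                   tolerance = 1e-8)
      # no-edge equivalence: omega zero <=> partial correlation zero
      expect_equal(sign(rho[i, j]), -sign(om[i, j]))
    }
  }
})

test_that("sample_mvn draws have the requested precision and are seeded", {
  x <- sample_mvn(diag(3), 100000, seed = 1)
  expect_equal(dim(x), c(100000, 3))
  expect_lt(max(abs(cov(x) - diag(3))), 0.02)

  om <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  x <- sample_mvn(om, 100000, seed = 2)
  expect_lt(max(abs(solve(cov(x)) - om)), 0.03)

  expect_identical(sample_mvn(om, 50, seed = 7), sample_mvn(om, 50, seed = 7))
  expect_error(sample_mvn(om, 1), "at least 2")
})

test_that("standardization centers, scales, and is idempotent", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 1, 5))
  z <- standardize_expression(x)
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(apply(z, 2, var), c(a = 1, b = 1))
  expect_true(attr(z, "standardized"))
  expect_equal(unclass(standardize_expression(z)), unclass(z),
               ignore_attr = TRUE, tolerance = 1e-12)

  xc <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_error(standardize_expression(xc), "a")
})

test_that("log pseudo-likelihood matches closed form and loop oracle", {
  td <- toy_fit_data(p = 4, n = 30)
  x <- td$x; n <- nrow(x); p <- ncol(x)

  # zero strengths, unit variances: sum of standard-normal log densities
  car0 <- list(beta = matrix(0, p, p), sigma2 = rep(1, p))
  expect_equal(log_pseudo_likelihood(x, car0),
               -(n * p / 2) * log(2 * pi) - sum(x^2) / 2, tolerance = 1e-10)

  car <- precision_to_car(td$omega)
  expect_equal(log_pseudo_likelihood(x, car),
               loop_pseudo_likelihood(x, car$beta, car$sigma2),
               tolerance = 1e-10)

  # exchangeable in the sample order
  expect_equal(log_pseudo_likelihood(x[sample(n), ], car),
               log_pseudo_likelihood(x, car), tolerance = 1e-10)

  expect_error(log_pseudo_likelihood(x, list(beta = car$beta,
                                             sigma2 = rep(-1, p))),
               "positive")
})
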