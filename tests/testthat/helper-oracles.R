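# Independent brute-force oracles used across the suite.

# Confusion metrics by an explicit loop over unordered pairs.
loop_confusion <- function(estimated, truth) {
  p <- ncol(truth)
  TP <- FP <- FN <- TN <- 0
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    e <- estimated[i, j]; t_ <- truth[i, j]
    if (e == 1 && t_ == 1) TP <- TP + 1
    else if (e == 1 && t_ == 0) FP <- FP + 1
    else if (e == 0 && t_ == 1) FN <- FN + 1
    else TN <- TN + 1
  }
  SEN <- if (TP + FN > 0) TP / (TP + FN) else 0
  SPE <- if (TN + FP > 0) TN / (TN + FP) else 0
  FDR <- if (TP + FP > 0) FP / (TP + FP) else 0
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  MCC <- if (den > 0) (TP * TN - FP * FN) / den else 0
  F1 <- if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else 0
  list(TP = TP, FP = FP, FN = FN, TN = TN, SEN = SEN, SPE = SPE,
       FDR = FDR, MCC = MCC, F1 = F1)
}

# Brier score by an explicit loop; prob_lookup maps "i,j" -> probability.
loop_brier <- function(prob, truth) {
  p <- ncol(truth)
  tot <- 0; npair <- 0
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    tot <- tot + (truth[i, j] - prob[i, j])^2
    npair <- npair + 1
  }
  tot / npair
}

# Partial correlation of a pair given all remaining variables, computed
# from the covariance by conditioning (independent of the -omega formula).
partial_corr_by_conditioning <- function(omega, i, j) {
  sigma <- solve(omega)
  rest <- setdiff(seq_len(ncol(sigma)), c(i, j))
  s_pp <- sigma[c(i, j), c(i, j)]
  if (length(rest)) {
    s_pr <- sigma[c(i, j), rest, drop = FALSE]
    s_rr <- sigma[rest, rest, drop = FALSE]
    s_pp <- s_pp - s_pr %*% solve(s_rr, t(s_pr))
  }
  s_pp[1, 2] / sqrt(s_pp[1, 1] * s_pp[2, 2])
}

# Naive double-loop CAR log pseudo-likelihood.
loop_pseudo_likelihood <- function(x, beta, sigma2) {
  n <- nrow(x); p <- ncol(x)
  tot <- 0
  for (j in seq_len(p)) for (i in seq_len(n)) {
    mu <- sum(beta[j, -j] * x[i, -j])
    tot <- tot + dnorm(x[i, j], mu, sqrt(sigma2[j]), log = TRUE)
  }
  tot
}

# Exact posterior edge probabilities on p = 3 by enumeration of the 8
# indicator configurations with trapezoid quadrature over the three
# strengths; the conditional variances are integrated out in closed form
# under their inverse-gamma prior.
edge_prob_oracle_p3 <- function(x, q = 0.5, tau1 = 2, tau0 = 20,
                                a0 = 0.01, b0 = 0.01,
                                lim = 0.75, n_grid = 151) {
  n <- nrow(x); S <- crossprod(x)
  g <- seq(-lim, lim, length.out = n_grid)
  h <- g[2] - g[1]
  wt <- rep(1, n_grid); wt[c(1, n_grid)] <- 0.5
  lw <- log(wt * h)
  G <- expand.grid(b12 = g, b13 = g, b23 = g)
  rss_row <- function(j) {
    if (j == 1)
      S[1, 1] + G$b12^2 * S[2, 2] + G$b13^2 * S[3, 3] +
        2 * G$b12 * G$b13 * S[2, 3] - 2 * G$b12 * S[1, 2] - 2 * G$b13 * S[1, 3]
    else if (j == 2)
      S[2, 2] + G$b12^2 * S[1, 1] + G$b23^2 * S[3, 3] +
        2 * G$b12 * G$b23 * S[1, 3] - 2 * G$b12 * S[1, 2] - 2 * G$b23 * S[2, 3]
    else
      S[3, 3] + G$b13^2 * S[1, 1] + G$b23^2 * S[2, 2] +
        2 * G$b13 * G$b23 * S[1, 2] - 2 * G$b13 * S[1, 3] - 2 * G$b23 * S[2, 3]
  }
  lml <- 0
  for (j in 1:3)
    lml <- lml + lgamma(a0 + n / 2) - lgamma(a0) + a0 * log(b0) -
      (a0 + n / 2) * log(b0 + rss_row(j) / 2) - (n / 2) * log(2 * pi)
  lpsi <- function(b, tau) log(tau / 2) - tau * abs(b)
  iw <- lw[match(G$b12, g)] + lw[match(G$b13, g)] + lw[match(G$b23, g)]
  bs <- list(G$b12, G$b13, G$b23)
  cfg <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  lws <- matrix(NA_real_, nrow(G), 8)
  for (ci in 1:8) {
    lp <- lml + iw
    for (m in 1:3) {
      gm <- cfg[ci, m]
      lp <- lp + lpsi(bs[[m]], if (gm == 1) tau1 else tau0) +
        (if (gm == 1) log(q) else log(1 - q))
    }
    lws[, ci] <- lp
  }
  M <- max(lws)
  Wg <- colSums(exp(lws - M))
  vapply(1:3, function(m) sum(Wg[cfg[, m] == 1]) / sum(Wg), 0)
}

# One-pair (p = 2) version of the same oracle on a 1-D grid.
edge_prob_oracle_p2 <- function(x, q = 0.5, tau1 = 2, tau0 = 20,
                                a0 = 0.01, b0 = 0.01,
                                lim = 0.9, n_grid = 4001) {
  n <- nrow(x); S <- crossprod(x)
  g <- seq(-lim, lim, length.out = n_grid)
  h <- g[2] - g[1]
  wt <- rep(1, n_grid); wt[c(1, n_grid)] <- 0.5
  rss1 <- S[1, 1] + g^2 * S[2, 2] - 2 * g * S[1, 2]
  rss2 <- S[2, 2] + g^2 * S[1, 1] - 2 * g * S[1, 2]
  lml <- 0
  for (rss in list(rss1, rss2))
    lml <- lml + lgamma(a0 + n / 2) - lgamma(a0) + a0 * log(b0) -
      (a0 + n / 2) * log(b0 + rss / 2) - (n / 2) * log(2 * pi)
  w1 <- exp(lml - max(lml)) * wt * q * tau1 / 2 * exp(-tau1 * abs(g))
  w0 <- exp(lml - max(lml)) * wt * (1 - q) * tau0 / 2 * exp(-tau0 * abs(g))
  sum(w1) / (sum(w1) + sum(w0))
}

# Batch-means Monte-Carlo standard error of a chain's mean.
batch_mcse <- function(v, n_batch = 50) {
  k <- length(v) %/% n_batch
  m <- colMeans(matrix(v[seq_len(k * n_batch)], k, n_batch))
  stats::sd(m) / sqrt(n_batch)
}

# Small deterministic fixture: data from a known sparse precision matrix.
toy_fit_data <- function(p = 5, n = 200, seed = 99) {
  om <- diag(p)
  om[1, 2] <- om[2, 1] <- 0.4
  if (p >= 4) om[3, 4] <- om[4, 3] <- -0.3
  x <- sample_mvn(om, n, seed = seed)
  list(omega = om, x = standardize_expression(x))
}
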