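# Independent oracles and small fixture builders used across tests.

# Brute-force numerical integration of the (beta, sigma2) marginal for a
# set of (phi, tau2rel) cells: midpoint quadrature over log(sigma2) with a
# beta grid recentred and rescaled per sigma2 node (flat beta prior,
# reciprocal sigma2 prior, intercept-only trend). Independent of the
# analytic conjugate formula under test.
marginal_quadrature_oracle <- function(coords, y, phis, taus,
                                       n_nodes = 801) {
  h <- as.matrix(stats::dist(coords))
  n <- length(y)
  zs <- seq(-12, 12, length.out = n_nodes)
  ts <- seq(-18, 20, length.out = n_nodes)
  cell <- function(phi, tau) {
    V <- exp(-h / phi) + tau * diag(n)
    Vi <- solve(V)
    ld <- as.numeric(determinant(V)$modulus)
    c0 <- drop(crossprod(y, Vi %*% y))
    c1 <- sum(Vi %*% y)
    c2 <- sum(Vi)
    bc <- c1 / c2
    tot <- 0
    for (t in ts) {
      s2 <- exp(t)
      sc <- sqrt(s2 / c2)
      bs <- bc + zs * sc
      q <- (c0 - 2 * bs * c1 + bs^2 * c2) / s2
      tot <- tot + sc * sum(exp(-(n / 2) * log(2 * pi * s2) - 0.5 * ld -
                                  0.5 * q))
    }
    tot
  }
  m <- mapply(cell, phis, taus)
  m / sum(m)
}

# Hand simple-kriging equations for fixed (beta, sigma2, phi, tau2rel):
# direct dense linear algebra, no eigendecomposition, no reuse of package
# internals.
kriging_hand_oracle <- function(coords, y, X, beta, sigma2, phi, tau2rel,
                                target, x0) {
  V <- exp(-as.matrix(stats::dist(coords)) / phi) +
    tau2rel * diag(length(y))
  r0 <- exp(-sqrt(colSums((t(coords) - target)^2)) / phi)
  w <- solve(V, r0)
  mean <- sum(x0 * beta) + sum(w * (y - X %*% beta))
  var <- sigma2 * (1 - sum(w * r0))
  list(mean = mean, var = var)
}

# Exhaustive best-subset search by AIC (same AIC convention as
# fit_linear): enumerates all 2^k subsets.
best_subset_oracle <- function(y, candidates) {
  nm <- names(candidates)
  best <- list(aic = Inf, terms = character(0))
  for (size in 0:length(nm)) {
    combos <- if (size == 0) list(character(0)) else
      utils::combn(nm, size, simplify = FALSE)
    for (terms in combos) {
      f <- fit_linear(y, candidates[, terms, drop = FALSE])
      if (f$aic < best$aic) best <- list(aic = f$aic, terms = sort(terms))
    }
  }
  best
}

# Hand-rolled posterior_draws data frame for prediction/summary tests.
make_draws <- function(phi, tau2rel, sigma2, beta) {
  beta <- as.matrix(beta)
  d <- data.frame(phi = phi, tau2rel = tau2rel, sigma2 = sigma2)
  cols <- c("beta_intercept", "beta_x", "beta_y")[seq_len(ncol(beta))]
  d[cols] <- beta
  class(d) <- c("posterior_draws", "data.frame")
  d
}

# An 81-core lipid fixture with a configurable number of cores lacking
# 16:0, for the filtering rules.
make_lipid_fixture <- function(n = 81, n_missing_16_0 = 9) {
  set.seed(401)
  tab <- data.frame(core_id = seq_len(n),
                    "16:0" = stats::runif(n, 5, 20),
                    "i15:0" = stats::runif(n, 1, 4),
                    "a15:0" = stats::runif(n, 1, 4),
                    "18:1w9c" = stats::runif(n, 5, 20),
                    "20:4w6c" = stats::runif(n, 0, 2),
                    check.names = FALSE)
  if (n_missing_16_0 > 0) tab[["16:0"]][seq_len(n_missing_16_0)] <- 0
  tab
}
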