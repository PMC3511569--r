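toy_obs <- function() {
  spatial_observations(c(0, 1, 2), c(0, 0, 0), c(0, 1, 0),
                       trend = "constant")
}

test_that("exponential correlation has the stated values and monotonicity", {
  expect_equal(exp_correlation(0, 2), 1)
  expect_equal(exp_correlation(2, 2), exp(-1))
  expect_equal(exp_correlation(6, 2), exp(-3))  # correlation at range 3*phi
  expect_error(exp_correlation(1, 0), "phi")
  expect_error(exp_correlation(-1, 1), "lag")
  # strictly decreasing in h and increasing in phi
  h <- seq(0, 20, by = 0.5)
  expect_true(all(diff(exp_correlation(h, 3)) < 0))
  phis <- seq(0.5, 10, by = 0.5)
  expect_true(all(diff(exp_correlation(4, phis)) > 0))
})

test_that("grid posterior matches brute-force numerical integration", {
  # three toys, n = 3..5, intercept-only trend; quadrature oracle
  toys <- list(
    list(coords = cbind(c(0, 1, 2), 0), y = c(0, 1, 0)),
    list(coords = cbind(c(0, 1, 3, 6), 0), y = c(0.2, -0.5, 1.1, 0.3)),
    list(coords = cbind(c(0, 1, 2, 0, 2), c(0, 1, 0, 2, 2)),
         y = c(1.4, 0.2, -0.6, 0.8, 0.1))
  )
  for (toy in toys) {
    obs <- spatial_observations(toy$coords[, 1], toy$coords[, 2], toy$y,
                                trend = "constant")
    pg <- compute_posterior(obs, prior_spec(phi_grid = c(0.5, 1, 2),
                                            tau2rel_grid = c(0.1, 1)))
    oracle <- marginal_quadrature_oracle(
      toy$coords, toy$y, pg$cells$phi, pg$cells$tau2rel)
    expect_lt(0.5 * sum(abs(pg$cells$mass - oracle)), 1e-4)
  }
})

test_that("log marginal is deterministic and reduces to the iid closed form", {
  obs <- toy_obs()
  two <- log_marginal(obs, c(1.3, 1.3), c(0.4, 0.4))
  expect_identical(two[1], two[2])
  # with phi far below the minimum lag, R = I and V = (1 + tau) I; the
  # marginal then equals the no-correlation closed form for every tau
  # -1/2 log|X'X| - (n-p)/2 log RSS, with n = 3, p = 1
  lm_iid <- -0.5 * log(3) - log(sum((obs$y - mean(obs$y))^2))
  for (tau in c(0, 0.5, 10, 1e6)) {
    expect_equal(log_marginal(obs, 1e-3, tau), lm_iid, tolerance = 1e-9)
  }
})

test_that("posterior normalizes, concentrates on single cells, and flags edges", {
  obs <- toy_obs()
  pg <- compute_posterior(obs, prior_spec(phi_grid = 1.5,
                                          tau2rel_grid = 0.3))
  expect_equal(pg$cells$mass, 1)
  d <- generate_design()
  o <- simulate_field(d, simulation_truth(sigma2 = 1, phi = 2,
                                          tau2_rel = 0.5), seed = 5)
  pg2 <- compute_posterior(o, prior_spec(n_phi = 20, n_tau = 20))
  expect_equal(sum(pg2$cells$mass), 1, tolerance = 1e-12)
  expect_true(all(pg2$cells$S2[is.finite(pg2$cells$log_post)] > 0))
})

test_that("posterior (phi, tau) masses are invariant to rescaling y", {
  d <- generate_design(spacings = rep(4, 8), n_rows = 4)
  o <- simulate_field(d, simulation_truth(beta = c(2, 0, 0), sigma2 = 1,
                                          phi = 3, tau2_rel = 0.4),
                      seed = 31)
  o2 <- spatial_observations(o$coords[, 1], o$coords[, 2], 3.7 * o$y)
  pr <- prior_spec(n_phi = 12, n_tau = 12)
  g1 <- compute_posterior(o, pr)
  g2 <- compute_posterior(o2, pr)
  expect_equal(g1$cells$mass, g2$cells$mass, tolerance = 1e-9)
  # sigma2 summaries scale by c^2
  s1 <- summarize_posterior(sample_posterior(g1, 4000, seed = 1))
  s2 <- summarize_posterior(sample_posterior(g2, 4000, seed = 1))
  expect_equal(s2$mean[s2$quantity == "sill"] /
                 s1$mean[s1$quantity == "sill"], 3.7^2, tolerance = 1e-6)
})

test_that("pure-nugget data drive the nugget ratio toward one", {
  d <- generate_design()
  o <- simulate_field(d, simulation_truth(sigma2 = 0.01, phi = 0.2,
                                          tau2_rel = 100), seed = 99)
  g <- compute_posterior(o, prior_spec(
    phi_grid = exp(seq(log(1), log(50), length.out = 25)),
    tau2rel_grid = c(0, exp(seq(log(0.1), log(400), length.out = 24)))))
  dr <- sample_posterior(g, 5000, seed = 100)
  ratio <- dr$tau2rel / (1 + dr$tau2rel)
  expect_gt(mean(ratio), 0.7)
  expect_gt(mean(ratio > 0.5), 0.6)
})

test_that("posterior mode recovers phi within a factor of two", {
  d <- generate_design()
  tr <- simulation_truth(beta = c(0, 0, 0), sigma2 = 1, phi = 3,
                         tau2_rel = 0.1)
  hits <- 0
  for (i in 1:50) {
    o <- simulate_field(d, tr, seed = 3000 + i)
    g <- compute_posterior(o, prior_spec(n_phi = 25, n_tau = 25))
    hits <- hits + (g$mode$phi >= 1.5 && g$mode$phi <= 6)
  }
  expect_gte(hits, 40)  # >= 80% of 50 replicates
})

test_that("posterior sampling matches grid masses and analytic moments", {
  obs <- toy_obs()
  # single cell: every draw shares it
  g1 <- compute_posterior(obs, prior_spec(phi_grid = 1.2,
                                          tau2rel_grid = 0.5))
  d1 <- sample_posterior(g1, 200, seed = 3)
  expect_equal(unique(d1$phi), 1.2)
  expect_equal(unique(d1$tau2rel), 0.5)
  expect_error(sample_posterior(g1, 0), "n_draws")

  d <- generate_design(spacings = rep(4, 8), n_rows = 3)
  o <- simulate_field(d, simulation_truth(sigma2 = 1, phi = 3,
                                          tau2_rel = 0.3), seed = 17)
  g <- compute_posterior(o, prior_spec(phi_grid = c(1, 3, 9),
                                       tau2rel_grid = c(0, 0.5, 2)))
  n <- 1e5
  dr <- sample_posterior(g, n, seed = 4)
  key <- paste(dr$phi, dr$tau2rel)
  gkey <- paste(g$cells$phi, g$cells$tau2rel)
  freq <- as.numeric(table(factor(key, levels = gkey))) / n
  se <- sqrt(g$cells$mass * (1 - g$cells$mass) / n)
  expect_true(all(abs(freq - g$cells$mass) <= 3 * se + 1e-12))
  # sigma2 posterior mean: grid-weighted S2 / (df - 2)
  mu_analytic <- sum(g$cells$mass * g$cells$S2 / (g$cells$df - 2))
  expect_equal(mean(dr$sigma2), mu_analytic, tolerance = 0.05)
})

test_that("kriging matches hand linear algebra and interpolates exactly", {
  # 1D three-point toy with one fixed draw: direct solve oracle, 1e-10
  coords <- cbind(c(0, 1, 2.5), 0)
  y <- c(0.3, 1.2, -0.4)
  obs <- spatial_observations(coords[, 1], coords[, 2], y,
                              trend = "constant")
  beta <- 0.25; sigma2 <- 1.7; phi <- 1.3; tau <- 0.4
  dr <- make_draws(phi, tau, sigma2, matrix(beta))
  tg <- data.frame(x_m = c(0.7, 1.9), y_m = c(0, 0))
  sf <- krige_predict(obs, dr, tg)
  for (j in 1:2) {
    hand <- kriging_hand_oracle(coords, y, matrix(1, 3, 1), beta, sigma2,
                                phi, tau, c(tg$x_m[j], 0), 1)
    expect_equal(sf$pred_mean[j], hand$mean, tolerance = 1e-10)
    expect_equal(sf$pred_var[j], hand$var, tolerance = 1e-10)
  }

  # tau2rel = 0: prediction at an observed location returns the datum
  d <- generate_design(spacings = rep(2, 8), n_rows = 3)
  o <- simulate_field(d, simulation_truth(beta = c(5, 0.1, 0), sigma2 = 2,
                                          phi = 4, tau2_rel = 0), seed = 3)
  g <- compute_posterior(o, prior_spec(phi_grid = 4, tau2rel_grid = 0))
  dro <- sample_posterior(g, 300, seed = 4)
  at_obs <- data.frame(x_m = o$coords[1:6, 1], y_m = o$coords[1:6, 2])
  sfo <- krige_predict(o, dro, at_obs)
  expect_equal(sfo$pred_mean, o$y[1:6], tolerance = 1e-8)
  expect_lt(max(sfo$pred_var), 1e-8)
})

test_that("predictions far beyond the range revert to the GLS trend", {
  d <- generate_design(spacings = rep(2, 8), n_rows = 3)
  o <- simulate_field(d, simulation_truth(beta = c(10, 0.5, 0), sigma2 = 1,
                                          phi = 1, tau2_rel = 0.3),
                      seed = 13)
  phi <- 1; tau <- 0.3
  g <- compute_posterior(o, prior_spec(phi_grid = phi, tau2rel_grid = tau))
  dr <- sample_posterior(g, 2000, seed = 14)
  far <- data.frame(x_m = 200, y_m = 200)  # >> 3*phi from all data
  expect_warning(sf <- krige_predict(o, dr, far), "outside")
  # GLS trend fit at the cell
  V <- exp_correlation(as.matrix(stats::dist(o$coords)), phi) +
    tau * diag(length(o$y))
  Vi <- solve(V)
  bh <- solve(t(o$X) %*% Vi %*% o$X, t(o$X) %*% Vi %*% o$y)
  trend_far <- sum(c(1, 200, 200) * bh)
  expect_equal(sf$pred_mean, trend_far, tolerance = 0.02 * abs(trend_far))
})

test_that("posterior summaries transform per draw, not per summary", {
  d1 <- make_draws(2, 0.5, 3, matrix(c(1, 0, 0), 1))
  s1 <- summarize_posterior(d1)
  expect_equal(s1$mean, s1$q05, tolerance = 1e-12)
  expect_equal(s1$mean, s1$q95, tolerance = 1e-12)
  expect_equal(s1$mean[s1$quantity == "range_m"], 6)
  expect_equal(s1$mean[s1$quantity == "nugget"], 1.5)

  d2 <- make_draws(c(1, 2, 3), 0, 1, matrix(0, 3, 1))
  s2 <- summarize_posterior(d2)
  expect_equal(s2$mean[s2$quantity == "range_m"], 6)

  # constructed bimodal draws: quantiles of per-draw ratios differ from
  # the ratio of summarized components
  d3 <- make_draws(1, c(rep(0.1, 500), rep(9, 500)), c(rep(10, 500),
                                                       rep(0.1, 500)),
                   matrix(0, 1000, 1))
  s3 <- summarize_posterior(d3)
  per_draw <- d3$tau2rel / (1 + d3$tau2rel)
  expect_equal(s3$mean[s3$quantity == "nugget_ratio"], mean(per_draw))
  ratio_of_means <- mean(d3$tau2rel * d3$sigma2) /
    (mean(d3$tau2rel * d3$sigma2) + mean(d3$sigma2))
  expect_gt(abs(s3$mean[s3$quantity == "nugget_ratio"] - ratio_of_means),
            0.05)
  expect_true(all(s3$q05 <= s3$q95))
})

test_that("leave-one-out validation separates signal from noise", {
  d <- generate_design()
  # noiseless, strongly autocorrelated, with a spatial trend: near-perfect
  # prediction (a trendless exponential field is rough at the 2 m grain,
  # which bounds attainable LOO skill regardless of phi)
  o_sig <- simulate_field(d, simulation_truth(beta = c(10, 0.2, 0.2),
                                              sigma2 = 1, phi = 15,
                                              tau2_rel = 0), seed = 41)
  cv_sig <- loo_cross_validate(o_sig, prior_spec(n_phi = 10, n_tau = 10))
  expect_gt(cv_sig$adj_r2, 0.95)
  # pure noise: no predictive skill
  o_nse <- simulate_field(d, simulation_truth(sigma2 = 0.01, phi = 0.2,
                                              tau2_rel = 100), seed = 42)
  cv_nse <- loo_cross_validate(o_nse, prior_spec(n_phi = 8, n_tau = 8))
  expect_lt(cv_nse$adj_r2, 0.3)
})

test_that("leave-one-out predictions are invariant to observation order", {
  d <- generate_design(spacings = rep(4, 8), n_rows = 3)
  o <- simulate_field(d, simulation_truth(sigma2 = 1, phi = 3,
                                          tau2_rel = 0.5), seed = 51)
  set.seed(61)
  perm <- sample(length(o$y))
  o_p <- spatial_observations(o$coords[perm, 1], o$coords[perm, 2],
                              o$y[perm], core_id = o$core_id[perm])
  pr <- prior_spec(n_phi = 6, n_tau = 6)
  cv1 <- loo_cross_validate(o, pr)
  cv2 <- loo_cross_validate(o_p, pr)
  m1 <- cv1$points[order(cv1$points$core_id), ]
  m2 <- cv2$points[order(cv2$points$core_id), ]
  expect_equal(m1$predicted, m2$predicted, tolerance = 1e-9)
  expect_equal(cv1$adj_r2, cv2$adj_r2, tolerance = 1e-9)
})

test_that("observation containers validate their invariants", {
  expect_error(spatial_observations(c(0, 0), c(0, 0), c(1, 2)),
               "duplicate location")
  expect_error(spatial_observations(c(0, 1), c(0, 0), c(1, NA)),
               "missing")
  expect_error(spatial_observations(0:3, rep(0, 4), 1:4),
               "at least")  # n < p + 2 for the linear trend
  expect_error(prior_spec(phi_grid = c(2, 1)), "increasing")
  expect_error(prior_spec(tau2rel_grid = c(-1, 0)), "increasing|>= 0")
})
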