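#' Spatial observations for kriging
#'
#' Container for one response measured at planar locations, with a trend
#' design matrix. The model fitted by [compute_posterior()] is
#' `Y = X beta + S + e` with `S` a zero-mean Gaussian process with
#' covariance `sigma2 * exp(-h/phi)` and `e` independent nugget noise of
#' variance `sigma2 * tau2_rel`.
#'
#' @param x,y Coordinates in metres (0-based from the plot's southwest
#'   corner).
#' @param value Response vector (same length; no missing values).
#' @param trend `"linear"` (default: intercept + x + y) or `"constant"`
#'   (intercept only), or a user-supplied full-rank numeric matrix whose
#'   first column is the intercept.
#' @param core_id Optional identifiers (default `1:n`).
#' @return An object of class `spatial_observations`: list with `coords`
#'   (n x 2 matrix), `y`, `X`, `core_id`, `trend`.
#' @export
spatial_observations <- function(x, y, value, trend = "linear",
                                 core_id = NULL) {
  x <- as.numeric(x); y <- as.numeric(y); value <- as.numeric(value)
  n <- length(value)
  if (length(x) != n || length(y) != n) stopf("x, y, value lengths differ")
  if (anyNA(x) || anyNA(y) || anyNA(value)) {
    stopf("missing coordinates or responses are not allowed")
  }
  coords <- cbind(x_m = x, y_m = y)
  if (anyDuplicated(coords) > 0) {
    dup <- which(duplicated(coords))[1L]
    stopf("duplicate location at row %d (x = %g, y = %g)", dup, x[dup], y[dup])
  }
  X <- if (is.matrix(trend)) {
    storage.mode(trend) <- "double"
    trend
  } else if (identical(trend, "linear")) {
    cbind(intercept = 1, x = x, y = y)
  } else if (identical(trend, "constant")) {
    cbind(intercept = rep(1, n))
  } else stopf("trend must be 'linear', 'constant', or a matrix")
  p <- ncol(X)
  if (n < p + 2) stopf("need at least p + 2 = %d observations, got %d", p + 2, n)
  structure(list(coords = coords, y = value, X = X,
                 core_id = core_id %||% seq_len(n),
                 trend = if (is.matrix(trend)) "custom" else trend),
            class = "spatial_observations")
}

#' @export
print.spatial_observations <- function(x, ...) {
  cat(sprintf("Spatial observations: n = %d, trend = %s (p = %d)\n",
              length(x$y), x$trend, ncol(x$X)))
  cat(sprintf("extent: x in [%g, %g] m, y in [%g, %g] m\n",
              min(x$coords[, 1]), max(x$coords[, 1]),
              min(x$coords[, 2]), max(x$coords[, 2])))
  invisible(x)
}

#' Exponential correlation function
#'
#' `exp(-h/phi)`: correlation of the spatial process at lag `h` for
#' correlation scale `phi`. The autocorrelation range (correlation ~ 0.05)
#' of this model is `3 * phi`.
#'
#' @param h Non-negative lag distance(s), m.
#' @param phi Correlation scale parameter, m (> 0).
#' @return Correlations in (0, 1].
#' @export
exp_correlation <- function(h, phi) {
  if (any(phi <= 0)) stopf("phi must be > 0")
  if (any(h < 0)) stopf("lag distances must be >= 0")
  exp(-h / phi)
}

#' Discrete prior grid for the correlation parameters
#'
#' The posterior of `(phi, tau2_rel)` is computed on a discrete grid with
#' uniform prior mass per cell; the trend coefficients get a flat prior and
#' the sill `sigma2` a reciprocal prior, both marginalized analytically.
#' Grids left `NULL` are resolved against the data when the posterior is
#' computed: `phi` log-spaced over `[extent/300, extent]` (extent = larger
#' side of the observation bounding box) and `tau2_rel` linear over
#' `[0, 4]` including 0.
#'
#' @param phi_grid Strictly increasing positive values (m), or `NULL`.
#' @param tau2rel_grid Strictly increasing values >= 0, or `NULL`.
#' @param n_phi,n_tau Grid sizes used when the corresponding grid is
#'   resolved automatically (default 100 x 100).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(phi_grid = NULL, tau2rel_grid = NULL,
                       n_phi = 100, n_tau = 100) {
  if (!is.null(phi_grid)) {
    if (any(phi_grid <= 0) || is.unsorted(phi_grid, strictly = TRUE)) {
      stopf("phi_grid must be strictly increasing and positive")
    }
  }
  if (!is.null(tau2rel_grid)) {
    if (any(tau2rel_grid < 0) ||
        (length(tau2rel_grid) > 1 &&
         is.unsorted(tau2rel_grid, strictly = TRUE))) {
      stopf("tau2rel_grid must be strictly increasing and >= 0")
    }
  }
  structure(list(phi_grid = phi_grid, tau2rel_grid = tau2rel_grid,
                 n_phi = n_phi, n_tau = n_tau),
            class = "prior_spec")
}

resolve_prior <- function(prior, obs) {
  stopifnot(inherits(prior, "prior_spec"))
  phi <- prior$phi_grid
  if (is.null(phi)) {
    extent <- max(diff(range(obs$coords[, 1])), diff(range(obs$coords[, 2])))
    if (extent <= 0) stopf("degenerate observation extent")
    phi <- exp(seq(log(extent / 300), log(extent), length.out = prior$n_phi))
  }
  tau <- prior$tau2rel_grid
  if (is.null(tau)) tau <- seq(0, 4, length.out = prior$n_tau)
  list(phi_grid = phi, tau2rel_grid = tau)
}

# Workhorse: per-cell conjugate statistics (and, optionally, prediction
# helpers at `targets`) for an explicit set of (phi, tau2_rel) cells.
#
# Marginalizing beta (flat) and sigma2 (reciprocal) gives, per cell,
#   log p(y | phi, tau) = -1/2 log|V| - 1/2 log|X'V^-1 X| - (n-p)/2 log S2
# with V = R(phi) + tau * I, beta_hat the GLS estimate and
# S2 = (y - X beta_hat)' V^-1 (y - X beta_hat). For each phi the symmetric
# eigendecomposition R = U L U' is shared across the tau grid: V^-1 solves
# become diagonal reweightings, so a 100x100 grid needs only 100
# factorizations.
#
# Returns list(cells, beta_hat [ncell x p], Ainv [p x p x ncell], and if
# targets: pred_u [ncell x m], pred_M [ncell x m x p], pred_q [ncell x m]).
geo_cells <- function(obs, phi_values, tau_values, targets = NULL,
                      eps = 1e-12) {
  X <- obs$X; y <- obs$y
  n <- length(y); p <- ncol(X)
  h <- cross_dist(obs$coords, obs$coords)
  cells <- data.frame(phi = phi_values, tau2rel = tau_values)
  ncell <- nrow(cells)
  log_post <- rep(-Inf, ncell)
  S2v <- rep(NA_real_, ncell)
  beta_hat <- matrix(NA_real_, ncell, p)
  Ainv <- array(NA_real_, c(p, p, ncell))
  m <- if (!is.null(targets)) nrow(targets) else 0L
  if (m > 0) {
    h0 <- cross_dist(targets, obs$coords)  # m x n
    X0 <- if (obs$trend == "linear") {
      cbind(1, targets[, 1], targets[, 2])
    } else if (obs$trend == "constant") {
      cbind(rep(1, m))
    } else stopf("prediction requires a named trend ('linear'/'constant')")
    pred_u <- matrix(NA_real_, ncell, m)
    pred_q <- matrix(NA_real_, ncell, m)
    pred_M <- array(NA_real_, c(ncell, m, p))
  }
  n_degenerate <- 0L
  n_jittered <- 0L

  for (phi in unique(cells$phi)) {
    idx <- which(cells$phi == phi)
    ee <- eigen(exp(-h / phi), symmetric = TRUE)
    lam <- pmax(ee$values, 0)
    U <- ee$vectors
    Xt <- crossprod(U, X)
    yt <- drop(crossprod(U, y))
    G <- if (m > 0) exp(-h0 / phi) %*% U else NULL

    for (i in idx) {
      tau <- cells$tau2rel[i]
      d <- lam + tau
      if (any(d <= eps * max(d))) {
        # near-singular correlation (large phi with tiny nugget): add a
        # relative jitter rather than discarding the cell
        d <- d + 1e-10 * max(d)
        n_jittered <- n_jittered + 1L
      }
      if (any(d <= 0)) { n_degenerate <- n_degenerate + 1L; next }
      w <- 1 / d
      A <- crossprod(Xt, Xt * w)
      cA <- tryCatch(chol(A), error = function(e) NULL)
      if (is.null(cA)) { n_degenerate <- n_degenerate + 1L; next }
      rhs <- drop(crossprod(Xt, yt * w))
      bhat <- backsolve(cA, backsolve(cA, rhs, transpose = TRUE))
      S2 <- sum(w * yt^2) - sum(rhs * bhat)
      if (!is.finite(S2) || S2 <= 0) { n_degenerate <- n_degenerate + 1L; next }
      log_post[i] <- -0.5 * sum(log(d)) - sum(log(diag(cA))) -
        0.5 * (n - p) * log(S2)
      S2v[i] <- S2
      beta_hat[i, ] <- bhat
      Ainv[, , i] <- chol2inv(cA)
      if (m > 0) {
        Gw <- sweep(G, 2, w, "*")
        pred_u[i, ] <- drop(Gw %*% yt)
        pred_M[i, , ] <- Gw %*% Xt
        pred_q[i, ] <- rowSums(Gw * G)
      }
    }
  }
  out <- list(cells = cbind(cells, log_post = log_post, S2 = S2v,
                            df = n - p),
              beta_hat = beta_hat, Ainv = Ainv,
              n_degenerate = n_degenerate, n_jittered = n_jittered,
              n = n, p = p)
  if (m > 0) {
    out$pred_u <- pred_u; out$pred_M <- pred_M; out$pred_q <- pred_q
    out$X0 <- X0
  }
  out
}

#' Log marginal density of the correlation parameters
#'
#' Log of `p(y | phi, tau2_rel)` with the trend coefficients (flat prior)
#' and sill (reciprocal prior) integrated out analytically, up to one
#' additive constant shared by every `(phi, tau2_rel)` cell.
#'
#' @param obs A [spatial_observations()] object.
#' @param phi Correlation scale (m, > 0); vectorized.
#' @param tau2rel Relative nugget (>= 0); recycled against `phi`.
#' @return Log density values; `-Inf` (with a warning) for numerically
#'   singular cells.
#' @export
log_marginal <- function(obs, phi, tau2rel) {
  stopifnot(inherits(obs, "spatial_observations"))
  k <- max(length(phi), length(tau2rel))
  phi <- rep_len(phi, k); tau2rel <- rep_len(tau2rel, k)
  if (any(phi <= 0)) stopf("phi must be > 0")
  if (any(tau2rel < 0)) stopf("tau2rel must be >= 0")
  fit <- geo_cells(obs, phi, tau2rel)
  if (fit$n_degenerate > 0) {
    warnf("%d cell(s) numerically singular; assigned zero posterior mass",
          fit$n_degenerate)
  }
  fit$cells$log_post
}

#' Discrete joint posterior over (phi, tau2_rel)
#'
#' Evaluates the marginal density of `(phi, tau2_rel)` on the full prior
#' grid, normalizes in log space, and caches the per-cell conjugate
#' statistics (GLS trend estimate, its covariance factor, residual scale,
#' degrees of freedom) needed for exact posterior sampling.
#'
#' @param obs A [spatial_observations()] object.
#' @param prior A [prior_spec()]; `NULL` grids are resolved from the data.
#' @return An object of class `posterior_grid`.
#' @export
compute_posterior <- function(obs, prior = prior_spec()) {
  stopifnot(inherits(obs, "spatial_observations"))
  g <- resolve_prior(prior, obs)
  grid <- expand.grid(phi = g$phi_grid, tau2rel = g$tau2rel_grid,
                      KEEP.OUT.ATTRS = FALSE)
  fit <- geo_cells(obs, grid$phi, grid$tau2rel)
  lp <- fit$cells$log_post
  if (all(!is.finite(lp))) {
    stopf("no admissible correlation parameters: every grid cell degenerate")
  }
  if (fit$n_degenerate > 0) {
    warnf("%d of %d grid cell(s) degenerate; assigned zero posterior mass",
          fit$n_degenerate, nrow(grid))
  }
  mass <- exp(lp - logsumexp(lp))
  mass <- mass / sum(mass)
  cells <- cbind(fit$cells, mass = mass)
  mode_i <- order(-mass, cells$phi)[1L]  # ties: smallest phi wins
  at_edge <- cells$phi[mode_i] %in% range(g$phi_grid) ||
    cells$tau2rel[mode_i] == max(g$tau2rel_grid)
  structure(list(cells = cells, beta_hat = fit$beta_hat, Ainv = fit$Ainv,
                 n_jittered = fit$n_jittered,
                 obs = obs, phi_grid = g$phi_grid,
                 tau2rel_grid = g$tau2rel_grid,
                 mode = cells[mode_i, c("phi", "tau2rel", "mass")],
                 mode_at_edge = at_edge,
                 n = fit$n, p = fit$p),
            class = "posterior_grid")
}

#' @export
print.posterior_grid <- function(x, ...) {
  cat(sprintf(
    "Posterior grid: %d x %d cells (phi in [%.3g, %.3g] m, tau2rel in [%g, %g])\n",
    length(x$phi_grid), length(x$tau2rel_grid), min(x$phi_grid),
    max(x$phi_grid), min(x$tau2rel_grid), max(x$tau2rel_grid)))
  cat(sprintf("mode: phi = %.3g m, tau2rel = %.3g (mass %.3g)%s\n",
              x$mode$phi, x$mode$tau2rel, x$mode$mass,
              if (x$mode_at_edge) " [at grid edge]" else ""))
  if (x$n_jittered > 0) {
    cat(sprintf("%d near-singular cell(s) stabilised with relative jitter\n",
                x$n_jittered))
  }
  invisible(x)
}

#' Draw from the joint posterior
#'
#' Samples `(phi, tau2_rel)` cells from the normalized grid masses, then
#' for each draw the sill from its scaled inverse-chi-squared conditional
#' and the trend coefficients from their Gaussian conditional — exact
#' sampling, no MCMC.
#'
#' @param grid A [compute_posterior()] result.
#' @param n_draws Number of draws (default 100000).
#' @param seed Integer seed for reproducibility.
#' @return A data frame of class `posterior_draws` with columns `phi`,
#'   `tau2rel`, `sigma2` and one `beta_*` column per trend coefficient.
#' @export
sample_posterior <- function(grid, n_draws = 1e5, seed = NULL) {
  stopifnot(inherits(grid, "posterior_grid"))
  if (n_draws < 1) stopf("n_draws must be >= 1")
  n_draws <- as.integer(n_draws)
  cells <- grid$cells
  p <- grid$p
  bnames <- paste0("beta_", colnames(grid$obs$X))
  with_seed(seed, {
    ci <- sample.int(nrow(cells), n_draws, replace = TRUE, prob = cells$mass)
    sigma2 <- numeric(n_draws)
    beta <- matrix(NA_real_, n_draws, p)
    for (i in unique(ci)) {
      k <- which(ci == i)
      s2 <- cells$S2[i] / stats::rchisq(length(k), df = cells$df[i])
      sigma2[k] <- s2
      Lb <- chol(grid$Ainv[, , i])  # upper: Ainv = Lb' Lb
      z <- matrix(stats::rnorm(length(k) * p), p)
      beta[k, ] <- rep(grid$beta_hat[i, ], each = length(k)) +
        t(crossprod(Lb, z)) * sqrt(s2)
    }
    draws <- data.frame(phi = cells$phi[ci], tau2rel = cells$tau2rel[ci],
                        sigma2 = sigma2)
    draws[bnames] <- beta
    class(draws) <- c("posterior_draws", "data.frame")
    attr(draws, "p") <- p
    draws
  })
}

#' Posterior summaries of the spatial model parameters
#'
#' Per-draw transforms are summarized by their mean and 5%/95% quantiles,
#' matching the convention "mean (5%, 95% CI)": trend intercept,
#' autocorrelation range `3 * phi` (m), sill `sigma2`, nugget
#' `tau2_rel * sigma2`, and the noise-to-total-variance ratio
#' `nugget / (nugget + sill)` (computed per draw, then summarized).
#'
#' @param draws A [sample_posterior()] result (>= 1 draw; quantile
#'   stability is only meaningful for ~1000+).
#' @param obs Optional [spatial_observations()]; if given, an additional
#'   `trend_plot_mean` row reports the per-draw plot-average trend
#'   `mean(X beta)` (an alternative reading of "trend" when the trend is
#'   non-constant).
#' @return A data frame (class `spatial_model_summary`) with columns
#'   `quantity`, `mean`, `q05`, `q95`.
#' @export
summarize_posterior <- function(draws, obs = NULL) {
  stopifnot(inherits(draws, "posterior_draws"))
  b0 <- draws[[grep("^beta_", names(draws))[1L]]]
  qty <- list(
    trend = b0,
    range_m = 3 * draws$phi,
    sill = draws$sigma2,
    nugget = draws$tau2rel * draws$sigma2,
    nugget_ratio = draws$tau2rel / (1 + draws$tau2rel)
  )
  if (!is.null(obs)) {
    B <- as.matrix(draws[grep("^beta_", names(draws))])
    qty$trend_plot_mean <- drop(B %*% colMeans(obs$X))
  }
  out <- do.call(rbind, lapply(names(qty), function(nm) {
    v <- qty[[nm]]
    q <- stats::quantile(v, c(0.05, 0.95), names = FALSE)
    data.frame(quantity = nm, mean = mean(v), q05 = q[1], q95 = q[2])
  }))
  class(out) <- c("spatial_model_summary", "data.frame")
  out
}

#' Regular prediction grid over the observation bounding box
#'
#' @param obs A [spatial_observations()] or [generate_design()] object.
#' @param spacing Grid spacing in metres (default 0.5).
#' @return Data frame of `x_m`, `y_m` prediction locations.
#' @export
prediction_grid <- function(obs, spacing = 0.5) {
  cc <- if (inherits(obs, "sampling_design")) {
    as.matrix(obs$points[, c("x_m", "y_m")])
  } else obs$coords
  expand.grid(x_m = seq(min(cc[, 1]), max(cc[, 1]), by = spacing),
              y_m = seq(min(cc[, 2]), max(cc[, 2]), by = spacing),
              KEEP.OUT.ATTRS = FALSE)
}

#' Bayesian kriging prediction at target locations
#'
#' For every posterior draw, forms the conditional Gaussian mean and
#' variance of the spatial signal (trend + correlated process, nugget
#' excluded) at each target given the observations; the surface reports the
#' across-draw predictive mean and the total predictive variance (mean of
#' conditional variances plus variance of conditional means).
#'
#' @param obs A [spatial_observations()] object.
#' @param draws A [sample_posterior()] result.
#' @param targets Data frame or matrix with columns `x_m`, `y_m` (e.g.
#'   [prediction_grid()]). Targets outside the observation bounding box
#'   trigger a warning, not an error.
#' @param chunk Targets are processed in blocks of this size to bound
#'   memory (default 500).
#' @return Data frame of class `predictive_surface`: `x_m`, `y_m`,
#'   `pred_mean`, `pred_var`, `pred_sd`.
#' @export
krige_predict <- function(obs, draws, targets, chunk = 500) {
  stopifnot(inherits(obs, "spatial_observations"),
            inherits(draws, "posterior_draws"))
  tg <- as.matrix(as.data.frame(targets)[, c("x_m", "y_m")])
  cc <- obs$coords
  if (any(tg[, 1] < min(cc[, 1]) | tg[, 1] > max(cc[, 1]) |
          tg[, 2] < min(cc[, 2]) | tg[, 2] > max(cc[, 2]))) {
    warnf("some targets lie outside the observation bounding box; %s",
          "predictions there revert toward the trend")
  }
  B <- as.matrix(draws[grep("^beta_", names(draws))])
  nd <- nrow(draws)
  cell_key <- paste(draws$phi, draws$tau2rel)
  draw_groups <- split(seq_len(nd), cell_key)
  ucells <- do.call(rbind, lapply(draw_groups, function(k) {
    c(phi = draws$phi[k[1L]], tau2rel = draws$tau2rel[k[1L]])
  }))

  out <- vector("list", ceiling(nrow(tg) / chunk))
  for (b in seq_along(out)) {
    rows <- ((b - 1L) * chunk + 1L):min(b * chunk, nrow(tg))
    tgb <- tg[rows, , drop = FALSE]
    fit <- geo_cells(obs, ucells[, "phi"], ucells[, "tau2rel"],
                     targets = tgb)
    m <- nrow(tgb)
    sum_m <- sum_m2 <- sum_v <- numeric(m)
    for (i in seq_along(draw_groups)) {
      k <- draw_groups[[i]]
      if (!is.finite(fit$cells$log_post[i])) {
        stopf("posterior cell (phi = %g, tau2rel = %g) is degenerate for %s",
              ucells[i, "phi"], ucells[i, "tau2rel"], "prediction")
      }
      # conditional mean per draw: X0 b + u - M b  (linear in b)
      coefmat <- fit$X0 - matrix(fit$pred_M[i, , ], nrow = m)  # m x p
      mu <- coefmat %*% t(B[k, , drop = FALSE]) + fit$pred_u[i, ]  # m x ndk
      vcond <- pmax(1 - fit$pred_q[i, ], 0) %o% draws$sigma2[k]
      sum_m <- sum_m + rowSums(mu)
      sum_m2 <- sum_m2 + rowSums(mu^2)
      sum_v <- sum_v + rowSums(vcond)
    }
    pm <- sum_m / nd
    pv <- sum_v / nd + pmax(sum_m2 / nd - pm^2, 0)
    out[[b]] <- data.frame(x_m = tgb[, 1], y_m = tgb[, 2],
                           pred_mean = pm, pred_var = pv,
                           pred_sd = sqrt(pv))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("predictive_surface", "data.frame")
  res
}

#' Leave-one-out cross-validation of the spatial model
#'
#' Each observation is predicted from the remaining `n - 1` with a full
#' posterior refit on a reduced grid (default 25 x 25; supply `prior` for a
#' different grid, including the full 100 x 100). Prediction marginalizes
#' the cell posterior analytically — the predictive mean is the
#' mass-weighted conditional mean at the GLS trend estimate, and the
#' predictive variance combines within-cell conditional variance (at the
#' posterior mean of `sigma2`), trend-estimate uncertainty, and
#' between-cell spread — so the procedure is deterministic.
#'
#' @param obs A [spatial_observations()] object (`n >= p + 3`).
#' @param prior A [prior_spec()]; default `prior_spec(n_phi = 25, n_tau =
#'   25)`.
#' @return List of class `loo_result`: `points` (data frame `core_id`,
#'   `observed`, `predicted`, `pred_var`), `r2`, `adj_r2` (`1 - (1 - R2)
#'   (n-1)/(n-p-1)` with `R2` the squared Pearson correlation of observed
#'   and predicted), `n_used`, `flagged` (core ids of folds whose refit
#'   degenerated, excluded from the summary).
#' @export
loo_cross_validate <- function(obs, prior = prior_spec(n_phi = 25,
                                                       n_tau = 25)) {
  stopifnot(inherits(obs, "spatial_observations"))
  n <- length(obs$y); p <- ncol(obs$X)
  if (n < p + 3) stopf("need n >= p + 3 for leave-one-out")
  g <- resolve_prior(prior, obs)
  grid <- expand.grid(phi = g$phi_grid, tau2rel = g$tau2rel_grid,
                      KEEP.OUT.ATTRS = FALSE)
  pred <- pvar <- rep(NA_real_, n)
  flagged <- integer(0)
  for (i in seq_len(n)) {
    obs_i <- spatial_observations(obs$coords[-i, 1], obs$coords[-i, 2],
                                  obs$y[-i], trend = obs$trend,
                                  core_id = obs$core_id[-i])
    fit <- geo_cells(obs_i, grid$phi, grid$tau2rel,
                     targets = obs$coords[i, , drop = FALSE])
    lp <- fit$cells$log_post
    ok <- is.finite(lp)
    if (!any(ok)) { flagged <- c(flagged, i); next }
    mass <- exp(lp[ok] - logsumexp(lp[ok]))
    mass <- mass / sum(mass)
    df <- fit$cells$df[1L]
    if (df <= 2) stopf("too few degrees of freedom for analytic LOO variance")
    pm_cell <- vv_cell <- numeric(sum(ok))
    for (jj in seq_along(which(ok))) {
      j <- which(ok)[jj]
      bhat <- fit$beta_hat[j, ]
      coef <- drop(fit$X0) - drop(fit$pred_M[j, , ])
      pm_cell[jj] <- sum(fit$X0 * bhat) + fit$pred_u[j, 1] -
        sum(fit$pred_M[j, , ] * bhat)
      Es2 <- fit$cells$S2[j] / (df - 2)
      vv_cell[jj] <- Es2 * (max(1 - fit$pred_q[j, 1], 0) +
                              drop(coef %*% fit$Ainv[, , j] %*% coef))
    }
    pred[i] <- sum(mass * pm_cell)
    pvar[i] <- sum(mass * (vv_cell + pm_cell^2)) - pred[i]^2
  }
  use <- setdiff(seq_len(n), flagged)
  if (length(use) < 3) stopf("too few valid folds for cross-validation")
  r2 <- stats::cor(obs$y[use], pred[use])^2
  adj <- 1 - (1 - r2) * (length(use) - 1) / (length(use) - p - 1)
  structure(list(
    points = data.frame(core_id = obs$core_id, observed = obs$y,
                        predicted = pred, pred_var = pvar),
    r2 = r2, adj_r2 = adj, n_used = length(use),
    flagged = obs$core_id[flagged]),
    class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("Leave-one-out CV: n = %d, R2 = %.3f, adjusted R2 = %.3f\n",
              x$n_used, x$r2, x$adj_r2))
  if (length(x$flagged)) {
    cat("flagged (excluded) cores:", paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}
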