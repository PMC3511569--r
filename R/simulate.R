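#' Ground-truth parameters for field simulation
#'
#' Bundles the parameters of the Gaussian spatial linear model used by the
#' simulator and recovered by the kriging machinery: a linear trend in the
#' coordinates, a zero-mean stationary Gaussian process with exponential
#' correlation, and independent nugget noise.
#'
#' @param beta Numeric trend coefficients `(intercept, slope_x, slope_y)` in
#'   response units (slopes per metre).
#' @param sigma2 Partial sill: variance of the spatially structured process
#'   (response units squared). Must be positive.
#' @param phi Correlation scale parameter (m); the autocorrelation range of
#'   the exponential model is `3 * phi`. Must be positive.
#' @param tau2_rel Relative nugget `tau2 / sigma2` (dimensionless, >= 0).
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(beta = c(0, 0, 0), sigma2 = 1, phi = 2,
                             tau2_rel = 0.7) {
  if (sigma2 <= 0) stopf("sigma2 must be > 0")
  if (phi <= 0) stopf("phi must be > 0")
  if (tau2_rel < 0) stopf("tau2_rel must be >= 0")
  if (length(beta) != 3L) stopf("beta must be (intercept, slope_x, slope_y)")
  structure(list(beta = as.numeric(beta), sigma2 = sigma2, phi = phi,
                 tau2_rel = tau2_rel),
            class = "simulation_truth")
}

#' Simulate a spatially structured response on a sampling design
#'
#' Draws one realisation of `Y = X beta + S + e` at the design locations,
#' where `S` is a zero-mean Gaussian process with covariance
#' `sigma2 * exp(-h / phi)` and `e` is independent Gaussian nugget noise
#' with variance `sigma2 * tau2_rel`. The trend matrix is
#' `X = (1, x, y)`.
#'
#' @param design A [generate_design()] object.
#' @param truth A [simulation_truth()] object.
#' @param seed Integer seed; identical seeds reproduce the draw exactly.
#' @return A [spatial_observations()] object carrying the simulated
#'   response, with the truth stored in attribute `"truth"`.
#' @export
simulate_field <- function(design, truth, seed = NULL) {
  stopifnot(inherits(design, "sampling_design"),
            inherits(truth, "simulation_truth"))
  pts <- design$points
  n <- nrow(pts)
  h <- design_distances(design)
  R <- exp(-h / truth$phi)
  L <- tryCatch(chol(R), error = function(e) {
    stopf(paste("correlation matrix is not positive definite (phi = %g m is",
                "numerically degenerate for this design): %s"),
          truth$phi, conditionMessage(e))
  })
  X <- cbind(1, pts$x_m, pts$y_m)
  y <- with_seed(seed, {
    s <- sqrt(truth$sigma2) * drop(crossprod(L, rnorm(n)))
    eps <- if (truth$tau2_rel > 0) {
      rnorm(n, sd = sqrt(truth$sigma2 * truth$tau2_rel))
    } else 0
    drop(X %*% truth$beta) + s + eps
  })
  obs <- spatial_observations(pts$x_m, pts$y_m, y, core_id = pts$core_id,
                              trend = "linear")
  attr(obs, "truth") <- truth
  obs
}

#' Simulate a per-core lipid table with a known plot-level profile
#'
#' Generates core-by-lipid amounts (nmol) whose plot-mean mole percents
#' recover a supplied target profile, with per-core compositional noise and
#' spatially autocorrelated total abundance. Each core's total is
#' `total_mean` plus a zero-mean Gaussian field scaled to standard deviation
#' `total_sd`, with correlation structure taken from `spatial` (the trend
#' coefficients of `spatial` are ignored: only its `phi` and `tau2_rel`
#' shape the field). Compositions are Dirichlet draws centred on the
#' profile; `profile_conc = Inf` switches compositional noise off.
#'
#' @param design A [generate_design()] object.
#' @param profile Named numeric vector of target mole percents (sums to
#'   100 within `tol`); names are lipid names such as `"16:0"`,
#'   `"15:0iso"`. `NA` entries are treated as absent (0). When the
#'   profile sums to less than 100 (a dominant-lipids-only profile), the
#'   shortfall is carried as an explicit `unassigned` column so that the
#'   simulated mole percents of the named lipids keep their stated means.
#' @param total_mean,total_sd Mean and standard deviation of per-core total
#'   lipid abundance (nmol); both must be non-negative.
#' @param spatial A [simulation_truth()] giving the correlation structure
#'   of the total-abundance field.
#' @param profile_conc Dirichlet precision of per-core compositions
#'   (larger = less compositional noise; `Inf` = exact profile).
#' @param seed Integer seed.
#' @param tol Tolerance on `sum(profile) - 100` (default 10, loose enough
#'   for plot-mean profiles with absent lipids and rounded entries; the
#'   profile is renormalised to exactly 100 before use).
#' @return A data frame (`core_id`, `x_m`, `y_m`, one column per lipid)
#'   of amounts in nmol; negative totals are truncated at zero.
#' @export
simulate_lipid_table <- function(design, profile, total_mean, total_sd,
                                 spatial = simulation_truth(),
                                 profile_conc = 200, seed = NULL, tol = 10) {
  stopifnot(inherits(design, "sampling_design"))
  if (total_mean < 0 || total_sd < 0) {
    stopf("total_mean and total_sd must be non-negative")
  }
  profile[is.na(profile)] <- 0
  if (is.null(names(profile)) || any(!nzchar(names(profile)))) {
    stopf("profile must be a named vector of lipid mole percents")
  }
  if (abs(sum(profile) - 100) > tol) {
    stopf("profile sums to %.2f, not 100 +/- %g", sum(profile), tol)
  }
  if (sum(profile) < 100 - 1e-6) {
    profile <- c(profile, unassigned = 100 - sum(profile))
  }
  p <- profile / sum(profile)
  pts <- design$points
  n <- nrow(pts)
  k <- length(p)

  tab <- with_seed(seed, {
    totals <- if (total_sd > 0) {
      h <- design_distances(design)
      R <- exp(-h / spatial$phi)
      L <- chol(R)
      z <- drop(crossprod(L, rnorm(n))) +
        rnorm(n, sd = sqrt(spatial$tau2_rel))
      total_mean + total_sd * z / sqrt(1 + spatial$tau2_rel)
    } else rep(total_mean, n)
    totals <- pmax(totals, 0)
    comp <- if (is.finite(profile_conc)) {
      g <- matrix(stats::rgamma(n * k, shape = rep(profile_conc * p, each = n)),
                  nrow = n)
      g / rowSums(g)
    } else matrix(p, nrow = n, ncol = k, byrow = TRUE)
    amounts <- comp * totals
    colnames(amounts) <- names(p)
    data.frame(core_id = pts$core_id, x_m = pts$x_m, y_m = pts$y_m,
               amounts, check.names = FALSE)
  })
  tab
}
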