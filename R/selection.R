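# Stepwise-AIC selection of linear predictors of net N mineralization.

#' Candidate predictor set for net N mineralization models
#'
#' The cover, soil and microbial variables entered into stepwise selection.
#' @return Character vector of candidate names.
#' @export
candidate_predictors <- function() {
  c("rock_pct", "charred_litter_pct", "fresh_litter_pct", "mineral_soil_pct",
    "coarse_wood_pct", "lupinus_pct", "ceanothus_pct", "forbs_pct",
    "graminoids_pct", "shrubs_pct", "pinus_contorta_pct",
    "nonveg_cover_pct", "veg_cover_pct", "ph", "abundance", "fungi",
    "bacteria", "fb_ratio", "gm_pos", "gm_neg")
}

#' Gaussian linear fit with AIC
#'
#' Ordinary least squares via [stats::lm()]; reports coefficients,
#' residual variance (ML, `RSS/n`), log-likelihood, `AIC = -2 loglik + 2k`
#' with `k` counting the coefficients plus the error-variance parameter,
#' and per-coefficient p-values. Collinear columns are dropped with a
#' warning before fitting.
#'
#' @param y Response vector.
#' @param X Data frame or matrix of predictors (no intercept column; one
#'   is added). May have zero columns for an intercept-only fit.
#' @return List of class `linear_fit`: `coefficients`, `sigma2_ml`,
#'   `loglik`, `aic`, `p_values`, `adj_r2`, `n`, `dropped`, `fit` (the
#'   `lm` object).
#' @export
fit_linear <- function(y, X) {
  X <- as.data.frame(X)
  n <- length(y)
  if (nrow(X) && nrow(X) != n) stopf("y and X row counts differ")
  dat <- cbind(data.frame(.y = y), X)
  fm <- if (ncol(X)) {
    stats::as.formula(paste(".y ~", paste(sprintf("`%s`", names(X)),
                                          collapse = " + ")))
  } else .y ~ 1
  fit <- stats::lm(fm, data = dat)
  dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(dropped)) {
    warnf("dropping collinear column(s): %s",
          paste(gsub("`", "", dropped), collapse = ", "))
    keep <- setdiff(names(X), gsub("`", "", dropped))
    return(fit_linear(y, X[, keep, drop = FALSE]))
  }
  k <- length(stats::coef(fit)) + 1L  # + error variance
  if (n <= k) stopf("n = %d too small for %d parameters", n, k)
  ll <- as.numeric(stats::logLik(fit))
  sm <- summary(fit)
  pv <- stats::coef(sm)[, "Pr(>|t|)"]
  names(pv) <- gsub("`", "", names(pv))
  cf <- stats::coef(fit)
  names(cf) <- gsub("`", "", names(cf))
  structure(list(coefficients = cf,
                 sigma2_ml = sum(stats::resid(fit)^2) / n,
                 loglik = ll, aic = -2 * ll + 2 * k, p_values = pv,
                 adj_r2 = sm$adj.r.squared, n = n, dropped = dropped,
                 fit = fit),
            class = "linear_fit")
}

#' Bidirectional stepwise selection by AIC
#'
#' Starts from the full model (optionally the intercept-only model), and at
#' each step evaluates every single-term deletion and addition, applying
#' the move with the largest AIC decrease until none decreases it. Ties
#' are broken deterministically: deletion is preferred over addition, then
#' alphabetical term order. Rank-deficient starting models fall back to
#' the largest full-rank subset (reported).
#'
#' @param y Response vector.
#' @param candidates Data frame of candidate predictors (>= 2 columns).
#'   Rows with missing values (in `y` or any candidate) are dropped and
#'   reported.
#' @param start `"full"` (default) or `"intercept"`.
#' @return List of class `selected_model`: `terms` (retained predictor
#'   names), `fit` (the [fit_linear()] of the final model), `sign`
#'   (coefficient signs), `bands` (significance labels), `aic`, `adj_r2`,
#'   `n_used`, `n_dropped_rows`, `path` (data frame of moves), `dropped`
#'   (columns removed for collinearity before the search).
#' @export
stepwise_select <- function(y, candidates, start = c("full", "intercept")) {
  start <- match.arg(start)
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) < 2) stopf("need >= 2 candidate predictors")
  cc <- stats::complete.cases(y, candidates)
  n_dropped <- sum(!cc)
  y <- y[cc]
  candidates <- candidates[cc, , drop = FALSE]

  # largest full-rank subset: greedy by QR pivoting on the full matrix
  Xfull <- as.matrix(candidates)
  qrd <- qr(cbind(1, scale(Xfull, scale = FALSE)))
  rank_ok <- qrd$rank - 1L  # minus intercept
  usable <- names(candidates)
  removed_collinear <- character(0)
  if (rank_ok < ncol(candidates)) {
    keep_idx <- sort(setdiff(qrd$pivot[seq_len(qrd$rank)], 1L) - 1L)
    removed_collinear <- setdiff(usable, usable[keep_idx])
    warnf("rank-deficient candidate matrix; removed: %s",
          paste(removed_collinear, collapse = ", "))
    usable <- usable[keep_idx]
  }

  current <- if (start == "full") sort(usable) else character(0)
  fit_terms <- function(terms) {
    fit_linear(y, candidates[, terms, drop = FALSE])
  }
  cur_fit <- fit_terms(current)
  path <- data.frame(step = 0L, move = "start",
                     term = NA_character_, aic = cur_fit$aic)
  step_no <- 0L
  repeat {
    # candidate moves: deletions first, then additions, alphabetical within
    dels <- sort(current)
    adds <- sort(setdiff(usable, current))
    moves <- rbind(
      if (length(dels)) data.frame(move = "drop", term = dels),
      if (length(adds)) data.frame(move = "add", term = adds)
    )
    if (is.null(moves) || !nrow(moves)) break
    aics <- vapply(seq_len(nrow(moves)), function(i) {
      trms <- if (moves$move[i] == "drop") {
        setdiff(current, moves$term[i])
      } else c(current, moves$term[i])
      tryCatch(fit_terms(trms)$aic, error = function(e) Inf)
    }, 0)
    best <- which.min(aics)  # first minimum: drop-then-add, alphabetical
    if (aics[best] >= cur_fit$aic - 1e-10) break
    current <- if (moves$move[best] == "drop") {
      setdiff(current, moves$term[best])
    } else sort(c(current, moves$term[best]))
    cur_fit <- fit_terms(current)
    step_no <- step_no + 1L
    path <- rbind(path, data.frame(step = step_no, move = moves$move[best],
                                   term = moves$term[best],
                                   aic = cur_fit$aic))
  }

  cf <- cur_fit$coefficients[setdiff(names(cur_fit$coefficients),
                                     "(Intercept)")]
  pv <- cur_fit$p_values[names(cf)]
  structure(list(terms = names(cf), fit = cur_fit,
                 sign = ifelse(cf >= 0, "+", "-"),
                 bands = significance_bands(pv),
                 aic = cur_fit$aic, adj_r2 = cur_fit$adj_r2,
                 n_used = cur_fit$n, n_dropped_rows = n_dropped,
                 path = path, dropped = removed_collinear),
            class = "selected_model")
}

#' @export
print.selected_model <- function(x, ...) {
  cat(sprintf("Stepwise-AIC selected model (AIC = %.2f, adj R2 = %.3f, n = %d)\n",
              x$aic, x$adj_r2, x$n_used))
  if (!length(x$terms)) {
    cat("  (intercept only)\n")
  } else {
    for (i in seq_along(x$terms)) {
      cat(sprintf("  %s %s %s\n", x$sign[i], x$terms[i], x$bands[i]))
    }
  }
  invisible(x)
}

#' Significance bands for p-values
#'
#' Labels: `"****"` for p below numerical zero (p < 1e-16, the "P = 0"
#' convention), `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for
#' p < 0.05, `""` otherwise.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
significance_bands <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  out <- character(length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[p < 1e-16] <- "****"
  out[is.na(p)] <- NA_character_
  out
}
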