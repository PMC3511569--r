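# Isotope pool-dilution net-rate arithmetic and plot comparisons.

#' Net transformation rate from pool-dilution components
#'
#' The pool-dilution identity: net rate = gross production - consumption,
#' in identical units (conventionally ug N g-soil^-1 d^-1). Negative
#' values indicate net immobilization.
#'
#' @param gross Gross production rate(s), >= 0.
#' @param consumption Consumption rate(s), >= 0, same units.
#' @return `gross - consumption` (vectorized).
#' @export
net_rate <- function(gross, consumption) {
  if (any(gross < 0, na.rm = TRUE) || any(consumption < 0, na.rm = TRUE)) {
    stopf("gross and consumption rates must be >= 0")
  }
  gross - consumption
}

#' Compare a per-core rate between two plots
#'
#' Plot means, standard errors, and a Welch (unequal-variance) two-sample
#' t-test of the difference.
#'
#' @param values Numeric per-core values.
#' @param plot Plot labels (exactly two levels; >= 2 cores each).
#' @return List of class `plot_comparison`: `summary` (per-plot mean, se,
#'   n), `difference` (first minus second level), `p_value`, `conf_int`.
#' @export
compare_plots <- function(values, plot) {
  plot <- as.factor(plot)
  if (nlevels(plot) != 2) {
    stopf("compare_plots requires exactly 2 plots, got %d", nlevels(plot))
  }
  keep <- !is.na(values) & !is.na(plot)
  values <- values[keep]; plot <- droplevels(plot[keep])
  counts <- table(plot)
  if (any(counts < 2)) stopf("each plot needs >= 2 cores")
  sums <- do.call(rbind, lapply(levels(plot), function(l) {
    s <- plot_summary(values[plot == l])
    data.frame(plot = l, mean = s["mean"], se = s["se"], n = s["n"],
               row.names = NULL)
  }))
  tt <- stats::t.test(values ~ plot, var.equal = FALSE)
  structure(list(summary = sums,
                 difference = sums$mean[1] - sums$mean[2],
                 p_value = tt$p.value, conf_int = unname(tt$conf.int)),
            class = "plot_comparison")
}

#' @export
print.plot_comparison <- function(x, ...) {
  print(x$summary)
  cat(sprintf("difference (%s - %s) = %.4g, Welch p = %.4g\n",
              x$summary$plot[1], x$summary$plot[2], x$difference, x$p_value))
  invisible(x)
}

#' Net rates for a pool-dilution table
#'
#' Adds `net_nh4` and `net_no3` columns (gross - consumption per row) to a
#' rates table. Gross NH4 mineralization may be absent (`NA` net rate).
#'
#' @param rates Data frame with columns `gross_nitrification`,
#'   `nh4_consumption`, `no3_consumption` and optionally
#'   `gross_nh4_mineralization` (all in ug N g^-1 d^-1).
#' @return The table with `net_nh4` and `net_no3` appended.
#' @export
pool_dilution_net <- function(rates) {
  need <- c("gross_nitrification", "nh4_consumption", "no3_consumption")
  miss <- setdiff(need, names(rates))
  if (length(miss)) stopf("missing rate column(s): %s",
                          paste(miss, collapse = ", "))
  rates$net_no3 <- net_rate(rates$gross_nitrification, rates$no3_consumption)
  rates$net_nh4 <- if ("gross_nh4_mineralization" %in% names(rates)) {
    net_rate(rates$gross_nh4_mineralization, rates$nh4_consumption)
  } else NA_real_
  rates
}
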