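#' Nested-spacing sampling design for a square plot
#'
#' Builds the planar coordinates of soil-core locations laid out in parallel
#' rows with unequal within-row spacings. The default configuration is the
#' nested design used for post-fire 50 m x 50 m plots: 9 rows of 9 cores,
#' rows 2 m apart, within-row intervals drawn from \{2, 4, 8\} m, and the
#' interval order reversed in the middle three rows so that short and long
#' lags are balanced against any directional trend. The default yields 81
#' cores and guarantees that the pairwise-distance multiset contains lags at
#' exactly 2, 4, and 8 m.
#'
#' @param spacings Ordered numeric vector of within-row intervals (m)
#'   between consecutive cores of a row. The default
#'   `c(2, 2, 4, 4, 8, 8, 4, 2)` gives 9 cores per row spanning 34 m.
#' @param n_rows Number of rows (default 9).
#' @param row_spacing Distance between adjacent rows (m, default 2).
#' @param plot_size Side of the square plot (m, default 50). Coordinates
#'   must fit inside `[0, plot_size]`.
#' @param reverse_middle If `TRUE` (default) the middle three rows use the
#'   reversed interval order.
#' @return An object of class `sampling_design`: a list with `points`
#'   (data frame `core_id`, `x_m`, `y_m`), `plot_size`, `n_rows`,
#'   `row_spacing`, and `within_row_spacings`.
#' @examples
#' d <- generate_design()
#' nrow(d$points)  # 81
#' @export
generate_design <- function(spacings = c(2, 2, 4, 4, 8, 8, 4, 2),
                            n_rows = 9,
                            row_spacing = 2,
                            plot_size = 50,
                            reverse_middle = TRUE) {
  if (n_rows < 1) stopf("n_rows must be >= 1")
  if (any(spacings <= 0)) stopf("within-row spacings must be positive")
  span_x <- sum(spacings)
  span_y <- (n_rows - 1) * row_spacing
  if (span_x > plot_size) {
    stopf("within-row intervals span %.1f m, exceeding plot_size = %.1f m",
          span_x, plot_size)
  }
  if (span_y > plot_size) {
    stopf("rows span %.1f m, exceeding plot_size = %.1f m", span_y, plot_size)
  }

  xs_fwd <- cumsum(c(0, spacings))
  xs_rev <- cumsum(c(0, rev(spacings)))

  middle <- integer(0)
  if (reverse_middle && n_rows >= 3) {
    mid <- (n_rows + 1) / 2
    middle <- unique(pmin(pmax(round(c(mid - 1, mid, mid + 1)), 1L), n_rows))
  }

  pts <- do.call(rbind, lapply(seq_len(n_rows), function(r) {
    xs <- if (r %in% middle) xs_rev else xs_fwd
    data.frame(x_m = xs, y_m = (r - 1) * row_spacing)
  }))
  pts <- data.frame(core_id = seq_len(nrow(pts)), pts)

  if (anyDuplicated(pts[, c("x_m", "y_m")]) > 0) {
    stopf("design produced duplicate coordinates")
  }

  structure(
    list(points = pts, plot_size = plot_size, n_rows = n_rows,
         row_spacing = row_spacing, within_row_spacings = spacings),
    class = "sampling_design"
  )
}

#' @export
print.sampling_design <- function(x, ...) {
  cat(sprintf(
    "Sampling design: %d cores in %d rows (%g m apart) on a %g m x %g m plot\n",
    nrow(x$points), x$n_rows, x$row_spacing, x$plot_size, x$plot_size))
  cat("within-row intervals (m):", paste(x$within_row_spacings, collapse = ", "),
      "\n")
  invisible(x)
}

#' Pairwise distances of a sampling design
#'
#' @param design A `sampling_design`.
#' @return The full n x n Euclidean distance matrix (m).
#' @export
design_distances <- function(design) {
  cross_dist(design$points[, c("x_m", "y_m")], design$points[, c("x_m", "y_m")])
}
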