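# CSV readers/writers. All coordinates are 0-based metres from the plot's
# southwest corner; all tabular I/O is plain CSV.

read_csv_checked <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
}

check_numeric_col <- function(df, col, path) {
  v <- df[[col]]
  if (is.null(v)) stopf("%s: missing required column '%s'", path, col)
  num <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(num))
  if (length(bad)) {
    stopf("%s: non-numeric value(s) in column '%s' at data line(s) %s",
          path, col, paste(utils::head(bad, 5), collapse = ", "))
  }
  num
}

check_core_ids <- function(ids, path) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stopf("%s: duplicate core_id(s): %s", path,
          paste(utils::head(dup, 10), collapse = ", "))
  }
}

check_coords <- function(x, y, path, plot_size = NULL) {
  if (any(x < 0 | y < 0, na.rm = TRUE)) {
    stopf("%s: negative coordinate(s); coordinates are 0-based metres", path)
  }
  if (!is.null(plot_size) && any(x > plot_size | y > plot_size, na.rm = TRUE)) {
    stopf("%s: coordinate(s) outside the %g m plot", path, plot_size)
  }
}

#' Read spatial observations from CSV
#'
#' Expects columns `core_id`, `x_m`, `y_m` and a response column.
#'
#' @param path CSV path.
#' @param value_col Name of the response column (default `"value"`).
#' @param trend,plot_size Passed to validation / [spatial_observations()].
#' @return A [spatial_observations()] object.
#' @export
read_observations <- function(path, value_col = "value", trend = "linear",
                              plot_size = NULL) {
  df <- read_csv_checked(path)
  for (col in c("core_id", "x_m", "y_m", value_col)) {
    if (!col %in% names(df)) stopf("%s: missing required column '%s'",
                                   path, col)
  }
  x <- check_numeric_col(df, "x_m", path)
  y <- check_numeric_col(df, "y_m", path)
  v <- check_numeric_col(df, value_col, path)
  check_core_ids(df$core_id, path)
  check_coords(x, y, path, plot_size)
  if (anyNA(v)) {
    stopf("%s: missing response value(s) at data line(s) %s", path,
          paste(utils::head(which(is.na(v)), 5), collapse = ", "))
  }
  spatial_observations(x, y, v, trend = trend, core_id = df$core_id)
}

#' Write spatial observations to CSV
#'
#' @param obs A [spatial_observations()] object.
#' @param path Output CSV path.
#' @param value_col Response column name.
#' @export
write_observations <- function(obs, path, value_col = "value") {
  df <- data.frame(core_id = obs$core_id, x_m = obs$coords[, 1],
                   y_m = obs$coords[, 2])
  df[[value_col]] <- obs$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a wide per-core lipid table from CSV
#'
#' Columns: `core_id`, optional `x_m`/`y_m`, then one column per lipid
#' (amounts in nmol). Lipid names are validated by [parse_lipid_name()].
#'
#' @param path CSV path.
#' @param plot_size Optional coordinate bound (m).
#' @return Data frame suitable for [filter_cores()].
#' @export
read_lipids <- function(path, plot_size = NULL) {
  df <- read_csv_checked(path)
  if (!"core_id" %in% names(df)) stopf("%s: missing column 'core_id'", path)
  check_core_ids(df$core_id, path)
  cols <- lipid_columns(df)
  if (!length(cols)) stopf("%s: no lipid columns", path)
  parse_lipid_name(cols)
  for (col in cols) df[[col]] <- check_numeric_col(df, col, path)
  if (all(c("x_m", "y_m") %in% names(df))) {
    df$x_m <- check_numeric_col(df, "x_m", path)
    df$y_m <- check_numeric_col(df, "y_m", path)
    check_coords(df$x_m, df$y_m, path, plot_size)
  }
  neg <- cols[vapply(cols, function(cc) any(df[[cc]] < 0, na.rm = TRUE),
                     TRUE)]
  if (length(neg)) stopf("%s: negative amount(s) in column(s) %s", path,
                         paste(neg, collapse = ", "))
  df
}

#' Write a lipid table to CSV
#' @param table Wide lipid table.
#' @param path Output CSV path.
#' @export
write_lipids <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a pool-dilution rates table from CSV
#'
#' Columns: `plot`, `core_id`, `gross_nitrification`, `nh4_consumption`,
#' `no3_consumption`, optional `gross_nh4_mineralization` (ug N g^-1
#' d^-1).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_rates <- function(path) {
  df <- read_csv_checked(path)
  need <- c("plot", "gross_nitrification", "nh4_consumption",
            "no3_consumption")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path,
                          paste(miss, collapse = ", "))
  for (col in setdiff(need, "plot")) {
    df[[col]] <- check_numeric_col(df, col, path)
  }
  df
}

#' Export a kriged surface as an ESRI ASCII grid raster
#'
#' The surface must come from a regular [prediction_grid()].
#'
#' @param surface A [krige_predict()] result.
#' @param path Output path (`.asc`).
#' @param field Which column to rasterize (default `"pred_mean"`).
#' @export
write_ascii_grid <- function(surface, path, field = "pred_mean") {
  xs <- sort(unique(surface$x_m)); ys <- sort(unique(surface$y_m))
  if (length(xs) > 1) {
    dx <- diff(xs)
    if (max(abs(dx - dx[1])) > 1e-9) stopf("surface is not a regular grid")
  }
  cell <- if (length(xs) > 1) xs[2] - xs[1] else 1
  m <- matrix(NA_real_, length(ys), length(xs))
  m[cbind(match(surface$y_m, ys), match(surface$x_m, xs))] <- surface[[field]]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("ncols %d", length(xs)),
               sprintf("nrows %d", length(ys)),
               sprintf("xllcorner %g", min(xs) - cell / 2),
               sprintf("yllcorner %g", min(ys) - cell / 2),
               sprintf("cellsize %g", cell),
               "NODATA_value -9999"), con)
  for (r in rev(seq_along(ys))) {  # north to south
    row <- m[r, ]; row[is.na(row)] <- -9999
    writeLines(paste(format(row, trim = TRUE), collapse = " "), con)
  }
  invisible(path)
}

#' Path to a bundled example data file
#'
#' Bundled plain-text data: plot-level lipid mole-percent profiles,
#' microbial summaries, pool-dilution rates and spatial posterior
#' summaries from a four-plot post-fire soil survey (two fire severities
#' at two Greater Yellowstone sites), plus a demo pipeline config.
#'
#' @param file File name; with no argument, lists available files.
#' @return Full path (or a character vector of file names).
#' @export
firekrige_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "firekrige")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stopf("no bundled file '%s'", file)
  path
}

#' Plot-level lipid mole-percent profiles
#'
#' Reads the bundled long-format plot summaries (26 lipids x 4 plots,
#' mean and SE of relative mole percent) into a lipid-by-plot matrix of
#' means.
#'
#' @param path CSV path (default: the bundled survey summaries).
#' @return List: `mean` and `se` matrices (lipid x plot), `lipids`
#'   (parse table from [parse_lipid_name()]).
#' @export
plot_lipid_profiles <- function(path = firekrige_example("plot_lipid_molepct.csv")) {
  df <- read_csv_checked(path)
  need <- c("lipid", "plot", "mean_molepct", "se_molepct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path,
                          paste(miss, collapse = ", "))
  info <- parse_lipid_name(unique(df$lipid))
  plots <- unique(df$plot)
  mk <- function(col) {
    m <- matrix(NA_real_, nrow(info), length(plots),
                dimnames = list(info$name, plots))
    m[cbind(match(df$lipid, info$name), match(df$plot, plots))] <- df[[col]]
    m
  }
  list(mean = mk("mean_molepct"), se = mk("se_molepct"), lipids = info)
}
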