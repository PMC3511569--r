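# PLFA (phospholipid fatty acid) community metrics.
#
# Lipid-name grammar: [prefix i|a|cy] CHAIN [:unsats] [wN] [c|t] [2OH],
# with the iso/anteiso branching alternatively written as a suffix
# ("15:0iso" == "i15:0"). Chain length is the integer before ":".
# Unicode variants (ratio colon, omega) are normalized on input.

canon_lipid <- function(x) {
  x <- gsub("∶", ":", x)   # ratio colon
  x <- gsub("ω", "w", x)   # omega
  x <- gsub("[[:space:]*]", "", x)
  tolower(x)
}

RX_PREFIX <- "^(i|a|cy)?([0-9]+):([0-9]+)(w[0-9]+)?(c|t)?(2oh)?$"
RX_SUFFIX <- "^([0-9]+):([0-9]+)(w[0-9]+)?(c|t)?(iso|anteiso)$"

#' Parse a lipid name
#'
#' Parses biomarker nomenclature such as `"16:0"`, `"i15:0"`,
#' `"15:0anteiso"`, `"cy17:0"`, `"16:1w5c"`, `"19:1w8t"`, `"18:02OH"`.
#'
#' @param name Character vector of lipid names (Unicode omega / ratio
#'   colon accepted). The conventional pool name `"unassigned"` (the
#'   non-dominant remainder emitted by [simulate_lipid_table()]) is
#'   accepted with `NA` chain length; it counts toward totals but matches
#'   no marker and is never dropped by the chain-length rule.
#' @return Data frame with `name`, `canonical` (prefix form, e.g.
#'   `"a15:0"`), `chain` (integer chain length), `unsat`.
#'   Unparseable names raise an error naming the offender.
#' @export
parse_lipid_name <- function(name) {
  cx <- canon_lipid(name)
  out <- data.frame(name = name, canonical = NA_character_,
                    chain = NA_integer_, unsat = NA_integer_,
                    stringsAsFactors = FALSE)
  pre <- regmatches(cx, regexec(RX_PREFIX, cx))
  suf <- regmatches(cx, regexec(RX_SUFFIX, cx))
  for (i in seq_along(cx)) {
    if (cx[i] == "unassigned") {
      out$canonical[i] <- "unassigned"
    } else if (length(pre[[i]])) {
      m <- pre[[i]]
      out$canonical[i] <- paste0(m[2], m[3], ":", m[4], m[5], m[6],
                                 if (nzchar(m[7])) "2OH" else "")
      out$chain[i] <- as.integer(m[3])
      out$unsat[i] <- as.integer(m[4])
    } else if (length(suf[[i]])) {
      m <- suf[[i]]
      prefix <- if (m[6] == "iso") "i" else "a"
      out$canonical[i] <- paste0(prefix, m[2], ":", m[3], m[4], m[5])
      out$chain[i] <- as.integer(m[2])
      out$unsat[i] <- as.integer(m[3])
    } else {
      stopf("unparseable lipid name: '%s'", name[i])
    }
  }
  out
}

META_COLS <- c("core_id", "x_m", "y_m", "plot")

lipid_columns <- function(table) setdiff(names(table), META_COLS)

# Marker sets (canonical prefix nomenclature). The fungi-to-bacteria ratio
# is fungal_markers / bacterial_markers; names without a cis/trans suffix
# match suffixed columns when no exact match exists.
FUNGAL_MARKERS <- c("18:1w9c", "16:1w5")
BACTERIAL_MARKERS <- c("a15:0", "i15:0", "15:0", "i16:0", "15:1w8c",
                       "16:1w7c", "cy17:0", "a17:0", "17:1w7c")
GM_POS_MARKERS <- c("i15:0", "a15:0", "i16:0", "a17:0", "i17:0")
GM_NEG_MARKERS <- c("15:1w8", "16:1w7", "17:1w7", "19:1w8t", "15:1w9")

strip_ct <- function(x) sub("(c|t)$", "", x)

# Map marker names to column names: exact canonical match first, then
# cis/trans-suffix-tolerant match (all matching columns are summed).
match_markers <- function(markers, columns) {
  canon <- parse_lipid_name(columns)$canonical
  lapply(markers, function(m) {
    hit <- columns[canon == m]
    if (!length(hit)) hit <- columns[strip_ct(canon) == strip_ct(m)]
    hit
  })
}

sum_markers <- function(values, markers) {
  hits <- match_markers(markers, names(values))
  sum(vapply(hits, function(h) sum(values[h]), 0), na.rm = TRUE)
}

#' Marker coverage of a lipid table
#'
#' Reports, for each marker in the fungal, bacterial, Gram-positive and
#' Gram-negative sets, which table column(s) it matched. Unmatched
#' markers contribute zero to every metric.
#'
#' @param table A wide lipid table (`core_id`, optional `x_m`/`y_m`, one
#'   column per lipid).
#' @return Data frame with `set`, `marker`, `matched` (comma-separated
#'   column names, `""` if absent).
#' @export
marker_coverage <- function(table) {
  cols <- lipid_columns(table)
  sets <- list(fungal = FUNGAL_MARKERS, bacterial = BACTERIAL_MARKERS,
               gm_pos = GM_POS_MARKERS, gm_neg = GM_NEG_MARKERS)
  do.call(rbind, lapply(names(sets), function(s) {
    hits <- match_markers(sets[[s]], cols)
    data.frame(set = s, marker = sets[[s]],
               matched = vapply(hits, paste, "", collapse = ","))
  }))
}

#' Filter cores and lipid columns before analysis
#'
#' Applies the two inclusion rules used for these data: cores lacking the
#' ubiquitous lipid 16:0 are removed (and listed in the report), and lipid
#' columns with chain length >= 20 are dropped. Retained values pass
#' through unchanged.
#'
#' @param table Wide lipid table (one row per core; `core_id` plus lipid
#'   columns, amounts in nmol).
#' @return List of class `lipid_filter`: `table` (filtered), `removed`
#'   (data frame of removed cores and the reason), `dropped_lipids`
#'   (character).
#' @export
filter_cores <- function(table) {
  cols <- lipid_columns(table)
  if (!length(cols)) stopf("no lipid columns found")
  info <- parse_lipid_name(cols)  # errors on unparseable names
  drop <- cols[!is.na(info$chain) & info$chain >= 20]
  keep_cols <- setdiff(cols, drop)

  hit16 <- match_markers("16:0", keep_cols)[[1L]]
  present <- if (length(hit16)) {
    rowSums(as.matrix(table[, hit16, drop = FALSE]), na.rm = TRUE) > 0
  } else rep(FALSE, nrow(table))
  removed <- table$core_id[!present]
  structure(list(
    table = table[present, c(intersect(META_COLS, names(table)), keep_cols),
                  drop = FALSE],
    removed = data.frame(core_id = removed,
                         reason = rep("lipid 16:0 absent", length(removed))),
    dropped_lipids = drop),
    class = "lipid_filter")
}

#' Per-core relative mole percent
#'
#' Rescales each core's lipid amounts to percentages of its total, so each
#' row sums to 100.
#'
#' @param table Filtered wide lipid table.
#' @return Same shape, lipid columns as mole percents.
#' @export
mole_percent <- function(table) {
  cols <- lipid_columns(table)
  amt <- as.matrix(table[, cols, drop = FALSE])
  tot <- rowSums(amt, na.rm = TRUE)
  if (any(tot <= 0)) {
    stopf("core(s) %s have zero total lipid; cannot normalize",
          paste(table$core_id[tot <= 0], collapse = ", "))
  }
  mp <- 100 * amt / tot
  for (j in seq_along(cols)) table[[cols[j]]] <- unname(mp[, j])
  table
}

#' Fungi-to-bacteria ratio of one core
#'
#' `(18:1w9c + 16:1w5) / (a15:0 + i15:0 + 15:0 + i16:0 + 15:1w8c +
#' 16:1w7c + cy17:0 + a17:0 + 17:1w7c)`. Absent markers contribute 0; the
#' ratio is scale-invariant, so amounts, mole percents, and mole fractions
#' give identical results.
#'
#' @param values Named numeric vector (lipid name -> amount or fraction)
#'   for a single core.
#' @return The ratio, or `NA` (flagged-undefined) when every bacterial
#'   marker is absent.
#' @export
fb_ratio <- function(values) {
  num <- sum_markers(values, FUNGAL_MARKERS)
  den <- sum_markers(values, BACTERIAL_MARKERS)
  if (den == 0) return(NA_real_)
  num / den
}

#' Gram-positive and Gram-negative marker sums of one core
#'
#' Sums the designated marker sets: Gm+ = `i15:0, a15:0, i16:0, a17:0,
#' i17:0`; Gm- = `15:1w8, 16:1w7, 17:1w7, 19:1w8t, 15:1w9`. Absent
#' markers contribute 0. Supply mole fractions to obtain the conventional
#' mole-fraction scale.
#'
#' @param values Named numeric vector for a single core.
#' @return Named numeric `c(gm_pos, gm_neg)`.
#' @export
marker_sums <- function(values) {
  c(gm_pos = sum_markers(values, GM_POS_MARKERS),
    gm_neg = sum_markers(values, GM_NEG_MARKERS))
}

#' Branching stress ratio i15:0 / a15:0
#'
#' @param values Named numeric vector for a single core.
#' @return The ratio, or `NA` (flagged-undefined) when a15:0 is absent.
#' @export
stress_ratio <- function(values) {
  num <- sum_markers(values, "i15:0")
  den <- sum_markers(values, "a15:0")
  if (den == 0) return(NA_real_)
  num / den
}

#' Per-core community metrics
#'
#' Computes, for every core of a (filtered) lipid table: total lipid
#' abundance (nmol), the fungi-to-bacteria ratio, Gram-positive and
#' Gram-negative marker sums as mole fractions, and the i15:0/a15:0
#' stress ratio.
#'
#' @param table Filtered wide lipid table of amounts (nmol).
#' @return Data frame `core_id`, `abundance_nmol`, `fb_ratio`, `gm_pos`,
#'   `gm_neg`, `stress_ratio` (plus `x_m`, `y_m` when present).
#' @export
community_metrics <- function(table) {
  cols <- lipid_columns(table)
  mp <- mole_percent(table)
  out <- data.frame(core_id = table$core_id)
  for (cc in intersect(c("x_m", "y_m"), names(table))) out[[cc]] <- table[[cc]]
  amt <- as.matrix(table[, cols, drop = FALSE])
  out$abundance_nmol <- rowSums(amt, na.rm = TRUE)
  frac <- as.matrix(mp[, cols, drop = FALSE]) / 100
  out$fb_ratio <- apply(frac, 1, function(v) fb_ratio(stats::setNames(v, cols)))
  ms <- t(apply(frac, 1, function(v) marker_sums(stats::setNames(v, cols))))
  out$gm_pos <- ms[, "gm_pos"]
  out$gm_neg <- ms[, "gm_neg"]
  out$stress_ratio <- apply(frac, 1,
                            function(v) stress_ratio(stats::setNames(v, cols)))
  out
}

#' Plot-level mean and standard error
#'
#' @param values Numeric vector of per-core values; `NA`s are excluded
#'   from `n`.
#' @return Named numeric `c(mean, se, n)`; `se` is `sd/sqrt(n)`, `NA`
#'   (flagged-undefined) when `n < 2`.
#' @export
plot_summary <- function(values) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 1) return(c(mean = NA_real_, se = NA_real_, n = 0))
  c(mean = mean(v),
    se = if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_,
    n = n)
}

#' Plot-level summary of community metrics
#'
#' Mean, standard error and n of every metric column — the per-core
#' mean-of-ratios convention. (The alternative ratio-of-means reading of a
#' plot-level fungi-to-bacteria ratio is `fb_ratio()` applied to the
#' plot-mean mole-percent profile.)
#'
#' @param metrics A [community_metrics()] data frame.
#' @return Data frame `metric`, `mean`, `se`, `n`.
#' @export
plot_metrics_summary <- function(metrics) {
  cols <- setdiff(names(metrics), c("core_id", "x_m", "y_m"))
  do.call(rbind, lapply(cols, function(cc) {
    s <- plot_summary(metrics[[cc]])
    data.frame(metric = cc, mean = s["mean"], se = s["se"], n = s["n"],
               row.names = NULL)
  }))
}
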