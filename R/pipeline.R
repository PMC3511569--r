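# YAML-configured pipeline driver: design -> simulate (or ingest CSVs) ->
# PLFA metrics -> kriging per variable -> stepwise selection -> rates ->
# summary reports, with a manifest recording config hash and seeds.

PIPELINE_KEYS <- c("seed", "output_dir", "design", "simulate", "inputs",
                   "krige", "select", "rates")

validate_config <- function(config) {
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown)) {
    stopf("config: unknown top-level key(s): %s",
          paste(unknown, collapse = ", "))
  }
  if (is.null(config$seed)) stopf("config: 'seed' is required")
  if (is.null(config$output_dir)) stopf("config: 'output_dir' is required")
  if (is.null(config$simulate) && is.null(config$inputs)) {
    stopf("config: provide either 'simulate' or 'inputs'")
  }
  invisible(config)
}

# Echo all resolved defaults so a "default" run stays reproducible after
# package defaults change.
resolve_config <- function(config) {
  d <- config$design %||% list()
  config$design <- list(
    spacings = unlist(d$spacings) %||% c(2, 2, 4, 4, 8, 8, 4, 2),
    n_rows = d$n_rows %||% 9, row_spacing = d$row_spacing %||% 2,
    plot_size = d$plot_size %||% 50,
    reverse_middle = d$reverse_middle %||% TRUE)
  k <- config$krige %||% list()
  config$krige <- list(
    variables = unlist(k$variables) %||% "value",
    n_phi = k$n_phi %||% 100, n_tau = k$n_tau %||% 100,
    n_draws = k$n_draws %||% 1e5,
    prediction_spacing = k$prediction_spacing %||% 0.5,
    loo = k$loo %||% TRUE,
    loo_n_phi = k$loo_n_phi %||% 25, loo_n_tau = k$loo_n_tau %||% 25,
    trend = k$trend %||% "linear")
  config
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
  message(sprintf("[%s] done in %.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full analysis pipeline from one config
#'
#' Stages: sampling design -> simulated or ingested observations and lipid
#' table -> core filtering and community metrics -> Bayesian kriging of
#' each requested variable (posterior summary, kriged surface,
#' leave-one-out diagnostics) -> stepwise-AIC selection of net-N-min
#' predictors -> pool-dilution net rates. Every stochastic stage derives
#' its seed from the single config seed, so a rerun with an identical
#' config reproduces identical outputs.
#'
#' @param config Path to a YAML config, or an equivalent named list. Keys:
#'   `seed`, `output_dir` (required); `design` (spacings, n_rows,
#'   row_spacing, plot_size); `simulate` (`response`: beta/sigma2/phi/
#'   tau2_rel; optional `lipids`: profile_file/profile_plot/total_mean/
#'   total_sd/profile_conc) or `inputs` (`observations`, optional
#'   `value_col`, `lipids`, `rates` CSV paths); `krige` (variables, n_phi,
#'   n_tau, n_draws, prediction_spacing, loo); `select` (logical or list);
#'   `rates` (`file`).
#' @param output_dir Optional override of the config's output directory.
#' @return Invisibly, a run report: list with `manifest` (also written as
#'   YAML), `outputs` (paths), and the in-memory stage results.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  config <- resolve_config(config)
  out <- output_dir %||% config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  outputs <- character(0)
  counts <- list()
  add_out <- function(path) outputs[[length(outputs) + 1L]] <<- path

  design <- stage("design", do.call(generate_design, config$design))
  counts$design <- nrow(design$points)

  obs <- lipids <- rates_tab <- NULL
  if (!is.null(config$simulate)) {
    r <- config$simulate$response %||% list()
    truth <- simulation_truth(
      beta = unlist(r$beta) %||% c(0, 0, 0),
      sigma2 = r$sigma2 %||% 1, phi = r$phi %||% 2,
      tau2_rel = r$tau2_rel %||% 0.7)
    obs <- stage("simulate_field", simulate_field(design, truth, seed = seed))
    if (!is.null(config$simulate$lipids)) {
      l <- config$simulate$lipids
      prof <- plot_lipid_profiles(l$profile_file %||%
                                    firekrige_example("plot_lipid_molepct.csv"))
      pm <- prof$mean[, l$profile_plot %||% colnames(prof$mean)[1]]
      lipids <- stage("simulate_lipids", simulate_lipid_table(
        design, profile = pm, total_mean = l$total_mean %||% 300,
        total_sd = l$total_sd %||% 100,
        spatial = simulation_truth(sigma2 = 1, phi = truth$phi,
                                   tau2_rel = truth$tau2_rel),
        profile_conc = l$profile_conc %||% 200, seed = seed + 1L))
    }
  } else {
    inp <- config$inputs
    obs <- stage("read_observations", read_observations(
      inp$observations, value_col = inp$value_col %||% "value",
      trend = config$krige$trend, plot_size = config$design$plot_size))
    if (!is.null(inp$lipids)) {
      lipids <- stage("read_lipids",
                      read_lipids(inp$lipids,
                                  plot_size = config$design$plot_size))
    }
    if (!is.null(inp$rates)) {
      rates_tab <- stage("read_rates", read_rates(inp$rates))
    }
  }
  counts$observations <- length(obs$y)
  write_observations(obs, file.path(out, "observations.csv"))
  add_out(file.path(out, "observations.csv"))

  metrics <- NULL
  if (!is.null(lipids)) {
    flt <- stage("filter_cores", filter_cores(lipids))
    counts$cores_retained <- nrow(flt$table)
    counts$cores_removed <- nrow(flt$removed)
    metrics <- stage("community_metrics", community_metrics(flt$table))
    write_lipids(lipids, file.path(out, "lipids.csv"))
    utils::write.csv(metrics, file.path(out, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(plot_metrics_summary(metrics),
                     file.path(out, "metrics_summary.csv"), row.names = FALSE)
    utils::write.csv(marker_coverage(flt$table),
                     file.path(out, "marker_coverage.csv"), row.names = FALSE)
    add_out(file.path(out, "metrics.csv"))
    add_out(file.path(out, "metrics_summary.csv"))
  }

  krige_results <- list()
  for (v in config$krige$variables) {
    vo <- if (v == "value") obs else {
      if (is.null(metrics) || !v %in% names(metrics)) {
        stopf("stage 'krige' failed: variable '%s' not available", v)
      }
      ok <- !is.na(metrics[[v]])
      spatial_observations(metrics$x_m[ok], metrics$y_m[ok],
                           metrics[[v]][ok], trend = config$krige$trend,
                           core_id = metrics$core_id[ok])
    }
    res <- stage(paste0("krige:", v), {
      grid <- compute_posterior(vo, prior_spec(n_phi = config$krige$n_phi,
                                               n_tau = config$krige$n_tau))
      draws <- sample_posterior(grid, n_draws = config$krige$n_draws,
                                seed = seed + 2L)
      summ <- summarize_posterior(draws, obs = vo)
      surf <- krige_predict(vo, draws[seq_len(min(nrow(draws), 2000)), ],
                            prediction_grid(vo,
                                            config$krige$prediction_spacing))
      loo <- if (isTRUE(config$krige$loo)) {
        loo_cross_validate(vo, prior_spec(n_phi = config$krige$loo_n_phi,
                                          n_tau = config$krige$loo_n_tau))
      }
      list(grid = grid, draws = draws, summary = summ, surface = surf,
           loo = loo)
    })
    sfile <- file.path(out, sprintf("posterior_summary_%s.csv", v))
    ssum <- res$summary
    if (!is.null(res$loo)) {
      ssum <- rbind(ssum, data.frame(quantity = "cv_adj_r2",
                                     mean = res$loo$adj_r2,
                                     q05 = NA, q95 = NA))
    }
    utils::write.csv(ssum, sfile, row.names = FALSE)
    utils::write.csv(res$surface,
                     file.path(out, sprintf("surface_%s.csv", v)),
                     row.names = FALSE)
    if (!is.null(res$loo)) {
      utils::write.csv(res$loo$points,
                       file.path(out, sprintf("loo_%s.csv", v)),
                       row.names = FALSE)
    }
    add_out(sfile)
    add_out(file.path(out, sprintf("surface_%s.csv", v)))
    krige_results[[v]] <- res
  }

  selection <- NULL
  if (!is.null(metrics) && !isFALSE(config$select)) {
    sel_cfg <- if (is.list(config$select)) config$select else list()
    merged <- merge(data.frame(core_id = obs$core_id, value = obs$y),
                    metrics, by = "core_id")
    cand_cols <- unlist(sel_cfg$candidates) %||%
      setdiff(names(metrics), c("core_id", "x_m", "y_m"))
    selection <- stage("stepwise_select", stepwise_select(
      merged$value, merged[, cand_cols, drop = FALSE]))
    sel_df <- if (length(selection$terms)) {
      data.frame(predictor = selection$terms, sign = selection$sign,
                 band = selection$bands)
    } else data.frame(predictor = character(0), sign = character(0),
                      band = character(0))
    sel_df <- rbind(sel_df, data.frame(predictor = "(adj_r2)",
                                       sign = "", band =
                                         sprintf("%.3f", selection$adj_r2)))
    utils::write.csv(sel_df, file.path(out, "selection.csv"),
                     row.names = FALSE)
    add_out(file.path(out, "selection.csv"))
  }

  if (!is.null(config$rates) && !is.null(config$rates$file)) {
    rates_tab <- stage("read_rates", read_rates(config$rates$file))
  }
  if (!is.null(rates_tab)) {
    rates_net <- stage("net_rates", pool_dilution_net(rates_tab))
    utils::write.csv(rates_net, file.path(out, "rates_net.csv"),
                     row.names = FALSE)
    add_out(file.path(out, "rates_net.csv"))
  }

  manifest <- list(
    package = "firekrige",
    version = as.character(utils::packageVersion("firekrige")),
    config = config,
    config_md5 = if (!is.null(config_path)) {
      unname(tools::md5sum(config_path))
    } else unname(tools::md5sum(
      local({ f <- tempfile(); yaml::write_yaml(config, f); f }))),
    seeds = list(field = seed, lipids = seed + 1L, draws = seed + 2L),
    row_counts = counts,
    outputs = unlist(outputs))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  add_out(file.path(out, "manifest.yaml"))

  invisible(list(manifest = manifest, outputs = unlist(outputs),
                 observations = obs, metrics = metrics,
                 krige = krige_results, selection = selection,
                 rates = rates_tab))
}
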