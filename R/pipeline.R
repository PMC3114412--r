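# Pipeline configuration, the four-stage driver (preprocess -> model ->
# statistics -> export) and the exporters behind the CLI.

#' Default pipeline configuration
#'
#' Returns the full default configuration as a named list; every field can
#' be overridden in the JSON/YAML config consumed by [run_pipeline()] and
#' the CLI. `input$format` is one of `"preset"` (simulate a bundled
#' scenario), `"container"`, `"txt"` or `"edf"`.
#'
#' @return Named list of defaults.
#' @export
config_template <- function() {
  list(
    input = list(format = "preset", path = NULL, preset = "chain3",
                 srate = NULL, t_start = 0,
                 events = NULL, tmin = NULL, tmax = NULL),
    preprocess = list(detrend = "linear", normalize = list("temporal", "ensemble"),
                      downsample = 1),
    window = list(win_len = NULL, step = NULL),
    model = list(order = NULL, p_range = c(1, 10), criterion = "bic",
                 method = "ols"),
    measures = list("dtf", "ddtf"),
    freqs = NULL,
    stats = list(test = "none", n_surrogates = 199, seed = 1, q = 0.05,
                 mode = "bh", alpha = 0.05),
    graph_band = NULL,
    seed = 1,
    out_dir = "varconn_out"
  )
}

# Merge a user config over the defaults (shallow per section).
merge_config <- function(user) {
  base <- config_template()
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && !is.null(names(base[[nm]]))) {
      for (k in names(user[[nm]])) base[[nm]][[k]] <- user[[nm]][[k]]
    } else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load a pipeline configuration file
#'
#' JSON (default) or YAML, merged over [config_template()] and validated
#' before any computation.
#'
#' @param path Config file path (`.json`, `.yaml`/`.yml`).
#' @return Validated config list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  user <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(merge_config(user))
}

validate_config <- function(config) {
  meas <- unlist(config$measures)
  bad <- setdiff(meas, c(measure_registry(), "gc_time", "ggc_spectral"))
  if (length(bad))
    stop(sprintf("config error: unknown measure(s) %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  fmt <- config$input$format
  if (!fmt %in% c("preset", "container", "txt", "edf"))
    stop(sprintf("config error: unknown input format '%s'", fmt), call. = FALSE)
  if (fmt == "preset" && !config$input$preset %in% names(preset_scenarios()))
    stop(sprintf("config error: unknown preset '%s'", config$input$preset),
         call. = FALSE)
  if (fmt != "preset") {
    if (is.null(config$input$path))
      stop("config error: input$path is required", call. = FALSE)
    if (!all(file.exists(unlist(config$input$path))))
      stop(sprintf("config error: input file(s) not found: %s",
                   paste(unlist(config$input$path), collapse = ", ")), call. = FALSE)
  }
  if (!config$stats$test %in% c("none", "surrogate", "analytic"))
    stop(sprintf("config error: unknown stats test '%s'", config$stats$test),
         call. = FALSE)
  config
}

vc_log <- function(level, stage, msg) {
  lv <- c(debug = 1, info = 2, warn = 3, error = 4)
  thr <- getOption("varconn.log_level", "info")
  if (lv[[level]] >= lv[[thr]])
    message(sprintf("%s [%s] %s: %s",
                    format(Sys.time(), "%H:%M:%S"), level, stage, msg))
}

load_input <- function(config) {
  inp <- config$input
  switch(inp$format,
    preset = {
      spec <- preset_scenarios()[[inp$preset]]
      simulate_var(spec, seed = config$seed)$ts
    },
    container = {
      obj <- vc_read(inp$path)
      if (!inherits(obj, "epoched_ts") && !is.null(obj$ts)) obj <- obj$ts
      assert_ets(obj, "input container payload")
    },
    txt = read_ets_txt(unlist(inp$path), srate = inp$srate,
                       t_start = inp$t_start %||% 0),
    edf = {
      ts <- read_edf(inp$path)
      if (!is.null(inp$events))
        ts <- epoch_recording(ts, unlist(inp$events), inp$tmin, inp$tmax)
      ts
    })
}

#' Run the full connectivity pipeline
#'
#' Executes the four-stage flow -- preprocessing, sliding-window model
#' fitting and connectivity estimation, statistics, export -- from a
#' single configuration, and writes all artifacts plus a run manifest
#' (config echo, seeds, package version, model diagnostics) to
#' `config$out_dir`. Deterministic given the configured seeds.
#'
#' @param config A config list (see [config_template()]) or a path to a
#'   JSON/YAML config file.
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  else config <- validate_config(merge_config(config))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- "input"
  result <- tryCatch({
    vc_log("info", stage, "loading data")
    ts <- load_input(config)

    stage <- "preprocess"
    pp <- config$preprocess
    if (!is.null(pp$detrend)) ts <- detrend(ts, pp$detrend)
    for (nm in unlist(pp$normalize)) ts <- normalize_ensemble(ts, nm)
    if ((pp$downsample %||% 1) > 1) ts <- downsample(ts, pp$downsample)
    vc_log("info", stage, sprintf("%d ch x %d samp x %d trials @ %g Hz",
                                  n_channels(ts), n_samples(ts), n_trials(ts),
                                  ts$srate))

    stage <- "model"
    win <- if (!is.null(config$window$win_len))
      window_spec(config$window$win_len, config$window$step) else NULL
    freqs <- if (is.null(config$freqs)) default_freqs(ts$srate)
             else unlist(config$freqs)
    meas <- unlist(config$measures)
    spectral_meas <- setdiff(meas, c("gc_time", "ggc_spectral"))
    crs <- connectivity(ts, order = config$model$order,
                        measures = if (length(spectral_meas)) spectral_meas else "dtf",
                        freqs = freqs, window = win,
                        method = config$model$method,
                        p_range = unlist(config$model$p_range),
                        criterion = config$model$criterion)
    models <- attr(crs, "models")
    if ("gc_time" %in% meas)
      crs$gc_time <- gc_time(ts, models[[1]]$order, method = config$model$method)
    if ("ggc_spectral" %in% meas)
      crs$ggc_spectral <- ggc_spectral(ts, models[[1]]$order, freqs,
                                       method = config$model$method)
    crs <- crs[intersect(meas, names(crs))]
    wins <- if (is.null(win)) list(list(center = mean(range(ts$times)), data = ts))
            else segment_windows(ts, win)
    diags <- mapply(function(m, w) validate_model(m, w$data), models, wins,
                    SIMPLIFY = FALSE)
    vc_log("info", stage, sprintf(
      "%d window(s); whiteness pass fraction %.2f; all stable: %s",
      length(models),
      mean(vapply(diags, function(d) d$whiteness_pvalue > 0.05, TRUE), na.rm = TRUE),
      all(vapply(diags, `[[`, TRUE, "is_stable"))))

    stage <- "stats"
    st <- NULL
    if (config$stats$test == "surrogate") {
      pl <- make_pipeline(meas[1], order = models[[1]]$order, freqs = freqs,
                          window = win, method = config$model$method)
      st <- surrogate_test(pl, ts, n_surrogates = config$stats$n_surrogates,
                           seed = config$stats$seed, q = config$stats$q,
                           mode = config$stats$mode)
    } else if (config$stats$test == "analytic") {
      m0 <- intersect(meas, c("pdc", "dtf"))
      if (!length(m0))
        stop("analytic test requires measure pdc or dtf", call. = FALSE)
      st <- analytic_test(crs[[m0[1]]], models, measure = m0[1],
                          alpha = config$stats$alpha, q = config$stats$q,
                          mode = config$stats$mode)
    }

    stage <- "export"
    for (nm in names(crs)) {
      dir_m <- file.path(out_dir, nm)
      export_tf_grid(crs[[nm]],
                     sr = if (!is.null(st) && identical(st$observed$measure, nm)) st,
                     path = dir_m)
      export_long(crs[[nm]], file.path(out_dir, paste0(nm, "_long.tsv")))
    }
    if (!is.null(config$graph_band)) {
      gm <- graph_measures(crs[[1]], unlist(config$graph_band))
      utils::write.table(gm$nodes, file.path(out_dir, "graph_nodes.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(gm$density, file.path(out_dir, "graph_density.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    vc_write(list(connectivity = crs, models = models, stats = st),
             file.path(out_dir, "results.vc.rds"))

    manifest <- list(
      package = "varconn",
      version = as.character(utils::packageVersion("varconn")),
      config = config,
      seeds = list(pipeline = config$seed, stats = config$stats$seed),
      diagnostics = list(
        n_windows = length(models),
        orders = vapply(models, `[[`, 0L, "order"),
        stable = vapply(diags, `[[`, TRUE, "is_stable"),
        spectral_radius = vapply(diags, `[[`, 0, "spectral_radius"),
        whiteness_pvalue = vapply(diags, `[[`, 0, "whiteness_pvalue"),
        whiteness_pass_fraction =
          mean(vapply(diags, function(d) d$whiteness_pvalue > 0.05, TRUE),
               na.rm = TRUE),
        consistency_pct = vapply(diags, `[[`, 0, "consistency_pct")),
      complete = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    vc_log("info", stage, sprintf("artifacts written to %s", out_dir))
    0L
  }, error = function(e) {
    vc_log("error", stage, conditionMessage(e))
    jsonlite::write_json(
      list(package = "varconn", complete = FALSE, failed_stage = stage,
           error = conditionMessage(e)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(out_dir)
}

#' Export a connectivity result as time-frequency grid files
#'
#' Writes, per (sink, source) channel pair, a window x frequency matrix
#' (`pair_<sink>_from_<source>.tsv`: first column the window center in
#' seconds, remaining columns the frequency grid) and, when a
#' [surrogate_test()]/[analytic_test()] result is supplied, an aligned
#' significance mask file (`mask_<sink>_from_<source>.tsv`). The diagonal
#' files of a `power` result hold the auto-spectra.
#'
#' @param cr A `connectivity_result`.
#' @param sr Optional matching `stat_result`.
#' @param path Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
export_tf_grid <- function(cr, sr = NULL, path) {
  stopifnot(inherits(cr, "connectivity_result"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  d <- dim(cr$values)
  labs <- cr$channel_labels %||% paste0("ch", seq_len(d[1]))
  header <- c("window_center", paste0("f", cr$freqs))
  written <- character(0)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    m <- matrix(cr$values[i, j, , ], nrow = d[4], byrow = TRUE)
    tab <- cbind(cr$window_centers, m)
    colnames(tab) <- header
    f <- file.path(path, sprintf("pair_%s_from_%s.tsv", labs[i], labs[j]))
    utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, f)
    if (!is.null(sr)) {
      mk <- matrix(as.integer(sr$mask[i, j, , ]), nrow = d[4], byrow = TRUE)
      tabm <- cbind(cr$window_centers, mk)
      colnames(tabm) <- header
      fm <- file.path(path, sprintf("mask_%s_from_%s.tsv", labs[i], labs[j]))
      utils::write.table(tabm, fm, sep = "\t", row.names = FALSE, quote = FALSE)
      written <- c(written, fm)
    }
  }
  invisible(written)
}

#' Export a connectivity result as a long-format table
#'
#' One row per (window_center, freq, sink, source) cell; the standard
#' interchange format for downstream plotting.
#'
#' @inheritParams export_tf_grid
#' @param path Output file path (TSV).
#' @export
export_long <- function(cr, path) {
  stopifnot(inherits(cr, "connectivity_result"))
  d <- dim(cr$values)
  labs <- cr$channel_labels %||% paste0("ch", seq_len(d[1]))
  g <- expand.grid(sink = labs, source = labs, freq = cr$freqs,
                   window_center = cr$window_centers,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$measure <- cr$measure
  g$value <- as.vector(cr$values)
  g <- g[, c("window_center", "freq", "sink", "source", "measure", "value")]
  utils::write.table(g, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
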