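#' Default pipeline configuration
#'
#' All defaults mirror the measurement protocol: 125 Hz common rate (the
#' platform's native rate), 60 beats/min tempo, limits of agreement at
#' confidence level 0.95, relative-RMSE span between the 2.5% and 97.5%
#' quantiles of the platform waveform, lag search within +/-5 s.
#'
#' @param ... named overrides of any default key (unknown keys rejected).
#' @return A validated configuration list with keys:
#'   `seed`, `participants`, `applications`, `sock_rate_hz`,
#'   `resample_rate_hz`, `max_lag_s`, `max_gap_s`, `marker_rel_threshold`,
#'   `marker_min_duration_s`, `quantile_low`, `quantile_high`,
#'   `rel_reference`, `alpha_loa`, `alpha_ci`, `scheme`, `lag_range_s`,
#'   `offset_range_mm`, `foot_scale_range`, `sensor_noise_sd`,
#'   `sensor_baseline`, `sensor_saturation`, `sensitivity_range`,
#'   `jitter_sd_mm`, `platform_noise_sd_mm`, `out_dir`, `log_level`.
#' @name default_config
NULL

config_template <- function() {
  list(
    seed = 1L,
    participants = 10L,
    applications = 2L,
    sock_rate_hz = 125,
    resample_rate_hz = 125,
    max_lag_s = 5.0,
    max_gap_s = 0.2,
    marker_rel_threshold = 0.1,
    marker_min_duration_s = 2.0,
    quantile_low = 0.025,
    quantile_high = 0.975,
    rel_reference = "platform",
    alpha_loa = 0.95,
    alpha_ci = 0.05,
    scheme = "both",
    lag_range_s = c(-0.5, 0.5),
    offset_range_mm = c(-30, 30),
    foot_scale_range = c(0.9, 1.1),
    sensitivity_range = c(0.5, 3.0),
    sensor_baseline = 0.5,
    sensor_saturation = 300,
    sensor_noise_sd = 1,
    jitter_sd_mm = 2,
    platform_noise_sd_mm = 0.5,
    out_dir = NULL,
    log_level = "info"
  )
}

#' @export
default_config <- function(...) {
  cfg <- config_template()
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(over)] <- over
  }
  validate_config(cfg)
}

#' Ideal (error-free) pipeline configuration
#'
#' Unit sensitivities, no sensor baseline/noise/saturation/jitter, no
#' platform noise or placement offset, zero inter-instrument lag and unit
#' foot scale: the end-to-end pipeline then reproduces the ground truth
#' exactly, giving CCC = 1 and RMSE = 0 for every pair. Used as the
#' perfect-agreement control.
#'
#' @param ... further overrides passed to [default_config()].
#' @return A validated configuration list.
#' @export
ideal_config <- function(...) {
  default_config(
    sensitivity_range = c(1, 1), sensor_baseline = 0,
    sensor_saturation = Inf, sensor_noise_sd = 0, jitter_sd_mm = 0,
    platform_noise_sd_mm = 0, lag_range_s = c(0, 0),
    offset_range_mm = c(0, 0), foot_scale_range = c(1, 1), ...)
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys and type/range violations before any stage runs.
#'
#' @param cfg a configuration list (e.g. parsed from YAML).
#' @return The validated config, invisibly usable.
#' @export
validate_config <- function(cfg) {
  template <- config_template()
  unknown <- setdiff(names(cfg), names(template))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  full <- template
  full[names(cfg)] <- cfg
  cfg <- full
  for (key in c("sock_rate_hz", "resample_rate_hz", "max_lag_s", "max_gap_s",
                "marker_rel_threshold", "marker_min_duration_s",
                "participants", "applications")) {
    stop_if_not_scalar_number(cfg[[key]], key, positive = TRUE)
  }
  if (cfg$marker_rel_threshold >= 1) {
    stop("`marker_rel_threshold` must be < 1", call. = FALSE)
  }
  if (!(cfg$quantile_low >= 0 && cfg$quantile_high <= 1 &&
        cfg$quantile_low < cfg$quantile_high)) {
    stop("quantile pair must satisfy 0 <= low < high <= 1", call. = FALSE)
  }
  if (!cfg$rel_reference %in% c("platform", "sock")) {
    stop("`rel_reference` must be 'platform' or 'sock'", call. = FALSE)
  }
  if (!cfg$scheme %in% c("strict", "loose", "both")) {
    stop("`scheme` must be 'strict', 'loose' or 'both'", call. = FALSE)
  }
  if (!cfg$log_level %in% c("quiet", "info", "debug")) {
    stop("`log_level` must be 'quiet', 'info' or 'debug'", call. = FALSE)
  }
  for (key in c("lag_range_s", "offset_range_mm", "foot_scale_range",
                "sensitivity_range")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 2L || v[1] > v[2]) {
      stop(sprintf("`%s` must be a nondecreasing 2-vector", key), call. = FALSE)
    }
  }
  cfg
}

pipeline_log <- function(cfg, level, fmt, ...) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[cfg$log_level]] >= levels[[level]]) {
    message(sprintf(fmt, ...))
  }
}

config_sensor_model <- function(cfg) {
  sensor_model(sensitivity_range = cfg$sensitivity_range,
               baseline = cfg$sensor_baseline,
               saturation = cfg$sensor_saturation,
               noise_sd = cfg$sensor_noise_sd,
               jitter_sd = cfg$jitter_sd_mm)
}

config_platform_model <- function(cfg) {
  platform_model(rate = 125, noise_sd = cfg$platform_noise_sd_mm)
}

config_design <- function(cfg) {
  study_design(participants = cfg$participants,
               applications = cfg$applications,
               lag_range = cfg$lag_range_s,
               offset_range = cfg$offset_range_mm,
               foot_scale_range = cfg$foot_scale_range)
}

# Process one simulated trial into per-axis agreement records.
process_trial <- function(tr, cfg) {
  sock_series <- sock_cop(tr$sock, sensor_geometry())
  sock_rs <- resample_cop(sock_series, rate = cfg$resample_rate_hz,
                          max_gap = cfg$max_gap_s)
  plat_rs <- resample_cop(tr$platform, rate = cfg$resample_rate_hz,
                          max_gap = cfg$max_gap_s)
  al <- align_cop(sock_rs, plat_rs, max_lag = cfg$max_lag_s)
  lapply(al[c("x", "y")], function(pair) {
    cop_agreement(pair,
                  quantiles = c(cfg$quantile_low, cfg$quantile_high),
                  reference = cfg$rel_reference,
                  alpha_loa = cfg$alpha_loa, alpha_ci = cfg$alpha_ci)
  })
}

#' Run the full simulate-reconstruct-align-agree pipeline
#'
#' Orchestrates every stage: simulate (or accept) a study, reconstruct sock
#' CoP from conductances, resample both modalities to the common rate,
#' estimate and apply the inter-instrument lag, mean-centre, and compute
#' all agreement metrics per waveform pair. Deterministic given
#' `config$seed`. Trials that fail a stage are reported in the exclusion
#' log with their identity and reason, never silently dropped.
#'
#' @param config a configuration from [default_config()], [ideal_config()]
#'   or [read_config()].
#' @param study optionally, a pre-built `cop_study` (e.g. from
#'   [generate_study()] or loaded from disk); when `NULL` one is simulated
#'   from the config.
#' @return An object of class `cop_pipeline_result`: `metrics` (data frame,
#'   one row per waveform pair), `summary` (from [summarize_agreement()]),
#'   `exclusions` (data frame), `manifest`, `config`.
#' @export
run_pipeline <- function(config = default_config(), study = NULL) {
  config <- validate_config(config)
  if (is.null(study)) {
    pipeline_log(config, "info", "simulating study (seed %s)...",
                 format(config$seed))
    study <- generate_study(design = config_design(config),
                            seed = config$seed,
                            sensor_model = config_sensor_model(config),
                            platform_model = config_platform_model(config),
                            sock_rate = config$sock_rate_hz)
  }
  if (!inherits(study, "cop_study")) {
    stop("`study` must be a cop_study", call. = FALSE)
  }
  pipeline_log(config, "info", "processing %d trials...", length(study$trials))
  rows <- list()
  excl <- list()
  for (i in seq_along(study$trials)) {
    tr <- study$trials[[i]]
    fits <- tryCatch(process_trial(tr, config), error = function(e) e)
    if (inherits(fits, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(
        trial = i, participant = tr$participant, exercise = tr$exercise,
        foot = tr$foot, application = tr$application,
        reason = conditionMessage(fits), stringsAsFactors = FALSE)
      next
    }
    for (pair_fit in fits) {
      df <- as.data.frame(pair_fit)
      df$trial <- i
      rows[[length(rows) + 1L]] <- df
    }
  }
  if (!length(rows)) stop("every trial failed; see exclusions", call. = FALSE)
  metrics <- do.call(rbind, rows)
  metrics <- metrics[c("trial", setdiff(names(metrics), "trial"))]
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(trial = integer(0), participant = character(0),
               exercise = character(0), foot = character(0),
               application = integer(0), reason = character(0))
  res <- structure(
    list(metrics = metrics, summary = summarize_agreement(metrics),
         exclusions = exclusions, manifest = study$manifest,
         config = config),
    class = "cop_pipeline_result"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(metrics, file.path(config$out_dir, "metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(report(res), file.path(config$out_dir, "summary.txt"))
    jsonlite::write_json(study$manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (nrow(exclusions)) {
      utils::write.table(exclusions,
                         file.path(config$out_dir, "exclusions.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  res
}

#' @export
print.cop_pipeline_result <- function(x, ...) {
  cat(sprintf("CoP agreement pipeline: %d waveform pairs analysed, %d excluded\n",
              nrow(x$metrics), nrow(x$exclusions)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Human-readable agreement report
#'
#' Formats the per-axis and overall concordance summary the way a
#' validation study states it: counts and percentages at the 0.90 / 0.60 /
#' 0.40 CCC thresholds and the CCC and RMSE ranges. Optionally writes
#' scatter and Bland-Altman plot files for each pair.
#'
#' @param x a `cop_pipeline_result` or a metrics data frame.
#' @param plots logical; write per-pair diagnostic plots (needs
#'   `plot_dir`).
#' @param plot_dir directory for plot files (deterministic names
#'   `pair<trial>_<axis>.pdf`).
#' @param study the `cop_study` the metrics came from (required for
#'   plots).
#' @return Character vector of report lines, invisibly; also printed.
#' @export
report <- function(x, plots = FALSE, plot_dir = NULL, study = NULL) {
  metrics <- if (inherits(x, "cop_pipeline_result")) x$metrics else x
  if (!is.data.frame(metrics) || nrow(metrics) == 0L) {
    stop("empty metrics; nothing to report", call. = FALSE)
  }
  s <- summarize_agreement(metrics)
  lines <- c("CoP agreement report", "====================")
  for (i in seq_len(nrow(s))) {
    r <- s[i, ]
    lines <- c(lines,
      sprintf("%s: n = %d waveform pairs", r$group, r$n),
      sprintf("  CCC range %.2f to %.2f; RMSE range %.1f to %.1f mm",
              r$ccc_min, r$ccc_max, r$rmse_min_mm, r$rmse_max_mm),
      sprintf("  CCC >= 0.90: %d (%.0f%%); CCC >= 0.60: %d (%.0f%%); CCC < 0.40: %d (%.0f%%)",
              r$n_ccc_ge_090, 100 * r$frac_ccc_ge_090,
              r$n_ccc_ge_060, 100 * r$frac_ccc_ge_060,
              r$n_ccc_lt_040, 100 * r$frac_ccc_lt_040))
  }
  if (isTRUE(plots)) {
    if (is.null(plot_dir) || is.null(study)) {
      stop("plots need `plot_dir` and the originating `study`", call. = FALSE)
    }
    dir.create(plot_dir, showWarnings = FALSE, recursive = TRUE)
    cfg <- if (inherits(x, "cop_pipeline_result")) x$config else default_config()
    for (i in seq_len(nrow(metrics))) {
      row <- metrics[i, ]
      tr <- study$trials[[row$trial]]
      al <- align_cop(
        resample_cop(sock_cop(tr$sock), cfg$resample_rate_hz, cfg$max_gap_s),
        resample_cop(tr$platform, cfg$resample_rate_hz, cfg$max_gap_s),
        max_lag = cfg$max_lag_s)
      pair <- al[[row$axis]]
      fit <- cop_agreement(pair)
      file <- file.path(plot_dir, sprintf("pair%03d_%s.pdf", row$trial, row$axis))
      grDevices::pdf(file, width = 8, height = 4)
      plot(fit, pair)
      grDevices::dev.off()
    }
    lines <- c(lines, sprintf("wrote %d plot files to %s", nrow(metrics), plot_dir))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
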