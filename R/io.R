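# Delimited-text interfaces: sock recordings (t,u0..u5), CoP series
# (t,x,y,valid), metrics TSV, study manifests. All plain UTF-8 CSV/TSV with
# '.' decimal separator, so datasets survive version control and travel
# between tools.

read_delim_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", basename(path),
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

check_monotone_time <- function(t, path) {
  bad <- which(diff(t) <= 0)
  if (length(bad)) {
    # +1 for the header line, +1 because the violation is at the next row
    stop(sprintf("%s: non-monotone timestamp at line %d", basename(path),
                 bad[1] + 2L), call. = FALSE)
  }
}

#' Read and write sock conductance recordings
#'
#' CSV schema: header `t,u0,u1,u2,u3,u4,u5`; time in seconds; conductances
#' nonnegative. Values round-trip losslessly (full double precision).
#'
#' @param path file path.
#' @param ... annotations passed to [conductance_series()] when reading
#'   (foot, participant, ...).
#' @return `read_conductance_csv()` returns a [conductance_series()];
#'   `write_conductance_csv()` returns `path` invisibly.
#' @export
read_conductance_csv <- function(path, ...) {
  df <- read_delim_checked(path, c("t", paste0("u", 0:5)))
  check_monotone_time(df$t, path)
  conductance_series(df$t, as.matrix(df[paste0("u", 0:5)]), ...)
}

#' @rdname read_conductance_csv
#' @param series a [conductance_series()].
#' @export
write_conductance_csv <- function(series, path) {
  if (!inherits(series, "conductance_series")) {
    stop("`series` must be a conductance_series", call. = FALSE)
  }
  df <- data.frame(t = series$time, series$values, check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write CoP series
#'
#' CSV schema: header `t,x,y,valid`; time in seconds, coordinates in mm,
#' `valid` 0/1. Invalid samples keep empty coordinates.
#'
#' @param path file path.
#' @param source source tag for the series read (`"sock"`, `"platform"`,
#'   `"truth"`).
#' @param ... further annotations passed to [cop_series()].
#' @return `read_cop_csv()` returns a [cop_series()];
#'   `write_cop_csv()` returns `path` invisibly.
#' @export
read_cop_csv <- function(path, source = "platform", ...) {
  df <- read_delim_checked(path, c("t", "x", "y", "valid"))
  check_monotone_time(df$t, path)
  cop_series(df$t, df$x, df$y, valid = df$valid != 0, source = source, ...)
}

#' @rdname read_cop_csv
#' @param series a [cop_series()].
#' @export
write_cop_csv <- function(series, path) {
  if (!inherits(series, "cop_series")) {
    stop("`series` must be a cop_series", call. = FALSE)
  }
  num <- function(v) ifelse(is.na(v), "",
                            format(v, digits = 17, trim = TRUE,
                                   scientific = FALSE))
  df <- data.frame(t = num(series$time), x = num(series$x),
                   y = num(series$y), valid = as.integer(series$valid))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated study to disk
#'
#' One sock CSV, one platform CSV and one ground-truth CSV per trial, plus
#' a JSON manifest recording the design, master seed and every per-trial
#' parameter draw. Deterministic: the same study object writes byte-identical
#' files.
#'
#' @param study a `cop_study` from [generate_study()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!inherits(study, "cop_study")) stop("`study` must be a cop_study", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(study$trials)) {
    tr <- study$trials[[i]]
    stem <- sprintf("trial%03d_%s_%s_%s_app%d", i, tr$participant,
                    tr$exercise, tr$foot, tr$application)
    write_conductance_csv(tr$sock, file.path(dir, paste0(stem, "_sock.csv")))
    write_cop_csv(tr$platform, file.path(dir, paste0(stem, "_platform.csv")))
    write_cop_csv(tr$truth, file.path(dir, paste0(stem, "_truth.csv")))
  }
  manifest <- list(
    seed = study$seed,
    design = list(participants = study$design$participants,
                  applications = study$design$applications,
                  conditions = study$design$conditions),
    pairs = study$manifest,
    trial_params = lapply(study$trials, function(tr) {
      list(participant = tr$participant, exercise = tr$exercise,
           foot = tr$foot, application = tr$application,
           lag = tr$params$lag, offset = tr$params$offset,
           foot_scale = tr$params$foot_scale, seed = tr$params$seed)
    })
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Strict schema: unknown keys are rejected (see [validate_config()]).
#'
#' @param path YAML file path.
#' @return A validated config list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}
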