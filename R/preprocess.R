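#' Detect lift calibration markers in a conductance recording
#'
#' At the start of each exercise set the participant lifts the instrumented
#' leg for about 3 s, unloading every sensor: total conductance drops to near
#' zero. This reference mark is used for synchronisation. A marker is a
#' maximal interval where the total conductance stays below
#' `rel_threshold` times its trial median, lasting at least `min_duration`.
#'
#' @param series a [conductance_series()].
#' @param rel_threshold fraction of the trial-median total conductance below
#'   which the foot counts as unloaded (default 0.1).
#' @param min_duration minimum marker duration in seconds (default 2).
#' @return A data frame with columns `start`, `end` (s), `kind` (`"lift"`)
#'   and `foot`; zero rows when no interval qualifies.
#' @export
detect_lift_marker <- function(series, rel_threshold = 0.1, min_duration = 2) {
  if (!inherits(series, "conductance_series")) {
    stop("`series` must be a conductance_series", call. = FALSE)
  }
  stop_if_not_scalar_number(rel_threshold, "rel_threshold", positive = TRUE)
  stop_if_not_scalar_number(min_duration, "min_duration", positive = TRUE)
  if (rel_threshold >= 1) stop("`rel_threshold` must be < 1", call. = FALSE)
  total <- rowSums(series$values)
  low <- total < rel_threshold * stats::median(total)
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(start = numeric(0), end = numeric(0),
                    kind = character(0), foot = character(0),
                    stringsAsFactors = FALSE)
  for (i in which(r$values)) {
    t0 <- series$time[starts[i]]
    t1 <- series$time[ends[i]]
    if (t1 - t0 >= min_duration) {
      out <- rbind(out, data.frame(start = t0, end = t1, kind = "lift",
                                   foot = series$foot,
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(out$start), , drop = FALSE]
}

#' Resample a CoP series onto a uniform grid
#'
#' Linear interpolation of the valid samples onto a uniform grid at `rate`,
#' spanning the valid input range only (never extrapolating). Gaps between
#' consecutive valid input samples longer than `max_gap` are not
#' interpolated across: output samples falling in such a gap are flagged
#' invalid with `NA` coordinates.
#'
#' @param series a [cop_series()].
#' @param rate target sampling rate (Hz); default 125, the force platform's
#'   native rate, so the slower instrument's information content bounds the
#'   common timeline.
#' @param max_gap longest invalid gap (s) that may be bridged by
#'   interpolation (default 0.2).
#' @return A [cop_series()] on a uniform grid.
#' @export
resample_cop <- function(series, rate = 125, max_gap = 0.2) {
  if (!inherits(series, "cop_series")) {
    stop("`series` must be a cop_series", call. = FALSE)
  }
  stop_if_not_scalar_number(rate, "rate", positive = TRUE)
  stop_if_not_scalar_number(max_gap, "max_gap", positive = TRUE)
  ok <- series$valid
  if (sum(ok) < 2L) stop("resampling needs at least 2 valid samples", call. = FALSE)
  vt <- series$time[ok]
  dt <- 1 / rate
  grid <- vt[1] + dt * seq.int(0L, floor((vt[length(vt)] - vt[1]) / dt))
  x <- stats::approx(vt, series$x[ok], xout = grid, ties = "ordered")$y
  y <- stats::approx(vt, series$y[ok], xout = grid, ties = "ordered")$y
  # flag outputs that fall inside an over-long gap between valid inputs
  iv <- findInterval(grid, vt, rightmost.closed = TRUE)
  iv[iv < 1L] <- 1L
  iv[iv >= length(vt)] <- length(vt) - 1L
  gap <- vt[iv + 1L] - vt[iv]
  bad <- gap > max_gap & grid > vt[iv] & grid < vt[iv + 1L]
  x[bad] <- NA_real_
  y[bad] <- NA_real_
  cop_series(grid, x, y, valid = !bad, source = series$source,
             participant = series$participant, exercise = series$exercise,
             repetition = series$repetition, foot = series$foot)
}

#' Mean-centre a CoP series
#'
#' Normalisation step for method comparison: each waveform is centred by
#' subtracting its own mean (computed over its valid samples, full
#' duration). This removes the platform's absolute foot-placement offset and
#' the sock's placement-dependent baseline, leaving the CoP excursion
#' pattern.
#'
#' @param series a [cop_series()].
#' @return The centred [cop_series()]; validity flags preserved.
#' @export
normalize_cop <- function(series) {
  if (!inherits(series, "cop_series")) {
    stop("`series` must be a cop_series", call. = FALSE)
  }
  ok <- series$valid
  if (!any(ok)) stop("no valid samples to centre", call. = FALSE)
  series$x <- series$x - mean(series$x[ok])
  series$y <- series$y - mean(series$y[ok])
  series
}

#' Paired, aligned, centred CoP waveforms for one axis
#'
#' Container produced by [align_cop()]: sock and platform CoP values of one
#' axis on a common uniform timeline, each mean-centred over the aligned
#' overlap. The subtracted means are retained so absolute-scale analyses
#' (e.g. baseline-shift inspection) can be reconstructed.
#'
#' @param time common timestamps (s), uniform grid, length >= 3.
#' @param sock,platform centred CoP values (mm).
#' @param axis `"x"` or `"y"`.
#' @param lag applied lag (s): how much the platform clock was shifted to
#'   match the sock clock.
#' @param mu_sock,mu_platform means removed from each series (mm).
#' @param cor_align Pearson correlation at the chosen lag (QC).
#' @param annotations named list (participant, exercise, repetition, foot).
#' @return An object of class `aligned_pair`.
#' @export
aligned_pair <- function(time, sock, platform, axis = c("x", "y"), lag = 0,
                         mu_sock = 0, mu_platform = 0, cor_align = NA_real_,
                         annotations = list()) {
  axis <- match.arg(axis)
  n <- length(time)
  if (n < 3L) stop("an aligned pair needs at least 3 samples", call. = FALSE)
  if (length(sock) != n || length(platform) != n) {
    stop("`sock` and `platform` must match `time` in length", call. = FALSE)
  }
  if (!is_uniform_grid(time)) {
    stop("aligned pair requires a uniform timeline", call. = FALSE)
  }
  if (abs(mean(sock)) > 1e-9 || abs(mean(platform)) > 1e-9) {
    stop("aligned pair series must be mean-centred (|mean| <= 1e-9 mm)",
         call. = FALSE)
  }
  structure(
    list(time = time, sock = sock, platform = platform, axis = axis,
         lag = lag, mu_sock = mu_sock, mu_platform = mu_platform,
         cor_align = cor_align, annotations = annotations),
    class = "aligned_pair"
  )
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf(
    "Aligned CoP pair, axis %s: n = %d, rate = %.6g Hz, lag = %.4g s (r = %.3f)\n",
    toupper(x$axis), length(x$time), 1 / diff(x$time[1:2]), x$lag, x$cor_align))
  invisible(x)
}

#' @export
plot.aligned_pair <- function(x, ...) {
  graphics::plot(x$time, x$platform, type = "l", col = "blue",
                 xlab = "time (s)", ylab = sprintf("CoP %s (mm, centred)", toupper(x$axis)),
                 main = sprintf("sock vs platform, lag %.3f s", x$lag), ...)
  graphics::lines(x$time, x$sock, col = "red")
  graphics::legend("topright", c("platform", "sock"), col = c("blue", "red"),
                   lty = 1, bty = "n")
  invisible(x)
}

# Pearson correlation of the overlap between s (on grid indices 1..ns) and
# p shifted by k samples, using samples valid in both; NA when overlap or
# variance is insufficient.
shifted_cor <- function(s, p, vs, vp, k, min_overlap) {
  ns <- length(s); np <- length(p)
  i0 <- max(1L, 1L + k)
  i1 <- min(ns, np + k)
  if (i1 - i0 + 1L < min_overlap) return(NA_real_)
  i <- i0:i1
  j <- i - k
  ok <- vs[i] & vp[j]
  if (sum(ok) < min_overlap) return(NA_real_)
  a <- s[i][ok]; b <- p[j][ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Time-align a sock/platform CoP pair
#'
#' The two instruments share one clock offset, estimated once and applied to
#' both axes. The lag is found by exhaustive search over integer-sample
#' shifts within `[-max_lag, +max_lag]`, maximising the Pearson correlation
#' of the mean-centred overlapping segments on the axis with the larger
#' platform variance (ties broken toward the smallest absolute lag). Both
#' series are then cropped to the aligned overlap, restricted to the largest
#' contiguous run valid in both, and mean-centred.
#'
#' @param sock,platform [cop_series()] objects resampled to the same rate
#'   (see [resample_cop()]).
#' @param max_lag search half-width in seconds (default 5).
#' @param min_overlap minimum usable overlap in samples (default 3).
#' @return A list with elements `x` and `y` ([aligned_pair()] per axis),
#'   `lag` (s) and `cor_align`.
#' @export
align_cop <- function(sock, platform, max_lag = 5, min_overlap = 3L) {
  if (!inherits(sock, "cop_series") || !inherits(platform, "cop_series")) {
    stop("`sock` and `platform` must be cop_series", call. = FALSE)
  }
  stop_if_not_scalar_number(max_lag, "max_lag", positive = TRUE)
  dts <- diff(sock$time[1:2]); dtp <- diff(platform$time[1:2])
  if (!is_uniform_grid(sock$time) || !is_uniform_grid(platform$time) ||
      abs(dts - dtp) > 1e-9 * dts) {
    stop("both series must be on uniform grids at the same rate; resample first",
         call. = FALSE)
  }
  dt <- dts
  # place the platform on the sock's grid phase: integer base offset plus
  # sub-sample snap (absorbed into the reported lag)
  base <- round((platform$time[1] - sock$time[1]) / dt)
  snap <- (platform$time[1] - sock$time[1]) - base * dt

  s <- list(x = sock$x, y = sock$y)
  p <- list(x = platform$x, y = platform$y)
  vs <- sock$valid; vp <- platform$valid
  # centre (valid samples) before correlation; cor() re-centres anyway but
  # this keeps the variance bookkeeping explicit
  varp <- vapply(p, function(v) stats::var(v[vp]), numeric(1))
  if (all(!is.finite(varp) | varp == 0)) {
    stop("flat signal, alignment undefined", call. = FALSE)
  }
  axis_ref <- names(which.max(varp))

  K <- as.integer(round(max_lag / dt))
  ks <- seq.int(-K, K)
  ks <- ks[order(abs(ks), ks)]  # smallest |lag| first -> ties resolve there
  cors <- vapply(ks, function(k) {
    shifted_cor(s[[axis_ref]], p[[axis_ref]], vs, vp, base - k, min_overlap)
  }, numeric(1))
  if (all(is.na(cors))) {
    stop("no admissible lag with sufficient overlap or variance", call. = FALSE)
  }
  best <- ks[which.max(cors)]
  cor_best <- max(cors, na.rm = TRUE)
  shift <- base - best

  ns <- length(vs); np <- length(vp)
  i0 <- max(1L, 1L + shift); i1 <- min(ns, np + shift)
  i <- i0:i1; j <- i - shift
  both <- vs[i] & vp[j]
  if (sum(both) < min_overlap) stop("aligned overlap too short", call. = FALSE)
  # largest contiguous both-valid run keeps the timeline uniform
  r <- rle(both)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  pick <- runs[which.max(r$lengths[runs])]
  sel <- starts[pick]:ends[pick]
  i <- i[sel]; j <- j[sel]
  if (length(i) < min_overlap) stop("aligned overlap too short", call. = FALSE)

  lag_applied <- best * dt + snap
  ann <- list(participant = sock$participant, exercise = sock$exercise,
              repetition = sock$repetition, foot = sock$foot)
  out <- list()
  for (axis in c("x", "y")) {
    sv <- s[[axis]][i]; pv <- p[[axis]][j]
    out[[axis]] <- aligned_pair(
      time = sock$time[i], sock = sv - mean(sv), platform = pv - mean(pv),
      axis = axis, lag = lag_applied, mu_sock = mean(sv),
      mu_platform = mean(pv), cor_align = cor_best, annotations = ann)
  }
  out$lag <- lag_applied
  out$cor_align <- cor_best
  out
}
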