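#' Sensor geometry of a six-sensor plantar pressure sock
#'
#' The six knitted pressure sensors sit in a sock-local coordinate frame:
#' X is mediolateral, Y is anteroposterior, both in millimetres. The default
#' layout places two sensors under the metatarsal heads, two under the
#' midfoot and two under the heel:
#' e0 = (50, 100), e1 = (-50, 100), e2 = (50, 0), e3 = (-50, 0),
#' e4 = (25, -100), e5 = (-25, -100). The centroid of the default layout is
#' the origin. Coordinates are relative: they encode the spatial relationship
#' between sensors, not absolute anatomical positions, so the reconstructed
#' centre of pressure (CoP) describes relative motion of the load.
#'
#' @param positions numeric 6 x 2 matrix of sensor positions (mm), rows
#'   ordered e0..e5, columns X (mediolateral) and Y (anteroposterior).
#'   Defaults to the layout above.
#' @param mirror logical; flip the X axis. The instrument convention is a
#'   common sign for both feet (positive X toward e0/e2/e4); set
#'   `mirror = TRUE` to express a left-foot recording in anatomical
#'   medial/lateral terms.
#' @return An object of class `sensor_geometry`: the position matrix with
#'   axis metadata.
#' @examples
#' g <- sensor_geometry()
#' g$positions["e0", ]   # c(50, 100)
#' @export
sensor_geometry <- function(positions = NULL, mirror = FALSE) {
  if (is.null(positions)) {
    positions <- rbind(
      e0 = c(50, 100),
      e1 = c(-50, 100),
      e2 = c(50, 0),
      e3 = c(-50, 0),
      e4 = c(25, -100),
      e5 = c(-25, -100)
    )
  }
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || nrow(positions) != 6L || ncol(positions) != 2L ||
      any(!is.finite(positions))) {
    stop("`positions` must be a finite numeric 6 x 2 matrix (mm)", call. = FALSE)
  }
  if (is.null(rownames(positions))) rownames(positions) <- paste0("e", 0:5)
  colnames(positions) <- c("x", "y")
  if (isTRUE(mirror)) positions[, "x"] <- -positions[, "x"]
  structure(
    list(positions = positions,
         axes = c(x = "mediolateral", y = "anteroposterior"),
         units = "mm"),
    class = "sensor_geometry"
  )
}

#' @export
print.sensor_geometry <- function(x, ...) {
  cat("Six-sensor sock geometry (mm; X mediolateral, Y anteroposterior)\n")
  print(x$positions)
  invisible(x)
}

# Ordered convex hull (counter-clockwise index vector) of the sensor layout.
geometry_hull <- function(geometry) {
  p <- geometry$positions
  grDevices::chull(p[, 1], p[, 2])
}

# Is each point of an n x 2 matrix inside (or on) the sensor convex hull?
in_sensor_hull <- function(points, geometry, tol = 1e-9) {
  points <- matrix(points, ncol = 2L)
  p <- geometry$positions
  h <- geometry_hull(geometry)
  v <- p[h, , drop = FALSE]
  k <- nrow(v)
  inside <- rep(TRUE, nrow(points))
  # chull() order may be either winding; normalise via the shoelace area sign.
  nxt <- c(seq_len(k)[-1], 1L)
  orient <- sign(sum(v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2]))
  for (i in seq_len(k)) {
    a <- v[i, ]; b <- v[nxt[i], ]
    cross <- (b[1] - a[1]) * (points[, 2] - a[2]) -
             (b[2] - a[2]) * (points[, 1] - a[1])
    inside <- inside & (orient * cross >= -tol * max(1, abs(b[1]) + abs(b[2])))
  }
  inside
}

#' Convert sensor resistances to conductances
#'
#' The acquisition unit records sensor electrical resistance in kilo-ohms;
#' the CoP computation works with conductance (its reciprocal, millisiemens
#' when the input is in kilo-ohms). Conductance rises with applied plantar
#' pressure in these knitted sensors.
#'
#' @param resistance numeric vector or matrix of resistances (kOhm), all
#'   strictly positive. A matrix is interpreted as samples x channels.
#' @param time optional numeric vector of timestamps (s). When supplied with
#'   a 6-column `resistance` matrix, a [conductance_series()] is returned.
#' @param ... passed to [conductance_series()] (foot, participant, ...).
#' @return Conductances (mS), same shape as `resistance`, or a
#'   `conductance_series` when `time` is given.
#' @export
resistance_to_conductance <- function(resistance, time = NULL, ...) {
  if (!is.numeric(resistance)) {
    stop("`resistance` must be numeric (kOhm)", call. = FALSE)
  }
  bad <- which(!is.finite(resistance) | resistance <= 0)
  if (length(bad)) {
    if (is.matrix(resistance)) {
      idx <- arrayInd(bad[1], dim(resistance))
      stop(sprintf(
        "nonpositive resistance at sample %d, channel %d (and %d more)",
        idx[1], idx[2], length(bad) - 1L), call. = FALSE)
    }
    stop(sprintf("nonpositive resistance at position %d (and %d more)",
                 bad[1], length(bad) - 1L), call. = FALSE)
  }
  u <- 1 / resistance
  if (is.null(time)) return(u)
  conductance_series(time, u, ...)
}

#' Six-channel conductance recording
#'
#' Container for one sock recording of a single trial: strictly increasing
#' timestamps and a samples x 6 matrix of nonnegative sensor conductances
#' (scale-free; nominally millisiemens). Annotations identify the trial.
#'
#' @param time numeric vector of timestamps (s), strictly increasing.
#' @param values numeric matrix, `length(time)` x 6, conductances >= 0.
#' @param foot `"left"` or `"right"`.
#' @param participant,exercise,repetition trial annotations (free-form).
#' @return An object of class `conductance_series`.
#' @export
conductance_series <- function(time, values, foot = c("right", "left"),
                               participant = NA, exercise = NA,
                               repetition = NA) {
  foot <- match.arg(foot)
  time <- as.numeric(time)
  values <- as.matrix(values)
  if (length(time) == 0L) stop("empty conductance series", call. = FALSE)
  if (ncol(values) != 6L) {
    stop(sprintf("conductance series must have 6 channels, got %d",
                 ncol(values)), call. = FALSE)
  }
  if (nrow(values) != length(time)) {
    stop("`time` and `values` lengths disagree", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop(sprintf("timestamps must be strictly increasing (first violation after t = %.6g s)",
                 time[which(diff(time) <= 0)[1]]), call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(values))
    stop(sprintf("negative or non-finite conductance at sample %d, channel u%d",
                 idx[1], idx[2] - 1L), call. = FALSE)
  }
  colnames(values) <- paste0("u", 0:5)
  structure(
    list(time = time, values = values, foot = foot,
         participant = participant, exercise = exercise,
         repetition = repetition),
    class = "conductance_series"
  )
}

#' @export
print.conductance_series <- function(x, ...) {
  cat(sprintf("Conductance series: %d samples, 6 channels, %.2f-%.2f s (%s foot)\n",
              length(x$time), min(x$time), max(x$time), x$foot))
  if (!is.na(x$participant)) {
    cat(sprintf("  participant %s, %s, repetition %s\n",
                x$participant, x$exercise, x$repetition))
  }
  invisible(x)
}

#' Centre-of-pressure time series
#'
#' CoP coordinates in the sock-local frame (mm), with a validity flag per
#' sample. Invalid samples (no foot contact: zero total load) are flagged,
#' never dropped, so downstream stages can see and handle the gaps.
#'
#' @param time numeric timestamps (s), strictly increasing.
#' @param x,y CoP coordinates (mm); may be `NA` where `valid` is `FALSE`.
#' @param valid logical vector; defaults to `TRUE` where `x` and `y` are
#'   finite.
#' @param source one of `"sock"`, `"platform"`, `"truth"`.
#' @param participant,exercise,repetition,foot optional annotations.
#' @return An object of class `cop_series`.
#' @export
cop_series <- function(time, x, y, valid = NULL,
                       source = c("sock", "platform", "truth"),
                       participant = NA, exercise = NA, repetition = NA,
                       foot = NA) {
  source <- match.arg(source)
  time <- as.numeric(time)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(time)
  if (n == 0L) stop("empty CoP series", call. = FALSE)
  if (length(x) != n || length(y) != n) {
    stop("`x`, `y` must match `time` in length", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (is.null(valid)) valid <- is.finite(x) & is.finite(y)
  valid <- as.logical(valid)
  if (length(valid) != n) stop("`valid` must match `time` in length", call. = FALSE)
  if (any(valid & (!is.finite(x) | !is.finite(y)))) {
    stop("valid samples must have finite coordinates", call. = FALSE)
  }
  structure(
    list(time = time, x = x, y = y, valid = valid, source = source,
         participant = participant, exercise = exercise,
         repetition = repetition, foot = foot),
    class = "cop_series"
  )
}

#' @export
print.cop_series <- function(x, ...) {
  cat(sprintf("CoP series [%s]: %d samples (%d valid), %.2f-%.2f s\n",
              x$source, length(x$time), sum(x$valid), min(x$time), max(x$time)))
  if (any(x$valid)) {
    cat(sprintf("  X range %.1f to %.1f mm, Y range %.1f to %.1f mm\n",
                min(x$x[x$valid]), max(x$x[x$valid]),
                min(x$y[x$valid]), max(x$y[x$valid])))
  }
  invisible(x)
}

#' @export
plot.cop_series <- function(x, type = c("time", "trajectory"), ...) {
  type <- match.arg(type)
  ok <- x$valid
  if (type == "trajectory") {
    graphics::plot(x$x[ok], x$y[ok], type = "l", asp = 1,
                   xlab = "CoP X (mm, mediolateral)",
                   ylab = "CoP Y (mm, anteroposterior)",
                   main = sprintf("CoP trajectory [%s]", x$source), ...)
  } else {
    old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(old))
    graphics::plot(x$time[ok], x$x[ok], type = "l", xlab = "time (s)",
                   ylab = "CoP X (mm)", main = sprintf("[%s]", x$source), ...)
    graphics::plot(x$time[ok], x$y[ok], type = "l", xlab = "time (s)",
                   ylab = "CoP Y (mm)", ...)
  }
  invisible(x)
}

# Vectorised CoP reconstruction: values is n x 6 nonnegative, returns
# list(x, y, valid). Zero-total frames are flagged invalid (no contact).
cop_from_conductance <- function(values, geometry) {
  p <- geometry$positions
  s <- rowSums(values)
  valid <- s > 0
  x <- as.numeric(values %*% p[, 1])
  y <- as.numeric(values %*% p[, 2])
  x <- ifelse(valid, x / s, NA_real_)
  y <- ifelse(valid, y / s, NA_real_)
  list(x = x, y = y, valid = valid)
}

#' Centre of pressure of a single conductance frame
#'
#' The CoP is the conductance-weighted mean of the sensor position vectors:
#' `CoP = sum(U_i * e_i) / sum(U_i)`, with conductance `U_i` proportional to
#' the pressure on sensor `i`. The result is in millimetres, lies in the
#' convex hull of the sensor positions, and is invariant to rescaling all
#' conductances by a common factor (so the conductance unit never matters).
#'
#' @param u numeric vector of 6 nonnegative conductances.
#' @param geometry a [sensor_geometry()].
#' @return Named numeric `c(x, y)` in mm with attribute `valid`. A frame with
#'   zero total conductance (no contact) returns `c(NA, NA)` with
#'   `valid = FALSE` rather than an error, so series-level processing can
#'   flag and continue.
#' @examples
#' compute_cop(rep(1, 6))              # centroid (0, 0)
#' compute_cop(c(1, 0, 0, 0, 0, 0))    # sensor e0 at (50, 100)
#' @export
compute_cop <- function(u, geometry = sensor_geometry()) {
  if (!inherits(geometry, "sensor_geometry")) {
    stop("`geometry` must be a sensor_geometry", call. = FALSE)
  }
  u <- as.numeric(u)
  if (length(u) != 6L) stop("a conductance frame has 6 channels", call. = FALSE)
  neg <- which(!is.finite(u) | u < 0)
  if (length(neg)) {
    stop(sprintf("negative or non-finite conductance on channel u%d", neg[1] - 1L),
         call. = FALSE)
  }
  r <- cop_from_conductance(matrix(u, nrow = 1L), geometry)
  structure(c(x = r$x, y = r$y), valid = r$valid)
}

#' Reconstruct a CoP waveform from a conductance recording
#'
#' Applies the weighted vector summation frame by frame. Frames with zero
#' total conductance (swing phase / no contact) yield flagged-invalid
#' samples; annotations are carried over and the result is tagged
#' `source = "sock"`.
#'
#' @param series a [conductance_series()].
#' @param geometry a [sensor_geometry()].
#' @return A [cop_series()] with `source = "sock"`.
#' @export
sock_cop <- function(series, geometry = sensor_geometry()) {
  if (!inherits(series, "conductance_series")) {
    stop("`series` must be a conductance_series", call. = FALSE)
  }
  r <- cop_from_conductance(series$values, geometry)
  cop_series(series$time, r$x, r$y, valid = r$valid, source = "sock",
             participant = series$participant, exercise = series$exercise,
             repetition = series$repetition, foot = series$foot)
}
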