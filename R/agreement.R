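#' Root-mean-square error between paired CoP waveforms
#'
#' Absolute RMSE of the per-sample difference (sock minus platform), plus a
#' relative RMSE expressed as a fraction of the reference waveform's
#' inter-quantile span `delta_q`. Because both waveforms are mean-centred
#' during preprocessing, a mean-based relative error would be degenerate;
#' the quantile span of the reference instrument's waveform is used instead.
#'
#' @param pair an [aligned_pair()], or a numeric sock vector (with
#'   `platform` supplied).
#' @param platform numeric platform values when `pair` is numeric.
#' @param quantiles low/high probabilities of the span (default
#'   `c(0.025, 0.975)`).
#' @param reference which waveform provides `delta_q`: `"platform"` (the
#'   reference instrument, default) or `"sock"`.
#' @return A list of class `rmse_result`: `rmse_abs` (mm), `delta_q` (mm),
#'   `rmse_rel` (fraction; `NA` with `degenerate = TRUE` when
#'   `delta_q == 0`), `quantile_pair`, `n`.
#' @export
cop_rmse <- function(pair, platform = NULL, quantiles = c(0.025, 0.975),
                     reference = c("platform", "sock")) {
  reference <- match.arg(reference)
  if (inherits(pair, "aligned_pair")) {
    s <- pair$sock; p <- pair$platform
  } else {
    s <- as.numeric(pair); p <- as.numeric(platform)
  }
  if (length(s) != length(p) || length(s) < 2L) {
    stop("RMSE needs two equal-length series with N >= 2", call. = FALSE)
  }
  if (!is.numeric(quantiles) || length(quantiles) != 2L ||
      any(quantiles < 0 | quantiles > 1) || quantiles[1] >= quantiles[2]) {
    stop("`quantiles` must be increasing probabilities in [0, 1]", call. = FALSE)
  }
  d <- s - p
  rmse_abs <- sqrt(mean(d^2))
  ref <- if (reference == "platform") p else s
  q <- stats::quantile(ref, quantiles, names = FALSE)
  delta_q <- q[2] - q[1]
  degenerate <- delta_q <= 0
  structure(
    list(rmse_abs = rmse_abs,
         delta_q = delta_q,
         rmse_rel = if (degenerate) NA_real_ else rmse_abs / delta_q,
         quantile_pair = quantiles,
         reference = reference,
         degenerate = degenerate,
         n = length(d)),
    class = "rmse_result"
  )
}

#' @export
print.rmse_result <- function(x, ...) {
  cat(sprintf("RMSE: %.3f mm absolute; %s of the %.1f%%-%.1f%% span (%.2f mm) of the %s waveform\n",
              x$rmse_abs,
              if (x$degenerate) "relative form undefined (zero span)"
              else sprintf("%.1f%%", 100 * x$rmse_rel),
              100 * x$quantile_pair[1], 100 * x$quantile_pair[2],
              x$delta_q, x$reference))
  invisible(x)
}

#' Bland-Altman limits of agreement
#'
#' For each time point the difference `d = sock - platform` is formed; the
#' bias is `mean(d)`, and at confidence level 0.95 the limits of agreement
#' are `bias +/- 1.96 * S(d)` with `S(d)` the sample standard deviation of
#' the differences. About 95% of differences are expected inside the limits
#' when the differences are approximately normal.
#'
#' @inheritParams cop_rmse
#' @param alpha confidence level (default 0.95; the conventional 1.96
#'   multiplier is used at 0.95, the matching normal quantile otherwise).
#' @return A list of class `bland_altman_result`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high` (mm), `frac_outside`, `alpha`, `n`.
#' @export
bland_altman <- function(pair, platform = NULL, alpha = 0.95) {
  if (inherits(pair, "aligned_pair")) {
    s <- pair$sock; p <- pair$platform
  } else {
    s <- as.numeric(pair); p <- as.numeric(platform)
  }
  if (length(s) != length(p) || length(s) < 3L) {
    stop("Bland-Altman needs two equal-length series with N >= 3", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a confidence level in (0, 1)", call. = FALSE)
  }
  z <- if (isTRUE(all.equal(alpha, 0.95))) 1.96 else stats::qnorm(1 - (1 - alpha) / 2)
  d <- s - p
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa <- bias + c(-1, 1) * z * sd_diff
  structure(
    list(bias = bias, sd_diff = sd_diff, loa_low = loa[1], loa_high = loa[2],
         frac_outside = mean(d < loa[1] | d > loa[2]),
         alpha = alpha, z = z, n = length(d)),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f mm, S(d) %.3f mm, LoA [%.3f, %.3f] mm (alpha = %.2f)\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high, x$alpha))
  cat(sprintf("  %.2f%% of %d differences outside the limits\n",
              100 * x$frac_outside, x$n))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement with the identity line, not mere correlation:
#' `CCC = rho * chi` where `rho` is the Pearson correlation (precision) and
#' `chi = 2 / (v^2 + omega + 1/omega)` is the accuracy coefficient built
#' from the squared location shift `v^2 = (mu_s - mu_p)^2 / (s_s * s_p)`
#' and the scale shift `omega = s_s / s_p`. Standard deviations use the
#' sample (N-1) convention. `|CCC| <= |rho|`, with equality exactly when
#' the means and scales agree.
#'
#' @param pair an [aligned_pair()] or a numeric sock vector.
#' @param platform numeric platform values when `pair` is numeric.
#' @param raw logical; for an `aligned_pair`, add the stored means back and
#'   compute the CCC on absolute values (used for baseline-shift analyses).
#'   Centred values (the default) match the standard pipeline.
#' @return A list of class `ccc_result` with `ccc`, `rho`, `v2`, `omega`,
#'   `chi`, the moments `mu_s`, `mu_p`, `s_s`, `s_p`, and `n`.
#' @examples
#' lin_ccc(c(-1, 0, 1), c(-2, 0, 2))$ccc   # 0.8: scale shift penalised
#' @export
lin_ccc <- function(pair, platform = NULL, raw = FALSE) {
  if (inherits(pair, "aligned_pair")) {
    s <- pair$sock; p <- pair$platform
    if (isTRUE(raw)) {
      s <- s + pair$mu_sock
      p <- p + pair$mu_platform
    }
  } else {
    s <- as.numeric(pair); p <- as.numeric(platform)
  }
  n <- length(s)
  if (length(p) != n || n < 3L) {
    stop("CCC needs two equal-length series with N >= 3", call. = FALSE)
  }
  s_s <- stats::sd(s); s_p <- stats::sd(p)
  if (s_s == 0 || s_p == 0) {
    stop("CCC undefined for flat signal", call. = FALSE)
  }
  mu_s <- mean(s); mu_p <- mean(p)
  rho <- stats::cor(s, p)
  v2 <- (mu_s - mu_p)^2 / (s_s * s_p)
  omega <- s_s / s_p
  chi <- 2 / (v2 + omega + 1 / omega)
  ccc <- rho * chi
  # guard against floating-point excursions beyond the theoretical range
  ccc <- max(-1, min(1, ccc))
  structure(
    list(ccc = ccc, rho = rho, v2 = v2, omega = omega, chi = chi,
         mu_s = mu_s, mu_p = mu_p, s_s = s_s, s_p = s_p, n = n),
    class = "ccc_result"
  )
}

#' @export
print.ccc_result <- function(x, ...) {
  cat(sprintf("Lin's CCC = %.4f  (rho = %.4f, chi = %.4f; v^2 = %.4g, omega = %.4g, n = %d)\n",
              x$ccc, x$rho, x$chi, x$v2, x$omega, x$n))
  invisible(x)
}

#' Fisher-transform confidence interval for the CCC
#'
#' `lambda = atanh(CCC)` is treated as approximately normal with variance
#' \deqn{\sigma_\lambda^2 = \frac{1}{n-2}\left[
#'   \frac{(1-\rho^2)\,CCC^2}{(1-CCC^2)\,\rho^2}
#'   + \frac{2\,CCC^3 (1-CCC)\, v^2}{\rho\,(1-CCC^2)^2}
#'   - \frac{CCC^4 v^4}{2 \rho^2 (1-CCC^2)^2} \right]}{
#'   var = (1/(n-2)) [ (1-rho^2) CCC^2 / ((1-CCC^2) rho^2)
#'   + 2 CCC^3 (1-CCC) v^2 / (rho (1-CCC^2)^2)
#'   - CCC^4 v^4 / (2 rho^2 (1-CCC^2)^2) ]}
#' and the interval is `tanh(lambda -/+ z * sigma)`. For mean-centred
#' waveforms (`v = 0`) with equal scales the variance collapses to
#' `1/(n-2)`.
#'
#' @param result a `ccc_result` from [lin_ccc()].
#' @param alpha significance level (default 0.05, `z = 1.96`).
#' @return A list of class `ccc_ci`: `ci_low`, `ci_high`, `lambda`,
#'   `var_lambda`, `alpha`, and a `degenerate` flag. `|CCC| = 1` yields the
#'   degenerate interval `(CCC, CCC)`; `rho = 0` yields an undefined
#'   (all-`NA`) interval with the flag set.
#' @export
ccc_confidence_interval <- function(result, alpha = 0.05) {
  if (!inherits(result, "ccc_result")) {
    stop("`result` must come from lin_ccc()", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  n <- result$n
  if (n <= 2L) stop("CCC confidence interval needs n > 2", call. = FALSE)
  ccc <- result$ccc; rho <- result$rho; v2 <- result$v2
  if (abs(ccc) >= 1) {
    return(structure(list(ci_low = ccc, ci_high = ccc, lambda = Inf * sign(ccc),
                          var_lambda = 0, alpha = alpha, degenerate = TRUE),
                     class = "ccc_ci"))
  }
  if (rho == 0) {
    return(structure(list(ci_low = NA_real_, ci_high = NA_real_,
                          lambda = NA_real_, var_lambda = NA_real_,
                          alpha = alpha, degenerate = TRUE),
                     class = "ccc_ci"))
  }
  z <- if (isTRUE(all.equal(alpha, 0.05))) 1.96 else stats::qnorm(1 - alpha / 2)
  lambda <- atanh(ccc)
  one_m <- 1 - ccc^2
  var_lambda <- (1 / (n - 2)) * (
    (1 - rho^2) * ccc^2 / (one_m * rho^2) +
    2 * ccc^3 * (1 - ccc) * v2 / (rho * one_m^2) -
    ccc^4 * v2^2 / (2 * rho^2 * one_m^2)
  )
  half <- z * sqrt(var_lambda)
  structure(
    list(ci_low = tanh(lambda - half), ci_high = tanh(lambda + half),
         lambda = lambda, var_lambda = var_lambda, alpha = alpha,
         degenerate = FALSE),
    class = "ccc_ci"
  )
}

#' @export
print.ccc_ci <- function(x, ...) {
  if (x$degenerate && is.na(x$ci_low)) {
    cat("CCC confidence interval undefined (rho = 0)\n")
  } else {
    cat(sprintf("CCC %d%% CI: [%.4f, %.4f]%s\n", round(100 * (1 - x$alpha)),
                x$ci_low, x$ci_high,
                if (x$degenerate) " (degenerate)" else ""))
  }
  invisible(x)
}

#' Classify a concordance coefficient
#'
#' Two complementary vocabularies: the strict scheme judges whether the
#' wearable could replace the reference instrument for absolute CoP
#' measurement (>= 0.99 "almost perfect", 0.95-0.99 "substantial",
#' 0.90-0.95 "moderate", below 0.90 "poor"); the loose,
#' correlation-oriented scheme judges its use for tracking relative CoP
#' changes (>= 0.80 "high", 0.60-0.80 "moderate", 0.40-0.60 "fair", below
#' 0.40 "poor"). Lower bounds are inclusive.
#'
#' @param ccc concordance value(s) in `[-1, 1]`.
#' @param scheme `"strict"` or `"loose"`.
#' @return Character vector of labels.
#' @export
classify_concordance <- function(ccc, scheme = c("strict", "loose")) {
  scheme <- match.arg(scheme)
  ccc_num <- if (inherits(ccc, "ccc_result")) ccc$ccc else as.numeric(ccc)
  if (any(!is.finite(ccc_num) | ccc_num < -1 | ccc_num > 1)) {
    stop("`ccc` values must lie in [-1, 1]", call. = FALSE)
  }
  if (scheme == "strict") {
    breaks <- c(-Inf, 0.90, 0.95, 0.99, Inf)
    labels <- c("poor", "moderate", "substantial", "almost perfect")
  } else {
    breaks <- c(-Inf, 0.40, 0.60, 0.80, Inf)
    labels <- c("poor", "fair", "moderate", "high")
  }
  as.character(cut(ccc_num, breaks = breaks, labels = labels, right = FALSE))
}

#' Per-segment CCC of an aligned pair
#'
#' Splits the pair at the given break times, re-centres each segment
#' independently, and computes the CCC within each. Used to separate a
#' baseline shift (e.g. a side-step changing foot placement on the
#' platform) from waveform-tracking performance: a mid-trial shift ruins
#' the whole-waveform CCC but leaves the within-segment CCC high when the
#' wearable tracks relative CoP changes well.
#'
#' @param pair an [aligned_pair()].
#' @param breaks numeric break times (s) interior to the pair's time range.
#' @return A data frame with `start`, `end`, `n`, `ccc` per segment.
#' @export
ccc_by_segment <- function(pair, breaks) {
  if (!inherits(pair, "aligned_pair")) {
    stop("`pair` must be an aligned_pair", call. = FALSE)
  }
  t <- pair$time
  edges <- c(t[1], sort(as.numeric(breaks)), t[length(t)] + 1e-9)
  out <- data.frame(start = numeric(0), end = numeric(0), n = integer(0),
                    ccc = numeric(0))
  for (k in seq_len(length(edges) - 1L)) {
    sel <- t >= edges[k] & t < edges[k + 1L]
    if (sum(sel) < 3L) next
    s <- pair$sock[sel]; p <- pair$platform[sel]
    cc <- lin_ccc(s - mean(s), p - mean(p))$ccc
    out <- rbind(out, data.frame(start = min(t[sel]), end = max(t[sel]),
                                 n = sum(sel), ccc = cc))
  }
  if (nrow(out) == 0L) stop("no segment has at least 3 samples", call. = FALSE)
  out
}

#' Fit the full agreement analysis for one waveform pair
#'
#' The central per-pair "fit": given an aligned, centred sock/platform CoP
#' waveform pair, computes the RMSE (absolute and quantile-span relative),
#' the Bland-Altman bias and limits of agreement, Lin's CCC with its
#' Fisher-transform confidence interval, and the strict and loose
#' concordance classifications.
#'
#' @param pair an [aligned_pair()].
#' @param quantiles probabilities of the relative-RMSE span (default
#'   `c(0.025, 0.975)`).
#' @param reference waveform providing the span (default `"platform"`).
#' @param alpha_loa confidence level of the limits of agreement (0.95).
#' @param alpha_ci significance level of the CCC interval (0.05).
#' @return An object of class `cop_agreement` bundling the component
#'   results with the pair's annotations; see [as.data.frame.cop_agreement()]
#'   for the flat one-row form.
#' @export
cop_agreement <- function(pair, quantiles = c(0.025, 0.975),
                          reference = c("platform", "sock"),
                          alpha_loa = 0.95, alpha_ci = 0.05) {
  if (!inherits(pair, "aligned_pair")) {
    stop("`pair` must be an aligned_pair (see align_cop())", call. = FALSE)
  }
  reference <- match.arg(reference)
  rmse <- cop_rmse(pair, quantiles = quantiles, reference = reference)
  ba <- bland_altman(pair, alpha = alpha_loa)
  ccc <- lin_ccc(pair)
  ci <- ccc_confidence_interval(ccc, alpha = alpha_ci)
  structure(
    list(rmse = rmse, bland_altman = ba, ccc = ccc, ci = ci,
         class_strict = classify_concordance(ccc$ccc, "strict"),
         class_loose = classify_concordance(ccc$ccc, "loose"),
         n = ccc$n, axis = pair$axis, lag = pair$lag,
         annotations = pair$annotations),
    class = "cop_agreement"
  )
}

#' @export
print.cop_agreement <- function(x, ...) {
  a <- x$annotations
  hdr <- sprintf("Agreement, CoP %s", toupper(x$axis))
  if (!is.null(a$participant) && !is.na(a$participant)) {
    hdr <- sprintf("%s (participant %s, %s, application %s, %s foot)",
                   hdr, a$participant, a$exercise, a$repetition, a$foot)
  }
  cat(hdr, "\n")
  cat(sprintf("  n = %d samples, applied lag %.3f s\n", x$n, x$lag))
  print(x$rmse)
  print(x$bland_altman)
  print(x$ccc)
  print(x$ci)
  cat(sprintf("  classification: %s (strict), %s (loose)\n",
              x$class_strict, x$class_loose))
  invisible(x)
}

#' @export
summary.cop_agreement <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @rdname cop_agreement
#' @param x a `cop_agreement` object.
#' @param row.names,optional,... standard [as.data.frame()] arguments
#'   (ignored).
#' @export
as.data.frame.cop_agreement <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  a <- x$annotations
  data.frame(
    participant = a$participant %||% NA,
    exercise = a$exercise %||% NA,
    repetition = a$repetition %||% NA,
    foot = a$foot %||% NA,
    axis = x$axis,
    n = x$n,
    lag_s = x$lag,
    rmse_abs_mm = x$rmse$rmse_abs,
    rmse_rel = x$rmse$rmse_rel,
    delta_q_mm = x$rmse$delta_q,
    bias_mm = x$bland_altman$bias,
    loa_low_mm = x$bland_altman$loa_low,
    loa_high_mm = x$bland_altman$loa_high,
    frac_outside = x$bland_altman$frac_outside,
    ccc = x$ccc$ccc,
    rho = x$ccc$rho,
    ccc_ci_low = x$ci$ci_low,
    ccc_ci_high = x$ci$ci_high,
    class_strict = x$class_strict,
    class_loose = x$class_loose,
    stringsAsFactors = FALSE
  )
}

#' @export
plot.cop_agreement <- function(x, pair = NULL, ...) {
  if (is.null(pair)) {
    stop("supply the aligned_pair the fit came from: plot(fit, pair)",
         call. = FALSE)
  }
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old))
  lim <- range(pair$sock, pair$platform)
  graphics::plot(pair$platform, pair$sock, pch = 16, cex = 0.4, asp = 1,
                 xlim = lim, ylim = lim,
                 xlab = "platform CoP (mm, centred)",
                 ylab = "sock CoP (mm, centred)",
                 main = sprintf("CoP %s: CCC = %.2f", toupper(x$axis), x$ccc$ccc))
  graphics::abline(0, 1, col = "grey40")
  m <- (pair$sock + pair$platform) / 2
  d <- pair$sock - pair$platform
  graphics::plot(m, d, pch = 16, cex = 0.4,
                 xlab = "mean of methods (mm)",
                 ylab = "difference sock - platform (mm)",
                 main = "Bland-Altman")
  graphics::abline(h = x$bland_altman$bias, col = "blue")
  graphics::abline(h = c(x$bland_altman$loa_low, x$bland_altman$loa_high),
                   col = "red", lty = 2)
  invisible(x)
}

#' Summarise a table of agreement records
#'
#' Aggregates per-pair metrics the way a validation study reports them:
#' counts and fractions of pairs with CCC at or above 0.90 (acceptable
#' absolute agreement), at or above 0.60 (moderate-or-better correlation)
#' and below 0.40 (poor), plus CCC and RMSE ranges, per axis and overall.
#'
#' @param metrics a data frame with at least columns `ccc`, `rmse_abs_mm`
#'   and `axis` (as produced by [run_pipeline()] or by row-binding
#'   [as.data.frame.cop_agreement()] outputs).
#' @return A data frame, one row per axis plus an `"overall"` row.
#' @export
summarize_agreement <- function(metrics) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0L) {
    stop("`metrics` must be a nonempty data frame", call. = FALSE)
  }
  need <- c("ccc", "rmse_abs_mm", "axis")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) {
    stop("`metrics` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  one <- function(df, label) {
    data.frame(
      group = label,
      n = nrow(df),
      n_ccc_ge_090 = sum(df$ccc >= 0.90),
      frac_ccc_ge_090 = mean(df$ccc >= 0.90),
      n_ccc_ge_060 = sum(df$ccc >= 0.60),
      frac_ccc_ge_060 = mean(df$ccc >= 0.60),
      n_ccc_lt_040 = sum(df$ccc < 0.40),
      frac_ccc_lt_040 = mean(df$ccc < 0.40),
      ccc_min = min(df$ccc), ccc_max = max(df$ccc),
      rmse_min_mm = min(df$rmse_abs_mm), rmse_max_mm = max(df$rmse_abs_mm),
      stringsAsFactors = FALSE
    )
  }
  parts <- lapply(split(metrics, metrics$axis), function(df) {
    one(df, unique(df$axis))
  })
  out <- do.call(rbind, c(parts, list(one(metrics, "overall"))))
  rownames(out) <- NULL
  out
}
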