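#' Plate-reader growth curve
#'
#' Time series of optical density (and optionally fluorescence) readings at
#' a fixed sampling interval, as produced by a shaking plate reader.
#'
#' @param time_min times in minutes, strictly increasing, >= 5 points.
#' @param od optical density readings (blank not yet subtracted).
#' @param fluorescence optional fluorescence readings (arbitrary units).
#' @return An object of class `growth_curve` (a data.frame).
#' @export
growth_curve <- function(time_min, od, fluorescence = NULL) {
  stopifnot(length(time_min) >= 5, all(diff(time_min) > 0),
            length(od) == length(time_min))
  df <- data.frame(time_min = time_min, od = od)
  if (!is.null(fluorescence)) {
    stopifnot(length(fluorescence) == length(time_min))
    df$fluorescence <- fluorescence
  }
  class(df) <- c("growth_curve", "data.frame")
  df
}

#' Read and write growth curves as CSV
#'
#' Columns `time_min`, `od` and optionally `fluorescence`.
#'
#' @param curve a [growth_curve()].
#' @param path file path.
#' @return `write_growth_curve()` returns `path` invisibly;
#'   `read_growth_curve()` a [growth_curve()].
#' @export
write_growth_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_growth_curve
#' @export
read_growth_curve <- function(path) {
  df <- utils::read.csv(path)
  growth_curve(df$time_min, df$od, df$fluorescence)
}

# blank subtraction: minimum of the first `n` readings (or explicit value)
subtract_blank <- function(od, blank = "auto", n = 5) {
  if (identical(blank, "none")) return(od)
  b <- if (identical(blank, "auto")) min(od[seq_len(min(n, length(od)))])
       else blank
  od - b
}

#' Maximum specific growth rate from a plate-reader curve
#'
#' Per-interval specific rates are discrete differences of log OD,
#' `diff(log(od)) / diff(t)`; the reported rate averages the intervals whose
#' midpoints fall within `half_window` minutes of the maximum. Readings at
#' or below `od_floor` (after blank subtraction) are excluded — below it the
#' reader signal is dominated by background. The log (specific) form is
#' used so the rate has units of min^-1, as the fluorescence-based
#' copy-number relation requires.
#'
#' @param curve a [growth_curve()].
#' @param half_window window half-width in minutes (default 6).
#' @param od_floor minimum usable OD after blank subtraction (default 0.01).
#' @param blank `"auto"` (minimum of the first 5 readings), `"none"`, or a
#'   numeric blank value.
#' @return A list with `mu_max` (min^-1), `t_max` (minutes, midpoint of the
#'   fastest interval) and `window_idx` (indices of the averaged
#'   intervals). `mu_max` is `NA` when no interval clears the floor.
#' @export
max_growth_rate <- function(curve, half_window = 6, od_floor = 0.01,
                            blank = "auto") {
  stopifnot(inherits(curve, "growth_curve"))
  od <- subtract_blank(curve$od, blank)
  t <- curve$time_min
  ok <- od > od_floor
  use <- ok[-1] & ok[-length(ok)]
  if (!any(use))
    return(list(mu_max = NA_real_, t_max = NA_real_, window_idx = integer()))
  rates <- diff(log(od)) / diff(t)
  mids <- (t[-1] + t[-length(t)]) / 2
  rates[!use] <- NA
  imax <- which.max(rates)
  win <- which(abs(mids - mids[imax]) <= half_window & !is.na(rates))
  list(mu_max = mean(rates[win]), t_max = mids[imax], window_idx = win)
}

#' Expression level at maximal growth
#'
#' The fluorescence-per-OD signal at the point of maximal growth rate: the
#' mean fluorescence over the same +/- `half_window` minutes used for the
#' growth rate, divided by the mean OD over that window.
#'
#' @inheritParams max_growth_rate
#' @return `G`, fluorescence per OD unit at maximal growth (`NA` if the
#'   curve has no fluorescence channel or no usable window).
#' @export
expression_level <- function(curve, half_window = 6, od_floor = 0.01,
                             blank = "auto") {
  stopifnot(inherits(curve, "growth_curve"))
  if (is.null(curve$fluorescence)) return(NA_real_)
  mg <- max_growth_rate(curve, half_window, od_floor, blank)
  if (!is.finite(mg$mu_max)) return(NA_real_)
  od <- subtract_blank(curve$od, blank)
  # window indices refer to intervals; take both endpoints of each
  idx <- sort(unique(c(mg$window_idx, mg$window_idx + 1L)))
  mean(curve$fluorescence[idx]) / mean(od[idx])
}

#' Copy number from fluorescence, growth rate and a calibration constant
#'
#' In exponential phase the steady-state fluorescence-per-OD signal of a
#' plasmid-encoded reporter scales as copy number over growth rate, so
#' \eqn{P = G \mu / k}. `fit_k()` estimates the constant from anchor
#' constructs whose copy number was measured by droplet PCR (typically the
#' two induction endpoints), by least squares of \eqn{G\mu} on \eqn{P}
#' through the origin.
#'
#' @param G fluorescence per OD from [expression_level()].
#' @param mu growth rate (min^-1).
#' @param k calibration constant (> 0).
#' @return `pcn_from_fluorescence()`: plasmids per genome.
#' @export
pcn_from_fluorescence <- function(G, mu, k) {
  stopifnot(all(k > 0), all(mu > 0))
  G * mu / k
}

#' @rdname pcn_from_fluorescence
#' @param anchors data.frame with columns `G`, `mu` and `pcn` (droplet-PCR
#'   plasmids per genome), >= 1 row.
#' @return `fit_k()`: the fitted constant `k`.
#' @export
fit_k <- function(anchors) {
  stopifnot(is.data.frame(anchors),
            all(c("G", "mu", "pcn") %in% names(anchors)), nrow(anchors) >= 1)
  y <- anchors$G * anchors$mu
  sum(y * anchors$pcn) / sum(anchors$pcn^2)
}

#' Digital droplet PCR run
#'
#' Classified droplet counts for the two channels of a copy-number ddPCR:
#' the plasmid target (e.g. the plasmid-borne `bla` gene) and the
#' single-copy genomic reference (e.g. `dxs`).
#'
#' @param positives_target,total_target positive / total droplets, target
#'   channel.
#' @param positives_ref,total_ref positive / total droplets, reference
#'   channel.
#' @return An object of class `ddpcr_run`.
#' @export
ddpcr_run <- function(positives_target, total_target,
                      positives_ref, total_ref) {
  stopifnot(total_target >= 1, total_ref >= 1,
            positives_target >= 0, positives_target <= total_target,
            positives_ref >= 0, positives_ref <= total_ref)
  structure(list(positives_target = positives_target,
                 total_target = total_target,
                 positives_ref = positives_ref, total_ref = total_ref),
            class = "ddpcr_run")
}

#' Read and write ddPCR runs as CSV
#'
#' One row per sample with the four droplet-count columns.
#'
#' @param runs a [ddpcr_run()] or list of them.
#' @param path file path.
#' @return `write_ddpcr_runs()` returns `path` invisibly;
#'   `read_ddpcr_runs()` a list of [ddpcr_run()] objects.
#' @export
write_ddpcr_runs <- function(runs, path) {
  if (inherits(runs, "ddpcr_run")) runs <- list(runs)
  df <- do.call(rbind, lapply(runs, function(r)
    data.frame(positives_target = r$positives_target,
               total_target = r$total_target,
               positives_ref = r$positives_ref, total_ref = r$total_ref)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ddpcr_runs
#' @export
read_ddpcr_runs <- function(path) {
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(i)
    ddpcr_run(df$positives_target[i], df$total_target[i],
              df$positives_ref[i], df$total_ref[i]))
}

#' Poisson concentration and copy-number ratio from a ddPCR run
#'
#' Droplet partitioning is Poisson, so the mean template occupancy per
#' droplet is \eqn{\lambda = -\ln(1 - p)} with `p` the positive-droplet
#' fraction; the plasmid copy number per genome is the ratio of the target
#' and reference occupancies. The 95% confidence interval propagates the
#' binomial error on each positive fraction through the log transform and
#' into the ratio by the delta method (on the log-ratio scale).
#'
#' @param run a [ddpcr_run()].
#' @param conf confidence level (default 0.95).
#' @return A list of class `ddpcr_est` with `lambda_target`, `lambda_ref`,
#'   `ratio` (plasmids per genome), `ci` (length-2 vector), and flags
#'   `saturated` (a channel with all droplets positive) and `undefined`
#'   (reference channel with no positives). Saturated or undefined runs
#'   report `NA` estimates.
#' @export
ddpcr_concentration <- function(run, conf = 0.95) {
  stopifnot(inherits(run, "ddpcr_run"))
  p_t <- run$positives_target / run$total_target
  p_r <- run$positives_ref / run$total_ref
  saturated <- p_t >= 1 || p_r >= 1
  undefined <- run$positives_ref == 0
  if (saturated || undefined)
    return(structure(list(lambda_target = if (saturated) NA_real_ else
                            -log(1 - p_t),
                          lambda_ref = if (saturated) NA_real_ else
                            -log(1 - p_r),
                          ratio = NA_real_, ci = c(NA_real_, NA_real_),
                          saturated = saturated, undefined = undefined),
                     class = "ddpcr_est"))
  lam_t <- -log(1 - p_t)
  lam_r <- -log(1 - p_r)
  ratio <- if (lam_r > 0) lam_t / lam_r else NA_real_
  # var(lambda) = p (1-p) / n / (1-p)^2 = p / (n (1-p))
  vl_t <- p_t / (run$total_target * (1 - p_t))
  vl_r <- p_r / (run$total_ref * (1 - p_r))
  ci <- c(NA_real_, NA_real_)
  if (is.finite(ratio) && lam_t > 0) {
    sd_log <- sqrt(vl_t / lam_t^2 + vl_r / lam_r^2)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- ratio * exp(c(-1, 1) * z * sd_log)
  }
  structure(list(lambda_target = lam_t, lambda_ref = lam_r, ratio = ratio,
                 ci = ci, saturated = FALSE, undefined = FALSE),
            class = "ddpcr_est")
}

#' @export
print.ddpcr_est <- function(x, ...) {
  if (x$saturated) cat("ddPCR estimate: saturated channel, unavailable\n")
  else if (x$undefined) cat("ddPCR estimate: no reference positives\n")
  else cat(sprintf(
    "ddPCR: lambda_target = %.4g, lambda_ref = %.4g, ratio = %.4g [%.4g, %.4g]\n",
    x$lambda_target, x$lambda_ref, x$ratio, x$ci[1], x$ci[2]))
  invisible(x)
}
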