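#' Linear metabolic-burden model
#'
#' Growth rate as a linear function of plasmid copy number:
#' \deqn{\mu(x) = b\,(1 - a x)}
#' where `b` is the plasmid-free growth rate (min^-1) and `a` the fractional
#' burden per plasmid copy (dimensionless; conventionally reported as a
#' percentage). Predicted growth is clamped at zero. The per-copy burden of a
#' small ColE1 vector is of the same order as the plasmid-to-genome length
#' ratio, consistent with a resource-allocation picture in which each copy
#' sequesters a share of the synthesis capacity proportional to its size.
#'
#' @param a fractional burden per plasmid copy (e.g. 0.00065 for 0.065%).
#' @param b plasmid-free growth rate (min^-1).
#' @param var_a,var_b coefficient variances (0 when not estimated).
#' @return An object of class `burden_model`.
#' @examples
#' m <- burden_model(a = 0.00065, b = 0.019)
#' predict_growth(m, c(0, 400, 800))
#' @export
burden_model <- function(a, b, var_a = 0, var_b = 0) {
  stopifnot(is.numeric(a), length(a) == 1L, a >= 0,
            is.numeric(b), length(b) == 1L, b > 0,
            var_a >= 0, var_b >= 0)
  structure(list(a = a, b = b, var_a = var_a, var_b = var_b),
            class = "burden_model")
}

#' @export
print.burden_model <- function(x, ...) {
  cat(sprintf("Linear burden model: growth(x) = b (1 - a x)\n"))
  cat(sprintf("  a = %.4g%% per copy   b = %.4g min^-1\n", 100 * x$a, x$b))
  invisible(x)
}

#' Predicted growth rate at a given copy number
#'
#' @param model a [burden_model()] or [fit_burden()] object.
#' @param x plasmid copies per cell (nonnegative, vectorized).
#' @return Growth rate (min^-1), clamped at 0.
#' @export
predict_growth <- function(model, x) {
  stopifnot(inherits(model, "burden_model") || inherits(model, "burden_fit"))
  stopifnot(all(x >= 0))
  if (inherits(model, "burden_fit")) model <- model$model
  pmax(model$b * (1 - model$a * x), 0)
}

#' Fit the linear metabolic-burden relation by weighted least squares
#'
#' Regresses growth rate on plasmid copy number with inverse-variance
#' weights and reparameterizes the line \eqn{\mu = \beta_0 + \beta_1 x} as
#' \eqn{\mu = b(1 - a x)} with `b` the intercept and `a = -slope/intercept`;
#' coefficient variances follow by the delta method from the WLS covariance.
#'
#' Weights are `1 / pmax(se, se_floor)^2`: the floor stops a single
#' ultra-low-error point from dominating the fit. Points flagged as runaway
#' or loss-prone are down-weighted (multiplicatively) rather than excluded,
#' mirroring how low-confidence points are de-emphasized, not dropped, when
#' the relation is displayed.
#'
#' @param x plasmid copy numbers (length >= 3).
#' @param rate growth rates (min^-1), same length.
#' @param se relative standard errors used for weighting; `NULL` for equal
#'   weights.
#' @param flags optional character vector; entries `"runaway"` or `"loss"`
#'   get their weight multiplied by `flag_weight`.
#' @param se_floor lower bound applied to `se` before weighting
#'   (default 0.01, i.e. 1% relative).
#' @param flag_weight multiplicative down-weight for flagged points
#'   (default 0.1).
#' @return An object of class `burden_fit`: a list with `model` (the fitted
#'   [burden_model()]), `lm` (the underlying weighted [stats::lm] fit),
#'   `data` (x, rate, weights) and `n`.
#' @examples
#' m <- burden_model(a = 5e-4, b = 0.02)
#' x <- c(10, 200, 600)
#' fit <- fit_burden(x, predict_growth(m, x))
#' coef(fit)
#' @export
fit_burden <- function(x, rate, se = NULL, flags = NULL,
                       se_floor = 0.01, flag_weight = 0.1) {
  stopifnot(is.numeric(x), is.numeric(rate), length(x) == length(rate))
  keep <- is.finite(x) & is.finite(rate)
  if (!is.null(se)) keep <- keep & is.finite(se) & se > 0
  x <- x[keep]; rate <- rate[keep]
  if (length(x) < 3) stop("need at least 3 points with finite values")
  if (diff(range(x)) == 0) stop("singular design: all copy numbers equal")
  w <- if (is.null(se)) rep(1, length(x)) else 1 / pmax(se[keep], se_floor)^2
  if (!is.null(flags)) {
    fl <- flags[keep]
    w[fl %in% c("runaway", "loss", "loss_prone")] <- flag_weight *
      w[fl %in% c("runaway", "loss", "loss_prone")]
  }
  fit <- stats::lm(rate ~ x, weights = w)
  beta <- stats::coef(fit)
  # vcov warns on exactly collinear (noise-free) data; variances are then 0
  V <- suppressWarnings(stats::vcov(fit))
  b <- unname(beta[1])
  slope <- unname(beta[2])
  if (b <= 0) stop("fitted plasmid-free growth rate is not positive")
  a <- -slope / b
  # delta method: a = -s/b, grad = (s/b^2, -1/b) wrt (b, s)
  g <- c(slope / b^2, -1 / b)
  var_a <- drop(t(g) %*% V %*% g)
  structure(list(model = burden_model(a = max(a, 0), b = b,
                                      var_a = var_a, var_b = V[1, 1]),
                 a = a, lm = fit,
                 data = data.frame(x = x, rate = rate, weight = w),
                 n = length(x)),
            class = "burden_fit")
}

#' @export
print.burden_fit <- function(x, ...) {
  cat(sprintf("Weighted linear burden fit (n = %d):\n", x$n))
  cat(sprintf("  a = %.4g%% +/- %.2g%% per copy\n",
              100 * x$a, 100 * sqrt(x$model$var_a)))
  cat(sprintf("  b = %.4g +/- %.2g min^-1\n",
              x$model$b, sqrt(x$model$var_b)))
  invisible(x)
}

#' @export
coef.burden_fit <- function(object, ...) {
  c(a = object$a, b = object$model$b)
}

#' @export
summary.burden_fit <- function(object, ...) {
  se <- sqrt(c(object$model$var_a, object$model$var_b))
  tab <- cbind(Estimate = coef(object), `Std. Error` = se)
  rownames(tab) <- c("a (fraction per copy)", "b (min^-1)")
  out <- list(coefficients = tab, n = object$n,
              lm_summary = summary(object$lm))
  class(out) <- "summary.burden_fit"
  out
}

#' @export
print.summary.burden_fit <- function(x, ...) {
  cat(sprintf("Linear burden fit, growth(x) = b (1 - a x), n = %d\n", x$n))
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' @export
predict.burden_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata$x else newdata
  predict_growth(object$model, x)
}

#' @export
fitted.burden_fit <- function(object, ...) {
  predict_growth(object$model, object$data$x)
}

#' @export
residuals.burden_fit <- function(object, ...) {
  object$data$rate - fitted(object)
}

#' @export
simulate.burden_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  # weighted residual sd; simulate per-point noise inversely to weight
  s2 <- sum(object$data$weight * residuals(object)^2) /
    (object$n - 2)
  sds <- sqrt(s2 / object$data$weight)
  out <- as.data.frame(replicate(nsim, stats::rnorm(object$n, mu, sds)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.burden_fit <- function(x, ...) {
  d <- x$data
  cex <- 0.4 + 1.2 * (rank(d$weight) / nrow(d))  # larger = more confident
  graphics::plot(d$x, d$rate, cex = cex, pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.6),
                 xlab = "plasmid copy number",
                 ylab = "growth rate (min^-1)", ...)
  xs <- seq(0, max(d$x), length.out = 200)
  graphics::lines(xs, predict_growth(x$model, xs), lwd = 2, col = "firebrick")
  invisible(x)
}

#' Plasmid length as a fraction of the host genome
#'
#' The per-copy metabolic burden of a small high-copy vector is comparable
#' to the fraction of the cell's DNA synthesis it represents. This helper
#' returns the plasmid/genome length ratio as a percentage; defaults are the
#' 2686 bp pUC19 plasmid and the 4,641,652 bp E. coli K-12 MG1655
#' chromosome.
#'
#' @param plasmid_bp plasmid length in base pairs.
#' @param genome_bp host genome length in base pairs.
#' @return Length ratio in percent.
#' @examples
#' plasmid_genome_fraction()  # ~0.058%
#' @export
plasmid_genome_fraction <- function(plasmid_bp = 2686, genome_bp = 4641652) {
  stopifnot(plasmid_bp > 0, genome_bp > 0)
  100 * plasmid_bp / genome_bp
}
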