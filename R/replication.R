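#' Parameters of the ColE1 inhibitor-dilution replication model
#'
#' Bundles the kinetic parameters controlling ColE1-type copy number: the
#' priming RNA (RNA-p) initiates replication in cis, the antisense inhibitory
#' RNA (RNA-i) sequesters it in trans, and copy number settles where
#' inhibition balances dilution by cell growth.
#'
#' All rates are per minute. `n_steps` is the number of rate-limiting
#' inhibition steps: `1` gives hyperbolic inhibition, `Inf` the exponential
#' limit. `Inf` is an explicit sentinel, not a large integer, so the
#' `(.)^(1/n)` evaluation never overflows.
#'
#' @param epsilon RNA degradation rate (min^-1).
#' @param rho RNA-p priming probability, in (0, 1].
#' @param r host growth rate (min^-1).
#' @param k_i RNA-i transcription initiation rate (min^-1).
#' @param k_p RNA-p transcription initiation rate (min^-1).
#' @param n_steps number of rate-limiting inhibition steps (integer >= 1 or
#'   `Inf`).
#' @return An object of class `rep_params`.
#' @examples
#' p <- rep_params(k_p = 0.3135)
#' copy_number(p)
#' @export
rep_params <- function(epsilon = 0.545, rho = 0.65, r = 0.01, k_i = 0.95,
                       k_p, n_steps = 1) {
  p <- structure(list(epsilon = epsilon, rho = rho, r = r, k_i = k_i,
                      k_p = k_p, n_steps = n_steps),
                 class = "rep_params")
  validate_rep_params(p)
  p
}

validate_rep_params <- function(p) {
  stopifnot(inherits(p, "rep_params"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(p$epsilon) || p$epsilon <= 0) stop("epsilon must be > 0")
  if (!num1(p$rho) || p$rho <= 0 || p$rho > 1) stop("rho must be in (0, 1]")
  if (!num1(p$r) || p$r <= 0) stop("r must be > 0")
  if (!num1(p$k_i) || p$k_i <= 0) stop("k_i must be > 0")
  if (!num1(p$k_p) || p$k_p <= 0) stop("k_p must be > 0")
  n <- p$n_steps
  ok_n <- (is.numeric(n) && length(n) == 1L) &&
    (identical(n, Inf) || (is.finite(n) && n >= 1 && n == round(n)))
  if (!ok_n) stop("n_steps must be an integer >= 1 or Inf")
  invisible(p)
}

#' @export
print.rep_params <- function(x, ...) {
  cat("ColE1 replication parameters (rates in min^-1):\n")
  cat(sprintf("  epsilon = %g  rho = %g  r = %g\n", x$epsilon, x$rho, x$r))
  cat(sprintf("  k_i = %g  k_p = %g  n_steps = %s\n",
              x$k_i, x$k_p, ifelse(is.finite(x$n_steps),
                                   format(x$n_steps), "Inf")))
  invisible(x)
}

# Core evaluation, total over the parameter domain: returns Inf for the
# runaway domain (k_p >= k_i) and a negative value when rho*k_p/r < 1
# (loss domain). copy_number() and classify_regime() interpret the flags.
cn_eval <- function(epsilon, rho, r, k_i, k_p, n_steps) {
  ifelse(k_p >= k_i, Inf, {
    x <- rho * k_p / r
    bracket <- if (is.finite(n_steps)) n_steps * (x^(1 / n_steps) - 1) else log(x)
    (epsilon + r) / (k_i - k_p) * bracket
  })
}

#' Steady-state plasmid copy number of a ColE1 origin
#'
#' Evaluates the inhibitor-dilution steady state
#' \deqn{N_p = \frac{n(\epsilon + r)}{k_i - k_p}
#'       \left[\left(\frac{\rho k_p}{r}\right)^{1/n} - 1\right]}
#' with the exponential-inhibition limit
#' \eqn{N_p = (\epsilon + r)/(k_i - k_p)\,\ln(\rho k_p / r)} when
#' `n_steps = Inf`.
#'
#' The expression has a finite fixed point only for `k_p < k_i` (otherwise
#' inhibition cannot keep up and replication runs away) and a nonnegative one
#' only for `rho * k_p / r >= 1` (otherwise replication cannot keep up with
#' dilution and the plasmid is lost). Outside that domain this function
#' signals an error; use [classify_regime()] for a total classification.
#'
#' @param params a [rep_params()] object.
#' @return Plasmid copies per cell (nonnegative scalar).
#' @seealso [classify_regime()], [copy_number_vs_growth()]
#' @export
copy_number <- function(params) {
  validate_rep_params(params)
  if (params$k_p >= params$k_i)
    stop("no finite fixed point: k_p >= k_i (runaway replication); ",
         "use classify_regime()")
  if (params$rho * params$k_p / params$r < 1)
    stop("rho * k_p / r < 1: replication cannot match dilution ",
         "(plasmid loss); use classify_regime()")
  cn_eval(params$epsilon, params$rho, params$r, params$k_i, params$k_p,
          params$n_steps)
}

#' Copy number as a function of host growth rate
#'
#' Element-wise evaluation of the replication steady state with the host
#' growth rate substituted, as used to predict how copy number rises as the
#' host divides more slowly. Out-of-domain growth rates are flagged per
#' element instead of failing globally.
#'
#' @param params a [rep_params()] object (its `r` is ignored).
#' @param growth_rates numeric vector of host growth rates (min^-1).
#' @return A data.frame with columns `r`, `copy_number` and `flag`
#'   (`"ok"`, `"runaway"` or `"loss"`). `copy_number` is `Inf` for runaway
#'   and `NA` for loss entries.
#' @export
copy_number_vs_growth <- function(params, growth_rates) {
  validate_rep_params(params)
  stopifnot(is.numeric(growth_rates), all(growth_rates > 0))
  cn <- vapply(growth_rates, function(ri)
    cn_eval(params$epsilon, params$rho, ri, params$k_i, params$k_p,
            params$n_steps), numeric(1))
  flag <- rep("ok", length(cn))
  flag[!is.finite(cn)] <- "runaway"
  loss <- is.finite(cn) & cn < 0
  flag[loss] <- "loss"
  cn[loss] <- NA_real_
  data.frame(r = growth_rates, copy_number = cn, flag = flag)
}

#' Classify the replication regime of a parameter set
#'
#' Total classification of a ColE1 parameter set into `stable`, `runaway`
#' (no finite fixed point: `k_p >= k_i`, or replication exceeding what
#' inhibition can balance) or `loss_prone` (steady-state copy number at or
#' below `loss_threshold`, so cell division is likely to produce
#' plasmid-free daughters). Loss also covers the domain
#' `rho * k_p / r < 1`, where the nominal steady state is negative.
#'
#' @param params a [rep_params()] object.
#' @param loss_threshold copies per cell below which the plasmid is deemed
#'   loss-prone (default 1).
#' @return An object of class `regime_label`: a list with `label` (one of
#'   `"stable"`, `"runaway"`, `"loss_prone"`) and `copy_number` (`Inf` for
#'   runaway, 0 for the negative-domain loss case).
#' @export
classify_regime <- function(params, loss_threshold = 1) {
  validate_rep_params(params)
  cn <- cn_eval(params$epsilon, params$rho, params$r, params$k_i, params$k_p,
                params$n_steps)
  if (!is.finite(cn)) {
    lab <- "runaway"; cn <- Inf
  } else if (cn < 0) {
    lab <- "loss_prone"; cn <- 0
  } else if (cn <= loss_threshold) {
    lab <- "loss_prone"
  } else {
    lab <- "stable"
  }
  structure(list(label = lab, copy_number = cn), class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("regime: %s (copy number %s)\n", x$label, format(x$copy_number)))
  invisible(x)
}

#' Self-consistent copy number under growth burden feedback
#'
#' Copy number and growth rate are mutually coupled: plasmid maintenance
#' slows growth (the burden model), and slower growth dilutes the inhibitor
#' less, raising copy number further. This solves for the joint fixed point
#' \eqn{N^* = N_p(r^*)}, \eqn{r^* = b(1 - a N^*)} by damped fixed-point
#' iteration on the growth rate.
#'
#' Non-convergence (the burden feedback amplifying copy number without
#' bound, ultimately as \eqn{r \to 0}) is reported as a `runaway_feedback`
#' flag rather than an error, so parameter sweeps need no error handling.
#'
#' @param params a [rep_params()] object; its `r` is taken as the starting
#'   growth rate unless `burden` provides a plasmid-free rate.
#' @param burden a [burden_model()] object.
#' @param damping damping factor on the growth-rate update (default 0.5).
#' @param tol relative convergence tolerance (default 1e-8).
#' @param max_iter maximum iterations (default 1e4).
#' @param r_floor lower clamp on the growth rate during iteration (min^-1),
#'   keeping the replication model finite (default 1e-6).
#' @return A list with `copy_number`, `growth_rate`, `converged` (logical),
#'   `flag` (`"ok"`, `"runaway"`, or `"runaway_feedback"`) and `iterations`.
#' @export
solve_self_consistent <- function(params, burden, damping = 0.5, tol = 1e-8,
                                  max_iter = 1e4, r_floor = 1e-6) {
  validate_rep_params(params)
  stopifnot(inherits(burden, "burden_model"))
  if (params$k_p >= params$k_i)
    return(list(copy_number = Inf, growth_rate = NA_real_, converged = FALSE,
                flag = "runaway", iterations = 0L))
  r <- burden$b  # plasmid-free growth rate
  n_cur <- NA_real_
  for (it in seq_len(max_iter)) {
    n_cur <- cn_eval(params$epsilon, params$rho, max(r, r_floor), params$k_i,
                     params$k_p, params$n_steps)
    r_new <- max(predict_growth(burden, max(n_cur, 0)), r_floor)
    r_next <- (1 - damping) * r + damping * r_new
    if (abs(r_next - r) <= tol * max(abs(r), r_floor)) {
      n_fin <- cn_eval(params$epsilon, params$rho, max(r_next, r_floor),
                       params$k_i, params$k_p, params$n_steps)
      # settling onto the growth-rate floor means the burden feedback has
      # driven r -> 0: copy number is floor-limited, not a true fixed point
      at_floor <- r_next <= r_floor * (1 + 10 * tol)
      return(list(copy_number = if (at_floor) Inf else n_fin,
                  growth_rate = r_next, converged = !at_floor,
                  flag = if (at_floor) "runaway_feedback" else "ok",
                  iterations = it))
    }
    r <- r_next
  }
  # hitting the floor without settling = burden feedback has won
  list(copy_number = n_cur, growth_rate = r, converged = FALSE,
       flag = "runaway_feedback", iterations = max_iter)
}

#' Read and write replication parameter sets as flat key-value text
#'
#' Plain-text, one `name = value` per line, so parameter provenance can be
#' echoed into result files. `Inf` round-trips for `n_steps`.
#'
#' @param params a [rep_params()] object.
#' @param path file path.
#' @return `write_params()` returns `path` invisibly; `read_params()` a
#'   [rep_params()] object.
#' @export
write_params <- function(params, path) {
  validate_rep_params(params)
  keys <- c("epsilon", "rho", "r", "k_i", "k_p", "n_steps")
  writeLines(sprintf("%s = %s", keys,
                     vapply(params[keys], function(v)
                       format(v, digits = 17), character(1))), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  kv <- read_keyvalue(path)
  rep_params(epsilon = as.numeric(kv[["epsilon"]]),
             rho = as.numeric(kv[["rho"]]),
             r = as.numeric(kv[["r"]]),
             k_i = as.numeric(kv[["k_i"]]),
             k_p = as.numeric(kv[["k_p"]]),
             n_steps = as.numeric(kv[["n_steps"]]))
}

# parse "name = value" lines into a named character list
read_keyvalue <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  vals <- lapply(parts, function(p) trimws(p[2]))
  names(vals) <- vapply(parts, function(p) trimws(p[1]), character(1))
  vals
}
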