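#' CRISPRi effector / binding-site system
#'
#' Bookkeeping for a thermodynamic titration model of a DNA-binding
#' effector (a dCas12a-crRNA complex) shared between an active regulatory
#' target, decoy ("sponge") sites carried on a plasmid, and the nonspecific
#' genomic background. Decoy and active sites carry the same sequence motif
#' and hence the same binding energy by default; `decoy_offset` (k_BT) lets
#' the decoy energy differ.
#'
#' @param delta_eps specific binding energy in units of k_BT (negative =
#'   favorable), relative to nonspecific binding.
#' @param R effector copies per cell (>= 0).
#' @param N_NS nonspecific genomic sites (>= 1); default 4.6e6, genome scale.
#' @param N_a active target sites per cell (>= 1).
#' @param N_c decoy (sponge) sites per cell (>= 0).
#' @param decoy_offset additive energy offset for decoy sites (k_BT,
#'   default 0).
#' @return An object of class `sponge_system`.
#' @examples
#' s <- sponge_system(delta_eps = -13.25, R = 100, N_c = 270)
#' active_site_occupancy(s)
#' @export
sponge_system <- function(delta_eps, R = 100, N_NS = 4.6e6, N_a = 1,
                          N_c = 0, decoy_offset = 0) {
  stopifnot(is.finite(delta_eps), R >= 0, N_NS >= 1, N_a >= 1, N_c >= 0)
  structure(list(delta_eps = delta_eps, R = R, N_NS = N_NS, N_a = N_a,
                 N_c = N_c, decoy_offset = decoy_offset),
            class = "sponge_system")
}

#' @export
print.sponge_system <- function(x, ...) {
  cat(sprintf(
    "sponge_system: delta_eps = %g kBT, R = %g, N_NS = %g, N_a = %g, N_c = %g\n",
    x$delta_eps, x$R, x$N_NS, x$N_a, x$N_c))
  invisible(x)
}

# Mean-field (self-consistent) occupancy. Solves for the free effector
# count R_free on [0, R] such that R_free plus the implied bound effectors
# equals R, then reads off the active-site occupancy. With no decoy offset
# this is identical to bisecting p = w/(1+w), w = (R - p (N_a+N_c))/N_NS
# * exp(-delta_eps).
occupancy_meanfield <- function(sys, tol = 1e-10) {
  if (sys$R == 0) return(0)
  wa_of <- function(rf) rf / sys$N_NS * exp(-sys$delta_eps)
  wc_of <- function(rf) rf / sys$N_NS * exp(-(sys$delta_eps +
                                              sys$decoy_offset))
  g <- function(rf) {
    wa <- wa_of(rf); wc <- wc_of(rf)
    rf + sys$N_a * wa / (1 + wa) + sys$N_c * wc / (1 + wc) - sys$R
  }
  # g is strictly increasing; g(0) = -R < 0, g(R) >= 0
  lo <- 0; hi <- sys$R
  while (hi - lo > tol * max(sys$R, 1)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  wa <- wa_of((lo + hi) / 2)
  wa / (1 + wa)
}

# Exact canonical occupancy by partition-function enumeration over the
# number of effectors on specific sites. Effectors are indistinguishable;
# sites are distinct; nonspecific binding is the energy reference.
occupancy_exact <- function(sys) {
  R <- as.integer(round(sys$R))
  Na <- as.integer(round(sys$N_a)); Nc <- as.integer(round(sys$N_c))
  Nns <- sys$N_NS
  if (R == 0) return(0)
  if (sys$decoy_offset == 0) {
    Ns <- Na + Nc
    m <- 0:min(R, Ns)
    lw <- lchoose(Ns, m) + lchoose(Nns, R - m) - m * sys$delta_eps
    w <- exp(lw - max(lw))
    sum(m * w) / sum(w) / Ns
  } else {
    ma <- 0:min(R, Na)
    tot <- 0; num <- 0; lmax <- -Inf
    grid <- expand.grid(ma = ma, mc = 0:min(R, Nc))
    grid <- grid[grid$ma + grid$mc <= R, ]
    lw <- lchoose(Na, grid$ma) + lchoose(Nc, grid$mc) +
      lchoose(Nns, R - grid$ma - grid$mc) -
      grid$ma * sys$delta_eps -
      grid$mc * (sys$delta_eps + sys$decoy_offset)
    w <- exp(lw - max(lw))
    sum(grid$ma * w) / sum(w) / Na
  }
}

#' Equilibrium occupancy of the active site
#'
#' Probability that the active regulatory site is bound by the effector,
#' with the effector pool titrated by the decoy sites and the nonspecific
#' genomic background. Two routes are implemented: exact canonical
#' partition-function enumeration, and a mean-field self-consistent
#' solution (bisection on the free-effector count, tolerance 1e-10).
#' `method = "auto"` (default) uses the exact enumeration whenever the
#' system is small enough (`R * (N_a + N_c) <= 1e6` with integer counts)
#' and the mean-field solution otherwise. At very small effector and site
#' counts the mean-field answer can deviate from the exact one by a few
#' percent (molecular-number fluctuations); the automatic switch keeps the
#' returned value exact there.
#'
#' @param system a [sponge_system()].
#' @param method `"auto"`, `"meanfield"` or `"exact"`.
#' @return Occupancy in `[0, 1]`.
#' @export
active_site_occupancy <- function(system, method = c("auto", "meanfield",
                                                     "exact")) {
  stopifnot(inherits(system, "sponge_system"))
  method <- match.arg(method)
  enumerable <- system$R * (system$N_a + system$N_c) <= 1e6 &&
    system$R == round(system$R) && system$N_a == round(system$N_a) &&
    system$N_c == round(system$N_c) && system$N_NS == round(system$N_NS)
  if (method == "exact" && !enumerable)
    stop("system too large for exact enumeration")
  if (method == "exact" || (method == "auto" && enumerable))
    occupancy_exact(system)
  else
    occupancy_meanfield(system)
}

#' Fold-change and dynamic range of a CRISPRi inverter
#'
#' Reporter expression is proportional to the unoccupied fraction of the
#' active site, `1 - occupancy`. Comparing the crRNA-induced (ON) state
#' with the uninduced (OFF) state — the two systems differing only in the
#' effector count `R` — gives the repression fold-change
#' (OFF-state expression over ON-state expression) and the dynamic range
#' (OFF minus ON expression, on the normalized 0-1 scale).
#'
#' @param system_on the crRNA-induced system (high `R`, repressed reporter).
#' @param system_off the uninduced system (low `R`).
#' @param method passed to [active_site_occupancy()].
#' @return A list with `expression_on`, `expression_off`, `fold_change`
#'   (`Inf` with `infinite = TRUE` when ON-state expression is zero) and
#'   `dynamic_range`.
#' @export
fold_change <- function(system_on, system_off, method = "auto") {
  e_on <- 1 - active_site_occupancy(system_on, method)
  e_off <- 1 - active_site_occupancy(system_off, method)
  fc <- if (e_on == 0) Inf else e_off / e_on
  list(expression_on = e_on, expression_off = e_off, fold_change = fc,
       infinite = e_on == 0, dynamic_range = e_off - e_on)
}

#' Active-site occupancy versus sponge-site count
#'
#' Sweeps the decoy-site count and evaluates the occupancy at two binding
#' energies forming an envelope (defaults -13.25 and -12.25 k_BT, a
#' stronger and a weaker binding bound). Each curve is monotonically
#' non-increasing in the number of sponge sites.
#'
#' @param base a [sponge_system()]; its `N_c` and `delta_eps` are overridden.
#' @param nc_values nonnegative decoy-site counts to sweep.
#' @param energies length-2 vector of binding energies (k_BT), strongest
#'   first.
#' @param method passed to [active_site_occupancy()].
#' @return A data.frame with columns `n_c`, `occ_strong`, `occ_weak`.
#' @export
occupancy_vs_sponge_curve <- function(base, nc_values,
                                      energies = c(-13.25, -12.25),
                                      method = "auto") {
  stopifnot(inherits(base, "sponge_system"), all(nc_values >= 0),
            length(energies) == 2)
  ev <- function(de) vapply(nc_values, function(nc) {
    s <- base; s$N_c <- nc; s$delta_eps <- de
    active_site_occupancy(s, method)
  }, numeric(1))
  data.frame(n_c = nc_values, occ_strong = ev(min(energies)),
             occ_weak = ev(max(energies)))
}
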