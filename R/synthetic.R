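#' Passaging scheme for the pooled serial-dilution assay
#'
#' Describes the growth/dilution protocol the pooled assay emulates: the
#' transformed library is grown to a target optical density, a fraction is
#' saved for plasmid extraction and the rest diluted and regrown, repeatedly.
#' Elapsed times are explicit parameters: `t_first` is minutes from
#' transformation to the first sampling, `delta_t` minutes between adjacent
#' samplings.
#'
#' @param dilution_factor fold dilution at each passage (default 4).
#' @param num_passages number of sampled timepoints (default 4).
#' @param od_target optical density at which each culture is sampled
#'   (default 1.0; bookkeeping only, growth is modeled as exponential).
#' @param t_first minutes from transformation to the first sampling
#'   (default 120).
#' @param delta_t minutes between adjacent samplings (default 90,
#'   roughly log2(4) bulk doublings per 1:4 passage).
#' @return An object of class `passaging_scheme`.
#' @export
passaging_scheme <- function(dilution_factor = 4, num_passages = 4,
                             od_target = 1.0, t_first = 120, delta_t = 90) {
  stopifnot(dilution_factor > 1, num_passages >= 1, t_first > 0, delta_t > 0)
  structure(list(dilution_factor = dilution_factor,
                 num_passages = num_passages, od_target = od_target,
                 t_first = t_first, delta_t = delta_t),
            class = "passaging_scheme")
}

#' Design of a synthetic promoter-mutagenesis plasmid library
#'
#' Describes a library of ColE1 origin variants generated by randomizing the
#' -35 box, -10 box and +1 position of the promoter driving the priming RNA.
#' Variant "strength" can be sampled either on the priming rate `k_p` (the
#' mechanistic route: copy number and growth then follow from the
#' replication model coupled to the burden model) or directly on the true
#' copy number (the phenomenological route used for estimator validation,
#' with growth from the burden model alone).
#'
#' @param num_variants number of variants (>= 2; at most 1024, the size of
#'   the degenerate promoter space).
#' @param sampler a list describing the variant sampler: one of
#'   `list(type = "kp_loguniform", min =, max =)`,
#'   `list(type = "kp_fixed", value =)`,
#'   `list(type = "pcn_loguniform", min =, max =)`,
#'   `list(type = "pcn_fixed", value =)`.
#' @param base_params a [rep_params()] template; `k_p` is overridden per
#'   variant (only used by the `kp_*` samplers).
#' @param burden a [burden_model()] giving growth rate vs copy number.
#' @param concentration symmetric Dirichlet concentration for the initial
#'   ligation fractions (default 5; smaller = more uneven representation).
#' @param seed integer seed making the whole library deterministic.
#' @return An object of class `library_design`.
#' @export
library_design <- function(num_variants,
                           sampler = list(type = "pcn_loguniform",
                                          min = 1, max = 800),
                           base_params = rep_params(k_p = 0.3135),
                           burden = burden_model(a = 0.00065, b = 0.019),
                           concentration = 5, seed = 1L) {
  stopifnot(num_variants >= 2, num_variants <= 1024,
            concentration > 0,
            sampler$type %in% c("kp_loguniform", "kp_fixed",
                                "pcn_loguniform", "pcn_fixed"))
  validate_rep_params(base_params)
  stopifnot(inherits(burden, "burden_model"))
  structure(list(num_variants = as.integer(num_variants), sampler = sampler,
                 base_params = base_params, burden = burden,
                 concentration = concentration, seed = as.integer(seed)),
            class = "library_design")
}

# Degenerate ori-region template: a fixed priming-promoter context with the
# nine degenerate IUPAC positions of the mutagenic primers (-35 box KKKM,
# -10 box WWRM, +1 N), giving 2^4 * 2^4 * 4 = 1024 sequence variants.
ORI_TEMPLATE <- "GCGCGTKKKMTGCTGCTAGCTTTTTTTCTACWWRMTAGAAGNACAGTATTTGG"

IUPAC_CHOICES <- list(K = c("G", "T"), M = c("A", "C"), W = c("A", "T"),
                      R = c("A", "G"), N = c("A", "C", "G", "T"))

# Enumerate all realizations of the degenerate template, in a fixed order.
enumerate_ori_variants <- function(template = ORI_TEMPLATE) {
  chars <- strsplit(template, "")[[1]]
  deg <- which(chars %in% names(IUPAC_CHOICES))
  combos <- expand.grid(lapply(chars[deg], function(cc) IUPAC_CHOICES[[cc]]),
                        stringsAsFactors = FALSE)
  apply(combos, 1, function(row) {
    chars[deg] <- row
    paste(chars, collapse = "")
  })
}

#' Generate a synthetic variant library
#'
#' Realizes a [library_design()]: samples per-variant promoter strengths,
#' derives each variant's true copy number and doubling time (for the
#' mechanistic `kp_*` samplers via [solve_self_consistent()]; for `pcn_*`
#' samplers directly, with growth from the burden model), assigns a distinct
#' degenerate-promoter sequence to each variant, and draws initial ligation
#' fractions from a symmetric Dirichlet. Variants classified runaway or
#' loss-prone under the mechanistic route are excluded from the emitted
#' table; the count of exclusions is recorded as an attribute.
#'
#' @param design a [library_design()].
#' @return A data.frame of class `variant_library` with columns `id`,
#'   `ori_seq`, `k_p` (`NA` for the direct samplers), `true_pcn`,
#'   `true_tau` (minutes), `init_fraction`; attributes `n_excluded` and
#'   `design`.
#' @export
generate_library <- function(design) {
  stopifnot(inherits(design, "library_design"))
  set.seed(design$seed)
  n <- design$num_variants
  s <- design$sampler
  draw <- switch(s$type,
    kp_loguniform  = exp(stats::runif(n, log(s$min), log(s$max))),
    kp_fixed       = rep(s$value, n),
    pcn_loguniform = exp(stats::runif(n, log(s$min), log(s$max))),
    pcn_fixed      = rep(s$value, n))
  if (startsWith(s$type, "kp")) {
    k_p <- draw
    sol <- lapply(k_p, function(kp) {
      p <- design$base_params; p$k_p <- kp
      if (kp >= p$k_i)
        return(list(copy_number = Inf, growth_rate = NA_real_, flag = "runaway"))
      solve_self_consistent(p, design$burden)
    })
    pcn <- vapply(sol, `[[`, numeric(1), "copy_number")
    rate <- vapply(sol, `[[`, numeric(1), "growth_rate")
    flag <- vapply(sol, `[[`, character(1), "flag")
    ok <- flag == "ok" & is.finite(pcn) & pcn > 1
  } else {
    k_p <- rep(NA_real_, n)
    pcn <- draw
    rate <- predict_growth(design$burden, pcn)
    ok <- rate > 0 & pcn >= 1
  }
  n_excl <- sum(!ok)
  if (!any(ok)) stop("sampler produced no valid variants (empty library)")
  seq_pool <- enumerate_ori_variants()
  seqs <- sample(seq_pool, n, replace = FALSE)
  f0 <- stats::rgamma(n, shape = design$concentration)
  lib <- data.frame(id = sprintf("v%04d", seq_len(n)),
                    ori_seq = seqs, k_p = k_p,
                    true_pcn = pcn,
                    true_tau = log(2) / rate,
                    init_fraction = f0,
                    stringsAsFactors = FALSE)[ok, ]
  lib$init_fraction <- lib$init_fraction / sum(lib$init_fraction)
  rownames(lib) <- NULL
  class(lib) <- c("variant_library", "data.frame")
  attr(lib, "n_excluded") <- n_excl
  attr(lib, "design") <- design
  lib
}

#' Simulate competitive passaging of a variant library
#'
#' Deterministic exponential competition: each variant's cell fraction at
#' time `t` is proportional to its initial fraction times `2^(t / tau)`,
#' renormalized at every sampled timepoint (all cultures are sampled at the
#' same optical density, so only composition matters). Also reports the
#' bulk (mixture-implied) doubling time over each inter-sample interval,
#' which downstream inference needs as its `tau_av` reference.
#'
#' @param library a [generate_library()] result.
#' @param scheme a [passaging_scheme()].
#' @return A list of class `passaging_sim`: `fractions` (variant x
#'   timepoint matrix, columns summing to 1), `times` (minutes since
#'   transformation), `tau_bulk` (per-interval bulk doubling times, first
#'   entry for the interval from transformation to the first sampling) and
#'   `tau_av` (the overall bulk doubling time across the full experiment).
#' @export
simulate_passaging <- function(library, scheme = passaging_scheme()) {
  stopifnot(inherits(library, "variant_library"), nrow(library) >= 1,
            inherits(scheme, "passaging_scheme"))
  times <- scheme$t_first + (seq_len(scheme$num_passages) - 1) * scheme$delta_t
  lw0 <- log(library$init_fraction)
  # log2 mass of each variant at each time; normalization via log-sum-exp
  logmass <- outer(library$true_tau, times,
                   function(tau, t) t / tau) * log(2) + lw0
  norm <- apply(logmass, 2, function(col) {
    m <- max(col); m + log(sum(exp(col - m)))
  })
  fr <- exp(sweep(logmass, 2, norm))
  dimnames(fr) <- list(library$id, paste0("t", seq_along(times)))
  # bulk doubling time per interval: total mass growth M(t_j)/M(t_{j-1}),
  # M(0) = 1 by construction
  lens <- diff(c(0, times))
  dbl <- diff(c(0, norm)) / log(2)
  structure(list(fractions = fr, times = times,
                 tau_bulk = lens / dbl,
                 tau_av = times[length(times)] /
                   (norm[length(norm)] / log(2))),
            class = "passaging_sim")
}

#' Simulate plasmid-prep sequencing counts for a passaged library
#'
#' The sequencing libraries are made from isolated plasmids, so a variant's
#' expected read share at each timepoint is proportional to its cell
#' fraction times its copy number (renormalized). The initial-library
#' (ligation) column reflects plasmid abundance in the ligation product and
#' is drawn from the initial fractions alone. Counts are multinomial at the
#' stated depth; `noise = "none"` returns the expected (non-integer) counts,
#' used for noise-free round-trip validation.
#'
#' @param passaging a [simulate_passaging()] result.
#' @param library the [generate_library()] result it came from.
#' @param depth reads per timepoint (default 1e6).
#' @param seed integer seed.
#' @param noise `"multinomial"` (default) or `"none"`.
#' @return A [count_table()] with the ligation column first. Attributes:
#'   `c_true`, the expected relative copy number noise-free inference
#'   recovers (copy number over the ligation-weighted mean copy number);
#'   `tau_bulk_reads`, the per-interval bulk doubling times of the
#'   *sequenced plasmid pool*; and `tau_bulk`, the cell-pool equivalent
#'   from the passaging simulation. Because read fractions are normalized
#'   by the plasmid-weighted pool, the drift-correction reference
#'   (`tau_av`) that makes the count inference self-consistent is
#'   `tau_bulk_reads`; when copy number anticorrelates with growth the two
#'   pools grow at different rates and using the cell-pool value biases
#'   every inferred rate by a common offset.
#' @export
simulate_reads <- function(passaging, library, depth = 1e6, seed = 1L,
                           noise = c("multinomial", "none")) {
  noise <- match.arg(noise)
  stopifnot(inherits(passaging, "passaging_sim"),
            inherits(library, "variant_library"),
            nrow(library) == nrow(passaging$fractions), depth >= 1)
  w <- passaging$fractions * library$true_pcn
  tot <- colSums(w)
  if (any(tot <= 0)) stop("zero total expected read weight at a timepoint")
  expw <- sweep(w, 2, tot, "/")
  expected <- cbind(ligation = library$init_fraction, expw)
  if (noise == "multinomial") {
    set.seed(seed)
    counts <- apply(expected, 2, function(p) stats::rmultinom(1, depth, p))
  } else {
    counts <- expected * depth
  }
  dimnames(counts) <- list(library$id, colnames(expected))
  tab <- count_table(counts, times = passaging$times, ids = library$id)
  # read-mass (plasmid-pool) growth: logsumexp of f_i * 2^(t/tau) * PCN
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  lw0 <- log(library$init_fraction) + log(library$true_pcn)
  logW <- vapply(c(0, passaging$times), function(t)
    lse(lw0 + t * log(2) / library$true_tau), numeric(1))
  lens <- diff(c(0, passaging$times))
  attr(tab, "tau_bulk_reads") <- lens / (diff(logW) / log(2))
  attr(tab, "tau_bulk") <- passaging$tau_bulk
  # truth for the relative copy number: PCN / ligation-weighted mean PCN
  attr(tab, "c_true") <- library$true_pcn / exp(logW[1])
  tab
}

#' Simulate a plate-reader growth curve for one construct
#'
#' Logistic optical-density trajectory with maximum specific growth rate
#' `log(2) / tau`, sampled at a fixed interval. Fluorescence accumulates at
#' rate `k_expr * pcn * OD(t)`, so in exponential phase the fluorescence-
#' per-OD signal `G` satisfies `pcn = G * mu / k_expr` exactly — the
#' convention the fluorescence-based copy-number estimator inverts.
#' Additive Gaussian measurement noise on both channels.
#'
#' @param tau doubling time in minutes.
#' @param pcn plasmid copy number of the construct.
#' @param duration total minutes (default 1440).
#' @param sample_interval minutes between readings (default 3).
#' @param od0 inoculum optical density (default 1e-4).
#' @param od_max carrying capacity (default 1.5).
#' @param k_expr per-copy expression rate constant (default 1).
#' @param noise_sd additive Gaussian noise sd on OD; fluorescence noise is
#'   scaled by the fluorescence range (default 0).
#' @param seed integer seed.
#' @return A [growth_curve()] object.
#' @export
simulate_plate_reader <- function(tau, pcn, duration = 1440,
                                  sample_interval = 3, od0 = 1e-4,
                                  od_max = 1.5, k_expr = 1, noise_sd = 0,
                                  seed = 1L) {
  stopifnot(tau > 0, pcn >= 0, duration > 0, sample_interval > 0)
  mu <- log(2) / tau
  t <- seq(0, duration, by = sample_interval)
  od <- od_max * od0 * exp(mu * t) / (od_max + od0 * (exp(mu * t) - 1))
  # cumulative integral of k * pcn * OD dt (trapezoid)
  dF <- k_expr * pcn * od
  fl <- c(0, cumsum((dF[-1] + dF[-length(dF)]) / 2 * diff(t)))
  if (noise_sd > 0) {
    set.seed(seed)
    od <- pmax(od + stats::rnorm(length(od), 0, noise_sd), 0)
    fl <- pmax(fl + stats::rnorm(length(fl), 0, noise_sd * max(fl)), 0)
  }
  growth_curve(time_min = t, od = od, fluorescence = fl)
}

#' Simulate a digital droplet PCR run
#'
#' Template molecules partition into droplets as Poisson; a droplet is
#' positive when it received at least one molecule, so the per-droplet
#' positive probability at mean occupancy `lambda` is `1 - exp(-lambda)`.
#' Two channels are simulated: a genomic reference at `lambda_ref` and the
#' plasmid target at `true_ratio * lambda_ref`.
#'
#' @param true_ratio plasmids per genome.
#' @param lambda_ref mean reference copies per droplet.
#' @param n_droplets droplets per channel (default 20000).
#' @param seed integer seed.
#' @return A [ddpcr_run()] object.
#' @export
simulate_ddpcr <- function(true_ratio, lambda_ref, n_droplets = 20000,
                           seed = 1L) {
  stopifnot(true_ratio >= 0, lambda_ref > 0, n_droplets >= 1)
  set.seed(seed)
  p_t <- 1 - exp(-true_ratio * lambda_ref)
  p_r <- 1 - exp(-lambda_ref)
  ddpcr_run(positives_target = stats::rbinom(1, n_droplets, p_t),
            total_target = n_droplets,
            positives_ref = stats::rbinom(1, n_droplets, p_r),
            total_ref = n_droplets)
}

#' Write a variant library's reads as FASTQ
#'
#' Emits `reads_per_variant` identical reads per variant, each embedding the
#' variant's ori-region sequence between fixed flanks, with constant Phred
#' qualities — enough structure to exercise exact-match read counting.
#'
#' @param library a [generate_library()] result.
#' @param path output FASTQ path.
#' @param reads_per_variant integer vector (recycled) of read counts.
#' @param mutate_first if `TRUE`, the first read of the first variant gets a
#'   single substitution inside its ori region (a read that the
#'   zero-mismatch rule must discard). Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_library_fastq <- function(library, path, reads_per_variant = 1,
                                mutate_first = FALSE) {
  stopifnot(inherits(library, "variant_library"))
  nrep <- rep_len(reads_per_variant, nrow(library))
  reads <- rep(paste0("ACGTACGT", library$ori_seq, "TGCATGCA"),
               times = nrep)
  ids <- paste0(rep(library$id, times = nrep), "_read",
                unlist(lapply(nrep, seq_len)))
  if (mutate_first && length(reads) > 0) {
    pos <- 8L + 3L  # inside the ori region
    ch <- substr(reads[1], pos, pos)
    substr(reads[1], pos, pos) <- setdiff(c("A", "C", "G", "T"), ch)[1]
  }
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                strrep("I", nchar(reads))))
  invisible(path)
}

#' Write the generator manifest
#'
#' Records every parameter and seed of a simulated experiment as flat
#' `name = value` text so results carry their provenance and downstream
#' inference can pick up the timing parameters and bulk doubling times.
#'
#' @param path output path.
#' @param design the [library_design()] used.
#' @param scheme the [passaging_scheme()] used.
#' @param passaging the [simulate_passaging()] result (for cell-pool bulk
#'   doubling times); optional.
#' @param table the [simulate_reads()] result (for the sequenced-pool bulk
#'   doubling times inference should use as `tau_av`); optional.
#' @param depth sequencing depth used; optional.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, design, scheme, passaging = NULL,
                           table = NULL, depth = NULL) {
  fmt <- function(v) paste(format(v, digits = 17), collapse = ",")
  kv <- c(num_variants = design$num_variants,
          sampler_type = design$sampler$type,
          sampler_min = if (!is.null(design$sampler$min)) fmt(design$sampler$min),
          sampler_max = if (!is.null(design$sampler$max)) fmt(design$sampler$max),
          sampler_value = if (!is.null(design$sampler$value)) fmt(design$sampler$value),
          concentration = fmt(design$concentration),
          seed = design$seed,
          burden_a = fmt(design$burden$a), burden_b = fmt(design$burden$b),
          epsilon = fmt(design$base_params$epsilon),
          rho = fmt(design$base_params$rho),
          r = fmt(design$base_params$r),
          k_i = fmt(design$base_params$k_i),
          n_steps = fmt(design$base_params$n_steps),
          dilution_factor = fmt(scheme$dilution_factor),
          num_passages = scheme$num_passages,
          t_first = fmt(scheme$t_first), delta_t = fmt(scheme$delta_t))
  if (!is.null(passaging)) {
    kv <- c(kv, tau_bulk = fmt(passaging$tau_bulk),
            tau_av = fmt(passaging$tau_av))
  }
  if (!is.null(table)) {
    kv <- c(kv, tau_bulk_reads = fmt(attr(table, "tau_bulk_reads")))
  }
  if (!is.null(depth)) kv <- c(kv, depth = fmt(depth))
  writeLines(sprintf("%s = %s", names(kv), kv), path)
  invisible(path)
}

#' Write a variant library as TSV
#'
#' @param library a [generate_library()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(library, path) {
  utils::write.table(as.data.frame(library), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
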