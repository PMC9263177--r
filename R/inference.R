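#' Variant-by-timepoint sequencing count table
#'
#' Container for pooled-assay read counts: one row per variant, a `ligation`
#' column holding the initial-library counts (pre-transformation, so its
#' time is undefined) followed by one column per sampled timepoint, with the
#' sampling times in minutes since transformation.
#'
#' @param counts numeric matrix (variant x column) with the ligation column
#'   first; nonnegative, every column total > 0.
#' @param times sampling times in minutes, strictly increasing, one per
#'   non-ligation column.
#' @param ids variant identifiers (defaults to rownames).
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, times, ids = rownames(counts)) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(times) + 1L,
            all(counts >= 0), all(colSums(counts) > 0),
            all(diff(times) > 0), all(times > 0))
  if (is.null(ids)) ids <- sprintf("v%04d", seq_len(nrow(counts)))
  rownames(counts) <- ids
  colnames(counts) <- c("ligation", paste0("t", seq_along(times)))
  structure(list(counts = counts, times = as.numeric(times), ids = ids),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d variants x %d timepoints (+ ligation)\n",
              nrow(x$counts), length(x$times)))
  cat("  times (min):", paste(x$times, collapse = ", "), "\n")
  cat("  column totals:", paste(format(colSums(x$counts)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read and write count tables as TSV
#'
#' The TSV has a header `variant_id`, `ligation`, `t1`..`tk`; the sampling
#' times live in a sidecar key-value config (see [inference_config()] /
#' [write_manifest()]), so `read_count_table()` takes them as an argument.
#'
#' @param table a [count_table()].
#' @param path file path.
#' @param times sampling times (minutes) for the `t1..tk` columns.
#' @return `write_count_table()` returns `path` invisibly;
#'   `read_count_table()` a [count_table()].
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(variant_id = table$ids, table$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path, times) {
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot("variant_id" %in% names(df), "ligation" %in% names(df))
  m <- as.matrix(df[setdiff(names(df), "variant_id")])
  count_table(m, times = times, ids = as.character(df$variant_id))
}

#' Configuration for pooled-assay inference
#'
#' `tau_av` is the bulk-culture doubling time the variant-specific rates are
#' measured against. It must be supplied — either a scalar (one bulk
#' doubling time for the whole experiment) or a vector with one entry per
#' sampled timepoint giving the bulk doubling time over each preceding
#' interval (the first entry covering transformation to the first sampling),
#' as emitted by [simulate_passaging()]. There is no default: running
#' without a measured bulk doubling time would silently bias every estimate.
#'
#' @param tau_av bulk doubling time, minutes (scalar or per-interval vector).
#' @param delta_t minutes between adjacent sampled timepoints.
#' @param t_first minutes from transformation to the first sampled timepoint.
#' @param pseudo_count added to every count before forming fractions
#'   (default 0.5, a Jeffreys-style guard against zeros).
#' @param min_reads minimum summed sampled-column counts for a variant to be
#'   estimated (default 20).
#' @param fraction_floor pairs whose fractions fall at or below this floor
#'   are excluded from the doubling-time average (default 0).
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(tau_av, delta_t, t_first, pseudo_count = 0.5,
                             min_reads = 20, fraction_floor = 0) {
  stopifnot(is.numeric(tau_av), length(tau_av) >= 1, all(tau_av > 0),
            delta_t > 0, t_first > 0, pseudo_count >= 0, min_reads >= 0)
  structure(list(tau_av = tau_av, delta_t = delta_t, t_first = t_first,
                 pseudo_count = pseudo_count, min_reads = min_reads,
                 fraction_floor = fraction_floor),
            class = "inference_config")
}

# per-interval bulk rate (doublings/min), expanded to k sampled timepoints
bulk_rates <- function(config, k) {
  tav <- config$tau_av
  if (length(tav) == 1L) rep(1 / tav, k)
  else if (length(tav) == k) 1 / tav
  else stop("tau_av must be scalar or one entry per sampled timepoint")
}

#' Pseudo-counted read fractions
#'
#' Adds the pseudo-count to every cell and normalizes each column to sum
#' to one.
#'
#' @param table a [count_table()].
#' @param config an [inference_config()].
#' @return Matrix of fractions, same shape as the counts.
#' @export
read_fractions <- function(table, config) {
  stopifnot(inherits(table, "count_table"),
            inherits(config, "inference_config"))
  m <- table$counts + config$pseudo_count
  sweep(m, 2, colSums(m), "/")
}

#' Doubling time of one variant from its read-fraction trajectory
#'
#' Read fractions drift between timepoints according to the gap between a
#' variant's division rate and the bulk's: over an interval `delta_t`,
#' \eqn{f_n = f_{n-1} 2^{\delta t (1/\tau - 1/\tau_{av})}}. Each adjacent
#' pair therefore yields \eqn{1/\tau = \log_2(f_n/f_{n-1})/\delta t +
#' 1/\tau_{av}}; the reported doubling time is the inverse of the mean of
#' the per-pair rates. Pairs with a fraction at or below
#' `config$fraction_floor` are excluded and reported.
#'
#' @param fractions numeric vector of sampled-timepoint fractions for one
#'   variant (ligation excluded), length >= 2.
#' @param config an [inference_config()].
#' @return A list with `tau` (minutes; `NA` if every pair was excluded),
#'   `per_pair` (per-pair division rates, doublings/min) and `n_excluded`.
#' @export
infer_doubling_time <- function(fractions, config) {
  stopifnot(length(fractions) >= 2)
  k <- length(fractions)
  rb <- bulk_rates(config, k)
  lead <- fractions[-1]; lag <- fractions[-k]
  rates <- log2(lead / lag) / config$delta_t + rb[-1]
  ok <- is.finite(rates) & lead > config$fraction_floor &
    lag > config$fraction_floor
  if (!any(ok))
    return(list(tau = NA_real_, per_pair = rates, n_excluded = sum(!ok)))
  list(tau = 1 / mean(rates[ok]), per_pair = rates,
       n_excluded = sum(!ok))
}

#' Relative copy number of one variant
#'
#' Plasmid preps are sequenced, so a variant's read share is its cell share
#' weighted by its copy number; the ligation library has no such weighting.
#' Comparing the sampled fraction with the ligation fraction, after backing
#' out the growth-competition drift accumulated since transformation, leaves
#' the relative copy number:
#' \deqn{C = \frac{f_f}{f_i}\, 2^{-t\,(1/\tau - 1/\tau_{av})}}
#' evaluated at the first sampled timepoint (`t = t_first`), the form
#' obtained by substituting the growth-rate relation into the read-share
#' model. A value is computed at every later timepoint as well; their spread
#' feeds the uncertainty estimate.
#'
#' @param f_i ligation (initial-library) fraction.
#' @param fractions sampled-timepoint fractions, length >= 1.
#' @param tau the variant's doubling time from [infer_doubling_time()].
#' @param config an [inference_config()].
#' @return A list with `c_relative` (the first-timepoint estimate) and
#'   `per_timepoint` (one estimate per sampled timepoint).
#' @export
infer_relative_copy_number <- function(f_i, fractions, tau, config) {
  if (!is.finite(f_i) || f_i <= 0 || !is.finite(tau))
    return(list(c_relative = NA_real_, per_timepoint = rep(NA_real_,
                                                           length(fractions))))
  k <- length(fractions)
  rb <- bulk_rates(config, k)
  lens <- c(config$t_first, rep(config$delta_t, k - 1))[seq_len(k)]
  t_n <- cumsum(lens)
  bulk_doublings <- cumsum(lens * rb)
  cs <- (fractions / f_i) * 2^(-(t_n / tau) + bulk_doublings)
  list(c_relative = cs[1], per_timepoint = cs)
}

#' Counting-noise and consistency error for one variant's estimates
#'
#' First-order (delta-method) propagation of the multinomial counting error
#' on the read fractions through the copy-number expression — which, after
#' the per-pair rates are averaged, depends on the first and last sampled
#' counts and the ligation count — combined with the across-timepoint
#' spread of the copy-number estimates. The combined relative standard
#' error is binned into the three reporting classes at 5% and 25%
#' (boundaries closed on the middle class).
#'
#' @param counts_row the variant's raw counts (ligation first), pseudo-count
#'   not yet added.
#' @param c_per_timepoint per-timepoint copy-number estimates from
#'   [infer_relative_copy_number()].
#' @param config an [inference_config()].
#' @return A list with `se_fraction` (relative SE), `se_counting`,
#'   `se_spread` and `error_class` (one of `"<5%"`, `"5-25%"`, `">25%"`).
#' @export
estimate_errors <- function(counts_row, c_per_timepoint, config) {
  n <- counts_row + config$pseudo_count
  k <- length(n) - 1L
  u <- if (k > 1) config$t_first / ((k - 1) * config$delta_t) else 0
  # ln C = (1+u) ln f1 - u ln fk - ln f_i + const
  var_ln <- (1 + u)^2 / n[2] + u^2 / n[k + 1] + 1 / n[1]
  se_count <- sqrt(var_ln)
  cs <- c_per_timepoint[is.finite(c_per_timepoint)]
  se_spread <- if (length(cs) >= 2)
    stats::sd(cs) / mean(cs) / sqrt(length(cs)) else 0
  se <- sqrt(se_count^2 + se_spread^2)
  cls <- if (!is.finite(se)) ">25%"
         else if (se < 0.05) "<5%"
         else if (se <= 0.25) "5-25%"
         else ">25%"
  list(se_fraction = unname(se), se_counting = unname(se_count),
       se_spread = se_spread, error_class = cls)
}

#' Per-construct estimates from a pooled count table
#'
#' Runs the full inference over every variant of a [count_table()]:
#' pseudo-counted fractions, per-variant doubling time, relative copy
#' number, and error class. Variants whose summed sampled counts fall below
#' `config$min_reads` are reported with `NA` estimates.
#'
#' @param table a [count_table()].
#' @param config an [inference_config()].
#' @return A data.frame of class `construct_estimates`: `variant_id`,
#'   `tau_min`, `c_relative`, `pcn_absolute` (`NA` until
#'   [calibrate_absolute()]), `se_fraction`, `error_class`, `n_reads`.
#' @export
infer_constructs <- function(table, config) {
  stopifnot(inherits(table, "count_table"),
            inherits(config, "inference_config"))
  fr <- read_fractions(table, config)
  k <- length(table$times)
  out <- data.frame(variant_id = table$ids,
                    tau_min = NA_real_, c_relative = NA_real_,
                    pcn_absolute = NA_real_, se_fraction = NA_real_,
                    error_class = NA_character_,
                    n_reads = rowSums(table$counts[, -1, drop = FALSE]),
                    stringsAsFactors = FALSE)
  for (v in seq_len(nrow(fr))) {
    if (out$n_reads[v] < config$min_reads) next
    dt <- infer_doubling_time(fr[v, -1], config)
    cc <- infer_relative_copy_number(fr[v, 1], fr[v, -1], dt$tau, config)
    er <- estimate_errors(table$counts[v, ], cc$per_timepoint, config)
    out$tau_min[v] <- dt$tau
    out$c_relative[v] <- cc$c_relative
    out$se_fraction[v] <- er$se_fraction
    out$error_class[v] <- er$error_class
  }
  class(out) <- c("construct_estimates", "data.frame")
  out
}

#' Calibrate relative copy numbers to plasmids per genome
#'
#' Sequencing gives copy number only up to a common scale; droplet-PCR
#' measurements of a few anchor constructs pin it down. A single
#' multiplicative factor is fit in log space (slope fixed to 1):
#' `scale = exp(mean(log(anchor PCN) - log(anchor C)))`, with the RMS
#' residual in log10 reported as a fit diagnostic.
#'
#' @param estimates a [infer_constructs()] data.frame, or a numeric vector
#'   of relative copy numbers.
#' @param anchors data.frame with columns `c_relative` and `pcn_ddpcr`
#'   (plasmids per genome), >= 1 row with positive values.
#' @return A list with `scale`, `log10_rms`, `narrow_range` (`TRUE` when
#'   the anchors span less than 2-fold, flagging extrapolation risk) and
#'   `pcn_absolute` (the calibrated values; if `estimates` was a
#'   `construct_estimates` data.frame it is returned in `estimates` with
#'   `pcn_absolute` filled in).
#' @export
calibrate_absolute <- function(estimates, anchors) {
  stopifnot(is.data.frame(anchors),
            all(c("c_relative", "pcn_ddpcr") %in% names(anchors)))
  a <- anchors[is.finite(anchors$c_relative) & anchors$c_relative > 0 &
               is.finite(anchors$pcn_ddpcr) & anchors$pcn_ddpcr > 0, ]
  if (nrow(a) < 1) stop("no usable anchors")
  lr <- log(a$pcn_ddpcr) - log(a$c_relative)
  scale <- exp(mean(lr))
  log10_rms <- sqrt(mean((lr - mean(lr))^2)) / log(10)
  narrow <- nrow(a) >= 2 &&
    max(a$pcn_ddpcr) / min(a$pcn_ddpcr) < 2
  if (narrow) warning("anchors span less than 2-fold; calibration may ",
                      "extrapolate poorly")
  cvals <- if (is.data.frame(estimates)) estimates$c_relative else estimates
  pcn <- scale * cvals
  res <- list(scale = scale, log10_rms = log10_rms, narrow_range = narrow,
              pcn_absolute = pcn)
  if (is.data.frame(estimates)) {
    estimates$pcn_absolute <- pcn
    res$estimates <- estimates
  }
  res
}

#' Count reads matching library variants exactly
#'
#' Assigns each read to a variant by exact substring match of the variant's
#' ori-region sequence; reads with any mismatch in the ori region (no exact
#' occurrence of any variant sequence) are discarded and counted. Reads
#' matching more than one variant (impossible when ori regions are unique
#' and equal-length) are discarded as ambiguous.
#'
#' @param fastq_path path to a FASTQ file (qualities ignored).
#' @param library a [generate_library()] result, or any data.frame with
#'   `id` and `ori_seq` columns (sequences must be unique and equal length).
#' @return A list with `counts` (named integer vector per variant),
#'   `n_discarded` and `n_ambiguous`.
#' @export
count_exact_variants <- function(fastq_path, library) {
  stopifnot(all(c("id", "ori_seq") %in% names(library)))
  if (anyDuplicated(library$ori_seq))
    stop("variant ori-region sequences must be unique")
  if (length(unique(nchar(library$ori_seq))) != 1L)
    stop("variant ori-region sequences must have equal length")
  reads <- Biostrings::readDNAStringSet(fastq_path, format = "fastq")
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(library$ori_seq))
  hits <- Biostrings::vcountPDict(pd, reads)  # variants x reads
  nmatch <- colSums(hits > 0)
  counts <- as.integer(rowSums(hits[, nmatch == 1L, drop = FALSE] > 0))
  names(counts) <- library$id
  list(counts = counts,
       n_discarded = sum(nmatch == 0L),
       n_ambiguous = sum(nmatch > 1L))
}

#' Write per-construct estimates with a run log
#'
#' @param estimates an [infer_constructs()] data.frame.
#' @param path output TSV path.
#' @param config the [inference_config()] used; when given, a `<path>.log`
#'   key-value file records every configuration value.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path, config = NULL) {
  utils::write.table(estimates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(config)) {
    kv <- c(tau_av = paste(format(config$tau_av, digits = 17),
                           collapse = ","),
            delta_t = format(config$delta_t, digits = 17),
            t_first = format(config$t_first, digits = 17),
            pseudo_count = format(config$pseudo_count),
            min_reads = format(config$min_reads),
            fraction_floor = format(config$fraction_floor))
    writeLines(sprintf("%s = %s", names(kv), kv), paste0(path, ".log"))
  }
  invisible(path)
}
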