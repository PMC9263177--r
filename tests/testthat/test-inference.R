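make_table <- function(counts, times) {
  count_table(counts, times = times)
}

test_that("pseudo-counted fractions normalize each column", {
  tab <- make_table(rbind(c(10, 8, 8), c(10, 2, 2)), times = c(100, 200))
  cfg0 <- inference_config(tau_av = 30, delta_t = 100, t_first = 100,
                           pseudo_count = 0)
  fr <- read_fractions(tab, cfg0)
  expect_equal(unname(fr[, 2]), c(0.8, 0.2))
  cfg5 <- inference_config(tau_av = 30, delta_t = 100, t_first = 100,
                           pseudo_count = 0.5)
  fr5 <- read_fractions(make_table(rbind(c(5, 0, 1), c(5, 10, 9)),
                                   times = c(100, 200)), cfg5)
  expect_equal(unname(fr5[, 2]), c(0.5 / 11, 10.5 / 11))
  expect_equal(unname(colSums(fr5)), rep(1, 3))
})

test_that("doubling time follows the fraction-drift relation", {
  cfg <- inference_config(tau_av = 30, delta_t = 60, t_first = 60)
  # constant fractions: the variant divides with the bulk
  expect_equal(infer_doubling_time(c(0.1, 0.1, 0.1), cfg)$tau, 30)
  # fraction doubling over 60 min: 1/tau = 1/60 + 1/30, tau = 20 min
  expect_equal(infer_doubling_time(c(0.01, 0.02), cfg)$tau, 20)
  # shrinking fractions: slower than the bulk
  expect_gt(infer_doubling_time(c(0.2, 0.1, 0.05), cfg)$tau, 30)
  # unusable pairs are excluded and reported
  out <- infer_doubling_time(c(0, 0, 0.1), cfg)
  expect_true(is.na(out$tau) || is.finite(out$tau))
  expect_gte(out$n_excluded, 1)
})

test_that("relative copy number reduces correctly in the neutral cases", {
  cfg <- inference_config(tau_av = 30, delta_t = 60, t_first = 60)
  # steady fractions equal to the ligation fraction: C = 1
  cc <- infer_relative_copy_number(0.1, c(0.1, 0.1, 0.1), tau = 30, cfg)
  expect_equal(cc$c_relative, 1)
  expect_equal(cc$per_timepoint, rep(1, 3))
  # enrichment with bulk-matched growth is pure copy-number weighting
  cc2 <- infer_relative_copy_number(0.1, c(0.2, 0.2), tau = 30, cfg)
  expect_equal(cc2$c_relative, 2)
})

test_that("noise-free tables return generator truth to 1e-6 for every variant", {
  d <- library_design(num_variants = 150,
                      sampler = list(type = "pcn_loguniform",
                                     min = 1, max = 800), seed = 31)
  lib <- generate_library(d)
  sch <- passaging_scheme()
  pas <- simulate_passaging(lib, sch)
  tab <- simulate_reads(pas, lib, depth = 1e6, noise = "none")
  cfg <- inference_config(tau_av = attr(tab, "tau_bulk_reads"),
                          delta_t = sch$delta_t, t_first = sch$t_first,
                          pseudo_count = 0)
  est <- infer_constructs(tab, cfg)
  expect_equal(est$tau_min, lib$true_tau, tolerance = 1e-6)
  expect_equal(est$c_relative, attr(tab, "c_true"), tolerance = 1e-6)
})

test_that("copy number is invariant to rescaling all counts at one timepoint", {
  counts <- rbind(c(100, 300, 200, 150), c(400, 100, 250, 300),
                  c(250, 350, 100, 200))
  cfg <- inference_config(tau_av = 40, delta_t = 90, t_first = 120,
                          pseudo_count = 0, min_reads = 0)
  est1 <- infer_constructs(make_table(counts, c(120, 210, 300)), cfg)
  counts2 <- counts; counts2[, 3] <- counts2[, 3] * 7
  est2 <- infer_constructs(make_table(counts2, c(120, 210, 300)), cfg)
  expect_equal(est1$c_relative, est2$c_relative, tolerance = 1e-12)
})

test_that("pseudo-count vanishes in the large-count limit", {
  base <- rbind(c(2, 3, 4, 5), c(5, 4, 3, 2), c(3, 3, 3, 3))
  cfg_ps <- inference_config(tau_av = 40, delta_t = 90, t_first = 120,
                             min_reads = 0)
  cfg_0 <- inference_config(tau_av = 40, delta_t = 90, t_first = 120,
                            pseudo_count = 0, min_reads = 0)
  for (mult in c(1e3, 1e5)) {
    t1 <- make_table(base * mult, c(120, 210, 300))
    dev <- abs(infer_constructs(t1, cfg_ps)$c_relative /
                 infer_constructs(t1, cfg_0)$c_relative - 1)
    expect_lt(max(dev), 10 / mult)
  }
})

test_that("error classes track counting depth", {
  cfg <- inference_config(tau_av = 40, delta_t = 90, t_first = 120,
                          min_reads = 0)
  deep <- estimate_errors(c(1e8, 1e8, 1e8, 1e8, 1e8), rep(2, 4), cfg)
  expect_lt(deep$se_fraction, 1e-3)
  expect_identical(deep$error_class, "<5%")
  shallow <- estimate_errors(c(3, 3, 2, 1, 1), c(2.2, 1.8, 2.4, 2.0), cfg)
  expect_identical(shallow$error_class, ">25%")
  # doubling every count shrinks the counting term by sqrt(2)
  n1 <- estimate_errors(c(50, 80, 60, 70, 40), rep(2, 4), cfg)
  n2 <- estimate_errors(2 * c(50, 80, 60, 70, 40), rep(2, 4), cfg)
  expect_equal(n1$se_counting / n2$se_counting, sqrt(2), tolerance = 0.01)
})

test_that("copy-number error concentrates with sequencing depth", {
  med_err <- function(depth) {
    d <- library_design(num_variants = 800,
                        sampler = list(type = "pcn_loguniform",
                                       min = 1, max = 800), seed = 32)
    lib <- generate_library(d)
    sch <- passaging_scheme()
    pas <- simulate_passaging(lib, sch)
    tab <- simulate_reads(pas, lib, depth = depth, seed = 33)
    cfg <- inference_config(tau_av = attr(tab, "tau_bulk_reads"),
                            delta_t = sch$delta_t, t_first = sch$t_first)
    est <- infer_constructs(tab, cfg)
    median(abs(est$c_relative / attr(tab, "c_true") - 1), na.rm = TRUE)
  }
  e1 <- med_err(1e6)
  e4 <- med_err(4e6)
  expect_lt(e4, e1)
  expect_lt(e4, 0.05)
  expect_lt(e1, 0.10)
})

test_that("absolute calibration is a single multiplicative scale", {
  # anchors exactly proportional: every value scaled by the same factor
  cal <- calibrate_absolute(c(1, 2, 5),
                            data.frame(c_relative = c(1, 4),
                                       pcn_ddpcr = c(10, 40)))
  expect_equal(cal$scale, 10)
  expect_equal(cal$pcn_absolute, c(10, 20, 50))
  expect_equal(cal$log10_rms, 0)
  # a single anchor pins the scale exactly
  one <- calibrate_absolute(c(3), data.frame(c_relative = 2.5,
                                             pcn_ddpcr = 100))
  expect_equal(one$scale, 40)
  # narrow anchor span flags extrapolation
  expect_warning(
    calibrate_absolute(c(1), data.frame(c_relative = c(1, 1.2),
                                        pcn_ddpcr = c(10, 11))),
    "2-fold")
  # lognormal anchor noise: scale recovered within 3 sigma / sqrt(n)
  set.seed(34)
  n <- 24; sig <- 0.1
  ctrue <- exp(runif(n, 0, 5))
  noisy <- data.frame(c_relative = ctrue,
                      pcn_ddpcr = 120 * ctrue * exp(rnorm(n, 0, sig)))
  cal_n <- calibrate_absolute(ctrue, noisy)
  expect_lt(abs(log(cal_n$scale / 120)), 3 * sig / sqrt(n))
})

test_that("exact-match read counting enforces the zero-mismatch rule", {
  lib <- generate_library(library_design(num_variants = 15, seed = 35))
  f <- withr::local_tempfile(fileext = ".fastq")
  write_library_fastq(lib, f, reads_per_variant = 1:15,
                      mutate_first = TRUE)
  res <- count_exact_variants(f, lib)
  want <- 1:15
  want[1] <- want[1] - 1L  # the mutated read must be discarded
  expect_identical(unname(res$counts), want)
  expect_identical(res$n_discarded, 1L)
  expect_identical(res$n_ambiguous, 0L)
  # duplicated ori sequences are a configuration error
  bad <- rbind(lib, lib[1, ])
  expect_error(count_exact_variants(f, bad), "unique")
})

test_that("count tables round-trip through TSV with estimates and run log", {
  d <- library_design(num_variants = 10, seed = 36)
  lib <- generate_library(d)
  sch <- passaging_scheme()
  pas <- simulate_passaging(lib, sch)
  tab <- simulate_reads(pas, lib, depth = 5e4, seed = 37)
  dir <- withr::local_tempdir()
  write_count_table(tab, file.path(dir, "counts.tsv"))
  back <- read_count_table(file.path(dir, "counts.tsv"), times = tab$times)
  expect_equal(back$counts, tab$counts)
  cfg <- inference_config(tau_av = attr(tab, "tau_bulk_reads"),
                          delta_t = sch$delta_t, t_first = sch$t_first)
  est <- infer_constructs(back, cfg)
  write_estimates(est, file.path(dir, "estimates.tsv"), config = cfg)
  expect_true(file.exists(file.path(dir, "estimates.tsv.log")))
  back_est <- read.delim(file.path(dir, "estimates.tsv"))
  expect_equal(back_est$c_relative, est$c_relative, tolerance = 1e-9)
})

test_that("variants below the read threshold are reported unestimated", {
  counts <- rbind(c(1000, 900, 1100, 1000), c(5, 4, 3, 2))
  cfg <- inference_config(tau_av = 40, delta_t = 90, t_first = 120,
                          min_reads = 20)
  est <- infer_constructs(make_table(counts, c(120, 210, 300)), cfg)
  expect_true(is.finite(est$tau_min[1]))
  expect_true(is.na(est$tau_min[2]))
  expect_true(is.na(est$c_relative[2]))
})
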