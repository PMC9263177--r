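test_that("degenerate samplers give degenerate libraries", {
  d <- library_design(num_variants = 10,
                      sampler = list(type = "pcn_fixed", value = 50),
                      seed = 5)
  lib <- generate_library(d)
  expect_true(all(lib$true_pcn == 50))
  expect_equal(length(unique(lib$true_tau)), 1L)
  # zero burden slope: every variant doubles at the plasmid-free rate
  d0 <- library_design(num_variants = 10,
                       sampler = list(type = "pcn_loguniform",
                                      min = 1, max = 800),
                       burden = burden_model(a = 0, b = 0.019), seed = 5)
  lib0 <- generate_library(d0)
  expect_equal(lib0$true_tau, rep(log(2) / 0.019, nrow(lib0)))
  expect_equal(sum(lib0$init_fraction), 1)
})

test_that("mechanistic sampling matches per-variant fixed-point evaluation", {
  d <- library_design(num_variants = 40,
                      sampler = list(type = "kp_loguniform",
                                     min = 0.05, max = 0.9),
                      burden = burden_model(a = 2e-4, b = 0.01), seed = 6)
  lib <- generate_library(d)
  expect_gt(nrow(lib), 0)
  for (v in seq_len(nrow(lib))) {
    p <- d$base_params; p$k_p <- lib$k_p[v]
    sol <- solve_self_consistent(p, d$burden)
    expect_equal(lib$true_pcn[v], sol$copy_number, tolerance = 1e-9)
    expect_equal(lib$true_tau[v], log(2) / sol$growth_rate,
                 tolerance = 1e-9)
    # emitted variants are neither runaway nor loss-prone
    expect_gt(lib$true_pcn[v], 1)
  }
  expect_identical(nrow(lib) + attr(lib, "n_excluded"), 40L)
})

test_that("ori-region sequences are unique realizations of the degenerate set", {
  lib <- generate_library(library_design(num_variants = 100, seed = 7))
  expect_false(anyDuplicated(lib$ori_seq) > 0)
  expect_equal(unique(nchar(lib$ori_seq)), nchar(pcnassay:::ORI_TEMPLATE))
  pool <- pcnassay:::enumerate_ori_variants()
  expect_length(pool, 1024L)
  expect_false(anyDuplicated(pool) > 0)
  expect_true(all(lib$ori_seq %in% pool))
})

test_that("passaging is neutral for equal fitness and selective otherwise", {
  d <- library_design(num_variants = 8,
                      sampler = list(type = "pcn_loguniform",
                                     min = 1, max = 800),
                      burden = burden_model(a = 0, b = 0.019), seed = 8)
  lib <- generate_library(d)
  pas <- simulate_passaging(lib, passaging_scheme())
  expect_equal(unname(colSums(pas$fractions)), rep(1, 4))
  for (j in 1:4) expect_equal(unname(pas$fractions[, j]),
                              lib$init_fraction)
  # two variants, doubling times 20 and 40 min, sampled at t = 40:
  # the faster strain's odds double relative to its initial odds
  lib2 <- lib[1:2, ]
  lib2$true_tau <- c(20, 40)
  lib2$init_fraction <- c(0.5, 0.5)
  class(lib2) <- class(lib)
  pas2 <- simulate_passaging(lib2, passaging_scheme(t_first = 40,
                                                    num_passages = 1))
  odds <- pas2$fractions[1, 1] / pas2$fractions[2, 1]
  expect_equal(odds, 2 * (0.5 / 0.5))
  # bulk doubling time sits between the two strains' doubling times
  expect_gt(pas2$tau_bulk[1], 20)
  expect_lt(pas2$tau_bulk[1], 40)
})

test_that("read shares are cell shares weighted by copy number", {
  d <- library_design(num_variants = 6,
                      sampler = list(type = "pcn_fixed", value = 30),
                      seed = 9)
  lib <- generate_library(d)
  pas <- simulate_passaging(lib, passaging_scheme())
  tab <- simulate_reads(pas, lib, depth = 1e6, noise = "none")
  # equal copy number: expected read fractions equal cell fractions
  expect_equal(tab$counts[, -1] / 1e6, pas$fractions, tolerance = 1e-12)
  expect_equal(unname(tab$counts[, 1]) / 1e6, lib$init_fraction)
})

test_that("multinomial counts sum to depth and converge to expectations", {
  d <- library_design(num_variants = 3,
                      sampler = list(type = "pcn_loguniform",
                                     min = 5, max = 100),
                      seed = 10)
  lib <- generate_library(d)
  pas <- simulate_passaging(lib, passaging_scheme())
  depth <- 4e5
  tab <- simulate_reads(pas, lib, depth = depth, seed = 2)
  expect_true(all(colSums(tab$counts) == depth))
  exp_tab <- simulate_reads(pas, lib, depth = depth, noise = "none")
  p <- exp_tab$counts / depth
  sigma <- sqrt(p * (1 - p) * depth)
  expect_true(all(abs(tab$counts - depth * p) <= 3 * sigma + 1e-9))
})

test_that("fixing the seed fixes every emitted byte", {
  gen <- function() {
    d <- library_design(num_variants = 12, seed = 11)
    lib <- generate_library(d)
    pas <- simulate_passaging(lib, passaging_scheme())
    tab <- simulate_reads(pas, lib, depth = 1e4, seed = 12)
    dir <- withr::local_tempdir()
    write_variant_table(lib, file.path(dir, "lib.tsv"))
    write_count_table(tab, file.path(dir, "counts.tsv"))
    write_manifest(file.path(dir, "manifest.cfg"), d, passaging_scheme(),
                   passaging = pas, table = tab, depth = 1e4)
    write_library_fastq(lib, file.path(dir, "reads.fastq"),
                        reads_per_variant = 2)
    lapply(list.files(dir, full.names = TRUE), readLines)
  }
  expect_identical(gen(), gen())
})

test_that("plate-reader curves invert to the generating growth rate and PCN", {
  g <- simulate_plate_reader(tau = 35, pcn = 40, k_expr = 3, noise_sd = 0)
  mg <- max_growth_rate(g)
  expect_equal(mg$mu_max, log(2) / 35, tolerance = 0.01)
  G <- expression_level(g)
  expect_equal(pcn_from_fluorescence(G, mg$mu_max, 3), 40, tolerance = 0.05)
  # doubling the copy number doubles the expression signal
  g2 <- simulate_plate_reader(tau = 35, pcn = 80, k_expr = 3, noise_sd = 0)
  expect_equal(expression_level(g2) / G, 2, tolerance = 0.02)
})

test_that("droplet simulation follows Poisson partitioning", {
  # lambda = ln 2 makes half the droplets positive in expectation
  n <- 200000
  run <- simulate_ddpcr(true_ratio = 1, lambda_ref = log(2),
                        n_droplets = n, seed = 3)
  expect_equal(run$positives_ref / n, 0.5, tolerance = 0.01)
  expect_equal(run$positives_target / n, 0.5, tolerance = 0.01)
  est <- ddpcr_concentration(run)
  expect_equal(est$ratio, 1, tolerance = 0.02)
})
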